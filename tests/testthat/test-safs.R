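test_that("sagittal slice selection follows the 40%/60% rule", {
  mk <- function(x0, x1) {
    m <- array(FALSE, c(120, 8, 8)); m[x0:x1, 3:6, 3:6] <- TRUE
    LungMask(m, side = "left")
  }
  expect_equal(selectSagittalSlices(mk(1, 101)), c(41, 61))
  # round half away from zero on a 5-voxel extent
  expect_equal(selectSagittalSlices(mk(11, 16)), c(13, 14))
  x <- selectSagittalSlices(mk(7, 93))
  expect_equal(x, c(round(7 + 0.4 * 86), round(7 + 0.6 * 86)))
  m <- array(FALSE, c(20, 8, 8)); m[4, 2:7, 2:7] <- TRUE
  expect_error(selectSagittalSlices(LungMask(m, side = "left")),
               "degenerate")
  # on the phantom both slices intersect the truth fissure's x extent
  ph <- default_phantom()
  truth <- ph@truthSurfaces$left_oblique
  lab <- labelArray(ph@truthLobes)
  left <- array(lab %in% c(1L, 2L), dim = dim(lab))
  xs <- selectSagittalSlices(LungMask(left, side = "left"))
  expect_true(all(xs >= min(truth[, 1]) & xs <= max(truth[, 1])))
})

test_that("scan-line R and L follow the run-length definitions", {
  hu <- matrix(-880, 5, 3)
  hu[, 2] <- c(-980, -980, -950, -990, -990)
  mask <- matrix(FALSE, 5, 3); mask[, 2] <- TRUE
  p <- safsParams("horizontal", r = 2, k = 0.1, air_cut = -970,
                  angles = 0)
  lines <- traceScanLines(hu, mask, 0, p)
  l2 <- Filter(function(l) l$offset == 2, lines)[[1]]
  expect_equal(l2$R, 5)
  expect_equal(l2$L, 2)
  expect_true(l2$accepted)      # R = 5 > 2 and 2/5 > 0.1
  # too short a lung intersection fails R > r
  p10 <- safsParams("horizontal", r = 10, k = 0.1, air_cut = -970,
                    angles = 0)
  expect_false(any(vapply(traceScanLines(hu, mask, 0, p10), `[[`,
                          logical(1), "accepted")))
  # empty mask gives no lines
  expect_length(traceScanLines(hu, matrix(FALSE, 5, 3), 0, p), 0)
})

test_that("acceptance is monotone in k and matches brute-force evaluation", {
  sl <- band_slice(45)
  for (k in c(0.4, 0.6, 0.8)) {
    p <- safsParams("oblique", k = k)
    lines <- traceScanLines(sl$hu, sl$mask, 45, p)
    for (l in lines) {
      # independent evaluation of the rule from the raw pixel values
      inm <- sl$mask[l$pixels]
      below <- inm & sl$hu[l$pixels] < p$air_cut
      R <- sum(inm)
      L <- 0L; run <- 0L
      for (b in below) { run <- if (b) run + 1L else 0L; L <- max(L, run) }
      expect_identical(l$accepted, R > p$r && L / max(R, 1) > p$k)
    }
  }
  acc <- function(k) {
    p <- safsParams("oblique", k = k)
    sum(vapply(traceScanLines(sl$hu, sl$mask, 45, p), `[[`, logical(1),
               "accepted"))
  }
  expect_gte(acc(0.4), acc(0.6))
  expect_gte(acc(0.6), acc(0.8))
})

test_that("largest connected region and deterministic tie-breaking", {
  fake_line <- function(px) list(pixels = px, run_pixels = px,
                                 R = nrow(px), L = nrow(px),
                                 accepted = TRUE, offset = 0)
  big <- cbind(10, 1:30); small <- cbind(20, 1:12)
  rg <- largestConnectedRegion(list(fake_line(big), fake_line(small)),
                               45, c(40, 40))
  expect_equal(nrow(rg@pixels), 30)
  expect_true(all(rg@pixels[, 1] == 10))
  expect_null(largestConnectedRegion(list(), 45, c(40, 40)))
  # equal-size tie: the component with the smallest (row, col) pixel wins,
  # whatever the input line order
  a <- cbind(5, 11:20); b <- cbind(25, 1:10)
  for (ord in list(list(a, b), list(b, a))) {
    rg <- largestConnectedRegion(lapply(ord, fake_line), 45, c(40, 40))
    expect_true(all(rg@pixels[, 1] == 5))
  }
})

test_that("region scoring favours many, long, uniform lines", {
  mkreg <- function(N, sdR, meanR)
    new("FissureRegion", theta = 45, pixels = cbind(1:3, 1:3),
        nLines = as.integer(N), sdR = sdR, meanR = meanR,
        score = NA_real_)
  p <- safsParams("oblique")
  # identical except sdR: the tighter region scores higher
  rs <- scoreRegions(list(mkreg(10, 2, 50), mkreg(10, 8, 50)), p)
  expect_gt(rs[[1]]@score, rs[[2]]@score)
  # raw-weight mode reproduces the plain weighted sum
  praw <- safsParams("oblique", standardize = FALSE)
  rs <- scoreRegions(list(mkreg(10, 2, 5)), praw)
  expect_equal(rs[[1]]@score, 1 * 10 - 1 * 2 + 1 * 5)
  # argmax under standardized scoring equals exhaustive comparison
  set.seed(3)
  cands <- lapply(1:5, function(i)
    mkreg(sample(3:30, 1), runif(1, 0, 8), runif(1, 30, 90)))
  rs <- scoreRegions(cands, p)
  feats <- t(vapply(cands, function(r) c(r@nLines, r@sdR, r@meanR),
                    numeric(3)))
  z <- scale(feats); z[is.nan(z)] <- 0
  expect_equal(which.max(vapply(rs, function(r) r@score, numeric(1))),
               which.max(z %*% c(1, -1, 1)))
  # score argmax is invariant under a joint increasing affine transform
  # of the standardized features (weights fixed)
  z2 <- 3 * z + 7
  expect_equal(which.max(z2 %*% c(1, -1, 1)),
               which.max(z %*% c(1, -1, 1)))
})

test_that("SAFS recovers the band angle on synthetic slices", {
  for (theta_star in c(35, 45, 55)) {
    sl <- band_slice(theta_star)
    fr <- suppressWarnings(runSAFS(sl$hu, sl$mask, safsParams("oblique")))
    expect_lte(abs(fr@theta - theta_star), 2)
    # the selected band contains no vessel pixel
    expect_true(all(sl$hu[fr@pixels] < -300))
    expect_true(all(sl$mask[fr@pixels]))
  }
  # determinism
  sl <- band_slice(45)
  fr1 <- suppressWarnings(runSAFS(sl$hu, sl$mask, safsParams("oblique")))
  fr2 <- suppressWarnings(runSAFS(sl$hu, sl$mask, safsParams("oblique")))
  expect_identical(fr1@pixels, fr2@pixels)
  expect_identical(fr1@theta, fr2@theta)
})

test_that("SAFS fails cleanly when no vessel-free band exists", {
  set.seed(5)
  n <- 120
  hu <- matrix(-980, n, n)
  # vessels everywhere on a tight grid: no direction has a clear run
  for (r in seq(4, n - 4, by = 5)) for (cc in seq(4, n - 4, by = 5))
    hu[r + (-1:1), cc + (-1:1)] <- -200
  ctr <- (n + 1) / 2
  mask <- (row(hu) - ctr)^2 + (col(hu) - ctr)^2 <= 55^2
  expect_error(suppressWarnings(runSAFS(hu, mask, safsParams("oblique"))),
               "SAFS failure")
})
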