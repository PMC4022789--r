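# A dense planar PFP cloud in index units, one point per (x, y) column.
planar_pfp <- function(nx = 90, ny = 90, a = 0.8, b = 10) {
  g <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  cbind(g$x, g$y, a * g$y + b)
}

test_that("PFP subsampling applies the grid and cube-count rules", {
  pfp <- planar_pfp()
  sub <- subsamplePFP(pfp)
  expect_gt(nrow(sub), 3)
  # kept points are pairwise separated by >= 30 px in x or y
  if (nrow(sub) > 1) {
    dx <- abs(outer(sub[, 1], sub[, 1], "-"))
    dy <- abs(outer(sub[, 2], sub[, 2], "-"))
    off <- upper.tri(dx)
    expect_true(all(dx[off] >= 30 | dy[off] >= 30))
  }
  # every kept point passes the 11^3 cube count (> 80); a plane through
  # the cube contributes at most 11 x 11 = 121 points
  for (i in seq_len(nrow(sub))) {
    cnt <- sum(abs(pfp[, 1] - sub[i, 1]) <= 5 &
               abs(pfp[, 2] - sub[i, 2]) <= 5 &
               abs(pfp[, 3] - sub[i, 3]) <= 5)
    expect_gt(cnt, 80)
    expect_lte(cnt, 121)
  }
  # an isolated point with a handful of neighbours is rejected
  iso <- rbind(c(200, 200, 50), c(201, 200, 50), c(200, 201, 50),
               c(202, 202, 50), c(199, 199, 50))
  expect_false(any(subsamplePFP(rbind(pfp, iso))[, 1] >= 150))
  # the kept set equals brute-force evaluation of both rules in scan order
  set.seed(4)
  cloud <- cbind(sample(1:80, 4000, TRUE), sample(1:80, 4000, TRUE),
                 sample(1:40, 4000, TRUE))
  sub2 <- subsamplePFP(cloud, grid_spacing = 20, cube = 11, min_count = 10)
  ord <- order(cloud[, 2], cloud[, 1], cloud[, 3])
  kept <- matrix(numeric(0), 0, 3)
  for (i in ord) {
    p <- cloud[i, ]
    if (nrow(kept) &&
        any(abs(kept[, 1] - p[1]) < 20 & abs(kept[, 2] - p[2]) < 20)) next
    cnt <- sum(abs(cloud[, 1] - p[1]) <= 5 & abs(cloud[, 2] - p[2]) <= 5 &
               abs(cloud[, 3] - p[3]) <= 5)
    if (cnt > 10) kept <- rbind(kept, p)
  }
  rownames(kept) <- NULL
  expect_equal(sub2, kept)
  expect_error(subsamplePFP(cbind(1, 1, 1)), "sparse")
})

test_that("average normals recover analytic plane normals", {
  # points on z = 0 with reference +z
  g <- as.matrix(expand.grid(x = -5:5, y = -5:5))
  pts0 <- cbind(g, 0)
  n0 <- averageNormal(c(0, 0, 0), pts0, c(0, 0, 1))
  expect_equal(n0, c(0, 0, 1), tolerance = 1e-9)
  # plane z = y (45 degrees), reference +z
  pts45 <- cbind(g[, 1], g[, 2], g[, 2])
  n45 <- averageNormal(c(0, 0, 0), pts45, c(0, 0, 1))
  expect_equal(n45, c(0, -sqrt(2) / 2, sqrt(2) / 2), tolerance = 1e-6)
  # least-squares plane fit oracle agrees
  sv <- svd(sweep(pts45, 2, colMeans(pts45)))$v[, 3]
  if (sum(sv * c(0, 0, 1)) < 0) sv <- -sv
  expect_equal(n45, sv, tolerance = 1e-6)
  # collinear points are degenerate
  expect_error(averageNormal(c(0, 0, 0), cbind(1:5, 0, 0), c(0, 0, 1)),
               "degenerate|collinear")
})

test_that("off-surface points sit at distance d on the positive side", {
  pfp <- planar_pfp(a = 0, b = 40)        # plane z = 40
  sub <- subsamplePFP(pfp)
  osp <- makeOffSurface(sub, pfp, d = 10, reference_dir = c(0, 0, 1))
  expect_equal(nrow(osp$off), nrow(osp$on))
  expect_equal(osp$off[, 3], rep(50, nrow(osp$off)), tolerance = 1e-9)
  expect_equal(sqrt(rowSums((osp$off - osp$on)^2)),
               rep(10, nrow(osp$on)), tolerance = 1e-9)
  # curved sheet: off-surface points stay within [0.8 d, 1.2 d] of the
  # analytic quadratic surface z = 40 + 0.02 (y - 45)^2
  g <- expand.grid(x = seq_len(90), y = seq_len(90))
  quad <- cbind(g$x, g$y, 40 + 0.02 * (g$y - 45)^2)
  subq <- subsamplePFP(quad)
  ospq <- makeOffSurface(subq, quad, d = 10, reference_dir = c(0, 0, 1))
  sd_true <- vapply(seq_len(nrow(ospq$off)), function(i) {
    f <- function(y) sqrt((y - ospq$off[i, 2])^2 +
                          (40 + 0.02 * (y - 45)^2 - ospq$off[i, 3])^2)
    stats::optimize(f, c(-50, 150))$objective
  }, numeric(1))
  expect_true(all(sd_true >= 8 & sd_true <= 12))
})

test_that("the tri-harmonic kernel and interpolation conditions are exact", {
  expect_equal(lobeseg:::.phiMatrix(matrix(c(0, 0, 0), 1),
                                    matrix(c(1, 2, 2), 1))[1, 1], 27)
  set.seed(6)
  on <- cbind(runif(20, 0, 60), runif(20, 0, 60), runif(20, 20, 25))
  off <- on + matrix(rep(c(0, 0, 10), each = 20), ncol = 3)
  s <- fitRBF(on, off, d = 10)
  expect_lt(max(abs(evalSurface(s, on))), 1e-6)
  expect_lt(max(abs(evalSurface(s, off) - 10)), 1e-6)
  # side conditions
  expect_lt(abs(sum(s@lambda)), 1e-8)
  expect_lt(max(abs(colSums(s@lambda * s@centers))), 1e-8)
  # gradient at on-surface points heads toward the off-surface side
  eps <- 1e-4
  gz <- (evalSurface(s, on + matrix(rep(c(0, 0, eps), each = 20), ncol = 3)) -
         evalSurface(s, on)) / eps
  expect_true(all(gz > 0))
})

test_that("the production solver matches naive Gaussian elimination", {
  set.seed(8)
  for (m_on in c(8, 13)) {
    on <- cbind(runif(m_on, 0, 40), runif(m_on, 0, 40),
                runif(m_on, 10, 14))
    off <- on + matrix(rep(c(0, 0.5, 9.9), each = m_on), ncol = 3)
    s <- fitRBF(on, off, d = 10)
    centers <- rbind(on, off)
    m <- nrow(centers)
    Phi <- lobeseg:::.phiMatrix(centers, centers)
    P <- cbind(1, centers)
    A <- rbind(cbind(Phi, P), cbind(t(P), matrix(0, 4, 4)))
    v <- c(rep(0, m_on), rep(10, m_on), rep(0, 4))
    sol <- gauss_solve(A, v)
    expect_equal(c(s@lambda, s@poly), sol, tolerance = 1e-8)
  }
})

test_that("a planar point set reproduces its plane as the zero level set", {
  pfp <- planar_pfp(a = 0.8, b = 10)
  sub <- subsamplePFP(pfp)
  osp <- makeOffSurface(sub, pfp, d = 10,
                        reference_dir = c(0, -0.8, 1))
  s <- fitRBF(osp$on, osp$off, d = 10)
  # root-find F along vertical lines over the convex hull of the centers
  xr <- range(osp$on[, 1]); yr <- range(osp$on[, 2])
  for (x in seq(xr[1], xr[2], length.out = 5))
    for (y in seq(yr[1], yr[2], length.out = 5)) {
      z_true <- 0.8 * y + 10
      f <- function(z) evalSurface(s, cbind(x, y, z))
      z0 <- stats::uniroot(f, c(z_true - 5, z_true + 5))$root
      expect_lt(abs(z0 - z_true), 0.5)
    }
  # refitting after removing 10% of centers barely moves the surface
  keep <- seq_len(nrow(osp$on))[-1]
  s2 <- fitRBF(osp$on[keep, ], osp$off[keep, ], d = 10)
  g <- as.matrix(expand.grid(x = seq(xr[1], xr[2], length.out = 8),
                             y = seq(yr[1], yr[2], length.out = 8)))
  z1 <- vapply(seq_len(nrow(g)), function(i)
    stats::uniroot(function(z) evalSurface(s, cbind(g[i, 1], g[i, 2], z)),
                   c(0.8 * g[i, 2] + 5, 0.8 * g[i, 2] + 15))$root,
    numeric(1))
  z2 <- vapply(seq_len(nrow(g)), function(i)
    stats::uniroot(function(z) evalSurface(s2, cbind(g[i, 1], g[i, 2], z)),
                   c(0.8 * g[i, 2] + 5, 0.8 * g[i, 2] + 15))$root,
    numeric(1))
  expect_lt(sqrt(mean((z1 - z2)^2)), 1)
})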