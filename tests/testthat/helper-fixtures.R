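# Shared fixtures, computed once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, expr, envir = .fixture_env)
  get(name, envir = .fixture_env)
}

default_phantom <- function() cached("phantom", generatePhantom(phantomSpec()))

default_pipeline <- function() {
  cached("pipeline", {
    ph <- default_phantom()
    suppressWarnings(runPipeline(ph@volume, phantomConfig(ph@spec)))
  })
}

# A sagittal test slice in the conditions of the clinical method: very low
# parenchymal HU so the default -970 HU vessel-free cut applies, vessel
# dots on a jittered grid everywhere except a clear band of the given
# half-width at angle theta_deg through the disk center.
band_slice <- function(theta_deg, n = 160, radius = 72, half_width = 10,
                       parenchyma = -980, vessel = -200, spacing = 6,
                       seed = 7) {
  set.seed(seed)
  hu <- matrix(parenchyma, n, n)
  ctr <- (n + 1) / 2
  rows <- row(hu) - ctr; cols <- col(hu) - ctr
  mask <- rows^2 + cols^2 <= radius^2
  d <- c(cos(theta_deg * pi / 180), sin(theta_deg * pi / 180))
  band <- abs(rows * d[2] - cols * d[1]) <= half_width
  gs <- seq(-radius, radius, by = spacing)
  ctrs <- expand.grid(r = gs, c = gs)
  ctrs <- ctrs + matrix(stats::runif(2 * nrow(ctrs), -2, 2), ncol = 2)
  for (i in seq_len(nrow(ctrs))) {
    r0 <- round(ctr + ctrs$r[i]); c0 <- round(ctr + ctrs$c[i])
    if (r0 < 2 || r0 > n - 1 || c0 < 2 || c0 > n - 1) next
    if (abs(ctrs$r[i] * d[2] - ctrs$c[i] * d[1]) <= half_width + 2) next
    hu[(r0 - 1):(r0 + 1), (c0 - 1):(c0 + 1)] <- vessel
  }
  hu[!mask] <- 0
  list(hu = hu, mask = mask)
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
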