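# shared fixture builders: everything is generated in code at test time

# centred cubic geometry with n voxels per axis
cube_geom <- function(n, spacing = 4.42) {
  grid_geometry(rep(n, 3), rep(spacing, 3), rep(-(n - 1) / 2 * spacing, 3))
}

# rasterise a centred sphere of the given volume as a binary VOI
sphere_voi <- function(vol_mL, geom, label = "sphere@B_L",
                       center = c(0, 0, 0)) {
  R <- (3 * vol_mL * 1000 / (4 * pi))^(1 / 3)
  co <- lapply(1:3, function(a)
    geom$origin[a] + (seq_len(geom$dim[a]) - 1) * geom$spacing[a] - center[a])
  m <- array(0, geom$dim)
  for (i in seq_len(geom$dim[1])) {
    r2 <- outer(co[[2]]^2, co[[3]]^2, "+") + co[[1]][i]^2
    m[i, , ] <- (r2 <= R^2) * 1
  }
  voi(m, geom, label)
}

# generating-kinetics sampler matching the cohort generator's defaults
sample_truth_params <- function() {
  b <- 0.01 * exp(stats::rnorm(1, 0, 0.15))
  cc <- 0.05 * exp(stats::rnorm(1, 0, 0.15))
  d <- 0.7 * exp(stats::rnorm(1, 0, 0.15))
  A2 <- exp(stats::rnorm(1, 0, 0.3))
  triexp_params(2 * A2, A2, b, cc, d)
}

# random strictly-positive-rate parameter draw for TIAC oracle checks
sample_valid_params <- function() {
  triexp_params(stats::runif(1, 0, 5), stats::runif(1, 0, 5),
                exp(stats::runif(1, log(1e-4), log(0.1))),
                exp(stats::runif(1, log(1e-3), log(1))),
                exp(stats::runif(1, log(0.1), log(10))))
}

# independent brute-force two-sided signed-rank p-value (enumeration over
# sign vectors via expand.grid; zero differences dropped, midranks)
bruteforce_signed_rank_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.vector(signs %*% r)
  p_le <- mean(Ws <= W + 1e-9)
  p_ge <- mean(Ws >= W - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# small fast experiment configuration for pipeline tests
tiny_config <- function(seed = 11, ...) {
  experiment_config(n_subjects = 2L, seed = seed, ...)
}
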