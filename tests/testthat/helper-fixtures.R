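# Shared fixtures, built in code.

straight_centerline <- function(length_cm = 12, n = 121L) {
  build_centerline(cbind(seq(0, length_cm, length.out = n), 0, 0))
}

# Independent cumulative arclength oracle: explicit loop, no vectorization.
arclength_oracle <- function(pts) {
  out <- numeric(nrow(pts))
  for (i in 2:nrow(pts)) {
    d <- 0
    for (j in 1:3) d <- d + (pts[i, j] - pts[i - 1, j])^2
    out[i] <- out[i - 1] + sqrt(d)
  }
  out
}

# One tuned LPN shared across tests (deterministic, so caching only saves
# time, not information).
.cache <- new.env(parent = emptyenv())

tuned_default <- function() {
  if (is.null(.cache$tuned)) .cache$tuned <- lpn_tune(default_clinical_targets())
  .cache$tuned
}

tuned_run <- function() {
  if (is.null(.cache$run)) {
    tg <- default_clinical_targets()
    .cache$run <- lpn_simulate(tuned_default(), tg$heart_rate, tol = 2e-4)
  }
  .cache$run
}

random_spec <- function(base_cl_len = 12) {
  d0 <- runif(1, 2, 5)
  d <- d0 * runif(1, 1.01, 3)
  l <- runif(1, 5, 70)
  s0 <- runif(1, 0.5, base_cl_len - l / 10 - 0.5)
  aneurysm_spec(d, l, s0, d0, "rand")
}
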