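# Shared fixtures, built once per test run.  The default model takes a few
# seconds to assemble (polynomial table fitting); the full in-silico
# experiment a couple of minutes, so both are cached lazily.

.fixture_cache <- new.env(parent = emptyenv())

cached_model <- function() {
  if (is.null(.fixture_cache$model))
    .fixture_cache$model <- lower_limb_model()
  .fixture_cache$model
}

# full default-protocol estimation experiment (sinusoidal hip, block-wise
# activation, default noise), fixed seed
cached_experiment <- function() {
  if (is.null(.fixture_cache$experiment))
    .fixture_cache$experiment <-
      run_estimation_experiment(cached_model(), sim_protocol(), seed = 42)
  .fixture_cache$experiment
}

# a short, cheap record + fit for structural tests
cached_short_fit <- function() {
  if (is.null(.fixture_cache$short_fit)) {
    blocks <- data.frame(muscle = c("SOL", "TA"), level = c(0.15, 0.2),
                         start = c(0, 4), duration = c(2.5, 2.5))
    p <- sim_protocol(duration = 8, blocks = blocks)
    set.seed(7)
    rec <- forward_simulate(cached_model(), p)
    .fixture_cache$short_fit <- ankle_sckf(rec, cached_model())
  }
  .fixture_cache$short_fit
}

# textbook covariance-form Kalman filter, used as the linear-Gaussian oracle
kf_step <- function(xh, P, y, F, H, Q, R) {
  xh <- drop(F %*% xh)
  P <- F %*% P %*% t(F) + Q
  S <- H %*% P %*% t(H) + R
  K <- P %*% t(H) %*% solve(S)
  xh <- xh + drop(K %*% (y - drop(H %*% xh)))
  P <- (diag(length(xh)) - K %*% H) %*% P
  list(x = xh, P = P)
}

rms <- function(e) sqrt(mean(e^2))
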