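# sEMG envelope extraction and band-limited differentiation of hip
# kinematics.  Filtering primitives come from the 'signal' package; this
# module fixes the processing chain and its defaults.

#' Linear-envelope extraction from raw sEMG
#'
#' Standard EMG conditioning chain: band-pass (default 10-500 Hz
#' Butterworth), full-wave rectification, low-pass linear envelope (default
#' 6 Hz), normalisation by the maximum-voluntary-contraction value, clipping
#' to `[0, 1]`, and polyphase resampling to the estimator rate.
#'
#' Causal filtering is the default (the estimator is a real-time method);
#' `zero_phase = TRUE` switches to forward-backward filtering for offline
#' analyses.
#'
#' @param raw Numeric vector of raw sEMG samples.
#' @param fs Sampling rate of `raw` (Hz), default 1500.
#' @param mvc Maximum-voluntary-contraction amplitude used for
#'   normalisation (> 0), in the units of `raw`.
#' @param out_rate Output (estimator) sampling rate (Hz), default 100.
#' @param band Band-pass corner frequencies (Hz).
#' @param envelope_cutoff Linear-envelope low-pass corner (Hz).
#' @param zero_phase Use zero-phase (filtfilt) filtering.
#' @return An object of class `envelope_series`: data frame with columns
#'   `time` (s) and `value` (normalised envelope in `[0, 1]`), with the rate
#'   stored as attribute `rate`.
#' @export
emg_envelope <- function(raw, fs = 1500, mvc, out_rate = 100,
                         band = c(10, 500), envelope_cutoff = 6,
                         zero_phase = FALSE) {
  if (missing(mvc) || mvc <= 0) stop("mvc must be positive", call. = FALSE)
  if (length(raw) < 3 * fs / band[1])
    stop("input too short for filter warm-up", call. = FALSE)
  nyq <- fs / 2
  hp <- signal::butter(2, band[1] / nyq, type = "high")
  lo_corner <- min(band[2], 0.95 * nyq)
  lp <- signal::butter(4, lo_corner / nyq, type = "low")
  env <- signal::butter(2, envelope_cutoff / nyq, type = "low")
  apply_f <- function(flt, x)
    if (zero_phase) signal::filtfilt(flt, x) else
      as.numeric(signal::filter(flt, x))
  x <- apply_f(hp, raw)
  x <- apply_f(lp, x)
  x <- abs(x)
  x <- apply_f(env, x)
  x <- pmin(pmax(x / mvc, 0), 1)
  if (out_rate != fs) {
    frac <- out_rate / fs
    pq <- .rate_fraction(frac)
    x <- signal::resample(x, pq[1], pq[2])
    x <- pmin(pmax(x, 0), 1)
  }
  structure(data.frame(time = seq_along(x) / out_rate - 1 / out_rate,
                       value = x),
            rate = out_rate, class = c("envelope_series", "data.frame"))
}

# small rational approximation p/q of a resampling ratio
.rate_fraction <- function(frac, max_den = 1000) {
  for (q in seq_len(max_den)) {
    p <- frac * q
    if (abs(p - round(p)) < 1e-9) return(c(round(p), q))
  }
  stop("resampling ratio has no small rational representation", call. = FALSE)
}

#' Band-limited differentiation filter
#'
#' Discrete (bilinear-transform) realisation of the continuous
#' differentiator \deqn{G(s) = \frac{s}{(s/30 + 1)(s/300 + 1)^2},} a pure
#' differentiator below 30 rad/s whose poles at 30 and 300 rad/s bound the
#' high-frequency noise gain.  Applied twice for a second derivative.
#'
#' @param x Uniformly sampled signal.
#' @param T_s Sampling period (s).
#' @param order Apply the filter once (first derivative) or twice (second
#'   derivative).
#' @return Filtered derivative series (same length as `x`).
#' @export
differentiate_filtered <- function(x, T_s, order = 1) {
  stopifnot(order %in% c(1, 2), T_s > 0)
  ba <- .diff_filter_coef(T_s)
  out <- as.numeric(signal::filter(ba$b, ba$a, x))
  if (order == 2) out <- as.numeric(signal::filter(ba$b, ba$a, out))
  out
}

# bilinear transform of G(s) = 2.7e6 s / ((s+30)(s+300)^2)
.diff_filter_coef <- function(T_s) {
  zpg <- signal::bilinear(Sz = 0, Sp = c(-30, -300, -300), Sg = 2.7e6,
                          T = T_s)
  b <- Re(zpg$g * .poly_from_roots(zpg$z))
  a <- Re(.poly_from_roots(zpg$p))
  list(b = b, a = a)
}

.poly_from_roots <- function(r) {
  p <- 1
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

#' Frequency response of the differentiation filter
#'
#' Analytic magnitude of the continuous-time prototype
#' \eqn{|G(j\omega)|}; used to validate the discrete realisation.
#'
#' @param omega Angular frequencies (rad/s).
#' @return Magnitude response.
#' @export
diff_filter_gain <- function(omega) {
  omega / (sqrt(1 + (omega / 30)^2) * (1 + (omega / 300)^2))
}
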