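# Fano-factor estimators: the standard variance-to-mean estimator, the
# intensity-invariant operational-time variant, and the shifted-window
# average that reuses spikes discarded by window shortening.

stop_undefined <- function(msg) {
  stop(structure(class = c("fanotime_undefined_estimate", "error",
                           "condition"),
                 list(message = msg, call = NULL)))
}

#' Estimate the firing intensity
#'
#' \eqn{\hat\lambda = \bar N(w)/w}: the mean spike count over trials
#' divided by the window length.
#'
#' @param set A [spike_train_set()].
#' @param window Counting window (defaults to the full recorded window;
#'   must not exceed it).
#' @return Estimated intensity (spikes per unit time, \eqn{\ge 0}).
#' @examples
#' s <- spike_train_set(list(c(0.2, 0.9), numeric(0), 0.5, 1.8), window = 2)
#' estimate_intensity(s)  # mean count 1 over window 2 -> 0.5
#' @export
estimate_intensity <- function(set, window = set$window) {
  mean(spike_counts(set, window = window)) / window
}

new_fano_estimate <- function(value, window_used, operational_window,
                              variant, counts) {
  structure(list(value = value, window_used = window_used,
                 operational_window = operational_window,
                 variant = variant, counts = counts),
            class = "fano_estimate")
}

#' @export
print.fano_estimate <- function(x, ...) {
  cat(sprintf("Fano factor estimate (%s): %.6g\n", x$variant, x$value))
  cat(sprintf("  window used %.6g over %d trials", x$window_used,
              length(x$counts)))
  if (!is.na(x$operational_window))
    cat(sprintf(", operational window %.6g", x$operational_window))
  cat("\n")
  invisible(x)
}

fano_from_counts <- function(counts) {
  if (length(counts) < 2L)
    stop("the Fano factor needs at least 2 trials", call. = FALSE)
  m <- mean(counts)
  if (m == 0)
    stop_undefined("Fano factor undefined: zero spikes in every trial")
  stats::var(counts) / m
}

#' Standard Fano-factor estimator
#'
#' \eqn{\hat F(w) = s^2_{N(w)}/\bar N(w)}: the unbiased sample variance
#' (divisor \eqn{n-1}) of the spike counts in \eqn{(0, w]} divided by
#' their sample mean. Raises a typed error (class
#' `"fanotime_undefined_estimate"`) when every trial is empty, rather
#' than returning `NaN`.
#'
#' @param set A [spike_train_set()] with at least 2 trials.
#' @param window Counting window length (defaults to the recorded
#'   window).
#' @param start Window start offset (counts taken on
#'   `(start, start + window]`).
#' @return A `"fano_estimate"` object; the estimate itself is in
#'   `$value`, the counts used in `$counts`.
#' @examples
#' s <- spike_train_set(list(c(0.2, 0.9), numeric(0), 0.5, 1.8), window = 2)
#' estimate_fano(s)$value  # counts 2,0,1,1 -> var 2/3 over mean 1
#' @export
estimate_fano <- function(set, window = set$window, start = 0) {
  counts <- spike_counts(set, window = window, start = start)
  new_fano_estimate(fano_from_counts(counts), window_used = window,
                    operational_window = NA_real_, variant = "standard",
                    counts = counts)
}

#' Greatest common operational window
#'
#' The operational-time length of a window of physical length \eqn{w} for
#' data with intensity \eqn{\lambda} is \eqn{w_o = w\lambda}
#' (dimensionless, in units of the mean ISI). When comparing \eqn{m}
#' experiments with windows \eqn{w_i} and estimated intensities
#' \eqn{\hat\lambda_i}, the largest operational window available to all
#' of them is \deqn{\bar w_o = \min_i\, w_i \hat\lambda_i.}
#'
#' @param sets A list of [spike_train_set()] objects (or a single set).
#' @param windows Optional vector of physical window lengths, one per
#'   set; defaults to each set's recorded window.
#' @return The common operational window \eqn{\bar w_o}.
#' @examples
#' # a set with mean count 1.5 on (0, 3] has estimated intensity 0.5,
#' # so a window of length 3 has operational length 1.5
#' s <- spike_train_set(list(c(1, 2), 1.5), window = 3)
#' common_operational_window(list(s))  # 1.5
#' @export
common_operational_window <- function(sets, windows = NULL) {
  if (inherits(sets, "spike_train_set")) sets <- list(sets)
  if (is.null(windows))
    windows <- vapply(sets, function(s) s$window, numeric(1))
  stopifnot(length(windows) == length(sets))
  rates <- mapply(function(s, w) estimate_intensity(s, window = w),
                  sets, windows)
  if (any(rates == 0))
    stop_undefined(
      "operational window undefined: an experiment has zero estimated intensity")
  min(windows * rates)
}

#' Operational Fano-factor estimator
#'
#' Evaluates the standard Fano estimator in a window of fixed
#' *operational* length \eqn{w_o} (units of the mean ISI): the intensity
#' is first estimated on the full recorded window,
#' \eqn{\hat\lambda = \bar N(w)/w}, and counts are then taken on the
#' shortened physical window \eqn{(start, start + w_o/\hat\lambda]}.
#' Because \eqn{\hat\lambda} rescales exactly with the data's clock, the
#' estimate is invariant under any linear rescaling of time (see
#' [rescale_time()]) — this is what makes Fano factors comparable across
#' experiments with different firing rates.
#'
#' `estimate_fano_operational_shifted()` averages the operational
#' estimator over \eqn{k = \lceil w/w_{eff} \rceil} windows whose starts
#' are evenly spaced between 0 and \eqn{w - w_{eff}}
#' (\eqn{w_{eff} = w_o/\hat\lambda}), so that every spike is used but as
#' few as possible twice; this recovers the information discarded by
#' window shortening and reduces the estimator's error.
#'
#' @param set A [spike_train_set()].
#' @param w_o Operational window length (> 0, dimensionless).
#' @param start Start offset of the counting window (default 0; the
#'   process being in equilibrium, the placement does not matter in
#'   expectation).
#' @return A `"fano_estimate"` with variant `"operational"` or
#'   `"operational_shifted"`.
#' @examples
#' s <- simulate_spike_trains(isi_gamma(2, 0.5), 10, 200, seed = 1)
#' f1 <- estimate_fano_operational(s, w_o = 5)
#' f2 <- estimate_fano_operational(rescale_time(s, 7), w_o = 5)
#' all.equal(f1$value, f2$value)  # exact rate invariance
#' @export
estimate_fano_operational <- function(set, w_o, start = 0) {
  check_positive(w_o, "w_o")
  lam <- estimate_intensity(set)
  if (lam == 0)
    stop_undefined("operational Fano factor undefined: zero estimated intensity")
  w_eff <- w_o / lam
  if (start + w_eff > set$window * (1 + 1e-9))
    stop("effective window w_o / lambda_hat + start = ", start + w_eff,
         " exceeds the recording window ", set$window, call. = FALSE)
  w_eff <- min(w_eff, set$window - start)
  counts <- spike_counts(set, window = w_eff, start = start)
  new_fano_estimate(fano_from_counts(counts), window_used = w_eff,
                    operational_window = w_o, variant = "operational",
                    counts = counts)
}

#' @rdname estimate_fano_operational
#' @export
estimate_fano_operational_shifted <- function(set, w_o) {
  check_positive(w_o, "w_o")
  lam <- estimate_intensity(set)
  if (lam == 0)
    stop_undefined("operational Fano factor undefined: zero estimated intensity")
  w_eff <- w_o / lam
  if (w_eff > set$window * (1 + 1e-9))
    stop("effective window w_o / lambda_hat = ", w_eff,
         " exceeds the recording window ", set$window, call. = FALSE)
  w_eff <- min(w_eff, set$window)
  k <- ceiling(set$window / w_eff - 1e-9)
  starts <- if (k == 1L) 0 else
    seq(0, set$window - w_eff, length.out = k)
  vals <- vapply(starts, function(s0) {
    fano_from_counts(spike_counts(set, window = w_eff, start = s0))
  }, numeric(1))
  new_fano_estimate(mean(vals), window_used = w_eff,
                    operational_window = w_o,
                    variant = "operational_shifted",
                    counts = spike_counts(set, window = w_eff, start = 0))
}

#' Fano-factor ratio between two experiments
#'
#' Computes \eqn{r(\hat F) = \hat F_2 / \hat F_1} for the requested
#' estimator variants. The operational variants first determine the
#' greatest common operational window \eqn{\bar w_o =
#' \min(w_1\hat\lambda_1, w_2\hat\lambda_2)} and evaluate both arms at
#' that operational length, so the comparison is intensity-invariant.
#'
#' @param set1,set2 [spike_train_set()] objects (denominator and
#'   numerator experiments, respectively).
#' @param methods Which ratio variants to compute (any subset of
#'   `"standard"`, `"operational"`, `"operational_shifted"`).
#' @return A list of class `"fano_ratio_result"` with elements
#'   `r_standard`, `r_operational`, `r_operational_shifted` (NA when not
#'   requested) and `common_operational_window`.
#' @examples
#' s1 <- simulate_spike_trains(isi_gamma(1, 0.5), 10, 100, seed = 1)
#' s2 <- rescale_time(s1, 2)        # same variability, half the rate
#' fano_ratio(s1, s2, "operational")$r_operational  # exactly 1
#' @export
fano_ratio <- function(set1, set2,
                       methods = c("standard", "operational",
                                   "operational_shifted")) {
  methods <- match.arg(methods, several.ok = TRUE)
  out <- list(r_standard = NA_real_, r_operational = NA_real_,
              r_operational_shifted = NA_real_,
              common_operational_window = NA_real_)
  ratio_of <- function(f1, f2) {
    if (f1$value == 0)
      stop_undefined("Fano-factor ratio undefined: denominator estimate is zero")
    f2$value / f1$value
  }
  if ("standard" %in% methods)
    out$r_standard <- ratio_of(estimate_fano(set1), estimate_fano(set2))
  if (any(c("operational", "operational_shifted") %in% methods)) {
    wbar <- common_operational_window(list(set1, set2))
    out$common_operational_window <- wbar
    if ("operational" %in% methods)
      out$r_operational <- ratio_of(
        estimate_fano_operational(set1, wbar),
        estimate_fano_operational(set2, wbar))
    if ("operational_shifted" %in% methods)
      out$r_operational_shifted <- ratio_of(
        estimate_fano_operational_shifted(set1, wbar),
        estimate_fano_operational_shifted(set2, wbar))
  }
  class(out) <- "fano_ratio_result"
  out
}

#' @export
print.fano_ratio_result <- function(x, ...) {
  cat("Fano-factor ratio (experiment 2 / experiment 1)\n")
  if (!is.na(x$r_standard))
    cat(sprintf("  standard:            %.6g\n", x$r_standard))
  if (!is.na(x$r_operational))
    cat(sprintf("  operational:         %.6g\n", x$r_operational))
  if (!is.na(x$r_operational_shifted))
    cat(sprintf("  operational shifted: %.6g\n", x$r_operational_shifted))
  if (!is.na(x$common_operational_window))
    cat(sprintf("  common operational window: %.6g\n",
                x$common_operational_window))
  invisible(x)
}

# ---- bias/variance approximations and error metrics -----------------------

#' Approximate bias and variance of the Fano-factor estimator
#'
#' First-order approximations of the finite-window, finite-sample
#' distortion of \eqn{\hat F(w)}:
#' \deqn{Bias(\hat F) \approx (F(w) - F) + \frac{F(w)}{\lambda w}
#'   - \frac{Cov(s^2_N, \bar N)}{(\lambda w)^2},}
#' \deqn{Var(\hat F) \approx F^2(w)\left(\frac{Var(s^2_N)}{Var^2(N(w))}
#'   - \frac{2\,Cov(s^2_N, \bar N)}{\lambda w\, Var(N(w))}
#'   + \frac{F(w)}{\lambda w}\right).}
#'
#' The moment arguments are *per-trial* (asymptotic) quantities: with
#' count central moments \eqn{\mu_k}, `var_s2` \eqn{= n\,Var(s^2_N)
#' \approx \mu_4 - \mu_2^2}, `var_count` \eqn{= Var(N(w)) = \mu_2} and
#' `cov_term` \eqn{= n\,Cov(s^2_N, \bar N) \approx \mu_3}. Use
#' [count_moments()] to estimate them by Monte Carlo from a model. Under
#' this convention the two bias correction terms cancel exactly for a
#' Poisson process, matching simulation. These are approximations and are
#' validated only against simulation, not exact results.
#'
#' @param fano_w True windowed Fano factor \eqn{F(w)}.
#' @param fano_limit Asymptotic Fano factor \eqn{F}.
#' @param rate Intensity \eqn{\lambda}.
#' @param window Window length \eqn{w} (\eqn{\lambda w > 0} required).
#' @param cov_term Per-trial covariance term \eqn{\approx \mu_3} (see
#'   Details).
#' @param var_s2 Per-trial variance of the sample count variance
#'   \eqn{\approx \mu_4 - \mu_2^2}.
#' @param var_count Per-trial count variance \eqn{Var(N(w))}.
#' @return A single number (approximate bias, or approximate variance on
#'   the per-trial scale).
#' @examples
#' approx_bias(fano_w = 1, fano_limit = 1, rate = 10, window = 1,
#'             cov_term = 0)  # 0.1
#' @export
approx_bias <- function(fano_w, fano_limit, rate, window, cov_term) {
  lw <- rate * window
  if (lw <= 0) stop("'rate * window' must be positive", call. = FALSE)
  (fano_w - fano_limit) + fano_w / lw - cov_term / lw^2
}

#' @rdname approx_bias
#' @export
approx_var <- function(fano_w, rate, window, var_s2, var_count, cov_term) {
  lw <- rate * window
  if (lw <= 0) stop("'rate * window' must be positive", call. = FALSE)
  fano_w^2 * (var_s2 / var_count^2 -
                2 * cov_term / (lw * var_count) + fano_w / lw)
}

#' Monte-Carlo count moments for the bias/variance approximations
#'
#' Simulates the model and estimates the per-trial moment inputs of
#' [approx_bias()] / [approx_var()] from the pooled spike counts: the
#' count variance \eqn{\mu_2}, the third and fourth central moments, and
#' the derived `var_s2` (\eqn{\mu_4 - \mu_2^2}) and `cov_term`
#' (\eqn{\mu_3}).
#'
#' @param model Any model accepted by [simulate_spike_trains()].
#' @param window Window length.
#' @param n_trials Number of simulated trials used to estimate the
#'   moments.
#' @param seed Optional RNG seed.
#' @return Named list with `var_count`, `var_s2`, `cov_term`, plus the
#'   raw `mu2`, `mu3`, `mu4` and the empirical `fano_w`.
#' @export
count_moments <- function(model, window, n_trials = 1e5, seed = NULL) {
  set <- simulate_spike_trains(model, window, n_trials, seed = seed)
  counts <- spike_counts(set)
  d <- counts - mean(counts)
  mu2 <- mean(d^2); mu3 <- mean(d^3); mu4 <- mean(d^4)
  list(var_count = mu2, var_s2 = mu4 - mu2^2, cov_term = mu3,
       mu2 = mu2, mu3 = mu3, mu4 = mu4,
       fano_w = stats::var(counts) / mean(counts))
}

#' Estimator error metrics over Monte-Carlo replicates
#'
#' `mae()` is the sample mean absolute error \eqn{E|\hat F - F|};
#' `mse_decomposition()` splits the sample mean squared error into
#' squared bias and (population, divisor \eqn{n}) variance, so that
#' `bias2 + variance` equals the MSE to floating tolerance.
#'
#' @param estimates Numeric vector of replicate estimates (length
#'   \eqn{\ge 1} for `mae`, \eqn{\ge 2} for the decomposition; `NA`s are
#'   dropped).
#' @param truth True parameter value.
#' @return `mae()`: a single non-negative number. `mse_decomposition()`:
#'   named vector `c(bias2, variance, mse)`.
#' @examples
#' mae(c(0, 2), 1)                  # 1
#' mse_decomposition(c(0, 2), 1)    # bias2 0, variance 1, mse 1
#' @export
mae <- function(estimates, truth) {
  estimates <- estimates[!is.na(estimates)]
  if (length(estimates) == 0L)
    stop("'estimates' must contain at least one value", call. = FALSE)
  mean(abs(estimates - truth))
}

#' @rdname mae
#' @export
mse_decomposition <- function(estimates, truth) {
  estimates <- estimates[!is.na(estimates)]
  if (length(estimates) < 2L)
    stop("need at least two replicate estimates", call. = FALSE)
  b2 <- (mean(estimates) - truth)^2
  v <- mean((estimates - mean(estimates))^2)
  c(bias2 = b2, variance = v, mse = b2 + v)
}

#' Standard error of the Fano-factor estimator
#'
#' Influence-function (delta-method) standard error of
#' \eqn{s^2_N/\bar N} computed from the observed counts; used to express
#' Monte-Carlo agreement in units of standard errors.
#'
#' @param counts Integer vector of spike counts (length \eqn{\ge 2},
#'   positive mean).
#' @return Estimated standard error of the Fano estimate.
#' @export
fano_standard_error <- function(counts) {
  n <- length(counts)
  if (n < 2L) stop("need at least 2 counts", call. = FALSE)
  m <- mean(counts)
  if (m == 0) stop_undefined("standard error undefined: zero mean count")
  d <- counts - m
  fhat <- stats::var(counts) / m
  infl <- (d^2 - mean(d^2)) / m - fhat * d / m
  stats::sd(infl) / sqrt(n)
}
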