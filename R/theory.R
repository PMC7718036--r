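# Exact/numerical windowed Fano-factor curves F(w) and asymptotic limits.
#
# For an equilibrium renewal process the variance-time relation gives
#   F(w) = (1/w) L^{-1}{ (1 + L{f}(s)) / (s^2 (1 - L{f}(s))) }(w) - lambda w,
# where f is the ISI density. The transform behaves like
# 2/(mu s^3) + CV^2/s^2 + c/s + ... as s -> 0; the first two (singular)
# terms are subtracted before numerical inversion and re-added in closed
# form (L^-1{2/(mu s^3)} = lambda w^2, which cancels the -lambda w term
# after division by w, and L^-1{CV^2/s^2}/w = CV^2). This removes the
# catastrophic cancellation that would otherwise dominate at large w.

#' Windowed Fano-factor curve of a spike-train model
#'
#' `fano_curve()` evaluates the Fano factor
#' \eqn{F(w) = Var(N(w))/E(N(w))} of the spike count in a window of length
#' `w`, on a user-supplied grid of windows. For renewal ISI models the
#' curve is computed by numerical Laplace-transform inversion
#' (`method = "laplace"`); for the pacemaker model a closed form is used;
#' for two-state Markov renewal models, which have no closed finite-window
#' form, the curve is estimated by Monte Carlo simulation.
#'
#' For renewal models \eqn{F(w) \to 1} as \eqn{w \to 0^+} and
#' \eqn{F(w) \to CV^2} as \eqn{w \to \infty}.
#'
#' @param model An [`isi_model`][isi_models] or [mrp_model()].
#' @param windows Ascending vector of positive window lengths.
#' @param method Computation route. Renewal models: `"laplace"`;
#'   pacemaker: `"closed_form"`; MRP (and optionally any model):
#'   `"monte_carlo"`.
#' @param n_trials,seed Monte-Carlo settings (used only when
#'   `method = "monte_carlo"`).
#' @param ... Passed on to [invert_laplace()] (e.g. `A`).
#' @return An object of class `"fano_curve"`: a data frame with columns
#'   `w` and `fano`, with the model and method stored as attributes.
#' @examples
#' fano_curve(isi_gamma(1, 0.5), c(0.5, 1, 5))
#' fano_curve(isi_pacemaker(1), c(0.5, 1.5, 3))
#' @export
fano_curve <- function(model, windows, ...) UseMethod("fano_curve")

#' @rdname fano_curve
#' @export
fano_curve.isi_model <- function(model, windows,
                                 method = c("laplace", "closed_form",
                                            "monte_carlo"),
                                 n_trials = 1e4, seed = NULL, ...) {
  method <- match.arg(method)
  if (inherits(model, "isi_pacemaker") && method != "monte_carlo")
    return(fano_curve_pacemaker(model$rate, windows))
  switch(method,
    laplace = fano_curve_renewal(model, windows, ...),
    closed_form = stop("closed_form is available only for the pacemaker ",
                       "model", call. = FALSE),
    monte_carlo = fano_curve_mc(model, windows, n_trials, seed)
  )
}

#' @rdname fano_curve
#' @export
fano_curve.mrp_model <- function(model, windows,
                                 method = "monte_carlo",
                                 n_trials = 1e4, seed = NULL, ...) {
  method <- match.arg(method, "monte_carlo")
  fano_curve_mc(model, windows, n_trials, seed)
}

new_fano_curve <- function(windows, values, model, method) {
  structure(data.frame(w = windows, fano = values),
            model = model, method = method,
            class = c("fano_curve", "data.frame"))
}

#' @export
print.fano_curve <- function(x, ...) {
  cat(sprintf("Fano-factor curve (%s method)\n", attr(x, "method")))
  print.data.frame(x, ...)
  invisible(x)
}

#' @rdname fano_curve
#' @export
fano_curve_renewal <- function(model, windows, ...) {
  if (!inherits(model, "isi_model"))
    stop("'model' must be a renewal ISI model", call. = FALSE)
  if (inherits(model, "isi_pacemaker"))
    stop("the pacemaker ISI distribution is degenerate; ",
         "use fano_curve_pacemaker()", call. = FALSE)
  if (any(windows <= 0)) stop("windows must be positive", call. = FALSE)
  mu <- isi_mean(model)
  cv2 <- isi_cv2(model)
  H <- function(s) {
    lf <- laplace_pdf(model, s)
    (1 + lf) / (s^2 * (1 - lf)) - 2 / (mu * s^3) - cv2 / s^2
  }
  vals <- cv2 + invert_laplace(H, windows, ...) / windows
  new_fano_curve(windows, vals, model, "laplace")
}

#' Closed-form Fano curve of the equilibrium pacemaker process
#'
#' The pacemaker fires equidistantly with a uniformly random phase, so the
#' count in a window of length `w` is \eqn{\tau + Bernoulli(\lambda w -
#' \tau)} with \eqn{\tau = \lfloor \lambda w \rfloor}, giving
#' \deqn{F(w) = 2\tau + 1 - \tau(\tau+1)/(\lambda w) - \lambda w,}
#' which is zero exactly when \eqn{\lambda w} is a positive integer (the
#' count is then deterministic).
#'
#' @param rate Firing intensity \eqn{\lambda > 0}.
#' @param windows Positive window lengths.
#' @return A [`fano_curve`][fano_curve] object.
#' @examples
#' fano_curve_pacemaker(1, c(0.5, 1, 1.5, 3))$fano  # 0.5, 0, 1/6, 0
#' @export
fano_curve_pacemaker <- function(rate, windows) {
  check_positive(rate, "rate")
  if (any(windows <= 0)) stop("windows must be positive", call. = FALSE)
  lw <- rate * windows
  tau <- floor(lw)
  vals <- 2 * tau + 1 - tau * (tau + 1) / lw - lw
  new_fano_curve(windows, vals, isi_pacemaker(rate), "closed_form")
}

fano_curve_mc <- function(model, windows, n_trials, seed) {
  if (any(windows <= 0)) stop("windows must be positive", call. = FALSE)
  set <- simulate_spike_trains(model, window = max(windows),
                               n_trials = n_trials, seed = seed)
  vals <- vapply(windows, function(w) {
    counts <- spike_counts(set, window = w)
    stats::var(counts) / mean(counts)
  }, numeric(1))
  new_fano_curve(windows, vals, model, "monte_carlo")
}

#' Asymptotic Fano factor (large-window limit)
#'
#' For an equilibrium renewal process the limit of \eqn{F(w)} as
#' \eqn{w \to \infty} equals the squared coefficient of variation of the
#' ISIs. For a symmetric two-state Markov renewal process the limit is
#' \deqn{F = \frac{\mu_2^2(2CV_1^2-1) + 2\mu_1\mu_2 + \mu_1^2(2CV_2^2-1)}
#'                {(\mu_1+\mu_2)^2}
#'         + \frac{1}{p}\frac{(\mu_2-\mu_1)^2}{(\mu_1+\mu_2)^2},}
#' which for exponential states (MPP) reduces to
#' \eqn{F = 1 + (1/p)(\mu_2-\mu_1)^2/(\mu_1+\mu_2)^2} and at \eqn{p = 1}
#' (alternating Poisson process) to
#' \eqn{F = 2(\mu_1^2+\mu_2^2)/(\mu_1+\mu_2)^2}, bounded in \eqn{[1, 2)}
#' with equality to 1 iff \eqn{\mu_1 = \mu_2} (Poisson process).
#'
#' @param model An [`isi_model`][isi_models] or [mrp_model()]. MRP models
#'   require `switch_prob > 0` (with `p = 0` the state never changes and
#'   the process has no stationary alternation).
#' @return A single non-negative number.
#' @examples
#' fano_limit(isi_gamma(3, 1.5))                      # 1.5
#' fano_limit(mrp_model(3, 1, switch_prob = 1))       # 1.25
#' @export
fano_limit <- function(model) UseMethod("fano_limit")

#' @export
fano_limit.isi_model <- function(model) isi_cv2(model)

#' @export
fano_limit.mrp_model <- function(model) {
  if (model$switch_prob <= 0)
    stop("the asymptotic Fano factor of an MRP requires switch_prob > 0",
         call. = FALSE)
  m1 <- model$mu1; m2 <- model$mu2
  s2 <- (m1 + m2)^2
  (m2^2 * (2 * model$cv1^2 - 1) + 2 * m1 * m2 +
     m1^2 * (2 * model$cv2^2 - 1)) / s2 +
    (1 / model$switch_prob) * (m2 - m1)^2 / s2
}

#' Rate/window interchangeability of the Fano curve
#'
#' For two equilibrium renewal processes that differ only in intensity
#' (\eqn{\lambda_1}, \eqn{\lambda_2}) the Fano curves satisfy
#' \eqn{F_1(w) = F_2((\lambda_1/\lambda_2) w)}: changing the rate is
#' equivalent to rescaling the window. This diagnostic evaluates both
#' sides by independent Laplace inversions; they should agree to the
#' inversion tolerance. This identity is the reason a naive comparison of
#' Fano factors across firing rates is biased, and what the operational
#' time correction exploits.
#'
#' @param model A renewal [`isi_model`][isi_models] with rate
#'   \eqn{\lambda_1}.
#' @param rate2 The second process's intensity \eqn{\lambda_2 > 0}.
#' @param w Window length (for the first process).
#' @param ... Passed to [fano_curve_renewal()].
#' @return Named vector `c(F1 = F1(w), F2 = F2(lambda1/lambda2 * w))`.
#' @examples
#' fano_scaling_check(isi_gamma(1, 1.5), rate2 = 2, w = 1)
#' @export
fano_scaling_check <- function(model, rate2, w, ...) {
  check_positive(rate2, "rate2")
  model2 <- model_from_config(
    utils::modifyList(model_to_config(model), list(rate = rate2)))
  f1 <- fano_curve_renewal(model, w, ...)$fano
  f2 <- fano_curve_renewal(model2, model$rate / rate2 * w, ...)$fano
  c(F1 = f1, F2 = f2)
}

#' Write a Fano curve to CSV
#'
#' Writes the `w`/`fano` columns with `#`-prefixed header comments
#' recording the method and model parameters.
#'
#' @param curve A [`fano_curve`][fano_curve].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fano_curve <- function(curve, path) {
  model <- attr(curve, "model")
  cfg <- model_to_config(model)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# fano_curve method: %s", attr(curve, "method")),
    sprintf("# model: %s", paste(sprintf("%s=%s", names(cfg), unlist(cfg)),
                                 collapse = " "))), con)
  utils::write.csv(as.data.frame(curve), con, row.names = FALSE)
  invisible(path)
}
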