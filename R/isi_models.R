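#' Parametric interspike-interval (ISI) models
#'
#' Constructors for the renewal ISI families used throughout the package.
#' Every family is parameterized by the firing intensity `rate`
#' (\eqn{\lambda}, spikes per unit time, so the mean ISI is \eqn{1/\lambda})
#' and, where applicable, by the asymptotic Fano factor `fano`
#' (\eqn{F = CV^2}, the squared coefficient of variation of the ISIs, which
#' equals the large-window limit of the windowed Fano factor for renewal
#' processes).
#'
#' Available families:
#' \describe{
#'   \item{`isi_gamma(rate, fano)`}{Gamma ISIs with shape \eqn{1/F} and
#'     scale \eqn{F/\lambda}; any \eqn{F > 0}.}
#'   \item{`isi_invgauss(rate, fano)`}{Inverse-Gaussian ISIs with mean
#'     \eqn{1/\lambda} and shape \eqn{1/(\lambda F)} (variance
#'     \eqn{F/\lambda^2}); any \eqn{F > 0}.}
#'   \item{`isi_exponential(rate)`}{Exponential ISIs (Poisson process);
#'     \eqn{F = 1} fixed.}
#'   \item{`isi_exp_refractory(rate, fano)`}{Exponential ISIs preceded by a
#'     dead time (refractory period) \eqn{r = (1-\sqrt{F})/\lambda}, with
#'     post-refractory mean \eqn{\sqrt{F}/\lambda}: the unique shifted
#'     exponential with total mean \eqn{1/\lambda} and \eqn{CV^2 = F}.
#'     Requires \eqn{0 < F \le 1}. The refractory period scales with the
#'     rate, keeping the family a scale family (a fixed, non-scaling dead
#'     time would break the rate/window interchangeability that the
#'     operational-time method relies on).}
#'   \item{`isi_pacemaker(rate)`}{Deterministic, equidistant spiking with a
#'     uniformly random phase; \eqn{F = 0} fixed.}
#' }
#'
#' All families satisfy the scale-family identity
#' \eqn{f(t; \lambda, F) = \lambda f(\lambda t; 1, F)}.
#'
#' @param rate Firing intensity \eqn{\lambda > 0} (spikes per unit time).
#' @param fano Asymptotic Fano factor \eqn{F} (equals \eqn{CV^2} of the
#'   ISIs). Admissible range depends on the family (see Details).
#'
#' @return An object of class `c("isi_<family>", "isi_model")`, a list with
#'   elements `family`, `rate` and `fano` plus family-specific parameters.
#'
#' @examples
#' m <- isi_gamma(rate = 1, fano = 0.5)
#' isi_mean(m)          # 1
#' fano_limit(m)        # 0.5
#' isi_pdf(m, c(0.5, 1, 2))
#'
#' @seealso [mrp_model()], [fano_curve()], [simulate_spike_trains()]
#' @name isi_models
NULL

new_isi_model <- function(family, rate, fano, ...) {
  structure(
    c(list(family = family, rate = rate, fano = fano), list(...)),
    class = c(paste0("isi_", family), "isi_model")
  )
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive finite number", name),
         call. = FALSE)
  invisible(x)
}

#' @rdname isi_models
#' @export
isi_gamma <- function(rate, fano) {
  check_positive(rate, "rate")
  check_positive(fano, "fano")
  new_isi_model("gamma", rate, fano,
                shape = 1 / fano, scale = fano / rate)
}

#' @rdname isi_models
#' @export
isi_invgauss <- function(rate, fano) {
  check_positive(rate, "rate")
  check_positive(fano, "fano")
  # mean 1/rate, shape 1/(rate*fano) => variance mean^3/shape = fano/rate^2
  new_isi_model("invgauss", rate, fano,
                mu = 1 / rate, lambda_shape = 1 / (rate * fano))
}

#' @rdname isi_models
#' @export
isi_exponential <- function(rate) {
  check_positive(rate, "rate")
  new_isi_model("exponential", rate, fano = 1)
}

#' @rdname isi_models
#' @export
isi_exp_refractory <- function(rate, fano) {
  check_positive(rate, "rate")
  check_positive(fano, "fano")
  if (fano > 1)
    stop("'fano' must lie in (0, 1] for the refractory-exponential family",
         call. = FALSE)
  # dead time (1 - sqrt(F))/rate and exponential mean sqrt(F)/rate: the
  # unique shifted exponential with mean 1/rate and CV^2 = F
  new_isi_model("exp_refractory", rate, fano,
                refractory = (1 - sqrt(fano)) / rate,
                exp_rate = rate / sqrt(fano))
}

#' @rdname isi_models
#' @export
isi_pacemaker <- function(rate) {
  check_positive(rate, "rate")
  new_isi_model("pacemaker", rate, fano = 0)
}

#' @export
print.isi_model <- function(x, ...) {
  cat(sprintf("ISI model: %s (rate = %g, asymptotic Fano factor = %g)\n",
              x$family, x$rate, x$fano))
  invisible(x)
}

#' ISI model characteristics
#'
#' Density, distribution function, mean and squared coefficient of
#' variation of an ISI model. `isi_mean()` is \eqn{1/\lambda} for every
#' family; `isi_cv2()` equals the model's asymptotic Fano factor.
#'
#' @param model An [`isi_model`][isi_models].
#' @param t Vector of times (ISI durations), \eqn{t \ge 0}.
#' @return `isi_pdf` and `isi_cdf` return numeric vectors the length of
#'   `t`; `isi_mean` and `isi_cv2` return single numbers.
#' @examples
#' isi_cdf(isi_exponential(2), 1)  # 1 - exp(-2)
#' @export
isi_pdf <- function(model, t) UseMethod("isi_pdf")

#' @export
isi_pdf.isi_gamma <- function(model, t)
  stats::dgamma(t, shape = model$shape, scale = model$scale)

#' @export
isi_pdf.isi_invgauss <- function(model, t) {
  mu <- model$mu; lam <- model$lambda_shape
  out <- numeric(length(t))
  pos <- is.finite(t) & t > 0
  tp <- t[pos]
  out[pos] <- sqrt(lam / (2 * pi * tp^3)) *
    exp(-lam * (tp - mu)^2 / (2 * mu^2 * tp))
  out[!is.finite(t)] <- 0
  out
}

#' @export
isi_pdf.isi_exponential <- function(model, t)
  stats::dexp(t, rate = model$rate)

#' @export
isi_pdf.isi_exp_refractory <- function(model, t)
  stats::dexp(t - model$refractory, rate = model$exp_rate)

#' @export
isi_pdf.isi_pacemaker <- function(model, t)
  stop("the pacemaker ISI is degenerate (point mass at 1/rate); ",
       "it has no density", call. = FALSE)

#' @rdname isi_pdf
#' @export
isi_cdf <- function(model, t) UseMethod("isi_cdf")

#' @export
isi_cdf.isi_gamma <- function(model, t)
  stats::pgamma(t, shape = model$shape, scale = model$scale)

#' @export
isi_cdf.isi_invgauss <- function(model, t) {
  # closed form via the normal cdf (Chhikara & Folks)
  mu <- model$mu; lam <- model$lambda_shape
  out <- numeric(length(t))
  pos <- is.finite(t) & t > 0
  tp <- t[pos]
  a <- sqrt(lam / tp)
  out[pos] <- stats::pnorm(a * (tp / mu - 1)) +
    exp(2 * lam / mu) * stats::pnorm(-a * (tp / mu + 1))
  out[is.infinite(t) & t > 0] <- 1
  out
}

#' @export
isi_cdf.isi_exponential <- function(model, t)
  stats::pexp(t, rate = model$rate)

#' @export
isi_cdf.isi_exp_refractory <- function(model, t)
  stats::pexp(t - model$refractory, rate = model$exp_rate)

#' @export
isi_cdf.isi_pacemaker <- function(model, t)
  as.numeric(t >= 1 / model$rate)

#' @rdname isi_pdf
#' @export
isi_mean <- function(model) 1 / model$rate

#' @rdname isi_pdf
#' @export
isi_cv2 <- function(model) model$fano

#' Laplace transform of the ISI density
#'
#' Evaluates \eqn{L\{f\}(s) = \int_0^\infty e^{-st} f(t)\,dt} in closed
#' form. Supported for all families except the pacemaker, whose counting
#' statistics have their own closed form (see [fano_curve_pacemaker()]).
#'
#' Closed forms (with \eqn{\lambda} = rate, \eqn{F} = fano):
#' exponential \eqn{\lambda/(\lambda+s)};
#' gamma \eqn{(1 + Fs/\lambda)^{-1/F}};
#' inverse Gaussian \eqn{\exp\{(1/F)(1 - \sqrt{1 + 2Fs/\lambda})\}};
#' refractory exponential \eqn{e^{-rs} a/(a + s)} with
#' \eqn{a = \lambda/\sqrt{F}} and \eqn{r = (1-\sqrt{F})/\lambda}.
#'
#' @param model An [`isi_model`][isi_models].
#' @param s Real or complex vector with non-negative real part.
#' @return Complex (or numeric, for real `s`) vector of transform values.
#' @examples
#' laplace_pdf(isi_exponential(1), 1)        # 0.5
#' laplace_pdf(isi_gamma(1, 0.5), 1)         # 1.5^-2
#' @export
laplace_pdf <- function(model, s) UseMethod("laplace_pdf")

#' @export
laplace_pdf.isi_exponential <- function(model, s)
  model$rate / (model$rate + s)

#' @export
laplace_pdf.isi_gamma <- function(model, s)
  (1 + model$fano * s / model$rate)^(-1 / model$fano)

#' @export
laplace_pdf.isi_invgauss <- function(model, s)
  exp((1 / model$fano) * (1 - sqrt(1 + 2 * model$fano * s / model$rate)))

#' @export
laplace_pdf.isi_exp_refractory <- function(model, s) {
  a <- model$exp_rate
  exp(-model$refractory * s) * a / (a + s)
}

#' @export
laplace_pdf.isi_pacemaker <- function(model, s)
  stop("Laplace-transform route is not supported for the pacemaker model; ",
       "use fano_curve_pacemaker() for its closed-form Fano curve",
       call. = FALSE)

# ---- two-state Markov renewal models --------------------------------------

#' Two-state Markov renewal process (MRP) models
#'
#' In a two-state MRP every ISI is drawn from one of two distributions
#' (state 1 with mean `mu1`, state 2 with mean `mu2`); the active state
#' evolves as a Markov chain with the symmetric transition matrix
#' \deqn{P = \begin{pmatrix} 1-p & p \\ p & 1-p \end{pmatrix},}
#' so after every ISI the state switches with probability `switch_prob`
#' \eqn{= p}. The process intensity is \eqn{\lambda = 2/(\mu_1+\mu_2)}.
#' With exponential states this is the Markov Poisson process (MPP);
#' `switch_prob = 1` gives the alternating (renewal) process (APP for
#' exponential states). Small `p` with very different state means gives a
#' bursting process.
#'
#' `mpp_state_means()` inverts the MPP parameterization: given a target
#' intensity, asymptotic Fano factor \eqn{F > 1} and switching probability
#' `p`, it returns the state means
#' \eqn{\mu_1 = (1 + \sqrt{p(F-1)})/\lambda}, \eqn{\mu_2 = 2/\lambda - \mu_1},
#' the unique pair satisfying \eqn{\lambda = 2/(\mu_1+\mu_2)} and
#' \eqn{F = 1 + (1/p)(\mu_2-\mu_1)^2/(\mu_1+\mu_2)^2}. `mpp_model()` wraps
#' this into an `mrp_model` directly.
#'
#' @param mu1,mu2 Mean ISI of states 1 and 2 (time units, both > 0).
#' @param cv1,cv2 Coefficient of variation of the per-state ISI
#'   distributions (1 for exponential states, the default).
#' @param switch_prob Probability \eqn{p \in [0,1]} of changing state after
#'   each ISI.
#' @param state_family ISI family used within states: `"exponential"` or
#'   `"gamma"` (gamma with the given per-state CV). `cv1`/`cv2` must be 1
#'   when `state_family = "exponential"`.
#' @param rate Target process intensity \eqn{\lambda > 0}.
#' @param fano Target asymptotic Fano factor, \eqn{F > 1}; `p (F-1) < 1` is
#'   required so that \eqn{\mu_2 > 0}.
#'
#' @return `mrp_model()`/`mpp_model()` return an object of class
#'   `"mrp_model"`; `mpp_state_means()` a named vector `c(mu1, mu2)`.
#'
#' @examples
#' mpp_state_means(rate = 1, fano = 1.5, p = 0.1)  # approx c(1.2236, 0.7764)
#' m <- mpp_model(rate = 1, fano = 1.5, switch_prob = 0.1)
#' fano_limit(m)  # 1.5
#' @export
mrp_model <- function(mu1, mu2, cv1 = 1, cv2 = 1, switch_prob,
                      state_family = c("exponential", "gamma")) {
  check_positive(mu1, "mu1")
  check_positive(mu2, "mu2")
  check_positive(cv1, "cv1")
  check_positive(cv2, "cv2")
  state_family <- match.arg(state_family)
  if (!is.numeric(switch_prob) || length(switch_prob) != 1L ||
      switch_prob < 0 || switch_prob > 1)
    stop("'switch_prob' must be a probability in [0, 1]", call. = FALSE)
  if (state_family == "exponential" && (cv1 != 1 || cv2 != 1))
    stop("exponential states have CV = 1; set cv1 = cv2 = 1 or use ",
         "state_family = \"gamma\"", call. = FALSE)
  state_model <- function(mu, cv) {
    if (state_family == "exponential") isi_exponential(1 / mu)
    else isi_gamma(1 / mu, cv^2)
  }
  structure(
    list(mu1 = mu1, mu2 = mu2, cv1 = cv1, cv2 = cv2,
         switch_prob = switch_prob, state_family = state_family,
         rate = 2 / (mu1 + mu2),
         states = list(state_model(mu1, cv1), state_model(mu2, cv2))),
    class = "mrp_model"
  )
}

#' @rdname mrp_model
#' @param p Alias of `switch_prob` in `mpp_state_means()`.
#' @export
mpp_state_means <- function(rate, fano, p) {
  check_positive(rate, "rate")
  if (!is.numeric(fano) || length(fano) != 1L || fano <= 1)
    stop("an MPP requires 'fano' > 1 (equality to 1 only in the Poisson ",
         "limit mu1 = mu2)", call. = FALSE)
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p > 1)
    stop("'p' must lie in (0, 1]", call. = FALSE)
  if (p * (fano - 1) >= 1)
    stop("parameters give a non-positive mu2: need p*(fano - 1) < 1",
         call. = FALSE)
  mu1 <- (1 + sqrt(p * (fano - 1))) / rate
  mu2 <- 2 / rate - mu1
  c(mu1 = mu1, mu2 = mu2)
}

#' @rdname mrp_model
#' @export
mpp_model <- function(rate, fano, switch_prob) {
  mus <- mpp_state_means(rate, fano, switch_prob)
  mrp_model(mu1 = mus[["mu1"]], mu2 = mus[["mu2"]],
            switch_prob = switch_prob, state_family = "exponential")
}

#' @export
print.mrp_model <- function(x, ...) {
  cat(sprintf(
    "Two-state Markov renewal model (%s states)\n", x$state_family))
  cat(sprintf("  mu1 = %g (CV %g), mu2 = %g (CV %g), switch prob p = %g\n",
              x$mu1, x$cv1, x$mu2, x$cv2, x$switch_prob))
  cat(sprintf("  intensity = %g, asymptotic Fano factor = %g\n",
              x$rate, fano_limit(x)))
  invisible(x)
}

# ---- flat config (de)serialization ----------------------------------------

#' Serialize and restore model specifications
#'
#' Models are serializable as a flat key-value configuration (JSON). This
#' is the dialect used by the command-line interface and the experiment
#' harness.
#'
#' @param model An [`isi_model`][isi_models] or [mrp_model()].
#' @param config A named list (as produced by `model_to_config()`), or a
#'   path to a JSON file holding one.
#' @return `model_to_config()` returns a named list of scalars;
#'   `model_from_config()` rebuilds the model object.
#' @examples
#' cfg <- model_to_config(isi_gamma(2, 1.5))
#' identical(model_from_config(cfg), isi_gamma(2, 1.5))
#' @export
model_to_config <- function(model) {
  if (inherits(model, "isi_model")) {
    list(type = "renewal", family = model$family,
         rate = model$rate, fano = model$fano)
  } else if (inherits(model, "mrp_model")) {
    list(type = "mrp", state_family = model$state_family,
         mu1 = model$mu1, mu2 = model$mu2, cv1 = model$cv1, cv2 = model$cv2,
         switch_prob = model$switch_prob)
  } else stop("not a model object", call. = FALSE)
}

#' @rdname model_to_config
#' @export
model_from_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (is.null(config$type))
    stop("model config needs a 'type' field (\"renewal\" or \"mrp\")",
         call. = FALSE)
  if (config$type == "mrp") {
    return(mrp_model(config$mu1, config$mu2,
                     cv1 = config$cv1 %||% 1, cv2 = config$cv2 %||% 1,
                     switch_prob = config$switch_prob,
                     state_family = config$state_family %||% "exponential"))
  }
  switch(config$family,
    gamma          = isi_gamma(config$rate, config$fano),
    invgauss       = isi_invgauss(config$rate, config$fano),
    exponential    = isi_exponential(config$rate),
    exp_refractory = isi_exp_refractory(config$rate, config$fano),
    pacemaker      = isi_pacemaker(config$rate),
    stop("unknown ISI family: ", config$family, call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
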