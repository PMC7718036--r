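# Equilibrium spike-train simulators. All simulators start the process in
# its time-stationary state, so E(N(w)) = lambda * w holds exactly for
# every window length, not just asymptotically. For renewal models this
# means drawing the time of the first spike from the forward-recurrence
# density f0(t) = lambda * (1 - CDF(t)); operationally we draw the
# interval covering time zero from the length-biased ISI distribution and
# place the origin uniformly inside it (the two constructions are
# equivalent, and length-biased draws are available in closed form for
# every family here).

#' Spike-train sets
#'
#' A `spike_train_set` holds `n` independent trials observed on a common
#' window \eqn{(0, w]}: a list of strictly increasing spike-time vectors
#' (empty trials allowed) plus the window length.
#'
#' @param trains List of numeric vectors of strictly increasing spike
#'   times in `(0, window]`.
#' @param window Common observation window length \eqn{w > 0}.
#' @return An object of class `"spike_train_set"`.
#' @examples
#' s <- spike_train_set(list(c(0.2, 0.9), numeric(0), 0.5), window = 1)
#' spike_counts(s)
#' @export
spike_train_set <- function(trains, window) {
  check_positive(window, "window")
  if (!is.list(trains)) stop("'trains' must be a list", call. = FALSE)
  for (i in seq_along(trains)) {
    tt <- trains[[i]]
    if (length(tt) == 0L) next
    if (!is.numeric(tt) || anyNA(tt))
      stop("trial ", i, ": spike times must be numeric", call. = FALSE)
    if (any(tt <= 0) || any(tt > window))
      stop("trial ", i, ": spike times must lie in (0, window]",
           call. = FALSE)
    if (is.unsorted(tt, strictly = TRUE))
      stop("trial ", i, ": spike times must be strictly increasing",
           call. = FALSE)
  }
  structure(list(trains = trains, window = window),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  cts <- spike_counts(x)
  cat(sprintf("Spike-train set: %d trials on (0, %g]\n",
              length(x$trains), x$window))
  cat(sprintf("  mean count %.3g, count range [%d, %d]\n",
              mean(cts), min(cts), max(cts)))
  invisible(x)
}

#' @export
length.spike_train_set <- function(x) length(x$trains)

#' Spike counts per trial
#'
#' Counts spikes in the half-open-left window `(start, start + window]`
#' for each trial. A spike exactly at a boundary belongs to the window on
#' its left.
#'
#' @param set A [spike_train_set()].
#' @param window Counting window length (defaults to the recorded window).
#' @param start Window start offset (default 0).
#' @return Integer vector of counts, one per trial.
#' @export
spike_counts <- function(set, window = set$window, start = 0) {
  if (start < 0 || window <= 0)
    stop("need start >= 0 and window > 0", call. = FALSE)
  if (start + window > set$window * (1 + 1e-9))
    stop("counting window (start + window = ", start + window,
         ") exceeds the recorded window ", set$window, call. = FALSE)
  hi <- start + window
  vapply(set$trains, function(tt) sum(tt > start & tt <= hi), integer(1))
}

# ---- family-specific samplers ---------------------------------------------

# inverse-Gaussian variates (Michael, Schucany & Haas transform)
rinvgauss <- function(n, mu, lambda) {
  z <- stats::rnorm(n)^2
  x <- mu * (1 + (mu * z - sqrt(4 * mu * lambda * z + mu^2 * z^2)) /
               (2 * lambda))
  u <- stats::runif(n)
  ifelse(u <= mu / (mu + x), x, mu^2 / x)
}

# i.i.d. ISIs from a renewal model
r_isi <- function(model, n) UseMethod("r_isi")
r_isi.isi_gamma <- function(model, n)
  stats::rgamma(n, shape = model$shape, scale = model$scale)
r_isi.isi_invgauss <- function(model, n)
  rinvgauss(n, model$mu, model$lambda_shape)
r_isi.isi_exponential <- function(model, n)
  stats::rexp(n, rate = model$rate)
r_isi.isi_exp_refractory <- function(model, n)
  model$refractory + stats::rexp(n, rate = model$exp_rate)
r_isi.isi_pacemaker <- function(model, n)
  rep(1 / model$rate, n)

# equilibrium forward-recurrence time (time from the origin to the first
# spike): uniform position inside a length-biased interval, or a direct
# analytic inverse where simpler
r_forward <- function(model, n) UseMethod("r_forward")
r_forward.isi_exponential <- function(model, n)
  stats::rexp(n, rate = model$rate)          # memoryless
r_forward.isi_gamma <- function(model, n) {
  # length-biased gamma(shape, scale) is gamma(shape + 1, scale)
  lb <- stats::rgamma(n, shape = model$shape + 1, scale = model$scale)
  stats::runif(n) * lb
}
r_forward.isi_invgauss <- function(model, n) {
  # length-biased IG(mu, lam) is the reciprocal of IG(1/mu, lam/mu^2)
  lb <- 1 / rinvgauss(n, mu = 1 / model$mu,
                      lambda = model$lambda_shape / model$mu^2)
  stats::runif(n) * lb
}
r_forward.isi_exp_refractory <- function(model, n) {
  # integrated survival: uniform mass lambda*r on [0, r), exponential tail
  u <- stats::runif(n)
  rate <- model$rate
  r <- model$refractory
  theta <- 1 / model$exp_rate
  ifelse(u < rate * r,
         u / rate,
         r - theta * log((1 - u) / (rate * theta)))
}
r_forward.isi_pacemaker <- function(model, n)
  stats::runif(n) / model$rate

# ---- simulators ------------------------------------------------------------

#' Simulate equilibrium spike trains
#'
#' Generates `n_trials` mutually independent stationary spike trains on
#' the window \eqn{(0, w]} from a renewal ISI model, the pacemaker, or a
#' two-state Markov renewal model. The process is started in equilibrium
#' (see the package vignette), so the mean count equals
#' \eqn{\lambda w} exactly for every `w`, including windows much shorter
#' than the mean ISI.
#'
#' For Markov renewal models the interval covering time zero is of type
#' \eqn{i} with the length-biased probability \eqn{\mu_i/(\mu_1+\mu_2)},
#' the time to the first spike is the equilibrium residual of that type,
#' and the following interval's type is obtained by applying the
#' transition matrix to the covering type.
#'
#' @param model An [`isi_model`][isi_models] or [mrp_model()].
#' @param window Observation window length \eqn{w > 0}.
#' @param n_trials Number of independent trials.
#' @param seed Optional integer; if supplied, the global RNG is seeded
#'   with `set.seed(seed)` before drawing, making the output
#'   reproducible.
#' @param keep_states (MRP only) if `TRUE`, attach an attribute `"states"`:
#'   a list, parallel to the trains, of the state labels (1 or 2) of the
#'   interval ending at each spike.
#' @return A [spike_train_set()].
#' @examples
#' s <- simulate_spike_trains(isi_gamma(1, 0.5), window = 10,
#'                            n_trials = 100, seed = 1)
#' mean(spike_counts(s))  # close to 10
#' @export
simulate_spike_trains <- function(model, window, n_trials, seed = NULL, ...)
  UseMethod("simulate_spike_trains")

#' @rdname simulate_spike_trains
#' @param ... Passed to methods.
#' @export
simulate_spike_trains.isi_model <- function(model, window, n_trials,
                                            seed = NULL, ...) {
  check_positive(window, "window")
  if (n_trials < 1) stop("'n_trials' must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_trials)
  t0 <- r_forward(model, n)
  trains <- accumulate_times(t0, n, window,
                             function(m, k) r_isi(model, m * k),
                             mean_isi = isi_mean(model))
  out <- spike_train_set(trains, window)
  attr(out, "model") <- model
  out
}

#' @rdname simulate_spike_trains
#' @export
simulate_spike_trains.mrp_model <- function(model, window, n_trials,
                                            seed = NULL,
                                            keep_states = FALSE, ...) {
  check_positive(window, "window")
  if (n_trials < 1) stop("'n_trials' must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_trials)
  p <- model$switch_prob
  s1 <- model$states[[1L]]; s2 <- model$states[[2L]]

  # stationary initialization
  cover <- 1L + (stats::runif(n) >= model$mu1 / (model$mu1 + model$mu2))
  t0 <- numeric(n)
  i1 <- cover == 1L
  t0[i1] <- r_forward(s1, sum(i1))
  t0[!i1] <- r_forward(s2, sum(!i1))
  nxt <- ifelse(stats::runif(n) < p, 3L - cover, cover)

  trains <- rep(list(numeric(0)), n)
  states <- if (keep_states) rep(list(integer(0)), n)
  # first spike (end of the covering interval) carries the covering label
  first_in <- t0 <= window
  for (i in which(first_in)) {
    trains[[i]] <- t0[i]
    if (keep_states) states[[i]] <- cover[i]
  }

  active <- which(first_in)
  cur <- t0
  cur_state <- nxt
  # size the ISI chunk by the faster state so even p = 0 trials frozen in
  # state 2 fit in one pass most of the time
  exp_max <- window / min(model$mu1, model$mu2)
  K <- max(8L, ceiling(exp_max +
                         8 * sqrt(exp_max * (1 + max(model$cv1, model$cv2)^2)) + 16))
  while (length(active)) {
    m <- length(active)
    sw <- matrix(stats::runif(m * K) < p, m, K)
    st <- matrix(0L, m, K)
    st[, 1L] <- cur_state[active]
    if (K > 1L)
      for (j in 2:K) st[, j] <- ifelse(sw[, j - 1L], 3L - st[, j - 1L],
                                       st[, j - 1L])
    a1 <- matrix(r_isi(s1, m * K), m, K)
    a2 <- matrix(r_isi(s2, m * K), m, K)
    x <- ifelse(st == 1L, a1, a2)
    for (j in seq_len(K)[-1L]) x[, j] <- x[, j] + x[, j - 1L]
    tm <- cur[active] + x
    keep <- tm <= window
    rows <- factor(row(tm)[keep], levels = seq_len(m))
    new_t <- split(tm[keep], rows)
    trains[active] <- Map(c, trains[active], new_t)
    if (keep_states) {
      new_s <- split(st[keep], rows)
      states[active] <- Map(c, states[active], new_s)
    }
    cur[active] <- tm[, K]
    cur_state[active] <- ifelse(sw[, K], 3L - st[, K], st[, K])
    active <- active[tm[, K] <= window]
    K <- 16L
  }
  out <- spike_train_set(trains, window)
  attr(out, "model") <- model
  if (keep_states) attr(out, "states") <- states
  out
}

# shared renewal accumulation: t0 are first-spike times, draw_fun(m, k)
# returns m*k further i.i.d. ISIs
accumulate_times <- function(t0, n, window, draw_fun, mean_isi) {
  exp_more <- max(1, window / mean_isi)
  K <- max(8L, ceiling(exp_more + 8 * sqrt(exp_more) + 8))
  trains <- rep(list(numeric(0)), n)
  first_in <- t0 <= window
  for (i in which(first_in)) trains[[i]] <- t0[i]
  active <- which(first_in)
  cur <- t0
  while (length(active)) {
    m <- length(active)
    x <- matrix(draw_fun(m, K), m, K)
    for (j in seq_len(K)[-1L]) x[, j] <- x[, j] + x[, j - 1L]
    tm <- cur[active] + x
    keep <- tm <= window
    rows <- factor(row(tm)[keep], levels = seq_len(m))
    trains[active] <- Map(c, trains[active], split(tm[keep], rows))
    cur[active] <- tm[, K]
    active <- active[tm[, K] <= window]
    K <- 16L
  }
  trains
}

#' Rescale the time axis of a spike-train set
#'
#' Multiplies every spike time and the window by `factor`, emulating the
#' same point process observed on a stretched or compressed clock: the
#' intensity becomes \eqn{\lambda/c}. The operational Fano-factor
#' estimator is exactly invariant under this transformation (see
#' [estimate_fano_operational()]); the standard estimator is not.
#'
#' @param set A [spike_train_set()].
#' @param factor Positive scale factor \eqn{c}.
#' @return A [spike_train_set()] on the window `c * w`.
#' @export
rescale_time <- function(set, factor) {
  check_positive(factor, "factor")
  out <- spike_train_set(lapply(set$trains, function(tt) tt * factor),
                         window = set$window * factor)
  attr(out, "model") <- attr(set, "model")
  out
}
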