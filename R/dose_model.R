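#' CRM model specification
#'
#' Specifies the one-parameter logistic dose-inefficacy model
#' `logit(p) = intercept - beta * d` (with `d` the standardised dose), the
#' prior on the slope `beta`, and the discretised support used for
#' posterior quadrature.
#'
#' The intercept is fixed, not estimated: with the default value 5 the
#' probability of inefficacy at dose 0 mg is `plogis(5) ~= 0.993`, encoding
#' the boundary condition that an untreated participant almost surely fails
#' to reach an effective drug concentration. The prior is supported on
#' `beta > 0` only, so the fitted inefficacy curve is always monotonically
#' decreasing in dose.
#'
#' Two diffuse prior families are available:
#' \describe{
#'   \item{`"uniform"`}{flat on `(0, beta_max]` (the default). Its
#'     prior-predictive 90% bands at most doses span nearly the whole
#'     probability range, i.e. the prior is vague in the sense relevant to
#'     the design.}
#'   \item{`"exponential"`}{density `dexp(beta, rate)`, `rate` given in
#'     `prior_params` (default 0.2, prior mean 5), truncated to the support.}
#' }
#'
#' @param intercept Fixed intercept of the logistic curve (default 5).
#' @param prior Prior family on the slope: `"uniform"` or `"exponential"`.
#' @param prior_params Named list of prior parameters; `list(rate = 0.2)` for
#'   the exponential family, ignored for the uniform.
#' @param beta_max Upper bound of the discretised slope support. At the
#'   default 10, even the lowest dose (10 mg) has inefficacy probability
#'   below 0.01, so mass beyond contributes nothing for any realistic
#'   scenario.
#' @param beta_points Number of quadrature points on `(0, beta_max]`
#'   (default 4001; spacing 0.0025).
#' @param estimate Active point-estimate convention for decision rules:
#'   `"mean"` (default) uses the posterior mean of each per-dose inefficacy
#'   probability; `"median"` plugs the posterior median of `beta` into the
#'   curve (the convention used for reporting fitted curves). Both are
#'   stored in every posterior summary; this switch selects which one
#'   drives decisions. The default is the convention that reproduces the
#'   published example realisations' cohort allocations.
#'
#' @return An object of class `crm_model_spec`.
#' @export
model_spec <- function(intercept = 5,
                       prior = c("uniform", "exponential"),
                       prior_params = NULL,
                       beta_max = 10,
                       beta_points = 4001,
                       estimate = c("mean", "median")) {
  prior <- match.arg(prior)
  estimate <- match.arg(estimate)
  if (beta_max <= 0 || beta_points < 10)
    stop("beta_max must be positive and beta_points at least 10")
  if (prior == "exponential") {
    if (is.null(prior_params)) prior_params <- list(rate = 0.2)
    if (is.null(prior_params$rate) || prior_params$rate <= 0)
      stop("exponential prior needs a positive 'rate'")
  }
  structure(
    list(intercept = intercept, prior = prior, prior_params = prior_params,
         beta_max = beta_max, beta_points = as.integer(beta_points),
         estimate = estimate),
    class = "crm_model_spec"
  )
}

# Discretised slope support: beta_points midpoint-rule quadrature nodes on
# (0, beta_max]. Node j sits at the centre of cell ((j-1)h, jh], so the
# cells tile the support exactly and cumulative masses estimate the CDF
# with second-order accuracy even when the posterior piles up at either end.
beta_support <- function(spec) {
  h <- spec$beta_max / spec$beta_points
  seq(h / 2, spec$beta_max - h / 2, length.out = spec$beta_points)
}

log_prior <- function(spec, beta) {
  switch(spec$prior,
         uniform = rep(0, length(beta)),
         exponential = stats::dexp(beta, rate = spec$prior_params$rate,
                                   log = TRUE))
}

#' Probability of inefficacy under the one-parameter logistic curve
#'
#' Evaluates `plogis(intercept - beta * d)` for a standardised dose `d`.
#' The curve is decreasing in both the slope and the dose, and approaches
#' `plogis(intercept)` (~0.993 at the default intercept) as the dose goes
#' to zero.
#'
#' @param beta Slope, `>= 0` (0 is the no-information boundary).
#' @param d Standardised dose, `>= 0`. Vectorised over both arguments.
#' @param intercept Fixed intercept, default 5.
#' @return Probability of inefficacy in (0, 1).
#' @examples
#' inefficacy_probability(1, 5)   # exactly 0.5
#' inefficacy_probability(0, 8)   # ~0.993: no drug effect
#' @export
inefficacy_probability <- function(beta, d, intercept = 5) {
  if (any(d < 0)) stop("standardised dose must be non-negative")
  if (any(beta < 0)) stop("beta must be non-negative")
  stats::plogis(intercept - beta * d)
}

#' Bernoulli log-likelihood of a trial history
#'
#' Sum over participants of the Bernoulli log-density of their binary
#' inefficacy response (`y = 1` ineffective, `y = 0` effective) at the
#' curve's probability for their administered dose.
#'
#' @param history A trial history (see [trial_history()]); may be empty.
#' @param beta Slope value(s); vectorised.
#' @param grid [dose_grid()] used to standardise the administered doses.
#' @param intercept Fixed intercept, default 5.
#' @return Log-likelihood, one value per element of `beta`; 0 for an empty
#'   history.
#' @export
log_likelihood <- function(history, beta, grid = dose_grid(), intercept = 5) {
  if (nrow(history) == 0) return(rep(0, length(beta)))
  d <- standardise_dose(grid, history$dose_mg)
  vapply(beta, function(b) {
    p <- inefficacy_probability(b, d, intercept)
    sum(history$y * log(p) + (1 - history$y) * log1p(-p))
  }, numeric(1))
}

# Precompute what posterior updating needs for a fixed (spec, grid) pair:
# the slope support, log-prior, and per-dose response probabilities (and their
# logs) at every support point. Reused across cohorts within one realisation.
model_cache <- function(spec, grid) {
  beta <- beta_support(spec)
  p <- stats::plogis(spec$intercept - outer(beta, grid$standardised))
  list(beta = beta, lp = log_prior(spec, beta),
       p = p, logp = log(p), log1mp = log1p(-p))
}

# Quantile of a distribution known through quadrature masses w at support
# points x. The cumulative mass at x_j estimates the CDF midway through the
# j-th cell (midpoint correction); the quantile function is read off by
# monotone cubic interpolation over the positive-mass region, so refining
# the support refines the quantile smoothly instead of snapping to grid
# points. Collapses to the step quantile when too few points carry mass.
weighted_quantile <- function(x, w, probs) {
  w <- w / sum(w)
  cw <- cumsum(w) - w / 2
  keep <- w > 0
  xs <- x[keep]
  cs <- cw[keep]
  # drop points whose cumulative mass is indistinguishable in floating point
  inc <- c(TRUE, diff(cs) > 0)
  xs <- xs[inc]
  cs <- cs[inc]
  qf <- if (length(xs) >= 4) {
    stats::splinefun(cs, xs, method = "hyman")
  } else {
    step <- cumsum(w)
    function(q) x[which(step >= q)[1]]
  }
  vapply(probs, function(q) {
    if (q <= cs[1]) return(xs[1])
    if (q >= cs[length(cs)]) return(xs[length(xs)])
    qf(q)
  }, numeric(1))
}

#' Update the posterior over the dose-inefficacy curve
#'
#' Computes the posterior of the slope `beta` by deterministic quadrature on
#' the discretised support: posterior mass at each support point is
#' proportional to the prior density times the Bernoulli likelihood of the
#' accumulated responses. Accumulation is in log space with max-subtraction
#' before exponentiation. With an empty history the prior itself is returned.
#'
#' Because the model is one-dimensional this replaces MCMC exactly (up to
#' grid resolution) and makes every design decision reproducible: the same
#' history always yields the same posterior and hence the same next dose.
#'
#' @param history Trial history ([trial_history()]); possibly empty.
#' @param spec [model_spec()].
#' @param grid [dose_grid()].
#' @param level Credible level for the stored per-dose intervals
#'   (default 0.90).
#' @param cache Internal precomputation; leave `NULL`.
#'
#' @return An object of class `crm_posterior` with elements
#'   `beta_support`, `beta_weights` (normalised masses), `beta_median`, and
#'   `per_dose`, a data frame with per-dose plug-in estimates at the median
#'   (`p_median`), posterior means (`p_mean`) and central credible interval
#'   endpoints (`ci_lo`, `ci_hi`).
#' @export
posterior_update <- function(history, spec = model_spec(), grid = dose_grid(),
                             level = 0.90, cache = NULL) {
  if (is.null(cache)) cache <- model_cache(spec, grid)
  k <- length(grid$actual_mg)
  n1 <- n0 <- numeric(k)
  if (nrow(history) > 0) {
    idx <- match(history$dose_mg, grid$actual_mg)
    if (anyNA(idx)) stop("history contains doses not on the grid")
    n1 <- vapply(seq_len(k), function(j) sum(history$y[idx == j]), numeric(1))
    n0 <- vapply(seq_len(k), function(j) sum(1 - history$y[idx == j]), numeric(1))
  }
  ll <- as.vector(cache$logp %*% n1 + cache$log1mp %*% n0) + cache$lp
  m <- max(ll)
  if (!is.finite(m)) stop("posterior update failed: all masses underflow")
  w <- exp(ll - m)
  w <- w / sum(w)
  beta_med <- weighted_quantile(cache$beta, w, 0.5)
  alpha <- (1 - level) / 2
  beta_ci <- weighted_quantile(cache$beta, w, c(alpha, 1 - alpha))
  d <- grid$standardised
  per_dose <- data.frame(
    dose_mg = grid$actual_mg,
    d_std = d,
    p_median = stats::plogis(spec$intercept - beta_med * d),
    p_mean = as.vector(crossprod(w, cache$p)),
    # curve decreasing in beta: upper beta quantile gives the lower p bound
    ci_lo = stats::plogis(spec$intercept - beta_ci[2] * d),
    ci_hi = stats::plogis(spec$intercept - beta_ci[1] * d)
  )
  structure(
    list(beta_support = cache$beta, beta_weights = w, beta_median = beta_med,
         per_dose = per_dose, level = level, n_obs = nrow(history),
         spec = spec, grid = grid),
    class = "crm_posterior"
  )
}

#' @export
print.crm_posterior <- function(x, ...) {
  cat(sprintf("CRM posterior from %d response(s); beta median %.3f (%s prior)\n",
              x$n_obs, x$beta_median, x$spec$prior))
  print(cbind(x$per_dose[, c("dose_mg", "p_median", "p_mean")],
              round(x$per_dose[, c("ci_lo", "ci_hi")], 3)),
        row.names = FALSE, digits = 3)
  invisible(x)
}

# active per-dose point estimates (named by dose in mg)
point_estimates <- function(post, convention = post$spec$estimate) {
  est <- switch(convention,
                median = post$per_dose$p_median,
                mean = post$per_dose$p_mean,
                stop("unknown estimate convention: ", convention))
  stats::setNames(est, post$per_dose$dose_mg)
}

#' Central credible interval for the inefficacy probability at a dose
#'
#' Maps the central credible interval of the slope through the (monotone)
#' dose-inefficacy curve, giving the equal-tail interval of the probability
#' of inefficacy at the requested dose.
#'
#' @param post A `crm_posterior` from [posterior_update()].
#' @param dose_mg A dose on the grid.
#' @param level Credible level in (0, 1); defaults to the level stored in
#'   `post`.
#' @return Numeric vector `c(lo, hi)`, both in \[0, 1\].
#' @export
credible_interval <- function(post, dose_mg, level = post$level) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  d <- standardise_dose(post$grid, dose_mg)
  alpha <- (1 - level) / 2
  bq <- weighted_quantile(post$beta_support, post$beta_weights,
                          c(alpha, 1 - alpha))
  ival <- stats::plogis(post$spec$intercept - bq * d)
  stats::setNames(sort(ival), c("lo", "hi"))
}

#' Serialise a posterior summary to JSON
#'
#' Writes the per-dose summaries, slope median and model configuration (not
#' the full support/weights vectors) for audit logs.
#'
#' @param post A `crm_posterior`.
#' @param path Optional file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when writing to a file).
#' @export
posterior_to_json <- function(post, path = NULL) {
  obj <- list(beta_median = post$beta_median, level = post$level,
              n_obs = post$n_obs, prior = post$spec$prior,
              prior_params = post$spec$prior_params,
              intercept = post$spec$intercept, per_dose = post$per_dose)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
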