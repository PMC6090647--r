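#' Model reliability: per-variable averaged coefficient of determination
#'
#' Quantifies agreement between an observed and a simulated time course.
#' For each variable j with observations \eqn{y_i} and model values
#' \eqn{\hat y_i}: \eqn{SSE = \sum_i (y_i-\hat y_i)^2},
#' \eqn{SST = \sum_i (y_i-\bar y)^2}, and the variable contributes
#' \eqn{1 - SSE/SST}. The aggregate statistic is the arithmetic mean of the
#' contributions over the m variables compared:
#' \deqn{R^2 = \frac{1}{m}\sum_{j=1}^{m}\left(1-\frac{SSE_j}{SST_j}\right)}
#' Contributions may be negative (model worse than the observed mean).
#' Variables with zero observed variance are excluded with a warning and m
#' reduced accordingly.
#'
#' @param observed,simulated data.frames with a `time_h` column and species
#'   columns (`X_gL`, `S_gL`, ...). The simulated series must cover the
#'   observed time range; model values at observed times are obtained by
#'   linear interpolation (exact when the simulation was evaluated on the
#'   observed grid).
#' @param variables species columns to compare; default: all species columns
#'   present in both inputs
#' @return list with `aggregate` (the averaged R-squared), `per_variable`
#'   (named vector of contributions) and `m` (number of variables used)
#' @export
#' @examples
#' obs <- data.frame(time_h = 1:3, PA_gL = c(1, 2, 3))
#' sim <- data.frame(time_h = 1:3, PA_gL = c(1, 2, 4))
#' coefficient_of_determination(obs, sim)$aggregate # 0.5
coefficient_of_determination <- function(observed, simulated,
                                         variables = NULL) {
  stopifnot(is.data.frame(observed), is.data.frame(simulated),
            "time_h" %in% names(observed), "time_h" %in% names(simulated))
  if (is.null(variables)) {
    variables <- intersect(intersect(names(observed), names(simulated)),
                           paste0(c(state_species(), "V"), "_gL"))
  }
  if (length(variables) == 0L) stop("no variables to compare")
  per <- numeric(0)
  for (v in variables) {
    y <- observed[[v]]
    keep <- is.finite(y)
    y <- y[keep]
    tt <- observed$time_h[keep]
    if (length(y) < 2L) {
      warning("variable ", v, " has fewer than 2 observations; excluded")
      next
    }
    sst <- sum((y - mean(y))^2)
    if (sst == 0) {
      warning("variable ", v, " has zero variance; excluded from R-squared")
      next
    }
    yhat <- stats::approx(simulated$time_h, simulated[[v]], xout = tt,
                          rule = 1)$y
    if (any(!is.finite(yhat))) {
      stop("simulated series does not cover observed times for ", v)
    }
    sse <- sum((y - yhat)^2)
    per[v] <- 1 - sse / sst
  }
  if (length(per) == 0L) stop("no variable with nonzero variance to compare")
  list(aggregate = mean(per), per_variable = per, m = length(per))
}

#' Stacked weighted residuals between data and model
#'
#' Simulates the model from the first observed row and stacks, per species
#' and time point, `(observed - simulated) / scale`. The default scale of
#' each species is its maximum observed value, which balances species of
#' very different magnitude (sucrose near 80 g/L vs pyruvate near 1 g/L).
#' If the simulation fails at a candidate parameter set, a large finite
#' penalty residual vector of the correct length is returned so that
#' optimisers can continue.
#'
#' @param p a [kinetic_parameters()] object (candidate)
#' @param data observed `fermentation_timeseries`-like data.frame with
#'   `time_h` and at least one species column
#' @param weights optional named per-species scale; defaults to
#'   `max(observed)` per species
#' @param initial initial state for the simulation; defaults to the first
#'   observed row (missing species start at 0)
#' @param mode,feed passed to [simulate_fermentation()]
#' @return numeric residual vector of length = total number of finite
#'   observations, with a `"species"` attribute
#' @export
objective_residuals <- function(p, data, weights = NULL, initial = NULL,
                                mode = "batch", feed = NULL) {
  spec_cols <- intersect(names(data), paste0(state_species(), "_gL"))
  if (length(spec_cols) == 0L) stop("data contains no species columns")
  if (nrow(data) < 2L) stop("data must contain at least 2 time points")
  if (is.null(weights)) {
    weights <- vapply(spec_cols, function(v) {
      mx <- max(data[[v]], na.rm = TRUE)
      if (!is.finite(mx) || mx <= 0) 1 else mx
    }, numeric(1))
  }
  if (is.null(initial)) initial <- initial_state_from_data(data, mode)
  n_per <- vapply(spec_cols, function(v) sum(is.finite(data[[v]])),
                  integer(1))
  sim <- tryCatch(
    simulate_fermentation(initial, p, times = data$time_h, mode = mode,
                          feed = feed),
    error = function(e) NULL)
  if (is.null(sim)) {
    res <- rep(1e6, sum(n_per))
    attr(res, "species") <- rep(spec_cols, n_per)
    attr(res, "penalised") <- TRUE
    return(res)
  }
  res <- numeric(0)
  lab <- character(0)
  for (v in spec_cols) {
    keep <- is.finite(data[[v]])
    res <- c(res, (data[[v]][keep] - sim[[v]][keep]) / weights[[v]])
    lab <- c(lab, rep(v, sum(keep)))
  }
  attr(res, "species") <- lab
  res
}

initial_state_from_data <- function(data, mode = "batch") {
  first <- data[1L, , drop = FALSE]
  get0 <- function(col) {
    v <- first[[col]]
    if (is.null(v) || !is.finite(v)) 0 else v
  }
  fermentation_state(X = get0("X_gL"), S = get0("S_gL"), PA = get0("PA_gL"),
                     PYR = get0("PYR_gL"), AA = get0("AA_gL"),
                     SA = get0("SA_gL"),
                     V = if (mode == "fedbatch") {
                       v <- first[["V_L"]]
                       if (is.null(v) || !is.finite(v)) 1 else v
                     } else NA_real_)
}

#' Fit kinetic parameters to an observed time course
#'
#' Nonlinear least squares on the stacked weighted residuals of
#' [objective_residuals()], using the Levenberg-Marquardt implementation in
#' [minpack.lm::nls.lm] with box constraints and finite-difference
#' Jacobians. To mitigate local minima, the optimisation is restarted from
#' `n_starts` multiplicatively jittered copies of the initial guess
#' (seeded, deterministic) and the best final objective is kept.
#'
#' `Ks` is typically held fixed (estimated separately from serum-bottle
#' Monod data via [fit_monod_ks()]), mirroring the two-stage estimation
#' workflow this model family uses.
#'
#' @param data observed time course (data.frame with `time_h` + species)
#' @param initial_guess a [kinetic_parameters()] starting point
#' @param bounds optional list with named numeric vectors `lower` and
#'   `upper` (full parameter vectors); defaults to
#'   [default_parameter_bounds()]
#' @param fixed character vector of parameter names held at their
#'   `initial_guess` value (commonly `"Ks"`)
#' @param mode,feed,weights,initial passed to [objective_residuals()]
#' @param n_starts number of jittered restarts (>= 1)
#' @param seed RNG seed for the jitter
#' @param control passed to [minpack.lm::nls.lm.control]
#' @return A `fermentation_fit`: list with elements `parameters`
#'   (kinetic_parameters at the optimum), `fixed_mask`, `per_variable_r2`,
#'   `aggregate_r2`, `residuals`, `objective` (final weighted SSE),
#'   `convergence` (logical), `iterations`, `n_obs`.
#' @export
fit_parameters <- function(data, initial_guess, bounds = NULL,
                           fixed = character(), mode = "batch", feed = NULL,
                           weights = NULL, initial = NULL,
                           n_starts = 5L, seed = 1L,
                           control = minpack.lm::nls.lm.control(maxiter = 200)) {
  validate_kinetic_parameters(initial_guess)
  if (nrow(data) < 2L) stop("need at least 2 time points to fit")
  all_names <- kinetic_parameter_names()
  fixed <- intersect(fixed, all_names)
  free <- setdiff(all_names, fixed)
  if (is.null(bounds)) bounds <- default_parameter_bounds()
  lower <- bounds$lower[free]
  upper <- bounds$upper[free]
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    stop("bounds must be finite for all free parameters")
  }
  p0 <- as.numeric_named(initial_guess)
  if (is.null(weights)) {
    spec_cols <- intersect(names(data), paste0(state_species(), "_gL"))
    weights <- vapply(spec_cols, function(v) {
      mx <- max(data[[v]], na.rm = TRUE)
      if (!is.finite(mx) || mx <= 0) 1 else mx
    }, numeric(1))
  }
  n_obs <- length(objective_residuals(make_params(p0[free], p0, free),
                                      data, weights, initial, mode, feed))
  if (n_obs <= length(free)) {
    stop("fewer observations (", n_obs, ") than free parameters (",
         length(free), ")")
  }

  fn <- function(theta) {
    p <- make_params(theta, p0, free)
    objective_residuals(p, data, weights = weights, initial = initial,
                        mode = mode, feed = feed)
  }

  set.seed(as.integer(seed))
  starts <- list(pmin(pmax(p0[free], lower), upper))
  if (n_starts > 1L) {
    for (k in seq_len(n_starts - 1L)) {
      jit <- p0[free] * stats::runif(length(free), 0.7, 1.4)
      starts[[k + 1L]] <- pmin(pmax(jit, lower), upper)
    }
  }

  best <- NULL
  for (th0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = th0, lower = lower, upper = upper,
                         fn = fn, control = control),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("all optimisation starts failed")

  p_hat <- make_params(best$par, p0, free)
  sim <- simulate_fermentation(
    if (is.null(initial)) initial_state_from_data(data, mode) else initial,
    p_hat, times = data$time_h, mode = mode, feed = feed)
  r2 <- coefficient_of_determination(data, sim)
  structure(list(parameters = p_hat,
                 fixed_mask = stats::setNames(all_names %in% fixed,
                                              all_names),
                 per_variable_r2 = r2$per_variable,
                 aggregate_r2 = r2$aggregate,
                 residuals = fn(best$par),
                 objective = best$deviance,
                 convergence = best$info %in% 1:4,
                 iterations = best$niter,
                 n_obs = n_obs),
            class = "fermentation_fit")
}

make_params <- function(theta, p0, free) {
  p <- p0
  p[free] <- theta
  structure(p, class = "kinetic_parameters")
}

#' @rdname fit_parameters
#' @export
default_parameter_bounds <- function() {
  nm <- kinetic_parameter_names()
  lower <- stats::setNames(rep(1e-6, length(nm)), nm)
  upper <- stats::setNames(rep(10, length(nm)), nm)
  lower[c("beta_pa", "beta_pyr", "beta_aa", "beta_sa")] <- -1
  lower["ms"] <- 0
  upper[c("Ks", "kipa", "kiaa")] <- c(50, 200, 400)
  upper["Yxs"] <- 1.5
  upper["rs_max"] <- 5
  list(lower = lower, upper = upper)
}

#' @export
print.fermentation_fit <- function(x, ...) {
  cat(sprintf("Kinetic model fit: %d observations, converged: %s\n",
              x$n_obs, x$convergence))
  cat(sprintf("  weighted SSE %.4g, aggregate R-squared %.4f\n",
              x$objective, x$aggregate_r2))
  cat("  per-variable R-squared:\n")
  print(round(x$per_variable_r2, 4))
  free <- names(x$fixed_mask)[!x$fixed_mask]
  cat("  free parameters:\n")
  print(round(as.numeric_named(x$parameters)[free], 5))
  invisible(x)
}

#' Estimate Monod constants from rate-vs-substrate data
#'
#' Fits \eqn{r = rs_{max} S / (K_s + S)} to uptake (or growth) rates
#' measured at several substrate levels, the serum-bottle design used to
#' pin down `Ks` before the full time-course fit (products are ~0 in those
#' cultures, so no inhibition terms enter). Nonlinear least squares via
#' [minpack.lm::nlsLM].
#'
#' @param substrate_levels substrate concentrations (g/L), >= 3 distinct
#'   values
#' @param rates matching specific rates (g / g DCW / h), positive
#' @return list with `Ks`, `rs_max`, their standard errors (`se_Ks`,
#'   `se_rs_max`) and the underlying `nls` fit object (`fit`, NULL in the
#'   degenerate saturated case)
#' @export
#' @examples
#' S <- c(1, 2, 5, 10, 20, 50)
#' r <- 0.8 * S / (5 + S)
#' fit_monod_ks(S, r)[c("Ks", "rs_max")]
fit_monod_ks <- function(substrate_levels, rates) {
  S <- as.numeric(substrate_levels)
  r <- as.numeric(rates)
  stopifnot(length(S) == length(r))
  if (length(unique(S)) < 3L) stop("need >= 3 distinct substrate levels")
  if (any(r[S > 0] <= 0)) stop("rates must be positive at positive S")
  o <- order(S)
  if (stats::sd(r) < 1e-12 * max(abs(r))) {
    # fully saturated regime: any Ks << min(S) fits; report the limit
    warning("rates constant across substrate levels: Ks is not ",
            "identifiable, reporting Ks -> 0")
    return(list(Ks = 0, rs_max = mean(r), se_Ks = Inf,
                se_rs_max = stats::sd(r) / sqrt(length(r)), fit = NULL))
  }
  if (all(diff(r[o]) <= 0)) {
    warning("rates do not increase with substrate: no saturation signal; ",
            "estimates unreliable")
  }
  rmax0 <- max(r) * 1.05
  ks0 <- max(S[which.min(abs(r - rmax0 / 2))], 1e-3)
  df <- data.frame(S = S, r = r)
  fit <- minpack.lm::nlsLM(r ~ rs_max * S / (Ks + S), data = df,
                           start = list(rs_max = rmax0, Ks = ks0),
                           lower = c(rs_max = 1e-9, Ks = 1e-9),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) c(rs_max = NA_real_, Ks = NA_real_))
  list(Ks = unname(est[["Ks"]]), rs_max = unname(est[["rs_max"]]),
       se_Ks = unname(se[["Ks"]]), se_rs_max = unname(se[["rs_max"]]),
       fit = fit)
}
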