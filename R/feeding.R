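#' Specification of a constant-feed design problem
#'
#' Collects everything needed to search for a feeding strategy: the
#' candidate grids for the feed rate and feed window, the feed sucrose
#' concentration, the path constraint on broth sucrose (the design rule is
#' high propionic acid production with sugar accumulation kept below a
#' ceiling, 40 g/L by default), the initial state, the kinetic parameters
#' and the simulation horizon.
#'
#' @param F_grid candidate feed rates (L/h)
#' @param t_start_grid,t_end_grid candidate window boundaries (h)
#' @param So feed sucrose concentration(s) (g/L); scalar or grid
#' @param S_max sugar-accumulation ceiling (g/L), > 0
#' @param initial a [fermentation_state()] with `V > 0`
#' @param parameters a [kinetic_parameters()] object
#' @param horizon simulation horizon (h)
#' @param dense_dt output step (h) on which the path constraint is checked;
#'   the constraint is enforced on this dense grid, not just at solver
#'   steps
#' @return object of class `"feed_design_spec"`
#' @export
feed_design_spec <- function(F_grid, t_start_grid, t_end_grid, So,
                             S_max = 40, initial, parameters,
                             horizon = 120, dense_dt = 0.1) {
  stopifnot(S_max > 0, length(F_grid) > 0, length(t_start_grid) > 0,
            length(t_end_grid) > 0, all(So >= 0), horizon > 0,
            dense_dt > 0)
  if (min(t_start_grid) >= max(t_end_grid)) {
    stop("grids admit no window with t_start < t_end")
  }
  if (max(t_end_grid) > horizon) stop("t_end grid exceeds the horizon")
  validate_kinetic_parameters(parameters)
  st <- as_state(initial, fedbatch = TRUE)
  structure(list(F_grid = sort(unique(F_grid)),
                 t_start_grid = sort(unique(t_start_grid)),
                 t_end_grid = sort(unique(t_end_grid)),
                 So = sort(unique(So)), S_max = S_max,
                 initial = st, parameters = parameters,
                 horizon = horizon, dense_dt = dense_dt),
            class = "feed_design_spec")
}

#' Evaluate one feeding candidate
#'
#' Simulates the fed-batch model under the candidate profile over the
#' design horizon on the dense output grid and reports the final propionic
#' acid titre, the maximum sucrose concentration reached, and feasibility
#' (sucrose never above `S_max` at any output point). A candidate whose
#' simulation fails is reported infeasible.
#'
#' @param candidate a [feed_profile()]
#' @param spec a [feed_design_spec()]
#' @return list with `final_pa` (g/L), `max_s` (g/L), `feasible` (logical)
#'   and `diagnostic` (character, non-empty on simulation failure)
#' @export
evaluate_feed_candidate <- function(candidate, spec) {
  stopifnot(inherits(candidate, "feed_profile"),
            inherits(spec, "feed_design_spec"))
  times <- seq(0, spec$horizon, by = spec$dense_dt)
  if (times[length(times)] < spec$horizon) times <- c(times, spec$horizon)
  sim <- tryCatch(
    simulate_fermentation(spec$initial, spec$parameters, times,
                          mode = "fedbatch", feed = candidate),
    error = function(e) e)
  if (inherits(sim, "error")) {
    return(list(final_pa = NA_real_, max_s = NA_real_, feasible = FALSE,
                diagnostic = conditionMessage(sim)))
  }
  max_s <- max(sim$S_gL)
  list(final_pa = sim$PA_gL[nrow(sim)], max_s = max_s,
       feasible = max_s <= spec$S_max, diagnostic = "")
}

#' Exhaustive search for the best constant-rate feed
#'
#' Evaluates every single-segment constant-rate candidate on the spec's
#' grids and returns the feasible candidate with the highest final
#' propionic acid titre. Ties are broken deterministically by lower total
#' fed sucrose mass, then by lower feed rate.
#'
#' @param spec a [feed_design_spec()]
#' @return list with `best` (a [feed_profile()], or NULL if no candidate is
#'   feasible), `best_eval` (its evaluation) and `ranking` (data.frame of
#'   all candidates with columns `F`, `t_start`, `t_end`, `So`,
#'   `final_pa`, `max_s`, `fed_sucrose_g`, `feasible`, sorted feasible
#'   first, then decreasing final PA)
#' @export
design_constant_feed <- function(spec) {
  stopifnot(inherits(spec, "feed_design_spec"))
  grid <- expand.grid(F = spec$F_grid, t_start = spec$t_start_grid,
                      t_end = spec$t_end_grid, So = spec$So,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[grid$t_start < grid$t_end, , drop = FALSE]
  if (nrow(grid) == 0L) stop("candidate grid is empty")
  res <- lapply(seq_len(nrow(grid)), function(i) {
    prof <- feed_profile(data.frame(t_start = grid$t_start[i],
                                    t_end = grid$t_end[i],
                                    F = grid$F[i]),
                         So = grid$So[i])
    evaluate_feed_candidate(prof, spec)
  })
  grid$final_pa <- vapply(res, `[[`, numeric(1), "final_pa")
  grid$max_s <- vapply(res, `[[`, numeric(1), "max_s")
  grid$fed_sucrose_g <- grid$F * (grid$t_end - grid$t_start) * grid$So
  grid$feasible <- vapply(res, `[[`, logical(1), "feasible")
  o <- order(!grid$feasible, -grid$final_pa, grid$fed_sucrose_g, grid$F)
  ranking <- grid[o, , drop = FALSE]
  rownames(ranking) <- NULL
  if (!any(ranking$feasible)) {
    warning("no feasible candidate on the grid")
    return(list(best = NULL, best_eval = NULL, ranking = ranking))
  }
  top <- ranking[ranking$feasible, , drop = FALSE][1L, ]
  best <- feed_profile(data.frame(t_start = top$t_start, t_end = top$t_end,
                                  F = top$F), So = top$So)
  list(best = best,
       best_eval = list(final_pa = top$final_pa, max_s = top$max_s,
                        feasible = TRUE, diagnostic = ""),
       ranking = ranking)
}
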