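#' Convert absorbance to dry cell weight concentration
#'
#' Linear conversion of A600 absorbance to biomass (g DCW/L). The strain
#' factors bundled with the package are 0.29 (g DCW/L per A600 unit) for
#' P. acidipropionici ATCC 55737 and 0.25 for the shuffled strain WGS7.
#'
#' @param a600 absorbance at 600 nm, >= 0
#' @param factor conversion factor (g DCW/L per A600 unit), > 0; see
#'   [dcw_factor()]
#' @return biomass in g DCW/L; vectorised
#' @export
#' @examples
#' od_to_dcw(0.3, dcw_factor("WGS7")) # inoculation density 0.075 g/L
od_to_dcw <- function(a600, factor) {
  if (any(a600 < 0)) stop("absorbance must be >= 0")
  if (any(factor <= 0)) stop("conversion factor must be > 0")
  a600 * factor
}

#' @rdname od_to_dcw
#' @param strain `"ATCC55737"` or `"WGS7"`
#' @export
dcw_factor <- function(strain = c("ATCC55737", "WGS7")) {
  strain <- match.arg(strain)
  c(ATCC55737 = 0.29, WGS7 = 0.25)[[strain]]
}

#' Locate the mid-exponential phase of a growth curve
#'
#' Slides a window of `width` consecutive points over the biomass series
#' and returns the window maximising the R-squared of the linear fit of
#' `ln(biomass)` against time, among windows with positive slope. Ties are
#' broken by taking the earliest such window. Windows containing
#' non-positive biomass are skipped.
#'
#' @param times sampling times (h), strictly increasing, >= 5 points
#' @param biomass biomass (g DCW/L or A600), same length
#' @param width window width in points (default 4)
#' @return numeric `c(t_lo, t_hi)` with an `"indices"` attribute giving the
#'   window rows
#' @export
midexponential_window <- function(times, biomass, width = 4L) {
  stopifnot(length(times) == length(biomass), width >= 2L)
  if (length(times) < 5L) stop("need at least 5 points")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  n <- length(times)
  if (width > n) stop("window wider than the series")
  best <- NULL
  for (i in seq_len(n - width + 1L)) {
    idx <- i:(i + width - 1L)
    x <- biomass[idx]
    if (any(!is.finite(x)) || any(x <= 0)) next
    fit <- stats::lm(log(x) ~ times[idx])
    slope <- stats::coef(fit)[[2L]]
    if (!is.finite(slope) || slope <= 0) next
    y <- log(x)
    sst <- sum((y - mean(y))^2)
    if (sst <= 0) next
    r2 <- 1 - sum(stats::resid(fit)^2) / sst
    if (is.null(best) || r2 > best$r2 + 1e-12) {
      best <- list(i = i, idx = idx, r2 = r2, slope = slope)
    }
  }
  if (is.null(best)) stop("no exponential phase: no window with positive slope")
  structure(c(t_lo = times[best$idx[1L]],
              t_hi = times[best$idx[length(best$idx)]]),
            indices = best$idx, slope = best$slope)
}

#' Specific growth rate at mid-exponential phase
#'
#' Slope of `ln(biomass)` versus time over the window selected by
#' [midexponential_window()]. With exactly two points the slope is the
#' log-difference quotient.
#'
#' @inheritParams midexponential_window
#' @return specific growth rate mu (1/h)
#' @export
#' @examples
#' t <- seq(0, 20, 2)
#' specific_growth_rate_midexp(t, 0.1 * exp(0.25 * t)) # 0.25
specific_growth_rate_midexp <- function(times, biomass, width = 4L) {
  if (length(times) == 2L) {
    if (any(biomass <= 0)) stop("biomass must be positive")
    return(diff(log(biomass)) / diff(times))
  }
  win <- midexponential_window(times, biomass, width = width)
  idx <- attr(win, "indices")
  unname(stats::coef(stats::lm(log(biomass[idx]) ~ times[idx]))[[2L]])
}

#' Product yield on substrate
#'
#' Total product formed over total substrate consumed, both in grams.
#'
#' @param total_product grams of product formed
#' @param consumed_substrate grams of substrate consumed, > 0
#' @return yield (g/g)
#' @export
product_yield <- function(total_product, consumed_substrate) {
  if (consumed_substrate <= 0) stop("consumed substrate must be > 0")
  total_product / consumed_substrate
}

#' Product yield from a fermentation time course
#'
#' Computes total product and consumed substrate in mass units between the
#' first and last sample. At constant volume the totals are concentration
#' differences times the volume; in fed-batch the endpoint masses use
#' `concentration * volume` and the substrate balance credits the sucrose
#' mass delivered by the feed.
#'
#' @param series a trajectory data.frame (`time_h`, `PA_gL`, `S_gL`,
#'   optionally `V_L`)
#' @param product,substrate column names (default PA on sucrose)
#' @param feed optional [feed_profile()]; when supplied with `V_L` the fed
#'   substrate mass `integral(F * So dt)` is added to the consumed total
#' @param volume assumed constant volume (L) when `V_L` is absent
#' @return yield (g/g)
#' @export
product_yield_timeseries <- function(series, product = "PA_gL",
                                     substrate = "S_gL", feed = NULL,
                                     volume = 1) {
  stopifnot(all(c("time_h", product, substrate) %in% names(series)))
  n <- nrow(series)
  has_v <- "V_L" %in% names(series)
  V0 <- if (has_v) series$V_L[1L] else volume
  Vn <- if (has_v) series$V_L[n] else volume
  prod_mass <- series[[product]][n] * Vn - series[[product]][1L] * V0
  fed_mass <- 0
  if (!is.null(feed)) {
    seg <- feed$segments
    t0 <- series$time_h[1L]; t1 <- series$time_h[n]
    dur <- pmax(pmin(seg$t_end, t1) - pmax(seg$t_start, t0), 0)
    fed_mass <- sum(seg$F * dur) * feed$So
  }
  cons_mass <- series[[substrate]][1L] * V0 + fed_mass -
    series[[substrate]][n] * Vn
  product_yield(prod_mass, cons_mass)
}

#' Ratio of total organic acid production
#'
#' Ratio of total propionic acid to a by-product acid (acetic or succinic)
#' over a whole run; higher ratios mean less by-product per unit PA.
#'
#' @param total_pa total PA produced (g or g/L at constant volume)
#' @param total_other total by-product produced (same units)
#' @return ratio (g/g); `Inf` with a warning when the by-product total is 0
#' @export
#' @examples
#' acid_ratio(44.2, 8.1)
acid_ratio <- function(total_pa, total_other) {
  if (total_pa < 0 || total_other < 0) stop("totals must be >= 0")
  if (total_other == 0) {
    warning("by-product total is zero: ratio reported as Inf")
    return(Inf)
  }
  total_pa / total_other
}

#' Volumetric productivity over a fixed interval
#'
#' Propionic acid accumulated per litre per hour between `interval[1]` and
#' `interval[2]` (default 15-30 h, the comparison window used for strain
#' characterisation). Endpoint concentrations are obtained by linear
#' interpolation between bracketing samples.
#'
#' @param series trajectory data.frame with `time_h` and `PA_gL`
#' @param interval numeric length-2, hours, inside the sampled range
#' @return Pv (g/L/h)
#' @export
volumetric_productivity <- function(series, interval = c(15, 30)) {
  stopifnot(all(c("time_h", "PA_gL") %in% names(series)))
  if (length(interval) != 2L || interval[1L] >= interval[2L]) {
    stop("interval must be (t_lo, t_hi) with t_lo < t_hi")
  }
  rng <- range(series$time_h)
  if (interval[1L] < rng[1L] || interval[2L] > rng[2L]) {
    stop("interval outside the sampled time range")
  }
  pa <- stats::approx(series$time_h, series$PA_gL, xout = interval)$y
  (pa[2L] - pa[1L]) / (interval[2L] - interval[1L])
}

#' Specific rate from the species-biomass correlation
#'
#' Mid-exponential specific consumption (sucrose) or production (PA) rate,
#' computed as the specific growth rate times the linear correlation
#' (regression slope) of the species concentration with biomass over the
#' mid-exponential window. Reported as a positive magnitude for both
#' consumption and production.
#'
#' @param series trajectory data.frame with `time_h`, `X_gL` and the
#'   species column
#' @param species column name, e.g. `"S_gL"` or `"PA_gL"`
#' @param mu specific growth rate (1/h); defaults to
#'   [specific_growth_rate_midexp()] on the series
#' @param width mid-exponential window width (points)
#' @return specific rate (g / g DCW / h), positive magnitude
#' @export
specific_rate_by_correlation <- function(series, species, mu = NULL,
                                         width = 4L) {
  stopifnot(all(c("time_h", "X_gL", species) %in% names(series)))
  win <- midexponential_window(series$time_h, series$X_gL, width = width)
  idx <- attr(win, "indices")
  if (length(idx) < 3L) stop("mid-exponential window needs >= 3 points")
  x <- series$X_gL[idx]
  y <- series[[species]][idx]
  if (stats::sd(x) < 1e-12) stop("biomass constant over the window")
  if (is.null(mu)) {
    mu <- unname(stats::coef(stats::lm(log(x) ~ series$time_h[idx]))[[2L]])
  }
  slope <- unname(stats::coef(stats::lm(y ~ x))[[2L]])
  abs(slope) * mu
}

#' Summarise fermentation performance
#'
#' One-call computation of the performance parameters used to compare
#' strains: mid-exponential specific growth rate, PA yield on sucrose,
#' PA:AA and PA:SA ratios, volumetric productivity over the stated
#' interval, specific sucrose uptake and PA production rates, and the
#' final PA titre.
#'
#' @param series trajectory data.frame (`time_h`, `X_gL`, `S_gL`, `PA_gL`,
#'   `AA_gL`, `SA_gL`, optionally `V_L`)
#' @param interval productivity interval (h), default `c(15, 30)`
#' @param feed optional [feed_profile()] for fed-batch yield accounting
#' @param dcw_factor_used recorded in the summary (metadata; `NA` when the
#'   series is already in g DCW/L)
#' @param width mid-exponential window width
#' @return object of class `"fermentation_summary"` (a named list)
#' @export
fermentation_summary <- function(series, interval = c(15, 30), feed = NULL,
                                 dcw_factor_used = NA_real_, width = 4L) {
  n <- nrow(series)
  mu <- specific_growth_rate_midexp(series$time_h, series$X_gL,
                                    width = width)
  yps <- product_yield_timeseries(series, feed = feed)
  dpa <- series$PA_gL[n] - series$PA_gL[1L]
  daa <- series$AA_gL[n] - series$AA_gL[1L]
  dsa <- series$SA_gL[n] - series$SA_gL[1L]
  structure(list(
    mu = mu,
    Yps = yps,
    ratio_pa_aa = acid_ratio(dpa, daa),
    ratio_pa_sa = acid_ratio(dpa, dsa),
    Pv = volumetric_productivity(series, interval = interval),
    interval = interval,
    qs = specific_rate_by_correlation(series, "S_gL", mu = mu,
                                      width = width),
    qp = specific_rate_by_correlation(series, "PA_gL", mu = mu,
                                      width = width),
    final_pa = series$PA_gL[n],
    dcw_factor = dcw_factor_used),
    class = "fermentation_summary")
}

#' @export
print.fermentation_summary <- function(x, ...) {
  cat("Fermentation performance summary:\n")
  cat(sprintf("  mu       %.4f 1/h (mid-exponential)\n", x$mu))
  cat(sprintf("  Yps      %.3f g/g\n", x$Yps))
  cat(sprintf("  PA:AA    %.2f g/g\n", x$ratio_pa_aa))
  cat(sprintf("  PA:SA    %.2f g/g\n", x$ratio_pa_sa))
  cat(sprintf("  Pv       %.3f g/L/h over %g-%g h\n", x$Pv,
              x$interval[1L], x$interval[2L]))
  cat(sprintf("  qs       %.3f g/gDCW/h\n", x$qs))
  cat(sprintf("  qp       %.3f g/gDCW/h\n", x$qp))
  cat(sprintf("  final PA %.2f g/L\n", x$final_pa))
  invisible(x)
}
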