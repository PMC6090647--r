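#' Kinetic parameter set for the propionic acid fermentation model
#'
#' Constructs and validates the full parameter vector of the non-structured
#' batch/fed-batch kinetic model. Substrate uptake follows Monod kinetics in
#' sucrose with hyperbolic product inhibition by propionic (PA) and acetic
#' (AA) acid; growth is tied to uptake through the biomass yield `Yxs` and a
#' maintenance coefficient `ms`; each organic acid is produced by a
#' Luedeking-Piret law with a growth-associated coefficient (`K1`, `K2`,
#' `K4`, `K6`) and a non-growth-associated rate (`beta_*`). Pyruvate is
#' additionally drained at a saturable rate (`K3`, half-saturation `K_pyr`)
#' and rerouted to acetate (`K5`) and succinate (`K7`).
#'
#' @param rs_max maximal specific sucrose uptake rate (g sucrose / g DCW / h)
#' @param Ks sucrose half-saturation constant (g/L)
#' @param kipa propionic acid inhibition constant (g/L)
#' @param kiaa acetic acid inhibition constant (g/L)
#' @param Yxs biomass yield on sucrose (g DCW / g sucrose), in (0, 1.5]
#' @param ms maintenance coefficient (g sucrose / g DCW / h), >= 0
#' @param K1,K2,K4,K6 growth-associated production coefficients for PA,
#'   pyruvate, AA and succinate (g product / g DCW), >= 0
#' @param beta_pa,beta_pyr,beta_aa,beta_sa non-growth-associated production
#'   rates (g product / g DCW / h); may be negative (net non-growth
#'   consumption), bounded below at -1
#' @param K3 maximal specific pyruvate consumption rate (g / g DCW / h), >= 0
#' @param K5,K7 pyruvate-to-acetate and pyruvate-to-succinate conversion
#'   rates (g / g DCW / h), >= 0
#' @param K_pyr pyruvate half-saturation constant (g/L), > 0
#'
#' @return A named numeric vector of class `"kinetic_parameters"`.
#' @seealso [reference_parameters()] for calibrated example sets,
#'   [batch_derivatives()], [simulate_fermentation()]
#' @export
#' @examples
#' p <- reference_parameters("wgs7")
#' p[["rs_max"]]
kinetic_parameters <- function(rs_max, Ks, kipa, kiaa, Yxs, ms,
                               K1, beta_pa, K2, beta_pyr, K3, K_pyr,
                               K4, beta_aa, K5, K6, beta_sa, K7) {
  p <- c(rs_max = rs_max, Ks = Ks, kipa = kipa, kiaa = kiaa,
         Yxs = Yxs, ms = ms,
         K1 = K1, beta_pa = beta_pa,
         K2 = K2, beta_pyr = beta_pyr, K3 = K3, K_pyr = K_pyr,
         K4 = K4, beta_aa = beta_aa, K5 = K5,
         K6 = K6, beta_sa = beta_sa, K7 = K7)
  validate_kinetic_parameters(p)
  structure(p, class = "kinetic_parameters")
}

#' @rdname kinetic_parameters
#' @param p object to validate
#' @export
validate_kinetic_parameters <- function(p) {
  required <- kinetic_parameter_names()
  missing <- setdiff(required, names(p))
  if (length(missing) > 0L) {
    stop("missing kinetic parameters: ", paste(missing, collapse = ", "))
  }
  p <- as.numeric_named(p)
  if (any(!is.finite(p))) stop("kinetic parameters must be finite")
  strictly_pos <- c("rs_max", "Ks", "kipa", "kiaa", "K_pyr")
  bad <- strictly_pos[p[strictly_pos] <= 0]
  if (length(bad) > 0L) {
    stop("parameters must be > 0: ", paste(bad, collapse = ", "))
  }
  if (p[["Yxs"]] <= 0 || p[["Yxs"]] > 1.5) {
    stop("Yxs must lie in (0, 1.5]")
  }
  if (p[["ms"]] < 0) stop("ms must be >= 0")
  nonneg <- c("K1", "K2", "K3", "K4", "K5", "K6", "K7")
  bad <- nonneg[p[nonneg] < 0]
  if (length(bad) > 0L) {
    stop("parameters must be >= 0: ", paste(bad, collapse = ", "))
  }
  betas <- c("beta_pa", "beta_pyr", "beta_aa", "beta_sa")
  if (any(p[betas] < -1)) {
    stop("beta terms are bounded below at -1 g/g/h")
  }
  # the equations do not couple the pyruvate drain to the AA/SA gain
  # stoichiometrically; flag the physically odd case without refusing it
  if (p[["K3"]] < p[["K5"]] + p[["K7"]]) {
    warning("K3 < K5 + K7: pyruvate-derived AA/SA exceeds pyruvate drained")
  }
  invisible(TRUE)
}

#' @rdname kinetic_parameters
#' @export
kinetic_parameter_names <- function() {
  c("rs_max", "Ks", "kipa", "kiaa", "Yxs", "ms",
    "K1", "beta_pa", "K2", "beta_pyr", "K3", "K_pyr",
    "K4", "beta_aa", "K5", "K6", "beta_sa", "K7")
}

# coerce a named numeric-ish vector/list, preserving names
as.numeric_named <- function(x) {
  out <- vapply(as.list(x), function(v) as.numeric(v)[1L], numeric(1))
  out
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat("Kinetic parameters (g, L, h units):\n")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Instantaneous fermentation state
#'
#' Bundles biomass and the five tracked metabolite concentrations, plus the
#' broth volume for fed-batch operation. All concentrations are g/L (biomass
#' as g dry cell weight per litre); volume in litres.
#'
#' @param X biomass (g DCW/L)
#' @param S sucrose (g/L)
#' @param PA propionic acid (g/L)
#' @param PYR pyruvic acid (g/L)
#' @param AA acetic acid (g/L)
#' @param SA succinic acid (g/L)
#' @param V broth volume (L); required (and > 0) only for fed-batch use
#' @return Named numeric vector of class `"fermentation_state"`.
#' @export
#' @examples
#' fermentation_state(X = 0.075, S = 80)
fermentation_state <- function(X, S, PA = 0, PYR = 0, AA = 0, SA = 0,
                               V = NA_real_) {
  st <- c(X = X, S = S, PA = PA, PYR = PYR, AA = AA, SA = SA, V = V)
  conc <- st[c("X", "S", "PA", "PYR", "AA", "SA")]
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("state concentrations must be finite and >= 0")
  }
  if (!is.na(V) && V <= 0) stop("volume V must be > 0")
  structure(st, class = "fermentation_state")
}

state_species <- function() c("X", "S", "PA", "PYR", "AA", "SA")

#' Piecewise-constant feed profile
#'
#' Describes a fed-batch feeding strategy as an ordered set of
#' non-overlapping time segments with constant volumetric feed rate, plus
#' the sucrose concentration of the feed solution. Outside all segments the
#' feed rate is zero.
#'
#' @param segments data.frame with columns `t_start`, `t_end` (h) and
#'   `F` (L/h); segments must be non-overlapping with `t_start < t_end`
#'   and `F >= 0`
#' @param So feed sucrose concentration (g/L), >= 0
#' @param medium_factor optional metadata: concentration multiple of the
#'   base medium (e.g. 5 for a fivefold-concentrated feed)
#' @return Object of class `"feed_profile"`.
#' @export
#' @examples
#' # constant 0.0066 L/h of a 350 g/L sucrose feed between 40 h and 64 h
#' feed_profile(data.frame(t_start = 40, t_end = 64, F = 0.0066), So = 350)
feed_profile <- function(segments, So, medium_factor = NA_real_) {
  stopifnot(is.data.frame(segments),
            all(c("t_start", "t_end", "F") %in% names(segments)))
  if (nrow(segments) > 0L) {
    if (any(segments$t_start >= segments$t_end)) {
      stop("feed segments need t_start < t_end")
    }
    if (any(segments$F < 0)) stop("feed rates must be >= 0")
    o <- order(segments$t_start)
    segments <- segments[o, , drop = FALSE]
    if (nrow(segments) > 1L &&
        any(segments$t_start[-1L] < segments$t_end[-nrow(segments)])) {
      stop("feed segments overlap")
    }
  }
  if (!is.finite(So) || So < 0) stop("So must be finite and >= 0")
  structure(list(segments = segments, So = So,
                 medium_factor = medium_factor),
            class = "feed_profile")
}

#' @rdname feed_profile
#' @param profile a `feed_profile`
#' @param t time(s) in h
#' @return `feed_rate()`: feed rate F(t) in L/h (vectorised over `t`).
#'   Segment ends are half-open: the rate applies on `[t_start, t_end)`.
#' @export
feed_rate <- function(profile, t) {
  stopifnot(inherits(profile, "feed_profile"))
  out <- numeric(length(t))
  seg <- profile$segments
  for (i in seq_len(nrow(seg))) {
    sel <- t >= seg$t_start[i] & t < seg$t_end[i]
    out[sel] <- seg$F[i]
  }
  out
}

#' @rdname feed_profile
#' @export
zero_feed <- function(So = 0) {
  feed_profile(data.frame(t_start = numeric(0), t_end = numeric(0),
                          F = numeric(0)), So = So)
}

# boundary times where F(t) jumps; used to restart the integrator
feed_breakpoints <- function(profile) {
  if (is.null(profile)) return(numeric(0))
  sort(unique(c(profile$segments$t_start, profile$segments$t_end)))
}
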