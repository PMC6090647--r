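#' Specific sucrose uptake rate
#'
#' Monod kinetics in sucrose with hyperbolic (non-competitive) product
#' inhibition by propionic and acetic acid:
#' \deqn{q_s = rs_{max} \frac{S}{K_s+S} \frac{k_{ipa}}{k_{ipa}+PA}
#'       \frac{k_{iaa}}{k_{iaa}+AA}}
#' The result is bounded in `[0, rs_max]`. Concentrations at or below zero
#' contribute their limiting value (uptake vanishes at S = 0), which keeps
#' simulated trajectories non-negative to solver tolerance without clipping.
#'
#' @param S sucrose (g/L)
#' @param PA propionic acid (g/L)
#' @param AA acetic acid (g/L)
#' @param p a [kinetic_parameters()] object
#' @return specific uptake rate qs (g sucrose / g DCW / h); vectorised
#' @export
#' @examples
#' p <- reference_parameters("wgs7")
#' substrate_uptake_rate(S = p[["Ks"]], PA = 0, AA = 0, p) # = rs_max / 2
substrate_uptake_rate <- function(S, PA, AA, p) {
  if (any(S < 0) || any(PA < 0) || any(AA < 0)) {
    stop("concentrations must be >= 0")
  }
  .qs(S, PA, AA, p)
}

# internal, unchecked version used inside the ODE right-hand side where the
# solver may probe marginally negative states
.qs <- function(S, PA, AA, p) {
  S <- pmax(S, 0)
  PA <- pmax(PA, 0)
  AA <- pmax(AA, 0)
  p[["rs_max"]] * S / (p[["Ks"]] + S) *
    p[["kipa"]] / (p[["kipa"]] + PA) *
    p[["kiaa"]] / (p[["kiaa"]] + AA)
}

#' Specific growth rate from substrate uptake
#'
#' Growth is proportional to uptake in excess of maintenance:
#' \eqn{\mu = q_s Y_{xs} - m_s Y_{xs}}. The rate is negative when uptake
#' falls below the maintenance requirement.
#'
#' @param qs specific substrate uptake rate (g / g DCW / h), >= 0
#' @inheritParams substrate_uptake_rate
#' @return specific growth rate (1/h); vectorised
#' @export
growth_rate <- function(qs, p) {
  if (any(qs < 0)) stop("qs must be >= 0")
  (qs - p[["ms"]]) * p[["Yxs"]]
}

#' Pyruvate saturation fraction
#'
#' The shared Michaelis term `PYR / (PYR + K_pyr)` that gates pyruvate
#' consumption and its rerouting to acetate and succinate.
#'
#' @param PYR pyruvate concentration (g/L)
#' @inheritParams substrate_uptake_rate
#' @return dimensionless fraction in `[0, 1)`; vectorised
#' @export
pyruvate_drain_term <- function(PYR, p) {
  if (any(PYR < 0)) stop("PYR must be >= 0")
  PYR / (PYR + p[["K_pyr"]])
}

.pyr_frac <- function(PYR, p) {
  PYR <- pmax(PYR, 0)
  PYR / (PYR + p[["K_pyr"]])
}

# shared RHS core: per-species time derivatives at concentrations (no
# dilution). Returns named vector over X, S, PA, PYR, AA, SA.
.batch_rhs <- function(st, p) {
  qs <- .qs(st[["S"]], st[["PA"]], st[["AA"]], p)
  u <- (qs - p[["ms"]]) * p[["Yxs"]]
  X <- st[["X"]]
  f <- .pyr_frac(st[["PYR"]], p)
  c(X  = u * X,
    S  = -qs * X,
    PA = (p[["K1"]] * u + p[["beta_pa"]]) * X,
    PYR = (p[["K2"]] * u + p[["beta_pyr"]] - p[["K3"]] * f) * X,
    AA = (p[["K4"]] * u + p[["beta_aa"]] + p[["K5"]] * f) * X,
    SA = (p[["K6"]] * u + p[["beta_sa"]] + p[["K7"]] * f) * X)
}

#' Batch model right-hand side
#'
#' Time derivatives of the six-state batch fermentation model: biomass grows
#' at `u*X`, sucrose is consumed at `qs*X`, and each acid follows a
#' Luedeking-Piret law, with pyruvate additionally drained into acetate and
#' succinate through a shared saturable term.
#'
#' @param state a [fermentation_state()] (the volume slot is ignored)
#' @inheritParams substrate_uptake_rate
#' @return named numeric vector of derivatives d(X,S,PA,PYR,AA,SA)/dt
#'   in g/L/h
#' @export
#' @examples
#' p <- reference_parameters("wgs7")
#' batch_derivatives(fermentation_state(X = 0.5, S = 60, PA = 5), p)
batch_derivatives <- function(state, p) {
  state <- as_state(state, fedbatch = FALSE)
  .batch_rhs(state, p)
}

#' Fed-batch model right-hand side
#'
#' Extends the batch model with feeding: the broth volume grows at the feed
#' rate `dV/dt = F(t)`, and the dilution rate `D = F(t)/V` dilutes every
#' broth component while the feed delivers sucrose at concentration `So`:
#' `dS/dt = -qs*X + D*(So - S)`; `dX/dt = u*X - D*X`; each product loses
#' `D*(product)`.
#'
#' @param state a [fermentation_state()] with volume `V > 0`
#' @param feed a [feed_profile()]
#' @param t time (h) at which the feed rate is evaluated
#' @inheritParams substrate_uptake_rate
#' @return named numeric vector of derivatives including `V` (L/h)
#' @export
fedbatch_derivatives <- function(state, p, feed, t) {
  state <- as_state(state, fedbatch = TRUE)
  stopifnot(inherits(feed, "feed_profile"))
  .fedbatch_rhs(state, p, feed, t)
}

# unchecked fed-batch RHS used inside the integrator, where the solver may
# probe marginally out-of-domain states
.fedbatch_rhs <- function(st, p, feed, t) {
  V <- st[["V"]]
  if (!is.finite(V) || V <= 0) stop("fed-batch state requires V > 0")
  Fnow <- feed_rate(feed, t)
  D <- Fnow / V
  d <- .batch_rhs(st, p)
  c(X  = d[["X"]] - D * st[["X"]],
    S  = d[["S"]] + D * (feed$So - st[["S"]]),
    PA = d[["PA"]] - D * st[["PA"]],
    PYR = d[["PYR"]] - D * st[["PYR"]],
    AA = d[["AA"]] - D * st[["AA"]],
    SA = d[["SA"]] - D * st[["SA"]],
    V  = Fnow)
}

as_state <- function(state, fedbatch = FALSE) {
  if (inherits(state, "fermentation_state")) {
    st <- unclass(state)
  } else {
    st <- as.numeric_named(state)
    missing <- setdiff(state_species(), names(st))
    if (length(missing) > 0L) {
      stop("state is missing components: ", paste(missing, collapse = ", "))
    }
    if (!"V" %in% names(st)) st <- c(st, V = NA_real_)
    conc <- st[state_species()]
    if (any(!is.finite(conc)) || any(conc < 0)) {
      stop("state concentrations must be finite and >= 0")
    }
  }
  if (fedbatch && (!is.finite(st[["V"]]) || st[["V"]] <= 0)) {
    stop("fed-batch state requires V > 0")
  }
  st
}
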