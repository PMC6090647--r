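#' BCECF emission ratio
#'
#' Ratiometric intracellular pH readout from dual-excitation BCECF
#' fluorescence: the 490 nm excitation is pH-sensitive, the 440 nm
#' excitation is not, and the filtrate intensities correct for
#' extracellular dye. The ratio is
#' \deqn{R = (S_{490} - S_{440}) / (F_{490} - F_{440})}
#' with S the cell-suspension and F the filtrate emission intensities.
#'
#' @param S490,S440 suspension emission intensities (a.u.), >= 0
#' @param F490,F440 filtrate emission intensities (a.u.), >= 0;
#'   `F490 != F440`
#' @return dimensionless ratio R; vectorised
#' @export
#' @examples
#' emission_ratio(S490 = 300, S440 = 100, F490 = 150, F440 = 50) # 2
emission_ratio <- function(S490, S440, F490, F440) {
  if (any(c(S490, S440, F490, F440) < 0)) {
    stop("intensities must be >= 0")
  }
  if (any(F490 == F440)) {
    stop("F490 equals F440: filtrate difference is zero, ratio undefined")
  }
  (S490 - S440) / (F490 - F440)
}

#' Fit a per-strain pH calibration curve
#'
#' Builds the monotone mapping between the BCECF emission ratio and pH
#' from equilibrated calibration points (cells treated so that
#' intracellular pH equals the buffer pH, typically at pH 4, 5, 6, 7 and
#' 8). Replicate readings at the same pH are averaged first. The default
#' mapping is a monotone piecewise-linear interpolant through the averaged
#' points; a 4-parameter logistic fit is available as an alternative.
#' Extrapolation beyond the calibrated range is refused downstream.
#'
#' @param pH buffer pH values of the calibration points
#' @param R matching emission ratios
#' @param method `"linear"` (piecewise-linear, default) or `"logistic"`
#'   (4-parameter logistic in pH)
#' @return object of class `"calibration_curve"` with elements `points`
#'   (averaged, sorted), `method`, `pH_range`, `R_range` and the forward /
#'   inverse mapping functions
#' @export
#' @examples
#' curve <- fit_calibration_curve(pH = 4:8, R = 0.5 * (4:8) - 1)
#' intracellular_ph(2.385, curve)
fit_calibration_curve <- function(pH, R, method = c("linear", "logistic")) {
  method <- match.arg(method)
  stopifnot(length(pH) == length(R))
  keep <- is.finite(pH) & is.finite(R)
  pH <- pH[keep]; R <- R[keep]
  avg <- tapply(R, pH, mean)
  ph_nodes <- as.numeric(names(avg))
  r_nodes <- as.numeric(avg)
  o <- order(ph_nodes)
  ph_nodes <- ph_nodes[o]; r_nodes <- r_nodes[o]
  if (length(ph_nodes) < 4L) {
    stop("calibration needs >= 4 distinct pH points")
  }
  d <- diff(r_nodes)
  if (!(all(d > 0) || all(d < 0))) {
    stop("averaged calibration ratios are not strictly monotone in pH: ",
         "calibration invalid")
  }
  if (method == "linear") {
    fwd <- stats::approxfun(ph_nodes, r_nodes, rule = 1)
    inv <- stats::approxfun(r_nodes, ph_nodes, rule = 1)
  } else {
    df <- data.frame(pH = ph_nodes, R = r_nodes)
    sgn <- if (d[1L] > 0) 1 else -1
    fit <- minpack.lm::nlsLM(
      R ~ lo + (hi - lo) / (1 + exp(-k * (pH - mid))),
      data = df,
      start = list(lo = min(r_nodes), hi = max(r_nodes),
                   k = sgn * 1, mid = stats::median(ph_nodes)),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    cf <- as.list(stats::coef(fit))
    fwd <- function(p) {
      cf$lo + (cf$hi - cf$lo) / (1 + exp(-cf$k * (p - cf$mid)))
    }
    inv <- function(r) {
      frac <- (r - cf$lo) / (cf$hi - cf$lo)
      cf$mid - log(1 / frac - 1) / cf$k
    }
  }
  structure(list(points = data.frame(pH = ph_nodes, R = r_nodes),
                 method = method,
                 pH_range = range(ph_nodes),
                 R_range = range(r_nodes),
                 forward = fwd, inverse = inv),
            class = "calibration_curve")
}

#' Intracellular pH from an emission ratio
#'
#' Inverse-maps a measured BCECF emission ratio through a fitted
#' [fit_calibration_curve()]. Ratios outside the calibrated range are an
#' error (extrapolation is not meaningful for a ratiometric probe).
#'
#' @param R emission ratio(s), within the curve's calibrated ratio range
#' @param curve a `calibration_curve`
#' @return intracellular pH; vectorised
#' @export
intracellular_ph <- function(R, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  out_of_range <- R < curve$R_range[1L] - 1e-12 |
    R > curve$R_range[2L] + 1e-12
  if (any(out_of_range)) {
    stop(sprintf("ratio %.4g outside calibration range [%.4g, %.4g]",
                 R[out_of_range][1L], curve$R_range[1L],
                 curve$R_range[2L]))
  }
  vapply(R, curve$inverse, numeric(1))
}

#' Transmembrane pH gradient
#'
#' Difference between intracellular and extracellular pH,
#' `delta pH = pHi - pHex`, a proxy for acid tolerance: acid-tolerant
#' strains maintain a larger gradient against an acidified medium.
#'
#' @param pHi intracellular pH
#' @param pHex extracellular (culture) pH
#' @return delta pH; vectorised
#' @export
#' @examples
#' ph_gradient(7.77, 6.5) # 1.27
ph_gradient <- function(pHi, pHex) {
  if (any(!is.finite(pHi)) || any(!is.finite(pHex))) {
    stop("pH values must be finite")
  }
  pHi - pHex
}
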