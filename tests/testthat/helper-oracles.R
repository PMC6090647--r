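# Independent oracles used across the suite. The right-hand side here is
# written as plain scalar arithmetic, separate from the package's vectorised
# implementation, and the RK4 stepper is a brute-force fixed-step integrator
# independent of the adaptive solver path.

# scalar hand evaluation of the batch balance equations
oracle_batch_rhs <- function(st, p) {
  S <- max(st[["S"]], 0); PA <- max(st[["PA"]], 0)
  AA <- max(st[["AA"]], 0); PYR <- max(st[["PYR"]], 0)
  qs <- p[["rs_max"]] * (S / (p[["Ks"]] + S)) *
    (p[["kipa"]] / (p[["kipa"]] + PA)) *
    (p[["kiaa"]] / (p[["kiaa"]] + AA))
  u <- qs * p[["Yxs"]] - p[["ms"]] * p[["Yxs"]]
  f <- PYR / (PYR + p[["K_pyr"]])
  X <- st[["X"]]
  c(X = u * X,
    S = -qs * X,
    PA = (p[["K1"]] * u + p[["beta_pa"]]) * X,
    PYR = (p[["K2"]] * u + p[["beta_pyr"]] - p[["K3"]] * f) * X,
    AA = (p[["K4"]] * u + p[["beta_aa"]] + p[["K5"]] * f) * X,
    SA = (p[["K6"]] * u + p[["beta_sa"]] + p[["K7"]] * f) * X)
}

oracle_fedbatch_rhs <- function(st, p, Fnow, So) {
  D <- Fnow / st[["V"]]
  d <- oracle_batch_rhs(st, p)
  c(X = d[["X"]] - D * st[["X"]],
    S = d[["S"]] + D * (So - st[["S"]]),
    PA = d[["PA"]] - D * st[["PA"]],
    PYR = d[["PYR"]] - D * st[["PYR"]],
    AA = d[["AA"]] - D * st[["AA"]],
    SA = d[["SA"]] - D * st[["SA"]],
    V = Fnow)
}

# fixed-step classical RK4 over a batch run; returns states at `out_times`
# (which must be multiples of dt away from t0)
oracle_rk4_batch <- function(y0, p, t_end, dt, out_times) {
  nsteps <- round(t_end / dt)
  y <- y0[c("X", "S", "PA", "PYR", "AA", "SA")]
  out <- matrix(NA_real_, nrow = length(out_times), ncol = 6,
                dimnames = list(NULL, names(y)))
  oi <- 1L
  tol <- dt / 2
  t <- 0
  if (abs(out_times[oi] - t) < tol) {
    out[oi, ] <- y
    oi <- oi + 1L
  }
  for (k in seq_len(nsteps)) {
    k1 <- oracle_batch_rhs(y, p)
    k2 <- oracle_batch_rhs(y + dt / 2 * k1, p)
    k3 <- oracle_batch_rhs(y + dt / 2 * k2, p)
    k4 <- oracle_batch_rhs(y + dt * k3, p)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- k * dt
    if (oi <= length(out_times) && abs(out_times[oi] - t) < tol) {
      out[oi, ] <- y
      oi <- oi + 1L
    }
  }
  out
}

# random but valid parameter draws for property tests
random_parameters <- function() {
  kinetic_parameters(
    rs_max = runif(1, 0.2, 2), Ks = runif(1, 0.1, 10),
    kipa = runif(1, 2, 50), kiaa = runif(1, 5, 100),
    Yxs = runif(1, 0.05, 0.6), ms = runif(1, 0, 0.2),
    K1 = runif(1, 0, 3), beta_pa = runif(1, -0.05, 0.2),
    K2 = runif(1, 0, 0.3), beta_pyr = runif(1, -0.01, 0.02),
    K3 = runif(1, 0.05, 0.3), K_pyr = runif(1, 0.1, 2),
    K4 = runif(1, 0, 1), beta_aa = runif(1, -0.01, 0.05),
    K5 = runif(1, 0, 0.02), K6 = runif(1, 0, 1),
    beta_sa = runif(1, -0.01, 0.05), K7 = runif(1, 0, 0.02))
}

random_state <- function(fedbatch = FALSE) {
  fermentation_state(X = runif(1, 0, 10), S = runif(1, 0, 120),
                     PA = runif(1, 0, 60), PYR = runif(1, 0, 3),
                     AA = runif(1, 0, 15), SA = runif(1, 0, 15),
                     V = if (fedbatch) runif(1, 0.3, 2) else NA_real_)
}
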