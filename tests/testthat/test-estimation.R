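test_that("coefficient of determination reproduces hand-computed values", {
  obs <- data.frame(time_h = 1:3, PA_gL = c(1, 2, 3))
  sim <- data.frame(time_h = 1:3, PA_gL = c(1, 2, 4))
  r <- coefficient_of_determination(obs, sim)
  expect_identical(r$m, 1L)
  expect_equal(r$aggregate, 0.5)          # SSE = 1, SST = 2
  # perfect fit
  expect_equal(coefficient_of_determination(obs, obs)$aggregate, 1)
  # constant prediction at the observed mean scores exactly 0
  simc <- data.frame(time_h = 1:3, PA_gL = rep(2, 3))
  expect_equal(coefficient_of_determination(obs, simc)$aggregate, 0)
})

test_that("averaged R-squared equals a brute-force oracle on random vectors", {
  set.seed(5)
  for (rep in 1:25) {
    n <- sample(3:10, 1)
    m <- sample(1:3, 1)
    vars <- paste0(c("S", "PA", "AA")[seq_len(m)], "_gL")
    obs <- data.frame(time_h = seq_len(n))
    sim <- data.frame(time_h = seq_len(n))
    expected <- numeric(m)
    for (j in seq_len(m)) {
      y <- runif(n, 0, 50)
      yh <- y + rnorm(n, 0, 5)
      obs[[vars[j]]] <- y
      sim[[vars[j]]] <- yh
      expected[j] <- 1 - sum((y - yh)^2) / sum((y - mean(y))^2)
    }
    r <- coefficient_of_determination(obs, sim, variables = vars)
    expect_equal(unname(r$per_variable), expected, tolerance = 1e-13)
    expect_equal(r$aggregate, mean(expected), tolerance = 1e-13)
  }
})

test_that("zero-variance variables are excluded with a warning, m reduced", {
  obs <- data.frame(time_h = 1:4, PA_gL = c(1, 2, 3, 4),
                    SA_gL = rep(2, 4))
  sim <- data.frame(time_h = 1:4, PA_gL = c(1, 2, 3, 4),
                    SA_gL = rep(2, 4))
  expect_warning(r <- coefficient_of_determination(obs, sim),
                 "zero variance")
  expect_identical(r$m, 1L)
  obs_all_flat <- data.frame(time_h = 1:4, SA_gL = rep(2, 4))
  expect_error(
    suppressWarnings(coefficient_of_determination(obs_all_flat, sim)),
    "no variable")
})

test_that("objective residuals are zero at the truth and scale with weights", {
  sc <- reference_scenario("wgs7", "batch")
  data <- generate_timeseries(sc$parameters, sc$initial,
                              sample_times = seq(0, 60, 4),
                              noise = noise_model(cv = 0))
  r0 <- objective_residuals(sc$parameters, data)
  expect_equal(max(abs(r0)), 0, tolerance = 1e-7)
  n_expected <- 6 * nrow(data)
  expect_length(r0, n_expected)
  # doubling every weight halves every residual
  p2 <- structure(as.numeric(unclass(sc$parameters)) * 1,
                  names = names(unclass(sc$parameters)),
                  class = "kinetic_parameters")
  p2["K1"] <- p2[["K1"]] * 1.2
  spec_cols <- paste0(c("X", "S", "PA", "PYR", "AA", "SA"), "_gL")
  w1 <- vapply(spec_cols, function(v) max(data[[v]]), numeric(1))
  r1 <- objective_residuals(p2, data, weights = w1)
  r2 <- objective_residuals(p2, data, weights = 2 * w1)
  expect_equal(r2, r1 / 2, tolerance = 1e-12)
})

test_that("simulation failure at a candidate yields finite penalty residuals", {
  sc <- reference_scenario("wgs7", "batch")
  data <- generate_timeseries(sc$parameters, sc$initial,
                              sample_times = seq(0, 40, 4),
                              noise = noise_model(cv = 0))
  bad <- unclass(sc$parameters)
  bad["Yxs"] <- -0.5     # invalid: simulate() will refuse
  bad <- structure(bad, class = "kinetic_parameters")
  r <- objective_residuals(bad, data)
  expect_true(all(is.finite(r)))
  expect_true(isTRUE(attr(r, "penalised")))
  expect_length(r, 6 * nrow(data))
})

test_that("noiseless parameter recovery is exact to within 1 percent", {
  sc <- reference_scenario("wgs7", "batch")
  data <- generate_timeseries(sc$parameters, sc$initial,
                              sample_times = seq(0, 96, 4),
                              noise = noise_model(cv = 0))
  free <- c("rs_max", "Yxs", "K1", "kipa")
  guess <- unclass(sc$parameters)
  guess[free] <- guess[free] * 1.5
  guess <- structure(guess, class = "kinetic_parameters")
  fit <- fit_parameters(data, guess,
                        fixed = setdiff(kinetic_parameter_names(), free),
                        n_starts = 1)
  truth <- unclass(sc$parameters)[free]
  est <- unclass(fit$parameters)[free]
  expect_true(all(abs(est - truth) / truth < 0.01))
  expect_gt(fit$aggregate_r2, 0.9999)
  expect_true(fit$convergence)
})

test_that("under-determined fits are refused", {
  sc <- reference_scenario("wgs7", "batch")
  one_row <- data.frame(time_h = 0, X_gL = 0.075, S_gL = 80, PA_gL = 0,
                        PYR_gL = 0, AA_gL = 0, SA_gL = 0)
  expect_error(fit_parameters(one_row, sc$parameters), "at least 2")
  two_rows <- generate_timeseries(sc$parameters, sc$initial,
                                  sample_times = c(0, 4),
                                  noise = noise_model(cv = 0))
  expect_error(fit_parameters(two_rows, sc$parameters,
                              fixed = character()),
               "fewer observations")
})

test_that("fit does not degrade the objective relative to the guess", {
  sc <- reference_scenario("wgs7", "batch")
  data <- generate_timeseries(sc$parameters, sc$initial,
                              sample_times = seq(0, 80, 8),
                              noise = noise_model(cv = 0.05, seed = 9))
  free <- c("rs_max", "Yxs", "K1")
  guess <- unclass(sc$parameters)
  guess[free] <- guess[free] * 1.3
  guess <- structure(guess, class = "kinetic_parameters")
  r_guess <- sum(objective_residuals(guess, data)^2)
  fit <- fit_parameters(data, guess,
                        fixed = setdiff(kinetic_parameter_names(), free),
                        n_starts = 1)
  expect_lte(fit$objective, r_guess + 1e-10)
  sim_fit <- simulate_fermentation(initial_state_from_data(data),
                                   fit$parameters, data$time_h)
  sim_guess <- simulate_fermentation(initial_state_from_data(data),
                                     guess, data$time_h)
  expect_gte(coefficient_of_determination(data, sim_fit)$aggregate,
             coefficient_of_determination(data, sim_guess)$aggregate)
})

test_that("permuting observation order leaves the optimum unchanged", {
  sc <- reference_scenario("wgs7", "batch")
  data <- generate_timeseries(sc$parameters, sc$initial,
                              sample_times = seq(0, 60, 6),
                              noise = noise_model(cv = 0.05, seed = 3))
  free <- c("rs_max", "K1")
  guess <- unclass(sc$parameters)
  guess[free] <- guess[free] * 1.25
  guess <- structure(guess, class = "kinetic_parameters")
  fixed <- setdiff(kinetic_parameter_names(), free)
  f1 <- fit_parameters(data, guess, fixed = fixed, n_starts = 1)
  # shuffle rows, then restore time order inside a fresh data.frame: the
  # stacked objective only depends on the set of (t, y) pairs
  shuffled <- data[sample(nrow(data)), ]
  shuffled <- shuffled[order(shuffled$time_h), ]
  f2 <- fit_parameters(shuffled, guess, fixed = fixed, n_starts = 1)
  expect_equal(unclass(f1$parameters)[free], unclass(f2$parameters)[free],
               tolerance = 1e-8)
})

test_that("Monod constants are recovered from rate data", {
  S <- c(1, 2, 5, 10, 20, 50)
  r <- 0.8 * S / (5 + S)
  fit <- fit_monod_ks(S, r)
  expect_equal(fit$Ks, 5, tolerance = 1e-6)
  expect_equal(fit$rs_max, 0.8, tolerance = 1e-6)
  # two points on a known curve determine (Ks, rs_max) in closed form:
  # r1(Ks + S1) rs = ..., solve the 2x2 system and compare
  S2 <- c(2, 18, 40)
  r2 <- 1.2 * S2 / (7 + S2)
  fit2 <- fit_monod_ks(S2, r2)
  # closed-form from the first two points
  ks_cf <- (r2[2] - r2[1]) / (r2[1] / S2[1] - r2[2] / S2[2])
  rs_cf <- r2[1] * (ks_cf + S2[1]) / S2[1]
  expect_equal(fit2$Ks, ks_cf, tolerance = 1e-6)
  expect_equal(fit2$rs_max, rs_cf, tolerance = 1e-6)
})

test_that("degenerate Monod data is flagged", {
  expect_warning(out <- fit_monod_ks(c(5, 10, 20), c(0.5, 0.5, 0.5)),
                 "Ks")
  expect_equal(out$Ks, 0)
  expect_equal(out$rs_max, 0.5)
  expect_error(fit_monod_ks(c(5, 5, 5), c(0.1, 0.2, 0.3)), "distinct")
})
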