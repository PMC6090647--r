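test_that("substrate uptake follows Monod kinetics with product inhibition", {
  p <- kinetic_parameters(rs_max = 0.8, Ks = 0.1, kipa = 20, kiaa = 40,
                          Yxs = 0.3, ms = 0.05,
                          K1 = 1, beta_pa = 0.01, K2 = 0.1,
                          beta_pyr = 0.001, K3 = 0.1, K_pyr = 1,
                          K4 = 0.2, beta_aa = 0.001, K5 = 0.01,
                          K6 = 0.2, beta_sa = 0.001, K7 = 0.01)
  # no substrate, no uptake
  expect_equal(substrate_uptake_rate(0, 10, 5, p), 0)
  # half-saturation without inhibitors
  expect_equal(substrate_uptake_rate(p[["Ks"]], 0, 0, p), p[["rs_max"]] / 2)
  # direct arithmetic evaluation
  expect_equal(substrate_uptake_rate(40, 20, 10, p),
               0.8 * (40 / 40.1) * (20 / 40) * (40 / 50),
               tolerance = 1e-12)
  expect_error(substrate_uptake_rate(-1, 0, 0, p), "must be >= 0")
})

test_that("uptake rate is bounded and monotone in its arguments", {
  set.seed(42)
  for (rep in 1:20) {
    p <- random_parameters()
    S <- seq(0, 150, length.out = 30)
    qs <- substrate_uptake_rate(S, 5, 3, p)
    expect_true(all(qs >= 0 & qs <= p[["rs_max"]]))
    expect_true(all(diff(qs) >= -1e-12))                    # increasing in S
    qpa <- substrate_uptake_rate(40, seq(0, 80, 2), 3, p)
    expect_true(all(diff(qpa) <= 1e-12))                    # decreasing in PA
    qaa <- substrate_uptake_rate(40, 5, seq(0, 80, 2), p)
    expect_true(all(diff(qaa) <= 1e-12))                    # decreasing in AA
  }
})

test_that("growth rate balances uptake against maintenance", {
  p <- reference_parameters("wgs7")
  expect_equal(growth_rate(p[["ms"]], p), 0)
  p2 <- unclass(p); p2["Yxs"] <- 1e-12
  p2 <- structure(p2, class = "kinetic_parameters")
  expect_equal(growth_rate(0.4, p2), (0.4 - p2[["ms"]]) * 1e-12)
  p3 <- kinetic_parameters(rs_max = 1, Ks = 1, kipa = 10, kiaa = 10,
                           Yxs = 0.3, ms = 0.05,
                           K1 = 0, beta_pa = 0, K2 = 0, beta_pyr = 0,
                           K3 = 0.1, K_pyr = 1, K4 = 0, beta_aa = 0,
                           K5 = 0, K6 = 0, beta_sa = 0, K7 = 0)
  expect_equal(growth_rate(0.4, p3), 0.105)
  # maintenance can exceed uptake: negative growth allowed
  expect_lt(growth_rate(0.01, p3), 0)
  expect_error(growth_rate(-0.1, p3), ">= 0")
})

test_that("pyruvate drain term is a saturation fraction", {
  p <- kinetic_parameters(rs_max = 1, Ks = 1, kipa = 10, kiaa = 10,
                          Yxs = 0.3, ms = 0, K1 = 0, beta_pa = 0,
                          K2 = 0, beta_pyr = 0, K3 = 0.1, K_pyr = 1,
                          K4 = 0, beta_aa = 0, K5 = 0, K6 = 0,
                          beta_sa = 0, K7 = 0)
  expect_equal(pyruvate_drain_term(0, p), 0)
  expect_equal(pyruvate_drain_term(1, p), 0.5)
  expect_equal(pyruvate_drain_term(3, p), 0.75)
  expect_true(pyruvate_drain_term(1e9, p) < 1)
  expect_error(pyruvate_drain_term(-0.1, p), ">= 0")
})

test_that("batch derivatives match independent scalar hand evaluation", {
  set.seed(7)
  for (rep in 1:50) {
    p <- random_parameters()
    st <- random_state()
    d <- batch_derivatives(st, p)
    expect_equal(d, oracle_batch_rhs(unclass(st), p), tolerance = 1e-13)
  }
})

test_that("batch derivatives vanish without biomass and drain vanishes without pyruvate", {
  p <- reference_parameters("wgs7")
  d0 <- batch_derivatives(fermentation_state(X = 0, S = 50, PA = 5), p)
  expect_equal(unname(d0), rep(0, 6))
  st <- fermentation_state(X = 2, S = 50, PA = 5, PYR = 0, AA = 1, SA = 1)
  d <- batch_derivatives(st, p)
  qs <- substrate_uptake_rate(50, 5, 1, p)
  u <- growth_rate(qs, p)
  expect_equal(d[["PYR"]], (p[["K2"]] * u + p[["beta_pyr"]]) * 2)
})

test_that("fed-batch derivatives reduce to batch when the feed is off", {
  set.seed(11)
  feed0 <- zero_feed(So = 350)
  for (rep in 1:50) {
    p <- random_parameters()
    st <- random_state(fedbatch = TRUE)
    dfb <- fedbatch_derivatives(st, p, feed0, t = runif(1, 0, 100))
    db <- batch_derivatives(st, p)
    expect_equal(dfb[names(db)], db, tolerance = 1e-14)
    expect_identical(dfb[["V"]], 0)
  }
})

test_that("fed-batch dilution follows D = F/V", {
  p <- reference_parameters("wgs7")
  feed <- feed_profile(data.frame(t_start = 40, t_end = 64, F = 0.0066),
                       So = 350)
  st <- fermentation_state(X = 5, S = 20, PA = 30, PYR = 0.5, AA = 5,
                           SA = 5, V = 0.7)
  d <- fedbatch_derivatives(st, p, feed, t = 50)
  D <- 0.0066 / 0.7
  expect_equal(D, 0.0094286, tolerance = 1e-4)
  db <- batch_derivatives(st, p)
  expect_equal(d[["X"]], db[["X"]] - D * 5)
  expect_equal(d[["S"]], db[["S"]] + D * (350 - 20))
  expect_equal(d[["PA"]], db[["PA"]] - D * 30)
  expect_equal(d[["V"]], 0.0066)
  # outside the feed window the rate is zero
  expect_equal(fedbatch_derivatives(st, p, feed, t = 10)[["V"]], 0)
  expect_error(
    fedbatch_derivatives(c(unclass(st)[1:6], V = -1), p, feed, 50),
    "V > 0")
})

test_that("feed profiles validate segments and evaluate F(t) half-open", {
  expect_error(feed_profile(data.frame(t_start = 10, t_end = 5, F = 0.01),
                            So = 100), "t_start < t_end")
  expect_error(feed_profile(data.frame(t_start = c(0, 5), t_end = c(6, 10),
                                       F = c(0.01, 0.02)), So = 100),
               "overlap")
  f <- feed_profile(data.frame(t_start = c(0, 10), t_end = c(5, 20),
                               F = c(0.01, 0.02)), So = 100)
  expect_equal(feed_rate(f, c(-1, 0, 4.9, 5, 9, 10, 19.9, 20, 25)),
               c(0, 0.01, 0.01, 0, 0, 0.02, 0.02, 0, 0))
})

test_that("parameter validation enforces the documented invariants", {
  expect_error(kinetic_parameters(rs_max = -1, Ks = 1, kipa = 10, kiaa = 10,
                                  Yxs = 0.3, ms = 0, K1 = 0, beta_pa = 0,
                                  K2 = 0, beta_pyr = 0, K3 = 0, K_pyr = 1,
                                  K4 = 0, beta_aa = 0, K5 = 0, K6 = 0,
                                  beta_sa = 0, K7 = 0), "> 0")
  expect_error(kinetic_parameters(rs_max = 1, Ks = 1, kipa = 10, kiaa = 10,
                                  Yxs = 2, ms = 0, K1 = 0, beta_pa = 0,
                                  K2 = 0, beta_pyr = 0, K3 = 0, K_pyr = 1,
                                  K4 = 0, beta_aa = 0, K5 = 0, K6 = 0,
                                  beta_sa = 0, K7 = 0), "Yxs")
  expect_error(kinetic_parameters(rs_max = 1, Ks = 1, kipa = 10, kiaa = 10,
                                  Yxs = 0.3, ms = 0, K1 = 0, beta_pa = -2,
                                  K2 = 0, beta_pyr = 0, K3 = 0, K_pyr = 1,
                                  K4 = 0, beta_aa = 0, K5 = 0, K6 = 0,
                                  beta_sa = 0, K7 = 0), "beta")
  expect_warning(kinetic_parameters(rs_max = 1, Ks = 1, kipa = 10,
                                    kiaa = 10, Yxs = 0.3, ms = 0, K1 = 0,
                                    beta_pa = 0, K2 = 0, beta_pyr = 0,
                                    K3 = 0.01, K_pyr = 1, K4 = 0,
                                    beta_aa = 0, K5 = 0.02, K6 = 0,
                                    beta_sa = 0, K7 = 0.02), "K3 < K5")
})
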