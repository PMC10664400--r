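test_that("integration matches closed forms and algebraic reductions", {
  tg <- seq(0, 20, length.out = 41)
  tr <- simulate_model(zoo_twocomp(), twocomp_truth, time_grid = tg)
  expect_lt(rel_diff(tr$states[, "x1"], 10 * exp(-0.5 * tg)), 1e-6)

  # hydrolysis model and its reparameterization trace identical trajectories
  # when b1 = k*kI/(Km-kI), b2 = Km*(kI+x0)/(Km-kI)
  k <- 2; Km <- 5; kI <- 3; x0 <- 10
  b1 <- k * kI / (Km - kI)
  b2 <- Km * (kI + x0) / (Km - kI)
  tgb <- seq(0, 30, length.out = 31)
  t1 <- simulate_model(zoo_betacasein(), c(k = k, Km = Km, kI = kI),
                       time_grid = tgb)
  t2 <- simulate_model(zoo_betacasein_reduced(), c(b1 = b1, b2 = b2),
                       time_grid = tgb)
  expect_lt(rel_diff(t1$states, t2$states), 1e-8)

  # washed-out chemostat: x1 = 0 is an invariant manifold
  t3 <- simulate_model(set_ic(zoo_monod_haldane(), x1 = 0), mh_truth,
                       mh_input(), mh_grid(21))
  expect_equal(max(abs(t3$states[, "x1"])), 0)

  # outputs are g applied to the states row-wise
  expect_equal(t1$outputs[, "y"], t1$states[, "x"])
})

test_that("self-convergence: halving the tolerance barely moves trajectories", {
  tg <- mh_grid(21)
  a <- simulate_model(zoo_monod_haldane(), mh_truth, mh_input(), tg, tol = 1e-8)
  b <- simulate_model(zoo_monod_haldane(), mh_truth, mh_input(), tg, tol = 5e-9)
  expect_lt(max(abs(a$outputs - b$outputs)), 10 * 1e-8 * max(abs(a$outputs)))
})

test_that("forward sensitivities match finite differences", {
  tg <- mh_grid(21)
  u <- mh_input()
  sb <- sensitivities(zoo_monod_haldane(), mh_truth, u, tg, tol = 1e-10)
  for (p in names(mh_truth)) {
    h <- mh_truth[[p]] * 1e-5
    tp <- mh_truth; tp[[p]] <- tp[[p]] + h
    tm <- mh_truth; tm[[p]] <- tm[[p]] - h
    fd <- (simulate_model(zoo_monod_haldane(), tp, u, tg, tol = 1e-10)$outputs -
           simulate_model(zoo_monod_haldane(), tm, u, tg, tol = 1e-10)$outputs) /
      (2 * h)
    expect_lt(max(abs(sb$output_sens[, , p] - fd)) / max(abs(fd)), 1e-4)
  }
})

test_that("sensitivity structure: IC blocks and structurally absent parameters", {
  # state sensitivities at t0: identity block for unknown ICs, zero elsewhere
  tg2 <- seq(0, 5, length.out = 6)
  sb2 <- sensitivities(zoo_twocomp(), twocomp_truth, time_grid = tg2)
  S0 <- sb2$state_sens[1L, , ]
  expect_equal(S0["x1", "x1_0"], 1)
  expect_equal(sum(abs(S0)) - 1, 0)

  # methanogen biomass and gas-phase H2 carry no information on YCH4
  nom <- unlist(zoo_methanogenesis()$metadata$nominal)
  sbm <- sensitivities(zoo_methanogenesis(), nom,
                       time_grid = seq(0, 100, length.out = 11))
  expect_equal(max(abs(sbm$output_sens[, c("xH2", "ng_H2"), "YCH4"])), 0)
  expect_equal(max(abs(sbm$output_sens[, c("xH2", "ng_H2"), "YCO2"])), 0)
})

test_that("synthetic data are seeded, exact at sigma = 0, and calibrated", {
  tg <- mh_grid()
  tab0 <- generate_synthetic_data(zoo_monod_haldane(), mh_truth, mh_input(),
                                  tg, noise = list(kind = "additive", sigma = 0),
                                  seed = 1)
  tr <- simulate_model(zoo_monod_haldane(), mh_truth, mh_input(), tg)
  expect_equal(as.matrix(tab0[, c("y1", "y2")]), tr$outputs,
               ignore_attr = TRUE)

  t1 <- generate_synthetic_data(zoo_monod_haldane(), mh_truth, mh_input(),
                                tg, noise = list(kind = "additive", sigma = 0.05),
                                seed = 42)
  t2 <- generate_synthetic_data(zoo_monod_haldane(), mh_truth, mh_input(),
                                tg, noise = list(kind = "additive", sigma = 0.05),
                                seed = 42)
  expect_identical(t1, t2)
  expect_false(identical(
    t1,
    generate_synthetic_data(zoo_monod_haldane(), mh_truth, mh_input(), tg,
                            noise = list(kind = "additive", sigma = 0.05),
                            seed = 43)))

  # Monte-Carlo calibration of the additive noise model: per-time sample SD
  # of y1 over 200 replicate seeds stays within 15% of sigma = 0.05
  reps <- vapply(1:200, function(s) {
    generate_synthetic_data(zoo_monod_haldane(), mh_truth, mh_input(), tg,
                            noise = list(kind = "additive", sigma = 0.05),
                            seed = s)$y1
  }, numeric(length(tg)))
  sds <- apply(reps, 1L, sd)
  expect_lt(max(abs(sds - 0.05)) / 0.05, 0.15)
})

test_that("integration failure is reported with the last successful time", {
  # finite-time blow-up: dx/dt = x^2 from x(0) = 1 escapes at t = 1
  m <- ode_model("blowup",
                 states = data.frame(name = "x", ic_known = TRUE, ic_value = 1),
                 odes = list(x = "x^2"), outputs = list(y = "x"))
  expect_error(
    suppressWarnings(simulate_model(m, time_grid = seq(0, 5, length.out = 11))),
    class = "odeident_integration_failure"
  )
})
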