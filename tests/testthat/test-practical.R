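test_that("FIM reproduces the linear-observation closed form and scaling law", {
  # clock state x = t with y = p*x: FIM = sum(t_k^2) / sigma^2
  m <- ode_model("ramp",
                 states = data.frame(name = "x", ic_known = TRUE, ic_value = 0),
                 parameters = data.frame(name = "p", known = FALSE, value = NA),
                 odes = list(x = "0*p + 1"), outputs = list(y = "p*x"))
  tk <- c(1, 2, 3, 5)
  f <- compute_fim(m, c(p = 0.7), experiment_design(c(0, tk), sigma = 1))
  expect_equal(unname(f$fim[1L, 1L]), sum(c(0, tk)^2), tolerance = 1e-6)

  # doubling every sigma multiplies det(FIM) by 2^(-2 n_unknowns)
  d1 <- experiment_design(mh_grid(20), mh_input(), sigma = 0.05)
  d2 <- experiment_design(mh_grid(20), mh_input(), sigma = 0.10)
  f1 <- compute_fim(zoo_monod_haldane(), mh_truth, d1)
  f2 <- compute_fim(zoo_monod_haldane(), mh_truth, d2)
  expect_equal(f2$log_det - f1$log_det, -2 * 2 * log(2), tolerance = 1e-9)

  # information monotonicity: adding sampling times cannot lose information
  d_more <- experiment_design(mh_grid(40), mh_input(), sigma = 0.05)
  f_more <- compute_fim(zoo_monod_haldane(), mh_truth, d_more)
  expect_gte(f_more$log_det, f1$log_det)
  ev <- eigen(f_more$fim - f1$fim, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-6 * max(abs(ev)))
})

test_that("structural non-identifiability shows up as a singular FIM", {
  d <- experiment_design(seq(0, 30, length.out = 25), sigma = 0.05)
  f <- compute_fim(zoo_betacasein(), c(k = 2, Km = 5, kI = 3), d)
  expect_true(f$singular)
  expect_true(all(is.na(f$sds)))
  expect_length(f$null_directions, 1L)
  # numeric cross-check: rank of sum S'S is at most 2
  sb <- sensitivities(zoo_betacasein(), c(k = 2, Km = 5, kI = 3),
                      time_grid = d$times)
  G <- crossprod(matrix(sb$output_sens[, 1L, ], ncol = 3L))
  expect_equal(qr(G, tol = 1e-10)$rank, 2L)
})

test_that("FIM from sensitivity ODEs agrees with finite-difference FIM", {
  tg <- mh_grid(20)
  u <- mh_input()
  f_sens <- compute_fim(zoo_monod_haldane(), mh_truth,
                        experiment_design(tg, u, sigma = 0.05))
  fd <- sapply(names(mh_truth), function(p) {
    h <- mh_truth[[p]] * 1e-5
    tp <- mh_truth; tp[[p]] <- tp[[p]] + h
    tm <- mh_truth; tm[[p]] <- tm[[p]] - h
    (simulate_model(zoo_monod_haldane(), tp, u, tg, tol = 1e-10)$outputs -
     simulate_model(zoo_monod_haldane(), tm, u, tg, tol = 1e-10)$outputs) /
      (2 * h)
  }, simplify = "array")
  fim_fd <- matrix(0, 2L, 2L)
  for (i in seq_along(tg)) for (o in 1:2) {
    fim_fd <- fim_fd + tcrossprod(fd[i, o, ]) / 0.05^2
  }
  expect_equal(f_sens$log_det, as.numeric(determinant(fim_fd)$modulus),
               tolerance = 1e-3)
})

test_that("noise-free data are recovered exactly by the multistart fit", {
  tg <- mh_grid()
  data <- generate_synthetic_data(zoo_monod_haldane(), mh_truth, mh_input(),
                                  tg, noise = list(kind = "additive", sigma = 0),
                                  seed = 1)
  fit <- fit_least_squares(zoo_monod_haldane(), data, mh_bounds,
                           sigma = 0.05, n_starts = 8, seed = 7,
                           input_signal = mh_input())
  expect_lt(rel_diff(fit$theta_hat, mh_truth), 1e-3)
  expect_lt(fit$rss, 1e-10)
  expect_gte(fit$converged_fraction, 0.5)
  # best terminus beats every other terminus
  expect_true(all(fit$termini$rss >= fit$rss - 1e-12, na.rm = TRUE))
})

test_that("estimates are unbiased across replicate noisy datasets", {
  tg <- mh_grid()
  khat <- vapply(1:30, function(s) {
    d <- generate_synthetic_data(zoo_monod_haldane(), mh_truth, mh_input(),
                                 tg, noise = list(kind = "additive", sigma = 0.05),
                                 seed = 400 + s)
    f <- minpack.lm::nls.lm(
      par = mh_truth, lower = c(0.1, 5), upper = c(20, 500),
      fn = function(p) {
        tr <- simulate_model(zoo_monod_haldane(), p, mh_input(), tg)
        c((d$y1 - tr$outputs[, 1L]) / 0.05, (d$y2 - tr$outputs[, 2L]) / 0.05)
      },
      control = minpack.lm::nls.lm.control(maxiter = 120))
    unlist(f$par)[["k"]]
  }, numeric(1L))
  se <- sd(khat) / sqrt(length(khat))
  expect_lt(abs(mean(khat) - 2), 3 * se + 1e-12)
})

test_that("profile likelihood brackets identifiable parameters", {
  tg <- mh_grid()
  data <- generate_synthetic_data(zoo_monod_haldane(), mh_truth, mh_input(),
                                  tg, noise = list(kind = "additive", sigma = 0.05),
                                  seed = 21)
  fit <- fit_least_squares(zoo_monod_haldane(), data, mh_bounds,
                           sigma = 0.05, n_starts = 6, seed = 7,
                           input_signal = mh_input())
  prof <- profile_likelihood(zoo_monod_haldane(), data, "k",
                             grid = seq(1.2, 3.2, length.out = 21),
                             theta_bounds = mh_bounds, sigma = 0.05,
                             fit = fit, input_signal = mh_input())
  expect_false(prof$ci$flat)
  expect_false(prof$ci$unbounded_low)
  expect_false(prof$ci$unbounded_high)
  expect_lt(prof$ci$lower, 2)
  expect_gt(prof$ci$upper, 2)
  # minimum of the profile sits at (within one grid step of) the estimate
  i_min <- which.min(prof$profiled_objective)
  expect_lt(abs(prof$grid[i_min] - fit$theta_hat[["k"]]),
            1.5 * diff(prof$grid[1:2]))

  # delta -> infinity: the confidence region is the whole grid
  prof_inf <- profile_likelihood(zoo_monod_haldane(), data, "k",
                                 grid = seq(1.2, 3.2, length.out = 9),
                                 theta_bounds = mh_bounds, sigma = 0.05,
                                 delta = 1e12, fit = fit,
                                 input_signal = mh_input())
  expect_equal(prof_inf$ci$lower, 1.2)
  expect_equal(prof_inf$ci$upper, 3.2)
})

test_that("non-identifiable quantities give flat profiles on noise-free data", {
  tg <- seq(0, 30, length.out = 20)
  truth <- c(k = 2, Km = 5, kI = 3)
  bounds <- list(k = c(0.05, 20), Km = c(0.05, 50), kI = c(0.05, 30))
  data <- generate_synthetic_data(zoo_betacasein(), truth, time_grid = tg,
                                  noise = list(kind = "additive", sigma = 0),
                                  seed = 1)
  # maxiter warnings are expected: the optimizer wanders a perfectly flat
  # valley of output-equivalent parameterizations
  fit <- suppressWarnings(
    fit_least_squares(zoo_betacasein(), data, bounds,
                      sigma = 0.05, n_starts = 6, seed = 3))
  prof <- profile_likelihood(zoo_betacasein(), data, "k",
                             grid = seq(1.4, 3.2, length.out = 10),
                             theta_bounds = bounds,
                             sigma = 0.05, fit = fit)
  expect_true(prof$ci$flat)
  # oracle: the objective is invariant along the compensating direction —
  # refitting (Km, kI) restores a near-perfect fit at a perturbed k
  expect_lt(diff(range(prof$profiled_objective, na.rm = TRUE)), 3.84 * 1e-2)
})
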