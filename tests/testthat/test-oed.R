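# Design optimization tests run at reduced multistart counts; the design
# space defaults (horizon 50 h, u in [0, 100], 20 sampling times,
# sigma = 0.05) are the package's documented configuration.

oed_space <- function(kind, n_nodes = 5) {
  design_space(kind, n_nodes = n_nodes, input_bounds = c(0, 100),
               horizon = c(0, 50), sigma = 0.05, theta_nominal = mh_truth)
}

test_that("a degenerate design box reduces to direct FIM evaluation", {
  sp <- design_space("constant", input_bounds = c(30, 30), horizon = c(0, 50),
                     sigma = 0.05, theta_nominal = mh_truth)
  res <- optimize_design(zoo_monod_haldane(), sp, n_starts = 2, seed = 3)
  expect_equal(res$optimal_input, 30)
  direct <- compute_fim(zoo_monod_haldane(), mh_truth,
                        experiment_design(sp$sampling_times,
                                          input_constant(30), 0.05))
  expect_equal(res$fim_report$log_det, direct$log_det, tolerance = 1e-9)
})

test_that("constant signals are a subspace of piecewise-linear signals", {
  sp_c <- oed_space("constant")
  res_c <- optimize_design(zoo_monod_haldane(), sp_c, n_starts = 3, seed = 3)
  u_star <- res_c$optimal_input
  # a 2-node piecewise signal with equal node values reproduces the
  # constant-input optimum
  sp2 <- oed_space("piecewise_linear", n_nodes = 2)
  d_eq <- experiment_design(sp2$sampling_times,
                            input_piecewise_linear(c(0, 50), rep(u_star, 2L)),
                            0.05)
  f_eq <- compute_fim(zoo_monod_haldane(), mh_truth, d_eq)
  expect_equal(f_eq$log_det, res_c$fim_report$log_det, tolerance = 1e-6)
})

test_that("dynamic inputs dominate constant inputs in D-optimality", {
  res_c <- optimize_design(zoo_monod_haldane(), oed_space("constant"),
                           n_starts = 3, seed = 3)
  res_d <- optimize_design(zoo_monod_haldane(), oed_space("piecewise_linear"),
                           n_starts = 4, seed = 3)
  expect_gte(res_d$fim_report$log_det, res_c$fim_report$log_det)
  # better information translates into strictly smaller Cramér-Rao SDs
  expect_lt(res_d$fim_report$sds[["k"]], res_c$fim_report$sds[["k"]])
  expect_lt(res_d$fim_report$sds[["kI"]], res_c$fim_report$sds[["kI"]])
  # returned design dominates every evaluated candidate
  expect_true(all(res_d$fim_report$log_det >= res_d$objective_trace - 1e-6))

  # design-space nesting: more nodes can only help (up to optimizer slack)
  res_d3 <- optimize_design(zoo_monod_haldane(),
                            oed_space("piecewise_linear", n_nodes = 3),
                            n_starts = 3, seed = 3)
  expect_gte(res_d$fim_report$log_det, res_d3$fim_report$log_det - 1e-6)
  expect_gte(res_d3$fim_report$log_det, res_c$fim_report$log_det - 1e-6)
})

test_that("rescaling noise shifts log det additively, leaving the input alone", {
  u <- c(80, 20, 60, 0, 100)
  d1 <- experiment_design(seq(0, 50, length.out = 20),
                          input_piecewise_linear(seq(0, 50, length.out = 5), u),
                          sigma = 0.05)
  d2 <- d1; d2$sigma <- 0.05 * 3
  f1 <- compute_fim(zoo_monod_haldane(), mh_truth, d1)
  f2 <- compute_fim(zoo_monod_haldane(), mh_truth, d2)
  expect_equal(f2$log_det, f1$log_det - 2 * 2 * log(3), tolerance = 1e-9)
})

test_that("compare_designs reproduces published-table arithmetic", {
  # determinants 1.27e10 and 8.40e12: det ratio ~660 (two significant
  # figures); dynamic-input SDs are 31% and 72% of the constant-input SDs
  tab <- compare_designs(list(
    design_summary("constant", 1.27e10, c(k = 0.0247, kI = 0.0282)),
    design_summary("dynamic", 8.40e12, c(k = 0.0076, kI = 0.0202))
  ))
  expect_equal(signif(tab$det_ratio[2L], 2), 660)
  expect_equal(round(tab$sd_k_pct[2L]), 31)
  expect_equal(round(tab$sd_kI_pct[2L]), 72)
  # self-comparison: all ratios 1
  self <- compare_designs(list(
    design_summary("a", 1.27e10, c(k = 0.0247)),
    design_summary("a", 1.27e10, c(k = 0.0247))
  ))
  expect_equal(self$det_ratio, c(1, 1))
  expect_equal(self$sd_k_pct, c(100, 100))
})
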