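test_that("Lie derivatives match hand-computed stacks", {
  # order 0 is the measured outputs themselves
  L0 <- lie_derivatives(zoo_betacasein(), observation_setup("y"), 0)
  expect_equal(deparse1(L0[["y|0"]]), "x")

  # twocomp, y = x2, order 1: [x2, p1*x1 - p2*x2]
  L <- lie_derivatives(zoo_twocomp(), observation_setup("y"), 1)
  expect_length(L, 2L)
  expect_equal(deparse1(L[["y|0"]]), "x2")
  pt <- list(x1 = 3, x2 = 7, p1 = 2, p2 = 5)
  expect_equal(eval(L[["y|1"]], pt), 2 * 3 - 5 * 7)

  # constant input class: no input-derivative indeterminates appear
  Lc <- lie_derivatives(zoo_monod_haldane(),
                        observation_setup(c("y1", "y2"), input_class = "constant"),
                        2)
  syms <- unique(unlist(lapply(Lc, all.vars)))
  expect_false(any(grepl("__d", syms)))

  # generic-smooth input class introduces u__d1 at order 2
  Lg <- lie_derivatives(zoo_monod_haldane(),
                        observation_setup("y2", input_class = "generic_smooth"),
                        2)
  expect_true("u__d1" %in% all.vars(Lg[["y2|2"]]))

  # a tiny node budget triggers the budget-exceeded error
  expect_error(
    lie_derivatives(zoo_methanogenesis(),
                    observation_setup(c("xH2", "ng_H2")), 4, node_budget = 10),
    class = "odeident_budget_exceeded"
  )
})

test_that("rank verdicts reproduce the worked examples", {
  # twocomp, y = x2, x1(0) unknown: locally identifiable (rank condition)
  r <- test_local_identifiability(zoo_twocomp(), observation_setup("y"))
  expect_equal(r$generic_rank, r$n_unknowns)
  expect_true(all(r$per_quantity_verdict == "locally_identifiable"))
  expect_length(r$nullspace_basis, 0L)

  # betacasein: all of k, Km, kI non-identifiable, rank deficiency 1
  rb <- test_local_identifiability(zoo_betacasein(), observation_setup("y"))
  expect_equal(rb$n_unknowns - rb$generic_rank, 1L)
  expect_true(all(rb$per_quantity_verdict == "non_identifiable"))

  # reparameterized model: both b1 and b2 identifiable
  rr <- test_local_identifiability(zoo_betacasein_reduced(),
                                   observation_setup("y"))
  expect_true(all(rr$per_quantity_verdict == "locally_identifiable"))

  # methanogenesis, measured {xH2, ng_H2}: yields of the unmeasured gases
  # are the only non-identifiable parameters
  rm2 <- test_local_identifiability(zoo_methanogenesis(),
                                    observation_setup(c("xH2", "ng_H2")))
  expect_equal(rm2$per_quantity_verdict[c("mu_max", "Ks", "kd", "Y")],
               c(mu_max = "locally_identifiable", Ks = "locally_identifiable",
                 kd = "locally_identifiable", Y = "locally_identifiable"))
  expect_equal(unname(rm2$per_quantity_verdict[c("YCO2", "YCH4")]),
               rep("non_identifiable", 2L))

  # adding the gas-phase CO2 and CH4 measurements identifies all six
  rm4 <- test_local_identifiability(
    zoo_methanogenesis(),
    observation_setup(c("xH2", "ng_H2", "ng_CO2", "ng_CH4")))
  expect_true(all(rm4$per_quantity_verdict == "locally_identifiable"))

  # the stoichiometric reduction leaves 4 unknowns, all identifiable from
  # the two-output scenario
  rred <- test_local_identifiability(zoo_methanogenesis_reduced(),
                                     observation_setup(c("xH2", "ng_H2")))
  expect_equal(rred$n_unknowns, 4L)
  expect_true(all(rred$per_quantity_verdict == "locally_identifiable"))
})

test_that("generic rank is seed-invariant and monotone in measured outputs", {
  for (s in c(1, 101, 2024)) {
    r <- test_local_identifiability(zoo_betacasein(), observation_setup("y"),
                                    seed = s)
    expect_equal(r$generic_rank, 2L, info = paste("seed", s))
  }
  scen <- list(c("xH2"), c("xH2", "ng_H2"),
               c("xH2", "ng_H2", "ng_CO2"),
               c("xH2", "ng_H2", "ng_CO2", "ng_CH4"))
  ranks <- integer(length(scen))
  verdicts <- list()
  for (i in seq_along(scen)) {
    r <- test_local_identifiability(zoo_methanogenesis(),
                                    observation_setup(scen[[i]]))
    ranks[i] <- r$generic_rank
    verdicts[[i]] <- r$per_quantity_verdict
  }
  expect_true(all(diff(ranks) >= 0))
  for (i in seq_len(length(scen) - 1L)) {
    was_ident <- names(which(verdicts[[i]] == "locally_identifiable"))
    expect_true(all(verdicts[[i + 1L]][was_ident] == "locally_identifiable"))
  }
})

test_that("null-space directions are compensation directions", {
  # betacasein: exactly one direction, orthogonal to the gradients of the
  # identifiable combinations b1(k,Km,kI), b2(k,Km,kI)
  r <- test_local_identifiability(zoo_betacasein(), observation_setup("y"))
  basis <- nullspace_directions(r)
  expect_length(basis, 1L)
  v <- basis[[1L]][c("k", "Km", "kI")]
  pt <- as.list(r$evaluation_point)
  b1 <- quote(k * kI / (Km - kI))
  b2 <- quote(Km * (kI + 10) / (Km - kI))
  for (b in list(b1, b2)) {
    grad <- vapply(c("k", "Km", "kI"),
                   function(s) eval(stats::D(b, s), pt), numeric(1L))
    expect_lt(abs(sum(grad * v)) / sqrt(sum(grad^2) * sum(v^2)), 1e-6)
  }

  # methanogenesis two-output scenario: the compensable directions live
  # entirely on the unmeasured-gas yields
  rm <- test_local_identifiability(zoo_methanogenesis(),
                                   observation_setup(c("xH2", "ng_H2")))
  nb <- nullspace_directions(rm)
  expect_length(nb, 2L)
  for (vec in nb) {
    expect_equal(unname(vec[c("mu_max", "Ks", "kd", "Y")]), rep(0, 4))
    expect_gt(max(abs(vec[c("YCO2", "YCH4")])), 0)
  }

  # full-rank result: empty list
  expect_length(
    nullspace_directions(
      test_local_identifiability(zoo_betacasein_reduced(),
                                 observation_setup("y"))),
    0L)
})

test_that("quantities absent from all Lie derivatives are non-identifiable", {
  # YCH4 never appears in the xH2 / ng_H2 equations
  L <- lie_derivatives(zoo_methanogenesis(),
                       observation_setup(c("xH2", "ng_H2")), 3)
  expect_false("YCH4" %in% unique(unlist(lapply(L, all.vars))))
  r <- test_local_identifiability(zoo_methanogenesis(),
                                  observation_setup(c("xH2", "ng_H2")))
  expect_equal(unname(r$per_quantity_verdict[["YCH4"]]), "non_identifiable")
})

test_that("structural results tidy into quantity tables", {
  r <- test_local_identifiability(zoo_betacasein(), observation_setup("y"))
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$quantity, c("k", "Km", "kI"))
  expect_false(any(td$identifiable))
  g <- glance(r)
  expect_equal(g$rank_deficiency, 1L)
})
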