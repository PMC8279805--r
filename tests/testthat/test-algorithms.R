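base_sc <- function(P) scenario(default_parameters(), P)

test_that("base-case expected costs match the hand-derived closed forms", {
  pars <- default_parameters()
  exact <- c(psg_first = 588.30, l2_first = 416.55,
             l3_then_psg = 606.69875, l3_then_l2 = 480.9348125)
  for (a in algorithm_ids()) {
    got <- expected_cost(build_algorithm(a, pars), base_sc(0.5))
    expect_equal(got, unname(exact[a]), tolerance = 1e-12)
    # and across P the whole affine curve matches the oracle
    for (P in seq(0, 1, by = 0.05)) {
      expect_equal(expected_cost(build_algorithm(a, pars), base_sc(P)),
                   ref_cost(a, P), tolerance = 1e-9)
    }
  }
  expect_equal(
    unname(round(sapply(algorithm_ids(), function(a) {
      expected_cost(build_algorithm(a, pars), base_sc(0.5))
    }))),
    c(588, 417, 607, 481))
})

test_that("PSG-first cost reduces to C(1 + ABP) when the CPAP trial is free", {
  set.seed(101)
  for (i in 1:20) {
    pars <- random_parameters()
    pars$cpap_trial_cost <- 0
    P <- runif(1)
    expected <- pars$psg_cost *
      (1 + pars$cpap_nonresponse_frac * pars$repeat_psg_frac * P)
    expect_equal(expected_cost(build_psg_first(pars), scenario(pars, P)),
                 expected, tolerance = 1e-9)
    # LII-first reduces to (K + JC) + CABP under the same condition
    expected_l2 <- pars$l2_cost + pars$l2_failure_rate * pars$psg_cost +
      pars$psg_cost * pars$cpap_nonresponse_frac * pars$repeat_psg_frac * P
    expect_equal(expected_cost(build_l2_first(pars), scenario(pars, P)),
                 expected_l2, tolerance = 1e-9)
  }
})

test_that("closed-form PSG cost equals tree evaluation at random scenarios", {
  set.seed(101)
  for (i in 1:50) {
    pars <- random_parameters()
    sc <- scenario(pars, runif(1))
    tree_val <- expected_cost(build_psg_first(pars), sc)
    cf <- closed_form_psg_cost(sc)
    expect_lt(abs(tree_val - cf) / max(abs(cf), 1), 1e-9)
  }
})

test_that("a never-failing LII priced like PSG degenerates to the PSG-first strategy", {
  set.seed(101)
  for (i in 1:10) {
    pars <- random_parameters()
    pars$l2_failure_rate <- 0
    pars$l2_cost <- pars$psg_cost
    for (P in c(0, 0.37, 1)) {
      sc <- scenario(pars, P)
      expect_identical(expected_cost(build_l2_first(pars), sc),
                       expected_cost(build_psg_first(pars), sc))
    }
  }
})

test_that("a free, perfect, never-failing LIII screen leaves only downstream study costs", {
  pars <- model_parameters(F = 1, G = 1, E = 0, I = 0)
  paths <- enumerate_paths(build_l3_then_psg(pars), scenario(pars, 0.5))
  # the true-positive responder exits having paid only the CPAP trial
  tp_resp <- paths[paths$outcome == "true positive, CPAP responder", ]
  expect_equal(tp_resp$cost, pars$cpap_trial_cost)
  # perfect screen: no false positives or false negatives reachable
  fn_fp <- grepl("^false", paths$outcome)
  expect_true(all(paths$probability[fn_fp] == 0))
})

test_that("PSG-first and LII-first costs are nondecreasing in pretest probability", {
  set.seed(101)
  for (i in 1:10) {
    pars <- random_parameters()
    for (a in c("psg_first", "l2_first")) {
      tree <- build_algorithm(a, pars)
      c0 <- expected_cost(tree, scenario(pars, 0))
      c1 <- expected_cost(tree, scenario(pars, 1))
      expect_gte(c1, c0 - 1e-12)
    }
  }
})

test_that("base-case least-cost frontier: LII first at low P, LIII->LII at very high P", {
  pars <- default_parameters()
  grid <- seq(0, 1, by = 0.01)
  sw <- sweep_costs(pars, grid)
  expect_true(all(sw$cheapest[sw$pretest_prob <= 0.80] == "l2_first"))
  expect_true(all(sw$cheapest[sw$pretest_prob >= 0.82] == "l3_then_l2"))
})

test_that("dispatch builds the four distinct strategies and rejects unknown ids", {
  pars <- default_parameters()
  expect_equal(expected_cost(build_algorithm("psg_first", pars), base_sc(0.2)),
               expected_cost(build_psg_first(pars), base_sc(0.2)))
  expect_equal(expected_cost(build_algorithm("L3_THEN_L2", pars), base_sc(0.2)),
               expected_cost(build_l3_then_l2(pars), base_sc(0.2)))
  expect_error(build_algorithm("l4_first", pars), "unknown algorithm")
  expect_identical(length(algorithm_ids()), 4L)
  expect_identical(algorithm_label("l2_first"), "Initial LII")
  expect_error(build_psg_first(model_parameters(A = 2)), "invalid")
})
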