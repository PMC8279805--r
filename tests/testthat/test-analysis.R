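base_sc <- function(P) scenario(default_parameters(), P)

test_that("sweep rows carry all four costs and the least-cost strategy", {
  sw <- sweep_costs(default_parameters(), 0.5)
  expect_identical(names(sw),
                   c("pretest_prob", "cost_psg_first", "cost_l2_first",
                     "cost_l3_then_psg", "cost_l3_then_l2", "cheapest"))
  expect_equal(round(unlist(sw[1, 2:5])),
               c(cost_psg_first = 588, cost_l2_first = 417,
                 cost_l3_then_psg = 607, cost_l3_then_l2 = 481))
  expect_identical(sw$cheapest, "l2_first")

  sw0 <- sweep_costs(default_parameters(), 0)
  expect_identical(sw0$cheapest, "l2_first")
  expect_equal(sw0$cost_l2_first, 383.25)

  expect_error(sweep_costs(default_parameters(), numeric(0)), "nonempty")
  expect_error(sweep_costs(default_parameters(), c(0.5, 0.2)), "increasing")
  expect_error(sweep_costs(default_parameters(), c(0.2, 1.2)), "\\[0, 1\\]")
})

test_that("the base-case least-cost frontier switches exactly once", {
  sw <- sweep_costs(default_parameters(), seq(0, 1, by = 0.01))
  runs <- rle(sw$cheapest)
  expect_identical(runs$values, c("l2_first", "l3_then_l2"))
})

test_that("crossover probabilities match the analytic curve intersections", {
  pars <- default_parameters()

  x1 <- crossover_probability("psg_first", "l3_then_psg", pars)
  expect_equal(x1$crossover_prob, 167 / 297.2025, tolerance = 1e-6)
  expect_lt(x1$crossover_prob, 0.6)

  x2 <- crossover_probability("l2_first", "l3_then_l2", pars)
  expect_equal(x2$crossover_prob, 167 / 205.230375, tolerance = 1e-6)
  expect_gt(x2$crossover_prob, 0.8)

  # agreement with the intersection of two-point affine fits
  for (x in list(x1, x2)) {
    ca <- sapply(c(0, 1), function(P) {
      expected_cost(build_algorithm(x$algorithm_a, pars), base_sc(P))
    })
    cb <- sapply(c(0, 1), function(P) {
      expected_cost(build_algorithm(x$algorithm_b, pars), base_sc(P))
    })
    analytic <- (cb[1] - ca[1]) / ((ca[2] - ca[1]) - (cb[2] - cb[1]))
    expect_equal(x$crossover_prob, analytic, tolerance = 1e-6)
  }
})

test_that("parallel cost curves report an absent crossover", {
  # PSG-first and LII-first share the slope C*A*B, offset K + JC - C < 0
  x <- crossover_probability("psg_first", "l2_first", default_parameters())
  expect_true(is.na(x$crossover_prob))
  expect_error(crossover_probability("l2_first", "l2_first",
                                     default_parameters()),
               "different")
  expect_error(crossover_probability("psg_first", "l2_first",
                                     default_parameters(), c(0.9, 0.1)),
               "bracket")
})

test_that("break-even LII cost equating PSG-first and LII-first is 471.75", {
  be <- breakeven_parameter("l2_cost", "psg_first", "l2_first",
                            base_sc(0.5), c(0, 1000))
  expect_equal(be$value, 471.75, tolerance = 1e-6)
  expect_equal(be$value_nearest_10, 470)

  # plugging the root back makes the strategies agree
  pars2 <- model_parameters(K = be$value)
  d <- expected_cost(build_psg_first(pars2), scenario(pars2, 0.5)) -
    expected_cost(build_l2_first(pars2), scenario(pars2, 0.5))
  expect_lt(abs(d), 1e-4)

  # with a never-failing LII the break-even sits exactly at PSG's price
  sc_nofail <- scenario(model_parameters(J = 0), 0.5)
  be0 <- breakeven_parameter("l2_cost", "psg_first", "l2_first",
                             sc_nofail, c(0, 1000))
  expect_equal(be0$value, 555, tolerance = 1e-6)
})

test_that("break-even without a sign change is reported, not raised", {
  be <- breakeven_parameter("psg_cost", "psg_first", "l3_then_psg",
                            base_sc(0.9), c(554, 556))
  expect_true(is.na(be$value))
  expect_identical(be$note, "no break-even in bracket")
  expect_error(breakeven_parameter("zz", "psg_first", "l2_first",
                                   base_sc(0.5), c(0, 1)),
               "unknown parameter field")
})

test_that("cohort savings follow the stated rounding policies", {
  sc <- base_sc(0.5)
  expect_equal(cohort_savings("psg_first", "l2_first", sc, 1000), 171000)
  expect_equal(cohort_savings("psg_first", "l2_first", sc, 1000,
                              rounding = "exact"), 171750)
  expect_equal(cohort_savings("l2_first", "l2_first", sc, 500), 0)
  expect_error(cohort_savings("psg_first", "l2_first", sc, 0), "positive")
})

test_that("one-way sensitivity moves only the targeted strategy's cost as expected", {
  tab <- one_way_sensitivity("l2_cost", c(300, 470, 555), base_sc(0.5))
  expect_identical(nrow(tab), 3L)
  expect_true(all(diff(tab$cost_l2_first) > 0))
  # at the break-even neighbourhood LII-first sits within $2 of PSG-first
  expect_lt(abs(tab$cost_l2_first[2] - tab$cost_psg_first[2]), 2)
  # the PSG-first column ignores the LII price entirely
  expect_equal(tab$cost_psg_first, rep(588.30, 3), tolerance = 1e-9)

  # varying a parameter at its default reproduces the baseline
  tab0 <- one_way_sensitivity("cpap_trial_cost", 0, base_sc(0.5))
  expect_equal(unlist(tab0[1, -1]),
               unlist(sweep_costs(default_parameters(), 0.5)[1, 2:5]),
               tolerance = 1e-12)
  expect_error(one_way_sensitivity("l2_cost", -5, base_sc(0.5)), "invalid")
})
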