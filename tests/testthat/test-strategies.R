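test_that("time_to_resistance picks the first census at or above threshold", {
  sc <- scenario(insecticide_params(start_frequency = 0.6),
                 insecticide_params())
  res <- run_single(sc, 1)
  expect_equal(res$time_locus1, 0L) # already above threshold at start
  expect_equal(time_to_resistance(res$trajectory, 1, 0.5), 0L)

  # no selection at all: threshold never reached, NA not an error
  quiet <- insecticide_params(effectiveness = 0, cost = 0)
  sc0 <- scenario(quiet, quiet, max_generations = 50)
  res0 <- run_single(sc0, 1)
  expect_true(is.na(res0$total_time))
  expect_identical(time_to_resistance(res0$trajectory, 1, 0.5), NA_integer_)
})

test_that("single deployment leaves the idle locus to cost selection only", {
  p2 <- insecticide_params(cost = 0.1, dominance_cost = 0.5,
                           start_frequency = 0.05)
  sc <- scenario(insecticide_params(), p2, max_generations = 100)
  res <- run_single(sc, 1)
  f2 <- res$trajectory$freq_locus2_mean
  expect_true(all(diff(f2) <= 1e-12)) # non-increasing under pure cost
})

test_that("stronger selection shortens single-use time-to-resistance", {
  base_time <- run_single(scenario_preset("base"), 1)$total_time
  tweak <- function(...) {
    scenario(insecticide_params(...), insecticide_params())
  }
  for (arg in c("effectiveness", "exposure", "dominance_resistance",
                "resistance_restoration")) {
    args <- stats::setNames(list(0.8), arg)
    t_hi <- run_single(do.call(tweak, args), 1)$total_time
    expect_lt(t_hi, base_time)
  }
  # cost slows resistance down
  t_cost <- run_single(tweak(cost = 0.15, dominance_cost = 0.5),
                       1)$total_time
  expect_gt(t_cost, base_time)
  # lower starting frequency strictly lengthens the wait
  t_low_start <- run_single(tweak(start_frequency = 0.001), 1)$total_time
  expect_gt(t_low_start, base_time)
})

test_that("sequence bookkeeping: switch after crossing, total at second crossing", {
  sc <- scenario_preset("base")
  res <- run_sequence(sc)
  tr <- res$trajectory
  # phase 1 rows (including the crossing generation) deploy insecticide 1
  expect_true(all(tr$deployment[tr$generation <= res$time_locus1] ==
                    "insecticide1"))
  expect_true(all(tr$deployment[tr$generation > res$time_locus1] ==
                    "insecticide2"))
  expect_equal(res$total_time, res$time_locus2)
  # symmetric scenario: the two phases take the same number of generations
  expect_equal(res$time_locus2 - res$time_locus1, res$time_locus1)
})

test_that("with costs the first resistance allele declines after the switch", {
  sc <- scenario_preset("cost_both")
  res <- run_sequence(sc)
  tr <- res$trajectory
  post <- tr$freq_locus1_mean[tr$generation > res$time_locus1]
  expect_true(all(diff(post) < 0))
})

test_that("mixture total time is the later of the two crossings", {
  sc <- scenario_preset("eff1_high")
  res <- run_mixture(sc)
  expect_equal(res$total_time, max(res$time_locus1, res$time_locus2))
  expect_gte(res$total_time, res$time_locus1)
  final <- res$trajectory[nrow(res$trajectory), ]
  expect_gte(final$freq_locus1_mean, 0.5)
  expect_gte(final$freq_locus2_mean, 0.5)
})

test_that("mixture protects each insecticide relative to sole use", {
  set.seed(2026)
  for (i in 1:25) {
    sc <- random_scenario(60)
    alone <- run_single(sc, 1)$trajectory
    mixed <- run_mixture(sc)$trajectory
    n <- min(nrow(alone), nrow(mixed))
    expect_true(all(mixed$freq_locus1_mean[1:n] <=
                      alone$freq_locus1_mean[1:n] + 1e-12))
  }
})

test_that("strategy ordering is robust to the threshold choice", {
  for (thr in c(0.25, 0.5, 0.75)) {
    sc <- scenario(insecticide_params(), insecticide_params(),
                   resistance_threshold = thr)
    cmp <- compare_strategies(sc)
    # sequence beats mixture on the base parameterisation at all thresholds
    expect_gt(cmp$sequence$total_time, cmp$mixture$total_time)
  }
  for (thr in c(0.25, 0.5, 0.75)) {
    p1 <- insecticide_params(effectiveness = 0.8)
    sc <- scenario(p1, insecticide_params(), resistance_threshold = thr)
    cmp <- compare_strategies(sc)
    # high effectiveness flips the ordering at all thresholds
    expect_lt(cmp$sequence$total_time, cmp$mixture$total_time)
  }
})

test_that("dominance, restoration and start frequency leave the ordering alone", {
  sign_base <- with(compare_strategies(scenario_preset("base")),
                    sign(mixture$total_time - sequence$total_time))
  for (preset in c("dominance1_high", "restoration1_high", "start1_low")) {
    cmp <- compare_strategies(scenario_preset(preset))
    expect_equal(sign(cmp$mixture$total_time - cmp$sequence$total_time),
                 sign_base)
  }
  # and on the high-effectiveness side, lowering start frequency keeps the
  # mixture favoured
  cmp_hi <- compare_strategies(scenario_preset("eff1_high"))
  cmp_hi_low <- compare_strategies(scenario_preset("eff1_high_start1_low"))
  expect_equal(sign(cmp_hi_low$mixture$total_time -
                      cmp_hi_low$sequence$total_time),
               sign(cmp_hi$mixture$total_time - cmp_hi$sequence$total_time))
})

test_that("the ratio is rounded half away from zero to one decimal", {
  expect_equal(irmsim:::round_half_up(0.75, 1), 0.8)
  expect_equal(irmsim:::round_half_up(0.6290, 1), 0.6)
  expect_equal(irmsim:::round_half_up(1.25, 1), 1.3)
  cmp <- compare_strategies(scenario_preset("base"))
  expect_equal(cmp$ratio, cmp$mixture$total_time / cmp$sequence$total_time)
  expect_equal(cmp$ratio_rounded, irmsim:::round_half_up(cmp$ratio, 1))
})

test_that("not-reached runs return sentinels, never exceptions", {
  quiet <- insecticide_params(effectiveness = 0.3,
                              resistance_restoration = 0.3)
  sc <- scenario(quiet, quiet, max_generations = 10)
  cmp <- compare_strategies(sc)
  expect_true(is.na(cmp$sequence$total_time))
  expect_true(is.na(cmp$ratio))
  expect_true(is.na(cmp$ratio_rounded))
})
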