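pyrethroid_data <- function() {
  read_bioassay(system.file("extdata", "bioassay_pyrethroid_kdr.csv",
                            package = "irmsim", mustWork = TRUE))
}
carbamate_data <- function() {
  read_bioassay(system.file("extdata", "bioassay_carbamate_ace1.csv",
                            package = "irmsim", mustWork = TRUE))
}

test_that("survival is alive over total, with boundary cases", {
  expect_equal(survival_from_counts(83, 17), 0.83)
  expect_equal(survival_from_counts(0, 50), 0)
  expect_equal(survival_from_counts(1, 0), 1)
  expect_equal(survival_from_counts(c(83, 0), c(17, 50)), c(0.83, 0))
  expect_error(survival_from_counts(0, 0), "positive")
  expect_error(survival_from_counts(-1, 2), "non-negative")
})

test_that("rescaling divides by the unexposed SS survival", {
  resc <- rescale_survivals(pyrethroid_data())
  get <- function(g, a) resc$survival[resc$genotype == g & resc$arm == a]
  expect_equal(get("RR", "exposed"), 1)
  expect_equal(round(get("SS", "exposed"), 2), 0.71)
  expect_equal(get("SS", "unexposed"), 1)
  expect_equal(round(get("RR", "unexposed"), 2), 0.81)

  # reference 1 is the identity transform
  d <- tibble::tibble(genotype = c("SS", "SS"),
                      arm = c("exposed", "unexposed"),
                      survival = c(0.4, 1))
  expect_equal(rescale_survivals(d)$survival, c(0.4, 1))

  # missing reference instructs the caller towards the no-cost path
  expect_error(rescale_survivals(carbamate_data()), "no-cost")

  # survivals above the reference are capped with a warning
  d2 <- tibble::tibble(genotype = c("SS", "RR", "SS"),
                       arm = c("exposed", "exposed", "unexposed"),
                       survival = c(0.5, 0.9, 0.8))
  expect_warning(out <- rescale_survivals(d2), "capped")
  expect_equal(max(out$survival), 1)
})

test_that("carbamate worked example: no control arm means no costs", {
  params <- derive_insecticide_params(carbamate_data())
  expect_equal(round(params$effectiveness, 2), 0.98)
  expect_equal(round(params$resistance_restoration, 2), 0.84)
  expect_equal(round(params$dominance_resistance, 2), 0.66)
  expect_equal(params$cost, 0)
  expect_equal(params$dominance_cost, 0)
})

test_that("pyrethroid worked example: rescaled parameters and the underdominance clamp", {
  expect_warning(
    params <- derive_insecticide_params(rescale_survivals(pyrethroid_data())),
    "underdominance"
  )
  expect_equal(round(params$effectiveness, 2), 0.29)
  expect_equal(round(params$cost, 2), 0.19)
  expect_equal(params$resistance_restoration, 1)
  expect_equal(round(params$dominance_resistance, 2), 0.54)
  expect_equal(params$dominance_cost, 1) # SR cost forced equal to RR cost

  # unrescaled exposed SS gives the raw effectiveness
  raw <- suppressWarnings(derive_insecticide_params(pyrethroid_data()))
  expect_equal(round(raw$effectiveness, 2), 0.41)
})

test_that("derivation clamps pathological signals with warnings", {
  # exposed RR below SS: no resistance signal
  d <- tibble::tibble(genotype = c("SS", "SR", "RR"), arm = "exposed",
                      survival = c(0.5, 0.4, 0.3))
  expect_warning(p <- derive_insecticide_params(d), "no resistance signal")
  expect_equal(p$resistance_restoration, 0)

  # boundary: complete kill and complete restoration
  d2 <- tibble::tibble(genotype = c("SS", "SR", "RR"), arm = "exposed",
                       survival = c(0, 0.5, 1))
  p2 <- derive_insecticide_params(d2)
  expect_equal(p2$effectiveness, 1)
  expect_equal(p2$resistance_restoration, 1)
})

test_that("derived parameters reproduce the input survivals (round trip)", {
  params <- suppressWarnings(
    derive_insecticide_params(rescale_survivals(pyrethroid_data())))
  resc <- rescale_survivals(pyrethroid_data())
  get <- function(g, a) resc$survival[resc$genotype == g & resc$arm == a]
  w_exp <- single_locus_fitness(params, exposed = TRUE)
  w_un <- single_locus_fitness(params, exposed = FALSE)
  wf <- function(tbl, g) tbl$fitness[tbl$genotype == g]
  expect_equal(wf(w_exp, "SS"), get("SS", "exposed"))
  expect_equal(wf(w_exp, "RR"), get("RR", "exposed"))
  expect_equal(wf(w_exp, "SR"), get("SR", "exposed")) # dominance not clamped
  expect_equal(wf(w_un, "SS"), get("SS", "unexposed"))
  expect_equal(wf(w_un, "RR"), get("RR", "unexposed"))
  # SR unexposed is clamped up to the RR fitness (underdominance removed)
  expect_equal(wf(w_un, "SR"), wf(w_un, "RR"))

  # exact round trip when nothing needs clamping
  p0 <- insecticide_params(effectiveness = 0.7, resistance_restoration = 0.6,
                           dominance_resistance = 0.3, cost = 0.1,
                           dominance_cost = 0.4)
  surv <- tibble::tibble(
    genotype = rep(c("SS", "SR", "RR"), 2),
    arm = rep(c("exposed", "unexposed"), each = 3),
    survival = c(single_locus_fitness(p0, TRUE)$fitness,
                 single_locus_fitness(p0, FALSE)$fitness)
  )
  p_back <- derive_insecticide_params(surv)
  for (f in c("effectiveness", "resistance_restoration",
              "dominance_resistance", "cost", "dominance_cost")) {
    expect_equal(p_back[[f]], p0[[f]], tolerance = 1e-12)
  }
})

test_that("rescaling commutes with derivation on the worked example", {
  params_a <- suppressWarnings(
    derive_insecticide_params(rescale_survivals(pyrethroid_data())))
  pre <- pyrethroid_data()
  pre$survival <- pre$survival / 0.83
  pre$survival <- pmin(pre$survival, 1)
  params_b <- suppressWarnings(derive_insecticide_params(pre))
  expect_equal(unclass(params_a)[names(unclass(params_a))],
               unclass(params_b)[names(unclass(params_b))],
               tolerance = 1e-12)
})

test_that("the display report rounds but the object keeps full precision", {
  params <- derive_insecticide_params(carbamate_data())
  rep <- calibration_report(params)
  expect_equal(rep$value_displayed[rep$parameter == "resistance_restoration"],
               0.84)
  expect_false(isTRUE(all.equal(
    params$resistance_restoration, 0.84, tolerance = 1e-6)))
})
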