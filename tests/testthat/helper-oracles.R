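# Closed-form one-locus selection recursion: allele frequency after one
# generation of viability selection with genotype fitnesses (w_ss, w_sr,
# w_rr), used as an independent oracle for the two-locus engine with one
# locus monomorphic.
one_locus_recursion <- function(p, w_ss, w_sr, w_rr) {
  mean_w <- p^2 * w_rr + 2 * p * (1 - p) * w_sr + (1 - p)^2 * w_ss
  p * (p * w_rr + (1 - p) * w_sr) / mean_w
}

base_scenario <- function(...) scenario_preset("base")

# A random but valid insecticide parameter draw with enough selection to be
# interesting; restoration bounded away from 0 so resistance exists.
# Exposure is shared across a scenario's insecticides (it is a property of
# the deployment setting, not of the molecule), so it is drawn separately.
random_params <- function(exposure = runif(1, 0.2, 1)) {
  insecticide_params(
    effectiveness = runif(1, 0.2, 1),
    exposure = exposure,
    resistance_restoration = runif(1, 0.3, 1),
    dominance_resistance = runif(1, 0, 1),
    start_frequency = runif(1, 0.001, 0.1),
    cost = runif(1, 0, 0.1),
    dominance_cost = runif(1, 0, 1)
  )
}

# 9-genotype fitness tibble that depends only on the locus-1 genotype.
locus1_only_fitness <- function(w_ss, w_sr, w_rr) {
  tidyr::expand_grid(genotype1 = c("SS", "SR", "RR"),
                     genotype2 = c("SS", "SR", "RR")) |>
    dplyr::mutate(fitness = c(SS = w_ss, SR = w_sr, RR = w_rr)[genotype1])
}

# Population state with locus 2 exactly monomorphic susceptible.
monomorphic_locus2_state <- function(p1) {
  irmsim:::new_population_state(
    stats::setNames(c(1 - p1, 0, p1, 0), c("S1S2", "S1R2", "R1S2", "R1R2")),
    stats::setNames(c(1 - p1, 0, p1, 0), c("S1S2", "S1R2", "R1S2", "R1R2")),
    0L
  )
}

# Scenario with two independent parameter draws sharing one exposure.
random_scenario <- function(max_generations = 60) {
  x <- runif(1, 0.2, 1)
  scenario(random_params(exposure = x), random_params(exposure = x),
           max_generations = max_generations)
}
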