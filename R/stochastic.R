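#' Finite-population stochastic counterpart of the deterministic engine
#'
#' Individual-based analogue of the deterministic recursion, used to check
#' that the infinite-population model is the correct limit: each generation
#' `n` offspring are formed by multinomial sampling of maternal and paternal
#' gamete pairs, assigned a sex by a fair coin, subjected to viability
#' selection (survival probability proportional to the sex-specific marginal
#' fitness), and the survivors' gametes (with recombination) parameterise
#' the next generation's draw. With large `n` the mean trajectory converges
#' on the deterministic one.
#'
#' @param scenario A [scenario()].
#' @param deployment One of `"none"`, `"insecticide1"`, `"insecticide2"`,
#'   `"mixture"`, held fixed for the whole run.
#' @param generations Number of generations to simulate.
#' @param n Number of offspring sampled per generation (population size).
#' @return A tibble with columns `generation`, `freq_locus1_mean`,
#'   `freq_locus2_mean` (sex-averaged adult allele frequencies).
#' @examples
#' set.seed(1)
#' simulate_stochastic(scenario(), "mixture", generations = 5, n = 500)
#' @export
simulate_stochastic <- function(scenario, deployment = "mixture",
                                generations = 20, n = 10000) {
  stopifnot(inherits(scenario, "scenario"), n >= 2, generations >= 1)
  wf4 <- expand_fitness(marginal_matrix(scenario, deployment, "female"))
  wm4 <- expand_fitness(marginal_matrix(scenario, deployment, "male"))
  if (max(wf4) > 1 || max(wm4) > 1) {
    stop("marginal fitnesses above 1 cannot be used as survival probabilities",
         call. = FALSE)
  }
  t_mat <- transmission_matrix(scenario$recombination_rate)
  gam_f <- gam_m <- init_population(scenario$insecticide1$start_frequency,
                                    scenario$insecticide2$start_frequency)$female

  rec <- matrix(NA_real_, nrow = generations + 1L, ncol = 2L)
  freq_of <- function(counts4x4) {
    # adult genotype counts -> allele frequencies (2 alleles per individual)
    tot <- sum(counts4x4)
    if (tot == 0) return(c(NA_real_, NA_real_))
    mat <- rowSums(counts4x4) # maternal haplotype counts
    pat <- colSums(counts4x4)
    c(sum(mat[HAP_HAS_R1] + pat[HAP_HAS_R1]) / (2 * tot),
      sum(mat[HAP_HAS_R2] + pat[HAP_HAS_R2]) / (2 * tot))
  }

  p0 <- c(sum(gam_f[HAP_HAS_R1]), sum(gam_f[HAP_HAS_R2]))
  rec[1L, ] <- p0

  for (g in seq_len(generations)) {
    pair_probs <- as.vector(outer(gam_f, gam_m)) # 16 ordered pairs
    offspring <- matrix(stats::rmultinom(1L, n, pair_probs), 4, 4)
    females <- matrix(stats::rbinom(16L, as.vector(offspring), 0.5), 4, 4)
    males <- offspring - females
    surv_f <- matrix(stats::rbinom(16L, as.vector(females),
                                   as.vector(wf4)), 4, 4)
    surv_m <- matrix(stats::rbinom(16L, as.vector(males),
                                   as.vector(wm4)), 4, 4)
    if (sum(surv_f) == 0 || sum(surv_m) == 0) {
      stop("stochastic population went extinct; increase n or fitnesses",
           call. = FALSE)
    }
    # pair order is (maternal row, paternal column): transmission indexes
    # rows as (i - 1) * 4 + j with i the first haplotype, so transpose
    gam_f <- drop(as.vector(t(surv_f / sum(surv_f))) %*% t_mat)
    gam_f <- gam_f / sum(gam_f)
    gam_m <- drop(as.vector(t(surv_m / sum(surv_m))) %*% t_mat)
    gam_m <- gam_m / sum(gam_m)
    pf <- freq_of(surv_f)
    pm <- freq_of(surv_m)
    rec[g + 1L, ] <- (pf + pm) / 2
  }

  tibble::tibble(
    generation = 0:generations,
    freq_locus1_mean = rec[, 1L],
    freq_locus2_mean = rec[, 2L]
  )
}
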