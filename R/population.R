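# Gamete transmission under Mendelian segregation with recombination.
# Rows index ordered parental haplotype pairs ((i - 1) * 4 + j), columns the
# emitted gamete. Each genotype transmits half of each constituent
# haplotype, except the two double heterozygotes (S1S2/R1R2 "coupling" and
# S1R2/R1S2 "repulsion"), which emit parental haplotypes with weight
# (1 - c) / 2 and recombinants with weight c / 2.
transmission_matrix <- function(recombination_rate) {
  c_ <- recombination_rate
  t_mat <- matrix(0, nrow = 16, ncol = 4,
                  dimnames = list(NULL, HAPLOTYPES))
  for (i in 1:4) {
    for (j in 1:4) {
      row <- (i - 1L) * 4L + j
      if ((i == 1L && j == 4L) || (i == 4L && j == 1L)) {
        t_mat[row, c(1L, 4L)] <- (1 - c_) / 2
        t_mat[row, c(2L, 3L)] <- c_ / 2
      } else if ((i == 2L && j == 3L) || (i == 3L && j == 2L)) {
        t_mat[row, c(2L, 3L)] <- (1 - c_) / 2
        t_mat[row, c(1L, 4L)] <- c_ / 2
      } else {
        t_mat[row, i] <- t_mat[row, i] + 0.5
        t_mat[row, j] <- t_mat[row, j] + 0.5
      }
    }
  }
  t_mat
}

# Expand a 3x3 genotype fitness matrix to the 4x4 ordered-haplotype-pair
# scale used by the engine: entry (i, j) is the fitness of the genotype
# formed by maternal haplotype i and paternal haplotype j.
expand_fitness <- function(w3) {
  g1 <- outer(HAP_HAS_R1, HAP_HAS_R1, `+`) + 1L # 1 = SS, 2 = SR, 3 = RR
  g2 <- outer(HAP_HAS_R2, HAP_HAS_R2, `+`) + 1L
  matrix(w3[cbind(as.vector(g1), as.vector(g2))], 4, 4)
}

new_population_state <- function(female, male, generation) {
  structure(
    list(female = female, male = male, generation = as.integer(generation)),
    class = "population_state"
  )
}

check_freqs <- function(x, label) {
  if (any(x < 0) || abs(sum(x) - 1) > 1e-12) {
    stop(sprintf("%s haplotype frequencies must be non-negative and sum to 1",
                 label), call. = FALSE)
  }
}

#' Initialise a population at linkage equilibrium
#'
#' Build the generation-0 haplotype (gamete) frequencies for both sexes from
#' the two starting resistance-allele frequencies, assuming linkage
#' equilibrium: each haplotype frequency is the product of its allele
#' frequencies, so the linkage disequilibrium coefficient D is exactly 0.
#'
#' @param p1,p2 Starting R-allele frequencies at locus 1 and 2, strictly
#'   inside `(0, 1)`.
#' @return A `population_state`: haplotype frequency vectors (order `S1S2`,
#'   `S1R2`, `R1S2`, `R1R2`) for each sex plus a generation counter.
#' @examples
#' init_population(0.01, 0.01)
#' @export
init_population <- function(p1, p2) {
  for (p in list(p1, p2)) {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p >= 1) {
      stop("starting allele frequencies must lie strictly inside (0, 1)",
           call. = FALSE)
    }
  }
  h <- c((1 - p1) * (1 - p2), (1 - p1) * p2, p1 * (1 - p2), p1 * p2)
  names(h) <- HAPLOTYPES
  new_population_state(h, h, 0L)
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("<population_state> generation %d\n", x$generation))
  print(rbind(female = x$female, male = x$male))
  invisible(x)
}

# Core deterministic update on raw haplotype vectors. wf4 / wm4 are 4x4
# expanded marginal fitness matrices; t_mat the transmission matrix.
step_core <- function(female, male, wf4, wm4, t_mat) {
  geno <- outer(female, male) # offspring ordered-pair frequencies
  next_sex <- function(w4, label) {
    sel <- geno * w4
    mean_w <- sum(sel)
    if (mean_w <= 0) {
      stop(sprintf(
        "mean fitness of %ss is zero: population extinct under this scenario",
        label), call. = FALSE)
    }
    g <- drop(as.vector(t(sel / mean_w)) %*% t_mat)
    g / sum(g) # renormalise to suppress numerical drift
  }
  list(female = next_sex(wf4, "female"), male = next_sex(wm4, "male"))
}

#' Advance the population one generation
#'
#' One full cycle of the deterministic recursion: random union of female and
#' male gametes into offspring genotypes, sex-specific viability selection
#' (genotype frequencies multiplied by marginal fitness and renormalised by
#' mean fitness), then gamete production with recombination between the two
#' loci. The population is effectively infinite, so the recursion is
#' deterministic; with all fitnesses equal it is the identity apart from the
#' decay of linkage disequilibrium by the factor `1 - recombination_rate`
#' per generation.
#'
#' @param state A `population_state` (see [init_population()]).
#' @param fitness_female,fitness_male 9-genotype marginal fitness tibbles as
#'   returned by [marginal_fitness()].
#' @param recombination_rate Recombination fraction in `[0, 0.5]`.
#' @return The `population_state` of the next generation.
#' @examples
#' sc <- scenario()
#' st <- init_population(0.01, 0.01)
#' step_generation(st, marginal_fitness(sc, "mixture", "female"),
#'                 marginal_fitness(sc, "mixture", "male"))
#' @export
step_generation <- function(state, fitness_female, fitness_male,
                            recombination_rate = 0.5) {
  stopifnot(inherits(state, "population_state"))
  check_freqs(state$female, "female")
  check_freqs(state$male, "male")
  if (recombination_rate < 0 || recombination_rate > 0.5) {
    stop("`recombination_rate` must be in [0, 0.5]", call. = FALSE)
  }
  wf4 <- expand_fitness(fitness_tbl_to_matrix(fitness_female))
  wm4 <- expand_fitness(fitness_tbl_to_matrix(fitness_male))
  if (any(wf4 < 0) || any(wm4 < 0)) {
    stop("fitness values must be non-negative", call. = FALSE)
  }
  t_mat <- transmission_matrix(recombination_rate)
  nxt <- step_core(state$female, state$male, wf4, wm4, t_mat)
  new_population_state(nxt$female, nxt$male, state$generation + 1L)
}

#' Resistance allele frequencies of a population state
#'
#' The R-allele frequency at each locus is the summed frequency of the
#' haplotypes carrying R there; the headline (sex-averaged) value is the
#' unweighted mean of the female and male frequencies.
#'
#' @param state A `population_state`.
#' @return A tibble with columns `locus`, `female`, `male`, `mean`.
#' @examples
#' allele_frequencies(init_population(0.01, 0.2))
#' @export
allele_frequencies <- function(state) {
  stopifnot(inherits(state, "population_state"))
  p_f <- c(sum(state$female[HAP_HAS_R1]), sum(state$female[HAP_HAS_R2]))
  p_m <- c(sum(state$male[HAP_HAS_R1]), sum(state$male[HAP_HAS_R2]))
  tibble::tibble(
    locus = 1:2,
    female = p_f,
    male = p_m,
    mean = (p_f + p_m) / 2
  )
}

# D and D' from one haplotype frequency vector.
ld_from_haps <- function(h) {
  p1 <- sum(h[HAP_HAS_R1])
  p2 <- sum(h[HAP_HAS_R2])
  d <- h[["R1R2"]] - p1 * p2
  d_max <- if (d > 0) {
    min(p1 * (1 - p2), (1 - p1) * p2)
  } else {
    min(p1 * p2, (1 - p1) * (1 - p2))
  }
  d_prime <- if (d == 0 || d_max <= 0) 0 else d / d_max
  c(D = d, Dprime = d_prime)
}

#' Linkage disequilibrium of a population state
#'
#' The coefficient `D = f(R1R2) - p1 * p2` measures the excess frequency of
#' the doubly resistant haplotype over the linkage-equilibrium expectation;
#' `D'` normalises it by the maximum magnitude attainable at the current
#' allele frequencies. A monomorphic locus gives `D = D' = 0`.
#'
#' @param state A `population_state`.
#' @return A tibble with columns `sex`, `D`, `Dprime`.
#' @examples
#' linkage_disequilibrium(init_population(0.1, 0.1))
#' @export
linkage_disequilibrium <- function(state) {
  stopifnot(inherits(state, "population_state"))
  lf <- ld_from_haps(state$female)
  lm <- ld_from_haps(state$male)
  tibble::tibble(
    sex = c("female", "male"),
    D = c(lf[["D"]], lm[["D"]]),
    Dprime = c(lf[["Dprime"]], lm[["Dprime"]])
  )
}
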