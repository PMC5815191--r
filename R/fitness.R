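# Haplotype (gamete) bookkeeping shared across the package. Order is fixed:
# S1S2, S1R2, R1S2, R1R2. Position must never change: the transmission
# matrix and the double-heterozygote pairs below depend on it.
HAPLOTYPES <- c("S1S2", "S1R2", "R1S2", "R1R2")
HAP_HAS_R1 <- c(FALSE, FALSE, TRUE, TRUE)
HAP_HAS_R2 <- c(FALSE, TRUE, FALSE, TRUE)
GENOTYPES <- c("SS", "SR", "RR")

# Single-locus fitness triple as a plain numeric c(SS, SR, RR).
# Exposed: effectiveness sets SS, restoration recovers a fraction of the
# loss for RR, dominance interpolates SR. Unexposed: SS is the reference 1,
# cost sets RR, dominance of cost interpolates SR.
fitness_triple <- function(params, exposed) {
  if (exposed) {
    w_ss <- 1 - params$effectiveness
    w_rr <- w_ss + params$effectiveness * params$resistance_restoration
    w_sr <- w_ss + params$dominance_resistance * (w_rr - w_ss)
  } else {
    w_ss <- 1
    w_rr <- 1 - params$cost
    w_sr <- 1 - params$dominance_cost * params$cost
  }
  c(SS = w_ss, SR = w_sr, RR = w_rr)
}

#' Single-locus genotype fitnesses
#'
#' Compute the relative fitnesses of the SS, SR and RR genotypes at one
#' resistance locus, either in the presence or the absence of the
#' insecticide. Unexposed SS is the reference genotype with fitness 1.
#'
#' When exposed, `effectiveness` kills that proportion of SS insects, so
#' `w_SS = 1 - effectiveness`; `resistance_restoration` recovers that
#' fraction of the loss for RR, `w_RR = w_SS + effectiveness *
#' resistance_restoration`; and `dominance_resistance` places SR linearly
#' between the homozygotes. When unexposed, `w_SS = 1`, `w_RR = 1 - cost`,
#' and `dominance_cost` places SR between them.
#'
#' @param params An [insecticide_params()] object.
#' @param exposed Logical: fitness in the presence (`TRUE`) or absence
#'   (`FALSE`) of the insecticide.
#' @return A tibble with columns `genotype` (SS, SR, RR), `exposed` and
#'   `fitness`.
#' @examples
#' single_locus_fitness(
#'   insecticide_params(effectiveness = 0.8, resistance_restoration = 0.5,
#'                      dominance_resistance = 0.7),
#'   exposed = TRUE
#' )
#' @export
single_locus_fitness <- function(params, exposed = TRUE) {
  validate_insecticide_params(params)
  stopifnot(is.logical(exposed), length(exposed) == 1L, !is.na(exposed))
  w <- fitness_triple(params, exposed)
  tibble::tibble(
    genotype = GENOTYPES,
    exposed = exposed,
    fitness = unname(w)
  )
}

# 3x3 matrix of two-locus genotype fitnesses for a fixed exposure class:
# rows locus-1 genotype, cols locus-2 genotype. Multiplicative across loci.
two_locus_matrix <- function(params1, params2, exposed1, exposed2) {
  outer(fitness_triple(params1, exposed1), fitness_triple(params2, exposed2))
}

#' Two-locus genotype fitnesses for one exposure class
#'
#' Fitness of each of the nine two-locus genotypes when the individual is
#' contacted by a given subset of the two deployed insecticides. Overall
#' fitness is multiplicative across loci: each locus contributes its
#' single-locus fitness, evaluated as exposed if that insecticide is in the
#' exposure class and unexposed otherwise.
#'
#' @param params1,params2 [insecticide_params()] for the two insecticides.
#' @param exposure_class Character vector naming the insecticides contacted:
#'   any subset of `c("insecticide1", "insecticide2")`; `character(0)` (the
#'   default `"none"` shorthand) means contacted by neither.
#' @return A tibble with columns `genotype1`, `genotype2` and `fitness`
#'   (9 rows).
#' @examples
#' two_locus_fitness(insecticide_params(), insecticide_params(),
#'                   c("insecticide1", "insecticide2"))
#' @export
two_locus_fitness <- function(params1, params2,
                              exposure_class = character(0)) {
  validate_insecticide_params(params1)
  validate_insecticide_params(params2)
  if (identical(exposure_class, "none")) exposure_class <- character(0)
  bad <- setdiff(exposure_class, c("insecticide1", "insecticide2"))
  if (length(bad) > 0) {
    stop("unknown exposure class entries: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  m <- two_locus_matrix(params1, params2,
                        "insecticide1" %in% exposure_class,
                        "insecticide2" %in% exposure_class)
  tidyr::expand_grid(genotype1 = GENOTYPES, genotype2 = GENOTYPES) |>
    dplyr::mutate(fitness = as.vector(t(m)))
}

# Marginal (exposure-weighted) 3x3 fitness matrix for one sex under a
# deployment. The exposed fraction x of that sex contacts every deployed
# insecticide simultaneously; the remaining 1 - x contacts none.
marginal_matrix <- function(scenario, deployment, sex) {
  p1 <- scenario$insecticide1
  p2 <- scenario$insecticide2
  if (!deployment %in% c("none", "insecticide1", "insecticide2", "mixture")) {
    stop("unknown deployment: ", deployment, call. = FALSE)
  }
  exposed1 <- deployment %in% c("insecticide1", "mixture")
  exposed2 <- deployment %in% c("insecticide2", "mixture")
  # single deployment: that insecticide's sex-specific exposure; mixture:
  # the two products are co-deployed so a single exposed fraction contacts
  # both (presets keep the two exposures equal; a mismatch is reported)
  x <- if (deployment == "none") {
    0
  } else if (deployment == "insecticide1") {
    if (sex == "female") p1$exposure_female else p1$exposure_male
  } else if (deployment == "insecticide2") {
    if (sex == "female") p2$exposure_female else p2$exposure_male
  } else {
    e1 <- if (sex == "female") p1$exposure_female else p1$exposure_male
    e2 <- if (sex == "female") p2$exposure_female else p2$exposure_male
    if (abs(e1 - e2) > 1e-12) {
      warning("mixture deployment with unequal exposures; using their mean",
              call. = FALSE)
    }
    (e1 + e2) / 2
  }
  w_exp <- two_locus_matrix(p1, p2, exposed1, exposed2)
  w_un <- two_locus_matrix(p1, p2, FALSE, FALSE)
  x * w_exp + (1 - x) * w_un
}

#' Marginal genotype fitness under a deployment
#'
#' Exposure-weighted fitness of each two-locus genotype for one sex: the
#' sex-specific exposed fraction experiences the deployed insecticide(s)
#' (both at once under a mixture), the rest experiences none, and the
#' marginal fitness is the weighted mean of the two exposure classes.
#'
#' @param scenario A [scenario()].
#' @param deployment One of `"none"`, `"insecticide1"`, `"insecticide2"`,
#'   `"mixture"`.
#' @param sex `"female"` or `"male"`.
#' @return A tibble with columns `genotype1`, `genotype2`, `fitness`
#'   (9 rows).
#' @examples
#' marginal_fitness(scenario(), "mixture", "female")
#' @export
marginal_fitness <- function(scenario, deployment = "none", sex = "female") {
  stopifnot(inherits(scenario, "scenario"))
  sex <- match.arg(sex, c("female", "male"))
  m <- marginal_matrix(scenario, deployment, sex)
  tidyr::expand_grid(genotype1 = GENOTYPES, genotype2 = GENOTYPES) |>
    dplyr::mutate(fitness = as.vector(t(m)))
}

# Convert a 9-row genotype fitness tibble (genotype1, genotype2, fitness)
# back to the internal 3x3 matrix.
fitness_tbl_to_matrix <- function(tbl) {
  stopifnot(all(c("genotype1", "genotype2", "fitness") %in% names(tbl)),
            nrow(tbl) == 9L)
  m <- matrix(NA_real_, 3, 3, dimnames = list(GENOTYPES, GENOTYPES))
  m[cbind(match(tbl$genotype1, GENOTYPES),
          match(tbl$genotype2, GENOTYPES))] <- tbl$fitness
  if (anyNA(m)) stop("fitness table does not cover all 9 genotypes",
                     call. = FALSE)
  m
}
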