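#' Insecticide parameter set
#'
#' Bundle the seven inputs that determine how one insecticide selects on its
#' resistance locus. All inputs are proportions. Fitness of the unexposed
#' fully susceptible (SS) genotype is the reference and equals 1 by
#' definition; every other genotype fitness is derived from these inputs.
#'
#' @param effectiveness Proportion of SS insects killed on exposure, in
#'   `[0, 1]`.
#' @param exposure Proportion of insects contacting the deployed
#'   insecticide(s) each generation, in `[0, 1]`. Convenience setter for both
#'   sexes; override per sex with `exposure_female` / `exposure_male`.
#' @param resistance_restoration Fraction of the insecticide-induced fitness
#'   loss that the RR genotype regains when exposed, in `[0, 1]`.
#' @param dominance_resistance Position of the exposed SR fitness between SS
#'   (0) and RR (1), in `[0, 1]`.
#' @param start_frequency Initial resistance-allele frequency at this locus,
#'   strictly inside `(0, 1)`.
#' @param cost Fitness reduction of the unexposed RR genotype, in `[0, 1]`.
#' @param dominance_cost Position of the unexposed SR fitness between SS (0)
#'   and RR (1), in `[0, 1]`.
#' @param exposure_female,exposure_male Sex-specific exposure proportions;
#'   default to `exposure`. Female mosquitoes seeking blood meals typically
#'   contact treated nets and walls more than males, so the two can differ.
#'
#' @return An object of class `insecticide_params` (a named list).
#' @examples
#' insecticide_params(effectiveness = 0.8, resistance_restoration = 0.5)
#' @export
insecticide_params <- function(effectiveness = 0.5,
                               exposure = 0.5,
                               resistance_restoration = 0.5,
                               dominance_resistance = 0.5,
                               start_frequency = 0.01,
                               cost = 0,
                               dominance_cost = 0,
                               exposure_female = exposure,
                               exposure_male = exposure) {
  p <- list(
    effectiveness = effectiveness,
    exposure_female = exposure_female,
    exposure_male = exposure_male,
    resistance_restoration = resistance_restoration,
    dominance_resistance = dominance_resistance,
    start_frequency = start_frequency,
    cost = cost,
    dominance_cost = dominance_cost
  )
  validate_insecticide_params(p)
  structure(p, class = "insecticide_params")
}

validate_insecticide_params <- function(p) {
  closed <- c("effectiveness", "exposure_female", "exposure_male",
              "resistance_restoration", "dominance_resistance",
              "cost", "dominance_cost")
  for (f in closed) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop(sprintf("`%s` must be a single number in [0, 1], got %s",
                   f, deparse(v)), call. = FALSE)
    }
  }
  sf <- p$start_frequency
  if (!is.numeric(sf) || length(sf) != 1L || is.na(sf) || sf <= 0 || sf >= 1) {
    stop(sprintf("`start_frequency` must lie strictly inside (0, 1), got %s",
                 deparse(sf)), call. = FALSE)
  }
  invisible(p)
}

#' @export
print.insecticide_params <- function(x, ...) {
  cat("<insecticide_params>\n")
  df <- tibble::enframe(unlist(unclass(x)), name = "parameter")
  print(as.data.frame(df), row.names = FALSE)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.insecticide_params <- function(x, ...) {
  tibble::enframe(unlist(unclass(x)), name = "parameter", value = "value")
}

#' Deployment scenario
#'
#' A scenario binds two insecticide parameter sets to the population-level
#' settings of a simulation: recombination rate between the two resistance
#' loci, the allele-frequency threshold at which resistance is declared, and
#' a cap on the number of generations simulated.
#'
#' @param insecticide1,insecticide2 [insecticide_params()] objects.
#' @param recombination_rate Recombination fraction between the two loci,
#'   in `[0, 0.5]`. The default 0.5 treats the loci as unlinked, i.e.
#'   independently segregating genes.
#' @param resistance_threshold Allele frequency at which a locus is declared
#'   resistant, strictly inside `(0, 1)`. Default 0.5.
#' @param max_generations Generation cap; runs that do not cross the
#'   threshold by then report `NA` ("not reached"). Default 500.
#'
#' @return An object of class `scenario`.
#' @examples
#' sc <- scenario(insecticide_params(), insecticide_params())
#' run_mixture(sc)$total_time
#' @export
scenario <- function(insecticide1 = insecticide_params(),
                     insecticide2 = insecticide_params(),
                     recombination_rate = 0.5,
                     resistance_threshold = 0.5,
                     max_generations = 500L) {
  if (!inherits(insecticide1, "insecticide_params"))
    insecticide1 <- do.call(insecticide_params, as.list(insecticide1))
  if (!inherits(insecticide2, "insecticide_params"))
    insecticide2 <- do.call(insecticide_params, as.list(insecticide2))
  if (!is.numeric(recombination_rate) || length(recombination_rate) != 1L ||
      is.na(recombination_rate) ||
      recombination_rate < 0 || recombination_rate > 0.5) {
    stop("`recombination_rate` must be a single number in [0, 0.5]",
         call. = FALSE)
  }
  if (!is.numeric(resistance_threshold) || length(resistance_threshold) != 1L ||
      is.na(resistance_threshold) ||
      resistance_threshold <= 0 || resistance_threshold >= 1) {
    stop("`resistance_threshold` must lie strictly inside (0, 1)",
         call. = FALSE)
  }
  max_generations <- as.integer(max_generations)
  if (is.na(max_generations) || max_generations < 1L) {
    stop("`max_generations` must be a positive integer", call. = FALSE)
  }
  structure(
    list(
      insecticide1 = insecticide1,
      insecticide2 = insecticide2,
      recombination_rate = recombination_rate,
      resistance_threshold = resistance_threshold,
      max_generations = max_generations
    ),
    class = "scenario"
  )
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario>\n")
  cat(sprintf("  recombination_rate: %g   resistance_threshold: %g   max_generations: %d\n",
              x$recombination_rate, x$resistance_threshold, x$max_generations))
  for (i in 1:2) {
    p <- x[[paste0("insecticide", i)]]
    cat(sprintf(
      "  insecticide%d: eff=%g exp(f/m)=%g/%g rest=%g dom=%g start=%g cost=%g domcost=%g\n",
      i, p$effectiveness, p$exposure_female, p$exposure_male,
      p$resistance_restoration, p$dominance_resistance,
      p$start_frequency, p$cost, p$dominance_cost))
  }
  invisible(x)
}

#' @export
tidy.scenario <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$insecticide1), insecticide = 1L, .before = 1),
    dplyr::mutate(tidy(x$insecticide2), insecticide = 2L, .before = 1),
    tibble::tibble(
      insecticide = NA_integer_,
      parameter = c("recombination_rate", "resistance_threshold",
                    "max_generations"),
      value = c(x$recombination_rate, x$resistance_threshold,
                as.numeric(x$max_generations))
    )
  )
}
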