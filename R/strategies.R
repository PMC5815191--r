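# Deterministic multi-generation engine. Deployment is chosen per
# generation by `deploy_fun(crossed1, crossed2)`, which returns one of
# "none", "insecticide1", "insecticide2", "mixture". Stops when `stop_fun`
# is satisfied or the generation cap is hit. Returns the raw per-generation
# record matrix plus crossing times.
run_engine <- function(scenario, deploy_fun, stop_fun) {
  p1 <- scenario$insecticide1
  p2 <- scenario$insecticide2
  thr <- scenario$resistance_threshold
  cap <- scenario$max_generations
  t_mat <- transmission_matrix(scenario$recombination_rate)

  # marginal fitness matrices are deployment- and sex-specific but constant
  # over time; build each deployment's pair on first use and cache it
  w_cache <- list()
  fitness_for <- function(dep) {
    if (is.null(w_cache[[dep]])) {
      w_cache[[dep]] <<- list(
        female = expand_fitness(marginal_matrix(scenario, dep, "female")),
        male = expand_fitness(marginal_matrix(scenario, dep, "male"))
      )
    }
    w_cache[[dep]]
  }

  female <- male <- init_population(p1$start_frequency,
                                    p2$start_frequency)$female

  rec <- matrix(NA_real_, nrow = cap + 1L, ncol = 8L)
  colnames(rec) <- c("freq_locus1_female", "freq_locus1_male",
                     "freq_locus1_mean", "freq_locus2_female",
                     "freq_locus2_male", "freq_locus2_mean", "D", "Dprime")
  deployment <- character(cap + 1L)

  snapshot <- function(f, m) {
    pf <- c(sum(f[HAP_HAS_R1]), sum(f[HAP_HAS_R2]))
    pm <- c(sum(m[HAP_HAS_R1]), sum(m[HAP_HAS_R2]))
    ld <- ld_from_haps((f + m) / 2)
    c(pf[1], pm[1], (pf[1] + pm[1]) / 2,
      pf[2], pm[2], (pf[2] + pm[2]) / 2,
      ld[["D"]], ld[["Dprime"]])
  }

  t1 <- NA_integer_
  t2 <- NA_integer_
  row <- snapshot(female, male)
  if (row[3] >= thr) t1 <- 0L
  if (row[6] >= thr) t2 <- 0L
  dep <- deploy_fun(!is.na(t1), !is.na(t2))
  rec[1L, ] <- row
  deployment[1L] <- dep
  n_rows <- 1L

  g <- 0L
  while (g < cap && !stop_fun(t1, t2)) {
    dep <- deploy_fun(!is.na(t1), !is.na(t2))
    w <- fitness_for(dep)
    nxt <- step_core(female, male, w$female, w$male, t_mat)
    female <- nxt$female
    male <- nxt$male
    g <- g + 1L
    row <- snapshot(female, male)
    if (is.na(t1) && row[3] >= thr) t1 <- g
    if (is.na(t2) && row[6] >= thr) t2 <- g
    rec[g + 1L, ] <- row
    deployment[g + 1L] <- dep
    n_rows <- g + 1L
  }

  list(
    trajectory = dplyr::bind_cols(
      tibble::tibble(
        generation = 0:(n_rows - 1L),
        deployment = deployment[seq_len(n_rows)]
      ),
      tibble::as_tibble(rec[seq_len(n_rows), , drop = FALSE])
    ),
    time_locus1 = t1,
    time_locus2 = t2
  )
}

new_strategy_result <- function(strategy, time_locus1, time_locus2,
                                total_time, trajectory, scenario) {
  structure(
    list(
      strategy = strategy,
      time_locus1 = time_locus1,
      time_locus2 = time_locus2,
      total_time = total_time,
      trajectory = trajectory,
      scenario = scenario
    ),
    class = "strategy_result"
  )
}

#' @export
print.strategy_result <- function(x, ...) {
  fmt <- function(t) if (is.na(t)) "NOT_REACHED" else as.character(t)
  cat(sprintf("<strategy_result: %s>\n", x$strategy))
  cat(sprintf("  time to resistance, locus 1: %s\n", fmt(x$time_locus1)))
  cat(sprintf("  time to resistance, locus 2: %s\n", fmt(x$time_locus2)))
  cat(sprintf("  total time: %s generations (%d simulated)\n",
              fmt(x$total_time), max(x$trajectory$generation)))
  invisible(x)
}

#' Time to resistance from a trajectory
#'
#' The time-to-resistance is the smallest census generation at which the
#' sex-averaged R-allele frequency at a locus is at or above the threshold.
#' Censuses happen at whole generations; no interpolation is performed. If
#' the trajectory never crosses, `NA` ("not reached") is returned.
#'
#' @param trajectory A trajectory tibble (see [run_mixture()]).
#' @param locus 1 or 2.
#' @param threshold Allele-frequency threshold in `(0, 1)`, default 0.5.
#' @return Integer generation, or `NA_integer_` if not reached.
#' @examples
#' res <- run_single(scenario(), 1)
#' time_to_resistance(res$trajectory, 1)
#' @export
time_to_resistance <- function(trajectory, locus, threshold = 0.5) {
  stopifnot(nrow(trajectory) > 0, locus %in% 1:2)
  col <- paste0("freq_locus", locus, "_mean")
  hit <- which(trajectory[[col]] >= threshold)
  if (length(hit) == 0L) NA_integer_ else
    as.integer(trajectory$generation[hit[1L]])
}

#' Run a single-insecticide deployment
#'
#' Deploy one insecticide alone until its resistance locus crosses the
#' scenario threshold (or the generation cap is hit). The other locus
#' experiences only unexposed selection, i.e. any fitness cost of carrying
#' its resistance allele.
#'
#' @param scenario A [scenario()].
#' @param which_insecticide 1 or 2: the insecticide deployed.
#' @return A `strategy_result`: crossing times per locus, `total_time`
#'   (the deployed locus's crossing time; `NA` if not reached) and the
#'   per-generation `trajectory` tibble with columns `generation`,
#'   `deployment`, `freq_locus{1,2}_{female,male,mean}`, `D`, `Dprime`.
#' @examples
#' run_single(scenario(), 1)
#' @export
run_single <- function(scenario, which_insecticide = 1) {
  stopifnot(inherits(scenario, "scenario"), which_insecticide %in% 1:2)
  dep <- paste0("insecticide", which_insecticide)
  own_crossed <- function(t1, t2) {
    if (which_insecticide == 1) !is.na(t1) else !is.na(t2)
  }
  out <- run_engine(scenario,
                    deploy_fun = function(c1, c2) dep,
                    stop_fun = function(t1, t2) own_crossed(t1, t2))
  total <- if (which_insecticide == 1) out$time_locus1 else out$time_locus2
  new_strategy_result("single", out$time_locus1, out$time_locus2,
                      total, out$trajectory, scenario)
}

#' Run a sequential deployment
#'
#' Deploy insecticide 1 until its locus crosses the resistance threshold;
#' from the next generation deploy insecticide 2 until its locus crosses.
#' The idle insecticide's locus experiences only unexposed (cost) selection
#' during each phase, so with a positive cost the first resistance allele
#' declines after the switch. The total time is the generation at which the
#' second locus crosses, or `NA` if the cap intervenes.
#'
#' @param scenario A [scenario()].
#' @return A `strategy_result`; `time_locus1` is the switch generation.
#' @examples
#' run_sequence(scenario())
#' @export
run_sequence <- function(scenario) {
  stopifnot(inherits(scenario, "scenario"))
  out <- run_engine(
    scenario,
    deploy_fun = function(c1, c2) if (!c1) "insecticide1" else "insecticide2",
    stop_fun = function(t1, t2) !is.na(t1) && !is.na(t2)
  )
  new_strategy_result("sequence", out$time_locus1, out$time_locus2,
                      out$time_locus2, out$trajectory, scenario)
}

#' Run a mixture deployment
#'
#' Deploy both insecticides concurrently: the exposed fraction of each sex
#' contacts both products every generation, with multiplicative fitness
#' across loci. The total time is the first generation at which both loci
#' have crossed the resistance threshold.
#'
#' @param scenario A [scenario()].
#' @return A `strategy_result`.
#' @examples
#' run_mixture(scenario())
#' @export
run_mixture <- function(scenario) {
  stopifnot(inherits(scenario, "scenario"))
  out <- run_engine(
    scenario,
    deploy_fun = function(c1, c2) "mixture",
    stop_fun = function(t1, t2) !is.na(t1) && !is.na(t2)
  )
  total <- if (is.na(out$time_locus1) || is.na(out$time_locus2)) {
    NA_integer_
  } else {
    max(out$time_locus1, out$time_locus2)
  }
  new_strategy_result("mixture", out$time_locus1, out$time_locus2,
                      total, out$trajectory, scenario)
}

# Round half away from zero, the convention used for the reported
# mixture/sequence ratio (base round() rounds half to even).
round_half_up <- function(x, digits = 1) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Compare the sequence and mixture strategies
#'
#' Run both two-insecticide strategies on the same scenario and report the
#' headline comparison statistic: mixture total time divided by sequence
#' total time. A ratio below 1 favours the sequence (resistance to both
#' insecticides arrives later under sequential use), above 1 favours the
#' mixture. The rounded value uses one decimal place, half away from zero.
#'
#' @param scenario A [scenario()].
#' @return A `strategy_comparison`: `sequence` and `mixture`
#'   `strategy_result`s, `ratio` (raw) and `ratio_rounded`; both `NA` if
#'   either strategy never reaches both thresholds.
#' @examples
#' cmp <- compare_strategies(scenario())
#' cmp$ratio_rounded
#' @export
compare_strategies <- function(scenario) {
  stopifnot(inherits(scenario, "scenario"))
  seq_res <- run_sequence(scenario)
  mix_res <- run_mixture(scenario)
  ratio <- if (is.na(seq_res$total_time) || is.na(mix_res$total_time)) {
    NA_real_
  } else {
    mix_res$total_time / seq_res$total_time
  }
  structure(
    list(
      sequence = seq_res,
      mixture = mix_res,
      ratio = ratio,
      ratio_rounded = if (is.na(ratio)) NA_real_ else round_half_up(ratio, 1),
      scenario = scenario
    ),
    class = "strategy_comparison"
  )
}

#' @export
print.strategy_comparison <- function(x, ...) {
  fmt <- function(t) if (is.na(t)) "NOT_REACHED" else as.character(t)
  cat("<strategy_comparison>\n")
  cat(sprintf("  sequence total time: %s\n", fmt(x$sequence$total_time)))
  cat(sprintf("  mixture  total time: %s\n", fmt(x$mixture$total_time)))
  if (is.na(x$ratio)) {
    cat("  mixture/sequence ratio: undefined (a threshold was not reached)\n")
  } else {
    cat(sprintf("  mixture/sequence ratio: %.4f (rounded %.1f)\n",
                x$ratio, x$ratio_rounded))
  }
  invisible(x)
}
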