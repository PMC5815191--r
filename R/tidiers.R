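#' @importFrom rlang .data
NULL

#' Tidy a strategy result
#'
#' `tidy()` returns the per-generation trajectory in long form (one row per
#' generation, locus and sex series); `glance()` returns a one-row summary
#' with the crossing times.
#'
#' @param x A `strategy_result` (from [run_single()], [run_sequence()] or
#'   [run_mixture()]).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.strategy_result <- function(x, ...) {
  x$trajectory |>
    tidyr::pivot_longer(
      dplyr::starts_with("freq_"),
      names_to = c("locus", "sex"),
      names_pattern = "freq_locus([12])_(.*)",
      values_to = "frequency"
    ) |>
    dplyr::mutate(
      locus = as.integer(.data$locus),
      strategy = x$strategy
    )
}

#' @rdname tidy.strategy_result
#' @export
glance.strategy_result <- function(x, ...) {
  tibble::tibble(
    strategy = x$strategy,
    time_locus1 = x$time_locus1,
    time_locus2 = x$time_locus2,
    total_time = x$total_time,
    resistance_threshold = x$scenario$resistance_threshold,
    generations_simulated = max(x$trajectory$generation),
    reached = !is.na(x$total_time)
  )
}

#' Tidy a strategy comparison
#'
#' `tidy()` stacks the sequence and mixture trajectories in long form;
#' `glance()` gives the one-row comparison summary including the
#' mixture/sequence total-time ratio.
#'
#' @param x A `strategy_comparison` (from [compare_strategies()]).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.strategy_comparison <- function(x, ...) {
  dplyr::bind_rows(tidy(x$sequence), tidy(x$mixture))
}

#' @rdname tidy.strategy_comparison
#' @export
glance.strategy_comparison <- function(x, ...) {
  tibble::tibble(
    sequence_total = x$sequence$total_time,
    mixture_total = x$mixture$total_time,
    ratio = x$ratio,
    ratio_rounded = x$ratio_rounded
  )
}

#' Plot a resistance trajectory
#'
#' Sex-averaged resistance-allele frequency over generations, one colour
#' per insecticide, with the resistance threshold as a horizontal line.
#' For comparisons, mixture runs are drawn solid and sequence runs dashed.
#'
#' @param object A `strategy_result` or `strategy_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' autoplot(run_mixture(scenario()))
#' @export
autoplot.strategy_result <- function(object, ...) {
  dat <- tidy(object) |> dplyr::filter(.data$sex == "mean")
  ggplot2::ggplot(dat, ggplot2::aes(.data$generation, .data$frequency,
                                    colour = factor(.data$locus))) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = object$scenario$resistance_threshold,
                        linetype = "dotted") +
    ggplot2::scale_colour_manual(
      values = c("1" = "#c23b22", "2" = "#1f6fb5"),
      name = "insecticide") +
    ggplot2::labs(
      x = "generation",
      y = "resistance allele frequency",
      title = sprintf("%s deployment", object$strategy)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.strategy_result
#' @export
autoplot.strategy_comparison <- function(object, ...) {
  dat <- tidy(object) |> dplyr::filter(.data$sex == "mean")
  ggplot2::ggplot(dat, ggplot2::aes(.data$generation, .data$frequency,
                                    colour = factor(.data$locus),
                                    linetype = .data$strategy)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_hline(
      yintercept = object$scenario$resistance_threshold,
      linetype = "dotted") +
    ggplot2::scale_colour_manual(
      values = c("1" = "#c23b22", "2" = "#1f6fb5"),
      name = "insecticide") +
    ggplot2::scale_linetype_manual(
      values = c(mixture = "solid", sequence = "dashed")) +
    ggplot2::labs(
      x = "generation",
      y = "resistance allele frequency",
      subtitle = if (is.na(object$ratio)) {
        "mixture/sequence ratio undefined"
      } else {
        sprintf("mixture/sequence total-time ratio %.1f", object$ratio_rounded)
      }
    ) +
    ggplot2::theme_minimal()
}
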