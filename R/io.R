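PARAM_KEYS <- c("effectiveness", "exposure", "exposure_female",
                "exposure_male", "resistance_restoration",
                "dominance_resistance", "start_frequency", "cost",
                "dominance_cost")
GLOBAL_KEYS <- c("insecticide1", "insecticide2", "recombination_rate",
                 "resistance_threshold", "max_generations")

#' Load a scenario from a YAML file
#'
#' The document has two keyed sections, `insecticide1` and `insecticide2`,
#' each accepting the [insecticide_params()] fields (with `exposure` as a
#' both-sexes shorthand), plus the global keys `recombination_rate`,
#' `resistance_threshold` and `max_generations`. Missing keys take the
#' package defaults (the base parameterisation: selection inputs 0.5, start
#' frequency 0.01, no costs; recombination 0.5, threshold 0.5, cap 500) and
#' are reported via a message. Unknown keys are rejected.
#'
#' @param path Path to a YAML scenario file.
#' @param quiet Suppress the defaults message.
#' @return A [scenario()].
#' @examples
#' path <- system.file("extdata", "scenario_base.yaml", package = "irmsim")
#' load_scenario(path)
#' @export
load_scenario <- function(path, quiet = FALSE) {
  doc <- yaml::read_yaml(path)
  if (!is.list(doc)) stop("scenario file is not a key/value document",
                          call. = FALSE)
  unknown <- setdiff(names(doc), GLOBAL_KEYS)
  if (length(unknown) > 0) {
    stop("unknown scenario keys: ", paste(unknown, collapse = ", "),
         "; legal keys: ", paste(GLOBAL_KEYS, collapse = ", "),
         call. = FALSE)
  }
  defaulted <- character(0)
  parse_insecticide <- function(section, label) {
    section <- section %||% list()
    unknown <- setdiff(names(section), PARAM_KEYS)
    if (length(unknown) > 0) {
      stop(sprintf("unknown keys under %s: %s; legal keys: %s",
                   label, paste(unknown, collapse = ", "),
                   paste(PARAM_KEYS, collapse = ", ")), call. = FALSE)
    }
    missing_keys <- setdiff(setdiff(PARAM_KEYS,
                                    c("exposure_female", "exposure_male")),
                            names(section))
    if (length(missing_keys) > 0) {
      defaulted <<- c(defaulted, paste0(label, ".", missing_keys))
    }
    tryCatch(
      do.call(insecticide_params, section),
      error = function(e) {
        stop(sprintf("in %s: %s", label, conditionMessage(e)), call. = FALSE)
      }
    )
  }
  p1 <- parse_insecticide(doc$insecticide1, "insecticide1")
  p2 <- parse_insecticide(doc$insecticide2, "insecticide2")
  for (k in c("recombination_rate", "resistance_threshold",
              "max_generations")) {
    if (is.null(doc[[k]])) defaulted <- c(defaulted, k)
  }
  sc <- scenario(
    p1, p2,
    recombination_rate = doc$recombination_rate %||% 0.5,
    resistance_threshold = doc$resistance_threshold %||% 0.5,
    max_generations = doc$max_generations %||% 500L
  )
  if (!quiet && length(defaulted) > 0) {
    message("using defaults for: ", paste(defaulted, collapse = ", "))
  }
  sc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

TRAJECTORY_COLS <- c("generation", "deployment",
                     "freq_locus1_female", "freq_locus1_male",
                     "freq_locus1_mean", "freq_locus2_female",
                     "freq_locus2_male", "freq_locus2_mean", "D", "Dprime")

#' Write and read trajectory CSV files
#'
#' One row per census generation with the stable column set `generation`,
#' `deployment`, `freq_locus{1,2}_{female,male,mean}`, `D`, `Dprime`.
#' Frequencies are written at full precision so that
#' `read_trajectory(write_trajectory(x, f))` round-trips losslessly.
#'
#' @param trajectory A trajectory tibble (from a `strategy_result`).
#' @param path Destination CSV path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns the trajectory tibble.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_trajectory(run_mixture(scenario())$trajectory, f)
#' read_trajectory(f)
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(all(TRAJECTORY_COLS %in% names(trajectory)))
  readr::write_csv(trajectory[TRAJECTORY_COLS], path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      generation = readr::col_integer(),
      deployment = readr::col_character(),
      .default = readr::col_double()
    )
  )
  missing_cols <- setdiff(TRAJECTORY_COLS, names(out))
  if (length(missing_cols) > 0) {
    stop("trajectory file lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out
}
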