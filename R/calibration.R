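#' Genotype survival from alive/dead counts
#'
#' Bioassay and hut-trial data typically arrive as numbers alive and dead
#' per genotype; the survival proportion `alive / (alive + dead)` is used as
#' the genotype's fitness estimate.
#'
#' @param alive,dead Non-negative integer counts (vectorised).
#' @return Survival proportion(s) in `[0, 1]`.
#' @examples
#' survival_from_counts(83, 17)
#' @export
survival_from_counts <- function(alive, dead) {
  if (any(alive < 0) || any(dead < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  total <- alive + dead
  if (any(total == 0)) {
    stop("alive + dead must be positive for every genotype", call. = FALSE)
  }
  alive / total
}

check_survival_data <- function(data) {
  stopifnot(is.data.frame(data))
  req <- c("genotype", "arm")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0) {
    stop("bioassay data needs columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"survival" %in% names(data)) {
    if (!all(c("alive", "dead") %in% names(data))) {
      stop("bioassay data needs either a `survival` column or both `alive` and `dead`",
           call. = FALSE)
    }
    data$survival <- survival_from_counts(data$alive, data$dead)
  }
  bad_g <- setdiff(unique(data$genotype), c("SS", "SR", "RR"))
  if (length(bad_g) > 0) {
    stop("unknown genotype values: ", paste(bad_g, collapse = ", "),
         call. = FALSE)
  }
  bad_a <- setdiff(unique(data$arm), c("exposed", "unexposed"))
  if (length(bad_a) > 0) {
    stop("unknown arm values (want exposed/unexposed): ",
         paste(bad_a, collapse = ", "), call. = FALSE)
  }
  if (any(data$survival < 0 | data$survival > 1)) {
    stop("survival proportions must be in [0, 1]", call. = FALSE)
  }
  if (anyDuplicated(data[c("genotype", "arm")]) > 0) {
    stop("duplicated genotype/arm rows in bioassay data", call. = FALSE)
  }
  tibble::as_tibble(data)
}

#' Read genotype bioassay data from CSV
#'
#' Expected columns: `genotype` (SS, SR, RR), `arm` (exposed, unexposed) and
#' either `survival` or both `alive` and `dead` counts, from which survival
#' is computed. The unexposed arm may be absent entirely (no-cost
#' calibration).
#'
#' @param path Path to a CSV file.
#' @return A tibble with columns `genotype`, `arm`, `survival` (plus any
#'   count columns present).
#' @export
read_bioassay <- function(path) {
  check_survival_data(readr::read_csv(path, show_col_types = FALSE))
}

survival_at <- function(data, g, a) {
  v <- data$survival[data$genotype == g & data$arm == a]
  if (length(v) == 0L) NA_real_ else v[[1L]]
}

#' Rescale survivals to the unexposed SS reference
#'
#' Model fitnesses are relative to the unexposed SS genotype, whose fitness
#' is 1 by definition. Field control arms often show background mortality
#' (unexposed SS survival below 1), so every survival is divided by the
#' unexposed SS survival before parameters are derived. Values exceeding 1
#' after rescaling are capped at 1 with a warning.
#'
#' @param data A bioassay tibble (see [read_bioassay()]) containing an
#'   unexposed SS row with positive survival.
#' @return The tibble with `survival` rescaled.
#' @examples
#' d <- tibble::tibble(
#'   genotype = c("SS", "SS"), arm = c("exposed", "unexposed"),
#'   survival = c(0.59, 0.83)
#' )
#' rescale_survivals(d)
#' @export
rescale_survivals <- function(data) {
  data <- check_survival_data(data)
  ref <- survival_at(data, "SS", "unexposed")
  if (is.na(ref) || ref <= 0) {
    stop(paste("unexposed SS survival missing or zero: cannot rescale;",
               "derive with the no-cost assumption instead"), call. = FALSE)
  }
  data$survival <- data$survival / ref
  if (any(data$survival > 1)) {
    warning("rescaled survival > 1 capped at 1", call. = FALSE)
    data$survival <- pmin(data$survival, 1)
  }
  data
}

#' Derive model inputs from genotype survival data
#'
#' Invert the fitness construction to recover the selection parameters from
#' genotype-specific survivals: with exposed survivals `SSfit`, `SRfit`,
#' `RRfit` (on the unexposed-SS = 1 scale),
#' `effectiveness = 1 - SSfit`,
#' `resistance_restoration = (RRfit - SSfit) / effectiveness`, and
#' `dominance_resistance = (SRfit - SSfit) / (RRfit - SSfit)`; from the
#' unexposed arm, `cost = 1 - RRfit` and
#' `dominance_cost = (SSfit - SRfit) / (SSfit - RRfit)`.
#'
#' If the unexposed arm is absent the calibration assumes no fitness costs
#' (`cost = 0`, `dominance_cost = 0`). A derived dominance outside `[0, 1]`
#' indicates apparent under- or over-dominance, biologically implausible for
#' these loci, and is set to 1 with a warning so that SR matches RR. An
#' exposed RR survival below SS (no resistance signal) yields restoration 0
#' with a warning.
#'
#' Exposure and starting allele frequency cannot be derived from bioassay
#' survivals; they are properties of the deployment setting and are passed
#' through from the arguments.
#'
#' @param data A bioassay tibble (see [read_bioassay()]). Rescale with
#'   [rescale_survivals()] first when the unexposed SS survival is below 1.
#' @param exposure,start_frequency User-supplied estimates passed into the
#'   resulting parameter set.
#' @return An [insecticide_params()] object; any clamps applied are recorded
#'   in its `"calibration_notes"` attribute (and raised as warnings).
#' @examples
#' carbamate <- tibble::tibble(
#'   genotype = c("SS", "SR", "RR"),
#'   arm = "exposed",
#'   survival = c(0.02, 0.56, 0.84)
#' )
#' derive_insecticide_params(carbamate)
#' @export
derive_insecticide_params <- function(data, exposure = 0.5,
                                      start_frequency = 0.01) {
  data <- check_survival_data(data)
  notes <- character(0)
  note <- function(msg) {
    warning(msg, call. = FALSE)
    notes <<- c(notes, msg)
  }

  ss_e <- survival_at(data, "SS", "exposed")
  sr_e <- survival_at(data, "SR", "exposed")
  rr_e <- survival_at(data, "RR", "exposed")
  if (anyNA(c(ss_e, sr_e, rr_e))) {
    stop("exposed survivals for all of SS, SR, RR are required",
         call. = FALSE)
  }

  effectiveness <- 1 - ss_e
  if (rr_e < ss_e) {
    note("exposed RR survival below SS: no resistance signal, restoration set to 0")
    restoration <- 0
    dominance <- 0
  } else {
    restoration <- if (effectiveness > 0) (rr_e - ss_e) / effectiveness else 0
    dominance <- if (rr_e > ss_e) (sr_e - ss_e) / (rr_e - ss_e) else 0
    if (dominance < 0 || dominance > 1) {
      note(sprintf(
        "derived dominance of resistance %.2f outside [0, 1]: set to 1", dominance))
      dominance <- 1
    }
  }
  if (restoration > 1) {
    note(sprintf("derived resistance restoration %.2f > 1: capped at 1",
                 restoration))
    restoration <- 1
  }

  ss_u <- survival_at(data, "SS", "unexposed")
  rr_u <- survival_at(data, "RR", "unexposed")
  sr_u <- survival_at(data, "SR", "unexposed")
  if (anyNA(c(ss_u, sr_u, rr_u))) {
    # no (complete) control arm: assume resistance carries no cost
    cost <- 0
    dominance_cost <- 0
  } else {
    cost <- 1 - rr_u
    if (cost < 0) {
      note("unexposed RR survival > 1 implies negative cost: set to 0")
      cost <- 0
    }
    dominance_cost <- if (cost > 0) (ss_u - sr_u) / (ss_u - rr_u) else 0
    if (dominance_cost < 0 || dominance_cost > 1) {
      note(sprintf(
        "derived dominance of cost %.2f outside [0, 1] (underdominance): set to 1",
        dominance_cost))
      dominance_cost <- 1
    }
  }

  out <- insecticide_params(
    effectiveness = effectiveness,
    exposure = exposure,
    resistance_restoration = restoration,
    dominance_resistance = dominance,
    start_frequency = start_frequency,
    cost = cost,
    dominance_cost = dominance_cost
  )
  attr(out, "calibration_notes") <- notes
  out
}

#' Calibration report
#'
#' Derived parameters as a tidy table, rounded for display only (the
#' underlying [insecticide_params()] carries full precision).
#'
#' @param params An [insecticide_params()], typically from
#'   [derive_insecticide_params()].
#' @param digits Display rounding, default 2.
#' @return A tibble with columns `parameter`, `value`, `value_displayed`.
#' @export
calibration_report <- function(params, digits = 2) {
  stopifnot(inherits(params, "insecticide_params"))
  tidy(params) |>
    dplyr::mutate(value_displayed = round(.data$value, digits))
}
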