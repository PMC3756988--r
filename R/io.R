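# Unit conversion constants (config-visible through the conversion helpers).
MGDL_PER_MM <- 18.016     # mg/dl of glucose per mmol/L
PM_PER_MUL <- 6.945       # pmol/L of insulin per mU/L (uIU/ml)
G_PER_MMOL <- 0.18016     # grams of glucose per mmol (molar mass 180.16 g/mol)

#' Unit conversions at the I/O boundary
#'
#' Internally the model works in mM (glucose), pM (insulin), mmol (dose) and
#' minutes. These helpers convert the common clinical units: glucose mg/dl is
#' divided by 18.016, insulin mU/L is multiplied by 6.945 (configurable), and
#' a dose in grams is divided by the glucose molar mass 180.16 g/mol.
#'
#' @param x Numeric vector of values to convert.
#' @param from Unit of `x`.
#' @param factor Insulin conversion factor (pmol/L per mU/L).
#' @return Converted numeric vector.
#' @name units
#' @examples
#' glucose_to_mM(85.54, from = "mg/dl")
#' dose_to_mmol(75, from = "g")
NULL

#' @rdname units
#' @export
glucose_to_mM <- function(x, from = c("mM", "mg/dl")) {
  from <- match.arg(from)
  if (from == "mM") x else x / MGDL_PER_MM
}

#' @rdname units
#' @export
glucose_from_mM <- function(x, to = c("mM", "mg/dl")) {
  to <- match.arg(to)
  if (to == "mM") x else x * MGDL_PER_MM
}

#' @rdname units
#' @export
insulin_to_pM <- function(x, from = c("pM", "mU/L"), factor = PM_PER_MUL) {
  from <- match.arg(from)
  if (from == "pM") x else x * factor
}

#' @rdname units
#' @export
insulin_from_pM <- function(x, to = c("pM", "mU/L"), factor = PM_PER_MUL) {
  to <- match.arg(to)
  if (to == "pM") x else x / factor
}

#' @rdname units
#' @export
dose_to_mmol <- function(x, from = c("mmol", "g")) {
  from <- match.arg(from)
  if (from == "mmol") x else x / G_PER_MMOL
}

#' @rdname units
#' @export
dose_to_g <- function(x, from = c("g", "mmol")) {
  from <- match.arg(from)
  if (from == "g") x else x * G_PER_MMOL
}

#' @param to Target unit.
#' @rdname units
#' @export
convert_units <- function(x, from, to, factor = PM_PER_MUL) {
  pair <- paste(from, to, sep = "->")
  switch(pair,
    "mg/dl->mM" = x / MGDL_PER_MM,
    "mM->mg/dl" = x * MGDL_PER_MM,
    "mU/L->pM" = x * factor,
    "pM->mU/L" = x / factor,
    "g->mmol" = x / G_PER_MMOL,
    "mmol->g" = x * G_PER_MMOL,
    abort(sprintf("unsupported unit conversion '%s'", pair))
  )
}

#' Read an OGTT table
#'
#' Reads a delimited file with one row per (subject, time) and columns
#' `subject`, `group`, `weight`, `dose`, `time`, `glucose`, `insulin`, and
#' converts everything to the model's internal units (glucose mM, insulin pM,
#' dose mmol, weight kg, time min). Units must be declared explicitly; there
#' is no guessing from magnitudes. A `time = 0` row per subject is required:
#' it provides the basal glycemia and insulinemia.
#'
#' @param path CSV file path.
#' @param glucose_unit `"mM"` or `"mg/dl"`.
#' @param insulin_unit `"pM"` or `"mU/L"`.
#' @param dose_unit `"mmol"` or `"g"`.
#' @param insulin_factor pmol/L per mU/L conversion factor.
#' @return A tibble of OGTT observations in model units with logical
#'   `glucose_valid` / `insulin_valid` columns (missing values are invalid).
#' @export
read_ogtt <- function(path, glucose_unit, insulin_unit, dose_unit = "g",
                      insulin_factor = PM_PER_MUL) {
  if (missing(glucose_unit) || missing(insulin_unit)) {
    abort("glucose_unit and insulin_unit must be declared (no unit guessing)")
  }
  x <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("subject", "time", "glucose", "insulin", "dose", "weight")
  miss <- setdiff(req, names(x))
  if (length(miss)) {
    abort(paste("missing required columns:", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(x[c("subject", "time")])) {
    abort("duplicate (subject, time) rows")
  }
  x <- mutate(
    x,
    glucose = glucose_to_mM(.data$glucose, glucose_unit),
    insulin = insulin_to_pM(.data$insulin, insulin_unit,
                            factor = insulin_factor),
    dose = dose_to_mmol(.data$dose, dose_unit)
  )
  if (!"group" %in% names(x)) x$group <- "all"
  no_basal <- x |>
    group_by(.data$subject) |>
    summarise(ok = any(.data$time == 0), .groups = "drop") |>
    filter(!.data$ok)
  if (nrow(no_basal)) {
    abort(paste("subjects without a t = 0 (basal) row:",
                paste(no_basal$subject, collapse = ", ")))
  }
  x |>
    mutate(glucose_valid = is.finite(.data$glucose),
           insulin_valid = is.finite(.data$insulin)) |>
    arrange(.data$subject, .data$time)
}

#' Write an OGTT table
#'
#' Writes observations back to CSV in declared units (inverse of
#' [read_ogtt()]); the round trip is lossless to numerical precision.
#'
#' @param data OGTT observations tibble in model units.
#' @inheritParams read_ogtt
#' @return `path`, invisibly.
#' @export
write_ogtt <- function(data, path, glucose_unit = "mM", insulin_unit = "pM",
                       dose_unit = "mmol", insulin_factor = PM_PER_MUL) {
  out <- mutate(
    data,
    glucose = glucose_from_mM(.data$glucose, glucose_unit),
    insulin = insulin_from_pM(.data$insulin, insulin_unit,
                              factor = insulin_factor),
    dose = if (dose_unit == "g") dose_to_g(.data$dose, "mmol") else .data$dose
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Per-subject fit eligibility
#'
#' A subject enters model identification only with at least five valid
#' glucose samples and at least five valid insulin samples out of the
#' seven-point grid, and a valid basal (t = 0) pair.
#'
#' @param data OGTT observations tibble (columns `subject`, `time`,
#'   `glucose`, `insulin`, optionally `glucose_valid` / `insulin_valid`).
#' @param min_valid Minimum number of valid samples per channel.
#' @param require_basal Additionally require a valid t = 0 glucose/insulin
#'   pair (needed before fitting, where basal values are taken from the t = 0
#'   sample).
#' @return A tibble with one row per subject: valid sample counts and an
#'   `eligible` flag.
#' @export
ogtt_eligible <- function(data, min_valid = 5, require_basal = TRUE) {
  data <- .ensure_validity(data)
  data |>
    group_by(.data$subject) |>
    summarise(
      n_glucose = sum(.data$glucose_valid),
      n_insulin = sum(.data$insulin_valid),
      basal_ok = any(.data$time == 0 & .data$glucose_valid &
                       .data$insulin_valid),
      .groups = "drop"
    ) |>
    mutate(eligible = .data$n_glucose >= min_valid &
             .data$n_insulin >= min_valid &
             (!require_basal | .data$basal_ok))
}

.ensure_validity <- function(data) {
  if (!"glucose_valid" %in% names(data)) {
    data$glucose_valid <- is.finite(data$glucose)
  }
  if (!"insulin_valid" %in% names(data)) {
    data$insulin_valid <- is.finite(data$insulin)
  }
  data$glucose_valid <- data$glucose_valid & is.finite(data$glucose)
  data$insulin_valid <- data$insulin_valid & is.finite(data$insulin)
  data
}
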