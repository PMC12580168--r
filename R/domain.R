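#' Core marker computations and CBC sample conventions
#'
#' A longitudinal cohort is stored as an ordinary tibble with one row per
#' visit. Units are fixed throughout the package: hemoglobin concentration
#' `hb` in g/dL, hematocrit `hct` in %, red-cell count `rbc` in 10^6/uL,
#' reticulocyte percentage `ret_pct` in %, mean corpuscular volume `mcv` in
#' fL, mean corpuscular hemoglobin concentration `mchc` in g/dL, plasma
#' volume in mL, height in cm, weight in kg, age in years. `visit_index` is
#' an ordinal (1, 2, ...) strictly increasing within a subject; real dates
#' are mapped to this order on import.
#'
#' @name cbc-conventions
NULL

# required columns of a CBC sample table, in canonical order
CBC_COLUMNS <- c(
  "subject_id", "sex", "age", "height", "weight", "visit_index",
  "hb", "hct", "rbc", "ret_pct", "mcv", "mchc"
)

# CBC markers that enter the PV estimator and the sensitivity analysis
CBC_MARKERS <- c("hb", "hct", "rbc", "ret_pct", "mcv", "mchc")

#' Validate a CBC sample table
#'
#' Checks the column contract and the physiological invariants (`hb > 0`,
#' `0 < hct < 100`, `0 <= ret_pct < 100`, strictly increasing
#' `visit_index` within each subject). `weight` and `pv_measured` may be
#' `NA` (weight-free operation is supported downstream); all other fields
#' must be complete.
#'
#' @param samples A data frame of per-visit CBC rows (see
#'   [cbc-conventions]).
#' @return The input as a tibble, invisibly usable downstream; errors if the
#'   contract is violated.
#' @export
validate_cbc <- function(samples) {
  samples <- tibble::as_tibble(samples)
  missing_cols <- setdiff(CBC_COLUMNS, names(samples))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(samples) == 0) stop("no samples", call. = FALSE)
  bad_sex <- setdiff(unique(samples$sex), c("male", "female"))
  if (length(bad_sex) > 0) {
    stop("sex must be 'male' or 'female'; found: ",
         paste(bad_sex, collapse = ", "), call. = FALSE)
  }
  core <- setdiff(CBC_COLUMNS, "weight")
  for (col in core) {
    if (anyNA(samples[[col]])) {
      stop("column '", col, "' contains missing values", call. = FALSE)
    }
  }
  stopifnot_domain(all(samples$hb > 0), "hb must be > 0")
  stopifnot_domain(all(samples$hct > 0 & samples$hct < 100),
                   "hct must be in (0, 100)")
  stopifnot_domain(all(samples$ret_pct >= 0 & samples$ret_pct < 100),
                   "ret_pct must be in [0, 100)")
  ok_order <- samples |>
    dplyr::summarise(
      ok = all(diff(.data$visit_index) > 0) || dplyr::n() == 1L,
      .by = "subject_id"
    )
  if (!all(ok_order$ok)) {
    stop("visit_index must be strictly increasing within each subject",
         call. = FALSE)
  }
  samples
}

stopifnot_domain <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

#' OFF-score from hemoglobin concentration and reticulocyte percentage
#'
#' The OFF-score is the secondary blood-doping marker of the ABP
#' hematological module, `OFFs = 10 * hb - 60 * sqrt(ret_pct)` with `hb` in
#' g/dL. The factor 10 converts hemoglobin to g/L; conversion happens only
#' inside this function, storage stays in g/dL.
#'
#' @param hb Hemoglobin concentration, g/dL. Vectorized.
#' @param ret_pct Reticulocyte percentage, %. Vectorized, recycled against
#'   `hb`.
#' @return Numeric OFF-score values (dimensionless).
#' @examples
#' off_score(15, 1)   # 90
#' off_score(14, 0.49) # 98
#' @export
off_score <- function(hb, ret_pct) {
  if (any(hb <= 0)) stop("hb must be > 0", call. = FALSE)
  if (any(ret_pct < 0)) {
    stop("ret_pct must be >= 0 (square root undefined)", call. = FALSE)
  }
  10 * hb - 60 * sqrt(ret_pct)
}

#' Plasma-volume z-scores against a sex-group mean and SD
#'
#' Standardizes PV estimates for the overlay display: `z = (pv - mean) /
#' sd`. The reference mean and SD are conventionally those of all estimated
#' PV values of the subject's sex in the loaded cohort; see [add_pv_z()]
#' for the grouped version.
#'
#' @param pv Plasma volumes, mL.
#' @param group_mean Sex-group mean PV, mL.
#' @param group_sd Sex-group SD of PV, mL; must be > 0.
#' @return z-scores (dimensionless).
#' @export
pv_z_scores <- function(pv, group_mean, group_sd) {
  if (!is.finite(group_sd) || group_sd <= 0) {
    stop("group_sd must be a positive finite number (degenerate group)",
         call. = FALSE)
  }
  (pv - group_mean) / group_sd
}

#' Add per-sex PV z-scores to a table of PV estimates
#'
#' Groups by `sex`, computes the cohort-level mean and SD of `pv`, and
#' appends a `pv_z` column. Within-subject standardization is available via
#' `within_subject = TRUE` (grouping by subject instead of sex).
#'
#' @param tbl Data frame with at least `pv` and `sex` (and `subject_id` if
#'   `within_subject`).
#' @param within_subject Standardize within each subject rather than within
#'   each sex. Default `FALSE`.
#' @return `tbl` with an added `pv_z` column.
#' @export
add_pv_z <- function(tbl, within_subject = FALSE) {
  by <- if (within_subject) "subject_id" else "sex"
  dplyr::mutate(
    tbl,
    pv_z = pv_z_scores(.data$pv, mean(.data$pv), stats::sd(.data$pv)),
    .by = dplyr::all_of(by)
  )
}
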