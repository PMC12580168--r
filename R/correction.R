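#' Plasma-volume correction of individual hemoglobin limits
#'
#' The core procedure: successive PV estimates give a relative fluid shift
#' `delta_pv_relative = (pv_curr - pv_prev) / pv_prev`, damped by the
#' per-sex weighting index R^2 (only the PV-attributable share of [Hb]
#' variation is corrected), and converted into a limit shift
#' `-delta_pv_weighted * midpoint(lower, upper)` applied equally to both
#' bounds. The original interval width is preserved exactly; PV expansion
#' (dilution, positive delta) moves the limits downward, tracking the
#' expected dilution of [Hb]. OFF-score limits are never corrected (its
#' RET% component is PV-independent).
#'
#' @name pv-correction
NULL

#' Relative plasma-volume change between successive visits
#'
#' @param pv_prev PV at the preceding visit, mL (> 0).
#' @param pv_curr PV at the current visit, mL.
#' @return Dimensionless fraction `(pv_curr - pv_prev) / pv_prev`.
#' @examples
#' delta_pv_relative(3750, 3900) # +0.04
#' @export
delta_pv_relative <- function(pv_prev, pv_curr) {
  if (any(pv_prev <= 0)) stop("pv_prev must be > 0", call. = FALSE)
  (pv_curr - pv_prev) / pv_prev
}

#' Weight a relative PV change by the per-sex R^2 index
#'
#' @param delta_rel Relative PV change (fraction), from
#'   [delta_pv_relative()].
#' @param sex `"male"` or `"female"`, recycled against `delta_rel`.
#' @param weights Named weights in \[0, 1\]; default [default_weighting()]
#'   (male 0.28, female 0.42).
#' @return `delta_rel * weights[sex]` (the weighted PV change).
#' @export
weight_shift <- function(delta_rel, sex, weights = default_weighting()) {
  if (!all(sex %in% names(weights))) {
    stop("no weighting index configured for sex: ",
         paste(setdiff(unique(sex), names(weights)), collapse = ", "),
         call. = FALSE)
  }
  w <- unname(weights[sex])
  if (any(w < 0 | w > 1)) stop("weights must lie in [0, 1]", call. = FALSE)
  delta_rel * w
}

#' Shift a limit pair for a weighted PV change
#'
#' `shift_applied = -delta_weighted * (lower + upper) / 2`; both bounds
#' move by the same amount, so the interval width is unchanged. The
#' corrected upper bound is constructed as `corrected_lower + width` so
#' preservation is exact at the bit level. All arguments vectorized.
#'
#' @param lower,upper Original limits, g/dL.
#' @param delta_weighted Weighted relative PV change (fraction).
#' @return Tibble with `lower`, `upper`, `shift_applied` (g/dL, signed).
#' @examples
#' correct_limits(12.1, 15.0, 0.0112) # shifts both bounds down by 0.1518
#' @export
correct_limits <- function(lower, upper, delta_weighted) {
  if (any(upper <= lower)) stop("invalid limits: upper <= lower",
                                call. = FALSE)
  width <- upper - lower
  shift <- -delta_weighted * (lower + upper) / 2
  new_lower <- lower + shift
  new_upper <- new_lower + width
  # enforce bit-level width preservation: where rounding broke the width,
  # re-derive the lower bound from the rounded upper bound (one step
  # suffices; the bounds move by at most one ulp)
  for (i in 1:3) {
    off <- (new_upper - new_lower) != width
    if (!any(off)) break
    new_lower[off] <- new_upper[off] - width[off]
  }
  tibble::tibble(
    lower = new_lower,
    upper = new_upper,
    shift_applied = shift
  )
}

#' Per-subject correction table and ATPF reclassification
#'
#' Builds the full per-visit correction record for one or more subjects:
#' relative and weighted PV changes (first visit of each subject: shift 0,
#' corrected limits equal the originals, since no predecessor exists),
#' corrected limits, the ATPF flag against the original limits, and the
#' reclassified flag. An ATPF whose value lies inside the corrected limits
#' becomes `"atpf_explained_by_pv"`; a non-flagged value falling outside
#' the corrected limits keeps flag `"none"` but is reported through the
#' `new_outlier` diagnostic column (the procedure is expected to generate
#' none on unremarkable profiles). Corrections reference the immediately
#' preceding visit and never accumulate.
#'
#' @param tbl Tibble with columns `subject_id`, `visit_index`, `sex`,
#'   `hb`, `pv` (estimated PV, mL), `lower`, `upper` (original limits,
#'   g/dL), ordered by visit within subject.
#' @param weights Per-sex weighting indices; default [default_weighting()].
#' @return `tbl` plus `delta_pv_rel`, `delta_pv_weighted`,
#'   `shift_applied`, `lower_corrected`, `upper_corrected`,
#'   `flag_original`, `flag`, `new_outlier`.
#' @export
correct_profile <- function(tbl, weights = default_weighting()) {
  needed <- c("subject_id", "visit_index", "sex", "hb", "pv",
              "lower", "upper")
  missing_cols <- setdiff(needed, names(tbl))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- tbl |>
    dplyr::mutate(
      # lag defaulting to the first value makes the first-visit delta 0
      delta_pv_rel = delta_pv_relative(
        dplyr::lag(.data$pv, default = dplyr::first(.data$pv)), .data$pv
      ),
      .by = "subject_id"
    ) |>
    dplyr::mutate(
      delta_pv_weighted = weight_shift(.data$delta_pv_rel, .data$sex,
                                       weights)
    )
  cl <- correct_limits(out$lower, out$upper, out$delta_pv_weighted)
  out$lower_corrected <- cl$lower
  out$upper_corrected <- cl$upper
  out$shift_applied <- cl$shift_applied
  out$flag_original <- flag_atpf(out$hb, out$lower, out$upper)
  inside_corrected <- out$hb >= out$lower_corrected &
    out$hb <= out$upper_corrected
  out$flag <- dplyr::case_when(
    out$flag_original == "atpf" & inside_corrected ~ "atpf_explained_by_pv",
    out$flag_original == "atpf" ~ "atpf",
    .default = "none"
  )
  out$new_outlier <- out$flag_original == "none" & !inside_corrected
  out
}
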