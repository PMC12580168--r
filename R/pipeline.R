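#' File I/O, profile rendering and the end-to-end pipeline
#'
#' The pipeline ties the stages together: read a longitudinal CBC table,
#' compute prequential individual limits for [Hb] and OFF-score, estimate
#' PV at every visit, correct the [Hb] limits for weighted PV shifts, flag
#' and reclassify ATPFs, and render the two profile displays (corrected
#' limits view and PV-overlay view). Everything is deterministic given the
#' configuration and seed.
#'
#' @name pipeline
NULL

CBC_COL_TYPES <- list(
  subject_id = "c", sex = "c", age = "d", height = "d", weight = "d",
  visit_index = "i", hb = "d", hct = "d", rbc = "d", ret_pct = "d",
  mcv = "d", mchc = "d", pv_measured = "d", visit_date = "D"
)

#' Read / write a CBC sample table (CSV)
#'
#' The dialect is plain UTF-8 CSV with '.' decimal and the documented
#' column names (see [cbc-conventions]). If `visit_index` is absent but a
#' `visit_date` column is present, dates are mapped to visit order within
#' each subject. Malformed rows raise a line-numbered error.
#'
#' @param path CSV file path.
#' @return A validated CBC tibble.
#' @export
read_cbc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  hdr <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  types <- do.call(readr::cols, CBC_COL_TYPES[intersect(names(CBC_COL_TYPES),
                                                        hdr)])
  # parsing problems are re-reported as a line-numbered error below
  samples <- suppressWarnings(
    readr::read_csv(path, col_types = types, progress = FALSE)
  )
  probs <- readr::problems(samples)
  if (nrow(probs) > 0) {
    stop("malformed CSV row(s) at line(s): ",
         paste(utils::head(unique(probs$row), 5), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(samples) == 0) stop("no samples", call. = FALSE)
  if (!"visit_index" %in% names(samples)) {
    if (!"visit_date" %in% names(samples)) {
      stop("need either visit_index or visit_date", call. = FALSE)
    }
    samples <- samples |>
      dplyr::arrange(.data$subject_id, .data$visit_date) |>
      dplyr::mutate(visit_index = dplyr::row_number(),
                    .by = "subject_id")
  }
  validate_cbc(samples)
}

#' @rdname read_cbc
#' @param samples CBC tibble to write.
#' @export
write_cbc <- function(samples, path) {
  readr::write_csv(samples, path)
  invisible(path)
}

#' Build the default (frozen-seed) synthetic-trained PV model
#'
#' A reproducible stand-in for a shipped model artifact: trains the given
#' regressor on the default synthetic cohort under a fixed seed, so every
#' call returns the identical model.
#'
#' @param regressor Regressor kind, see [train_pv_model()].
#' @param weight_free Drop body weight, see [train_pv_model()].
#' @param seed Generator/training seed (default 20240101).
#' @return A fitted `pv_model`.
#' @export
default_pv_model <- function(regressor = "ridge", weight_free = FALSE,
                             seed = 20240101L) {
  cohort <- generate_cohort(scenario_config(seed = seed))
  train <- cohort$samples
  train$pv_measured <- cohort$truth$pv_true
  train_pv_model(train, regressor = regressor, weight_free = weight_free,
                 seed = seed)
}

#' Assemble the full per-visit passport table for a cohort
#'
#' For every subject and visit: OFF-score, prequential [Hb] and OFF-score
#' limits, PV estimate and per-sex z-score, corrected [Hb] limits, ATPF
#' flags (original and PV-reclassified) for [Hb], and the OFF-score flag
#' (OFF-score limits are never corrected).
#'
#' @param samples A validated CBC tibble.
#' @param model A fitted `pv_model` (default [default_pv_model()]).
#' @param priors Named list of priors as in [default_priors()].
#' @param specificity Limit specificity, default 0.99.
#' @param weights Per-sex weighting indices, default [default_weighting()].
#' @return A tibble, one row per visit, with the columns above.
#' @export
passport_table <- function(samples, model = default_pv_model(),
                           priors = default_priors(),
                           specificity = 0.99,
                           weights = default_weighting()) {
  samples <- validate_cbc(samples)
  samples$offs <- off_score(samples$hb, samples$ret_pct)
  samples$pv <- estimate_pv(model, samples)
  samples <- add_pv_z(samples)

  with_limits <- samples |>
    dplyr::arrange(.data$subject_id, .data$visit_index) |>
    dplyr::group_split(.data$subject_id) |>
    lapply(function(tr) {
      sx <- tr$sex[1]
      lim_hb <- profile_limits(priors[[paste0("hb.", sx)]], tr$hb,
                               specificity)
      lim_offs <- profile_limits(priors[[paste0("offs.", sx)]], tr$offs,
                                 specificity)
      tr$lower <- lim_hb$lower
      tr$upper <- lim_hb$upper
      tr$offs_lower <- lim_offs$lower
      tr$offs_upper <- lim_offs$upper
      tr
    }) |>
    dplyr::bind_rows()

  out <- correct_profile(with_limits, weights)
  out$offs_flag <- flag_atpf(out$offs, out$offs_lower, out$offs_upper)
  out
}

#' Profile display: original and corrected limits
#'
#' The Fig-2-style corrected-limits view for one subject: the [Hb] series
#' in black, the original individual limits in red, the corrected limits
#' in purple; explained ATPFs are ringed in green.
#'
#' @param tbl One subject's rows of a [passport_table()].
#' @return A ggplot object.
#' @export
plot_profile_corrected <- function(tbl) {
  stopifnot(length(unique(tbl$subject_id)) == 1)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$visit_index)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$lower), color = "red") +
    ggplot2::geom_step(ggplot2::aes(y = .data$upper), color = "red") +
    ggplot2::geom_step(ggplot2::aes(y = .data$lower_corrected),
                       color = "purple") +
    ggplot2::geom_step(ggplot2::aes(y = .data$upper_corrected),
                       color = "purple") +
    ggplot2::geom_line(ggplot2::aes(y = .data$hb), color = "black") +
    ggplot2::geom_point(ggplot2::aes(y = .data$hb), color = "black") +
    ggplot2::geom_point(
      data = tbl[tbl$flag == "atpf_explained_by_pv", ],
      ggplot2::aes(y = .data$hb), shape = 21, size = 3, color = "green4"
    ) +
    ggplot2::scale_x_continuous(breaks = tbl$visit_index) +
    ggplot2::labs(
      title = paste0(tbl$subject_id[1], " - corrected limits"),
      x = "visit", y = "[Hb] (g/dL)"
    ) +
    ggplot2::theme_minimal()
}

#' Profile display: PV z-score overlay
#'
#' The Fig-2-style overlay view: [Hb] with its original limits on the left
#' axis, the estimated-PV z-score in blue on the right axis.
#'
#' @param tbl One subject's rows of a [passport_table()].
#' @return A ggplot object.
#' @export
plot_profile_pv <- function(tbl) {
  stopifnot(length(unique(tbl$subject_id)) == 1)
  # affine map of z in [-3, 3] onto the [Hb] axis range
  rng <- range(c(tbl$hb, tbl$lower, tbl$upper))
  z_to_hb <- function(z) rng[1] + (z + 3) / 6 * diff(rng)
  hb_to_z <- function(y) (y - rng[1]) / diff(rng) * 6 - 3
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$visit_index)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$lower), color = "red") +
    ggplot2::geom_step(ggplot2::aes(y = .data$upper), color = "red") +
    ggplot2::geom_line(ggplot2::aes(y = .data$hb), color = "black") +
    ggplot2::geom_point(ggplot2::aes(y = .data$hb), color = "black") +
    ggplot2::geom_line(ggplot2::aes(y = z_to_hb(.data$pv_z)),
                       color = "blue", linetype = 2) +
    ggplot2::scale_x_continuous(breaks = tbl$visit_index) +
    ggplot2::scale_y_continuous(
      sec.axis = ggplot2::sec_axis(hb_to_z, name = "PV z-score")
    ) +
    ggplot2::labs(
      title = paste0(tbl$subject_id[1], " - PV overlay"),
      x = "visit", y = "[Hb] (g/dL)"
    ) +
    ggplot2::theme_minimal()
}

#' Run the full passport pipeline
#'
#' Reads (or accepts) a cohort, builds the [passport_table()], writes one
#' correction CSV per subject plus a cohort summary, and renders the two
#' profile figures per subject. On failure, files created by the run are
#' removed.
#'
#' @param input CSV path or CBC data frame.
#' @param output_dir Output directory (created if needed).
#' @param model A fitted `pv_model`; default [default_pv_model()] with the
#'   given regressor.
#' @param regressor Regressor kind for the default model.
#' @param weight_free Train/use the weight-free default model.
#' @param priors,specificity,weights See [passport_table()].
#' @param render Write the per-subject PNG figures (default `TRUE`).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `table` (the full passport table),
#'   `counts` (samples, ATPFs, explained ATPFs, new outliers) and `files`.
#' @export
run_pipeline <- function(input, output_dir, model = NULL,
                         regressor = "ridge", weight_free = FALSE,
                         priors = default_priors(), specificity = 0.99,
                         weights = default_weighting(), render = TRUE,
                         quiet = FALSE) {
  samples <- if (is.character(input)) read_cbc(input) else
    validate_cbc(input)
  if (is.null(model)) {
    model <- default_pv_model(regressor = regressor,
                              weight_free = weight_free)
  }
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  created <- character()
  say <- function(...) if (!quiet) message(...)
  tryCatch({
    say("pipeline: ", nrow(samples), " samples from ",
        length(unique(samples$subject_id)), " subjects")
    tab <- passport_table(samples, model = model, priors = priors,
                          specificity = specificity, weights = weights)
    export_cols <- c("subject_id", "visit_index", "sex", "hb", "offs",
                     "pv", "pv_z", "delta_pv_rel", "delta_pv_weighted",
                     "shift_applied", "lower", "upper", "lower_corrected",
                     "upper_corrected", "flag_original", "flag",
                     "new_outlier", "offs_lower", "offs_upper",
                     "offs_flag")
    for (sid in unique(tab$subject_id)) {
      sub <- tab[tab$subject_id == sid, ]
      f <- file.path(output_dir, paste0("correction_", sid, ".csv"))
      readr::write_csv(sub[export_cols], f)
      created <- c(created, f)
      if (render) {
        f1 <- file.path(output_dir, paste0("profile_corrected_", sid,
                                           ".png"))
        f2 <- file.path(output_dir, paste0("profile_pv_", sid, ".png"))
        suppressMessages({
          ggplot2::ggsave(f1, plot_profile_corrected(sub), width = 7,
                          height = 4, dpi = 120)
          ggplot2::ggsave(f2, plot_profile_pv(sub), width = 7, height = 4,
                          dpi = 120)
        })
        created <- c(created, f1, f2)
      }
    }
    counts <- list(
      samples = nrow(tab),
      atpf = sum(tab$flag_original == "atpf"),
      atpf_explained = sum(tab$flag == "atpf_explained_by_pv"),
      new_outliers = sum(tab$new_outlier)
    )
    f <- file.path(output_dir, "summary.csv")
    readr::write_csv(tibble::as_tibble(counts), f)
    created <- c(created, f)
    say("pipeline: ", counts$atpf, " [Hb] ATPFs, ",
        counts$atpf_explained, " explained by PV, ",
        counts$new_outliers, " new outliers")
    invisible(list(table = tab, counts = counts, files = created))
  }, error = function(e) {
    unlink(created)
    stop(e)
  })
}
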