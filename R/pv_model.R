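#' Plasma-volume estimation from a complete blood count
#'
#' A retrainable regression estimator of plasma volume (mL) from the CBC
#' panel plus anthropometrics, standing in for the published
#' machine-learning blood-volume estimator (whose 384-point training set is
#' not available). Three regressor kinds are supported: `"linear"`
#' (ordinary least squares), `"ridge"` (glmnet, alpha = 0, lambda by
#' deterministic 10-fold CV), and `"gam"` (mgcv thin-plate smooths on the
#' CBC markers, the flexible/nonlinear option). The weight-free variant
#' drops body weight from the feature list, as weight is hard to obtain
#' reliably in the anti-doping context.
#'
#' @name pv-model
NULL

PV_FLOOR_ML <- 250 # physical floor for a clamped prediction, mL

default_pv_features <- function(weight_free = FALSE) {
  f <- c(CBC_MARKERS, "sex", "age", "height", "weight")
  if (weight_free) setdiff(f, "weight") else f
}

# numeric design frame: sex -> 0/1 indicator sex_male
pv_design <- function(samples, features) {
  missing_cols <- setdiff(features, names(samples))
  if (length(missing_cols) > 0) {
    stop("missing feature column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- samples[features]
  for (col in features) {
    if (anyNA(x[[col]])) {
      stop("feature column '", col, "' contains missing values",
           call. = FALSE)
    }
  }
  if ("sex" %in% features) {
    x$sex_male <- as.numeric(x$sex == "male")
    x$sex <- NULL
  }
  tibble::as_tibble(x)
}

#' Train a plasma-volume regression model
#'
#' @param samples CBC sample table (see [cbc-conventions]) with a
#'   `pv_measured` column (mL), e.g. CO-rebreathing measurements or the
#'   ground truth of a synthetic cohort. At least 30 complete rows.
#' @param regressor `"linear"`, `"ridge"` or `"gam"`.
#' @param weight_free Drop body weight from the features. Default `FALSE`.
#' @param features Character vector of feature columns; default
#'   [default_pv_features()].
#' @param seed Integer seed recorded in the training metadata; all fitting
#'   is deterministic (CV folds are assigned deterministically), so the
#'   same seed and data reproduce the same artifact bit for bit.
#' @return A `pv_model` object.
#' @export
train_pv_model <- function(samples, regressor = c("ridge", "linear", "gam"),
                           weight_free = FALSE, features = NULL,
                           seed = 1L) {
  regressor <- match.arg(regressor)
  if (is.null(features)) features <- default_pv_features(weight_free)
  if (weight_free) features <- setdiff(features, "weight")
  if (!"pv_measured" %in% names(samples) || anyNA(samples$pv_measured)) {
    stop("training requires a complete 'pv_measured' column (mL)",
         call. = FALSE)
  }
  x <- pv_design(samples, features)
  y <- samples$pv_measured
  if (nrow(x) < 30) {
    stop("refusing to train on fewer than 30 samples (got ", nrow(x), ")",
         call. = FALSE)
  }
  if (any(y <= 0)) stop("pv_measured must be > 0", call. = FALSE)

  scaling <- list(
    mean = vapply(x, mean, numeric(1)),
    sd = vapply(x, stats::sd, numeric(1))
  )

  fit <- NULL
  coefs <- NULL
  lambda <- NULL
  if (regressor == "linear") {
    df <- cbind(x, .pv = y)
    lmfit <- stats::lm(.pv ~ ., data = df)
    coefs <- stats::coef(lmfit)
    coefs[is.na(coefs)] <- 0 # collinear columns contribute nothing
  } else if (regressor == "ridge") {
    xm <- as.matrix(x)
    foldid <- rep_len(seq_len(10), nrow(xm)) # deterministic folds
    cv <- glmnet::cv.glmnet(xm, y, alpha = 0, foldid = foldid)
    fit <- glmnet::glmnet(xm, y, alpha = 0, lambda = cv$lambda)
    lambda <- cv$lambda.min
  } else { # gam
    smooth_terms <- intersect(CBC_MARKERS, names(x))
    lin_terms <- setdiff(names(x), smooth_terms)
    rhs <- c(sprintf("s(%s, k = 5)", smooth_terms), lin_terms)
    fml <- stats::as.formula(paste(".pv ~", paste(rhs, collapse = " + ")))
    df <- cbind(x, .pv = y)
    fit <- mgcv::gam(fml, data = df, method = "REML")
  }

  structure(
    list(
      regressor = regressor,
      features = features,
      design_names = names(x),
      weight_free = weight_free,
      fit = fit,
      coefs = coefs,
      lambda = lambda,
      scaling = scaling,
      training_meta = list(n = nrow(x), seed = as.integer(seed)),
      version = 1L
    ),
    class = "pv_model"
  )
}

#' Construct a linear PV model directly from coefficients
#'
#' Mainly for stubs and oracles: builds a fitted `pv_model` whose
#' prediction is `intercept + sum(coefficients * features)` on the raw
#' feature scale.
#'
#' @param intercept Intercept, mL.
#' @param coefficients Named numeric vector; names are design columns
#'   (`hb`, `hct`, ..., `sex_male`, `age`, `height`, `weight`).
#' @return A `pv_model` object of kind `"linear"`.
#' @export
linear_pv_model <- function(intercept, coefficients) {
  stopifnot(!is.null(names(coefficients)), all(nzchar(names(coefficients))))
  design <- names(coefficients)
  features <- design
  if ("sex_male" %in% design) {
    features <- c(setdiff(design, "sex_male"), "sex")
  }
  structure(
    list(
      regressor = "linear",
      features = features,
      design_names = design,
      weight_free = !"weight" %in% design,
      fit = NULL,
      coefs = c("(Intercept)" = unname(intercept), coefficients),
      lambda = NULL,
      scaling = NULL,
      training_meta = list(n = 0L, seed = NA_integer_),
      version = 1L
    ),
    class = "pv_model"
  )
}

#' @export
print.pv_model <- function(x, ...) {
  cat(sprintf(
    "<pv_model> %s regressor, %d features%s, trained on n = %d\n",
    x$regressor, length(x$features),
    if (x$weight_free) " (weight-free)" else "", x$training_meta$n
  ))
  invisible(x)
}

#' Estimate plasma volume for CBC samples
#'
#' Applies a fitted [train_pv_model()] artifact to one or more visits.
#' Predictions at or below zero are clamped to a small positive floor
#' (250 mL) with a warning; estimation is deterministic.
#'
#' @param model A `pv_model`.
#' @param samples CBC sample table containing the model's feature columns.
#' @return Numeric vector of PV estimates, mL (one per row of `samples`).
#' @export
estimate_pv <- function(model, samples) {
  stopifnot(inherits(model, "pv_model"))
  if (is.null(model$coefs) && is.null(model$fit)) {
    stop("model is not fitted", call. = FALSE)
  }
  x <- pv_design(samples, model$features)
  x <- x[model$design_names] # canonical column order
  pred <- switch(model$regressor,
    linear = {
      b <- model$coefs
      drop(as.matrix(x) %*% b[model$design_names]) + b[["(Intercept)"]]
    },
    ridge = as.numeric(
      stats::predict(model$fit, newx = as.matrix(x), s = model$lambda)
    ),
    gam = as.numeric(stats::predict(model$fit, newdata = x))
  )
  if (any(pred <= 0)) {
    warning("clamped ", sum(pred <= 0), " non-positive PV prediction(s) to ",
            PV_FLOOR_ML, " mL", call. = FALSE)
    pred <- pmax(pred, PV_FLOOR_ML)
  }
  unname(pred)
}

#' Save / load a PV model artifact
#'
#' The artifact is a single versioned file embedding the feature list and
#' scaling constants, so estimation elsewhere reproduces training-time
#' behavior exactly.
#'
#' @param model A `pv_model`.
#' @param path File path.
#' @return `read_pv_model` returns the `pv_model`; `write_pv_model` returns
#'   `path` invisibly.
#' @export
write_pv_model <- function(model, path) {
  stopifnot(inherits(model, "pv_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_pv_model
#' @export
read_pv_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "pv_model")) stop("not a pv_model artifact",
                                         call. = FALSE)
  model
}

#' Perturbation sensitivity analysis of the PV estimator
#'
#' Quantifies each CBC marker's leverage: marker m is scaled by
#' `1 + level/100` (one marker at a time, all else untouched), PV is
#' re-estimated, and the grid cell holds the mean difference from the
#' unperturbed estimates, in mL. Default levels are -0.2, -0.1, -0.05,
#' +0.05, +0.1, +0.2 percent.
#'
#' @param model A fitted `pv_model`.
#' @param samples CBC sample table.
#' @param levels Perturbation levels in percent (nonzero; a 0 level is
#'   allowed and yields exactly 0 by construction).
#' @param markers CBC marker names to perturb; default all of
#'   `hb, hct, rbc, ret_pct, mcv, mchc` that the model uses.
#' @return A tibble of class `sensitivity_grid`: column `level` (%) plus
#'   one column per marker with the mean PV delta (mL).
#' @export
sensitivity_analysis <- function(model, samples,
                                 levels = c(-0.2, -0.1, -0.05,
                                            0.05, 0.1, 0.2),
                                 markers = NULL) {
  stopifnot(inherits(model, "pv_model"))
  if (is.null(markers)) markers <- intersect(CBC_MARKERS, model$features)
  unknown <- setdiff(markers, names(samples))
  if (length(unknown) > 0) {
    stop("unknown marker(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  base <- estimate_pv(model, samples)
  grid <- matrix(0, nrow = length(levels), ncol = length(markers),
                 dimnames = list(NULL, markers))
  for (j in seq_along(markers)) {
    for (i in seq_along(levels)) {
      if (levels[i] == 0) next # no perturbation: delta is exactly 0
      pert <- samples
      pert[[markers[j]]] <- pert[[markers[j]]] * (1 + levels[i] / 100)
      grid[i, j] <- mean(estimate_pv(model, pert) - base)
    }
  }
  out <- tibble::as_tibble(as.data.frame(grid))
  out <- tibble::add_column(out, level = levels, .before = 1)
  class(out) <- c("sensitivity_grid", class(out))
  out
}

#' Heat-map display of a sensitivity grid
#'
#' Rows are perturbation levels, columns the CBC markers; color encodes the
#' mean PV delta in mL (white near zero).
#'
#' @param grid A [sensitivity_analysis()] result.
#' @return A ggplot object.
#' @export
plot_sensitivity <- function(grid) {
  long <- tidyr::pivot_longer(tibble::as_tibble(grid), -"level",
                              names_to = "marker", values_to = "delta_ml")
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$marker, y = factor(.data$level), fill = .data$delta_ml
  )) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", midpoint = 0) +
    ggplot2::labs(x = NULL, y = "perturbation (%)",
                  fill = expression(Delta * PV ~ (mL))) +
    ggplot2::theme_minimal()
}

#' Agreement between estimated and measured plasma volume
#'
#' Nonparametric validation of the estimator against a reference method
#' (CO-rebreathing in the source study): Spearman rank correlation and
#' Bland-Altman statistics (bias = mean(estimated - measured), limits of
#' agreement bias +/- 1.96 SD of the differences), overall and stratified
#' by sex when labels are given.
#'
#' @param estimated,measured Equal-length PV vectors, mL (n >= 3).
#' @param sex Optional per-element `"male"`/`"female"` labels.
#' @return A tibble, one row per stratum: `group`, `n`, `spearman_r`,
#'   `p_value`, `bias_ml`, `loa_lower_ml`, `loa_upper_ml`. A constant
#'   series yields `NA` correlation (undefined ranks).
#' @export
validate_pv_model <- function(estimated, measured, sex = NULL) {
  if (length(estimated) != length(measured)) {
    stop("estimated and measured must have equal length", call. = FALSE)
  }
  if (length(estimated) < 3) stop("need at least 3 pairs", call. = FALSE)
  one <- function(est, mea, label) {
    r <- NA_real_; p <- NA_real_
    if (stats::sd(est) > 0 && stats::sd(mea) > 0) {
      ct <- suppressWarnings(
        stats::cor.test(est, mea, method = "spearman", exact = FALSE)
      )
      r <- unname(ct$estimate); p <- ct$p.value
    }
    d <- est - mea
    bias <- mean(d)
    half <- 1.96 * stats::sd(d)
    tibble::tibble(group = label, n = length(est), spearman_r = r,
                   p_value = p, bias_ml = bias,
                   loa_lower_ml = bias - half, loa_upper_ml = bias + half)
  }
  out <- one(estimated, measured, "all")
  if (!is.null(sex)) {
    for (s in intersect(c("male", "female"), unique(sex))) {
      idx <- sex == s
      if (sum(idx) >= 3) {
        out <- dplyr::bind_rows(out, one(estimated[idx], measured[idx], s))
      }
    }
  }
  out
}

#' Weighting index: share of [Hb] variance attributable to PV
#'
#' The determination coefficient R^2 of the simple linear regression
#' between estimated PV and hemoglobin concentration. It damps the limit
#' correction so that only the PV-attributable share of an [Hb] change is
#' corrected. R^2 is orientation-free for a simple regression (it equals
#' the squared Pearson correlation either way).
#'
#' @param pv Estimated PV values, mL (n >= 3, non-constant).
#' @param hb Matching hemoglobin concentrations, g/dL (non-constant).
#' @return R^2 in \[0, 1\].
#' @seealso [default_weighting()] for the published per-sex constants used
#'   when no cohort is supplied.
#' @export
weighting_index <- function(pv, hb) {
  if (length(pv) != length(hb) || length(pv) < 3) {
    stop("pv and hb must be equal-length vectors with n >= 3", call. = FALSE)
  }
  if (stats::sd(pv) == 0 || stats::sd(hb) == 0) {
    stop("degenerate input: constant pv or hb series", call. = FALSE)
  }
  stats::cor(pv, hb)^2
}

#' Default per-sex weighting indices
#'
#' The published constants relating estimated PV to \[Hb\]: R^2 = 0.28 for
#' men and 0.42 for women, i.e. 28% / 42% of \[Hb\] variation attributed to
#' PV fluctuation. Used by the correction step whenever cohort-specific
#' indices are not recomputed.
#'
#' @return Named numeric vector `c(male = 0.28, female = 0.42)`.
#' @export
default_weighting <- function() {
  c(male = 0.28, female = 0.42)
}
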