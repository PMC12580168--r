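#' Synthetic longitudinal CBC cohorts with ground-truth plasma volume
#'
#' The generator emulates the shape of an ABP monitoring study (by default
#' 40 subjects, 27 men and 13 women, followed monthly for 12 visits) with
#' physiologically coupled quantities. Per subject, a baseline blood
#' volume comes from Nadler's height/weight formula (with a small
#' lognormal subject-level deviation), a baseline hemoglobin concentration
#' from per-sex normals, and total hemoglobin mass / red-cell volume follow
#' from mass conservation: `hb = 100 * hbmass / (pv + rcv)` with volumes in
#' mL and mass in g. Plasma volume fluctuates around baseline as a
#' stationary AR(1) process; confounder and doping events (hyperhydration,
#' exercise hemoconcentration, altitude, transfusion, rhEPO) perturb the
#' true quantities; the observed CBC is derived from the truth the way a
#' hematology analyzer builds it (HCT = RBC x MCV / 10, MCHC = Hb / HCT x
#' 100) and carries multiplicative analytic noise.
#'
#' @name synthetic-cohort
NULL

EVENT_KINDS <- c("hyperhydration", "exercise_hemoconcentration",
                 "altitude", "transfusion", "rhEPO")

#' Scenario configuration for the cohort generator
#'
#' Defaults mirror a monthly one-year monitoring study of 40 mixed-sex
#' subjects. All rates are fractions (0.15 = 15%).
#'
#' @param n_subjects Number of subjects (default 40).
#' @param n_visits Visits per subject (default 12, monthly for one year).
#' @param male_fraction Fraction of male subjects (default 27/40, the
#'   source cohort's mix).
#' @param seed Integer seed; the generator is bit-reproducible given the
#'   seed.
#' @param pv_ar1_rho Visit-to-visit autocorrelation of the PV fluctuation
#'   (default 0.3; monthly spacing leaves little carry-over of acute fluid
#'   shifts).
#' @param pv_cv Coefficient of variation of the PV fluctuation around
#'   baseline (default 0.05, consistent with the ~3% within-subject
#'   biological variation of \[Hb\]).
#' @param bv_subject_cv Lognormal subject-level deviation of baseline blood
#'   volume from the allometric prediction (default 0.03).
#' @param analytic_cv Named per-marker analytic CVs for `hb`, `rbc`, `mcv`,
#'   `ret_pct` (HCT and MCHC are derived quantities). Defaults 1-2%.
#'   A single scalar is recycled to all four markers.
#' @param ret_bio_cv Within-subject biological CV of RET% (default 0.10).
#' @param pv_measured_cv CV of the reference PV measurement error
#'   (CO-rebreathing; default 0.02). Set `include_pv_measured = FALSE` to
#'   drop the column.
#' @param include_pv_measured Include a noisy `pv_measured` column
#'   (default `TRUE`).
#' @param events `NULL`, or a data frame with columns `visit`, `kind`
#'   (one of `r paste(EVENT_KINDS, collapse = ", ")`), `magnitude`
#'   (fraction), and optionally `subject_id` (absent/`NA` = every
#'   subject). PV-scaling magnitudes are capped at 0.25 (acute PV shifts
#'   of up to ~25%).
#' @param altitude_ramp Total fractional Hbmass gain of an altitude event
#'   (default 0.04), reached linearly over `ramp_visits` visits.
#' @param rhepo_ret_multiplier RET% multiplier during rhEPO use
#'   (default 1.8).
#' @param rhepo_duration Number of visits with elevated RET% (default 2).
#' @param ramp_visits Visits over which Hbmass ramps reach their plateau
#'   (default 3).
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_subjects = 40, n_visits = 12,
                            male_fraction = 27 / 40, seed = 1L,
                            pv_ar1_rho = 0.3, pv_cv = 0.05,
                            bv_subject_cv = 0.03,
                            analytic_cv = c(hb = 0.010, rbc = 0.015,
                                            mcv = 0.005, ret_pct = 0.020),
                            ret_bio_cv = 0.10,
                            pv_measured_cv = 0.02,
                            include_pv_measured = TRUE,
                            events = NULL,
                            altitude_ramp = 0.04,
                            rhepo_ret_multiplier = 1.8,
                            rhepo_duration = 2L,
                            ramp_visits = 3L) {
  if (length(analytic_cv) == 1 && is.null(names(analytic_cv))) {
    analytic_cv <- c(hb = analytic_cv, rbc = analytic_cv,
                     mcv = analytic_cv, ret_pct = analytic_cv)
  }
  needed_cv <- c("hb", "rbc", "mcv", "ret_pct")
  if (!all(needed_cv %in% names(analytic_cv))) {
    stop("analytic_cv must name ", paste(needed_cv, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(events)) {
    events <- tibble::as_tibble(events)
    stopifnot(all(c("visit", "kind", "magnitude") %in% names(events)))
    bad_kind <- setdiff(events$kind, EVENT_KINDS)
    if (length(bad_kind) > 0) {
      stop("unknown event kind(s): ", paste(bad_kind, collapse = ", "),
           call. = FALSE)
    }
    if (any(events$visit < 1 | events$visit > n_visits)) {
      stop("event visit index outside 1..n_visits", call. = FALSE)
    }
    pv_events <- events$kind %in% c("hyperhydration",
                                    "exercise_hemoconcentration",
                                    "altitude")
    if (any(events$magnitude[pv_events] > 0.25)) {
      stop("PV event magnitudes are capped at 0.25 (25%)", call. = FALSE)
    }
    if (any(events$magnitude < 0)) {
      stop("event magnitudes must be >= 0", call. = FALSE)
    }
  }
  structure(
    list(n_subjects = n_subjects, n_visits = n_visits,
         male_fraction = male_fraction, seed = as.integer(seed),
         pv_ar1_rho = pv_ar1_rho, pv_cv = pv_cv,
         bv_subject_cv = bv_subject_cv, analytic_cv = analytic_cv,
         ret_bio_cv = ret_bio_cv, pv_measured_cv = pv_measured_cv,
         include_pv_measured = include_pv_measured, events = events,
         altitude_ramp = altitude_ramp,
         rhepo_ret_multiplier = rhepo_ret_multiplier,
         rhepo_duration = as.integer(rhepo_duration),
         ramp_visits = as.integer(ramp_visits)),
    class = "scenario_config"
  )
}

# Nadler's blood-volume formula, mL (height cm, weight kg)
nadler_bv <- function(sex, height, weight) {
  h_m <- height / 100
  ifelse(sex == "male",
         1000 * (0.3669 * h_m^3 + 0.03219 * weight + 0.6041),
         1000 * (0.3561 * h_m^3 + 0.03308 * weight + 0.1833))
}

#' Inject a confounder or doping event into one subject's ground truth
#'
#' Event templates are stylized but mass-conserving. Transient PV events
#' (`hyperhydration`, `exercise_hemoconcentration`) scale true PV at the
#' event visit only (up / down respectively). `altitude` contracts PV from
#' the event visit onward and ramps Hbmass up slowly. `transfusion` scales
#' Hbmass (and with it red-cell volume) up from the event visit onward and
#' transiently depresses RET%; PV is untouched. `rhEPO` multiplies RET%
#' for a few visits and then ramps Hbmass. Red-cell volume is always
#' derived as `100 * hbmass / mchc0`, so conservation holds by
#' construction.
#'
#' @param truth One subject's ground-truth tibble (columns `visit_index`,
#'   `pv_true`, `hbmass_true`, `ret_mult`, `mchc0`), visit-ordered.
#' @param visit Event visit index.
#' @param kind One of `r paste(EVENT_KINDS, collapse = ", ")`.
#' @param magnitude Fractional magnitude (0.15 = 15%); 0 leaves the truth
#'   unchanged.
#' @param altitude_ramp,rhepo_ret_multiplier,rhepo_duration,ramp_visits
#'   Dynamics parameters, see [scenario_config()].
#' @return The modified truth tibble.
#' @export
inject_event <- function(truth, visit, kind, magnitude,
                         altitude_ramp = 0.04,
                         rhepo_ret_multiplier = 1.8,
                         rhepo_duration = 2L, ramp_visits = 3L) {
  kind <- match.arg(kind, EVENT_KINDS)
  n <- nrow(truth)
  i <- match(visit, truth$visit_index)
  if (is.na(i)) stop("event visit ", visit, " not in truth", call. = FALSE)
  if (magnitude == 0) return(truth)
  after <- seq(i, n)
  since <- truth$visit_index[after] - visit # 0, 1, 2, ...
  ramp <- function(total) 1 + total * pmin(since / ramp_visits, 1)
  if (kind == "hyperhydration") {
    truth$pv_true[i] <- truth$pv_true[i] * (1 + magnitude)
  } else if (kind == "exercise_hemoconcentration") {
    truth$pv_true[i] <- truth$pv_true[i] * (1 - magnitude)
  } else if (kind == "altitude") {
    truth$pv_true[after] <- truth$pv_true[after] * (1 - magnitude)
    truth$hbmass_true[after] <- truth$hbmass_true[after] *
      ramp(altitude_ramp)
  } else if (kind == "transfusion") {
    truth$hbmass_true[after] <- truth$hbmass_true[after] * (1 + magnitude)
    depress <- seq(i, min(i + 2L, n))
    truth$ret_mult[depress] <- truth$ret_mult[depress] * 0.6
  } else { # rhEPO
    elevated <- seq(i, min(i + rhepo_duration - 1L, n))
    truth$ret_mult[elevated] <- truth$ret_mult[elevated] *
      rhepo_ret_multiplier
    truth$hbmass_true[after] <- truth$hbmass_true[after] * ramp(magnitude)
  }
  truth
}

#' Generate a synthetic cohort
#'
#' @param config A [scenario_config()].
#' @return List with `samples` (a CBC sample table, see
#'   [cbc-conventions], plus `pv_measured` when configured) and `truth`
#'   (per visit: `subject_id`, `visit_index`, `pv_true`, `hbmass_true`,
#'   `rcv_true`, `hb_prenoise`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  ns <- config$n_subjects
  nv <- config$n_visits
  n_male <- round(ns * config$male_fraction)
  sex <- rep(c("male", "female"), c(n_male, ns - n_male))

  subjects <- tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(ns)),
    sex = sex,
    age = round(stats::runif(ns, 18, 35)),
    height = round(ifelse(sex == "male", stats::rnorm(ns, 181, 6),
                          stats::rnorm(ns, 168, 6)), 1),
    weight = round(ifelse(sex == "male", stats::rnorm(ns, 75, 7),
                          stats::rnorm(ns, 62, 6)), 1),
    hb0 = ifelse(sex == "male", stats::rnorm(ns, 15.2, 0.9),
                 stats::rnorm(ns, 13.4, 0.9)),
    mchc0 = stats::rnorm(ns, 34, 0.8),
    mcv0 = stats::rnorm(ns, 88, 4),
    ret_base = pmin(pmax(stats::rlnorm(ns, log(1.0), 0.35), 0.2), 3)
  )
  subjects$bv0 <- nadler_bv(subjects$sex, subjects$height,
                            subjects$weight) *
    exp(stats::rnorm(ns, 0, config$bv_subject_cv))
  subjects$hbmass0 <- subjects$hb0 * subjects$bv0 / 100
  subjects$rcv0 <- 100 * subjects$hbmass0 / subjects$mchc0
  subjects$pv0 <- subjects$bv0 - subjects$rcv0

  # stationary AR(1) PV fluctuation, one row per subject x visit
  rho <- config$pv_ar1_rho
  eps <- matrix(stats::rnorm(ns * nv), ns, nv)
  e <- matrix(0, ns, nv)
  e[, 1] <- config$pv_cv * eps[, 1]
  if (nv > 1) {
    innov_sd <- config$pv_cv * sqrt(1 - rho^2)
    for (t in 2:nv) e[, t] <- rho * e[, t - 1] + innov_sd * eps[, t]
  }

  truth <- tidyr::expand_grid(
    subject_id = subjects$subject_id,
    visit_index = seq_len(nv)
  ) |>
    dplyr::left_join(subjects, by = "subject_id")
  truth$pv_true <- pmax(truth$pv0 * (1 + as.vector(t(e))), 500)
  truth$hbmass_true <- truth$hbmass0
  truth$ret_mult <- 1

  if (!is.null(config$events)) {
    ev <- config$events
    if (!"subject_id" %in% names(ev)) ev$subject_id <- NA_character_
    truth <- truth |>
      dplyr::group_split(.data$subject_id) |>
      lapply(function(tr) {
        sid <- tr$subject_id[1]
        rows <- which(is.na(ev$subject_id) | ev$subject_id == sid)
        for (r in rows) {
          tr <- inject_event(
            tr, ev$visit[r], ev$kind[r], ev$magnitude[r],
            altitude_ramp = config$altitude_ramp,
            rhepo_ret_multiplier = config$rhepo_ret_multiplier,
            rhepo_duration = config$rhepo_duration,
            ramp_visits = config$ramp_visits
          )
        }
        tr
      }) |>
      dplyr::bind_rows()
  }

  # mass conservation: rcv tracks hbmass, [Hb] = 100 * mass / volume
  truth$rcv_true <- 100 * truth$hbmass_true / truth$mchc0
  bv <- truth$pv_true + truth$rcv_true
  truth$hb_prenoise <- 100 * truth$hbmass_true / bv
  hct_prenoise <- 100 * truth$rcv_true / bv
  rbc_prenoise <- 10 * hct_prenoise / truth$mcv0
  ret_prenoise <- truth$ret_base * truth$ret_mult

  m <- nrow(truth)
  cv <- config$analytic_cv
  noise <- function(x, cv) x * exp(stats::rnorm(m, 0, cv))
  hb <- noise(truth$hb_prenoise, cv[["hb"]])
  rbc <- noise(rbc_prenoise, cv[["rbc"]])
  mcv <- noise(truth$mcv0, cv[["mcv"]])
  ret <- noise(ret_prenoise * exp(stats::rnorm(m, 0, config$ret_bio_cv)),
               cv[["ret_pct"]])
  hct <- rbc * mcv / 10          # analyzer-style derived quantities
  mchc <- 100 * hb / hct

  samples <- tibble::tibble(
    subject_id = truth$subject_id,
    sex = truth$sex,
    age = truth$age,
    height = truth$height,
    weight = truth$weight,
    visit_index = truth$visit_index,
    hb = hb, hct = hct, rbc = rbc, ret_pct = ret, mcv = mcv, mchc = mchc
  )
  if (config$include_pv_measured) {
    samples$pv_measured <- truth$pv_true *
      exp(stats::rnorm(m, 0, config$pv_measured_cv))
  }
  truth_out <- truth[c("subject_id", "visit_index", "pv_true",
                       "hbmass_true", "rcv_true", "hb_prenoise")]
  list(samples = validate_cbc(samples), truth = tibble::as_tibble(truth_out))
}
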