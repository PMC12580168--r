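# shared fixtures, built in code and cached per test run

.cache <- new.env(parent = emptyenv())

# reference PV model: ridge regressor trained on a clean default cohort
cached_pv_model <- function() {
  if (is.null(.cache$model)) {
    co <- generate_cohort(scenario_config(n_subjects = 40, n_visits = 12,
                                          seed = 10))
    tr <- co$samples
    tr$pv_measured <- co$truth$pv_true
    .cache$model <- train_pv_model(tr, regressor = "ridge", seed = 10)
  }
  .cache$model
}

# small noise-free sample table realizing pv = 30 * hb[g/dL] + 2000 (i.e.
# 3 mL per g/L of hemoglobin), all other features uninformative
linear_world_samples <- function(n = 60, seed = 99) {
  set.seed(seed)
  tibble::tibble(
    subject_id = sprintf("L%02d", seq_len(n)),
    sex = rep(c("male", "female"), length.out = n),
    age = runif(n, 18, 35),
    height = runif(n, 160, 195),
    weight = runif(n, 55, 95),
    visit_index = 1L,
    hb = runif(n, 12, 17),
    hct = runif(n, 36, 50),
    rbc = runif(n, 4, 6),
    ret_pct = runif(n, 0.4, 2),
    mcv = runif(n, 80, 98),
    mchc = runif(n, 32, 36),
    pv_measured = NA_real_
  ) |>
    dplyr::mutate(pv_measured = 30 * hb + 2000)
}

# independent conjugate-update oracle: one observation at a time, explicit
# posterior bookkeeping on the individual mean
oracle_limits <- function(prior, history, specificity) {
  m <- prior$mu_pop
  prec <- 1 / prior$sigma_between^2
  for (x in history) {
    prec_new <- prec + 1 / prior$sigma_within^2
    m <- (m * prec + x / prior$sigma_within^2) / prec_new
    prec <- prec_new
  }
  v <- prior$sigma_within^2 + 1 / prec
  z <- qnorm((1 + specificity) / 2)
  c(lower = m - z * sqrt(v), upper = m + z * sqrt(v))
}
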