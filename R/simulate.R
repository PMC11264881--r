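#' Simulation configuration for the neonatal cohort generator
#'
#' Defines the statistical structure of a synthetic matched case-control
#' neonatal dried-blood-spot metabolomics study. Defaults mirror the design of
#' the emulated cohort: 739 matched male pairs, 865 metabolite features
#' distributed over 19 plates, a 30.0% / 18.7% case/control family-history
#' rate, and a polygenic score with a case-control AUC of 0.58.
#'
#' @param n_pairs Number of 1:1 matched case-control pairs (>= 2).
#' @param n_features Number of metabolite features.
#' @param n_plates Number of 96-well plates (batches).
#' @param qc_per_plate Repeated QC injections per plate *of each type*
#'   (external control and plate pool).
#' @param drift_amplitude Relative amplitude of the smooth multiplicative
#'   injection-order drift, as a fraction of the undrifted intensity
#'   (`g(order) = 1 + amplitude * sin(pi * order / orders_per_plate)`).
#' @param batch_sd Log-scale standard deviation of the per-plate intensity
#'   offset.
#' @param analytical_cv Log-scale standard deviation of injection-to-injection
#'   (analytical) noise; this is the only noise source for QC rows.
#' @param biological_sd_range Range for the per-feature biological log-scale
#'   standard deviation, drawn uniformly.
#' @param signal_features `NULL` or a data frame with columns `feature_id`,
#'   `mode` (`"continuous"` or `"binary"`), `true_or` (> 0) and optionally
#'   `presence_target`. Continuous effects are planted as an equal-variance
#'   Gaussian location shift of `log(true_or)` standard deviations in cases,
#'   which induces a logistic coefficient of exactly `log(true_or)` for the
#'   standardized feature. Binary effects are planted on the presence odds.
#' @param presence_targets `NULL` (targets drawn to match the emulated
#'   452-continuous / 413-binary stratum mix, with a small detection-failure
#'   tail below 25%) or a numeric vector of per-feature target detection
#'   fractions in (0, 1].
#' @param prs_auc Target rank AUC of the polygenic score for case status,
#'   planted via a binormal shift `delta = sqrt(2) * qnorm(prs_auc)`.
#' @param fh_rate_case,fh_rate_control Family-history probabilities.
#' @param seed Integer seed; together with the config it fully determines all
#'   generator output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_pairs = 739L,
                       n_features = 865L,
                       n_plates = 19L,
                       qc_per_plate = 6L,
                       drift_amplitude = 0.2,
                       batch_sd = 0.10,
                       analytical_cv = 0.05,
                       biological_sd_range = c(0.35, 0.65),
                       signal_features = NULL,
                       presence_targets = NULL,
                       prs_auc = 0.58,
                       fh_rate_case = 0.300,
                       fh_rate_control = 0.187,
                       seed = 1L) {
  if (n_pairs < 2) config_error("n_pairs must be >= 2")
  for (r in c(fh_rate_case, fh_rate_control))
    if (!is.finite(r) || r <= 0 || r >= 1)
      config_error("family-history rates must lie in (0, 1)")
  if (prs_auc <= 0 || prs_auc >= 1) config_error("prs_auc must lie in (0, 1)")
  if (drift_amplitude < 0) config_error("drift_amplitude must be >= 0")
  if (batch_sd < 0 || analytical_cv < 0) config_error("noise SDs must be >= 0")
  if (!is.null(presence_targets)) {
    if (length(presence_targets) != n_features)
      config_error("presence_targets must have one entry per feature")
    if (any(presence_targets <= 0 | presence_targets > 1))
      config_error("presence targets must lie in (0, 1]")
  }
  if (!is.null(signal_features)) {
    signal_features <- as.data.frame(signal_features)
    need <- c("feature_id", "mode", "true_or")
    if (!all(need %in% names(signal_features)))
      config_error("signal_features needs columns: %s", paste(need, collapse = ", "))
    if (any(signal_features$true_or <= 0)) config_error("true_or must be > 0")
    bad <- setdiff(signal_features$mode, c("continuous", "binary"))
    if (length(bad)) config_error("unknown signal mode(s): %s", paste(bad, collapse = ", "))
    if (anyDuplicated(signal_features$feature_id))
      config_error("each signal feature may appear only once")
  }
  structure(list(
    n_pairs = as.integer(n_pairs), n_features = as.integer(n_features),
    n_plates = as.integer(n_plates), qc_per_plate = as.integer(qc_per_plate),
    drift_amplitude = drift_amplitude, batch_sd = batch_sd,
    analytical_cv = analytical_cv, biological_sd_range = biological_sd_range,
    signal_features = signal_features, presence_targets = presence_targets,
    prs_auc = prs_auc, fh_rate_case = fh_rate_case,
    fh_rate_control = fh_rate_control, seed = as.integer(seed)
  ), class = "sim_config")
}

season_of_date <- function(date) {
  m <- as.integer(format(date, "%m"))
  c("winter", "winter", "spring", "spring", "spring", "summer",
    "summer", "summer", "autumn", "autumn", "autumn", "winter")[m]
}

rnorm_clamped <- function(n, mean, sd, lo, hi) pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))

#' Generate a matched neonatal case-control cohort
#'
#' Produces `2 * n_pairs` subject records in 1:1 matched pairs. The case is
#' generated first; the matched control's birth date, gestational age and age
#' at sampling are drawn within the matching calipers (birth date +/- 14 days,
#' gestational age +/- 4 days, age at sampling +/- 1 day). Family history is
#' Bernoulli with group-specific rates; the polygenic score is unit-normal in
#' controls and shifted by `sqrt(2) * qnorm(prs_auc)` in cases (binormal model,
#' so the population AUC is exactly `prs_auc`); six genetic principal
#' components are independent unit normals. Cases carry an age at diagnosis
#' (years, truncated normal with mean 6, SD 2).
#'
#' @param config A [sim_config].
#' @return A list with `samples` (data frame of subject records, cases and
#'   controls interleaved by pair) and `truth` (ground-truth record for
#'   recovery tests; see [generate_feature_matrix()]).
#' @export
generate_neonatal_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, 1L))
  n <- config$n_pairs

  case_year <- sample(2003:2008, n, replace = TRUE)
  case_date <- as.Date(sprintf("%d-01-01", case_year)) + sample(0:364, n, replace = TRUE)
  case_ga <- rnorm_clamped(n, 40.0, 1.25, 34, 42)
  case_age <- rnorm_clamped(n, 5.8, 1.15, 3, 8)

  ctrl_date <- case_date + sample(-14:14, n, replace = TRUE)
  ctrl_ga <- pmin(42, pmax(34, case_ga + stats::runif(n, -4 / 7, 4 / 7)))
  ctrl_age <- pmin(8, pmax(3, case_age + stats::runif(n, -1, 1)))

  delta <- sqrt(2) * stats::qnorm(config$prs_auc)
  pair_id <- sprintf("P%04d", seq_len(n))

  build <- function(group, date, ga, age, fh_rate, prs_shift) {
    k <- length(date)
    df <- data.frame(
      sample_id = sprintf("%s%04d", ifelse(group == "case", "A", "C"), seq_len(k)),
      pair_id = pair_id, group = group,
      birth_date = as.character(date),
      birth_year = as.integer(format(date, "%Y")),
      season = season_of_date(date),
      gestational_age = ga, age_at_sampling = age,
      family_history = stats::rbinom(k, 1, fh_rate),
      prs = stats::rnorm(k, prs_shift, 1),
      stringsAsFactors = FALSE
    )
    pcs <- matrix(stats::rnorm(6 * k), k, 6, dimnames = list(NULL, paste0("pc", 1:6)))
    cbind(df, pcs)
  }
  cases <- build("case", case_date, case_ga, case_age, config$fh_rate_case, delta)
  ctrls <- build("control", ctrl_date, ctrl_ga, ctrl_age, config$fh_rate_control, 0)
  cases$age_at_diagnosis <- rnorm_clamped(n, 6.0, 2.0, 1, 15)
  ctrls$age_at_diagnosis <- NA_real_

  samples <- rbind(cases, ctrls)
  samples <- samples[order(samples$pair_id, samples$group), ]
  rownames(samples) <- NULL

  truth <- build_feature_truth(config)
  list(samples = samples, truth = truth)
}

# Draw per-feature base parameters, presence targets and planted effects.
# Drawing happens under the cohort stage seed, so cohort + truth are one unit.
build_feature_truth <- function(config) {
  p <- config$n_features
  fid <- sprintf("F%04d", seq_len(p))
  mu <- stats::runif(p, log(1e4), log(1e6))
  sigma <- stats::runif(p, config$biological_sd_range[1], config$biological_sd_range[2])

  if (is.null(config$presence_targets)) {
    # Mixture matching the emulated stratum mix: a small tail of features that
    # fail the 25% detection rule, the rest split ~452:413 continuous:binary.
    u <- stats::runif(p)
    p_drop <- 0.08
    p_cont <- (1 - p_drop) * 452 / 865
    target <- ifelse(u < p_drop, stats::runif(p, 0.05, 0.24),
              ifelse(u < p_drop + p_cont, stats::runif(p, 0.76, 1.00),
                     stats::runif(p, 0.26, 0.74)))
  } else target <- config$presence_targets

  mode <- rep("null", p)
  true_or <- rep(1, p)
  if (!is.null(config$signal_features)) {
    sf <- config$signal_features
    idx <- match(sf$feature_id, fid)
    if (any(is.na(idx)))
      config_error("signal feature id(s) not among generated features: %s",
                   paste(sf$feature_id[is.na(idx)], collapse = ", "))
    mode[idx] <- sf$mode
    true_or[idx] <- sf$true_or
    if ("presence_target" %in% names(sf) && any(!is.na(sf$presence_target))) {
      keep <- !is.na(sf$presence_target)
      target[idx[keep]] <- sf$presence_target[keep]
    } else {
      # ensure planted continuous features survive triage; planted binary
      # effects default to the mid-presence stratum
      target[idx][sf$mode == "continuous"] <- 1.0
      target[idx][sf$mode == "binary"] <- 0.5
    }
  }
  list(
    features = data.frame(
      feature_id = fid, mode = mode, true_or = true_or,
      true_log_or = log(true_or), presence_target = target,
      mu_log = mu, sigma_log = sigma, stringsAsFactors = FALSE
    ),
    drift = list(shape = "half_sine", amplitude = config$drift_amplitude),
    snps = NULL
  )
}

# Presence probabilities for cases/controls with presence odds ratio `or`
# and average presence `target`.
presence_rates <- function(target, or) {
  if (abs(or - 1) < 1e-12) return(c(control = target, case = target))
  f <- function(p0) (p0 + or * p0 / (1 + (or - 1) * p0)) / 2 - target
  lo <- 1e-9; hi <- min(1 - 1e-9, 2 * target)
  p0 <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  p1 <- or * p0 / (1 + (or - 1) * p0)
  c(control = p0, case = p1)
}

#' Generate the feature-intensity matrix for a simulated cohort
#'
#' Intensities are log-normal: per-feature base level plus biological noise,
#' a per-plate log offset (batch effect), smooth multiplicative injection-order
#' drift shared by all rows of a plate, and analytical noise. Case shifts
#' implement the planted effects described in [sim_config()]. Each feature is
#' then left-censored at the empirical intensity quantile that yields its
#' target detection fraction (group-specific quantiles for planted binary
#' effects, so that the presence odds ratio equals `true_or`). QC rows --
#' `qc_per_plate` external-control and `qc_per_plate` plate-pool injections per
#' plate, spaced evenly through the injection sequence -- carry the same drift
#' and batch structure but only analytical noise.
#'
#' @param samples Subject records from [generate_neonatal_cohort()].
#' @param truth Truth record from [generate_neonatal_cohort()].
#' @param config The same [sim_config].
#' @return A [feature_table] with analytical and QC rows.
#' @export
generate_feature_matrix <- function(samples, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, 2L))
  ft <- truth$features
  n_s <- nrow(samples)
  p <- nrow(ft)
  is_case <- samples$group == "case"

  plate_of <- sample(rep(seq_len(config$n_plates), length.out = n_s))
  plate_lab <- sprintf("plate%02d", plate_of)
  batch <- stats::rnorm(config$n_plates, 0, config$batch_sd)

  # injection layout: QC injections evenly spaced among the analytical ones
  n_qc <- 2L * config$qc_per_plate
  order_vec <- integer(n_s)
  qc_rows <- list()
  ec_offset <- stats::rnorm(p, 0, 0.3)  # external control is adult blood
  A <- config$drift_amplitude
  for (pl in seq_len(config$n_plates)) {
    on_plate <- which(plate_of == pl)
    slots <- length(on_plate) + n_qc
    qc_pos <- unique(round(seq(1, slots, length.out = n_qc)))
    while (length(qc_pos) < n_qc)           # tiny plates: fill adjacent slots
      qc_pos <- unique(c(qc_pos, setdiff(seq_len(slots), qc_pos)[1]))
    qc_pos <- sort(qc_pos[seq_len(n_qc)])
    order_vec[on_plate] <- setdiff(seq_len(slots), qc_pos)[
      sample.int(length(on_plate))]
    qc_type <- rep(c("external_control", "plate_pool"), length.out = n_qc)
    qc_rows[[pl]] <- data.frame(
      plate = sprintf("plate%02d", pl), order = qc_pos, type = qc_type,
      slots = slots, stringsAsFactors = FALSE
    )
  }
  qc_df <- do.call(rbind, qc_rows)
  qc_df$sample_id <- sprintf("QC_%s_%s_%02d",
                             ifelse(qc_df$type == "external_control", "EC", "PP"),
                             qc_df$plate, stats::ave(qc_df$order, qc_df$plate,
                                                     FUN = seq_along))
  slots_per_plate <- vapply(split(qc_df$slots, qc_df$plate), `[`, numeric(1), 1)

  drift_factor <- function(order, plate_idx) {
    1 + A * sin(pi * order / slots_per_plate[plate_idx])
  }

  n_q <- nrow(qc_df)
  n_tot <- n_s + n_q
  all_plate <- c(plate_lab, qc_df$plate)
  all_order <- c(order_vec, qc_df$order)
  all_flag <- c(rep("analytical", n_s), qc_df$type)
  all_ids <- c(samples$sample_id, qc_df$sample_id)
  plate_idx <- as.integer(sub("plate", "", all_plate))

  log_drift <- log(drift_factor(all_order, plate_idx))
  log_batch <- batch[plate_idx]

  sd_tot <- sqrt(ft$sigma_log^2 + config$analytical_cv^2)
  shift <- ifelse(ft$mode == "continuous", ft$true_log_or * sd_tot, 0)

  mat <- matrix(NA_real_, n_tot, p, dimnames = list(all_ids, ft$feature_id))
  analytical <- all_flag == "analytical"
  is_ec <- all_flag == "external_control"
  case_row <- c(is_case, rep(FALSE, n_q))

  for (f in seq_len(p)) {
    base <- rep(ft$mu_log[f], n_tot)
    base[is_ec] <- base[is_ec] + ec_offset[f]
    bio <- ifelse(analytical, stats::rnorm(n_tot, 0, ft$sigma_log[f]), 0)
    eps <- stats::rnorm(n_tot, 0, config$analytical_cv)
    lg <- base + bio + eps + log_batch + log_drift + shift[f] * case_row
    intens <- exp(lg)

    tgt <- ft$presence_target[f]
    if (ft$mode[f] == "binary" && abs(ft$true_or[f] - 1) > 1e-12) {
      pr <- presence_rates(tgt, ft$true_or[f])
      vals_case <- intens[analytical & case_row]
      vals_ctrl <- intens[analytical & !case_row]
      thr_case <- stats::quantile(vals_case, 1 - pr["case"], names = FALSE)
      thr_ctrl <- stats::quantile(vals_ctrl, 1 - pr["control"], names = FALSE)
      thr <- ifelse(case_row, thr_case, thr_ctrl)
      thr[!analytical] <- stats::quantile(intens[analytical], 1 - tgt, names = FALSE)
      intens[intens < thr] <- NA_real_
    } else if (tgt < 1) {
      thr <- stats::quantile(intens[analytical], 1 - tgt, names = FALSE)
      intens[intens < thr] <- NA_real_
    }
    mat[, f] <- intens
  }

  feature_table(mat, plate = all_plate, injection_order = all_order,
                qc_flag = all_flag)
}
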