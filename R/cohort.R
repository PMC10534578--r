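#' Configuration for the synthetic hospital cohort
#'
#' The generator emulates the validation study's observable structure with
#' a latent-trait, cumulative-threshold model. Each patient has a latent
#' physical-dependence trait D (the trait the Barthel Index responds to)
#' and a sensory-behaviour factor correlated `factor_cor` with it. Each
#' ASGO variable's ordinal level is drawn by cutting a standardized item
#' latent — a mix of the two factors given by `factor_loadings` plus
#' item-specific noise — at equally spaced thresholds; the threshold origin
#' is solved so the expected admission raw score matches
#' `mean_score_admission`. Barthel items are drawn the same way from
#' -D plus instrument and item noise. Discharge latents are the admission
#' latents shifted by `improvement_shift` (positive = healthier) plus an
#' innovation, and the latent instrument correlations at each timepoint are
#' calibrated by pilot simulation so the observed ASGO-BI Spearman
#' correlations hit `target_rho_admission` / `target_rho_discharge`.
#'
#' @param n_patients Cohort size (>= 10). Default 842.
#' @param target_rho_admission,target_rho_discharge Target Spearman
#'   correlations between ASGO raw score and Barthel total, in (-1, 0).
#'   Defaults -0.5916 and -0.7988.
#' @param improvement_shift Mean drop in the latent dependence trait from
#'   admission to discharge (positive values mean patients improve and the
#'   mean Barthel total rises). Default 0.35.
#' @param innovation_sd SD of the patient-level innovation added to the
#'   discharge trait. Default 0.3.
#' @param factor_loadings 10 x 2 matrix of planted loadings (physical,
#'   sensory) in instrument variable order. Default: 0.75 on the own block
#'   (physical: mental status, movement, elimination, feeding, sleep/wake,
#'   self-care; sensory: circulation, breathing, sensory system, mood) and
#'   0.2 on the other.
#' @param factor_cor Correlation between the two latent factors. Default 0.4.
#' @param noise_sd SD of the item-level noise on each Barthel item latent.
#'   Default 0.6.
#' @param p_multi Probability that a multi-select ASGO variable records a
#'   second modality. Default 0.1.
#' @param threshold_spacing Spacing of the equally spaced ordinal
#'   thresholds on the latent scale. Default 0.55.
#' @param mean_score_admission,mean_barthel_admission Expected admission
#'   means the thresholds are solved for. Defaults 27.1 and 39.2.
#' @param pairing_loss_rate Fraction of patients whose discharge record is
#'   dropped at random (missing paired assessments). Default 0.
#' @param demographics List of decorative marginals: `age_mean`, `age_sd`,
#'   `male_fraction`, `los_mean`, `los_sd`, `admission_reasons` (named
#'   probability vector).
#' @param seed Default RNG seed used by [generate_cohort()].
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 842L,
                          target_rho_admission = -0.5916,
                          target_rho_discharge = -0.7988,
                          improvement_shift = 0.35,
                          innovation_sd = 0.3,
                          factor_loadings = NULL,
                          factor_cor = 0.4,
                          noise_sd = 0.6,
                          p_multi = 0.1,
                          threshold_spacing = 0.55,
                          mean_score_admission = 27.1,
                          mean_barthel_admission = 39.2,
                          pairing_loss_rate = 0,
                          demographics = NULL,
                          seed = 20230842L) {
  if (n_patients < 10L) stop("n_patients must be at least 10")
  for (r in c(target_rho_admission, target_rho_discharge))
    if (!(r > -1 && r < 0))
      stop("target correlations must lie in the open interval (-1, 0)")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (is.null(factor_loadings)) {
    factor_loadings <- matrix(0.2, 10, 2)
    factor_loadings[.physical_block, 1] <- 0.75
    factor_loadings[-.physical_block, 2] <- 0.75
  }
  factor_loadings <- as.matrix(factor_loadings)
  stopifnot(nrow(factor_loadings) == 10L, ncol(factor_loadings) == 2L)
  com <- factor_loadings[, 1]^2 + factor_loadings[, 2]^2 +
    2 * factor_cor * factor_loadings[, 1] * factor_loadings[, 2]
  if (any(com > 1))
    stop("planted loading rows imply communality > 1; shrink the loadings")
  if (is.null(demographics)) {
    demographics <- list(
      age_mean = 76.4, age_sd = 12.3, male_fraction = 0.55,
      los_mean = 20.1, los_sd = 13.4,
      admission_reasons = c(cardiovascular = 0.314, respiratory = 0.155,
                            trauma = 0.122, gastrointestinal = 0.106,
                            cerebrovascular = 0.078, cancer = 0.073,
                            endocrine = 0.053, miscellaneous = 0.099))
  }
  structure(list(
    n_patients = as.integer(n_patients),
    target_rho_admission = target_rho_admission,
    target_rho_discharge = target_rho_discharge,
    improvement_shift = improvement_shift,
    innovation_sd = innovation_sd,
    factor_loadings = factor_loadings,
    factor_cor = factor_cor,
    noise_sd = noise_sd,
    p_multi = p_multi,
    threshold_spacing = threshold_spacing,
    mean_score_admission = mean_score_admission,
    mean_barthel_admission = mean_barthel_admission,
    pairing_loss_rate = pairing_loss_rate,
    demographics = demographics,
    seed = as.integer(seed),
    latent_cor = NULL), class = "cohort_config")
}

# instrument-order indices of the physical-functionality block
.physical_block <- c(1L, 2L, 5L, 6L, 7L, 9L)

# per-variable level multipliers (movement/ambulation skips level 6)
.level_multipliers <- function(instrument = asgo_instrument()) {
  lapply(instrument$variables, function(v) v$modalities$level)
}

# threshold origin such that the expected admission raw score matches the
# configured mean (closed form through the normal CDF; the small bias of
# the multi-select bump rule is ignored)
.solve_asgo_tau1 <- function(config, instrument = asgo_instrument()) {
  w <- vapply(instrument$variables, `[[`, numeric(1), "weight")
  mult <- .level_multipliers(instrument)
  multi <- vapply(instrument$variables, `[[`, logical(1), "multi_select")
  expected <- function(tau1) {
    single <- sum(vapply(seq_along(w), function(j) {
      k <- length(mult[[j]])
      tau <- tau1 + config$threshold_spacing * (0:(k - 2))
      pr <- diff(c(0, stats::pnorm(tau), 1))
      w[j] * sum(pr * mult[[j]])
    }, numeric(1)))
    extra <- config$p_multi *
      sum(w[multi] * vapply(mult[multi], mean, numeric(1)))
    single + extra
  }
  stats::uniroot(function(t) expected(t) - config$mean_score_admission,
                 interval = c(-3, 3), tol = 1e-8)$root
}

# threshold shift such that the expected admission Barthel total matches
.solve_barthel_shift <- function(config) {
  maxima <- vapply(barthel_items(), max, numeric(1))
  expected <- function(shift) {
    sum(vapply(maxima, function(mx) {
      m <- mx / 5
      tau <- shift + 0.8 * (0:(m - 1)) - 0.4 * (m - 1)
      5 * sum(1 - stats::pnorm(tau))
    }, numeric(1)))
  }
  stats::uniroot(function(s) expected(s) - config$mean_barthel_admission,
                 interval = c(-4, 4), tol = 1e-8)$root
}

# one timepoint's worth of assessments given the trait vector D
.simulate_timepoint <- function(D, latent_cor, config, instrument,
                                tau1, bshift) {
  n <- length(D)
  vars <- instrument$variables
  mult <- .level_multipliers(instrument)
  L <- config$factor_loadings
  rhoF <- config$factor_cor
  F1 <- D
  F2 <- rhoF * D + sqrt(1 - rhoF^2) * stats::rnorm(n)
  levels <- matrix(1L, n, 10)
  extras <- matrix(NA_integer_, n, 10)
  for (j in seq_len(10L)) {
    com <- L[j, 1]^2 + L[j, 2]^2 + 2 * rhoF * L[j, 1] * L[j, 2]
    y <- L[j, 1] * F1 + L[j, 2] * F2 +
      sqrt(max(1 - com, 0.05)) * stats::rnorm(n)
    y <- y / sqrt(com + max(1 - com, 0.05))
    k <- length(mult[[j]])
    tau <- tau1 + config$threshold_spacing * (0:(k - 2))
    levels[, j] <- mult[[j]][1L + colSums(outer(tau, y, "<"))]
    if (vars[[j]]$multi_select) {
      add <- stats::runif(n) < config$p_multi
      pick <- sample.int(k, n, replace = TRUE)
      lvl_idx <- match(levels[, j], mult[[j]])
      pick <- ifelse(pick == lvl_idx, (pick %% k) + 1L, pick)
      extras[, j] <- ifelse(add, mult[[j]][pick], NA_integer_)
    }
  }
  B <- latent_cor * D + sqrt(1 - latent_cor^2) * stats::rnorm(n)
  items <- barthel_items()
  bi <- matrix(0L, n, 10, dimnames = list(NULL, names(items)))
  for (k in seq_along(items)) {
    z <- (B + config$noise_sd * stats::rnorm(n)) /
      sqrt(1 + config$noise_sd^2)
    m <- max(items[[k]]) / 5
    tau <- bshift + 0.8 * (0:(m - 1)) - 0.4 * (m - 1)
    bi[, k] <- 5L * colSums(outer(tau, -z, "<"))
  }
  list(levels = levels, extras = extras, bi = bi)
}

# raw ASGO score implied by a simulated timepoint (sum combination rule)
.timepoint_raw_score <- function(tp, instrument) {
  w <- vapply(instrument$variables, `[[`, numeric(1), "weight")
  score <- tp$levels %*% w
  extra <- ifelse(is.na(tp$extras), 0, tp$extras) %*% w
  as.numeric(score + extra)
}

#' Calibrate the latent instrument correlations of a cohort configuration
#'
#' Runs a deterministic pilot simulation (internal fixed seed, `pilot_n`
#' patients) over a grid of latent correlation values, measures the
#' resulting ASGO-BI Spearman correlation at each timepoint, and inverts
#' the monotone relationship to find the latent correlations that deliver
#' the configured targets. Stops with the feasible bound when a target is
#' more extreme than the model can reach.
#'
#' @param config A `cohort_config`.
#' @param pilot_n Pilot sample size per grid point. Default 4000.
#' @return The config with `latent_cor` filled in.
#' @export
calibrate_cohort <- function(config, pilot_n = 4000L) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(config$latent_cor)) return(config)
  instrument <- asgo_instrument()
  tau1 <- .solve_asgo_tau1(config, instrument)
  bshift <- .solve_barthel_shift(config)
  grid <- c(0.40, 0.55, 0.70, 0.80, 0.88, 0.93, 0.96, 0.98, 0.995)
  pilot <- function(timepoint) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(271828L)
    D0 <- stats::rnorm(pilot_n)
    D <- if (timepoint == "admission") D0
         else D0 - config$improvement_shift +
           config$innovation_sd * stats::rnorm(pilot_n)
    vapply(grid, function(cc) {
      tp <- .simulate_timepoint(D, cc, config, instrument, tau1, bshift)
      stats::cor(.timepoint_raw_score(tp, instrument), rowSums(tp$bi),
                 method = "spearman")
    }, numeric(1))
  }
  invert <- function(rhos, target, label) {
    if (target < min(rhos))
      stop("target ", label, " correlation ", target,
           " is infeasible; the model reaches at most ",
           round(min(rhos), 3), " under this configuration")
    f <- stats::splinefun(grid, rhos, method = "hyman")
    stats::uniroot(function(cc) f(cc) - target,
                   interval = range(grid), tol = 1e-6)$root
  }
  config$latent_cor <- list(
    admission = invert(pilot("admission"), config$target_rho_admission,
                       "admission"),
    discharge = invert(pilot("discharge"), config$target_rho_discharge,
                       "discharge"))
  config$.thresholds <- list(tau1 = tau1, bshift = bshift)
  config
}

#' Generate a synthetic paired admission/discharge cohort
#'
#' Draws `n_patients` patients from the latent-trait model described in
#' [cohort_config()] and returns admission and discharge ASGO and Barthel
#' assessments per patient, along with the latent trait values for
#' ground-truth checks. Output is deterministic given the configuration and
#' seed.
#'
#' @param config A `cohort_config` (calibrated automatically if needed).
#' @param seed RNG seed; defaults to `config$seed`.
#' @return Object of class `asgo_cohort`: list with `records` (data frame,
#'   one row per patient-timepoint in the cohort CSV schema), `latents`
#'   (data frame of per-patient trait values), `config` and `seed`.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_config(n_patients = 50))
#' nrow(cohort$records)   # 100: admission + discharge rows
#' }
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  config <- calibrate_cohort(config)
  instrument <- asgo_instrument()
  tau1 <- config$.thresholds$tau1
  bshift <- config$.thresholds$bshift
  n <- config$n_patients
  set.seed(seed)
  dg <- config$demographics
  age <- round(pmin(pmax(stats::rnorm(n, dg$age_mean, dg$age_sd), 18), 105))
  gender <- ifelse(stats::runif(n) < dg$male_fraction, "male", "female")
  los <- round(pmax(stats::rnorm(n, dg$los_mean, dg$los_sd), 3), 1)
  reason <- sample(names(dg$admission_reasons), n, replace = TRUE,
                   prob = dg$admission_reasons)
  D_adm <- stats::rnorm(n)
  D_dis <- D_adm - config$improvement_shift +
    config$innovation_sd * stats::rnorm(n)
  adm <- .simulate_timepoint(D_adm, config$latent_cor$admission, config,
                             instrument, tau1, bshift)
  dis <- .simulate_timepoint(D_dis, config$latent_cor$discharge, config,
                             instrument, tau1, bshift)
  keep_discharge <- stats::runif(n) >= config$pairing_loss_rate
  ids <- sprintf("P%04d", seq_len(n))
  row_block <- function(tp, label) {
    sel <- vapply(seq_len(n), function(i) {
      vapply(seq_len(10L), function(j) {
        lv <- tp$levels[i, j]
        ex <- tp$extras[i, j]
        if (!is.na(ex)) paste(sort(c(lv, ex)), collapse = "|")
        else as.character(lv)
      }, character(1))
    }, character(10L))
    df <- data.frame(patient_id = ids, timepoint = label,
                     age = age, gender = gender, length_of_stay = los,
                     admission_reason = reason,
                     t(sel), tp$bi, check.names = FALSE)
    names(df)[7:16] <- paste0("asgo_", asgo_variable_names(instrument))
    names(df)[17:26] <- paste0("bi_", names(barthel_items()))
    df
  }
  records <- rbind(row_block(adm, "admission"),
                   row_block(dis, "discharge")[keep_discharge, ])
  records <- records[order(records$patient_id, records$timepoint), ]
  rownames(records) <- NULL
  structure(list(records = records,
                 latents = data.frame(patient_id = ids,
                                      d_admission = D_adm,
                                      d_discharge = D_dis),
                 config = config, seed = seed),
            class = "asgo_cohort")
}

#' @export
print.asgo_cohort <- function(x, ...) {
  cat("synthetic ASGO cohort:", x$config$n_patients, "patients,",
      nrow(x$records), "assessment rows (seed ", x$seed, ")\n")
  invisible(x)
}

#' Write a cohort to the pipeline's CSV schema
#'
#' @param cohort An `asgo_cohort` (or any data frame in the schema).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- if (inherits(cohort, "asgo_cohort")) cohort$records else cohort
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Check recovery of the planted two-factor structure
#'
#' Scores the cohort's assessments at one timepoint, runs the
#' principal-component factor analysis with varimax rotation on the
#' ten-variable item matrix, and compares each variable's dominant rotated
#' factor with its planted block (physical vs sensory), using whichever
#' factor-to-block mapping agrees best.
#'
#' @param cohort An `asgo_cohort` carrying latent ground truth.
#' @param timepoint Which assessments to analyse. Default `"admission"`.
#' @return List with `per_variable` (data frame: variable, planted block,
#'   dominant factor, match), `recovery_fraction`, `n_retained` and
#'   `indeterminate` (TRUE when the planted loadings do not distinguish the
#'   blocks).
#' @export
planted_structure_check <- function(cohort, timepoint = "admission") {
  stopifnot(inherits(cohort, "asgo_cohort"))
  if (is.null(cohort$latents))
    stop("cohort lacks latent ground truth; regenerate with generate_cohort()")
  L <- cohort$config$factor_loadings
  indeterminate <- all(abs(L[, 1] - L[, 2]) < 1e-12)
  df <- cohort$records[cohort$records$timepoint == timepoint, ]
  X <- asgo_item_matrix(df)
  fs <- pca_efa(X)
  k <- max(fs$n_retained, 2L)
  rot <- varimax_rotate(fs$loadings[, seq_len(k), drop = FALSE])$loadings
  dominant <- apply(abs(rot[, 1:2]), 1L, which.max)
  planted <- ifelse(seq_len(10L) %in% .physical_block, 1L, 2L)
  acc <- c(mean(dominant == planted), mean(dominant == 3L - planted))
  map_flip <- which.max(acc) == 2L
  matched <- if (map_flip) dominant == 3L - planted else dominant == planted
  list(per_variable = data.frame(
         variable = colnames(X),
         planted_block = c("physical", "sensory")[planted],
         dominant_factor = dominant,
         match = matched),
       recovery_fraction = max(acc),
       n_retained = fs$n_retained,
       indeterminate = indeterminate)
}
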