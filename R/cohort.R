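# Synthetic cohort generation -------------------------------------------
#
# The generator emulates the statistical shape of a single-institution
# oropharyngeal-cancer cohort: ~500 patients, ~300 retained continuous
# radiomic-style features organised in correlated families, 2-4 latent risk
# groups expressed both in the informative feature columns and in
# group-specific exponential hazards, ~20% observed events, and an 80/20
# train/test split. The latent groups are broad phenotypes: by default a
# third of the columns carry the group signal, mirroring how size,
# intensity and texture families jointly track tumor phenotype.

# Training-arm category frequencies used by sample_clinical_categories().
.clinical_freqs <- list(
  sex = c(Male = 0.878, Female = 0.122),
  hpv_status = c(Positive = 0.610, Negative = 0.093, Unknown = 0.297),
  smoking_status = c(Never = 0.434, Former = 0.358, Current = 0.208),
  t_raw = c(T1 = 0.3135, T2 = 0.3135, T3 = 0.1865, T4 = 0.1865),
  n_raw = c(N0 = 0.2555, N1 = 0.2555, N2 = 0.2445, N3 = 0.2445),
  therapeutic_combination = c(CC = 0.516, `IC+CC` = 0.269,
                              `IC+RT` = 0.100, RT = 0.115),
  ajcc_stage = c(I = 0.346, II = 0.186, III = 0.129, IV = 0.339)
)

#' Configuration for the synthetic cohort generator
#'
#' Builds a validated configuration object for [generate_cohort()]. Defaults
#' describe the cohort structure the clustering method targets: 500 patients,
#' 300 features in equicorrelated families of 10, two latent risk groups
#' separated by 2 SD in the informative columns and by a hazard ratio of 3,
#' exponential survival and censoring calibrated so that roughly 20% of
#' patients experience the event during follow-up, and an 80/20 split.
#'
#' @param n_patients number of patients.
#' @param n_features number of continuous feature columns.
#' @param n_latent_groups number of latent risk groups (2, 3 or 4).
#' @param feature_shift mean separation, in SD units, added to informative
#'   columns per latent-group step (group `g` gets `(g-1) * feature_shift`).
#' @param n_informative number of leading columns carrying the group signal.
#' @param block_correlation equicorrelation within each block of 10 columns,
#'   in `[0, 1)`; mimics redundant radiomic feature families.
#' @param baseline_hazard exponential event hazard per month for group 1.
#' @param group_hazard_ratios hazard ratios per group; first must be 1.
#' @param censor_rate exponential censoring hazard per month.
#' @param admin_censor_months administrative censoring horizon in months.
#' @param train_fraction fraction of patients assigned to the training split.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 500,
                          n_features = 300,
                          n_latent_groups = 2,
                          feature_shift = 2,
                          n_informative = 100,
                          block_correlation = 0.8,
                          baseline_hazard = 0.002,
                          group_hazard_ratios = c(1, 3),
                          censor_rate = 0.012,
                          admin_censor_months = 120,
                          train_fraction = 0.8,
                          seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_features = as.integer(n_features),
              n_latent_groups = as.integer(n_latent_groups),
              feature_shift = feature_shift,
              n_informative = as.integer(n_informative),
              block_correlation = block_correlation,
              baseline_hazard = baseline_hazard,
              group_hazard_ratios = as.numeric(group_hazard_ratios),
              censor_rate = censor_rate,
              admin_censor_months = admin_censor_months,
              train_fraction = train_fraction,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 1, cfg$n_features >= 1)
  if (!cfg$n_latent_groups %in% 2:4)
    stop("n_latent_groups must be 2, 3 or 4")
  if (cfg$feature_shift < 0) stop("feature_shift must be >= 0")
  if (cfg$n_informative > cfg$n_features)
    stop("n_informative cannot exceed n_features")
  if (cfg$block_correlation < 0 || cfg$block_correlation >= 1)
    stop("block_correlation must lie in [0, 1)")
  if (cfg$baseline_hazard <= 0 || cfg$censor_rate <= 0 ||
      cfg$admin_censor_months <= 0)
    stop("hazard, censoring rate and administrative horizon must be positive")
  if (length(cfg$group_hazard_ratios) != cfg$n_latent_groups)
    stop("group_hazard_ratios must have one entry per latent group")
  if (abs(cfg$group_hazard_ratios[1] - 1) > 1e-12)
    stop("first hazard ratio must be 1 (reference group)")
  if (any(cfg$group_hazard_ratios <= 0))
    stop("hazard ratios must be positive")
  if (cfg$train_fraction <= 0 || cfg$train_fraction >= 1)
    stop("train_fraction must lie in (0, 1)")
  invisible(cfg)
}

# Radiomic-style column names; blocks of 10 share a family stem. The two
# conventional anchor features (volume and global mean intensity) are always
# present when the matrix is wide enough to hold them.
radiomic_feature_names <- function(p) {
  stems <- c("ShapeVolume", "IntensityDirectGlobalMean",
             "GrayLevelCooccurenceMatrix25Contrast",
             "GrayLevelRunLengthMatrixShortRunEmphasis",
             "IntensityDirectKurtosis", "GrayLevelCooccurenceMatrix25ClusterShade",
             "IntensityDirectLocalRangeMax", "ShapeCompactness",
             "GrayLevelCooccurenceMatrix25Energy", "IntensityHistogramSkewness")
  block <- (seq_len(p) - 1L) %/% 10L
  within <- (seq_len(p) - 1L) %% 10L
  nm <- sprintf("F%d.%s.%02d", block + 1L,
                stems[(block %% length(stems)) + 1L], within + 1L)
  if (p >= 1) nm[1] <- "F25.ShapeVolume"
  if (p >= 11) nm[11] <- "F29.IntensityDirectGlobalMean"
  make.unique(nm)
}

#' Sample clinical and demographic covariates
#'
#' Draws a table of clinical covariates with the category frequencies of the
#' training arm of the cohort the method was developed for: predominantly
#' male (87.8%), 61% HPV positive, median age around 58 with inter-quartile
#' range (52.5, 65.8). T and N categories are drawn at the raw level
#' (T1..T4, N0..N3) so that [categorize_clinical()] can collapse them.
#' Covariates are sampled independently of each other and of any outcome.
#'
#' @param n number of rows to draw.
#' @param seed integer seed.
#' @return A data.frame with columns `sex`, `age`, `hpv_status`,
#'   `smoking_status`, `t_category` (raw), `n_category` (raw),
#'   `therapeutic_combination`, `ajcc_stage`.
#' @export
sample_clinical_categories <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  fq <- .clinical_freqs
  withr::with_seed(as.integer(seed), {
    draw <- function(tab) {
      p <- tab / sum(tab)
      factor(sample(names(tab), n, replace = TRUE, prob = p),
             levels = names(tab))
    }
    # Normal truncated to [25, 90]; location/scale matched to the target
    # median 58.2 and IQR (52.5, 65.8) -> sd ~ 13.3 / (2 * 0.6745).
    age <- rnorm(n, mean = 58.2, sd = 9.86)
    while (any(bad <- age < 25 | age > 90))
      age[bad] <- rnorm(sum(bad), mean = 58.2, sd = 9.86)
    data.frame(
      sex = draw(fq$sex),
      age = age,
      hpv_status = draw(fq$hpv_status),
      smoking_status = draw(fq$smoking_status),
      t_category = draw(fq$t_raw),
      n_category = draw(fq$n_raw),
      therapeutic_combination = draw(fq$therapeutic_combination),
      ajcc_stage = draw(fq$ajcc_stage),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a synthetic right-censored cohort
#'
#' Draws a full cohort from a [cohort_config()]: block-correlated Gaussian
#' features whose leading `n_informative` columns are mean-shifted by latent
#' group, exponential survival times with group-specific hazards, exponential
#' plus administrative censoring, clinical covariates drawn independently of
#' the latent group, and a random train/test split. The latent group is kept
#' on the object for evaluation only; accessors used by the fitting code
#' never expose it.
#'
#' @param config a [cohort_config()].
#' @return An object of class `cohort`: a list with `patient_ids`, `features`
#'   (named matrix), `clinical` (collapsed categories, see
#'   [categorize_clinical()]), `time_months`, `event`, `latent_group`,
#'   `split` and the generating `config`.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  n <- config$n_patients
  p <- config$n_features
  withr::with_seed(config$seed, {
    group <- sample.int(config$n_latent_groups, n, replace = TRUE)

    # Equicorrelated blocks of 10: x = sqrt(rho) * shared + sqrt(1-rho) * eps
    rho <- config$block_correlation
    n_blocks <- ceiling(p / 10)
    shared <- matrix(rnorm(n * n_blocks), n, n_blocks)
    eps <- matrix(rnorm(n * p), n, p)
    block_of <- (seq_len(p) - 1L) %/% 10L + 1L
    x <- sqrt(rho) * shared[, block_of, drop = FALSE] + sqrt(1 - rho) * eps
    if (config$n_informative > 0 && config$feature_shift > 0) {
      idx <- seq_len(config$n_informative)
      x[, idx] <- x[, idx] + (group - 1L) * config$feature_shift
    }
    colnames(x) <- radiomic_feature_names(p)

    hr <- config$group_hazard_ratios[group]
    t_event <- rexp(n, rate = config$baseline_hazard * hr)
    t_cens <- pmin(rexp(n, rate = config$censor_rate),
                   config$admin_censor_months)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)

    clin_seed <- (config$seed + 104729L) %% .Machine$integer.max
    clinical <- categorize_clinical(
      sample_clinical_categories(n, seed = clin_seed))

    ids <- sprintf("P%04d", seq_len(n))
    cohort <- structure(
      list(patient_ids = ids,
           features = `rownames<-`(x, ids),
           clinical = `rownames<-`(clinical, ids),
           time_months = time,
           event = event,
           latent_group = group,
           split = NULL,
           config = config),
      class = "cohort")
    split_seed <- (config$seed + 15485863L) %% .Machine$integer.max
    split_cohort(cohort, config$train_fraction, seed = split_seed)
  })
}

#' Assign a train/test split
#'
#' Randomly assigns each patient to the training or test split,
#' reproducibly for a given seed. The training size is
#' `round(n * train_fraction)`.
#'
#' @param cohort a `cohort`.
#' @param train_fraction fraction of patients in the training split.
#' @param seed integer seed.
#' @return The cohort with its `split` field set to `"train"`/`"test"`.
#' @export
split_cohort <- function(cohort, train_fraction, seed = 1L) {
  stopifnot(inherits(cohort, "cohort"))
  n <- length(cohort$patient_ids)
  if (n == 0) stop("cannot split an empty cohort")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie in (0, 1)")
  n_train <- max(1L, min(n - 1L, as.integer(round(n * train_fraction))))
  withr::with_seed(as.integer(seed), {
    idx <- sample.int(n, n_train)
  })
  split <- rep("test", n)
  split[idx] <- "train"
  cohort$split <- split
  cohort
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d patients x %d features; %d events (%.1f%%)\n",
              length(x$patient_ids), ncol(x$features), sum(x$event),
              100 * mean(x$event)))
  if (!is.null(x$split))
    cat(sprintf("  split: %d train / %d test\n",
                sum(x$split == "train"), sum(x$split == "test")))
  invisible(x)
}

#' Extract modelling data from a cohort
#'
#' Returns the pieces of a cohort that fitting code is allowed to see. The
#' latent group used by the generator is withheld unless
#' `include_latent = TRUE` (evaluation only).
#'
#' @param cohort a `cohort`.
#' @param split `"train"`, `"test"` or `"all"`.
#' @param include_latent expose the generator's latent group column.
#' @return A list with `features`, `clinical`, `time_months`, `event`,
#'   `patient_ids` (and `latent_group` if requested).
#' @export
cohort_data <- function(cohort, split = c("all", "train", "test"),
                        include_latent = FALSE) {
  split <- match.arg(split)
  keep <- if (split == "all") rep(TRUE, length(cohort$patient_ids))
          else cohort$split == split
  out <- list(patient_ids = cohort$patient_ids[keep],
              features = cohort$features[keep, , drop = FALSE],
              clinical = cohort$clinical[keep, , drop = FALSE],
              time_months = cohort$time_months[keep],
              event = cohort$event[keep])
  if (include_latent) out$latent_group <- cohort$latent_group[keep]
  out
}

#' Write a cohort to plain-text files
#'
#' Writes `features.csv`, `clinical.csv` and `outcomes.csv` (columns
#' `patient_id,time_months,event,split`) plus a `config.json` sidecar
#' recording the generator configuration and seed. The latent group is not
#' exported.
#'
#' @param cohort a `cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  feat <- data.frame(patient_id = cohort$patient_ids,
                     cohort$features, check.names = FALSE)
  write.csv(feat, file.path(dir, "features.csv"), row.names = FALSE)
  clin <- data.frame(patient_id = cohort$patient_ids,
                     cohort$clinical, check.names = FALSE)
  write.csv(clin, file.path(dir, "clinical.csv"), row.names = FALSE)
  out <- data.frame(patient_id = cohort$patient_ids,
                    time_months = cohort$time_months,
                    event = cohort$event,
                    split = if (is.null(cohort$split)) NA else cohort$split)
  write.csv(out, file.path(dir, "outcomes.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(cohort$config),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
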