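# Feature filtering and clinical categorization --------------------------
#
# All filter statistics (variances, Pearson correlations) are computed on
# training rows only; test rows are subset to the same retained columns.
# Thresholds are strict: a column is dropped iff |r| > threshold.

new_filter_report <- function(n_input, zero = character(),
                              pairwise = NULL, anchor = NULL) {
  if (is.null(pairwise))
    pairwise <- data.frame(kept = character(), dropped = character(),
                           correlation = numeric())
  if (is.null(anchor))
    anchor <- data.frame(anchor = character(), dropped = character(),
                         correlation = numeric())
  n_drop <- length(zero) + nrow(pairwise) + nrow(anchor)
  structure(list(n_input = n_input,
                 dropped_zero_variance = zero,
                 dropped_pairwise = pairwise,
                 dropped_anchor = anchor,
                 n_output = n_input - n_drop),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(paste0("<filter_report> %d -> %d features ",
                     "(zero-variance %d, pairwise %d, anchor %d)\n"),
              x$n_input, x$n_output, length(x$dropped_zero_variance),
              nrow(x$dropped_pairwise), nrow(x$dropped_anchor)))
  invisible(x)
}

merge_filter_reports <- function(a, b) {
  stopifnot(a$n_output == b$n_input)
  new_filter_report(a$n_input,
                    zero = c(a$dropped_zero_variance, b$dropped_zero_variance),
                    pairwise = rbind(a$dropped_pairwise, b$dropped_pairwise),
                    anchor = rbind(a$dropped_anchor, b$dropped_anchor))
}

#' Drop zero-variance features
#'
#' Removes columns whose sample variance on the training rows is zero.
#'
#' @param features numeric matrix with column names (all rows, train + test).
#' @param train_mask logical vector marking the training rows.
#' @return A list with the filtered `features` and a `report`
#'   (`filter_report`).
#' @export
drop_zero_variance <- function(features, train_mask) {
  stopifnot(is.matrix(features), sum(train_mask) >= 2)
  v <- apply(features[train_mask, , drop = FALSE], 2, var)
  drop <- colnames(features)[v == 0]
  if (length(drop) == ncol(features))
    stop("all features have zero variance on the training rows")
  list(features = features[, setdiff(colnames(features), drop), drop = FALSE],
       report = new_filter_report(ncol(features), zero = drop))
}

#' Drop pairwise-correlated features
#'
#' Greedy scan in column order: column `j` is dropped iff its absolute
#' Pearson correlation (training rows) with any earlier *kept* column
#' exceeds `threshold`. The earlier member of an offending pair is always
#' kept, so the result is deterministic in column order.
#'
#' @inheritParams drop_zero_variance
#' @param threshold drop iff `|r| > threshold` (default 0.99).
#' @return A list with filtered `features` and `report`.
#' @export
drop_pairwise_correlated <- function(features, train_mask, threshold = 0.99) {
  stopifnot(threshold > 0, threshold <= 1)
  r <- suppressWarnings(cor(features[train_mask, , drop = FALSE]))
  if (any(!is.finite(r)))
    stop("non-finite correlations; run drop_zero_variance first")
  p <- ncol(features)
  kept <- logical(p); kept[1] <- TRUE
  rec <- list()
  for (j in seq_len(p)[-1]) {
    rj <- abs(r[j, kept])
    hit <- which(rj > threshold)
    if (length(hit)) {
      partner <- colnames(features)[kept][hit[1]]
      rec[[length(rec) + 1L]] <- data.frame(
        kept = partner, dropped = colnames(features)[j],
        correlation = r[j, partner])
    } else kept[j] <- TRUE
  }
  pw <- if (length(rec)) do.call(rbind, rec) else NULL
  list(features = features[, kept, drop = FALSE],
       report = new_filter_report(p, pairwise = pw))
}

#' Drop features correlated with anchor features
#'
#' Removes every non-anchor column whose absolute Pearson correlation
#' (training rows) with any anchor exceeds `threshold`; the anchors
#' themselves are always retained. By convention the anchors are the tumor
#' volume and global mean intensity features, which are known prognostic
#' factors whose redundant correlates are removed.
#'
#' @inheritParams drop_zero_variance
#' @param anchors character vector of anchor column names.
#' @param threshold drop iff `|r| > threshold` (default 0.80).
#' @return A list with filtered `features` and `report`.
#' @export
drop_anchor_correlated <- function(features, train_mask, anchors,
                                   threshold = 0.80) {
  missing <- setdiff(anchors, colnames(features))
  if (length(missing))
    stop("anchor feature(s) not present: ", paste(missing, collapse = ", "))
  xa <- features[train_mask, anchors, drop = FALSE]
  r <- suppressWarnings(cor(features[train_mask, , drop = FALSE], xa))
  rec <- list()
  for (j in colnames(features)) {
    if (j %in% anchors) next
    hit <- which(abs(r[j, ]) > threshold)
    if (length(hit))
      rec[[length(rec) + 1L]] <- data.frame(
        anchor = anchors[hit[1]], dropped = j, correlation = r[j, hit[1]])
  }
  an <- if (length(rec)) do.call(rbind, rec) else NULL
  drop <- if (length(rec)) an$dropped else character()
  list(features = features[, setdiff(colnames(features), drop), drop = FALSE],
       report = new_filter_report(ncol(features), anchor = an))
}

#' Full feature-reduction pipeline
#'
#' Applies, in order: zero-variance removal, pairwise correlation filtering
#' at 0.99, and anchor-correlation filtering at 0.80 (skipped when no anchor
#' is present). All statistics use training rows only. The pipeline is
#' idempotent: re-running it on its own output drops nothing.
#'
#' @inheritParams drop_zero_variance
#' @param anchors anchor column names; anchors absent from `features` are
#'   ignored with a message (after the correlation filters an anchor may
#'   itself have been consumed by an earlier rule only if it entered later
#'   in column order).
#' @param pairwise_threshold,anchor_threshold strict drop thresholds.
#' @return A list with filtered `features` and a combined `report`.
#' @export
filter_features <- function(features, train_mask,
                            anchors = c("F25.ShapeVolume",
                                        "F29.IntensityDirectGlobalMean"),
                            pairwise_threshold = 0.99,
                            anchor_threshold = 0.80) {
  s1 <- drop_zero_variance(features, train_mask)
  s2 <- drop_pairwise_correlated(s1$features, train_mask, pairwise_threshold)
  rep12 <- merge_filter_reports(s1$report, s2$report)
  anchors <- intersect(anchors, colnames(s2$features))
  if (!length(anchors))
    return(list(features = s2$features, report = rep12))
  s3 <- drop_anchor_correlated(s2$features, train_mask, anchors,
                               anchor_threshold)
  list(features = s3$features,
       report = merge_filter_reports(rep12, s3$report))
}

# Reference levels fixed for reproducible one-hot encodings.
.clinical_levels <- list(
  sex = c("Male", "Female"),
  hpv_status = c("Positive", "Negative", "Unknown"),
  smoking_status = c("Never", "Former", "Current"),
  t_category = c("T1-2", "T3-4"),
  n_category = c("N0-1", "N2-3"),
  therapeutic_combination = c("CC", "IC+CC", "IC+RT", "RT"),
  ajcc_stage = c("I", "II", "III", "IV")
)

#' Collapse clinical categories
#'
#' Maps raw T category (T1..T4) to the binary grouping T1-2/T3-4 and raw N
#' category (N0..N3) to N0-1/N2-3, and fixes factor levels with declared
#' reference levels (HPV Positive, Smoking Never, T1-2, N0-1, CC, Stage I)
#' for downstream one-hot encoding. HPV "Unknown" is kept as its own level,
#' never imputed. Already-collapsed T/N values pass through unchanged.
#'
#' @param raw_clinical data.frame as from [sample_clinical_categories()].
#' @return data.frame with binary T/N groups and fixed factor levels.
#' @export
categorize_clinical <- function(raw_clinical) {
  x <- raw_clinical
  collapse <- function(v, map, what) {
    v <- as.character(v)
    bad <- setdiff(unique(v), names(map))
    if (length(bad))
      stop(sprintf("unknown %s value(s): %s", what,
                   paste(bad, collapse = ", ")))
    unname(map[v])
  }
  t_map <- c(T1 = "T1-2", T2 = "T1-2", T3 = "T3-4", T4 = "T3-4",
             `T1-2` = "T1-2", `T3-4` = "T3-4")
  n_map <- c(N0 = "N0-1", N1 = "N0-1", N2 = "N2-3", N3 = "N2-3",
             `N0-1` = "N0-1", `N2-3` = "N2-3")
  x$t_category <- collapse(x$t_category, t_map, "T category")
  x$n_category <- collapse(x$n_category, n_map, "N category")
  for (nm in intersect(names(.clinical_levels), names(x))) {
    v <- as.character(x[[nm]])
    bad <- setdiff(unique(v), .clinical_levels[[nm]])
    if (length(bad))
      stop(sprintf("unknown %s value(s): %s", nm, paste(bad, collapse = ", ")))
    x[[nm]] <- factor(v, levels = .clinical_levels[[nm]])
  }
  x
}

#' One-hot design matrix for the risk models
#'
#' Builds the numeric design matrix used by all base models. The clinical
#' baseline uses six covariates (age, HPV, smoking, therapeutic combination,
#' T and N category); AJCC stage, a cluster label (categorical, reference
#' cluster 1) and/or selected continuous features can be appended. One-hot
#' columns drop the declared reference level of each factor.
#'
#' @param clinical categorized clinical data.frame.
#' @param cluster_labels optional integer cluster labels (1..k).
#' @param extra_features optional numeric matrix of additional columns.
#' @param include_ajcc include AJCC stage dummies.
#' @return numeric matrix, one row per patient.
#' @export
design_matrix <- function(clinical, cluster_labels = NULL,
                          extra_features = NULL, include_ajcc = FALSE) {
  vars <- c("age", "hpv_status", "smoking_status",
            "therapeutic_combination", "t_category", "n_category")
  if (include_ajcc) vars <- c(vars, "ajcc_stage")
  df <- clinical[, vars, drop = FALSE]
  if (!is.null(cluster_labels)) {
    k <- max(cluster_labels)
    df$cluster <- factor(paste0("C", cluster_labels),
                         levels = paste0("C", seq_len(k)))
  }
  mm <- model.matrix(~ ., data = df)[, -1, drop = FALSE]
  if (!is.null(extra_features)) {
    stopifnot(nrow(extra_features) == nrow(mm))
    mm <- cbind(mm, as.matrix(extra_features))
  }
  mm
}

# z-scoring helpers for the regression-based learners (forests consume raw
# columns: splitting is invariant to monotone transforms).
zscore_fit <- function(x) {
  m <- colMeans(x)
  s <- apply(x, 2, sd)
  s[s == 0] <- 1
  list(center = m, scale = s)
}

zscore_apply <- function(x, scaler) {
  sweep(sweep(x, 2, scaler$center[colnames(x)]), 2,
        scaler$scale[colnames(x)], "/")
}
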