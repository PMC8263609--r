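# Discrimination metrics and stratification tests ------------------------

#' Harrell's concordance index
#'
#' Over comparable pairs — `(i, j)` with `T_i < T_j` and patient `i` having
#' the event, or tied times where exactly one patient has the event (the
#' event is treated as earlier) — the fraction in which the earlier-event
#' patient received the strictly higher risk, with ties in risk counting
#' one half. Pairs whose earlier time is censored are not comparable.
#'
#' @param risk predicted risk scores (higher = riskier).
#' @param time follow-up times.
#' @param event 0/1 event indicators.
#' @return concordance in `[0, 1]`.
#' @export
harrell_c_index <- function(risk, time, event) {
  stopifnot(length(risk) == length(time), length(time) == length(event))
  e_i <- matrix(event == 1, length(time), length(time))
  comp <- (outer(time, time, "<") & e_i) |
    (outer(time, time, "==") & e_i & t(!e_i))
  if (!any(comp)) stop("no comparable pairs")
  conc <- outer(risk, risk, ">")[comp]
  tie <- outer(risk, risk, "==")[comp]
  (sum(conc) + 0.5 * sum(tie)) / sum(comp)
}

#' IPCW-weighted AUC at the horizon
#'
#' Weighted Mann-Whitney statistic over patients with positive weight:
#' the probability, under the product weighting `w_i w_j`, that a positive
#' patient's risk exceeds a negative patient's, ties counting one half.
#' With unit weights this is the classical empirical AUC.
#'
#' @param risk predicted risks.
#' @param outcome a `horizon_outcome` from [ipcw_weights()].
#' @return AUC in `[0, 1]`.
#' @export
auc_horizon <- function(risk, outcome) {
  keep <- outcome$weight > 0
  y <- outcome$label[keep]; w <- outcome$weight[keep]; r <- risk[keep]
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0)
    stop(sprintf("degenerate classes at the horizon: %d positive, %d negative",
                 n_pos, n_neg))
  rp <- r[y == 1]; wp <- w[y == 1]
  rn <- r[y == 0]; wn <- w[y == 0]
  gt <- outer(rp, rn, ">") + 0.5 * outer(rp, rn, "==")
  ww <- outer(wp, wn)
  sum(ww * gt) / sum(ww)
}

#' k-group log-rank test
#'
#' Observed-minus-expected event counts per group accumulated over distinct
#' event times, with the hypergeometric covariance; the statistic is the
#' quadratic form over the first `k - 1` groups and is referred to a
#' chi-square distribution with `k - 1` degrees of freedom.
#'
#' @param labels group labels (any discrete vector; `cluster_labels` work).
#' @param time,event outcome vectors.
#' @return list with `chi2`, `df` and `p`.
#' @export
logrank_test <- function(labels, time, event) {
  g <- factor(as.vector(labels))
  k <- nlevels(g)
  if (k < 2) stop("log-rank test needs at least 2 non-empty groups")
  tk <- sort(unique(time[event == 1]))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in tk) {
    at_risk <- time >= t
    Y <- sum(at_risk)
    d <- sum(time == t & event == 1)
    Yg <- vapply(levels(g), function(l) sum(at_risk & g == l), numeric(1))
    dg <- vapply(levels(g),
                 function(l) sum(time == t & event == 1 & g == l), numeric(1))
    O <- O + dg
    E <- E + Yg * d / Y
    if (Y > 1) {
      f <- d * (Y - d) / (Y - 1)
      V <- V + f * (diag(Yg / Y, k) - tcrossprod(Yg / Y))
    }
  }
  idx <- seq_len(k - 1)
  u <- (O - E)[idx]
  Vi <- V[idx, idx, drop = FALSE]
  chi2 <- if (all(abs(u) < 1e-12)) 0 else
    as.numeric(crossprod(u, solve(Vi, u)))
  list(chi2 = chi2, df = k - 1L, p = pchisq(chi2, k - 1, lower.tail = FALSE))
}

#' Kaplan-Meier curves per group
#'
#' One product-limit curve per group, plus at-risk counts on a monthly
#' grid for plotting / export.
#'
#' @param labels group labels.
#' @param time,event outcome vectors.
#' @param grid_months monthly grid for at-risk counts (default
#'   `0:ceiling(max(time))`).
#' @return named list per group: `curve` (a `step_survival`), `n`, and
#'   `at_risk` (data.frame month/n_at_risk).
#' @export
km_curves_by_group <- function(labels, time, event, grid_months = NULL) {
  g <- factor(as.vector(labels))
  if (is.null(grid_months)) grid_months <- 0:ceiling(max(time))
  out <- lapply(levels(g), function(l) {
    sel <- g == l
    list(curve = km_estimator(time[sel], event[sel]),
         n = sum(sel),
         at_risk = data.frame(
           month = grid_months,
           n_at_risk = vapply(grid_months,
                              function(t) sum(time[sel] >= t), numeric(1))))
  })
  names(out) <- levels(g)
  out
}

#' Write per-group KM tables as CSV
#'
#' @param curves result of [km_curves_by_group()]; `dir` output directory;
#'   `prefix` file-name prefix.
#' @export
write_km_tables <- function(curves, dir, prefix = "km") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in names(curves)) {
    cv <- curves[[g]]$curve
    write.csv(data.frame(time = cv$times, survival = cv$surv),
              file.path(dir, sprintf("%s_group%s.csv", prefix, g)),
              row.names = FALSE)
  }
  invisible(dir)
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 for identical partitions, about 0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(as.vector(a), as.vector(b))
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_idx <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(0)
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}
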