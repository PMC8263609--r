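# Kaplan-Meier machinery and censoring weights ---------------------------
#
# Right-censored outcomes are converted into a weighted binary problem at a
# fixed horizon (5 years = 60 months by default) via inverse probability of
# censoring weighting: fully observed patients are up-weighted by the
# inverse of the Kaplan-Meier censoring-survival estimate, and patients
# censored event-free before the horizon get weight zero.

#' Step survival function
#'
#' Right-continuous non-increasing step function with value 1 before the
#' first jump time.
#'
#' @param times increasing jump times.
#' @param surv survival values after each jump, non-increasing in `(0, 1]`.
#' @return object of class `step_survival`.
#' @export
step_survival <- function(times, surv) {
  stopifnot(length(times) == length(surv), !is.unsorted(times),
            all(diff(c(1, surv)) <= 1e-12))
  structure(list(times = times, surv = surv), class = "step_survival")
}

#' Evaluate a step survival function
#'
#' @param s a `step_survival`.
#' @param t evaluation times.
#' @param left if `TRUE`, return the left limit `S(t-)`.
#' @return numeric vector of survival probabilities.
#' @export
step_survival_at <- function(s, t, left = FALSE) {
  idx <- findInterval(t, s$times, left.open = left)
  c(1, s$surv)[idx + 1L]
}

#' Kaplan-Meier estimator
#'
#' Product-limit estimate over distinct event times,
#' `S(t) = prod_{t_k <= t} (1 - d_k / Y_k)`, with the convention that
#' patients censored at an event time are still at risk at that time.
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicators.
#' @return a `step_survival`.
#' @export
km_estimator <- function(time, event) {
  if (!length(time)) stop("empty input")
  stopifnot(all(time > 0), all(event %in% c(0, 1)),
            length(time) == length(event))
  tk <- sort(unique(time[event == 1]))
  if (!length(tk)) return(step_survival(numeric(), numeric()))
  d <- vapply(tk, function(t) sum(time == t & event == 1), numeric(1))
  Y <- vapply(tk, function(t) sum(time >= t), numeric(1))
  step_survival(tk, cumprod(1 - d / Y))
}

#' Kaplan-Meier estimate of the censoring distribution
#'
#' Applies the product-limit estimator with the indicator flipped, so that
#' censoring is treated as the event: returns `G(t)`, the probability of
#' remaining uncensored past `t`.
#'
#' @inheritParams km_estimator
#' @return a `step_survival` for the censoring time.
#' @export
censoring_survival <- function(time, event) {
  km_estimator(time, 1 - event)
}

#' Inverse-probability-of-censoring weights at a horizon
#'
#' Converts `(time, event)` into a weighted binary outcome at
#' `horizon` months:
#' * event observed at or before the horizon: label 1,
#'   weight `1 / G(T-)` (left limit, avoiding self-inclusion);
#' * followed event-free to the horizon (`time >= horizon`): label 0,
#'   weight `1 / G(horizon)`;
#' * censored event-free before the horizon: label `NA`, weight 0.
#'
#' Weights are capped (default 20) to bound the variance contributed by
#' near-zero censoring-survival estimates; a warning notes when the cap or
#' a zero `G` evaluation is hit.
#'
#' @inheritParams km_estimator
#' @param horizon horizon in months (default 60 = 5 years).
#' @param cap maximum weight.
#' @return object of class `horizon_outcome`: list with `horizon_months`,
#'   `label` (0/1/NA) and `weight` (>= 0, zero exactly on the
#'   censored-early set).
#' @export
ipcw_weights <- function(time, event, horizon = 60, cap = 20) {
  stopifnot(horizon > 0)
  G <- censoring_survival(time, event)
  n <- length(time)
  label <- rep(NA_integer_, n)
  weight <- numeric(n)
  is_event <- event == 1 & time <= horizon
  is_ctrl <- !is_event & time >= horizon
  if (any(is_event)) {
    g <- step_survival_at(G, time[is_event], left = TRUE)
    label[is_event] <- 1L
    weight[is_event] <- 1 / g
  }
  if (any(is_ctrl)) {
    g <- step_survival_at(G, horizon)
    label[is_ctrl] <- 0L
    weight[is_ctrl] <- 1 / g
  }
  if (any(!is.finite(weight))) {
    warning("censoring survival reached 0 at an evaluation point; ",
            "weight set to cap")
    weight[!is.finite(weight)] <- cap
  }
  if (any(weight > cap)) {
    warning(sprintf("%d weight(s) capped at %g", sum(weight > cap), cap))
    weight[weight > cap] <- cap
  }
  structure(list(horizon_months = horizon, label = label, weight = weight),
            class = "horizon_outcome")
}

#' Export IPCW weights for audit
#'
#' @param outcome a `horizon_outcome`; `ids` patient identifiers;
#'   `path` CSV file path.
#' @export
write_ipcw <- function(outcome, ids, path) {
  write.csv(data.frame(patient_id = ids, label = outcome$label,
                       weight = outcome$weight),
            path, row.names = FALSE)
  invisible(path)
}
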