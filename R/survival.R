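#' Kaplan-Meier product-limit estimate
#'
#' S(t) = prod over event times t_i <= t of (1 - d_i / n_i); censored
#' observations leave the risk set after their time (events precede
#' censorings at tied times). Computed via the survival package, with the
#' Greenwood variance of S.
#'
#' @param time Follow-up times in months (>= 0).
#' @param event 1 = event, 0 = censored.
#' @return An object of class `km_curve`: `time` (distinct observed times),
#'   `n_risk`, `n_event`, `surv`, `var_greenwood`.
#' @export
km_estimate <- function(time, event) {
  if (length(time) < 1L) stop("need at least one record")
  if (any(time < 0)) stop("negative follow-up time")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  structure(
    list(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
         surv = fit$surv,
         var_greenwood = (fit$surv * fit$std.err)^2),
    class = "km_curve")
}

#' Survival probability at a time point
#'
#' Right-continuous step-function value of the KM curve; S(0) = 1 and the
#' last step extends beyond the last observed time.
#'
#' @param curve A `km_curve`.
#' @param t Time in months (>= 0).
#' @return Survival probability.
#' @export
survival_at <- function(curve, t) {
  if (any(t < 0)) stop("t must be >= 0")
  sf <- stats::stepfun(curve$time, c(1, curve$surv), right = FALSE)
  sf(t)
}

#' Two-group log-rank test
#'
#' Standard one-degree-of-freedom log-rank chi-square over the pooled
#' distinct event times, via survival::survdiff.
#'
#' @param time_a,event_a Times and event indicators of group A.
#' @param time_b,event_b Times and event indicators of group B.
#' @return List: `chi_square`, `p_value`, `observed`, `expected` (length-2,
#'   A then B).
#' @export
logrank <- function(time_a, event_a, time_b, event_b) {
  if (length(time_a) == 0L || length(time_b) == 0L) {
    stop("both groups must be non-empty")
  }
  if (sum(event_a) + sum(event_b) == 0L) {
    stop("no events in either group: log-rank undefined")
  }
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp <- rep(c("A", "B"), c(length(time_a), length(time_b)))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ grp)
  list(chi_square = sd_$chisq,
       p_value = stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE),
       observed = as.numeric(sd_$obs), expected = as.numeric(sd_$exp))
}

#' Survival stratification by predicted recurrence group
#'
#' Splits the cohort by the classifier's predicted label, estimates the KM
#' curve per predicted group for the chosen endpoint (recurrence-free or
#' overall survival, both timed from the treatment-start baseline), runs the
#' log-rank test, and reports the 5-year survival of each group.
#'
#' @param outcomes Outcomes data.frame (columns `time_rfs_months`,
#'   `event_rfs`, `time_os_months`, `event_os`).
#' @param predicted Character vector of predicted labels "R"/"NR", aligned
#'   with `outcomes` rows.
#' @param endpoint "RFS" or "OS".
#' @return List: `curves` (named list, predicted NR and R), `logrank`,
#'   `surv_5yr` (named, percent), `endpoint`.
#' @export
stratify_by_prediction <- function(outcomes, predicted,
                                   endpoint = c("RFS", "OS")) {
  endpoint <- match.arg(endpoint)
  if (length(predicted) != nrow(outcomes)) {
    stop("predictions must cover all patients")
  }
  if (length(unique(predicted)) < 2L) {
    stop("one predicted group is empty: cannot stratify")
  }
  tcol <- if (endpoint == "RFS") "time_rfs_months" else "time_os_months"
  ecol <- if (endpoint == "RFS") "event_rfs" else "event_os"
  grp <- split(seq_len(nrow(outcomes)), predicted)
  curves <- lapply(grp, function(ii) {
    km_estimate(outcomes[[tcol]][ii], outcomes[[ecol]][ii])
  })
  lr <- logrank(outcomes[[tcol]][grp$NR], outcomes[[ecol]][grp$NR],
                outcomes[[tcol]][grp$R], outcomes[[ecol]][grp$R])
  s5 <- vapply(curves, survival_at, numeric(1), t = 60) * 100
  list(curves = curves, logrank = lr, surv_5yr = s5, endpoint = endpoint)
}

#' Write a KM curve as CSV
#'
#' Columns: time, n_risk, survival, variance.
#' @param curve A `km_curve`.
#' @param path File path.
#' @export
write_km_curve <- function(curve, path) {
  utils::write.csv(
    data.frame(time = curve$time, n_risk = curve$n_risk,
               survival = curve$surv, variance = curve$var_greenwood),
    path, row.names = FALSE)
  invisible(path)
}
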