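## Survival stratification: Kaplan-Meier estimation, log-rank testing,
## median split, maximally selected log-rank cutpoints and the composite
## bulk CAF-S5 phenotype.

check_survival_table <- function(table) {
  stopifnot(all(c("time", "event") %in% colnames(table)))
  if (any(is.na(table$time)) || any(table$time < 0)) {
    stop("times must be non-negative and non-missing", call. = FALSE)
  }
  if (!all(table$event %in% c(0, 1))) {
    stop("event must be binary (1 = event, 0 = censored)", call. = FALSE)
  }
  invisible(table)
}

#' Kaplan-Meier product-limit estimate
#'
#' @param table Survival table with `time` (days) and `event` (1 = death or
#'   death/recurrence depending on endpoint, 0 = censored).
#' @return Object of class `caf_km`: data frame with `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv` (non-increasing step function starting
#'   at 1).
#' @export
km_estimate <- function(table) {
  check_survival_table(table)
  if (!nrow(table)) stop("need at least one patient", call. = FALSE)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = table)
  out <- data.frame(time = sf$time, n_risk = sf$n.risk,
                    n_event = sf$n.event, n_censor = sf$n.censor,
                    surv = sf$surv)
  class(out) <- c("caf_km", "data.frame")
  out
}

#' Survival probability at given times
#'
#' Evaluates the step function of a `caf_km` curve.
#'
#' @param km A [km_estimate()] result.
#' @param t Times (days).
#' @return Estimated S(t) for each time.
#' @export
km_survival_at <- function(km, t) {
  vapply(t, function(ti) {
    past <- km$time <= ti
    if (!any(past)) 1 else km$surv[max(which(past))]
  }, numeric(1))
}

#' Log-rank test across patient groups
#'
#' Standard observed-minus-expected statistic with hypergeometric variance
#' (via `survival::survdiff`), `df = groups - 1`.
#'
#' @param groups List of >= 2 non-empty survival tables, or a single table
#'   when `group` gives per-patient group labels.
#' @param group Optional grouping vector used when `groups` is one table.
#' @return List with `statistic` (chi-square), `df` and `p`.
#' @export
logrank_test <- function(groups, group = NULL) {
  if (is.data.frame(groups)) {
    stopifnot(!is.null(group), length(group) == nrow(groups))
    groups <- split(groups, group)
  }
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(vapply(groups, nrow, integer(1)) == 0)) {
    stop("every group must contain at least one patient", call. = FALSE)
  }
  tab <- do.call(rbind, lapply(seq_along(groups), function(i) {
    g <- check_survival_table(groups[[i]])
    data.frame(time = g$time, event = g$event, grp = i)
  }))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp, data = tab)
  df <- length(groups) - 1
  stat <- unname(sd$chisq)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Split a cohort at the median of a covariate
#'
#' High group: covariate strictly above the cohort median; low group: at or
#' below (ties go low). The split is exhaustive and disjoint.
#'
#' @param table Survival table.
#' @param covariate Covariate column name.
#' @return List with `high` and `low` survival tables.
#' @export
median_split <- function(table, covariate) {
  check_markers(table, covariate)
  x <- table[[covariate]]
  if (any(is.na(x))) stop("covariate must be complete", call. = FALSE)
  med <- median(x)
  high <- x > med
  if (!any(high) || all(high)) {
    stop("degenerate split: covariate has no variation about its median",
         call. = FALSE)
  }
  list(high = table[high, , drop = FALSE],
       low = table[!high, , drop = FALSE])
}

## Two-group log-rank score U = sum(O1 - E1) and hypergeometric variance V
## over distinct event times; `in_group` marks group 1.
logrank_score <- function(time, event, in_group) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; in_group <- in_group[ord]
  n <- length(time)
  ev_times <- unique(time[event == 1])
  U <- 0; V <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    n1_t <- sum(at_risk & in_group)
    d_t <- sum(time == t & event == 1)
    d1_t <- sum(time == t & event == 1 & in_group)
    U <- U + d1_t - d_t * n1_t / n_t
    if (n_t > 1) {
      V <- V + d_t * (n1_t / n_t) * (1 - n1_t / n_t) * (n_t - d_t) / (n_t - 1)
    }
  }
  list(score = U, var = V)
}

#' Maximally selected log-rank cutpoint
#'
#' Scans all candidate cutpoints (midpoints between adjacent sorted unique
#' covariate values) whose induced split leaves both groups with at least
#' `minprop * n` patients, and returns the cutpoint maximising the absolute
#' standardized two-group log-rank statistic (score / sqrt(variance)); ties
#' resolve to the smallest cutpoint. The high group is covariate > cutpoint.
#' No multiple-testing correction of the selection is applied; downstream
#' reporting uses the log-rank p of the chosen split.
#'
#' @param table Survival table.
#' @param covariate Covariate column name.
#' @param minprop Minimum fraction of patients per group (default 0.1).
#' @return Object of class `caf_cutpoint`: `covariate`, `cutpoint`,
#'   `statistic` (standardized, signed: positive when the high group has
#'   more events than expected), `n_high`, `n_low`, `minprop`.
#' @export
max_selected_cutpoint <- function(table, covariate, minprop = 0.1) {
  check_survival_table(table)
  check_markers(table, covariate)
  x <- table[[covariate]]
  n <- length(x)
  ux <- sort(unique(x))
  if (length(ux) < 2) stop("covariate is constant", call. = FALSE)
  cands <- (ux[-1] + ux[-length(ux)]) / 2
  n_min <- minprop * n
  best <- NULL
  for (cp in cands) {
    high <- x > cp
    if (sum(high) < n_min || sum(!high) < n_min) next
    ls <- logrank_score(table$time, table$event, high)
    if (ls$var <= 0) next
    z <- ls$score / sqrt(ls$var)
    if (is.null(best) || abs(z) > abs(best$statistic) + 1e-12) {
      best <- list(cutpoint = cp, statistic = z,
                   n_high = sum(high), n_low = sum(!high))
    }
  }
  if (is.null(best)) {
    stop("no admissible cutpoint under minprop = ", minprop, call. = FALSE)
  }
  structure(c(list(covariate = covariate), best, list(minprop = minprop)),
            class = "caf_cutpoint")
}

#' @export
print.caf_cutpoint <- function(x, ...) {
  cat(sprintf(
    "Maximally selected cutpoint for %s: %.4g (z = %.3f; n_high = %d, n_low = %d)\n",
    x$covariate, x$cutpoint, x$statistic, x$n_high, x$n_low))
  invisible(x)
}

#' Composite bulk CAF-S5 phenotype
#'
#' A patient carries the CAF-S5 phenotype iff their FAP and PDPN scores are
#' above and their aSMA score at or below the respective maximally selected
#' cutpoints; everyone else is `"other"`. The intended downstream contrast
#' is CAF-S5 phenotype versus all other patients via [logrank_test()].
#'
#' @param table Survival table with `FAP`, `PDPN` and `aSMA` score columns.
#' @param cutpoints Named list of [max_selected_cutpoint()] results for
#'   `FAP`, `PDPN` and `aSMA`.
#' @return Character vector per patient: `"CAF-S5"` or `"other"`.
#' @export
assign_bulk_phenotype <- function(table, cutpoints) {
  need <- c("FAP", "PDPN", "aSMA")
  if (!all(need %in% names(cutpoints))) {
    stop("cutpoints must be provided for FAP, PDPN and aSMA", call. = FALSE)
  }
  check_markers(table, need)
  pheno <- table$FAP > cutpoints$FAP$cutpoint &
    table$PDPN > cutpoints$PDPN$cutpoint &
    table$aSMA <= cutpoints$aSMA$cutpoint
  ifelse(pheno, "CAF-S5", "other")
}

#' Restrict follow-up to a fixed horizon
#'
#' Administratively censors every patient still under observation at
#' `days` (default five years = 1826 days): times are capped and events
#' beyond the horizon become censorings.
#'
#' @param table Survival table.
#' @param days Follow-up horizon in days.
#' @return The restricted survival table.
#' @export
restrict_followup <- function(table, days = 1826) {
  check_survival_table(table)
  beyond <- table$time > days
  table$event[beyond] <- 0L
  table$time[beyond] <- days
  table
}
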