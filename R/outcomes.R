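#' Administrative truncation of follow-up
#'
#' Restricts survival data to a fixed horizon (default two years): times
#' beyond the horizon are set to the horizon with the event flag cleared
#' (administrative censoring); times at or before the horizon, including
#' exactly at the boundary, are unchanged.
#'
#' @param clinical data frame with columns \code{os_months} and
#'   \code{os_event}.
#' @param horizon_months truncation horizon, > 0 (default 24).
#' @return the data frame with truncated follow-up.
#' @export
#' @examples
#' truncate_followup(data.frame(os_months = c(30, 12, 24),
#'                              os_event = c(1, 1, 1)))
truncate_followup <- function(clinical, horizon_months = 24) {
  if (length(horizon_months) != 1L || is.na(horizon_months) ||
      horizon_months <= 0)
    stop("'horizon_months' must be positive")
  if (!all(c("os_months", "os_event") %in% names(clinical)))
    stop("'clinical' needs os_months and os_event columns")
  if (any(clinical$os_months < 0, na.rm = TRUE))
    stop("negative survival times")
  over <- !is.na(clinical$os_months) & clinical$os_months > horizon_months
  clinical$os_event[over] <- 0L
  clinical$os_months[over] <- horizon_months
  clinical
}

.km_median <- function(time, surv) {
  hit <- which(surv <= 0.5)
  if (!length(hit)) NA_real_ else time[min(hit)]
}

#' Kaplan-Meier fit for one stratum
#'
#' Product-limit estimate of the survival function with the standard tie
#' convention (deaths precede censorings at equal times). The median is the
#' earliest time at which the estimated survival drops to 0.5 or below;
#' \code{NA} means the median was not reached within follow-up.
#'
#' @param time non-negative survival times (months).
#' @param event event indicators (1 = death, 0 = censored).
#' @return object of class \code{ctab_km}: list with \code{time},
#'   \code{surv}, \code{n_risk}, \code{n_event}, \code{n_censor},
#'   \code{median} and \code{n}.
#' @export
#' @examples
#' km_fit(c(1, 2, 3), c(1, 1, 1))$median  # 2
km_fit <- function(time, event) {
  if (!length(time)) stop("empty stratum")
  if (length(time) != length(event) || anyNA(time) || anyNA(event))
    stop("'time' and 'event' must be complete and of equal length")
  if (any(time < 0)) stop("negative survival times")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor,
                 median = .km_median(fit$time, fit$surv),
                 n = length(time)),
            class = "ctab_km")
}

#' @export
print.ctab_km <- function(x, ...) {
  cat("Kaplan-Meier fit: n =", x$n, ", events =", sum(x$n_event),
      ", median =", if (is.na(x$median)) "not reached" else
        format(x$median), "months\n")
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank chi-square comparison of two survival
#' distributions, via [survival::survdiff()]. A stratum with zero events
#' triggers a warning; the statistic is still returned when defined.
#'
#' @param time survival times.
#' @param event event indicators (1 = death, 0 = censored).
#' @param group stratum labels with exactly two levels.
#' @return list with \code{statistic} (chi-square, 1 df), \code{p_value}
#'   and \code{group_sizes}.
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  group <- droplevels(group)
  if (nlevels(group) != 2L) stop("need exactly 2 strata")
  ev <- tapply(event, group, sum)
  if (any(ev == 0))
    warning("stratum with zero events: ",
            paste(names(ev)[ev == 0], collapse = ", "))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  p <- stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE)
  list(statistic = unname(sd$chisq), p_value = p,
       group_sizes = as.integer(table(group)) |>
         stats::setNames(levels(group)))
}

.RECIST_LEVELS <- c("CR", "PR", "SD", "PD")

.check_recist <- function(recist) {
  if (anyNA(recist)) stop("missing RECIST category")
  bad <- setdiff(unique(recist), .RECIST_LEVELS)
  if (length(bad))
    stop("unknown RECIST category: ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Responder table from RECIST categories
#'
#' Cross-tabulates treatment groups against responder status, where
#' responders are patients with complete or partial response (CR or PR) and
#' non-responders those with stable or progressive disease (SD or PD).
#'
#' @param recist character vector of RECIST v1.1 categories (CR/PR/SD/PD).
#' @param group treatment-group labels, same length.
#' @return integer table, groups x (responder, non_responder).
#' @export
responder_table <- function(recist, group) {
  .check_recist(recist)
  if (length(recist) != length(group))
    stop("'recist' and 'group' must have the same length")
  status <- factor(ifelse(recist %in% c("CR", "PR"),
                          "responder", "non_responder"),
                   levels = c("responder", "non_responder"))
  table(group = group, status = status)
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric two-sided test (minimum-likelihood rule: the p-value
#' sums the probabilities of all tables no more likely than the observed
#' one) with the conditional maximum-likelihood odds ratio.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return list with \code{odds_ratio} and \code{p_value}.
#' @export
#' @examples
#' fisher_exact(matrix(c(3, 1, 1, 3), 2))$p_value  # 34/70
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!identical(dim(table), c(2L, 2L)))
    stop("'table' must be 2x2")
  if (anyNA(table) || any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  ft <- stats::fisher.test(table)
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

#' Stable-disease proportion comparison
#'
#' Compares the proportion of patients with stable disease (SD) between two
#' treatment groups with Fisher's exact test on the SD vs non-SD 2x2 table.
#'
#' @inheritParams responder_table
#' @return list with \code{table} (groups x SD/non-SD), \code{proportions}
#'   (per-group SD fraction), \code{odds_ratio} and \code{p_value}.
#' @export
sd_proportion_comparison <- function(recist, group) {
  .check_recist(recist)
  group <- factor(group)
  if (nlevels(droplevels(group)) != 2L) stop("need exactly 2 groups")
  status <- factor(ifelse(recist == "SD", "SD", "non_SD"),
                   levels = c("SD", "non_SD"))
  tab <- table(group = droplevels(group), status = status)
  ft <- fisher_exact(tab)
  list(table = tab,
       proportions = tab[, "SD"] / rowSums(tab),
       odds_ratio = ft$odds_ratio, p_value = ft$p_value)
}

#' Stratified survival and response comparison
#'
#' Convenience wrapper for the standard biomarker read-outs on a treated
#' cohort: per-stratum Kaplan-Meier medians, the two-group log-rank test,
#' and (when RECIST categories are supplied) the responder-rate Fisher
#' test.
#'
#' @param time survival times (already truncated to the analysis horizon;
#'   see [truncate_followup()]).
#' @param event event indicators.
#' @param group two-level stratum labels (e.g. CTAB class, or treatment
#'   arm).
#' @param recist optional RECIST categories for the response comparison.
#' @return list with \code{medians} (named per-stratum KM medians, NA = not
#'   reached), \code{logrank}, and optionally \code{responders} (table) and
#'   \code{fisher}.
#' @export
outcome_comparison <- function(time, event, group, recist = NULL) {
  group <- droplevels(factor(group))
  if (nlevels(group) != 2L) stop("need exactly 2 strata")
  fits <- lapply(split(seq_along(time), group), function(i)
    km_fit(time[i], event[i]))
  out <- list(medians = vapply(fits, `[[`, numeric(1), "median"),
              logrank = logrank_test(time, event, group))
  if (!is.null(recist)) {
    out$responders <- responder_table(recist, group)
    out$fisher <- fisher_exact(out$responders)
  }
  out
}
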