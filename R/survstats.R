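#' Kaplan-Meier estimate for a set of survival records
#'
#' Product-limit estimator via [survival::survfit()]. Records are
#' `(time_months, event, stratum)` rows; events at a time precede
#' censorings at the same time, the standard convention.
#'
#' @param records data.frame with columns `time_months` (> 0), `event`
#'   (1 event / 0 censored) and optionally `stratum`.
#' @param by_stratum estimate per stratum (default when a `stratum` column
#'   is present).
#' @return Object of class `km_curve`: list with the underlying `survfit`
#'   fit and a tidy `table` (`stratum`, `time`, `n_risk`, `n_event`,
#'   `surv`).
#' @export
km_estimate <- function(records, by_stratum = "stratum" %in% names(records)) {
  check_survival_records(records)
  fit <- if (by_stratum) {
    survival::survfit(survival::Surv(time_months, event) ~ stratum,
                      data = records)
  } else {
    survival::survfit(survival::Surv(time_months, event) ~ 1, data = records)
  }
  s <- summary(fit, censored = TRUE)
  tab <- data.frame(
    stratum = if (is.null(s$strata)) "all" else
      sub("^stratum=", "", as.character(s$strata)),
    time = s$time, n_risk = s$n.risk, n_event = s$n.event, surv = s$surv,
    stringsAsFactors = FALSE
  )
  structure(list(fit = fit, table = tab), class = "km_curve")
}

#' Survival probability at a given time from a KM curve
#'
#' Step-function lookup: the estimate at the largest event time not
#' exceeding `time`; 1 before the first event.
#'
#' @param km a `km_curve` from [km_estimate()].
#' @param time time in months.
#' @param stratum stratum name (`"all"` for unstratified fits).
#' @return Survival probability in `[0, 1]`.
#' @export
km_survival_at <- function(km, time, stratum = "all") {
  tab <- km$table[km$table$stratum == stratum & km$table$n_event > 0, ]
  if (!nrow(tab)) {
    if (!stratum %in% km$table$stratum)
      stop(sprintf("stratum %s not present in the fit", sQuote(stratum)))
    return(1)
  }
  idx <- which(tab$time <= time)
  if (!length(idx)) 1 else tab$surv[max(idx)]
}

#' Plot Kaplan-Meier curves
#'
#' Thin wrapper over the `survfit` plot method with months on the x axis.
#'
#' @param km a `km_curve`.
#' @param ... passed to `plot.survfit`.
#' @export
plot_km <- function(km, ...) {
  plot(km$fit, xlab = "Months since therapy start",
       ylab = "Survival probability", mark.time = TRUE, ...)
  invisible(km)
}

#' Two-sample log-rank test
#'
#' 1-df chi-square log-rank statistic comparing event timing between two
#' strata, via [survival::survdiff()].
#'
#' @param records data.frame with `time_months`, `event`, `stratum`.
#' @param stratum_a,stratum_b the two stratum labels to compare; default is
#'   the two strata present.
#' @return List with `statistic`, `p_value`, `observed`, `expected`
#'   (per-stratum event counts).
#' @export
logrank_test <- function(records, stratum_a = NULL, stratum_b = NULL) {
  check_survival_records(records)
  if (!"stratum" %in% names(records)) stop("records need a `stratum` column")
  if (is.null(stratum_a)) {
    lv <- unique(records$stratum)
    if (length(lv) != 2L)
      stop("specify stratum_a/stratum_b: found ", length(lv), " strata")
    stratum_a <- lv[1]; stratum_b <- lv[2]
  }
  sub <- records[records$stratum %in% c(stratum_a, stratum_b), ]
  if (!all(c(stratum_a, stratum_b) %in% sub$stratum))
    stop("both strata must be non-empty")
  if (sum(sub$event) == 0L) {
    warning("no events in either stratum; log-rank statistic set to 0")
    return(list(statistic = 0, p_value = 1,
                observed = c(0, 0), expected = c(NA_real_, NA_real_)))
  }
  sd <- survival::survdiff(survival::Surv(time_months, event) ~ stratum,
                           data = sub)
  list(statistic = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       observed = unname(sd$obs), expected = unname(sd$exp))
}

check_survival_records <- function(records) {
  need <- c("time_months", "event")
  if (!all(need %in% names(records)))
    stop("survival records need columns: ", paste(need, collapse = ", "))
  if (!nrow(records)) stop("no survival records")
  if (any(!is.finite(records$time_months)) || any(records$time_months <= 0))
    stop("all survival times must be positive and finite")
  if (!all(records$event %in% c(0, 1)))
    stop("`event` must be 0 (censored) or 1 (event)")
  invisible(records)
}

#' Responder / disease-control survival comparison
#'
#' Dichotomizes a classified cohort per criterion — responders (CMR/PMR)
#' vs non-responders (SMD/PMD), or disease control (CMR/PMR/SMD) vs PMD —
#' and runs Kaplan-Meier plus log-rank on the supplied records.
#'
#' @param classified output of [classify_cohort()].
#' @param records survival records (`patient_id`, `time_months`, `event`).
#' @param criterion `"eortc"`, `"percist"` or `"impercist"`.
#' @param split `"responders"` (CMR/PMR vs SMD/PMD) or `"control"`
#'   (CMR/PMR/SMD vs PMD).
#' @return List with `records` (stratified), `km` and `logrank`.
#' @export
survival_by_response <- function(classified, records,
                                 criterion = c("eortc", "percist", "impercist"),
                                 split = c("responders", "control")) {
  criterion <- match.arg(criterion)
  split <- match.arg(split)
  idx <- match(records$patient_id, classified$patient_id)
  if (anyNA(idx)) stop("survival records include unknown patient ids")
  cls <- as.character(classified[[criterion]])[idx]
  good <- if (split == "responders") c("CMR", "PMR") else c("CMR", "PMR", "SMD")
  lab <- if (split == "responders") c("responder", "non-responder")
    else c("disease-control", "progression")
  records$stratum <- ifelse(cls %in% good, lab[1], lab[2])
  km <- km_estimate(records)
  lr <- if (length(unique(records$stratum)) == 2L)
    logrank_test(records, lab[1], lab[2]) else NULL
  list(records = records, km = km, logrank = lr)
}
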