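#' Response categories
#'
#' The four ordinal metabolic response categories, best to worst:
#' complete metabolic response, partial metabolic response, stable metabolic
#' disease, progressive metabolic disease.
#' @export
RESPONSE_LEVELS <- c("CMR", "PMR", "SMD", "PMD")

#' Numeric rule parameters for the response criteria
#'
#' All thresholds on the 0-100 percent scale. EORTC uses +/-25% on summed
#' SUV_max; PERCIST and imPERCIST use +/-30% on summed SUL_peak; PERCIST
#' additionally escalates to PMD at a >= +75% increase in whole-body TLG.
#' Target selection is capped at five lesions, at most two per organ.
#'
#' @param eortc_pmr_threshold,eortc_pmd_threshold EORTC percent-change cuts.
#' @param percist_pmr_threshold,percist_pmd_threshold PERCIST/imPERCIST cuts.
#' @param tlg_pmd_threshold TLG escalation cut (PERCIST only).
#' @param max_targets,max_per_organ target-selection caps.
#' @param mtv_isocontour MTV threshold fraction of SUV_max.
#' @param percist_cmr_comparator `"mean_plus_2sd"` (default; matches the
#'   liver-referenced complete-response comparison on worked cases) or
#'   `"mean"` for the plain mean-liver comparison.
#' @return List of class `criteria_params`.
#' @export
criteria_params <- function(eortc_pmr_threshold = -25,
                            eortc_pmd_threshold = 25,
                            percist_pmr_threshold = -30,
                            percist_pmd_threshold = 30,
                            tlg_pmd_threshold = 75,
                            max_targets = 5L,
                            max_per_organ = 2L,
                            mtv_isocontour = 0.4,
                            percist_cmr_comparator = c("mean_plus_2sd", "mean")) {
  stopifnot(eortc_pmr_threshold < 0, eortc_pmd_threshold > 0,
            percist_pmr_threshold < 0, percist_pmd_threshold > 0,
            tlg_pmd_threshold > 0, max_targets >= 1, max_per_organ >= 1)
  structure(list(
    eortc_pmr_threshold = eortc_pmr_threshold,
    eortc_pmd_threshold = eortc_pmd_threshold,
    percist_pmr_threshold = percist_pmr_threshold,
    percist_pmd_threshold = percist_pmd_threshold,
    tlg_pmd_threshold = tlg_pmd_threshold,
    max_targets = as.integer(max_targets),
    max_per_organ = as.integer(max_per_organ),
    mtv_isocontour = mtv_isocontour,
    percist_cmr_comparator = match.arg(percist_cmr_comparator)
  ), class = "criteria_params")
}

#' Percent change between summed metrics
#'
#' `100 * (followup - baseline) / baseline`; the baseline sum must be
#' positive (an FDG-avid baseline lesion is an inclusion requirement).
#'
#' @param baseline_sum,followup_sum summed metric values.
#' @return Percent change on the 0-100 scale.
#' @export
percent_change <- function(baseline_sum, followup_sum) {
  if (any(baseline_sum <= 0)) stop("baseline sum must be > 0")
  100 * (followup_sum - baseline_sum) / baseline_sum
}

# greedy target selection: rank `frame` by `metric` descending (ties broken
# by lesion_id), keep at most `max_per_organ` per organ and `max_targets`
# total. The per-organ cap + total cap form a (truncated partition) matroid,
# so the greedy sum is the exhaustive optimum.
select_targets <- function(frame, params, metric) {
  if (!nrow(frame)) return(character(0))
  ord <- order(-frame[[metric]], frame$lesion_id)
  organ_used <- integer(0)
  picked <- character(0)
  for (i in ord) {
    if (length(picked) >= params$max_targets) break
    org <- frame$organ[i]
    used <- if (org %in% names(organ_used)) organ_used[[org]] else 0L
    if (used >= params$max_per_organ) next
    organ_used[org] <- used + 1L
    picked <- c(picked, frame$lesion_id[i])
  }
  picked
}

#' EORTC target selection
#'
#' Baseline lesions ranked by baseline SUV_max, at most two per organ and
#' five in total. The *same* lesions are followed on the second scan via
#' the identity map.
#'
#' @param pair a [scan_pair()].
#' @param params a [criteria_params()].
#' @return Character vector of baseline lesion ids.
#' @export
select_targets_eortc <- function(pair, params = criteria_params()) {
  if (!nrow(pair$baseline))
    stop("no baseline lesions for patient ", pair$patient_id,
         " (an FDG-avid baseline lesion is required)")
  select_targets(pair$baseline, params, "suv_max")
}

#' Hottest-lesion target selection (PERCIST)
#'
#' Lesions of one scan ranked by SUL_peak, at most two per organ and five
#' total, selected independently at each time point: the follow-up targets
#' need not be the baseline targets.
#'
#' @param scan data.frame of lesions (one time point).
#' @param params a [criteria_params()].
#' @return Character vector of lesion ids (possibly empty).
#' @export
select_targets_hottest <- function(scan, params = criteria_params()) {
  select_targets(scan, params, "sul_peak")
}

#' Detect new lesions on the follow-up scan
#'
#' Follow-up lesions with no baseline counterpart whose SUL_peak reaches
#' the PERCIST measurability floor (`1.5 * liver SUL mean + 2 SD`).
#' Unmapped lesions below the floor are not counted as new disease.
#'
#' @param pair a [scan_pair()].
#' @return The qualifying rows of `pair$followup`.
#' @export
detect_new_lesions <- function(pair) {
  fu <- pair$followup
  cand <- fu[is.na(fu$mapped_baseline_id), , drop = FALSE]
  cand[cand$sul_peak >= pair$liver_followup$measurability_floor, ,
       drop = FALSE]
}

new_assessment <- function(criterion, category, pct, bsum, fsum, rule, n_new,
                           target_ids) {
  structure(list(
    criterion = criterion,
    category = factor(category, levels = RESPONSE_LEVELS, ordered = TRUE),
    percent_change = pct,
    baseline_sum = bsum, followup_sum = fsum,
    fired_rule = rule, new_lesion_count = n_new,
    target_ids = target_ids
  ), class = "response_assessment")
}

#' @export
print.response_assessment <- function(x, ...) {
  cat(sprintf("<%s> %s  (%s; delta %s%%, %0.4g -> %0.4g, %d new lesion%s)\n",
              x$criterion, as.character(x$category), x$fired_rule,
              ifelse(is.na(x$percent_change), "NA",
                     sprintf("%+.1f", x$percent_change)),
              x$baseline_sum, x$followup_sum, x$new_lesion_count,
              if (x$new_lesion_count == 1L) "" else "s"))
  invisible(x)
}

# follow-up SUV_max for one baseline target: the mapped follow-up
# measurement (a resolved lesion contributes its measured residual value);
# a target with no follow-up row falls back to the follow-up background mean.
eortc_followup_value <- function(pair, baseline_id) {
  fu <- pair$followup
  hit <- which(!is.na(fu$mapped_baseline_id) &
                 fu$mapped_baseline_id == baseline_id)
  if (length(hit)) fu$suv_max[hit[1]] else pair$background_mean
}

#' Classify a scan pair under the EORTC criteria
#'
#' Summed SUV_max of the matched target lesions. Precedence: a new FDG-avid
#' lesion gives PMD; complete resolution of all follow-up lesions to
#' background level (SUV_max at or below background mean + 2 SD) gives CMR;
#' a decrease of at least 25% gives PMR, an increase of at least 25% PMD,
#' anything else SMD.
#'
#' @param pair a [scan_pair()].
#' @param params a [criteria_params()].
#' @return A `response_assessment`.
#' @export
classify_eortc <- function(pair, params = criteria_params()) {
  targets <- select_targets_eortc(pair, params)
  bsub <- pair$baseline[match(targets, pair$baseline$lesion_id), ]
  bsum <- sum(bsub$suv_max)
  fvals <- vapply(targets, function(id) eortc_followup_value(pair, id),
                  numeric(1))
  fsum <- sum(fvals)
  pct <- percent_change(bsum, fsum)
  new <- detect_new_lesions(pair)
  if (nrow(new) > 0L)
    return(new_assessment("EORTC", "PMD", pct, bsum, fsum,
                          "new FDG-avid lesion(s)", nrow(new), targets))
  bg_ceiling <- pair$background_mean + 2 * pair$background_sd
  if (!nrow(pair$followup) || all(pair$followup$suv_max <= bg_ceiling))
    return(new_assessment("EORTC", "CMR", pct, bsum, fsum,
                          "all uptake resolved to background", 0L, targets))
  cat_rule <- if (pct <= params$eortc_pmr_threshold) {
    c("PMR", sprintf("SUV_max sum decrease >= %g%%", -params$eortc_pmr_threshold))
  } else if (pct >= params$eortc_pmd_threshold) {
    c("PMD", sprintf("SUV_max sum increase >= %g%%", params$eortc_pmd_threshold))
  } else c("SMD", "change within stable band")
  new_assessment("EORTC", cat_rule[1], pct, bsum, fsum, cat_rule[2], 0L,
                 targets)
}

percist_cmr_threshold <- function(pair, params) {
  if (params$percist_cmr_comparator == "mean")
    pair$liver_followup$sul_mean else pair$liver_followup$sul_mean_plus_2sd
}

# whole-body TLG percent change, NA when unavailable or baseline zero
tlg_change <- function(pair) {
  if (!"tlg" %in% names(pair$baseline) || !"tlg" %in% names(pair$followup))
    return(NA_real_)
  b <- sum(pair$baseline$tlg)
  if (!is.finite(b) || b <= 0) return(NA_real_)
  f <- sum(pair$followup$tlg)
  if (!is.finite(f)) return(NA_real_)
  percent_change(b, f)
}

#' Classify a scan pair under PERCIST
#'
#' Summed SUL_peak of the hottest lesions selected independently on each
#' scan. Precedence: a new hypermetabolic lesion or a whole-body TLG
#' increase of at least 75% gives PMD; resolution of every follow-up lesion
#' below the liver comparator gives CMR; a SUL_peak sum change of at least
#' +/-30% gives PMD/PMR; anything else SMD.
#'
#' @inheritParams classify_eortc
#' @return A `response_assessment`.
#' @export
classify_percist <- function(pair, params = criteria_params()) {
  if (is.null(pair$liver_followup))
    stop("PERCIST requires a follow-up liver reference")
  bt <- select_targets_hottest(pair$baseline, params)
  if (!length(bt))
    stop("no baseline lesions for patient ", pair$patient_id)
  bsum <- sum(pair$baseline$sul_peak[match(bt, pair$baseline$lesion_id)])
  ft <- select_targets_hottest(pair$followup, params)
  fsum <- if (length(ft))
    sum(pair$followup$sul_peak[match(ft, pair$followup$lesion_id)]) else 0
  pct <- percent_change(bsum, fsum)
  new <- detect_new_lesions(pair)
  if (nrow(new) > 0L)
    return(new_assessment("PERCIST", "PMD", pct, bsum, fsum,
                          "new hypermetabolic lesion(s)", nrow(new), ft))
  dtlg <- tlg_change(pair)
  if (!is.na(dtlg) && dtlg >= params$tlg_pmd_threshold)
    return(new_assessment("PERCIST", "PMD", pct, bsum, fsum,
                          sprintf("whole-body TLG increase >= %g%%",
                                  params$tlg_pmd_threshold), 0L, ft))
  liver_cut <- percist_cmr_threshold(pair, params)
  if (!nrow(pair$followup) || all(pair$followup$sul_peak < liver_cut))
    return(new_assessment("PERCIST", "CMR", pct, bsum, fsum,
                          "all lesions below liver reference", 0L, ft))
  cat_rule <- if (pct >= params$percist_pmd_threshold) {
    c("PMD", sprintf("SUL_peak sum increase >= %g%%", params$percist_pmd_threshold))
  } else if (pct <= params$percist_pmr_threshold) {
    c("PMR", sprintf("SUL_peak sum decrease >= %g%%", -params$percist_pmr_threshold))
  } else c("SMD", "change within stable band")
  new_assessment("PERCIST", cat_rule[1], pct, bsum, fsum, cat_rule[2], 0L, ft)
}

#' Classify a scan pair under imPERCIST
#'
#' The immunotherapy modification of PERCIST: a new lesion alone never
#' forces PMD. Instead, new lesions enter the follow-up SUL_peak sum when
#' they are hotter than the persisting target lesions or when the baseline
#' scan held fewer than five targets; PMD then requires a sum increase of
#' at least 30%. Without new lesions the classification coincides with
#' PERCIST's threshold rules.
#'
#' @inheritParams classify_eortc
#' @return A `response_assessment`.
#' @export
classify_impercist <- function(pair, params = criteria_params()) {
  if (is.null(pair$liver_followup))
    stop("imPERCIST requires a follow-up liver reference")
  bt <- select_targets_hottest(pair$baseline, params)
  if (!length(bt))
    stop("no baseline lesions for patient ", pair$patient_id)
  bsum <- sum(pair$baseline$sul_peak[match(bt, pair$baseline$lesion_id)])
  fu <- pair$followup
  new <- detect_new_lesions(pair)
  persisting <- fu[!is.na(fu$mapped_baseline_id), , drop = FALSE]
  existing_peak <- if (nrow(persisting)) max(persisting$sul_peak) else -Inf
  eligible_new <- new[new$sul_peak > existing_peak |
                        length(bt) < params$max_targets, , drop = FALSE]
  candidates <- rbind(persisting, eligible_new)
  ft <- select_targets_hottest(candidates, params)
  fsum <- if (length(ft))
    sum(candidates$sul_peak[match(ft, candidates$lesion_id)]) else 0
  pct <- percent_change(bsum, fsum)
  if (pct >= params$percist_pmd_threshold)
    return(new_assessment("imPERCIST", "PMD", pct, bsum, fsum,
                          sprintf("SUL_peak sum (incl. new lesions) increase >= %g%%",
                                  params$percist_pmd_threshold),
                          nrow(new), ft))
  liver_cut <- percist_cmr_threshold(pair, params)
  if (!nrow(fu) || all(fu$sul_peak < liver_cut))
    return(new_assessment("imPERCIST", "CMR", pct, bsum, fsum,
                          "all lesions below liver reference", nrow(new), ft))
  if (pct <= params$percist_pmr_threshold)
    return(new_assessment("imPERCIST", "PMR", pct, bsum, fsum,
                          sprintf("SUL_peak sum decrease >= %g%%",
                                  -params$percist_pmr_threshold),
                          nrow(new), ft))
  new_assessment("imPERCIST", "SMD", pct, bsum, fsum,
                 "change within stable band", nrow(new), ft)
}

#' Classify a scan pair under all three criteria
#'
#' @inheritParams classify_eortc
#' @return Named list of three `response_assessment`s
#'   (`eortc`, `percist`, `impercist`).
#' @export
classify_all <- function(pair, params = criteria_params()) {
  list(eortc = classify_eortc(pair, params),
       percist = classify_percist(pair, params),
       impercist = classify_impercist(pair, params))
}

#' Tabulate assessments for a list of scan pairs
#'
#' @param pairs list of [scan_pair()]s.
#' @param params a [criteria_params()].
#' @return data.frame with one row per patient: `patient_id`, `eortc`,
#'   `percist`, `impercist` (factors over CMR/PMR/SMD/PMD) and the three
#'   percent changes.
#' @export
classify_cohort <- function(pairs, params = criteria_params()) {
  rows <- lapply(pairs, function(p) {
    a <- classify_all(p, params)
    data.frame(
      patient_id = p$patient_id,
      eortc = as.character(a$eortc$category),
      percist = as.character(a$percist$category),
      impercist = as.character(a$impercist$category),
      eortc_pct = a$eortc$percent_change,
      percist_pct = a$percist$percent_change,
      impercist_pct = a$impercist$percent_change,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  for (col in c("eortc", "percist", "impercist"))
    out[[col]] <- factor(out[[col]], levels = RESPONSE_LEVELS)
  out
}
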