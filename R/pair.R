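#' Baseline / follow-up scan pair for one patient
#'
#' Bundles the per-lesion measurements of the two time points with the
#' follow-up liver reference and the background activity used by the EORTC
#' complete-response test. Follow-up lesions carry a `mapped_baseline_id`:
#' `NA` marks a lesion with no baseline counterpart (a candidate new
#' lesion). The identity map must be injective.
#'
#' @param patient_id patient identifier.
#' @param baseline,followup data.frames with columns `lesion_id`, `organ`,
#'   `suv_max`, `suv_mean`, `suv_peak`, `sul_peak`, `mtv_ml`, `tlg`;
#'   `followup` additionally `mapped_baseline_id`.
#' @param liver_followup a [liver_reference_values()] object for the
#'   follow-up scan (PERCIST thresholds are taken from the follow-up liver).
#' @param liver_baseline optional baseline liver reference.
#' @param background_mean,background_sd mean and SD of normal surrounding
#'   background uptake on the follow-up scan (SUV units), used for the EORTC
#'   resolution test.
#' @return Object of class `scan_pair`.
#' @export
scan_pair <- function(patient_id, baseline, followup,
                      liver_followup, liver_baseline = NULL,
                      background_mean = 1.0, background_sd = 0.0) {
  need_b <- c("lesion_id", "organ", "suv_max", "sul_peak")
  need_f <- c(need_b, "mapped_baseline_id")
  if (!all(need_b %in% names(baseline)))
    stop("baseline frame lacks columns: ",
         paste(setdiff(need_b, names(baseline)), collapse = ", "))
  if (!all(need_f %in% names(followup)))
    stop("followup frame lacks columns: ",
         paste(setdiff(need_f, names(followup)), collapse = ", "))
  if (anyDuplicated(baseline$lesion_id))
    stop("duplicate baseline lesion_id for patient ", patient_id)
  if (anyDuplicated(followup$lesion_id))
    stop("duplicate follow-up lesion_id for patient ", patient_id)
  mapped <- followup$mapped_baseline_id[!is.na(followup$mapped_baseline_id)]
  if (anyDuplicated(mapped))
    stop("lesion identity map is not injective for patient ", patient_id)
  if (!all(mapped %in% baseline$lesion_id))
    stop("follow-up lesions map to unknown baseline ids for patient ",
         patient_id)
  if (!inherits(liver_followup, "liver_reference"))
    stop("`liver_followup` must be a liver_reference")
  for (fr in list(baseline, followup)) {
    num <- intersect(c("suv_max", "suv_mean", "suv_peak", "sul_peak",
                       "mtv_ml", "tlg"), names(fr))
    if (nrow(fr) && any(as.matrix(fr[num]) < 0, na.rm = TRUE))
      stop("negative lesion metric for patient ", patient_id)
  }
  structure(list(
    patient_id = patient_id,
    baseline = baseline, followup = followup,
    liver_baseline = liver_baseline, liver_followup = liver_followup,
    background_mean = background_mean, background_sd = background_sd
  ), class = "scan_pair")
}

#' @export
print.scan_pair <- function(x, ...) {
  cat(sprintf(
    "<scan_pair> patient %s: %d baseline / %d follow-up lesions (%d unmapped)\n",
    x$patient_id, nrow(x$baseline), nrow(x$followup),
    sum(is.na(x$followup$mapped_baseline_id))
  ))
  invisible(x)
}
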