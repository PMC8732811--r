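#' Worked-example scan pairs
#'
#' Two fully worked melanoma cases under checkpoint-inhibitor therapy,
#' encoded as lesion tables from their harmonized measurements:
#'
#' * `"nodal-regression"`: three pelvic/inguinal nodal metastases with
#'   near-complete resolution of uptake. The summed SUV_max falls 83.3%
#'   (PMR under EORTC), while every residual SUL_peak drops below the
#'   liver reference of 2.33 (CMR under PERCIST and imPERCIST).
#' * `"new-lesion"`: a regressing lung metastasis with a new subscapular
#'   muscle metastasis on follow-up. The new lesion forces PMD under EORTC
#'   and PERCIST; under imPERCIST it joins the SUL_peak sum, which rises
#'   44.7% (3.87 to 5.60), again PMD.
#'
#' @param case `"nodal-regression"` or `"new-lesion"`.
#' @return A [scan_pair()].
#' @export
example_scan_pair <- function(case = c("nodal-regression", "new-lesion")) {
  case <- match.arg(case)
  if (case == "nodal-regression") {
    base <- data.frame(
      lesion_id = c("common_iliac", "external_iliac", "inguinal"),
      organ = c("iliac_node_common", "iliac_node_external", "inguinal_node"),
      suv_max = c(14.67, 13.09, 16.19),
      suv_mean = c(9.32, 9.21, 10.09),
      suv_peak = c(12.15, 11.86, 14.62),
      sul_peak = c(9.60, 9.37, 11.55),
      mtv_ml = c(24.15, 24.15, 24.16),
      tlg = c(238.17, 238.17, 238.17),
      stringsAsFactors = FALSE
    )
    fu <- data.frame(
      lesion_id = c("common_iliac_fu", "external_iliac_fu", "inguinal_fu"),
      mapped_baseline_id = c("common_iliac", "external_iliac", "inguinal"),
      organ = c("iliac_node_common", "iliac_node_external", "inguinal_node"),
      suv_max = c(3.26, 1.97, 2.13),
      suv_mean = c(1.65, 1.43, 1.51),
      suv_peak = c(2.48, 1.97, 2.11),
      sul_peak = c(1.96, 1.62, 1.67),
      mtv_ml = c(6.45, 6.45, 6.45),
      tlg = c(10.19, 10.19, 10.20),
      stringsAsFactors = FALSE
    )
    # follow-up liver SUL mean + 2 SD = 2.33
    return(scan_pair("case_nodal", base, fu,
                     liver_followup = liver_reference_values(2.13, 0.10),
                     background_mean = 1.0, background_sd = 0.1))
  }
  base <- data.frame(
    lesion_id = "lung",
    organ = "lung",
    suv_max = 6.85, suv_mean = 4.50, suv_peak = 4.90, sul_peak = 3.87,
    mtv_ml = 2.22, tlg = 10.01,
    stringsAsFactors = FALSE
  )
  fu <- data.frame(
    lesion_id = c("lung_fu", "subscapular"),
    mapped_baseline_id = c("lung", NA_character_),
    organ = c("lung", "subscapular_muscle"),
    suv_max = c(4.21, 5.53),
    suv_mean = c(3.08, 3.81),
    suv_peak = c(3.09, 4.00),
    sul_peak = c(2.44, 3.16),
    mtv_ml = c(2.50, 3.10),
    tlg = c(7.70, 11.46),
    stringsAsFactors = FALSE
  )
  scan_pair("case_new_lesion", base, fu,
            liver_followup = liver_reference_values(1.80, 0.15),
            background_mean = 1.0, background_sd = 0.1)
}

#' Reference concordance tables from a 27-patient melanoma cohort
#'
#' The three pairwise 4x4 cross-classifications (CMR/PMR/SMD/PMD) observed
#' in a 27-patient multicenter melanoma cohort assessed under harmonized
#' EORTC, PERCIST and imPERCIST. These are the worked-example inputs for
#' [cohen_kappa()] and [percent_agreement()].
#'
#' @return Named list of three `confusion_matrix` objects:
#'   `percist_vs_eortc`, `eortc_vs_impercist`, `percist_vs_impercist`.
#' @export
reference_concordance_tables <- function() {
  list(
    percist_vs_eortc = as_confusion(matrix(c(
      3, 1, 0, 0,
      0, 4, 1, 0,
      0, 0, 3, 0,
      0, 0, 0, 15), 4, 4, byrow = TRUE),
      row_criterion = "PERCIST", col_criterion = "EORTC"),
    eortc_vs_impercist = as_confusion(matrix(c(
      3, 0, 0, 0,
      1, 4, 0, 0,
      0, 1, 3, 0,
      0, 0, 2, 13), 4, 4, byrow = TRUE),
      row_criterion = "EORTC", col_criterion = "imPERCIST"),
    percist_vs_impercist = as_confusion(matrix(c(
      4, 0, 0, 0,
      0, 5, 0, 0,
      0, 0, 3, 0,
      0, 0, 2, 13), 4, 4, byrow = TRUE),
      row_criterion = "PERCIST", col_criterion = "imPERCIST")
  )
}
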