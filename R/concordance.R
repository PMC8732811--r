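#' Cross-classification of two criteria
#'
#' 4x4 confusion matrix of response categories (rows: criterion A, columns:
#' criterion B), category order CMR, PMR, SMD, PMD.
#'
#' @param a,b vectors (character or factor) of categories over the same
#'   patients, in the same order, or two columns of [classify_cohort()]
#'   output.
#' @param row_criterion,col_criterion labels for reporting.
#' @return 4x4 integer matrix with dimnames, class `confusion_matrix`.
#' @export
build_confusion <- function(a, b, row_criterion = "A", col_criterion = "B") {
  if (length(a) != length(b))
    stop("assessment vectors differ in length")
  a <- factor(as.character(a), levels = RESPONSE_LEVELS)
  b <- factor(as.character(b), levels = RESPONSE_LEVELS)
  if (anyNA(a) || anyNA(b))
    stop("categories must be one of ", paste(RESPONSE_LEVELS, collapse = "/"))
  m <- table(a, b)
  m <- matrix(as.integer(m), 4, 4,
              dimnames = list(RESPONSE_LEVELS, RESPONSE_LEVELS))
  structure(m, row_criterion = row_criterion, col_criterion = col_criterion,
            class = c("confusion_matrix", "matrix"))
}

#' Treat an existing 4x4 count matrix as a confusion matrix
#'
#' @param counts 4x4 non-negative integer matrix, category order
#'   CMR/PMR/SMD/PMD in both dimensions.
#' @inheritParams build_confusion
#' @return A `confusion_matrix`.
#' @export
as_confusion <- function(counts, row_criterion = "A", col_criterion = "B") {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(4L, 4L)) || any(counts < 0))
    stop("`counts` must be a non-negative 4x4 matrix")
  m <- matrix(as.numeric(counts), 4, 4,
              dimnames = list(RESPONSE_LEVELS, RESPONSE_LEVELS))
  structure(m, row_criterion = row_criterion, col_criterion = col_criterion,
            class = c("confusion_matrix", "matrix"))
}

#' Weighted Cohen's kappa for ordinal agreement
#'
#' Chance-corrected agreement between two raters over the four ordinal
#' response categories. With weights
#' `w_ij = 1 - (|i - j| / 3)^q` (q = 1 linear, q = 2 quadratic; identity
#' weights for `"none"`), the observed and expected weighted agreements are
#' `po = sum(n_ij w_ij) / N` and `pe = sum(r_i c_j w_ij) / N^2`, and
#' `kappa = (po - pe) / (1 - pe)`. Quadratic weights are the package
#' default: disagreements are penalized by squared ordinal distance, which
#' is the convention under which published response-criteria concordances
#' in this setting reproduce.
#'
#' @param cm a `confusion_matrix` (or plain 4x4 matrix).
#' @param weighting `"quadratic"` (default), `"linear"`, or `"none"`.
#' @return List of class `kappa_result`: `kappa`, `weighting`,
#'   `observed_agreement_weighted`, `expected_agreement_weighted`, `label`.
#' @export
cohen_kappa <- function(cm, weighting = c("quadratic", "linear", "none")) {
  weighting <- match.arg(weighting)
  m <- unclass(as.matrix(cm))
  k <- nrow(m)
  n <- sum(m)
  if (n <= 0) stop("confusion matrix is empty")
  d <- abs(outer(seq_len(k), seq_len(k), "-"))
  w <- switch(weighting,
    none = (d == 0) * 1,
    linear = 1 - d / (k - 1),
    quadratic = 1 - (d / (k - 1))^2
  )
  po <- sum(m * w) / n
  pe <- sum(outer(rowSums(m), colSums(m)) * w) / n^2
  if (1 - pe <= .Machine$double.eps)
    stop("degenerate margins: expected agreement is 1, kappa undefined")
  kap <- (po - pe) / (1 - pe)
  structure(list(
    kappa = kap, weighting = weighting,
    observed_agreement_weighted = po,
    expected_agreement_weighted = pe,
    label = agreement_label(kap)
  ), class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa (%s weights): %.3f [%s]\n",
              x$weighting, x$kappa, x$label))
  invisible(x)
}

#' Percent agreement of a confusion matrix
#'
#' `100 * trace / total`: the share of patients classified identically by
#' both criteria.
#'
#' @param cm a `confusion_matrix`.
#' @return Percentage on the 0-100 scale.
#' @export
percent_agreement <- function(cm) {
  m <- unclass(as.matrix(cm))
  n <- sum(m)
  if (n <= 0) stop("confusion matrix is empty")
  100 * sum(diag(m)) / n
}

#' Verbal agreement band for a kappa value
#'
#' Standard bands: slight (< 0.21), fair (0.21-0.40), moderate (0.41-0.60),
#' substantial (0.61-0.80), nearly perfect (> 0.80). Because the bands are
#' printed to two decimals, kappa is rounded half-up to two decimals before
#' banding, so e.g. 0.205 falls in "fair".
#'
#' @param kappa numeric in `[-1, 1]`.
#' @return Character label.
#' @export
agreement_label <- function(kappa) {
  if (!is.numeric(kappa) || is.na(kappa) || kappa < -1 || kappa > 1)
    stop("`kappa` must lie in [-1, 1]")
  kr <- floor(kappa * 100 + 0.5) / 100  # half-up to 2 d.p.
  if (kr > 0.80) "nearly perfect"
  else if (kr >= 0.61) "substantial"
  else if (kr >= 0.41) "moderate"
  else if (kr >= 0.21) "fair"
  else "slight"
}

#' Pairwise concordance summary for a classified cohort
#'
#' Builds the three pairwise confusion matrices (EORTC vs PERCIST, EORTC vs
#' imPERCIST, PERCIST vs imPERCIST) with weighted kappa and percent
#' agreement for each.
#'
#' @param classified output of [classify_cohort()].
#' @param weighting kappa weighting, see [cohen_kappa()].
#' @return Named list of three elements, each with `confusion`, `kappa`,
#'   `percent_agreement`.
#' @export
concordance_summary <- function(classified, weighting = "quadratic") {
  pairs <- list(
    eortc_vs_percist = c("eortc", "percist"),
    eortc_vs_impercist = c("eortc", "impercist"),
    percist_vs_impercist = c("percist", "impercist")
  )
  lapply(pairs, function(p) {
    cm <- build_confusion(classified[[p[1]]], classified[[p[2]]],
                          row_criterion = toupper(p[1]),
                          col_criterion = toupper(p[2]))
    list(confusion = cm,
         kappa = cohen_kappa(cm, weighting),
         percent_agreement = percent_agreement(cm))
  })
}
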