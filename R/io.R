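#' Lesion-table serialization
#'
#' The lesion table is the package's delimited exchange format: one CSV row
#' per lesion per time point, with scan-level context (liver reference,
#' background) repeated on each row. Columns:
#' `patient_id, timepoint (baseline|followup), lesion_id,
#' mapped_baseline_id (empty for baseline rows and new lesions), organ,
#' suv_max, suv_mean, suv_peak, sul_peak, mtv_ml, tlg, is_new (0/1),
#' liver_sul_mean, liver_sul_sd, background_mean, background_sd`.
#'
#' @name lesion_table
NULL

lesion_table_columns <- c(
  "patient_id", "timepoint", "lesion_id", "mapped_baseline_id", "organ",
  "suv_max", "suv_mean", "suv_peak", "sul_peak", "mtv_ml", "tlg", "is_new",
  "liver_sul_mean", "liver_sul_sd", "background_mean", "background_sd"
)

empty_lesion_table <- function() {
  out <- data.frame(matrix(nrow = 0, ncol = length(lesion_table_columns)))
  names(out) <- lesion_table_columns
  for (col in c("patient_id", "timepoint", "lesion_id", "mapped_baseline_id",
                "organ"))
    out[[col]] <- character(0)
  for (col in setdiff(lesion_table_columns, names(out)[1:5]))
    out[[col]] <- numeric(0)
  out
}

#' Flatten scan pairs into a long lesion table
#'
#' @param pairs list of [scan_pair()]s.
#' @return data.frame in the [lesion_table] schema.
#' @export
pairs_to_table <- function(pairs) {
  if (!length(pairs)) return(empty_lesion_table())
  rows <- lapply(pairs, function(p) {
    ctx <- data.frame(
      liver_sul_mean = p$liver_followup$sul_mean,
      liver_sul_sd = p$liver_followup$sul_sd,
      background_mean = p$background_mean,
      background_sd = p$background_sd
    )
    metric_cols <- c("suv_max", "suv_mean", "suv_peak", "sul_peak",
                     "mtv_ml", "tlg")
    take <- function(fr, col) if (col %in% names(fr)) fr[[col]]
      else rep(NA_real_, nrow(fr))
    mk <- function(fr, tp) {
      if (!nrow(fr)) return(NULL)
      out <- data.frame(
        patient_id = p$patient_id, timepoint = tp,
        lesion_id = fr$lesion_id,
        mapped_baseline_id = if (tp == "followup")
          fr$mapped_baseline_id else NA_character_,
        organ = fr$organ, stringsAsFactors = FALSE
      )
      for (col in metric_cols) out[[col]] <- take(fr, col)
      out$is_new <- if (tp == "followup")
        as.integer(is.na(fr$mapped_baseline_id)) else 0L
      cbind(out, ctx[rep(1, nrow(fr)), , drop = FALSE])
    }
    rbind(mk(p$baseline, "baseline"), mk(p$followup, "followup"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[lesion_table_columns]
}

#' Write a lesion table to CSV
#'
#' @param table a lesion table (or a list of [scan_pair()]s).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lesion_table <- function(table, path) {
  if (is.list(table) && !is.data.frame(table)) table <- pairs_to_table(table)
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and validate a lesion table
#'
#' Parses the [lesion_table] CSV into validated [scan_pair()]s. All
#' validation failures cite the offending data row number(s).
#'
#' @param path CSV file path.
#' @return List of [scan_pair()]s, one per patient.
#' @export
read_lesion_table <- function(path) {
  if (!file.exists(path)) stop("no such lesion table: ", path)
  header <- names(utils::read.csv(path, nrows = 0))
  missing_cols <- setdiff(lesion_table_columns, header)
  if (length(missing_cols))
    stop("lesion table lacks column(s): ", paste(missing_cols, collapse = ", "))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(mapped_baseline_id = "character",
                                        lesion_id = "character",
                                        patient_id = "character"))
  table_to_pairs(tab)
}

#' Convert a long lesion table into scan pairs
#'
#' @param tab data.frame in the [lesion_table] schema.
#' @return List of [scan_pair()]s.
#' @export
table_to_pairs <- function(tab) {
  if (!nrow(tab)) return(list())
  tab$mapped_baseline_id[!is.na(tab$mapped_baseline_id) &
                           tab$mapped_baseline_id == ""] <- NA_character_
  rowno <- seq_len(nrow(tab))
  bad_tp <- rowno[!tab$timepoint %in% c("baseline", "followup")]
  if (length(bad_tp))
    stop("invalid timepoint in row(s) ", paste(bad_tp, collapse = ", "))
  num <- c("suv_max", "suv_mean", "suv_peak", "sul_peak", "mtv_ml", "tlg")
  for (col in num) {
    bad <- rowno[!is.na(tab[[col]]) & tab[[col]] < 0]
    if (length(bad))
      stop("negative ", col, " in row(s) ", paste(bad, collapse = ", "))
  }
  bad_peak <- rowno[!is.na(tab$suv_peak) & !is.na(tab$suv_max) &
                      tab$suv_peak > tab$suv_max + 1e-9]
  if (length(bad_peak))
    stop("suv_peak exceeds suv_max in row(s) ",
         paste(bad_peak, collapse = ", "))
  key <- paste(tab$patient_id, tab$timepoint, tab$lesion_id)
  if (anyDuplicated(key))
    stop("duplicate (patient, timepoint, lesion) in row(s) ",
         paste(rowno[duplicated(key)], collapse = ", "))
  bad_map <- rowno[tab$timepoint == "followup" & tab$is_new == 1 &
                     !is.na(tab$mapped_baseline_id)]
  if (length(bad_map))
    stop("new lesions must not carry a mapped_baseline_id: row(s) ",
         paste(bad_map, collapse = ", "))
  lapply(split(tab, tab$patient_id)[unique(tab$patient_id)], function(sub) {
    b <- sub[sub$timepoint == "baseline",
             c("lesion_id", "organ", num)]
    f <- sub[sub$timepoint == "followup",
             c("lesion_id", "mapped_baseline_id", "organ", num)]
    scan_pair(
      sub$patient_id[1], b, f,
      liver_followup = liver_reference_values(sub$liver_sul_mean[1],
                                              sub$liver_sul_sd[1]),
      background_mean = sub$background_mean[1],
      background_sd = sub$background_sd[1]
    )
  })
}
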