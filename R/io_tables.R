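LABEL_METHODS <- c("radio-GC", "radio-HPLC", "TLC", "HPLC-MS/MS", "unknown")

#' Read a labeled trans-prenyltransferase dataset
#'
#' The table is TSV with a header. Required columns are `id` and `label`, plus
#' either an inline `sequence` column or a `fasta` argument naming a FASTA file
#' in which every `id` can be found. Optional columns: `label_secondary` (a
#' second experimental outcome), `kingdom`, `phylum`, `method` (detection
#' method, one of radio-GC, radio-HPLC, TLC, HPLC-MS/MS, unknown).
#'
#' Labels are normalized with [parse_product_class()]; `"NA"` means no
#' activity was detected. A label such as `"C20/C25"` is split into `label`
#' (shorter class) and `label_secondary`. Rows whose label cannot be parsed
#' are rejected with their row numbers.
#'
#' @param path path to the TSV file.
#' @param fasta optional FASTA path supplying sequences by id.
#' @return a `labeled_dataset` data frame with columns `id`, `residues`,
#'   `label`, `label_secondary`, `kingdom`, `phylum`, `method`.
#' @export
read_labeled_dataset <- function(path, fasta = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("id", "label")
  if (is.null(fasta)) required <- c(required, "sequence")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0)
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  if (nrow(tab) == 0) stop("dataset has no rows: ", path)

  if (!is.null(fasta)) {
    seqs <- read_fasta(fasta)
    idx <- match(tab$id, seqs$id)
    if (anyNA(idx))
      stop("ids not found in FASTA: ",
           paste(tab$id[is.na(idx)], collapse = ", "))
    residues <- seqs$residues[idx]
  } else {
    residues <- toupper(tab$sequence)
  }

  raw <- as.character(tab$label)
  label <- parse_product_class(raw)
  if (anyNA(label))
    stop("unparseable label(s) at row(s) ",
         paste(which(is.na(label)), collapse = ", "), ": ",
         paste(unique(raw[is.na(label)]), collapse = ", "))
  secondary <- rep(NA_character_, nrow(tab))
  dual <- grepl("/", raw, fixed = TRUE)
  if (any(dual))
    secondary[dual] <- parse_product_class(sub("^[^/]*/", "", raw[dual]))
  if ("label_secondary" %in% names(tab)) {
    given <- parse_product_class(tab$label_secondary)
    secondary[!is.na(given)] <- given[!is.na(given)]
  }

  method <- if ("method" %in% names(tab)) as.character(tab$method)
            else rep("unknown", nrow(tab))
  method[is.na(method) | !method %in% LABEL_METHODS] <- "unknown"

  out <- protein_set(
    id = tab$id, residues = residues,
    kingdom = if ("kingdom" %in% names(tab)) tab$kingdom else NA_character_,
    phylum = if ("phylum" %in% names(tab)) tab$phylum else NA_character_
  )
  out$label <- label
  out$label_secondary <- secondary
  out$method <- method
  class(out) <- c("labeled_dataset", "protein_set", "data.frame")
  out
}

#' Write a labeled dataset to TSV
#'
#' @param dataset a `labeled_dataset` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labeled_dataset <- function(dataset, path) {
  stopifnot(all(c("id", "residues", "label") %in% names(dataset)))
  tab <- data.frame(
    id = dataset$id,
    sequence = dataset$residues,
    label = dataset$label,
    label_secondary = if ("label_secondary" %in% names(dataset))
      dataset$label_secondary else NA_character_,
    kingdom = if ("kingdom" %in% names(dataset)) dataset$kingdom else NA_character_,
    phylum = if ("phylum" %in% names(dataset)) dataset$phylum else NA_character_,
    method = if ("method" %in% names(dataset)) dataset$method else "unknown",
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

REPORT_COLUMNS <- c(
  "query_id", "best_template", "identity_pct",
  "f1_s1", "f1_s2", "f1_s3", "f2_s1", "f2_s2", "f2_s3",
  "f3_s1", "f3_s2", "f3_s3",
  "score_f1", "score_f2", "score_f3",
  "predicted", "primary", "secondary", "flags")

#' Write a prediction report to TSV
#'
#' One row per query, fixed column order: `query_id`, `best_template`,
#' `identity_pct` (percent, full precision), the nine floor residues
#' (`f1_s1` ... `f3_s3`, `-` marking an alignment gap), the three floor
#' blocking scores, `predicted` (rendered call, dual calls as `"C20/C25"`),
#' `primary` and `secondary` class tokens, and semicolon-separated
#' `flags` (`gap_at_floor`, `low_identity`, `ambiguous`).
#'
#' @param rows a `prediction_report` data frame, e.g. from [predict_batch()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_prediction_report <- function(rows, path) {
  missing <- setdiff(REPORT_COLUMNS, names(rows))
  if (length(missing) > 0)
    stop("report rows missing column(s): ", paste(missing, collapse = ", "))
  tab <- as.data.frame(rows)[, REPORT_COLUMNS, drop = FALSE]
  for (col in c("identity_pct", "score_f1", "score_f2", "score_f3"))
    tab[[col]] <- sprintf("%.17g", tab[[col]])
  con <- file(path, open = "wt")
  on.exit(close(con))
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a prediction report written by [write_prediction_report()]
#'
#' @param path path to the TSV report.
#' @return a `prediction_report` data frame.
#' @export
read_prediction_report <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", na.strings = "NA")
  missing <- setdiff(REPORT_COLUMNS, names(tab))
  if (length(missing) > 0)
    stop("not a prediction report, missing column(s): ",
         paste(missing, collapse = ", "))
  for (col in c("identity_pct", "score_f1", "score_f2", "score_f3"))
    tab[[col]] <- as.numeric(tab[[col]])
  tab$flags[is.na(tab$flags)] <- ""
  class(tab) <- c("prediction_report", "data.frame")
  tab
}
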