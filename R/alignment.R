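#' Alignment parameters
#'
#' Global (Needleman–Wunsch) alignment with affine gap penalties. The default
#' scheme is BLOSUM62 with gap-open 11 and gap-extend 1, the most common
#' protein defaults; the bundled template floor annotations are calibrated
#' under this scheme. A gap of length L costs `gap_open + L * gap_extend`.
#'
#' @param matrix a substitution-matrix name bundled with Biostrings
#'   (`"BLOSUM45"`, `"BLOSUM50"`, `"BLOSUM62"`, `"BLOSUM80"`, `"BLOSUM100"`,
#'   `"PAM30"`, `"PAM40"`, `"PAM70"`, `"PAM120"`, `"PAM250"`), a path to an
#'   NCBI-format matrix text file, or a numeric matrix.
#' @param gap_open gap opening penalty, positive score units.
#' @param gap_extend gap extension penalty per gap position, positive;
#'   must not exceed `gap_open`.
#' @return an `alignment_params` object.
#' @export
alignment_params <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  if (!(gap_open >= gap_extend && gap_extend > 0))
    stop("require gap_open >= gap_extend > 0")
  if (is.character(matrix) && length(matrix) == 1) {
    name <- matrix
    if (file.exists(matrix)) {
      mat <- as.matrix(utils::read.table(matrix, header = TRUE,
                                         check.names = FALSE, row.names = 1))
      name <- basename(matrix)
    } else {
      mat <- load_biostrings_matrix(matrix)
    }
  } else if (is.matrix(matrix)) {
    mat <- matrix
    name <- "custom"
  } else stop("matrix must be a name, file path, or numeric matrix")
  if (!identical(rownames(mat), colnames(mat)))
    stop("substitution matrix must have matching row and column names")
  out <- list(matrix_name = name, matrix = mat,
              gap_open = gap_open, gap_extend = gap_extend)
  class(out) <- "alignment_params"
  out
}

load_biostrings_matrix <- function(name) {
  known <- c("BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80", "BLOSUM100",
             "PAM30", "PAM40", "PAM70", "PAM120", "PAM250")
  if (!name %in% known)
    stop("unknown substitution matrix '", name, "'; known: ",
         paste(known, collapse = ", "))
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  get(name, envir = env)
}

#' Optimal global pairwise alignment
#'
#' Thin wrapper around [Biostrings::pairwiseAlignment()] (global mode) that
#' returns the two aligned rows, the score, the percent identity over
#' both-non-gap columns, and, for each subject position, the alignment column
#' it occupies — the map used to project template floor positions onto a
#' query.
#'
#' @param query,subject sequences: single-row `protein_set` data frames or
#'   plain residue strings.
#' @param params an [alignment_params()] object.
#' @return a `pairwise_alignment` list with elements `query_row`,
#'   `subject_row`, `score`, `identity`, `subject_cols`.
#' @export
global_align <- function(query, subject, params = alignment_params()) {
  q <- one_sequence(query)
  s <- one_sequence(subject)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(q), Biostrings::AAString(s),
    substitutionMatrix = params$matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    type = "global")
  qrow <- as.character(Biostrings::alignedPattern(aln))
  srow <- as.character(Biostrings::alignedSubject(aln))
  build_alignment(qrow, srow, Biostrings::score(aln))
}

one_sequence <- function(x) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1) stop("expected exactly one sequence, got ", nrow(x))
    x <- x$residues
  }
  x <- toupper(as.character(x))
  if (!nzchar(x)) stop("empty sequence")
  chars <- strsplit(x, "")[[1]]
  if (!any(chars %in% AA20))
    stop("sequence contains no scorable residues")
  x
}

build_alignment <- function(qrow, srow, score) {
  if (nchar(qrow) != nchar(srow)) stop("alignment rows differ in length")
  qc <- strsplit(qrow, "")[[1]]
  sc <- strsplit(srow, "")[[1]]
  both_gap <- qc == "-" & sc == "-"
  if (any(both_gap)) stop("alignment has a column gapped in both rows")
  aligned <- qc != "-" & sc != "-"
  if (!any(aligned)) stop("alignment has no both-non-gap columns")
  out <- list(
    query_row = qrow, subject_row = srow, score = score,
    identity = sum(qc == sc & aligned) / sum(aligned),
    subject_cols = which(sc != "-"))
  class(out) <- "pairwise_alignment"
  out
}

#' Percent identity of an alignment
#'
#' Identical residue pairs divided by the number of columns in which both rows
#' carry a residue. Terminal overhangs between full-length and truncated
#' sequences therefore do not dilute the identity.
#'
#' @param alignment a `pairwise_alignment` object.
#' @return a fraction in \[0, 1\].
#' @export
percent_identity <- function(alignment) {
  stopifnot(inherits(alignment, "pairwise_alignment"))
  alignment$identity
}

#' Select the best-matching template for a query
#'
#' Aligns the query against every template in the registry (independent
#' pairwise global alignments) and returns the template with the highest
#' percent identity. Ties go to the earlier template in registry order, for
#' determinism. All identities are retained for reporting.
#'
#' @param query a single sequence (see [global_align()]).
#' @param registry a [template_registry()].
#' @param params an [alignment_params()] object.
#' @return a `template_match` list: `template_id`, `alignment`, `identity`,
#'   and the named vector `all_identities`.
#' @export
select_best_template <- function(query, registry = default_registry(),
                                 params = alignment_params()) {
  stopifnot(inherits(registry, "template_registry"))
  if (length(registry$templates) == 0) stop("empty template registry")
  alignments <- lapply(registry$templates, function(tpl)
    global_align(query, tpl$sequence, params))
  identities <- vapply(alignments, percent_identity, numeric(1))
  names(identities) <- names(registry$templates)
  best <- which.max(identities)  # first maximum = earliest in registry order
  out <- list(template_id = names(registry$templates)[best],
              alignment = alignments[[best]],
              identity = identities[[best]],
              all_identities = identities)
  class(out) <- "template_match"
  out
}
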