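AA3_TO_1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
              Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
              Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
              Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")

#' Construct a floor assignment directly
#'
#' A floor assignment records, for each of the nine floor sites (three floors,
#' top to bottom, times three sites), the query residue occupying the site, or
#' a gap marker where the alignment places no query residue there. Normally it
#' is produced by [map_floor_residues()]; this constructor builds one by hand,
#' e.g. to score floor residues printed in the literature without the full
#' sequence.
#'
#' @param residues 3x3 matrix (rows = floors) or length-9 row-major vector of
#'   residues, as one-letter or three-letter codes; `NA` or `"-"` marks a gap.
#' @param query_pos optional matching 1-based query positions.
#' @param template_id,identity optional provenance.
#' @return a `floor_assignment` data frame with columns `floor`, `site`,
#'   `residue`, `query_pos`.
#' @export
floor_assignment <- function(residues, query_pos = NULL,
                             template_id = NA_character_, identity = NA_real_) {
  res <- if (is.matrix(residues)) as.vector(t(residues)) else as.character(residues)
  if (length(res) != 9) stop("need 9 floor-site residues (3 floors x 3 sites)")
  res[res %in% c("-", "")] <- NA_character_
  three <- !is.na(res) & nchar(res) == 3
  res[three] <- AA3_TO_1[vapply(res[three], function(x)
    paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, 3))), character(1))]
  res[!is.na(res)] <- toupper(res[!is.na(res)])
  bad <- !is.na(res) & !res %in% AA20
  if (any(bad)) {
    if (any(res[bad] == "X", na.rm = TRUE))
      stop("unscorable residue 'X' at a floor site")
    stop("unrecognized floor residue: ", paste(res[bad], collapse = ", "))
  }
  if (is.null(query_pos)) query_pos <- rep(NA_integer_, 9)
  out <- data.frame(floor = rep(1:3, each = 3), site = rep(1:3, times = 3),
                    residue = res, query_pos = as.integer(query_pos),
                    stringsAsFactors = FALSE)
  attr(out, "template_id") <- template_id
  attr(out, "identity") <- identity
  class(out) <- c("floor_assignment", "data.frame")
  out
}

#' Project template floor positions onto a query
#'
#' For each annotated floor position of the template, looks up the alignment
#' column that position occupies and returns the query residue found there, or
#' a gap marker if the query row is gapped in that column. A gap at a floor
#' site later scores as zero blocking and flags the prediction low-confidence:
#' a missing side chain cannot block the tunnel, and silent failure would hide
#' alignment problems. A query `X` at a floor site is an error — an unknown
#' residue cannot be scored.
#'
#' @param match a `template_match` from [select_best_template()], or any
#'   `pairwise_alignment` against the template's sequence.
#' @param template the [template()] carrying the floor annotations; defaults
#'   to the matched template looked up in `registry`.
#' @param registry registry used to resolve the matched template.
#' @return a `floor_assignment` (see [floor_assignment()]).
#' @export
map_floor_residues <- function(match, template = NULL,
                               registry = default_registry()) {
  if (inherits(match, "template_match")) {
    if (is.null(template)) template <- registry$templates[[match$template_id]]
    aln <- match$alignment
    identity <- match$identity
  } else {
    aln <- match
    identity <- aln$identity
  }
  if (is.null(template)) stop("no template supplied or resolvable")
  stopifnot(inherits(aln, "pairwise_alignment"),
            inherits(template, "pt_template"))
  srow_nogap <- gsub("-", "", aln$subject_row, fixed = TRUE)
  if (srow_nogap != template$sequence)
    stop("alignment subject row does not match template ", template$pdb_id,
         " sequence; align against the template used for annotation")
  qc <- strsplit(aln$query_row, "")[[1]]
  qpos_at_col <- cumsum(qc != "-")  # query position at each alignment column

  pos_flat <- as.vector(t(template$floor_positions))
  residue <- character(9)
  query_pos <- integer(9)
  for (k in seq_len(9)) {
    col <- aln$subject_cols[pos_flat[k]]
    if (qc[col] == "-") {
      residue[k] <- NA_character_
      query_pos[k] <- NA_integer_
    } else {
      residue[k] <- qc[col]
      query_pos[k] <- qpos_at_col[col]
    }
  }
  if (any(residue == "X", na.rm = TRUE))
    stop("query has unscorable residue 'X' at floor site(s): ",
         paste(which(residue == "X"), collapse = ", "))
  floor_assignment(residue, query_pos = query_pos,
                   template_id = template$pdb_id, identity = identity)
}

# 3x3 residue matrix view of an assignment (rows = floors)
assignment_matrix <- function(assignment) {
  matrix(assignment$residue, nrow = 3, ncol = 3, byrow = TRUE,
         dimnames = list(paste0("floor", 1:3), paste0("site", 1:3)))
}
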