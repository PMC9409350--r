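AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# accepted residue alphabet for query/template sequences; X marks an unknown
# residue and is tolerated anywhere except at a floor site
AA_ACCEPTED <- c(AA20, "X")

#' Construct a protein sequence table
#'
#' The package represents sequence collections as plain data frames with
#' columns `id`, `residues`, `description`, and optional taxonomy columns
#' `kingdom`, `phylum`, `organism`.
#'
#' @param id accession-like identifiers, unique within the collection.
#' @param residues uppercase amino-acid strings over the 20 canonical
#'   one-letter codes plus `X`.
#' @param description free-text descriptions.
#' @param kingdom,phylum,organism optional taxonomy strings.
#' @return a `protein_set` data frame.
#' @export
protein_set <- function(id, residues, description = "",
                        kingdom = NA_character_, phylum = NA_character_,
                        organism = NA_character_) {
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  if (length(id) != length(residues))
    stop("id and residues must have the same length")
  if (anyDuplicated(id))
    stop("duplicate sequence id: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  for (i in seq_along(residues)) {
    if (!nzchar(residues[i]))
      stop("empty sequence for id ", id[i])
    chars <- strsplit(residues[i], "")[[1]]
    bad <- which(!chars %in% AA_ACCEPTED)
    if (length(bad) > 0)
      stop(sprintf("illegal residue character '%s' at position %d in sequence '%s'",
                   chars[bad[1]], bad[1], id[i]))
  }
  out <- data.frame(id = id, residues = residues,
                    description = rep_len(as.character(description), length(id)),
                    kingdom = rep_len(as.character(kingdom), length(id)),
                    phylum = rep_len(as.character(phylum), length(id)),
                    organism = rep_len(as.character(organism), length(id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("protein_set", "data.frame")
  out
}

#' Read protein sequences from a FASTA file
#'
#' Parsing is done by [Biostrings::readAAStringSet()]; headers are split at the
#' first whitespace into id and description, sequences are uppercased, wrapped
#' and unwrapped records are both accepted, and blank lines are ignored.
#' Trailing `*` stop characters are stripped with a warning. Residues are then
#' validated against the 20 canonical amino acids plus `X`; the first illegal
#' character is reported with its 1-based position.
#'
#' @param path path to a FASTA file.
#' @return a `protein_set` data frame (see [protein_set()]), in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty FASTA file: ", path)
  fasta_scan(path)  # Biostrings drops illegal codes silently; reject them first
  set <- tryCatch(
    Biostrings::readAAStringSet(path, format = "fasta"),
    error = function(e) fasta_scan(path, conditionMessage(e))
  )
  if (length(set) == 0) stop("no FASTA records in ", path)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  residues <- toupper(as.character(set))
  if (any(grepl("\\*", residues))) {
    warning("stripping '*' stop characters from ",
            sum(grepl("\\*", residues)), " sequence(s)")
    residues <- gsub("*", "", residues, fixed = TRUE)
  }
  protein_set(id = unname(id), residues = unname(residues),
              description = unname(description))
}

# Biostrings neither reports where an illegal character sits nor refuses it
# (invalid codes are silently dropped), so scan the raw text and point at the
# first offender. With `original` set, also fail on an unparseable file.
fasta_scan <- function(path, original = NULL) {
  lines <- readLines(path, warn = FALSE)
  current <- "<no header>"
  pos <- 0L
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      current <- sub("\\s.*$", "", substring(ln, 2))
      pos <- 0L
      next
    }
    chars <- strsplit(toupper(ln), "")[[1]]
    for (ch in chars) {
      if (ch %in% c(" ", "\t")) next
      pos <- pos + 1L
      if (!ch %in% c(AA_ACCEPTED, "*"))
        stop(sprintf("illegal residue character '%s' at position %d in sequence '%s'",
                     ch, pos, current))
    }
  }
  if (!is.null(original))
    stop("malformed FASTA file ", path, ": ", original)
  invisible(TRUE)
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs a `protein_set` data frame.
#' @param path output path.
#' @param width line-wrap width in residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.data.frame(seqs), all(c("id", "residues") %in% names(seqs)))
  set <- Biostrings::AAStringSet(seqs$residues)
  names(set) <- ifelse(nzchar(seqs$description) & !is.na(seqs$description),
                       paste(seqs$id, seqs$description), seqs$id)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}
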