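KINGDOMS <- c("Archaea", "Bacteria", "Eukarya")

# fixed registry order of the eleven searching templates
TEMPLATE_ORDER <- c("2FOR", "3OYR", "3QQV", "3PKO", "1WMW", "3Q2Q",
                    "5E8H", "2E8W", "1FPS", "3AQ0", "1WY0")

#' Construct a searching template
#'
#' A template is a reference trans-prenyltransferase with a known structure:
#' its chain sequence, the nine annotated floor-site positions (three floors,
#' top to bottom, times three sites — one residue from each of the
#' tunnel-lining helices D, E and F), its native product class, and its
#' kingdom of origin.
#'
#' @param pdb_id 4-character PDB identifier.
#' @param sequence residue string.
#' @param floor_positions 3x3 integer matrix (rows = floors 1..3, columns =
#'   sites 1..3) of 1-based positions into `sequence`, or a length-9 vector in
#'   row-major floor order.
#' @param product_class native product class, one of C15, C20, C25, GE_C30.
#' @param kingdom one of Archaea, Bacteria, Eukarya.
#' @return a `pt_template` object.
#' @export
template <- function(pdb_id, sequence, floor_positions, product_class, kingdom) {
  pdb_id <- toupper(as.character(pdb_id))
  if (nchar(pdb_id) != 4)
    stop("pdb_id must be a 4-character string, got '", pdb_id, "'")
  sequence <- one_sequence(sequence)
  if (is.matrix(floor_positions)) {
    if (!all(dim(floor_positions) == c(3, 3)))
      stop("template ", pdb_id, ": floor_positions matrix must be 3x3")
    flat <- as.integer(t(floor_positions))  # row-major: floors then sites
  } else {
    if (length(floor_positions) != 9)
      stop("template ", pdb_id, ": need 9 floor positions")
    flat <- as.integer(floor_positions)
  }
  pos <- matrix(flat, nrow = 3, ncol = 3, byrow = TRUE,
                dimnames = list(paste0("floor", 1:3), paste0("site", 1:3)))
  if (anyNA(pos) || length(unique(as.vector(pos))) != 9)
    stop("template ", pdb_id, ": floor positions must be 9 distinct values")
  if (any(pos < 1) || any(pos > nchar(sequence)))
    stop("template ", pdb_id, ": floor position outside sequence (length ",
         nchar(sequence), ")")
  if (!product_class %in% predictable_classes())
    stop("template ", pdb_id, ": product class must be one of ",
         paste(predictable_classes(), collapse = ", "))
  if (!kingdom %in% KINGDOMS)
    stop("template ", pdb_id, ": kingdom must be one of ",
         paste(KINGDOMS, collapse = ", "))
  out <- list(pdb_id = pdb_id, sequence = sequence, floor_positions = pos,
              product_class = product_class, kingdom = kingdom)
  class(out) <- "pt_template"
  out
}

#' Construct a template registry
#'
#' An ordered collection of templates keyed by PDB id. The shipped default
#' registry (see [default_registry()]) holds the eleven searching templates in
#' the fixed order 2FOR, 3OYR, 3QQV, 3PKO, 1WMW, 3Q2Q, 5E8H, 2E8W, 1FPS,
#' 3AQ0, 1WY0.
#'
#' @param templates a list of [template()] objects.
#' @param tag a registry version tag recorded in models and reports.
#' @return a `template_registry` object.
#' @export
template_registry <- function(templates, tag = "user-registry") {
  stopifnot(is.list(templates),
            all(vapply(templates, inherits, logical(1), "pt_template")))
  ids <- vapply(templates, function(t) t$pdb_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate pdb id in registry: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(templates) <- ids
  out <- list(templates = templates, tag = tag)
  class(out) <- "template_registry"
  out
}

#' @export
print.template_registry <- function(x, ...) {
  cat("Template registry [", x$tag, "]: ", length(x$templates),
      " templates\n", sep = "")
  for (t in x$templates)
    cat(sprintf("  %s  %-8s %-6s length %d\n", t$pdb_id, t$kingdom,
                format_product_class(t$product_class), nchar(t$sequence)))
  invisible(x)
}

#' Read a template registry from its structured-text file
#'
#' One template per row; TSV columns `pdb_id`, `kingdom`, `product_class`,
#' `f1_s1` ... `f3_s3` (the nine floor positions), `sequence`. The format
#' round-trips bit-exactly through [write_registry()].
#'
#' @param path path to the registry TSV.
#' @param tag registry version tag; defaults to the file name.
#' @return a `template_registry`.
#' @export
read_registry <- function(path, tag = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("pdb_id", "kingdom", "product_class",
              as.vector(outer(paste0("f", 1:3), paste0("_s", 1:3), paste0)),
              "sequence")
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0)
    stop("registry file missing column(s): ", paste(missing, collapse = ", "))
  poscols <- c("f1_s1", "f1_s2", "f1_s3", "f2_s1", "f2_s2", "f2_s3",
               "f3_s1", "f3_s2", "f3_s3")
  templates <- lapply(seq_len(nrow(tab)), function(i)
    template(pdb_id = tab$pdb_id[i], sequence = tab$sequence[i],
             floor_positions = as.integer(tab[i, poscols]),
             product_class = parse_product_class(tab$product_class[i]),
             kingdom = tab$kingdom[i]))
  template_registry(templates, tag = tag)
}

#' Write a template registry
#'
#' @param registry a `template_registry`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "template_registry"))
  rows <- lapply(registry$templates, function(t) {
    pos <- as.vector(t(t$floor_positions))
    data.frame(pdb_id = t$pdb_id, kingdom = t$kingdom,
               product_class = format_product_class(t$product_class),
               f1_s1 = pos[1], f1_s2 = pos[2], f1_s3 = pos[3],
               f2_s1 = pos[4], f2_s2 = pos[5], f2_s3 = pos[6],
               f3_s1 = pos[7], f3_s2 = pos[8], f3_s3 = pos[9],
               sequence = t$sequence, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.registry_cache <- new.env(parent = emptyenv())

#' The shipped default template registry
#'
#' Loads the bundled registry of the eleven searching templates. The bundled
#' sequences are a deterministic synthetic stand-in (see
#' [make_synthetic_registry()]): the true chains of the eleven PDB entries are
#' not redistributed with the package, so a reproducible surrogate family with
#' annotated floor sites and class-consistent floor residues is shipped
#' instead, and every calibration and test in the package is defined against
#' it.
#'
#' @return a `template_registry` of 11 templates in the fixed order.
#' @export
default_registry <- function() {
  if (!is.null(.registry_cache$default)) return(.registry_cache$default)
  path <- system.file("extdata", "synthetic_template_registry.tsv",
                      package = "threefloors", mustWork = TRUE)
  reg <- read_registry(path, tag = "synthetic-registry-v1")
  .registry_cache$default <- reg
  reg
}
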