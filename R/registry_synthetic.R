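SYNTH_REGISTRY_SPEC <- list(
  #          kingdom     class      sub_rate  ins  del
  `2FOR` = list("Bacteria", "C15",    0.30, 0L, 0L),
  `3OYR` = list("Bacteria", "C20",    0.28, 0L, 0L),
  `3QQV` = list("Bacteria", "GE_C30", 0.32, 0L, 0L),
  `3PKO` = list("Bacteria", "GE_C30", 0.35, 0L, 0L),
  `1WMW` = list("Bacteria", "C20",    0.30, 0L, 3L),
  `3Q2Q` = list("Bacteria", "C20",    0.33, 3L, 0L),
  `5E8H` = list("Eukarya",  "C20",    0.12, 0L, 0L),
  `2E8W` = list("Eukarya",  "C20",    0.22, 4L, 0L),
  `1FPS` = list("Eukarya",  "C15",    0.25, 0L, 4L),
  `3AQ0` = list("Eukarya",  "GE_C30", 0.15, 0L, 0L),
  `1WY0` = list("Archaea",  "C25",    0.38, 6L, 0L))

#' Build the synthetic template registry
#'
#' Deterministically regenerates the bundled synthetic stand-in for the
#' eleven searching templates. The true PDB chains are not redistributed with
#' the package; instead a surrogate enzyme family is derived from a common
#' 320-residue ancestor: each template receives seeded substitutions away
#' from the floor sites (12–38% divergence), a few templates receive a short
#' loop insertion or C-terminal truncation, and the nine floor residues are
#' then set from the bulky pool at the template's decisive floor and the
#' small pool elsewhere, so every template's native product class is
#' recoverable from its own floors.
#'
#' Floor sites sit on three tunnel-lining helix segments (the D, E and F
#' helix positions of the ancestor), one helical turn apart between floors:
#' floor f occupies ancestor positions `144+4f`, `178+4f` and `212+4f`.
#' Kingdom assignments follow the organisms of the eleven PDB entries; the
#' native classes are plausible synthetic assignments, not curated structure
#' annotations.
#'
#' The shipped file `inst/extdata/synthetic_template_registry.tsv` is frozen
#' output of this function; a package test asserts they stay equal.
#'
#' @param seed generator seed (the shipped registry uses the default).
#' @return a `template_registry` of the 11 templates in fixed order.
#' @export
make_synthetic_registry <- function(seed = 101) {
  with_seed(seed, {
    ancestor <- sample(AA20, 320, replace = TRUE)
    base_pos <- as.vector(vapply(1:3, function(f)
      c(144L, 178L, 212L) + 4L * f, integer(3)))  # row-major floors x sites
    templates <- lapply(TEMPLATE_ORDER, function(id) {
      spec <- SYNTH_REGISTRY_SPEC[[id]]
      kingdom <- spec[[1]]; class <- spec[[2]]
      rate <- spec[[3]]; ins <- spec[[4]]; del <- spec[[5]]
      chars <- ancestor
      mutable <- setdiff(seq_along(chars), base_pos)
      hit <- mutable[stats::runif(length(mutable)) < rate]
      for (p in hit) chars[p] <- sample(setdiff(AA20, chars[p]), 1)
      pos <- base_pos
      if (ins > 0) {  # loop insertion upstream of the tunnel helices
        chars <- append(chars, sample(AA20, ins, replace = TRUE), after = 60)
        pos <- pos + ins
      }
      if (del > 0)    # C-terminal truncation, downstream of all floors
        chars <- chars[seq_len(length(chars) - del)]
      decisive <- DECISIVE_FLOOR[[class]]
      pos_mat <- matrix(pos, nrow = 3, byrow = TRUE)
      for (f in 1:3) {
        pool <- if (!is.na(decisive) && f == decisive) BULKY_POOL else SMALL_POOL
        chars[pos_mat[f, ]] <- sample(pool, 3, replace = TRUE)
      }
      template(pdb_id = id, sequence = paste(chars, collapse = ""),
               floor_positions = pos_mat, product_class = class,
               kingdom = kingdom)
    })
    template_registry(templates, tag = "synthetic-registry-v1")
  })
}
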