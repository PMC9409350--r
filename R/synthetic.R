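BULKY_POOL <- c("W", "F", "Y", "L", "M")
SMALL_POOL <- c("G", "A", "S", "C", "T")

# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Configuration for the floor-variant generator
#'
#' @param backbone template id whose sequence the variants are built on.
#' @param quota named integer vector: number of variants per product class
#'   (names among C15, C20, C25, GE_C30).
#' @param seed random seed; recorded so runs are byte-identical.
#' @param background_rate per-residue substitution probability outside floor
#'   sites, in \[0, 0.2\].
#' @param bulky,small residue pools used at blocked and open floors. The
#'   defaults are the large-side-chain residues discussed as tunnel blockers
#'   and their small counterparts.
#' @return a `generator_config` object.
#' @export
generator_config <- function(backbone = "5E8H",
                             quota = c(C15 = 5, C20 = 5, C25 = 5, GE_C30 = 5),
                             seed = 1, background_rate = 0.02,
                             bulky = BULKY_POOL, small = SMALL_POOL) {
  if (!all(names(quota) %in% predictable_classes()))
    stop("quota names must be predictable classes")
  if (any(quota < 0) || sum(quota) < 1) stop("quota must request >= 1 variant")
  if (background_rate < 0 || background_rate > 0.2)
    stop("background_rate must be in [0, 0.2]")
  stopifnot(all(bulky %in% AA20), all(small %in% AA20))
  out <- list(backbone = backbone, quota = quota, seed = as.integer(seed),
              background_rate = background_rate, bulky = bulky, small = small)
  class(out) <- "generator_config"
  out
}

# decisive floor of each class: the floor whose blocking terminates the chain
DECISIVE_FLOOR <- c(C15 = 1L, C20 = 2L, C25 = 3L, GE_C30 = NA_integer_)

#' Generate labeled floor-site variants on a template backbone
#'
#' Emulates a site-directed mutagenesis series: for each requested class, the
#' decisive floor's three sites are substituted from the bulky pool and every
#' other floor from the small pool (an open tunnel, GE_C30, is small
#' everywhere), then background substitutions are applied outside floor sites
#' at `background_rate`. Each variant's label is the generating model's own
#' `predict` output, so labels are consistent with the model by construction —
#' this is a pipeline-consistency fixture, not a biological simulation. An
#' error naming the class is raised if the pools cannot realize it under the
#' model.
#'
#' @param registry a [template_registry()] containing the backbone.
#' @param model the generating [predictor_model()].
#' @param config a [generator_config()].
#' @return a `labeled_dataset` data frame.
#' @export
generate_floor_variants <- function(registry = default_registry(),
                                    model = default_model(),
                                    config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  backbone <- registry$templates[[config$backbone]]
  if (is.null(backbone)) stop("backbone template not in registry: ",
                              config$backbone)
  with_seed(config$seed, {
    rows <- list()
    for (class in intersect(names(DECISIVE_FLOOR), names(config$quota))) {
      for (j in seq_len(config$quota[[class]])) {
        chars <- mutate_backbone(backbone, class, config)
        id <- sprintf("syn_%s_%s_%03d", config$backbone, class, j)
        rows[[length(rows) + 1]] <-
          list(id = id, residues = paste(chars, collapse = ""), class = class)
      }
    }
    finalize_variants(rows, backbone, registry, model)
  })
}

mutate_backbone <- function(backbone, class, config) {
  chars <- strsplit(backbone$sequence, "")[[1]]
  floor_pos <- as.vector(t(backbone$floor_positions))
  # background substitutions never touch floor sites
  mutable <- setdiff(seq_along(chars), floor_pos)
  hit <- mutable[stats::runif(length(mutable)) < config$background_rate]
  for (p in hit) chars[p] <- sample(setdiff(AA20, chars[p]), 1)
  decisive <- DECISIVE_FLOOR[[class]]
  for (f in 1:3) {
    pool <- if (!is.na(decisive) && f == decisive) config$bulky else config$small
    chars[backbone$floor_positions[f, ]] <-
      sample(pool, 3, replace = TRUE)
  }
  chars
}

finalize_variants <- function(rows, backbone, registry, model) {
  seqs <- protein_set(
    id = vapply(rows, `[[`, character(1), "id"),
    residues = vapply(rows, `[[`, character(1), "residues"),
    kingdom = backbone$kingdom)
  intended <- vapply(rows, `[[`, character(1), "class")
  labels <- vapply(seq_len(nrow(seqs)), function(i)
    predict_chain_length(seqs[i, , drop = FALSE], registry, model)$primary,
    character(1))
  off <- intended != labels
  if (any(off))
    stop("class unreachable under the given pools and model: ",
         paste(unique(intended[off]), collapse = ", "))
  seqs$label <- labels
  seqs$label_secondary <- NA_character_
  seqs$method <- "unknown"
  class(seqs) <- c("labeled_dataset", "protein_set", "data.frame")
  seqs
}

#' Generate the deterministic floor-site probe mutants
#'
#' A fixed series of 27 single-site and graded mutants on one backbone,
#' patterned after a site-directed mutagenesis training series. For each
#' probed floor, "single-site" probes place tryptophan at one site over a
#' uniform background of Gly, Thr or Lys, and "sandwich" probes place
#' methionine against a lysine background, producing scores that straddle the
#' floor threshold differently depending on which site carries the weight.
#' The probes make the per-site weighting factors identifiable from class
#' labels alone: under the shipped model, any zero-error weight assignment
#' must give floor sites 1/3 and 3/3 near-zero weight and make floor-2 site 2
#' that floor's dominant site. Labels come from the generating model's own
#' `predict` (closed loop).
#'
#' Non-probed floors are held open (all Gly) below the probe or at the
#' backbone's native residues above it, except that floor 3 is closed (all
#' Trp) behind a floor-2 probe so that passing floor 2 is observable as C25.
#'
#' @param registry a [template_registry()].
#' @param model the generating [predictor_model()].
#' @param backbone template id carrying the mutations.
#' @return a `labeled_dataset` of 27 records.
#' @export
generate_site_probes <- function(registry = default_registry(),
                                 model = default_model(),
                                 backbone = "5E8H") {
  tpl <- registry$templates[[backbone]]
  if (is.null(tpl)) stop("backbone template not in registry: ", backbone)

  single <- function(site, on, base) {
    r <- rep(base, 3); r[site] <- on; r
  }
  probes <- list()
  add <- function(floor, tag, resid) {
    probes[[length(probes) + 1]] <<- list(floor = floor, tag = tag,
                                          residues = resid)
  }
  for (s in 1:3) add(1, paste0("baseG_s", s), single(s, "W", "G"))
  for (s in 1:3) add(1, paste0("baseT_s", s), single(s, "W", "T"))
  for (s in 1:3) add(1, paste0("baseK_s", s), single(s, "W", "K"))
  for (s in 1:3) add(1, paste0("sandwichM_s", s), single(s, "M", "K"))
  for (s in 1:3) add(2, paste0("baseG_s", s), single(s, "W", "G"))
  for (s in 1:3) add(2, paste0("baseT_s", s), single(s, "W", "T"))
  for (s in 1:3) add(3, paste0("baseG_s", s), single(s, "W", "G"))
  for (s in 1:3) add(3, paste0("baseK_s", s), single(s, "W", "K"))
  for (s in 1:3) add(3, paste0("sandwichM_s", s), single(s, "M", "K"))

  rows <- lapply(probes, function(p) {
    chars <- strsplit(tpl$sequence, "")[[1]]
    if (p$floor >= 2) chars[tpl$floor_positions[1, ]] <- "G"
    if (p$floor == 3) chars[tpl$floor_positions[2, ]] <- "G"
    if (p$floor == 2) chars[tpl$floor_positions[3, ]] <- "W"
    chars[tpl$floor_positions[p$floor, ]] <- p$residues
    list(id = sprintf("probe_f%d_%s", p$floor, p$tag),
         residues = paste(chars, collapse = ""), class = NA_character_)
  })
  seqs <- protein_set(
    id = vapply(rows, `[[`, character(1), "id"),
    residues = vapply(rows, `[[`, character(1), "residues"),
    kingdom = tpl$kingdom)
  seqs$label <- vapply(seq_len(nrow(seqs)), function(i)
    predict_chain_length(seqs[i, , drop = FALSE], registry, model)$primary,
    character(1))
  seqs$label_secondary <- NA_character_
  seqs$method <- "unknown"
  class(seqs) <- c("labeled_dataset", "protein_set", "data.frame")
  seqs
}

#' Templates as a labeled dataset
#'
#' The registry templates themselves, labeled with their native product
#' classes — the experimentally characterized core of a training set.
#'
#' @param registry a [template_registry()].
#' @return a `labeled_dataset` of one record per template.
#' @export
templates_as_dataset <- function(registry = default_registry()) {
  tpls <- registry$templates
  seqs <- protein_set(
    id = vapply(tpls, `[[`, character(1), "pdb_id"),
    residues = vapply(tpls, `[[`, character(1), "sequence"),
    kingdom = vapply(tpls, `[[`, character(1), "kingdom"))
  seqs$label <- unname(vapply(tpls, `[[`, character(1), "product_class"))
  seqs$label_secondary <- NA_character_
  seqs$method <- "unknown"
  class(seqs) <- c("labeled_dataset", "protein_set", "data.frame")
  seqs
}

#' Generate a complete synthetic training set
#'
#' The 11 registry templates (native labels), the 27 deterministic site
#' probes, and `n - 38` background-mutated class-quota variants: a stand-in
#' for a curated training table of characterized enzymes plus a site-directed
#' mutant series.
#'
#' @param registry a [template_registry()].
#' @param model the generating [predictor_model()].
#' @param n total number of records (>= 42, so every class keeps random
#'   variants).
#' @param seed random seed for the variant portion.
#' @return a `labeled_dataset` of `n` records.
#' @export
generate_training_set <- function(registry = default_registry(),
                                  model = default_model(), n = 60, seed = 42) {
  n_fixed <- length(registry$templates) + 27
  if (n < n_fixed + 4)
    stop("n must be at least ", n_fixed + 4)
  m <- n - n_fixed
  base <- m %/% 4
  quota <- c(C15 = base, C20 = base, C25 = base, GE_C30 = base)
  quota[seq_len(m %% 4)] <- quota[seq_len(m %% 4)] + 1
  variants <- generate_floor_variants(
    registry, model,
    generator_config(backbone = "5E8H", quota = quota, seed = seed))
  out <- rbind(templates_as_dataset(registry),
               generate_site_probes(registry, model),
               variants)
  class(out) <- c("labeled_dataset", "protein_set", "data.frame")
  out
}
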