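# Side-chain van der Waals volumes (A^3): Creighton residue volumes minus the
# glycine baseline (48 A^3), so glycine has no side chain and no bulk.
SIDECHAIN_VOLUME <- c(
  A = 19, R = 100, N = 48, D = 43, C = 38, Q = 66, E = 61, G = 0, H = 70,
  I = 76, L = 76, K = 87, M = 76, F = 87, P = 42, S = 25, T = 45, W = 115,
  Y = 93, V = 57)

# Torsional-rigidity factor by side-chain class: a long flexible chain can
# rotate out of the tunnel, so its effective blocking is lower than a rigid
# side chain of equal volume. Classes follow the count of freely rotatable
# chi bonds, with aromatics kept high because the ring itself is rigid.
TORSION_FACTOR <- c(
  A = 1.00, G = 1.00, P = 1.00,             # no rotatable side-chain bonds
  S = 0.95, C = 0.95, T = 0.95, V = 0.95,   # one chi
  I = 0.85, L = 0.85, N = 0.85, D = 0.85,   # two chi, branched/short
  H = 0.90, F = 0.90, Y = 0.90, W = 0.90,   # chi1/chi2 plus rigid ring
  M = 0.70, E = 0.70, Q = 0.70,             # three chi, flexible
  K = 0.55, R = 0.55)                       # four chi, highly flexible

#' The default blocking-score table
#'
#' Each amino acid is assigned a dimensionless blocking score reflecting how
#' likely its side chain is to terminate chain elongation at a tunnel floor:
#' side-chain van der Waals volume normalized to tryptophan, multiplied by a
#' torsional-rigidity factor that down-weights long flexible side chains
#' (Lys, Arg, Met) relative to rigid aromatics of similar volume (Phe, Trp,
#' Tyr). Scores are rounded to three decimals and range from 0 (Gly) to 0.9
#' (Trp).
#'
#' @return named numeric vector over the 20 canonical residues.
#' @export
default_blocking_table <- function() {
  b <- round(SIDECHAIN_VOLUME / SIDECHAIN_VOLUME[["W"]] *
               TORSION_FACTOR[names(SIDECHAIN_VOLUME)], 3)
  validate_blocking_table(b)
  b
}

validate_blocking_table <- function(b) {
  if (!all(AA20 %in% names(b)))
    stop("blocking table must cover all 20 canonical residues; missing: ",
         paste(setdiff(AA20, names(b)), collapse = ", "))
  b <- b[AA20]
  if (any(!is.finite(b)) || any(b < 0))
    stop("blocking scores must be finite and nonnegative")
  if (b[["G"]] != min(b))
    stop("blocking table violates B(Gly) = minimum")
  if (b[["W"]] < b[["A"]])
    stop("blocking table violates B(Trp) >= B(Ala)")
  invisible(b)
}

#' Default site weighting factors
#'
#' The trained per-floor weighting factors of the three floor sites. On the
#' first floor, sites 1 and 2 contribute almost equally and site 3 only 1.1%;
#' on the second floor the three sites contribute 20.0%, 55.3% and 24.7%; on
#' the third floor, 36.5%, 62.9% and 0.6%. A higher weighting factor marks a
#' site the elongating prenyl chain is more likely to pass, so these weights
#' also trace the elongation route (see [trace_elongation_route()]).
#'
#' @return 3x3 numeric matrix, rows = floors, columns = sites; each row sums
#'   to 1.
#' @export
default_weights <- function() {
  matrix(c(0.4945, 0.4945, 0.011,
           0.200,  0.553,  0.247,
           0.365,  0.629,  0.006),
         nrow = 3, byrow = TRUE,
         dimnames = list(paste0("floor", 1:3), paste0("site", 1:3)))
}

validate_weights <- function(w) {
  if (!is.matrix(w) || !all(dim(w) == c(3, 3)))
    stop("weights must be a 3x3 matrix (floors x sites)")
  if (any(w < 0)) stop("weights must be nonnegative")
  if (any(abs(rowSums(w) - 1) > 1e-9))
    stop("each floor's weights must sum to 1 (tolerance 1e-9)")
  invisible(w)
}

#' Floor thresholds and ambiguity band
#'
#' The cascade compares each floor's blocking score against its threshold
#' (strictly greater blocks). `delta` is the relative half-width of the
#' ambiguity band: when the decisive comparison falls within
#' `delta * theta[f]` of the threshold, the adjacent class is emitted as a
#' secondary (dual) call such as `"C20/C25"`.
#'
#' @param theta numeric length 3, per-floor thresholds in score units.
#' @param delta nonnegative fraction, default 0.05 (5% of the decisive
#'   threshold).
#' @return a `floor_thresholds` object.
#' @export
floor_thresholds <- function(theta = c(0.43, 0.41, 0.43), delta = 0.05) {
  theta <- as.numeric(theta)
  if (length(theta) != 3 || any(!is.finite(theta)))
    stop("theta must be 3 finite values")
  if (!is.finite(delta) || delta < 0) stop("delta must be >= 0")
  out <- list(theta = theta, delta = delta)
  class(out) <- "floor_thresholds"
  out
}

#' Assemble a predictor model
#'
#' @param blocking named blocking-score table over the 20 residues.
#' @param weights 3x3 site-weight matrix, rows summing to 1.
#' @param thresholds a [floor_thresholds()] object.
#' @param align_params an [alignment_params()] object.
#' @param registry_tag version tag of the registry the model was calibrated
#'   against.
#' @param six_site if `TRUE`, run in the reduced six-residue mode: the
#'   near-zero-weight site 3 of floors 1 and 3 is dropped and the remaining
#'   weights on those floors renormalized.
#' @return a `predictor_model` object.
#' @export
predictor_model <- function(blocking = default_blocking_table(),
                            weights = default_weights(),
                            thresholds = floor_thresholds(),
                            align_params = alignment_params(),
                            registry_tag = "synthetic-registry-v1",
                            six_site = FALSE) {
  validate_blocking_table(blocking)
  validate_weights(weights)
  stopifnot(inherits(thresholds, "floor_thresholds"),
            inherits(align_params, "alignment_params"))
  if (isTRUE(six_site)) {
    weights[1, 3] <- 0
    weights[3, 3] <- 0
    weights <- weights / rowSums(weights)
  }
  out <- list(blocking = blocking[AA20], weights = weights,
              thresholds = thresholds, align_params = align_params,
              registry_tag = registry_tag, six_site = isTRUE(six_site))
  class(out) <- "predictor_model"
  out
}

#' The shipped default model
#'
#' Default blocking table, the trained site weights, thresholds
#' (0.43, 0.41, 0.43) with a 5% ambiguity band, and BLOSUM62/11/1 alignment
#' parameters, calibrated against the bundled synthetic registry.
#'
#' @param six_site see [predictor_model()].
#' @return a `predictor_model`.
#' @export
default_model <- function(six_site = FALSE) {
  predictor_model(six_site = six_site)
}

#' Weighted blocking score of one floor
#'
#' `S[f] = sum over sites s of w[f,s] * B(residue[f,s])`; a gap at a site
#' contributes zero blocking.
#'
#' @param assignment a `floor_assignment`.
#' @param floor floor index, 1 (top) to 3 (bottom).
#' @param model a `predictor_model`.
#' @return the floor's blocking score (dimensionless).
#' @export
floor_blocking_score <- function(assignment, floor, model = default_model()) {
  stopifnot(inherits(assignment, "floor_assignment"), floor %in% 1:3)
  res <- assignment$residue[assignment$floor == floor][1:3]
  b <- ifelse(is.na(res), 0, model$blocking[res])
  if (anyNA(b))
    stop("unscorable residue code at floor ", floor, ": ",
         paste(res[is.na(b) & !is.na(res)], collapse = ", "))
  sum(model$weights[floor, ] * b)
}

#' Threshold cascade over the three floors
#'
#' Floors are tested top to bottom: if `S[1] > theta[1]` the chain is
#' terminated at the first floor and the call is C15; otherwise the second
#' floor is tested (C20), then the third (C25); an enzyme whose tunnel is open
#' at all three floors is called GE_C30. Comparisons are strictly greater;
#' equality falls through to the next floor.
#'
#' If the first comparison (at or above the decisive floor) lying within the
#' ambiguity band `delta * theta[f]` of its threshold could have changed the
#' call to the adjacent class, that class is emitted as the secondary of a
#' dual call.
#'
#' @param scores numeric length 3, floor blocking scores.
#' @param thresholds a [floor_thresholds()] object.
#' @return list with `primary`, `secondary` (class token or `NA`),
#'   `decisive_floor` (1..3; 3 for GE_C30), `ambiguous` (within-band but no
#'   adjacent alternative representable).
#' @export
cascade <- function(scores, thresholds = floor_thresholds()) {
  stopifnot(length(scores) == 3, all(is.finite(scores)),
            inherits(thresholds, "floor_thresholds"))
  theta <- thresholds$theta
  band <- thresholds$delta * theta
  blocked <- scores > theta
  fstar <- if (any(blocked)) which(blocked)[1] else 4L
  floor_class <- c("C15", "C20", "C25", "GE_C30")
  primary <- floor_class[fstar]
  within <- abs(scores - theta) <= band

  secondary <- NA_character_
  ambiguous <- FALSE
  if (fstar <= 3 && within[fstar]) {
    # marginal block: had floor fstar passed, the cascade continues below;
    # that counterfactual is an admissible dual call only when adjacent
    continuation <- if (any(blocked[-seq_len(fstar)]))
      floor_class[fstar + which(blocked[-seq_len(fstar)])[1]] else "GE_C30"
    if (carbon_count(continuation) - carbon_count(primary) == 5L)
      secondary <- continuation
    else
      ambiguous <- TRUE
  } else if (fstar >= 2 && within[fstar - 1]) {
    # the floor just above the decisive one was passed only marginally
    secondary <- floor_class[fstar - 1]
  }
  list(primary = primary, secondary = secondary,
       decisive_floor = min(fstar, 3L), ambiguous = ambiguous)
}

#' Order floor sites along the elongation route
#'
#' A higher weighting factor marks a site the elongating prenyl group is more
#' likely to pass; sorting each floor's sites by descending weight (ties by
#' site index) traces a rough elongation route through the tunnel.
#'
#' @param model a `predictor_model`.
#' @return 3x3 integer matrix: row f holds the site indices of floor f in
#'   route order.
#' @export
trace_elongation_route <- function(model = default_model()) {
  w <- model$weights
  out <- t(vapply(1:3, function(f) order(-w[f, ], 1:3), integer(3)))
  dimnames(out) <- list(paste0("floor", 1:3), paste0("rank", 1:3))
  out
}
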