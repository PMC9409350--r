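LOW_IDENTITY_WARN <- 0.30

#' Predict the product chain length of a trans-prenyltransferase
#'
#' The full three-step pipeline: (1) align the query against every registry
#' template and select the best template by percent identity; (2) project the
#' template's nine floor positions onto the query; (3) compute the weighted
#' blocking score of each floor and run the threshold cascade. Deterministic
#' for a fixed model and registry; never emits C10 or NA.
#'
#' Predictions are flagged `low_identity` below 30% identity to the best
#' template (accuracy is known to degrade with template similarity) and
#' `gap_at_floor` when the alignment leaves any floor site without a query
#' residue.
#'
#' @param query a single sequence: one-row `protein_set` or residue string.
#' @param registry a [template_registry()].
#' @param model a [predictor_model()].
#' @return a `pt_prediction` list: `query_id`, `primary`, `secondary`,
#'   `scores` (length 3), `best_template`, `identity`, `assignment`, `flags`.
#' @examples
#' \donttest{
#' reg <- default_registry()
#' predict_chain_length(reg$templates[["5E8H"]]$sequence)
#' }
#' @export
predict_chain_length <- function(query, registry = default_registry(),
                                 model = default_model()) {
  id <- if (is.data.frame(query)) query$id[1] else "query"
  match <- select_best_template(query, registry, model$align_params)
  assignment <- map_floor_residues(match, registry = registry)
  prediction_from_assignment(assignment, model, query_id = id,
                             all_identities = match$all_identities)
}

#' Score a ready-made floor assignment
#'
#' Runs only steps (2)-(3) of the pipeline on a [floor_assignment()] that was
#' built by hand or obtained from [map_floor_residues()] — useful when the
#' floor residues are known but the full sequence is not.
#'
#' @param assignment a `floor_assignment`.
#' @param model a `predictor_model`.
#' @param query_id identifier used in the result.
#' @param all_identities optional named identity vector for reporting.
#' @return a `pt_prediction` (see [predict_chain_length()]).
#' @export
prediction_from_assignment <- function(assignment, model = default_model(),
                                       query_id = "query",
                                       all_identities = NULL) {
  stopifnot(inherits(assignment, "floor_assignment"),
            inherits(model, "predictor_model"))
  scores <- vapply(1:3, function(f)
    floor_blocking_score(assignment, f, model), numeric(1))
  call <- cascade(scores, model$thresholds)
  flags <- character(0)
  if (anyNA(assignment$residue)) flags <- c(flags, "gap_at_floor")
  identity <- attr(assignment, "identity")
  if (!is.na(identity) && identity < LOW_IDENTITY_WARN)
    flags <- c(flags, "low_identity")
  if (call$ambiguous) flags <- c(flags, "ambiguous")
  out <- list(query_id = query_id,
              primary = call$primary, secondary = call$secondary,
              scores = scores, decisive_floor = call$decisive_floor,
              best_template = attr(assignment, "template_id"),
              identity = identity, assignment = assignment,
              all_identities = all_identities, flags = flags)
  class(out) <- "pt_prediction"
  out
}

#' @export
print.pt_prediction <- function(x, ...) {
  cat(sprintf("%s: %s  (floors %.3f/%.3f/%.3f; template %s, identity %s%%%s)\n",
              x$query_id, format_product_class(x$primary, x$secondary),
              x$scores[1], x$scores[2], x$scores[3],
              if (is.na(x$best_template)) "-" else x$best_template,
              if (is.na(x$identity)) "-" else sprintf("%.1f", 100 * x$identity),
              if (length(x$flags)) paste0("; ", paste(x$flags, collapse = ","))
              else ""))
  invisible(x)
}

#' Predict a batch of sequences into a report table
#'
#' @param seqs a `protein_set` data frame.
#' @param registry a [template_registry()].
#' @param model a [predictor_model()].
#' @param on_error `"stop"` to fail on the first unpredictable record, or
#'   `"report"` to emit the row with empty calls and an `error:` flag.
#' @return a `prediction_report` data frame, one row per query (see
#'   [write_prediction_report()] for columns).
#' @export
predict_batch <- function(seqs, registry = default_registry(),
                          model = default_model(),
                          on_error = c("stop", "report")) {
  on_error <- match.arg(on_error)
  stopifnot(is.data.frame(seqs), nrow(seqs) > 0)
  rows <- lapply(seq_len(nrow(seqs)), function(i) {
    pred <- tryCatch(
      predict_chain_length(seqs[i, , drop = FALSE], registry, model),
      error = function(e) e)
    if (inherits(pred, "error")) {
      if (on_error == "stop")
        stop("record '", seqs$id[i], "': ", conditionMessage(pred))
      return(data.frame(
        query_id = seqs$id[i], best_template = NA_character_,
        identity_pct = NA_real_,
        f1_s1 = NA, f1_s2 = NA, f1_s3 = NA, f2_s1 = NA, f2_s2 = NA,
        f2_s3 = NA, f3_s1 = NA, f3_s2 = NA, f3_s3 = NA,
        score_f1 = NA_real_, score_f2 = NA_real_, score_f3 = NA_real_,
        predicted = NA_character_, primary = NA_character_,
        secondary = NA_character_,
        flags = paste0("error:", gsub("[\t\n]", " ", conditionMessage(pred))),
        stringsAsFactors = FALSE))
    }
    prediction_row(pred)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("prediction_report", "data.frame")
  out
}

prediction_row <- function(pred) {
  res <- pred$assignment$residue
  res[is.na(res)] <- "-"
  data.frame(
    query_id = pred$query_id, best_template = pred$best_template,
    identity_pct = 100 * pred$identity,
    f1_s1 = res[1], f1_s2 = res[2], f1_s3 = res[3],
    f2_s1 = res[4], f2_s2 = res[5], f2_s3 = res[6],
    f3_s1 = res[7], f3_s2 = res[8], f3_s3 = res[9],
    score_f1 = pred$scores[1], score_f2 = pred$scores[2],
    score_f3 = pred$scores[3],
    predicted = format_product_class(pred$primary, pred$secondary),
    primary = pred$primary, secondary = pred$secondary,
    flags = paste(pred$flags, collapse = ";"),
    stringsAsFactors = FALSE)
}
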