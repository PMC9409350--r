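#' Score predictions against experimental labels
#'
#' A prediction is counted correct when either its primary or its secondary
#' (dual-call) class equals the experimental label — a dual call such as
#' `"C20/C25"` is credited for a C25 enzyme; this either-class crediting is
#' how dual calls enter every accuracy in the package. The GE_C30 bin matches
#' any determined product of C30 or longer. Records labeled NA (no activity
#' detected) are counted incorrect, or dropped entirely with
#' `exclude_na = TRUE`; the within-one-C5 accuracy additionally credits
#' predictions whose carbon count is within 5 of the label's.
#'
#' @param predictions a `prediction_report` data frame ([predict_batch()] or
#'   [read_prediction_report()]).
#' @param labels a `labeled_dataset` covering the same ids.
#' @param exclude_na drop NA-labeled records instead of counting them wrong.
#' @return an `evaluation_report` list: `n`, `n_correct`, `exact_accuracy`,
#'   `within_one_accuracy`, `mean_identity_pct`, per-group accuracy tables
#'   (`by_kingdom`, `by_phylum`, `by_template`), the 4x6 `confusion` matrix
#'   (predicted x labeled), and the predicted `class_distribution`.
#' @export
score_predictions <- function(predictions, labels, exclude_na = FALSE) {
  stopifnot(is.data.frame(predictions), is.data.frame(labels))
  orphan_pred <- setdiff(predictions$query_id, labels$id)
  orphan_lab <- setdiff(labels$id, predictions$query_id)
  if (length(orphan_pred) || length(orphan_lab))
    stop("id mismatch between predictions and labels; without labels: ",
         paste(orphan_pred, collapse = ", "), "; without predictions: ",
         paste(orphan_lab, collapse = ", "))
  labels <- labels[match(predictions$query_id, labels$id), , drop = FALSE]

  if (exclude_na) {
    keep <- labels$label != "NA"
    predictions <- predictions[keep, , drop = FALSE]
    labels <- labels[keep, , drop = FALSE]
  }
  n <- nrow(predictions)
  if (n == 0) stop("no records to evaluate")

  label_secondary <- if ("label_secondary" %in% names(labels))
    labels$label_secondary else rep(NA_character_, n)
  correct <- logical(n)
  within_one <- logical(n)
  for (i in seq_len(n)) {
    pred_classes <- stats::na.omit(c(predictions$primary[i],
                                     predictions$secondary[i]))
    lab_classes <- stats::na.omit(c(labels$label[i], label_secondary[i]))
    lab_classes <- lab_classes[lab_classes != "NA"]
    if (length(pred_classes) == 0 || length(lab_classes) == 0) next
    correct[i] <- any(pred_classes %in% lab_classes)
    dc <- abs(outer(carbon_count(pred_classes), carbon_count(lab_classes), "-"))
    within_one[i] <- min(dc) <= 5
  }

  confusion <- table(
    predicted = factor(predictions$primary, levels = predictable_classes()),
    labeled = factor(labels$label, levels = product_classes()))

  group_table <- function(key) {
    key[is.na(key) | key == ""] <- "unclassified"
    agg <- lapply(split(seq_len(n), key), function(idx)
      data.frame(n = length(idx), n_correct = sum(correct[idx]),
                 accuracy = mean(correct[idx])))
    out <- do.call(rbind, agg)
    out <- data.frame(group = rownames(out), out, row.names = NULL,
                      stringsAsFactors = FALSE)
    out[order(-out$n, out$group), , drop = FALSE]
  }

  out <- list(
    n = n, n_correct = sum(correct),
    exact_accuracy = mean(correct),
    within_one_accuracy = mean(within_one),
    mean_identity_pct = mean(predictions$identity_pct, na.rm = TRUE),
    by_kingdom = group_table(if ("kingdom" %in% names(labels))
      labels$kingdom else rep(NA_character_, n)),
    by_phylum = group_table(if ("phylum" %in% names(labels))
      labels$phylum else rep(NA_character_, n)),
    by_template = group_table(predictions$best_template),
    confusion = confusion,
    class_distribution = class_distribution(predictions),
    excluded_na = exclude_na)
  class(out) <- "evaluation_report"
  out
}

#' Distribution of predicted product classes
#'
#' Primary-class counts normalized to fractions over the four predictable
#' classes (order C15, C20, C25, GE_C30).
#'
#' @param predictions a `prediction_report` data frame, or a character vector
#'   of primary class tokens.
#' @return named numeric vector of fractions summing to 1.
#' @export
class_distribution <- function(predictions) {
  primary <- if (is.data.frame(predictions)) predictions$primary
             else as.character(predictions)
  primary <- primary[!is.na(primary)]
  if (length(primary) == 0) stop("no predictions to tally")
  counts <- table(factor(primary, levels = predictable_classes()))
  stats::setNames(as.numeric(counts) / length(primary), predictable_classes())
}

# percentages rounded half-up, mirroring how accuracies are usually printed
percent_int <- function(x) floor(100 * x + 0.5)

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Prediction accuracy: %d%% (%d/%d)\n",
              percent_int(x$exact_accuracy), x$n_correct, x$n))
  cat(sprintf("Within one C5 unit:  %d%%\n",
              percent_int(x$within_one_accuracy)))
  if (is.finite(x$mean_identity_pct))
    cat(sprintf("Mean best-template identity: %.1f%%\n", x$mean_identity_pct))
  kt <- x$by_kingdom
  if (!identical(kt$group, "unclassified")) {
    cat("By kingdom:\n")
    for (i in seq_len(nrow(kt)))
      cat(sprintf("  %-12s %d%% (%d/%d)\n", kt$group[i],
                  percent_int(kt$accuracy[i]), kt$n_correct[i], kt$n[i]))
  }
  cat("Predicted class distribution:",
      paste(sprintf("%s %d%%", names(x$class_distribution),
                    percent_int(x$class_distribution)), collapse = ", "),
      "\n")
  invisible(x)
}
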