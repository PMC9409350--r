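# Shared fixtures, built once per test run. The default registry and model
# are deterministic package data; the substitution matrix backs the oracle.
REG <- default_registry()
MOD <- default_model()
BLOSUM62M <- alignment_params()$matrix

write_tmp_fasta <- function(text) {
  path <- withr::local_tempfile(fileext = ".fa", .local_envir = parent.frame())
  writeLines(text, path)
  path
}

# substitute residues (named by 1-based position) in a template's sequence
substitute_at <- function(sequence, replacements) {
  chars <- strsplit(sequence, "")[[1]]
  chars[as.integer(names(replacements))] <- replacements
  paste(chars, collapse = "")
}

# a minimal labeled dataset built in code
make_labels <- function(ids, residues, labels, kingdom = NA_character_,
                        phylum = NA_character_) {
  out <- protein_set(ids, rep_len(residues, length(ids)),
                     kingdom = kingdom, phylum = phylum)
  out$label <- labels
  out$label_secondary <- NA_character_
  out$method <- "unknown"
  class(out) <- c("labeled_dataset", "protein_set", "data.frame")
  out
}

# a prediction-report row without running the predictor (for accounting tests)
make_report <- function(query_id, primary, secondary = NA_character_,
                        best_template = "5E8H", identity_pct = 50) {
  n <- length(query_id)
  secondary <- rep_len(secondary, n)
  out <- data.frame(
    query_id = query_id, best_template = rep_len(best_template, n),
    identity_pct = rep_len(identity_pct, n),
    f1_s1 = "A", f1_s2 = "A", f1_s3 = "A", f2_s1 = "A", f2_s2 = "A",
    f2_s3 = "A", f3_s1 = "A", f3_s2 = "A", f3_s3 = "A",
    score_f1 = 0.1, score_f2 = 0.1, score_f3 = 0.1,
    predicted = unname(mapply(format_product_class, primary, secondary)),
    primary = unname(primary), secondary = unname(secondary), flags = "",
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("prediction_report", "data.frame")
  out
}
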