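#' Save a predictor model to structured text
#'
#' JSON serialization of the blocking table, site weights, thresholds and
#' ambiguity band, alignment parameters, and registry tag, at full floating
#' point precision so that save/load round-trips bit-exactly. A custom
#' substitution matrix is embedded; a named matrix is stored by name.
#'
#' @param model a `predictor_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "predictor_model"))
  ap <- model$align_params
  obj <- list(
    format = "threefloors-model-v1",
    blocking = as.list(model$blocking),
    weights = apply(model$weights, 1, as.numeric, simplify = FALSE),
    theta = model$thresholds$theta,
    delta = model$thresholds$delta,
    alignment = list(
      matrix_name = ap$matrix_name,
      matrix = if (ap$matrix_name %in% c("custom")) {
        m <- ap$matrix
        list(labels = rownames(m), values = apply(m, 1, as.numeric,
                                                  simplify = FALSE))
      },
      gap_open = ap$gap_open, gap_extend = ap$gap_extend),
    registry_tag = model$registry_tag,
    six_site = model$six_site)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Load a predictor model saved by [save_model()]
#'
#' @param path path to the model JSON file.
#' @return a `predictor_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "threefloors-model-v1"))
    stop("not a threefloors model file: ", path)
  blocking <- unlist(obj$blocking)
  weights <- do.call(rbind, lapply(obj$weights, unlist))
  storage.mode(weights) <- "double"
  dimnames(weights) <- list(paste0("floor", 1:3), paste0("site", 1:3))
  al <- obj$alignment
  gap_open <- as.numeric(al$gap_open)
  gap_extend <- as.numeric(al$gap_extend)
  params <- if (!is.null(al$matrix)) {
    m <- do.call(rbind, lapply(al$matrix$values, unlist))
    dimnames(m) <- list(unlist(al$matrix$labels), unlist(al$matrix$labels))
    alignment_params(m, gap_open, gap_extend)
  } else {
    alignment_params(al$matrix_name, gap_open, gap_extend)
  }
  predictor_model(
    blocking = as.numeric(blocking) |> stats::setNames(names(blocking)),
    weights = weights,
    thresholds = floor_thresholds(as.numeric(unlist(obj$theta)),
                                  as.numeric(obj$delta)),
    align_params = params, registry_tag = obj$registry_tag,
    six_site = isTRUE(obj$six_site))
}
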