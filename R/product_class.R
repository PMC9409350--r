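#' Product classes of trans-prenyltransferases
#'
#' The predominant products of short- and long-chain trans-prenyltransferases
#' are binned into classes by carbon count: GPP (C10), FPP (C15), GGPP (C20),
#' GFPP (C25), and polyprenyl pyrophosphates of C30 and above (`"GE_C30"`).
#' `"NA"` is an experimental-label-only value meaning no activity was detected.
#' The predictor itself only ever emits C15, C20, C25 or GE_C30: the floors of
#' the elongation tunnel begin above FPP length, and an inactive enzyme is not
#' a chain-length class.
#'
#' @format `product_classes()` returns the six canonical class tokens in chain
#'   length order; `predictable_classes()` the four the cascade can emit.
#' @name product_classes
NULL

#' @rdname product_classes
#' @export
product_classes <- function() c("C10", "C15", "C20", "C25", "GE_C30", "NA")

#' @rdname product_classes
#' @export
predictable_classes <- function() c("C15", "C20", "C25", "GE_C30")

#' Carbon count of a product class
#'
#' @param class character vector of canonical class tokens.
#' @return integer vector; 10, 15, 20, 25 or 30 (the GE_C30 bin is counted at
#'   its lower bound), `NA` for the no-activity label.
#' @examples
#' carbon_count(c("C15", "GE_C30"))
#' @export
carbon_count <- function(class) {
  map <- c(C10 = 10L, C15 = 15L, C20 = 20L, C25 = 25L, GE_C30 = 30L, "NA" = NA_integer_)
  bad <- setdiff(unique(class), names(map))
  if (length(bad) > 0)
    stop("unknown product class: ", paste(bad, collapse = ", "))
  unname(map[class])
}

#' Parse a product-class label
#'
#' Accepts the spellings used in experimental tables: `"C15"` etc.,
#' `">=C30"`/`"≥C30"`/`"GE_C30"`/`"C30"` for the long-chain bin, and
#' `"NA"` (or an empty cell) for no detected activity. A dual experimental
#' outcome written `"C20/C25"` parses to its first (shorter) class; use
#' [read_labeled_dataset()] to retain the second class.
#'
#' @param x character vector of labels.
#' @return character vector of canonical tokens, `NA_character_` where the
#'   label is not a recognized class.
#' @export
parse_product_class <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[is.na(x) | x == "" | x == "NA" | x == "N/A" | x == "NONE"] <- "NA"
  x <- sub("/.*$", "", x)            # dual outcome: keep shorter class
  x[x %in% c(">=C30", "≥C30", "GE_C30", "C30", "C30+", ">C30")] <- "GE_C30"
  ok <- x %in% product_classes()
  x[!ok] <- NA_character_
  x
}

#' Render one or two product classes for reports
#'
#' A dual call is serialized with the shorter chain first, e.g. `"C20/C25"`,
#' regardless of which of the two is the primary call.
#'
#' @param primary canonical class token.
#' @param secondary optional canonical class token (adjacent class of a dual
#'   call), or `NA`.
#' @return a single string such as `"C20"`, `"C20/C25"` or `">=C30"`.
#' @export
format_product_class <- function(primary, secondary = NA_character_) {
  render1 <- function(cl) if (identical(cl, "GE_C30")) ">=C30" else cl
  if (is.na(secondary) || !nzchar(secondary)) return(render1(primary))
  pair <- c(primary, secondary)
  pair <- pair[order(carbon_count(pair))]
  paste(vapply(pair, render1, character(1)), collapse = "/")
}

# inverse of format_product_class(); returns list(primary=, secondary=)
unformat_product_class <- function(x) {
  parts <- strsplit(x, "/", fixed = TRUE)[[1]]
  parts <- vapply(parts, function(p) {
    p <- parse_product_class(p)
    if (is.na(p)) stop("unparseable predicted class: ", x)
    p
  }, character(1), USE.NAMES = FALSE)
  list(primary = parts[1],
       secondary = if (length(parts) > 1) parts[2] else NA_character_)
}
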