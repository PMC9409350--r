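# Independent three-state (Gotoh) dynamic-programming oracle for the optimal
# global affine-gap alignment score. Written against the textbook recurrences,
# not against the package's alignment wrapper: a gap of length L costs
# open + L * extend. Used to cross-check alignment scores on short sequences.
oracle_global_score <- function(a, b, mat, open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)  # X: gap in b row, Y: gap in a row
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -open - i * ext
  for (j in seq_len(m)) Y[1, j + 1] <- -open - j * ext
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[av[i], bv[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Exhaustive enumeration of every gapped alignment (no both-gap columns),
# scoring each under the same affine convention; feasible only for very short
# sequences. Validates the DP oracle itself.
oracle_enumerate_score <- function(a, b, mat, open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  score_cols <- function(cols) {
    total <- 0
    run <- ""  # current gap state: "", "a", or "b"
    for (col in cols) {
      if (col[1] == "-") {
        total <- total - ext - if (run == "a") 0 else open
        run <- "a"
      } else if (col[2] == "-") {
        total <- total - ext - if (run == "b") 0 else open
        run <- "b"
      } else {
        total <- total + mat[col[1], col[2]]
        run <- ""
      }
    }
    total
  }
  best <- -Inf
  recurse <- function(i, j, cols) {
    if (i > length(av) && j > length(bv)) {
      best <<- max(best, score_cols(cols))
      return()
    }
    if (i <= length(av) && j <= length(bv))
      recurse(i + 1, j + 1, c(cols, list(c(av[i], bv[j]))))
    if (i <= length(av))
      recurse(i + 1, j, c(cols, list(c(av[i], "-"))))
    if (j <= length(bv))
      recurse(i, j + 1, c(cols, list(c("-", bv[j]))))
  }
  recurse(1, 1, list())
  best
}

random_peptide <- function(len) paste(sample(threefloors:::AA20, len,
                                             replace = TRUE), collapse = "")
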