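#' Training configuration
#'
#' @param grid_step weight grid resolution on each floor's 2-simplex; must
#'   divide 1 evenly. The default 0.01 matches the three-decimal precision of
#'   the reported trained weights.
#' @param seed random seed, recorded in the fitted result.
#' @param loss `"misclassification"` (0/1) or `"within_one_weighted"` (0 for
#'   an exact class, 0.5 within one C5 unit, 1 otherwise).
#' @param max_rounds maximum coordinate-descent rounds over the three floors.
#' @param fit_blocking if `TRUE`, after weights and thresholds converge, the
#'   blocking table is refined by single-residue perturbations that are
#'   accepted only when they reduce the loss. Off by default: with a training
#'   set of a few dozen records, 20 extra free parameters invite overfitting.
#' @return a `training_config` object.
#' @export
training_config <- function(grid_step = 0.01, seed = 1,
                            loss = c("misclassification", "within_one_weighted"),
                            max_rounds = 20, fit_blocking = FALSE) {
  k <- 1 / grid_step
  if (abs(k - round(k)) > 1e-8)
    stop("grid_step must divide 1 evenly")
  out <- list(grid_step = grid_step, k = as.integer(round(k)),
              seed = as.integer(seed), loss = match.arg(loss),
              max_rounds = as.integer(max_rounds),
              fit_blocking = isTRUE(fit_blocking))
  class(out) <- "training_config"
  out
}

# all weight triples on the 2-simplex with denominator k, as a 3 x K matrix,
# with per-column distance-from-uniform for tie-breaking
simplex_grid <- function(k) {
  ij <- expand.grid(i = 0:k, j = 0:k)
  ij <- ij[ij$i + ij$j <= k, ]
  W <- rbind(ij$i, ij$j, k - ij$i - ij$j) / k
  list(W = W, nonuniformity = colSums((W - 1 / 3)^2))
}

# per-record loss of predicting class p (1..4 = C15..GE_C30) for label carbon
# count lc; within-one credit is half
loss_value <- function(pred_idx, label_carbon, loss) {
  pc <- c(15L, 20L, 25L, 30L)[pred_idx]
  exact <- pc == label_carbon
  if (loss == "misclassification") return(as.numeric(!exact))
  ifelse(exact, 0, ifelse(abs(pc - label_carbon) <= 5, 0.5, 1))
}

# map every record of a labeled dataset onto per-floor blocking-value
# matrices under a fixed registry and alignment scheme
prepare_training_data <- function(dataset, registry, model) {
  keep_na <- dataset$label != "NA"
  if (!all(keep_na)) {
    message("excluding ", sum(!keep_na), " NA-labeled record(s) from training")
    dataset <- dataset[keep_na, , drop = FALSE]
  }
  residues <- vector("list", nrow(dataset))
  ok <- logical(nrow(dataset))
  for (i in seq_len(nrow(dataset))) {
    res <- tryCatch({
      match <- select_best_template(dataset[i, , drop = FALSE], registry,
                                    model$align_params)
      assignment <- map_floor_residues(match, registry = registry)
      matrix(assignment$residue, nrow = 3, byrow = TRUE)  # floors x sites
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("excluding unmappable record '", dataset$id[i], "': ",
              conditionMessage(res))
    } else {
      residues[[i]] <- res
      ok[i] <- TRUE
    }
  }
  if (length(unique(dataset$label[ok])) < 2)
    stop("training requires examples of at least 2 classes")
  list(dataset = dataset[ok, , drop = FALSE], residues = residues[ok],
       bvals = lapply(residues[ok], residue_blocking, model$blocking),
       n_excluded = sum(!ok) + sum(!keep_na),
       excluded_ids = dataset$id[!ok])
}

# 3x3 residue matrix -> 3x3 blocking values (gaps block nothing)
residue_blocking <- function(res, blocking) {
  b <- res
  b[] <- ifelse(is.na(res), 0, blocking[res])
  mode(b) <- "numeric"
  b
}

#' Fit site weights and floor thresholds from labeled data
#'
#' Exhaustive search: each floor's three site weights are optimized over a
#' simplex grid jointly with a 1-D sweep of that floor's threshold over the
#' observed floor scores, by coordinate descent in fixed floor order 1, 2, 3,
#' repeated until the parameters stop changing (at most `max_rounds` rounds).
#' The loss is a step function of the thresholds and the search space is
#' three independent 2-simplices, so the exhaustive search is both cheap and
#' fully deterministic. Loss ties are broken toward more uniform weights,
#' then toward higher (more permissive) thresholds, then toward grid order;
#' a permissive tie-break keeps records flowing past floors whose calls are
#' currently indifferent, so the floors below them still receive training
#' signal during coordinate descent.
#'
#' NA-labeled records are excluded (the model has no inactive class);
#' records that cannot be mapped onto floors are excluded with a warning and
#' counted in the result.
#'
#' @param dataset a `labeled_dataset`.
#' @param registry a [template_registry()].
#' @param config a [training_config()].
#' @param model starting model supplying the blocking table, alignment
#'   parameters and ambiguity band.
#' @return a `training_result` list: `model` (fitted), `training_accuracy`,
#'   `confusion`, `loss_trajectory`, `n_excluded`, `config`.
#' @export
fit_model <- function(dataset, registry = default_registry(),
                      config = training_config(), model = default_model()) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(config, "training_config"))
  prep <- prepare_training_data(dataset, registry, model)
  data <- prep$dataset
  n <- nrow(data)
  label_carbon <- carbon_count(data$label)
  # blocking values per floor: n x 3 matrices
  bmat <- lapply(1:3, function(f)
    t(vapply(prep$bvals, function(m) m[f, ], numeric(3))))

  grid <- simplex_grid(config$k)
  W <- grid$W
  K <- ncol(W)

  weights <- matrix(1 / 3, 3, 3,
                    dimnames = list(paste0("floor", 1:3), paste0("site", 1:3)))
  theta <- rep(Inf, 3)
  trajectory <- numeric(0)
  for (round in seq_len(config$max_rounds)) {
    prev_w <- weights; prev_t <- theta
    for (f in 1:3) {
      sweep <- sweep_floor(f, bmat, weights, theta, label_carbon,
                           config$loss, W, grid$nonuniformity)
      weights[f, ] <- sweep$w
      theta[f] <- sweep$theta
    }
    trajectory <- c(trajectory,
                    total_loss(bmat, weights, theta, label_carbon, config$loss))
    if (identical(weights, prev_w) && identical(theta, prev_t)) break
  }

  # a floor no training record ever reaches keeps a pass-all threshold;
  # replace the sentinel with a finite value above every observed score
  if (any(!is.finite(theta))) {
    scores <- floor_scores(bmat, weights)
    for (f in which(!is.finite(theta)))
      theta[f] <- max(scores[, f]) + 1
  }

  fitted <- predictor_model(
    blocking = model$blocking, weights = weights,
    thresholds = floor_thresholds(theta, model$thresholds$delta),
    align_params = model$align_params, registry_tag = registry$tag)

  if (config$fit_blocking)
    fitted <- refine_blocking(fitted, prep, label_carbon, config)

  report <- predict_batch(data, registry, fitted)
  evaluation <- score_predictions(report, data)
  out <- list(model = fitted,
              training_accuracy = evaluation$exact_accuracy,
              confusion = evaluation$confusion,
              loss_trajectory = trajectory,
              n_excluded = prep$n_excluded,
              excluded_ids = prep$excluded_ids,
              config = config)
  class(out) <- "training_result"
  out
}

# floor scores under given weights: n x 3 matrix (columns = floors)
floor_scores <- function(bmat, weights) {
  vapply(1:3, function(f) as.numeric(bmat[[f]] %*% weights[f, ]),
         numeric(nrow(bmat[[1]])))
}

predicted_class_idx <- function(scores, theta) {
  blocked <- sweep(scores, 2, theta, ">")
  idx <- max.col(cbind(blocked, TRUE), ties.method = "first")
  pmin(idx, 4L)
}

total_loss <- function(bmat, weights, theta, label_carbon, loss) {
  scores <- floor_scores(bmat, weights)
  sum(loss_value(predicted_class_idx(scores, theta), label_carbon, loss))
}

# optimize (w_f, theta_f) with the other floors held fixed
sweep_floor <- function(f, bmat, weights, theta, label_carbon, loss,
                        W, nonuniformity) {
  n <- length(label_carbon)
  scores_other <- floor_scores(bmat, weights)  # only floors != f used
  blocked_other <- sweep(scores_other, 2, theta, ">")

  reach <- rep(TRUE, n)
  if (f > 1)
    reach <- !apply(blocked_other[, seq_len(f - 1), drop = FALSE], 1, any)
  # class when floor f passes: first blocked floor below, else open tunnel
  below <- (f + 1):3
  class_if_pass <- rep(4L, n)
  if (f < 3) {
    sub <- blocked_other[, below, drop = FALSE]
    hit <- max.col(cbind(sub, TRUE), ties.method = "first")
    class_if_pass <- pmin(f + hit, 4L)
  }
  # records stopped above floor f keep their class regardless of (w_f, theta_f)
  const_loss <- 0
  if (any(!reach)) {
    stopped <- which(!reach)
    first_block <- max.col(blocked_other[stopped, seq_len(f - 1), drop = FALSE],
                           ties.method = "first")
    const_loss <- sum(loss_value(first_block, label_carbon[stopped], loss))
  }
  m <- sum(reach)
  if (m == 0)  # nothing reaches this floor; keep current parameters
    return(list(w = weights[f, ], theta = theta[f]))

  lb <- loss_value(rep(f, m), label_carbon[reach], loss)
  lp <- loss_value(class_if_pass[reach], label_carbon[reach], loss)
  S_all <- bmat[[f]][reach, , drop = FALSE] %*% W  # m x K

  best <- NULL
  for (k in seq_len(ncol(W))) {
    s <- S_all[, k]
    o <- order(s)
    s_o <- s[o]
    d_o <- (lb - lp)[o]
    cum <- cumsum(d_o)
    total_d <- cum[m]
    u <- unique(s_o)
    nu <- length(u)
    last_idx <- findInterval(u, s_o)
    # candidates in ascending theta order: a block-all sentinel below the
    # minimum, midpoints between consecutive distinct scores, and a pass-all
    # sentinel above the maximum; midpoints keep the fitted threshold clear
    # of any observed score, so strict comparisons are stable
    cand_theta <- c(u[1] - 1,
                    if (nu > 1) (u[-nu] + u[-1]) / 2,
                    u[nu] + 1)
    cand_loss <- c(sum(lp) + total_d,
                   sum(lp) + total_d - cum[last_idx])
    # among equal-loss thresholds take the highest: a permissive floor keeps
    # records flowing to the floors below it, which coordinate descent needs
    # to train them (a block-everything tie would starve floors 2 and 3)
    j <- max(which(cand_loss == min(cand_loss)))
    cand <- list(loss = cand_loss[j] + const_loss, theta = cand_theta[j],
                 nonuni = nonuniformity[k], k = k)
    if (is.null(best) ||
        cand$loss < best$loss - 1e-12 ||
        (abs(cand$loss - best$loss) <= 1e-12 &&
         (cand$nonuni < best$nonuni - 1e-12 ||
          (abs(cand$nonuni - best$nonuni) <= 1e-12 &&
           cand$theta > best$theta + 1e-12))))
      best <- cand
  }
  list(w = W[, best$k], theta = best$theta)
}

# optional greedy refinement of the blocking table, one residue at a time
refine_blocking <- function(fitted, prep, label_carbon, config) {
  current <- fitted$blocking
  base_loss <- blocking_loss(current, fitted, prep, label_carbon, config$loss)
  for (aa in AA20) {
    for (mult in c(0.9, 1.1)) {
      candidate <- current
      candidate[aa] <- round(current[aa] * mult, 4)
      ok <- tryCatch({validate_blocking_table(candidate); TRUE},
                     error = function(e) FALSE)
      if (!ok) next
      cand_loss <- blocking_loss(candidate, fitted, prep, label_carbon,
                                 config$loss)
      if (cand_loss < base_loss - 1e-12) {
        current <- candidate
        base_loss <- cand_loss
      }
    }
  }
  predictor_model(blocking = current, weights = fitted$weights,
                  thresholds = fitted$thresholds,
                  align_params = fitted$align_params,
                  registry_tag = fitted$registry_tag)
}

blocking_loss <- function(blocking, fitted, prep, label_carbon, loss) {
  bvals <- lapply(prep$residues, residue_blocking, blocking)
  bmat <- lapply(1:3, function(f)
    t(vapply(bvals, function(m) m[f, ], numeric(3))))
  total_loss(bmat, fitted$weights, fitted$thresholds$theta, label_carbon, loss)
}

#' Stratified cross-validation of the fitting procedure
#'
#' Folds are stratified by product class; a class with fewer members than
#' folds is merged into a common stratum with a warning. The partition is
#' deterministic for a given `config$seed`. Each fold's held-out accuracy is
#' the exact accuracy of [score_predictions()] under the model fitted on the
#' remaining records.
#'
#' @param dataset a `labeled_dataset`.
#' @param registry a [template_registry()].
#' @param config a [training_config()].
#' @param folds number of folds, between 2 and the dataset size;
#'   `folds = nrow(dataset)` is leave-one-out.
#' @param model starting model (see [fit_model()]).
#' @return list with `fold_accuracy`, `mean_accuracy`, and the integer
#'   `fold` assignment per record.
#' @export
cross_validate <- function(dataset, registry = default_registry(),
                           config = training_config(), folds = 5,
                           model = default_model()) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  n <- nrow(dataset)
  if (folds < 2 || folds > n)
    stop("folds must be between 2 and the dataset size (", n, ")")
  usable <- dataset$label != "NA"
  data <- dataset[usable, , drop = FALSE]
  n <- nrow(data)

  counts <- table(data$label)
  small <- names(counts)[counts < folds]
  if (length(small) > 0)
    warning("class(es) with fewer members than folds merged into one stratum: ",
            paste(small, collapse = ", "))
  stratum <- ifelse(data$label %in% small, ".merged", data$label)

  fold <- integer(n)
  with_seed(config$seed, {
    for (s in unique(stratum)) {
      idx <- which(stratum == s)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })

  accuracy <- vapply(seq_len(folds), function(kf) {
    train <- data[fold != kf, , drop = FALSE]
    test <- data[fold == kf, , drop = FALSE]
    if (nrow(test) == 0) return(NA_real_)
    fitted <- fit_model(train, registry, config, model)$model
    report <- predict_batch(test, registry, fitted)
    score_predictions(report, test)$exact_accuracy
  }, numeric(1))
  list(fold_accuracy = accuracy,
       mean_accuracy = mean(accuracy, na.rm = TRUE),
       fold = fold)
}
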