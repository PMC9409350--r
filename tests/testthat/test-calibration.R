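# Coarser grids than the default keep these fits fast; the full-resolution
# grid is exercised by the acceptance suite.

test_that("training configuration validates its grid", {
  expect_error(training_config(grid_step = 0.03), "divide 1 evenly")
  cfg <- training_config(grid_step = 0.05, seed = 3)
  expect_equal(cfg$k, 20L)
  expect_equal(cfg$seed, 3L)
})

test_that("the simplex grid enumerates exactly the normalized triples", {
  g <- threefloors:::simplex_grid(10)
  expect_equal(ncol(g$W), 66)  # (k+1)(k+2)/2
  expect_equal(colSums(g$W), rep(1, 66))
  expect_true(all(g$W >= 0))
})

test_that("two records separated at floor-1 site 2 get a separating threshold", {
  tpl <- REG$templates[["5E8H"]]
  pos <- tpl$floor_positions[1, ]
  blocked <- substitute_at(tpl$sequence,
                           stats::setNames(c("K", "W", "K"), pos))
  open <- substitute_at(tpl$sequence,
                        stats::setNames(c("K", "G", "K"), pos))
  ds <- make_labels(c("blocked", "open"), c(blocked, open), c("C15", "C20"))
  res <- fit_model(ds, REG, training_config(grid_step = 0.1))
  m <- res$model
  s_blocked <- floor_blocking_score(
    map_floor_residues(select_best_template(blocked, REG), registry = REG),
    1, m)
  s_open <- floor_blocking_score(
    map_floor_residues(select_best_template(open, REG), registry = REG),
    1, m)
  expect_gt(s_blocked, m$thresholds$theta[1])
  expect_lte(s_open, m$thresholds$theta[1])
  expect_equal(res$training_accuracy, 1)
})

test_that("refitting with the same seed and config is bit-identical", {
  ds <- generate_floor_variants(
    REG, MOD, generator_config(quota = c(C15 = 3, C20 = 3, GE_C30 = 3),
                               seed = 8))
  cfg <- training_config(grid_step = 0.1)
  r1 <- fit_model(ds, REG, cfg)
  r2 <- fit_model(ds, REG, cfg)
  expect_identical(r1$model, r2$model)
  expect_identical(r1$loss_trajectory, r2$loss_trajectory)
})

test_that("separable synthetic data is fit to training accuracy 1", {
  ds <- generate_training_set(REG, MOD, n = 42, seed = 12)
  res <- fit_model(ds, REG, training_config(grid_step = 0.05))
  expect_equal(res$training_accuracy, 1)
  w <- res$model$weights
  expect_equal(rowSums(w), c(floor1 = 1, floor2 = 1, floor3 = 1))
  expect_true(all(w >= 0))
  # reported accuracy is recomputable from the fitted model on the same data
  rep <- predict_batch(ds, REG, res$model)
  expect_equal(score_predictions(rep, ds)$exact_accuracy,
               res$training_accuracy)
})

test_that("single-class data and NA labels are handled as specified", {
  ds <- make_labels(c("a", "b"),
                    rep(REG$templates[["5E8H"]]$sequence, 2),
                    c("C20", "C20"))
  expect_error(fit_model(ds, REG, training_config(grid_step = 0.2)),
               "at least 2 classes")
  ds2 <- make_labels(c("a", "b", "c"),
                     c(REG$templates[["5E8H"]]$sequence,
                       REG$templates[["1FPS"]]$sequence,
                       REG$templates[["2FOR"]]$sequence),
                     c("C20", "C15", "NA"))
  expect_message(res <- fit_model(ds2, REG, training_config(grid_step = 0.2)),
                 "excluding 1 NA-labeled")
  expect_equal(res$n_excluded, 1)
})

test_that("cross-validation is stratified, seeded, and warns on tiny classes", {
  ds <- generate_floor_variants(
    REG, MOD, generator_config(quota = c(C15 = 4, C20 = 4, C25 = 1), seed = 2))
  cfg <- training_config(grid_step = 0.2, seed = 5)
  expect_warning(cv <- cross_validate(ds, REG, cfg, folds = 3),
                 "fewer members than folds.*C25")
  expect_length(cv$fold_accuracy, 3)
  expect_equal(sort(unique(cv$fold)), 1:3)
  expect_warning(cv2 <- cross_validate(ds, REG, cfg, folds = 3), ".")
  expect_identical(cv$fold, cv2$fold)
  expect_error(cross_validate(ds, REG, cfg, folds = 1), "folds")
})

test_that("held-out accuracy does not exceed training accuracy on separable data", {
  accs <- vapply(1:3, function(seed) {
    ds <- generate_floor_variants(
      REG, MOD, generator_config(quota = c(C15 = 3, C20 = 3, GE_C30 = 3),
                                 seed = seed))
    cfg <- training_config(grid_step = 0.2, seed = seed)
    fit <- fit_model(ds, REG, cfg)
    cv <- cross_validate(ds, REG, cfg, folds = 3)
    c(cv$mean_accuracy, fit$training_accuracy)
  }, numeric(2))
  expect_true(mean(accs[1, ]) <= mean(accs[2, ]) + 1e-9)
})
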