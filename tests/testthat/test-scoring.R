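test_that("the default blocking table satisfies its structural invariants", {
  b <- default_blocking_table()
  expect_setequal(names(b), threefloors:::AA20)
  expect_equal(unname(b["G"]), 0)
  expect_equal(unname(which.min(b[threefloors:::AA20])), 8L)  # glycine
  expect_gte(b[["W"]], b[["A"]])
  expect_true(all(b >= 0))
  # rigid aromatics block more than flexible chains of similar volume
  expect_gt(b[["F"]], b[["K"]])
  expect_gt(b[["Y"]], b[["R"]])
})

test_that("floor weights are per-floor normalized", {
  w <- default_weights()
  expect_equal(rowSums(w), c(floor1 = 1, floor2 = 1, floor3 = 1))
  expect_error(threefloors:::validate_weights(w * 2), "sum to 1")
  w2 <- w; w2[1, 1] <- -w2[1, 1]
  expect_error(threefloors:::validate_weights(w2), "nonnegative")
})

test_that("a uniform-residue floor scores exactly that residue's blocking", {
  for (aa in c("G", "A", "W")) {
    fa <- floor_assignment(rep(aa, 9))
    expect_equal(floor_blocking_score(fa, 2, MOD),
                 unname(MOD$blocking[aa]))
  }
})

test_that("floor scores equal the hand-computed weighted sum", {
  fa <- floor_assignment(c("A", "T", "I", "L", "F", "M", "G", "S", "W"))
  b <- MOD$blocking
  w <- MOD$weights
  expect_equal(floor_blocking_score(fa, 1, MOD),
               w[1, 1] * b[["A"]] + w[1, 2] * b[["T"]] + w[1, 3] * b[["I"]])
  expect_equal(floor_blocking_score(fa, 2, MOD),
               w[2, 1] * b[["L"]] + w[2, 2] * b[["F"]] + w[2, 3] * b[["M"]])
  expect_equal(floor_blocking_score(fa, 3, MOD),
               w[3, 1] * b[["G"]] + w[3, 2] * b[["S"]] + w[3, 3] * b[["W"]])
})

test_that("raising a positively weighted site's blocking raises the score", {
  fa <- floor_assignment(c("A", "C", "A", rep("G", 6)))
  boosted <- MOD$blocking
  boosted["C"] <- boosted["C"] * 2
  m2 <- predictor_model(blocking = boosted)
  expect_gt(floor_blocking_score(fa, 1, m2), floor_blocking_score(fa, 1, MOD))
})

test_that("gap sites contribute zero blocking", {
  fa <- floor_assignment(c("W", NA, "W", rep("G", 6)))
  w <- MOD$weights
  expect_equal(floor_blocking_score(fa, 1, MOD),
               (w[1, 1] + w[1, 3]) * MOD$blocking[["W"]])
})

test_that("the cascade maps every score triple to exactly one primary class", {
  th <- MOD$thresholds
  set.seed(41)
  for (i in 1:200) {
    s <- stats::runif(3, 0, 0.9)
    call <- cascade(s, th)
    expect_true(call$primary %in% predictable_classes())
    if (!is.na(call$secondary))  # dual calls are adjacent only
      expect_equal(abs(carbon_count(call$secondary) -
                         carbon_count(call$primary)), 5L)
    # verbatim cascade semantics
    expected <- if (s[1] > th$theta[1]) "C15"
                else if (s[2] > th$theta[2]) "C20"
                else if (s[3] > th$theta[3]) "C25" else "GE_C30"
    expect_equal(call$primary, expected)
  }
})

test_that("threshold equality falls through to the next floor", {
  th <- floor_thresholds(c(0.4, 0.4, 0.4), delta = 0)
  expect_equal(cascade(c(0.4, 0.5, 0), th)$primary, "C20")
  expect_equal(cascade(c(0.4, 0.4, 0.4), th)$primary, "GE_C30")
})

test_that("saturated and open tunnels give clean single calls", {
  expect_equal(cascade(c(0.9, 0.9, 0.9), MOD$thresholds),
               list(primary = "C15", secondary = NA_character_,
                    decisive_floor = 1L, ambiguous = FALSE))
  expect_equal(cascade(c(0.01, 0.01, 0.01), MOD$thresholds)$primary, "GE_C30")
})

test_that("near-threshold comparisons emit adjacent dual calls", {
  th <- floor_thresholds(c(0.43, 0.41, 0.43), delta = 0.05)
  # floor 2 passed just under threshold, floor 3 blocked: C20/C25
  call <- cascade(c(0.1, 0.40, 0.6), th)
  expect_equal(call$primary, "C25")
  expect_equal(call$secondary, "C20")
  expect_equal(format_product_class(call$primary, call$secondary), "C20/C25")
  # floor 2 blocked just above threshold with floor 3 blocked below it
  call2 <- cascade(c(0.1, 0.42, 0.6), th)
  expect_equal(call2$primary, "C20")
  expect_equal(call2$secondary, "C25")
  # open tunnel with floor 3 marginally passed: C25/>=C30
  call3 <- cascade(c(0.1, 0.1, 0.425), th)
  expect_equal(call3$primary, "GE_C30")
  expect_equal(call3$secondary, "C25")
})

test_that("a marginal block with a non-adjacent continuation is flagged", {
  th <- floor_thresholds(c(0.43, 0.41, 0.43), delta = 0.05)
  call <- cascade(c(0.44, 0.1, 0.1), th)  # would continue to GE_C30
  expect_equal(call$primary, "C15")
  expect_true(is.na(call$secondary))
  expect_true(call$ambiguous)
})

test_that("elongation route orders sites by descending weight", {
  w <- default_weights()
  w[2, ] <- c(0.200, 0.553, 0.247)
  m <- predictor_model(weights = w)
  route <- trace_elongation_route(m)
  expect_equal(unname(route[2, ]), c(2L, 3L, 1L))
  uni <- predictor_model(weights = matrix(1 / 3, 3, 3))
  expect_equal(unname(trace_elongation_route(uni)[1, ]), c(1L, 2L, 3L))
})

test_that("model serialization round-trips bit-exactly", {
  path <- withr::local_tempfile(fileext = ".json")
  save_model(MOD, path)
  back <- load_model(path)
  expect_identical(back$blocking, MOD$blocking)
  expect_identical(back$weights, MOD$weights)
  expect_identical(back$thresholds, MOD$thresholds)
  expect_identical(back$align_params$gap_open, MOD$align_params$gap_open)
  expect_identical(back$registry_tag, MOD$registry_tag)
})

test_that("six-site mode drops the near-zero sites and renormalizes", {
  m6 <- default_model(six_site = TRUE)
  expect_equal(m6$weights[1, 3], 0)
  expect_equal(m6$weights[3, 3], 0)
  expect_equal(rowSums(m6$weights), c(floor1 = 1, floor2 = 1, floor3 = 1))
  # the worked floor pattern is unaffected: still a C20 call
  fa <- floor_assignment(c("A", "T", "I", "L", "F", "M", "G", "G", "G"))
  expect_equal(prediction_from_assignment(fa, m6)$primary, "C20")
})

test_that("end-to-end prediction is deterministic", {
  query <- REG$templates[["2E8W"]]$sequence
  p1 <- predict_chain_length(query, REG, MOD)
  p2 <- predict_chain_length(query, REG, MOD)
  expect_identical(p1, p2)
  expect_false(p1$primary %in% c("C10", "NA"))
})
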