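test_that("class quotas are met exactly and labels close the loop", {
  cfg <- generator_config(quota = c(C15 = 5, C20 = 5, C25 = 5, GE_C30 = 5),
                          seed = 7)
  ds <- generate_floor_variants(REG, MOD, cfg)
  expect_equal(nrow(ds), 20)
  expect_equal(as.vector(table(factor(ds$label, predictable_classes()))),
               c(5L, 5L, 5L, 5L))
  # closed loop: every emitted label is reproduced by predict()
  for (i in seq_len(nrow(ds)))
    expect_equal(predict_chain_length(ds[i, , drop = FALSE], REG, MOD)$primary,
                 ds$label[i])
})

test_that("zero background rate mutates floor sites only", {
  cfg <- generator_config(quota = c(C20 = 3), seed = 5, background_rate = 0)
  ds <- generate_floor_variants(REG, MOD, cfg)
  backbone <- REG$templates[["5E8H"]]
  floors <- as.vector(backbone$floor_positions)
  for (i in seq_len(nrow(ds))) {
    v <- strsplit(ds$residues[i], "")[[1]]
    b <- strsplit(backbone$sequence, "")[[1]]
    expect_true(all(which(v != b) %in% floors))
  }
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- generator_config(quota = c(C15 = 2, GE_C30 = 2), seed = 42,
                          background_rate = 0.05)
  expect_identical(generate_floor_variants(REG, MOD, cfg),
                   generate_floor_variants(REG, MOD, cfg))
  cfg2 <- generator_config(quota = c(C15 = 2, GE_C30 = 2), seed = 43,
                           background_rate = 0.05)
  expect_false(identical(generate_floor_variants(REG, MOD, cfg)$residues,
                         generate_floor_variants(REG, MOD, cfg2)$residues))
})

test_that("background mutation rate never touches floor-site residues", {
  backbone <- REG$templates[["5E8H"]]
  floors <- as.vector(t(backbone$floor_positions))
  for (rate in c(0, 0.2)) {
    cfg <- generator_config(quota = c(C25 = 2), seed = 9,
                            background_rate = rate)
    ds <- generate_floor_variants(REG, MOD, cfg)
    chars <- strsplit(ds$residues[1], "")[[1]]
    expect_true(all(chars[floors[1:6]] %in% threefloors:::SMALL_POOL))
    expect_true(all(chars[floors[7:9]] %in% threefloors:::BULKY_POOL))
  }
})

test_that("generator validates its configuration", {
  expect_error(generator_config(background_rate = 0.5), "background_rate")
  expect_error(generator_config(quota = c(C99 = 5)), "quota names")
  expect_error(
    generate_floor_variants(REG, MOD,
                            generator_config(backbone = "XXXX",
                                             quota = c(C15 = 1))),
    "backbone template")
})

test_that("an unreachable class is reported by name", {
  # with an all-glycine 'bulky' pool no floor can ever block
  cfg <- generator_config(quota = c(C15 = 1), seed = 1,
                          bulky = c("G"), small = c("G"))
  expect_error(generate_floor_variants(REG, MOD, cfg), "unreachable.*C15")
})

test_that("site probes are deterministic and show per-site asymmetry", {
  probes <- generate_site_probes(REG, MOD)
  expect_equal(nrow(probes), 27)
  expect_identical(probes, generate_site_probes(REG, MOD))
  lab <- stats::setNames(probes$label, probes$id)
  # tryptophan at floor-1 site 1 or 2 blocks the first floor; at the
  # near-zero-weight site 3 the chain passes on to the (blocked) second floor
  expect_equal(unname(lab[c("probe_f1_baseK_s1", "probe_f1_baseK_s2",
                            "probe_f1_baseK_s3")]), c("C15", "C15", "C20"))
  # floor 2 is dominated by site 2
  expect_equal(unname(lab[c("probe_f2_baseG_s1", "probe_f2_baseG_s2",
                            "probe_f2_baseG_s3")]), c("C25", "C20", "C25"))
  # floor 3 mirrors floor 1: site 3 carries almost no weight
  expect_equal(unname(lab[c("probe_f3_baseK_s1", "probe_f3_baseK_s2",
                            "probe_f3_baseK_s3")]), c("C25", "C25", "GE_C30"))
})

test_that("templates convert to a labeled dataset with native classes", {
  ds <- templates_as_dataset(REG)
  expect_equal(ds$id, names(REG$templates))
  expect_equal(ds$label,
               vapply(REG$templates, `[[`, character(1), "product_class"),
               ignore_attr = TRUE)
})

test_that("the assembled training set has the documented composition", {
  ds <- generate_training_set(REG, MOD, n = 45, seed = 1)
  expect_equal(nrow(ds), 45)
  expect_equal(sum(startsWith(ds$id, "probe_")), 27)
  expect_equal(sum(ds$id %in% names(REG$templates)), 11)
  expect_equal(sum(startsWith(ds$id, "syn_")), 7)
})
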