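test_that("the default bundle holds the 11 templates in fixed order", {
  expect_equal(names(REG$templates),
               c("2FOR", "3OYR", "3QQV", "3PKO", "1WMW", "3Q2Q",
                 "5E8H", "2E8W", "1FPS", "3AQ0", "1WY0"))
  expect_equal(REG$tag, "synthetic-registry-v1")
  for (t in REG$templates) {
    expect_length(unique(as.vector(t$floor_positions)), 9)
    expect_true(all(t$floor_positions >= 1 &
                      t$floor_positions <= nchar(t$sequence)))
  }
})

test_that("the shipped registry file is frozen output of its generator", {
  expect_equal(make_synthetic_registry()$templates, REG$templates)
})

test_that("registry round-trips load-save-load bit-exactly", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_registry(REG, path)
  back <- read_registry(path, tag = REG$tag)
  expect_equal(back, REG)
  expect_identical(readLines(path), {
    path2 <- withr::local_tempfile()
    write_registry(back, path2)
    readLines(path2)
  })
})

test_that("registry validation names the offending template", {
  tpl <- REG$templates[["2FOR"]]
  expect_error(template("2FOR", tpl$sequence, rep(5000L, 9), "C15", "Bacteria"),
               "2FOR.*9 distinct")
  expect_error(template("2FOR", tpl$sequence, c(1:8, 5000L), "C15", "Bacteria"),
               "2FOR.*outside sequence")
  expect_error(template("2FOR", tpl$sequence, 1:9, "C17", "Bacteria"),
               "product class")
  expect_error(template_registry(list(tpl, tpl)), "duplicate pdb id.*2FOR")
})

test_that("projection is the identity map when query equals the template", {
  tpl <- REG$templates[["1WY0"]]
  match <- select_best_template(tpl$sequence, REG)
  fa <- map_floor_residues(match, registry = REG)
  chars <- strsplit(tpl$sequence, "")[[1]]
  expect_equal(fa$residue, chars[as.vector(t(tpl$floor_positions))])
  expect_equal(fa$query_pos, as.vector(t(tpl$floor_positions)))
  expect_equal(attr(fa, "template_id"), "1WY0")
})

test_that("a single floor substitution changes exactly that entry", {
  tpl <- REG$templates[["5E8H"]]
  pos <- tpl$floor_positions[2, 2]
  old <- substr(tpl$sequence, pos, pos)
  new <- setdiff(c("W", "G"), old)[1]
  query <- substitute_at(tpl$sequence, stats::setNames(new, pos))
  fa <- map_floor_residues(select_best_template(query, REG), registry = REG)
  ref <- map_floor_residues(select_best_template(tpl$sequence, REG),
                            registry = REG)
  differs <- fa$residue != ref$residue
  expect_equal(which(differs), which(fa$floor == 2 & fa$site == 2))
  expect_equal(fa$residue[differs], new)
})

test_that("assignment is invariant to non-floor substitutions", {
  tpl <- REG$templates[["3AQ0"]]
  set.seed(33)
  mutable <- setdiff(seq_len(nchar(tpl$sequence)),
                     as.vector(tpl$floor_positions))
  subs <- sample(mutable, 8)
  repl <- vapply(subs, function(p)
    sample(setdiff(threefloors:::AA20, substr(tpl$sequence, p, p)), 1),
    character(1))
  query <- substitute_at(tpl$sequence, stats::setNames(repl, subs))
  fa <- map_floor_residues(select_best_template(query, REG), registry = REG)
  ref_chars <- strsplit(tpl$sequence, "")[[1]]
  expect_equal(fa$residue, ref_chars[as.vector(t(tpl$floor_positions))])
})

test_that("a deletion spanning a floor site yields a gap marker there only", {
  tpl <- REG$templates[["5E8H"]]
  pos <- tpl$floor_positions[1, 1]
  chars <- strsplit(tpl$sequence, "")[[1]]
  query <- paste(chars[-(pos:(pos + 1))], collapse = "")
  fa <- map_floor_residues(select_best_template(query, REG), registry = REG)
  expect_true(is.na(fa$residue[fa$floor == 1 & fa$site == 1]))
  expect_false(anyNA(fa$residue[!(fa$floor == 1 & fa$site == 1)]))
  pred <- prediction_from_assignment(fa, MOD)
  expect_true("gap_at_floor" %in% pred$flags)
})

test_that("an X at a floor site is rejected as unscorable", {
  tpl <- REG$templates[["5E8H"]]
  query <- substitute_at(tpl$sequence,
                         stats::setNames("X", tpl$floor_positions[3, 1]))
  expect_error(map_floor_residues(select_best_template(query, REG),
                                  registry = REG),
               "unscorable residue 'X'")
  expect_error(floor_assignment(c("A", "X", "A", rep("G", 6))),
               "unscorable residue 'X'")
})

test_that("three-letter floor residue codes are accepted", {
  fa <- floor_assignment(c("Ala", "Thr", "Ile", "Leu", "Phe", "Met",
                           "Gly", "Gly", "Gly"))
  expect_equal(fa$residue[1:6], c("A", "T", "I", "L", "F", "M"))
})
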