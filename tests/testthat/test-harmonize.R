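test_that("gingivitis scoring follows each era's rule", {
  expect_identical(gingivitis_score("ERA1", c(3, 3, 3, 3)), 12L)
  expect_identical(gingivitis_score("ERA1", c(2, 2, 2, 2)), 8L)
  expect_false(gingivitis_flag("ERA1", gingivitis_score("ERA1", c(2, 2, 2, 2))))
  expect_identical(gingivitis_score("ERA2", c(rep("2", 7), rep(NA, 5))), 7L)
  expect_identical(gingivitis_score("ERA2", c("1", "1", "2", NA)), 1L)  # only code 2 counts
  expect_identical(gingivitis_score("ERA3", c(rep("1", 4), rep(NA, 8))), 4L)
  expect_identical(gingivitis_score("ERA3", c("X", "1")), 1L)  # missing tooth scores 0
  expect_error(gingivitis_score("ERA1", c(4, 0, 0, 0)), "alphabet")
  expect_error(gingivitis_score("ERA3", "2"), "alphabet")
})

test_that("gingivitis flags threshold at 9 (ERA1) and 6 (ERA2/ERA3)", {
  expect_true(gingivitis_flag("ERA1", 9L))
  expect_false(gingivitis_flag("ERA1", 8L))
  expect_true(gingivitis_flag("ERA3", 6L))
  expect_false(gingivitis_flag("ERA2", 5L))
})

test_that("pocket counting: ERA1 flag, ERA2 code-5 only, ERA3 indicator sum", {
  expect_identical(pocket_count("ERA1", "X"), "X")
  expect_identical(pocket_count("ERA1", NA), NA_character_)
  expect_identical(pocket_count("ERA2", c("5", "5", "5", "4", "4", rep(NA, 7))), 3L)
  expect_identical(pocket_count("ERA3", rep("1", 12)), 12L)
  expect_identical(pocket_count("ERA3", c("1", "X", "0", rep(NA, 9))), 1L)
  expect_true(periodontitis_flag("ERA1", "X"))
  expect_false(periodontitis_flag("ERA1", NA_character_))
  expect_false(periodontitis_flag("ERA2", 5L))
  expect_true(periodontitis_flag("ERA3", 6L))
})

test_that("DMF-S counts qualifying surface codes per dentition and variant", {
  perm <- "11:M:1;12:D:2;13:B:4;14:L:6;15:O:0;16:M:0"
  expect_identical(dmf_surfaces(perm, "permanent", "ERA2"), 4L)
  expect_identical(dmf_surfaces(perm, "temporary", "ERA2"), 0L)
  tmp5 <- "55:O:5;54:M:5"
  expect_identical(dmf_surfaces(tmp5, "temporary", "ERA2"), 0L)
  expect_identical(dmf_surfaces(tmp5, "temporary", "ERA2", "scor_provided"), 2L)
  expect_identical(dmf_surfaces(tmp5, "temporary", "ERA1", "scor_provided"), 0L)
  expect_identical(dmf_surfaces("55:O:0", "temporary", "ERA3"), 0L)
  expect_identical(dmf_surfaces(NA_character_, "permanent", "ERA1"), 0L)
})

test_that("a fully blank record scores zero with all-blank indicators set", {
  agg <- harmonize_visits(make_visit("ERA2"))
  expect_identical(agg$gingivitis_score, 0L)
  expect_false(agg$gingivitis_flag)
  expect_true(agg$gingivitis_all_blank)
  expect_identical(agg$pocket_count, 0L)
  expect_false(agg$periodontitis_flag)
  expect_true(agg$periodontitis_all_blank)
  expect_identical(agg$dmf_total, 0L)
})

test_that("aggregate_visit composes the per-disease rules", {
  v <- make_visit("ERA1", ging_12 = "3", ging_16 = "2", ging_42 = "2", ging_46 = "2",
                  surfaces = "11:M:2;21:O:1;36:B:4")
  agg <- aggregate_visit(v)
  expect_identical(agg$gingivitis_score, 9L)
  expect_true(agg$gingivitis_flag)
  expect_false(agg$periodontitis_flag)
  expect_true(agg$periodontitis_all_blank)
  expect_identical(agg$DMF_S, 3L)
  expect_identical(agg$dmf_s, 0L)
  expect_identical(agg$dmf_total, 3L)
})

test_that("ERA2 code 4 never enters an aggregate but is reported diagnostically", {
  v <- make_visit("ERA2", poch_11 = "4", poch_12 = "4", poch_16 = "5")
  agg <- harmonize_visits(v)
  expect_identical(agg$pocket_count, 1L)
  expect_identical(agg$pocket_code4_count, 2L)
  expect_false(agg$periodontitis_flag)
})

test_that("an ERA1 gingivitis-positive visit always carries a grade-3 tooth", {
  # exhaustive: over all 4^4 grade tuples, a total >= 9 forces a 3
  grid <- expand.grid(0:3, 0:3, 0:3, 0:3)
  totals <- apply(grid, 1, function(g) gingivitis_score("ERA1", g))
  has3 <- apply(grid, 1, function(g) any(g == 3))
  expect_true(all(has3[totals >= 9]))
  expect_false(all(has3[totals >= 8]))  # 8 = (2,2,2,2) does not force a 3
})

test_that("raising one code from non-qualifying to qualifying never lowers a score", {
  base <- make_visit("ERA2", ging_11 = "1", poch_11 = "4")
  up <- make_visit("ERA2", ging_11 = "2", poch_11 = "5")
  a <- harmonize_visits(base); b <- harmonize_visits(up)
  expect_gte(b$gingivitis_score, a$gingivitis_score)
  expect_gte(b$pocket_count, a$pocket_count)
  # flag monotone across full score range
  for (s in 0:11) {
    expect_true(gingivitis_flag("ERA2", s + 1L) >= gingivitis_flag("ERA2", s))
    expect_true(periodontitis_flag("ERA3", s + 1L) >= periodontitis_flag("ERA3", s))
  }
})

test_that("caries variants agree whenever no code-5 surfaces exist", {
  set.seed(33)
  for (i in 1:50) {
    teeth <- sample(fdi_teeth(), 5)
    codes <- sample(c(0, 1, 2, 4, 6), 5, TRUE)
    s <- format_surfaces(teeth, sample(c("M", "D", "B", "L", "O"), 5, TRUE), codes)
    for (dent in c("temporary", "permanent")) {
      expect_identical(dmf_surfaces(s, dent, "ERA2", "international"),
                       dmf_surfaces(s, dent, "ERA2", "scor_provided"))
    }
  }
})

test_that("harmonization equals an independent naive re-count on random records", {
  set.seed(99)
  for (i in 1:200) {
    era <- sample(era_levels(), 1)
    d <- c(ERA1 = "era1", ERA2 = "era2", ERA3 = "era3")[[era]]
    schema <- dialect_schema(d)
    args <- list(era = era)
    for (col in schema$gingiva_cols) {
      args[[col]] <- sample(c(NA_character_, schema$gingiva_alphabet), 1)
    }
    if (era == "ERA1") {
      args$pato_pocket <- sample(c(NA_character_, "X"), 1)
    } else {
      for (col in schema$pocket_cols) {
        args[[col]] <- sample(c(NA_character_, schema$pocket_alphabet), 1)
      }
    }
    n_surf <- sample(0:6, 1)
    if (n_surf > 0) {
      args$surfaces <- format_surfaces(sample(fdi_teeth(), n_surf),
                                       sample(c("M", "D", "B", "L", "O"), n_surf, TRUE),
                                       sample(c(0, 1, 2, 4, 5, 6), n_surf, TRUE))
    }
    v <- do.call(make_visit, args)
    agg <- harmonize_visits(v)
    gcols <- unlist(v[1, schema$gingiva_cols])
    expect_identical(agg$gingivitis_score, naive_gingivitis_score(era, gcols))
    if (era != "ERA1") {
      pcols <- unlist(v[1, schema$pocket_cols])
      expect_identical(agg$pocket_count, naive_pocket_count(era, pcols))
    }
    expect_identical(agg$dmf_s, naive_dmf(v$surfaces, "temporary", era))
    expect_identical(agg$DMF_S, naive_dmf(v$surfaces, "permanent", era))
  }
})
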