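test_that("group coding follows the age-by-experience rule", {
  expect_equal(assign_group_code(16, 1), "16E1")
  expect_equal(assign_group_code(17, 2), "17E2")
  expect_equal(assign_group_code(18, 3), "18E3")
  expect_equal(assign_group_code(16, 8), "16EM")
  expect_equal(assign_group_code(17, 3), "17EM")
  # total on the declared domain, never an aggregate code
  grid <- expand.grid(age = 16:18, exp = 1:12)
  codes <- assign_group_code(grid$age, grid$exp)
  expect_true(all(codes %in% group_codes()$label))
  expect_false(any(grepl("all$", codes)))
  expect_error(assign_group_code(15, 1), "16, 17 or 18")
  expect_error(assign_group_code(16, 0), ">= 1")
})

test_that("records round-trip through delimited text byte-for-byte", {
  recs <- small_records()
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(recs, path)
  first <- readLines(path)
  again <- load_records(path)
  expect_equal(as.data.frame(again), as.data.frame(recs))
  write_records(again, path)
  expect_identical(readLines(path), first)
  # tab-separated accepted
  write_records(recs, path, sep = "\t")
  expect_equal(as.data.frame(load_records(path, sep = "\t")),
               as.data.frame(recs))
})

test_that("unknown tokens and missing columns are rejected with location", {
  df <- as.data.frame(small_records())
  df$injury[2] <- "XYZ"
  expect_error(injury_records(df), "row 2.*injury.*XYZ")
  df <- as.data.frame(small_records())
  df$cause[3] <- "Q"
  expect_error(injury_records(df), "row 3.*cause")
  df <- as.data.frame(small_records())
  df$injury[3] <- "ASH"  # head-only category on a spine record
  expect_error(injury_records(df), "body system 'spine'")
  expect_error(injury_records(small_records()[, -3]), "schema error.*body_system")
  df <- as.data.frame(small_records())
  df$month[1] <- 13L
  expect_error(injury_records(df), "month")
})

test_that("crosstab counts cells, preserves the grand total and ignores order", {
  cfg <- synthetic_config(n_records = 200, seed = 42)
  recs <- generate_registry(cfg)
  tab <- crosstab(recs, "injury", "group")
  expect_equal(sum(tab$counts), nrow(recs))
  shuffled <- recs[with_seed_sample(nrow(recs)), ]
  expect_equal(crosstab(shuffled, "injury", "group")$counts, tab$counts)
  one <- crosstab(recs[1, ], "injury", "group")
  expect_equal(sum(one$counts), 1L)
  expect_equal(sum(one$counts > 0), 1L)
  empty <- crosstab(recs[0, ], "injury", "group")
  expect_equal(sum(empty$counts), 0L)
})

test_that("records missing an axis drop only from tabulations over it", {
  recs <- small_records()  # one record has no cause
  by_injury <- crosstab(recs[recs$body_system == "head", ], "injury", "group")
  by_cause <- crosstab(recs[recs$body_system == "head", ], "cause", "group")
  expect_equal(sum(by_injury$counts), 2L)
  expect_equal(sum(by_cause$counts), 1L)
})

test_that("the packaged head-injury records reproduce the printed blocks", {
  recs <- head_injury_records()
  expect_equal(nrow(recs), 48L)
  tab <- crosstab(recs, "injury", "group")
  ref <- group_table_variant(fixture_table("table2_head_injuries"), "separate")
  expect_equal(tab$counts[rownames(ref$counts), colnames(ref$counts)],
               ref$counts)
  expect_equal(tab$counts["ASH", "16E1"], 12L)
  # ASH cause plays, via the combined cause-and-site axis
  ash <- recs[recs$injury == "ASH", ]
  cs <- crosstab(ash, "cause_site", "group")
  ref2 <- group_table_variant(fixture_table("table2_ash_causes"), "separate")
  expect_equal(cs$counts[rownames(ref2$counts), colnames(ref2$counts)],
               ref2$counts)
  # outcomes as reported in aggregate
  expect_equal(as.integer(table(ash$outcome)[c("recovered", "sequelae",
                                               "death", "unknown")]),
               c(13L, 6L, 2L, 7L))
})

test_that("proportion_summary sums blocks and honours printed margins", {
  head_tab <- fixture_table("table2_head_injuries")
  all_sel <- proportion_summary(head_tab)
  expect_equal(all_sel$fraction, 1)
  e_cols <- c("16E1", "17E2", "18E3")
  expect_equal(proportion_summary(head_tab, cols = e_cols)$count, 35)
  expect_equal(proportion_summary(head_tab, cols = e_cols,
                                  margins = "printed")$count, 35)
  # the spinal table's printed totals disagree with its cells in 16E1
  spine <- fixture_table("table2_spine_injuries")
  expect_equal(proportion_summary(spine, cols = e_cols)$count, 41)
  expect_equal(proportion_summary(spine, cols = e_cols,
                                  margins = "printed")$count, 43)
  expect_error(proportion_summary(head_tab, rows = "nope"), "unknown row")
  zero <- contingency_table(matrix(0L, 1, 1, dimnames = list("a", "b")))
  expect_error(proportion_summary(zero), "undefined fraction")
})

test_that("percent rounding is half-up to integer percent", {
  expect_equal(proportion_summary(fixture_table("table2_spine_injuries"),
                                  cols = c("16E1", "17E2", "18E3"),
                                  margins = "printed")$percent, 80)
  tab <- contingency_table(matrix(c(5L, 3L), 1,
                                  dimnames = list("r", c("a", "b"))))
  expect_equal(proportion_summary(tab, cols = "a")$percent, 63)  # 62.5 -> 63
})
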