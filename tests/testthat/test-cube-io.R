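test_that("top-category merge maps 3 to 2 and leaves other scores alone", {
  rec <- raw_qids_records(persons = "a", times = 1)
  rec$score <- rep(c(0L, 1L, 2L, 3L), 4)
  out <- merge_top_category(rec)
  expect_equal(nrow(out), nrow(rec))
  expect_equal(out$score, rep(c(0L, 1L, 2L, 2L), 4))
  rec$score[1] <- 5L
  expect_error(merge_top_category(rec), "invalid score",
               class = "hetcube_invalid_input")
})

test_that("composite items collapse by the maximum rule to 12 items", {
  rec <- raw_qids_records(persons = "a", times = 1, score = 0L)
  rec$score[rec$item %in% c("1", "3")] <- c(2L, 1L)
  rec$score[rec$item == "6"] <- 1L
  out <- recode_items(rec)
  expect_equal(nrow(out), 12L)
  expect_setequal(out$item, qids_item_order())
  expect_equal(out$score[out$item == "1-3"], 2L)   # max of (2, 0, 1)
  expect_equal(out$score[out$item == "6/7"], 1L)
  expect_equal(out$score[out$item == "8/9"], 0L)
  # idempotence on already-recoded records
  expect_identical(recode_items(out), out)
})

test_that("recoding flags violations of mutual exclusivity and missing parts", {
  rec <- raw_qids_records(persons = "a", times = 1, score = 0L)
  rec$score[rec$item %in% c("6", "7")] <- 1L
  expect_warning(out <- recode_items(rec), "both members nonzero")
  expect_equal(out$score[out$item == "6/7"], 1L)
  expect_error(recode_items(rec[rec$item != "2", ]), "incomplete",
               class = "hetcube_incomplete_data")
})

test_that("cube assembly enforces completeness and keeps QIDS item order", {
  rec <- tiny_records()
  cube <- build_cube(rec)
  expect_equal(dim(cube), c(2, 2, 2))
  expect_error(build_cube(rec[-1, ]), "missing data",
               class = "hetcube_missing_data")
  raw <- suppressWarnings(  # constant-score fixture triggers the exclusivity flag
    recode_items(raw_qids_records(persons = sprintf("p%02d", 1:3), times = 1:3)))
  cube2 <- build_cube(raw)
  expect_equal(dimnames(cube2)$items, qids_item_order())
  expect_equal(dim(cube2), c(3, 12, 3))
})

test_that("cube round-trips through long records and CSV byte-stably", {
  rec <- tiny_records(n = 3, m = 2, TT = 4)
  cube <- build_cube(rec)
  rec2 <- cube_to_records(cube)
  expect_identical(build_cube(rec2), cube)
  f <- tempfile(fileext = ".csv")
  write_records(rec2, f)
  first <- readBin(f, "raw", file.size(f))
  write_records(read_records(f), f)
  expect_identical(readBin(f, "raw", file.size(f)), first)
})

test_that("sum scores add the recoded items per person-time", {
  rec <- tiny_records(n = 2, m = 2, TT = 2)
  cube <- build_cube(rec)
  s <- sum_scores(cube)
  expect_equal(unname(s), apply(unclass(cube), c(1, 3), sum), ignore_attr = TRUE)
  all2 <- build_cube(within(tiny_records(3, 2, 2), score <- 2L))
  expect_true(all(sum_scores(all2) == 2 * 2))
  expect_error(sum_scores(unclass(cube) + 0.5), "integer",
               class = "hetcube_invalid_input")
  # permutation equivariance
  perm <- sum_scores(cube[c(2, 1), , ])
  expect_equal(unname(perm), unname(s[c(2, 1), ]))
})
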