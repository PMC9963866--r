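# crossdata: I/O round trip, invariant enforcement, aggregation arithmetic,
# CI classification and the CI -> 0-4 pollen-scale transform.

write_records_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  path
}

test_that("read_cross_records round-trips a well-formed TSV with typed fields", {
  df <- data.frame(female_taxon = c("A", "A", "B"), male_taxon = "B",
                   replicate_id = c("r1", "r2", "r3"),
                   pollen_score = c(4L, 2L, NA), fruit_set = c(TRUE, FALSE, TRUE),
                   fruit_weight = c(80.5, NA, 12.0),
                   seed_count = c(120L, NA, 3L),
                   seeds_sown = c(100L, 0L, 3L), seeds_germinated = c(90L, 0L, 0L))
  path <- write_records_tsv(df)
  rec <- suppressMessages(read_cross_records(path))
  expect_s3_class(rec, "cross_records")
  expect_identical(nrow(rec), 3L)
  expect_type(rec$pollen_score, "integer")
  expect_type(rec$fruit_set, "logical")
  expect_type(rec$fruit_weight, "double")
  expect_identical(rec$seed_count, c(120L, NA, 3L))
})

test_that("invariant violations are rejected naming row and field", {
  df <- data.frame(female_taxon = "A", male_taxon = "B", fruit_set = TRUE,
                   seeds_sown = 5L, seeds_germinated = 9L)
  expect_error(suppressMessages(read_cross_records(write_records_tsv(df))),
               "row 1.*seeds_germinated")
  df2 <- data.frame(female_taxon = c("A", "A"), male_taxon = "B",
                    pollen_score = c(2L, 7L), fruit_set = FALSE,
                    seeds_sown = 0L, seeds_germinated = 0L)
  expect_error(suppressMessages(read_cross_records(write_records_tsv(df2))),
               "row 2.*pollen_score")
  expect_error(suppressMessages(read_cross_records(
    write_records_tsv(df[0, ]))), "empty")
  df3 <- df; df3$female_taxon <- "A B"  # embedded space
  expect_error(validate_cross_records(df3), "unsupported characters")
})

test_that("fruit_set FALSE with seed data is rejected, or coerced in lenient mode", {
  df <- data.frame(female_taxon = "A", male_taxon = "B", fruit_set = FALSE,
                   seed_count = 10L, seeds_sown = 0L, seeds_germinated = 0L)
  path <- write_records_tsv(df)
  expect_error(suppressMessages(read_cross_records(path)), "row 1.*fruit_set")
  rec <- suppressMessages(read_cross_records(path,
    cross_schema(lenient = TRUE)))
  # oracle: re-check the invariant on the loaded data
  bad <- !rec$fruit_set & (!is.na(rec$fruit_weight) | !is.na(rec$seed_count))
  expect_false(any(bad, na.rm = TRUE))
})

test_that("aggregation arithmetic: means, fruit fraction, pooled germination", {
  rec <- make_records(
    list(pollen_score = 4L, fruit_set = NA),
    list(pollen_score = 4L, fruit_set = NA),
    list(pollen_score = 2L, fruit_set = NA))
  s <- aggregate_crosses(rec)
  expect_equal(s$mean_pollen_score, 10 / 3)

  # 25 pollinations, 10 fruits -> 0.40 (hand count)
  fr <- do.call(make_records, lapply(seq_len(25), function(i)
    list(fruit_set = i <= 10,
         fruit_weight = if (i <= 10) 50 else NA,
         seed_count = if (i <= 10) 100L else NA)))
  expect_equal(aggregate_crosses(fr)$fruit_set_fraction, 0.40)

  # pooled germination: sown {10, 10}, germinated {0, 2} -> 0.10
  ge <- make_records(
    list(fruit_set = TRUE, seed_count = 10L, seeds_sown = 10L,
         seeds_germinated = 0L),
    list(fruit_set = TRUE, seed_count = 10L, seeds_sown = 10L,
         seeds_germinated = 2L))
  expect_equal(aggregate_crosses(ge)$germination_rate, 0.10)
})

test_that("aggregation is invariant to record order and warns on empty pairs", {
  rec <- make_records(
    list(pollen_score = 3L, fruit_set = TRUE, fruit_weight = 10,
         seed_count = 5L, seeds_sown = 5L, seeds_germinated = 1L),
    list(pollen_score = 1L, fruit_set = FALSE),
    list(female_taxon = "B", male_taxon = "A", pollen_score = 0L,
         fruit_set = FALSE))
  s1 <- aggregate_crosses(rec)
  s2 <- aggregate_crosses(rec[rev(seq_len(nrow(rec))), ])
  expect_equal(s1[order(s1$female_taxon), ], s2[order(s2$female_taxon), ],
               ignore_attr = TRUE)
  empty <- make_records(list(pollen_score = NA, fruit_set = NA))
  expect_warning(aggregate_crosses(empty), "all stage values missing")
})

test_that("crossability classification follows the decision cascade", {
  # all tubes halted before stigma half, zero fruit -> level 8
  s8 <- make_summary("A", "B", mean_pollen_score = 0, modal_pollen_score = 0L,
                     any_fertilized = FALSE, fruit_set_fraction = 0,
                     mean_fruit_weight = NA, mean_seed_count = NA,
                     germination_rate = NA)
  self <- make_summary("A", "A", hybrid_fertility = "fertile")
  expect_identical(classify_crossability(s8, self)$level, 8L)
  # arrest sites map to 7/6/5; ties break toward the more severe level
  for (mode in 1:3) {
    s <- s8; s$modal_pollen_score <- mode
    expect_identical(classify_crossability(s, self)$level, 8L - mode)
  }
  expect_identical(.modal_severe(c(0L, 0L, 3L, 3L, 2L)), 0L)

  # fruit set with seeds but zero germination -> level 4
  s4 <- make_summary("A", "B", germination_rate = 0)
  expect_identical(classify_crossability(s4, self)$level, 4L)

  # self-pollination with fertile progeny -> level 1
  expect_identical(classify_crossability(self, self)$level, 1L)

  # viable hybrids: fertility decides 2 vs 3
  s2 <- make_summary("A", "B", germination_rate = 0.5,
                     hybrid_fertility = "male_sterile")
  expect_identical(classify_crossability(s2, self)$level, 2L)
  s3 <- make_summary("A", "B", germination_rate = 0.5,
                     hybrid_fertility = "fully_sterile")
  expect_identical(classify_crossability(s3, self)$level, 3L)
  s3b <- make_summary("A", "B", germination_rate = 0.05)  # unknown fate, <10%
  expect_identical(classify_crossability(s3b, self)$level, 3L)

  # insufficient information -> explicit undetermined, never a default
  und <- make_summary("A", "B", germination_rate = 0.5,
                      hybrid_fertility = "unknown")
  cl <- classify_crossability(und, self)
  expect_true(is.na(cl$level))
  expect_identical(cl$reason, "germinating seed but hybrid fate unknown")

  # fertilized ovules observed yet no fruit and no germination path: starred
  sflag <- make_summary("A", "B", modal_pollen_score = 4L,
                        any_fertilized = TRUE, fruit_set_fraction = 0,
                        mean_fruit_weight = NA, mean_seed_count = NA,
                        germination_rate = NA)
  clf <- classify_crossability(sflag, self)
  expect_identical(clf$level, 4L)  # fertilization with no germinating seed

  # determinism: identical inputs give identical results
  expect_identical(classify_crossability(s8, self),
                   classify_crossability(s8, self))
})

test_that("ci_to_pollen_scale maps levels onto the 0-4 arrest scale", {
  expect_identical(ci_to_pollen_scale(8), 0L)
  expect_identical(ci_to_pollen_scale(1), 4L)
  all_levels <- ci_to_pollen_scale(1:8)
  expect_identical(all_levels, c(4L, 4L, 4L, 4L, 3L, 2L, 1L, 0L))
  expect_true(all(diff(all_levels) <= 0))  # monotone non-increasing
  expect_error(ci_to_pollen_scale(0), "out of range")
  expect_error(ci_to_pollen_scale(9), "out of range")

  # a cross whose tubes fertilize ovules always transforms to 4
  self <- make_summary("A", "A", hybrid_fertility = "fertile")
  for (germ in c(0, 0.5)) {
    s <- make_summary("A", "B", germination_rate = germ,
                      hybrid_fertility = "male_sterile")
    lvl <- classify_crossability(s, self)$level
    expect_identical(ci_to_pollen_scale(lvl), 4L)
  }
})

test_that("ci_matrix assembles levels, flags and reasons per directed pair", {
  summ <- bind_summaries(
    make_summary("A", "A", hybrid_fertility = "fertile"),
    make_summary("B", "B", hybrid_fertility = "fertile"),
    make_summary("A", "B", mean_pollen_score = 0, modal_pollen_score = 0L,
                 any_fertilized = FALSE, fruit_set_fraction = 0,
                 mean_fruit_weight = NA, mean_seed_count = NA,
                 germination_rate = NA),
    make_summary("B", "A", germination_rate = 0))
  ci <- ci_matrix(summ)
  expect_identical(ci$levels["A", "B"], 8L)
  expect_identical(ci$levels["B", "A"], 4L)
  expect_identical(ci$levels["A", "A"], 1L)
})
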