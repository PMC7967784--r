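test_that("accumulate_counts matches hand enumeration on a two-record fixture", {
  rec <- make_records(list(
    list(age = 70, sex = "male", chain = c("I25.1", "C34.9"), underlying = "C34.9"),
    list(age = 70, sex = "male", chain = "C34.9", underlying = "C34.9")))
  counts <- accumulate_counts(rec)
  get <- function(cause) counts[counts$cause == cause, ]
  expect_equal(get("C34.9")$occur, 2L)
  expect_equal(get("C34.9")$death, 2L)
  expect_equal(get("I25.1")$occur, 1L)
  expect_equal(get("I25.1")$death, 0L)
  expect_equal(attr(counts, "total_records"), 2L)
  expect_equal(nrow(accumulate_counts(rec[0, ])), 0L)
})

test_that("accumulate_counts equals an independent brute-force recount", {
  for (seed in 1:3) {
    coh <- generate_cohort(small_config(n = 500L, seed = seed,
                                        history_rate = 1))
    for (ih in c(TRUE, FALSE)) {
      fast <- as.data.frame(accumulate_counts(coh, include_history = ih))
      slow <- brute_force_counts(coh, include_history = ih)
      rownames(fast) <- rownames(slow) <- NULL
      expect_equal(fast, slow, ignore_attr = TRUE)
    }
  }
})

test_that("accumulate_counts requires labels and preserves death <= occur", {
  rec <- make_records(list(list(chain = "I25.1", underlying = "I25.1",
                                record_id = "lab1"),
                           list(chain = "C34.9", record_id = "unlab1")))
  expect_error(accumulate_counts(rec), "unlab1")
  for (seed in 4:6) {
    counts <- accumulate_counts(generate_cohort(small_config(n = 400L,
                                                             seed = seed)))
    expect_true(all(counts$death <= counts$occur))
    expect_true(all(counts$occur >= 0L))
    # each record contributes exactly one underlying death
    expect_equal(sum(counts$death), 400L)
  }
})

test_that("compute_cdcp matches closed-form arithmetic", {
  cells <- data.frame(cause = "I25.1", age_group = "old", gender = "male",
                      occur = 100L, death = 25L)
  ct <- structure(cells, total_records = 100L, include_history = TRUE,
                  class = c("count_table", "data.frame"))
  expect_equal(compute_cdcp(ct, "raw")$cells$cdcp, 0.25)
  expect_equal(compute_cdcp(ct, "log")$cells$cdcp, log2(2.5))
  ct$occur <- 10L; ct$death <- 0L
  expect_equal(compute_cdcp(ct, "raw", smoothing_alpha = 1)$cells$cdcp, 1 / 12)
  # saturation: death == occur
  ct$occur <- 7L; ct$death <- 7L
  expect_equal(compute_cdcp(ct, "raw")$cells$cdcp, 1)
  expect_equal(compute_cdcp(ct, "log")$cells$cdcp, log2(10))
  # zero-raw cells are dropped from the log table with a warning
  ct$death <- 0L
  expect_warning(tbl <- compute_cdcp(ct, "log"), "dropped")
  expect_equal(nrow(tbl$cells), 0L)
})

test_that("raw CDCP lies in [0,1], log is bounded by log2(10), rankings agree", {
  for (seed in 1:5) {
    counts <- accumulate_counts(generate_cohort(small_config(n = 300L,
                                                             seed = seed)))
    raw <- compute_cdcp(counts, "raw", smoothing_alpha = 0.5)
    lg <- compute_cdcp(counts, "log", smoothing_alpha = 0.5)
    expect_true(all(raw$cells$cdcp >= 0 & raw$cells$cdcp <= 1))
    expect_true(all(lg$cells$cdcp <= log2(10) + 1e-12))
    # log2(10x) is strictly increasing: identical within-stratum ranking
    key <- paste(raw$cells$age_group, raw$cells$gender)
    for (s in unique(key)) {
      expect_identical(order(raw$cells$cdcp[key == s]),
                       order(lg$cells$cdcp[key == s]))
    }
  }
})

test_that("compute_rdcp matches hand enumeration and normalizes per region", {
  rec <- make_records(list(
    list(chain = "I25.1", underlying = "I25.1"),
    list(chain = "I25.1", underlying = "I25.1"),
    list(chain = "C34.9", underlying = "C34.9")))
  rd <- compute_rdcp(rec)
  expect_equal(rd$rdcp[rd$cause == "I25.1"], 2 / 3)
  expect_equal(rd$rdcp[rd$cause == "C34.9"], 1 / 3)
  # degenerate: all deaths from one cause
  rec1 <- make_records(list(list(chain = "J60", underlying = "J60"),
                            list(chain = "J60", underlying = "J60")))
  expect_equal(compute_rdcp(rec1)$rdcp, 1)
  # per-region sums = 1 within 1e-9 on simulated multi-region cohorts
  for (seed in 1:5) {
    rd <- compute_rdcp(generate_cohort(small_config(n = 400L, seed = seed)))
    sums <- tapply(rd$rdcp, rd$region, sum)
    expect_true(all(abs(sums - 1) < 1e-9))
  }
})

test_that("lookup_cdcp falls back through pooled counts, not averaged values", {
  # cause seen twice in old females (1 death), once in young females (0 deaths)
  rec <- make_records(list(
    list(age = 70, sex = "female", chain = c("C34.9", "I25.1"), underlying = "C34.9"),
    list(age = 80, sex = "female", chain = c("C34.9", "J60"), underlying = "J60"),
    list(age = 10, sex = "female", chain = "C34.9", underlying = "C34.9")))
  tbl <- compute_cdcp(accumulate_counts(rec))
  # exact cell present
  expect_equal(lookup_cdcp(tbl, "C34.9", "old", "female"), 1 / 2)
  # gender-pooled: (old male) missing -> pooled over gender at old = 1/2
  expect_equal(lookup_cdcp(tbl, "C34.9", "old", "male"), 1 / 2)
  # age-pooled: J60 seen only in old females; (young male) falls through
  # gender pool (no J60 young cells) to age pool keyed by gender -> absent
  # for male, then global: 1/1
  expect_equal(lookup_cdcp(tbl, "J60", "young", "male"), 1)
  # never-seen cause stays absent under the full fallback chain
  expect_true(is.na(lookup_cdcp(tbl, "A41.9", "old", "female")))
  # policy "none" disables fallback
  expect_true(is.na(lookup_cdcp(tbl, "C34.9", "old", "male",
                                fallback_policy = "none")))
})

test_that("fitted tables serialize to JSON and round-trip byte-stably", {
  coh <- generate_cohort(small_config(n = 400L, seed = 11L))
  counts <- accumulate_counts(coh)
  paths <- c(withr::local_tempfile(fileext = ".json"),
             withr::local_tempfile(fileext = ".json"),
             withr::local_tempfile(fileext = ".json"))
  serialize_table(counts, paths[1])
  expect_equal(deserialize_table(paths[1]), counts)

  cdcp <- compute_cdcp(counts, "log", smoothing_alpha = 0.5)
  serialize_table(cdcp, paths[2])
  back <- deserialize_table(paths[2])
  expect_equal(back$cells, cdcp$cells)
  expect_equal(back$transform, "log")
  expect_equal(back$smoothing_alpha, 0.5)
  # deserialized tables answer pooled lookups identically
  q <- cdcp$cells[1:5, ]
  expect_equal(lookup_cdcp(back, q$cause, q$age_group, q$gender),
               lookup_cdcp(cdcp, q$cause, q$age_group, q$gender))
  # serialize-deserialize-serialize is byte-stable
  serialize_table(back, paths[3])
  expect_identical(readLines(paths[2]), readLines(paths[3]))

  rdcp <- compute_rdcp(coh)
  serialize_table(rdcp, paths[1])
  expect_equal(as.data.frame(deserialize_table(paths[1])),
               as.data.frame(rdcp))

  # empty count table round-trips
  empty <- accumulate_counts(coh[0, ])
  serialize_table(empty, paths[1])
  expect_equal(nrow(deserialize_table(paths[1])), 0L)

  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"format": "other"}', bad)
  expect_error(deserialize_table(bad), "sinkcod")
})
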