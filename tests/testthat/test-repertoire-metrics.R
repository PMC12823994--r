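test_that("metrics follow their definitions on worked examples", {
  m <- compute_metrics(clone_table(c("c1", "c2", "c3"), c(5, 3, 2)), k = 2)
  expect_equal(m$S, 10)
  expect_equal(m$D, 3)
  expect_equal(m$S_2, 8)
  expect_equal(m$P_2, 80)
  expect_equal(m$log10_S, 1)

  # k beyond richness: the top-k block is the whole repertoire
  m1 <- compute_metrics(clone_table("only", 7), k = 1000)
  expect_equal(m1$S, 7)
  expect_equal(m1$D, 1)
  expect_equal(m1$S_1000, 7)
  expect_equal(m1$P_1000, 100)

  # tie-saturated repertoire: every clone a singleton
  m2 <- compute_metrics(rep(1, 1500), k = 1000)
  expect_equal(m2$S, 1500)
  expect_equal(m2$D, 1500)
  expect_equal(m2$S_1000, 1000)
  expect_equal(m2$P_1000, 100 * 1000 / 1500)
})

test_that("metrics are invariant to clone ordering and match a sort oracle", {
  withr::local_seed(101)
  for (rep in 1:25) {
    n <- sample(1:50, 1)
    counts <- sample(1:40, n, replace = TRUE)
    ks <- sort(sample(1:60, 4))
    base <- compute_metrics(counts, k = ks)
    shuf <- compute_metrics(counts[sample.int(n)], k = ks)
    expect_equal(base, shuf)
    # brute-force oracle: sort the full vector, take partial sums directly
    srt <- sort(counts, decreasing = TRUE)
    for (k in ks) {
      expect_identical(base[[paste0("S_", k)]],
                       sum(srt[seq_len(min(k, n))]))
    }
    # S_k non-decreasing in k, S_D = S, P_k in (0, 100]
    sk <- vapply(ks, function(k) base[[paste0("S_", k)]], numeric(1))
    expect_true(all(diff(sk) >= 0))
    expect_identical(compute_metrics(counts, k = n)[[paste0("S_", n)]],
                     sum(counts))
    pk <- vapply(ks, function(k) base[[paste0("P_", k)]], numeric(1))
    expect_true(all(pk > 0 & pk <= 100))
  }
})

test_that("clone table validation rejects malformed input", {
  expect_error(clone_table(c("a", "b"), c(3, 0)), "non-positive")
  expect_error(clone_table(c("a", "b"), c(3, -1)), "non-positive")
  expect_error(clone_table(c("a", "b"), c(3, 2.5)), "fractional")
  expect_error(clone_table(c("a", "a"), c(3, 2)), "unique")
  expect_error(clone_table(character(0), numeric(0)), "empty")
})

test_that("simple and AIRR dialects parse, with format errors on bad files", {
  tmp <- withr::local_tempdir()
  simple <- file.path(tmp, "s1.tsv")
  writeLines(c("clone_id\ttemplates", "c1\t5", "c2\t3", "c3\t2"), simple)
  ct <- read_clone_table(simple)
  expect_s3_class(ct, "tcr_clone_table")
  expect_equal(nrow(ct), 3)
  expect_equal(sum(ct$templates), 10)
  expect_equal(subject_id(ct), "s1")

  zero <- file.path(tmp, "zero.tsv")
  writeLines(c("clone_id\ttemplates", "c1\t5", "c2\t0"), zero)
  expect_error(read_clone_table(zero), "row 2")

  airr <- file.path(tmp, "a1.tsv")
  writeLines(c("sequence_id\tclone_id\tduplicate_count",
               "r1\tcl1\t4", "r2\tcl2\t6"), airr)
  aa <- read_clone_table(airr, dialect = "airr")
  expect_equal(sum(aa$templates), 10)

  dup <- file.path(tmp, "dup.tsv")
  writeLines(c("clone_id\tduplicate_count", "cl1\t4", "cl1\t6"), dup)
  expect_error(read_clone_table(dup, dialect = "airr"), "unique")

  nocol <- file.path(tmp, "nocol.tsv")
  writeLines(c("foo\tbar", "x\t1"), nocol)
  expect_error(read_clone_table(nocol), "missing required column")

  empty <- file.path(tmp, "empty.tsv")
  writeLines("clone_id\ttemplates", empty)
  expect_error(read_clone_table(empty), "empty")
})

test_that("cohort assembly joins on subject id and reports exclusions", {
  mets <- dplyr::bind_rows(lapply(1:3, function(i) {
    m <- compute_metrics(clone_table(paste0("c", 1:4), c(9, 4, 2, 1),
                                     subject_id = paste0("s", i)), k = 2)
    m
  }))
  covs <- tibble::tibble(subject_id = paste0("s", 1:3),
                         age = c(30, 45, 60),
                         sex = c("male", "female", "female"),
                         cmv_status = c("negative", "positive", "unknown"))
  co <- build_cohort_table(mets, covs)
  expect_equal(nrow(co), 3)

  expect_message(co2 <- build_cohort_table(mets, covs[1:2, ]),
                 "excluded 1 unmatched")
  expect_equal(nrow(co2), 2)

  expect_error(build_cohort_table(mets, covs[c(1, 1, 2), ]),
               "duplicate subject_id")
  bad <- covs; bad$sex[1] <- "other"
  expect_error(build_cohort_table(mets, bad), "invalid sex")
})

test_that("cohort tables round-trip through CSV losslessly", {
  sim <- simulate_cohort(simulation_params(n_subjects = 25, seed = 9))
  cohort <- sim$cohort
  cohort$site <- rep(c("A", "B"), length.out = 25) # opaque extra covariate
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_cohort_table(cohort, tmp)
  back <- read_cohort_table(tmp)
  expect_equal(back[order(names(back))], cohort[order(names(cohort))],
               ignore_attr = TRUE)

  # file missing D is a format error
  broken <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::select(tibble::as_tibble(cohort), -"D"), broken)
  expect_error(read_cohort_table(broken), "missing required cohort column")
})
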