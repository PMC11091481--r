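test_that("count files parse, validate and round-trip", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("room,time_point,n_wt_hom,n_het,n_ko_hom",
               "room1,0,5,0,5"), f)
  rec <- read_counts(f)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$n_wt_hom, 5L)
  expect_equal(rec$n_het, 0L)
  expect_equal(rec$time_point, 0L)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("room,time_point,n_wt_hom,n_het,n_ko_hom",
               "room1,3,10,-1,2"), bad)
  expect_error(read_counts(bad), class = "enclosabc_validation_error")

  nocol <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("room,time_point,n_wt_hom,n_het", "room1,3,10,1"), nocol)
  expect_error(read_counts(nocol), class = "enclosabc_format_error")

  # write-then-read equality on a generated dataset (sex + cohort columns)
  ps <- make_pseudo_observed(toy_design(s = 0.3), seed = 4)
  out <- withr::local_tempfile(fileext = ".csv")
  write_counts(ps$counts, out)
  again <- read_counts(out)
  expect_equal(as.data.frame(again), as.data.frame(ps$counts))
})

test_that("allele frequency matches the cumulative study counts", {
  counts <- study_cumulative_counts()
  f <- allele_frequency(counts)
  expect_equal(round(f, 2), c(0.53, 0.52, 0.60))
  expect_equal(f[1], (2 * 338 + 576) / (2 * 1181))
  # fixation and scaling invariance
  expect_equal(allele_frequency(data.frame(n_wt_hom = 7, n_het = 0,
                                           n_ko_hom = 0)), 1)
  for (k in c(2L, 5L, 17L)) {
    expect_equal(allele_frequency(counts),
                 allele_frequency(dplyr::mutate(
                   counts, dplyr::across(dplyr::starts_with("n_"), ~ .x * k))))
  }
  expect_error(allele_frequency(data.frame(n_wt_hom = 0, n_het = 0,
                                           n_ko_hom = 0)),
               class = "enclosabc_undefined_frequency")
})

test_that("HWE chi-square reproduces the study values and basic properties", {
  counts <- study_cumulative_counts()
  chi2 <- hwe_chi_square(counts)
  expect_equal(chi2[1], 0.52, tolerance = 0.01)
  expect_equal(chi2[2], 1.07, tolerance = 0.01)
  # exact HWE proportions give exactly zero
  expect_equal(hwe_chi_square(data.frame(n_wt_hom = 25, n_het = 50,
                                         n_ko_hom = 25)), 0)
  expect_true(all(chi2 >= 0))
  expect_error(hwe_chi_square(data.frame(n_wt_hom = 10, n_het = 0,
                                         n_ko_hom = 0)),
               class = "enclosabc_degenerate_test")
})

test_that("HWE test rejects at its nominal 5% rate under the null", {
  set.seed(42)
  n_rep <- 10000
  draws <- stats::rmultinom(n_rep, 500, c(0.25, 0.5, 0.25))
  counts <- data.frame(n_wt_hom = draws[1, ], n_het = draws[2, ],
                       n_ko_hom = draws[3, ])
  chi2 <- hwe_chi_square(counts)
  rate <- mean(chi2 > stats::qchisq(0.95, df = 1))
  expect_gt(rate, 0.04)
  expect_lt(rate, 0.06)
})

test_that("cumulative summary sums counts per room and excludes founders", {
  counts <- study_cumulative_counts()
  sm <- cumulative_summary(counts)
  expect_equal(sm$n_total, c(1181, 1205, 578))
  expect_equal(round(sm$f_wt, 2), c(0.53, 0.52, 0.60))
  expect_equal(round(sm$chi2_hwe, 2)[1:2], c(0.52, 1.07))
  expect_true(all(sm$p_hwe > 0.05))

  # additivity: two records per room reduce to their element-wise sum
  split2 <- dplyr::bind_rows(
    dplyr::mutate(counts, n_wt_hom = n_wt_hom - 10L, time_point = 1L),
    dplyr::mutate(counts, n_wt_hom = 10L, n_het = 0L, n_ko_hom = 0L,
                  time_point = 2L))
  expect_equal(cumulative_summary(split2), sm)

  # founder exclusion via the cohort filter
  with_f0 <- dplyr::bind_rows(
    dplyr::mutate(counts, cohort = "later"),
    tibble::tibble(room = "room1", time_point = 0L, n_wt_hom = 10L,
                   n_het = 0L, n_ko_hom = 10L, cohort = "F0"))
  expect_equal(cumulative_summary(with_f0)$n_total, sm$n_total)

  expect_warning(empty <- cumulative_summary(counts[0, ]), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("observation vectors follow the frozen ordering contract", {
  ps <- make_pseudo_observed(toy_design(), seed = 9)
  v <- observation_vector(ps$counts, "A", start_time = 4)
  # 2 rooms x 3 included points
  expect_length(v, 6)
  expect_equal(names(v), c("room1.4", "room1.5", "room1.6",
                           "room2.4", "room2.5", "room2.6"))
  expect_true(all(v >= 0 & v <= 1))

  g <- observation_vector(ps$counts, "G", start_time = 4)
  expect_length(g, 18)
  sums <- tapply(g, rep(seq_len(6), each = 3), sum)
  expect_equal(as.numeric(sums), rep(1, 6), tolerance = 1e-12)

  # all-heterozygote population gives constant 0.5 in mode A
  het <- tibble::tibble(room = "r1", time_point = 1:3, n_wt_hom = 0L,
                        n_het = 50L, n_ko_hom = 0L)
  expect_equal(unname(observation_vector(het, "A", 1)), rep(0.5, 3))

  ragged <- ps$counts[!(ps$counts$room == "room2" &
                          ps$counts$time_point == 5), ]
  expect_error(observation_vector(ragged, "A", start_time = 4),
               class = "enclosabc_alignment_error")
})
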