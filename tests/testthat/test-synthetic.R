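test_that("default designs mirror the experimental structure", {
  d <- synthetic_design()
  sch <- make_schedule(d)
  expect_equal(length(unique(sch$room)), 3)
  expect_equal(unique(table(sch$room)), 9L)
  # founders enter at step 1 and leave at step 4 in every room
  f0 <- sch[sch$cohort == "F0", ]
  expect_equal(f0$step, rep(1L, 3))
  expect_equal(f0$n_new_females + f0$n_new_males, rep(20L, 3))
  expect_equal(f0$n_new_females, f0$n_new_males)
  rem4 <- sch[sch$step == 4, ]
  expect_true(all(grepl("F0", rem4$cohorts_removed)))
  # replayed bookkeeping hits the growth targets exactly
  sizes <- implied_sizes(sch)
  for (r in 1:3) {
    expect_equal(sizes$n_alive[sizes$room == paste0("room", r)],
                 d$growth_targets[[r]])
  }
  # populations grow to several hundred adults
  expect_true(all(vapply(d$growth_targets, max, numeric(1)) >= 260))
})

test_that("flat growth targets need no births and infeasible ones error", {
  d <- synthetic_design(n_rooms = 1, n_timepoints = 4,
                        growth_targets = list(rep(20, 4)),
                        cohort_removals = list())
  sch <- make_schedule(d)
  expect_equal(sch$n_new_females[-1], rep(0L, 3))
  expect_equal(sch$n_new_males[-1], rep(0L, 3))

  bad <- synthetic_design(n_rooms = 1, n_timepoints = 4,
                          growth_targets = list(c(20, 200, 10, 10)),
                          cohort_removals = list())
  expect_error(make_schedule(bad), class = "enclosabc_design_error")
})

test_that("pseudo-observed datasets are reproducible and round-trip", {
  d <- toy_design(s = 0.4, seed = 6)
  ps1 <- make_pseudo_observed(d)
  ps2 <- make_pseudo_observed(d)
  expect_identical(ps1$counts, ps2$counts)
  expect_identical(ps1$truth, ps2$truth)
  expect_equal(ps1$truth$s_male, 0.4)
  expect_equal(ps1$truth$s_female, 0)

  dir <- withr::local_tempdir()
  write_synthetic_dataset(ps1, dir)
  counts <- read_counts(file.path(dir, "counts.csv"))
  expect_equal(as.data.frame(counts), as.data.frame(ps1$counts))
  sch <- read_schedule(file.path(dir, "schedule.csv"))
  expect_equal(as.data.frame(sch), as.data.frame(ps1$schedule))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$s_male, 0.4)
  expect_equal(truth$seed, 6)
})

test_that("neutral pseudo-data conserve frequency; strong selection shifts it", {
  term_f <- function(counts) {
    last <- counts[counts$time_point == max(counts$time_point), ]
    sum(2 * last$n_wt_hom + last$n_het) /
      (2 * sum(last$n_wt_hom + last$n_het + last$n_ko_hom))
  }
  neutral_d <- toy_design(s = 0)
  set.seed(1)
  fs <- vapply(1:400, function(i) {
    term_f(make_pseudo_observed(neutral_d, seed = 10000 + i)$counts)
  }, numeric(1))
  se <- sd(fs) / sqrt(length(fs))
  expect_lt(abs(mean(fs) - 0.5), 3 * se)

  strong_d <- toy_design(s = 9, h = 1)
  up <- vapply(1:200, function(i) {
    term_f(make_pseudo_observed(strong_d, seed = 20000 + i)$counts) > 0.5
  }, logical(1))
  expect_gt(mean(up), 0.99)
})
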