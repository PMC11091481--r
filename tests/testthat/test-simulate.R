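test_that("schedules validate and replay their bookkeeping", {
  d <- toy_design()
  sch <- make_schedule(d)
  sizes <- implied_sizes(sch)
  expect_equal(sizes$n_alive[sizes$room == "room1"], d$growth_targets[[1]])
  expect_equal(sizes$n_alive[sizes$room == "room2"], d$growth_targets[[2]])
  # schedule totals never depend on a fitness model
  expect_true(all(sizes$n_females + sizes$n_males == sizes$n_alive))

  bad <- sch
  bad$cohorts_removed[bad$step == 2 & bad$room == "room1"] <- "S5"
  expect_error(enclosabc:::validate_schedule(bad),
               class = "enclosabc_validation_error")
  neg <- sch
  neg$n_new_females[3] <- -1L
  expect_error(enclosabc:::validate_schedule(neg),
               class = "enclosabc_validation_error")

  f <- withr::local_tempfile(fileext = ".csv")
  write_schedule(sch, f)
  expect_equal(as.data.frame(read_schedule(f)), as.data.frame(sch))
})

test_that("zero-birth schedules give constant trajectories", {
  sch <- tibble::tibble(room = "r1", step = 1:4, cohort = paste0("S", 1:4),
                        n_new_females = c(6L, 0L, 0L, 0L),
                        n_new_males = c(6L, 0L, 0L, 0L),
                        cohorts_removed = "", include_in_stats = TRUE)
  init <- tibble::tibble(sex = rep(c("F", "M"), each = 6),
                         genotype = rep(c("WT/WT", "WT/ko", "ko/ko"), 4),
                         cohort = "S1")
  traj <- simulate_room(sch, fitness_model("males_only", s = 2), init,
                        start_step = 1)
  pooled <- dplyr::count(traj, time_point, wt = n_wt_hom + n_het + n_ko_hom)
  expect_equal(pooled$n, rep(12L, 4))
  per_t <- split(traj[c("n_wt_hom", "n_het", "n_ko_hom")], traj$time_point)
  for (tp in per_t) expect_equal(colSums(as.matrix(tp)), c(n_wt_hom = 4,
                                                           n_het = 4,
                                                           n_ko_hom = 4))
})

test_that("population composition is schedule-determined for any model", {
  d <- toy_design()
  sch <- make_schedule(d)
  founders <- enclosabc:::founder_population(d)
  sizes <- implied_sizes(sch)
  for (m in list(fitness_model("males_only", s = 0),
                 fitness_model("males_only", s = 5, h = 1),
                 fitness_model("sex_averaged", s = 0.8, h = 0.2, g = 0.3),
                 fitness_model("males_only", s = 0.5, lambda = 0.9))) {
    set.seed(11)
    traj <- simulate_room(sch[sch$room == "room1", ], m, founders, 1)
    tot <- traj %>% dplyr::group_by(time_point, sex) %>%
      dplyr::summarise(n = sum(n_wt_hom + n_het + n_ko_hom), .groups = "drop")
    expect_equal(tot$n[tot$sex == "F"],
                 sizes$n_females[sizes$room == "room1"])
    expect_equal(tot$n[tot$sex == "M"],
                 sizes$n_males[sizes$room == "room1"])
  }
})

test_that("neutral dynamics conserve the expected allele frequency", {
  d <- toy_design()
  sch <- make_schedule(d)
  founders <- enclosabc:::founder_population(d)
  comp <- enclosabc:::compile_schedule(sch[sch$room == "room1", ], 1)[["room1"]]
  ci <- enclosabc:::compile_init(founders, comp$coh_levels)
  neutral <- fitness_model("males_only", s = 0)
  set.seed(123)
  n_rep <- 1000
  term <- vapply(seq_len(n_rep), function(i) {
    cen <- enclosabc:::sim_room_fast(comp, neutral, ci)
    last <- cen[nrow(cen), ]
    n2 <- last[1] + last[4]; n1 <- last[2] + last[5]
    (2 * n2 + n1) / (2 * sum(last))
  }, numeric(1))
  se <- stats::sd(term) / sqrt(n_rep)
  expect_lt(abs(mean(term) - 0.5), 3 * se)
})

test_that("one large reproduction step matches the deterministic recursion", {
  set.seed(5)
  # large parental pool at Hardy-Weinberg proportions, p = 0.6
  p <- 0.6
  gt_f <- stats::rbinom(5000, 2, p)
  gt_m <- stats::rbinom(5000, 2, p)
  model <- fitness_model("males_only", s = 0.5, h = 0.5)
  off <- enclosabc:::reproduce_step(
    gt = c(gt_f, gt_m), male = rep(c(FALSE, TRUE), each = 5000),
    wf_tab = c(1, 1, 1), wm_tab = 1 + 0.5 * c(0, 0.5, 1),
    g = 0, lambda = 0, n_f = 5000, n_m = 5000)
  f_off <- mean(off$gt) / 2
  w <- 1 + 0.5 * c(0, 0.5, 1)[gt_m + 1]
  f_m_sel <- sum((gt_m / 2) * w) / sum(w)
  f_expected <- (mean(gt_f) / 2 + f_m_sel) / 2
  expect_lt(abs(f_off - f_expected), 0.01)
})

test_that("g = 0 reduces the noisy model to the base model exactly", {
  d <- toy_design()
  sch <- make_schedule(d)
  founders <- enclosabc:::founder_population(d)
  m_base <- fitness_model("males_only", s = 0.4, h = 0.3)
  m_g0 <- fitness_model("males_only", s = 0.4, h = 0.3, g = 0)
  set.seed(77)
  t1 <- simulate_room(sch[sch$room == "room1", ], m_base, founders, 1)
  set.seed(77)
  t2 <- simulate_room(sch[sch$room == "room1", ], m_g0, founders, 1)
  expect_identical(t1, t2)
})

test_that("experiment statistics are deterministic given a seed and react to s", {
  d <- toy_design()
  sch <- make_schedule(d)
  founders <- enclosabc:::founder_population(d)
  inits <- list(room1 = founders, room2 = founders)
  v1 <- simulate_experiment(sch, fitness_model("males_only"), inits, "A",
                            start_step = 1, seed = 42)
  v2 <- simulate_experiment(sch, fitness_model("males_only"), inits, "A",
                            start_step = 1, seed = 42)
  expect_identical(v1, v2)
  expect_true(all(v1 >= 0 & v1 <= 1))
  expect_length(v1, 2 * 5)  # 2 rooms x steps 2..6
  v3 <- simulate_experiment(sch, fitness_model("males_only", s = 9, h = 1),
                            inits, "A", start_step = 1, seed = 42)
  expect_false(identical(v1, v3))
})

test_that("strong male selection raises the terminal frequency above neutral", {
  d <- toy_design()
  sch <- make_schedule(d)
  founders <- enclosabc:::founder_population(d)
  comp <- enclosabc:::compile_schedule(sch[sch$room == "room1", ], 1)[["room1"]]
  ci <- enclosabc:::compile_init(founders, comp$coh_levels)
  terminal_f <- function(model, seed) {
    set.seed(seed)
    cen <- enclosabc:::sim_room_fast(comp, model, ci)
    last <- cen[nrow(cen), ]
    (2 * (last[1] + last[4]) + last[2] + last[5]) / (2 * sum(last))
  }
  strong <- fitness_model("males_only", s = 9, h = 1)
  neutral <- fitness_model("males_only", s = 0)
  wins <- vapply(1:200, function(i) {
    terminal_f(strong, 5000 + i) > terminal_f(neutral, 9000 + i)
  }, logical(1))
  expect_gt(mean(wins), 0.95)
})

test_that("initial populations are realised deterministically by largest remainder", {
  counts <- tibble::tibble(room = "room1", time_point = 3L,
                           n_wt_hom = 8L, n_het = 1L, n_ko_hom = 6L)
  sch <- make_schedule(toy_design())[1:6, ]
  init <- build_init_population(counts, sch, start_step = 3)
  expect_equal(nrow(init), 30)  # schedule-implied size at point 3
  expect_identical(init, build_init_population(counts, sch, start_step = 3))
  # genotype totals track the observed frequencies
  frac <- c(8, 1, 6) / 15
  tot <- table(factor(init$genotype, levels = c(2, 1, 0)))
  expect_true(all(abs(as.numeric(tot) - frac * 30) <= 2))
  # extinction surfaces as a typed condition
  sch_ext <- tibble::tibble(room = "r", step = 1:2, cohort = c("F0", "S2"),
                            n_new_females = c(4L, 4L), n_new_males = c(0L, 4L),
                            cohorts_removed = "", include_in_stats = TRUE)
  init_f <- tibble::tibble(sex = rep("F", 4), genotype = "WT/ko",
                           cohort = "F0")
  expect_error(simulate_room(sch_ext, fitness_model("males_only"), init_f, 1),
               class = "enclosabc_extinction")
})
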