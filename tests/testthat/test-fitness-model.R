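test_that("fitness follows 1, 1 + hs, 1 + s per sex", {
  m <- fitness_model("males_only", s = 0.5, h = 0.5)
  ind <- tibble::tibble(sex = c("M", "M", "M", "F", "F", "F"),
                        genotype = rep(c("WT/WT", "WT/ko", "ko/ko"), 2))
  expect_equal(individual_fitness(ind, m), c(1.5, 1.25, 1, 1, 1, 1))

  m2 <- fitness_model("males_only", s = 0.4, h = 0.5)
  expect_equal(individual_fitness(tibble::tibble(sex = "M", genotype = "WT/ko"),
                                  m2), 1.2)
  avg <- fitness_model("sex_averaged", s = 0.4, h = 1)
  expect_equal(individual_fitness(ind, avg), c(1.4, 1.4, 1, 1.4, 1.4, 1))

  spec <- fitness_model("sex_specific", s = 0.4, h = 1,
                        s_female = 0.2, h_female = 0)
  expect_equal(individual_fitness(ind, spec), c(1.4, 1.4, 1, 1.2, 1, 1))

  expect_error(fitness_model("males_only", s = -1.2))
  expect_error(fitness_model("sex_specific", s = 0.2))
})

test_that("non-genetic noise is truncated at zero and vanishes at g = 0", {
  m <- fitness_model("males_only", s = 0.1, g = 3)
  ind <- tibble::tibble(sex = rep("M", 2000), genotype = "ko/ko")
  set.seed(1)
  w <- individual_fitness(ind, m)
  expect_true(all(w >= 0))
  expect_true(any(w == 0))   # truncation active at sd 3 around mean 1
  m0 <- fitness_model("males_only", s = 0.1, g = 0)
  expect_equal(individual_fitness(ind[1:5, ], m0), rep(1, 5))
})

test_that("mating modifier implements the shared-allele rule symmetrically", {
  lam <- 0.8
  expect_equal(mating_modifier("WT/WT", "ko/ko", lam), 1)
  expect_equal(mating_modifier("WT/ko", "WT/ko", lam), 1 - lam)
  expect_equal(mating_modifier("WT/WT", "WT/WT", lam), 1 - lam)
  expect_equal(mating_modifier("ko/ko", "ko/ko", lam), 1 - lam)
  expect_equal(mating_modifier("WT/WT", "WT/ko", lam), 1 - lam / 2)
  expect_equal(mating_modifier("ko/ko", "WT/ko", lam), 1 - lam / 2)
  gts <- c("WT/WT", "WT/ko", "ko/ko")
  for (a in gts) for (b in gts) {
    expect_equal(mating_modifier(a, b, 0.37), mating_modifier(b, a, 0.37))
    expect_equal(mating_modifier(a, b, 0), 1)
  }
})

test_that("Mendelian segregation matches exhaustive gamete enumeration", {
  # oracle: enumerate the 2x2 gamete table for every cross
  gamete_pool <- function(gt) switch(gt, "WT/WT" = c(1, 1), "WT/ko" = c(1, 0),
                                     "ko/ko" = c(0, 0))
  oracle <- function(a, b) {
    kids <- outer(gamete_pool(a), gamete_pool(b), "+")
    tab <- tabulate(kids + 1, 3) / 4   # index 1 = 0 WT alleles
    rev(tab)                           # reorder to WT/WT, WT/ko, ko/ko
  }
  gts <- c("WT/WT", "WT/ko", "ko/ko")
  for (a in gts) for (b in gts) {
    expect_equal(unname(mendelian_probs(a, b)), oracle(a, b),
                 info = paste(a, "x", b))
  }
  # sampled offspring agree with the exact distribution
  set.seed(7)
  draws <- mendelian_offspring("WT/ko", "WT/ko", n = 40000)
  emp <- table(factor(draws, levels = gts)) / 40000
  expect_equal(as.numeric(emp), c(0.25, 0.5, 0.25), tolerance = 0.02)
  expect_equal(unique(mendelian_offspring("WT/WT", "ko/ko", 100)), "WT/ko")
})

test_that("parent pairs are sampled proportional to fitness", {
  one_f <- tibble::tibble(sex = "F", genotype = "WT/ko", cohort = "a")
  one_m <- tibble::tibble(sex = "M", genotype = "ko/ko", cohort = "a")
  pair <- sample_parent_pair(one_f, one_m, fitness_model("males_only"))
  expect_equal(pair$mother$genotype, "WT/ko")
  expect_equal(pair$father$genotype, "ko/ko")

  # neutral: two males equally likely
  males2 <- tibble::tibble(sex = "M", genotype = c("WT/WT", "ko/ko"))
  set.seed(3)
  picks <- vapply(1:10000, function(i) {
    sample_parent_pair(one_f, males2, fitness_model("males_only"))$father$genotype
  }, character(1))
  expect_equal(mean(picks == "WT/WT"), 0.5, tolerance = 3 * sqrt(0.25 / 10000))

  # males-only s = 1: WT/WT father weight 2 vs 1 -> probability 2/3
  set.seed(4)
  sel <- fitness_model("males_only", s = 1, h = 0.5)
  picks <- vapply(1:10000, function(i) {
    sample_parent_pair(one_f, males2, sel)$father$genotype
  }, character(1))
  expect_equal(mean(picks == "WT/WT"), 2 / 3, tolerance = 3 * sqrt(2 / 9 / 10000))
})
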