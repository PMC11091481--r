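#' Construct a fitness model
#'
#' Defines the relative-fitness scheme acting on the wildtype/knockout locus.
#' The knockout homozygote has fitness 1, the wildtype homozygote `1 + s`
#' and the heterozygote `1 + h * s`, with the selection coefficient `s` and
#' dominance coefficient `h` applied per sex according to the variant:
#'
#' * `males_only` — selection acts in males only; all females have fitness 1.
#' * `sex_averaged` — the same `(s, h)` act in both sexes.
#' * `sex_specific` — independent `(s, h)` per sex.
#'
#' Two optional components extend any variant: `g`, the standard deviation of
#' Gaussian non-genetic fitness noise added per individual (truncated below
#' at 0 so weights stay non-negative), and `lambda`, a non-random-mating
#' penalty multiplying a candidate father's weight by `1 - lambda` when the
#' pair's allele sets are identical, `1 - lambda/2` when exactly one allele
#' is shared, and 1 when none is shared.
#'
#' @param variant One of `"males_only"`, `"sex_averaged"`, `"sex_specific"`.
#' @param s Selection coefficient in males (> -1).
#' @param h Dominance coefficient in males, in \[0, 1\].
#' @param s_female,h_female Female coefficients; required for
#'   `sex_specific`, forced to `s`/`h` for `sex_averaged` and to 0 for
#'   `males_only`.
#' @param g Standard deviation of non-genetic fitness noise (>= 0).
#' @param lambda Non-random-mating penalty, in \[0, 1\].
#' @return An object of class `fitness_model`.
#' @export
#' @examples
#' fitness_model("males_only", s = 0.5, h = 0.5)
fitness_model <- function(variant = c("males_only", "sex_averaged", "sex_specific"),
                          s = 0, h = 0.5, s_female = NULL, h_female = NULL,
                          g = 0, lambda = 0) {
  variant <- match.arg(variant)
  stopifnot(is.numeric(s), length(s) == 1, s > -1,
            is.numeric(h), length(h) == 1, h >= 0, h <= 1,
            is.numeric(g), length(g) == 1, g >= 0,
            is.numeric(lambda), length(lambda) == 1, lambda >= 0, lambda <= 1)
  if (variant == "males_only") {
    s_female <- 0; h_female <- 0
  } else if (variant == "sex_averaged") {
    s_female <- s; h_female <- h
  } else {
    if (is.null(s_female) || is.null(h_female)) {
      abort("sex_specific models require s_female and h_female")
    }
    stopifnot(s_female > -1, h_female >= 0, h_female <= 1)
  }
  structure(
    list(variant = variant, s_male = s, h_male = h,
         s_female = s_female, h_female = h_female, g = g, lambda = lambda),
    class = "fitness_model"
  )
}

#' @export
print.fitness_model <- function(x, ...) {
  cat("<fitness_model> variant:", x$variant, "\n")
  cat(sprintf("  males:   s = %.4g, h = %.4g\n", x$s_male, x$h_male))
  cat(sprintf("  females: s = %.4g, h = %.4g\n", x$s_female, x$h_female))
  if (x$g > 0) cat(sprintf("  non-genetic noise g = %.4g\n", x$g))
  if (x$lambda > 0) cat(sprintf("  non-random mating lambda = %.4g\n", x$lambda))
  invisible(x)
}

# Base (noise-free) fitness for integer genotypes (number of WT alleles)
# of one sex.  Vectorised over gt.
base_fitness <- function(gt, male, model) {
  s <- if (male) model$s_male else model$s_female
  h <- if (male) model$h_male else model$h_female
  1 + s * c(0, h, 1)[gt + 1L]
}

#' Realised fitness of individuals
#'
#' Returns each individual's sampling weight under a fitness model: the
#' genotype- and sex-determined base fitness, plus (when `g > 0`) a Gaussian
#' non-genetic deviate with standard deviation `g`, truncated below at 0.
#' Draws consume the current RNG stream; with `g = 0` the result is
#' deterministic.
#'
#' @param individuals Data frame with columns `sex` (`"F"`/`"M"`) and
#'   `genotype` (labels `"WT/WT"`, `"WT/ko"`, `"ko/ko"` or integer number of
#'   wildtype alleles 2/1/0).
#' @param model A [fitness_model()].
#' @return Numeric vector of non-negative fitness weights.
#' @export
individual_fitness <- function(individuals, model) {
  gt <- individuals$genotype
  if (!is.numeric(gt)) gt <- genotype_code(gt)
  male <- individuals$sex == "M"
  w <- ifelse(male, base_fitness(gt, TRUE, model), base_fitness(gt, FALSE, model))
  if (model$g > 0) {
    w <- pmax(0, rnorm(length(w), mean = w, sd = model$g))
  }
  w
}

#' Non-random-mating pair modifier
#'
#' Multiplier applied to a candidate pairing's weight under the non-random
#' mating model: `1 - lambda` when the two genotypes carry identical allele
#' sets (both heterozygous, or the same homozygote), `1 - lambda/2` when
#' exactly one allele is shared (a homozygote with a heterozygote), and 1
#' when no allele is shared (opposite homozygotes).
#'
#' @param gen_a,gen_b Genotypes, as labels or integer wildtype-allele counts;
#'   vectorised (recycled to common length).
#' @param lambda Penalty in \[0, 1\].
#' @return Numeric multiplier(s) in \[0, 1\].
#' @export
#' @examples
#' mating_modifier("WT/WT", "ko/ko", 0.8)  # disjoint allele sets -> 1
#' mating_modifier("WT/ko", "WT/ko", 0.8)  # identical sets -> 0.2
mating_modifier <- function(gen_a, gen_b, lambda) {
  stopifnot(lambda >= 0, lambda <= 1)
  a <- if (is.numeric(gen_a)) as.integer(gen_a) else genotype_code(gen_a)
  b <- if (is.numeric(gen_b)) as.integer(gen_b) else genotype_code(gen_b)
  shared <- shared_allele_classes(a, b)
  c(1, 1 - lambda / 2, 1 - lambda)[shared + 1L]
}

# 0 = no shared allele, 1 = exactly one shared, 2 = identical allele sets.
shared_allele_classes <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  out <- integer(n)
  out[a == b] <- 2L                                   # same genotype
  het <- (a == 1L) | (b == 1L)
  out[het & a != b] <- 1L                             # hom x het
  out                                                 # opposite homs stay 0
}

#' Mendelian offspring genotype distribution
#'
#' Exact segregation probabilities for a cross, over offspring genotypes in
#' the order WT/WT, WT/ko, ko/ko.  Each parent transmits a wildtype allele
#' with probability equal to half its wildtype-allele count.
#'
#' @param mother,father Parental genotypes (label or integer code).
#' @return Named numeric 3-vector of probabilities summing to 1.
#' @export
#' @examples
#' mendelian_probs("WT/ko", "WT/ko")  # 1/4, 1/2, 1/4
mendelian_probs <- function(mother, father) {
  gm <- if (is.numeric(mother)) mother else genotype_code(mother)
  gf <- if (is.numeric(father)) father else genotype_code(father)
  pm <- gm / 2; pf <- gf / 2
  setNames(c(pm * pf, pm * (1 - pf) + (1 - pm) * pf, (1 - pm) * (1 - pf)),
           GENOTYPE_LEVELS)
}

#' Draw Mendelian offspring genotypes
#'
#' Samples offspring genotypes for a cross from the exact segregation
#' distribution ([mendelian_probs()]).
#'
#' @param mother,father Parental genotypes (label or integer code).
#' @param n Number of offspring to draw.
#' @return Character vector of offspring genotype labels.
#' @export
mendelian_offspring <- function(mother, father, n = 1) {
  gm <- if (is.numeric(mother)) mother else genotype_code(mother)
  gf <- if (is.numeric(father)) father else genotype_code(father)
  gt <- rbinom(n, 1L, gm / 2) + rbinom(n, 1L, gf / 2)
  genotype_label(gt)
}

#' Sample one parent pair by fitness
#'
#' Draws a mother proportional to female fitness and a father proportional
#' to male fitness; under non-random mating (`lambda > 0`) the father's
#' weight is additionally multiplied by [mating_modifier()] against the
#' already-chosen mother.  Sampling is with replacement across offspring.
#'
#' @param females,males Data frames of candidate parents with columns `sex`
#'   and `genotype` (see [individual_fitness()]).
#' @param model A [fitness_model()].
#' @return A list with elements `mother` and `father`, each a one-row tibble.
#' @export
sample_parent_pair <- function(females, males, model) {
  if (nrow(females) == 0 || nrow(males) == 0) {
    abort("both parental pools must be non-empty", class = "enclosabc_extinction")
  }
  w_f <- individual_fitness(females, model)
  if (sum(w_f) <= 0) {
    abort("all female weights are zero", class = "enclosabc_degenerate_weights")
  }
  mi <- sample.int(nrow(females), 1L, prob = w_f)
  w_m <- individual_fitness(males, model)
  if (model$lambda > 0) {
    gm <- females$genotype[mi]
    if (!is.numeric(gm)) gm <- genotype_code(gm)
    gts <- males$genotype
    if (!is.numeric(gts)) gts <- genotype_code(gts)
    w_m <- w_m * mating_modifier(gm, gts, model$lambda)
  }
  if (sum(w_m) <= 0) {
    abort("all male weights are zero", class = "enclosabc_degenerate_weights")
  }
  fi <- sample.int(nrow(males), 1L, prob = w_m)
  list(mother = as_tibble(females[mi, , drop = FALSE]),
       father = as_tibble(males[fi, , drop = FALSE]))
}
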