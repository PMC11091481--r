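# Shared fixtures, all generated in code.

# Table 1 of the enclosure study: cumulative genotype counts per room
# (founders excluded).  Used as the reference input for the descriptive
# statistics.
study_cumulative_counts <- function() {
  tibble::tibble(
    room = c("room1", "room2", "room3"),
    time_point = 0L,
    n_wt_hom = c(338L, 329L, 216L),
    n_het = c(576L, 584L, 264L),
    n_ko_hom = c(267L, 292L, 98L)
  )
}

# A small 2-room, 6-point design for cheap unit tests (not the study-scale
# default design).
toy_design <- function(s = 0, h = 0.5, variant = "males_only", g = 0,
                       lambda = 0, seed = 1L) {
  synthetic_design(
    n_rooms = 2, founders_per_genotype = 10, n_timepoints = 6,
    growth_targets = list(c(20, 20, 30, 50, 80, 110),
                          c(20, 20, 26, 44, 70, 96)),
    founder_removal_point = 4,
    cohort_removals = list(F0 = 4),
    true_model = fitness_model(variant, s = s, h = h, g = g, lambda = lambda),
    seed = seed
  )
}

# Full pipeline context for a pseudo-observed dataset: observation vector,
# init populations and a reference table of the requested size.
make_fit_context <- function(design, variant = "males_only", n_sims = 2000,
                             mode = "A", seed = 1L, fixed = list(),
                             prior = prior_spec()) {
  ps <- make_pseudo_observed(design, seed = seed)
  pol <- excluded_timepoint_policy(ps$counts)
  rooms <- sort(unique(ps$schedule$room))
  inits <- stats::setNames(lapply(rooms, function(rm) {
    build_init_population(
      dplyr::filter(pol$init_records, room == rm),
      ps$schedule[ps$schedule$room == rm, ], pol$init_time)
  }), rooms)
  table <- build_reference_table(n_sims, prior, variant, ps$schedule, inits,
                                 start_step = pol$init_time, mode = mode,
                                 seed = derive_test_seed(seed, 11))
  obs <- observation_vector(ps$counts, mode = mode,
                            start_time = pol$obs_start)
  list(ps = ps, pol = pol, inits = inits, table = table, obs = obs)
}

derive_test_seed <- function(seed, k) (seed * 1009 + k) %% 2147483647

# Conjugate toy model: theta ~ N(0, 1), stat = theta + N(0, sd).
toy_linear_table <- function(n, sd = 0.1, seed = 1L) {
  set.seed(seed)
  theta <- stats::rnorm(n)
  stat <- theta + stats::rnorm(n, 0, sd)
  reference_table(data.frame(theta = theta), matrix(stat, ncol = 1,
                                                    dimnames = list(NULL, "S1")))
}

# Two reference tables whose statistic clouds are Gaussian with a given
# separation (in SD units); parameters are irrelevant for model choice.
two_cloud_tables <- function(n = 500, separation = 0, d = 3, seed = 1L) {
  set.seed(seed)
  mk <- function(center) {
    stats_m <- matrix(stats::rnorm(n * d, mean = center), ncol = d)
    reference_table(data.frame(theta = stats::rnorm(n)), stats_m)
  }
  list(m0 = mk(0), m1 = mk(separation))
}
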