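#' Specify one model-suite run
#'
#' One row of the experiment grid: a model variant fitted with one summary
#' statistic mode.  Non-random-mating variants are restricted to genotype
#' frequencies (`mode = "G"`), since the mating penalty leaves allele
#' frequencies nearly uninformative about it.  The default number of
#' simulations is 100,000, doubled when an extra parameter (`g` or
#' `lambda`) is active.
#'
#' @param variant Variant name (see [variant_spec()]).
#' @param mode `"A"` or `"G"`.
#' @param n_sims Simulations in the reference table (`NULL` = default).
#' @param tolerance Rejection tolerance.
#' @return A list of class `model_run_spec`.
#' @export
model_run_spec <- function(variant, mode = c("A", "G"), n_sims = NULL,
                           tolerance = 0.1) {
  mode <- match.arg(mode)
  vs <- variant_spec(variant)
  if (vs$with_lambda && mode == "A") {
    abort("non-random-mating variants are fitted on genotype frequencies only (mode G)",
          class = "enclosabc_config_error")
  }
  if (is.null(n_sims)) {
    n_sims <- if (vs$with_g || vs$with_lambda) 200000L else 100000L
  }
  structure(list(variant = vs, mode = mode, n_sims = as.integer(n_sims),
                 tolerance = tolerance),
            class = "model_run_spec")
}

#' Initial conditions and statistic window from observed counts
#'
#' The founding animals are homozygotes only and therefore far from
#' Hardy-Weinberg proportions, so the first monitoring points are dominated
#' by them.  This policy drops the first `n_excluded` time points, uses the
#' next one as the initial condition, and includes all later points in the
#' summary statistics.
#'
#' @param counts Observed counts tibble ([read_counts()] format).
#' @param n_excluded Leading time points dropped (default 2).
#' @return A list with `init_time` (the time point providing initial
#'   conditions), `obs_start` (first time point entering the statistics),
#'   `init_records` (counts rows at `init_time`) and `time_points` (the
#'   common grid).
#' @export
excluded_timepoint_policy <- function(counts, n_excluded = 2) {
  grids <- counts %>%
    distinct(.data$room, .data$time_point) %>%
    arrange(.data$room, .data$time_point)
  per_room <- split(grids$time_point, grids$room)
  short <- names(per_room)[lengths(per_room) < n_excluded + 2]
  if (length(short) > 0) {
    abort(paste0("room(s) with fewer than ", n_excluded + 2,
                 " time points: ", paste(short, collapse = ", ")),
          class = "enclosabc_config_error")
  }
  common <- sort(Reduce(intersect, per_room))
  if (length(common) < n_excluded + 2) {
    abort("rooms do not share enough common time points",
          class = "enclosabc_config_error")
  }
  init_time <- common[n_excluded + 1]
  obs_start <- common[n_excluded + 2]
  list(init_time = init_time, obs_start = obs_start,
       init_records = filter(counts, .data$time_point == init_time),
       time_points = common)
}

#' Run the full model-suite experiment grid
#'
#' For each run specification: builds the selection-model reference table
#' from the demography and the observed initial conditions, fits the ABC
#' posterior with ridge adjustment, performs model choice against the
#' neutral model (the selection side pins `s` at its posterior point
#' estimate while `h` — and any nuisance parameter — is drawn from its
#' prior), and computes goodness-of-fit p-values under both models.  A
#' failing specification is reported in its row rather than aborting the
#' suite.
#'
#' @param specs List of [model_run_spec()]s.
#' @param counts Observed counts tibble.
#' @param schedules Multi-room schedule tibble.
#' @param prior A [prior_spec()].
#' @param seed Root seed; per-spec seeds are derived from it.
#' @param n_null_gof Null draws per goodness-of-fit test.
#' @return A `suite_report` tibble: one row per spec with the posterior
#'   summary (list column `posterior`), `p_neutral`, `p_selection`,
#'   `gof_neutral`, `gof_selection` and an `error` column.
#' @export
run_suite <- function(specs, counts, schedules, prior = prior_spec(),
                      seed = 1L, n_null_gof = 100) {
  if (inherits(specs, "model_run_spec")) specs <- list(specs)
  rows <- purrr::imap(specs, function(spec, k) {
    res <- tryCatch(
      run_one_spec(spec, counts, schedules, prior,
                   seed = derive_seed(seed, k), n_null_gof = n_null_gof),
      error = function(e) {
        tibble(variant = spec$variant$name, mode = spec$mode,
               n_sims = spec$n_sims, tolerance = spec$tolerance,
               posterior = list(NULL), p_neutral = NA_real_,
               p_selection = NA_real_, gof_neutral = NA_real_,
               gof_selection = NA_real_, error = conditionMessage(e))
      })
    res
  })
  out <- bind_rows(rows)
  structure(out, class = c("suite_report", class(out)), seed = seed)
}

run_one_spec <- function(spec, counts, schedules, prior, seed, n_null_gof) {
  pol <- excluded_timepoint_policy(counts)
  schedules <- validate_schedule(schedules)
  rooms <- sort(unique(schedules$room))
  inits <- setNames(lapply(rooms, function(rm) {
    build_init_population(
      filter(pol$init_records, .data$room == rm),
      schedules[schedules$room == rm, ], pol$init_time)
  }), rooms)
  obs <- observation_vector(counts, mode = spec$mode,
                            start_time = pol$obs_start)
  ref <- build_reference_table(spec$n_sims, prior, spec$variant, schedules,
                               inits, start_step = pol$init_time,
                               mode = spec$mode, seed = derive_seed(seed, 1))
  fit <- suppressWarnings(abc_fit(obs, ref, tolerance = spec$tolerance))

  neutral <- build_reference_table(spec$n_sims, prior, "neutral", schedules,
                                   inits, start_step = pol$init_time,
                                   mode = spec$mode,
                                   seed = derive_seed(seed, 2))
  # selection model for model choice: s pinned at the posterior point
  # estimate; h (and nuisance parameters) drawn from the prior
  s_terms <- grep("^s", fit$summary$term, value = TRUE)
  fixed <- as.list(setNames(
    fit$summary$estimate[match(s_terms, fit$summary$term)], s_terms))
  mod1 <- build_reference_table(spec$n_sims, prior, spec$variant, schedules,
                                inits, start_step = pol$init_time,
                                mode = spec$mode, fixed = fixed,
                                seed = derive_seed(seed, 3))
  mc <- suppressWarnings(
    model_posterior(obs, list(neutral = neutral, selection = mod1),
                    tolerance = spec$tolerance))
  gof_sel <- goodness_of_fit(obs, ref, n_null = n_null_gof,
                             tolerance = spec$tolerance,
                             seed = derive_seed(seed, 4))
  gof_neu <- goodness_of_fit(obs, neutral, n_null = n_null_gof,
                             tolerance = spec$tolerance,
                             seed = derive_seed(seed, 5))
  tibble(variant = spec$variant$name, mode = spec$mode,
         n_sims = spec$n_sims, tolerance = spec$tolerance,
         posterior = list(fit$summary),
         p_neutral = mc$posterior_prob[mc$model == "neutral"],
         p_selection = mc$posterior_prob[mc$model == "selection"],
         gof_neutral = gof_neu$p_value, gof_selection = gof_sel$p_value,
         error = NA_character_)
}

#' Format a suite report for display
#'
#' Flattens the posterior list column into `estimate [lo, hi]` strings in
#' the conventional column order.
#'
#' @param report A `suite_report` from [run_suite()].
#' @return A tibble of formatted strings.
#' @export
format_suite_report <- function(report) {
  fmt <- function(post) {
    if (is.null(post) || nrow(post) == 0) return(NA_character_)
    paste(sprintf("%s = %.3f [%.3f, %.3f]", post$term, post$estimate,
                  post$conf.low, post$conf.high), collapse = "; ")
  }
  report %>%
    mutate(posterior = vapply(.data$posterior, fmt, character(1)),
           across(c("p_neutral", "p_selection"),
                  ~ ifelse(is.na(.x), NA_character_,
                           sprintf("%.0f%%", 100 * .x))),
           across(c("gof_neutral", "gof_selection"),
                  ~ ifelse(is.na(.x), NA_character_, sprintf("%.3f", .x)))) %>%
    as_tibble()
}
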