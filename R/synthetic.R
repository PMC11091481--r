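#' Describe a synthetic enclosure experiment
#'
#' Parameterises a synthetic study design with the structure of the real
#' experiment: three replicate rooms founded by 10 wildtype and 10 knockout
#' homozygotes each (equal sex ratio), censused over nine monitoring points,
#' growing to several hundred adults per room, founders removed at
#' monitoring point 4 and two later cohorts removed near the end.
#'
#' @param n_rooms Number of replicate rooms.
#' @param founders_per_genotype Founders of each homozygous genotype per
#'   room (split equally between the sexes; must be even).
#' @param n_timepoints Number of monitoring points.
#' @param growth_targets List (length `n_rooms`) of per-point adult census
#'   targets; `NULL` uses a default ramp shaped like the study (slow through
#'   point 3, steep afterwards; room 3 roughly half the size of rooms 1-2).
#' @param founder_removal_point Monitoring point at which the founder cohort
#'   is removed.
#' @param cohort_removals Named list mapping cohort labels (`"F0"`, `"S4"`,
#'   ...) to the step at which they are removed; `NULL` uses the default
#'   (founders at `founder_removal_point`, `S4` at 8, `S5` at 9 when the
#'   design has 9 points).
#' @param true_model [fitness_model()] generating any pseudo-observed data.
#' @param seed Integer seed stored with the design.
#' @return An object of class `synthetic_design`.
#' @export
synthetic_design <- function(n_rooms = 3, founders_per_genotype = 10,
                             n_timepoints = 9, growth_targets = NULL,
                             founder_removal_point = 4,
                             cohort_removals = NULL,
                             true_model = fitness_model("males_only", s = 0,
                                                        h = 0.5),
                             seed = 1L) {
  stopifnot(n_rooms >= 1, founders_per_genotype %% 2 == 0,
            n_timepoints >= founder_removal_point)
  n_found <- 2L * founders_per_genotype
  if (is.null(growth_targets)) {
    big <- c(20, 20, 30, 60, 120, 200, 280, 360, 440)
    small <- c(20, 20, 26, 44, 80, 130, 180, 230, 260)
    base <- lapply(seq_len(n_rooms), function(r) {
      v <- if (r %% 3 == 0) small else big
      v[seq_len(min(n_timepoints, length(v)))]
    })
    growth_targets <- lapply(base, function(v) {
      if (length(v) < n_timepoints) {
        v <- c(v, rep(v[length(v)], n_timepoints - length(v)))
      }
      v[1] <- n_found
      v
    })
  }
  stopifnot(length(growth_targets) == n_rooms,
            all(vapply(growth_targets, length, integer(1)) == n_timepoints))
  if (any(vapply(growth_targets, function(v) v[1], numeric(1)) != n_found)) {
    abort("growth target at point 1 must equal the founder count",
          class = "enclosabc_design_error")
  }
  if (is.null(cohort_removals)) {
    cohort_removals <- list()
    cohort_removals[["F0"]] <- founder_removal_point
    if (n_timepoints >= 8) cohort_removals[["S4"]] <- 8L
    if (n_timepoints >= 9) cohort_removals[["S5"]] <- 9L
  }
  structure(list(n_rooms = n_rooms,
                 founders_per_genotype = founders_per_genotype,
                 n_timepoints = n_timepoints,
                 growth_targets = growth_targets,
                 founder_removal_point = founder_removal_point,
                 cohort_removals = cohort_removals,
                 true_model = true_model, seed = seed),
            class = "synthetic_design")
}

#' Build demography schedules from a synthetic design
#'
#' Converts per-point census targets into a demography schedule whose
#' replayed bookkeeping hits the targets exactly: births at step *t* equal
#' the target increment plus the members removed at *t*.  Founders enter as
#' the step-1 cohort `F0`; later cohorts are labelled `S<step>`.  A design
#' whose targets would require negative births is rejected.
#'
#' @param design A [synthetic_design()].
#' @return A validated multi-room schedule tibble (see [read_schedule()]).
#' @export
make_schedule <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  removal_steps <- design$cohort_removals
  purrr::map_dfr(seq_len(design$n_rooms), function(r) {
    targets <- design$growth_targets[[r]]
    room <- paste0("room", r)
    cohorts <- c("F0", paste0("S", seq_len(design$n_timepoints)[-1]))
    births <- integer(design$n_timepoints)
    births[1] <- targets[1]
    sizes <- setNames(integer(length(cohorts)), cohorts)
    sizes["F0"] <- births[1]
    removed_at <- vapply(seq_len(design$n_timepoints), function(t) {
      paste(names(removal_steps)[unlist(removal_steps) == t], collapse = ";")
    }, character(1))
    for (t in seq_len(design$n_timepoints)[-1]) {
      rem <- cohort_list(removed_at[t])
      rem_n <- sum(sizes[intersect(rem, names(sizes))])
      b <- targets[t] - targets[t - 1] + rem_n
      if (b < 0) {
        abort(sprintf(
          "room %s: growth target at point %d requires %d births", room, t, b),
          class = "enclosabc_design_error")
      }
      births[t] <- b
      sizes[cohorts[t]] <- b
    }
    # even split; any odd remainder alternates between the sexes by step
    n_f <- births %/% 2 + (births %% 2) * (seq_along(births) %% 2)
    tibble(room = room, step = seq_len(design$n_timepoints),
           cohort = cohorts, n_new_females = as.integer(n_f),
           n_new_males = as.integer(births - n_f),
           cohorts_removed = removed_at, include_in_stats = TRUE)
  }) %>% validate_schedule()
}

founder_population <- function(design) {
  per_cell <- design$founders_per_genotype / 2
  tibble(sex = rep(c("F", "M"), each = 2 * per_cell),
         genotype = rep(c(rep(2L, per_cell), rep(0L, per_cell)), 2),
         cohort = "F0")
}

#' Generate a pseudo-observed dataset
#'
#' Simulates the full experiment under the design's true fitness model,
#' starting from the founder populations (homozygotes only, equal sex
#' ratio), and emits the monitoring counts in the [read_counts()] format
#' together with the generating truth.  Rooms that go extinct are resampled
#' from a fresh derived stream, up to a bounded retry count.
#'
#' @param design A [synthetic_design()].
#' @param seed Integer seed; defaults to the design's seed.
#' @return A list of class `pseudo_observed` with elements `counts`
#'   (tibble), `schedule` (tibble) and `truth` (list of generating
#'   parameters and the seed).
#' @export
make_pseudo_observed <- function(design, seed = design$seed) {
  schedule <- make_schedule(design)
  founders <- founder_population(design)
  rooms <- sort(unique(schedule$room))
  counts <- purrr::map_dfr(seq_along(rooms), function(ri) {
    rm <- rooms[ri]
    for (retry in 0:30) {
      set.seed(derive_seed(seed, ri, retry))
      traj <- tryCatch(
        simulate_room(schedule[schedule$room == rm, ], design$true_model,
                      founders, start_step = 1L),
        enclosabc_extinction = function(e) NULL,
        enclosabc_degenerate_weights = function(e) NULL)
      if (!is.null(traj)) return(as_tibble(traj))
    }
    abort(sprintf("room %s went extinct in 31 consecutive attempts", rm),
          class = "enclosabc_simulation_failure")
  })
  tm <- design$true_model
  structure(list(
    counts = counts, schedule = schedule,
    truth = list(variant = tm$variant, s_male = tm$s_male, h_male = tm$h_male,
                 s_female = tm$s_female, h_female = tm$h_female,
                 g = tm$g, lambda = tm$lambda, seed = seed)),
    class = "pseudo_observed")
}

#' Write a pseudo-observed dataset to a directory
#'
#' Emits `counts.csv`, `schedule.csv` and a `truth.json` sidecar so that a
#' pseudo-dataset is fully reproducible and the generating parameters are
#' never guessed downstream.
#'
#' @param pseudo A `pseudo_observed` object from [make_pseudo_observed()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(pseudo, dir) {
  stopifnot(inherits(pseudo, "pseudo_observed"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_counts(pseudo$counts, file.path(dir, "counts.csv"))
  write_schedule(pseudo$schedule, file.path(dir, "schedule.csv"))
  jsonlite::write_json(pseudo$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(dir)
}
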