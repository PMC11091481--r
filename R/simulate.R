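#' Read or write a demography schedule
#'
#' A demography schedule lists, per room and monitoring step, the number of
#' new adults of each sex that enter the population (the offspring cohort
#' recruited since the previous monitoring point), the cohort label assigned
#' to them, the cohorts removed at that step, and whether the step's census
#' enters the summary statistics.  The schedule fully determines population
#' size and sex composition at every step, independently of any fitness
#' model.
#'
#' Columns: `room`, `step`, `cohort` (optional; defaults to `S<step>`),
#' `n_new_females`, `n_new_males`, `cohorts_removed` (semicolon-separated
#' labels, empty for none), `include_in_stats` (logical; optional, default
#' `TRUE`).
#'
#' @param path Path to a CSV/TSV schedule file.
#' @return A validated schedule tibble, ordered by room and step.
#' @export
read_schedule <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("schedule file not found: ", path), class = "enclosabc_io_error")
  }
  reader <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) {
    readr::read_tsv
  } else {
    readr::read_csv
  }
  raw <- reader(path, show_col_types = FALSE, progress = FALSE)
  validate_schedule(as_tibble(raw))
}

#' @rdname read_schedule
#' @param schedule A schedule tibble.
#' @export
write_schedule <- function(schedule, path) {
  schedule <- validate_schedule(schedule)
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) {
    readr::write_tsv(schedule, path, progress = FALSE)
  } else {
    readr::write_csv(schedule, path, progress = FALSE)
  }
  invisible(path)
}

validate_schedule <- function(schedule) {
  required <- c("room", "step", "n_new_females", "n_new_males")
  missing_cols <- setdiff(required, names(schedule))
  if (length(missing_cols) > 0) {
    abort(paste0("schedule is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "enclosabc_format_error")
  }
  schedule <- mutate(schedule,
                     room = as.character(.data$room),
                     step = as.integer(.data$step),
                     n_new_females = as.integer(.data$n_new_females),
                     n_new_males = as.integer(.data$n_new_males))
  if (!"cohort" %in% names(schedule)) {
    schedule$cohort <- paste0("S", schedule$step)
  }
  if (!"cohorts_removed" %in% names(schedule)) {
    schedule$cohorts_removed <- ""
  }
  schedule$cohorts_removed <- ifelse(is.na(schedule$cohorts_removed), "",
                                     as.character(schedule$cohorts_removed))
  if (!"include_in_stats" %in% names(schedule)) {
    schedule$include_in_stats <- TRUE
  }
  schedule$include_in_stats <- as.logical(schedule$include_in_stats)
  if (any(schedule$n_new_females < 0 | schedule$n_new_males < 0)) {
    abort("schedule entry counts must be non-negative",
          class = "enclosabc_validation_error")
  }
  schedule <- arrange(schedule, .data$room, .data$step)
  for (rm in unique(schedule$room)) {
    rows <- schedule[schedule$room == rm, ]
    seen <- character()
    for (i in seq_len(nrow(rows))) {
      seen <- c(seen, rows$cohort[i])
      removed <- cohort_list(rows$cohorts_removed[i])
      unknown <- setdiff(removed, seen)
      if (length(unknown) > 0) {
        abort(paste0("room ", rm, " step ", rows$step[i],
                     " removes cohort(s) never created: ",
                     paste(unknown, collapse = ", ")),
              class = "enclosabc_validation_error")
      }
    }
  }
  schedule[c("room", "step", "cohort", "n_new_females", "n_new_males",
             "cohorts_removed", "include_in_stats")]
}

cohort_list <- function(x) {
  if (is.na(x) || x == "") character() else strsplit(x, ";", fixed = TRUE)[[1]]
}

#' Schedule-implied population sizes
#'
#' Replays a schedule's bookkeeping (entries and cohort removals) to give the
#' number of alive adults per sex after each step.  This depends on the
#' schedule alone, never on genotypes or fitness.
#'
#' @param schedule A schedule tibble (see [read_schedule()]).
#' @return A tibble with `room`, `step`, `n_females`, `n_males`, `n_alive`.
#' @export
implied_sizes <- function(schedule) {
  schedule <- validate_schedule(schedule)
  purrr::map_dfr(split(schedule, schedule$room), function(rows) {
    sizes <- tibble(cohort = rows$cohort,
                    f = rows$n_new_females, m = rows$n_new_males)
    alive <- setNames(vector("list", 0), character())
    out <- vector("list", nrow(rows))
    live_f <- integer(0); live_m <- integer(0); live_coh <- character(0)
    for (i in seq_len(nrow(rows))) {
      live_coh <- c(live_coh, rows$cohort[i])
      live_f <- c(live_f, rows$n_new_females[i])
      live_m <- c(live_m, rows$n_new_males[i])
      keep <- !(live_coh %in% cohort_list(rows$cohorts_removed[i]))
      live_coh <- live_coh[keep]; live_f <- live_f[keep]; live_m <- live_m[keep]
      out[[i]] <- tibble(room = rows$room[i], step = rows$step[i],
                         n_females = sum(live_f), n_males = sum(live_m))
    }
    bind_rows(out)
  }) %>%
    mutate(n_alive = .data$n_females + .data$n_males)
}

#' Simulate one enclosure room
#'
#' Forward individual-based simulation of a single room under a fitness
#' model, with per-step adult numbers and removals following the demography
#' schedule exactly.  Each monitoring interval is one reproduction event: the
#' scheduled number of new adults of each sex is created by repeatedly
#' sampling a mother and a father (fitness-proportional, with replacement)
#' and drawing a Mendelian offspring genotype; then the scheduled cohorts are
#' removed; then the census is taken.
#'
#' @param schedule Schedule rows for one room ([read_schedule()] format).
#' @param model A [fitness_model()].
#' @param init Individuals alive at the census of step `start_step`: a data
#'   frame with columns `sex` (`"F"`/`"M"`), `genotype` (labels or integer
#'   codes) and `cohort` (matching schedule cohort labels).
#' @param start_step The monitoring step that `init` represents; steps after
#'   it are simulated.
#' @return A trajectory tibble (class `enclosure_trajectory`): per included
#'   step and sex, counts of the three genotypes among alive adults.
#' @export
simulate_room <- function(schedule, model, init, start_step) {
  schedule <- validate_schedule(schedule)
  if (length(unique(schedule$room)) != 1) {
    abort("simulate_room expects a single room's schedule")
  }
  room <- schedule$room[1]
  comp <- compile_schedule(schedule, start_step)[[room]]
  ci <- compile_init(init, comp$coh_levels)

  exp_sizes <- implied_sizes(schedule)
  start_row <- exp_sizes[exp_sizes$step == start_step, ]
  if (nrow(start_row) == 1 &&
      (sum(!ci$male) != start_row$n_females ||
       sum(ci$male) != start_row$n_males)) {
    abort(sprintf(
      "init for room %s step %d has %d F / %d M but the schedule implies %d F / %d M",
      room, start_step, sum(!ci$male), sum(ci$male),
      start_row$n_females, start_row$n_males),
      class = "enclosabc_validation_error")
  }
  census_to_trajectory(sim_room_fast(comp, model, ci), room)
}

# Expand the fast core's census matrix into the tidy trajectory layout.
census_to_trajectory <- function(census, room) {
  steps <- as.integer(rownames(census))
  traj <- tibble(
    room = room,
    time_point = rep(steps, each = 2),
    sex = rep(c("F", "M"), length(steps)),
    n_wt_hom = as.integer(t(census[, c(1, 4), drop = FALSE])),
    n_het = as.integer(t(census[, c(2, 5), drop = FALSE])),
    n_ko_hom = as.integer(t(census[, c(3, 6), drop = FALSE]))
  )
  class(traj) <- c("enclosure_trajectory", class(traj))
  traj
}

#' Simulate a replicated enclosure experiment
#'
#' Runs [simulate_room()] for every room in a multi-room schedule and
#' flattens the resulting trajectories into a summary-statistic vector with
#' [observation_vector()], under the same ordering contract as the observed
#' data.
#'
#' @param schedules Schedule tibble covering all rooms.
#' @param model A [fitness_model()].
#' @param inits Named list (by room id) of init individual tables; see
#'   [simulate_room()].
#' @param mode `"A"` (allele frequencies) or `"G"` (genotype frequencies).
#' @param start_step Monitoring step the inits represent; statistics cover
#'   steps `start_step + 1` onward.
#' @param seed Optional integer seed (set before simulating).
#' @param return_trajectory If `TRUE`, return a list with elements `stat`
#'   and `trajectory`; otherwise just the named statistic vector.
#' @return Named numeric statistic vector, or a list when
#'   `return_trajectory = TRUE`.
#' @export
simulate_experiment <- function(schedules, model, inits,
                                mode = c("A", "G"), start_step,
                                seed = NULL, return_trajectory = FALSE) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  schedules <- validate_schedule(schedules)
  rooms <- sort(unique(schedules$room))
  if (!all(rooms %in% names(inits))) {
    abort(paste0("missing init population(s) for room(s): ",
                 paste(setdiff(rooms, names(inits)), collapse = ", ")))
  }
  comp_rooms <- compile_schedule(schedules, start_step)
  census <- lapply(rooms, function(rm) {
    sim_room_fast(comp_rooms[[rm]], model,
                  compile_init(inits[[rm]], comp_rooms[[rm]]$coh_levels))
  })
  names(census) <- rooms
  stat <- stats_from_census(census, mode, stat_start = start_step + 1L)
  if (!return_trajectory) return(stat)
  traj <- bind_rows(lapply(rooms, function(rm) {
    census_to_trajectory(census[[rm]], rm)
  }))
  class(traj) <- c("enclosure_trajectory", class(traj))
  list(stat = stat, trajectory = traj)
}

#' Realise an initial population from observed frequencies
#'
#' Builds a reproducible initial individual table for one room from observed
#' genotype frequencies and the schedule-implied composition at the start
#' step.  Counts are allocated by deterministic largest-remainder rounding of
#' frequency x cell size within every (sex, cohort) cell, so the initial
#' state contains no randomness.
#'
#' @param counts One room's observed counts at the start time point (rows of
#'   a [read_counts()] tibble); sexes pooled for the frequency estimate
#'   unless a `sex` column splits them.
#' @param schedule The room's schedule rows.
#' @param start_step Monitoring step the init represents.
#' @return An individual tibble with columns `sex`, `genotype`, `cohort`.
#' @export
build_init_population <- function(counts, schedule, start_step) {
  schedule <- validate_schedule(schedule)
  room <- schedule$room[1]
  # cohorts alive at the start-step census, with per-sex sizes
  rows <- schedule[schedule$step <= start_step, ]
  live <- tibble(cohort = rows$cohort, f = rows$n_new_females,
                 m = rows$n_new_males, step = rows$step)
  removed <- unique(unlist(lapply(rows$cohorts_removed, cohort_list)))
  live <- live[!(live$cohort %in% removed), ]
  if (sum(live$f) + sum(live$m) == 0) {
    abort("schedule implies an empty population at start_step",
          class = "enclosabc_validation_error")
  }
  freq_for_sex <- function(sx) {
    sub <- counts
    if ("sex" %in% names(counts) && any(counts$sex == sx)) {
      sub <- counts[counts$sex == sx, ]
    }
    tot <- c(sum(sub$n_wt_hom), sum(sub$n_het), sum(sub$n_ko_hom))
    if (sum(tot) == 0) abort("empty start-point counts",
                             class = "enclosabc_undefined_frequency")
    tot / sum(tot)
  }
  fr <- list(F = freq_for_sex("F"), M = freq_for_sex("M"))
  cells <- tidyr::pivot_longer(live, c("f", "m"), names_to = "sex",
                               values_to = "n") %>%
    mutate(sex = ifelse(.data$sex == "f", "F", "M")) %>%
    filter(.data$n > 0)
  purrr::pmap_dfr(cells[c("cohort", "sex", "n")], function(cohort, sex, n) {
    k <- largest_remainder(fr[[sex]], n)
    tibble(sex = sex,
           genotype = rep(c(2L, 1L, 0L), k),
           cohort = cohort)
  })
}

# Deterministic largest-remainder apportionment of n into length(p) classes.
# Ties in the fractional remainders are broken by class order.
largest_remainder <- function(p, n) {
  p <- p / sum(p)
  raw <- p * n
  k <- floor(raw)
  left <- n - sum(k)
  if (left > 0) {
    frac <- raw - k
    ord <- order(-frac, seq_along(p))
    k[ord[seq_len(left)]] <- k[ord[seq_len(left)]] + 1
  }
  as.integer(k)
}
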