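#' Construct a reference table directly
#'
#' Low-level constructor pairing a parameter table with a summary-statistic
#' matrix.  [build_reference_table()] is the simulation-driven builder; this
#' constructor also accepts arbitrary tables (e.g. analytic toy models used
#' to validate the regression adjustment).
#'
#' @param params Data frame (N x p) of parameter draws.
#' @param stats Numeric matrix (N x d) of summary statistics; column names
#'   are kept if present.
#' @param estimate Character vector of parameter columns to estimate
#'   (default: all).
#' @param variant Optional [variant_spec()] or name.
#' @param mode Optional statistic mode label (`"A"`/`"G"`).
#' @param meta Optional metadata list.
#' @return An object of class `abc_reftable`.
#' @export
reference_table <- function(params, stats, estimate = names(params),
                            variant = NULL, mode = NULL, meta = list()) {
  params <- as_tibble(params)
  stats <- as.matrix(stats)
  if (nrow(params) != nrow(stats)) {
    abort("params and stats must have the same number of rows")
  }
  if (any(!is.finite(stats))) {
    abort("statistics must be finite for all rows")
  }
  if (is.null(colnames(stats))) {
    colnames(stats) <- paste0("S", seq_len(ncol(stats)))
  }
  if (is.character(variant)) variant <- variant_spec(variant)
  structure(list(params = params, stats = stats, estimate = estimate,
                 variant = variant, mode = mode, meta = meta),
            class = "abc_reftable")
}

#' @export
print.abc_reftable <- function(x, ...) {
  cat("<abc_reftable> ", nrow(x$stats), " simulations, ",
      ncol(x$stats), " statistics\n", sep = "")
  if (!is.null(x$variant)) cat("  variant:", x$variant$name, "\n")
  if (!is.null(x$mode)) cat("  mode:", x$mode, "\n")
  if (ncol(x$params) > 0) {
    cat("  parameters:", paste(names(x$params), collapse = ", "),
        "(estimated:", paste(x$estimate, collapse = ", "), ")\n")
  }
  invisible(x)
}

#' @export
dim.abc_reftable <- function(x) c(nrow(x$stats), ncol(x$stats))

#' Build a simulation reference table
#'
#' Draws `n` parameter vectors from the prior and simulates the replicated
#' enclosure experiment once per draw, pairing each draw with its
#' summary-statistic vector.  Replicates in which a room loses all members
#' of one sex (or all sampling weights vanish) are resampled with a fresh
#' derived seed, up to a bounded number of retries; persistent failure
#' aborts with a diagnostic.
#'
#' Reproducibility: replicate `i` always uses the seed derived from
#' `(seed, i, retry)`, so the table is identical for identical `seed`
#' regardless of evaluation order.
#'
#' @param n Number of simulation replicates.
#' @param prior A [prior_spec()].
#' @param variant A [variant_spec()] or variant name.
#' @param schedules Multi-room schedule tibble.
#' @param inits Named list of per-room init individual tables.
#' @param start_step Monitoring step the inits represent.
#' @param mode `"A"` or `"G"`.
#' @param seed Integer root seed.
#' @param fixed Named list of parameters pinned to constants (see
#'   [sample_prior()]).
#' @param max_fail_frac Abort when failed attempts exceed
#'   `max(10, max_fail_frac * n)`.
#' @return An `abc_reftable`.
#' @export
build_reference_table <- function(n, prior, variant, schedules, inits,
                                  start_step, mode = c("A", "G"), seed = 1L,
                                  fixed = list(), max_fail_frac = 0.01) {
  mode <- match.arg(mode)
  if (is.character(variant)) variant <- variant_spec(variant)
  schedules <- validate_schedule(schedules)
  stopifnot(n >= 1)
  comp_rooms <- compile_schedule(schedules, start_step)
  if (!all(names(comp_rooms) %in% names(inits))) {
    abort(paste0("missing init population(s) for room(s): ",
                 paste(setdiff(names(comp_rooms), names(inits)),
                       collapse = ", ")))
  }
  comp_inits <- lapply(setNames(names(comp_rooms), names(comp_rooms)),
                       function(rm) {
                         compile_init(inits[[rm]], comp_rooms[[rm]]$coh_levels)
                       })
  param_rows <- vector("list", n)
  stat_rows <- vector("list", n)
  n_failed <- 0L
  fail_budget <- max(10, max_fail_frac * n)
  for (i in seq_len(n)) {
    done <- FALSE
    for (retry in 0:30) {
      set.seed(derive_seed(seed, i, retry))
      draw <- sample_prior_row(prior, variant, fixed = fixed)
      model <- params_to_model_fast(draw, variant)
      stat <- tryCatch(
        sim_experiment_fast(comp_rooms, model, comp_inits, mode,
                            stat_start = start_step + 1L),
        enclosabc_extinction = function(e) NULL,
        enclosabc_degenerate_weights = function(e) NULL
      )
      if (!is.null(stat)) {
        param_rows[[i]] <- draw
        stat_rows[[i]] <- stat
        done <- TRUE
        break
      }
      n_failed <- n_failed + 1L
      if (n_failed > fail_budget) {
        abort(sprintf(
          "persistent simulation failure: %d failed attempts over %d replicates (variant %s); check the schedule/model for near-certain extinction",
          n_failed, i, variant$name), class = "enclosabc_simulation_failure")
      }
    }
    if (!done) {
      abort(sprintf("replicate %d failed after 31 attempts", i),
            class = "enclosabc_simulation_failure")
    }
  }
  stats <- do.call(rbind, stat_rows)
  rownames(stats) <- NULL
  params <- if (length(variant$sampled) == 0) {
    tibble(.rows = n)
  } else {
    as_tibble(lapply(setNames(variant$sampled, variant$sampled), function(p) {
      vapply(param_rows, function(r) r[[p]], numeric(1))
    }))
  }
  reference_table(params, stats,
                  estimate = variant$estimate, variant = variant, mode = mode,
                  meta = list(seed = seed, n = n, start_step = start_step,
                              n_failed = n_failed, prior = prior))
}

#' Persist a reference table as delimited text
#'
#' Writes parameter columns followed by statistic columns to CSV, plus a
#' JSON metadata sidecar (`<path>.meta.json`) recording the seed, variant,
#' mode and prior hyperparameters needed to regenerate the table.
#'
#' @param table An `abc_reftable`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_reference_table <- function(table, path) {
  p <- ncol(table$params)
  df <- bind_cols(table$params, as_tibble(table$stats, .name_repair = "minimal"))
  readr::write_csv(df, path, progress = FALSE)
  meta <- list(
    n_params = p, param_names = names(table$params),
    estimate = table$estimate,
    variant = if (!is.null(table$variant)) table$variant$name else NULL,
    mode = table$mode,
    meta = table$meta[setdiff(names(table$meta), "prior")],
    prior = unclass(table$meta$prior)
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_reference_table
#' @export
read_reference_table <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  pn <- meta$param_names %||% character()
  reference_table(df[, pn, drop = FALSE],
                  as.matrix(df[, setdiff(names(df), pn), drop = FALSE]),
                  estimate = meta$estimate %||% pn,
                  variant = if (!is.null(meta$variant)) meta$variant else NULL,
                  mode = meta$mode, meta = as.list(meta$meta))
}

# Subset a reference table by row index (used by cross-validation and
# leave-one-out procedures).
reftable_subset <- function(table, idx) {
  reference_table(table$params[idx, , drop = FALSE],
                  table$stats[idx, , drop = FALSE],
                  estimate = table$estimate, variant = table$variant,
                  mode = table$mode, meta = table$meta)
}
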