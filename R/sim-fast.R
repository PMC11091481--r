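# Fast simulation core.  The public simulate_room()/simulate_experiment()
# interfaces validate and return tibbles; reference-table construction runs
# thousands of replicates, so the hot path below works on a precompiled
# schedule and plain integer vectors and never touches a data frame.

# Precompile a validated multi-room schedule into per-room lists of plain
# vectors.  Cohort labels are mapped to integer ids.
compile_schedule <- function(schedule, start_step) {
  rooms <- sort(unique(schedule$room))
  lapply(setNames(rooms, rooms), function(rm) {
    rows <- schedule[schedule$room == rm, ]
    coh_levels <- rows$cohort
    removals <- lapply(rows$cohorts_removed, function(x) {
      match(cohort_list(x), coh_levels)
    })
    todo <- which(rows$step > start_step)
    list(room = rm, steps = rows$step, n_f = rows$n_new_females,
         n_m = rows$n_new_males, coh_id = seq_along(coh_levels),
         coh_levels = coh_levels, removals = removals,
         include = rows$include_in_stats, todo = todo,
         start_idx = match(start_step, rows$step))
  })
}

# Convert an init individuals table to the internal representation.
compile_init <- function(init, coh_levels) {
  gt <- init$genotype
  if (!is.numeric(gt)) gt <- genotype_code(gt)
  coh <- match(as.character(init$cohort), coh_levels)
  if (anyNA(coh)) {
    abort("init cohort label(s) not present in the schedule",
          class = "enclosabc_validation_error")
  }
  list(gt = as.integer(gt), male = init$sex == "M", coh = coh)
}

# One reproduction event.  Parents are drawn with replacement, mothers
# proportional to female fitness, fathers proportional to male fitness times
# the non-random-mating modifier against the chosen mother (father sampling
# grouped by maternal genotype: only three weight vectors are ever needed).
# Offspring genotypes follow Mendelian segregation; offspring sexes match
# the scheduled per-sex counts exactly.  wf_tab/wm_tab are the genotype ->
# base-fitness lookup tables (index = wildtype-allele count + 1).
reproduce_step <- function(gt, male, wf_tab, wm_tab, g, lambda, n_f, n_m) {
  n_off <- n_f + n_m
  f_idx <- which(!male); m_idx <- which(male)
  if (length(f_idx) == 0L || length(m_idx) == 0L) {
    abort("reproduction step with an empty parental sex",
          class = "enclosabc_extinction")
  }
  w_f <- wf_tab[gt[f_idx] + 1L]
  w_m <- wm_tab[gt[m_idx] + 1L]
  if (g > 0) {
    w_f <- pmax(0, rnorm(length(w_f), w_f, g))
    w_m <- pmax(0, rnorm(length(w_m), w_m, g))
  }
  if (sum(w_f) <= 0 || sum(w_m) <= 0) {
    abort("all parental weights are zero", class = "enclosabc_degenerate_weights")
  }
  mothers <- f_idx[sample.int(length(f_idx), n_off, replace = TRUE, prob = w_f)]
  gm <- gt[mothers]
  if (lambda == 0) {
    fathers <- m_idx[sample.int(length(m_idx), n_off, replace = TRUE,
                                prob = w_m)]
  } else {
    fathers <- integer(n_off)
    gts_m <- gt[m_idx]
    for (mg in unique(gm)) {
      sel <- which(gm == mg)
      w <- w_m * mating_modifier(mg, gts_m, lambda)
      if (sum(w) <= 0) {
        abort("all male weights are zero under the mating modifier",
              class = "enclosabc_degenerate_weights")
      }
      fathers[sel] <- m_idx[sample.int(length(m_idx), length(sel),
                                       replace = TRUE, prob = w)]
    }
  }
  child_gt <- rbinom(n_off, 1L, gm / 2) + rbinom(n_off, 1L, gt[fathers] / 2)
  list(gt = as.integer(child_gt),
       male = rep(c(FALSE, TRUE), c(n_f, n_m)))
}

# Census tally: counts per (sex, genotype) cell in the fixed column order
# female WT/WT, WT/ko, ko/ko then male ditto.
tally_census <- function(gt, male) {
  tabulate((2L - gt) + 3L * male + 1L, nbins = 6L)
}

# Simulate one room on the compiled representation.  Returns a 6-column
# matrix (see tally_census) with included step numbers as rownames.
sim_room_fast <- function(comp, model, init, record_start = TRUE) {
  gt <- init$gt; male <- init$male; coh <- init$coh
  wf_tab <- 1 + model$s_female * c(0, model$h_female, 1)
  wm_tab <- 1 + model$s_male * c(0, model$h_male, 1)
  n_rec <- sum(comp$include[comp$todo]) +
    (record_start && !is.na(comp$start_idx) &&
       isTRUE(comp$include[comp$start_idx]))
  recs <- matrix(0L, nrow = n_rec, ncol = 6L)
  steps_rec <- integer(n_rec)
  r <- 0L
  if (record_start && !is.na(comp$start_idx) &&
      isTRUE(comp$include[comp$start_idx])) {
    r <- r + 1L
    recs[r, ] <- tally_census(gt, male)
    steps_rec[r] <- comp$steps[comp$start_idx]
  }
  for (i in comp$todo) {
    n_f <- comp$n_f[i]; n_m <- comp$n_m[i]
    if (n_f + n_m > 0L) {
      off <- reproduce_step(gt, male, wf_tab, wm_tab, model$g, model$lambda,
                            n_f, n_m)
      gt <- c(gt, off$gt)
      male <- c(male, off$male)
      coh <- c(coh, rep.int(comp$coh_id[i], n_f + n_m))
    }
    rem <- comp$removals[[i]]
    if (length(rem) > 0L) {
      keep <- !(coh %in% rem)
      gt <- gt[keep]; male <- male[keep]; coh <- coh[keep]
    }
    if (comp$include[i]) {
      r <- r + 1L
      recs[r, ] <- tally_census(gt, male)
      steps_rec[r] <- comp$steps[i]
    }
  }
  rownames(recs) <- steps_rec
  recs
}

# Summary statistics from census matrices of all rooms (list in room order):
# mode A gives f_WT per room/step, mode G the three genotype frequencies.
# Only steps >= stat_start contribute.  Ordering matches
# observation_vector(): rooms ascending, steps ascending, genotypes
# WT/WT, WT/ko, ko/ko.
stats_from_census <- function(census_list, mode, stat_start) {
  out <- lapply(names(census_list), function(rm) {
    m <- census_list[[rm]]
    steps <- as.integer(rownames(m))
    sel <- steps >= stat_start
    m <- m[sel, , drop = FALSE]
    steps <- steps[sel]
    n2 <- m[, 1] + m[, 4]; n1 <- m[, 2] + m[, 5]; n0 <- m[, 3] + m[, 6]
    tot <- n2 + n1 + n0
    if (any(tot == 0)) {
      abort("empty census in statistic window", class = "enclosabc_extinction")
    }
    if (mode == "A") {
      setNames((2 * n2 + n1) / (2 * tot), paste(rm, steps, sep = "."))
    } else {
      v <- as.numeric(rbind(n2 / tot, n1 / tot, n0 / tot))
      names(v) <- paste(rm, rep(steps, each = 3),
                        rep(c("WT/WT", "WT/ko", "ko/ko"), length(steps)),
                        sep = ".")
      v
    }
  })
  unlist(out)
}

# One full experiment replicate on compiled inputs; errors with
# enclosabc_extinction / enclosabc_degenerate_weights on failure.
sim_experiment_fast <- function(comp_rooms, model, comp_inits, mode,
                                stat_start) {
  census <- lapply(names(comp_rooms), function(rm) {
    sim_room_fast(comp_rooms[[rm]], model, comp_inits[[rm]])
  })
  names(census) <- names(comp_rooms)
  stats_from_census(census, mode, stat_start)
}

# Fast prior draw for the hot loop: a named list, no tibble.
sample_prior_row <- function(prior, variant, fixed = list()) {
  out <- vector("list", length(variant$sampled))
  names(out) <- variant$sampled
  for (par in variant$sampled) {
    out[[par]] <- if (par %in% names(fixed)) {
      fixed[[par]]
    } else {
      switch(sub("_(male|female)$", "", par),
        s = rgamma(1, shape = prior$s_shape, rate = prior$s_rate) + prior$s_shift,
        h = runif(1, prior$h_min, prior$h_max),
        g = runif(1, prior$g_min, prior$g_max),
        lambda = runif(1, prior$lambda_min, prior$lambda_max))
    }
  }
  out
}

# Fast fitness-model construction for the hot loop (inputs already valid).
params_to_model_fast <- function(p, variant) {
  g <- if (variant$with_g) p$g else 0
  lam <- if (variant$with_lambda) p$lambda else 0
  if (variant$name == "neutral") {
    s_f <- 0; h_f <- 0; s_m <- 0; h_m <- 0
  } else if (variant$base == "sex_specific") {
    s_f <- p$s_female; h_f <- p$h_female; s_m <- p$s_male; h_m <- p$h_male
  } else if (variant$base == "sex_averaged") {
    s_f <- p$s; h_f <- p$h; s_m <- p$s; h_m <- p$h
  } else {
    s_f <- 0; h_f <- 0; s_m <- p$s; h_m <- p$h
  }
  structure(list(variant = variant$base, s_male = s_m, h_male = h_m,
                 s_female = s_f, h_female = h_f, g = g, lambda = lam),
            class = "fitness_model")
}
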