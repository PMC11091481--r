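#' Read a genotype-count monitoring table
#'
#' Reads a delimited text file of genotype counts from enclosure monitoring:
#' one row per room and monitoring time point (optionally further split by
#' sex and tagged by cohort), with counts of the three genotypes at the
#' wildtype/knockout locus.
#'
#' The required columns are `room`, `time_point`, `n_wt_hom`, `n_het` and
#' `n_ko_hom`; `sex` (`"F"`/`"M"`) and `cohort` are optional.  The delimiter
#' is auto-detected from the file extension (`.tsv`/`.txt` are read as
#' tab-separated, anything else as comma-separated).
#'
#' @param path Path to a CSV/TSV file.
#' @param dialect `"auto"` (default, by extension), `"csv"` or `"tsv"`.
#' @return A tibble with one row per record, counts as non-negative integers,
#'   ordered by room and time point.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("room,time_point,n_wt_hom,n_het,n_ko_hom",
#'              "room1,0,5,0,5"), f)
#' read_counts(f)
read_counts <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(paste0("counts file not found: ", path), class = "enclosabc_io_error")
  }
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  reader <- if (dialect == "tsv") readr::read_tsv else readr::read_csv
  raw <- reader(path, show_col_types = FALSE, progress = FALSE,
                col_types = readr::cols(.default = readr::col_character()))
  required <- c("room", "time_point", "n_wt_hom", "n_het", "n_ko_hom")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("counts file is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "enclosabc_format_error")
  }
  validate_counts(parse_count_columns(raw))
}

parse_count_columns <- function(raw) {
  out <- tibble(
    room = as.character(raw$room),
    time_point = parse_nonneg_int(raw$time_point, "time_point"),
    n_wt_hom = parse_nonneg_int(raw$n_wt_hom, "n_wt_hom"),
    n_het = parse_nonneg_int(raw$n_het, "n_het"),
    n_ko_hom = parse_nonneg_int(raw$n_ko_hom, "n_ko_hom")
  )
  if ("sex" %in% names(raw)) out$sex <- as.character(raw$sex)
  if ("cohort" %in% names(raw)) out$cohort <- as.character(raw$cohort)
  cols <- intersect(c("room", "time_point", "sex", "cohort",
                      "n_wt_hom", "n_het", "n_ko_hom"), names(out))
  arrange(out[cols], .data$room, .data$time_point)
}

parse_nonneg_int <- function(x, what) {
  num <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(num) | num < 0 | num != round(num))
  if (length(bad) > 0) {
    abort(paste0("column '", what, "' must hold non-negative integers; ",
                 "offending row(s): ", paste(head(bad, 5), collapse = ", "),
                 " (value(s): ", paste(head(x[bad], 5), collapse = ", "), ")"),
          class = "enclosabc_validation_error")
  }
  as.integer(num)
}

validate_counts <- function(counts) {
  stopifnot(is.data.frame(counts))
  for (col in c("n_wt_hom", "n_het", "n_ko_hom")) {
    if (any(counts[[col]] < 0)) {
      abort(paste0("negative count in column ", col),
            class = "enclosabc_validation_error")
    }
  }
  if ("sex" %in% names(counts)) {
    bad <- setdiff(unique(counts$sex), c("F", "M", NA_character_))
    if (length(bad) > 0) {
      abort(paste0("sex column must be 'F' or 'M'; found: ",
                   paste(bad, collapse = ", ")),
            class = "enclosabc_validation_error")
    }
  }
  counts
}

#' Write genotype counts back to delimited text
#'
#' Inverse of [read_counts()]; used by the synthetic-data generator so that
#' emitted fixtures round-trip exactly.
#'
#' @param counts A counts tibble as returned by [read_counts()].
#' @param path Output path; `.tsv`/`.txt` write tab-separated, else CSV.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  counts <- validate_counts(counts)
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) {
    readr::write_tsv(counts, path, progress = FALSE)
  } else {
    readr::write_csv(counts, path, progress = FALSE)
  }
  invisible(path)
}

#' Wildtype allele frequency from genotype counts
#'
#' Computes `f_WT = (2 n_WT/WT + n_het) / (2 N)` for each row of a genotype
#' count table.
#'
#' @param counts Data frame with columns `n_wt_hom`, `n_het`, `n_ko_hom`.
#' @return Numeric vector of wildtype allele frequencies, one per row.
#' @export
#' @examples
#' allele_frequency(data.frame(n_wt_hom = 338, n_het = 576, n_ko_hom = 267))
allele_frequency <- function(counts) {
  n <- counts$n_wt_hom + counts$n_het + counts$n_ko_hom
  if (any(n == 0)) {
    abort("allele frequency undefined for empty sample (N = 0)",
          class = "enclosabc_undefined_frequency")
  }
  (2 * counts$n_wt_hom + counts$n_het) / (2 * n)
}

#' Hardy-Weinberg chi-square statistic
#'
#' Pearson chi-square over the three genotype classes against expected counts
#' \eqn{N p^2, 2 N p q, N q^2}, with the allele frequency \eqn{p} estimated
#' from the same sample (1 degree of freedom, no continuity correction).
#'
#' @param counts Data frame with columns `n_wt_hom`, `n_het`, `n_ko_hom`.
#' @return Numeric vector of chi-square statistics, one per row.
#' @export
#' @examples
#' hwe_chi_square(data.frame(n_wt_hom = 25, n_het = 50, n_ko_hom = 25))
hwe_chi_square <- function(counts) {
  n <- counts$n_wt_hom + counts$n_het + counts$n_ko_hom
  if (any(n == 0)) {
    abort("HWE test undefined for empty sample (N = 0)",
          class = "enclosabc_undefined_frequency")
  }
  p <- allele_frequency(counts)
  if (any(p <= 0 | p >= 1)) {
    abort("HWE chi-square undefined for monomorphic sample (p = 0 or 1)",
          class = "enclosabc_degenerate_test")
  }
  q <- 1 - p
  e_wt <- n * p^2
  e_het <- 2 * n * p * q
  e_ko <- n * q^2
  (counts$n_wt_hom - e_wt)^2 / e_wt +
    (counts$n_het - e_het)^2 / e_het +
    (counts$n_ko_hom - e_ko)^2 / e_ko
}

#' Cumulative per-room genotype summary
#'
#' Sums genotype counts across monitoring time points (and sexes, if split)
#' within each room, then reports totals, allele frequencies and the
#' Hardy-Weinberg chi-square per room.  Founder animals are excluded by
#' filtering on the cohort label before summation.
#'
#' @param counts Counts tibble from [read_counts()].
#' @param exclude_cohort Cohort label(s) dropped before summing (default
#'   `"F0"`, the founders); ignored when there is no `cohort` column.
#' @return A tibble with one row per room: `room`, `n_total`, the three
#'   summed genotype counts, `chi2_hwe`, `p_hwe` (1 df), `f_wt`, `f_ko`.
#' @export
cumulative_summary <- function(counts, exclude_cohort = "F0") {
  if (nrow(counts) == 0) {
    warn("empty counts input; returning empty summary")
    return(tibble(room = character(), n_total = integer(),
                  n_wt_hom = integer(), n_het = integer(), n_ko_hom = integer(),
                  chi2_hwe = numeric(), p_hwe = numeric(),
                  f_wt = numeric(), f_ko = numeric()))
  }
  if ("cohort" %in% names(counts) && length(exclude_cohort) > 0) {
    counts <- filter(counts, !(.data$cohort %in% exclude_cohort))
  }
  sums <- counts %>%
    group_by(.data$room) %>%
    summarise(n_wt_hom = sum(.data$n_wt_hom), n_het = sum(.data$n_het),
              n_ko_hom = sum(.data$n_ko_hom), .groups = "drop")
  sums %>%
    mutate(
      n_total = .data$n_wt_hom + .data$n_het + .data$n_ko_hom,
      chi2_hwe = hwe_chi_square(sums),
      p_hwe = pchisq(.data$chi2_hwe, df = 1, lower.tail = FALSE),
      f_wt = allele_frequency(sums),
      f_ko = 1 - .data$f_wt
    ) %>%
    select("room", "n_total", "n_wt_hom", "n_het", "n_ko_hom",
           "chi2_hwe", "p_hwe", "f_wt", "f_ko")
}

#' Round a cumulative summary for reporting
#'
#' Formats a [cumulative_summary()] in the conventional layout: frequencies
#' and chi-square rounded to two decimals, full precision retained upstream.
#'
#' @param summary Tibble from [cumulative_summary()].
#' @return A tibble rounded for display.
#' @export
format_summary <- function(summary) {
  mutate(summary,
         chi2_hwe = round(.data$chi2_hwe, 2),
         p_hwe = round(.data$p_hwe, 3),
         f_wt = round(.data$f_wt, 2),
         f_ko = round(.data$f_ko, 2))
}

#' Flatten counts into an ABC observation vector
#'
#' Builds the ordered summary-statistic vector used as the ABC observation:
#' either the wildtype allele frequency (`mode = "A"`) or all three genotype
#' frequencies (`mode = "G"`) for every room and every monitoring time point
#' from `start_time` onward.  Rows split by sex or cohort are pooled first.
#'
#' The ordering contract is frozen: rooms in ascending id, time points
#' ascending within room, genotypes in the order WT/WT, WT/ko, ko/ko.  The
#' simulator emits its statistics under the same contract, so observed and
#' simulated vectors are directly comparable.
#'
#' @param counts Counts tibble from [read_counts()].
#' @param mode `"A"` (allele frequencies) or `"G"` (genotype frequencies).
#' @param start_time First time point included (earlier points dropped).
#' @return Named numeric vector; names are `room.time` (mode A) or
#'   `room.time.genotype` (mode G).
#' @export
observation_vector <- function(counts, mode = c("A", "G"), start_time = 0L) {
  mode <- match.arg(mode)
  pooled <- counts %>%
    filter(.data$time_point >= start_time) %>%
    group_by(.data$room, .data$time_point) %>%
    summarise(n_wt_hom = sum(.data$n_wt_hom), n_het = sum(.data$n_het),
              n_ko_hom = sum(.data$n_ko_hom), .groups = "drop") %>%
    arrange(.data$room, .data$time_point)
  if (nrow(pooled) == 0) {
    abort("no records at or after start_time", class = "enclosabc_alignment_error")
  }
  grids <- split(pooled$time_point, pooled$room)
  all_points <- sort(unique(pooled$time_point))
  ragged <- purrr::imap(grids, function(g, room) setdiff(all_points, g))
  ragged <- ragged[lengths(ragged) > 0]
  if (length(ragged) > 0) {
    msg <- paste(purrr::imap_chr(ragged, function(m, room) {
      paste0(room, ": missing time point(s) ", paste(m, collapse = ", "))
    }), collapse = "; ")
    abort(paste0("rooms do not share a common time-point grid - ", msg),
          class = "enclosabc_alignment_error")
  }
  n_tot <- pooled$n_wt_hom + pooled$n_het + pooled$n_ko_hom
  if (any(n_tot == 0)) {
    abort("empty census (N = 0) in observation window",
          class = "enclosabc_undefined_frequency")
  }
  if (mode == "A") {
    setNames((2 * pooled$n_wt_hom + pooled$n_het) / (2 * n_tot),
             paste(pooled$room, pooled$time_point, sep = "."))
  } else {
    freqs <- rbind(pooled$n_wt_hom, pooled$n_het, pooled$n_ko_hom) /
      rep(n_tot, each = 3)
    nm <- paste(rep(pooled$room, each = 3), rep(pooled$time_point, each = 3),
                rep(c("WT/WT", "WT/ko", "ko/ko"), nrow(pooled)), sep = ".")
    setNames(as.numeric(freqs), nm)
  }
}
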