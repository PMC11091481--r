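#' Leave-one-out cross-validation of ABC parameter estimation
#'
#' Repeatedly holds one simulation out of the reference table, uses its
#' summary statistics as a pseudo-observation, estimates the parameters from
#' the remaining simulations, and compares the estimates with the true
#' values used in the held-out simulation.  The prediction error per
#' parameter is
#' \deqn{E = \sum_i (\hat\theta_i - \theta_i)^2 / (n \,\mathrm{Var}(\theta)),}
#' the mean squared estimation error normalised by the variance of the true
#' values over the sampled folds — approximately 1 for a parameter the
#' statistics carry no information about, and near 0 for a perfectly
#' identified one.
#'
#' @param table An `abc_reftable`.
#' @param n_folds Number of held-out simulations.
#' @param tolerance Rejection tolerance.
#' @param seed Integer seed selecting the held-out rows.
#' @param method `"ridge"` (default) or `"rejection"` estimator.
#' @return An object of class `abc_cv`: a tibble with `term` and
#'   `prediction_error`, plus an `estimates` attribute holding the per-fold
#'   true and estimated values.
#' @export
cross_validate <- function(table, n_folds = 100, tolerance = 0.1,
                           seed = 1L, method = c("ridge", "rejection")) {
  method <- match.arg(method)
  n <- nrow(table$stats)
  stopifnot(n_folds >= 2, n_folds <= n)
  est_pars <- intersect(table$estimate, names(table$params))
  if (length(est_pars) == 0) abort("table has no parameters to estimate")
  set.seed(derive_seed(seed, 7L))
  folds <- sample.int(n, n_folds)
  rows <- purrr::map_dfr(folds, function(i) {
    obs <- table$stats[i, ]
    sub <- reftable_subset(table, setdiff(seq_len(n), i))
    fit <- suppressWarnings(
      abc_fit(obs, sub, tolerance = tolerance, method = method))
    tibble(fold = i, term = est_pars,
           true = as.numeric(table$params[i, est_pars]),
           estimate = fit$summary$estimate[match(est_pars, fit$summary$term)])
  })
  errs <- rows %>%
    group_by(.data$term) %>%
    summarise(prediction_error =
                sum((.data$estimate - .data$true)^2) /
                (dplyr::n() * var(.data$true)),
              .groups = "drop")
  errs <- errs[match(est_pars, errs$term), ]
  structure(errs, class = c("abc_cv", class(errs)),
            estimates = rows, n_folds = n_folds, tolerance = tolerance,
            method = method)
}

#' @export
print.abc_cv <- function(x, ...) {
  cat("<abc_cv> ", attr(x, "n_folds"), " leave-one-out folds, tolerance ",
      attr(x, "tolerance"), "\n", sep = "")
  print(as.data.frame(unclass(x)[c("term", "prediction_error")]),
        row.names = FALSE)
  invisible(x)
}

#' @export
tidy.abc_cv <- function(x, ...) as_tibble(unclass(x)[c("term", "prediction_error")])

#' ABC goodness-of-fit test
#'
#' Distance-based posterior predictive check.  The test statistic is the
#' mean MAD-scaled Euclidean distance between a target vector and its
#' accepted set under the rejection step.  Its null distribution is built
#' from `n_null` pseudo-observations drawn from the reference table itself
#' (each excluded from its own reference set); the p-value is the fraction
#' of null statistics at least as large as the observed one.  Small p means
#' the observed data sit farther from the simulated cloud than data
#' generated by the model itself typically do.
#'
#' @param obs Observed summary-statistic vector.
#' @param table An `abc_reftable`.
#' @param n_null Number of null pseudo-observations (>= 100 recommended).
#' @param tolerance Rejection tolerance defining the accepted set.
#' @param seed Integer seed for the null draws.
#' @return An object of class `abc_gof`: list with `p_value`, `D_obs` and
#'   the null distances `D_null`.
#' @export
goodness_of_fit <- function(obs, table, n_null = 200, tolerance = 0.1,
                            seed = 1L) {
  n <- nrow(table$stats)
  mean_dist <- function(target, tab) {
    fit <- suppressWarnings(abc_reject(target, tab, tolerance))
    mean(fit$distances)
  }
  D_obs <- mean_dist(obs, table)
  set.seed(derive_seed(seed, 13L))
  rows <- sample.int(n, n_null, replace = n_null > n)
  D_null <- vapply(rows, function(i) {
    mean_dist(table$stats[i, ], reftable_subset(table, setdiff(seq_len(n), i)))
  }, numeric(1))
  structure(list(p_value = mean(D_null >= D_obs), D_obs = D_obs,
                 D_null = D_null, n_null = n_null, tolerance = tolerance),
            class = "abc_gof")
}

#' @export
print.abc_gof <- function(x, ...) {
  cat("<abc_gof> mean-distance statistic: ", signif(x$D_obs, 4),
      ", null draws: ", x$n_null, ", p = ", signif(x$p_value, 3), "\n",
      sep = "")
  invisible(x)
}
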