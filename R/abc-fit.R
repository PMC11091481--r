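# Parameter transforms applied before regression adjustment so adjusted
# draws stay inside their supports: selection coefficients via log(1 + s),
# dominance and mating penalty via logit, noise sd via log.  Unrecognised
# parameter names are left untransformed.
param_transform <- function(name) {
  base <- sub("_(male|female)$", "", name)
  switch(base,
    s = list(fwd = function(x) log1p(pmax(x, -1 + 1e-12)),
             bwd = function(z) expm1(z)),
    h = ,
    lambda = list(fwd = function(x) stats::qlogis(pmin(pmax(x, 1e-9), 1 - 1e-9)),
                  bwd = function(z) stats::plogis(z)),
    g = list(fwd = function(x) log(pmax(x, 1e-12)),
             bwd = function(z) exp(z)),
    list(fwd = identity, bwd = identity)
  )
}

#' ABC rejection step
#'
#' Scales every summary-statistic column by its median absolute deviation
#' (computed over the full reference table; zero-MAD columns are dropped
#' with a warning), computes Euclidean distances to the observed vector, and
#' accepts the `ceiling(tolerance * N)` closest simulations.  Accepted rows
#' receive Epanechnikov kernel weights `1 - (d / d_max)^2`; ties at the
#' acceptance radius are broken by row index.
#'
#' @param obs Observed summary-statistic vector (length = statistic
#'   dimension of `table`).
#' @param table An `abc_reftable`.
#' @param tolerance Fraction of simulations accepted, in (0, 1\].
#' @return An object of class `abc_fit` (method `"rejection"`) holding the
#'   accepted parameter draws, weights and posterior summaries.
#' @export
abc_reject <- function(obs, table, tolerance = 0.1) {
  stopifnot(inherits(table, "abc_reftable"),
            tolerance > 0, tolerance <= 1)
  obs <- as.numeric(obs)
  stats_m <- table$stats
  if (length(obs) != ncol(stats_m)) {
    abort(sprintf("observation has length %d but the table has %d statistics",
                  length(obs), ncol(stats_m)))
  }
  mads <- apply(stats_m, 2, mad)
  keep <- mads > 0
  if (!any(keep)) abort("all statistic columns have zero MAD")
  if (any(!keep)) {
    warn(paste0("dropping ", sum(!keep),
                " zero-MAD statistic column(s) before distance computation"))
  }
  scaled <- sweep(stats_m[, keep, drop = FALSE], 2, mads[keep], "/")
  obs_sc <- obs[keep] / mads[keep]
  centred <- sweep(scaled, 2, obs_sc, "-")
  d <- sqrt(rowSums(centred^2))
  n_acc <- ceiling(tolerance * nrow(stats_m))
  ord <- order(d)[seq_len(n_acc)]
  d_acc <- d[ord]
  d_max <- d_acc[n_acc]
  w <- if (d_max > 0) 1 - (d_acc / d_max)^2 else rep(1, n_acc)
  if (sum(w) <= 0) w <- rep(1, n_acc)
  w <- w / sum(w)
  est <- intersect(table$estimate, names(table$params))
  adjusted <- table$params[ord, est, drop = FALSE]
  fit <- structure(list(
    method = "rejection",
    accepted_idx = ord,
    weights = w,
    distances = d_acc,
    adjusted = adjusted,
    params_accepted = table$params[ord, , drop = FALSE],
    X = centred[ord, , drop = FALSE],
    obs = obs,
    estimate = est,
    tolerance = tolerance,
    n_sims = nrow(stats_m),
    table_params = table$params,
    mode = table$mode,
    variant = if (!is.null(table$variant)) table$variant$name else NULL
  ), class = "abc_fit")
  fit$summary <- summarise_posterior(fit)
  fit
}

# Weighted posterior mean and equal-tailed 95% interval per estimated
# parameter.
summarise_posterior <- function(fit) {
  if (length(fit$estimate) == 0) {
    return(tibble(term = character(), estimate = numeric(),
                  conf.low = numeric(), conf.high = numeric()))
  }
  purrr::map_dfr(fit$estimate, function(par) {
    x <- fit$adjusted[[par]]
    tibble(term = par,
           estimate = wmean(x, fit$weights),
           conf.low = wquantile(x, fit$weights, 0.025),
           conf.high = wquantile(x, fit$weights, 0.975))
  })
}

# Weighted ridge regression of a response on the accepted (obs-centred,
# MAD-scaled) statistics, with the penalty chosen by generalised
# cross-validation on a log grid.  Works from a shared SVD of the weighted,
# weighted-mean-centred design so multiple responses are cheap.
ridge_engine <- function(X, w, penalty_grid) {
  sw <- sqrt(w / sum(w))
  mx <- colSums((w / sum(w)) * X)
  Xc <- sweep(X, 2, mx, "-")
  Xw <- Xc * sw
  sv <- svd(Xw)
  list(sv = sv, mx = mx, sw = sw, Xc = Xc, grid = penalty_grid)
}

ridge_solve <- function(eng, y, w) {
  wn <- w / sum(w)
  my <- sum(wn * y)
  yc <- y - my
  yw <- yc * eng$sw
  uty <- crossprod(eng$sv$u, yw)
  dvals <- eng$sv$d
  n <- length(y)
  best <- NULL
  for (lam in eng$grid) {
    shrink <- dvals / (dvals^2 + lam)
    b <- eng$sv$v %*% (shrink * uty)
    rss <- sum((yw - eng$sv$u %*% (dvals * shrink * uty))^2)
    df <- sum(dvals^2 / (dvals^2 + lam))
    gcv <- rss / (1 - min(df / n, 0.999))^2
    if (is.null(best) || gcv < best$gcv) {
      best <- list(b = b, gcv = gcv, lambda = lam)
    }
  }
  b <- drop(best$b)
  fitted <- my + drop(eng$Xc %*% b)
  # prediction at the observation, where the centred design is identically 0
  pred_obs <- my - sum(eng$mx * b)
  list(b = b, fitted = fitted, pred_obs = pred_obs, penalty = best$lambda)
}

#' Ridge regression posterior adjustment
#'
#' Post-rejection correction of the accepted parameter draws: each estimated
#' parameter (on its transformed scale) is regressed on the obs-centred,
#' MAD-scaled statistics by weighted ridge regression, and the draws are
#' replaced by the regression prediction at the observation plus their
#' residuals.  A heteroscedasticity correction additionally rescales each
#' residual by the ratio of the local residual standard deviation at the
#' observation to that at the simulation, both obtained from a second
#' weighted ridge regression of the log squared residuals on the same
#' design.  The ridge penalty is chosen by generalised cross-validation over
#' a log grid on the accepted set.  If the adjustment fails numerically, the
#' rejection-only result is returned with a warning.
#'
#' @param fit An `abc_fit` from [abc_reject()].
#' @param transform Transform parameters to unconstrained scales before
#'   regression and back-transform afterwards (default `TRUE`), keeping
#'   adjusted draws inside their supports.
#' @param hcorr Apply the heteroscedasticity correction (default `TRUE`).
#' @param penalty_grid Ridge penalties searched by GCV.
#' @return An `abc_fit` with method `"ridge"` and adjusted draws.
#' @export
ridge_adjust <- function(fit, transform = TRUE, hcorr = TRUE,
                         penalty_grid = 10^seq(-4, 0, length.out = 9)) {
  stopifnot(inherits(fit, "abc_fit"))
  if (length(fit$estimate) == 0) return(fit)
  n_acc <- nrow(fit$X)
  if (n_acc < length(fit$estimate) + 2) {
    warn("too few accepted simulations for regression adjustment; returning rejection result")
    return(fit)
  }
  out <- tryCatch({
    eng <- ridge_engine(fit$X, fit$weights, penalty_grid)
    adjusted <- fit$adjusted
    penalties <- numeric(0)
    for (par in fit$estimate) {
      tr <- if (transform) param_transform(par) else
        list(fwd = identity, bwd = identity)
      y <- tr$fwd(fit$params_accepted[[par]])
      sol <- ridge_solve(eng, y, fit$weights)
      e <- y - sol$fitted
      ystar <- sol$pred_obs + e
      if (hcorr) {
        sol2 <- ridge_solve(eng, log(e^2 + 1e-30), fit$weights)
        sig <- exp(sol2$fitted / 2)
        sig_obs <- exp(sol2$pred_obs / 2)
        ystar <- sol$pred_obs + e * (sig_obs / pmax(sig, 1e-12))
      }
      adjusted[[par]] <- tr$bwd(ystar)
      penalties[par] <- sol$penalty
    }
    fit$adjusted <- adjusted
    fit$method <- "ridge"
    fit$penalty <- penalties
    fit$summary <- summarise_posterior(fit)
    fit
  }, error = function(e) {
    warn(paste0("regression adjustment failed (", conditionMessage(e),
                "); returning rejection-only result"))
    fit
  })
  out
}

#' Fit ABC posteriors for an observation
#'
#' One-call wrapper: [abc_reject()] followed (by default) by
#' [ridge_adjust()].
#'
#' @inheritParams abc_reject
#' @param method `"ridge"` (rejection + regression adjustment, default) or
#'   `"rejection"`.
#' @param transform,hcorr Passed to [ridge_adjust()].
#' @return An `abc_fit`.
#' @export
#' @examples
#' tab <- reference_table(data.frame(theta = rnorm(500)),
#'                        matrix(rnorm(500), ncol = 1))
#' fit <- abc_fit(0.2, tab, tolerance = 0.2)
#' tidy(fit)
abc_fit <- function(obs, table, tolerance = 0.1,
                    method = c("ridge", "rejection"),
                    transform = TRUE, hcorr = TRUE) {
  method <- match.arg(method)
  fit <- abc_reject(obs, table, tolerance)
  if (method == "ridge") fit <- ridge_adjust(fit, transform = transform,
                                             hcorr = hcorr)
  fit
}

#' @export
print.abc_fit <- function(x, ...) {
  cat("<abc_fit> method:", x$method,
      " tolerance:", x$tolerance,
      " accepted:", length(x$accepted_idx), "/", x$n_sims, "\n")
  if (nrow(x$summary) > 0) print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' Tidy an ABC fit
#'
#' @param x An `abc_fit`.
#' @param ... Unused.
#' @return A tibble with one row per estimated parameter: `term`,
#'   `estimate` (weighted posterior mean), `conf.low`, `conf.high`
#'   (weighted equal-tailed 95% interval).
#' @export
tidy.abc_fit <- function(x, ...) x$summary

#' @rdname tidy.abc_fit
#' @return For `glance()`: a one-row tibble with fit-level metadata.
#' @export
glance.abc_fit <- function(x, ...) {
  tibble(method = x$method, tolerance = x$tolerance,
         n_accepted = length(x$accepted_idx), n_sims = x$n_sims,
         mode = x$mode %||% NA_character_,
         variant = x$variant %||% NA_character_)
}
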