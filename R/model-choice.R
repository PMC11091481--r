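#' Posterior model probabilities
#'
#' Pools the candidate models' reference tables, applies the rejection step
#' on the pooled, MAD-scaled statistics, and estimates posterior model
#' probabilities at the observation.  The default estimator fits a
#' multinomial logistic regression of the model label on the scaled
#' statistics over the accepted simulations (Epanechnikov-weighted) and
#' evaluates it at the observed vector; `method = "rejection"` instead uses
#' the weighted label frequencies among the accepted simulations.
#'
#' @param obs Observed summary-statistic vector.
#' @param tables Named list of `abc_reftable`s, one per candidate model,
#'   with identical statistic dimensions.
#' @param tolerance Fraction of the pooled simulations accepted.
#' @param method `"mnlogistic"` (default) or `"rejection"`.
#' @return An object of class `model_choice`: a tibble with columns `model`
#'   and `posterior_prob` (summing to 1), plus metadata attributes.
#' @export
model_posterior <- function(obs, tables, tolerance = 0.1,
                            method = c("mnlogistic", "rejection")) {
  method <- match.arg(method)
  stopifnot(length(tables) >= 2)
  if (is.null(names(tables)) || any(names(tables) == "")) {
    abort("tables must be a named list (one name per model)")
  }
  dims <- vapply(tables, function(t) ncol(t$stats), integer(1))
  if (length(unique(dims)) != 1) {
    abort("all models must share the same statistic dimension")
  }
  obs <- as.numeric(obs)
  labels <- factor(rep(names(tables), vapply(tables, function(t) nrow(t$stats),
                                             integer(1))),
                   levels = names(tables))
  stats_m <- do.call(rbind, lapply(tables, function(t) t$stats))
  mads <- apply(stats_m, 2, mad)
  keep <- mads > 0
  if (!any(keep)) abort("all pooled statistic columns have zero MAD")
  scaled <- sweep(stats_m[, keep, drop = FALSE], 2, mads[keep], "/")
  obs_sc <- obs[keep] / mads[keep]
  d <- sqrt(rowSums(sweep(scaled, 2, obs_sc, "-")^2))
  n_acc <- ceiling(tolerance * nrow(scaled))
  ord <- order(d)[seq_len(n_acc)]
  d_max <- d[ord[n_acc]]
  w <- if (d_max > 0) 1 - (d[ord] / d_max)^2 else rep(1, n_acc)
  if (sum(w) <= 0) w <- rep(1, n_acc)
  lab_acc <- droplevels(labels[ord])
  present <- levels(lab_acc)
  absent <- setdiff(names(tables), present)
  if (length(absent) > 0) {
    warn(paste0("model(s) absent from the accepted set get probability 0: ",
                paste(absent, collapse = ", ")))
  }
  probs <- setNames(rep(0, length(tables)), names(tables))
  if (length(present) == 1) {
    probs[present] <- 1
  } else if (method == "rejection") {
    for (m in present) probs[m] <- sum(w[lab_acc == m]) / sum(w)
  } else {
    df <- as.data.frame(scaled[ord, , drop = FALSE])
    names(df) <- paste0("S", seq_len(ncol(df)))
    df$.label <- lab_acc
    newdata <- as.data.frame(matrix(obs_sc, nrow = 1))
    names(newdata) <- paste0("S", seq_len(ncol(df) - 1))
    pr <- tryCatch({
      fit <- nnet::multinom(.label ~ ., data = df, weights = w, trace = FALSE,
                            maxit = 500, MaxNWts = 5000)
      p <- predict(fit, newdata = newdata, type = "probs")
      if (length(present) == 2) setNames(c(1 - p, p), present) else p[1, present]
    }, error = function(e) {
      warn(paste0("multinomial regression failed (", conditionMessage(e),
                  "); falling back to rejection frequencies"))
      vapply(present, function(m) sum(w[lab_acc == m]) / sum(w), numeric(1))
    })
    probs[present] <- pr[present]
  }
  probs <- pmin(pmax(probs, 0), 1)
  probs <- probs / sum(probs)
  out <- tibble(model = names(tables), posterior_prob = unname(probs))
  structure(out, class = c("model_choice", class(out)),
            tolerance = tolerance, method = method,
            n_accepted = n_acc, n_pooled = nrow(scaled))
}

#' Model-choice confusion matrix by leave-one-out cross-validation
#'
#' For each candidate model, repeatedly treats one of its simulations as
#' pseudo-observed data, removes it from its reference table, computes
#' posterior model probabilities from the remaining simulations, and
#' records which model wins.  The confusion matrix reports, per true model,
#' the proportion of pseudo-observations assigned to each candidate.
#'
#' @param tables Named list of `abc_reftable`s.
#' @param n_pseudo Pseudo-observations drawn per model.
#' @param tolerance Rejection tolerance passed to [model_posterior()].
#' @param seed Integer seed for the pseudo-observation draws.
#' @param method Passed to [model_posterior()].
#' @return An object of class `abc_confusion`: a tibble with `true_model`,
#'   `assigned_model` and `proportion` (rows per true model sum to 1).
#' @export
confusion_matrix <- function(tables, n_pseudo = 1000, tolerance = 0.1,
                             seed = 1L, method = c("mnlogistic", "rejection")) {
  method <- match.arg(method)
  stopifnot(n_pseudo >= 1)
  model_names <- names(tables)
  tally <- matrix(0L, length(model_names), length(model_names),
                  dimnames = list(true = model_names, assigned = model_names))
  for (mi in seq_along(model_names)) {
    m <- model_names[mi]
    n_m <- nrow(tables[[m]]$stats)
    set.seed(derive_seed(seed, mi))
    rows <- sample.int(n_m, n_pseudo, replace = n_pseudo > n_m)
    for (r in rows) {
      pseudo <- tables[[m]]$stats[r, ]
      loo <- tables
      loo[[m]] <- reftable_subset(tables[[m]], setdiff(seq_len(n_m), r))
      mc <- suppressWarnings(
        model_posterior(pseudo, loo, tolerance = tolerance, method = method))
      win <- mc$model[which.max(mc$posterior_prob)]
      tally[m, win] <- tally[m, win] + 1L
    }
  }
  props <- tally / n_pseudo
  out <- as_tibble(as.data.frame.table(props, responseName = "proportion")) %>%
    rename(true_model = "true", assigned_model = "assigned") %>%
    mutate(true_model = as.character(.data$true_model),
           assigned_model = as.character(.data$assigned_model))
  structure(out, class = c("abc_confusion", class(out)),
            n_pseudo = n_pseudo, tolerance = tolerance, matrix = props)
}

#' @export
print.abc_confusion <- function(x, ...) {
  cat("<abc_confusion> leave-one-out model assignment proportions\n")
  print(attr(x, "matrix"))
  invisible(x)
}
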