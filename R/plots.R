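#' Plot an enclosure trajectory
#'
#' Adult genotype counts (stacked areas) and the wildtype allele frequency
#' (line) over monitoring points, facetted by room.
#'
#' @param object An `enclosure_trajectory` from [simulate_room()] /
#'   [simulate_experiment()], or any counts tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enclosure_trajectory <- function(object, ...) {
  pooled <- as_tibble(object) %>%
    group_by(.data$room, .data$time_point) %>%
    summarise(across(c("n_wt_hom", "n_het", "n_ko_hom"), sum),
              .groups = "drop")
  long <- tidyr::pivot_longer(pooled, c("n_wt_hom", "n_het", "n_ko_hom"),
                              names_to = "genotype", values_to = "n") %>%
    mutate(genotype = factor(.data$genotype,
                             levels = c("n_wt_hom", "n_het", "n_ko_hom"),
                             labels = c("WT/WT", "WT/ko", "ko/ko")))
  freq <- mutate(pooled, f_wt = allele_frequency(pooled),
                 n_tot = .data$n_wt_hom + .data$n_het + .data$n_ko_hom)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_point)) +
    ggplot2::geom_area(ggplot2::aes(y = .data$n, fill = .data$genotype),
                       alpha = 0.7) +
    ggplot2::geom_line(data = freq,
                       ggplot2::aes(y = .data$f_wt * max(.data$n_tot)),
                       linewidth = 0.8) +
    ggplot2::facet_wrap(~room) +
    ggplot2::labs(x = "monitoring point", y = "adults (line: scaled f_WT)",
                  fill = "genotype") +
    ggplot2::theme_minimal()
}

#' Plot ABC posterior densities
#'
#' Weighted posterior density of each estimated parameter, with the prior
#' draws of the reference table overlaid for comparison.
#'
#' @param object An `abc_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.abc_fit <- function(object, ...) {
  post <- tidyr::pivot_longer(
    bind_cols(object$adjusted, .weight = object$weights),
    all_of(object$estimate), names_to = "term", values_to = "value")
  prior <- tidyr::pivot_longer(
    object$table_params[, object$estimate, drop = FALSE],
    all_of(object$estimate), names_to = "term", values_to = "value")
  ggplot2::ggplot(post, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(data = prior, linetype = "dashed",
                          ggplot2::aes(colour = "prior")) +
    ggplot2::geom_density(ggplot2::aes(weight = .data$.weight,
                                       colour = "posterior")) +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot posterior model probabilities
#'
#' @param object A `model_choice` from [model_posterior()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.model_choice <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$model, y = .data$posterior_prob)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "posterior model probability") +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix
#'
#' @param object An `abc_confusion` from [confusion_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.abc_confusion <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$true_model, y = .data$assigned_model,
                               fill = .data$proportion)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$proportion))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "true model", y = "assigned model") +
    ggplot2::theme_minimal()
}

#' Plot cross-validation estimates against truth
#'
#' @param object An `abc_cv` from [cross_validate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.abc_cv <- function(object, ...) {
  est <- attr(object, "estimates")
  ggplot2::ggplot(est, ggplot2::aes(x = .data$true, y = .data$estimate)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(linetype = "dashed") +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = "true value", y = "ABC estimate") +
    ggplot2::theme_minimal()
}
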