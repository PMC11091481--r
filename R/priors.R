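#' Prior specification for the selection model parameters
#'
#' Default priors: the selection coefficient `s` follows a shifted Gamma,
#' `Gamma(shape = 3, rate = 3) - 1`, giving support `(-1, Inf)` and mean 0;
#' the dominance coefficient `h` is Uniform(0, 1); the non-genetic fitness
#' noise `g` is Uniform(0, 0.5); the non-random-mating penalty `lambda` is
#' Uniform(0, 1).
#'
#' @param s_shape,s_rate,s_shift Shifted-Gamma hyperparameters for `s`.
#' @param h_min,h_max Uniform bounds for `h`.
#' @param g_min,g_max Uniform bounds for `g`.
#' @param lambda_min,lambda_max Uniform bounds for `lambda`.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(s_shape = 3, s_rate = 3, s_shift = -1,
                       h_min = 0, h_max = 1,
                       g_min = 0, g_max = 0.5,
                       lambda_min = 0, lambda_max = 1) {
  structure(list(s_shape = s_shape, s_rate = s_rate, s_shift = s_shift,
                 h_min = h_min, h_max = h_max, g_min = g_min, g_max = g_max,
                 lambda_min = lambda_min, lambda_max = lambda_max),
            class = "prior_spec")
}

#' Model-variant specification
#'
#' Maps a variant name to the set of parameters it samples and the subset it
#' estimates (reports and regression-adjusts).  Parameters that are sampled
#' but not estimated — `g` in the `*_g` variants and `lambda` in the
#' two-parameter non-random-mating variant — are integrated over their prior
#' during inference and model comparison.
#'
#' Available variants: `males_only`, `sex_averaged`, `sex_specific`,
#' `males_only_g`, `males_only_lambda` (s, h estimated; lambda integrated),
#' `males_only_lambda3` (s, h, lambda jointly estimated),
#' `males_only_lambda_g`, and `neutral` (all effects 0).
#'
#' @param name Variant name.
#' @return A list of class `variant_spec` with elements `name`, `base`
#'   (fitness-model variant), `with_g`, `with_lambda`, `sampled`, `estimate`.
#' @export
variant_spec <- function(name) {
  defs <- list(
    males_only = list(base = "males_only", with_g = FALSE, with_lambda = FALSE,
                      sampled = c("s", "h"), estimate = c("s", "h")),
    sex_averaged = list(base = "sex_averaged", with_g = FALSE, with_lambda = FALSE,
                        sampled = c("s", "h"), estimate = c("s", "h")),
    sex_specific = list(base = "sex_specific", with_g = FALSE, with_lambda = FALSE,
                        sampled = c("s_female", "h_female", "s_male", "h_male"),
                        estimate = c("s_female", "h_female", "s_male", "h_male")),
    males_only_g = list(base = "males_only", with_g = TRUE, with_lambda = FALSE,
                        sampled = c("s", "h", "g"), estimate = c("s", "h")),
    males_only_lambda = list(base = "males_only", with_g = FALSE,
                             with_lambda = TRUE,
                             sampled = c("s", "h", "lambda"),
                             estimate = c("s", "h")),
    males_only_lambda3 = list(base = "males_only", with_g = FALSE,
                              with_lambda = TRUE,
                              sampled = c("s", "h", "lambda"),
                              estimate = c("s", "h", "lambda")),
    males_only_lambda_g = list(base = "males_only", with_g = TRUE,
                               with_lambda = TRUE,
                               sampled = c("s", "h", "lambda", "g"),
                               estimate = c("s", "h")),
    neutral = list(base = "males_only", with_g = FALSE, with_lambda = FALSE,
                   sampled = character(), estimate = character())
  )
  if (!name %in% names(defs)) {
    abort(paste0("unknown model variant '", name, "'; available: ",
                 paste(names(defs), collapse = ", ")))
  }
  structure(c(list(name = name), defs[[name]]), class = "variant_spec")
}

#' Draw parameters from the prior
#'
#' Samples `n` parameter vectors for a model variant.  Entries of `fixed`
#' override sampling with a constant (used, e.g., when the selection model
#' for model choice pins `s` at its posterior point estimate while `h` is
#' still drawn from its prior).
#'
#' @param prior A [prior_spec()].
#' @param variant A [variant_spec()] or variant name.
#' @param n Number of draws.
#' @param fixed Named list of parameter values held constant.
#' @return A tibble with `n` rows and one column per sampled parameter.
#' @export
#' @examples
#' draws <- sample_prior(prior_spec(), "males_only", n = 5)
sample_prior <- function(prior, variant, n = 1, fixed = list()) {
  if (is.character(variant)) variant <- variant_spec(variant)
  draw_one <- function(par) {
    if (par %in% names(fixed)) return(rep(fixed[[par]], n))
    switch(sub("_(male|female)$", "", par),
      s = rgamma(n, shape = prior$s_shape, rate = prior$s_rate) + prior$s_shift,
      h = runif(n, prior$h_min, prior$h_max),
      g = runif(n, prior$g_min, prior$g_max),
      lambda = runif(n, prior$lambda_min, prior$lambda_max),
      abort(paste0("no prior defined for parameter ", par))
    )
  }
  cols <- lapply(variant$sampled, draw_one)
  names(cols) <- variant$sampled
  as_tibble(cols, .name_repair = "minimal")[, variant$sampled, drop = FALSE]
}

# Turn one prior-draw row into a concrete fitness model.
params_to_model <- function(params, variant) {
  if (is.character(variant)) variant <- variant_spec(variant)
  p <- as.list(params)
  g <- if (variant$with_g) p$g else 0
  lam <- if (variant$with_lambda) p$lambda else 0
  if (variant$name == "neutral") {
    return(fitness_model("males_only", s = 0, h = 0, g = 0, lambda = 0))
  }
  if (variant$base == "sex_specific") {
    fitness_model("sex_specific", s = p$s_male, h = p$h_male,
                  s_female = p$s_female, h_female = p$h_female,
                  g = g, lambda = lam)
  } else {
    fitness_model(variant$base, s = p$s, h = min(max(p$h, 0), 1),
                  g = g, lambda = lam)
  }
}
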