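# The phenomenological suppressivity model. Grande (wild-type) and Petite
# mtDNAs contribute equal content at mating, enter as monomeric repeat
# units (input numbers inversely proportional to unit length), and replicate
# independently and exponentially at rates nu * rho: replication speed times
# origin density. The Petite fraction after the competition window t* is
#
#   S = 1 / (1 + (L_P / L_G) * exp(nuG*rhoG*t - nuP*rhoP*t)),
#
# fitted with the speed-time products nuG*t and nuP*t (bp) as parameters.

#' Grande (wild-type) reference parameters
#'
#' Defaults: the 85,779 bp mitochondrial reference with its eight
#' replication origins, and a competition window equal to the 90 min
#' doubling time of a diploid Grande population.
#'
#' @param L_G Grande repeat-unit (genome) length, bp.
#' @param n_ori_G Intact origin count.
#' @param t_star Competition window, minutes.
#' @return List with the three fields plus origin density `rho_G` (1/bp).
#' @export
grande_params <- function(L_G = 85779, n_ori_G = 8, t_star = 90) {
  stopifnot(L_G > 0, n_ori_G > 0, t_star > 0)
  list(L_G = L_G, n_ori_G = n_ori_G, t_star = t_star,
       rho_G = n_ori_G / L_G)
}

suppressivity_variants <- c("full", "equal_input", "linear_growth",
                            "equal_input_linear")

#' Predict suppressivity from repeat-unit structure
#'
#' Evaluates the competition model for Petite samples described by their
#' repeat-unit length `L_P` (sum of unique alignment lengths, bp) and
#' intact-origin count `n_ori_P`. A sample with no intact origin replicates
#' at rate zero under the model. Variants: `equal_input` drops the
#' `L_P / L_G` input-fraction prefactor; `linear_growth` replaces
#' exponential growth `exp(nu rho t)` by `1 + nu rho t`;
#' `equal_input_linear` does both.
#'
#' @param samples Tibble with columns `L_P` and `n_ori_P`.
#' @param grande [grande_params()].
#' @param nu_G_t,nu_P_t Speed-time products, bp.
#' @param variant Model variant.
#' @return Numeric vector of suppressivities in (0, 1).
#' @export
predict_suppressivity <- function(samples, grande, nu_G_t, nu_P_t,
                                  variant = "full") {
  variant <- match.arg(variant, suppressivity_variants)
  rho_P <- samples$n_ori_P / samples$L_P
  rho_G <- grande$rho_G
  prefactor <- if (variant %in% c("equal_input", "equal_input_linear")) {
    1
  } else {
    samples$L_P / grande$L_G
  }
  ratio <- if (variant %in% c("linear_growth", "equal_input_linear")) {
    (1 + nu_G_t * rho_G) / (1 + nu_P_t * rho_P)
  } else {
    exp(nu_G_t * rho_G - nu_P_t * rho_P)
  }
  1 / (1 + prefactor * ratio)
}

#' Fit the suppressivity model by bounded least squares
#'
#' Minimises the sum of squared differences between modelled and observed
#' suppressivities over the two speed-time products, constrained positive,
#' with a fixed fan of multiplicative multi-starts around the initial guess
#' to guard against local minima. `R^2` is computed on untransformed
#' suppressivities.
#'
#' @param samples Tibble with columns `L_P`, `n_ori_P`, `suppressivity`.
#' @param grande [grande_params()].
#' @param start Initial guess `c(nu_G_t, nu_P_t)` in bp (default
#'   `c(10000, 2000)`).
#' @param variant Model variant (see [predict_suppressivity()]).
#' @param n_starts Number of multi-start points (default 5).
#' @return A `suppressivity_fit` object: fields `nu_G_t`, `nu_P_t`,
#'   `r_squared`, `rss`, `variant`, `grande`, `data`, `fitted`.
#' @export
fit_suppressivity <- function(samples, grande = grande_params(),
                              start = c(10000, 2000), variant = "full",
                              n_starts = 5) {
  variant <- match.arg(variant, suppressivity_variants)
  stopifnot(all(c("L_P", "n_ori_P", "suppressivity") %in% names(samples)))
  if (nrow(samples) < 3L) abort("need at least 3 samples to fit")
  obs <- samples$suppressivity
  resid_fn <- function(par) {
    predict_suppressivity(samples, grande, par[1], par[2], variant) - obs
  }
  # multiplicative fan spanning ~0.08x to ~12x around the guess, so an
  # initial guess an order of magnitude off still brackets the optimum
  fan <- exp(seq(-2.5, 2.5, length.out = n_starts))
  best <- NULL
  for (f in fan) {
    fit <- try(minpack.lm::nls.lm(
      par = start * f, lower = c(1e-9, 0), upper = c(1e9, 1e9),
      fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)
    ), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss_) {
      best <- fit
      best$rss_ <- rss
    }
  }
  if (is.null(best)) abort("suppressivity fit failed to converge")
  par <- coef(best)
  fitted <- predict_suppressivity(samples, grande, par[1], par[2], variant)
  ss_tot <- sum((obs - mean(obs))^2)
  r2 <- if (ss_tot > 0) 1 - best$rss_ / ss_tot else {
    warn("constant observed suppressivities; R^2 undefined, reporting -Inf")
    -Inf
  }
  structure(list(
    nu_G_t = unname(par[1]), nu_P_t = unname(par[2]),
    r_squared = r2, rss = best$rss_, variant = variant,
    grande = grande, data = samples, fitted = fitted
  ), class = "suppressivity_fit")
}

#' @export
print.suppressivity_fit <- function(x, ...) {
  cat("Suppressivity model fit (", x$variant, ")\n", sep = "")
  cat(sprintf("  nuG*t = %.1f bp, nuP*t = %.1f bp\n", x$nu_G_t, x$nu_P_t))
  cat(sprintf("  R^2 = %.4f on %d samples (RSS %.3g)\n",
              x$r_squared, nrow(x$data), x$rss))
  invisible(x)
}

#' @export
tidy.suppressivity_fit <- function(x, ...) {
  tibble(term = c("nu_G_t", "nu_P_t"),
         estimate = c(x$nu_G_t, x$nu_P_t),
         units = "bp")
}

#' @export
glance.suppressivity_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, rss = x$rss, nobs = nrow(x$data),
         variant = x$variant)
}

#' @export
predict.suppressivity_fit <- function(object, newdata = NULL, ...) {
  newdata <- newdata %||% object$data
  predict_suppressivity(newdata, object$grande, object$nu_G_t,
                        object$nu_P_t, object$variant)
}

#' @export
autoplot.suppressivity_fit <- function(object, ...) {
  df <- object$data %>%
    mutate(fitted = object$fitted, rho_P = .data$n_ori_P / .data$L_P)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$L_P)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$suppressivity,
                                     colour = factor(.data$n_ori_P))) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted,
                                    colour = factor(.data$n_ori_P),
                                    group = factor(.data$n_ori_P))) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Petite repeat-unit length (bp)", y = "suppressivity",
                  colour = "intact origins",
                  title = sprintf("nuG t* = %.0f bp, nuP t* = %.0f bp, R2 = %.2f",
                                  object$nu_G_t, object$nu_P_t,
                                  object$r_squared))
}

#' Fit all suppressivity model variants
#'
#' Fits each variant by least squares and reports parameters and residual
#' sums of squares for comparison; on data generated by the full model the
#' full model attains the lowest RSS.
#'
#' @inheritParams fit_suppressivity
#' @param variants Character vector of variants to fit.
#' @return Tibble: `variant`, `nu_G_t`, `nu_P_t`, `r_squared`, `rss`.
#' @export
fit_model_variants <- function(samples, grande = grande_params(),
                               start = c(10000, 2000),
                               variants = suppressivity_variants) {
  purrr::map_dfr(variants, function(v) {
    fit <- fit_suppressivity(samples, grande, start = start, variant = v)
    tibble(variant = v, nu_G_t = fit$nu_G_t, nu_P_t = fit$nu_P_t,
           r_squared = fit$r_squared, rss = fit$rss)
  })
}

#' Back-of-envelope Grande mtDNA replication speed
#'
#' If wild-type mtDNA doubles once over the competition window under
#' exponential growth at rate `nu * rho_G`, then
#' `nu = ln(2) / (rho_G * t*) = ln(2) * (L_G / n_ori_G) / t*`.
#' With the defaults (85,779 bp, 8 origins, 90 min) this gives ~82 bp/min.
#'
#' @param grande [grande_params()].
#' @return Replication speed, bp/min.
#' @export
grande_speed_estimate <- function(grande = grande_params()) {
  log(2) * (grande$L_G / grande$n_ori_G) / grande$t_star
}

#' Generate synthetic suppressivity samples from the model
#'
#' Draws Petite repeat-unit lengths log-uniformly over `length_range`,
#' intact-origin counts uniformly over `ori_range`, and computes
#' suppressivities from the model with the supplied parameters plus
#' optional Gaussian noise (clamped to (0, 1)).
#'
#' @param n Number of samples.
#' @param nu_G_t,nu_P_t Generating speed-time products, bp.
#' @param grande [grande_params()].
#' @param length_range Repeat-unit length range, bp.
#' @param ori_range Intact-origin count range.
#' @param noise_sd Gaussian noise SD on suppressivity (0 = noiseless).
#' @param seed RNG seed.
#' @param variant Generating variant.
#' @return Tibble: `sample`, `L_P`, `n_ori_P`, `suppressivity`.
#' @export
simulate_suppressivity_samples <- function(n = 20, nu_G_t = 10677,
                                           nu_P_t = 2296,
                                           grande = grande_params(),
                                           length_range = c(2000, 70000),
                                           ori_range = c(1L, 3L),
                                           noise_sd = 0, seed = NULL,
                                           variant = "full") {
  if (!is.null(seed)) set.seed(seed)
  L_P <- exp(runif(n, log(length_range[1]), log(length_range[2])))
  n_ori_P <- sample(seq(ori_range[1], ori_range[2]), n, replace = TRUE)
  s <- tibble(sample = sprintf("sim%02d", seq_len(n)),
              L_P = L_P, n_ori_P = n_ori_P)
  su <- predict_suppressivity(s, grande, nu_G_t, nu_P_t, variant)
  if (noise_sd > 0) {
    su <- pmin(pmax(su + rnorm(n, 0, noise_sd), 1e-6), 1 - 1e-6)
  }
  mutate(s, suppressivity = su)
}
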