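#' Colony genetic variance
#'
#' Under the worker-direct + queen-maternal model the total genetic
#' variance expressed at the colony level is
#' `sigma_C^2 = sigma_W^2 + sigma_MQ^2 + 2 Cov_W-MQ`.
#' A covariance violating positive semi-definiteness can make this
#' negative; the value is returned as computed and flagged by a warning.
#'
#' @param sigma2_w Worker direct genetic variance.
#' @param sigma2_mq Queen maternal genetic variance.
#' @param cov_w_mq Their covariance.
#' @return The colony genetic variance (scalar).
#' @export
#' @examples
#' colony_variance(12.93, 5.97, -8.38) # 2.14
colony_variance <- function(sigma2_w, sigma2_mq, cov_w_mq) {
  assert_scalar_number(sigma2_w, "sigma2_w")
  assert_scalar_number(sigma2_mq, "sigma2_mq")
  assert_scalar_number(cov_w_mq, "cov_w_mq")
  out <- sigma2_w + sigma2_mq + 2 * cov_w_mq
  if (out < 0) {
    warn("Negative colony variance: components are not PSD-consistent.")
  }
  out
}

#' Phenotypic variance under a summation convention
#'
#' The phenotypic variance of the colony model is the sum of its
#' components, but a direct-maternal covariance can be counted in more
#' than one way and published tables are not always internally
#' consistent. Three conventions are provided:
#' \describe{
#'   \item{`"sum_2cov"`}{`sigma_W^2 + sigma_MQ^2 + 2 Cov + sigma_cell^2 +
#'     sigma_e^2` -- consistent with the colony genetic variance; the
#'     package default.}
#'   \item{`"table"`}{the covariance counted once -- reproduces the
#'     printed honey-yield and defensive-behaviour phenotypic variances
#'     of the source registry analysis.}
#'   \item{`"abs"`}{the absolute covariance counted once -- reproduces the
#'     printed swarming-behaviour value.}
#' }
#' Under the queen-direct model there is no covariance and all
#' conventions coincide.
#'
#' @param components Named list or vector with (model 1) `sigma2_w`,
#'   `sigma2_mq`, `cov_w_mq` or (model 2) `sigma2_q`, plus `sigma2_cell`
#'   and `sigma2_e`.
#' @param convention One of `"sum_2cov"`, `"table"`, `"abs"`.
#' @return Phenotypic variance (scalar).
#' @export
#' @examples
#' phenotypic_variance(c(sigma2_q = 50.14, sigma2_cell = 105.85,
#'                       sigma2_e = 35.98)) # 191.97
phenotypic_variance <- function(components,
                                convention = c("sum_2cov", "table", "abs")) {
  convention <- match.arg(convention)
  cmp <- as.list(components)
  need <- function(nm) {
    if (is.null(cmp[[nm]])) {
      stop_beeval(sprintf("Component `%s` is required.", nm),
                  "beeval_bad_argument")
    }
    cmp[[nm]]
  }
  env <- need("sigma2_cell") + need("sigma2_e")
  if (!is.null(cmp$sigma2_q)) return(cmp$sigma2_q + env)
  w <- need("sigma2_w"); m <- need("sigma2_mq"); cv <- need("cov_w_mq")
  gen <- switch(convention,
    sum_2cov = w + m + 2 * cv,
    table = w + m + cv,
    abs = w + m + abs(cv))
  gen + env
}

#' Heritability
#'
#' Ratio of a genetic variance to the phenotypic variance, kept at full
#' precision; round only for presentation (the registry analysis prints
#' 2 decimals, see [round_half_up()]). Values above 1 -- possible when the
#' numerator is a component that the phenotypic sum counts differently --
#' are returned as computed with a warning.
#'
#' @param numerator_variance Genetic variance in the numerator.
#' @param sigma2_p Phenotypic variance (must be positive).
#' @return Heritability (scalar).
#' @export
#' @examples
#' heritability(50.14, 191.97) # 0.2611...
heritability <- function(numerator_variance, sigma2_p) {
  assert_scalar_number(numerator_variance, "numerator_variance")
  assert_scalar_number(sigma2_p, "sigma2_p")
  if (sigma2_p <= 0) {
    stop_beeval("Phenotypic variance must be positive.", "beeval_bad_argument")
  }
  h2 <- numerator_variance / sigma2_p
  if (h2 > 1) warn(sprintf("Heritability above 1 (%.3f).", h2))
  h2
}

#' Genetic correlation
#'
#' @param cov Genetic covariance between the two effects or traits.
#' @param var1,var2 The corresponding genetic variances (positive).
#' @return `cov / sqrt(var1 * var2)`.
#' @export
#' @examples
#' genetic_correlation(-8.38, 12.93, 5.97) # -0.953...
genetic_correlation <- function(cov, var1, var2) {
  assert_scalar_number(cov, "cov")
  assert_scalar_number(var1, "var1")
  assert_scalar_number(var2, "var2")
  if (var1 <= 0 || var2 <= 0) {
    stop_beeval("Variances must be positive.", "beeval_bad_argument")
  }
  cov / sqrt(var1 * var2)
}

#' Delta-method / posterior standard error of a component ratio
#'
#' Standard error of `f(theta) = num(theta) / den(theta)` where both
#' numerator and denominator are linear combinations of estimated
#' variance components. Two routes: from a REML fit, the first-order
#' delta method using the inverse-AI covariance of the components; from a
#' Gibbs chain, the posterior standard deviation of the per-iteration
#' ratio.
#'
#' @param fit A `beeval_reml` object (delta-method route) or a
#'   `beeval_chain` object (posterior route).
#' @param num_coef Named numeric vector of coefficients defining the
#'   numerator in terms of the fit's parameters (REML route), e.g.
#'   `c(sigma2_q = 1)`.
#' @param den_coef Same for the denominator, e.g.
#'   `c(sigma2_q = 1, sigma2_cell = 1, sigma2_e = 1)`.
#' @param ratio_fun For the Gibbs route: function mapping one chain row
#'   (named list) to the scalar ratio.
#' @return List with `estimate` and `se`.
#' @export
standard_error_ratio <- function(fit, num_coef = NULL, den_coef = NULL,
                                 ratio_fun = NULL) {
  if (inherits(fit, "beeval_reml")) {
    if (is.null(fit$vcov)) {
      stop_beeval("REML fit has no parameter covariance (AI not invertible).",
                  "beeval_no_covariance")
    }
    th <- fit$theta
    a <- setNames(numeric(length(th)), names(th)); a[names(num_coef)] <- num_coef
    b <- setNames(numeric(length(th)), names(th)); b[names(den_coef)] <- den_coef
    num <- sum(a * th); den <- sum(b * th)
    r <- num / den
    grad <- a / den - num * b / den^2
    se <- sqrt(max(0, as.numeric(t(grad) %*% fit$vcov %*% grad)))
    list(estimate = r, se = se)
  } else if (inherits(fit, "beeval_chain")) {
    if (is.null(ratio_fun)) {
      stop_beeval("Gibbs route needs `ratio_fun`.", "beeval_bad_argument")
    }
    vals <- purrr::map_dbl(seq_len(nrow(fit$samples)), function(i)
      ratio_fun(as.list(fit$samples[i, ])))
    list(estimate = mean(vals), se = stats::sd(vals))
  } else {
    stop_beeval("`fit` must be a beeval_reml or beeval_chain object.",
                "beeval_bad_argument")
  }
}

#' Genetic parameters from estimated components
#'
#' One call from a variance-component set to the derived quantities:
#' heritabilities (worker, maternal, colony under model 1; queen under
#' model 2), the direct-maternal genetic correlation, the colony and
#' phenotypic variances, and -- multi-trait -- pairwise genetic
#' correlations. Estimates are full precision; `round_half_up(x, 2)`
#' matches the registry's printed tables.
#'
#' @param components A [variance_components()] object.
#' @param convention Phenotypic-variance convention, see
#'   [phenotypic_variance()].
#' @return Tibble with columns `trait`, `parameter`, `value`.
#' @export
genetic_parameters <- function(components,
                               convention = c("sum_2cov", "table", "abs")) {
  convention <- match.arg(convention)
  vc <- components
  out <- list()
  if (vc$model == "model1") {
    tr <- vc$traits[1]
    w <- vc$G0["w", "w"]; m <- vc$G0["mq", "mq"]; cv <- vc$G0["w", "mq"]
    sc <- colony_variance(w, m, cv)
    sp <- phenotypic_variance(
      list(sigma2_w = w, sigma2_mq = m, cov_w_mq = cv,
           sigma2_cell = vc$sigma2_cell[[tr]], sigma2_e = vc$R0[tr, tr]),
      convention)
    out[[tr]] <- tibble(
      trait = tr,
      parameter = c("sigma2_C", "sigma2_p", "h2_W", "h2_MQ", "h2_C", "r_W_MQ"),
      value = c(sc, sp, w / sp, m / sp, sc / sp,
                genetic_correlation(cv, w, m)))
  } else {
    for (tr in vc$traits) {
      gg <- if (length(vc$traits) == 1) vc$G0["q", "q"]
            else vc$G0[paste0("q:", tr), paste0("q:", tr)]
      sp <- gg + vc$sigma2_cell[[tr]] + vc$R0[tr, tr]
      out[[tr]] <- tibble(trait = tr,
                          parameter = c("sigma2_p", "h2_Q"),
                          value = c(sp, gg / sp))
    }
    if (length(vc$traits) > 1) {
      prs <- utils::combn(vc$traits, 2, simplify = FALSE)
      out$correlations <- purrr::map_dfr(prs, function(pr) {
        i <- paste0("q:", pr[1]); j <- paste0("q:", pr[2])
        tibble(trait = paste(pr, collapse = ":"),
               parameter = "r_G",
               value = genetic_correlation(vc$G0[i, j], vc$G0[i, i],
                                           vc$G0[j, j]))
      })
    }
  }
  dplyr::bind_rows(out)
}
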