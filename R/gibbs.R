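#' Gibbs sampler configuration
#'
#' @param n_iterations Total iterations; defaults to 100000 for
#'   single-trait and 500000 for multi-trait runs.
#' @param burn_in_fraction Fraction of initial iterations discarded
#'   (default 0.10).
#' @param thinning Keep every `thinning`-th post-burn-in sample; defaults
#'   to 1 (single-trait) or 10 (multi-trait) to bound chain memory.
#' @param seed Integer seed; mandatory -- chains must be reproducible.
#' @param threshold_scheme Identifiability constraint for 5-category
#'   threshold traits: `"fix2"` fixes the first two thresholds at 0 and 1
#'   and estimates the residual variance (needed when residual variances
#'   are reported on the liability scale); `"unitvar"` fixes the first
#'   threshold at 0 and the residual variance at 1. Binary traits always
#'   use `"unitvar"`. Heritabilities are invariant to the choice.
#' @return A `beeval_gibbs_config` list.
#' @export
gibbs_config <- function(n_iterations = NULL, burn_in_fraction = 0.10,
                         thinning = NULL, seed = NULL,
                         threshold_scheme = c("fix2", "unitvar")) {
  threshold_scheme <- match.arg(threshold_scheme)
  if (!is.null(burn_in_fraction) &&
      (burn_in_fraction <= 0 || burn_in_fraction >= 1)) {
    stop_beeval("`burn_in_fraction` must be in (0, 1).", "beeval_bad_argument")
  }
  structure(list(n_iterations = n_iterations,
                 burn_in_fraction = burn_in_fraction,
                 thinning = thinning, seed = seed,
                 threshold_scheme = threshold_scheme),
            class = "beeval_gibbs_config")
}

# shared engine behind the exported samplers
run_gibbs_engine <- function(design, config, components = NULL,
                             multitrait_default = FALSE) {
  if (is.null(config$seed)) {
    stop_beeval("A seed is mandatory for Gibbs runs.", "beeval_bad_argument")
  }
  spec <- design$spec
  traits <- spec$traits
  Tn <- length(traits)
  n_iter <- config$n_iterations %||% if (multitrait_default) 500000L else 100000L
  thin <- config$thinning %||% if (multitrait_default) 10L else 1L
  burn_in <- floor(n_iter * config$burn_in_fraction)
  if ((n_iter - burn_in) / thin < 100) {
    stop_beeval("Fewer than 100 retained samples; increase iterations or reduce thinning/burn-in.",
                "beeval_too_short")
  }

  # drop records observed for no analysed trait, rebuild the design so the
  # fixed-effect columns stay full rank on the analysed subset
  keep <- Reduce(`|`, design$obs[traits])
  if (!all(keep)) {
    design <- build_design(design$records[keep, , drop = FALSE],
                           design$pedigree, spec)
  }
  n <- design$n
  q <- nrow(design$pedigree)

  # category codes / augmented-data initialization
  z <- matrix(0, n, Tn)
  category <- matrix(0L, n, Tn)
  n_cat <- integer(Tn)
  scheme <- integer(Tn)
  trait_type <- ifelse(spec$trait_types == "threshold", 1L, 0L)
  Kmax <- 2L
  thr_list <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    yv <- design$y[[traits[t]]]
    if (trait_type[t] == 0) {
      mu <- mean(yv, na.rm = TRUE)
      z[, t] <- ifelse(is.na(yv), mu, yv)
      category[, t] <- ifelse(is.na(yv), -1L, 0L)
    } else {
      K <- max(yv, na.rm = TRUE)
      if (K < 2) {
        stop_beeval("Threshold trait needs at least 2 observed categories.",
                    "beeval_bad_data")
      }
      seen <- tabulate(yv[!is.na(yv)], nbins = K)
      if (any(seen == 0)) {
        stop_beeval(sprintf(
          "Trait %s: categories with zero observations (%s); merge adjacent categories before analysis.",
          traits[t], paste(which(seen == 0), collapse = ", ")),
          "beeval_empty_category")
      }
      n_cat[t] <- K
      scheme[t] <- if (K == 2) 1L else
        if (config$threshold_scheme == "fix2") 0L else 1L
      if (Tn > 1 && scheme[t] == 1L && K > 2) {
        stop_beeval("Multi-trait runs need the fix2 threshold scheme.",
                    "beeval_bad_argument")
      }
      # threshold init from observed cumulative frequencies, mapped onto
      # the scheme's fixed points
      raw <- qnorm(cumsum(seen)[1:(K - 1)] / sum(seen))
      thr0 <- if (scheme[t] == 0L) (raw - raw[1]) / (raw[2] - raw[1])
              else raw - raw[1]
      thr_list[[t]] <- thr0
      mid <- c(thr0[1] - 0.7,
               if (K > 2) (thr0[-(K - 1)] + thr0[-1]) / 2,
               thr0[K - 1] + 0.7)
      z[, t] <- ifelse(is.na(yv), 0, mid[pmax(yv, 1L)])
      category[, t] <- ifelse(is.na(yv), -1L, as.integer(yv))
      Kmax <- max(Kmax, K)
    }
  }
  thr_init <- matrix(0, Kmax - 1L, Tn)
  for (t in seq_len(Tn)) {
    if (trait_type[t] == 1L)
      thr_init[seq_len(n_cat[t] - 1L), t] <- thr_list[[t]]
  }

  # starting (or fixed) variance components
  update_var <- is.null(components)
  vc0 <- components %||% default_start_components(design, traits, trait_type)
  effects <- vc0$effects
  g <- length(design$genetic)
  m <- g * Tn
  if (nrow(vc0$G0) != m) {
    stop_beeval("components G0 does not match the design's genetic effects.",
                "beeval_bad_argument")
  }
  sample_residual <- !(Tn == 1 && trait_type[1] == 1L && scheme[1] == 1L)
  if (!update_var) sample_residual <- FALSE

  n_cells <- length(design$cell_levels)
  if (n_cells < 3 && update_var) {
    stop_beeval("Sampling the cell variance needs at least 3 observed cells.",
                "beeval_bad_data")
  }

  fixed_cols <- sparse_col_list(design$X)
  cell_cols <- sparse_col_list(design$Z_cell)
  gen_carrier <- do.call(cbind, design$genetic)
  Ag <- methods::as(methods::as(design$Ainv, "generalMatrix"), "CsparseMatrix")

  set.seed(config$seed)
  res <- gibbs_sampler_cpp(z, category, trait_type, n_cat, scheme,
                           fixed_cols, cell_cols, gen_carrier,
                           Ag@i, Ag@p, Ag@x, q,
                           as.matrix(vc0$G0),
                           as.matrix(vc0$R0),
                           as.numeric(vc0$sigma2_cell),
                           thr_init,
                           as.integer(n_iter), as.integer(burn_in),
                           as.integer(thin),
                           update_var, sample_residual)

  samples <- as_tibble(as.data.frame(res$samples))
  names(samples) <- chain_column_names(effects, traits, trait_type, n_cat)
  ebv <- purrr::map_dfr(seq_along(effects), function(k) {
    tibble(id = design$pedigree$id, tier = design$pedigree$tier,
           effect = effects[k], ebv = res$u_mean[, k])
  })
  structure(
    list(samples = samples, ebv = ebv,
         model = spec$model, traits = traits, effects = effects,
         trait_types = spec$trait_types, n_cat = n_cat, scheme = scheme,
         n_iterations = n_iter, burn_in = burn_in, thinning = thin,
         seed = config$seed, update_variances = update_var,
         n_obs = n, n_clamped = res$clamped, n_not_pd = res$n_not_pd),
    class = "beeval_chain")
}

default_start_components <- function(design, traits, trait_type) {
  Tn <- length(traits)
  gvar <- cellv <- resv <- numeric(Tn)
  for (t in seq_len(Tn)) {
    if (trait_type[t] == 0) {
      v <- stats::var(design$y[[traits[t]]], na.rm = TRUE)
      gvar[t] <- v / 3; cellv[t] <- v / 3; resv[t] <- v / 3
    } else {
      gvar[t] <- 0.5; cellv[t] <- 0.3; resv[t] <- 1
    }
  }
  g <- length(design$genetic)
  if (g == 2) { # model 1: split the genetic variance over w and mq
    G0 <- diag(c(gvar[1] / 2, gvar[1] / 2))
  } else {
    G0 <- diag(gvar, nrow = Tn)
  }
  variance_components(design$spec$model, traits, G0, cellv,
                      diag(resv, nrow = Tn))
}

sparse_col_list <- function(M) {
  M <- methods::as(methods::as(M, "generalMatrix"), "CsparseMatrix")
  lapply(seq_len(ncol(M)), function(j) {
    idx <- (M@p[j] + 1L):M@p[j + 1L]
    if (M@p[j] == M@p[j + 1L]) integer(0) else M@i[idx] + 1L
  })
}

chain_column_names <- function(effects, traits, trait_type, n_cat) {
  m <- length(effects)
  gn <- character(0)
  for (a in seq_len(m)) for (b in a:m) {
    gn <- c(gn, if (a == b) paste0("sigma2_", effects[a])
            else paste0("cov_", effects[a], "_", effects[b]))
  }
  cn <- paste0("sigma2_cell_", traits)
  Tn <- length(traits)
  rn <- character(0)
  for (a in seq_len(Tn)) for (b in a:Tn) {
    rn <- c(rn, if (a == b) paste0("sigma2_e_", traits[a])
            else paste0("cov_e_", traits[a], "_", traits[b]))
  }
  tn <- character(0)
  for (t in seq_len(Tn)) {
    if (trait_type[t] == 1L)
      tn <- c(tn, paste0("t", seq_len(n_cat[t] - 1L), "_", traits[t]))
  }
  c(gn, cn, rn, tn)
}

#' Single-trait threshold-model Gibbs sampling
#'
#' Bayesian estimation for one 5-category (or collapsed) behaviour score:
#' liabilities are drawn from truncated normals given the category and
#' current location/scale, location effects from their univariate
#' conditionals over a precomputed sparse structure, free thresholds from
#' their uniform conditionals, and (co)variance components from scaled
#' inverse chi-square / inverse-Wishart conditionals (flat priors, so
#' posterior means are comparable to REML). Works for the queen-direct
#' model and the worker/maternal model (2x2 genetic block).
#'
#' @param design A [build_design()] whose spec holds exactly one
#'   threshold trait.
#' @param config A [gibbs_config()]; `seed` required.
#' @param components Optional [variance_components()]: when supplied the
#'   variances are held fixed and only locations, liabilities and
#'   thresholds are sampled (the "known variance components" evaluation
#'   mode used for threshold-trait EBVs).
#' @return A `beeval_chain`: `samples` (one row per retained iteration),
#'   posterior-mean `ebv` tibble, and run metadata. Summarize with
#'   [posterior_summary()].
#' @export
run_threshold_gibbs <- function(design, config, components = NULL) {
  spec <- design$spec
  if (length(spec$traits) != 1 || spec$trait_types[1] != "threshold") {
    stop_beeval("run_threshold_gibbs needs a single threshold trait; use run_multitrait_gibbs otherwise.",
                "beeval_bad_argument")
  }
  run_gibbs_engine(design, config, components, multitrait_default = FALSE)
}

#' Multi-trait linear-threshold Gibbs sampling
#'
#' Joint Bayesian estimation of up to three traits (one continuous plus
#' categorical scores) under the queen-direct model: a T x T genetic
#' covariance matrix over the queen pedigree and a T x T residual
#' covariance are sampled from inverse-Wishart conditionals; missing
#' trait values and liabilities are imputed by conditional draws, so
#' trait-wise missingness is handled exactly.
#'
#' @inheritParams run_threshold_gibbs
#' @param design A [build_design()] under `"model2"`.
#' @return A `beeval_chain`.
#' @export
run_multitrait_gibbs <- function(design, config, components = NULL) {
  if (design$spec$model != "model2") {
    stop_beeval("Multi-trait sampling is defined for the queen-direct model.",
                "beeval_bad_argument")
  }
  run_gibbs_engine(design, config, components,
                   multitrait_default = length(design$spec$traits) > 1)
}

#' @export
print.beeval_chain <- function(x, ...) {
  cat(sprintf(
    "Gibbs chain (%s; %s): %d iterations, burn-in %d, thinning %d -> %d stored\n",
    x$model, paste(x$traits, collapse = ", "),
    x$n_iterations, x$burn_in, x$thinning, nrow(x$samples)))
  if (x$n_not_pd > 0)
    cat(sprintf("  %d non-PD covariance draws required jitter\n", x$n_not_pd))
  invisible(x)
}

# per-iteration derived parameters (heritabilities, correlations)
derive_chain_params <- function(chain) {
  s <- chain$samples
  out <- s
  if (chain$model == "model1") {
    tr <- chain$traits[1]
    sC <- s$sigma2_w + s$sigma2_mq + 2 * s$cov_w_mq
    sp <- sC + s[[paste0("sigma2_cell_", tr)]] + s[[paste0("sigma2_e_", tr)]]
    out$sigma2_C <- sC
    out$sigma2_p <- sp
    out$h2_W <- s$sigma2_w / sp
    out$h2_MQ <- s$sigma2_mq / sp
    out$h2_C <- sC / sp
    out$r_W_MQ <- s$cov_w_mq / sqrt(s$sigma2_w * s$sigma2_mq)
  } else {
    for (t in seq_along(chain$traits)) {
      tr <- chain$traits[t]
      e <- chain$effects[t]
      gt <- s[[paste0("sigma2_", e)]]
      sp <- gt + s[[paste0("sigma2_cell_", tr)]] + s[[paste0("sigma2_e_", tr)]]
      out[[paste0("h2_", tr)]] <- gt / sp
    }
    if (length(chain$traits) > 1) {
      prs <- utils::combn(seq_along(chain$traits), 2, simplify = FALSE)
      for (pr in prs) {
        e1 <- chain$effects[pr[1]]; e2 <- chain$effects[pr[2]]
        cv <- s[[paste0("cov_", e1, "_", e2)]]
        out[[paste0("r_g_", chain$traits[pr[1]], "_", chain$traits[pr[2]])]] <-
          cv / sqrt(s[[paste0("sigma2_", e1)]] * s[[paste0("sigma2_", e2)]])
      }
    }
  }
  out
}

# spectral density at frequency zero via an AR fit (for Geweke's diagnostic)
spectrum0 <- function(x) {
  if (stats::sd(x) == 0) return(0)
  fit <- try(stats::ar(x, aic = TRUE, order.max = min(30, length(x) %/% 10)),
             silent = TRUE)
  if (inherits(fit, "try-error") || length(fit$ar) == 0) return(stats::var(x))
  fit$var.pred / (1 - sum(fit$ar))^2
}

geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  x1 <- x[seq_len(max(2, floor(frac1 * n)))]
  x2 <- x[(n - floor(frac2 * n) + 1):n]
  v <- spectrum0(x1) / length(x1) + spectrum0(x2) / length(x2)
  if (v == 0) return(0)
  (mean(x1) - mean(x2)) / sqrt(v)
}

#' Posterior summary of a Gibbs chain
#'
#' Means, posterior standard deviations (the approximate standard
#' errors), central 95\% credible intervals and Geweke convergence
#' z-scores for every sampled parameter and for the derived quantities
#' (heritabilities, genetic correlations, colony variance), each computed
#' per retained iteration before averaging.
#'
#' @param chain A `beeval_chain` (already excludes its burn-in).
#' @param burn_in_fraction Optional extra leading fraction to discard.
#' @return Tibble: `parameter`, `mean`, `sd`, `q2.5`, `q97.5`, `geweke_z`.
#' @export
posterior_summary <- function(chain, burn_in_fraction = 0) {
  s <- derive_chain_params(chain)
  if (burn_in_fraction > 0) {
    s <- s[-seq_len(floor(nrow(s) * burn_in_fraction)), , drop = FALSE]
  }
  if (nrow(s) < 100) {
    stop_beeval("Fewer than 100 retained samples after burn-in.",
                "beeval_too_short")
  }
  purrr::map_dfr(names(s), function(nm) {
    v <- s[[nm]]
    tibble(parameter = nm, mean = mean(v), sd = stats::sd(v),
           q2.5 = stats::quantile(v, 0.025, names = FALSE),
           q97.5 = stats::quantile(v, 0.975, names = FALSE),
           geweke_z = geweke_z(v))
  })
}

#' @rdname tidy.beeval_reml
#' @method tidy beeval_chain
#' @export
tidy.beeval_chain <- function(x, ...) {
  dplyr::rename(posterior_summary(x), component = "parameter",
                estimate = "mean", std.error = "sd")
}

#' @rdname tidy.beeval_reml
#' @method glance beeval_chain
#' @export
glance.beeval_chain <- function(x, ...) {
  tibble(n_iterations = x$n_iterations, burn_in = x$burn_in,
         thinning = x$thinning, n_stored = nrow(x$samples),
         seed = x$seed, n_obs = x$n_obs,
         max_abs_geweke = max(abs(posterior_summary(x)$geweke_z)))
}

#' Posterior-mean variance components of a chain
#'
#' @param chain A `beeval_chain`.
#' @return A [variance_components()] built from posterior means.
#' @export
chain_components <- function(chain) {
  s <- chain$samples
  m <- length(chain$effects)
  G0 <- matrix(0, m, m)
  for (a in seq_len(m)) for (b in a:m) {
    nm <- if (a == b) paste0("sigma2_", chain$effects[a])
          else paste0("cov_", chain$effects[a], "_", chain$effects[b])
    G0[a, b] <- G0[b, a] <- mean(s[[nm]])
  }
  Tn <- length(chain$traits)
  R0 <- matrix(0, Tn, Tn)
  for (a in seq_len(Tn)) for (b in a:Tn) {
    nm <- if (a == b) paste0("sigma2_e_", chain$traits[a])
          else paste0("cov_e_", chain$traits[a], "_", chain$traits[b])
    R0[a, b] <- R0[b, a] <- mean(s[[nm]])
  }
  cellv <- vapply(chain$traits,
                  function(tr) mean(s[[paste0("sigma2_cell_", tr)]]), 0)
  variance_components(chain$model, chain$traits, G0, cellv, R0)
}

#' Category probabilities implied by threshold-model parameters
#'
#' For a linear predictor `eta`, thresholds `t` and residual SD `sd`, the
#' probability of each of the K categories is the normal mass between
#' consecutive thresholds; the probabilities sum to one by construction.
#'
#' @param eta Numeric vector of linear predictors (fitted liabilities).
#' @param thresholds Increasing threshold vector (length K-1).
#' @param sd Residual (liability) standard deviation.
#' @return Matrix `length(eta) x K` of category probabilities.
#' @export
category_probabilities <- function(eta, thresholds, sd = 1) {
  K <- length(thresholds) + 1L
  cuts <- c(-Inf, thresholds, Inf)
  out <- vapply(seq_len(K), function(k) {
    pnorm((cuts[k + 1] - eta) / sd) - pnorm((cuts[k] - eta) / sd)
  }, numeric(length(eta)))
  matrix(out, nrow = length(eta), ncol = K)
}
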