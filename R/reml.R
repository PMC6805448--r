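#' Average-information REML for a continuous trait
#'
#' Estimates the variance components of the colony model for a continuous
#' trait (honey yield) by restricted maximum likelihood. The restricted
#' log-likelihood is evaluated through the sparse mixed-model equations
#' (log-determinant from a sparse Cholesky factorization, never a dense
#' phenotypic covariance), updates use the average-information (AI) matrix
#' as curvature with monotone step-halving -- a step is accepted only if it
#' increases the likelihood, so the likelihood trace is non-decreasing by
#' construction -- and approximate standard errors come from the inverse AI
#' matrix at convergence. The score vector is obtained by central finite
#' differences of the likelihood; each AI element costs one extra solve
#' against the already-factorized equations.
#'
#' Components pinned at the variance floor (`floor_frac` times the
#' phenotypic variance) are reported as boundary estimates with their
#' standard errors marked unreliable, not silently truncated.
#'
#' @param design A [build_design()] object.
#' @param trait Continuous trait name (default `"honey_yield"`).
#' @param start Optional `beeval_varcomp` or named numeric vector of
#'   starting values; default is an equal partition of the phenotypic
#'   variance across components (the covariance starting at 0 under
#'   model 1).
#' @param tol Convergence tolerance on the maximum relative parameter
#'   change (default 1e-12); iteration also stops when the likelihood
#'   gain drops below 1e-10 (the resolution of the finite-difference
#'   score) or at `max_iter`.
#' @param max_iter Iteration cap (default 100).
#' @param floor_frac Variance floor as a fraction of phenotypic variance.
#' @param verbose Print the likelihood trace.
#' @return A `beeval_reml` object: `components` (a [variance_components()]
#'   with standard errors), `AI` matrix, `logLik` trace, `iterations`,
#'   `converged`, `boundary` flags.
#' @export
ai_reml <- function(design, trait = "honey_yield", start = NULL,
                    tol = 1e-12, max_iter = 100L, floor_frac = 1e-8,
                    verbose = FALSE) {
  if (design$spec$trait_types[match(trait, design$spec$traits)] != "linear") {
    stop_beeval("ai_reml is for continuous traits; use the Gibbs sampler for threshold traits.",
                "beeval_bad_argument")
  }
  sys <- trait_system(design, trait)
  y <- sys$y
  varP <- stats::var(y)
  floor_v <- floor_frac * varP
  model1 <- design$spec$model == "model1"
  par_names <- if (model1) {
    c("sigma2_w", "sigma2_mq", "cov_w_mq",
      if (sys$include_cell) "sigma2_cell", "sigma2_e")
  } else {
    c("sigma2_q", if (sys$include_cell) "sigma2_cell", "sigma2_e")
  }
  p <- length(par_names)
  is_var <- par_names != "cov_w_mq"

  theta0 <- if (is.null(start)) {
    if (model1) {
      v <- varP / (3 + sys$include_cell)
      c(v, v, 0, if (sys$include_cell) v, v)
    } else {
      v <- varP / (2 + sys$include_cell)
      rep(v, p)
    }
  } else if (inherits(start, "beeval_varcomp")) {
    pack_theta(start, par_names, trait)
  } else {
    as.numeric(start[par_names])
  }
  names(theta0) <- par_names

  unpack <- function(theta) {
    if (model1) {
      G0 <- matrix(c(theta["sigma2_w"], theta["cov_w_mq"],
                     theta["cov_w_mq"], theta["sigma2_mq"]), 2, 2)
    } else {
      G0 <- matrix(theta["sigma2_q"], 1, 1)
    }
    variance_components(design$spec$model, trait, G0,
                        if (sys$include_cell) theta["sigma2_cell"] else 0,
                        matrix(theta["sigma2_e"], 1, 1))
  }
  feasible <- function(theta) {
    if (any(theta[is_var] < floor_v)) return(FALSE)
    if (model1 &&
        theta["cov_w_mq"]^2 >
          (1 - 1e-10) * theta["sigma2_w"] * theta["sigma2_mq"]) return(FALSE)
    TRUE
  }
  project <- function(theta) {
    theta[is_var] <- pmax(theta[is_var], floor_v)
    if (model1) {
      bound <- sqrt((1 - 1e-10) * theta["sigma2_w"] * theta["sigma2_mq"])
      theta["cov_w_mq"] <- max(min(theta["cov_w_mq"], bound), -bound)
    }
    theta
  }

  WtW <- Matrix::crossprod(sys$W)
  Wty <- as.numeric(Matrix::crossprod(sys$W, y))
  yty <- sum(y^2)
  q <- sys$q
  chA <- Matrix::Cholesky(Matrix::forceSymmetric(design$Ainv), perm = TRUE,
                          LDL = FALSE, super = FALSE)

  # restricted log-likelihood (constants dropped) + factorization reuse
  eval_ll <- function(theta) {
    vc <- unpack(theta)
    se2 <- theta["sigma2_e"]
    C <- tryCatch(
      WtW / se2 + prior_precision(sys, design, vc$G0,
                                  vc$sigma2_cell[[trait]]),
      error = function(e) NULL)
    if (is.null(C)) return(NULL)
    # trial steps may propose non-PD systems; they are rejected, so the
    # CHOLMOD chatter is muffled along with the error
    ch <- tryCatch(
      suppressWarnings(
        Matrix::Cholesky(Matrix::forceSymmetric(C), perm = TRUE,
                         LDL = FALSE, super = FALSE)),
      error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    rhs <- Wty / se2
    sol <- as.numeric(Matrix::solve(ch, rhs))
    ldC <- 2 * c(Matrix::determinant(ch, sqrt = TRUE)$modulus)
    ldG <- q * c(determinant(as.matrix(vc$G0), logarithm = TRUE)$modulus)
    ldcell <- if (sys$include_cell) {
      length(sys$blocks$cell) * log(vc$sigma2_cell[[trait]])
    } else 0
    yPy <- yty / se2 - sum(sol * rhs)
    ll <- -0.5 * (ldC + ldG + ldcell + sys$n_obs * log(se2) + yPy)
    list(ll = ll, ch = ch, sol = sol, vc = vc)
  }

  # exact AI matrix at theta given the current fit
  ai_matrix <- function(theta, fit) {
    se2 <- theta["sigma2_e"]
    e <- y - as.numeric(sys$W %*% fit$sol)
    Py <- e / se2
    Fcols <- matrix(0, sys$n_obs, p)
    gmaps <- sys$blocks$genetic
    Zt_Py <- lapply(sys$effects, function(ef)
      as.numeric(Matrix::crossprod(
        genetic_incidence_cached(design, ef, sys$mask), Py)))
    names(Zt_Py) <- sys$effects
    Aprod <- function(v) as.numeric(Matrix::solve(chA, v)) # A v = (A^-1)^-1 v
    Zmul <- function(ef, v) {
      pos <- design$genetic[[ef]][sys$mask]
      v[pos]
    }
    for (k in seq_len(p)) {
      nm <- par_names[k]
      Fcols[, k] <- switch(nm,
        sigma2_q = Zmul("q", Aprod(Zt_Py[["q"]])),
        sigma2_w = Zmul("w", Aprod(Zt_Py[["w"]])),
        sigma2_mq = Zmul("mq", Aprod(Zt_Py[["mq"]])),
        cov_w_mq = Zmul("w", Aprod(Zt_Py[["mq"]])) +
                   Zmul("mq", Aprod(Zt_Py[["w"]])),
        sigma2_cell = {
          v <- as.numeric(Matrix::crossprod(design$Z_cell[sys$mask, , drop = FALSE], Py))
          as.numeric(design$Z_cell[sys$mask, , drop = FALSE] %*% v)
        },
        sigma2_e = Py)
    }
    PF <- matrix(0, sys$n_obs, p)
    for (k in seq_len(p)) {
      rhs_k <- as.numeric(Matrix::crossprod(sys$W, Fcols[, k])) / se2
      sol_k <- as.numeric(Matrix::solve(fit$ch, rhs_k))
      PF[, k] <- (Fcols[, k] - as.numeric(sys$W %*% sol_k)) / se2
    }
    AI <- 0.5 * crossprod(Fcols, PF)
    (AI + t(AI)) / 2
  }

  # The iteration runs in an unconstrained parameterization -- log variances
  # and, under model 1, the atanh of the direct-maternal correlation -- so
  # the positive-definiteness cone never truncates a step. This matters on
  # the flat ridge that worker/residual confounding produces: cone-clipped
  # steps crawl, unconstrained ones traverse it.
  phi_min <- log(floor_v)
  cov_k <- if (model1) which(par_names == "cov_w_mq") else integer(0)
  to_phi <- function(theta) {
    phi <- log(pmax(theta[is_var], floor_v))
    if (model1) {
      r <- theta["cov_w_mq"] /
        sqrt(theta["sigma2_w"] * theta["sigma2_mq"])
      r <- max(min(r, 1 - 1e-10), -1 + 1e-10)
      phi <- append(phi, atanh(r), after = cov_k - 1L)
    }
    unname(phi)
  }
  to_theta <- function(phi) {
    theta <- numeric(p)
    theta[is_var] <- exp(pmax(pmin(phi[is_var], 50), phi_min))
    if (model1) {
      r <- max(min(tanh(phi[cov_k]), 1 - 1e-6), -1 + 1e-6)
      theta[cov_k] <- r *
        sqrt(theta[par_names == "sigma2_w"] * theta[par_names == "sigma2_mq"])
    }
    setNames(theta, par_names)
  }
  jacobian <- function(phi) {
    J <- matrix(0, p, p)
    for (k in seq_len(p)) {
      h <- 1e-6
      up <- phi; up[k] <- up[k] + h
      dn <- phi; dn[k] <- dn[k] - h
      J[, k] <- (to_theta(up) - to_theta(dn)) / (2 * h)
    }
    J
  }
  score_phi <- function(phi) {
    g <- numeric(p)
    for (k in seq_len(p)) {
      # the likelihood carries ~1e-5 absolute noise at registry scale, so
      # the step must be wide enough to dominate it
      h <- 1e-3
      up <- phi; up[k] <- up[k] + h
      dn <- phi; dn[k] <- dn[k] - h
      fu <- eval_ll(to_theta(up)); fd <- eval_ll(to_theta(dn))
      if (is.null(fu) || is.null(fd)) { g[k] <- 0; next }
      g[k] <- (fu$ll - fd$ll) / (2 * h)
    }
    g
  }

  theta <- project(theta0)
  phi <- to_phi(theta)
  fit <- eval_ll(theta)
  if (is.null(fit)) {
    stop_beeval("Likelihood not computable at the starting values.",
                "beeval_bad_start")
  }
  ll_trace <- fit$ll
  converged <- FALSE
  AI <- NULL
  # Marquardt-damped AI updates: the AI matrix is singular along the
  # ridge that worker/residual confounding creates, so a raw Newton solve
  # explodes there; damping interpolates towards a scaled gradient step
  # and keeps the likelihood monotone by construction.
  lam <- 1e-6
  for (iter in seq_len(max_iter)) {
    g_phi <- score_phi(phi)
    AI <- ai_matrix(theta, fit)
    J <- jacobian(phi)
    AI_phi <- t(J) %*% AI %*% J
    AI_phi <- (AI_phi + t(AI_phi)) / 2
    dscale <- pmax(diag(AI_phi), 1e-8 * max(diag(AI_phi), 1e-300))
    accepted <- FALSE
    for (attempt in 1:40) {
      step <- tryCatch(solve(AI_phi + lam * diag(dscale, p), g_phi),
                       error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) {
        lam <- max(lam * 10, 1e-4)
        next
      }
      cand_phi <- phi + step
      cand_phi[is_var] <- pmax(cand_phi[is_var], phi_min)
      cand <- to_theta(cand_phi)
      f2 <- eval_ll(cand)
      if (!is.null(f2) && is.finite(f2$ll) && f2$ll >= fit$ll - 1e-12) {
        rel_change <- max(abs(cand - theta) / pmax(abs(theta), 1e-3 * varP))
        gain <- f2$ll - fit$ll
        theta <- cand; phi <- cand_phi; fit <- f2
        accepted <- TRUE
        lam <- max(lam / 4, 1e-10)
        break
      }
      lam <- lam * 10
    }
    if (!accepted) { converged <- TRUE; break } # no uphill move available
    ll_trace <- c(ll_trace, fit$ll)
    if (verbose) {
      message(sprintf("iter %d: logL %.8f, max rel change %.2e, damping %.1e",
                      iter, fit$ll, rel_change, lam))
    }
    if (rel_change < tol || gain < 1e-10) { converged <- TRUE; break }
  }

  boundary <- is_var & (abs(theta) <= floor_v * 1.0001)
  names(boundary) <- par_names
  se <- rep(NA_real_, p)
  covm <- tryCatch(solve(AI), error = function(e) NULL)
  if (!is.null(covm)) {
    dv <- diag(covm)
    se <- ifelse(dv > 0, sqrt(dv), NA_real_)
  }
  names(se) <- par_names
  if (any(boundary)) se[boundary] <- NA_real_

  vc <- fit$vc
  se_named <- rename_se(se, trait, model1)
  vc$se <- se_named
  structure(
    list(components = vc, theta = setNames(theta, par_names), se = se,
         AI = AI, vcov = covm, logLik = ll_trace,
         iterations = length(ll_trace) - 1L,
         converged = converged, boundary = boundary,
         trait = trait, n_obs = sys$n_obs, model = design$spec$model),
    class = "beeval_reml")
}

# map internal parameter names to tidy() component names
rename_se <- function(se, trait, model1) {
  nm <- names(se)
  nm[nm == "sigma2_q"] <- "sigma2_q"
  nm[nm == "cov_w_mq"] <- "cov_w_mq"
  nm[nm == "sigma2_cell"] <- paste0("sigma2_cell_", trait)
  nm[nm == "sigma2_e"] <- paste0("sigma2_e_", trait)
  setNames(se, nm)
}

pack_theta <- function(vc, par_names, trait) {
  th <- numeric(length(par_names))
  names(th) <- par_names
  for (nm in par_names) {
    th[nm] <- switch(nm,
      sigma2_q = vc$G0["q", "q"],
      sigma2_w = vc$G0["w", "w"],
      sigma2_mq = vc$G0["mq", "mq"],
      cov_w_mq = vc$G0["w", "mq"],
      sigma2_cell = vc$sigma2_cell[[trait]],
      sigma2_e = vc$R0[trait, trait])
  }
  th
}

# genetic_incidence is cheap; thin alias kept for clarity at call sites
genetic_incidence_cached <- genetic_incidence

#' @export
print.beeval_reml <- function(x, ...) {
  cat(sprintf("AI-REML fit (%s, trait %s): %d iterations, %s\n",
              x$model, x$trait, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  est <- x$theta
  for (k in seq_along(est)) {
    cat(sprintf("  %-12s %10.4f (SE %s)%s\n", names(est)[k], est[k],
                ifelse(is.na(x$se[k]), "n/a", sprintf("%.4f", x$se[k])),
                if (x$boundary[k]) "  [boundary]" else ""))
  }
  invisible(x)
}

#' Tidy methods for fitted objects
#'
#' `tidy()` returns one row per parameter (estimates, standard errors,
#' boundary flags where applicable); `glance()` returns a one-row model
#' summary. Both follow the broom conventions so fits drop into dplyr
#' pipelines.
#'
#' @param x A fitted object (`beeval_reml`, `beeval_varcomp`,
#'   `beeval_blup`, `beeval_chain`).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy beeval_reml
#' @export
tidy.beeval_reml <- function(x, ...) {
  tibble(component = names(x$theta),
         estimate = unname(x$theta),
         std.error = unname(x$se),
         boundary = unname(x$boundary))
}

#' @rdname tidy.beeval_reml
#' @method glance beeval_reml
#' @export
glance.beeval_reml <- function(x, ...) {
  tibble(logLik = x$logLik[length(x$logLik)],
         iterations = x$iterations,
         converged = x$converged,
         any_boundary = any(x$boundary),
         n_obs = x$n_obs)
}
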