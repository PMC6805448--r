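# --- Henderson mixed-model equations (single trait) -------------------------

# Observed-rows design for one trait: sparse W = [X | Z_cell | Z_genetic...],
# response, and column-block bookkeeping. Cell effect is dropped when the
# data hold a single observed cell (it would be confounded with the mean).
trait_system <- function(design, trait, include_cell = NULL) {
  if (!trait %in% design$spec$traits) {
    stop_beeval(sprintf("Trait `%s` is not in the model spec.", trait),
                "beeval_bad_argument")
  }
  mask <- design$obs[[trait]]
  if (!any(mask)) stop_beeval("No observed records for trait.", "beeval_no_data")
  include_cell <- include_cell %||% (length(design$cell_levels) > 1L)
  q <- nrow(design$pedigree)
  effects <- names(design$genetic)
  Xo <- design$X[mask, , drop = FALSE]
  blocks <- list(fixed = seq_len(ncol(Xo)))
  Wparts <- list(Xo)
  if (include_cell) {
    Zc <- design$Z_cell[mask, , drop = FALSE]
    blocks$cell <- ncol(Xo) + seq_len(ncol(Zc))
    Wparts <- c(Wparts, list(Zc))
  }
  off <- sum(vapply(Wparts, ncol, 1L))
  blocks$genetic <- lapply(setNames(seq_along(effects), effects),
                           function(k) off + (k - 1L) * q + seq_len(q))
  Wparts <- c(Wparts, lapply(effects, function(e)
    genetic_incidence(design, e, mask)))
  W <- do.call(cbind, Wparts)
  list(W = W, y = design$y[[trait]][mask], n_obs = sum(mask),
       blocks = blocks, include_cell = include_cell,
       q = q, effects = effects, mask = mask)
}

# Augmented prior precision matching trait_system's column layout.
prior_precision <- function(sys, design, G0, sigma2_cell) {
  p <- length(sys$blocks$fixed)
  parts <- list(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                     dims = c(p, p)))
  if (sys$include_cell) {
    nc <- length(sys$blocks$cell)
    parts <- c(parts, list(Matrix::Diagonal(nc, 1 / sigma2_cell)))
  }
  G0inv <- solve(as.matrix(G0))
  parts <- c(parts, list(Matrix::kronecker(as(G0inv, "sparseMatrix"),
                                           design$Ainv)))
  Matrix::bdiag(parts)
}

#' Assemble Henderson's mixed-model equations
#'
#' Builds the sparse symmetric coefficient matrix and right-hand side of
#' the mixed-model equations for one trait at given variance components:
#' `C = W'W / sigma_e^2 + diag(0, I / sigma_cell^2, G0^-1 kron A^-1)`,
#' `rhs = W'y / sigma_e^2`.
#'
#' @param design A [build_design()] object.
#' @param components A [variance_components()] object (its `G0` must match
#'   the design's genetic effects; a singular `G0` is an error -- hold a
#'   boundary component slightly above zero instead).
#' @param trait Trait to assemble (default: the spec's first trait).
#' @return A `beeval_mme` list with elements `C`, `rhs`, `W`, `y`,
#'   `sigma2_e`, `blocks`.
#' @export
assemble_mme <- function(design, components, trait = design$spec$traits[1]) {
  sys <- trait_system(design, trait)
  G0 <- components$G0
  if (abs(det(as.matrix(G0))) < 1e-300) {
    stop_beeval(paste("Singular genetic covariance; keep boundary components",
                      "at a small positive floor rather than exactly zero."),
                "beeval_singular_G")
  }
  sigma2_e <- components$R0[trait, trait]
  C <- Matrix::crossprod(sys$W) / sigma2_e +
    prior_precision(sys, design, G0, components$sigma2_cell[[trait]])
  rhs <- as.numeric(Matrix::crossprod(sys$W, sys$y)) / sigma2_e
  structure(list(C = methods::as(C, "generalMatrix"), rhs = rhs, W = sys$W,
                 y = sys$y, sigma2_e = sigma2_e, blocks = sys$blocks,
                 q = sys$q, effects = sys$effects, trait = trait,
                 pedigree_ids = design$pedigree$id,
                 pedigree_tier = design$pedigree$tier),
            class = "beeval_mme")
}

#' Solve the mixed-model equations
#'
#' Sparse Cholesky solve with iterative refinement until the relative
#' residual of the linear system is at most `tol`.
#'
#' @param mme A [assemble_mme()] object.
#' @param tol Relative residual tolerance (default 1e-12).
#' @param max_refine Refinement iteration cap.
#' @return A `beeval_blup` object: fixed/cell solutions, per-individual
#'   genetic solutions (`ebv`, a tibble with one row per pedigree
#'   individual and effect, unphenotyped ancestors included), and solving
#'   metadata (`rel_residual`, `refinements`).
#' @export
solve_blup <- function(mme, tol = 1e-12, max_refine = 10L) {
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(mme$C), perm = TRUE,
                         LDL = FALSE, super = FALSE)
  x <- as.numeric(Matrix::solve(ch, mme$rhs))
  rhs_norm <- sqrt(sum(mme$rhs^2))
  rel <- Inf
  for (it in seq_len(max_refine)) {
    r <- mme$rhs - as.numeric(mme$C %*% x)
    rel <- sqrt(sum(r^2)) / max(rhs_norm, .Machine$double.xmin)
    if (rel <= tol) break
    x <- x + as.numeric(Matrix::solve(ch, r))
  }
  if (rel > tol) {
    stop_beeval(sprintf(
      "MME solve did not reach tolerance %.1e (relative residual %.2e).",
      tol, rel), "beeval_no_convergence")
  }
  ebv <- purrr::map_dfr(mme$effects, function(e) {
    tibble(id = mme$pedigree_ids,
           tier = mme$pedigree_tier,
           effect = e,
           ebv = x[mme$blocks$genetic[[e]]])
  })
  structure(list(solution = x,
                 fixed = x[mme$blocks$fixed],
                 cell = if (!is.null(mme$blocks$cell)) x[mme$blocks$cell],
                 ebv = ebv,
                 trait = mme$trait,
                 rel_residual = rel, refinements = it),
            class = "beeval_blup")
}

#' Fit BLUP breeding values at known variance components
#'
#' Convenience wrapper: [assemble_mme()] then [solve_blup()].
#'
#' @inheritParams assemble_mme
#' @inheritParams solve_blup
#' @return A `beeval_blup` object (see [solve_blup()]).
#' @export
fit_blup <- function(design, components, trait = design$spec$traits[1],
                     tol = 1e-12) {
  solve_blup(assemble_mme(design, components, trait), tol = tol)
}

#' @export
print.beeval_blup <- function(x, ...) {
  cat(sprintf("BLUP solution (%s): %d equations, relative residual %.1e\n",
              x$trait, length(x$solution), x$rel_residual))
  invisible(x)
}

#' @rdname tidy.beeval_reml
#' @method tidy beeval_blup
#' @export
tidy.beeval_blup <- function(x, ...) x$ebv
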