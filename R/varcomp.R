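#' Variance components container
#'
#' Holds the (co)variance components of a colony model: the genetic
#' (co)variance matrix `G0` (1x1 queen-direct for model 2; 2x2
#' worker-direct/queen-maternal for model 1; T x T across traits for the
#' multi-trait queen model), the year x apiary environmental variance per
#' trait, and the residual (co)variance `R0`. Continuous-trait components
#' are in kg^2; threshold-trait components are on the liability scale.
#'
#' @param model `"model1"` or `"model2"`.
#' @param traits Character vector of trait names.
#' @param G0 Genetic (co)variance matrix (scalar accepted), with one
#'   row/column per genetic effect (`w`, `mq` for model 1; one per trait
#'   for model 2).
#' @param sigma2_cell Year x apiary interaction variance(s), one per trait.
#' @param R0 Residual (co)variance matrix (scalar accepted).
#' @param se Optional named numeric vector of approximate standard errors.
#' @return A `beeval_varcomp` object.
#' @export
variance_components <- function(model, traits, G0, sigma2_cell, R0,
                                se = NULL) {
  G0 <- as.matrix(G0); R0 <- as.matrix(R0)
  effects <- if (model == "model1") c("w", "mq") else {
    if (length(traits) == 1) "q" else paste0("q:", traits)
  }
  if (nrow(G0) != length(effects)) {
    stop_beeval("G0 dimension does not match the model's genetic effects.",
                "beeval_bad_argument")
  }
  dimnames(G0) <- list(effects, effects)
  dimnames(R0) <- list(traits, traits)
  ev <- eigen(G0, symmetric = TRUE, only.values = TRUE)$values
  structure(
    list(model = model, traits = traits, effects = effects,
         G0 = G0, sigma2_cell = setNames(as.numeric(sigma2_cell), traits),
         R0 = R0, se = se,
         psd = min(ev) >= -1e-10 * max(abs(ev))),
    class = "beeval_varcomp")
}

#' @export
print.beeval_varcomp <- function(x, ...) {
  cat(sprintf("Variance components (%s; traits: %s)\n", x$model,
              paste(x$traits, collapse = ", ")))
  cat("Genetic G0:\n"); print(round(x$G0, 4))
  cat("year x apiary:", paste(round(x$sigma2_cell, 4), collapse = ", "), "\n")
  cat("Residual R0:\n"); print(round(x$R0, 4))
  if (!x$psd) cat("NOTE: genetic matrix is not positive semi-definite\n")
  invisible(x)
}

#' @rdname tidy.beeval_reml
#' @method tidy beeval_varcomp
#' @export
tidy.beeval_varcomp <- function(x, ...) {
  gl <- which(upper.tri(x$G0, diag = TRUE), arr.ind = TRUE)
  gen <- tibble(
    component = ifelse(gl[, 1] == gl[, 2],
                       paste0("sigma2_", rownames(x$G0)[gl[, 1]]),
                       paste0("cov_", rownames(x$G0)[gl[, 1]], "_",
                              colnames(x$G0)[gl[, 2]])),
    estimate = x$G0[gl])
  rl <- which(upper.tri(x$R0, diag = TRUE), arr.ind = TRUE)
  res <- tibble(
    component = ifelse(rl[, 1] == rl[, 2],
                       paste0("sigma2_e_", rownames(x$R0)[rl[, 1]]),
                       paste0("cov_e_", rownames(x$R0)[rl[, 1]], "_",
                              colnames(x$R0)[rl[, 2]])),
    estimate = x$R0[rl])
  cell <- tibble(component = paste0("sigma2_cell_", names(x$sigma2_cell)),
                 estimate = unname(x$sigma2_cell))
  out <- dplyr::bind_rows(gen, cell, res)
  if (!is.null(x$se)) {
    out$std.error <- unname(x$se[out$component])
  }
  out
}
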