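#' Specify a colony genetic-evaluation model
#'
#' Two genetic parameterizations of the colony phenotype are supported.
#' `"model1"` carries a worker-group direct effect plus a queen maternal
#' effect with a 2x2 genetic covariance over the two-tier pedigree (the
#' colony genetic variance is then `sigma_W^2 + sigma_MQ^2 + 2 Cov`);
#' `"model2"` attributes a single direct genetic effect to the queen.
#' Both share the environmental structure: fixed test-year and
#' tester-apiary effects and a random year x apiary interaction.
#'
#' @param model `"model1"` (worker direct + queen maternal) or `"model2"`
#'   (queen direct).
#' @param traits Character vector, ordered subset of
#'   `c("honey_yield", "defensive", "swarming")`. Honey yield is continuous;
#'   the behaviour scores are threshold traits with 5 categories.
#' @return A `beeval_model_spec` list.
#' @export
model_spec <- function(model = c("model2", "model1"),
                       traits = "honey_yield") {
  model <- match.arg(model)
  known <- c("honey_yield", "defensive", "swarming")
  if (!length(traits) || !all(traits %in% known)) {
    stop_beeval(sprintf("`traits` must be a subset of: %s",
                        paste(known, collapse = ", ")),
                "beeval_bad_argument")
  }
  if (model == "model1" && length(traits) > 1) {
    stop_beeval("model1 (worker + maternal) is fit single-trait only.",
                "beeval_bad_argument")
  }
  structure(
    list(model = model,
         traits = traits,
         trait_types = ifelse(traits == "honey_yield", "linear", "threshold"),
         n_categories = ifelse(traits == "honey_yield", NA_integer_, 5L)),
    class = "beeval_model_spec")
}

#' Build design structures for a model
#'
#' Translates records plus a pedigree into the index structures estimation
#' needs: fixed-effect incidence (all test-year levels, tester-apiary
#' levels with the first observed level as reference -- a reparameterization
#' of the usual intercept + two constrained factors that leaves EBVs and
#' fitted values unchanged), the observed year x apiary cells for the
#' random environmental effect (unobserved cells get no level), the
#' genetic carrier map per effect (worker group and queen under model 1,
#' queen under model 2), per-trait observation masks, and the sparse
#' inverse relationship matrix.
#'
#' @param records Records tibble (see [read_performance_records()]).
#' @param pedigree Pedigree tibble: two-tier for model 1; for model 2 a
#'   queen pedigree (a two-tier pedigree is reduced to its queen tier).
#' @param spec A [model_spec()].
#' @return A `beeval_design` list.
#' @export
build_design <- function(records, pedigree, spec) {
  stopifnot(inherits(spec, "beeval_model_spec"))
  n <- nrow(records)
  if (n == 0) stop_beeval("No records.", "beeval_bad_argument")

  py_levels <- sort(unique(records$test_year))
  ta_levels <- sort(unique(records$apiary))
  cell_levels <- sort(unique(records$year_apiary_cell))
  py_idx <- match(records$test_year, py_levels)
  ta_idx <- match(records$apiary, ta_levels) - 1L # 0 = reference level
  cell_idx <- match(records$year_apiary_cell, cell_levels)

  if (spec$model == "model1") {
    if (!any(pedigree$tier == "worker_group")) {
      stop_beeval("model1 needs a two-tier pedigree with worker groups.",
                  "beeval_bad_argument")
    }
  } else if (any(pedigree$tier == "worker_group")) {
    keep <- pedigree$tier == "queen"
    pedigree <- finalize_pedigree(
      pedigree[keep, c("id", "sire", "dam", "year", "tier")], resort = FALSE)
  }
  q_pos <- match(records$queen_id, pedigree$id)
  if (anyNA(q_pos)) {
    stop_beeval(sprintf("Record queens missing from pedigree: %s",
                        paste(utils::head(records$queen_id[is.na(q_pos)], 5),
                              collapse = ", ")),
                "beeval_unknown_queen")
  }
  genetic <- if (spec$model == "model1") {
    w_pos <- match(paste0("W:", records$colony_id), pedigree$id)
    if (anyNA(w_pos)) {
      stop_beeval(sprintf("Colonies without worker-group entries: %s",
                          paste(utils::head(records$colony_id[is.na(w_pos)], 5),
                                collapse = ", ")),
                  "beeval_unknown_worker_group")
    }
    list(w = w_pos, mq = q_pos)
  } else {
    list(q = q_pos)
  }

  y <- lapply(setNames(spec$traits, spec$traits),
              function(tr) as.numeric(records[[tr]]))
  obs <- lapply(y, function(v) !is.na(v))

  n_fixed <- length(py_levels) + length(ta_levels) - 1L
  # sparse fixed incidence: one 1 per factor present per row
  xi <- c(seq_len(n), seq_len(n)[ta_idx > 0L])
  xj <- c(py_idx, length(py_levels) + ta_idx[ta_idx > 0L])
  X <- Matrix::sparseMatrix(i = xi, j = xj, x = 1, dims = c(n, n_fixed))
  # sparse year/apiary layouts can nest an apiary inside a single year (or
  # vice versa); drop linearly dependent columns so the equations stay
  # full rank -- estimable contrasts and EBVs are unaffected
  qrX <- qr(as.matrix(Matrix::crossprod(X)))
  if (qrX$rank < n_fixed) {
    keep <- sort(qrX$pivot[seq_len(qrX$rank)])
    X <- X[, keep, drop = FALSE]
  }
  Z_cell <- Matrix::sparseMatrix(i = seq_len(n), j = cell_idx, x = 1,
                                 dims = c(n, length(cell_levels)))

  structure(
    list(spec = spec,
         records = records,
         pedigree = pedigree,
         Ainv = build_A_inverse(pedigree),
         n = n,
         y = y,
         obs = obs,
         py_levels = py_levels, ta_levels = ta_levels,
         cell_levels = cell_levels,
         py_idx = py_idx, ta_idx = ta_idx, cell_idx = cell_idx,
         X = X, Z_cell = Z_cell,
         genetic = genetic),
    class = "beeval_design")
}

#' @export
print.beeval_design <- function(x, ...) {
  cat(sprintf(
    "beeval design: %s, %d records, traits: %s\n  %d year level(s), %d apiary level(s), %d observed year:apiary cell(s)\n  pedigree: %d (%d queens, %d worker groups)\n",
    x$spec$model, x$n, paste(x$spec$traits, collapse = ", "),
    length(x$py_levels), length(x$ta_levels), length(x$cell_levels),
    nrow(x$pedigree), sum(x$pedigree$tier == "queen"),
    sum(x$pedigree$tier == "worker_group")))
  invisible(x)
}

# sparse incidence for one genetic effect (observed rows only when mask given)
genetic_incidence <- function(design, effect, mask = NULL) {
  pos <- design$genetic[[effect]]
  rows <- seq_len(design$n)
  if (!is.null(mask)) { rows <- rows[mask]; pos <- pos[mask] }
  Matrix::sparseMatrix(i = seq_along(rows), j = pos, x = 1,
                       dims = c(length(rows), nrow(design$pedigree)))
}
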