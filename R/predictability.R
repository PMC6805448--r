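#' Select validation queens for the record-removal comparison
#'
#' Queens eligible to have their colony performance withheld: the queen
#' has a colony record, her dam has more than `min_family_size` recorded
#' daughters (so the family keeps information after removal), and -- by
#' default -- her maternal granddam is known. When more queens qualify
#' than requested, a seeded random subset is drawn.
#'
#' @param records Colony records tibble.
#' @param pedigree Queen or two-tier pedigree tibble.
#' @param n Number of validation queens wanted (default 150).
#' @param min_family_size Dam family-size threshold (strict, default 3).
#' @param require_grandparents Require a known maternal granddam.
#' @param seed Seed for the subset draw.
#' @return Tibble: `queen_id`, `dam_id`, `family_size`.
#' @export
select_validation_queens <- function(records, pedigree, n = 150,
                                     min_family_size = 3,
                                     require_grandparents = TRUE,
                                     seed = NULL) {
  queens <- pedigree[pedigree$tier == "queen", ]
  fam <- dplyr::count(queens[!is.na(queens$dam), ], .data$dam,
                      name = "family_size")
  cand <- queens[queens$id %in% unique(records$queen_id), ]
  cand <- dplyr::inner_join(cand, fam, by = c(dam = "dam"),
                            relationship = "many-to-one")
  cand <- cand[cand$family_size > min_family_size, ]
  if (require_grandparents) {
    granddam <- queens$dam[match(cand$dam, queens$id)]
    cand <- cand[!is.na(granddam), ]
  }
  out <- tibble(queen_id = cand$id, dam_id = cand$dam,
                family_size = cand$family_size)
  if (nrow(out) < n) {
    warn(sprintf("Only %d queens qualify (requested %d); returning all.",
                 nrow(out), n))
    return(out)
  }
  if (!is.null(seed)) set.seed(seed)
  out[sort(sample.int(nrow(out), n)), ]
}

#' Predictability: correlation of reduced-data EBVs with withheld information
#'
#' Withholds the colony phenotypes of the validation queens (the pedigree
#' is untouched), refits breeding values on the reduced data at the given
#' variance components, and correlates the validation queens' predictions
#' with (a) their withheld phenotypes -- raw, and adjusted for the fixed
#' effects estimated in the reduced fit, since year/apiary variance is
#' no part of what a breeding value can predict -- and (b) their full-data
#' EBVs. The strongest correlation points to the better model. Under the
#' worker/maternal model the prediction for a withheld colony is the sum
#' of its worker-group direct and queen maternal solutions.
#'
#' @param design A [build_design()] object containing the full records.
#' @param components [variance_components()] at which EBVs are computed.
#' @param validation_queens Output of [select_validation_queens()] or a
#'   character vector of queen ids.
#' @param trait Trait whose records are withheld (default: first of the
#'   spec). For behaviour scores the integer scores are used directly.
#' @param definition Which correlation is the headline `predictability`:
#'   `"phenotype"` (adjusted withheld phenotypes; default) or
#'   `"full_ebv"` (full-data EBVs).
#' @return A `beeval_predictability` list: `summary` tibble with
#'   `r_ebv_y`, `r_ebv_y_raw`, `r_ebv_ebv`, `predictability`, `n_validation`;
#'   `validation` tibble of per-queen predictions.
#' @export
compute_predictability <- function(design, components, validation_queens,
                                   trait = design$spec$traits[1],
                                   definition = c("phenotype", "full_ebv")) {
  definition <- match.arg(definition)
  vq <- if (is.data.frame(validation_queens)) validation_queens$queen_id
        else as.character(validation_queens)
  records <- design$records
  has_pheno <- vq %in% records$queen_id[!is.na(records[[trait]])]
  if (any(!has_pheno)) {
    warn(sprintf("%d validation queens have no %s phenotype; excluded.",
                 sum(!has_pheno), trait))
    vq <- vq[has_pheno]
  }
  if (length(vq) < 3) {
    stop_beeval("Fewer than 3 usable validation queens.", "beeval_bad_data")
  }
  withheld <- records$queen_id %in% vq & !is.na(records[[trait]])

  reduced_records <- records
  reduced_records[[trait]][withheld] <- NA
  reduced_design <- build_design(reduced_records, design$pedigree,
                                 design$spec)
  red <- fit_blup(reduced_design, components, trait)
  full <- fit_blup(design, components, trait)

  val_rec <- records[withheld, ]
  predict_colony <- function(fit) {
    if (design$spec$model == "model1") {
      w <- fit$ebv$ebv[fit$ebv$effect == "w"]
      mq <- fit$ebv$ebv[fit$ebv$effect == "mq"]
      ids <- fit$ebv$id[fit$ebv$effect == "w"]
      w[match(paste0("W:", val_rec$colony_id), ids)] +
        mq[match(val_rec$queen_id, ids)]
    } else {
      eff <- if (length(design$spec$traits) > 1) paste0("q:", trait) else "q"
      sub <- fit$ebv[fit$ebv$effect == eff, ]
      sub$ebv[match(val_rec$queen_id, sub$id)]
    }
  }
  pred_red <- predict_colony(red)
  pred_full <- predict_colony(full)

  # withheld phenotypes, raw and adjusted by the reduced fit's fixed effects
  y <- records[[trait]][withheld]
  Xv <- reduced_design$X[withheld, , drop = FALSE]
  y_adj <- y - as.numeric(Xv %*% red$fixed)

  summary <- tibble(
    trait = trait,
    n_validation = length(y),
    r_ebv_y = stats::cor(pred_red, y_adj),
    r_ebv_y_raw = stats::cor(pred_red, y),
    r_ebv_ebv = stats::cor(pred_red, pred_full))
  summary$predictability <- if (definition == "phenotype") summary$r_ebv_y
                            else summary$r_ebv_ebv
  structure(
    list(summary = summary,
         validation = tibble(queen_id = val_rec$queen_id,
                             colony_id = val_rec$colony_id,
                             y = y, y_adjusted = y_adj,
                             ebv_reduced = pred_red, ebv_full = pred_full),
         definition = definition, trait = trait),
    class = "beeval_predictability")
}

#' @export
print.beeval_predictability <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Predictability (%s, %d withheld colonies):\n  r(EBV, adjusted Y) = %.3f   r(EBV, raw Y) = %.3f   r(EBV, full EBV) = %.3f\n",
    x$trait, s$n_validation, s$r_ebv_y, s$r_ebv_y_raw, s$r_ebv_ebv))
  invisible(x)
}

#' @rdname tidy.beeval_reml
#' @method tidy beeval_predictability
#' @export
tidy.beeval_predictability <- function(x, ...) x$summary
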