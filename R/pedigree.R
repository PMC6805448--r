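#' Build the queen pedigree
#'
#' Takes raw pedigree rows (queen id, sire id, dam id, birth year) and
#' returns a topologically sorted pedigree tibble: every parent appears
#' before its offspring, dams that are referenced but not listed are added
#' as founders, and integer parent indices are attached. In the maternal
#' registry setting all sires are unknown; known sires are still supported
#' (they are exercised by the relationship-matrix oracle tests).
#'
#' @param entries Data frame with columns `id`, `dam`, and optionally
#'   `sire` and `year`. Unknown parents are `NA`, `""`, or `"0"`.
#' @return A `beeval_pedigree` tibble with columns `id`, `sire`, `dam`,
#'   `year`, `tier` (`"queen"` here), `sire_idx`, `dam_idx` (row positions
#'   or `NA`), and inbreeding coefficient `F`.
#' @export
build_queen_pedigree <- function(entries) {
  entries <- as_tibble(entries)
  if (!all(c("id") %in% names(entries))) {
    stop_beeval("Pedigree entries need an `id` column.", "beeval_bad_argument")
  }
  norm_parent <- function(x) {
    x <- as.character(x)
    x[x %in% c("", "0", "NA") | is.na(x)] <- NA_character_
    x
  }
  ped <- tibble(
    id   = as.character(entries$id),
    sire = norm_parent(entries$sire %||% rep(NA_character_, nrow(entries))),
    dam  = norm_parent(entries$dam %||% rep(NA_character_, nrow(entries))),
    year = as.integer(entries$year %||% rep(NA_integer_, nrow(entries))),
    tier = "queen"
  )
  if (anyDuplicated(ped$id)) {
    stop_beeval("Duplicated pedigree ids.", "beeval_duplicate_id")
  }
  # referenced-but-absent parents become founders (prepended)
  referenced <- unique(c(ped$sire, ped$dam))
  referenced <- referenced[!is.na(referenced)]
  absent <- setdiff(referenced, ped$id)
  if (length(absent)) {
    ped <- dplyr::bind_rows(
      tibble(id = absent, sire = NA_character_, dam = NA_character_,
             year = NA_integer_, tier = "queen"),
      ped)
  }
  finalize_pedigree(ped)
}

# topological sort (stable in input order within a generation depth),
# parent indices, inbreeding
finalize_pedigree <- function(ped, resort = TRUE) {
  n <- nrow(ped)
  sire_i <- match(ped$sire, ped$id)
  dam_i <- match(ped$dam, ped$id)
  depth <- rep(NA_integer_, n)
  pending <- seq_len(n)
  repeat {
    ready <- pending[vapply(pending, function(i) {
      (is.na(sire_i[i]) || !is.na(depth[sire_i[i]])) &&
        (is.na(dam_i[i]) || !is.na(depth[dam_i[i]]))
    }, logical(1))]
    if (!length(ready)) break
    depth[ready] <- vapply(ready, function(i) {
      1L + max(0L, depth[sire_i[i]], depth[dam_i[i]], na.rm = TRUE)
    }, integer(1))
    pending <- setdiff(pending, ready)
  }
  if (length(pending)) {
    stop_beeval(sprintf("Pedigree contains a cycle involving: %s",
                        paste(utils::head(ped$id[pending], 10), collapse = ", ")),
                "beeval_pedigree_cycle")
  }
  if (resort) ped <- ped[order(depth, seq_len(n)), ]
  ped$sire_idx <- match(ped$sire, ped$id)
  ped$dam_idx <- match(ped$dam, ped$id)
  if (!resort) {
    bad <- which(ped$sire_idx >= seq_len(n) | ped$dam_idx >= seq_len(n))
    if (length(bad)) {
      stop_beeval("Pedigree not in parents-before-offspring order.",
                  "beeval_pedigree_order")
    }
  }
  ped$F <- inbreeding_coefficients(ped)
  class(ped) <- c("beeval_pedigree", class(tibble()))
  ped
}

#' Append worker-group pseudo-individuals for tested colonies
#'
#' The colony phenotype is expressed by the workers, a group of
#' full/half-sister daughters of the colony queen. For the worker-direct +
#' queen-maternal model each tested colony gets one pseudo-individual in a
#' second pedigree tier: dam = the colony queen, sire unknown, year = test
#' year. Queens keep their relative order; worker groups are appended
#' after all queens, so the topological invariant is preserved (a worker
#' group is never a parent).
#'
#' @param queen_pedigree Pedigree from [build_queen_pedigree()].
#' @param records Colony records tibble; one worker group per row is added
#'   with id `"W:"` + colony id.
#' @return Extended `beeval_pedigree` tibble.
#' @export
extend_with_worker_groups <- function(queen_pedigree, records) {
  missing <- setdiff(unique(records$queen_id), queen_pedigree$id)
  if (length(missing)) {
    stop_beeval(sprintf("Record queens absent from pedigree: %s",
                        paste(utils::head(missing, 10), collapse = ", ")),
                "beeval_unknown_queen")
  }
  workers <- tibble(
    id = paste0("W:", records$colony_id),
    sire = NA_character_,
    dam = records$queen_id,
    year = as.integer(records$test_year),
    tier = "worker_group"
  )
  if (anyDuplicated(workers$id)) {
    stop_beeval("Duplicated colony ids among worker groups.",
                "beeval_duplicate_id")
  }
  # queens (already sorted) first, worker groups appended: topological,
  # since a worker group is never a parent
  ped <- dplyr::bind_rows(
    queen_pedigree[, c("id", "sire", "dam", "year", "tier")], workers)
  finalize_pedigree(ped, resort = FALSE)
}

#' Inbreeding coefficients from a sorted pedigree
#'
#' Standard recursion on additive relationships: `F_i = a(sire, dam) / 2`,
#' zero whenever either parent is unknown (unknown parents are taken as
#' unrelated, non-inbred base individuals -- the situation of a maternal
#' pedigree, where every sire is unknown and every `F` is exactly 0).
#'
#' @param pedigree Sorted pedigree tibble with `sire_idx`, `dam_idx`.
#' @return Numeric vector of inbreeding coefficients, in pedigree order.
#' @export
inbreeding_coefficients <- function(pedigree) {
  n <- nrow(pedigree)
  s <- pedigree$sire_idx %||% match(pedigree$sire, pedigree$id)
  d <- pedigree$dam_idx %||% match(pedigree$dam, pedigree$id)
  Fv <- numeric(n)
  both <- which(!is.na(s) & !is.na(d))
  if (!length(both)) return(Fv)
  memo <- new.env(parent = emptyenv(), size = 4L * length(both))
  # additive relationship between i and j, valid when F of all strictly
  # earlier individuals is already final (guaranteed by topological order)
  arel <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    if (i == j) return(1 + Fv[i])
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    key <- paste0(i, ":", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- 0.5 * (arel(i, s[j]) + arel(i, d[j]))
    memo[[key]] <- val
    val
  }
  for (i in both) Fv[i] <- 0.5 * arel(s[i], d[i])
  Fv
}

#' Inverse numerator relationship matrix
#'
#' Assembles the sparse inverse of the additive relationship matrix A
#' directly from per-individual Mendelian-sampling variances (Henderson's
#' rules with inbreeding), with the unknown-parent variants: both parents
#' unknown gives variance 1, dam known only gives `0.75 - 0.25 F_dam`,
#' both known gives `0.5 - 0.25 (F_sire + F_dam)`.
#'
#' @param pedigree Sorted pedigree tibble (queen-only or two-tier).
#' @return Sparse symmetric `Matrix::dsCMatrix` of dimension `nrow(pedigree)`,
#'   rows/columns in pedigree order with the ids as dimnames.
#' @export
build_A_inverse <- function(pedigree) {
  n <- nrow(pedigree)
  s <- pedigree$sire_idx
  d <- pedigree$dam_idx
  Fv <- pedigree$F
  tri_i <- vector("list", n); tri_j <- vector("list", n); tri_x <- vector("list", n)
  for (k in seq_len(n)) {
    par <- c(s[k], d[k]); par <- par[!is.na(par)]
    mendelian <- switch(as.character(length(par)),
      "0" = 1,
      "1" = 0.75 - 0.25 * Fv[par],
      "2" = 0.5 - 0.25 * (Fv[par[1]] + Fv[par[2]]))
    a <- 1 / mendelian
    idx <- c(k, par)
    cf <- c(1, rep(-0.5, length(par)))
    # rank-one contribution a * cf cf' scattered to idx x idx; keep the
    # upper triangle once (symmetric storage holds the full-matrix value)
    ci <- rep(idx, times = length(idx))
    cj <- rep(idx, each = length(idx))
    cx <- a * rep(cf, times = length(cf)) * rep(cf, each = length(cf))
    keep <- ci <= cj
    tri_i[[k]] <- ci[keep]; tri_j[[k]] <- cj[keep]; tri_x[[k]] <- cx[keep]
  }
  Matrix::sparseMatrix(i = unlist(tri_i), j = unlist(tri_j), x = unlist(tri_x),
                       dims = c(n, n), symmetric = TRUE,
                       dimnames = list(pedigree$id, pedigree$id))
}

#' Additive relationships among selected individuals (tabular method)
#'
#' Brute-force oracle: fills the full dense A row by row with the tabular
#' recursion (`A[i,j] = (A[sire_i,j] + A[dam_i,j])/2`,
#' `A[i,i] = 1 + A[sire_i,dam_i]/2`) and returns the requested block.
#' Intended for small pedigrees (tests, spot checks); quadratic memory.
#'
#' @param pedigree Sorted pedigree tibble.
#' @param ids Character vector of ids to extract (default: all).
#' @return Dense symmetric matrix with `ids` as dimnames.
#' @export
relationship_submatrix <- function(pedigree, ids = pedigree$id) {
  n <- nrow(pedigree)
  if (n > 3000) {
    stop_beeval("Tabular oracle is dense; refusing pedigree > 3000.",
                "beeval_too_large")
  }
  unknown <- setdiff(ids, pedigree$id)
  if (length(unknown)) {
    stop_beeval(sprintf("Ids not in pedigree: %s",
                        paste(utils::head(unknown, 5), collapse = ", ")),
                "beeval_unknown_id")
  }
  s <- pedigree$sire_idx; d <- pedigree$dam_idx
  A <- matrix(0, n, n)
  at <- function(i, j) if (is.na(i) || is.na(j)) 0 else A[i, j]
  for (i in seq_len(n)) {
    if (i > 1) {
      for (j in seq_len(i - 1L)) {
        A[i, j] <- A[j, i] <- 0.5 * (at(s[i], j) + at(d[i], j))
      }
    }
    A[i, i] <- 1 + 0.5 * at(s[i], d[i])
  }
  dimnames(A) <- list(pedigree$id, pedigree$id)
  A[ids, ids, drop = FALSE]
}
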