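# shared fixtures, built in code; the larger simulations are cached per
# test run so several tests can share one dataset

toy_queen_pedigree <- function() {
  build_queen_pedigree(tibble::tibble(
    id = c("D", "Q1", "Q2"), sire = NA, dam = c(NA, "D", "D"), year = 1))
}

toy_records <- function(queens = c("Q1", "Q2"), year = 2L, apiary = "A1",
                        hy = c(10, 12)) {
  tibble::tibble(colony_id = paste0("c", seq_along(queens)),
                 queen_id = queens, apiary = apiary,
                 test_year = year,
                 year_apiary_cell = paste(year, apiary, sep = ":"),
                 honey_yield = hy, defensive = NA_integer_,
                 swarming = NA_integer_)
}

# random pedigree with known and unknown parents (oracle tests)
random_pedigree <- function(n, seed, p_dam = 0.7, p_sire = 0.5,
                            n_founders = max(5L, n %/% 6L)) {
  set.seed(seed)
  ids <- sprintf("I%04d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in (n_founders + 1L):n) {
    if (runif(1) < p_dam) dam[i] <- ids[sample.int(i - 1L, 1)]
    if (runif(1) < p_sire) sire[i] <- ids[sample.int(i - 1L, 1)]
  }
  build_queen_pedigree(tibble::tibble(id = ids, sire = sire, dam = dam,
                                      year = NA))
}

# random two-tier pedigree: maternal queens plus worker groups
random_two_tier <- function(n_queens, n_colonies, seed) {
  set.seed(seed)
  ids <- sprintf("Q%04d", seq_len(n_queens))
  dam <- rep(NA_character_, n_queens)
  nf <- max(3L, n_queens %/% 5L)
  for (i in (nf + 1L):n_queens) dam[i] <- ids[sample.int(i - 1L, 1)]
  qped <- build_queen_pedigree(tibble::tibble(id = ids, sire = NA, dam = dam,
                                              year = NA))
  rec <- tibble::tibble(colony_id = sprintf("c%04d", seq_len(n_colonies)),
                        queen_id = sample(ids, n_colonies, replace = TRUE),
                        test_year = 1L)
  list(pedigree = extend_with_worker_groups(qped, rec), records = rec,
       queen_pedigree = qped)
}

.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(key, config) {
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_colony_data(config)
  }
  .sim_cache[[key]]
}

registry_sim <- function() {
  cached_sim("registry", sim_config(seed = 20191021))
}
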