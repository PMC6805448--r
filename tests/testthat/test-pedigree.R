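test_that("queen pedigree sorts topologically and adds absent dams as founders", {
  entries <- tibble::tibble(
    id = c("B1", "B2", "B3", "K1", "K2"),
    sire = NA, dam = c(NA, NA, NA, "B1", "K1"), year = c(1, 1, 1, 2, 3))
  ped <- build_queen_pedigree(entries)
  expect_equal(nrow(ped), 5)
  pos <- match(ped$id, ped$id)
  expect_true(all(ped$dam_idx < seq_len(nrow(ped)), na.rm = TRUE))
  expect_true(which(ped$id == "B1") < which(ped$id == "K1"))
  expect_true(which(ped$id == "K1") < which(ped$id == "K2"))

  # dam referenced but not listed becomes a founder
  ped2 <- build_queen_pedigree(tibble::tibble(id = "X", sire = NA,
                                              dam = "GHOST", year = 2))
  expect_equal(nrow(ped2), 2)
  expect_true(is.na(ped2$dam[ped2$id == "GHOST"]))

  # cycles are named
  expect_error(
    build_queen_pedigree(tibble::tibble(id = c("a", "b"), sire = NA,
                                        dam = c("b", "a"), year = 1)),
    class = "beeval_pedigree_cycle")
})

test_that("large maternal pedigrees sort correctly (full-scan order check)", {
  sim <- registry_sim()
  ped <- sim$pedigree
  n <- nrow(ped)
  # brute-force scan of the topological invariant
  expect_true(all(ped$dam_idx < seq_len(n), na.rm = TRUE))
  expect_true(all(is.na(ped$sire_idx)))
  # two tiers, worker groups never act as parents
  expect_false(any(ped$dam %in% ped$id[ped$tier == "worker_group"],
                   na.rm = TRUE))
})

test_that("worker-group extension adds one entry per colony with the queen as dam", {
  tt <- random_two_tier(40, 25, seed = 2)
  expect_equal(nrow(tt$pedigree), 40 + 25)
  expect_equal(sum(tt$pedigree$tier == "worker_group"), 25)
  w <- tt$pedigree[tt$pedigree$tier == "worker_group", ]
  expect_true(all(is.na(w$sire)))
  expect_equal(w$dam, tt$records$queen_id[match(sub("^W:", "", w$id),
                                                tt$records$colony_id)])
  # queens keep their relative order
  q_before <- tt$queen_pedigree$id
  q_after <- tt$pedigree$id[tt$pedigree$tier == "queen"]
  expect_equal(q_after, q_before)
  expect_error(
    extend_with_worker_groups(tt$queen_pedigree,
                              tibble::tibble(colony_id = "cx",
                                             queen_id = "NOPE",
                                             test_year = 1)),
    class = "beeval_unknown_queen")
})

test_that("inbreeding: zero with any unknown parent, textbook and tabular otherwise", {
  # the maternal registry situation: every sire unknown -> all F exactly 0
  tt <- random_two_tier(60, 40, seed = 3)
  expect_identical(tt$pedigree$F, rep(0, 100))
  A <- relationship_submatrix(tt$pedigree)
  expect_identical(unname(diag(A)), rep(1, 100))

  # daughter of a sire-dam pair that are parent and offspring: F = 0.25
  ped <- build_queen_pedigree(tibble::tibble(
    id = c("S", "D", "X"), sire = c(NA, "S", "S"), dam = c(NA, NA, "D"),
    year = 1:3))
  expect_equal(ped$F[ped$id == "X"], 0.25)

  # random pedigree with known sires: F equals the tabular diagonal - 1
  ped50 <- random_pedigree(50, seed = 9)
  A50 <- relationship_submatrix(ped50)
  expect_equal(ped50$F, unname(diag(A50)) - 1, tolerance = 1e-12)
})

test_that("Henderson A-inverse matches the tabular oracle on random pedigrees", {
  for (seed in 1:3) {
    ped <- random_pedigree(150, seed = seed)
    A <- relationship_submatrix(ped)
    Ainv <- build_A_inverse(ped)
    expect_lt(max(abs(as.matrix(Ainv %*% A) - diag(nrow(ped)))), 1e-8)
  }
  # two-tier variant with the dam-known-only Mendelian variance rule
  tt <- random_two_tier(120, 80, seed = 5)
  A <- relationship_submatrix(tt$pedigree)
  Ainv <- build_A_inverse(tt$pedigree)
  expect_lt(max(abs(as.matrix(Ainv %*% A) - diag(200))), 1e-8)
  # trivial cases
  single <- build_queen_pedigree(tibble::tibble(id = "F0", sire = NA,
                                                dam = NA, year = 1))
  expect_equal(as.matrix(build_A_inverse(single)), matrix(1),
               ignore_attr = TRUE)
  pair <- build_queen_pedigree(tibble::tibble(id = c("D", "X"), sire = NA,
                                              dam = c(NA, "D"), year = 1:2))
  expect_equal(relationship_submatrix(pair),
               matrix(c(1, .5, .5, 1), 2, dimnames = list(c("D", "X"),
                                                          c("D", "X"))))
})

test_that("relationships among queens and worker groups follow diploid rules", {
  qp <- toy_queen_pedigree()
  rec <- toy_records()
  tt <- extend_with_worker_groups(qp, rec)
  A <- relationship_submatrix(tt)
  # maternal half-sister queens (shared dam, unknown unrelated sires)
  expect_equal(A["Q1", "Q2"], 0.25)
  # worker group vs own queen: parent-offspring
  expect_equal(A["W:c1", "Q1"], 0.5)
  # worker groups of half-sister queens
  expect_equal(A["W:c1", "W:c2"], 0.0625)
  # two worker groups of the same queen: maternal half-sib groups
  rec2 <- tibble::tibble(colony_id = c("c1", "c2"), queen_id = "Q1",
                         test_year = 2)
  A2 <- relationship_submatrix(extend_with_worker_groups(qp, rec2))
  expect_equal(A2["W:c1", "W:c2"], 0.25)

  expect_error(relationship_submatrix(tt, "nope"),
               class = "beeval_unknown_id")
})

test_that("gene-dropping realized relationships confirm the tabular values", {
  # Monte-Carlo oracle: covariance of gene-dropped values estimates A
  qp <- toy_queen_pedigree()
  tt <- extend_with_worker_groups(qp, toy_records())
  nrep <- 20000
  set.seed(42)
  vals <- replicate(nrep, simulate_breeding_values(tt, matrix(1))[, 1])
  Ahat <- stats::cov(t(vals))
  A <- relationship_submatrix(tt)
  expect_lt(max(abs(Ahat - A)), 4 * sqrt(2 / nrep) * 1.5)
  expect_lt(abs(Ahat["W:c1", "W:c2"] - 0.0625), 0.03)
})
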