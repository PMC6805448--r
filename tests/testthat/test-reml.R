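# dense GLS oracle: V = Z G Z' + R computed in full, estimates by textbook
# formulas; used to verify the sparse mixed-model machinery
dense_gls <- function(design, vc, trait = "honey_yield") {
  sys <- beeval:::trait_system(design, trait)
  W <- as.matrix(sys$W)
  y <- sys$y
  p <- length(sys$blocks$fixed)
  X <- W[, sys$blocks$fixed, drop = FALSE]
  Zlist <- lapply(sys$blocks$genetic, function(ix) W[, ix, drop = FALSE])
  A <- relationship_submatrix(design$pedigree)
  m <- length(Zlist)
  Z <- do.call(cbind, Zlist)
  G <- kronecker(as.matrix(vc$G0), A)
  V <- Z %*% G %*% t(Z) + diag(vc$R0[trait, trait], length(y))
  if (sys$include_cell) {
    Zc <- W[, sys$blocks$cell, drop = FALSE]
    V <- V + vc$sigma2_cell[[trait]] * Zc %*% t(Zc)
  }
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  u <- G %*% t(Z) %*% Vi %*% (y - X %*% beta)
  list(beta = as.numeric(beta), u = as.numeric(u))
}

test_that("BLUP equals dense GLS on small systems (both models)", {
  # model 2 toy
  qp <- toy_queen_pedigree()
  rec <- toy_records(hy = c(9, 14))
  des <- build_design(rec, qp, model_spec("model2", "honey_yield"))
  vc <- variance_components("model2", "honey_yield", 4, 0, 3)
  fit <- fit_blup(des, vc)
  oracle <- dense_gls(des, vc)
  expect_lt(max(abs(fit$fixed - oracle$beta)), 1e-8)
  expect_lt(max(abs(fit$ebv$ebv - oracle$u)), 1e-8)
  # the unphenotyped dam gets a parent-average style solution, from the
  # same equations as the dense solve
  dam_ebv <- fit$ebv$ebv[fit$ebv$id == "D"]
  expect_lt(abs(dam_ebv - oracle$u[which(des$pedigree$id == "D")]), 1e-8)
  expect_gt(abs(dam_ebv), 0)

  # model 1 toy, 3 colonies, 2x2 genetic covariance
  rec3 <- tibble::tibble(colony_id = c("c1", "c2", "c3"),
                         queen_id = c("Q1", "Q2", "Q1"),
                         apiary = "A1", test_year = 2,
                         year_apiary_cell = "2:A1",
                         honey_yield = c(8, 15, 11),
                         defensive = NA_integer_, swarming = NA_integer_)
  tt <- extend_with_worker_groups(qp, rec3)
  des1 <- build_design(rec3, tt, model_spec("model1", "honey_yield"))
  vc1 <- variance_components("model1", "honey_yield",
                             matrix(c(5, -1.5, -1.5, 2), 2), 0, 4)
  fit1 <- fit_blup(des1, vc1)
  oracle1 <- dense_gls(des1, vc1)
  expect_lt(max(abs(fit1$ebv$ebv - oracle1$u)), 1e-8)

  # larger random system against the dense oracle
  ttr <- random_two_tier(30, 40, seed = 8)
  set.seed(8)
  recr <- ttr$records
  recr$apiary <- sample(c("A1", "A2"), nrow(recr), TRUE)
  recr$test_year <- sample(1:2, nrow(recr), TRUE)
  recr$year_apiary_cell <- paste(recr$test_year, recr$apiary, sep = ":")
  recr$honey_yield <- rnorm(nrow(recr), 20, 5)
  recr$defensive <- NA_integer_; recr$swarming <- NA_integer_
  desr <- build_design(recr, ttr$pedigree, model_spec("model1", "honey_yield"))
  vcr <- variance_components("model1", "honey_yield",
                             matrix(c(6, 1, 1, 3), 2), 2, 5)
  fitr <- fit_blup(desr, vcr)
  oracler <- dense_gls(desr, vcr)
  expect_lt(max(abs(fitr$ebv$ebv - oracler$u)), 1e-8)
})

test_that("MME dimensions and the vanishing-genetic-variance limit", {
  qp <- toy_queen_pedigree()
  rec <- toy_records()
  des <- build_design(rec, qp, model_spec("model2", "honey_yield"))
  vc <- variance_components("model2", "honey_yield", 4, 0, 3)
  mme <- assemble_mme(des, vc)
  # n_fixed + genetic (cell dropped: single observed cell)
  expect_equal(nrow(mme$C), 1 + 3)
  expect_error(
    assemble_mme(des, variance_components("model2", "honey_yield", 0, 0, 3)),
    class = "beeval_singular_G")

  # sigma_q -> 0: EBVs -> 0 and fixed effects -> least squares
  vc0 <- variance_components("model2", "honey_yield", 1e-10, 0, 3)
  fit0 <- fit_blup(des, vc0)
  expect_lt(max(abs(fit0$ebv$ebv)), 1e-6)
  expect_equal(fit0$fixed, mean(rec$honey_yield), tolerance = 1e-6)
})

test_that("AI-REML matches closed-form REML on a balanced one-way design", {
  set.seed(1)
  g <- 10L; r <- 5L
  qped <- build_queen_pedigree(tibble::tibble(id = sprintf("G%02d", 1:g),
                                              sire = NA, dam = NA, year = 1))
  recs <- tibble::tibble(colony_id = sprintf("c%03d", 1:(g * r)),
                         queen_id = rep(qped$id, each = r),
                         apiary = "A1", test_year = 2,
                         year_apiary_cell = "2:A1",
                         honey_yield = rep(rnorm(g, 0, 2), each = r) +
                           rnorm(g * r, 10, 1.5),
                         defensive = NA_integer_, swarming = NA_integer_)
  des <- build_design(recs, qped, model_spec("model2", "honey_yield"))
  fit <- ai_reml(des)
  grp <- tapply(recs$honey_yield, recs$queen_id, mean)
  MSW <- sum((recs$honey_yield - grp[recs$queen_id])^2) / (g * (r - 1))
  MSB <- r * stats::var(grp)
  expect_equal(unname(fit$theta["sigma2_q"]), (MSB - MSW) / r,
               tolerance = 1e-5)
  expect_equal(unname(fit$theta["sigma2_e"]), MSW, tolerance = 1e-5)
  expect_true(fit$converged)
  # accepted steps never decrease the restricted likelihood
  expect_true(all(diff(fit$logLik) >= -1e-10))
})

test_that("REML estimates are invariant to record order", {
  sim <- cached_sim("design_smoke", sim_config(n_colonies = 500, seed = 13))
  des1 <- build_design(sim$records, sim$queen_pedigree,
                       model_spec("model2", "honey_yield"))
  set.seed(2)
  des2 <- build_design(sim$records[sample.int(nrow(sim$records)), ],
                       sim$queen_pedigree, model_spec("model2", "honey_yield"))
  f1 <- ai_reml(des1)
  f2 <- ai_reml(des2)
  expect_equal(f1$theta, f2$theta, tolerance = 1e-5)
})

test_that("zero genetic variance in truth drives the estimate to the boundary", {
  cfg <- sim_config(n_colonies = 500, seed = 17,
                    truth = variance_components("model2", "honey_yield",
                                                1e-12, 105.85, 35.98))
  sim <- simulate_colony_data(cfg)
  des <- build_design(sim$records, sim$queen_pedigree,
                      model_spec("model2", "honey_yield"))
  fit <- ai_reml(des)
  sigma2_p <- sum(fit$theta)
  expect_true(fit$boundary["sigma2_q"] ||
                fit$theta["sigma2_q"] < 0.05 * sigma2_p)
  if (fit$boundary["sigma2_q"]) expect_true(is.na(fit$se["sigma2_q"]))
})

test_that("worker-residual confounding converges rather than oscillates", {
  # one worker group per colony makes sigma_W and sigma_e weakly separable;
  # the fit must terminate cleanly (possibly at a boundary) on several seeds
  for (seed in 1:3) {
    cfg <- sim_config(n_colonies = 300, model = "model1", seed = 100 + seed)
    sim <- simulate_colony_data(cfg)
    des <- build_design(sim$records, sim$pedigree,
                        model_spec("model1", "honey_yield"))
    fit <- ai_reml(des, max_iter = 60)
    expect_true(fit$converged)
    expect_true(all(diff(fit$logLik) >= -1e-10))
    expect_true(all(fit$theta[c("sigma2_w", "sigma2_mq", "sigma2_e")] >= 0))
  }
})

test_that("delta-method and posterior ratio standard errors behave", {
  sim <- cached_sim("design_smoke", sim_config(n_colonies = 500, seed = 13))
  des <- build_design(sim$records, sim$queen_pedigree,
                      model_spec("model2", "honey_yield"))
  fit <- ai_reml(des)
  h <- standard_error_ratio(fit, c(sigma2_q = 1),
                            c(sigma2_q = 1, sigma2_cell = 1, sigma2_e = 1))
  expect_gt(h$se, 0)
  expect_equal(h$estimate,
               unname(fit$theta["sigma2_q"] / sum(fit$theta)))
  # denominator fixed, error-free numerator -> zero SE
  fit0 <- fit
  fit0$vcov <- matrix(0, 3, 3)
  h0 <- standard_error_ratio(fit0, c(sigma2_q = 1), c(sigma2_e = 1))
  expect_equal(h0$se, 0)
})
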