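make_threshold_design <- function(n = 600, seed = 31, trait = "defensive") {
  sim <- cached_sim(paste0("gibbs_", trait, "_", n, "_", seed),
                    sim_config(n_colonies = n, traits = trait, seed = seed))
  list(sim = sim,
       design = build_design(sim$records, sim$queen_pedigree,
                             model_spec("model2", trait)))
}

test_that("chains are bit-identical under the same seed and config", {
  d <- make_threshold_design()
  cfg <- gibbs_config(n_iterations = 600, seed = 77)
  ch1 <- run_threshold_gibbs(d$design, cfg)
  ch2 <- run_threshold_gibbs(d$design, cfg)
  expect_identical(ch1$samples, ch2$samples)
  expect_identical(ch1$ebv, ch2$ebv)
  ch3 <- run_threshold_gibbs(d$design, gibbs_config(n_iterations = 600,
                                                    seed = 78))
  expect_false(identical(ch1$samples, ch3$samples))
  # seed is mandatory
  expect_error(run_threshold_gibbs(d$design, gibbs_config(n_iterations = 600)),
               class = "beeval_bad_argument")
})

test_that("burn-in and thinning bookkeeping match the configuration", {
  d <- make_threshold_design()
  ch <- run_threshold_gibbs(d$design,
                            gibbs_config(n_iterations = 1000,
                                         burn_in_fraction = 0.1, seed = 5))
  expect_equal(nrow(ch$samples), 900)
  ch2 <- run_threshold_gibbs(d$design,
                             gibbs_config(n_iterations = 2000, thinning = 4,
                                          seed = 5))
  expect_equal(nrow(ch2$samples), 450)
  expect_error(
    run_threshold_gibbs(d$design, gibbs_config(n_iterations = 100, seed = 1)),
    class = "beeval_too_short")
})

test_that("threshold ordering holds at every retained iteration", {
  d <- make_threshold_design()
  ch <- run_threshold_gibbs(d$design, gibbs_config(n_iterations = 1500,
                                                   seed = 19))
  s <- ch$samples
  expect_true(all(s$t1_defensive == 0))
  expect_true(all(s$t2_defensive == 1))
  expect_true(all(s$t2_defensive < s$t3_defensive))
  expect_true(all(s$t3_defensive < s$t4_defensive))
  # residual variance is estimated (fix2 scheme), strictly positive
  expect_true(all(s$sigma2_e_defensive > 0))
})

test_that("category probabilities from posterior means sum to one", {
  d <- make_threshold_design()
  ch <- run_threshold_gibbs(d$design, gibbs_config(n_iterations = 800,
                                                   seed = 3))
  ps <- posterior_summary(ch)
  thr <- ps$mean[match(paste0("t", 1:4, "_defensive"), ps$parameter)]
  sde <- sqrt(ps$mean[ps$parameter == "sigma2_e_defensive"])
  eta <- rnorm(50, 0.5, 1.2)
  P <- category_probabilities(eta, thr, sde)
  expect_equal(rowSums(P), rep(1, 50), tolerance = 1e-12)
  expect_true(all(P >= 0))
})

test_that("empty categories and wrong trait types are rejected", {
  d <- make_threshold_design()
  rec <- d$sim$records
  rec$defensive[rec$defensive == 2] <- 3L # empty category 2
  des <- build_design(rec, d$sim$queen_pedigree,
                      model_spec("model2", "defensive"))
  expect_error(run_threshold_gibbs(des, gibbs_config(n_iterations = 500,
                                                     seed = 1)),
               class = "beeval_empty_category")
  des_hy <- build_design(d$sim$records, d$sim$queen_pedigree,
                         model_spec("model2", "honey_yield"))
  expect_error(run_threshold_gibbs(des_hy, gibbs_config(seed = 1)),
               class = "beeval_bad_argument")
})

test_that("posterior_summary: constant and iid pseudo-chains behave as expected", {
  fake <- structure(list(
    samples = tibble::tibble(sigma2_q = rep(2.5, 500),
                             sigma2_cell_honey_yield = rep(1, 500),
                             sigma2_e_honey_yield = rep(1.5, 500)),
    model = "model2", traits = "honey_yield", effects = "q",
    trait_types = "linear", n_cat = 0L, scheme = 0L),
    class = "beeval_chain")
  ps <- posterior_summary(fake)
  expect_equal(ps$mean[ps$parameter == "sigma2_q"], 2.5)
  expect_equal(ps$sd[ps$parameter == "sigma2_q"], 0)
  expect_equal(ps$mean[ps$parameter == "h2_honey_yield"], 0.5)

  set.seed(6)
  n <- 4000
  fake2 <- fake
  fake2$samples <- tibble::tibble(
    sigma2_q = rnorm(n) + 10,
    sigma2_cell_honey_yield = rep(1, n),
    sigma2_e_honey_yield = rep(1.5, n))
  ps2 <- posterior_summary(fake2)
  expect_lt(abs(ps2$mean[ps2$parameter == "sigma2_q"] - 10), 4 / sqrt(n))
  expect_lt(abs(ps2$geweke_z[ps2$parameter == "sigma2_q"]), 4)

  expect_error(posterior_summary(fake, burn_in_fraction = 0.9),
               class = "beeval_too_short")
})

test_that("location sampler with fixed variances reproduces BLUP", {
  sim <- cached_sim("design_smoke", sim_config(n_colonies = 500, seed = 13))
  des <- build_design(sim$records, sim$queen_pedigree,
                      model_spec("model2", "honey_yield"))
  vc <- sim$truth
  ch <- run_multitrait_gibbs(des, gibbs_config(n_iterations = 4000, seed = 23),
                             components = vc)
  bl <- fit_blup(des, vc)
  diff <- ch$ebv$ebv - bl$ebv$ebv
  # Monte-Carlo error of a posterior mean over ~3600 correlated draws
  expect_gt(stats::cor(ch$ebv$ebv, bl$ebv$ebv), 0.999)
  expect_lt(mean(abs(diff)), 0.15)
  # fixed variances: the chain stores them unchanged
  expect_true(all(ch$samples$sigma2_q == vc$G0["q", "q"]))
})

test_that("zero genetic variance truth concentrates the posterior near zero", {
  cfg <- sim_config(n_colonies = 800, traits = "defensive", seed = 41,
                    truth = variance_components("model2", "defensive",
                                                1e-9, 1.33, 3.24))
  sim <- simulate_colony_data(cfg)
  des <- build_design(sim$records, sim$queen_pedigree,
                      model_spec("model2", "defensive"))
  ch <- run_threshold_gibbs(des, gibbs_config(n_iterations = 4000, seed = 7))
  ps <- posterior_summary(ch)
  sp <- ps$mean[ps$parameter == "sigma2_q"] +
    ps$mean[ps$parameter == "sigma2_cell_defensive"] +
    ps$mean[ps$parameter == "sigma2_e_defensive"]
  expect_lt(ps$mean[ps$parameter == "sigma2_q"], 0.05 * sp)
})

test_that("model 1 threshold sampling keeps the 2x2 genetic block PSD-summarizable", {
  cfg <- sim_config(n_colonies = 500, model = "model1", traits = "defensive",
                    seed = 53)
  sim <- simulate_colony_data(cfg)
  des <- build_design(sim$records, sim$pedigree,
                      model_spec("model1", "defensive"))
  ch <- run_threshold_gibbs(des, gibbs_config(n_iterations = 1500, seed = 11))
  ps <- posterior_summary(ch)
  expect_true(all(c("sigma2_w", "sigma2_mq", "cov_w_mq", "r_W_MQ", "h2_C")
                  %in% ps$parameter))
  # every sampled G0 is PD, so the correlation stays inside (-1, 1)
  r <- ch$samples$cov_w_mq /
    sqrt(ch$samples$sigma2_w * ch$samples$sigma2_mq)
  expect_true(all(abs(r) < 1))
})
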