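test_that("colony variance: identity, registry values, simulation oracle", {
  expect_equal(colony_variance(12.93, 5.97, -8.38), 2.14)
  expect_equal(colony_variance(7, 0, 0), 7)
  expect_warning(colony_variance(1, 1, -2), "Negative colony variance")

  # brute force: var(w + mq) under bivariate normal draws
  set.seed(2)
  for (i in 1:3) {
    v1 <- runif(1, 1, 10); v2 <- runif(1, 1, 10)
    cv <- runif(1, -1, 1) * sqrt(v1 * v2) * 0.9
    G <- matrix(c(v1, cv, cv, v2), 2)
    x <- matrix(rnorm(2 * 2e5), ncol = 2) %*% chol(G)
    expect_equal(colony_variance(v1, v2, cv), stats::var(x[, 1] + x[, 2]),
                 tolerance = 0.05)
  }
})

test_that("phenotypic variance conventions reproduce the printed sums", {
  # queen-direct model: all conventions agree
  expect_equal(phenotypic_variance(c(sigma2_q = 50.14, sigma2_cell = 105.85,
                                     sigma2_e = 35.98)), 191.97)
  m1_hy <- c(sigma2_w = 71.12, sigma2_mq = 24.73, cov_w_mq = 0.34,
             sigma2_cell = 110.75, sigma2_e = 6.97)
  expect_equal(phenotypic_variance(m1_hy, "table"), 213.91)
  expect_equal(phenotypic_variance(m1_hy, "sum_2cov"), 214.25)
  m1_sb <- c(sigma2_w = 17.46, sigma2_mq = 8.81, cov_w_mq = -11.39,
             sigma2_cell = 1.83, sigma2_e = 0.43)
  expect_equal(phenotypic_variance(m1_sb, "abs"), 39.92)
  expect_error(phenotypic_variance(c(sigma2_q = 1, sigma2_e = 1)),
               class = "beeval_bad_argument")
})

test_that("heritability and correlation arithmetic at full precision", {
  expect_equal(round_half_up(heritability(50.14, 191.97)), 0.26)
  expect_equal(round_half_up(heritability(5.97, 12.52)), 0.48)
  expect_equal(heritability(3, 3), 1)
  expect_error(heritability(1, 0), class = "beeval_bad_argument")
  expect_warning(heritability(13, 12.52), "above 1")

  expect_equal(round_half_up(genetic_correlation(-8.38, 12.93, 5.97)), -0.95)
  expect_equal(round_half_up(genetic_correlation(-11.39, 17.46, 8.81)), -0.92)
  expect_equal(genetic_correlation(0, 3, 7), 0)
  expect_error(genetic_correlation(1, 0, 1), class = "beeval_bad_argument")
})

test_that("half-up presentation rounding differs from banker's rounding", {
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(-0.125, 2), -0.13)
  expect_equal(round_half_up(0.174999, 2), 0.17)
  expect_equal(round(0.125, 2), 0.12) # the behaviour we are avoiding
})

test_that("genetic_parameters assembles the derived table for both models", {
  vc1 <- variance_components("model1", "defensive",
                             matrix(c(12.93, -8.38, -8.38, 5.97), 2),
                             1.76, 0.24)
  gp <- genetic_parameters(vc1, convention = "table")
  get <- function(p) gp$value[gp$parameter == p]
  expect_equal(get("sigma2_C"), 2.14)
  expect_equal(get("sigma2_p"), 12.52)
  expect_equal(round_half_up(get("h2_MQ")), 0.48)
  expect_equal(round_half_up(get("h2_C")), 0.17)
  expect_equal(round_half_up(get("r_W_MQ")), -0.95)

  vc2 <- default_truth("model2", c("honey_yield", "defensive", "swarming"))
  gp2 <- genetic_parameters(vc2)
  expect_equal(round_half_up(gp2$value[gp2$parameter == "h2_Q" &
                                         gp2$trait == "honey_yield"]), 0.25)
  rg <- gp2$value[gp2$parameter == "r_G"]
  expect_equal(round_half_up(rg), c(0.19, 0.41, 0.62))
})

test_that("Gibbs-route ratio SE equals the SD of the per-iteration ratio", {
  set.seed(4)
  fake <- structure(list(
    samples = tibble::tibble(sigma2_q = rchisq(300, 10),
                             sigma2_e_honey_yield = rchisq(300, 20))),
    class = "beeval_chain")
  out <- standard_error_ratio(fake, ratio_fun = function(row)
    row$sigma2_q / (row$sigma2_q + row$sigma2_e_honey_yield))
  direct <- fake$samples$sigma2_q /
    (fake$samples$sigma2_q + fake$samples$sigma2_e_honey_yield)
  expect_equal(out$estimate, mean(direct))
  expect_equal(out$se, stats::sd(direct))
})

test_that("delta-method SE agrees with a parametric-bootstrap SE", {
  # simulate REML fits of a one-way design; bootstrap the heritability SE
  set.seed(10)
  g <- 40L; r <- 5L
  qped <- build_queen_pedigree(tibble::tibble(id = sprintf("G%02d", 1:g),
                                              sire = NA, dam = NA, year = 1))
  sim_fit <- function() {
    y <- rep(rnorm(g, 0, sqrt(2)), each = r) + rnorm(g * r, 10, sqrt(4))
    recs <- tibble::tibble(colony_id = sprintf("c%03d", 1:(g * r)),
                           queen_id = rep(qped$id, each = r), apiary = "A1",
                           test_year = 2, year_apiary_cell = "2:A1",
                           honey_yield = y, defensive = NA_integer_,
                           swarming = NA_integer_)
    des <- build_design(recs, qped, model_spec("model2", "honey_yield"))
    ai_reml(des)
  }
  fit <- sim_fit()
  delta <- standard_error_ratio(fit, c(sigma2_q = 1),
                                c(sigma2_q = 1, sigma2_e = 1))
  boots <- replicate(60, {
    f <- sim_fit()
    unname(f$theta["sigma2_q"] / sum(f$theta))
  })
  # 60 bootstrap draws leave ~10% noise on the SD itself
  expect_lt(abs(delta$se - stats::sd(boots)) / stats::sd(boots), 0.4)
})
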