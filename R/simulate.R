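#' Configuration for the synthetic breeding-program generator
#'
#' Defaults emulate the structure of the Italian queen registry data the
#' colony models were developed for: about 4000 tested colonies from about
#' 4160 queens descending from 186 base queens, right-skewed dam family
#' sizes (mean about 2.4 daughters per dam, range 1-33), 13 test years,
#' 72 tester apiaries with 207 observed year x apiary cells, skewed
#' 5-category behaviour scores (55.4% of defensive scores in category 4;
#' 88.7% of swarming scores in categories 3-5), a small trait-wise
#' missing-record rate, and true variance components equal to the
#' registry estimates. Passing a smaller `n_colonies` scales the pedigree,
#' apiary and cell counts proportionally (explicit arguments always win).
#'
#' @param n_colonies Number of tested colonies (records).
#' @param model `"model2"` (queen direct) or `"model1"` (worker + maternal).
#' @param traits Trait subset, see [model_spec()].
#' @param n_queens,n_base,n_years,n_apiaries,n_cells Pedigree and
#'   environment dimensions; defaults derived from `n_colonies`.
#' @param mean_family_size,family_dispersion,max_family_size Dam family
#'   sizes are `1 + NegBin(mu = mean - 1, size = dispersion)` resampled
#'   above the maximum.
#' @param truth Optional [variance_components()] giving the simulation
#'   truth; default: the registry single-trait estimates (or, multi-trait,
#'   genetic variances from the multi-trait heritabilities with the
#'   registry correlation structure).
#' @param mu Named trait means (kg for honey yield; liability traits are
#'   centred at 0).
#' @param fixed_sd Named per-trait standard deviation of the test-year and
#'   tester-apiary fixed effects (each factor gets this SD).
#' @param category_probs Named list of length-5 category probabilities for
#'   threshold traits.
#' @param missing_rate Named per-trait probability that a record lacks the
#'   trait.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A `beeval_sim_config` list.
#' @export
sim_config <- function(n_colonies = 3974,
                       model = c("model2", "model1"),
                       traits = "honey_yield",
                       n_queens = NULL, n_base = NULL,
                       n_years = 13L, n_apiaries = NULL, n_cells = NULL,
                       mean_family_size = 2.45,
                       family_dispersion = 0.25,
                       max_family_size = 33L,
                       truth = NULL,
                       mu = c(honey_yield = 22.64, defensive = 0,
                              swarming = 0),
                       fixed_sd = c(honey_yield = 8.4, defensive = 0.5,
                                    swarming = 0.6),
                       category_probs = list(
                         defensive = c(0.020, 0.060, 0.130, 0.554, 0.236),
                         swarming  = c(0.035, 0.078, 0.250, 0.350, 0.287)),
                       missing_rate = c(honey_yield = 0, defensive = 0.011,
                                        swarming = 0.027),
                       seed = NULL) {
  model <- match.arg(model)
  scale <- n_colonies / 3974
  n_queens <- n_queens %||% max(n_colonies, round(4160 * scale))
  n_base <- n_base %||% max(5L, round(186 * scale))
  # keep at least ~2 active apiaries per year when scaling down, so the
  # year x apiary cells never collapse onto the year main effect
  n_apiaries <- n_apiaries %||% max(4L, round(72 * scale))
  n_cells <- n_cells %||% max(2L * n_years, min(round(207 * scale),
                                                n_years * n_apiaries))
  truth <- truth %||% default_truth(model, traits)
  for (pr in category_probs) {
    stopifnot(length(pr) == 5, abs(sum(pr) - 1) < 1e-8, all(pr > 0))
  }
  structure(
    list(n_colonies = n_colonies, model = model, traits = traits,
         n_queens = n_queens, n_base = n_base, n_years = as.integer(n_years),
         n_apiaries = n_apiaries, n_cells = n_cells,
         mean_family_size = mean_family_size,
         family_dispersion = family_dispersion,
         max_family_size = max_family_size,
         truth = truth, mu = mu, fixed_sd = fixed_sd,
         category_probs = category_probs, missing_rate = missing_rate,
         seed = seed),
    class = "beeval_sim_config")
}

#' Registry-estimate truth components
#'
#' The built-in simulation truths: single-trait variance components as
#' estimated from the registry data under each model, and for the
#' multi-trait queen model genetic variances implied by the multi-trait
#' heritabilities (0.25, 0.43, 0.42) on the single-trait phenotypic
#' scales, with genetic correlations 0.19 (HY-DB), 0.41 (HY-SB) and
#' 0.62 (DB-SB).
#'
#' @param model `"model1"` or `"model2"`.
#' @param traits Trait subset.
#' @return A [variance_components()] object.
#' @export
default_truth <- function(model, traits) {
  tab2 <- list( # model 2, single trait: sigma2_q, sigma2_cell, sigma2_e
    honey_yield = c(50.14, 105.85, 35.98),
    defensive   = c(2.59, 1.33, 3.24),
    swarming    = c(4.18, 1.64, 6.35))
  tab1 <- list( # model 1: sigma2_w, sigma2_mq, cov, sigma2_cell, sigma2_e
    honey_yield = c(71.12, 24.73, 0.34, 110.75, 6.97),
    defensive   = c(12.93, 5.97, -8.38, 1.76, 0.24),
    swarming    = c(17.46, 8.81, -11.39, 1.83, 0.43))
  if (model == "model1") {
    v <- tab1[[traits[1]]]
    return(variance_components("model1", traits[1],
                               matrix(c(v[1], v[3], v[3], v[2]), 2, 2),
                               v[4], v[5]))
  }
  if (length(traits) == 1) {
    v <- tab2[[traits[1]]]
    return(variance_components("model2", traits,
                               matrix(v[1], 1, 1), v[2], v[3]))
  }
  all_tr <- c("honey_yield", "defensive", "swarming")
  h2 <- c(honey_yield = 0.25, defensive = 0.43, swarming = 0.42)
  sp <- c(honey_yield = 191.97, defensive = 7.17, swarming = 12.17)
  rg <- matrix(c(1, 0.19, 0.41,
                 0.19, 1, 0.62,
                 0.41, 0.62, 1), 3, 3, dimnames = list(all_tr, all_tr))
  g <- h2 * sp
  cell <- c(honey_yield = 105.85, defensive = 1.33, swarming = 1.64)
  G0 <- diag(sqrt(g[traits])) %*% rg[traits, traits] %*% diag(sqrt(g[traits]))
  resid <- sp[traits] - g[traits] - cell[traits]
  variance_components("model2", traits, G0, cell[traits],
                      diag(resid, nrow = length(traits)))
}

# truncated shifted negative binomial family sizes
draw_family_sizes <- function(n, mean, size, max) {
  f <- 1L + stats::rnbinom(n, mu = mean - 1, size = size)
  while (any(f > max)) {
    k <- f > max
    f[k] <- 1L + stats::rnbinom(sum(k), mu = mean - 1, size = size)
  }
  f
}

#' Simulate a registry-shaped pedigree and colony skeleton
#'
#' Generates base queens, then yearly cohorts whose dams are drawn from
#' the one or two preceding cohorts with right-skewed family sizes; every
#' sire is unknown. A subset of queens is assigned a tested colony in the
#' year after birth, spread over tester apiaries so that the configured
#' number of year x apiary cells is observed (each active apiary is
#' guaranteed at least one colony). Worker-group pseudo-individuals for
#' the tested colonies form the second pedigree tier.
#'
#' @param config A [sim_config()]; its `seed`, when non-NULL, seeds the
#'   generator so equal configs give identical pedigrees.
#' @return List: `queen_pedigree`, `pedigree` (two-tier), `skeleton`
#'   (tibble colony_id, queen_id, apiary, test_year).
#' @export
simulate_pedigree <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n_base <- config$n_base
  ids <- sprintf("Q%05d", seq_len(n_base))
  ped <- tibble(id = ids, sire = NA_character_, dam = NA_character_,
                year = 0L)
  n_cohorts <- config$n_years - 1L
  per_cohort <- ceiling((config$n_queens - n_base) / max(n_cohorts, 1L))
  counter <- n_base
  used_dam <- character(0)
  for (yr in seq_len(n_cohorts)) {
    eligible <- setdiff(ped$id[ped$year >= yr - 2L & ped$year <= yr - 1L],
                        used_dam)
    if (!length(eligible)) eligible <- setdiff(ped$id[ped$year < yr], used_dam)
    if (!length(eligible)) break
    remaining <- per_cohort
    dams_order <- sample(eligible)
    di <- 0L
    rows <- list()
    while (remaining > 0L && di < length(dams_order)) {
      di <- di + 1L
      dam <- dams_order[di]
      f <- draw_family_sizes(1L, config$mean_family_size,
                             config$family_dispersion,
                             config$max_family_size)
      new_ids <- sprintf("Q%05d", counter + seq_len(f))
      counter <- counter + f
      rows[[length(rows) + 1L]] <-
        tibble(id = new_ids, sire = NA_character_, dam = dam, year = yr)
      used_dam <- c(used_dam, dam)
      remaining <- remaining - f
    }
    ped <- dplyr::bind_rows(ped, dplyr::bind_rows(rows))
  }
  queen_ped <- build_queen_pedigree(ped)

  # tested colonies: queens are tested the year after birth, so birth
  # years 0..n_years-1 map onto test years 1..n_years
  testable <- queen_ped$id[queen_ped$year <= config$n_years - 1L]
  n_col <- min(config$n_colonies, length(testable))
  tested <- if (n_col < length(testable)) sample(testable, n_col) else testable
  test_year <- queen_ped$year[match(tested, queen_ped$id)] + 1L

  # active apiaries per test year to hit the observed-cell target
  years <- sort(unique(test_year))
  k_per_year <- table(factor(rep(years, length.out = config$n_cells),
                             levels = years))
  apiary <- character(length(tested))
  for (y in years) {
    in_y <- which(test_year == y)
    k <- min(max(1L, k_per_year[[as.character(y)]]), length(in_y),
             config$n_apiaries)
    active <- sample(sprintf("A%02d", seq_len(config$n_apiaries)), k)
    # each active apiary gets at least one colony, rest at random
    lab <- c(active, sample(active, length(in_y) - k, replace = TRUE))
    apiary[in_y] <- lab[sample.int(length(in_y))]
  }
  skeleton <- tibble(colony_id = paste0("C", tested),
                     queen_id = tested,
                     apiary = apiary,
                     test_year = test_year)
  pedigree <- extend_with_worker_groups(queen_ped, skeleton)
  list(queen_pedigree = queen_ped, pedigree = pedigree, skeleton = skeleton)
}

#' Gene-drop breeding values down a pedigree
#'
#' Founders draw from `N(0, G0)`; a non-founder with known dam and
#' unknown sire draws `a = a_dam / 2 + m` with Mendelian deviation
#' `m ~ N(0, (0.75 - 0.25 F_dam) G0)`, the variance that keeps `Var(a) =
#' G0` in an unselected population when every sire is an unrelated,
#' non-inbred base individual (the estimation model's assumption; real
#' polyandrous bee matings are not modelled). With both parents known the
#' usual `(0.5 - 0.25 (F_s + F_d)) G0` deviation applies.
#'
#' @param pedigree Sorted pedigree tibble.
#' @param G0 Genetic (co)variance matrix of the effect vector carried by
#'   each individual (scalar accepted).
#' @param seed Optional seed.
#' @return Matrix `nrow(pedigree) x ncol(G0)` of true breeding values,
#'   rows in pedigree order.
#' @export
simulate_breeding_values <- function(pedigree, G0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  G0 <- as.matrix(G0)
  m <- ncol(G0)
  n <- nrow(pedigree)
  a <- matrix(0, n, m)
  if (all(G0 == 0)) return(a)
  L <- chol(G0) # upper triangular: z %*% L has covariance G0
  s <- pedigree$sire_idx; d <- pedigree$dam_idx; Fv <- pedigree$F
  for (i in seq_len(n)) {
    known <- c(s[i], d[i]); known <- known[!is.na(known)]
    if (length(known) == 0L) {
      a[i, ] <- rnorm(m) %*% L
    } else if (length(known) == 1L) {
      a[i, ] <- 0.5 * a[known, ] +
        rnorm(m) %*% L * sqrt(0.75 - 0.25 * Fv[known])
    } else {
      a[i, ] <- 0.5 * (a[known[1], ] + a[known[2], ]) +
        rnorm(m) %*% L * sqrt(0.5 - 0.25 * (Fv[known[1]] + Fv[known[2]]))
    }
  }
  rownames(a) <- pedigree$id
  colnames(a) <- colnames(G0)
  a
}

# thresholds putting the configured category mass on a N(0, total_var) margin
category_thresholds <- function(probs, total_sd) {
  qnorm(cumsum(probs)[-length(probs)], sd = total_sd)
}

#' Simulate colony phenotypes
#'
#' Builds colony records on the skeleton: for each trait,
#' `y = mu + year + apiary + cell + genetic + residual` with the year and
#' apiary effects drawn once per level at the configured fixed-effect SD,
#' the cell effect at the truth's year x apiary variance, the genetic
#' value from the gene-dropped effects (worker + maternal sum under
#' model 1, queen value under model 2), and residuals (jointly, across
#' traits) at the truth's residual covariance. Threshold traits cut the
#' liability at thresholds placed so the marginal category probabilities
#' match the configured ones; records then lose each trait independently
#' at the configured missing rate.
#'
#' @param sim_ped Output of [simulate_pedigree()].
#' @param effects Gene-dropped values from [simulate_breeding_values()]
#'   (rows in two-tier pedigree order).
#' @param config The [sim_config()].
#' @param seed Optional seed.
#' @return List: `records` (a `beeval_records` tibble), `liabilities`
#'   (matrix of the underlying continuous values), `thresholds` (list per
#'   threshold trait).
#' @export
simulate_phenotypes <- function(sim_ped, effects, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sk <- sim_ped$skeleton
  ped <- sim_ped$pedigree
  n <- nrow(sk)
  traits <- config$traits
  vc <- config$truth
  Tn <- length(traits)

  years <- sort(unique(sk$test_year))
  apiaries <- sort(unique(sk$apiary))
  cells <- sort(unique(paste(sk$test_year, sk$apiary, sep = ":")))
  cell_of <- match(paste(sk$test_year, sk$apiary, sep = ":"), cells)
  py_of <- match(sk$test_year, years)
  ta_of <- match(sk$apiary, apiaries)

  # genetic record values per trait
  gmat <- matrix(0, n, Tn)
  if (config$model == "model1") {
    w_pos <- match(paste0("W:", sk$colony_id), ped$id)
    q_pos <- match(sk$queen_id, ped$id)
    gmat[, 1] <- effects[w_pos, "w"] + effects[q_pos, "mq"]
  } else {
    q_pos <- match(sk$queen_id, ped$id)
    gmat <- effects[q_pos, , drop = FALSE]
  }

  R0 <- as.matrix(vc$R0)
  Emat <- matrix(rnorm(n * Tn), n, Tn) %*% chol(R0)
  liab <- matrix(0, n, Tn, dimnames = list(NULL, traits))
  thresholds <- list()
  out <- sk
  for (t in seq_len(Tn)) {
    tr <- traits[t]
    fx_sd <- config$fixed_sd[[tr]]
    py_eff <- rnorm(length(years), 0, fx_sd)
    ta_eff <- rnorm(length(apiaries), 0, fx_sd)
    cl_eff <- rnorm(length(cells), 0, sqrt(vc$sigma2_cell[[tr]]))
    liab[, t] <- config$mu[[tr]] + py_eff[py_of] + ta_eff[ta_of] +
      cl_eff[cell_of] + gmat[, t] + Emat[, t]
    if (tr == "honey_yield") {
      val <- liab[, t]
    } else {
      gvar <- if (config$model == "model1") {
        colony_variance(vc$G0["w", "w"], vc$G0["mq", "mq"], vc$G0["w", "mq"])
      } else {
        vc$G0[t, t]
      }
      total_sd <- sqrt(2 * fx_sd^2 + vc$sigma2_cell[[tr]] + gvar +
                         R0[t, t])
      th <- config$mu[[tr]] + category_thresholds(config$category_probs[[tr]],
                                                  total_sd)
      thresholds[[tr]] <- th
      val <- as.integer(findInterval(liab[, t], th) + 1L)
    }
    mr <- unname(config$missing_rate[tr])
    if (is.na(mr)) mr <- 0
    miss <- runif(n) < mr
    val[miss] <- NA
    out[[tr]] <- val
  }
  for (tr in setdiff(c("honey_yield", "defensive", "swarming"), traits)) {
    out[[tr]] <- NA
  }
  out <- dplyr::mutate(out,
    year_apiary_cell = paste(.data$test_year, .data$apiary, sep = ":"))
  out <- out[, c("colony_id", "queen_id", "apiary", "test_year",
                 "year_apiary_cell", "honey_yield", "defensive", "swarming")]
  class(out) <- c("beeval_records", class(tibble()))
  list(records = out, liabilities = liab, thresholds = thresholds)
}

#' One-call synthetic dataset
#'
#' Runs [simulate_pedigree()], [simulate_breeding_values()] and
#' [simulate_phenotypes()] under a single seed.
#'
#' @param config A [sim_config()] (its `seed` is required here).
#' @return A `beeval_sim` list: `records`, `queen_pedigree`, `pedigree`,
#'   `skeleton`, `effects` (true breeding values), `liabilities`,
#'   `thresholds`, `truth`, `config`.
#' @export
simulate_colony_data <- function(config) {
  if (is.null(config$seed)) {
    stop_beeval("`config$seed` is required for a reproducible dataset.",
                "beeval_bad_argument")
  }
  set.seed(config$seed)
  cfg <- config; cfg$seed <- NULL
  sim_ped <- simulate_pedigree(cfg)
  ped_for_bv <- if (config$model == "model1") sim_ped$pedigree
                else sim_ped$queen_pedigree
  effects <- simulate_breeding_values(ped_for_bv, config$truth$G0)
  # model 2: map queen effects onto the two-tier order for convenience
  if (config$model != "model1") {
    eff_full <- matrix(0, nrow(sim_ped$pedigree), ncol(effects),
                       dimnames = list(sim_ped$pedigree$id, colnames(effects)))
    eff_full[rownames(effects), ] <- effects
    effects_two_tier <- eff_full
  } else {
    effects_two_tier <- effects
  }
  colnames(effects_two_tier) <- config$truth$effects
  ph <- simulate_phenotypes(sim_ped, effects_two_tier, cfg)
  structure(
    c(ph, sim_ped,
      list(effects = effects_two_tier, truth = config$truth, config = config)),
    class = "beeval_sim")
}
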