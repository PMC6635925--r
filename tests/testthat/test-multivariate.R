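test_that("condition_matrix symmetrizes, rounds, and lifts eigenvalues", {
  expect_equal(condition_matrix(diag(2)), diag(2))
  out <- condition_matrix(diag(c(1, 0)))
  expect_equal(diag(out), c(1, 1e-10))
  M <- matrix(c(1, 0.5 + 1e-14, 0.5, 2), 2, 2)
  out2 <- condition_matrix(M)
  expect_identical(out2, t(out2))
  # idempotent and floor-monotone over random matrices
  set.seed(31)
  for (i in 1:20) {
    p <- sample(2:6, 1)
    B <- matrix(rnorm(p * p), p)
    M <- crossprod(B) - diag(p) * 0.5    # may be indefinite
    c1 <- condition_matrix(M)
    c2 <- condition_matrix(c1)
    expect_equal(c2, c1, tolerance = 1e-9)
    expect_gte(min(eigen(c1, symmetric = TRUE)$values), 1e-11 *
                 max(abs(eigen(c1, symmetric = TRUE)$values)))
  }
  expect_error(condition_matrix(matrix(1, 2, 3)), class = "validation_error")
})

test_that("estimate_rho recovers exact proportionality constants to 1e-6", {
  set.seed(17)
  for (i in 1:100) {
    p <- sample(2:6, 1)
    cc <- sample(c(0.5, 2, 3), 1)
    B <- matrix(rnorm(p * p), p)
    A0 <- crossprod(B) + diag(p) * 0.1
    n0 <- runif(1, 5, 50)
    pair <- structure(list(g_a = A0, g_s = cc * A0,
                           ms_b = A0 * (1 + n0 * cc), df_a = 50L,
                           df_b = 1L, n0 = n0,
                           trait_names = paste0("t", 1:p)),
                      class = "g_matrix_pair")
    expect_lt(abs(estimate_rho(pair) - cc), 1e-6)
    expect_lt(abs(rho_oracle(pair) - cc), 1e-6)
  }
})

test_that("estimate_rho agrees with the closed-form Wishart maximizer", {
  set.seed(23)
  for (i in 1:20) {
    p <- sample(2:5, 1)
    A0 <- crossprod(matrix(rnorm(p * p), p)) + diag(p) * 0.1
    S <- crossprod(matrix(rnorm(p * p), p)) + diag(p) * 0.1
    n0 <- 20
    pair <- structure(list(g_a = A0, ms_b = A0 + n0 * S, g_s = S,
                           df_a = 40L, df_b = 1L, n0 = n0,
                           trait_names = paste0("t", 1:p)),
                      class = "g_matrix_pair")
    expect_equal(estimate_rho(pair), max(rho_oracle(pair), 0),
                 tolerance = 1e-6)
  }
})

test_that("rho is scale equivariant and handles edge shapes", {
  set.seed(5)
  A0 <- crossprod(matrix(rnorm(9), 3)) + diag(3) * 0.1
  pair <- structure(list(g_a = A0, ms_b = A0 * (1 + 10 * 1.7),
                         g_s = 1.7 * A0, df_a = 30L, df_b = 1L, n0 = 10,
                         trait_names = paste0("t", 1:3)),
                    class = "g_matrix_pair")
  pair_scaled <- pair
  pair_scaled$g_a <- pair$g_a * 25
  pair_scaled$ms_b <- pair$ms_b * 25
  expect_equal(estimate_rho(pair), estimate_rho(pair_scaled),
               tolerance = 1e-8)
  # p = 1: scalar ratio g_s / g_a
  pair1 <- structure(list(g_a = matrix(2), ms_b = matrix(2 * (1 + 8 * 0.6)),
                          g_s = matrix(1.2), df_a = 20L, df_b = 1L, n0 = 8,
                          trait_names = "t"),
                     class = "g_matrix_pair")
  expect_equal(estimate_rho(pair1), 1.2 / 2, tolerance = 1e-6)
  # ~zero species-level signal pushes rho to ~0
  pair0 <- pair
  pair0$ms_b <- A0 * 0.5
  expect_lt(estimate_rho(pair0), 1e-8)
})

test_that("accession matrix is mean-standardized with complete rows", {
  cfg <- fixture_config("tiny", seed = 3)
  p <- simulate_phenotypes(cfg)
  m <- accession_trait_matrix(p, c("corolla_width", "nectar_volume",
                                   "herkogamy"), transforms = c())
  expect_equal(unname(colMeans(m)), rep(1, 3))
  expect_identical(length(attr(m, "species")), nrow(m))
})

test_that("G-matrix estimation: no divergence means G_S ~ 0, and p=1 matches the ANOVA", {
  set.seed(11)
  n <- 40
  m <- matrix(rnorm(2 * n * 3), 2 * n, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  sp <- rep(c("A", "B"), each = n)
  pair <- estimate_g_matrices(m, sp)
  expect_lt(max(abs(pair$g_s)), 0.1)
  expect_equal(pair$n0, 2 * n * n / (2 * n))

  # univariate consistency with the two-level ANOVA on balanced data:
  # accession-mean MS equals the individual-level MS_A / replicates
  p <- toy_phenotypes(sp_means = c(0, 1), n_site = 2, n_acc_per_site = 4,
                      n_rep = 2, sigma_acc = 0.5, sigma_err = 0.5, seed = 9)
  vc <- qst_components(p, "y")
  am <- aggregate(value ~ accession + species, as.data.frame(p), mean)
  mm <- matrix(am$value, ncol = 1, dimnames = list(am$accession, "y"))
  pair1 <- estimate_g_matrices(mm, am$species)
  expect_equal(pair1$g_a[1, 1],
               unname(vc$ms["between_accessions"]) / 2, tolerance = 1e-9)

  expect_error(estimate_g_matrices(m[c(1, 2, 41, 42), ],
                                   sp[c(1, 2, 41, 42)]),
               class = "rank_error")
})

test_that("expected_rho reproduces the printed neutral values and its shape", {
  expect_equal(round(expected_rho(0.442, "selfing")$value, 4), 0.2466)
  expect_equal(round(expected_rho(0.390, "selfing")$value, 4), 0.2379)
  expect_equal(expected_rho(0.5, "outcrossing")$value, 0.5)
  # symmetric about 1/2, zero at the boundaries
  expect_equal(expected_rho(0.3)$value, expected_rho(0.7)$value)
  expect_equal(expected_rho(0)$value, 0)
  expect_equal(expected_rho(1)$value, 0)
  fst <- structure(list(estimator = "weir_cockerham", value = 0.442,
                        ci_low = 0.437, ci_high = 0.447, n_loci = 100L,
                        ascertainment = "all"), class = "fst_estimate")
  er <- expected_rho(fst, "selfing")
  expect_equal(round(er$ci_low, 4), round(0.437 * (1 - 0.437), 4))
  expect_lte(er$ci_low, er$value)
  expect_gte(er$ci_high, er$value)
})

test_that("rho bootstrap CI is deterministic and brackets a proportional truth", {
  p_tr <- 4
  Sig <- 0.4 * (0.3 + 0.7 * diag(p_tr))
  tr <- data.frame(name = paste0("tr", 1:p_tr), mean_1 = 10, mean_2 = 10,
                   sigma2_acc = diag(Sig), sigma2_err = 0.1)
  G_A_true <- Sig + 0.1 * diag(p_tr) / 2
  set.seed(71)
  mu <- MASS::mvrnorm(2, rep(0, p_tr), 3 * G_A_true)
  tr$mean_1 <- 10 + mu[1, ]; tr$mean_2 <- 10 + mu[2, ]
  cfg <- simulation_config(n_loci = 50, sites_per_species = c(12, 12),
                           accessions_per_species = c(30, 30),
                           traits = tr, trait_cov_acc = Sig,
                           trait_cov_err = 0.1 * diag(p_tr), seed = 6)
  ph <- simulate_phenotypes(cfg)
  ci1 <- rho_bootstrap_ci(ph, tr$name, n_boot = 120, seed = 9,
                          transforms = c())
  ci2 <- rho_bootstrap_ci(ph, tr$name, n_boot = 120, seed = 9,
                          transforms = c())
  expect_identical(attr(ci1, "boot"), attr(ci2, "boot"))
  expect_lt(ci1[1], ci1[2])
  expect_gt(ci1[2], 0.3)     # interval reaches into positive rho territory
})

test_that("multivariate test flags selection and stays quiet under proportional drift", {
  p_tr <- 5
  Sig <- 0.4 * (0.3 + 0.7 * diag(p_tr))
  G_A_true <- Sig + 0.1 * diag(p_tr) / 2
  run_once <- function(rho_true, seed) {
    set.seed(seed)
    mu <- MASS::mvrnorm(2, rep(0, p_tr), rho_true * G_A_true)
    tr <- data.frame(name = paste0("tr", 1:p_tr),
                     mean_1 = 10 + mu[1, ], mean_2 = 10 + mu[2, ],
                     sigma2_acc = diag(Sig), sigma2_err = 0.1)
    tr$mean_1 <- pmax(tr$mean_1, 0.1); tr$mean_2 <- pmax(tr$mean_2, 0.1)
    cfg <- simulation_config(n_loci = 400, target_fst = 0.44,
                             sites_per_species = c(12, 13),
                             accessions_per_species = c(31, 33),
                             traits = tr, trait_cov_acc = Sig,
                             trait_cov_err = 0.1 * diag(p_tr),
                             seed = seed + 1)
    ds <- simulate_dataset(cfg)
    multivariate_test(ds$phenotypes, ds$genotypes, tr$name,
                      cfg = analysis_config(n_boot = 150, seed = seed),
                      transforms = c())$verdict
  }
  sel <- vapply(1:5, function(s) run_once(2.0, 900 + s), character(1))
  neu <- vapply(1:5, function(s) run_once(0.2466, 950 + s), character(1))
  expect_gte(sum(sel == "nonneutral"), 4L)
  expect_gte(sum(neu == "neutral"), 4L)
})
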