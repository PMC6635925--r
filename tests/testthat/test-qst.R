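test_that("nectar and pollen derivation formulas evaluate exactly", {
  expect_equal(capillary_volume(c(0, 16, 32)), c(0, 1, 2))
  expect_error(capillary_volume(33), class = "range_error")

  expect_equal(brix_to_mgml(0), 1.3904)
  expect_equal(brix_to_mgml(10), 0.0524 * 100 + 9.6554 * 10 + 1.3904)
  expect_equal(brix_to_mgml(10), 103.1844)
  expect_equal(brix_to_mgml(30), 338.2124, tolerance = 1e-10)
  expect_error(brix_to_mgml(-1), class = "range_error")

  expect_equal(dilution_correct(100, 2.5), 200)
  expect_equal(dilution_correct(100, 5), 150)
  expect_error(dilution_correct(100, 0), class = "range_error")
  # final concentration is the mean of undiluted and corrected estimates
  expect_equal(nectar_sugar_concentration(10, 5, 2.5),
               (brix_to_mgml(10) + 2 * brix_to_mgml(5)) / 2)

  expect_equal(pollen_per_ovule(c(0, 100, 126)), c(0, 125, 157.5))
})

test_that("individual means average repeated measurements and add internode_sum", {
  df <- data.frame(
    individual = rep("i1", 6),
    species = "A", site = "s1", accession = "a1", replicate = "1",
    trait = c("corolla_width", "corolla_width", "corolla_width",
              "internode1", "internode2", "internode3"),
    value = c(14, 15, 16, 13.37, 13.35, 52.20))
  pm <- individual_means(phenotype_table(df))
  d <- as.data.frame(pm)
  expect_equal(d$value[d$trait == "corolla_width"], 15)
  expect_equal(d$value[d$trait == "internode_sum"], 78.92)
  expect_equal(d$value[d$trait == "internode1"], 13.37)   # single value kept
})

test_that("relative divergence reproduces the printed ratios", {
  expect_equal(round(relative_divergence(0.77, 3.33), 2), 0.77)
  expect_equal(round(relative_divergence(0.28, 3.35), 2), 0.92)
  expect_equal(relative_divergence(4, 4), 0)
  expect_error(relative_divergence(0, 0), class = "undefined_estimate")
})

test_that("two-level components match the balanced EMS oracle", {
  p <- toy_phenotypes(sp_means = c(0, 2), n_site = 1, n_acc_per_site = 3,
                      n_rep = 2, sigma_acc = 1, sigma_err = 0.5, seed = 7)
  vc <- qst_components(p, "y")
  d <- as.data.frame(individual_means(p))
  d <- d[d$trait == "y", ]
  oracle <- balanced_vc_oracle(d)
  expect_equal(unname(vc$sigma2_raw), unname(oracle), tolerance = 1e-10)
  # balanced-design coefficients: k_rep = reps, k_acc = accessions x reps
  expect_equal(unname(vc$k["k_rep"]), 2)
  expect_equal(unname(vc$k["k_acc"]), 6)
})

test_that("degenerate component patterns behave as specified", {
  # no accession or residual variance, species separated
  p <- toy_phenotypes(sp_means = c(0, 3), n_site = 2, n_acc_per_site = 2,
                      n_rep = 2, sigma_acc = 0, sigma_err = 0)
  vc <- qst_components(p, "y")
  expect_equal(unname(vc$sigma2["betw_acc"]), 0)
  expect_equal(unname(vc$sigma2["err"]), 0)
  expect_gt(vc$sigma2["betw_sp"], 0)
  q <- qst_star(vc)
  expect_equal(q$qst_star, 1)

  vc0 <- vc; vc0$sigma2[] <- 0
  expect_error(qst_star(vc0), class = "undefined_estimate")

  vc13 <- vc
  vc13$sigma2 <- c(betw_sp = 1.7, betw_acc = 1.7, err = 0.2)
  expect_equal(qst_star(vc13)$qst_star, 1 / 3)
  vc13$sigma2["betw_sp"] <- 0
  expect_equal(qst_star(vc13)$qst_star, 0)
})

test_that("pure noise recovers sigma2_sp ~ 0 and sigma2_err ~ 1", {
  p <- toy_phenotypes(sp_means = c(0, 0), n_site = 10, n_acc_per_site = 20,
                      n_rep = 2, sigma_acc = 0, sigma_err = 1, seed = 12)
  vc <- qst_components(p, "y")
  expect_lt(abs(vc$sigma2["err"] - 1), 0.15)
  expect_lt(vc$sigma2["betw_sp"], 0.05)
})

test_that("Qst* recovery: true value 0.5 at 200 accessions per species", {
  tr <- data.frame(name = "t1", mean_1 = 0, mean_2 = 1,
                   sigma2_acc = 0.25, sigma2_err = 0.25)
  ests <- vapply(1:10, function(s) {
    cfg <- simulation_config(n_loci = 10, sites_per_species = c(20, 20),
                             accessions_per_species = c(200, 200),
                             max_accessions_per_site = 10, replicates = 2,
                             traits = tr, seed = s)
    qst_star(qst_components(simulate_phenotypes(cfg), "t1"))$qst_star
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.5), 0.05)
})

test_that("divergence ANOVA separates clearly diverged species", {
  p <- toy_phenotypes(sp_means = c(0, 5), n_site = 3, n_acc_per_site = 3,
                      n_rep = 2, sigma_acc = 0.05, sigma_err = 0.05,
                      seed = 3)
  res <- divergence_anova(p, "y")
  expect_lt(res$p_raw, 0.001)
  expect_equal(res$df1, 1)
})

test_that("the species F test uses the site stratum and falls back to accessions", {
  p <- toy_phenotypes(sp_means = c(0, 1), n_site = 3, n_acc_per_site = 2,
                      n_rep = 2, sigma_acc = 0.3, sigma_err = 0.3, seed = 5)
  res <- divergence_anova(p, "y")
  expect_equal(res$df2, 2 * 3 - 2)          # sites minus species
  p1 <- toy_phenotypes(sp_means = c(0, 1), n_site = 1, n_acc_per_site = 4,
                       n_rep = 2, sigma_acc = 0.3, sigma_err = 0.3, seed = 5)
  res1 <- divergence_anova(p1, "y")
  expect_equal(res1$df2, 2 * 4 - 2)         # accessions minus sites
})

test_that("BH correction in divergence_table matches the hand step-up rule", {
  expect_equal(bh_oracle(c(0.01, 0.02, 0.04, 0.90)),
               c(0.04, 0.04, 0.04 * 4 / 3, 0.90))
  cfg <- fixture_config("tiny", seed = 9)
  p <- simulate_phenotypes(cfg)
  dv <- divergence_table(p)
  expect_equal(dv$p_fdr, bh_oracle(dv$p_raw))
  expect_true(all(dv$p_fdr >= dv$p_raw))
})

test_that("null divergence p-values are approximately uniform", {
  tr <- data.frame(name = "t1", mean_1 = 5, mean_2 = 5,
                   sigma2_acc = 0.4, sigma2_err = 0.6)
  pv <- vapply(1:60, function(s) {
    cfg <- simulation_config(n_loci = 10, sites_per_species = c(6, 6),
                             accessions_per_species = c(15, 15),
                             traits = tr, seed = 400 + s)
    divergence_anova(simulate_phenotypes(cfg), "t1")$p_raw
  }, numeric(1))
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
})
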