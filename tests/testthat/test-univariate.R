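# shared fixture: moderate paper-like simulation with one selected and one
# drift-scale trait
uni_fixture <- local({
  tr <- data.frame(name = c("sel", "mid"),
                   mean_1 = c(0, 0), mean_2 = c(3, 1),
                   sigma2_acc = c(0.25, 0.25), sigma2_err = c(0.25, 0.25))
  cfg <- simulation_config(n_loci = 400, target_fst = 0.44,
                           sites_per_species = c(12, 13),
                           accessions_per_species = c(31, 33),
                           replicates = 2, traits = tr, seed = 77)
  ds <- simulate_dataset(cfg)
  ds$g_all <- ascertain_snps(ds$genotypes, "all")
  ds
})

test_that("both tests are deterministic given the seed", {
  a <- standard_bootstrap_test(uni_fixture$phenotypes, uni_fixture$g_all,
                               "sel", n_boot = 25, seed = 5)
  b <- standard_bootstrap_test(uni_fixture$phenotypes, uni_fixture$g_all,
                               "sel", n_boot = 25, seed = 5)
  expect_identical(a$distribution, b$distribution)
  expect_identical(a$p_value, b$p_value)
  expect_length(a$distribution, 25L)

  pa <- parametric_bootstrap_test(uni_fixture$phenotypes, uni_fixture$g_all,
                                  "sel", n_sim = 50, seed = 5)
  pb <- parametric_bootstrap_test(uni_fixture$phenotypes, uni_fixture$g_all,
                                  "sel", n_sim = 50, seed = 5)
  expect_identical(pa$distribution, pb$distribution)
})

test_that("the bootstrap D distribution is location invariant", {
  p2 <- uni_fixture$phenotypes
  p2$value[p2$trait == "sel"] <- p2$value[p2$trait == "sel"] + 100
  a <- standard_bootstrap_test(uni_fixture$phenotypes, uni_fixture$g_all,
                               "sel", n_boot = 40, seed = 8)
  b <- standard_bootstrap_test(p2, uni_fixture$g_all, "sel",
                               n_boot = 40, seed = 8)
  expect_equal(a$observed_d, b$observed_d, tolerance = 1e-9)
  expect_equal(a$distribution, b$distribution, tolerance = 1e-9)
  expect_identical(a$p_value, b$p_value)
})

test_that("p is the empirical CDF of D at zero and selection is detected", {
  res <- standard_bootstrap_test(uni_fixture$phenotypes, uni_fixture$g_all,
                                 "sel", n_boot = 300, seed = 2)
  expect_identical(res$p_value, mean(res$distribution <= 0))
  expect_lte(res$p_value, 0.05)     # true Qst* 0.9 vs Fst 0.44
  expect_gt(res$observed_qst, res$observed_fst)
})

test_that("missing traits and bad inputs are signalled", {
  expect_error(standard_bootstrap_test(uni_fixture$phenotypes,
                                       uni_fixture$g_all, "absent",
                                       n_boot = 5, seed = 1),
               class = "validation_error")
  expect_error(parametric_bootstrap_test(uni_fixture$phenotypes,
                                         uni_fixture$g_all, "sel",
                                         n_sim = 5, seed = 1,
                                         relatedness = 0),
               class = "config_error")
})

test_that("parametric neutral mean squares respect the drift expectation", {
  res <- parametric_bootstrap_test(uni_fixture$phenotypes,
                                   uni_fixture$g_all, "mid",
                                   n_sim = 4000, seed = 3)
  expected <- neutral_sigma2_between(res$observed_fst, res$v_a)
  got <- mean(res$sim_sigma2_sp_raw)
  expect_lt(abs(got - expected) / expected, 0.15)
})

test_that("parametric p responds monotonically to effect size", {
  p_sel <- parametric_bootstrap_test(uni_fixture$phenotypes,
                                     uni_fixture$g_all, "sel",
                                     n_sim = 400, seed = 4)$p_value
  p_mid <- parametric_bootstrap_test(uni_fixture$phenotypes,
                                     uni_fixture$g_all, "mid",
                                     n_sim = 400, seed = 4)$p_value
  expect_lt(p_sel, p_mid)
})

test_that("run_trait_family produces the four-p-value report shape", {
  tab <- run_trait_family(uni_fixture$phenotypes, uni_fixture$genotypes,
                          c("sel", "mid"),
                          cfg = analysis_config(n_boot = 60, seed = 21))
  expect_identical(nrow(tab), 2L)
  expect_true(all(c("p_standard_all", "p_standard_shared",
                    "p_parametric_all", "p_parametric_shared",
                    "qst_star", "fst_all", "fst_shared") %in% names(tab)))
  # the selected trait ranks below the drift-scale trait in each column
  for (cc in c("p_standard_all", "p_standard_shared",
               "p_parametric_all", "p_parametric_shared"))
    expect_lte(tab[tab$trait == "sel", cc], tab[tab$trait == "mid", cc])
  empty <- run_trait_family(uni_fixture$phenotypes, uni_fixture$genotypes,
                            character(0),
                            cfg = analysis_config(n_boot = 10, seed = 1))
  expect_identical(nrow(empty), 0L)
})

test_that("standard bootstrap power at paper-like design", {
  # true Qst* = 0.9 vs Fst 0.44; expect p <= 0.05 in most seeds
  hits <- 0L
  for (s in 1:8) {
    tr <- data.frame(name = "sel", mean_1 = 0, mean_2 = 3,
                     sigma2_acc = 0.25, sigma2_err = 0.25)
    cfg <- simulation_config(n_loci = 300, target_fst = 0.44,
                             sites_per_species = c(12, 13),
                             accessions_per_species = c(31, 33),
                             replicates = 2, traits = tr, seed = 500 + s)
    ds <- simulate_dataset(cfg)
    res <- standard_bootstrap_test(ds$phenotypes,
                                   ascertain_snps(ds$genotypes, "all"),
                                   "sel", n_boot = 200, seed = s)
    if (res$p_value <= 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 7L)
})
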