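# Univariate Qst-Fst tests: the standard (accession-resampling) bootstrap
# and the parametric (chi-square mean-square) bootstrap of the neutral
# D = Qst - Fst distribution.

new_qstfst_test <- function(trait, qst, fst, d, dist, p, method, n_iter,
                            seed, estimator, ascertainment, extra = list()) {
  structure(c(list(trait = trait, observed_qst = qst, observed_fst = fst,
                   observed_d = d, distribution = dist, p_value = p,
                   method = method, n_iter = n_iter, seed = seed,
                   estimator = estimator, ascertainment = ascertainment),
              extra),
            class = "qstfst_test")
}

#' @export
print.qstfst_test <- function(x, ...) {
  cat(sprintf("%s test, trait '%s'%s\n", x$method, x$trait,
              if (!is.na(x$ascertainment))
                paste0(" (", x$ascertainment, " SNPs)") else ""))
  cat(sprintf("  Qst* = %.3f, Fst = %.3f, D = %.3f, p = %.4g (%d iterations)\n",
              x$observed_qst, x$observed_fst, x$observed_d, x$p_value,
              x$n_iter))
  invisible(x)
}

#' Standard bootstrap Qst-Fst test
#'
#' Resamples accessions (the maternal family, the replicated genetic unit)
#' within each species with replacement; each draw determines both the
#' phenotype rows (all replicates of the chosen accessions, with repeated
#' draws kept as distinct pseudo-accessions) and the genotyped individuals
#' (chosen accessions' selfed offspring, entering the Fst estimate with
#' their draw multiplicity). Qst*, Fst and D = Qst* - Fst are recomputed
#' for each resample; the p value is the proportion of bootstrap D values
#' that are <= 0.
#'
#' @param p a \code{phenotype_table}.
#' @param g a \code{genotype_matrix} (after ascertainment); its individual
#'   ids are accession ids, which is how the two tables are linked.
#' @param trait trait name.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @param transform optional transform applied to trait values.
#' @param joint if \code{TRUE} (default) one accession draw per species
#'   drives both tables, using the union of phenotyped and genotyped
#'   accession ids; if \code{FALSE} each table is resampled over its own
#'   accession list (for datasets whose identifiers do not overlap at all).
#' @param max_missing_calls per-locus missing-call cap for Fst.
#' @param estimator Fst estimator.
#' @param p_floor if \code{TRUE}, report max(count, 1)/n_boot instead of a
#'   possibly zero raw proportion.
#' @return a \code{qstfst_test} result.
#' @export
standard_bootstrap_test <- function(p, g, trait, n_boot = 1000L, seed = 1L,
                                    transform = NULL, joint = TRUE,
                                    max_missing_calls = 1L,
                                    estimator = c("weir_cockerham",
                                                  "hudson"),
                                    p_floor = FALSE) {
  estimator <- match.arg(estimator)
  validate_genotype_matrix(g)
  pm <- individual_means(p)
  d <- trait_values(pm, trait, transform)
  sp_levels <- levels(g$species)
  if (!setequal(unique(d$species), sp_levels))
    qfk_stop("phenotype and genotype species labels disagree",
             "validation_error")
  ss <- geno_suffstats(g)
  vc_obs <- two_level_components(d$value, match(d$species, sp_levels),
                                 match(d$accession, unique(d$accession)))
  qst_obs <- qst_star(vc_obs)$qst_star
  fst_obs <- fst_point(g, estimator, max_missing_calls, ss = ss)
  d_obs <- qst_obs - fst_obs

  pheno_rows <- split(seq_len(nrow(d)), d$accession)
  geno_row <- setNames(seq_along(g$individual_ids), g$individual_ids)
  pools <- lapply(sp_levels, function(s) {
    ph <- unique(d$accession[d$species == s])
    ge <- g$individual_ids[g$species == s]
    if (joint) union(ph, ge) else list(pheno = ph, geno = ge)
  })
  names(pools) <- sp_levels

  one_rep <- function() {
    draw <- lapply(sp_levels, function(s) {
      pool <- pools[[s]]
      if (joint) sample(pool, length(pool), replace = TRUE)
      else list(pheno = sample(pool$pheno, length(pool$pheno), TRUE),
                geno = sample(pool$geno, length(pool$geno), TRUE))
    })
    ph_draw <- if (joint) draw else lapply(draw, `[[`, "pheno")
    ge_draw <- if (joint) draw else lapply(draw, `[[`, "geno")
    # phenotype side: repeats become distinct pseudo-accessions
    acc_codes <- integer(0); rows <- integer(0); code <- 0L
    for (s in seq_along(sp_levels)) {
      for (a in ph_draw[[s]]) {
        idx <- pheno_rows[[a]]
        if (is.null(idx)) next
        code <- code + 1L
        rows <- c(rows, idx)
        acc_codes <- c(acc_codes, rep(code, length(idx)))
      }
    }
    n_acc_sp <- tapply(acc_codes, d$species[rows], function(z)
      length(unique(z)))
    if (length(n_acc_sp) < 2L || any(n_acc_sp < 2L)) return(NULL)
    # genotype side: draw multiplicities as weights
    w <- numeric(length(geno_row))
    for (s in seq_along(sp_levels)) {
      tb <- table(ge_draw[[s]][ge_draw[[s]] %in% names(geno_row)])
      w[geno_row[names(tb)]] <- as.numeric(tb)
    }
    if (any(tapply(w, g$species, sum) == 0)) return(NULL)
    vc <- two_level_components(d$value[rows],
                               match(d$species[rows], sp_levels), acc_codes)
    qst_b <- tryCatch(qst_star(vc)$qst_star, qstfstkit_error = function(e) 0)
    fst_b <- tryCatch(fst_point(g, estimator, max_missing_calls, w = w,
                                ss = ss),
                      qstfstkit_error = function(e) NULL)
    if (is.null(fst_b)) return(NULL)
    qst_b - fst_b
  }

  redraws <- 0L
  dist <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    repeat {
      val <- one_rep()
      if (!is.null(val)) return(val)
      redraws <<- redraws + 1L
      if (redraws > 50L * n_boot)
        qfk_stop("standard bootstrap: too many degenerate resamples",
                 "bootstrap_error")
    }
  }, numeric(1)))
  if (redraws > 0L)
    qfk_log(sprintf("standard bootstrap: %d degenerate resample(s) redrawn",
                    redraws))
  cnt <- sum(dist <= 0)
  pval <- if (p_floor) max(cnt, 1L) / n_boot else cnt / n_boot
  new_qstfst_test(trait, qst_obs, fst_obs, d_obs, dist, pval,
                  "standard_bootstrap", n_boot, seed, estimator,
                  attr(g, "ascertainment") %||% NA_character_,
                  extra = list(redraws = redraws))
}

#' Parametric bootstrap Qst-Fst test
#'
#' Simulates the neutral distribution of D = Qst - Fst. Each iteration (i)
#' resamples Fst by bootstrapping loci; (ii) sets the neutral
#' between-species variance to 2 Fst V_A / (1 - Fst), with V_A estimated
#' from the observed between-accession component divided by the
#' dam-offspring relatedness (1 for selfed offspring, so V_A is really V_G
#' and the test is conservative); (iii) draws the three nested mean squares
#' from chi-square distributions scaled by their neutral expectations
#' (between-species df = 1, which dominates the test's low power with two
#' groups) and reassembles a simulated Qst*. The p value is the proportion
#' of neutral D values >= the observed D.
#'
#' @inheritParams standard_bootstrap_test
#' @param n_sim neutral simulations.
#' @param relatedness dam-offspring relatedness in (0, 1]; 1 for selfed
#'   offspring.
#' @return a \code{qstfst_test} result.
#' @export
parametric_bootstrap_test <- function(p, g, trait, n_sim = 1000L, seed = 1L,
                                      relatedness = 1,
                                      transform = NULL,
                                      max_missing_calls = 1L,
                                      estimator = c("weir_cockerham",
                                                    "hudson"),
                                      p_floor = FALSE) {
  estimator <- match.arg(estimator)
  if (relatedness <= 0 || relatedness > 1)
    qfk_stop("relatedness must lie in (0, 1]", "config_error")
  validate_genotype_matrix(g)
  vc <- qst_components(p, trait, transform = transform)
  qst_obs <- qst_star(vc)$qst_star
  ss <- geno_suffstats(g)
  lt <- fst_locus_terms(ss, estimator, max_missing_calls = max_missing_calls)
  num <- lt$num[lt$valid]; den <- lt$den[lt$valid]
  if (!length(num) || sum(den) <= 0)
    qfk_stop("Fst undefined: no usable loci", "undefined_estimate")
  fst_obs <- sum(num) / sum(den)
  d_obs <- qst_obs - fst_obs
  v_a <- unname(vc$sigma2["betw_acc"]) / relatedness
  if (v_a <= 0)
    qfk_stop("parametric bootstrap undefined: estimated V_A is not positive",
             "undefined_estimate")
  s2_err <- unname(vc$sigma2["err"])
  s2_acc <- unname(vc$sigma2["betw_acc"])
  k <- vc$k
  df_b <- unname(vc$df["between_species"])
  df_a <- unname(vc$df["between_accessions"])
  df_w <- unname(vc$df["within"])
  L <- length(num)
  dist <- with_seed(seed, {
    fst_i <- vapply(seq_len(n_sim), function(i) {
      idx <- sample.int(L, L, replace = TRUE)
      sum(num[idx]) / sum(den[idx])
    }, numeric(1))
    fst_eq3 <- pmin(pmax(fst_i, 0), 1 - 1e-9)
    s2_sp_neutral <- neutral_sigma2_between(fst_eq3, v_a)
    ms_w <- s2_err * rchisq(n_sim, df_w) / df_w
    ms_a <- (s2_err + k["k_rep"] * s2_acc) * rchisq(n_sim, df_a) / df_a
    ms_b <- (s2_err + k["k_rep_b"] * s2_acc + k["k_acc"] * s2_sp_neutral) *
      rchisq(n_sim, df_b) / df_b
    s2_acc_raw_i <- (ms_a - ms_w) / k["k_rep"]
    s2_sp_raw_i <- (ms_b - ms_w - k["k_rep_b"] * s2_acc_raw_i) / k["k_acc"]
    s2_acc_i <- pmax(s2_acc_raw_i, 0)
    s2_sp_i <- pmax((ms_b - ms_w - k["k_rep_b"] * s2_acc_i) / k["k_acc"], 0)
    tot <- s2_sp_i + 2 * s2_acc_i
    qst_i <- ifelse(tot > 0, s2_sp_i / tot, 0)
    out <- qst_i - fst_i
    attr(out, "sim_sigma2_sp_raw") <- s2_sp_raw_i
    out
  })
  sim_sp <- attr(dist, "sim_sigma2_sp_raw")
  dist <- as.vector(dist)
  cnt <- sum(dist >= d_obs)
  pval <- if (p_floor) max(cnt, 1L) / n_sim else cnt / n_sim
  new_qstfst_test(trait, qst_obs, fst_obs, d_obs, dist, pval,
                  "parametric_bootstrap", n_sim, seed, estimator,
                  attr(g, "ascertainment") %||% NA_character_,
                  extra = list(v_a = v_a, relatedness = relatedness,
                               sim_sigma2_sp_raw = sim_sp))
}

#' Run the univariate Qst-Fst tests over a trait family
#'
#' Both tests, under both SNP ascertainments, for every listed trait; the
#' result mirrors the study's univariate report: one row per trait with
#' four p-value columns (method x ascertainment) plus the observed Qst* and
#' the two Fst estimates.
#'
#' @param p a \code{phenotype_table}.
#' @param g an unascertained \code{genotype_matrix}.
#' @param traits character vector of traits to test.
#' @param cfg an \code{\link{analysis_config}}.
#' @param methods subset of \code{c("standard", "parametric")}.
#' @param ascertainments subset of \code{c("all", "shared")}.
#' @param transforms named per-trait transform vector.
#' @return a data frame with class \code{qstfst_table}; the full
#'   \code{qstfst_test} objects sit in \code{attr(, "tests")}.
#' @export
run_trait_family <- function(p, g, traits, cfg = analysis_config(),
                             methods = c("standard", "parametric"),
                             ascertainments = c("all", "shared"),
                             transforms = default_transforms) {
  g_asc <- lapply(setNames(ascertainments, ascertainments),
                  function(a) ascertain_snps(g, a))
  tests <- list()
  rows <- lapply(seq_along(traits), function(i) {
    tr <- traits[i]
    trans <- if (tr %in% names(transforms)) transforms[[tr]] else NULL
    row <- list(trait = tr)
    for (a in ascertainments) {
      for (m in methods) {
        seed_i <- cfg$seed + 101L * i + 13L * match(a, c("all", "shared")) +
          7L * match(m, c("standard", "parametric"))
        res <- if (m == "standard")
          standard_bootstrap_test(p, g_asc[[a]], tr, n_boot = cfg$n_boot,
                                  seed = seed_i, transform = trans,
                                  max_missing_calls = max(1L, floor(
                                    nrow(g$geno) * (1 - cfg$call_rate_floor))))
        else
          parametric_bootstrap_test(p, g_asc[[a]], tr, n_sim = cfg$n_boot,
                                    seed = seed_i, transform = trans)
        tests[[paste(tr, m, a, sep = ".")]] <<- res
        row[[paste0("p_", m, "_", a)]] <- res$p_value
        row[["qst_star"]] <- res$observed_qst
        row[[paste0("fst_", a)]] <- res$observed_fst
      }
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(trait = character(0))
  attr(out, "tests") <- tests
  class(out) <- c("qstfst_table", "data.frame")
  out
}
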