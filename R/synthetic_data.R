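# Synthetic genotype + phenotype generator. Genotypes follow the
# Balding-Nichols model (per-species allele frequencies beta-distributed
# around an ancestral frequency, with Fst as the direct dispersion
# parameter) with within-species inbreeding; phenotypes follow the nested
# species / site / accession / replicate effects model that the Qst
# machinery assumes, so true Qst* is known in closed form.

#' Simulation configuration
#'
#' Defines a two-species study: the sampling design (sites per species,
#' accessions allocated over sites, selfed-offspring replicates), the
#' genotype model (number of biallelic loci, target between-species Fst,
#' ancestral allele-frequency Beta, per-species inbreeding coefficients),
#' and the trait model (per-species means, between-accession variance,
#' residual variance for each trait).
#'
#' @param n_loci number of biallelic SNP loci.
#' @param target_fst Balding-Nichols dispersion parameter, in (0, 1); the
#'   realized multi-locus Fst converges to it.
#' @param ancestral_beta length-2 shape parameters of the ancestral
#'   allele-frequency Beta distribution.
#' @param f_is length-2 within-species inbreeding coefficients (one per
#'   species); heterozygote probability is 2p(1-p)(1-f).
#' @param species length-2 species labels.
#' @param sites_per_species length-2 number of collection sites.
#' @param accessions_per_species length-2 number of maternal accessions,
#'   spread as evenly as possible over sites subject to
#'   \code{max_accessions_per_site}.
#' @param max_accessions_per_site cap per site.
#' @param replicates phenotyped selfed offspring per accession.
#' @param genotyped_per_accession genotyped selfed offspring per accession
#'   (0 or 1; the genotyped individual carries the accession id).
#' @param ungenotyped_accessions length-2 count of accessions (taken from the
#'   end of each species' list) phenotyped but not genotyped.
#' @param traits data frame with columns \code{name}, \code{mean_1},
#'   \code{mean_2}, \code{sigma2_acc}, \code{sigma2_err}.
#' @param trait_cov_acc optional p x p accession-effect covariance matrix
#'   across traits (defaults to \code{diag(traits$sigma2_acc)}).
#' @param trait_cov_err optional p x p residual covariance matrix.
#' @param site_sd standard deviation of site effects (default 0: the study
#'   design found no detectable within-species site differentiation).
#' @param non_flowering_rate probability an individual never flowers, in
#'   which case its floral-trait rows are absent.
#' @param round_herkogamy round simulated herkogamy to integers in 0..5
#'   (off by default; rounding breaks exact variance-component recovery).
#' @param missing_rate per-call genotype missingness probability.
#' @param seed integer seed.
#' @return a \code{simulation_config} list.
#' @export
simulation_config <- function(n_loci = 1000L, target_fst = 0.44,
                              ancestral_beta = c(0.8, 0.8),
                              f_is = c(0.95, 0.67),
                              species = c("lacunosa", "cordatotriloba"),
                              sites_per_species = c(12L, 13L),
                              accessions_per_species = c(31L, 33L),
                              max_accessions_per_site = 3L,
                              replicates = 2L,
                              genotyped_per_accession = 1L,
                              ungenotyped_accessions = c(0L, 0L),
                              traits = default_traits(),
                              trait_cov_acc = NULL, trait_cov_err = NULL,
                              site_sd = 0, non_flowering_rate = 0,
                              round_herkogamy = FALSE,
                              missing_rate = 0, seed = 1L) {
  if (target_fst <= 0 || target_fst >= 1)
    qfk_stop("target_fst must lie strictly in (0, 1)", "config_error")
  if (any(f_is < 0 | f_is > 1))
    qfk_stop("f_is must lie in [0, 1]", "config_error")
  if (any(traits$sigma2_acc < 0) || any(traits$sigma2_err < 0))
    qfk_stop("trait variances must be >= 0", "config_error")
  if (any(c(sites_per_species, accessions_per_species, replicates) < 1L))
    qfk_stop("design counts must be >= 1", "config_error")
  if (any(accessions_per_species >
          sites_per_species * max_accessions_per_site))
    qfk_stop("accessions_per_species exceeds site capacity", "config_error")
  structure(list(
    n_loci = as.integer(n_loci), target_fst = target_fst,
    ancestral_beta = ancestral_beta, f_is = f_is, species = species,
    sites_per_species = as.integer(sites_per_species),
    accessions_per_species = as.integer(accessions_per_species),
    max_accessions_per_site = as.integer(max_accessions_per_site),
    replicates = as.integer(replicates),
    genotyped_per_accession = as.integer(genotyped_per_accession),
    ungenotyped_accessions = as.integer(ungenotyped_accessions),
    traits = traits, trait_cov_acc = trait_cov_acc,
    trait_cov_err = trait_cov_err, site_sd = site_sd,
    non_flowering_rate = non_flowering_rate,
    round_herkogamy = round_herkogamy,
    missing_rate = missing_rate, seed = as.integer(seed)),
    class = "simulation_config")
}

#' Between-accession variance implied by a target Qst*
#'
#' Inverts Qst* = s2_sp / (s2_sp + 2 s2_acc) with
#' s2_sp = (m1 - m2)^2 / 2 (the variance of the two species means about
#' their grand mean), so trait rows can be parameterized by printed species
#' means and a target Qst*.
#'
#' @param mean_1,mean_2 species trait means.
#' @param qst target Qst* in (0, 1).
#' @return the between-accession variance component.
#' @export
sigma2_acc_for_qst <- function(mean_1, mean_2, qst) {
  if (any(qst <= 0 | qst >= 1))
    qfk_stop("qst must lie strictly in (0, 1)", "config_error")
  s2_sp <- (mean_1 - mean_2)^2 / 2
  s2_sp * (1 - qst) / (2 * qst)
}

#' Neutral between-species variance for a given Fst
#'
#' The drift expectation sigma2_BetwSp = 2 Fst V_A / (1 - Fst): under
#' neutral divergence the between-group variance of a trait scales with the
#' neutral-marker differentiation. Used to generate drift-null traits and
#' inside the parametric bootstrap.
#'
#' @param fst neutral differentiation in [0, 1).
#' @param v_a additive genetic variance (here approximated from the
#'   between-accession component).
#' @return the neutral between-species variance component.
#' @export
neutral_sigma2_between <- function(fst, v_a) {
  if (any(fst < 0 | fst >= 1)) qfk_stop("fst must lie in [0, 1)", "config_error")
  2 * fst * v_a / (1 - fst)
}

#' Default trait panel emulating the study's Table-1 regime
#'
#' Eleven diverged traits with per-species means matching the printed trait
#' means and between-accession variances back-solved from the printed Qst
#' values (so the simulated Qst* spectrum spans ~0.35-0.9); residual
#' variance is set equal to the between-accession variance.
#'
#' @return a traits data frame for \code{simulation_config}.
#' @export
default_traits <- function() {
  tt <- data.frame(
    name = c("internode1", "internode2", "internode3", "flowers_per_day",
             "inflorescence_length", "corolla_length", "corolla_width",
             "nectar_volume", "nectar_concentration", "pollen_per_ovule",
             "herkogamy"),
    mean_1 = c(13.37, 13.35, 52.20, 4.09, 9.59, 20.00, 15.09, 0.77,
               228.06, 157.79, 0.28),
    mean_2 = c(5.67, 6.22, 20.80, 1.87, 19.85, 32.09, 34.44, 3.33,
               361.40, 213.00, 3.35),
    qst = c(0.738, 0.537, 0.559, 0.671, 0.355, 0.837, 0.892, 0.753,
            0.824, 0.400, 0.766))
  tt$sigma2_acc <- sigma2_acc_for_qst(tt$mean_1, tt$mean_2, tt$qst)
  tt$sigma2_err <- tt$sigma2_acc
  tt[, c("name", "mean_1", "mean_2", "sigma2_acc", "sigma2_err")]
}

#' Named fixture configurations
#'
#' \code{"paper_like"} reproduces the study dimensions: 12 + 13 sites, 31 +
#' 33 accessions (at most 3 per site), 2 phenotyped selfed offspring per
#' accession, one genotyped offspring for all but 3 accessions (61
#' genotyped individuals), high within-species homozygosity and
#' between-species Fst 0.44 at many loci, plus a non-flowering rate that
#' brings the flowering count near 114. \code{"tiny"} is a fast balanced
#' design for examples and smoke tests.
#'
#' @param name \code{"paper_like"} or \code{"tiny"}.
#' @param seed integer seed.
#' @return a \code{simulation_config}.
#' @export
fixture_config <- function(name = c("paper_like", "tiny"), seed = 1L) {
  name <- match.arg(name)
  if (name == "paper_like") {
    simulation_config(
      n_loci = 5000L, target_fst = 0.44, f_is = c(0.95, 0.67),
      sites_per_species = c(12L, 13L), accessions_per_species = c(31L, 33L),
      replicates = 2L, ungenotyped_accessions = c(0L, 3L),
      non_flowering_rate = 0.11, missing_rate = 0.003, seed = seed)
  } else {
    tr <- data.frame(name = c("corolla_width", "nectar_volume", "herkogamy"),
                     mean_1 = c(15, 0.8, 0.3), mean_2 = c(34, 3.3, 3.3),
                     sigma2_acc = c(8, 0.3, 0.5),
                     sigma2_err = c(4, 0.2, 0.5))
    simulation_config(
      n_loci = 200L, target_fst = 0.44, sites_per_species = c(2L, 2L),
      accessions_per_species = c(6L, 6L), replicates = 2L, traits = tr,
      seed = seed)
  }
}

# Accession-level design table shared by both simulators.
design_table <- function(cfg) {
  out <- lapply(1:2, function(s) {
    n_sites <- cfg$sites_per_species[s]
    n_acc <- cfg$accessions_per_species[s]
    base <- n_acc %/% n_sites
    extra <- n_acc %% n_sites
    per_site <- rep(base, n_sites) + c(rep(1L, extra),
                                       rep(0L, n_sites - extra))
    sp <- cfg$species[s]
    site <- rep(sprintf("%s_site%02d", sp, seq_len(n_sites)), per_site)
    acc_in_site <- unlist(lapply(per_site, seq_len))
    acc <- sprintf("%s_a%d", site, acc_in_site)
    genotyped <- rep(cfg$genotyped_per_accession > 0L, n_acc)
    if (cfg$ungenotyped_accessions[s] > 0L) {
      drop <- seq(n_acc - cfg$ungenotyped_accessions[s] + 1L, n_acc)
      genotyped[drop] <- FALSE
    }
    data.frame(species = sp, site = site, accession = acc,
               genotyped = genotyped, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# One Balding-Nichols locus set for all genotyped individuals; loci
# monomorphic in both sampled species are redrawn so every locus passes the
# "all" ascertainment filter.
#' Simulate genotypes under the Balding-Nichols model
#'
#' For each locus an ancestral frequency p is drawn from the configured
#' Beta; each species' frequency from Beta(p(1-F)/F, (1-p)(1-F)/F) with
#' F = \code{target_fst}; individual genotypes with heterozygote probability
#' 2 p_s (1 - p_s)(1 - f_is). One selfed offspring per accession is
#' genotyped (minus any configured ungenotyped accessions) and carries the
#' accession id, which is what links genotypes to phenotypes downstream.
#'
#' @param cfg a \code{simulation_config}.
#' @return a \code{genotype_matrix}.
#' @export
simulate_genotypes <- function(cfg) {
  des <- design_table(cfg)
  des <- des[des$genotyped, , drop = FALSE]
  n <- nrow(des)
  sp_idx <- match(des$species, cfg$species)
  with_seed(cfg$seed, {
    draw_block <- function(n_loci) {
      p0 <- rbeta(n_loci, cfg$ancestral_beta[1], cfg$ancestral_beta[2])
      FF <- cfg$target_fst
      ps <- matrix(0, n_loci, 2)
      for (s in 1:2)
        ps[, s] <- rbeta(n_loci, p0 * (1 - FF) / FF,
                         (1 - p0) * (1 - FF) / FF)
      # genotype draw per individual x locus from the inbreeding trinomial
      p_ind <- t(ps[, sp_idx, drop = FALSE])        # n x n_loci
      f_ind <- cfg$f_is[sp_idx]
      p_het <- 2 * p_ind * (1 - p_ind) * (1 - f_ind)
      p_alt <- p_ind^2 + f_ind * p_ind * (1 - p_ind)
      u <- matrix(runif(n * n_loci), n, n_loci)
      gmat <- (u < p_alt) * 2L + (u >= p_alt & u < p_alt + p_het) * 1L
      storage.mode(gmat) <- "integer"
      gmat
    }
    poly_in_some_species <- function(gmat) {
      ok <- rep(FALSE, ncol(gmat))
      for (s in 1:2) {
        sub <- gmat[sp_idx == s, , drop = FALSE]
        ok <- ok | (col_polymorphic(sub))
      }
      ok
    }
    gmat <- draw_block(cfg$n_loci)
    keep <- poly_in_some_species(gmat)
    tries <- 0L
    while (any(!keep) && tries < 100L) {
      redraw <- draw_block(sum(!keep))
      gmat[, !keep] <- redraw
      keep[!keep] <- poly_in_some_species(redraw)
      tries <- tries + 1L
    }
    if (any(!keep))
      qfk_log(sprintf("%d locus/loci remained monomorphic after redraws",
                      sum(!keep)))
    if (cfg$missing_rate > 0) {
      miss <- matrix(runif(length(gmat)) < cfg$missing_rate,
                     nrow(gmat), ncol(gmat))
      gmat[miss] <- NA_integer_
    }
    genotype_matrix(gmat, des$species, individual_ids = des$accession,
                    locus_ids = sprintf("snp%05d", seq_len(ncol(gmat))))
  })
}

# polymorphic = more than one distinct non-missing genotype value, or any het
col_polymorphic <- function(m) {
  if (nrow(m) == 0L) return(rep(FALSE, ncol(m)))
  mx <- suppressWarnings(apply(m, 2, max, na.rm = TRUE))
  mn <- suppressWarnings(apply(m, 2, min, na.rm = TRUE))
  res <- is.finite(mx) & is.finite(mn) & (mx != mn | mx == 1L)
  res
}

floral_traits <- c("flowers_per_day", "flowers_on_inflorescence",
                   "inflorescence_length", "corolla_length", "corolla_width",
                   "nectar_volume", "nectar_concentration",
                   "pollen_per_ovule", "herkogamy", "sepal_length")

#' Simulate phenotypes in the nested design
#'
#' Each individual value is species mean + site effect + accession effect +
#' residual, with accession effects drawn (optionally with cross-trait
#' covariance) from N(0, sigma2_acc) and residuals from N(0, sigma2_err).
#' The implied Qst* is s2_sp / (s2_sp + 2 sigma2_acc) with
#' s2_sp = (mean_1 - mean_2)^2 / 2, so parameter-recovery tests have a
#' closed-form truth. Non-flowering individuals lose their floral rows.
#'
#' @param cfg a \code{simulation_config}.
#' @return a \code{phenotype_table}.
#' @export
simulate_phenotypes <- function(cfg) {
  des <- design_table(cfg)
  tr <- cfg$traits
  p <- nrow(tr)
  Sig_a <- cfg$trait_cov_acc %||% diag(tr$sigma2_acc, p)
  Sig_e <- cfg$trait_cov_err %||% diag(tr$sigma2_err, p)
  n_acc <- nrow(des)
  n_ind <- n_acc * cfg$replicates
  with_seed(cfg$seed + 1L, {
    acc_eff <- MASS::mvrnorm(n_acc, rep(0, p), Sig_a)
    site_names <- unique(des$site)
    site_eff <- matrix(rnorm(length(site_names) * p, 0, cfg$site_sd),
                       length(site_names), p,
                       dimnames = list(site_names, NULL))
    res_eff <- MASS::mvrnorm(n_ind, rep(0, p), Sig_e)
    dim(acc_eff) <- c(n_acc, p)
    rows <- vector("list", n_ind)
    flowering <- runif(n_ind) >= cfg$non_flowering_rate
    k <- 0L
    for (a in seq_len(n_acc)) {
      sp_i <- match(des$species[a], cfg$species)
      mu <- if (sp_i == 1) tr$mean_1 else tr$mean_2
      for (r in seq_len(cfg$replicates)) {
        k <- k + 1L
        val <- mu + site_eff[des$site[a], ] + acc_eff[a, ] + res_eff[k, ]
        names(val) <- tr$name
        if (cfg$round_herkogamy && "herkogamy" %in% tr$name)
          val["herkogamy"] <- pmin(5, pmax(0, round(val["herkogamy"])))
        keep <- if (flowering[k]) rep(TRUE, p) else !(tr$name %in% floral_traits)
        if (!any(keep)) next
        rows[[k]] <- data.frame(
          individual = sprintf("%s_r%d", des$accession[a], r),
          species = des$species[a], site = des$site[a],
          accession = des$accession[a], replicate = as.character(r),
          trait = tr$name[keep], value = unname(val[keep]),
          stringsAsFactors = FALSE)
      }
    }
    phenotype_table(do.call(rbind, rows))
  })
}

#' Simulate a complete genotype + phenotype dataset
#'
#' Composes the two simulators over a shared design and seed stream. With
#' \code{fixture_config("paper_like")} this reproduces the study's
#' dimensions: 25 sites, at most 3 accessions per site, 2 phenotyped
#' replicates per accession, 61 genotyped individuals.
#'
#' @param cfg a \code{simulation_config}.
#' @return a list with elements \code{genotypes} and \code{phenotypes}.
#' @export
simulate_dataset <- function(cfg) {
  list(genotypes = simulate_genotypes(cfg),
       phenotypes = simulate_phenotypes(cfg))
}
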