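# End-to-end orchestration: divergence screen -> Fst (both ascertainments)
# -> Qst* per diverged trait -> univariate tests -> multivariate test, with
# TSV/JSON reports and a run manifest. A pure function of (inputs, config,
# seed): rerunning with the same seed reproduces every report byte for
# byte.

#' Read a pipeline configuration from YAML
#'
#' The file either names input files (\code{genotypes}, \code{phenotypes})
#' or requests simulation (\code{simulate: fixture: paper_like} or explicit
#' \code{simulation_config} fields), plus analysis settings (\code{seed},
#' \code{n_boot}, \code{fdr_alpha}, \code{mating_system},
#' \code{out_dir}, optional \code{multivariate_traits} and
#' \code{screen: false} to skip the divergence screen).
#'
#' @param path YAML file path.
#' @return the configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    qfk_stop(paste("config file not found:", path), "io_error")
  yaml::read_yaml(path)
}

resolve_sim_config <- function(sim, seed) {
  if (!is.null(sim$fixture))
    return(fixture_config(sim$fixture, seed = seed))
  args <- sim
  args$seed <- seed
  if (!is.null(args$traits)) args$traits <- as.data.frame(
    do.call(rbind, lapply(args$traits, as.data.frame)))
  do.call(simulation_config, args)
}

#' Run the full Qst-Fst pipeline
#'
#' Executes every stage on a conforming dataset (or a simulated one),
#' writing a trait-divergence table (means, SDs, F, p, FDR-adjusted p,
#' relative divergence, Qst*), an Fst table under both ascertainments, a
#' univariate Qst-Fst p-value table (both bootstrap methods, both
#' ascertainments), and the multivariate proportionality result, plus a
#' manifest recording config, input digests, seed, package version and
#' per-stage runtimes. Qst and the Qst-Fst tests run only on traits passing
#' the FDR divergence screen unless \code{screen: false}.
#'
#' @param config a configuration list (see
#'   \code{\link{read_pipeline_config}}) or a YAML path.
#' @return a \code{run_manifest}, invisibly; reports are on disk under
#'   \code{out_dir}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% "qstfst_results"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- analysis_config(
    n_boot = config$n_boot %||% 1000L, seed = seed,
    mating_system = config$mating_system %||% "selfing",
    fdr_alpha = config$fdr_alpha %||% 0.05,
    eigenvalue_floor = config$eigenvalue_floor %||% 1e-10)
  manifest <- list(package_version = as.character(packageVersion("qstfstkit")),
                   seed = seed, config = config, out_dir = out_dir,
                   stages = list(), inputs = list(), outputs = list())
  stage <- function(name, expr) {
    qfk_log("stage: ", name)
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      qfk_stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
               "pipeline_error"))
    manifest$stages[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  emit <- function(df, file) {
    path <- file.path(out_dir, file)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$outputs[[file]] <<- path
    path
  }

  dat <- stage("inputs", {
    if (!is.null(config$simulate)) {
      sim_cfg <- resolve_sim_config(config$simulate, seed)
      ds <- simulate_dataset(sim_cfg)
      gp <- file.path(out_dir, "simulated_genotypes.tsv")
      pp <- file.path(out_dir, "simulated_phenotypes.tsv")
      write_genotypes(ds$genotypes, gp)
      write_phenotypes(ds$phenotypes, pp)
      manifest$inputs <- list(genotypes = gp, phenotypes = pp,
                              simulated = TRUE)
      ds
    } else {
      for (f in c(config$genotypes, config$phenotypes))
        if (!file.exists(f))
          qfk_stop(paste("input file not found:", f), "io_error")
      manifest$inputs <- list(genotypes = config$genotypes,
                              phenotypes = config$phenotypes,
                              simulated = FALSE)
      fmt <- config$genotype_format %||% "table"
      list(genotypes = read_genotypes(config$genotypes, format = fmt,
                                      species = unlist(config$species_map)),
           phenotypes = read_phenotypes(
             config$phenotypes,
             check_trait_ranges = !identical(config$check_trait_ranges,
                                             FALSE)))
    }
  })
  manifest$input_digests <- lapply(manifest$inputs[c("genotypes",
                                                     "phenotypes")],
                                   function(f) unname(tools::md5sum(f)))

  div <- stage("diverge", divergence_table(dat$phenotypes,
                                           fdr_alpha = cfg$fdr_alpha))
  fst_tab <- stage("fst", {
    rows <- lapply(c("all", "shared"), function(a) {
      ga <- ascertain_snps(dat$genotypes, a)
      est <- fst_bootstrap_ci(ga, "weir_cockerham", n_boot = cfg$n_boot,
                              seed = seed + 17L)
      hud <- hudson_fst(ga)
      data.frame(ascertainment = a, estimator = c("weir_cockerham",
                                                  "hudson"),
                 fst = c(est$value, hud$value),
                 ci_low = c(est$ci_low, NA), ci_high = c(est$ci_high, NA),
                 n_loci = c(est$n_loci, hud$n_loci))
    })
    do.call(rbind, rows)
  })

  screen <- !identical(config$screen, FALSE)
  diverged <- if (screen) div$trait[div$significant] else div$trait
  qst_tab <- stage("qst", {
    vals <- vapply(diverged, function(tr) {
      tryCatch(qst_star(qst_components(dat$phenotypes, tr,
                                       transform = if (tr %in% names(
                                         default_transforms))
                                         default_transforms[[tr]] else
                                           NULL))$qst_star,
               qstfstkit_error = function(e) NA_real_)
    }, numeric(1))
    data.frame(trait = diverged, qst_star = vals)
  })
  div$qst_star <- qst_tab$qst_star[match(div$trait, qst_tab$trait)]
  emit(div, "trait_divergence.tsv")
  emit(fst_tab, "fst.tsv")

  uni <- stage("univariate",
               run_trait_family(dat$phenotypes, dat$genotypes, diverged,
                                cfg = cfg))
  emit(as.data.frame(uni), "univariate_qstfst.tsv")

  multi <- stage("multivariate", {
    mtraits <- config$multivariate_traits %||% {
      mt <- diverged
      if (any(c("internode1", "internode2", "internode3") %in% mt))
        mt <- c(setdiff(mt, c("internode1", "internode2", "internode3")),
                "internode_sum")
      mt
    }
    if (length(mtraits) < 1L) NULL else
      multivariate_test(dat$phenotypes, dat$genotypes, mtraits, cfg = cfg)
  })
  if (!is.null(multi)) {
    mj <- file.path(out_dir, "multivariate.json")
    jsonlite::write_json(
      list(rho_obs = multi$rho_obs, rho_ci = multi$rho_ci,
           rho_exp = multi$rho_exp$value,
           rho_exp_ci = c(multi$rho_exp$ci_low, multi$rho_exp$ci_high),
           mating = multi$mating, verdict = multi$verdict),
      mj, auto_unbox = TRUE, digits = NA)
    manifest$outputs[["multivariate.json"]] <- mj
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  manifest$tables <- list(divergence = div, fst = fst_tab, univariate = uni,
                          multivariate = multi)
  class(manifest) <- "run_manifest"
  invisible(manifest)
}

#' Human-readable pipeline summary
#'
#' Renders the divergence, Fst and univariate tables with the conventional
#' star marking traits significant after the FDR correction, and the
#' multivariate verdict.
#'
#' @param manifest a \code{run_manifest} from \code{\link{run_pipeline}}.
#' @return \code{manifest}, invisibly; output is printed.
#' @export
report <- function(manifest) {
  tb <- manifest$tables
  cat("== Trait divergence (", "* = significant after FDR correction ) ==\n",
      sep = "")
  div <- tb$divergence
  if (nrow(div)) {
    div_print <- data.frame(
      trait = paste0(div$trait, ifelse(div$significant, "*", "")),
      mean_1 = sprintf("%.2f (%.2f)", div$mean_1, div$sd_1),
      mean_2 = sprintf("%.2f (%.2f)", div$mean_2, div$sd_2),
      F = round(div$F_ratio, 3), p = signif(div$p_raw, 3),
      p_fdr = signif(div$p_fdr, 3),
      rel_div = round(div$relative_divergence, 2),
      qst_star = ifelse(is.na(div$qst_star), "NA",
                        sprintf("%.3f", div$qst_star)))
    print(div_print, row.names = FALSE)
  } else cat("(no traits)\n")
  cat("\n== Fst ==\n")
  print(tb$fst, row.names = FALSE)
  cat("\n== Univariate Qst-Fst p values ==\n")
  if (nrow(tb$univariate)) print(as.data.frame(tb$univariate),
                                 row.names = FALSE)
  else cat("(no diverged traits)\n")
  if (!is.null(tb$multivariate)) {
    cat("\n== Multivariate proportionality ==\n")
    print(tb$multivariate)
  }
  invisible(manifest)
}
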