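# Core data containers: a genotype matrix of alternate-allele counts for two
# species, and a long-format phenotype table over the nested design
# species / site / accession / replicate.

#' Construct a genotype matrix
#'
#' The substrate for all Fst estimation: a matrix of per-individual,
#' per-locus alternate-allele counts (0, 1, 2 or \code{NA}) at biallelic SNP
#' loci, with a species label for each individual. Exactly two species must
#' be present. Phase is discarded: the estimators only need allele and
#' heterozygote counts.
#'
#' @param geno integer matrix, individuals x loci, entries in \{0, 1, 2, NA\}.
#' @param species character or factor of per-individual species labels
#'   (exactly two distinct values).
#' @param individual_ids,locus_ids optional identifiers; default to the
#'   dimnames of \code{geno} or generated ids.
#' @return an object of class \code{genotype_matrix} with elements
#'   \code{geno}, \code{species} (factor), \code{individual_ids},
#'   \code{locus_ids}.
#' @export
genotype_matrix <- function(geno, species, individual_ids = NULL,
                            locus_ids = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  individual_ids <- individual_ids %||% rownames(geno) %||%
    sprintf("ind%03d", seq_len(nrow(geno)))
  locus_ids <- locus_ids %||% colnames(geno) %||%
    sprintf("locus%05d", seq_len(ncol(geno)))
  rownames(geno) <- individual_ids
  colnames(geno) <- locus_ids
  obj <- structure(
    list(geno = geno, species = factor(species),
         individual_ids = as.character(individual_ids),
         locus_ids = as.character(locus_ids)),
    class = "genotype_matrix")
  validate_genotype_matrix(obj)
  obj
}

#' Validate a genotype matrix
#'
#' Checks the class invariants: exactly two species labels, all genotype
#' values in \{0, 1, 2, NA\}, consistent dimensions.
#'
#' @param g a \code{genotype_matrix}.
#' @return \code{g}, invisibly; signals a validation error otherwise.
#' @export
validate_genotype_matrix <- function(g) {
  if (!inherits(g, "genotype_matrix"))
    qfk_stop("not a genotype_matrix", "validation_error")
  if (nlevels(g$species) != 2L)
    qfk_stop(sprintf("expected exactly 2 species labels, found %d (%s)",
                     nlevels(g$species),
                     paste(levels(g$species), collapse = ", ")),
             "validation_error")
  if (length(g$species) != nrow(g$geno))
    qfk_stop("species labels and genotype rows differ in length",
             "validation_error")
  bad <- !(g$geno %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad))
    qfk_stop(sprintf("%d genotype entries outside {0,1,2,NA}", sum(bad)),
             "validation_error")
  if (length(g$locus_ids) != ncol(g$geno))
    qfk_stop("locus_ids and genotype columns differ in length",
             "validation_error")
  invisible(g)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci\n",
              nrow(x$geno), ncol(x$geno)))
  tb <- table(x$species)
  cat(sprintf("  species: %s\n",
              paste(sprintf("%s (n=%d)", names(tb), tb), collapse = ", ")))
  cat(sprintf("  missing calls: %.3f%%\n", 100 * mean(is.na(x$geno))))
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param x a \code{genotype_matrix}.
#' @param i individual index (row) selector.
#' @param j locus index (column) selector.
#' @param ... unused.
#' @return a \code{genotype_matrix} restricted to the selected rows/columns.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$geno))
  if (missing(j)) j <- seq_len(ncol(x$geno))
  structure(
    list(geno = x$geno[i, j, drop = FALSE],
         species = factor(x$species[i]),
         individual_ids = x$individual_ids[i],
         locus_ids = x$locus_ids[j]),
    class = "genotype_matrix")
}

trait_units <- c(
  internode1 = "mm", internode2 = "mm", internode3 = "mm",
  internode_sum = "mm", flowers_per_day = "count",
  flowers_on_inflorescence = "count", inflorescence_length = "mm",
  corolla_length = "mm", corolla_width = "mm", nectar_volume = "ul",
  nectar_concentration = "mg/ml", pollen_per_ovule = "count",
  herkogamy = "anthers below stigma (0-5)", leaf_length_width = "ratio",
  leaf_dissection = "5-point scale", sepal_length = "mm")

dissection_levels <- c(0, 0.25, 0.5, 0.75, 1)

#' Construct a phenotype table
#'
#' Canonical long form of the nested phenotyping design: one row per
#' measurement, with columns \code{individual}, \code{species}, \code{site},
#' \code{accession}, \code{replicate}, \code{trait}, \code{value}. Accessions
#' are nested in sites and sites in species; plants that never flowered have
#' no floral rows (absent, not zero).
#'
#' @param df data frame with the columns above (\code{replicate} optional).
#' @param check_trait_ranges if \code{TRUE}, enforce raw-score ranges
#'   (herkogamy an integer in 0..5, leaf dissection on the 5-point scale).
#'   Off by default so that latent-scale simulated traits validate.
#' @return an object of class \code{phenotype_table} (a data frame).
#' @export
phenotype_table <- function(df, check_trait_ranges = FALSE) {
  need <- c("individual", "species", "site", "accession", "trait", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    qfk_stop(paste("missing phenotype columns:", paste(miss, collapse = ", ")),
             "validation_error")
  if (!"replicate" %in% names(df)) df$replicate <- NA_character_
  df <- df[, c("individual", "species", "site", "accession", "replicate",
               "trait", "value")]
  for (cc in c("individual", "species", "site", "accession", "trait"))
    df[[cc]] <- as.character(df[[cc]])
  df$value <- as.numeric(df$value)
  obj <- structure(df, class = c("phenotype_table", "data.frame"))
  validate_phenotype_table(obj, check_trait_ranges = check_trait_ranges)
  obj
}

#' Validate a phenotype table
#'
#' Enforces the nesting invariants (no accession under two sites, no site
#' under two species), finiteness of values, and optionally the raw-score
#' ranges of herkogamy and leaf dissection.
#'
#' @inheritParams phenotype_table
#' @param p a \code{phenotype_table}.
#' @return \code{p}, invisibly.
#' @export
validate_phenotype_table <- function(p, check_trait_ranges = FALSE) {
  if (nlevels(factor(p$species)) < 1L)
    qfk_stop("no species labels", "validation_error")
  if (any(!is.finite(p$value)))
    qfk_stop(sprintf("%d non-finite trait values", sum(!is.finite(p$value))),
             "validation_error")
  acc_site <- unique(p[, c("accession", "site")])
  dup <- acc_site$accession[duplicated(acc_site$accession)]
  if (length(dup))
    qfk_stop(paste("accession(s) recorded under more than one site:",
                   paste(unique(dup), collapse = ", ")), "validation_error")
  site_sp <- unique(p[, c("site", "species")])
  dup <- site_sp$site[duplicated(site_sp$site)]
  if (length(dup))
    qfk_stop(paste("site(s) recorded under more than one species:",
                   paste(unique(dup), collapse = ", ")), "validation_error")
  if (check_trait_ranges) {
    h <- p$value[p$trait == "herkogamy"]
    if (length(h) && any(h != round(h) | h < 0 | h > 5))
      qfk_stop("herkogamy values must be integers in [0, 5]",
               "validation_error")
    d <- p$value[p$trait == "leaf_dissection"]
    if (length(d) && any(!d %in% dissection_levels))
      qfk_stop("leaf_dissection values must lie on the 5-point scale {0, 0.25, 0.5, 0.75, 1}",
               "validation_error")
  }
  invisible(p)
}

#' Read genotypes from a VCF or a delimited table
#'
#' VCF input follows the standard diploid \code{GT} convention: \code{0/0},
#' \code{0/1}, \code{1/1} become alternate-allele counts 0, 1, 2 and
#' \code{./.} becomes \code{NA}. Multiallelic sites are dropped with a logged
#' count. Table input is individuals x loci with \code{individual} and
#' \code{species} columns followed by one column per locus.
#'
#' @param path file path.
#' @param format \code{"vcf"} or \code{"table"}.
#' @param species for VCF input (which carries no species field), a named
#'   character vector mapping sample id to species label.
#' @param sep field separator for table input.
#' @return a \code{genotype_matrix}.
#' @export
read_genotypes <- function(path, format = c("table", "vcf"), species = NULL,
                           sep = "\t") {
  format <- match.arg(format)
  if (!file.exists(path))
    qfk_stop(paste("genotype file not found:", path), "io_error")
  if (format == "table") {
    df <- tryCatch(
      read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                 stringsAsFactors = FALSE),
      error = function(e) qfk_stop(paste0("malformed genotype table '", path,
                                          "': ", conditionMessage(e)),
                                   "parse_error"))
    if (!all(c("individual", "species") %in% names(df)))
      qfk_stop("genotype table needs 'individual' and 'species' columns",
               "parse_error")
    loci <- setdiff(names(df), c("individual", "species"))
    m <- as.matrix(df[, loci, drop = FALSE])
    if (!is.numeric(m))
      qfk_stop("non-numeric genotype entries in table", "parse_error")
    rownames(m) <- df$individual
    return(genotype_matrix(m, df$species, individual_ids = df$individual,
                           locus_ids = loci))
  }
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e)
                    qfk_stop(paste0("malformed VCF '", path, "': ",
                                    conditionMessage(e)), "parse_error"))
  fix <- vcfR::getFIX(vcf)
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi))
    qfk_log(sprintf("dropping %d multiallelic VCF site(s)", sum(multi)))
  gt <- vcfR::extract.gt(vcf, element = "GT")           # loci x samples
  gt <- gt[!multi, , drop = FALSE]
  ids <- fix[!multi, "ID"]
  ids <- ifelse(is.na(ids) | ids == ".",
                paste0(fix[!multi, "CHROM"], ":", fix[!multi, "POS"]), ids)
  counts <- apply(gt, 2, function(col) {
    a1 <- substr(col, 1, 1)
    a2 <- substr(col, 3, 3)
    out <- (a1 == "1") + (a2 == "1")
    out[a1 == "." | a2 == "." | is.na(col)] <- NA_integer_
    out
  })
  counts <- matrix(as.integer(counts), nrow = nrow(gt),
                   dimnames = list(ids, colnames(gt)))
  samples <- colnames(gt)
  if (is.null(species))
    qfk_stop("VCF input requires a named 'species' vector (sample -> species)",
             "validation_error")
  miss <- setdiff(samples, names(species))
  if (length(miss))
    qfk_stop(paste("no species label for sample(s):",
                   paste(miss, collapse = ", ")), "validation_error")
  genotype_matrix(t(counts), species[samples], individual_ids = samples,
                  locus_ids = ids)
}

#' Write genotypes to a delimited table
#'
#' The inverse of \code{read_genotypes(format = "table")}; the round trip is
#' lossless.
#'
#' @param g a \code{genotype_matrix}.
#' @param path output path.
#' @param sep field separator.
#' @return \code{path}, invisibly.
#' @export
write_genotypes <- function(g, path, sep = "\t") {
  df <- data.frame(individual = g$individual_ids,
                   species = as.character(g$species),
                   g$geno, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read phenotypes from delimited text (long or wide)
#'
#' Long input has columns \code{individual, species, site, accession,
#' [replicate,] trait, value}; wide input has one column per trait after the
#' design columns. Missing (empty/NA) cells in wide input are treated as
#' absent measurements, mirroring plants that never expressed a trait. Raw
#' trait-score ranges (herkogamy, leaf dissection) are enforced on read.
#'
#' @param path file path.
#' @param sep field separator.
#' @param check_trait_ranges enforce raw-score ranges (herkogamy, leaf
#'   dissection); disable when reading latent-scale simulated phenotypes.
#' @return a \code{phenotype_table} in canonical long form.
#' @export
read_phenotypes <- function(path, sep = "\t", check_trait_ranges = TRUE) {
  if (!file.exists(path))
    qfk_stop(paste("phenotype file not found:", path), "io_error")
  df <- tryCatch(
    read.table(path, header = TRUE, sep = sep, check.names = FALSE,
               stringsAsFactors = FALSE),
    error = function(e) qfk_stop(paste0("malformed phenotype file '", path,
                                        "': ", conditionMessage(e)),
                                 "parse_error"))
  design <- intersect(c("individual", "species", "site", "accession",
                        "replicate"), names(df))
  if (!all(c("individual", "species", "site", "accession") %in% design))
    qfk_stop("phenotype file needs individual/species/site/accession columns",
             "parse_error")
  if (all(c("trait", "value") %in% names(df))) {
    long <- df
  } else {
    traits <- setdiff(names(df), design)
    pieces <- lapply(traits, function(tr) {
      v <- df[[tr]]
      if (is.character(v)) {
        conv <- suppressWarnings(as.numeric(v))
        bad <- which(!is.na(v) & v != "" & is.na(conv))
        if (length(bad))
          qfk_stop(sprintf("non-numeric value for trait '%s' at data row %d: '%s'",
                           tr, bad[1], v[bad[1]]), "parse_error")
        v <- conv
      }
      keep <- !is.na(v)
      if (sum(!keep))
        qfk_log(sprintf("trait '%s': %d individual(s) without a measurement (rows omitted)",
                        tr, sum(!keep)))
      cbind(df[keep, design, drop = FALSE],
            data.frame(trait = tr, value = v[keep]))
    })
    long <- do.call(rbind, pieces)
  }
  if (is.character(long$value)) {
    conv <- suppressWarnings(as.numeric(long$value))
    bad <- which(!is.na(long$value) & is.na(conv))
    if (length(bad))
      qfk_stop(sprintf("non-numeric trait value at data row %d: '%s'",
                       bad[1], long$value[bad[1]]), "parse_error")
    long$value <- conv
  }
  phenotype_table(long, check_trait_ranges = check_trait_ranges)
}

#' Write a phenotype table in canonical long form
#'
#' @param p a \code{phenotype_table}.
#' @param path output path.
#' @param sep field separator.
#' @return \code{path}, invisibly.
#' @export
write_phenotypes <- function(p, path, sep = "\t") {
  write.table(as.data.frame(p), path, sep = sep, quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Analysis configuration
#'
#' A single declarative bundle of the tunable analysis knobs shared across
#' stages.
#'
#' @param n_boot bootstrap/simulation replicates (default 1000).
#' @param seed integer seed; every randomised stage derives its stream from
#'   this.
#' @param ascertainment SNP ascertainment rule, \code{"all"} (polymorphic in
#'   at least one species) or \code{"shared"} (polymorphic in both).
#' @param mating_system selects the neutral proportionality multiplier:
#'   \code{"selfing"} (m = 1) or \code{"outcrossing"} (m = 2).
#' @param eigenvalue_floor relative floor for G-matrix conditioning.
#' @param fdr_alpha familywise FDR level for the divergence screen.
#' @param call_rate_floor per-locus minimum fraction of called individuals
#'   retained for Fst (default 60/61, i.e. at most one missing call in a
#'   61-individual panel).
#' @return an \code{analysis_config} list.
#' @export
analysis_config <- function(n_boot = 1000L, seed = 1L,
                            ascertainment = c("all", "shared"),
                            mating_system = c("selfing", "outcrossing"),
                            eigenvalue_floor = 1e-10, fdr_alpha = 0.05,
                            call_rate_floor = 60 / 61) {
  ascertainment <- match.arg(ascertainment)
  mating_system <- match.arg(mating_system)
  if (n_boot < 1L) qfk_stop("n_boot must be >= 1", "config_error")
  if (eigenvalue_floor <= 0)
    qfk_stop("eigenvalue_floor must be > 0", "config_error")
  if (fdr_alpha <= 0 || fdr_alpha >= 1)
    qfk_stop("fdr_alpha must be in (0, 1)", "config_error")
  structure(list(n_boot = as.integer(n_boot), seed = as.integer(seed),
                 ascertainment = ascertainment, mating_system = mating_system,
                 eigenvalue_floor = eigenvalue_floor, fdr_alpha = fdr_alpha,
                 call_rate_floor = call_rate_floor),
            class = "analysis_config")
}
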