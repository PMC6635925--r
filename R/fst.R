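# Multi-locus Fst between the two species: SNP ascertainment filters,
# Weir-Cockerham (1984) and Hudson ratio-of-averages estimators, and a
# nonparametric bootstrap-over-loci percentile confidence interval.

new_fst_estimate <- function(estimator, value, ci_low, ci_high, n_loci,
                             ascertainment = NA_character_) {
  structure(list(estimator = estimator, value = value, ci_low = ci_low,
                 ci_high = ci_high, n_loci = n_loci,
                 ascertainment = ascertainment),
            class = "fst_estimate")
}

#' @export
print.fst_estimate <- function(x, ...) {
  cat(sprintf("Fst (%s%s): %.4f", x$estimator,
              if (!is.na(x$ascertainment)) paste0(", ", x$ascertainment,
                                                  " SNPs") else "",
              x$value))
  if (!is.na(x$ci_low))
    cat(sprintf("  95%% CI [%.4f, %.4f]", x$ci_low, x$ci_high))
  cat(sprintf("  (%d loci)\n", x$n_loci))
  invisible(x)
}

# per-species polymorphism: a locus is polymorphic within a species when the
# called genotypes imply allele frequency strictly inside (0, 1)
species_polymorphic <- function(g) {
  sp <- levels(g$species)
  sapply(sp, function(s) {
    sub <- g$geno[g$species == s, , drop = FALSE]
    mx <- suppressWarnings(apply(sub, 2, max, na.rm = TRUE))
    mn <- suppressWarnings(apply(sub, 2, min, na.rm = TRUE))
    is.finite(mx) & is.finite(mn) & (mx != mn | mx == 1L)
  })
}

#' SNP ascertainment filter
#'
#' \code{mode = "all"} keeps loci polymorphic in at least one species;
#' \code{mode = "shared"} keeps loci polymorphic in both. The shared set is
#' always a subset of the all set. Because "all" retains variants fixed
#' between the species (including ancestral variants lost in one lineage),
#' Fst from "all" SNPs tends to exceed Fst from "shared" SNPs.
#'
#' @param g a \code{genotype_matrix}.
#' @param mode \code{"all"} or \code{"shared"}.
#' @return the filtered \code{genotype_matrix}; its \code{ascertainment}
#'   attribute records the mode.
#' @export
ascertain_snps <- function(g, mode = c("all", "shared")) {
  mode <- match.arg(mode)
  validate_genotype_matrix(g)
  poly <- species_polymorphic(g)
  keep <- if (mode == "all") poly[, 1] | poly[, 2] else poly[, 1] & poly[, 2]
  if (!any(keep))
    warning("ascertainment '", mode, "' retained no loci")
  out <- g[, keep]
  attr(out, "ascertainment") <- mode
  qfk_log(sprintf("ascertainment '%s': kept %d of %d loci", mode,
                  sum(keep), ncol(g$geno)))
  out
}

# Sufficient statistics for weighted Fst recomputation: per-species 0/1
# matrices so that individual weights turn into per-locus counts by a single
# vector-matrix product. Used by both estimators and by the accession
# bootstrap, where weights are resample multiplicities.
geno_suffstats <- function(g) {
  called <- !is.na(g$geno)
  alt <- g$geno
  alt[!called] <- 0L
  het <- (g$geno == 1L) & called
  list(called = called * 1, alt = alt * 1, het = het * 1,
       species = g$species, n_ind = nrow(g$geno), L = ncol(g$geno))
}

# Per-locus Weir-Cockerham (1984) variance components a (among species),
# b (among individuals within species), c (within individuals) for r = 2,
# from per-species called counts, allele frequencies and heterozygote
# frequencies. Vectors over loci.
wc_abc <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (n1 + n2) - (n1^2 + n2^2) / (n1 + n2)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  list(a = a, b = b, c = c)
}

# Weighted per-locus numerator/denominator for either estimator. w is a
# non-negative per-individual weight vector (1 = plain estimate).
fst_locus_terms <- function(ss, estimator, w = NULL,
                            max_missing_calls = 1L) {
  w <- w %||% rep(1, ss$n_ind)
  sp <- levels(ss$species)
  stat <- lapply(sp, function(s) {
    ws <- w * (ss$species == s)
    n <- drop(crossprod(ws, ss$called))
    list(n = n,
         p = drop(crossprod(ws, ss$alt)) / (2 * n),
         h = drop(crossprod(ws, ss$het)) / n)
  })
  n1 <- stat[[1]]$n; n2 <- stat[[2]]$n
  tot_w <- sum(w)
  valid <- n1 >= 1 & n2 >= 1 & (n1 + n2) >= tot_w - max_missing_calls
  if (estimator == "weir_cockerham") {
    comp <- wc_abc(n1, stat[[1]]$p, stat[[1]]$h,
                   n2, stat[[2]]$p, stat[[2]]$h)
    num <- comp$a
    den <- comp$a + comp$b + comp$c
  } else {
    m1 <- 2 * n1; m2 <- 2 * n2        # allele sample sizes
    p1 <- stat[[1]]$p; p2 <- stat[[2]]$p
    valid <- valid & m1 >= 2 & m2 >= 2
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (m1 - 1) - p2 * (1 - p2) / (m2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
  }
  valid <- valid & is.finite(num) & is.finite(den)
  list(num = num, den = den, valid = valid)
}

fst_point <- function(g, estimator, max_missing_calls = 1L, w = NULL,
                      ss = NULL) {
  ss <- ss %||% geno_suffstats(g)
  lt <- fst_locus_terms(ss, estimator, w = w,
                        max_missing_calls = max_missing_calls)
  if (!any(lt$valid) || sum(lt$den[lt$valid]) <= 0)
    qfk_stop("Fst undefined: no polymorphic, sufficiently called loci",
             "undefined_estimate")
  sum(lt$num[lt$valid]) / sum(lt$den[lt$valid])
}

#' Weir-Cockerham multi-locus Fst
#'
#' Ratio-of-averages estimate theta = sum(a_l) / sum(a_l + b_l + c_l) over
#' loci, with the per-locus 1984 variance components a (among species), b
#' (among individuals within species) and c (within individuals) computed
#' from observed per-species sample sizes, allele frequencies and
#' heterozygote counts. The two species play the role of the two
#' populations; loci with zero total variance contribute nothing, and
#' negative multi-locus estimates are reported as computed.
#'
#' @param g a \code{genotype_matrix} (typically after
#'   \code{\link{ascertain_snps}}).
#' @param max_missing_calls loci with more missing calls than this are
#'   dropped before estimation (default 1, the "at least 60 of 61 called"
#'   hard-filter equivalent).
#' @return an \code{fst_estimate} (CI fields \code{NA}; see
#'   \code{\link{fst_bootstrap_ci}}).
#' @export
weir_cockerham_fst <- function(g, max_missing_calls = 1L) {
  validate_genotype_matrix(g)
  ss <- geno_suffstats(g)
  lt <- fst_locus_terms(ss, "weir_cockerham",
                        max_missing_calls = max_missing_calls)
  if (!any(lt$valid) || sum(lt$den[lt$valid]) <= 0)
    qfk_stop("Fst undefined: all loci monomorphic or insufficiently called",
             "undefined_estimate")
  new_fst_estimate("weir_cockerham",
                   sum(lt$num[lt$valid]) / sum(lt$den[lt$valid]),
                   NA_real_, NA_real_, sum(lt$valid),
                   attr(g, "ascertainment") %||% NA_character_)
}

#' Hudson multi-locus Fst
#'
#' Ratio-of-averages form sum(N_l) / sum(D_l) with per-locus numerator
#' (p1 - p2)^2 - p1(1 - p1)/(m1 - 1) - p2(1 - p2)/(m2 - 1) and denominator
#' p1(1 - p2) + p2(1 - p1), where m_j is the number of called allele copies
#' in species j.
#'
#' @inheritParams weir_cockerham_fst
#' @return an \code{fst_estimate}.
#' @export
hudson_fst <- function(g, max_missing_calls = 1L) {
  validate_genotype_matrix(g)
  ss <- geno_suffstats(g)
  lt <- fst_locus_terms(ss, "hudson", max_missing_calls = max_missing_calls)
  if (!any(lt$valid) || sum(lt$den[lt$valid]) <= 0)
    qfk_stop("Fst undefined: every locus lacks two called allele copies per species",
             "undefined_estimate")
  new_fst_estimate("hudson", sum(lt$num[lt$valid]) / sum(lt$den[lt$valid]),
                   NA_real_, NA_real_, sum(lt$valid),
                   attr(g, "ascertainment") %||% NA_character_)
}

#' Bootstrap-over-loci confidence interval for Fst
#'
#' Percentile interval from \code{n_boot} resamples of loci with
#' replacement, deterministic given \code{seed}. Loci are the resampling
#' unit because multi-locus Fst uncertainty is locus-driven.
#'
#' @inheritParams weir_cockerham_fst
#' @param estimator \code{"weir_cockerham"} or \code{"hudson"}.
#' @param n_boot number of resamples (>= 100 for a stable 95\% interval).
#' @param seed integer seed.
#' @param level confidence level.
#' @return an \code{fst_estimate} with percentile \code{ci_low},
#'   \code{ci_high} and a \code{boot} attribute holding the resampled
#'   values.
#' @export
fst_bootstrap_ci <- function(g, estimator = c("weir_cockerham", "hudson"),
                             n_boot = 1000L, seed = 1L, level = 0.95,
                             max_missing_calls = 1L) {
  estimator <- match.arg(estimator)
  if (n_boot < 100L)
    warning("n_boot < 100 gives an unstable 95% percentile interval")
  est <- if (estimator == "weir_cockerham")
    weir_cockerham_fst(g, max_missing_calls) else
    hudson_fst(g, max_missing_calls)
  ss <- geno_suffstats(g)
  lt <- fst_locus_terms(ss, estimator, max_missing_calls = max_missing_calls)
  num <- lt$num[lt$valid]; den <- lt$den[lt$valid]
  L <- length(num)
  if (L == 1L)
    warning("single usable locus: bootstrap CI is degenerate")
  vals <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(L, L, replace = TRUE)
    sum(num[idx]) / sum(den[idx])
  }, numeric(1)))
  qs <- quantile(vals, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE,
                 type = 7)
  out <- new_fst_estimate(estimator, est$value, qs[1], qs[2], L,
                          est$ascertainment)
  attr(out, "boot") <- vals
  out
}
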