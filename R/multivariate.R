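# Multivariate Qst-Fst: estimate the accession-level (G_A) and
# between-species (G_S) trait covariance matrices from a MANOVA on
# accession means, the proportionality coefficient rho relating them, a
# bootstrap CI for rho by resampling accessions, and the neutral
# expectation rho_Exp = m * Fst * (1 - Fst).

#' Accession x trait matrix of transformed, mean-standardized means
#'
#' Builds the substrate of the MANOVA: one row per accession, one column
#' per trait, each entry the accession mean of (optionally transformed)
#' individual values, with every column divided by its grand mean so that
#' traits on different scales are comparable (each column has mean 1).
#' Accessions missing any requested trait are dropped with a logged count.
#'
#' @param p a \code{phenotype_table}.
#' @param traits trait columns (use \code{internode_sum} in place of the
#'   three internodes for the early-growth axis).
#' @param transforms named per-trait transform vector (default: log for
#'   pollen per ovule).
#' @return a numeric matrix with a \code{species} attribute giving each
#'   row's species.
#' @export
accession_trait_matrix <- function(p, traits,
                                   transforms = default_transforms) {
  pm <- as.data.frame(individual_means(p))
  pm <- pm[pm$trait %in% traits, , drop = FALSE]
  for (tr in intersect(names(transforms), traits)) {
    f <- match.fun(transforms[[tr]])
    pm$value[pm$trait == tr] <- f(pm$value[pm$trait == tr])
  }
  agg <- aggregate(value ~ accession + species + trait, data = pm,
                   FUN = mean)
  wide <- reshape(agg, idvar = c("accession", "species"),
                  timevar = "trait", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  miss <- setdiff(traits, names(wide))
  if (length(miss))
    qfk_stop(paste("trait(s) absent:", paste(miss, collapse = ", ")),
             "validation_error")
  complete <- stats::complete.cases(wide[, traits, drop = FALSE])
  if (any(!complete))
    qfk_log(sprintf("%d accession(s) dropped for missing traits",
                    sum(!complete)))
  wide <- wide[complete, , drop = FALSE]
  m <- as.matrix(wide[, traits, drop = FALSE])
  rownames(m) <- wide$accession
  m <- sweep(m, 2, colMeans(m), "/")
  attr(m, "species") <- wide$species
  m
}

#' Symmetrize, round and lift a covariance matrix to positive definiteness
#'
#' Averages the matrix with its transpose, rounds entries to 12 decimal
#' places (so near-symmetry lost to floating-point cancellation becomes
#' exact), eigendecomposes, replaces eigenvalues below the floor with the
#' floor, and reconstructs. The floor is relative:
#' \code{floor * max(eigenvalue)} (absolute when the largest eigenvalue is
#' not positive). Idempotent up to the rounding precision and never
#' decreases the smallest eigenvalue.
#'
#' @param M a square matrix.
#' @param floor relative eigenvalue floor (default 1e-10).
#' @return a symmetric positive-definite matrix.
#' @export
condition_matrix <- function(M, floor = 1e-10) {
  if (!is.matrix(M) || nrow(M) != ncol(M))
    qfk_stop("condition_matrix needs a square matrix", "validation_error")
  M <- round((M + t(M)) / 2, 12)
  e <- eigen(M, symmetric = TRUE)
  lift <- if (max(e$values) > 0) floor * max(e$values) else floor
  vals <- pmax(e$values, lift)
  out <- e$vectors %*% (vals * t(e$vectors))
  round((out + t(out)) / 2, 12)
}

#' Estimate the accession-level and species-level G-matrices
#'
#' MANOVA with species as the factor on the accession-mean matrix:
#' G_A is the residual (within-species) sums-of-squares-and-cross-products
#' matrix divided by its degrees of freedom (accessions - 2); MS_B is the
#' between-species SSCP on 1 df; and G_S = (MS_B - G_A) / n0 with the
#' unbalanced two-group coefficient n0 = 2 n1 n2 / (n1 + n2) (accessions
#' per species n1, n2), i.e. (A - sum n_s^2 / A) / (groups - 1). G_A is
#' conditioned to positive definiteness; G_S is symmetrized and rounded.
#'
#' @param m an accession x trait matrix from
#'   \code{\link{accession_trait_matrix}} (or any matrix with one row per
#'   accession).
#' @param species_labels per-row species; defaults to the matrix's
#'   \code{species} attribute.
#' @param floor eigenvalue floor for conditioning.
#' @return a \code{g_matrix_pair}: \code{g_a}, \code{g_s}, \code{ms_b},
#'   \code{df_a}, \code{df_b}, \code{n0}, \code{trait_names}.
#' @export
estimate_g_matrices <- function(m, species_labels = attr(m, "species"),
                                floor = 1e-10) {
  sp <- factor(species_labels)
  if (nlevels(sp) != 2L)
    qfk_stop("need exactly two species", "validation_error")
  A <- nrow(m); p <- ncol(m)
  if (p >= A - 1L)
    qfk_stop(sprintf(
      "rank error: %d traits but only %d accessions; the residual SSCP cannot have full rank",
      p, A), "rank_error")
  fit <- lm(m ~ sp)
  E <- crossprod(residuals(fit))
  tot <- crossprod(sweep(m, 2, colMeans(m)))
  H <- tot - E
  df_a <- A - 2L
  df_b <- 1L
  n_s <- as.numeric(table(sp))
  n0 <- A - sum(n_s^2) / A                 # = 2 n1 n2 / A, one df at species
  g_a <- condition_matrix(E / df_a, floor)
  ms_b <- condition_matrix(H / df_b, floor)
  g_s <- round((ms_b - g_a) / n0, 12)
  g_s <- (g_s + t(g_s)) / 2
  structure(list(g_a = g_a, g_s = g_s, ms_b = ms_b, df_a = df_a,
                 df_b = df_b, n0 = n0,
                 trait_names = colnames(m) %||% sprintf("t%d", seq_len(p))),
            class = "g_matrix_pair")
}

#' @export
print.g_matrix_pair <- function(x, ...) {
  cat(sprintf("G-matrix pair over %d traits (df_a = %d, df_b = %d, n0 = %.3f)\n",
              length(x$trait_names), x$df_a, x$df_b, x$n0))
  invisible(x)
}

#' Maximum-likelihood proportionality coefficient rho
#'
#' Under neutral divergence the species-level matrix is proportional to the
#' accession-level matrix: E[MS_B] = G_A (1 + n0 rho). rho is estimated by
#' maximizing the Wishart log-density of the between-species SSCP with
#' scale matrix G_A (1 + n0 rho), a one-dimensional profile likelihood in
#' rho solved by bracketed search with relative tolerance 1e-8.
#'
#' @param pair a conditioned \code{g_matrix_pair}.
#' @param tol relative search tolerance.
#' @return the scalar rho estimate (>= 0).
#' @export
estimate_rho <- function(pair, tol = 1e-8) {
  g_a <- pair$g_a; ms_b <- pair$ms_b
  p <- ncol(g_a)
  ev <- eigen(g_a, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    qfk_stop("G_A is not positive definite; apply condition_matrix first",
             "conditioning_error")
  tr_val <- sum(diag(solve(g_a, ms_b)))
  n0 <- pair$n0
  ll <- function(rho) {
    cc <- 1 + n0 * rho
    -0.5 * pair$df_b * (p * log(cc) + tr_val / cc)
  }
  rho_closed <- (tr_val / p - 1) / n0      # stationary point, used as bracket
  hi <- max(1, 4 * abs(rho_closed))
  opt <- optimize(ll, c(0, hi), maximum = TRUE,
                  tol = tol * max(1, abs(rho_closed)))
  if (ll(0) >= opt$objective) 0 else opt$maximum
}

#' Bootstrap confidence interval for rho
#'
#' The two-species comparison leaves a single degree of freedom at the
#' species level, so no analytic CI exists; instead accessions are
#' resampled within each species with replacement, the G-matrix pair and
#' rho are re-estimated per resample, and the percentile interval of the
#' resulting distribution is reported. Degenerate resamples (rank-deficient
#' even after conditioning) are redrawn with a logged count.
#'
#' @param p a \code{phenotype_table}.
#' @param traits traits for the accession matrix.
#' @param n_boot bootstrap replicates (>= 100).
#' @param seed integer seed.
#' @param level confidence level.
#' @param floor eigenvalue floor.
#' @param transforms per-trait transforms.
#' @return length-2 vector (low, high) with the bootstrap draws in
#'   \code{attr(, "boot")}.
#' @export
rho_bootstrap_ci <- function(p, traits, n_boot = 1000L, seed = 1L,
                             level = 0.95, floor = 1e-10,
                             transforms = default_transforms) {
  if (n_boot < 100L)
    warning("n_boot < 100 gives an unstable percentile interval")
  m <- accession_trait_matrix(p, traits, transforms)
  sp <- attr(m, "species")
  idx_by_sp <- split(seq_len(nrow(m)), sp)
  redraws <- 0L
  one <- function() {
    idx <- unlist(lapply(idx_by_sp, function(ii)
      sample(ii, length(ii), replace = TRUE)), use.names = FALSE)
    mb <- m[idx, , drop = FALSE]
    attr(mb, "species") <- sp[idx]
    tryCatch({
      pair <- estimate_g_matrices(mb, sp[idx], floor = floor)
      estimate_rho(pair)
    }, error = function(e) NULL)
  }
  vals <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    repeat {
      v <- one()
      if (!is.null(v) && is.finite(v)) return(v)
      redraws <<- redraws + 1L
      if (redraws > 0.5 * n_boot * (1 + 1))
        qfk_stop("rho bootstrap: persistent degeneracy (>50% of resamples redrawn)",
                 "bootstrap_error")
    }
  }, numeric(1)))
  if (redraws > 0L)
    qfk_log(sprintf("rho bootstrap: %d degenerate resample(s) redrawn",
                    redraws))
  ci <- quantile(vals, c((1 - level) / 2, 1 - (1 - level) / 2),
                 names = FALSE, type = 7)
  attr(ci, "boot") <- vals
  ci
}

#' Neutral expectation of the proportionality coefficient
#'
#' rho_Exp = m Fst (1 - Fst) with m = 1 for a highly selfing species and
#' m = 2 for an outcrosser. Confidence-interval endpoints are mapped
#' through the same function (monotone for Fst < 0.5) and sorted.
#'
#' @param fst an \code{fst_estimate} or a bare numeric Fst in [0, 1].
#' @param mating \code{"selfing"} or \code{"outcrossing"}.
#' @return a list with \code{value}, \code{ci_low}, \code{ci_high} (NA when
#'   the Fst carried no CI), and \code{mating}.
#' @export
expected_rho <- function(fst, mating = c("selfing", "outcrossing")) {
  mating <- match.arg(mating)
  m <- if (mating == "selfing") 1 else 2
  val <- if (inherits(fst, "fst_estimate")) fst$value else fst
  if (val < 0 || val > 1)
    qfk_stop("Fst must lie in [0, 1]", "range_error")
  f <- function(x) m * x * (1 - x)
  ci <- c(NA_real_, NA_real_)
  if (inherits(fst, "fst_estimate") && !is.na(fst$ci_low))
    ci <- sort(f(c(fst$ci_low, fst$ci_high)))
  list(value = f(val), ci_low = ci[1], ci_high = ci[2], mating = mating)
}

#' Multivariate Qst-Fst proportionality test
#'
#' Composes the full multivariate comparison: Fst with a bootstrap-over-loci
#' CI, the neutral interval for rho_Exp = m Fst (1 - Fst), the observed rho
#' with its accession-bootstrap CI, and the verdict — "nonneutral" when the
#' two 95\% intervals are strictly disjoint (open intervals), "neutral"
#' otherwise.
#'
#' @param p a \code{phenotype_table}.
#' @param g an unascertained \code{genotype_matrix}.
#' @param traits traits entering the G-matrices.
#' @param cfg an \code{\link{analysis_config}}.
#' @param transforms per-trait transforms.
#' @return a \code{proportionality_result}.
#' @export
multivariate_test <- function(p, g, traits, cfg = analysis_config(),
                              transforms = default_transforms) {
  g_a <- ascertain_snps(g, cfg$ascertainment)
  fst <- fst_bootstrap_ci(g_a, "weir_cockerham", n_boot = cfg$n_boot,
                          seed = cfg$seed + 17L)
  r_exp <- expected_rho(fst, cfg$mating_system)
  m <- accession_trait_matrix(p, traits, transforms)
  pair <- estimate_g_matrices(m, floor = cfg$eigenvalue_floor)
  rho_obs <- estimate_rho(pair)
  ci <- rho_bootstrap_ci(p, traits, n_boot = cfg$n_boot,
                         seed = cfg$seed + 29L,
                         floor = cfg$eigenvalue_floor,
                         transforms = transforms)
  disjoint <- ci[1] > r_exp$ci_high || ci[2] < r_exp$ci_low
  structure(list(rho_obs = rho_obs, rho_ci = c(ci[1], ci[2]),
                 rho_exp = r_exp, fst = fst, pair = pair,
                 mating = cfg$mating_system,
                 verdict = if (disjoint) "nonneutral" else "neutral"),
            class = "proportionality_result")
}

#' @export
print.proportionality_result <- function(x, ...) {
  cat(sprintf("rho_Obs = %.3f, 95%% CI [%.4f, %.4f]\n", x$rho_obs,
              x$rho_ci[1], x$rho_ci[2]))
  cat(sprintf("rho_Exp (%s, %s SNPs) = %.4f, 95%% CI [%.4f, %.4f]\n",
              x$mating, x$fst$ascertainment %||% "?", x$rho_exp$value,
              x$rho_exp$ci_low, x$rho_exp$ci_high))
  cat("verdict:", x$verdict, "\n")
  invisible(x)
}
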