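# Phenotype-derivation formulas, per-individual averaging, nested-ANOVA
# divergence testing and the conservative Qst* estimator. All variance
# components are method-of-moments: sums of squares are equated to their
# expectations with Sokal-Rohlf weighted coefficients for unbalanced data,
# which coincides with REML in balanced designs and is closed-form.

#' Nectar volume from capillary-tube height
#'
#' A 32 mm microcapillary tube holds 2 ul, so V = 2 * height / 32.
#'
#' @param height_mm nectar column height in mm, in [0, 32].
#' @return volume in ul.
#' @export
capillary_volume <- function(height_mm) {
  if (any(height_mm < 0 | height_mm > 32))
    qfk_stop("capillary height must lie in [0, 32] mm", "range_error")
  2 * height_mm / 32
}

#' Refractometer w/w reading to sugar concentration in mg/ml
#'
#' Evaluates the quadratic calibration
#' mg/ml = 0.0524 (w/w)^2 + 9.6554 (w/w) + 1.3904, a regression of CRC
#' sucrose-solution data (mol/L scaled by the molecular weight of sucrose)
#' on percent weight/weight. The printed coefficients are used as constants.
#'
#' @param w_w refractometer reading (percent weight/weight), >= 0.
#' @return concentration in mg/ml.
#' @export
brix_to_mgml <- function(w_w) {
  if (any(w_w < 0))
    qfk_stop("w/w reading must be >= 0", "range_error")
  0.0524 * w_w^2 + 9.6554 * w_w + 1.3904
}

#' Dilution correction for diluted nectar readings
#'
#' Low nectar volumes are read after adding 2.5 ul water; the diluted mg/ml
#' value is scaled back by (nectar + 2.5) / nectar.
#'
#' @param mgml_diluted concentration of the diluted sample in mg/ml.
#' @param nectar_ul actual nectar volume in ul, > 0.
#' @return corrected concentration in mg/ml.
#' @export
dilution_correct <- function(mgml_diluted, nectar_ul) {
  if (any(nectar_ul <= 0))
    qfk_stop("dilution correction undefined for nectar volume <= 0",
             "range_error")
  mgml_diluted * (nectar_ul + 2.5) / nectar_ul
}

#' Nectar sugar concentration from paired readings
#'
#' The undiluted estimate and the dilution-corrected estimate are averaged
#' to produce the concentration used in analysis.
#'
#' @param w_w_undiluted,w_w_diluted refractometer readings.
#' @param nectar_ul actual nectar volume in ul.
#' @return concentration in mg/ml.
#' @export
nectar_sugar_concentration <- function(w_w_undiluted, w_w_diluted,
                                       nectar_ul) {
  (brix_to_mgml(w_w_undiluted) +
     dilution_correct(brix_to_mgml(w_w_diluted), nectar_ul)) / 2
}

#' Pollen grains per ovule from an aliquot count
#'
#' The grain count in a 100 ul aliquot of a 500 ul suspension is scaled by
#' five and divided by the fixed ovule number 4.
#'
#' @param count_in_100ul non-negative grain count.
#' @return pollen grains per ovule.
#' @export
pollen_per_ovule <- function(count_in_100ul) {
  if (any(count_in_100ul < 0))
    qfk_stop("pollen count must be >= 0", "range_error")
  count_in_100ul * 5 / 4
}

#' Per-individual trait means and the early-growth sum
#'
#' Collapses repeated measurements (flowers, leaves) to one arithmetic mean
#' per individual per trait, and adds the derived trait
#' \code{internode_sum} = internode1 + internode2 + internode3 (the
#' early-growth measure used in multivariate analysis) for individuals with
#' all three internodes. Individuals lacking a trait are simply absent for
#' it.
#'
#' @param p a \code{phenotype_table}.
#' @return a \code{phenotype_table} with one row per individual per trait.
#' @export
individual_means <- function(p) {
  key <- c("individual", "species", "site", "accession", "replicate",
           "trait")
  agg <- aggregate(value ~ individual + species + site + accession +
                     replicate + trait, data = as.data.frame(p), FUN = mean)
  agg <- agg[, c(key, "value")]
  inter <- agg[agg$trait %in% c("internode1", "internode2", "internode3"), ]
  if (nrow(inter)) {
    cnt <- table(inter$individual)
    full <- names(cnt)[cnt == 3L]
    if (length(full)) {
      sums <- aggregate(value ~ individual, data = inter[
        inter$individual %in% full, ], FUN = sum)
      meta <- unique(agg[agg$individual %in% full,
                         c("individual", "species", "site", "accession",
                           "replicate")])
      extra <- merge(meta, sums, by = "individual")
      extra$trait <- "internode_sum"
      agg <- rbind(agg, extra[, c(key, "value")])
    }
  }
  phenotype_table(agg[order(agg$individual, agg$trait), ])
}

#' Relative divergence between species means
#'
#' |m1 - m2| / max(m1, m2): the absolute mean difference scaled by the
#' larger species mean, a unit-free descriptive measure of divergence.
#'
#' @param m1,m2 species trait means (non-negative in practice).
#' @return relative divergence in [0, 1].
#' @export
relative_divergence <- function(m1, m2) {
  mx <- pmax(m1, m2)
  if (any(mx <= 0))
    qfk_stop("relative divergence undefined when the larger mean is <= 0",
             "undefined_estimate")
  abs(m1 - m2) / mx
}

trait_values <- function(p, trait, transform = NULL) {
  d <- as.data.frame(p)
  d <- d[d$trait == trait, , drop = FALSE]
  if (!nrow(d))
    qfk_stop(paste0("trait '", trait, "' absent from phenotype table"),
             "validation_error")
  if (!is.null(transform)) {
    f <- if (is.function(transform)) transform else match.fun(transform)
    d$value <- f(d$value)
  }
  d
}

# Sums of squares and df for an arbitrary nesting chain given as a list of
# grouping factors from outermost to innermost; returns per-stratum SS/df
# plus group-size bookkeeping for the EMS coefficients.
nested_strata <- function(y, groups) {
  grand <- mean(y)
  n_lv <- length(groups)
  ss <- df <- numeric(n_lv + 1)
  upper_mean <- rep(grand, length(y))
  n_groups_above <- 1L
  for (k in seq_len(n_lv)) {
    key <- do.call(paste, c(groups[seq_len(k)], sep = "\r"))
    gm <- ave(y, key)
    sizes <- table(key)
    ss[k] <- sum((gm - upper_mean)^2)
    df[k] <- length(sizes) - n_groups_above
    upper_mean <- gm
    n_groups_above <- length(sizes)
  }
  ss[n_lv + 1] <- sum((y - upper_mean)^2)
  df[n_lv + 1] <- length(y) - n_groups_above
  list(ss = ss, df = df)
}

#' Two-level nested variance components for Qst
#'
#' Fits the ANOVA species / accession-in-species / residual on per-individual
#' values (sites are ignored, matching the weak within-species structure the
#' design can resolve) and extracts method-of-moments variance components
#' using unbalanced-design coefficients:
#' \itemize{
#'   \item \code{E[MS_W] = s2_err}
#'   \item \code{E[MS_A] = s2_err + k_rep * s2_betw_acc}
#'   \item \code{E[MS_B] = s2_err + k_rep_b * s2_betw_acc + k_acc * s2_betw_sp}
#' }
#' with \code{k_rep = (N - sum_s sum_a n_sa^2 / N_s) / (A - 2)},
#' \code{k_rep_b = (sum_s sum_a n_sa^2 / N_s - sum n_sa^2 / N)},
#' \code{k_acc = (N - sum_s N_s^2 / N)} (the Sokal-Rohlf weighted
#' coefficients; the species stratum has 1 df so no further division).
#' Negative moment estimates are clamped to zero, with the raw values
#' retained.
#'
#' @param p a \code{phenotype_table} (individual means; repeated
#'   measurements are averaged first).
#' @param trait trait name.
#' @param transform optional transform (function or name, e.g. \code{"log"})
#'   applied to values before the ANOVA.
#' @return a \code{variance_components} object.
#' @export
qst_components <- function(p, trait, transform = NULL) {
  d <- trait_values(individual_means(p), trait, transform)
  sp <- factor(d$species)
  if (nlevels(sp) != 2L)
    qfk_stop("Qst components need exactly two species", "validation_error")
  acc <- paste(d$species, d$accession, sep = "\r")
  vc <- two_level_components(d$value, as.integer(sp),
                             match(acc, unique(acc)))
  vc$trait <- trait
  vc
}

# Workhorse shared with the accession bootstrap: y numeric, sp integer
# species codes (1/2), acc integer accession codes (unique across species).
two_level_components <- function(y, sp, acc) {
  N <- length(y)
  acc_sum <- as.vector(rowsum(y, acc))
  acc_n <- as.vector(rowsum(rep(1, N), acc))
  sp_of_acc <- as.vector(rowsum(sp, acc)) / acc_n  # constant within accession
  A <- length(acc_sum)
  N_s <- as.vector(rowsum(rep(1, N), sp))
  if (length(N_s) != 2L)
    qfk_stop("Qst components need exactly two species", "validation_error")
  acc_per_sp <- as.vector(rowsum(rep(1, A), sp_of_acc))
  if (any(acc_per_sp < 2))
    qfk_stop("each species needs at least 2 accessions for Qst components",
             "undefined_estimate")
  sp_sum <- as.vector(rowsum(y, sp))
  sum_na2_by_sp <- as.vector(rowsum(acc_n^2, sp_of_acc))
  ss_acc_fit <- sum(acc_sum^2 / acc_n)
  ss_sp_fit <- sum(sp_sum^2 / N_s)
  ss <- c(ss_sp_fit - sum(y)^2 / N,        # between species
          ss_acc_fit - ss_sp_fit,          # accessions within species
          sum(y^2) - ss_acc_fit)           # within accessions
  df <- c(1, A - 2, N - A)
  k_rep <- (N - sum(sum_na2_by_sp / N_s)) / (A - 2)
  k_rep_b <- sum(sum_na2_by_sp / N_s) - sum(acc_n^2) / N
  k_acc <- N - sum(N_s^2) / N
  ms <- ss / ifelse(df > 0, df, NA)
  names(ms) <- names(df) <- c("between_species", "between_accessions",
                              "within")
  s2_err <- ms["within"]
  s2_acc_raw <- (ms["between_accessions"] - s2_err) / k_rep
  s2_sp_raw <- (ms["between_species"] - s2_err - k_rep_b * s2_acc_raw) /
    k_acc
  raw <- c(betw_sp = unname(s2_sp_raw), betw_acc = unname(s2_acc_raw),
           err = unname(s2_err))
  structure(list(trait = NA_character_, ms = ms, df = df,
                 sigma2 = pmax(raw, 0), sigma2_raw = raw,
                 k = c(k_rep = k_rep, k_rep_b = k_rep_b, k_acc = k_acc),
                 n = c(individuals = N, accessions = A),
                 n_per_species = as.numeric(N_s)),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("variance components for '%s'\n", x$trait))
  print(round(rbind(MS = x$ms, df = x$df), 4))
  cat("components (clamped at 0):\n")
  print(round(x$sigma2, 4))
  invisible(x)
}

#' The conservative Qst* statistic
#'
#' Qst* = s2_BetwSp / (s2_BetwSp + 2 s2_BetwAcc). Because the
#' between-accession component estimates the total genetic variance (at
#' least the additive part) under selfing, s2_BetwAcc >= V_A and Qst* is an
#' underestimate of Qst, which keeps the Qst-Fst comparison conservative.
#'
#' @param vc a \code{variance_components} object (see
#'   \code{\link{qst_components}}).
#' @return a \code{qst_estimate} with fields \code{trait}, \code{qst_star},
#'   \code{components}.
#' @export
qst_star <- function(vc) {
  s2 <- vc$sigma2
  if (s2["betw_sp"] == 0 && s2["betw_acc"] == 0)
    qfk_stop("Qst* undefined: both variance components are zero",
             "undefined_estimate")
  structure(list(trait = vc$trait,
                 qst_star = unname(s2["betw_sp"] /
                                     (s2["betw_sp"] + 2 * s2["betw_acc"])),
                 components = vc),
            class = "qst_estimate")
}

#' @export
print.qst_estimate <- function(x, ...) {
  cat(sprintf("Qst* (%s) = %.3f\n", x$trait, x$qst_star))
  invisible(x)
}

#' Nested ANOVA divergence test for one trait
#'
#' Three-level nesting (species / site-in-species / accession-in-site /
#' residual) on per-individual means, by method of moments. The species
#' effect is tested against the site-in-species mean square (the next
#' stratum down, per standard nested-ANOVA expected-mean-square logic), or
#' against the accession mean square when the site stratum has no degrees
#' of freedom.
#'
#' @inheritParams qst_components
#' @return a \code{divergence_result}: species means/SDs/N, F ratio, df,
#'   raw p value (\code{p_fdr} is filled by \code{\link{divergence_table}}),
#'   and the relative divergence of the (untransformed) means.
#' @export
divergence_anova <- function(p, trait, transform = NULL) {
  d_raw <- trait_values(individual_means(p), trait, NULL)
  d <- trait_values(individual_means(p), trait, transform)
  sp <- factor(d$species)
  if (nlevels(sp) != 2L)
    qfk_stop("divergence test needs exactly two species", "validation_error")
  site <- paste(d$species, d$site, sep = "\r")
  acc <- paste(site, d$accession, sep = "\r")
  st <- nested_strata(d$value, list(sp, factor(site), factor(acc)))
  ms <- st$ss / ifelse(st$df > 0, st$df, NA)
  # choose the error stratum: site-in-species when it has df, else accession
  if (st$df[2] > 0) {
    f_den <- ms[2]; df2 <- st$df[2]
  } else if (st$df[3] > 0) {
    f_den <- ms[3]; df2 <- st$df[3]
  } else {
    qfk_stop("no degrees of freedom in any error stratum", "undefined_estimate")
  }
  F_ratio <- ms[1] / f_den
  p_raw <- pf(F_ratio, st$df[1], df2, lower.tail = FALSE)
  lv <- levels(sp)
  m <- tapply(d_raw$value, d_raw$species, mean)[lv]
  s <- tapply(d_raw$value, d_raw$species, sd)[lv]
  n <- tapply(d_raw$value, d_raw$species, length)[lv]
  structure(list(trait = trait, species = lv,
                 mean = unname(m), sd = unname(s), n = unname(n),
                 F_ratio = unname(F_ratio), df1 = st$df[1], df2 = df2,
                 p_raw = unname(p_raw), p_fdr = NA_real_,
                 relative_divergence = relative_divergence(m[1], m[2])),
            class = "divergence_result")
}

#' @export
print.divergence_result <- function(x, ...) {
  cat(sprintf(
    "%s: %s %.2f (%.2f), %s %.2f (%.2f); F(%d,%d) = %.3f, p = %.4g, rel. div. = %.2f\n",
    x$trait, x$species[1], x$mean[1], x$sd[1], x$species[2], x$mean[2],
    x$sd[2], x$df1, x$df2, x$F_ratio, x$p_raw, x$relative_divergence))
  invisible(x)
}

default_transforms <- c(pollen_per_ovule = "log")

#' Trait-family divergence table with FDR correction
#'
#' Runs \code{\link{divergence_anova}} for every trait, applies the
#' Benjamini-Hochberg step-up correction across the whole family in one
#' call, and flags traits significant at \code{fdr_alpha}. Pollen per ovule
#' is log-transformed by default; other traits enter untransformed.
#'
#' @param p a \code{phenotype_table}.
#' @param traits traits to test; defaults to every trait present except the
#'   derived \code{internode_sum}.
#' @param fdr_alpha FDR level for the significance flag.
#' @param transforms named character vector of per-trait transform names.
#' @return a data frame, one row per trait, with class
#'   \code{divergence_table}.
#' @export
divergence_table <- function(p, traits = NULL, fdr_alpha = 0.05,
                             transforms = default_transforms) {
  traits <- traits %||% setdiff(unique(as.data.frame(p)$trait),
                                "internode_sum")
  res <- lapply(traits, function(tr)
    divergence_anova(p, tr,
                     transform = if (tr %in% names(transforms))
                       transforms[[tr]] else NULL))
  p_fdr <- p.adjust(vapply(res, `[[`, numeric(1), "p_raw"), method = "BH")
  out <- data.frame(
    trait = traits,
    mean_1 = vapply(res, function(r) r$mean[1], numeric(1)),
    sd_1 = vapply(res, function(r) r$sd[1], numeric(1)),
    n_1 = vapply(res, function(r) r$n[1], numeric(1)),
    mean_2 = vapply(res, function(r) r$mean[2], numeric(1)),
    sd_2 = vapply(res, function(r) r$sd[2], numeric(1)),
    n_2 = vapply(res, function(r) r$n[2], numeric(1)),
    F_ratio = vapply(res, `[[`, numeric(1), "F_ratio"),
    p_raw = vapply(res, `[[`, numeric(1), "p_raw"),
    p_fdr = p_fdr,
    relative_divergence = vapply(res, `[[`, numeric(1),
                                 "relative_divergence"),
    significant = p_fdr < fdr_alpha,
    stringsAsFactors = FALSE)
  attr(out, "species") <- res[[1]]$species
  attr(out, "fdr_alpha") <- fdr_alpha
  class(out) <- c("divergence_table", "data.frame")
  out
}
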