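# Independent oracles and fixture builders. The oracles are deliberately
# written in a different style from the package internals (scalar loops,
# direct textbook formulas) so that agreement is evidence, not tautology.

options(qstfstkit.verbose = FALSE)

# Brute-force Weir-Cockerham (1984) theta for two populations: loop over
# loci, compute a, b, c from first principles, ratio of sums.
wc_oracle <- function(geno, species) {
  sp <- sort(unique(as.character(species)))
  stopifnot(length(sp) == 2)
  r <- 2
  num_total <- 0
  den_total <- 0
  for (l in seq_len(ncol(geno))) {
    ns <- ps <- hs <- numeric(2)
    usable <- TRUE
    for (s in 1:2) {
      gl <- geno[as.character(species) == sp[s], l]
      gl <- gl[!is.na(gl)]
      if (length(gl) < 1) {
        usable <- FALSE
        next
      }
      ns[s] <- length(gl)
      ps[s] <- sum(gl) / (2 * length(gl))
      hs[s] <- sum(gl == 1) / length(gl)
    }
    if (!usable) next
    n_tot <- ns[1] + ns[2]
    nbar <- n_tot / r
    if (nbar <= 1) next
    nc <- (n_tot - (ns[1]^2 + ns[2]^2) / n_tot) / (r - 1)
    pbar <- (ns[1] * ps[1] + ns[2] * ps[2]) / n_tot
    hbar <- (ns[1] * hs[1] + ns[2] * hs[2]) / n_tot
    s2 <- (ns[1] * (ps[1] - pbar)^2 + ns[2] * (ps[2] - pbar)^2) /
      ((r - 1) * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 / 2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    num_total <- num_total + a
    den_total <- den_total + a + b + cc
  }
  num_total / den_total
}

# Hudson two-population estimator, per-locus loop from the printed formula.
hudson_oracle <- function(geno, species) {
  sp <- sort(unique(as.character(species)))
  num_total <- den_total <- 0
  for (l in seq_len(ncol(geno))) {
    g1 <- geno[species == sp[1], l]; g1 <- g1[!is.na(g1)]
    g2 <- geno[species == sp[2], l]; g2 <- g2[!is.na(g2)]
    m1 <- 2 * length(g1); m2 <- 2 * length(g2)
    if (m1 < 2 || m2 < 2) next
    p1 <- sum(g1) / m1; p2 <- sum(g2) / m2
    num_total <- num_total + (p1 - p2)^2 -
      p1 * (1 - p1) / (m1 - 1) - p2 * (1 - p2) / (m2 - 1)
    den_total <- den_total + p1 * (1 - p2) + p2 * (1 - p1)
  }
  num_total / den_total
}

# Benjamini-Hochberg step-up, literal: order p, q_i = p_(i) * m / i,
# enforce monotonicity from the largest down.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# Closed-form maximizer of the rank-one Wishart profile likelihood used for
# rho: c* = tr(G_A^-1 MS_B) / p, rho = (c* - 1) / n0.
rho_oracle <- function(pair) {
  p <- ncol(pair$g_a)
  (sum(diag(solve(pair$g_a) %*% pair$ms_b)) / p - 1) / pair$n0
}

# Balanced two-level EMS solution: s species x a accessions x n reps.
balanced_vc_oracle <- function(df) {
  # df: columns species, accession, value; balanced design assumed
  reps <- table(paste(df$species, df$accession))
  stopifnot(length(unique(reps)) == 1)
  n_rep <- unname(reps[1])
  a_per_sp <- length(unique(paste(df$species, df$accession))) / 2
  fit <- aov(value ~ species + species:accession, data = df)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  s2_err <- ms[3]
  s2_acc <- (ms[2] - s2_err) / n_rep
  s2_sp <- (ms[1] - s2_err - n_rep * s2_acc) / (a_per_sp * n_rep)
  c(betw_sp = s2_sp, betw_acc = s2_acc, err = s2_err)
}

# Small random two-species genotype matrix with entries in {0,1,2}.
toy_genotypes <- function(n_per_sp = 10, n_loci = 20, seed = 1) {
  set.seed(seed)
  g <- matrix(sample(0:2, 2 * n_per_sp * n_loci, replace = TRUE),
              nrow = 2 * n_per_sp)
  genotype_matrix(g, rep(c("spA", "spB"), each = n_per_sp))
}

# Balanced nested phenotype table with explicit effects.
toy_phenotypes <- function(sp_means = c(0, 1), n_site = 2, n_acc_per_site = 2,
                           n_rep = 2, sigma_acc = 0, sigma_err = 0,
                           seed = 1, trait = "y") {
  set.seed(seed)
  rows <- list()
  for (s in 1:2) {
    for (st in seq_len(n_site)) {
      for (a in seq_len(n_acc_per_site)) {
        acc_eff <- rnorm(1, 0, sigma_acc)
        for (r in seq_len(n_rep)) {
          rows[[length(rows) + 1L]] <- data.frame(
            individual = sprintf("s%d_t%d_a%d_r%d", s, st, a, r),
            species = paste0("sp", s), site = sprintf("sp%d_site%d", s, st),
            accession = sprintf("sp%d_t%d_a%d", s, st, a),
            replicate = as.character(r), trait = trait,
            value = sp_means[s] + acc_eff + rnorm(1, 0, sigma_err))
        }
      }
    }
  }
  phenotype_table(do.call(rbind, rows))
}

# Minimal diploid VCF written as text.
write_toy_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", "s4", sep = "\t"),
    paste("chr1", "100", "snp1", "A", "T", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", "0/0", sep = "\t"),
    paste("chr1", "200", "snp2", "G", "C,T", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", "0/0", sep = "\t"),
    paste("chr1", "300", "snp3", "G", "C", ".", "PASS", ".", "GT",
          "./.", "0/1", "1/1", "1/1", sep = "\t"))
  writeLines(lines, path)
  path
}
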