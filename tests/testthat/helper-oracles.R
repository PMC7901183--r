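# Independent oracles used to check the package implementations. Written
# deliberately as plain, slow enumerations sharing no code with R/.

# Brute-force mixture-genotyping posterior: enumerate every genotype
# configuration with nested loops, accumulate log-likelihood + HWE log-prior,
# normalize with log-sum-exp. Returns per-locus posterior matrix (loci x
# configs, config label "g1g2..") and the index of the maximum.
oracle_deconvolve <- function(alt, n, af, weights, error_rate) {
  k <- length(weights)
  gsets <- if (k == 2) {
    expand.grid(g2 = 0:2, g1 = 0:2)[, c("g1", "g2")]
  } else {
    expand.grid(g3 = 0:2, g2 = 0:2, g1 = 0:2)[, c("g1", "g2", "g3")]
  }
  ord <- if (k == 3) order(gsets$g1, gsets$g2, gsets$g3) else order(gsets$g1, gsets$g2)
  gsets <- gsets[ord, , drop = FALSE]
  L <- length(alt)
  post <- matrix(NA_real_, L, nrow(gsets))
  colnames(post) <- apply(gsets, 1, paste, collapse = "")
  map <- integer(L)
  hwe <- function(g, p) choose(2, g) * p^g * (1 - p)^(2 - g)
  for (i in seq_len(L)) {
    lp <- numeric(nrow(gsets))
    for (j in seq_len(nrow(gsets))) {
      q <- sum(unlist(gsets[j, ]) * weights) / 2
      pe <- q * (1 - error_rate) + (1 - q) * error_rate
      ll <- dbinom(alt[i], n[i], pe, log = TRUE)
      pri <- 0
      for (comp in seq_len(k)) pri <- pri + log(hwe(gsets[j, comp], af[i]))
      lp[j] <- ll + pri
    }
    m <- max(lp)
    w <- exp(lp - (m + log(sum(exp(lp - m)))))
    post[i, ] <- w
    map[i] <- which.max(lp)
  }
  list(posterior = post, map = map, configs = as.matrix(gsets))
}

# Closed-form expected mrs of two unrelated Hardy-Weinberg genotypes at a
# single allele frequency, by enumerating the nine genotype pairs.
oracle_mrs_unrelated <- function(af) {
  p <- c((1 - af)^2, 2 * af * (1 - af), af^2)
  num <- 0; den <- 0
  for (a in 0:2) {
    for (b in 0:2) {
      if (a == 0 && b == 0) next
      den <- den + p[a + 1] * p[b + 1]
      if (a == b) num <- num + p[a + 1] * p[b + 1]
    }
  }
  list(p_match = num / den, p_denom = den)
}

# Small panel used by several tests (100 autosomal loci, 10 + 10 ZF).
small_panel <- function(seed = 402) {
  generate_panel(panel_spec(chr13 = 40, chr18 = 30, chr21 = 30,
                            other_autosomes = 0, n_zfx = 10, n_zfy = 10),
                 seed = seed)
}
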