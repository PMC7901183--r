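# Enumerate all 3^k genotype configurations, one row per config, columns
# are components. Row order is lexicographic in (g1, g2, ..., gk).
genotype_configs <- function(k) {
  grid <- expand.grid(rep(list(0:2), k))[, k:1, drop = FALSE]
  cfg <- as.matrix(grid[do.call(order, as.data.frame(grid)), , drop = FALSE])
  dimnames(cfg) <- list(apply(cfg, 1, paste, collapse = ""),
                        paste0("g", seq_len(k)))
  storage.mode(cfg) <- "integer"
  cfg
}

#' Maximum-likelihood joint genotyping of a cfDNA mixture
#'
#' Deconvolves per-locus allele depths of a k-genome mixture into
#' per-component genotypes. For each locus all 3^k genotype configurations
#' (g_1, ..., g_k) are enumerated; the likelihood of a configuration is
#' Binomial(alt_count | n, p) with expected alt fraction
#' q = sum_k w_k g_k / 2 and read-error adjustment
#' p = q(1 - eps) + (1 - q) eps; the prior is the product of
#' Hardy-Weinberg genotype probabilities at the locus's population allele
#' frequency, treating components as independent population draws (a flat
#' prior is available for sensitivity analysis). The maximum a posteriori
#' configuration and the full posterior are reported. With k = 2 this is
#' pseudo-tetraploid genotyping (the classic maternal/fetal plasma model);
#' k = 3 extends it to a pseudo-hexaploid model with an additional donor
#' component.
#'
#' Posterior ties (possible at symmetric q) are broken toward the
#' configuration with the higher prior, then toward the lexicographically
#' smallest configuration; a message reports how many loci required a
#' tie-break. Loci with zero depth are emitted as missing.
#'
#' @param depths Data frame with columns `region_id`, `ref_count`,
#'   `alt_count`.
#' @param weights Mixture fractions of the k components (k = 2 or 3), each
#'   strictly positive, summing to 1 within 1e-9. A zero weight is an
#'   error: that component's genotype is unidentifiable and should be
#'   dropped by the caller.
#' @param pop_af Named vector of population alt-allele frequencies (names
#'   are `region_id`s), or a `cfmix_panel` to take them from.
#' @param error_rate Per-read substitution error eps in [0, 0.5).
#' @param prior `"hwe"` (default) or `"flat"`.
#' @return A data frame of class `cfmix_calls` with columns `region_id`,
#'   `g1` ... `gk`, `map_posterior`, `loglik`, `q_hat` (expected alt
#'   fraction of the MAP configuration); missing calls carry `NA`. The
#'   full per-locus posterior over configurations is attached as attribute
#'   `"posterior"` (loci x 3^k), the configuration matrix as `"configs"`,
#'   and `weights` as `"weights"`.
#' @export
deconvolve <- function(depths, weights, pop_af, error_rate = 0.005,
                       prior = c("hwe", "flat")) {
  prior <- match.arg(prior)
  k <- length(weights)
  if (!k %in% 2:3)
    stop("deconvolve supports k = 2 (pseudo-tetraploid) or k = 3 (pseudo-hexaploid)")
  if (any(weights <= 0))
    stop("all mixture weights must be strictly positive; drop zero-weight components")
  if (abs(sum(weights) - 1) > 1e-9)
    stop("mixture weights must sum to 1")
  stopifnot(error_rate >= 0, error_rate < 0.5,
            all(c("region_id", "ref_count", "alt_count") %in% names(depths)))
  if (inherits(pop_af, "cfmix_panel")) {
    auto <- panel_autosomal(pop_af)
    pop_af <- stats::setNames(auto$pop_af, auto$region_id)
  }
  af <- pop_af[depths$region_id]
  if (anyNA(af))
    stop("missing pop_af for region ", depths$region_id[which(is.na(af))[1]])

  cfg <- genotype_configs(k)
  ncfg <- nrow(cfg)
  q <- as.vector(cfg %*% weights) / 2
  p <- seq_error_prob(q, error_rate)
  n <- depths$ref_count + depths$alt_count
  alt <- depths$alt_count
  L <- length(n)

  loglik <- matrix(0, L, ncfg)
  logpri <- matrix(0, L, ncfg)
  for (j in seq_len(ncfg)) {
    loglik[, j] <- stats::dbinom(alt, n, p[j], log = TRUE)
    if (prior == "hwe") {
      lp <- 0
      for (comp in seq_len(k))
        lp <- lp + stats::dbinom(cfg[j, comp], 2L, af, log = TRUE)
      logpri[, j] <- lp
    }
  }
  logpost <- loglik + logpri
  lmax <- apply(logpost, 1, max)
  post <- exp(logpost - lmax)
  post <- post / rowSums(post)
  dimnames(post) <- list(depths$region_id, rownames(cfg))

  # MAP with tie-breaks: higher prior first, then lexicographically
  # smallest config (configs are enumerated in lexicographic order).
  map_idx <- integer(L)
  ties <- 0L
  for (i in seq_len(L)) {
    top <- which(logpost[i, ] >= max(logpost[i, ]) - 1e-9)
    if (length(top) > 1L) {
      ties <- ties + 1L
      top <- top[order(-logpri[i, top], top)]
    }
    map_idx[i] <- top[1]
  }
  if (ties > 0) message(sprintf("deconvolve: %d loci required a posterior tie-break", ties))

  calls <- data.frame(region_id = depths$region_id, stringsAsFactors = FALSE)
  for (comp in seq_len(k)) calls[[paste0("g", comp)]] <- cfg[map_idx, comp]
  calls$map_posterior <- post[cbind(seq_len(L), map_idx)]
  calls$loglik <- loglik[cbind(seq_len(L), map_idx)]
  calls$q_hat <- q[map_idx]
  calls$n <- n
  calls$alt_count <- alt

  zero <- n == 0
  if (any(zero)) {
    for (comp in seq_len(k)) calls[[paste0("g", comp)]][zero] <- NA_integer_
    calls$map_posterior[zero] <- NA_real_
    calls$loglik[zero] <- NA_real_
    calls$q_hat[zero] <- NA_real_
    post[zero, ] <- NA_real_
  }

  structure(calls, posterior = post, configs = cfg, weights = weights,
            error_rate = error_rate, prior = prior,
            class = c("cfmix_calls", "data.frame"))
}

#' Split two-component calls into major and minor genotype rows
#'
#' Takes k = 2 deconvolution calls and emits two genotype vectors named
#' `<sample_id>major` (the larger-weight component) and
#' `<sample_id>minor`. Loci whose MAP posterior falls below
#' `posterior_floor` are set to missing so that low-confidence calls do
#' not pollute downstream relatedness denominators.
#'
#' In addition, loci where even the best two-genome configuration cannot
#' explain the observed allele fraction are flagged missing: when the
#' sample actually mixes more than two genomes, loci where the pooled
#' major genomes disagree sit many standard deviations from every
#' two-genome expectation, and emitting a forced call there would corrupt
#' both rows. The filter is a two-sided binomial tail test of the
#' alt-read count under the MAP configuration's expected fraction;
#' `misfit_alpha = 0` disables it.
#'
#' @param calls A `cfmix_calls` from a k = 2 [deconvolve()] run.
#' @param sample_id Prefix for the two row names.
#' @param posterior_floor Minimum MAP posterior to emit a call (default
#'   0.9).
#' @param misfit_alpha Significance level of the model-misfit filter
#'   (default 1e-4).
#' @return A 2 x n_loci integer matrix with rows `<sample_id>major`,
#'   `<sample_id>minor` and columns named by `region_id`.
#' @export
split_major_minor <- function(calls, sample_id = "sample",
                              posterior_floor = 0.9, misfit_alpha = 1e-4) {
  stopifnot(inherits(calls, "cfmix_calls"), misfit_alpha >= 0,
            misfit_alpha < 1)
  w <- attr(calls, "weights")
  if (length(w) != 2) stop("split_major_minor requires k = 2 calls")
  if (w[1] == w[2]) stop("equal weights: major/minor labels are undefined")
  keep <- !is.na(calls$map_posterior) & calls$map_posterior >= posterior_floor
  if (misfit_alpha > 0) {
    p_hat <- seq_error_prob(calls$q_hat, attr(calls, "error_rate"))
    lower <- stats::pbinom(calls$alt_count, calls$n, p_hat)
    upper <- stats::pbinom(calls$alt_count - 1L, calls$n, p_hat,
                           lower.tail = FALSE)
    fit_p <- pmin(1, 2 * pmin(lower, upper))
    keep <- keep & !is.na(fit_p) & fit_p >= misfit_alpha
  }
  g1 <- ifelse(keep, calls$g1, NA_integer_)
  g2 <- ifelse(keep, calls$g2, NA_integer_)
  major_first <- w[1] > w[2]
  out <- rbind(if (major_first) g1 else g2,
               if (major_first) g2 else g1)
  storage.mode(out) <- "integer"
  dimnames(out) <- list(paste0(sample_id, c("major", "minor")),
                        calls$region_id)
  out
}

#' Minor-allele-fraction spectrum and band-deviation diagnostic
#'
#' A single diploid genome sequenced deeply shows three bands of per-locus
#' alt fractions centered at 0, 0.5 and 1 (hom-ref, het, hom-alt); DNA
#' admixture from additional genomes creates intermediate levels. The
#' band deviation is the fraction of well-covered loci whose alt fraction
#' lies outside delta-neighborhoods of {0, 0.5, 1} — a simple scalar
#' summary of how mixed the sample is.
#'
#' @param depths Data frame with `region_id`, `ref_count`, `alt_count`.
#' @param min_depth Minimum total depth for a locus to enter the spectrum
#'   (>= 1).
#' @param delta Half-width of each band, in (0, 0.25).
#' @return A list of class `cfmix_maf` with `af` (named vector of alt
#'   fractions), `band_deviation`, `min_depth`, `delta`.
#' @export
maf_spectrum <- function(depths, min_depth = 50, delta = 0.1) {
  stopifnot(min_depth >= 1, delta > 0, delta < 0.25)
  n <- depths$ref_count + depths$alt_count
  keep <- n >= min_depth
  if (!any(keep)) stop("no locus reaches min_depth ", min_depth)
  af <- depths$alt_count[keep] / n[keep]
  names(af) <- depths$region_id[keep]
  dist_to_band <- pmin(af, abs(af - 0.5), 1 - af)
  structure(list(af = af, band_deviation = mean(dist_to_band > delta),
                 min_depth = min_depth, delta = delta),
            class = "cfmix_maf")
}

#' @export
print.cfmix_maf <- function(x, ...) {
  cat(sprintf("<cfmix_maf> %d loci (depth >= %g): band deviation %.3f (delta %.2f)\n",
              length(x$af), x$min_depth, x$band_deviation, x$delta))
  invisible(x)
}

#' Call diploid genotypes for a single-genome sample
#'
#' MAP genotype per locus under the same binomial read model as
#' [deconvolve()] with k = 1: likelihood Binomial(alt | n, p) with
#' p = (g/2)(1 - eps) + (1 - g/2) eps, Hardy-Weinberg prior at the
#' population allele frequency. Loci with zero depth or MAP posterior
#' below `posterior_floor` are missing.
#'
#' @inheritParams deconvolve
#' @param posterior_floor Minimum posterior to emit a call.
#' @return Named integer vector of genotypes (0/1/2, `NA` when missing).
#' @export
call_genotypes <- function(depths, pop_af, error_rate = 0.005,
                           posterior_floor = 0.9) {
  stopifnot(error_rate >= 0, error_rate < 0.5)
  if (inherits(pop_af, "cfmix_panel")) {
    auto <- panel_autosomal(pop_af)
    pop_af <- stats::setNames(auto$pop_af, auto$region_id)
  }
  af <- pop_af[depths$region_id]
  if (anyNA(af))
    stop("missing pop_af for region ", depths$region_id[which(is.na(af))[1]])
  n <- depths$ref_count + depths$alt_count
  alt <- depths$alt_count
  p <- seq_error_prob(c(0, 0.5, 1), error_rate)
  logpost <- vapply(1:3, function(j)
    stats::dbinom(alt, n, p[j], log = TRUE) +
      stats::dbinom(j - 1L, 2L, af, log = TRUE),
    numeric(length(n)))
  logpost <- matrix(logpost, ncol = 3)
  lmax <- apply(logpost, 1, max)
  post <- exp(logpost - lmax)
  post <- post / rowSums(post)
  g <- max.col(post, ties.method = "first") - 1L
  conf <- post[cbind(seq_along(g), g + 1L)]
  g[n == 0 | conf < posterior_floor] <- NA_integer_
  stats::setNames(as.integer(g), depths$region_id)
}
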