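#' Match-ratio statistic (mrs) between two genotype vectors
#'
#' The mrs of a sample pair is the number of identical genotypes at shared
#' loci divided by the total number of common non-reference loci: shared
#' loci are those called (non-missing) in both samples; the denominator
#' keeps shared loci where at least one of the two genotypes is
#' non-reference (> 0); the numerator counts denominator loci where the
#' two genotypes are identical. Loci where both samples are homozygous
#' reference carry no information about sharing of rare material and are
#' excluded from both counts.
#'
#' `mode = "both"` restricts the denominator to loci non-reference in both
#' samples, an alternative reading of "common non-reference" provided for
#' sensitivity analysis.
#'
#' @param gt_a,gt_b Integer genotype vectors (0/1/2, `NA` = missing)
#'   indexed on the same panel (equal length, same locus order).
#' @param mode `"either"` (default) or `"both"`.
#' @return A list of class `cfmix_mrs` with `mrs`, `n_shared`,
#'   `n_denominator`.
#' @examples
#' mrs(c(0, 1, 2, 1), c(1, 1, 2, 0))  # denominator 4, numerator 2 -> 0.5
#' @export
mrs <- function(gt_a, gt_b, mode = c("either", "both")) {
  mode <- match.arg(mode)
  stopifnot(length(gt_a) == length(gt_b))
  shared <- !is.na(gt_a) & !is.na(gt_b)
  nonref <- if (mode == "either") (gt_a > 0 | gt_b > 0) else (gt_a > 0 & gt_b > 0)
  denom <- shared & nonref
  n_den <- sum(denom)
  if (n_den == 0)
    stop("no common non-reference loci: mrs undefined for this pair")
  structure(list(mrs = sum(denom & gt_a == gt_b) / n_den,
                 n_shared = sum(shared), n_denominator = n_den),
            class = "cfmix_mrs")
}

#' @export
print.cfmix_mrs <- function(x, ...) {
  cat(sprintf("<cfmix_mrs> %.4f (%d of %d common non-reference loci; %d shared)\n",
              x$mrs, round(x$mrs * x$n_denominator), x$n_denominator,
              x$n_shared))
  invisible(x)
}

#' Classify a pairwise relationship from its mrs value
#'
#' Thresholds the mrs into `MZD` (duplicate of the same biological sample
#' or monozygotic-twin equivalent), `1st` (first-degree relatives) and
#' `NR` (no biological relationship): mrs >= `t_mzd` is MZD,
#' `t_first` <= mrs < `t_mzd` is 1st (closed lower bound), mrs < `t_first`
#' is NR. A value within `margin` of either threshold is reported as
#' `ambiguous` — mixture-contaminated components often sit between
#' classes.
#'
#' @param mrs_value Numeric mrs in [0, 1] (or a `cfmix_mrs`).
#' @param t_mzd,t_first Class thresholds with `t_mzd > t_first`, e.g. from
#'   [calibrate_thresholds()].
#' @param margin Half-width of the ambiguity band around each threshold
#'   (default 0 = never ambiguous).
#' @return One of `"MZD"`, `"1st"`, `"NR"`, `"ambiguous"`.
#' @export
classify_relationship <- function(mrs_value, t_mzd, t_first, margin = 0) {
  if (inherits(mrs_value, "cfmix_mrs")) mrs_value <- mrs_value$mrs
  stopifnot(t_mzd > t_first, margin >= 0)
  if (margin > 0 &&
      (abs(mrs_value - t_mzd) < margin || abs(mrs_value - t_first) < margin))
    return("ambiguous")
  if (mrs_value >= t_mzd) "MZD" else if (mrs_value >= t_first) "1st" else "NR"
}

#' Calibrate mrs classification thresholds by simulation
#'
#' Simulates pedigrees on the panel and computes mrs for three kinds of
#' pairs: duplicates (the same genome observed twice with independent
#' per-locus genotyping error), first-degree relatives (mother vs her
#' sibling donor) and unrelated individuals (mother vs father). Each
#' threshold is the midpoint between adjacent class means. If the classes
#' overlap so much that more than `confusion_tol` of simulated pairs would
#' be misclassified at the chosen thresholds, a warning is raised.
#'
#' @param panel A `cfmix_panel`.
#' @param n_reps Number of simulated pedigrees (>= 50).
#' @param seed Integer seed.
#' @param genotyping_error Per-locus miscall probability applied to each
#'   duplicate copy (default 0.01).
#' @param confusion_tol Tolerated misclassification fraction before
#'   warning (default 0.05).
#' @return A list of class `cfmix_thresholds` with `t_mzd`, `t_first`,
#'   `class_stats` (mean/sd/n per class) and `values` (per-class mrs
#'   vectors).
#' @export
calibrate_thresholds <- function(panel, n_reps = 100, seed = 1L,
                                 genotyping_error = 0.01,
                                 confusion_tol = 0.05) {
  stopifnot(n_reps >= 50)
  vals <- list(MZD = numeric(0), `1st` = numeric(0), NR = numeric(0))
  safe_mrs <- function(a, b)
    tryCatch(mrs(a, b)$mrs, error = function(e) NA_real_)
  for (r in seq_len(n_reps)) {
    ped <- simulate_pedigree(panel, derive_seed(seed, r))
    G <- ped$genotypes
    dup_a <- perturb_genotypes(G["mother", ], genotyping_error,
                               derive_seed(seed, r + n_reps))
    dup_b <- perturb_genotypes(G["mother", ], genotyping_error,
                               derive_seed(seed, r + 2L * n_reps))
    vals$MZD <- c(vals$MZD, safe_mrs(dup_a, dup_b))
    vals$`1st` <- c(vals$`1st`, safe_mrs(G["mother", ], G["bm_donor", ]))
    vals$NR <- c(vals$NR, safe_mrs(G["mother", ], G["father", ]))
  }
  vals <- lapply(vals, function(v) v[!is.na(v)])
  if (any(lengths(vals) == 0)) {
    warning("panel too small to separate relationship classes; thresholds unreliable")
    vals <- lapply(vals, function(v) if (length(v)) v else NA_real_)
  }
  mu <- vapply(vals, mean, 0, na.rm = TRUE)
  t_mzd <- (mu[["MZD"]] + mu[["1st"]]) / 2
  t_first <- (mu[["1st"]] + mu[["NR"]]) / 2
  labels <- rep(names(vals), lengths(vals))
  pooled <- unlist(vals, use.names = FALSE)
  predicted <- vapply(pooled, function(v) {
    if (is.na(v)) return(NA_character_)
    classify_relationship(v, t_mzd, t_first)
  }, "")
  confusion <- mean(predicted != labels, na.rm = TRUE)
  if (is.na(confusion) || confusion > confusion_tol)
    warning(sprintf("relationship classes overlap: %.1f%% confusion at calibrated thresholds",
                    100 * confusion))
  class_stats <- data.frame(class = names(vals),
                            mean = mu,
                            sd = vapply(vals, stats::sd, 0),
                            n = lengths(vals), row.names = NULL)
  structure(list(t_mzd = t_mzd, t_first = t_first,
                 class_stats = class_stats, values = vals,
                 confusion = confusion),
            class = "cfmix_thresholds")
}

#' @export
print.cfmix_thresholds <- function(x, ...) {
  cat(sprintf("<cfmix_thresholds> t_mzd %.3f, t_first %.3f (confusion %.1f%%)\n",
              x$t_mzd, x$t_first, 100 * x$confusion))
  print(x$class_stats)
  invisible(x)
}

#' Identity-by-state distance matrix
#'
#' PLINK-style allele-sharing distance between genotype rows:
#' IBS(g_a, g_b) = 2 - |g_a - g_b| alleles shared at a locus, and
#' distance(a, b) = 1 - sum(IBS) / (2 * n_shared) over loci called in
#' both samples.
#'
#' @param genotypes Samples x loci matrix of genotypes (0/1/2, `NA`
#'   allowed) with row names.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
ibs_distance <- function(genotypes) {
  G <- as.matrix(genotypes)
  n <- nrow(G)
  if (n < 2) stop("need at least 2 samples")
  D <- matrix(0, n, n, dimnames = list(rownames(G), rownames(G)))
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      shared <- !is.na(G[a, ]) & !is.na(G[b, ])
      if (!any(shared))
        stop(sprintf("samples %s and %s share no called loci",
                     rownames(G)[a], rownames(G)[b]))
      ibs <- 2 - abs(G[a, shared] - G[b, shared])
      D[a, b] <- D[b, a] <- 1 - sum(ibs) / (2 * sum(shared))
    }
  }
  D
}

#' Classical (metric) multidimensional scaling of a distance matrix
#'
#' Torgerson's method: double-center the squared distances,
#' eigendecompose, and return the top-k coordinates scaled by the square
#' root of the eigenvalues. Negative eigenvalues (the IBS distance need
#' not be Euclidean) are truncated to zero with a warning.
#'
#' @param d Square symmetric distance matrix.
#' @param k Embedding dimension, `k < nrow(d)`.
#' @return n x k coordinate matrix (row names preserved).
#' @export
classical_mds <- function(d, k = 2) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (k >= n) stop("embedding dimension k must be smaller than the number of samples")
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  if (any(e$values < -1e-8 * max(abs(e$values))))
    warning("negative eigenvalues truncated: distances are not exactly Euclidean")
  lambda <- pmax(e$values[seq_len(k)], 0)
  coords <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(lambda), k)
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("C", seq_len(k))
  coords
}

#' Pairwise relatedness table for a set of samples
#'
#' Computes mrs and a relationship class for every sample pair and
#' returns them sorted by descending mrs, the shape of a relatedness
#' report table.
#'
#' @inheritParams ibs_distance
#' @inheritParams classify_relationship
#' @param mode Denominator mode passed to [mrs()].
#' @return Data frame with columns `pair`, `sample_a`, `sample_b`, `mrs`,
#'   `n_shared`, `n_denominator`, `class`.
#' @export
relatedness_table <- function(genotypes, t_mzd, t_first, margin = 0,
                              mode = "either") {
  G <- as.matrix(genotypes)
  n <- nrow(G)
  if (n < 2) stop("need at least 2 samples")
  rows <- list()
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      rec <- mrs(G[a, ], G[b, ], mode = mode)
      rows[[length(rows) + 1L]] <- data.frame(
        pair = paste(rownames(G)[a], rownames(G)[b], sep = "-"),
        sample_a = rownames(G)[a], sample_b = rownames(G)[b],
        mrs = rec$mrs, n_shared = rec$n_shared,
        n_denominator = rec$n_denominator,
        class = classify_relationship(rec$mrs, t_mzd, t_first, margin),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(-out$mrs), , drop = FALSE]
}
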