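#' Sex-chromosome dosage of a sample from ZFX/ZFY depths
#'
#' Estimates X and Y copy numbers by normalizing mean ZFX/ZFY region depth
#' against a known 46,XX calibration sample, for which CN_X = 2 and
#' CN_Y = 0: `cn_x = 2 * mean(zfx) / female_ref_depth` and likewise for Y.
#' Shares are the copy numbers normalized to sum to 1, the scale on which
#' a sample that is m male : (1 - m) female reads
#' x_share = (2 - m)/2, y_share = m/2.
#'
#' @param zfx_depths,zfy_depths Numeric vectors of per-region depths
#'   (at least one each).
#' @param female_ref_depth Mean ZFX depth of a known 46,XX calibrator
#'   (> 0).
#' @return A list of class `cfmix_xydosage` with `cn_x`, `cn_y`,
#'   `x_share`, `y_share`.
#' @export
xy_dosage <- function(zfx_depths, zfy_depths, female_ref_depth) {
  stopifnot(length(zfx_depths) >= 1, length(zfy_depths) >= 1,
            female_ref_depth > 0)
  if (all(c(zfx_depths, zfy_depths) == 0))
    stop("all ZFX/ZFY depths are zero; dosage undefined")
  cn_x <- 2 * mean(zfx_depths) / female_ref_depth
  cn_y <- 2 * mean(zfy_depths) / female_ref_depth
  tot <- cn_x + cn_y
  structure(list(cn_x = cn_x, cn_y = cn_y,
                 x_share = cn_x / tot, y_share = cn_y / tot),
            class = "cfmix_xydosage")
}

#' @export
print.cfmix_xydosage <- function(x, ...) {
  cat(sprintf("<cfmix_xydosage> CN_X %.3f, CN_Y %.3f (shares %.3f / %.3f)\n",
              x$cn_x, x$cn_y, x$x_share, x$y_share))
  invisible(x)
}

#' X:Y dosage shares implied by a male-DNA fraction
#'
#' Forward model: a sample that is a fraction m male (46,XY) and 1 - m
#' female (46,XX) has CN_X = 2 - m and CN_Y = m, so on the normalized
#' scale x_share = (2 - m)/2 and y_share = m/2.
#'
#' @param m Male-DNA fraction in [0, 1].
#' @return Named numeric vector `c(x_share, y_share)`.
#' @export
dosage_shares_from_male_fraction <- function(m) {
  stopifnot(m >= 0, m <= 1)
  c(x_share = (2 - m) / 2, y_share = m / 2)
}

#' Male-DNA fraction from X:Y dosage
#'
#' Inverts the forward model of [dosage_shares_from_male_fraction()]:
#' m = 2 * y_share, clipped to [0, 1] with a warning (noisy dosage near
#' the boundaries is expected).
#'
#' @param dosage A `cfmix_xydosage`.
#' @return Male-DNA fraction m in [0, 1].
#' @export
male_fraction_from_xy <- function(dosage) {
  stopifnot(inherits(dosage, "cfmix_xydosage"))
  m <- 2 * dosage$y_share
  if (m < 0 || m > 1) {
    warning(sprintf("male fraction %.4f outside [0, 1]; clipped", m))
    m <- min(max(m, 0), 1)
  }
  m
}

#' Call sample sex from X:Y dosage
#'
#' Thresholds the male-DNA fraction m: below `t_low` the sample is called
#' female, above `t_high` male, otherwise a mixed sample (e.g. plasma
#' containing genomes of both sexes) with m reported. The defaults sit far
#' outside counting noise at typical panel depths.
#'
#' @param dosage A `cfmix_xydosage`.
#' @param t_low,t_high Thresholds on m (0 < t_low < t_high < 1).
#' @return A list of class `cfmix_sexcall` with `label` in
#'   `{"female", "male", "mixed"}` and `male_fraction`.
#' @export
infer_sex <- function(dosage, t_low = 0.05, t_high = 0.95) {
  stopifnot(t_low > 0, t_high < 1, t_low < t_high)
  m <- male_fraction_from_xy(dosage)
  label <- if (m < t_low) "female" else if (m > t_high) "male" else "mixed"
  structure(list(label = label, male_fraction = m), class = "cfmix_sexcall")
}

#' @export
print.cfmix_sexcall <- function(x, ...) {
  cat(sprintf("<cfmix_sexcall> %s (male fraction %.3f)\n",
              x$label, x$male_fraction))
  invisible(x)
}

#' Three-component fractions from male-DNA and placental fractions
#'
#' Splits a plasma sample into (A) donor-hematopoietic, (B) residual
#' maternal and (C) placental fractions given the total male-DNA fraction
#' m (from Y dosage) and the placental fraction f (from an external
#' fetal-fraction estimate or [estimate_fractions_ls()]). The donor is
#' male and the mother female, so for a male (XY) fetus
#' (w_A, w_B, w_C) = (m - f, 1 - m, f); for a female (XX) fetus
#' (w_A, w_B, w_C) = (m, 1 - m - f, f). An XY fetus with f > m, or an XX
#' fetus with m + f > 1, contradicts the stated sex and raises an error.
#'
#' @param m Male-DNA fraction in [0, 1].
#' @param f Placental fraction in [0, 1].
#' @param fetal_sex `"XY"` or `"XX"`.
#' @return A list of class `cfmix_fractions` with `w_A`, `w_B`, `w_C` and
#'   karyotype labels `sex_A`, `sex_B`, `sex_C`.
#' @examples
#' component_fractions(0.82, 0.0936, "XY")  # 0.7264 / 0.18 / 0.0936
#' @export
component_fractions <- function(m, f, fetal_sex = c("XY", "XX")) {
  fetal_sex <- match.arg(fetal_sex)
  stopifnot(m >= 0, m <= 1, f >= 0, f <= 1)
  tol <- 1e-9
  if (fetal_sex == "XY") {
    if (f > m + tol)
      stop(sprintf(paste("placental fraction %.4f exceeds male fraction %.4f:",
                         "inconsistent with a male fetus"), f, m))
    w <- c(A = m - f, B = 1 - m, C = f)
  } else {
    if (m + f > 1 + tol)
      stop(sprintf(paste("male fraction %.4f + placental fraction %.4f exceed 1:",
                         "inconsistent with a female fetus"), m, f))
    w <- c(A = m, B = 1 - m - f, C = f)
  }
  w <- pmin(pmax(w, 0), 1)
  structure(list(w_A = w[["A"]], w_B = w[["B"]], w_C = w[["C"]],
                 sex_A = "46,XY", sex_B = "46,XX",
                 sex_C = if (fetal_sex == "XY") "46,XY" else "46,XX"),
            class = "cfmix_fractions")
}

#' @export
print.cfmix_fractions <- function(x, ...) {
  cat(sprintf(paste0("<cfmix_fractions> A (%s, %.2f%%), B (%s, %.2f%%), ",
                     "C (%s, %.2f%%)\n"),
              x$sex_A, 100 * x$w_A, x$sex_B, 100 * x$w_B, x$sex_C, 100 * x$w_C))
  invisible(x)
}

#' Estimate mixture fractions from SNP allele balance by least squares
#'
#' Given per-locus plasma alt-allele fractions and the genotypes of k
#' candidate component genomes, finds the simplex weights minimizing
#' sum_l (af_l - sum_k w_k g_lk / 2)^2. Solved by non-negative least
#' squares followed by normalization to the simplex; with noiseless input
#' the recovery is exact. A rank-deficient genotype matrix (components
#' indistinguishable on the panel) is flagged and warned about.
#'
#' @param plasma_af Numeric vector of per-locus alt fractions in [0, 1].
#' @param G Loci x k matrix of candidate genotypes in 0/1/2.
#' @return A list of class `cfmix_lsfit` with `weights` (length k, sums
#'   to 1), `objective` (residual sum of squares at the solution) and
#'   `degenerate` flag.
#' @export
estimate_fractions_ls <- function(plasma_af, G) {
  G <- as.matrix(G)
  stopifnot(length(plasma_af) == nrow(G), all(G %in% 0:2),
            all(plasma_af >= 0), all(plasma_af <= 1))
  k <- ncol(G)
  informative <- apply(G, 1, function(g) length(unique(g)) > 1) | k == 1
  if (sum(informative) < k)
    stop("fewer informative loci than components; fractions unidentifiable")
  A <- G / 2
  degenerate <- qr(A)$rank < k
  if (degenerate)
    warning("genotype matrix is rank-deficient: components are indistinguishable on this panel")
  fit <- pracma::lsqnonneg(A, as.numeric(plasma_af))
  w <- fit$x
  if (sum(w) <= 0) {
    degenerate <- TRUE
    warning("non-negative least squares returned the zero vector; returning uniform weights")
    w <- rep(1 / k, k)
  } else {
    w <- w / sum(w)
  }
  names(w) <- colnames(G)
  structure(list(weights = w,
                 objective = sum((plasma_af - as.vector(A %*% w))^2),
                 degenerate = degenerate),
            class = "cfmix_lsfit")
}

#' @export
print.cfmix_lsfit <- function(x, ...) {
  cat("<cfmix_lsfit> weights:",
      paste(sprintf("%.4f", x$weights), collapse = " / "),
      sprintf("(RSS %.4g%s)\n", x$objective,
              if (x$degenerate) ", DEGENERATE" else ""))
  invisible(x)
}
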