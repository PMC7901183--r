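#' Simulate the case pedigree on a panel
#'
#' Draws unphased diploid genotypes (0/1/2 alt-allele copies) for the five
#' genomes involved in the case: the mother, her bone-marrow donor (a
#' first-degree relative), an unrelated egg donor, the father, and the fetus
#' conceived from egg donor x father. Founders are drawn per locus from
#' Binomial(2, pop_af) (Hardy-Weinberg equilibrium); children receive one
#' allele from each parent by independent Mendelian transmission. Under the
#' default `donor_mode = "sibling"` the donor is a full sibling of the
#' mother (IBD 0/1/2 with probability 1/4, 1/2, 1/4 per locus); the
#' `"parent"` mode makes the donor one of the mother's parents instead.
#'
#' Note that in this pedigree the fetus is genetically unrelated to the
#' mother: the oocyte came from an unrelated egg donor.
#'
#' @param panel A `cfmix_panel`; only autosomal SNP regions are used.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param donor_mode `"sibling"` (default) or `"parent"`.
#' @return A list of class `cfmix_pedigree` with element `genotypes`, a
#'   5 x n_loci integer matrix with rows `mother`, `bm_donor`, `egg_donor`,
#'   `father`, `fetus` and columns named by `region_id`, plus `pop_af`,
#'   `donor_mode` and `seed`.
#' @export
simulate_pedigree <- function(panel, seed = 1L,
                              donor_mode = c("sibling", "parent")) {
  donor_mode <- match.arg(donor_mode)
  auto <- panel_autosomal(panel)
  if (nrow(auto) == 0) stop("panel has no autosomal SNP regions")
  af <- auto$pop_af
  L <- length(af)
  with_seed(seed, {
    founder <- function() stats::rbinom(L, 2L, af)
    child <- function(g1, g2)
      stats::rbinom(L, 1L, g1 / 2) + stats::rbinom(L, 1L, g2 / 2)
    gp1 <- founder(); gp2 <- founder()       # mother's parents
    mother <- child(gp1, gp2)
    bm_donor <- if (donor_mode == "sibling") child(gp1, gp2) else gp1
    egg_donor <- founder()
    father <- founder()
    fetus <- child(egg_donor, father)
    G <- rbind(mother = mother, bm_donor = bm_donor, egg_donor = egg_donor,
               father = father, fetus = fetus)
    storage.mode(G) <- "integer"
    colnames(G) <- auto$region_id
    structure(list(genotypes = G,
                   pop_af = stats::setNames(af, auto$region_id),
                   donor_mode = donor_mode, seed = seed),
              class = "cfmix_pedigree")
  })
}

#' @export
print.cfmix_pedigree <- function(x, ...) {
  cat(sprintf("<cfmix_pedigree> %d loci, donor mode '%s' (seed %d)\n",
              ncol(x$genotypes), x$donor_mode, x$seed))
  cat("roles:", paste(rownames(x$genotypes), collapse = ", "), "\n")
  invisible(x)
}

# Sequencing model shared by the read simulators: a read drawn from a
# template pool with alt-allele fraction q reports the alt allele with
# probability p = q(1 - eps) + (1 - q) eps, where eps is the per-read
# substitution error rate.
seq_error_prob <- function(q, error_rate) q * (1 - error_rate) + (1 - q) * error_rate

sim_allele_counts <- function(region_id, q, depth, error_rate, depth_model) {
  L <- length(q)
  n <- switch(depth_model,
              poisson = stats::rpois(L, depth),
              fixed = rep.int(as.integer(round(depth)), L))
  alt <- stats::rbinom(L, n, seq_error_prob(q, error_rate))
  data.frame(region_id = region_id, ref_count = as.integer(n - alt),
             alt_count = as.integer(alt), stringsAsFactors = FALSE)
}

#' Simulate targeted sequencing allele depths for a single genome
#'
#' Per locus, total depth n ~ Poisson(`depth`) (or fixed at `depth` under
#' `depth_model = "fixed"`), and the alt-read count is
#' Binomial(n, p) with p = (g/2)(1 - eps) + (1 - g/2) eps for genotype g.
#'
#' @param genotypes Named integer vector of genotypes in 0/1/2, names are
#'   `region_id`s.
#' @param depth Mean reads per locus (> 0).
#' @param error_rate Per-read substitution error eps in [0, 0.5); default
#'   0.005, typical of hybrid-capture sequencing.
#' @param seed Integer seed.
#' @param depth_model `"poisson"` (default) or `"fixed"`.
#' @return Data frame with columns `region_id`, `ref_count`, `alt_count`.
#' @export
simulate_gdna_reads <- function(genotypes, depth, error_rate = 0.005,
                                seed = 1L, depth_model = c("poisson", "fixed")) {
  depth_model <- match.arg(depth_model)
  stopifnot(depth > 0, error_rate >= 0, error_rate < 0.5,
            all(genotypes %in% 0:2), !is.null(names(genotypes)))
  with_seed(seed,
    sim_allele_counts(names(genotypes), genotypes / 2, depth, error_rate,
                      depth_model))
}

#' Simulate allele depths for a cfDNA mixture of several genomes
#'
#' The template pool mixes k genomes with weights w on the simplex; the
#' expected alt fraction at a locus is q = sum_k w_k g_k / 2 and the
#' alt-read count is Binomial(n, q(1 - eps) + (1 - q) eps).
#'
#' @param genotypes k x n_loci matrix of component genotypes (0/1/2), with
#'   column names `region_id`s; rows ordered as `weights`.
#' @param weights Numeric vector of k mixture fractions; must be
#'   nonnegative and sum to 1 within 1e-9.
#' @inheritParams simulate_gdna_reads
#' @return Data frame with columns `region_id`, `ref_count`, `alt_count`.
#' @export
simulate_cfdna_mixture <- function(genotypes, weights, depth = 2500,
                                   error_rate = 0.005, seed = 1L,
                                   depth_model = c("poisson", "fixed")) {
  depth_model <- match.arg(depth_model)
  genotypes <- as.matrix(genotypes)
  stopifnot(depth > 0, error_rate >= 0, error_rate < 0.5,
            nrow(genotypes) == length(weights), !is.null(colnames(genotypes)))
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
    stop("mixture weights must be nonnegative and sum to 1")
  q <- as.vector(weights %*% genotypes) / 2
  with_seed(seed,
    sim_allele_counts(colnames(genotypes), q, depth, error_rate, depth_model))
}

#' Sex-chromosome copy numbers of a karyotype label
#'
#' @param karyotype Character vector of `"46,XX"` / `"46,XY"` labels.
#' @return Matrix with one row per karyotype and columns `x`, `y` giving
#'   sex-chromosome copy numbers.
#' @export
karyotype_cn <- function(karyotype) {
  stopifnot(all(karyotype %in% c("46,XX", "46,XY")))
  cn <- cbind(x = ifelse(karyotype == "46,XX", 2, 1),
              y = ifelse(karyotype == "46,XX", 0, 1))
  rownames(cn) <- names(karyotype)
  cn
}

#' Simulate ZFX/ZFY region depths for a (possibly mixed) sample
#'
#' A mixture with weights w over components with sex-chromosome copy
#' numbers CN_k has mixed copy numbers CN_mix = sum_k w_k CN_k. Each ZFX
#' region's depth is Poisson(depth * CN_X_mix / 2) and each ZFY region's
#' Poisson(depth * CN_Y_mix / 2): `depth` is the per-region depth a
#' two-copy (diploid autosomal) target would attain.
#'
#' @param panel A `cfmix_panel` containing ZFX/ZFY regions.
#' @param sex_cn k x 2 matrix of per-component (X, Y) copy numbers, e.g.
#'   from [karyotype_cn()]; a length-2 vector for a single component.
#' @param weights Component weights on the simplex (default single
#'   component).
#' @param depth Nominal diploid per-region depth.
#' @param seed Integer seed.
#' @return Data frame with columns `region_id`, `chrom`, `depth`.
#' @export
simulate_sex_dosage <- function(panel, sex_cn, weights = 1, depth = 2500,
                                seed = 1L) {
  if (is.null(dim(sex_cn))) sex_cn <- matrix(sex_cn, nrow = 1,
                                             dimnames = list(NULL, c("x", "y")))
  stopifnot(nrow(sex_cn) == length(weights), depth > 0)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
    stop("mixture weights must be nonnegative and sum to 1")
  sex <- panel[panel$chrom %in% c("ZFX", "ZFY"), , drop = FALSE]
  if (nrow(sex) == 0) stop("panel has no ZFX/ZFY regions")
  cn_mix <- as.vector(weights %*% sex_cn)  # (X, Y)
  lambda <- ifelse(sex$chrom == "ZFX", depth * cn_mix[1] / 2,
                   depth * cn_mix[2] / 2)
  with_seed(seed, {
    data.frame(region_id = sex$region_id, chrom = sex$chrom,
               depth = stats::rpois(nrow(sex), lambda),
               stringsAsFactors = FALSE)
  })
}

#' Corrupt genotypes with independent per-locus call errors
#'
#' With probability `error_rate` a genotype is replaced by one of the two
#' other genotype values (equal probability). Used to emulate the residual
#' genotyping error between technical replicates of the same DNA.
#'
#' @param genotypes Integer vector of genotypes in 0/1/2 (NA passed
#'   through).
#' @param error_rate Per-locus miscall probability.
#' @param seed Integer seed.
#' @return Integer vector of the same length and names.
#' @export
perturb_genotypes <- function(genotypes, error_rate = 0.01, seed = 1L) {
  stopifnot(error_rate >= 0, error_rate <= 1)
  with_seed(seed, {
    out <- genotypes
    hit <- which(!is.na(out) & stats::runif(length(out)) < error_rate)
    if (length(hit)) {
      shift <- sample.int(2L, length(hit), replace = TRUE)
      out[hit] <- (out[hit] + shift) %% 3L
    }
    out
  })
}
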