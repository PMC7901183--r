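panel <- small_panel()
ped <- simulate_pedigree(panel, seed = 301)
af <- ped$pop_af

test_that("mixture genotyping posteriors match brute-force enumeration", {
  w2 <- c(0.9064, 0.0936)
  w3 <- c(0.7264, 0.18, 0.0936)
  G2 <- ped$genotypes[c("mother", "fetus"), ]
  G3 <- ped$genotypes[c("bm_donor", "mother", "fetus"), ]
  for (setup in list(list(G = G2, w = w2), list(G = G3, w = w3))) {
    d <- simulate_cfdna_mixture(setup$G, setup$w, depth = 2500,
                                error_rate = 0.005, seed = 17)
    calls <- deconvolve(d, setup$w, af, error_rate = 0.005)
    orc <- oracle_deconvolve(d$alt_count, d$ref_count + d$alt_count,
                             af[d$region_id], setup$w, 0.005)
    expect_equal(unname(attr(calls, "posterior")), unname(orc$posterior),
                 tolerance = 1e-9)
    k <- length(setup$w)
    est_cfg <- as.matrix(calls[paste0("g", seq_len(k))])
    expect_equal(unname(est_cfg), unname(orc$configs[orc$map, , drop = FALSE]),
                 ignore_attr = TRUE)
    # posteriors are proper distributions and the MAP attains the maximum
    expect_equal(rowSums(attr(calls, "posterior")), rep(1, nrow(calls)),
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(calls$map_posterior, apply(attr(calls, "posterior"), 1, max),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("unambiguous depth patterns give the expected MAP configs", {
  w <- c(0.9064, 0.0936)
  d0 <- data.frame(region_id = "r1", ref_count = 2500L, alt_count = 0L)
  calls <- deconvolve(d0, w, c(r1 = 0.3), error_rate = 0)
  expect_equal(c(calls$g1, calls$g2), c(0L, 0L))
  # 117/2500 = 0.047 sits at the fetal-het level q = 0.0936/2
  d1 <- data.frame(region_id = "r1", ref_count = 2383L, alt_count = 117L)
  calls1 <- deconvolve(d1, w, c(r1 = 0.3), error_rate = 0.005)
  orc <- oracle_deconvolve(117L, 2500L, 0.3, w, 0.005)
  expect_equal(c(calls1$g1, calls1$g2),
               unname(orc$configs[orc$map, ]), ignore_attr = TRUE)
  expect_equal(c(calls1$g1, calls1$g2), c(0L, 1L))
})

test_that("deconvolve rejects invalid mixtures and emits missing at zero depth", {
  d <- data.frame(region_id = c("r1", "r2"),
                  ref_count = c(100L, 0L), alt_count = c(5L, 0L))
  paf <- c(r1 = 0.3, r2 = 0.3)
  expect_error(deconvolve(d, c(1, 0), paf), "strictly positive")
  expect_error(deconvolve(d, c(0.6, 0.3), paf), "sum to 1")
  expect_error(deconvolve(d, c(0.25, 0.25, 0.25, 0.25), paf), "k = 2")
  calls <- deconvolve(d, c(0.9, 0.1), paf)
  expect_true(is.na(calls$g1[2]) && is.na(calls$map_posterior[2]))
  expect_false(is.na(calls$g1[1]))
})

test_that("major/minor split recovers both genomes of a deep two-way mixture", {
  G <- ped$genotypes[c("mother", "fetus"), ]
  d <- simulate_cfdna_mixture(G, c(0.9, 0.1), depth = 1e5, error_rate = 0,
                              seed = 23, depth_model = "fixed")
  calls <- deconvolve(d, c(0.9, 0.1), af, error_rate = 1e-6)
  sp <- split_major_minor(calls, "pl")
  expect_identical(rownames(sp), c("plmajor", "plminor"))
  called <- !is.na(sp["plmajor", ])
  expect_gt(mean(called), 0.95)
  expect_equal(sp["plmajor", called], G["mother", called], ignore_attr = TRUE)
  expect_equal(sp["plminor", called], G["fetus", called], ignore_attr = TRUE)
})

test_that("pseudo-tetraploid major calls track the maternal genome in a standard pregnancy", {
  G <- ped$genotypes[c("mother", "fetus"), ]
  d <- simulate_cfdna_mixture(G, c(0.9064, 0.0936), depth = 2500,
                              error_rate = 0.005, seed = 29)
  calls <- deconvolve(d, c(0.9064, 0.0936), af, error_rate = 0.005)
  sp <- split_major_minor(calls, "pl")
  called <- !is.na(sp["plmajor", ])
  expect_gt(mean(sp["plmajor", called] == G["mother", called]), 0.99)
})

test_that("split ordering follows the weights and degenerate splits error", {
  G <- ped$genotypes[c("mother", "fetus"), ]
  d <- simulate_cfdna_mixture(G, c(0.18, 0.82), depth = 2500,
                              error_rate = 0.005, seed = 31)
  calls <- deconvolve(d, c(0.18, 0.82), af, error_rate = 0.005)
  sp <- split_major_minor(calls, "s")
  # the 0.82 component (here listed second) must be labelled major
  called <- !is.na(sp["smajor", ])
  expect_gt(mean(sp["smajor", called] == G["fetus", called]), 0.95)
  expect_error(split_major_minor(calls, "s", posterior_floor = 0.9,
                                 misfit_alpha = 1),
               "misfit_alpha")
  calls_eq <- calls
  attr(calls_eq, "weights") <- c(0.5, 0.5)
  expect_error(split_major_minor(calls_eq), "undefined")
})

test_that("an all-missing split is possible under a strict confidence floor", {
  G <- ped$genotypes[c("mother", "fetus"), ]
  d <- simulate_cfdna_mixture(G, c(0.9, 0.1), depth = 3, error_rate = 0.01,
                              seed = 37, depth_model = "fixed")
  calls <- deconvolve(d, c(0.9, 0.1), af, error_rate = 0.01)
  sp <- split_major_minor(calls, "s", posterior_floor = 0.9999)
  expect_true(all(is.na(sp)))
})

test_that("component concordance decreases with fraction and with depth", {
  w3 <- c(0.7264, 0.18, 0.0936)
  G3 <- ped$genotypes[c("bm_donor", "mother", "fetus"), ]
  conc <- function(depth, seed) {
    d <- simulate_cfdna_mixture(G3, w3, depth = depth, error_rate = 0.005,
                                seed = seed)
    calls <- deconvolve(d, w3, af, error_rate = 0.005)
    vapply(1:3, function(comp)
      mean(calls[[paste0("g", comp)]] == G3[comp, calls$region_id],
           na.rm = TRUE), 0)
  }
  at2500 <- rowMeans(sapply(1:5, function(s) conc(2500, 40 + s)))
  at500 <- rowMeans(sapply(1:5, function(s) conc(500, 40 + s)))
  at100 <- rowMeans(sapply(1:5, function(s) conc(100, 40 + s)))
  expect_gt(at2500[1], at2500[3])       # major component easier than minor
  expect_gte(at2500[1] + 0.01, at500[1])  # concordance nonincreasing in depth
  expect_gte(at500[1] + 0.01, at100[1])
  expect_gte(at2500[3] + 0.01, at500[3])
})

test_that("MAF band deviation separates pure genomes from mixtures", {
  g <- ped$genotypes["father", ]
  pure <- simulate_gdna_reads(g, depth = 2500, error_rate = 0.005, seed = 51)
  ms_pure <- maf_spectrum(pure, min_depth = 50, delta = 0.1)
  expect_lt(ms_pure$band_deviation, 0.01)

  w3 <- c(0.7264, 0.18, 0.0936)
  G3 <- ped$genotypes[c("bm_donor", "mother", "fetus"), ]
  mixd <- simulate_cfdna_mixture(G3, w3, depth = 2500, error_rate = 0.005,
                                 seed = 52)
  ms_mix <- maf_spectrum(mixd, min_depth = 50, delta = 0.1)
  expect_gt(ms_mix$band_deviation, 0.1)

  # delta -> 0.25 makes the bands cover [0, 1]
  expect_lt(maf_spectrum(mixd, min_depth = 50, delta = 0.2499)$band_deviation,
            0.01)
  expect_error(maf_spectrum(pure, min_depth = 1e9), "min_depth")
})

test_that("single-genome genotype calling is near-perfect at depth", {
  g <- ped$genotypes["mother", ]
  d <- simulate_gdna_reads(g, depth = 500, error_rate = 0.005, seed = 61)
  called <- call_genotypes(d, af, error_rate = 0.005)
  ok <- !is.na(called)
  expect_gt(mean(ok), 0.99)
  expect_equal(called[ok], g[ok])
})
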