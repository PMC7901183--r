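panel <- generate_panel(seed = 401)

test_that("mrs follows its pinned definition on hand-enumerated genotypes", {
  # loci: (0,1) (1,1) (2,2) (1,0) -> all four have a non-reference member;
  # loci 2 and 3 match -> mrs = 2/4
  rec <- mrs(c(0, 1, 2, 1), c(1, 1, 2, 0))
  expect_equal(rec$mrs, 0.5)
  expect_equal(rec$n_shared, 4)
  expect_equal(rec$n_denominator, 4)
  # identical genotypes with at least one non-reference locus
  expect_equal(mrs(c(0, 1, 2), c(0, 1, 2))$mrs, 1)
  # hom-ref/hom-ref loci enter neither numerator nor denominator
  rec2 <- mrs(c(0, 0, 1), c(0, 0, 1))
  expect_equal(rec2$n_denominator, 1)
  expect_equal(rec2$mrs, 1)
})

test_that("the strict both-non-reference denominator mode is available", {
  rec <- mrs(c(0, 1, 2, 1), c(1, 1, 2, 0), mode = "both")
  expect_equal(rec$n_denominator, 2)  # only loci 2 and 3 non-ref in both
  expect_equal(rec$mrs, 1)
})

test_that("mrs is symmetric, permutation-invariant, and ignores hom-ref loci", {
  set.seed(7)
  for (i in 1:20) {
    a <- sample(0:2, 300, replace = TRUE, prob = c(0.5, 0.35, 0.15))
    b <- sample(0:2, 300, replace = TRUE, prob = c(0.5, 0.35, 0.15))
    expect_identical(mrs(a, b)$mrs, mrs(b, a)$mrs)
    perm <- sample(300)
    expect_identical(mrs(a[perm], b[perm])$mrs, mrs(a, b)$mrs)
    expect_identical(mrs(c(a, rep(0, 50)), c(b, rep(0, 50)))$mrs, mrs(a, b)$mrs)
  }
})

test_that("mrs handles missing genotypes and degenerate pairs", {
  a <- c(0, 1, NA, 2)
  b <- c(1, NA, 1, 2)
  rec <- mrs(a, b)
  expect_equal(rec$n_shared, 2)   # loci 1 and 4
  expect_equal(rec$n_denominator, 2)
  expect_equal(rec$mrs, 0.5)
  expect_error(mrs(c(0, 0), c(0, 0)), "undefined")
})

test_that("unrelated-pair mrs matches the Hardy-Weinberg enumeration oracle", {
  orc <- oracle_mrs_unrelated(0.3)
  set.seed(11)
  a <- rbinom(1e4, 2, 0.3)
  b <- rbinom(1e4, 2, 0.3)
  rec <- mrs(a, b)
  sigma <- sqrt(orc$p_match * (1 - orc$p_match) / (orc$p_denom * 1e4))
  expect_lt(abs(rec$mrs - orc$p_match), 3 * sigma)
})

test_that("relationship classification respects thresholds and boundaries", {
  expect_equal(classify_relationship(0.99, 0.9, 0.6), "MZD")
  expect_equal(classify_relationship(0.6, 0.9, 0.6), "1st")  # closed bound
  expect_equal(classify_relationship(0.59999, 0.9, 0.6), "NR")
  expect_equal(classify_relationship(0.61, 0.9, 0.6, margin = 0.02),
               "ambiguous")
  expect_error(classify_relationship(0.5, 0.6, 0.9), "t_mzd > t_first")
})

test_that("threshold calibration separates the three relationship groups", {
  thr <- calibrate_thresholds(panel, n_reps = 60, seed = 5)
  expect_gt(thr$t_mzd, thr$t_first)
  st <- thr$class_stats
  mzd <- st[st$class == "MZD", ]
  first <- st[st$class == "1st", ]
  nr <- st[st$class == "NR", ]
  expect_gt(mzd$mean, 0.95)
  gap_sd <- function(a, b) sqrt((a$sd^2 + b$sd^2) / 2)
  expect_gt(mzd$mean - first$mean, 2 * gap_sd(mzd, first))
  expect_gt(first$mean - nr$mean, 2 * gap_sd(first, nr))
})

test_that("calibration warns on an unseparable single-locus panel", {
  tiny <- generate_panel(panel_spec(chr13 = 1, chr18 = 0, chr21 = 0,
                                    other_autosomes = 0, n_zfx = 0,
                                    n_zfy = 0), seed = 1)
  expect_warning(calibrate_thresholds(tiny, n_reps = 50, seed = 2),
                 "unreliable|overlap")
})

test_that("IBS distance has metric structure and expected extremes", {
  G <- rbind(s1 = c(0L, 1L, 2L), s2 = c(0L, 1L, 2L), s3 = c(2L, 1L, 0L),
             s4 = c(2L, 2L, 2L))
  D <- ibs_distance(G)
  expect_equal(D["s1", "s2"], 0)
  expect_equal(ibs_distance(rbind(a = c(0L, 0L), b = c(2L, 2L)))["a", "b"], 1)
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))
  expect_true(all(D >= 0))
  expect_error(ibs_distance(rbind(a = c(NA, 1), b = c(1, NA))), "share no")
})

test_that("parent-child IBS distance is smaller than unrelated in expectation", {
  pc <- un <- numeric(10)
  for (s in 1:10) {
    G <- simulate_pedigree(panel, seed = 600 + s)$genotypes
    D <- ibs_distance(G)
    pc[s] <- D["father", "fetus"]
    un[s] <- D["mother", "fetus"]   # donor-egg pregnancy: unrelated
  }
  expect_gt(mean(un), mean(pc))
})

test_that("classical MDS reproduces Euclidean configurations exactly", {
  set.seed(13)
  X <- matrix(rnorm(10), 5, 2)
  D <- as.matrix(stats::dist(X))
  Y <- classical_mds(D, k = 2)
  expect_equal(as.matrix(stats::dist(Y)), D, tolerance = 1e-6,
               ignore_attr = TRUE)
  # cross-check against the reference implementation up to reflection
  Yref <- stats::cmdscale(D, k = 2)
  expect_equal(abs(Y), abs(Yref), tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(classical_mds(D, k = 5), "smaller")
})

test_that("MDS embedding preserves the duplicate-pair/outlier ordering", {
  D <- matrix(c(0, 0.02, 0.6,
                0.02, 0, 0.61,
                0.6, 0.61, 0), 3, 3,
              dimnames = list(c("dup1", "dup2", "out"),
                              c("dup1", "dup2", "out")))
  Y <- classical_mds(D, k = 2)
  d <- as.matrix(stats::dist(Y))
  expect_lt(d["dup1", "dup2"], d["dup1", "out"])
  expect_lt(d["dup1", "dup2"], d["dup2", "out"])
})

test_that("non-Euclidean distances trigger the truncation warning", {
  D <- matrix(1, 4, 4) - diag(4)
  D[1, 2] <- D[2, 1] <- 1.9  # violates embeddability
  expect_warning(classical_mds(D, k = 2), "negative eigenvalues")
})

test_that("case-pedigree MDS places gDNA duplicates adjacent", {
  hits <- 0L
  for (s in 1:20) {
    G <- simulate_pedigree(panel, seed = 700 + s)$genotypes
    dup <- perturb_genotypes(G["father", ], 0.01, seed = s)
    M <- rbind(G, father_dup = dup)
    Y <- suppressWarnings(classical_mds(ibs_distance(M), k = 2))
    d <- as.matrix(stats::dist(Y))
    others <- setdiff(rownames(M), c("father", "father_dup"))
    if (d["father", "father_dup"] < min(d["father", others]))
      hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("the relatedness table is complete and sorted", {
  G <- simulate_pedigree(panel, seed = 801)$genotypes
  tab <- relatedness_table(G, t_mzd = 0.9, t_first = 0.4)
  expect_equal(nrow(tab), choose(nrow(G), 2))
  expect_true(!is.unsorted(rev(tab$mrs)))
  expect_true(all(tab$class %in% c("MZD", "1st", "NR", "ambiguous")))
})
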