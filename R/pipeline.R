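#' Configuration of the end-to-end case study
#'
#' Bundles every parameter of the simulated case workflow: a pregnant
#' woman whose blood is chimeric after a bone-marrow transplant from a
#' male first-degree relative, carrying a donor-egg pregnancy, so her
#' plasma cfDNA mixes three genomes — donor hematopoietic (A), residual
#' maternal (B) and placental (C). Defaults reproduce the study
#' conditions: a 739-region panel, plasma mixture weights
#' (0.7264, 0.18, 0.0936) at 2500x target depth, gDNA samples at 500x,
#' and a placental fraction of 0.0936 supplied as an external input (in
#' the clinic it comes from a read-distribution fetal-fraction
#' predictor).
#'
#' @param seed Master seed; every stage derives its own stream from it.
#' @param panel_spec A [panel_spec()].
#' @param weights Named plasma mixture weights `c(A=, B=, C=)`.
#' @param placental_fraction Placental fraction f used for component
#'   arithmetic and the pseudo-tetraploid (k = 2) split.
#' @param fetal_sex `"XY"` or `"XX"` (the case fetus is male).
#' @param depth_plasma,depth_gdna Mean per-locus depths.
#' @param error_rate Per-read substitution error.
#' @param residual_host_fraction Fraction of the mother's own genome still
#'   present in her white-blood-cell sample (0 = complete donor
#'   replacement, the case presentation).
#' @param donor_mode Donor relationship, see [simulate_pedigree()].
#' @param posterior_floor Minimum MAP posterior for emitting genotype
#'   calls.
#' @param min_depth,delta MAF-spectrum parameters, see [maf_spectrum()].
#' @param t_low,t_high Sex-call thresholds, see [infer_sex()].
#' @param calib_reps Pedigree replicates for mrs threshold calibration.
#' @param margin Ambiguity margin for [classify_relationship()].
#' @return A list of class `cfmix_config`.
#' @export
case_config <- function(seed = 1L,
                        panel_spec = cfmix::panel_spec(),
                        weights = c(A = 0.7264, B = 0.18, C = 0.0936),
                        placental_fraction = 0.0936,
                        fetal_sex = "XY",
                        depth_plasma = 2500,
                        depth_gdna = 500,
                        error_rate = 0.005,
                        residual_host_fraction = 0,
                        donor_mode = "sibling",
                        posterior_floor = 0.9,
                        min_depth = 50,
                        delta = 0.1,
                        t_low = 0.05,
                        t_high = 0.95,
                        calib_reps = 60L,
                        margin = 0) {
  stopifnot(abs(sum(weights) - 1) < 1e-9, all(weights >= 0),
            fetal_sex %in% c("XY", "XX"),
            residual_host_fraction >= 0, residual_host_fraction < 1)
  structure(as.list(environment()), class = "cfmix_config")
}

config_hash <- function(config) {
  fnv1a_hash(paste(deparse(config[order(names(config))]), collapse = "\n"))
}

# Karyotypes of the six case samples. The mother's white blood cells are
# (near-)completely donor-derived, hence male.
case_samples <- function() {
  data.frame(
    sample_id = c("mother_wbc", "mother_plasma", "mother_oral",
                  "father_wbc", "father_plasma", "fetus_amnio"),
    role = c("mother", "mother", "mother", "father", "father", "fetus"),
    material = c("white blood cell gDNA", "plasma cfDNA", "oral mucosa gDNA",
                 "white blood cell gDNA", "plasma cfDNA",
                 "amniotic fluid gDNA"),
    stringsAsFactors = FALSE)
}

#' Run the full simulated case study
#'
#' Executes the whole workflow on synthetic data: generate the panel,
#' simulate the pedigree and the six case samples (mother WBC / plasma /
#' oral mucosa, father WBC / plasma, fetal amniocytes), call sample sex
#' from ZFX/ZFY dosage, estimate the male-DNA fraction and the three
#' component fractions, refine fractions from SNP allele balance by
#' constrained least squares, deconvolve the plasma mixture (k = 2
#' major/minor split and k = 3 per-component genotypes with concordance
#' against the simulated truth), compute the pairwise relatedness table
#' with calibrated thresholds, the IBS distance matrix with a 2-D
#' classical MDS embedding, and MAF spectra. Deterministic given the
#' config seed: the same config yields a byte-identical artifact bundle.
#'
#' The k = 2 split models the plasma as (1 - f) major : f minor — the
#' standard pseudo-tetraploid framing with the placental fraction as the
#' minor component — so the major genotype tracks the pooled non-placental
#' DNA (donor-dominated here) and the minor genotype the fetus.
#'
#' @param config A [case_config()].
#' @param out_dir Optional directory; when given, every artifact (panel,
#'   depth and genotype TSVs, relatedness and MDS tables, JSON +
#'   Markdown report) is written there, each stamped with the config
#'   hash and seed.
#' @return A list of class `cfmix_report`; see the elements written to
#'   `report.json`.
#' @export
run_case_study <- function(config = case_config(), out_dir = NULL) {
  stopifnot(inherits(config, "cfmix_config"))
  seed <- config$seed
  hash <- config_hash(config)
  warn_log <- character(0)
  note <- function(...) warn_log <<- c(warn_log, sprintf(...))

  panel <- generate_panel(config$panel_spec, derive_seed(seed, 1))
  ped <- simulate_pedigree(panel, derive_seed(seed, 2),
                           donor_mode = config$donor_mode)
  G <- ped$genotypes
  af <- ped$pop_af
  w <- config$weights
  f <- config$placental_fraction

  ## --- simulate the six samples: autosomal allele depths ---------------
  mix3 <- G[c("bm_donor", "mother", "fetus"), , drop = FALSE]
  rhf <- config$residual_host_fraction
  depth_tables <- list(
    mother_wbc = if (rhf > 0) {
      simulate_cfdna_mixture(G[c("bm_donor", "mother"), ], c(1 - rhf, rhf),
                             config$depth_gdna, config$error_rate,
                             derive_seed(seed, 11))
    } else {
      simulate_gdna_reads(G["bm_donor", ], config$depth_gdna,
                          config$error_rate, derive_seed(seed, 11))
    },
    mother_plasma = simulate_cfdna_mixture(mix3, w, config$depth_plasma,
                                           config$error_rate,
                                           derive_seed(seed, 12)),
    mother_oral = simulate_gdna_reads(G["mother", ], config$depth_gdna,
                                      config$error_rate, derive_seed(seed, 13)),
    father_wbc = simulate_gdna_reads(G["father", ], config$depth_gdna,
                                     config$error_rate, derive_seed(seed, 14)),
    father_plasma = simulate_gdna_reads(G["father", ], config$depth_plasma,
                                        config$error_rate, derive_seed(seed, 15)),
    fetus_amnio = simulate_gdna_reads(G["fetus", ], config$depth_gdna,
                                      config$error_rate, derive_seed(seed, 16)))

  ## --- sex-chromosome dosage -------------------------------------------
  male <- karyotype_cn("46,XY")
  female <- karyotype_cn("46,XX")
  plasma_cn <- rbind(male, female, karyotype_cn(paste0("46,", config$fetal_sex)))
  sex_tables <- list(
    mother_wbc = simulate_sex_dosage(panel, male, 1, config$depth_gdna,
                                     derive_seed(seed, 21)),
    mother_plasma = simulate_sex_dosage(panel, plasma_cn, w,
                                        config$depth_plasma,
                                        derive_seed(seed, 22)),
    mother_oral = simulate_sex_dosage(panel, female, 1, config$depth_gdna,
                                      derive_seed(seed, 23)),
    father_wbc = simulate_sex_dosage(panel, male, 1, config$depth_gdna,
                                     derive_seed(seed, 24)),
    father_plasma = simulate_sex_dosage(panel, male, 1, config$depth_plasma,
                                        derive_seed(seed, 25)),
    fetus_amnio = simulate_sex_dosage(panel, male, 1, config$depth_gdna,
                                      derive_seed(seed, 26)))

  # Calibrate dosage against the known 46,XX sample (oral mucosa),
  # rescaled to each sample's nominal depth.
  ref_tab <- sex_tables$mother_oral
  female_ref <- mean(ref_tab$depth[ref_tab$chrom == "ZFX"])
  nominal <- c(mother_wbc = config$depth_gdna, mother_plasma = config$depth_plasma,
               mother_oral = config$depth_gdna, father_wbc = config$depth_gdna,
               father_plasma = config$depth_plasma, fetus_amnio = config$depth_gdna)
  dosages <- lapply(names(sex_tables), function(s) {
    tab <- sex_tables[[s]]
    ref <- female_ref * nominal[[s]] / config$depth_gdna
    xy_dosage(tab$depth[tab$chrom == "ZFX"], tab$depth[tab$chrom == "ZFY"], ref)
  })
  names(dosages) <- names(sex_tables)
  sex_calls <- withCallingHandlers(
    lapply(dosages, infer_sex, t_low = config$t_low, t_high = config$t_high),
    warning = function(cond) { note("dosage: %s", conditionMessage(cond))
                               invokeRestart("muffleWarning") })
  sex_df <- data.frame(
    sample_id = names(sex_calls),
    sex_call = vapply(sex_calls, `[[`, "", "label"),
    male_fraction = vapply(sex_calls, `[[`, 0, "male_fraction"),
    cn_x = vapply(dosages, `[[`, 0, "cn_x"),
    cn_y = vapply(dosages, `[[`, 0, "cn_y"),
    row.names = NULL, stringsAsFactors = FALSE)

  ## --- component fractions ----------------------------------------------
  m <- withCallingHandlers(
    male_fraction_from_xy(dosages$mother_plasma),
    warning = function(cond) { note("dosage: %s", conditionMessage(cond))
                               invokeRestart("muffleWarning") })
  fractions <- component_fractions(m, f, config$fetal_sex)

  ## --- genotype calls for single-genome samples -------------------------
  called <- lapply(depth_tables[c("mother_wbc", "mother_oral", "father_wbc",
                                  "father_plasma", "fetus_amnio")],
                   call_genotypes, pop_af = af,
                   error_rate = config$error_rate,
                   posterior_floor = config$posterior_floor)

  ## --- least-squares fraction refinement --------------------------------
  cand <- rbind(A = called$mother_wbc, B = called$mother_oral,
                C = called$fetus_amnio)
  pl <- depth_tables$mother_plasma
  n_pl <- pl$ref_count + pl$alt_count
  ok <- n_pl > 0 & colSums(is.na(cand[, pl$region_id, drop = FALSE])) == 0
  ls_fit <- estimate_fractions_ls(pl$alt_count[ok] / n_pl[ok],
                                  t(cand[, pl$region_id[ok], drop = FALSE]))

  ## --- plasma deconvolution ---------------------------------------------
  k2_weights <- c(major = 1 - f, minor = f)
  calls2 <- deconvolve(pl, k2_weights, af, config$error_rate)
  plasma_split <- split_major_minor(calls2, "mother_plasma",
                                    config$posterior_floor)
  w3 <- c(A = fractions$w_A, B = fractions$w_B, C = fractions$w_C)
  calls3 <- deconvolve(pl, w3, af, config$error_rate)
  truth3 <- mix3[, calls3$region_id, drop = FALSE]
  conf3 <- !is.na(calls3$map_posterior) &
    calls3$map_posterior >= config$posterior_floor
  concordance <- vapply(1:3, function(comp) {
    est <- calls3[[paste0("g", comp)]]
    mean(est[conf3] == truth3[comp, conf3])
  }, 0)
  names(concordance) <- c("A", "B", "C")

  ## --- relatedness -------------------------------------------------------
  thr <- withCallingHandlers(
    calibrate_thresholds(panel, n_reps = config$calib_reps,
                         seed = derive_seed(seed, 31)),
    warning = function(cond) { note("calibration: %s", conditionMessage(cond))
                               invokeRestart("muffleWarning") })
  gmat <- rbind(do.call(rbind, called), plasma_split)
  rel <- relatedness_table(gmat, thr$t_mzd, thr$t_first, config$margin)
  dist <- ibs_distance(gmat)
  mds <- withCallingHandlers(
    classical_mds(dist, 2),
    warning = function(cond) { note("mds: %s", conditionMessage(cond))
                               invokeRestart("muffleWarning") })

  ## --- MAF spectra --------------------------------------------------------
  maf <- list(mother_plasma = maf_spectrum(pl, config$min_depth, config$delta),
              father_wbc = maf_spectrum(depth_tables$father_wbc,
                                        config$min_depth, config$delta))

  report <- structure(list(
    config = config, config_hash = hash, seed = seed,
    samples = case_samples(),
    sex_calls = sex_df,
    male_fraction = m,
    placental_fraction = f,
    fractions = fractions,
    ls_weights = ls_fit$weights,
    ls_objective = ls_fit$objective,
    k2_weights = k2_weights,
    concordance = concordance,
    thresholds = thr,
    relatedness = rel,
    distance = dist,
    mds = mds,
    maf_band_deviation = vapply(maf, `[[`, 0, "band_deviation"),
    maf = maf,
    truth = list(pedigree = ped, weights = w),
    warnings = warn_log), class = "cfmix_report")

  if (!is.null(out_dir))
    write_report_bundle(report, panel, depth_tables, sex_tables, gmat, out_dir)
  report
}

#' @export
print.cfmix_report <- function(x, ...) {
  cat(sprintf("<cfmix_report> config %s, seed %d\n", x$config_hash, x$seed))
  cat("\nSex calls:\n"); print(x$sex_calls)
  cat(sprintf("\nMale-DNA fraction m = %.4f; placental fraction f = %.4f\n",
              x$male_fraction, x$placental_fraction))
  print(x$fractions)
  cat("Least-squares refined weights:",
      paste(sprintf("%s=%.4f", names(x$ls_weights), x$ls_weights),
            collapse = " "), "\n")
  cat(sprintf("\nk = 3 deconvolution concordance: A %.3f, B %.3f, C %.3f\n",
              x$concordance[["A"]], x$concordance[["B"]], x$concordance[["C"]]))
  cat(sprintf("MAF band deviation: plasma %.3f, gDNA control %.3f\n",
              x$maf_band_deviation[["mother_plasma"]],
              x$maf_band_deviation[["father_wbc"]]))
  cat("\nTop relatedness pairs:\n")
  print(utils::head(x$relatedness[c("pair", "mrs", "n_denominator", "class")], 8),
        row.names = FALSE)
  if (length(x$warnings)) {
    cat("\nWarnings:\n"); cat(paste0("  - ", x$warnings, collapse = "\n"), "\n")
  }
  invisible(x)
}

write_report_bundle <- function(report, panel, depth_tables, sex_tables,
                                gmat, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- sprintf("cfmix config=%s seed=%d", report$config_hash, report$seed)
  write_panel(panel, file.path(out_dir, "panel"))

  depth_long <- do.call(rbind, lapply(names(depth_tables), function(s)
    cbind(sample_id = s, depth_tables[[s]])))
  write_depth_table(depth_long, file.path(out_dir, "allele_depths.tsv"), meta)

  sex_long <- do.call(rbind, lapply(names(sex_tables), function(s)
    cbind(sample_id = s, sex_tables[[s]][c("region_id", "depth")])))
  write_region_depth_table(sex_long, file.path(out_dir, "sex_region_depths.tsv"),
                           meta)

  write_genotype_table(gmat, file.path(out_dir, "genotypes.tsv"), meta)
  write_tsv_meta(report$relatedness, file.path(out_dir, "relatedness.tsv"), meta)
  mds_df <- data.frame(sample_id = rownames(report$mds), report$mds)
  write_tsv_meta(mds_df, file.path(out_dir, "mds_coordinates.tsv"), meta)

  maf_df <- do.call(rbind, lapply(names(report$maf), function(s)
    data.frame(sample_id = s, region_id = names(report$maf[[s]]$af),
               alt_fraction = sprintf("%.6f", report$maf[[s]]$af))))
  write_tsv_meta(maf_df, file.path(out_dir, "maf_spectrum.tsv"), meta)

  json <- list(schema = "cfmix-report/1", config_hash = report$config_hash,
               seed = report$seed,
               sex_calls = report$sex_calls,
               male_fraction = report$male_fraction,
               placental_fraction = report$placental_fraction,
               fractions = list(w_A = report$fractions$w_A,
                                w_B = report$fractions$w_B,
                                w_C = report$fractions$w_C),
               ls_weights = as.list(report$ls_weights),
               concordance = as.list(report$concordance),
               thresholds = list(t_mzd = report$thresholds$t_mzd,
                                 t_first = report$thresholds$t_first),
               maf_band_deviation = as.list(report$maf_band_deviation),
               relatedness = report$relatedness,
               warnings = report$warnings)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  md <- c(sprintf("# cfmix case report (`%s`, seed %d)", report$config_hash,
                  report$seed), "",
          "## Sex calls", "",
          paste(utils::capture.output(print(report$sex_calls)), collapse = "\n"),
          "",
          sprintf("Male-DNA fraction m = %.4f, placental fraction f = %.4f;",
                  report$male_fraction, report$placental_fraction),
          sprintf("components A/B/C = %.4f / %.4f / %.4f.",
                  report$fractions$w_A, report$fractions$w_B,
                  report$fractions$w_C), "",
          "## Relatedness", "",
          paste(utils::capture.output(
            print(report$relatedness, row.names = FALSE)), collapse = "\n"))
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(out_dir)
}
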