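#' Specification of a synthetic SNP capture panel
#'
#' Describes how many capture regions to place on each chromosome and the
#' distribution of region lengths and population alt-allele frequencies.
#' The defaults emulate a clinical targeted panel of 739 regions: 679
#' autosomal SNP-bearing regions concentrated on chromosomes 13, 18 and 21
#' (222/221/194) with the remaining 42 spread over the other autosomes, plus
#' 30 dosage-only regions on each of the homologous ZFX and ZFY genes used
#' to quantify sex-chromosome copy number.
#'
#' Autosomal regions each carry one biallelic SNP placed within the last 30
#' bp of the region (capture efficiency is highest near the 3' end of a
#' probe, so panels place the interrogated base there). ZFX/ZFY regions
#' carry no SNP: they are used only for depth.
#'
#' @param chr13,chr18,chr21 Region counts on the three trisomy-screening
#'   chromosomes.
#' @param other_autosomes Total regions distributed round-robin over the
#'   remaining 19 autosomes.
#' @param n_zfx,n_zfy Dosage-only region counts on ZFX and ZFY.
#' @param af_min,af_max Bounds of the uniform population alt-allele
#'   frequency distribution; kept away from 0 and 1 so loci are informative
#'   for mixture detection.
#' @param len_min,len_max Bounds of the uniform region-length distribution
#'   (bp); defaults give a mean length of 100 bp.
#' @param snp_margin SNP must lie within this many bp of the region 3' end.
#' @return A list of class `cfmix_panel_spec`.
#' @export
panel_spec <- function(chr13 = 222L, chr18 = 221L, chr21 = 194L,
                       other_autosomes = 42L,
                       n_zfx = 30L, n_zfy = 30L,
                       af_min = 0.2, af_max = 0.5,
                       len_min = 60L, len_max = 140L,
                       snp_margin = 30L) {
  stopifnot(chr13 >= 0, chr18 >= 0, chr21 >= 0, other_autosomes >= 0,
            n_zfx >= 0, n_zfy >= 0,
            af_min > 0, af_max < 1, af_min <= af_max,
            len_min >= 40, len_max >= len_min, snp_margin >= 1)
  structure(list(chr13 = as.integer(chr13), chr18 = as.integer(chr18),
                 chr21 = as.integer(chr21),
                 other_autosomes = as.integer(other_autosomes),
                 n_zfx = as.integer(n_zfx), n_zfy = as.integer(n_zfy),
                 af_min = af_min, af_max = af_max,
                 len_min = as.integer(len_min), len_max = as.integer(len_max),
                 snp_margin = as.integer(snp_margin)),
            class = "cfmix_panel_spec")
}

panel_chrom_levels <- c(as.character(1:22), "ZFX", "ZFY")

#' Generate a synthetic capture panel
#'
#' Draws region coordinates, lengths, SNP positions, alleles and population
#' allele frequencies according to a [panel_spec()]. Coordinates are 0-based
#' half-open (BED convention) on synthetic per-chromosome scaffolds; regions
#' never overlap and are sorted by (chromosome, start). Deterministic given
#' `seed`: equal seeds give bit-identical panels, and different seeds change
#' only coordinates, alleles and frequencies, never the per-chromosome
#' counts.
#'
#' @param spec A [panel_spec()].
#' @param seed Integer seed.
#' @return A data frame of class `cfmix_panel` with columns `region_id`,
#'   `chrom`, `start`, `end`, `snp_offset`, `ref`, `alt`, `pop_af`.
#'   `snp_offset`, `ref`, `alt` and `pop_af` are `NA` for ZFX/ZFY
#'   dosage-only regions.
#' @examples
#' p <- generate_panel(seed = 1)
#' nrow(p)                      # 739
#' table(p$chrom)[c("13", "18", "21", "ZFX", "ZFY")]
#' @export
generate_panel <- function(spec = panel_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cfmix_panel_spec"))
  other_chroms <- as.character(c(1:12, 14:17, 19, 20, 22))
  counts <- c(`13` = spec$chr13, `18` = spec$chr18, `21` = spec$chr21)
  if (spec$other_autosomes > 0) {
    rr <- table(rep(other_chroms, length.out = spec$other_autosomes))
    counts <- c(counts, stats::setNames(as.integer(rr), names(rr)))
  }
  if (sum(counts) == 0)
    stop("panel spec has zero autosomal regions; downstream genotyping is impossible")
  counts <- c(counts, ZFX = spec$n_zfx, ZFY = spec$n_zfy)
  counts <- counts[counts > 0]
  chrom_order <- panel_chrom_levels[panel_chrom_levels %in% names(counts)]

  with_seed(seed, {
    rows <- lapply(chrom_order, function(ch) {
      n <- counts[[ch]]
      len <- as.integer(round(stats::runif(n, spec$len_min, spec$len_max)))
      gap <- as.integer(round(stats::runif(n, 1000, 6000)))
      start <- cumsum(gap + c(0L, len[-n][seq_len(n - 1)]))
      end <- start + len
      sexchrom <- ch %in% c("ZFX", "ZFY")
      if (sexchrom) {
        off <- rep(NA_integer_, n)
        ref <- alt <- rep(NA_character_, n)
        af <- rep(NA_real_, n)
      } else {
        # SNP within the last `snp_margin` bp of the region 3' end
        off <- len - sample.int(spec$snp_margin, n, replace = TRUE)
        ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
        shift <- sample.int(3L, n, replace = TRUE)
        alt <- c("A", "C", "G", "T")[(match(ref, c("A", "C", "G", "T")) - 1L + shift) %% 4L + 1L]
        af <- stats::runif(n, spec$af_min, spec$af_max)
      }
      data.frame(region_id = sprintf("chr%s_%04d", ch, seq_len(n)),
                 chrom = ch, start = start, end = end,
                 snp_offset = off, ref = ref, alt = alt, pop_af = af,
                 stringsAsFactors = FALSE)
    })
    panel <- do.call(rbind, rows)
    rownames(panel) <- NULL
    class(panel) <- c("cfmix_panel", "data.frame")
    validate_panel(panel)
    panel
  })
}

#' @export
print.cfmix_panel <- function(x, ...) {
  tab <- table(factor(x$chrom, levels = panel_chrom_levels))
  cat(sprintf("<cfmix_panel> %d regions (%d autosomal SNP, %d ZFX, %d ZFY)\n",
              nrow(x), sum(!x$chrom %in% c("ZFX", "ZFY")),
              tab[["ZFX"]], tab[["ZFY"]]))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... and %d more regions\n", nrow(x) - 6L))
  invisible(x)
}

# Check every structural invariant of a panel; stop on the first violation.
validate_panel <- function(panel) {
  stopifnot(is.data.frame(panel))
  needed <- c("region_id", "chrom", "start", "end", "snp_offset", "ref", "alt", "pop_af")
  missing_cols <- setdiff(needed, names(panel))
  if (length(missing_cols))
    stop("panel is missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(panel$region_id))
    stop("duplicate region_id: ",
         panel$region_id[duplicated(panel$region_id)][1])
  if (!all(panel$chrom %in% panel_chrom_levels))
    stop("unknown chromosome label: ",
         setdiff(panel$chrom, panel_chrom_levels)[1])
  bad <- which(panel$end <= panel$start)
  if (length(bad))
    stop(sprintf("region %s has end <= start", panel$region_id[bad[1]]))
  auto <- !panel$chrom %in% c("ZFX", "ZFY")
  if (any(auto)) {
    af <- panel$pop_af[auto]
    if (anyNA(af) || any(af <= 0 | af >= 1))
      stop("autosomal pop_af must lie strictly in (0, 1)")
    off <- panel$snp_offset[auto]
    len <- panel$end[auto] - panel$start[auto]
    if (anyNA(off) || any(off < 0 | off >= len))
      stop("autosomal snp_offset must lie inside the region")
  }
  if (any(!auto) && any(!is.na(panel$pop_af[!auto])))
    stop("ZFX/ZFY dosage regions must not carry a pop_af")
  ord <- order(factor(panel$chrom, levels = panel_chrom_levels), panel$start)
  if (!identical(ord, seq_len(nrow(panel))))
    stop("panel regions must be sorted by (chrom, start)")
  invisible(panel)
}

# Autosomal (SNP-bearing) subset of a panel, in panel order.
panel_autosomal <- function(panel) {
  panel[!panel$chrom %in% c("ZFX", "ZFY"), , drop = FALSE]
}

#' Write / read a panel as BED plus a SNP sidecar table
#'
#' `write_panel()` serializes a panel to `<prefix>.bed` (tab-separated
#' `chrom start end region_id`, no header) and `<prefix>.snps.tsv`
#' (header `region_id ref alt snp_offset pop_af`; ZFX/ZFY rows carry `NA`).
#' `read_panel()` reverses the process and validates, naming the offending
#' line on malformed input. The round trip is bit-exact: frequencies are
#' written with full double precision.
#'
#' @param panel A `cfmix_panel`.
#' @param prefix Path prefix for the two files.
#' @return `write_panel()` the prefix, invisibly; `read_panel()` a
#'   `cfmix_panel`.
#' @export
write_panel <- function(panel, prefix) {
  validate_panel(panel)
  bed <- data.frame(chrom = panel$chrom, start = panel$start, end = panel$end,
                    region_id = panel$region_id)
  utils::write.table(bed, paste0(prefix, ".bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  snp <- data.frame(region_id = panel$region_id, ref = panel$ref,
                    alt = panel$alt, snp_offset = panel$snp_offset,
                    pop_af = ifelse(is.na(panel$pop_af), NA,
                                    sprintf("%.17g", panel$pop_af)))
  utils::write.table(snp, paste0(prefix, ".snps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(prefix)
}

#' @rdname write_panel
#' @export
read_panel <- function(prefix) {
  bed_path <- paste0(prefix, ".bed")
  snp_path <- paste0(prefix, ".snps.tsv")
  bed_lines <- readLines(bed_path)
  fields <- strsplit(bed_lines, "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    if (length(fields[[i]]) != 4L)
      stop(sprintf("%s line %d: expected 4 tab-separated fields", bed_path, i))
  }
  bed <- data.frame(chrom = vapply(fields, `[[`, "", 1L),
                    start = as.integer(vapply(fields, `[[`, "", 2L)),
                    end = as.integer(vapply(fields, `[[`, "", 3L)),
                    region_id = vapply(fields, `[[`, "", 4L),
                    stringsAsFactors = FALSE)
  bad <- which(is.na(bed$start) | is.na(bed$end))
  if (length(bad))
    stop(sprintf("%s line %d: non-numeric coordinates", bed_path, bad[1]))
  bad <- which(bed$end <= bed$start)
  if (length(bad))
    stop(sprintf("%s line %d: end <= start for region %s",
                 bed_path, bad[1], bed$region_id[bad[1]]))
  dup <- which(duplicated(bed$region_id))
  if (length(dup))
    stop(sprintf("%s line %d: duplicate region_id %s",
                 bed_path, dup[1], bed$region_id[dup[1]]))

  snp <- utils::read.table(snp_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "character",
                                          "integer", "numeric"),
                           na.strings = "NA")
  bad <- which(!is.na(snp$pop_af) & (snp$pop_af <= 0 | snp$pop_af >= 1))
  if (length(bad))
    stop(sprintf("%s line %d: pop_af %g outside (0, 1) for region %s",
                 snp_path, bad[1] + 1L, snp$pop_af[bad[1]], snp$region_id[bad[1]]))
  if (!setequal(bed$region_id, snp$region_id))
    stop("BED and SNP sidecar disagree on region_ids")
  idx <- match(bed$region_id, snp$region_id)
  panel <- data.frame(region_id = bed$region_id, chrom = bed$chrom,
                      start = bed$start, end = bed$end,
                      snp_offset = snp$snp_offset[idx],
                      ref = snp$ref[idx], alt = snp$alt[idx],
                      pop_af = snp$pop_af[idx], stringsAsFactors = FALSE)
  class(panel) <- c("cfmix_panel", "data.frame")
  validate_panel(panel)
  panel
}
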