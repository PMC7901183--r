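# Tabular artifact I/O. All tables are tab-separated with a header line;
# lines starting with '#' are metadata (config hash, seed) and skipped on
# read. Line numbers in error messages count data rows including the
# header and any metadata lines, i.e. as seen in the file.

write_tsv_meta <- function(df, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta)) writeLines(paste0("# ", meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

read_tsv_meta <- function(path, colClasses) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  df <- utils::read.table(text = lines[!is_meta], header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = colClasses,
                          na.strings = "NA")
  attr(df, "line_offset") <- sum(is_meta) + 1L  # metadata + header
  df
}

check_regions <- function(region_id, panel, path) {
  if (is.null(panel)) return(invisible())
  unknown <- setdiff(unique(region_id), panel$region_id)
  if (length(unknown))
    stop(sprintf("%s references region %s absent from the panel",
                 path, unknown[1]))
}

#' Read and write per-sample allele-depth tables
#'
#' Columns `sample_id region_id ref_count alt_count`; counts must be
#' nonnegative integers. When a `panel` is supplied, region ids are
#' checked against it. The round trip is an identity.
#'
#' @param depths Data frame with the four columns above.
#' @param path File path.
#' @param meta Optional character vector of metadata lines (written
#'   `#`-prefixed).
#' @param panel Optional `cfmix_panel` to validate region ids against.
#' @return `read_depth_table()` the validated data frame.
#' @export
write_depth_table <- function(depths, path, meta = NULL) {
  stopifnot(all(c("sample_id", "region_id", "ref_count", "alt_count")
                %in% names(depths)))
  write_tsv_meta(depths[c("sample_id", "region_id", "ref_count", "alt_count")],
                 path, meta)
}

#' @rdname write_depth_table
#' @export
read_depth_table <- function(path, panel = NULL) {
  df <- read_tsv_meta(path, c("character", "character", "integer", "integer"))
  off <- attr(df, "line_offset")
  bad <- which(is.na(df$ref_count) | is.na(df$alt_count) |
                 df$ref_count < 0 | df$alt_count < 0)
  if (length(bad))
    stop(sprintf("%s line %d: counts must be nonnegative integers",
                 path, bad[1] + off))
  check_regions(df$region_id, panel, path)
  attr(df, "line_offset") <- NULL
  df
}

#' Read and write genotype tables
#'
#' Columns `sample_id region_id genotype`; genotypes in 0/1/2 or `NA`
#' (missing).
#'
#' @param genotypes Data frame with the three columns above, or a
#'   samples x loci matrix (converted to long form).
#' @inheritParams write_depth_table
#' @return `read_genotype_table()` the validated long-form data frame;
#'   `genotype_table_to_matrix()` a samples x loci matrix.
#' @export
write_genotype_table <- function(genotypes, path, meta = NULL) {
  if (is.matrix(genotypes)) genotypes <- genotype_matrix_to_table(genotypes)
  stopifnot(all(c("sample_id", "region_id", "genotype") %in% names(genotypes)))
  write_tsv_meta(genotypes[c("sample_id", "region_id", "genotype")], path, meta)
}

#' @rdname write_genotype_table
#' @export
read_genotype_table <- function(path, panel = NULL) {
  df <- read_tsv_meta(path, c("character", "character", "integer"))
  off <- attr(df, "line_offset")
  bad <- which(!is.na(df$genotype) & !df$genotype %in% 0:2)
  if (length(bad))
    stop(sprintf("%s line %d: genotype must be 0, 1, 2 or NA",
                 path, bad[1] + off))
  check_regions(df$region_id, panel, path)
  attr(df, "line_offset") <- NULL
  df
}

#' @rdname write_genotype_table
#' @export
genotype_table_to_matrix <- function(genotypes) {
  samples <- unique(genotypes$sample_id)
  loci <- unique(genotypes$region_id)
  G <- matrix(NA_integer_, length(samples), length(loci),
              dimnames = list(samples, loci))
  G[cbind(match(genotypes$sample_id, samples),
          match(genotypes$region_id, loci))] <- genotypes$genotype
  G
}

genotype_matrix_to_table <- function(G) {
  data.frame(sample_id = rep(rownames(G), each = ncol(G)),
             region_id = rep(colnames(G), times = nrow(G)),
             genotype = as.integer(t(G)), stringsAsFactors = FALSE)
}

#' Read and write ZFX/ZFY region depth tables
#'
#' Columns `sample_id region_id depth`; depths must be nonnegative.
#'
#' @param depths Data frame with the three columns above.
#' @inheritParams write_depth_table
#' @export
write_region_depth_table <- function(depths, path, meta = NULL) {
  stopifnot(all(c("sample_id", "region_id", "depth") %in% names(depths)))
  write_tsv_meta(depths[c("sample_id", "region_id", "depth")], path, meta)
}

#' @rdname write_region_depth_table
#' @export
read_region_depth_table <- function(path, panel = NULL) {
  df <- read_tsv_meta(path, c("character", "character", "numeric"))
  off <- attr(df, "line_offset")
  bad <- which(is.na(df$depth) | df$depth < 0)
  if (length(bad))
    stop(sprintf("%s line %d: depth must be nonnegative", path, bad[1] + off))
  check_regions(df$region_id, panel, path)
  attr(df, "line_offset") <- NULL
  df
}
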