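# Plain-text readers and writers for the pipeline's interchange formats.

#' Write a synthetic world to a directory
#'
#' Emits `isolation.tsv`, `stations.tsv`, `observations.csv`,
#' `genotypes.tsv`, `genotypes.vcf`, `annotations.tsv` and `truth.yaml`.
#'
#' @param world a `synthetic_world`.
#' @param dir output directory (created if absent).
#' @return invisibly, the written file paths.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write.table(world$records, p("isolation.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(world$stations, p("stations.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.csv(world$obs, p("observations.csv"), row.names = FALSE)
  write_genotypes_tsv(world$genotypes, p("genotypes.tsv"))
  write_genotypes_vcf(world$genotypes, p("genotypes.vcf"))
  write.table(world$annotations, p("annotations.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  truth <- world$truth
  truth$true_isolation_date <- as.character(truth$true_isolation_date)
  yaml::write_yaml(truth, p("truth.yaml"))
  invisible(p(c("isolation.tsv", "stations.tsv", "observations.csv",
                "genotypes.tsv", "genotypes.vcf", "annotations.tsv",
                "truth.yaml")))
}

#' Write a genotype matrix as TSV
#' @param G strains x markers 0/1 matrix with dimnames.
#' @param path output path.
#' @export
write_genotypes_tsv <- function(G, path) {
  df <- data.frame(strain = rownames(G), G, check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Read a genotype matrix from TSV
#' @param path TSV with a `strain` column and one 0/1 column per marker.
#' @param markers optional marker metadata data.frame to attach.
#' @return 0/1 matrix with strain rownames.
#' @export
read_genotypes_tsv <- function(path, markers = NULL) {
  df <- read.delim(path, check.names = FALSE)
  G <- as.matrix(df[, -1, drop = FALSE])
  rownames(G) <- df$strain
  storage.mode(G) <- "integer"
  if (!is.null(markers)) attr(G, "markers") <- markers
  G
}

#' Write a minimal GT-only haploid VCF for a genotype matrix
#'
#' One sample column per strain; genotypes are written as haploid `0`/`1`
#' calls with placeholder REF/ALT alleles. Marker metadata (attribute
#' `"markers"`) supplies CHROM/POS when present.
#'
#' @param G strains x markers 0/1 matrix.
#' @param path output `.vcf` path.
#' @export
write_genotypes_vcf <- function(G, path) {
  mk <- attr(G, "markers")
  if (is.null(mk))
    mk <- data.frame(marker = colnames(G), chrom = "I",
                     pos = seq_len(ncol(G)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", rownames(G)),
                     collapse = "\t")), con)
  gt <- t(G)  # markers x strains
  body <- paste(mk$chrom, mk$pos, mk$marker, "A", "T", ".", "PASS", ".",
                "GT", sep = "\t")
  gt_str <- apply(gt, 1, paste, collapse = "\t")
  writeLines(paste(body, gt_str, sep = "\t"), con)
}

#' Read a minimal GT-only VCF into a genotype matrix
#'
#' Parses haploid (`0`/`1`) or homozygous diploid (`0/0`, `1|1`) GT calls;
#' anything else (heterozygous or missing) becomes `NA`.
#'
#' @param path `.vcf` path.
#' @return 0/1 matrix strains x markers with `"markers"` metadata attribute.
#' @export
read_genotypes_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("no #CHROM header line")
  cols <- strsplit(lines[hdr], "\t")[[1]]
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t")
  gt_of <- function(s) {
    s <- sub(":.*", "", s)
    ifelse(s %in% c("0", "0/0", "0|0"), 0L,
           ifelse(s %in% c("1", "1/1", "1|1"), 1L, NA_integer_))
  }
  G <- t(vapply(fields, function(f) gt_of(f[-(1:9)]),
                integer(length(samples))))
  if (length(samples) == 1L) G <- matrix(G, ncol = 1L)
  G <- t(G)  # strains x markers
  dimnames(G) <- list(samples, vapply(fields, `[`, "", 3L))
  attr(G, "markers") <- data.frame(
    marker = colnames(G),
    chrom = vapply(fields, `[`, "", 1L),
    pos = as.integer(vapply(fields, `[`, "", 2L)),
    stringsAsFactors = FALSE)
  G
}

#' Read an observation CSV
#' @param path CSV with station_id, timestamp, param, value, unit columns.
#' @return data.frame with `timestamp` parsed to Date.
#' @export
read_observations <- function(path) {
  obs <- read.csv(path, stringsAsFactors = FALSE)
  obs$timestamp <- as.Date(obs$timestamp)
  obs
}

#' Read isolation records TSV
#' @param path TSV with strain, lat, lon, year, month, day, date_precision.
#' @return data.frame.
#' @export
read_isolation_records <- function(path) read.delim(path)

#' Read a station catalog TSV
#' @param path TSV with station_id, lat, lon, elevation.
#' @return data.frame.
#' @export
read_stations <- function(path) read.delim(path)

#' Read a ddPCR competition count table
#' @param path CSV with temperature, replicate, transfer, count_A, count_B.
#' @return data.frame.
#' @export
read_competition_counts <- function(path) read.csv(path)
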