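## File formats: VCF + sample map in, plain-text VCF/BED/bedGraph/TSV/JSON
## out. All interval formats are 0-based half-open (BED convention); VCF
## POS is 1-based and converted on read/write.

AUTOSOME_EXCLUDE <- c("X", "Y", "MT", "M", "chrX", "chrY", "chrM", "chrMT")

#' Read a sample-to-population map
#'
#' Tab-separated file with columns `sample_id`, `population`, `continent`
#' (header required).
#'
#' @param path File path.
#' @return data.frame with the three columns.
#' @export
read_sample_map <- function(path) {
  m <- read.table(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  need <- c("sample_id", "population", "continent")
  if (!all(need %in% names(m)))
    stop("sample map needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(m$sample_id)) stop("duplicate sample_id in map")
  m[, need]
}

#' @rdname read_sample_map
#' @param samples data.frame to write.
#' @export
write_sample_map <- function(samples, path) {
  write.table(samples[, c("sample_id", "population", "continent")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a diploid genotype panel from VCF plus sample map
#'
#' Keeps biallelic SNPs only (multi-allelic and indel records are dropped
#' and counted); genotypes are coded as alternate-allele dosage 0/1/2 with
#' `NA` for missing; the X chromosome and other non-autosomes are excluded
#' by default. Every VCF sample must appear in the map unless
#' `on_unmapped = "drop"`.
#'
#' @param vcf_path VCF file (plain text or bgzipped).
#' @param sample_map_path Sample map TSV (see [read_sample_map()]).
#' @param autosomes_only Drop X/Y/MT records (default `TRUE`).
#' @param on_unmapped `"error"` (default) or `"drop"` for VCF samples
#'   absent from the map.
#' @return A `genotype_panel`; attribute `drop_log` counts dropped
#'   records.
#' @export
read_panel <- function(vcf_path, sample_map_path, autosomes_only = TRUE,
                       on_unmapped = c("error", "drop")) {
  on_unmapped <- match.arg(on_unmapped)
  map <- read_sample_map(sample_map_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  n0 <- nrow(fix)
  snp <- vcfR::is.biallelic(v) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  auto <- rep(TRUE, n0)
  if (autosomes_only) auto <- !fix$CHROM %in% AUTOSOME_EXCLUDE
  keep <- which(snp & auto)
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]

  vcf_samples <- colnames(gt)
  unmapped <- setdiff(vcf_samples, map$sample_id)
  if (length(unmapped) > 0L) {
    if (on_unmapped == "error")
      stop("VCF sample(s) absent from map: ",
           paste(unmapped, collapse = ", "))
    vcf_samples <- setdiff(vcf_samples, unmapped)
    gt <- gt[, vcf_samples, drop = FALSE]
  }
  ## dosage: count "1" alleles in GT strings like 0/1, 1|1, ./.
  dose <- function(x) {
    out <- rep(NA_integer_, length(x))
    out[x %in% c("0/0", "0|0")] <- 0L
    out[x %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    out[x %in% c("1/1", "1|1")] <- 2L
    out
  }
  G <- t(matrix(dose(as.vector(gt)), nrow(gt), ncol(gt)))  # samples x SNPs
  rownames(G) <- vcf_samples
  samples <- map[match(vcf_samples, map$sample_id), ]
  rownames(samples) <- NULL
  sites <- data.frame(chrom = fix$CHROM,
                      pos = as.integer(fix$POS) - 1L,   # to 0-based
                      id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                  sprintf("snp_%s_%s", fix$CHROM, fix$POS),
                                  fix$ID),
                      ancestral_freq = NA_real_,
                      in_sweep = NA,
                      stringsAsFactors = FALSE)
  ## chromosome lengths from ##contig headers when present, else the
  ## rightmost observed position
  contig <- regmatches(v@meta,
                       regexec("^##contig=<ID=([^,>]+),length=([0-9]+)",
                               v@meta))
  contig <- contig[lengths(contig) == 3L]
  chrom_lengths <- tapply(sites$pos, sites$chrom, max) + 1
  chrom_lengths <- chrom_lengths[unique(sites$chrom)]
  if (length(contig) > 0L) {
    cl <- setNames(as.numeric(vapply(contig, `[`, character(1), 3L)),
                   vapply(contig, `[`, character(1), 2L))
    hit <- names(chrom_lengths)[names(chrom_lengths) %in% names(cl)]
    chrom_lengths[hit] <- cl[hit]
  }
  panel <- structure(list(genotypes = G, sites = sites, samples = samples,
                          chrom_lengths = chrom_lengths,
                          seed = NULL),
                     class = "genotype_panel")
  attr(panel, "drop_log") <- c(not_biallelic_snp = sum(!snp),
                               non_autosome = sum(snp & !auto),
                               unmapped_samples = length(unmapped))
  panel
}

#' Write a genotype panel as a plain-text VCF
#'
#' Minimal VCF 4.2 with one biallelic record per site (REF `A`, ALT `G`
#' for simulated panels lacking real alleles) and unphased GT calls.
#'
#' @param panel A `genotype_panel`.
#' @param path Output path (`.vcf`).
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "genotype_panel"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##source=netsel", " ",
                      as.character(utils::packageVersion("netsel"))),
               sprintf("##contig=<ID=%s,length=%d>",
                       names(panel$chrom_lengths),
                       as.integer(panel$chrom_lengths)),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT",
                       panel$samples$sample_id), collapse = "\t")),
             con)
  gt_str <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  G <- panel$genotypes
  gt <- matrix("./.", nrow(G), ncol(G))
  ok <- !is.na(G)
  gt[ok] <- gt_str[as.character(G[ok])]
  lines <- paste(panel$sites$chrom, panel$sites$pos + 1L, panel$sites$id,
                 "A", "G", ".", "PASS", ".", "GT",
                 apply(gt, 2L, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read and write BED interval files
#'
#' BED3+ (chrom, start, end, optional name): 0-based half-open, no
#' header. On read, a fourth column becomes `name`.
#'
#' @param path File path.
#' @return data.frame with `chrom`, `start`, `end` (+ `name`).
#' @export
read_bed <- function(path) {
  b <- read.table(path, header = FALSE, sep = "\t",
                  stringsAsFactors = FALSE)
  names(b)[1:3] <- c("chrom", "start", "end")
  if (ncol(b) >= 4L) names(b)[4L] <- "name"
  b[, seq_len(min(4L, ncol(b)))]
}

#' @rdname read_bed
#' @param regions data.frame with `chrom`, `start`, `end` and optionally
#'   `name` (or `window_id`/`source_locus`, used as the name).
#' @export
write_bed <- function(regions, path) {
  name <- regions$name %||% regions$window_id %||% regions$source_locus
  cols <- data.frame(regions$chrom, as.integer(regions$start),
                     as.integer(regions$end))
  if (!is.null(name)) cols <- cbind(cols, name)
  write.table(cols, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read and write position-scored tracks (bedGraph dialect)
#'
#' Four columns (chrom, start, end, score), no header; each record scores
#' one site, whose position is taken as `start`.
#'
#' @param path File path.
#' @return An `ihs_track` data.frame (`chrom`, `pos`, `score`).
#' @export
read_bedgraph <- function(path) {
  b <- read.table(path, header = FALSE, sep = "\t",
                  stringsAsFactors = FALSE)
  if (ncol(b) < 4L) stop("bedGraph needs 4 columns")
  track <- data.frame(chrom = b[[1L]], pos = b[[2L]], score = b[[4L]],
                      stringsAsFactors = FALSE)
  track <- track[order(track$chrom, track$pos), ]
  rownames(track) <- NULL
  class(track) <- c("ihs_track", "data.frame")
  track
}

#' @rdname read_bedgraph
#' @param track An `ihs_track` (columns `chrom`, `pos`, `score`).
#' @export
write_bedgraph <- function(track, path) {
  write.table(data.frame(track$chrom, as.integer(track$pos),
                         as.integer(track$pos) + 1L, track$score),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read and write ancient-individual site tables
#'
#' Tab-separated with header: `site_id`, `chrom`, `pos`, `depth`, `call`
#' (`hom_ref`/`het`/`hom_alt`/`missing`), `derived_freq`.
#'
#' @param path File path.
#' @return An `ancient_sites` data.frame.
#' @export
read_ancient_sites <- function(path) {
  a <- read.table(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  need <- c("site_id", "chrom", "pos", "depth", "call", "derived_freq")
  if (!all(need %in% names(a)))
    stop("ancient site table needs columns: ",
         paste(need, collapse = ", "))
  a <- a[, need]
  class(a) <- c("ancient_sites", "data.frame")
  a
}

#' @rdname read_ancient_sites
#' @param sites An `ancient_sites` data.frame.
#' @export
write_ancient_sites <- function(sites, path) {
  write.table(as.data.frame(sites), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write per-site FST scan results as TSV
#'
#' Columns: chrom, pos, id, n_a, n_b, p_a, p_b, fst, qualifying.
#'
#' @param scan An `fst_scan`.
#' @param path Output path.
#' @export
write_fst_tsv <- function(scan, path) {
  write.table(as.data.frame(scan)[, c("chrom", "pos", "id", "n_a", "n_b",
                                      "p_a", "p_b", "fst", "qualifying")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-region scores as TSV
#'
#' @param scores A `region_scores` data.frame.
#' @param path Output path.
#' @export
write_region_scores <- function(scores, path) {
  write.table(as.data.frame(scores), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
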