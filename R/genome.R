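#' Define a genome: chromosome names, lengths, centromeres, mitochondrial contig
#'
#' The genome table is the coordinate backbone for every other object in
#' hicforge. It is an ordinary tibble with one row per chromosome, validated
#' for the invariants all downstream code assumes.
#'
#' @param chrom Character vector of chromosome names; order is kept and defines
#'   genome-wide bin order.
#' @param length Chromosome lengths in bp (> 0).
#' @param centromere_mid Centromere midpoint in bp per chromosome, or `NA` where
#'   no centromere is annotated (acrocentric-style contigs, the mitochondrial
#'   contig). Must satisfy `0 < centromere_mid < length` where present.
#' @param is_mito Logical flag; at most one chromosome may be mitochondrial.
#'
#' @return A tibble with columns `chrom`, `length`, `centromere_mid`, `is_mito`.
#' @export
#' @examples
#' genome(c("chrA", "chrM"), c(50e6, 16571), c(20e6, NA), c(FALSE, TRUE))
genome <- function(chrom, length, centromere_mid = NA_real_, is_mito = FALSE) {
  g <- tibble::tibble(
    chrom = as.character(chrom),
    length = as.numeric(length),
    centromere_mid = as.numeric(rep_len(centromere_mid, base::length(chrom))),
    is_mito = rep_len(as.logical(is_mito), base::length(chrom))
  )
  validate_genome(g)
}

validate_genome <- function(g) {
  stopifnot(is.data.frame(g), all(c("chrom", "length") %in% names(g)))
  if (!"centromere_mid" %in% names(g)) g$centromere_mid <- NA_real_
  if (!"is_mito" %in% names(g)) g$is_mito <- FALSE
  if (anyDuplicated(g$chrom)) stop("duplicate chromosome names", call. = FALSE)
  if (any(g$length <= 0)) stop("chromosome lengths must be > 0", call. = FALSE)
  bad <- !is.na(g$centromere_mid) &
    (g$centromere_mid <= 0 | g$centromere_mid >= g$length)
  if (any(bad)) {
    stop("centromere_mid must lie strictly inside the chromosome: ",
         paste(g$chrom[bad], collapse = ", "), call. = FALSE)
  }
  if (sum(g$is_mito) > 1) stop("at most one mitochondrial contig", call. = FALSE)
  tibble::as_tibble(g)
}

#' Read a UCSC-style two-column chromsizes file
#'
#' @param path Path to a TSV with columns chrom, length (no header).
#' @param mito_name Chromosome name to flag as the mitochondrial contig, if
#'   present in the file.
#' @return A genome tibble (see [genome()]) with `centromere_mid = NA`.
#' @export
read_chromsizes <- function(path, mito_name = "chrM") {
  x <- readr::read_tsv(path, col_names = c("chrom", "length"),
                       col_types = "cd", comment = "#")
  genome(x$chrom, x$length, NA_real_, x$chrom == mito_name)
}

#' Read a centromere table and attach it to a genome
#'
#' @param genome A genome tibble.
#' @param path Three-column TSV: chrom, mid_bp, label (no header).
#' @return The genome with `centromere_mid` filled in for listed chromosomes.
#' @export
read_centromeres <- function(genome, path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "mid_bp", "label"),
                       col_types = "cdc", comment = "#")
  idx <- match(genome$chrom, x$chrom)
  hit <- !is.na(idx)
  genome$centromere_mid[hit] <- x$mid_bp[idx[hit]]
  validate_genome(genome)
}

#' Desk-scale simulation genomes
#'
#' `sim_genome_small()` is the default test genome: 8 metacentric-ish
#' chromosomes between 30 and 60 Mb plus a 16.6 kb mitochondrial contig.
#' `sim_genome_scaled()` is a 22-autosome genome with human chromosome length
#' *proportions* scaled down by `scale`, used where per-bin statistics need
#' many bins (e.g. the compartment-switch round trip).
#'
#' @param scale Multiplier applied to human autosome lengths (default 0.65,
#'   giving ~1.9 Gb and ~7500 bins at 250 kb).
#' @return A genome tibble.
#' @export
sim_genome_small <- function() {
  lens <- c(60, 55, 50, 46, 42, 38, 34, 30) * 1e6
  cens <- c(0.45, 0.40, 0.48, 0.38, 0.42, 0.35, 0.45, 0.40) * lens
  genome(
    chrom = c(paste0("chr", 1:8), "chrM"),
    length = c(lens, 16571),
    centromere_mid = c(cens, NA),
    is_mito = c(rep(FALSE, 8), TRUE)
  )
}

#' @rdname sim_genome_small
#' @export
sim_genome_scaled <- function(scale = 0.65) {
  # hg38 autosome lengths (Mb) and approximate centromere midpoints (Mb)
  lens <- c(248.96, 242.19, 198.30, 190.21, 181.54, 170.81, 159.35, 145.14,
            138.39, 133.80, 135.09, 133.28, 114.36, 107.04, 101.99, 90.34,
            83.26, 80.37, 58.62, 64.44, 46.71, 50.82) * 1e6
  cens <- c(123.4, 93.9, 90.9, 50.0, 48.8, 59.8, 60.1, 45.2, 43.0, 39.8,
            53.4, 35.5, 17.7, 17.2, 19.0, 36.8, 25.1, 18.5, 26.2, 28.1,
            12.0, 15.0) * 1e6
  genome(
    chrom = c(paste0("chr", 1:22), "chrM"),
    length = c(round(lens * scale), 16571),
    centromere_mid = c(round(cens * scale), NA),
    is_mito = c(rep(FALSE, 22), TRUE)
  )
}

#' Partition a genome into fixed-size bins with arm and end-region annotations
#'
#' Bins are 0-based, half-open, and tile each chromosome without gaps or
#' overlaps; the last bin of a chromosome may be short. Each bin carries its
#' arm (`p` iff the bin lies at or before the centromere midpoint; bins
#' spanning the centromere are assigned by bin midpoint), a telomere-end flag
#' (bin overlaps the terminal `end_size` of the chromosome) and a
#' centromere-flank flag (bin overlaps `centromere_mid +/- end_size`).
#'
#' The mitochondrial contig is binned too (a single bin at usual sizes) but is
#' exempt from the minimum-length check and never carries arm or end flags.
#'
#' @param genome A genome tibble (see [genome()]).
#' @param bin_size Bin size in bp (> 0).
#' @param end_size End-region size in bp (>= `bin_size`). Chromosomes (other
#'   than the mitochondrial contig) shorter than `2 * end_size` are rejected
#'   because their telomere flags would overlap.
#' @return A tibble with columns `bin_id` (1-based, genome-wide), `chrom`,
#'   `start`, `end`, `mid`, `arm`, `in_telomere_end`, `in_centromere_flank`,
#'   `is_mito`, and attributes `bin_size`, `end_size`, `genome`.
#' @export
#' @examples
#' g <- genome("chrA", 10e6, centromere_mid = 4e6)
#' build_bin_table(g, bin_size = 1e6, end_size = 1e6)
build_bin_table <- function(genome, bin_size, end_size = bin_size) {
  genome <- validate_genome(genome)
  stopifnot(bin_size > 0)
  if (end_size < bin_size) stop("end_size must be >= bin_size", call. = FALSE)
  short <- !genome$is_mito & genome$length < 2 * end_size
  if (any(short)) {
    stop("chromosome(s) shorter than 2*end_size (telomere flags would overlap): ",
         paste(genome$chrom[short], collapse = ", "), call. = FALSE)
  }

  bins <- purrr::pmap_dfr(genome, function(chrom, length, centromere_mid, is_mito) {
    start <- seq(0, length - 1, by = bin_size)
    end <- pmin(start + bin_size, length)
    mid <- (start + end) / 2
    if (is_mito) {
      arm <- NA_character_
      tel <- FALSE
      cen <- FALSE
    } else {
      if (is.na(centromere_mid)) {
        arm <- NA_character_
        cen <- rep(FALSE, base::length(start))
      } else {
        arm <- ifelse(end <= centromere_mid, "p",
                      ifelse(start >= centromere_mid, "q",
                             ifelse(mid <= centromere_mid, "p", "q")))
        cen <- start < centromere_mid + end_size & end > centromere_mid - end_size
      }
      tel <- start < end_size | end > length - end_size
    }
    tibble::tibble(chrom = chrom, start = start, end = end, mid = mid,
                   arm = arm, in_telomere_end = tel, in_centromere_flank = cen,
                   is_mito = is_mito)
  })
  bins <- dplyr::mutate(bins, bin_id = dplyr::row_number(), .before = 1)
  attr(bins, "bin_size") <- bin_size
  attr(bins, "end_size") <- end_size
  attr(bins, "genome") <- genome
  bins
}

bin_size_of <- function(bins) {
  bs <- attr(bins, "bin_size")
  if (is.null(bs)) stop("bin table lacks a bin_size attribute", call. = FALSE)
  bs
}

genome_of <- function(bins) {
  g <- attr(bins, "genome")
  if (is.null(g)) stop("bin table lacks a genome attribute", call. = FALSE)
  g
}

#' Locate the bin containing a genomic position
#' @noRd
bin_index_at <- function(bins, chrom, pos) {
  idx <- which(bins$chrom == chrom & bins$start <= pos & bins$end > pos)
  if (length(idx) == 0) NA_integer_ else idx[[1]]
}
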