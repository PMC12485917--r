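#' Construct a contact map
#'
#' A `contact_map` bundles a bin table with a symmetric matrix of contact
#' counts (or expected contact probabilities), per-bin balancing weights and a
#' per-bin validity mask. Masked bins keep their stored counts (storage is
#' never mutated by masking) but are excluded from every statistic.
#'
#' @param bins A bin table from [build_bin_table()].
#' @param counts Symmetric nonnegative numeric matrix, one row/column per bin.
#' @param weights Per-bin balancing multipliers (`NA` where undefined).
#' @param mask Logical per-bin validity flag (`TRUE` = usable).
#' @param expected Set `TRUE` for noise-free expected maps from the generator;
#'   such maps carry unit weights so balanced-map statistics apply directly.
#' @return An object of class `contact_map`.
#' @export
contact_map <- function(bins, counts, weights = NULL, mask = NULL,
                        expected = FALSE) {
  n <- nrow(bins)
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == n, ncol(counts) == n)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (max(abs(counts - t(counts))) > 1e-8 * max(1, max(counts))) {
    stop("counts must be symmetric", call. = FALSE)
  }
  counts <- (counts + t(counts)) / 2
  if (is.null(mask)) mask <- rep(TRUE, n)
  if (is.null(weights)) weights <- if (expected) rep(1, n) else rep(NA_real_, n)
  weights[!mask] <- NA_real_
  structure(
    list(
      bins = bins,
      counts = counts,
      weights = weights,
      mask = mask,
      total_contacts = upper_tri_sum(counts),
      expected = expected,
      balance = NULL
    ),
    class = "contact_map"
  )
}

# sum over unordered bin pairs, diagonal included once
upper_tri_sum <- function(m) (sum(m) + sum(diag(m))) / 2

#' @export
print.contact_map <- function(x, ...) {
  g <- genome_of(x$bins)
  cat(sprintf(
    "<contact_map> %d bins (%d valid) on %d chromosomes, bin size %s bp\n",
    nrow(x$bins), sum(x$mask), nrow(g), format(bin_size_of(x$bins), big.mark = ",")
  ))
  cat(sprintf("  total contacts: %s%s%s\n",
              format(x$total_contacts, big.mark = ","),
              if (x$expected) " (expected map)" else "",
              if (is_balanced(x)) ", balanced" else ""))
  invisible(x)
}

is_balanced <- function(m) any(!is.na(m$weights))

#' Balanced contact values of a map
#'
#' Returns the matrix of `w_i * O_ij * w_j` with `NA` at masked bins. Expected
#' maps carry unit weights, so this is the expected matrix itself.
#'
#' @param m A `contact_map`.
#' @return A numeric matrix.
#' @export
balanced_matrix <- function(m) {
  if (!is_balanced(m)) {
    stop("matrix is not balanced; run ic_balance() first", call. = FALSE)
  }
  w <- m$weights
  b <- m$counts * outer(w, w)
  b[!m$mask, ] <- NA_real_
  b[, !m$mask] <- NA_real_
  b
}

#' One-line summary of a contact map
#'
#' @param x A `contact_map`.
#' @param ... Unused.
#' @return A one-row tibble: bin counts, validity, totals, cis percentage and
#'   balancing status.
#' @export
glance.contact_map <- function(x, ...) {
  tibble::tibble(
    n_bins = nrow(x$bins),
    n_valid = sum(x$mask),
    n_chrom = length(unique(x$bins$chrom)),
    bin_size = bin_size_of(x$bins),
    total_contacts = x$total_contacts,
    cis_percent = tryCatch(cis_fraction(x), error = function(e) NA_real_),
    balanced = is_balanced(x),
    expected = x$expected
  )
}

#' Tidy a contact map into a sparse triplet tibble
#'
#' @param x A `contact_map`.
#' @param ... Unused.
#' @return A tibble of the nonzero upper-triangle entries: `bin1_id`,
#'   `bin2_id`, `count`.
#' @export
tidy.contact_map <- function(x, ...) {
  idx <- which(upper.tri(x$counts, diag = TRUE) & x$counts != 0, arr.ind = TRUE)
  tibble::tibble(
    bin1_id = idx[, 1],
    bin2_id = idx[, 2],
    count = x$counts[idx]
  ) |>
    dplyr::arrange(.data$bin1_id, .data$bin2_id)
}

#' Read binned contacts from disk
#'
#' Two plain-text formats are supported. `"pairs"` is 4DN-style text (columns
#' readID chrom1 pos1 chrom2 pos2 strand1 strand2, `#` header lines); bp
#' positions are aggregated into the supplied bin table. `"triplet_tsv"` is a
#' three-column TSV of 1-based bin ids and counts, upper triangle only.
#'
#' @param path File path.
#' @param bins Bin table the contacts are aggregated onto.
#' @param format `"pairs"` or `"triplet_tsv"`.
#' @return A raw (unbalanced) `contact_map`.
#' @export
read_contacts <- function(path, bins, format = c("triplet_tsv", "pairs")) {
  format <- match.arg(format)
  n <- nrow(bins)
  counts <- matrix(0, n, n)
  if (format == "pairs") {
    x <- utils::read.table(path, comment.char = "#", stringsAsFactors = FALSE,
                           col.names = c("readID", "chrom1", "pos1",
                                         "chrom2", "pos2", "strand1", "strand2"))
    g <- genome_of(bins)
    for (side in 1:2) {
      ch <- x[[paste0("chrom", side)]]
      pos <- x[[paste0("pos", side)]]
      len <- g$length[match(ch, g$chrom)]
      bad <- is.na(len) | pos < 0 | pos >= len
      if (any(bad)) {
        stop("pair position outside chromosome length at record ",
             x$readID[which(bad)[1]], call. = FALSE)
      }
    }
    i <- pair_bin_index(bins, x$chrom1, x$pos1)
    j <- pair_bin_index(bins, x$chrom2, x$pos2)
    for (k in seq_along(i)) {
      counts[i[k], j[k]] <- counts[i[k], j[k]] + 1
      if (i[k] != j[k]) counts[j[k], i[k]] <- counts[j[k], i[k]] + 1
    }
  } else {
    x <- readr::read_tsv(path, col_names = c("bin1_id", "bin2_id", "count"),
                         col_types = "iid", comment = "#")
    if (any(x$bin1_id < 1 | x$bin1_id > n | x$bin2_id < 1 | x$bin2_id > n)) {
      stop("bin id outside bin table", call. = FALSE)
    }
    key <- paste(pmin(x$bin1_id, x$bin2_id), pmax(x$bin1_id, x$bin2_id))
    if (anyDuplicated(key)) {
      stop("duplicate mirrored entry for bin pair ", key[duplicated(key)][1],
           call. = FALSE)
    }
    for (k in seq_len(nrow(x))) {
      i <- x$bin1_id[k]; j <- x$bin2_id[k]
      counts[i, j] <- counts[i, j] + x$count[k]
      if (i != j) counts[j, i] <- counts[j, i] + x$count[k]
    }
  }
  contact_map(bins, counts)
}

pair_bin_index <- function(bins, chrom, pos) {
  bs <- bin_size_of(bins)
  first <- tapply(bins$bin_id, bins$chrom, min)[chrom]
  as.integer(first + floor(pos / bs))
}

#' Write binned contacts to disk
#'
#' `"triplet_tsv"` writes the nonzero upper triangle as 1-based
#' (bin1_id, bin2_id, count); `read_contacts()` of that file reproduces the
#' counts exactly. `"pairs"` writes one synthetic pair line per contact with
#' positions at bin midpoints (lossy in bp, exact in binned counts).
#'
#' @param m A `contact_map`.
#' @param path Output path.
#' @param format `"triplet_tsv"` or `"pairs"`.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(m, path, format = c("triplet_tsv", "pairs")) {
  format <- match.arg(format)
  tri <- tidy(m)
  if (format == "triplet_tsv") {
    readr::write_tsv(tri, path, col_names = FALSE)
  } else {
    b <- m$bins
    rep_id <- rep.int(seq_len(nrow(tri)), tri$count)
    i <- tri$bin1_id[rep_id]; j <- tri$bin2_id[rep_id]
    lines <- sprintf("read%07d\t%s\t%d\t%s\t%d\t+\t-",
                     seq_along(i), b$chrom[i], round(b$mid[i]),
                     b$chrom[j], round(b$mid[j]))
    writeLines(c("## pairs format v1.0", lines), path)
  }
  invisible(path)
}

#' Write a per-bin scalar track as bedGraph
#'
#' @param bins Bin table.
#' @param values Per-bin numeric values (`NA` rows are skipped).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(bins, values, path) {
  keep <- !is.na(values)
  readr::write_tsv(
    tibble::tibble(chrom = bins$chrom[keep],
                   start = as.integer(bins$start[keep]),
                   end = as.integer(bins$end[keep]),
                   value = values[keep]),
    path, col_names = FALSE)
  invisible(path)
}

#' Write genomic intervals as BED
#'
#' @param df Tibble with columns `chrom`, `start`, `end` and optionally
#'   `name` and `score` (scores clamped to 0-1000).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  out <- tibble::tibble(
    chrom = df$chrom,
    start = as.integer(df$start),
    end = as.integer(df$end),
    name = if ("name" %in% names(df)) df$name else ".",
    score = if ("score" %in% names(df)) {
      as.integer(pmin(1000, pmax(0, round(df$score))))
    } else 0L
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}
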