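resolve_subset <- function(bins, subset) {
  g <- genome_of(bins)
  g <- g[!g$is_mito, ]
  if (length(subset) == 1 && subset %in% c("all", "large", "small")) {
    ord <- g$chrom[order(-g$length)]
    half <- ceiling(length(ord) / 2)
    switch(subset,
           all = g$chrom,
           large = ord[seq_len(half)],
           small = ord[(half + 1):length(ord)])
  } else {
    bad <- setdiff(subset, g$chrom)
    if (length(bad) > 0) {
      stop("unknown chromosomes in subset: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    subset
  }
}

#' Average scaled inter-chromosomal (trans) contact map
#'
#' For every ordered pair of chromosomes in the subset, the trans block of the
#' balanced map is divided by its mean (observed/expected), rescaled to
#' `n_scaled x n_scaled` universal chromosome coordinates by length-weighted
#' bin averaging (both axes oriented p -> q), and averaged over pairs. With
#' clustered telomeres the diagonal profile peaks at both ends; clustered
#' centromeres peak at the length-proportional centromere position.
#'
#' @param m A balanced (or expected) `contact_map`.
#' @param n_scaled Size of the scaled map (default 40).
#' @param subset `"all"`, `"large"` (longer half of the chromosomes),
#'   `"small"` (shorter half), or a character vector of chromosome names;
#'   must contain at least 2 chromosomes.
#' @return A `hic_scaled_trans` object: the scaled matrix, its
#'   `diagonal_profile`, the subset label and the number of pairs averaged.
#' @export
scaled_trans_map <- function(m, n_scaled = 40, subset = "all") {
  bins <- m$bins
  chroms <- resolve_subset(bins, subset)
  if (length(chroms) < 2) stop("subset must contain >= 2 chromosomes",
                               call. = FALSE)
  B <- balanced_matrix(m)

  # aggregation operator: scaled row s is the coverage-weighted mean of the
  # chromosome's bins overlapping scaled window s
  agg_op <- function(idx) {
    g <- genome_of(bins)
    L <- g$length[g$chrom == bins$chrom[idx[1]]]
    edges <- seq(0, L, length.out = n_scaled + 1)
    A <- matrix(0, n_scaled, length(idx))
    for (s in seq_len(n_scaled)) {
      ov <- pmin(bins$end[idx], edges[s + 1]) - pmax(bins$start[idx], edges[s])
      ov[ov < 0] <- 0
      A[s, ] <- ov
    }
    A
  }

  acc <- matrix(0, n_scaled, n_scaled)
  wacc <- matrix(0, n_scaled, n_scaled)
  n_pairs <- 0L
  ops <- lapply(chroms, function(c) agg_op(which(bins$chrom == c)))
  names(ops) <- chroms
  for (a in chroms) {
    for (b in chroms) {
      if (a == b) next
      i1 <- which(bins$chrom == a)
      i2 <- which(bins$chrom == b)
      blk <- B[i1, i2, drop = FALSE]
      mu <- mean(blk, na.rm = TRUE)
      if (!is.finite(mu) || mu == 0) next
      OE <- blk / mu
      val <- OE
      val[is.na(val)] <- 0
      wt <- (!is.na(OE)) * 1
      A1 <- ops[[a]]; A2 <- ops[[b]]
      acc <- acc + (A1 %*% val %*% t(A2))
      wacc <- wacc + (A1 %*% wt %*% t(A2))
      n_pairs <- n_pairs + 1L
    }
  }
  if (n_pairs == 0) stop("no usable trans blocks in subset", call. = FALSE)
  S <- acc / wacc
  structure(
    list(scaled = S, diagonal_profile = diag(S),
         subset = if (length(subset) == 1) subset else "custom",
         n_scaled = n_scaled, n_pairs = n_pairs),
    class = "hic_scaled_trans"
  )
}

#' @export
print.hic_scaled_trans <- function(x, ...) {
  cat(sprintf("<hic_scaled_trans> %dx%d, subset %s, %d ordered pairs\n",
              x$n_scaled, x$n_scaled, x$subset, x$n_pairs))
  invisible(x)
}

#' Plot a scaled trans map
#' @param object A `hic_scaled_trans`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hic_scaled_trans <- function(object, ...) {
  df <- tidyr::expand_grid(i = seq_len(object$n_scaled),
                           j = seq_len(object$n_scaled))
  df$enrichment <- as.vector(object$scaled)
  ggplot2::ggplot(df, ggplot2::aes(.data$j, .data$i,
                                   fill = log2(.data$enrichment))) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = "scaled position (p -> q)", y = "scaled position (p -> q)",
                  fill = "log2 O/E") +
    ggplot2::theme_minimal()
}

#' Telomere and centromere trans clustering enrichment
#'
#' Each statistic is the mean trans observed/expected contact over bin pairs
#' where both bins carry the corresponding end-region flag (telomere-telomere,
#' centromere-centromere, telomere-centromere), divided by the mean over all
#' trans pairs within the chromosome subset.
#'
#' @param m A balanced (or expected) `contact_map`.
#' @param subset As in [scaled_trans_map()].
#' @return A tibble: `statistic` (`tel_tel`, `cen_cen`, `tel_cen`),
#'   `enrichment`, `n_pairs`.
#' @export
telcen_aggregate <- function(m, subset = "all") {
  bins <- m$bins
  chroms <- resolve_subset(bins, subset)
  if (length(chroms) < 2) stop("subset must contain >= 2 chromosomes",
                               call. = FALSE)
  B <- balanced_matrix(m)
  tel <- bins$in_telomere_end
  cen <- bins$in_centromere_flank
  if (!any(tel) && !any(cen)) {
    stop("no telomere/centromere-flagged bins in the bin table", call. = FALSE)
  }

  sums <- c(tel_tel = 0, cen_cen = 0, tel_cen = 0, all = 0)
  cnts <- c(tel_tel = 0, cen_cen = 0, tel_cen = 0, all = 0)
  for (a in seq_along(chroms)) {
    for (b in seq_along(chroms)) {
      if (b <= a) next
      i1 <- which(bins$chrom == chroms[a] & m$mask)
      i2 <- which(bins$chrom == chroms[b] & m$mask)
      blk <- B[i1, i2, drop = FALSE]
      mu <- mean(blk, na.rm = TRUE)
      if (!is.finite(mu) || mu == 0) next
      OE <- blk / mu
      pair_sets <- list(
        tel_tel = outer(tel[i1], tel[i2], "&"),
        cen_cen = outer(cen[i1], cen[i2], "&"),
        tel_cen = outer(tel[i1], cen[i2], "&") | outer(cen[i1], tel[i2], "&"),
        all = matrix(TRUE, length(i1), length(i2))
      )
      for (s in names(pair_sets)) {
        v <- OE[pair_sets[[s]]]
        v <- v[!is.na(v)]
        sums[s] <- sums[s] + sum(v)
        cnts[s] <- cnts[s] + length(v)
      }
    }
  }
  if (cnts["all"] == 0) stop("no valid trans pairs in subset", call. = FALSE)
  base <- (sums["all"] / cnts["all"])
  stats <- c("tel_tel", "cen_cen", "tel_cen")
  tibble::tibble(
    statistic = stats,
    enrichment = as.numeric((sums[stats] / cnts[stats]) / base),
    n_pairs = as.numeric(cnts[stats])
  )
}

#' Pairwise telomere-end contact matrix
#'
#' For every unordered pair of chromosome-arm ends (the terminal `end_size`
#' of each p and q arm), the mean balanced contact over the end x end block,
#' normalized by the genome-wide mean trans balanced contact. Cis entries
#' exist only for the p-q pair of the same chromosome and use the same
#' normalization (documented: they share the trans scale, so cis values are
#' large). Arms shorter than `end_size` give entries flagged undefined,
#' never silently zero.
#'
#' @param m A balanced (or expected) `contact_map`.
#' @param end_size End-region size in bp (>= bin size; default the bin
#'   table's `end_size`).
#' @return A tibble of class `hic_telpairs`: `chrom1`, `arm1`, `chrom2`,
#'   `arm2`, `cis`, `defined`, `value`.
#' @export
telomere_pair_matrix <- function(m, end_size = NULL) {
  bins <- m$bins
  bs <- bin_size_of(bins)
  if (is.null(end_size)) end_size <- attr(bins, "end_size")
  if (end_size < bs) stop("end_size must be >= bin size", call. = FALSE)
  g <- genome_of(bins)
  g <- g[!g$is_mito, ]
  B <- balanced_matrix(m)

  # genome-wide mean trans contact (valid non-mito pairs)
  tsum <- 0; tcnt <- 0
  for (a in seq_len(nrow(g))) {
    for (b in seq_len(nrow(g))) {
      if (b <= a) next
      i1 <- which(bins$chrom == g$chrom[a] & m$mask)
      i2 <- which(bins$chrom == g$chrom[b] & m$mask)
      blk <- B[i1, i2, drop = FALSE]
      tsum <- tsum + sum(blk, na.rm = TRUE)
      tcnt <- tcnt + sum(!is.na(blk))
    }
  }
  if (tcnt == 0) {
    # degenerate single-chromosome genome: normalize by the overall mean
    keep <- which(m$mask & !bins$is_mito)
    blk <- B[keep, keep]
    trans_mean <- mean(blk[upper.tri(blk)], na.rm = TRUE)
  } else {
    trans_mean <- tsum / tcnt
  }

  ends <- purrr::pmap_dfr(g[, c("chrom", "length", "centromere_mid")],
                          function(chrom, length, centromere_mid) {
    p_len <- if (is.na(centromere_mid)) Inf else centromere_mid
    q_len <- if (is.na(centromere_mid)) Inf else length - centromere_mid
    tibble::tibble(
      chrom = chrom,
      arm = c("p", "q"),
      lo = c(0, length - end_size),
      hi = c(end_size, length),
      defined = c(p_len >= end_size, q_len >= end_size)
    )
  })

  end_bins <- lapply(seq_len(nrow(ends)), function(k) {
    which(bins$chrom == ends$chrom[k] & bins$start < ends$hi[k] &
            bins$end > ends$lo[k] & m$mask)
  })

  out <- list()
  for (a in seq_len(nrow(ends))) {
    for (b in seq_len(nrow(ends))) {
      if (b <= a) next
      same <- ends$chrom[a] == ends$chrom[b]
      # cis entries only for the p-q pair of one chromosome
      blk <- B[end_bins[[a]], end_bins[[b]], drop = FALSE]
      def <- ends$defined[a] && ends$defined[b] && any(!is.na(blk))
      out[[length(out) + 1]] <- tibble::tibble(
        chrom1 = ends$chrom[a], arm1 = ends$arm[a],
        chrom2 = ends$chrom[b], arm2 = ends$arm[b],
        cis = same, defined = def,
        value = if (def) mean(blk, na.rm = TRUE) / trans_mean else NA_real_
      )
    }
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("hic_telpairs", class(res))
  res
}

#' Plot a telomere-pair matrix
#' @param object A `hic_telpairs` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hic_telpairs <- function(object, ...) {
  df <- dplyr::mutate(object,
                      end1 = paste0(.data$chrom1, .data$arm1),
                      end2 = paste0(.data$chrom2, .data$arm2))
  lv <- unique(c(df$end1, df$end2))
  df <- dplyr::bind_rows(df,
                         dplyr::rename(df, end1 = "end2", end2 = "end1"))
  df$end1 <- factor(df$end1, levels = lv)
  df$end2 <- factor(df$end2, levels = lv)
  ggplot2::ggplot(df, ggplot2::aes(.data$end2, .data$end1,
                                   fill = log2(.data$value))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2 norm.") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Virtual 4C profile of an anchor region
#'
#' The mean balanced contact between the anchor's bins and every other bin,
#' normalized so the profile sums to 1 over the defined bins of the anchor's
#' chromosome.
#'
#' @param m A balanced (or expected) `contact_map`.
#' @param anchor A list or one-row data frame with `chrom`, `start`, `end`.
#' @return A tibble: `bin_id`, `chrom`, `start`, `value`.
#' @export
virtual_4c <- function(m, anchor) {
  bins <- m$bins
  a_idx <- which(bins$chrom == anchor$chrom & bins$start < anchor$end &
                   bins$end > anchor$start & m$mask)
  if (length(a_idx) == 0) {
    stop("anchor covers no unmasked bin", call. = FALSE)
  }
  B <- balanced_matrix(m)
  prof <- colMeans(B[a_idx, , drop = FALSE], na.rm = TRUE)
  prof[!m$mask] <- NA_real_
  prof[is.nan(prof)] <- NA_real_
  on_chrom <- bins$chrom == anchor$chrom & !is.na(prof)
  norm <- sum(prof[on_chrom])
  if (!is.finite(norm) || norm <= 0) stop("empty anchor chromosome profile",
                                          call. = FALSE)
  tibble::tibble(bin_id = bins$bin_id, chrom = bins$chrom,
                 start = bins$start, value = prof / norm)
}

#' Mitochondrial-nuclear contact enrichment score
#'
#' `(mito x nuclear contact sum / total contact sum)` divided by the share of
#' mito x nuclear pairs among all unordered bin pairs. Values above 1 indicate
#' enrichment of the mitochondrial-nuclear background signal. Computed on raw
#' counts over all bins: this is a count-share statistic, and the
#' mitochondrial contig is low-coverage by construction, so the balancing
#' mask is deliberately ignored here.
#'
#' @param m A `contact_map` whose genome contains a mitochondrial contig.
#' @return A scalar score.
#' @export
mito_nuclear_score <- function(m) {
  bins <- m$bins
  if (!any(bins$is_mito)) stop("genome has no mitochondrial contig",
                               call. = FALSE)
  mi <- which(bins$is_mito)
  nu <- which(!bins$is_mito)
  M <- m$counts
  total <- upper_tri_sum(M)
  if (total == 0) stop("empty matrix", call. = FALSE)
  mn_sum <- sum(m$counts[mi, nu])
  n_all <- length(mi) + length(nu)
  pair_share <- (length(mi) * length(nu)) / (n_all * (n_all + 1) / 2)
  (mn_sum / total) / pair_share
}
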