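#' Genome-wide cis (intra-chromosomal) contact percentage
#'
#' The territoriality statistic: the percentage of contacts whose two ends lie
#' on the same chromosome. Computed on raw (unbalanced) counts because the
#' fraction of reads is a count statistic; the mitochondrial contig is
#' excluded entirely; diagonal (self-bin) pairs are included; masked bins are
#' excluded, matching every other statistic.
#'
#' @param m A `contact_map`.
#' @return Percentage in \[0, 100\].
#' @export
cis_fraction <- function(m) {
  keep <- m$mask & !m$bins$is_mito
  M <- m$counts[keep, keep, drop = FALSE]
  total <- upper_tri_sum(M)
  if (total == 0) stop("no contacts on non-mitochondrial chromosomes", call. = FALSE)
  ch <- m$bins$chrom[keep]
  cis <- sum(vapply(unique(ch), function(c) {
    idx <- ch == c
    upper_tri_sum(M[idx, idx, drop = FALSE])
  }, numeric(1)))
  100 * cis / total
}

#' Fraction of cis contacts beyond a distance cutoff
#'
#' @param m A `contact_map`.
#' @param cutoff Distance in bp (midpoint-to-midpoint; default 2 Mb).
#' @return Fraction in \[0, 1\] of cis (non-mitochondrial, raw) contacts at
#'   distance > `cutoff`; self-bin pairs count as distance 0.
#' @export
long_range_fraction <- function(m, cutoff = 2e6) {
  keep <- m$mask & !m$bins$is_mito
  b <- m$bins[keep, ]
  M <- m$counts[keep, keep, drop = FALSE]
  tot <- 0
  far <- 0
  for (c in unique(b$chrom)) {
    idx <- which(b$chrom == c)
    sub <- M[idx, idx, drop = FALSE]
    d <- abs(outer(b$mid[idx], b$mid[idx], "-"))
    ut <- upper.tri(sub, diag = TRUE)
    tot <- tot + sum(sub[ut])
    far <- far + sum(sub[ut & d > cutoff])
  }
  if (tot == 0) stop("no cis contacts", call. = FALSE)
  far / tot
}

#' Contact frequency as a function of genomic distance, P(s)
#'
#' Per log-spaced distance bin, the mean balanced contact over all valid cis
#' bin pairs pooled across (non-mitochondrial) chromosomes, with distances
#' measured between bin midpoints. Curves are normalized to unit area in log
#' space (`sum(P * d log10 s) = 1`) so cross-sample comparisons are
#' shape-only. The derivative `d log10 P / d log10 s` is a centered finite
#' difference after moving-average smoothing of `log10 P` over
#' `smooth_window` curve points.
#'
#' @param m A balanced `contact_map` (or an expected map).
#' @param bins_per_decade Number of log-spaced distance bins per decade
#'   (default 8).
#' @param smooth_window Odd moving-average window (in curve points, default 5)
#'   applied to `log10 P` before differentiation.
#' @return A tibble of class `hic_ps`: `s_lo`, `s_hi`, `s_mid` (geometric
#'   midpoint, bp), `p`, `n_pairs`, `deriv`.
#' @export
ps_curve <- function(m, bins_per_decade = 8, smooth_window = 5) {
  stopifnot(bins_per_decade > 0, smooth_window >= 1)
  B <- balanced_matrix(m)
  keep <- m$mask & !m$bins$is_mito
  b <- m$bins[keep, ]
  B <- B[keep, keep, drop = FALSE]

  dist_all <- numeric(0)
  val_all <- numeric(0)
  for (c in unique(b$chrom)) {
    idx <- which(b$chrom == c)
    if (length(idx) < 2) next
    sub <- B[idx, idx, drop = FALSE]
    d <- abs(outer(b$mid[idx], b$mid[idx], "-"))
    ut <- upper.tri(sub)
    dist_all <- c(dist_all, d[ut])
    val_all <- c(val_all, sub[ut])
  }
  ok <- !is.na(val_all)
  dist_all <- dist_all[ok]
  val_all <- val_all[ok]
  if (length(dist_all) == 0) stop("no valid cis pairs", call. = FALSE)

  lo <- log10(min(dist_all)) - 1e-9
  hi <- log10(max(dist_all)) + 1e-9
  n_edge <- max(2, ceiling((hi - lo) * bins_per_decade) + 1)
  edges <- 10^seq(lo, hi, length.out = n_edge)
  grp <- findInterval(log10(dist_all), log10(edges), rightmost.closed = TRUE)
  sums <- tapply(val_all, grp, sum)
  cnts <- tapply(rep(1, length(grp)), grp, sum)
  k <- as.integer(names(sums))

  ps <- tibble::tibble(
    s_lo = edges[k], s_hi = edges[k + 1],
    s_mid = sqrt(edges[k] * edges[k + 1]),
    p = as.numeric(sums / cnts),
    n_pairs = as.numeric(cnts)
  )
  ps <- ps[ps$n_pairs > 0, ]
  if (nrow(ps) < 3) stop("fewer than 3 nonempty distance bins", call. = FALSE)

  # unit area in log space
  dlog <- log10(ps$s_hi) - log10(ps$s_lo)
  ps$p <- ps$p / sum(ps$p * dlog)

  x <- log10(ps$s_mid)
  y <- log10(ps$p)
  y[!is.finite(y)] <- NA_real_
  ys <- moving_average(y, smooth_window)
  n <- nrow(ps)
  deriv <- rep(NA_real_, n)
  if (n >= 3) {
    deriv[2:(n - 1)] <- (ys[3:n] - ys[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  }
  ps$deriv <- deriv
  class(ps) <- c("hic_ps", class(ps))
  ps
}

moving_average <- function(y, window) {
  if (window <= 1) return(y)
  h <- floor(window / 2)
  n <- length(y)
  vapply(seq_len(n), function(i) {
    idx <- max(1, i - h):min(n, i + h)
    mean(y[idx], na.rm = TRUE)
  }, numeric(1))
}

#' Log-log slope of a P(s) curve over a distance range
#'
#' @param ps A `hic_ps` tibble from [ps_curve()].
#' @param s_range Distance range in bp over which to fit (default 0.5-10 Mb).
#' @return The fitted slope of `log10 P` vs `log10 s`.
#' @export
ps_slope <- function(ps, s_range = c(5e5, 1e7)) {
  sel <- ps$s_mid >= s_range[1] & ps$s_mid <= s_range[2] & ps$p > 0
  if (sum(sel) < 3) stop("fewer than 3 curve points in s_range", call. = FALSE)
  unname(stats::coef(stats::lm(log10(p) ~ log10(s_mid), data = ps[sel, ]))[2])
}

#' Plot a P(s) curve and its derivative
#'
#' @param object A `hic_ps` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hic_ps <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::transmute(object, s = .data$s_mid, `P(s)` = .data$p,
                     `d log10 P / d log10 s` = .data$deriv),
    -"s", names_to = "panel", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$s, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "genomic separation s (bp)", y = NULL) +
    ggplot2::theme_minimal()
}
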