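#' Diamond-window insulation score
#'
#' For each bin `i`, the mean balanced contact over the `w x w` diamond just
#' off the diagonal (rows `i-w ... i-1`, columns `i+1 ... i+w`, with
#' `w = window / bin_size`), log2-normalized by the chromosome-wide mean
#' diamond value. Undefined (`NA`) within `w` bins of chromosome ends, at
#' masked bins, and where the diamond contains no valid pair.
#'
#' @param m A balanced (or expected) `contact_map`.
#' @param window Diamond window in bp; must be a multiple of the bin size and
#'   at least 2 bins.
#' @return A tibble of class `hic_insulation`: `bin_id`, `chrom`, `start`,
#'   `insulation`; attribute `window`.
#' @export
insulation_track <- function(m, window) {
  bins <- m$bins
  bs <- bin_size_of(bins)
  w <- window / bs
  if (abs(w - round(w)) > 1e-9) {
    stop("window must be a multiple of the bin size", call. = FALSE)
  }
  w <- as.integer(round(w))
  if (w < 2) stop("window must span at least 2 bins", call. = FALSE)
  B <- balanced_matrix(m)

  ins <- rep(NA_real_, nrow(bins))
  for (c in unique(bins$chrom[!bins$is_mito])) {
    idx <- which(bins$chrom == c)
    nc <- length(idx)
    if (nc <= 2 * w) {
      warning("window exceeds chromosome ", c, "; insulation undefined there",
              call. = FALSE)
      next
    }
    sub <- B[idx, idx, drop = FALSE]
    raw <- rep(NA_real_, nc)
    for (i in (w + 1):(nc - w)) {
      if (!m$mask[idx[i]]) next
      d <- sub[(i - w):(i - 1), (i + 1):(i + w), drop = FALSE]
      if (all(is.na(d))) next
      raw[i] <- mean(d, na.rm = TRUE)
    }
    mu <- mean(raw, na.rm = TRUE)
    if (is.finite(mu) && mu > 0) {
      ins[idx] <- log2(raw / mu)
    }
  }
  out <- tibble::tibble(bin_id = bins$bin_id, chrom = bins$chrom,
                        start = bins$start, insulation = ins)
  attr(out, "window") <- window
  attr(out, "bins") <- bins
  class(out) <- c("hic_insulation", class(out))
  out
}

#' Call TAD boundaries from an insulation track
#'
#' Boundaries are local minima of the insulation score (strictly lower than
#' both defined neighbors; a flat minimum plateau takes its leftmost bin).
#' Strength is the prominence of the minimum: the difference to the lower of
#' the two flanking maxima (the highest value reached walking left/right
#' within the defined run before the score falls again), in log2 units.
#' `is_strong` applies the strict threshold `strength > strong_threshold`.
#'
#' @param track A `hic_insulation` tibble.
#' @param strong_threshold Strong-boundary threshold on prominence
#'   (default 0.1).
#' @return A tibble of class `hic_boundaries`: `chrom`, `bin_id`, `start`,
#'   `insulation`, `strength`, `is_strong`.
#' @export
call_boundaries <- function(track, strong_threshold = 0.1) {
  out <- list()
  for (c in unique(track$chrom)) {
    sub <- track[track$chrom == c, ]
    y <- sub$insulation
    runs <- split(seq_along(y), cumsum(is.na(y)))
    for (r in runs) {
      r <- r[!is.na(y[r])]
      if (length(r) < 3) next
      v <- y[r]
      nr <- length(v)
      i <- 2L
      while (i <= nr - 1) {
        # extend over a flat plateau
        j <- i
        while (j < nr && v[j + 1] == v[i]) j <- j + 1
        if (j >= nr) break
        if (v[i - 1] > v[i] && v[j + 1] > v[i]) {
          left_max <- max(v[1:(i - 1)][cummax_from_right(v[1:(i - 1)])])
          right_max <- max(v[(j + 1):nr][cummax_from_left(v[(j + 1):nr])])
          strength <- min(left_max, right_max) - v[i]
          out[[length(out) + 1]] <- tibble::tibble(
            chrom = c, bin_id = sub$bin_id[r[i]], start = sub$start[r[i]],
            insulation = v[i], strength = strength
          )
        }
        i <- j + 1L
      }
    }
  }
  res <- if (length(out) > 0) dplyr::bind_rows(out) else {
    tibble::tibble(chrom = character(), bin_id = integer(), start = numeric(),
                   insulation = numeric(), strength = numeric())
  }
  res$is_strong <- res$strength > strong_threshold
  class(res) <- c("hic_boundaries", class(res))
  res
}

# helper: mark, scanning away from a minimum, the rising stretch up to the
# first local peak (prominence uses the nearest flanking maximum)
cummax_from_right <- function(v) {
  # values to the left of the minimum, scan right-to-left until first drop
  n <- length(v)
  keep <- logical(n)
  peak <- -Inf
  for (i in n:1) {
    if (v[i] >= peak) {
      peak <- v[i]
      keep[i] <- TRUE
    } else break
  }
  keep
}

cummax_from_left <- function(v) {
  n <- length(v)
  keep <- logical(n)
  peak <- -Inf
  for (i in 1:n) {
    if (v[i] >= peak) {
      peak <- v[i]
      keep[i] <- TRUE
    } else break
  }
  keep
}

#' Partition two boundary sets into specific and common calls
#'
#' Greedy nearest matching within `match_tol_bins` bins, per chromosome; each
#' boundary is matched at most once. The partition is exhaustive
#' (`|a_specific| + |common| + |b_specific| = |union|`) and symmetric:
#' swapping the inputs swaps the specific sets.
#'
#' @param calls_a,calls_b `hic_boundaries` tibbles on the same bin table.
#' @param match_tol_bins Maximum distance in bins for a match (default 1).
#' @return A list of tibbles `a_specific`, `common` (with paired positions),
#'   `b_specific`.
#' @export
compare_boundary_sets <- function(calls_a, calls_b, match_tol_bins = 1) {
  common <- list()
  a_keep <- rep(TRUE, nrow(calls_a))
  b_keep <- rep(TRUE, nrow(calls_b))
  for (c in union(calls_a$chrom, calls_b$chrom)) {
    ia <- which(calls_a$chrom == c)
    ib <- which(calls_b$chrom == c)
    if (length(ia) == 0 || length(ib) == 0) next
    cand <- tidyr::expand_grid(a = ia, b = ib)
    cand$dist <- abs(calls_a$bin_id[cand$a] - calls_b$bin_id[cand$b])
    cand <- cand[cand$dist <= match_tol_bins, ]
    # symmetric deterministic order: by distance, then by pair midpoint
    cand <- cand[order(cand$dist,
                       calls_a$bin_id[cand$a] + calls_b$bin_id[cand$b],
                       pmin(calls_a$bin_id[cand$a], calls_b$bin_id[cand$b])), ]
    for (k in seq_len(nrow(cand))) {
      a <- cand$a[k]; b <- cand$b[k]
      if (a_keep[a] && b_keep[b]) {
        a_keep[a] <- FALSE
        b_keep[b] <- FALSE
        common[[length(common) + 1]] <- tibble::tibble(
          chrom = c, bin_a = calls_a$bin_id[a], bin_b = calls_b$bin_id[b],
          start_a = calls_a$start[a], start_b = calls_b$start[b]
        )
      }
    }
  }
  list(
    a_specific = calls_a[a_keep, ],
    common = if (length(common) > 0) dplyr::bind_rows(common) else
      tibble::tibble(chrom = character(), bin_a = integer(), bin_b = integer(),
                     start_a = numeric(), start_b = numeric()),
    b_specific = calls_b[b_keep, ]
  )
}

#' Aggregate insulation scores around boundaries
#'
#' Stacks each track's insulation values at `boundary +/- flank` and averages
#' across boundaries; boundaries whose flank window contains undefined values
#' (or leaves the chromosome) are dropped and counted.
#'
#' @param tracks A named list of `hic_insulation` tibbles on the same bins.
#' @param boundaries A `hic_boundaries` tibble (non-empty).
#' @param flank Flanking distance in bp, a multiple of the bin size
#'   (default 200 kb; the narrower 100 kb view is just `flank = 1e5`).
#' @return A list: `profile` (tibble `track`, `offset`, `mean_insulation`,
#'   `n_boundaries`) and `stackup` (list of boundary x offset matrices),
#'   plus `n_dropped` per track.
#' @export
aggregate_insulation <- function(tracks, boundaries, flank = 2e5) {
  if (nrow(boundaries) == 0) stop("empty boundary list", call. = FALSE)
  if (!is.list(tracks) || inherits(tracks, "hic_insulation")) {
    tracks <- list(track = tracks)
  }
  if (is.null(names(tracks))) names(tracks) <- paste0("track", seq_along(tracks))
  bs <- bin_size_of(attr(tracks[[1]], "bins"))
  f <- flank / bs
  if (abs(f - round(f)) > 1e-9) {
    stop("flank must be a multiple of the bin size", call. = FALSE)
  }
  f <- as.integer(round(f))
  offsets <- (-f):f

  profile <- list()
  stackup <- list()
  n_dropped <- integer(length(tracks))
  names(n_dropped) <- names(tracks)
  for (t in names(tracks)) {
    tr <- tracks[[t]]
    rows <- matrix(NA_real_, nrow(boundaries), length(offsets))
    for (k in seq_len(nrow(boundaries))) {
      ctr <- boundaries$bin_id[k]
      span <- ctr + offsets
      ok <- span >= 1 & span <= nrow(tr) &
        tr$chrom[pmax(pmin(span, nrow(tr)), 1)] == boundaries$chrom[k]
      if (!all(ok)) next
      rows[k, ] <- tr$insulation[span]
    }
    keep <- stats::complete.cases(rows)
    n_dropped[t] <- sum(!keep)
    rows <- rows[keep, , drop = FALSE]
    stackup[[t]] <- rows
    profile[[t]] <- tibble::tibble(
      track = t,
      offset = offsets * bs,
      mean_insulation = colMeans(rows),
      n_boundaries = nrow(rows)
    )
  }
  list(profile = dplyr::bind_rows(profile), stackup = stackup,
       n_dropped = n_dropped)
}

#' Plot an insulation track
#' @param object A `hic_insulation` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hic_insulation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$start, .data$insulation)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "insulation (log2)") +
    ggplot2::theme_minimal()
}

#' Write boundary calls as BED (score = strength x 1000, clamped)
#'
#' @param calls A `hic_boundaries` tibble.
#' @param bins The bin table the calls were made on.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_boundaries_bed <- function(calls, bins, path) {
  df <- tibble::tibble(
    chrom = calls$chrom,
    start = calls$start,
    end = bins$end[calls$bin_id],
    name = ifelse(calls$is_strong, "strong", "weak"),
    score = calls$strength * 1000
  )
  write_bed(df, path)
}
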