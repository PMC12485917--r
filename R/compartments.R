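#' Observed/expected transformation of a cis block
#'
#' Divides each off-center diagonal by its mean over valid entries, the
#' standard distance normalization behind eigenvector and saddle analysis.
#' @noRd
oe_cis <- function(B) {
  nc <- nrow(B)
  D <- abs(outer(seq_len(nc), seq_len(nc), "-"))
  means <- tapply(as.vector(B), as.vector(D), mean, na.rm = TRUE)
  E <- matrix(means[as.character(D)], nc, nc)
  OE <- B / E
  OE[!is.finite(OE)] <- 0
  OE
}

#' Compartment eigenvector (EV1) of a balanced contact map
#'
#' Per chromosome: the balanced cis matrix is distance-normalized
#' (observed/expected), centered (`O/E - 1`) and eigendecomposed — principal
#' component analysis of the interaction matrix. Among the top `n_candidates`
#' eigenvectors the one with maximal absolute correlation to `reference` is
#' selected (the largest eigenvector does not always carry the compartment
#' signal), sign-oriented so that the correlation is positive, and scaled
#' cooltools-style by the square root of its eigenvalue (unit-norm vector
#' times `sqrt(lambda)`), which puts per-bin values on the O/E-amplitude
#' scale where the conventional +/-0.05 A/B call thresholds live.
#' Eigendecomposing the centered O/E map rather than its row-correlation
#' matrix matters for bins without compartment preference: correlation
#' renormalizes every row to unit scale, amplifying pure-noise rows to a
#' depth-independent noise floor, whereas O/E eigenvector noise shrinks with
#' sequencing depth. Chromosome tracks are concatenated genome-wide; masked
#' bins, the mitochondrial contig and chromosomes with fewer than `min_bins`
#' valid bins carry `NA`.
#'
#' @param m A balanced (or expected) `contact_map`.
#' @param reference Per-bin numeric reference track for eigenvector selection
#'   and sign fixing (a GC-like proxy on real data; the planted eigenvector
#'   track on simulations), or a character label track (`A` -> +1, `B` -> -1,
#'   otherwise 0).
#' @param ev_threshold Call threshold: A iff `ev1 > +ev_threshold`, B iff
#'   `ev1 < -ev_threshold`, else ambiguous (default 0.05).
#' @param n_candidates Number of leading eigenvectors screened (default 3).
#' @param min_bins Minimum valid bins per chromosome (default 20); smaller
#'   chromosomes get an undefined track with a warning.
#' @param clip_percentile O/E values above this quantile are clipped before
#'   eigendecomposition (default 0.999), guarding against stray single
#'   counts at sparsely covered distances.
#' @param neutralize_ends Zero out both-telomeric and both-centromeric pairs
#'   before eigendecomposition (default `TRUE`): Rabl-like end clustering is
#'   a non-compartmental structure that otherwise contaminates the leading
#'   eigenvectors.
#' @return A tibble of class `hic_compartments`: `bin_id`, `chrom`, `ev1`,
#'   `call`; attribute `selection` records, per chromosome, the chosen
#'   eigenvector index and its reference correlation.
#' @export
compute_ev1 <- function(m, reference, ev_threshold = 0.05,
                        n_candidates = 3, min_bins = 20,
                        clip_percentile = 0.999, neutralize_ends = TRUE) {
  bins <- m$bins
  n <- nrow(bins)
  if (is.character(reference)) {
    reference <- ifelse(reference == "A", 1, ifelse(reference == "B", -1, 0))
  }
  stopifnot(length(reference) == n)
  B <- balanced_matrix(m)

  ev <- rep(NA_real_, n)
  sel <- list()
  for (c in unique(bins$chrom[!bins$is_mito])) {
    idx <- which(bins$chrom == c & m$mask & !bins$is_mito)
    if (length(idx) < min_bins) {
      warning("chromosome ", c, " has fewer than ", min_bins,
              " valid bins; EV1 undefined there", call. = FALSE)
      next
    }
    OE <- oe_cis(B[idx, idx, drop = FALSE])
    # single stray counts at sparsely covered distances produce huge O/E
    # outliers that can dominate the eigendecomposition; clip them
    hi <- stats::quantile(OE, clip_percentile, na.rm = TRUE)[[1]]
    OE[OE > hi] <- hi
    M <- OE - 1
    M[OE == 0] <- 0   # pairs with empty expected carry no signal
    if (neutralize_ends) {
      # Rabl-like end clustering (telomere-telomere, centromere-centromere)
      # is a non-compartmental structure that can contaminate the leading
      # eigenvectors; both-flagged pairs carry no compartment information here
      tl <- bins$in_telomere_end[idx]
      cn <- bins$in_centromere_flank[idx]
      if (any(tl)) M[tl, tl] <- 0
      if (any(cn)) M[cn, cn] <- 0
    }
    eg <- eigen(M, symmetric = TRUE)
    k_max <- min(n_candidates, ncol(eg$vectors))
    ref <- reference[idx]
    cors <- vapply(seq_len(k_max), function(k) {
      v <- eg$vectors[, k]
      if (stats::sd(v) == 0 || stats::sd(ref) == 0) return(NA_real_)
      stats::cor(v, ref)
    }, numeric(1))
    if (all(is.na(cors))) {
      pick <- 1L
      r <- 0
    } else {
      pick <- which.max(abs(cors))
      r <- cors[pick]
    }
    if (is.na(r) || abs(r) < 0.2) {
      warning("chromosome ", c,
              ": no clear compartment structure (|cor with reference| = ",
              sprintf("%.2f", abs(r)), ")", call. = FALSE)
    }
    v <- eg$vectors[, pick]
    if (!is.na(r) && r < 0) v <- -v
    v <- v / sqrt(sum(v^2)) * sqrt(max(eg$values[pick], 0))
    ev[idx] <- v
    sel[[c]] <- tibble::tibble(chrom = c, eigenvector = pick,
                               ref_cor = abs(r))
  }
  out <- tibble::tibble(
    bin_id = bins$bin_id,
    chrom = bins$chrom,
    ev1 = ev,
    call = dplyr::case_when(
      is.na(ev) ~ NA_character_,
      ev > ev_threshold ~ "A",
      ev < -ev_threshold ~ "B",
      TRUE ~ "ambiguous"
    )
  )
  attr(out, "selection") <- dplyr::bind_rows(sel)
  attr(out, "bins") <- bins
  class(out) <- c("hic_compartments", class(out))
  out
}

#' Saddle plot and compartmentalization strength
#'
#' Bins are sorted by EV1 into `n_quantiles` quantile groups (ambiguous and
#' undefined bins excluded) and the observed/expected enrichment (cis:
#' distance-normalized per chromosome; trans: per chromosome-pair block mean)
#' is aggregated into quantile-pair cells. Compartmentalization strength is
#' the mean enrichment of the homotypic corner over the heterotypic corner of
#' the top/bottom `top_frac` quantiles: `strength_AA` = mean over
#' (top x top) cells / mean over (top x bottom) cells, `strength_BB`
#' analogously with the bottom quantiles.
#'
#' @param m A balanced (or expected) `contact_map`.
#' @param track A `hic_compartments` track on the same bins.
#' @param scope `"cis"` or `"trans"`.
#' @param n_quantiles Number of EV1 quantile groups (default 50).
#' @param top_frac Fraction of sorted bins forming the A (top) and B (bottom)
#'   corners (default 0.20).
#' @param min_pairs Cells with fewer valid pairs are dropped from the corner
#'   means (default 10).
#' @return A `hic_saddle` object: the saddle matrix, `strength_AA`,
#'   `strength_BB`, the scope and the number of dropped cells.
#' @export
saddle_strength <- function(m, track, scope = c("cis", "trans"),
                            n_quantiles = 50, top_frac = 0.2, min_pairs = 10) {
  scope <- match.arg(scope)
  bins <- m$bins
  stopifnot(nrow(track) == nrow(bins))
  elig <- m$mask & !bins$is_mito & !is.na(track$ev1) &
    !is.na(track$call) & track$call != "ambiguous"
  if (sum(elig) < 2 * n_quantiles) {
    stop("too few eligible bins for ", n_quantiles, " quantiles", call. = FALSE)
  }
  Q <- n_quantiles
  qgrp <- rep(NA_integer_, nrow(bins))
  qgrp[elig] <- as.integer(ceiling(rank(track$ev1[elig], ties.method = "first") /
                                     sum(elig) * Q))
  B <- balanced_matrix(m)

  ssum <- matrix(0, Q, Q)
  scnt <- matrix(0, Q, Q)
  add_cells <- function(qi, qj, val) {
    ok <- !is.na(val) & !is.na(qi) & !is.na(qj)
    if (!any(ok)) return()
    cell <- (qi[ok] - 1L) * Q + qj[ok]
    s <- rowsum(val[ok], cell)
    k <- as.integer(rownames(s))
    ssum[k] <<- ssum[k] + s[, 1]
    cn <- rowsum(rep(1, sum(ok)), cell)
    scnt[k] <<- scnt[k] + cn[, 1]
  }

  if (scope == "cis") {
    for (c in unique(bins$chrom[!bins$is_mito])) {
      idx <- which(bins$chrom == c & m$mask)
      if (length(idx) < 2) next
      OE <- oe_cis(B[idx, idx, drop = FALSE])
      ut <- which(upper.tri(OE), arr.ind = TRUE)
      add_cells(qgrp[idx][ut[, 1]], qgrp[idx][ut[, 2]], OE[ut])
    }
  } else {
    chroms <- unique(bins$chrom[!bins$is_mito])
    for (a in seq_along(chroms)) {
      for (b in seq_along(chroms)) {
        if (b <= a) next
        i1 <- which(bins$chrom == chroms[a] & m$mask)
        i2 <- which(bins$chrom == chroms[b] & m$mask)
        blk <- B[i1, i2, drop = FALSE]
        mu <- mean(blk, na.rm = TRUE)
        if (!is.finite(mu) || mu == 0) next
        OE <- blk / mu
        qi <- rep(qgrp[i1], times = length(i2))
        qj <- rep(qgrp[i2], each = length(i1))
        add_cells(qi, qj, as.vector(OE))
      }
    }
  }
  ssum <- ssum + t(ssum)
  scnt <- scnt + t(scnt)
  S <- ssum / scnt
  S[scnt < min_pairs] <- NA_real_
  dropped <- sum(scnt < min_pairs & scnt > 0)

  n_top <- floor(Q * top_frac)
  top <- (Q - n_top + 1):Q
  bottom <- 1:n_top
  AA <- mean(S[top, top], na.rm = TRUE)
  BB <- mean(S[bottom, bottom], na.rm = TRUE)
  AB <- mean(S[top, bottom], na.rm = TRUE)
  structure(
    list(saddle = S, strength_AA = AA / AB, strength_BB = BB / AB,
         scope = scope, n_quantiles = Q, top_frac = top_frac,
         dropped_cells = dropped),
    class = "hic_saddle"
  )
}

#' @export
print.hic_saddle <- function(x, ...) {
  cat(sprintf("<hic_saddle> %s, %d quantiles: strength_AA = %.3f, strength_BB = %.3f\n",
              x$scope, x$n_quantiles, x$strength_AA, x$strength_BB))
  invisible(x)
}

#' Tidy a saddle result into its strengths
#' @param x A `hic_saddle`.
#' @param ... Unused.
#' @return A tibble with one row per corner statistic.
#' @export
tidy.hic_saddle <- function(x, ...) {
  tibble::tibble(scope = x$scope,
                 statistic = c("strength_AA", "strength_BB"),
                 value = c(x$strength_AA, x$strength_BB))
}

#' @rdname tidy.hic_saddle
#' @export
glance.hic_saddle <- function(x, ...) {
  tibble::tibble(scope = x$scope, n_quantiles = x$n_quantiles,
                 strength_AA = x$strength_AA, strength_BB = x$strength_BB,
                 dropped_cells = x$dropped_cells)
}

#' Plot a saddle matrix
#' @param object A `hic_saddle`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hic_saddle <- function(object, ...) {
  df <- tidyr::expand_grid(q1 = seq_len(object$n_quantiles),
                           q2 = seq_len(object$n_quantiles))
  df$enrichment <- as.vector(object$saddle)
  ggplot2::ggplot(df, ggplot2::aes(.data$q2, .data$q1,
                                   fill = log2(.data$enrichment))) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = "EV1 quantile (B -> A)", y = "EV1 quantile (B -> A)",
                  fill = "log2 O/E",
                  title = sprintf("%s saddle: AA %.2f, BB %.2f", object$scope,
                                  object$strength_AA, object$strength_BB)) +
    ggplot2::theme_minimal()
}

#' Classify per-bin compartment switches across three cell states
#'
#' Each bin gets a three-letter category (one letter per state, e.g. `ABA`);
#' bins ambiguous (or undefined) in any state are `ambiguous` (`NA` if
#' undefined in any state). The summary reports each category's share of the
#' genome (all bins with defined calls, ambiguous included) and its share of
#' classified (non-ambiguous) bins.
#'
#' @param tracks A list of exactly three `hic_compartments` tracks on
#'   identical bin tables, in state order (the category letters follow the
#'   list order).
#' @return A `hic_switches` object: per-bin tibble (`bin_id`, `chrom`,
#'   `category`) and a `summary` tibble (`category`, `n`, `frac_genome`,
#'   `frac_classified`).
#' @export
classify_switches <- function(tracks) {
  stopifnot(is.list(tracks), length(tracks) == 3)
  ids <- lapply(tracks, function(t) paste(t$bin_id, t$chrom))
  if (!all(vapply(ids[-1], identical, logical(1), ids[[1]]))) {
    stop("tracks are not on identical bin tables", call. = FALSE)
  }
  calls <- do.call(cbind, lapply(tracks, function(t) t$call))
  category <- apply(calls, 1, function(x) {
    if (anyNA(x)) return(NA_character_)
    if (any(x == "ambiguous")) return("ambiguous")
    paste(x, collapse = "")
  })
  bins_tbl <- tibble::tibble(bin_id = tracks[[1]]$bin_id,
                             chrom = tracks[[1]]$chrom,
                             category = category)
  defined <- !is.na(category)
  classified <- defined & category != "ambiguous"
  summary <- bins_tbl |>
    dplyr::filter(!is.na(.data$category)) |>
    dplyr::count(.data$category) |>
    dplyr::mutate(
      frac_genome = .data$n / sum(defined),
      frac_classified = ifelse(.data$category == "ambiguous", NA_real_,
                               .data$n / sum(classified))
    ) |>
    dplyr::arrange(dplyr::desc(.data$n))
  structure(list(bins = bins_tbl, summary = summary,
                 bin_table = attr(tracks[[1]], "bins")),
            class = "hic_switches")
}

#' @export
print.hic_switches <- function(x, ...) {
  cat("<hic_switches>\n")
  print(x$summary)
  invisible(x)
}

#' Tidy a switch table
#' @param x A `hic_switches`.
#' @param ... Unused.
#' @return The per-category summary tibble.
#' @export
tidy.hic_switches <- function(x, ...) x$summary

#' Fraction of bins with identical switch category across replicates
#'
#' Over bins that are non-ambiguous (and defined) in every replicate, the
#' fraction assigned the identical three-letter category in all of them.
#'
#' @param switch_tables A list of two or more `hic_switches` on the same bins.
#' @return A fraction in \[0, 1\].
#' @export
intersection_fraction <- function(switch_tables) {
  if (!is.list(switch_tables) || length(switch_tables) < 2) {
    stop("need at least two switch tables", call. = FALSE)
  }
  cats <- do.call(cbind, lapply(switch_tables, function(s) s$bins$category))
  if (length(unique(vapply(switch_tables, function(s) nrow(s$bins),
                           integer(1)))) != 1) {
    stop("switch tables are not on the same bin table", call. = FALSE)
  }
  ok <- apply(cats, 1, function(x) !anyNA(x) && all(x != "ambiguous"))
  if (!any(ok)) stop("no bins classified in all replicates", call. = FALSE)
  same <- apply(cats[ok, , drop = FALSE], 1,
                function(x) all(x == x[1]))
  mean(same)
}

#' Summarize gene expression by switch category
#'
#' Genes are assigned to the switch category of the bin containing their
#' midpoint; per category and sample, the TPM distribution is summarized.
#'
#' @param switch A `hic_switches` object (carrying its bin table).
#' @param expr Expression tibble: `gene_id`, `chrom`, `start`, `end`, then one
#'   numeric TPM column per sample (TPM >= 0).
#' @return A tibble: `category`, `sample`, `n_genes`, `median_tpm`, `q25`,
#'   `q75`; attribute `n_skipped` counts genes outside the binned genome.
#' @export
summarize_by_group <- function(switch, expr) {
  bins <- switch$bin_table
  if (is.null(bins)) stop("switch table lacks its bin table", call. = FALSE)
  sample_cols <- setdiff(names(expr), c("gene_id", "chrom", "start", "end"))
  if (nrow(expr) == 0) {
    out <- tibble::tibble(category = character(), sample = character(),
                          n_genes = integer(), median_tpm = numeric(),
                          q25 = numeric(), q75 = numeric())
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  if (any(unlist(expr[sample_cols]) < 0)) {
    stop("TPM values must be >= 0", call. = FALSE)
  }
  mid <- (expr$start + expr$end) / 2
  bin_idx <- vapply(seq_len(nrow(expr)), function(i) {
    bin_index_at(bins, expr$chrom[i], mid[i])
  }, integer(1))
  skipped <- sum(is.na(bin_idx))
  keep <- !is.na(bin_idx)
  df <- expr[keep, c("gene_id", sample_cols)]
  df$category <- switch$bins$category[bin_idx[keep]]
  out <- df |>
    tidyr::pivot_longer(dplyr::all_of(sample_cols), names_to = "sample",
                        values_to = "tpm") |>
    dplyr::filter(!is.na(.data$category)) |>
    dplyr::group_by(.data$category, .data$sample) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      median_tpm = stats::median(.data$tpm),
      q25 = stats::quantile(.data$tpm, 0.25)[[1]],
      q75 = stats::quantile(.data$tpm, 0.75)[[1]],
      .groups = "drop"
    )
  attr(out, "n_skipped") <- skipped
  out
}
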