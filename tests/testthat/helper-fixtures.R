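# Shared fixtures and independent reference implementations (oracles).
# Oracles are deliberately written as plain loops, independent of the
# package's vectorized code paths.

tiny_genome <- function(with_mito = TRUE) {
  if (with_mito) {
    genome(c("chrA", "chrB", "chrM"), c(12e6, 10e6, 16571),
           c(5e6, 4e6, NA), c(FALSE, FALSE, TRUE))
  } else {
    genome(c("chrA", "chrB"), c(12e6, 10e6), c(5e6, 4e6))
  }
}

tiny_bins <- function(bin_size = 5e5, with_mito = TRUE) {
  build_bin_table(tiny_genome(with_mito), bin_size, end_size = 1e6)
}

# a contact_map with given counts and unit weights (acts as balanced)
unit_map <- function(bins, counts) {
  m <- contact_map(bins, counts, expected = TRUE)
  m
}

# uniform map: every pair (incl. diagonal) the same value
uniform_map <- function(bins, value = 1) {
  n <- nrow(bins)
  unit_map(bins, matrix(value, n, n))
}

# reference Sinkhorn: plain alternating scaling, many iterations
oracle_sinkhorn <- function(O, iters = 1000) {
  w <- rep(1, nrow(O))
  for (i in seq_len(iters)) {
    r <- numeric(nrow(O))
    for (a in seq_len(nrow(O))) {
      s <- 0
      for (b in seq_len(ncol(O))) s <- s + w[a] * O[a, b] * w[b]
      r[a] <- s
    }
    w <- w / sqrt(r / mean(r))
  }
  w
}

# brute-force diamond insulation for one chromosome block (weights = 1)
oracle_insulation <- function(M, w) {
  nc <- nrow(M)
  raw <- rep(NA_real_, nc)
  for (i in seq_len(nc)) {
    if (i - w < 1 || i + w > nc) next
    vals <- c()
    for (a in (i - w):(i - 1)) {
      for (b in (i + 1):(i + w)) vals <- c(vals, M[a, b])
    }
    raw[i] <- mean(vals)
  }
  log2(raw / mean(raw, na.rm = TRUE))
}

# brute-force saddle-style homotypic/heterotypic mean O/E ratio from labels
oracle_affinity_ratio <- function(M, labels) {
  nc <- nrow(M)
  oe <- matrix(NA_real_, nc, nc)
  for (d in 1:(nc - 1)) {
    vals <- c()
    for (i in 1:(nc - d)) vals <- c(vals, M[i, i + d])
    mu <- mean(vals)
    for (i in 1:(nc - d)) {
      oe[i, i + d] <- M[i, i + d] / mu
      oe[i + d, i] <- oe[i, i + d]
    }
  }
  aa <- c(); ab <- c(); bb <- c()
  for (i in 1:(nc - 1)) {
    for (j in (i + 1):nc) {
      if (labels[i] == "A" && labels[j] == "A") aa <- c(aa, oe[i, j])
      else if (labels[i] == "B" && labels[j] == "B") bb <- c(bb, oe[i, j])
      else ab <- c(ab, oe[i, j])
    }
  }
  list(AA = mean(aa) / mean(ab), BB = mean(bb) / mean(ab))
}

# labels alternating in fixed-size blocks along each chromosome
alternating_labels <- function(bins, block_bp = 2e6) {
  lab <- character(nrow(bins))
  for (c in unique(bins$chrom)) {
    idx <- which(bins$chrom == c)
    if (bins$is_mito[idx[1]]) {
      lab[idx] <- "ambiguous"
    } else {
      block <- floor(bins$start[idx] / block_bp)
      lab[idx] <- ifelse(block %% 2 == 0, "A", "B")
    }
  }
  lab
}

# a compartment track built directly from planted labels; a small
# deterministic jitter keeps EV values untied (exactly tied values would
# rank into chromosome-contiguous quantile blocks, a degenerate layout
# continuous eigenvectors never produce)
planted_track <- function(bins, labels) {
  jit <- 1 + 0.001 * ((bins$bin_id * 37) %% 89) / 89
  out <- tibble::tibble(
    bin_id = bins$bin_id, chrom = bins$chrom,
    ev1 = ifelse(labels == "A", jit, ifelse(labels == "B", -jit, 0)),
    call = ifelse(labels %in% c("A", "B"), labels, "ambiguous")
  )
  attr(out, "bins") <- bins
  class(out) <- c("hic_compartments", class(out))
  out
}

# synthetic insulation track from a plain numeric vector on one chromosome
synthetic_ins_track <- function(values, chrom = "chrA", bin_size = 25e3) {
  out <- tibble::tibble(
    bin_id = seq_along(values), chrom = chrom,
    start = (seq_along(values) - 1) * bin_size,
    insulation = values
  )
  g <- genome(chrom, length(values) * bin_size, NA_real_)
  b <- build_bin_table(g, bin_size, end_size = bin_size)
  attr(out, "bins") <- b
  attr(out, "window") <- 4 * bin_size
  class(out) <- c("hic_insulation", class(out))
  out
}

# random (aperiodic) A/B block labels: strictly periodic blocks make label
# composition depend on distance, which the per-diagonal expected absorbs —
# aperiodic blocks keep the closed-form affinity ratio intact
random_block_labels <- function(bins, block_bp = 2e6, seed = 1) {
  set.seed(seed)
  lab <- character(nrow(bins))
  for (c in unique(bins$chrom)) {
    idx <- which(bins$chrom == c)
    if (bins$is_mito[idx[1]]) {
      lab[idx] <- "ambiguous"
      next
    }
    block <- floor(bins$start[idx] / block_bp)
    keys <- sample(c("A", "B"), max(block) + 1, replace = TRUE)
    lab[idx] <- keys[block + 1]
  }
  lab
}

saddle_genome <- function() {
  genome(c("s1", "s2"), c(30e6, 30e6), c(14e6, 15e6))
}
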