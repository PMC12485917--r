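#' Parameters of the synthetic contact-map generator
#'
#' The generative model writes an expected contact probability for every bin
#' pair and samples contacts multinomially from it. Cis pairs follow a broken
#' power law in midpoint separation `s` (`s^-alpha1` up to the crossover `s0`,
#' continuing as `s^-alpha2` beyond it), multiplied by a compartment affinity
#' (`c_AA`, `c_BB`, `c_AB`; label "ambiguous" is neutral, multiplier 1), an
#' attenuation `prod(1 - beta)` over planted insulating boundaries strictly
#' between the two bins (applied only below 3 Mb separation, the TAD scale),
#' and end-region clustering multipliers `w_tel` / `w_cen` when both bins
#' carry the corresponding flag. Trans pairs use the analogous `t_*`
#' affinities and the same both-flagged clustering rule. Mitochondrial-nuclear
#' pairs get `lambda_mito` times the mean trans pair probability. Cis mass is
#' rescaled to exactly `f_cis` of the whole matrix.
#'
#' @param alpha1,alpha2 Power-law decay exponents below/above `s0` (> 0).
#' @param s0 Crossover distance in bp (default 2 Mb).
#' @param f_cis Target genome-wide cis contact share, in (0, 1).
#' @param c_AA,c_BB,c_AB Cis compartment affinity multipliers (> 0).
#' @param t_AA,t_BB,t_AB Trans analogues (> 0).
#' @param boundaries Tibble of planted boundaries: `chrom`, `pos` (bp),
#'   `beta` in (0, 1\]. May be empty.
#' @param w_tel,w_cen Telomere-end / centromere-flank clustering multipliers
#'   (>= 1).
#' @param lambda_mito Mitochondrial-nuclear leak multiplier (>= 0).
#' @param n_contacts Total contacts to sample (>= 1).
#' @param seed Integer RNG seed (or `NA` to leave the RNG state alone).
#' @param boundary_beta Default strength used when boundaries are planted for
#'   this parameter set via [default_boundaries()].
#' @return A `sim_params` list.
#' @export
sim_params <- function(alpha1 = 1, alpha2 = 1, s0 = 2e6, f_cis = 0.7,
                       c_AA = 1, c_BB = 1, c_AB = 1,
                       t_AA = 1, t_BB = 1, t_AB = 1,
                       boundaries = NULL, w_tel = 1, w_cen = 1,
                       lambda_mito = 1, n_contacts = 5e6, seed = NA_integer_,
                       boundary_beta = 0.5) {
  if (is.null(boundaries)) {
    boundaries <- tibble::tibble(chrom = character(), pos = numeric(),
                                 beta = numeric())
  }
  p <- list(alpha1 = alpha1, alpha2 = alpha2, s0 = s0, f_cis = f_cis,
            c_AA = c_AA, c_BB = c_BB, c_AB = c_AB,
            t_AA = t_AA, t_BB = t_BB, t_AB = t_AB,
            boundaries = tibble::as_tibble(boundaries),
            w_tel = w_tel, w_cen = w_cen, lambda_mito = lambda_mito,
            n_contacts = n_contacts, seed = seed,
            boundary_beta = boundary_beta)
  mult <- c(p$c_AA, p$c_BB, p$c_AB, p$t_AA, p$t_BB, p$t_AB)
  stopifnot(all(mult > 0), p$alpha1 > 0, p$alpha2 > 0,
            p$f_cis > 0, p$f_cis < 1, p$w_tel >= 1, p$w_cen >= 1,
            p$lambda_mito >= 0, p$n_contacts >= 1)
  if (nrow(p$boundaries) > 0) {
    stopifnot(all(p$boundaries$beta > 0), all(p$boundaries$beta <= 1))
  }
  structure(p, class = "sim_params")
}

#' Simulator presets for the fibroblast-to-motor-neuron trajectory
#'
#' Fixed parameter sets emulating the cell states of the maturation time
#' course: primary fibroblasts (`PF`), iPSCs (`IPSC`), immature and maturing
#' motor neurons (`MN_W0`, `MN_W3`, `MN_W6`) and a C9orf72-ALS mature motor
#' neuron (`ALS_MN_W6`). The trajectory encodes the observed arc: cis share
#' rises 0.70, 0.70, 0.72, 0.78, 0.85; homotypic affinities dip at iPSC and
#' peak at PF / MN_W6 (B-B slightly below A-A at W6); long-range cis is
#' depleted via `alpha2 > alpha1` as maturation progresses; telomere and
#' centromere clustering is absent in PF/iPSC and rises monotonically from
#' MN_W0 to MN_W6. The ALS preset sits between MN_W3 and MN_W6 (closer to W3:
#' reduced maturation) and carries an elevated mitochondrial-nuclear leak.
#'
#' @param name One of `"PF"`, `"IPSC"`, `"MN_W0"`, `"MN_W3"`, `"MN_W6"`,
#'   `"ALS_MN_W6"`.
#' @return A `sim_params` object.
#' @export
#' @examples
#' preset("MN_W6")$f_cis
preset <- function(name) {
  tab <- list(
    PF        = list(f_cis = 0.70, alpha2 = 1.1,  c_AA = 2.2,  c_BB = 2.2,
                     t_AA = 1.60, t_BB = 1.60, w_tel = 1.0, w_cen = 1.0,
                     lambda_mito = 1, boundary_beta = 0.35),
    IPSC      = list(f_cis = 0.70, alpha2 = 1.3,  c_AA = 1.6,  c_BB = 1.6,
                     t_AA = 1.30, t_BB = 1.30, w_tel = 1.0, w_cen = 1.0,
                     lambda_mito = 1, boundary_beta = 0.35),
    MN_W0     = list(f_cis = 0.72, alpha2 = 1.3,  c_AA = 1.8,  c_BB = 1.8,
                     t_AA = 1.40, t_BB = 1.40, w_tel = 1.2, w_cen = 1.2,
                     lambda_mito = 1, boundary_beta = 0.30),
    MN_W3     = list(f_cis = 0.78, alpha2 = 1.5,  c_AA = 2.0,  c_BB = 2.0,
                     t_AA = 1.50, t_BB = 1.50, w_tel = 1.8, w_cen = 1.8,
                     lambda_mito = 1, boundary_beta = 0.45),
    MN_W6     = list(f_cis = 0.85, alpha2 = 1.7,  c_AA = 2.3,  c_BB = 2.1,
                     t_AA = 1.65, t_BB = 1.55, w_tel = 2.6, w_cen = 2.6,
                     lambda_mito = 1, boundary_beta = 0.60),
    ALS_MN_W6 = list(f_cis = 0.80, alpha2 = 1.55, c_AA = 2.05, c_BB = 2.02,
                     t_AA = 1.52, t_BB = 1.51, w_tel = 2.0, w_cen = 2.0,
                     lambda_mito = 4, boundary_beta = 0.50)
  )
  if (!name %in% names(tab)) {
    stop("unknown preset '", name, "'; valid presets: ",
         paste(names(tab), collapse = ", "), call. = FALSE)
  }
  p <- tab[[name]]
  # log-bilinear affinity: heterotypic contacts are depleted by the geometric
  # mean of the homotypic enrichments (saddle corners below 1, as observed),
  # and compartment-free bins sit exactly at the neutral level 1
  p$c_AB <- 1 / sqrt(p$c_AA * p$c_BB)
  p$t_AB <- 1 / sqrt(p$t_AA * p$t_BB)
  do.call(sim_params, c(p, list(alpha1 = 1, s0 = 2e6)))
}

#' Compartment-switch category probabilities
#'
#' Probabilities of the eight three-state A/B switch categories (first letter
#' = fibroblast state, second = iPSC, third = motor neuron) plus an ambiguous
#' class, together with the per-bin planted eigenvector magnitude model.
#' Defaults: always-A (`AAA`) 0.165, always-B (`BBB`) 0.199, 0.07 for each of
#' the six mixed orders, remainder (0.216) ambiguous.
#'
#' @param p Named numeric vector of category probabilities over
#'   `AAA, AAB, ABA, ABB, BAA, BAB, BBA, BBB, ambiguous`; must sum to 1.
#' @param ev_magnitude_mean,ev_noise_sd Mean and spread of the planted per-bin
#'   eigenvector magnitude for compartment-assigned bins; ambiguous bins get
#'   near-zero magnitude.
#' @return A `switch_probs` list.
#' @export
switch_probs <- function(p = NULL, ev_magnitude_mean = 1, ev_noise_sd = 0.2) {
  if (is.null(p)) {
    p <- c(AAA = 0.165, AAB = 0.07, ABA = 0.07, ABB = 0.07,
           BAA = 0.07, BAB = 0.07, BBA = 0.07, BBB = 0.199)
    p <- c(p, ambiguous = 1 - sum(p))
  }
  cats <- c("AAA", "AAB", "ABA", "ABB", "BAA", "BAB", "BBA", "BBB", "ambiguous")
  stopifnot(setequal(names(p), cats), all(p >= 0))
  p <- p[cats]
  if (abs(sum(p) - 1) > 1e-9) stop("probabilities must sum to 1", call. = FALSE)
  structure(list(p = p, ev_magnitude_mean = ev_magnitude_mean,
                 ev_noise_sd = ev_noise_sd),
            class = "switch_probs")
}

#' Sample three-state compartment label tracks with domain structure
#'
#' Draws a switch category per *domain* (run lengths geometric with mean
#' `mean_domain_length`), giving maps megabase-scale block structure, then
#' expands to bins. Each bin gets one label per cell state (A/B, or ambiguous
#' in all three states for the ambiguous category) and a planted eigenvector
#' value per state: signed `Normal(ev_magnitude_mean, ev_noise_sd)` magnitude
#' for A (+) and B (-), near-zero for ambiguous. The mitochondrial contig is
#' always ambiguous.
#'
#' @param bins A bin table.
#' @param probs A [switch_probs()] object.
#' @param mean_domain_length Mean domain length in bp (default 1 Mb).
#' @param seed Integer RNG seed (optional).
#' @return A tibble: `bin_id`, `chrom`, `category`, labels `pf`, `ipsc`, `mn`,
#'   planted values `ev_pf`, `ev_ipsc`, `ev_mn`.
#' @export
sample_switch_tracks <- function(bins, probs = switch_probs(),
                                 mean_domain_length = 1e6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bs <- bin_size_of(bins)
  p_dom <- min(1, bs / mean_domain_length)
  cats <- names(probs$p)

  category <- character(nrow(bins))
  for (c in unique(bins$chrom)) {
    idx <- which(bins$chrom == c)
    if (bins$is_mito[idx[1]]) {
      category[idx] <- "ambiguous"
      next
    }
    n_c <- length(idx)
    # draw per-bin categories independently, then rearrange that exact
    # multiset into contiguous geometric-length runs: maps get domain
    # structure while category masses keep per-bin multinomial precision
    drawn <- sample(cats, n_c, replace = TRUE, prob = probs$p)
    remaining <- table(factor(drawn, levels = cats))
    filled <- 0L
    while (filled < n_c) {
      cat_k <- sample(cats, 1, prob = remaining / sum(remaining))
      len <- 1L + stats::rgeom(1, p_dom)
      len <- min(len, remaining[[cat_k]], n_c - filled)
      category[idx[filled + seq_len(len)]] <- cat_k
      remaining[[cat_k]] <- remaining[[cat_k]] - len
      filled <- filled + len
    }
  }

  states <- c("pf", "ipsc", "mn")
  out <- tibble::tibble(bin_id = bins$bin_id, chrom = bins$chrom,
                        category = category)
  for (k in seq_along(states)) {
    letter <- ifelse(category == "ambiguous", "ambiguous",
                     substr(category, k, k))
    mag <- abs(stats::rnorm(nrow(bins), probs$ev_magnitude_mean,
                            probs$ev_noise_sd))
    ev <- dplyr::case_when(
      letter == "A" ~ mag,
      letter == "B" ~ -mag,
      TRUE ~ stats::rnorm(nrow(bins), 0, 0.02)
    )
    out[[states[k]]] <- letter
    out[[paste0("ev_", states[k])]] <- ev
  }
  out
}

#' Plant equally spaced insulating boundaries
#'
#' @param bins A bin table.
#' @param beta Boundary strength in (0, 1\].
#' @param spacing Distance between planted boundaries in bp (default 3 Mb);
#'   boundaries are kept at least `spacing` away from chromosome ends.
#' @return A boundary tibble (`chrom`, `pos`, `beta`) for [sim_params()].
#' @export
default_boundaries <- function(bins, beta = 0.5, spacing = 3e6) {
  g <- genome_of(bins)
  g <- g[!g$is_mito, ]
  purrr::pmap_dfr(g[, c("chrom", "length")], function(chrom, length) {
    pos <- seq(spacing, length - spacing, by = spacing)
    tibble::tibble(chrom = chrom, pos = pos, beta = beta)
  })
}

decay_weight <- function(d, bin_size, alpha1, alpha2, s0) {
  s <- pmax(d, bin_size)
  ifelse(s <= s0, s^(-alpha1), s0^(alpha2 - alpha1) * s^(-alpha2))
}

affinity_lookup <- function(hom_A, hom_B, het) {
  m <- matrix(1, 3, 3, dimnames = list(c("A", "B", "ambiguous"),
                                       c("A", "B", "ambiguous")))
  m["A", "A"] <- hom_A
  m["B", "B"] <- hom_B
  m["A", "B"] <- m["B", "A"] <- het
  m
}

#' Expected contact probability matrix of the generative model
#'
#' Builds the dense expected probability matrix described in [sim_params()].
#' Cis and trans masses are rescaled so the non-mitochondrial cis share is
#' exactly `f_cis`, mitochondrial pairs receive `lambda_mito` times the mean
#' trans pair probability, and the whole matrix sums to 1.
#'
#' @param bins A bin table.
#' @param labels Per-bin compartment labels in `{"A", "B", "ambiguous"}`
#'   (a character vector, or a track tibble column).
#' @param params A [sim_params()] object.
#' @return A `contact_map` with `expected = TRUE` (unit weights).
#' @export
expected_contact_map <- function(bins, labels, params) {
  n <- nrow(bins)
  labels <- as.character(labels)
  stopifnot(length(labels) == n)
  labels[!labels %in% c("A", "B")] <- "ambiguous"
  bs <- bin_size_of(bins)
  g <- genome_of(bins)
  max_len <- max(g$length[!g$is_mito])
  if (params$s0 <= bs || params$s0 >= max_len) {
    stop("s0 must lie strictly between the bin size and the longest chromosome",
         call. = FALSE)
  }

  nuc <- which(!bins$is_mito)
  mito <- which(bins$is_mito)
  lab_n <- labels[nuc]

  # trans backbone over non-mito bins
  t_look <- affinity_lookup(params$t_AA, params$t_BB, params$t_AB)
  W <- t_look[lab_n, lab_n]
  tel <- which(bins$in_telomere_end[nuc])
  cen <- which(bins$in_centromere_flank[nuc])
  if (params$w_tel != 1 && length(tel) > 0) {
    W[tel, tel] <- W[tel, tel] * params$w_tel
  }
  if (params$w_cen != 1 && length(cen) > 0) {
    W[cen, cen] <- W[cen, cen] * params$w_cen
  }

  # cis blocks overwrite the backbone
  c_look <- affinity_lookup(params$c_AA, params$c_BB, params$c_AB)
  chroms <- unique(bins$chrom[nuc])
  cis_mass <- 0
  for (c in chroms) {
    loc <- which(bins$chrom[nuc] == c)
    mid <- bins$mid[nuc][loc]
    D <- abs(outer(mid, mid, "-"))
    Wc <- decay_weight(D, bs, params$alpha1, params$alpha2, params$s0) *
      c_look[lab_n[loc], lab_n[loc]]
    bd <- params$boundaries[params$boundaries$chrom == c, ]
    if (nrow(bd) > 0) {
      for (k in seq_len(nrow(bd))) {
        left <- mid < bd$pos[k]
        cross <- outer(left, left, "!=") & D < 3e6
        Wc[cross] <- Wc[cross] * (1 - bd$beta[k])
      }
    }
    tl <- bins$in_telomere_end[nuc][loc]
    cn <- bins$in_centromere_flank[nuc][loc]
    if (params$w_tel != 1 && any(tl)) {
      Wc[tl, tl] <- Wc[tl, tl] * params$w_tel
    }
    if (params$w_cen != 1 && any(cn)) {
      Wc[cn, cn] <- Wc[cn, cn] * params$w_cen
    }
    W[loc, loc] <- Wc
    cis_mass <- cis_mass + upper_tri_sum(Wc)
  }
  trans_mass <- upper_tri_sum(W) - cis_mass

  # rescale: cis mass = f_cis exactly; mito pairs carved out of the trans share
  n_nuc <- length(nuc)
  n_mito <- length(mito)
  chrom_sizes <- table(bins$chrom[nuc])
  n_tp <- (n_nuc^2 - sum(chrom_sizes^2)) / 2
  n_mp <- n_mito * n_nuc + n_mito * (n_mito + 1) / 2

  if (n_tp == 0) {
    # degenerate single-chromosome genome: no trans block to share mass with
    W <- W * (1 / cis_mass)
    t_target <- 0
  } else {
    lam_share <- if (n_mito > 0) params$lambda_mito * n_mp / n_tp else 0
    t_target <- (1 - params$f_cis) / (1 + lam_share)
    sc_t <- t_target / trans_mass
    W <- W * sc_t
    sc_c <- params$f_cis / cis_mass
    for (c in chroms) {
      loc <- which(bins$chrom[nuc] == c)
      W[loc, loc] <- W[loc, loc] * (sc_c / sc_t)
    }
  }

  full <- matrix(0, n, n)
  full[nuc, nuc] <- W
  if (n_mito > 0 && n_tp > 0) {
    mt <- params$lambda_mito * t_target / n_tp
    full[mito, ] <- mt
    full[, mito] <- mt
  }
  total <- upper_tri_sum(full)
  # symmetric storage sums pairs once; scale so unordered-pair mass is 1
  full <- full / total
  contact_map(bins, full, expected = TRUE)
}

#' Sample a contact map from an expected matrix
#'
#' A single multinomial draw of `n_contacts` over unordered bin pairs
#' (diagonal included); counts are stored symmetrically and
#' `total_contacts` equals `n_contacts` exactly.
#'
#' @param expected A `contact_map` with `expected = TRUE`.
#' @param n_contacts Number of contacts to draw (>= 1).
#' @param seed Integer RNG seed (optional).
#' @return A raw `contact_map` of sampled counts.
#' @export
sample_contact_map <- function(expected, n_contacts, seed = NULL) {
  stopifnot(inherits(expected, "contact_map"), expected$expected)
  if (n_contacts < 1) stop("n_contacts must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  W <- expected$counts
  ut <- upper.tri(W, diag = TRUE)
  p <- W[ut]
  v <- stats::rmultinom(1, size = n_contacts, prob = p)[, 1]
  C <- matrix(0, nrow(W), ncol(W))
  C[ut] <- v
  Ct <- t(C)
  diag(Ct) <- 0
  contact_map(expected$bins, C + Ct)
}

#' Simulate a contact map in one call
#'
#' Convenience wrapper: [expected_contact_map()] followed by
#' [sample_contact_map()] with the parameter set's `n_contacts`.
#'
#' @param bins A bin table.
#' @param labels Per-bin compartment labels (see [expected_contact_map()]).
#' @param params A [sim_params()] object.
#' @param n_contacts Override of `params$n_contacts` (optional).
#' @param seed Integer RNG seed (optional; falls back to `params$seed`).
#' @return A raw `contact_map`.
#' @export
simulate_map <- function(bins, labels, params, n_contacts = NULL, seed = NULL) {
  if (is.null(n_contacts)) n_contacts <- params$n_contacts
  if (is.null(seed) && !is.na(params$seed)) seed <- params$seed
  exp_map <- expected_contact_map(bins, labels, params)
  sample_contact_map(exp_map, n_contacts, seed = seed)
}
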