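test_that("EV1 matches an independent dense eigendecomposition oracle", {
  # single chromosome, 200 bins, alternating 2 Mb compartment blocks
  g <- genome("c1", 50e6, 25e6)
  bins <- build_bin_table(g, 2.5e5, 1e6)
  expect_equal(nrow(bins), 200)
  labs <- alternating_labels(bins)
  p <- sim_params(c_AA = 2, c_BB = 2, c_AB = 1, f_cis = 0.95,
                  lambda_mito = 0)
  em <- expected_contact_map(bins, labs, p)
  ref <- ifelse(labs == "A", 1, -1)
  ev <- compute_ev1(em, ref, neutralize_ends = FALSE, clip_percentile = 1)

  # oracle: brute-force O/E by per-diagonal means, centered, eigen, screened
  M <- em$counts
  nc <- nrow(M)
  oe <- matrix(0, nc, nc)
  for (d in 0:(nc - 1)) {
    vals <- c()
    for (i in 1:(nc - d)) vals <- c(vals, M[i, i + d])
    mu <- mean(vals)
    for (i in 1:(nc - d)) {
      oe[i, i + d] <- M[i, i + d] / mu
      oe[i + d, i] <- oe[i, i + d]
    }
  }
  eg <- eigen(oe - 1, symmetric = TRUE)
  cors <- sapply(1:3, function(k) cor(eg$vectors[, k], ref))
  pick <- which.max(abs(cors))
  v <- eg$vectors[, pick] * sign(cors[pick])
  v <- v / sqrt(sum(v^2)) * sqrt(max(eg$values[pick], 0))

  expect_gt(abs(cor(ev$ev1, v)), 0.99)
  expect_equal(ev$ev1, v, tolerance = 1e-6)
  # and the planted pattern itself is recovered
  expect_gt(abs(cor(ev$ev1, ref)), 0.9)
})

test_that("EV1 flips sign exactly with the reference and warns without structure", {
  bins <- tiny_bins(bin_size = 5e5)
  labs <- alternating_labels(bins)
  em <- expected_contact_map(bins, labs, preset("PF"))
  ref <- ifelse(labs == "A", 1, ifelse(labs == "B", -1, 0))
  ev_pos <- compute_ev1(em, ref)
  ev_neg <- compute_ev1(em, -ref)
  expect_equal(ev_pos$ev1, -ev_neg$ev1)

  # no compartments: fall back to the leading eigenvector, warn
  flat <- expected_contact_map(bins, labs,
                               sim_params(f_cis = 0.7, lambda_mito = 0))
  expect_warning(ev0 <- compute_ev1(flat, ref), "no clear compartment")
  sel <- attr(ev0, "selection")
  expect_true(all(sel$ref_cor < 0.5))
})

test_that("saddle strength equals the closed-form affinity ratio on expected maps", {
  bins <- build_bin_table(saddle_genome(), 5e5, 1e6)
  labs <- random_block_labels(bins, block_bp = 5e5, seed = 14)
  track <- planted_track(bins, labs)
  em <- expected_contact_map(bins, labs,
                             sim_params(c_AA = 2, c_BB = 2, c_AB = 1,
                                        t_AA = 2, t_BB = 2, t_AB = 1,
                                        f_cis = 0.7, lambda_mito = 0))
  sad <- saddle_strength(em, track, "cis", n_quantiles = 10)
  expect_equal(sad$strength_AA, 2, tolerance = 0.05)
  expect_equal(sad$strength_BB, 2, tolerance = 0.05)
  sad_t <- saddle_strength(em, track, "trans", n_quantiles = 10)
  expect_equal(sad_t$strength_AA, 2, tolerance = 0.05)

  # null affinities: strengths are 1
  em0 <- expected_contact_map(bins, labs,
                              sim_params(f_cis = 0.7, lambda_mito = 0))
  sad0 <- saddle_strength(em0, track, "cis", n_quantiles = 10)
  expect_equal(sad0$strength_AA, 1, tolerance = 0.02)
  expect_equal(sad0$strength_BB, 1, tolerance = 0.02)

  # independent brute-force check of the cis ratio on one chromosome
  idx <- which(bins$chrom == "s1")
  oracle <- oracle_affinity_ratio(em$counts[idx, idx], labs[idx])
  expect_equal(oracle$AA, 2, tolerance = 0.05)
})

test_that("saddle strength is monotone in the planted affinity ratio", {
  bins <- build_bin_table(saddle_genome(), 5e5, 1e6)
  labs <- random_block_labels(bins, block_bp = 5e5, seed = 14)
  track <- planted_track(bins, labs)
  strengths <- vapply(c(1, 1.5, 2, 3), function(cc) {
    em <- expected_contact_map(bins, labs,
                               sim_params(c_AA = cc, c_BB = cc, c_AB = 1,
                                          f_cis = 0.7, lambda_mito = 0))
    saddle_strength(em, track, "cis", n_quantiles = 10)$strength_AA
  }, numeric(1))
  expect_true(all(diff(strengths) > 0))
})

test_that("elevated trans homotypic affinity moves only the matching corner", {
  bins <- build_bin_table(saddle_genome(), 5e5, 1e6)
  labs <- random_block_labels(bins, block_bp = 5e5, seed = 14)
  track <- planted_track(bins, labs)
  em <- expected_contact_map(bins, labs,
                             sim_params(t_AA = 2, t_BB = 1, t_AB = 1,
                                        f_cis = 0.7, lambda_mito = 0))
  sad <- saddle_strength(em, track, "trans", n_quantiles = 10)
  expect_gt(sad$strength_AA, 1.5)
  expect_equal(sad$strength_BB, 1, tolerance = 0.1)
})

test_that("switch classification follows calls and thresholds", {
  bins <- build_bin_table(genome("c1", 10e6, 4e6), 1e6, 1e6)
  mk <- function(ev) {
    t <- planted_track(bins, rep("A", nrow(bins)))
    t$ev1 <- ev
    t$call <- ifelse(is.na(ev), NA_character_,
                     ifelse(ev > 0.05, "A", ifelse(ev < -0.05, "B",
                                                   "ambiguous")))
    t
  }
  ev1 <- rep(1, 10); ev2 <- rep(1, 10); ev3 <- rep(1, 10)
  ev2[4] <- -1            # ABA at bin 4
  ev3[7] <- 0.03          # ambiguous in one state -> ambiguous
  sw <- classify_switches(list(mk(ev1), mk(ev2), mk(ev3)))
  expect_equal(sw$bins$category[1], "AAA")
  expect_equal(sw$bins$category[4], "ABA")
  expect_equal(sw$bins$category[7], "ambiguous")
  s <- sw$summary
  expect_equal(s$frac_genome[s$category == "AAA"], 8 / 10)
  expect_equal(s$frac_classified[s$category == "AAA"], 8 / 9)

  other <- build_bin_table(genome("c2", 10e6, 4e6), 1e6, 1e6)
  expect_error(
    classify_switches(list(mk(ev1), mk(ev2),
                           planted_track(other, rep("A", 10)))),
    "identical bin tables")
})

test_that("intersection fraction is exact on small cases and random tables", {
  bins <- build_bin_table(genome("c1", 10e6, 4e6), 1e6, 1e6)
  mk_cat <- function(cats) {
    structure(list(bins = tibble::tibble(bin_id = seq_along(cats),
                                         chrom = "c1", category = cats),
                   bin_table = bins),
              class = "hic_switches")
  }
  a <- mk_cat(rep("AAA", 10))
  expect_equal(intersection_fraction(list(a, a)), 1)
  b <- mk_cat(c(rep("AAA", 9), "BBB"))
  expect_equal(intersection_fraction(list(a, b)), 0.9)
  expect_error(intersection_fraction(list(a)), "at least two")

  # analytic: two independent uniform tables over 8 categories agree 1/8
  cats8 <- c("AAA", "AAB", "ABA", "ABB", "BAA", "BAB", "BBA", "BBB")
  set.seed(2)
  n <- 8000
  r1 <- mk_cat(sample(cats8, n, replace = TRUE))
  r2 <- mk_cat(sample(cats8, n, replace = TRUE))
  expect_equal(intersection_fraction(list(r1, r2)), 1 / 8,
               tolerance = 3 * sqrt(7 / 8 / n) / (1 / 8))
})

test_that("expression summaries group genes by bin category", {
  bins <- build_bin_table(genome("c1", 10e6, 4e6), 1e6, 1e6)
  cats <- c(rep("AAA", 5), rep("BBB", 5))
  sw <- structure(list(bins = tibble::tibble(bin_id = 1:10, chrom = "c1",
                                             category = cats),
                       bin_table = bins),
                  class = "hic_switches")
  set.seed(4)
  expr <- tibble::tibble(
    gene_id = paste0("g", 1:40),
    chrom = "c1",
    start = rep(seq(0.2e6, 9.2e6, 1e6), each = 4),
    end = rep(seq(0.4e6, 9.4e6, 1e6), each = 4)
  )
  in_a <- expr$start < 5e6
  expr$s1 <- ifelse(in_a, rnorm(40, 100, 5), rnorm(40, 2, 0.5))
  expr$s2 <- ifelse(in_a, rnorm(40, 80, 5), rnorm(40, 1, 0.3))
  out <- summarize_by_group(sw, expr)
  med <- tidyr::pivot_wider(out[, c("category", "sample", "median_tpm")],
                            names_from = "category",
                            values_from = "median_tpm")
  expect_true(all(med$AAA > med$BBB))
  expect_equal(attr(out, "n_skipped"), 0L)

  # genes off the binned genome are skipped and counted
  expr2 <- expr
  expr2$chrom[1] <- "chrZ"
  out2 <- summarize_by_group(sw, expr2)
  expect_equal(attr(out2, "n_skipped"), 1L)

  empty <- summarize_by_group(sw, expr[0, ])
  expect_equal(nrow(empty), 0)
})
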