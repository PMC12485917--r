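test_that("all enrichment statistics are 1 on null generator maps", {
  bins <- tiny_bins(bin_size = 5e5)
  em <- expected_contact_map(bins, rep("A", nrow(bins)),
                             sim_params(f_cis = 0.7, lambda_mito = 0))
  tc <- telcen_aggregate(em)
  expect_true(all(abs(tc$enrichment - 1) < 0.01))
  st <- scaled_trans_map(em, n_scaled = 20)
  expect_true(all(abs(st$diagonal_profile - 1) < 0.05))
})

test_that("telomere clustering recovers the planted multiplier, centromeres unaffected", {
  # end bins must be a small share of all bins, or the per-pair block-mean
  # normalizer absorbs part of the planted signal
  bins <- build_bin_table(sim_genome_small(), 250e3, 1e6)
  em <- expected_contact_map(bins, rep("A", nrow(bins)),
                             sim_params(f_cis = 0.7, w_tel = 3, w_cen = 1,
                                        lambda_mito = 0))
  tc <- telcen_aggregate(em)
  get <- function(s) tc$enrichment[tc$statistic == s]
  expect_equal(get("tel_tel"), 3, tolerance = 0.05)
  expect_equal(get("cen_cen"), 1, tolerance = 0.05)
  expect_equal(get("tel_cen"), 1, tolerance = 0.05)

  # strict monotonicity in w_tel, cross-talk below 5%
  b2 <- tiny_bins(bin_size = 5e5)
  tels <- vapply(c(1, 1.5, 2, 3), function(w) {
    e <- expected_contact_map(b2, rep("A", nrow(b2)),
                              sim_params(f_cis = 0.7, w_tel = w,
                                         lambda_mito = 0))
    t <- telcen_aggregate(e)
    t$enrichment[t$statistic == "tel_tel"]
  }, numeric(1))
  expect_true(all(diff(tels) > 0))
})

test_that("scaled trans maps localize telomere and centromere peaks", {
  bins <- tiny_bins(bin_size = 5e5)
  labs <- rep("A", nrow(bins))
  st_tel <- scaled_trans_map(
    expected_contact_map(bins, labs, sim_params(w_tel = 3, lambda_mito = 0)),
    n_scaled = 20)
  prof <- st_tel$diagonal_profile
  expect_gt(prof[1], 1.5)
  expect_gt(prof[20], 1.5)
  expect_lt(max(prof[8:13]), 1.2)

  st_cen <- scaled_trans_map(
    expected_contact_map(bins, labs, sim_params(w_cen = 3, lambda_mito = 0)),
    n_scaled = 20)
  # centromeres sit at ~40% of the scaled axis on this genome
  pc <- st_cen$diagonal_profile
  expect_gt(max(pc[6:11]), 1.5)
  expect_lt(max(pc[c(1, 20)]), 1.2)

  expect_error(scaled_trans_map(uniform_map(bins), subset = "chrA"),
               ">= 2 chromosomes")
})

test_that("telomere pair matrices normalize, flag short arms, handle one chromosome", {
  bins <- tiny_bins(bin_size = 5e5)
  tp <- telomere_pair_matrix(uniform_map(bins))
  expect_true(all(abs(tp$value[!tp$cis & tp$defined] - 1) < 1e-9))
  expect_true(all(tp$cis == (tp$chrom1 == tp$chrom2)))

  # arm shorter than end_size: undefined, never zero
  g2 <- genome(c("cA", "cB"), c(10e6, 10e6), c(0.5e6, 5e6))
  b2 <- build_bin_table(g2, 5e5, 1e6)
  tp2 <- telomere_pair_matrix(uniform_map(b2))
  pa <- tp2[tp2$chrom1 == "cA" & tp2$arm1 == "p", ]
  expect_true(all(!pa$defined))
  expect_true(all(is.na(pa$value)))

  # single chromosome: only the cis p-q entry is defined
  g1 <- genome("cA", 10e6, 5e6)
  b1 <- build_bin_table(g1, 5e5, 1e6)
  tp1 <- telomere_pair_matrix(uniform_map(b1))
  expect_equal(nrow(tp1), 1)
  expect_true(tp1$cis && tp1$defined)

  # rising preset w_tel lifts the matrix mean monotonically
  labs <- rep("A", nrow(bins))
  means <- vapply(c("MN_W0", "MN_W3", "MN_W6"), function(n) {
    e <- expected_contact_map(bins, labs, preset(n))
    t <- telomere_pair_matrix(e)
    mean(t$value[t$defined & !t$cis])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("virtual 4C profiles normalize and find distal telomere peaks", {
  bins <- tiny_bins(bin_size = 5e5)
  m <- uniform_map(bins)
  prof <- virtual_4c(m, list(chrom = "chrA", start = 0, end = 12e6))
  on_a <- prof$chrom == "chrA" & !is.na(prof$value)
  expect_equal(sum(prof$value[on_a]), 1)
  expect_lt(diff(range(prof$value[on_a])), 1e-9)

  em <- expected_contact_map(bins, rep("A", nrow(bins)),
                             sim_params(f_cis = 0.7, w_tel = 4,
                                        lambda_mito = 0))
  p4 <- virtual_4c(em, list(chrom = "chrA", start = 0, end = 1e6))
  a_idx <- which(p4$chrom == "chrA")
  distal <- a_idx[bins$mid[a_idx] > 6e6]
  peak <- distal[which.max(p4$value[distal])]
  expect_true(bins$in_telomere_end[peak])
  expect_gt(bins$start[peak], 10e6)

  masked <- m
  masked$mask[bins$chrom == "chrA" & bins$start < 1e6] <- FALSE
  expect_error(virtual_4c(masked, list(chrom = "chrA", start = 0, end = 1e6)),
               "no unmasked bin")
})

test_that("mito-nuclear score scales with the planted leak", {
  bins <- tiny_bins(bin_size = 5e5)
  labs <- rep("A", nrow(bins))
  em0 <- expected_contact_map(bins, labs, sim_params(lambda_mito = 0))
  expect_equal(mito_nuclear_score(em0), 0, tolerance = 1e-12)
  s1 <- mito_nuclear_score(expected_contact_map(bins, labs,
                                                sim_params(lambda_mito = 1)))
  s2 <- mito_nuclear_score(expected_contact_map(bins, labs,
                                                sim_params(lambda_mito = 2)))
  # closed form: mito mass is lambda * t_share * r / (1 + lambda * r), with
  # r the mito/trans pair-count ratio, so doubling lambda scales the score
  # by 2 (1 + r) / (1 + 2 r)
  n_mito <- sum(bins$is_mito)
  n_nuc <- sum(!bins$is_mito)
  n_tp <- (n_nuc^2 - sum(table(bins$chrom[!bins$is_mito])^2)) / 2
  r <- (n_mito * n_nuc + n_mito * (n_mito + 1) / 2) / n_tp
  expect_equal(s2 / s1, 2 * (1 + r) / (1 + 2 * r), tolerance = 1e-6)
  # on a realistic genome the pair-share ratio is small: score ~ doubles
  bb <- build_bin_table(sim_genome_small(), 250e3, 1e6)
  lb <- rep("A", nrow(bb))
  sb1 <- mito_nuclear_score(expected_contact_map(bb, lb,
                                                 sim_params(lambda_mito = 1)))
  sb2 <- mito_nuclear_score(expected_contact_map(bb, lb,
                                                 sim_params(lambda_mito = 2)))
  expect_equal(sb2 / sb1, 2, tolerance = 0.02)
  expect_gt(
    mito_nuclear_score(
      sample_contact_map(
        expected_contact_map(bins, labs, preset("ALS_MN_W6")), 1e6, seed = 3)),
    mito_nuclear_score(
      sample_contact_map(
        expected_contact_map(bins, labs, preset("MN_W6")), 1e6, seed = 3)))

  b0 <- tiny_bins(with_mito = FALSE)
  expect_error(mito_nuclear_score(uniform_map(b0)), "no mitochondrial")
})
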