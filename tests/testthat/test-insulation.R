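test_that("insulation is zero on uniform maps and matches the brute-force oracle", {
  g <- genome("c1", 30e6, 15e6)
  bins <- build_bin_table(g, 5e5, 1e6)
  m <- uniform_map(bins)
  ins <- insulation_track(m, 2e6)
  defined <- !is.na(ins$insulation)
  expect_true(any(defined))
  expect_true(all(abs(ins$insulation[defined]) < 1e-12))

  # planted boundary: exact equality with the independent diamond oracle
  bd <- tibble::tibble(chrom = "c1", pos = 15e6, beta = 0.5)
  em <- expected_contact_map(bins, rep("A", nrow(bins)),
                             sim_params(f_cis = 0.9, boundaries = bd,
                                        lambda_mito = 0))
  ins2 <- insulation_track(em, 2e6)
  w <- 4
  oracle <- oracle_insulation(em$counts[1:60, 1:60], w)
  expect_equal(ins2$insulation, oracle, tolerance = 1e-12)
  # local minimum sits at the boundary
  min_bin <- which.min(ins2$insulation)
  expect_lte(abs(bins$mid[min_bin] - 15e6), 5e5)
  calls <- call_boundaries(ins2)
  expect_equal(nrow(calls), 1)
  expect_true(calls$is_strong)
})

test_that("insulation window validation and edge handling", {
  g <- genome("c1", 30e6, 15e6)
  bins <- build_bin_table(g, 5e5, 1e6)
  m <- uniform_map(bins)
  expect_error(insulation_track(m, 75e4), "multiple")
  expect_error(insulation_track(m, 5e5), "at least 2")
  expect_warning(ins <- insulation_track(m, 16e6), "exceeds chromosome")
  expect_true(all(is.na(ins$insulation)))
})

test_that("boundary insulation deepens with planted strength", {
  g <- genome("c1", 30e6, 15e6)
  bins <- build_bin_table(g, 5e5, 1e6)
  depths <- vapply(c(0.2, 0.4, 0.6), function(beta) {
    bd <- tibble::tibble(chrom = "c1", pos = 15e6, beta = beta)
    em <- expected_contact_map(bins, rep("A", nrow(bins)),
                               sim_params(f_cis = 0.9, boundaries = bd,
                                          lambda_mito = 0))
    min(insulation_track(em, 2e6)$insulation, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(depths) < 0))
})

test_that("adjacent boundaries inside one window merge into a broad minimum", {
  g <- genome("c1", 30e6, 15e6)
  bins <- build_bin_table(g, 5e5, 1e6)
  bd <- tibble::tibble(chrom = "c1", pos = c(14.5e6, 15.5e6), beta = 0.5)
  em <- expected_contact_map(bins, rep("A", nrow(bins)),
                             sim_params(f_cis = 0.9, boundaries = bd,
                                        lambda_mito = 0))
  ins <- insulation_track(em, 2e6)
  calls <- call_boundaries(ins)
  near <- calls[abs(bins$mid[calls$bin_id] - 15e6) < 2.5e6, ]
  expect_equal(nrow(near), 1)
})

test_that("boundary calling handles plateaus, monotone tracks and thresholds", {
  expect_equal(nrow(call_boundaries(synthetic_ins_track(seq(0, 1, 0.01)))), 0)

  # plateau minimum takes the leftmost bin
  v <- c(0.5, 0.3, 0, 0, 0, 0.3, 0.5)
  calls <- call_boundaries(synthetic_ins_track(v))
  expect_equal(calls$bin_id, 3)
  expect_equal(calls$strength, 0.5)

  # strength exactly at the threshold is not strong (strict >)
  v2 <- c(0.1, 0, 0.1, 0.15)
  c2 <- call_boundaries(synthetic_ins_track(v2), strong_threshold = 0.1)
  expect_equal(c2$strength, 0.1)
  expect_false(c2$is_strong)

  # prominence uses the lower flanking maximum
  v3 <- c(0.8, -0.2, 0.3, 0.1, 0.4)
  c3 <- call_boundaries(synthetic_ins_track(v3))
  expect_equal(c3$strength[1], 0.5)
})

test_that("all planted boundaries are recovered on the expected map", {
  bins <- tiny_bins(bin_size = 2.5e5)
  bd <- default_boundaries(bins, beta = 0.5, spacing = 3e6)
  expect_gte(nrow(bd), 5)
  em <- expected_contact_map(bins, rep("A", nrow(bins)),
                             sim_params(f_cis = 0.8, boundaries = bd))
  ins <- insulation_track(em, 1e6)
  calls <- call_boundaries(ins)
  hit <- vapply(seq_len(nrow(bd)), function(k) {
    idx <- which(bins$chrom == bd$chrom[k] &
                   abs(bins$mid - bd$pos[k]) <= 2.5e5)
    any(calls$bin_id %in% c(idx - 1, idx, idx + 1))
  }, logical(1))
  expect_true(all(hit))
  expect_true(all(calls$is_strong[calls$bin_id %in%
                                    unlist(lapply(seq_len(nrow(bd)), function(k)
                                      which(abs(bins$mid - bd$pos[k]) <= 2.5e5)))]))
})

test_that("boundary set comparison partitions exhaustively and symmetrically", {
  mk <- function(bin_ids, chrom = "c1") {
    tibble::tibble(chrom = chrom, bin_id = bin_ids,
                   start = (bin_ids - 1) * 25e3,
                   insulation = -0.5, strength = 0.3, is_strong = TRUE)
  }
  a <- mk(c(10, 50, 90))
  cmp <- compare_boundary_sets(a, a, 1)
  expect_equal(nrow(cmp$common), 3)
  expect_equal(nrow(cmp$a_specific), 0)

  b <- mk(c(200, 300))
  cmp2 <- compare_boundary_sets(a, b, 1)
  expect_equal(nrow(cmp2$common), 0)
  expect_equal(nrow(cmp2$a_specific), 3)
  expect_equal(nrow(cmp2$b_specific), 2)

  cmp3 <- compare_boundary_sets(mk(10), mk(11), 1)
  expect_equal(nrow(cmp3$common), 1)

  # property: sizes partition the union; swapping inputs swaps specifics
  set.seed(6)
  for (rep in 1:5) {
    x <- mk(sort(sample(1:300, 25)))
    y <- mk(sort(sample(1:300, 30)))
    cmp <- compare_boundary_sets(x, y, 2)
    expect_equal(nrow(cmp$a_specific) + nrow(cmp$common), nrow(x))
    expect_equal(nrow(cmp$b_specific) + nrow(cmp$common), nrow(y))
    rev <- compare_boundary_sets(y, x, 2)
    expect_equal(nrow(rev$common), nrow(cmp$common))
    expect_equal(rev$a_specific$bin_id, cmp$b_specific$bin_id)
    expect_equal(rev$b_specific$bin_id, cmp$a_specific$bin_id)
  }
})

test_that("aggregate insulation profiles dip at boundaries and stay flat on null maps", {
  bins <- tiny_bins(bin_size = 2.5e5)
  bd <- default_boundaries(bins, beta = 0.5, spacing = 4e6)
  em <- expected_contact_map(bins, rep("A", nrow(bins)),
                             sim_params(f_cis = 0.8, boundaries = bd))
  ins <- insulation_track(em, 1e6)
  calls <- call_boundaries(ins)
  agg <- aggregate_insulation(list(w = ins), calls[calls$is_strong, ],
                              flank = 1e6)
  prof <- agg$profile
  expect_equal(prof$offset[which.min(prof$mean_insulation)], 0)

  # flat on a boundary-free map at random positions
  em0 <- expected_contact_map(bins, rep("A", nrow(bins)),
                              sim_params(f_cis = 0.8))
  ins0 <- insulation_track(em0, 1e6)
  set.seed(8)
  fake <- tibble::tibble(
    chrom = "chrA",
    bin_id = sample(which(bins$chrom == "chrA" & !is.na(ins0$insulation) &
                            bins$start > 3e6 & bins$start < 9e6), 10),
    start = 0, insulation = 0, strength = 0, is_strong = TRUE)
  agg0 <- aggregate_insulation(list(w = ins0), fake, flank = 1e6)
  expect_lt(max(abs(agg0$profile$mean_insulation)), 0.05)

  expect_error(aggregate_insulation(list(w = ins), calls[0, ]), "empty")

  # stronger planted boundaries give deeper aggregate minima
  em_w0 <- expected_contact_map(
    bins, rep("A", nrow(bins)),
    sim_params(f_cis = 0.72,
               boundaries = default_boundaries(bins, beta = preset("MN_W0")$boundary_beta)))
  em_w6 <- expected_contact_map(
    bins, rep("A", nrow(bins)),
    sim_params(f_cis = 0.85,
               boundaries = default_boundaries(bins, beta = preset("MN_W6")$boundary_beta)))
  ins_w0 <- insulation_track(em_w0, 1e6)
  ins_w6 <- insulation_track(em_w6, 1e6)
  calls_w6 <- call_boundaries(ins_w6)
  agg2 <- aggregate_insulation(list(W0 = ins_w0, W6 = ins_w6),
                               calls_w6[calls_w6$is_strong, ], flank = 1e6)
  at0 <- agg2$profile[agg2$profile$offset == 0, ]
  expect_lt(at0$mean_insulation[at0$track == "W6"],
            at0$mean_insulation[at0$track == "W0"])
})
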