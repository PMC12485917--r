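#' Build and validate a pipeline run configuration
#'
#' A run configuration names the samples (simulator presets or contact files),
#' the binning and analysis parameters, and the seed. It can also be loaded
#' from YAML with [read_run_config()]. Validation happens here, before any
#' compute: sample names must be unique and referenced files must exist.
#'
#' @param samples A tibble (or data frame) with columns `name`, `source`
#'   (a preset name or an existing file path) and optionally `state`
#'   (`"pf"`, `"ipsc"` or `"mn"`; which planted label track a simulated
#'   sample uses, default `"mn"`).
#' @param genome `"small"`, `"scaled"`, or a genome tibble.
#' @param bin_size,end_size,window,flank Analysis resolutions in bp.
#' @param n_contacts Contacts per simulated sample.
#' @param strong_threshold,ev_threshold,n_quantiles,top_frac Estimator
#'   thresholds, surfaced here so none is hard-coded downstream.
#' @param seed Integer master seed; sample `i` draws with `seed + i`.
#' @return A validated `run_config` list.
#' @export
run_config <- function(samples, genome = "small", bin_size = 250e3,
                       end_size = 1e6, window = 2.5e6, flank = 2e5,
                       n_contacts = 2e6, strong_threshold = 0.1,
                       ev_threshold = 0.05, n_quantiles = 50, top_frac = 0.2,
                       seed = 1L) {
  samples <- tibble::as_tibble(samples)
  stopifnot(all(c("name", "source") %in% names(samples)))
  if (!"state" %in% names(samples)) samples$state <- "mn"
  if (anyDuplicated(samples$name)) {
    stop("sample names must be unique", call. = FALSE)
  }
  preset_names <- c("PF", "IPSC", "MN_W0", "MN_W3", "MN_W6", "ALS_MN_W6")
  is_preset <- samples$source %in% preset_names
  missing <- !is_preset & !file.exists(samples$source)
  if (any(missing)) {
    stop("missing contact file(s): ",
         paste(samples$source[missing], collapse = ", "), call. = FALSE)
  }
  stopifnot(all(samples$state %in% c("pf", "ipsc", "mn")))
  structure(list(samples = samples, genome = genome, bin_size = bin_size,
                 end_size = end_size, window = window, flank = flank,
                 n_contacts = n_contacts, strong_threshold = strong_threshold,
                 ev_threshold = ev_threshold, n_quantiles = n_quantiles,
                 top_frac = top_frac, seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param path Path to a YAML file with the fields of [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$samples <- dplyr::bind_rows(lapply(y$samples, tibble::as_tibble))
  do.call(run_config, y)
}

resolve_config_genome <- function(config) {
  if (is.data.frame(config$genome)) return(validate_genome(config$genome))
  switch(config$genome,
         small = sim_genome_small(),
         scaled = sim_genome_scaled(),
         stop("unknown genome spec: ", config$genome, call. = FALSE))
}

#' Run the full simulate/analyze pipeline over a sample set
#'
#' For each sample: obtain the contact map (simulator preset or contact
#' file), mask and balance it, and compute the per-sample battery (EV1 track,
#' cis and trans saddle strengths, P(s) with slope and derivative, cis
#' percentage, long-range fraction, insulation and boundary calls,
#' telomere/centromere aggregates, telomere pair matrix mean, mitochondrial
#' score). Across samples: a switch table when the sample set carries the
#' three states pf/ipsc/mn, and a boundary-set comparison of the first vs
#' last sample. Deterministic given the config seed.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory; when given, tracks are written
#'   as bedGraph, boundaries as BED, tables as TSV and the summary as JSON.
#' @return A report list: `samples` (per-sample results), `stats` (long
#'   tibble: sample, statistic, value), `switches`, `boundary_comparison`,
#'   `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  g <- resolve_config_genome(config)
  bins <- build_bin_table(g, config$bin_size, config$end_size)
  tracks <- sample_switch_tracks(bins, seed = config$seed)

  results <- list()
  for (i in seq_len(nrow(config$samples))) {
    s <- config$samples[i, ]
    seed_i <- config$seed + i
    if (s$source %in% c("PF", "IPSC", "MN_W0", "MN_W3", "MN_W6", "ALS_MN_W6")) {
      params <- preset(s$source)
      params$boundaries <- default_boundaries(bins, beta = params$boundary_beta)
      map <- simulate_map(bins, tracks[[s$state]], params,
                          n_contacts = config$n_contacts, seed = seed_i)
    } else {
      map <- read_contacts(s$source, bins, format = "triplet_tsv")
    }
    map <- mask_low_coverage(map)
    map <- ic_balance(map)
    reference <- tracks[[paste0("ev_", s$state)]]
    ev <- suppressWarnings(compute_ev1(map, reference,
                                       ev_threshold = config$ev_threshold))
    sad_cis <- saddle_strength(map, ev, "cis", config$n_quantiles,
                               config$top_frac)
    sad_trans <- saddle_strength(map, ev, "trans", config$n_quantiles,
                                 config$top_frac)
    ps <- ps_curve(map)
    ins <- suppressWarnings(insulation_track(map, config$window))
    bd <- call_boundaries(ins, config$strong_threshold)
    tc <- telcen_aggregate(map)
    tp <- telomere_pair_matrix(map)
    results[[s$name]] <- list(
      map = map, ev = ev, ps = ps, insulation = ins, boundaries = bd,
      saddle_cis = sad_cis, saddle_trans = sad_trans,
      telcen = tc, telpairs = tp,
      stats = tibble::tibble(
        sample = s$name,
        statistic = c("cis_percent", "long_range_fraction", "ps_slope",
                      "strength_AA_cis", "strength_BB_cis",
                      "strength_AA_trans", "strength_BB_trans",
                      "n_strong_boundaries", "tel_tel", "cen_cen", "tel_cen",
                      "telpair_mean", "mito_score"),
        value = c(cis_fraction(map), long_range_fraction(map),
                  tryCatch(ps_slope(ps), error = function(e) NA_real_),
                  sad_cis$strength_AA, sad_cis$strength_BB,
                  sad_trans$strength_AA, sad_trans$strength_BB,
                  sum(bd$is_strong),
                  tc$enrichment[match(c("tel_tel", "cen_cen", "tel_cen"),
                                      tc$statistic)],
                  mean(tp$value[tp$defined & !tp$cis], na.rm = TRUE),
                  if (any(bins$is_mito)) mito_nuclear_score(map) else NA_real_)
      )
    )
  }

  stats <- dplyr::bind_rows(lapply(results, `[[`, "stats"))

  switches <- NULL
  st <- config$samples$state
  if (all(c("pf", "ipsc", "mn") %in% st)) {
    pick <- vapply(c("pf", "ipsc", "mn"),
                   function(x) which(st == x)[1], integer(1))
    switches <- classify_switches(
      lapply(config$samples$name[pick], function(nm) results[[nm]]$ev))
  }

  boundary_comparison <- NULL
  if (nrow(config$samples) >= 2) {
    first <- results[[config$samples$name[1]]]$boundaries
    last <- results[[config$samples$name[nrow(config$samples)]]]$boundaries
    boundary_comparison <- compare_boundary_sets(
      first[first$is_strong, ], last[last$is_strong, ])
  }

  report <- list(samples = results, stats = stats, switches = switches,
                 boundary_comparison = boundary_comparison, config = config,
                 genome = g)

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report$samples)) {
    r <- report$samples[[nm]]
    d <- file.path(out_dir, nm)
    dir.create(d, showWarnings = FALSE)
    bins <- r$map$bins
    write_bedgraph(bins, r$ev$ev1, file.path(d, "ev1.bedGraph"))
    write_bedgraph(bins, r$insulation$insulation,
                   file.path(d, "insulation.bedGraph"))
    write_boundaries_bed(r$boundaries, bins, file.path(d, "boundaries.bed"))
    readr::write_tsv(tibble::as_tibble(r$ps), file.path(d, "ps_curve.tsv"))
    readr::write_tsv(r$telcen, file.path(d, "telcen.tsv"))
    readr::write_tsv(tibble::as_tibble(r$telpairs),
                     file.path(d, "telomere_pairs.tsv"))
  }
  readr::write_tsv(report$stats, file.path(out_dir, "stats.tsv"))
  if (!is.null(report$switches)) {
    readr::write_tsv(report$switches$summary,
                     file.path(out_dir, "switch_summary.tsv"))
  }
  summary <- split(stats::setNames(report$stats$value, report$stats$statistic),
                   report$stats$sample)
  jsonlite::write_json(lapply(summary, as.list),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Compare two groups of pipeline reports statistic by statistic
#'
#' For every per-sample statistic: group means, their difference, an exact
#' (or near-exact) two-sided permutation test over group labels using the
#' difference of means, and a Welch t-test as a secondary output for
#' comparability with small-sample t-testing practice. With few samples the
#' permutation null is enumerated exactly, so the smallest attainable
#' p-value is `1 / choose(n_a + n_b, n_a)`.
#'
#' @param control,case Reports from [run_pipeline()] (their `$stats` are
#'   used), or long stats tibbles (`sample`, `statistic`, `value`).
#' @param max_exact Enumerate all label assignments when
#'   `choose(n, n_a) <= max_exact` (default 20000), otherwise sample that
#'   many permutations.
#' @return A tibble: `statistic`, `mean_control`, `mean_case`, `diff`,
#'   `p_perm`, `p_welch`, `sd_control`, `sd_case` (clone-level variability).
#' @export
compare_groups <- function(control, case, max_exact = 20000) {
  get_stats <- function(x) {
    if (is.list(x) && !is.data.frame(x) && !is.null(x$stats)) x$stats
    else tibble::as_tibble(x)
  }
  a <- get_stats(control)
  b <- get_stats(case)
  if (!setequal(unique(a$statistic), unique(b$statistic))) {
    stop("groups report different statistics (mismatched pipelines/genomes)",
         call. = FALSE)
  }
  purrr::map_dfr(unique(a$statistic), function(st) {
    va <- a$value[a$statistic == st]
    vb <- b$value[b$statistic == st]
    va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
    if (length(va) == 0 || length(vb) == 0) {
      return(tibble::tibble(statistic = st, mean_control = NA_real_,
                            mean_case = NA_real_, diff = NA_real_,
                            p_perm = NA_real_, p_welch = NA_real_,
                            sd_control = NA_real_, sd_case = NA_real_))
    }
    obs <- mean(vb) - mean(va)
    pooled <- c(va, vb)
    n <- length(pooled)
    na <- length(va)
    if (choose(n, na) <= max_exact) {
      combs <- utils::combn(n, na)
      diffs <- apply(combs, 2, function(idx) {
        mean(pooled[-idx]) - mean(pooled[idx])
      })
    } else {
      diffs <- vapply(seq_len(max_exact), function(k) {
        idx <- sample.int(n, na)
        mean(pooled[-idx]) - mean(pooled[idx])
      }, numeric(1))
    }
    p_perm <- mean(abs(diffs) >= abs(obs) - 1e-12)
    p_welch <- if (length(va) > 1 && length(vb) > 1 &&
                   (stats::sd(va) > 0 || stats::sd(vb) > 0)) {
      tryCatch(stats::t.test(vb, va)$p.value, error = function(e) NA_real_)
    } else NA_real_
    tibble::tibble(statistic = st, mean_control = mean(va),
                   mean_case = mean(vb), diff = obs,
                   p_perm = p_perm, p_welch = p_welch,
                   sd_control = stats::sd(va), sd_case = stats::sd(vb))
  })
}

#' Simulate -> eigenvector -> classify round trip over three cell states
#'
#' The end-to-end recovery experiment behind the switch taxonomy: sample
#' three-state compartment label tracks, simulate one contact map per state
#' with its preset, mask, balance, estimate EV1 against the planted reference
#' and classify every bin into the eight switch groups. The default depth
#' (1e8 contacts per state) matches the per-cis-pair coverage of a deep
#' (~1.5 billion contact) human Hi-C library at 100 kb resolution, scaled to
#' the 250 kb bins of the default simulation genome.
#'
#' @param bins A bin table with at least ~5000 bins for stable fractions
#'   (e.g. `build_bin_table(sim_genome_scaled(), 250e3, 1e6)`).
#' @param probs A [switch_probs()] object.
#' @param presets Named character vector mapping states `pf`, `ipsc`, `mn`
#'   to preset names.
#' @param n_contacts Contacts per state map.
#' @param seed Integer master seed (tracks use `seed`, state maps
#'   `seed + 1..3`).
#' @return A list: `switches` (a `hic_switches`), `tracks` (planted),
#'   `evs` (estimated tracks per state).
#' @export
switch_roundtrip <- function(bins, probs = switch_probs(),
                             presets = c(pf = "PF", ipsc = "IPSC",
                                         mn = "MN_W6"),
                             n_contacts = 1e8, seed = 1L) {
  tracks <- sample_switch_tracks(bins, probs, seed = seed)
  evs <- list()
  for (k in seq_along(presets)) {
    state <- names(presets)[k]
    params <- preset(presets[[k]])
    m <- simulate_map(bins, tracks[[state]], params, n_contacts = n_contacts,
                      seed = seed + k)
    m <- ic_balance(mask_low_coverage(m))
    evs[[state]] <- suppressWarnings(
      compute_ev1(m, tracks[[paste0("ev_", state)]]))
    rm(m)
    gc(verbose = FALSE)
  }
  list(switches = classify_switches(evs), tracks = tracks, evs = evs)
}
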