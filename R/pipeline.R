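#' Validate and default a pipeline configuration
#'
#' Accepts a (possibly nested, possibly partial) list or a JSON file path,
#' fills defaults, checks types and cross-field constraints, and returns a
#' fully resolved `pipeline_config`. The resolved config round-trips
#' losslessly through JSON and is written beside every run's outputs.
#'
#' Sections: `input` (paths: `contact`, `chrom_sizes`, `transcripts`,
#' `genome`) or `simulation` ([sim_config()] fields); `caller` (`windows`,
#' `delta`, `fdr`, `min_boundary_distance`); `tracks` (`min_signal`,
#' `gap_tolerance`, `min_array_length`, `min_aa`); `correspondence`
#' (`max_dist`, `flank`, `n_perm`); plus `resolution`, `seed`, `outdir`.
#'
#' @param raw A list, a JSON file path, or NULL/empty for all defaults.
#' @return A `pipeline_config`.
#' @export
validate_config <- function(raw = NULL) {
  if (is.character(raw) && length(raw) == 1)
    raw <- jsonlite::read_json(raw, simplifyVector = TRUE)
  raw <- raw %||% list()
  if (!is.list(raw)) stop_config("config must be a list or a JSON path")
  num_in <- function(x, field, lo, hi) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi)
      stop_config(sprintf("%s must be a number in [%g, %g]", field, lo, hi))
    x
  }
  cfg <- list(
    resolution = num_in(raw$resolution %||% 5e4, "resolution", 1, Inf),
    seed = as.integer(num_in(raw$seed %||% 1, "seed", 0, 2^31 - 1)),
    outdir = raw$outdir %||% "dinotad_out",
    input = raw$input,
    simulation = raw$simulation %||% (if (is.null(raw$input)) list() else NULL),
    caller = list(
      windows = as.integer(unlist(raw$caller$windows %||% c(2, 4, 6, 10))),
      delta = num_in(raw$caller$delta %||% 0.01, "caller.delta", 0, Inf),
      fdr = raw$caller$fdr %||% 0.05,
      min_boundary_distance = raw$caller$min_boundary_distance
    ),
    tracks = list(
      min_signal = num_in(raw$tracks$min_signal %||% 0.1, "tracks.min_signal",
                          1e-12, Inf),
      gap_tolerance = num_in(raw$tracks$gap_tolerance %||% 2.5e4,
                             "tracks.gap_tolerance", 1, Inf),
      min_array_length = num_in(raw$tracks$min_array_length %||% 1e5,
                                "tracks.min_array_length", 1, Inf),
      min_aa = num_in(raw$tracks$min_aa %||% 60, "tracks.min_aa", 0, Inf)
    ),
    correspondence = list(
      max_dist = num_in(raw$correspondence$max_dist %||% 5e4,
                        "correspondence.max_dist", 0, Inf),
      flank = num_in(raw$correspondence$flank %||% 10, "correspondence.flank",
                     1, Inf),
      n_perm = as.integer(num_in(raw$correspondence$n_perm %||% 999,
                                 "correspondence.n_perm", 100, Inf))
    ),
    compare = raw$compare %||% NULL   # optional: list(mixings = ...)
  )
  f <- cfg$caller$fdr
  if (!is.numeric(f) || f <= 0 || f >= 1)
    stop_config("caller.fdr must be in (0, 1)")
  if (any(cfg$caller$windows < 2) || is.unsorted(cfg$caller$windows))
    stop_config("caller.windows must be sorted integers >= 2")
  if (is.null(cfg$input) && is.null(cfg$simulation))
    stop_config("config needs either an input section or a simulation section")
  if (!is.null(cfg$input) && is.null(cfg$input$contact))
    stop_config("input.contact (contact map path) is required")
  if (!is.null(cfg$simulation)) {
    sim <- cfg$simulation
    sim$resolution <- sim$resolution %||% cfg$resolution
    sim$seed <- sim$seed %||% cfg$seed
    if (!is.null(sim$chrom_lengths)) sim$chrom_lengths <- unlist(sim$chrom_lengths)
    cfg$simulation <- unclass(do.call(sim_config, sim))
  }
  structure(cfg, class = "pipeline_config")
}

#' Serialize a pipeline config to JSON
#' @param cfg A `pipeline_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  x <- unclass(cfg)
  if (!is.null(x$simulation))
    x$simulation$chrom_lengths <- as.list(x$simulation$chrom_lengths)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Run the full dinoTAD analysis
#'
#' Executes the pipeline end to end: load or simulate inputs; mask and
#' KR-balance the contact map; separation scoring and FDR-controlled
#' boundary calling; domain assembly and statistics; strand inference, ORF
#' filtering, strand tracks, array segmentation and junction classification
#' (when transcripts/genome are available); boundary-junction matching and
#' enrichment test; optional condition comparison (simulated inhibition
#' series). All interface files, a machine-readable `summary.json` and a
#' `manifest.json` with checksums are written under `cfg$outdir`.
#' Deterministic given the config seed.
#'
#' @param cfg A `pipeline_config` (see [validate_config()]).
#' @return A results list (invisible components: `boundaries`, `domains`,
#'   `stats`, `arrays`, `junctions`, `match`, `enrichment`, `summary`,
#'   `manifest`).
#' @export
run_analysis <- function(cfg) {
  if (!inherits(cfg, "pipeline_config")) cfg <- validate_config(cfg)
  outdir <- cfg$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(name, path) { paths[[name]] <<- path; path }

  truth <- NULL
  if (!is.null(cfg$simulation)) {
    truth <- simulate_genome(structure(cfg$simulation, class = "sim_config"))
    map <- simulate_contact_map(truth)
    grid <- truth$grid
    emit("truth_dir", file.path(outdir, "truth"))
    write_truth(truth, file.path(outdir, "truth"))
  } else {
    if (!file.exists(cfg$input$contact %||% ""))
      abort(paste0("missing input file: input.contact = ", cfg$input$contact),
            class = "dinotad_path_error")
    if (is.null(cfg$input$chrom_sizes) || !file.exists(cfg$input$chrom_sizes))
      abort("missing input file: input.chrom_sizes",
            class = "dinotad_path_error")
    grid <- bin_grid(read_chrom_sizes(cfg$input$chrom_sizes), cfg$resolution)
    map <- load_contact_map(cfg$input$contact, grid)
  }

  balanced <- balance_map(map)
  track <- tad_separation_score(balanced, cfg$caller$windows)
  boundaries <- call_boundaries(track, balanced, delta = cfg$caller$delta,
                                fdr = cfg$caller$fdr,
                                min_boundary_distance =
                                  cfg$caller$min_boundary_distance)
  domains <- assemble_domains(boundaries, grid)
  stats <- domain_stats(domains, grid)
  oe <- observed_over_expected(balanced)
  write_track_bedgraph(track, emit("score", file.path(outdir, "separation.bedgraph")))
  write_boundaries_bed(boundaries, emit("boundaries", file.path(outdir, "boundaries.bed")))
  write_domains_bed(domains, emit("domains", file.path(outdir, "domains.bed")))
  readr::write_tsv(glance.domain_stats(stats),
                   emit("stats", file.path(outdir, "domain_stats.tsv")),
                   progress = FALSE)

  arrays <- junctions <- match <- enr <- NULL
  tracks <- NULL
  if (!is.null(truth)) {
    tx <- infer_transcript_strand(truth$transcripts, truth$genome)
    tx <- longest_orf_aa(tx[tx$strand != "*", ], truth$genome)
    tx <- filter_short_orf(tx, cfg$tracks$min_aa)
    tracks <- build_strand_tracks(tx, grid)
  } else if (!is.null(cfg$input$transcripts)) {
    tx <- read_transcripts_gff3(cfg$input$transcripts)
    if (!is.null(cfg$input$genome)) {
      genome <- Biostrings::readDNAStringSet(cfg$input$genome)
      names(genome) <- sub("\\s.*", "", names(genome))
      tx <- infer_transcript_strand(tx, genome)
      tx <- longest_orf_aa(tx[tx$strand != "*", ], genome)
      tx <- filter_short_orf(tx, cfg$tracks$min_aa)
    }
    tracks <- build_strand_tracks(tx[tx$strand != "*", ], grid)
  }
  if (!is.null(tracks)) {
    arrays <- segment_gene_arrays(tracks,
                                  min_array_length = cfg$tracks$min_array_length,
                                  gap_tolerance = cfg$tracks$gap_tolerance,
                                  min_signal = cfg$tracks$min_signal)
    junctions <- classify_junctions(arrays)
    tp <- write_tracks_bedgraph(tracks, file.path(outdir, "tracks"))
    emit("track_fwd", tp[1]); emit("track_rev", tp[2])
    write_arrays_bed(arrays, emit("arrays", file.path(outdir, "arrays.bed")))
    write_junctions_bed(junctions, emit("junctions", file.path(outdir, "junctions.bed")))
    if (nrow(boundaries) > 0 && nrow(junctions) > 0) {
      match <- match_boundaries_to_junctions(boundaries, junctions,
                                             max_dist = cfg$correspondence$max_dist)
      enr <- junction_enrichment_test(boundaries, junctions, grid,
                                      max_dist = cfg$correspondence$max_dist,
                                      n_perm = cfg$correspondence$n_perm,
                                      seed = derive_seed(cfg$seed, 7L))
      readr::write_tsv(as_tibble(match),
                       emit("match", file.path(outdir, "boundary_junction_match.tsv")),
                       progress = FALSE)
    }
  }

  trend <- NULL
  if (!is.null(truth) && !is.null(cfg$compare)) {
    series <- simulate_condition_series(truth,
                                        mixings = unlist(cfg$compare$mixings))
    trend <- compare_conditions(series, boundaries,
                                window = cfg$correspondence$flank,
                                seed = derive_seed(cfg$seed, 8L))
    readr::write_tsv(trend$summary,
                     emit("trend", file.path(outdir, "condition_trend.tsv")),
                     progress = FALSE)
  }

  summary <- list(
    n_boundaries = nrow(boundaries),
    n_domains = nrow(domains),
    median_domain_size = stats$size_percentiles[["p50"]],
    matched_fraction = if (!is.null(match)) attr(match, "matched_fraction") else NULL,
    enrichment_p = if (!is.null(enr)) enr$p_value else NULL,
    trend_rho = if (!is.null(trend)) trend$rho else NULL,
    trend_p = if (!is.null(trend)) trend$p_value else NULL
  )
  if (!is.null(truth)) {
    rec <- boundary_recovery(boundaries, truth)
    summary$boundary_recall <- rec$recall
    summary$boundary_precision <- rec$precision
  }
  jsonlite::write_json(summary, emit("summary", file.path(outdir, "summary.json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_config(cfg, emit("config", file.path(outdir, "config.json")))
  manifest <- tibble(name = names(paths), path = unname(paths),
                     md5 = purrr::map_chr(unname(paths), function(p)
                       if (file.exists(p) && !dir.exists(p))
                         unname(tools::md5sum(p)) else NA_character_))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       dataframe = "rows", null = "null")
  invisible(list(boundaries = boundaries, domains = domains, stats = stats,
                 track = track, map = balanced, oe = oe, tracks = tracks,
                 arrays = arrays, junctions = junctions, match = match,
                 enrichment = enr, trend = trend, truth = truth,
                 summary = summary, manifest = manifest))
}

#' Recall and precision of called boundaries against planted truth
#'
#' A planted boundary is recovered if a call lies within `tol_bins` bins of
#' it; a call is correct if a planted boundary lies within `tol_bins` of the
#' call.
#'
#' @param boundaries A `boundary_set`.
#' @param truth A [simulate_genome()] result.
#' @param tol_bins Matching tolerance in bins (default 1).
#' @return A one-row tibble (`recall`, `precision`, `n_true`, `n_called`).
#' @export
boundary_recovery <- function(boundaries, truth, tol_bins = 1) {
  tol <- tol_bins * truth$grid$resolution
  tb <- truth$boundaries
  hit_true <- purrr::map_lgl(seq_len(nrow(tb)), function(i) {
    any(boundaries$chrom == tb$chrom[i] &
          abs(boundaries$pos - tb$pos[i]) <= tol)
  })
  hit_call <- purrr::map_lgl(seq_len(nrow(boundaries)), function(i) {
    any(tb$chrom == boundaries$chrom[i] &
          abs(tb$pos - boundaries$pos[i]) <= tol)
  })
  tibble(recall = if (nrow(tb) > 0) mean(hit_true) else NA_real_,
         precision = if (nrow(boundaries) > 0) mean(hit_call) else NA_real_,
         n_true = nrow(tb), n_called = nrow(boundaries))
}
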