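test_that("the generator is a pure function of config and seed", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 1.5e6), domain_size = 5e5,
                    depth = 2e5, seed = 5)
  t1 <- simulate_genome(cfg)
  t2 <- simulate_genome(cfg)
  expect_identical(as.character(t1$genome), as.character(t2$genome))
  expect_identical(t1$boundaries, t2$boundaries)
  expect_identical(t1$transcripts$tpm, t2$transcripts$tpm)
  m1 <- simulate_contact_map(t1)
  m2 <- simulate_contact_map(t2)
  expect_identical(m1$counts, m2$counts)
  r1 <- simulate_reads(t1, 200)
  r2 <- simulate_reads(t2, 200)
  expect_identical(r1, r2)
})

test_that("the planted layout is divergent pairs bounded by convergent junctions", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 5e6), domain_size = 5e5,
                    domain_jitter = 0, depth = 2e5, seed = 2)
  truth <- simulate_genome(cfg, with_sequence = FALSE)
  expect_equal(nrow(truth$domains), 10)
  expect_equal(nrow(truth$boundaries), 9)
  expect_equal(nrow(truth$arrays), 20)
  expect_equal(truth$arrays$strand, rep(c("-", "+"), 10))
  internal <- truth$junctions
  expect_equal(internal$type,
               rep(c("divergent", "convergent"), length.out = nrow(internal)))
  # every planted boundary is exactly a convergent junction
  conv <- internal$pos[internal$type == "convergent"]
  expect_setequal(truth$boundaries$pos, conv)
  # divergent junctions are strictly interior to domains
  div <- internal$pos[internal$type == "divergent"]
  expect_false(any(div %in% c(truth$domains$start, truth$domains$end)))
})

test_that("transcripts stay inside their arrays and share their strand", {
  truth <- simulate_genome(small_sim(), with_sequence = FALSE)
  arr <- truth$arrays
  for (i in seq_len(nrow(truth$transcripts))) {
    t <- truth$transcripts[i, ]
    ex <- t$exons[[1]]
    hit <- which(arr$chrom == t$chrom & arr$start <= min(ex$start) &
                   arr$end >= max(ex$end))
    expect_length(hit, 1)
    expect_equal(arr$strand[hit], t$strand)
  }
})

test_that("sampled contact totals concentrate at the target depth", {
  truth <- simulate_genome(small_sim(), with_sequence = FALSE)
  cfg <- truth$config
  map <- simulate_contact_map(truth)
  m <- map$counts$chr1
  total <- sum(m[upper.tri(m, diag = TRUE)])
  expect_lt(abs(total - cfg$depth), 3 * sqrt(cfg$depth))
  expect_identical(m, t(m))
  expect_error(simulate_contact_map(truth, sim_config(depth = 0)),
               class = "dinotad_config_error")
})

test_that("flat enrichment produces maps without callable boundaries", {
  cfg <- small_sim(enrichment = 1, sub_enrichment = 1)
  truth <- simulate_genome(cfg, with_sequence = FALSE)
  map <- simulate_contact_map(truth)
  bal <- balance_map(map)
  bs <- call_boundaries(tad_separation_score(bal), bal)
  n_edges <- truth$grid$nbins[["chr1"]] - 1
  expect_lte(nrow(bs) / n_edges, 0.05)
})

test_that("simulated reads respect their truth labels", {
  truth <- simulate_genome(small_sim(), with_sequence = FALSE)
  cfg0 <- truth$config; cfg0$nascent_fraction <- 0
  reads0 <- simulate_reads(truth, 800, cfg0)
  expect_false(any(reads0$nascent))
  uf0 <- unspliced_fraction(reads0, truth$transcripts)
  expect_equal(uf0$fraction, 0)

  reads <- simulate_reads(truth, 500)
  spans <- truth$transcripts |>
    dplyr::mutate(s = purrr::map_dbl(exons, ~ min(.x$start)),
                  e = purrr::map_dbl(exons, ~ max(.x$end))) |>
    dplyr::select(source_id = "transcript_id", "s", "e")
  joined <- dplyr::left_join(reads, spans, by = "source_id")
  expect_true(all(joined$start >= joined$s & joined$end <= joined$e))
})

test_that("labeled nascent share matches the configured fraction", {
  truth <- simulate_genome(sim_config(chrom_lengths = c(chr1 = 3e6),
                                      domain_size = 6e5, depth = 5e5, seed = 7),
                           with_sequence = FALSE)
  reads <- simulate_reads(truth, 10000)
  share <- mean(reads$nascent[!duplicated(reads$read_id)])
  expect_lt(abs(share - 0.3), 0.02)
})

test_that("generator and analyzer close the loop on planted arrays", {
  truth <- simulate_genome(small_sim())
  tx <- infer_transcript_strand(truth$transcripts, truth$genome)
  tx <- filter_short_orf(longest_orf_aa(tx[tx$strand != "*", ], truth$genome))
  tracks <- build_strand_tracks(tx, truth$grid)
  arr <- segment_gene_arrays(tracks)
  gap_tol <- 2.5e4
  expect_equal(nrow(arr), nrow(truth$arrays))
  ta <- dplyr::arrange(truth$arrays, .data$chrom, .data$start)
  ca <- dplyr::arrange(arr, .data$chrom, .data$start)
  expect_equal(ca$strand, ta$strand)
  expect_true(all(abs(ca$start - ta$start) <= gap_tol))
  expect_true(all(abs(ca$end - ta$end) <= gap_tol))
})

test_that("condition series are reproducible and ordered", {
  truth <- simulate_genome(small_sim(), with_sequence = FALSE)
  s1 <- simulate_condition_series(truth, c(0, 0.5, 1))
  s2 <- simulate_condition_series(truth, c(0, 0.5, 1))
  expect_identical(s1$map[[2]]$counts, s2$map[[2]]$counts)
  expect_equal(s1$dose_rank, 1:3)
  expect_equal(s1$nascent_fraction, 0.3 * c(1, 0.5, 0))
  expect_error(simulate_condition_series(truth, numeric(0)),
               class = "dinotad_config_error")
  one <- simulate_condition_series(truth, 0)
  expect_equal(nrow(one), 1)
})
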