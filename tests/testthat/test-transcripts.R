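# genome assembled by hand: pads of C's never create ATGs or stops
pad <- function(n) strrep("C", n)

genome_of <- function(...) Biostrings::DNAStringSet(c(...))

test_that("splice-junction orientation votes follow the GT-AG / CT-AC rule", {
  # exon [0,10) - intron [10,20) - exon [20,30)
  seq_plus <- paste0(pad(10), "GT", pad(6), "AG", pad(10))
  seq_minus <- paste0(pad(10), "CT", pad(6), "AC", pad(10))
  seq_odd <- paste0(pad(10), "AA", pad(6), "AA", pad(10))
  g <- genome_of(chrP = seq_plus, chrM = seq_minus, chrO = seq_odd)
  ex <- tibble::tibble(start = c(0, 20), end = c(10, 30))
  tx <- transcript_table(c("p", "m", "o"), c("chrP", "chrM", "chrO"),
                         list(ex, ex, ex))
  out <- infer_transcript_strand(tx, g)
  expect_equal(out$strand, c("+", "-", "*"))
})

test_that("conflicting junctions yield unknown under strict mode, majority under majority", {
  # two introns: first GT..AG (+), second CT..AC (-)
  s <- paste0(pad(10), "GT", pad(6), "AG", pad(10), "CT", pad(6), "AC", pad(10))
  g <- genome_of(chrC = s)
  ex <- tibble::tibble(start = c(0, 20, 40), end = c(10, 30, 50))
  tx <- transcript_table("c", "chrC", list(ex))
  expect_equal(infer_transcript_strand(tx, g, mode = "strict")$strand, "*")
  expect_equal(infer_transcript_strand(tx, g, mode = "majority")$strand, "*")
  # add a second + intron: majority resolves, strict does not
  s2 <- paste0(pad(10), "GT", pad(6), "AG", pad(10), "GT", pad(6), "AG",
               pad(10), "CT", pad(6), "AC", pad(10))
  g2 <- genome_of(chrC = s2)
  ex2 <- tibble::tibble(start = c(0, 20, 40, 60), end = c(10, 30, 50, 70))
  tx2 <- transcript_table("c", "chrC", list(ex2))
  expect_equal(infer_transcript_strand(tx2, g2, mode = "strict")$strand, "*")
  expect_equal(infer_transcript_strand(tx2, g2, mode = "majority")$strand, "+")
})

test_that("single-exon transcripts are unknown and tiny introns error", {
  g <- genome_of(chrA = pad(50))
  tx1 <- transcript_table("s", "chrA", list(tibble::tibble(start = 0, end = 30)))
  expect_equal(infer_transcript_strand(tx1, g)$strand, "*")
  tx2 <- transcript_table("t", "chrA",
                          list(tibble::tibble(start = c(0, 12), end = c(10, 20))))
  expect_error(infer_transcript_strand(tx2, g), class = "dinotad_model_error")
})

test_that("the longest ORF is counted as codons between start and stop", {
  codons63 <- strrep("GCT", 63)
  s <- paste0(pad(9), "ATG", codons63, "TAA", pad(9))
  g <- genome_of(chrA = s)
  tx <- transcript_table("a", "chrA",
                         list(tibble::tibble(start = 0, end = nchar(s))),
                         strand = "+")
  expect_equal(longest_orf_aa(tx, g)$orf_aa, 63)

  g0 <- genome_of(chrA = pad(300))        # no ATG anywhere
  tx0 <- transcript_table("z", "chrA",
                          list(tibble::tibble(start = 0, end = 300)), strand = "+")
  expect_equal(longest_orf_aa(tx0, g0)$orf_aa, 0)

  expect_error(longest_orf_aa(dplyr::mutate(tx, strand = "*"), g),
               class = "dinotad_config_error")
})

test_that("longest ORF matches a brute-force scan on random sequence", {
  brute <- function(s) {
    L <- nchar(s); best <- 0
    stops <- c("TAA", "TAG", "TGA")
    for (at in seq_len(L - 5)) {
      if (substr(s, at, at + 2) != "ATG") next
      k <- at + 3
      while (k + 2 <= L) {
        if (substr(s, k, k + 2) %in% stops) {
          best <- max(best, (k - at - 3) / 3)
          break
        }
        k <- k + 3
      }
    }
    best
  }
  withr::with_seed(21, {
    for (rep in 1:5) {
      s <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                 collapse = "")
      g <- genome_of(chrA = s)
      tx <- transcript_table("r", "chrA",
                             list(tibble::tibble(start = 0, end = 2000)),
                             strand = "+")
      expect_equal(longest_orf_aa(tx, g)$orf_aa, brute(s))
    }
  })
})

test_that("the ORF filter removes 59 aa and keeps 60 aa, and is monotone", {
  mk <- function(aa) paste0(pad(9), "ATG", strrep("GCT", aa), "TAA", pad(9))
  g <- genome_of(chr59 = mk(59), chr60 = mk(60), chr200 = mk(200),
                 chr0 = pad(120))
  tx <- transcript_table(c("t0", "t59", "t60", "t200"),
                         c("chr0", "chr59", "chr60", "chr200"),
                         purrr::map(c(120, nchar(mk(59)), nchar(mk(60)),
                                      nchar(mk(200))),
                                    ~ tibble::tibble(start = 0, end = .x)),
                         strand = "+")
  tx <- longest_orf_aa(tx, g)
  expect_equal(tx$orf_aa, c(0, 59, 60, 200))
  kept <- filter_short_orf(tx, min_aa = 60)
  expect_equal(kept$transcript_id, c("t60", "t200"))
  expect_equal(filter_short_orf(tx, min_aa = 0)$transcript_id, tx$transcript_id)
  # monotone: raising min_aa never adds transcripts
  prev <- tx$transcript_id
  for (m in c(1, 60, 100, 500)) {
    cur <- filter_short_orf(tx, min_aa = m)$transcript_id
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("strand tracks follow the summed-TPM definition", {
  g_len <- c(chrA = 1000)
  t1 <- transcript_table("a", "chrA",
                         list(tibble::tibble(start = c(0, 200), end = c(100, 300))),
                         strand = "+", tpm = 5)
  tr <- build_strand_tracks(t1, g_len)
  f <- as.numeric(tr$forward$chrA)
  expect_equal(f[1:100], rep(5, 100))
  expect_equal(f[101:200], rep(0, 100))
  expect_equal(f[201:300], rep(5, 100))
  expect_equal(sum(as.numeric(tr$reverse$chrA)), 0)

  t2 <- dplyr::bind_rows(
    transcript_table("a", "chrA", list(tibble::tibble(start = 0, end = 100)),
                     strand = "+", tpm = 2),
    transcript_table("b", "chrA", list(tibble::tibble(start = 50, end = 150)),
                     strand = "+", tpm = 3))
  f2 <- as.numeric(build_strand_tracks(t2, g_len)$forward$chrA)
  expect_equal(f2[51:100], rep(5, 50))

  over <- transcript_table("x", "chrA",
                           list(tibble::tibble(start = 900, end = 1100)),
                           strand = "+", tpm = 1)
  expect_error(build_strand_tracks(over, g_len),
               class = "dinotad_coordinate_error")
})

test_that("track mass equals a brute-force per-bp accumulation", {
  g_len <- c(chrA = 10000)
  withr::with_seed(31, {
    txs <- purrr::map(1:100, function(i) {
      n_ex <- sample(1:3, 1)
      starts <- sort(sample(0:9000, n_ex))
      ex <- tibble::tibble(start = starts,
                           end = pmin(starts + sample(50:400, n_ex, TRUE), 10000))
      ex <- ex[!duplicated(ex$start), , drop = FALSE]
      # keep exons disjoint
      keep <- rep(TRUE, nrow(ex))
      if (nrow(ex) > 1)
        for (k in 2:nrow(ex)) keep[k] <- ex$start[k] >= max(ex$end[seq_len(k - 1)])
      ex <- ex[keep, , drop = FALSE]
      transcript_table(paste0("t", i), "chrA", list(ex),
                       strand = sample(c("+", "-"), 1),
                       tpm = round(runif(1, 0.1, 20), 3))
    })
  })
  tx <- dplyr::bind_rows(txs)
  tracks <- build_strand_tracks(tx, g_len)
  # oracle: accumulate per bp in a plain numeric vector
  acc <- list(`+` = numeric(10000), `-` = numeric(10000))
  for (i in seq_len(nrow(tx))) {
    ex <- tx$exons[[i]]
    for (k in seq_len(nrow(ex)))
      acc[[tx$strand[i]]][(ex$start[k] + 1):ex$end[k]] <-
        acc[[tx$strand[i]]][(ex$start[k] + 1):ex$end[k]] + tx$tpm[i]
  }
  expect_equal(as.numeric(tracks$forward$chrA), acc[["+"]])
  expect_equal(as.numeric(tracks$reverse$chrA), acc[["-"]])
  expect_equal(track_mass(tracks, "+") + track_mass(tracks, "-"),
               sum(tx$tpm * purrr::map_dbl(tx$exons, ~ sum(.x$end - .x$start))))
})
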