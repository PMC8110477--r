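rle_of <- function(values, lengths) S4Vectors::Rle(values, lengths)

test_that("clean strand-partitioned signal segments into two arrays", {
  L <- 9e5
  fwd <- rle_of(c(3, 0), c(5e5, 4e5))
  rev <- rle_of(c(0, 2), c(5e5, 4e5))
  tr <- tracks_from_rle(list(chrA = fwd), list(chrA = rev), c(chrA = L))
  arr <- segment_gene_arrays(tr)
  expect_equal(nrow(arr), 2)
  expect_equal(arr$strand, c("+", "-"))
  expect_equal(arr$start, c(0, 5e5))
  expect_equal(arr$end, c(5e5, 9e5))
})

test_that("internal gaps up to the tolerance are bridged", {
  fwd <- rle_of(c(1, 0, 1, 0), c(2e5, 5e3, 2e5, 1e5))
  rev <- rle_of(0, 5.05e5)
  tr <- tracks_from_rle(list(chrA = fwd), list(chrA = rev), c(chrA = 5.05e5))
  arr <- segment_gene_arrays(tr, gap_tolerance = 1e4)
  expect_equal(nrow(arr), 1)
  expect_equal(arr$start, 0)
  expect_equal(arr$end, 4.05e5)
  # a gap beyond tolerance splits the run
  arr2 <- segment_gene_arrays(tr, gap_tolerance = 4e3)
  expect_equal(nrow(arr2), 2)
})

test_that("empty tracks give an empty array table", {
  tr <- tracks_from_rle(list(chrA = rle_of(0, 1e5)),
                        list(chrA = rle_of(0, 1e5)), c(chrA = 1e5))
  expect_equal(nrow(segment_gene_arrays(tr)), 0)
})

test_that("strand overlaps are resolved by integrated signal", {
  # forward strong over [0, 300k); reverse weakly overlaps [250k, 500k)
  fwd <- rle_of(c(5, 0), c(3e5, 2e5))
  rev <- rle_of(c(0, 1, 1), c(2.5e5, 0.5e5, 2e5))
  tr <- tracks_from_rle(list(chrA = fwd), list(chrA = rev), c(chrA = 5e5))
  arr <- segment_gene_arrays(tr)
  expect_equal(arr$strand, c("+", "-"))
  expect_equal(arr$end[1], 3e5)          # forward keeps the overlap
  expect_equal(arr$start[2], 3e5)        # reverse truncated
})

test_that("junction types follow the strand pair", {
  arr <- tibble::tibble(chrom = "chrA", start = c(0, 5e5), end = c(5e5, 9e5),
                        strand = c("+", "-"))
  j <- classify_junctions(arr)
  expect_equal(j$type, "convergent")
  expect_equal(j$pos, 5e5)

  arr$strand <- c("-", "+")
  expect_equal(classify_junctions(arr)$type, "divergent")

  alt <- tibble::tibble(chrom = "chrA",
                        start = c(0, 2e5, 4e5, 6e5), end = c(2e5, 4e5, 6e5, 8e5),
                        strand = c("-", "+", "-", "+"))
  expect_equal(classify_junctions(alt)$type,
               c("divergent", "convergent", "divergent"))

  bad <- alt[c(2, 1, 3, 4), ]
  expect_error(classify_junctions(dplyr::mutate(bad, start = c(0, 1e5, 0.5e5, 6e5),
                                                end = c(2e5, 1.5e5, 4e5, 8e5))),
               class = "dinotad_coordinate_error")
})

test_that("convergent and divergent junctions alternate without tandems", {
  withr::with_seed(77, {
    for (rep in 1:10) {
      k <- sample(3:12, 1)
      first <- sample(c("+", "-"), 1)
      strands <- rep(c(first, setdiff(c("+", "-"), first)), length.out = k)
      edges <- sort(sample(seq(1e5, 5e6, by = 1e5), k + 1))
      arr <- tibble::tibble(chrom = "chrA", start = head(edges, -1),
                            end = tail(edges, -1), strand = strands)
      j <- classify_junctions(arr)
      nontandem <- j$type[j$type %in% c("convergent", "divergent")]
      expect_true(all(nontandem[-1] != nontandem[-length(nontandem)]))
    }
  })
})

test_that("the unspliced fraction hits its degenerate extremes", {
  ex <- tibble::tibble(start = c(0, 200), end = c(100, 300))
  tx <- transcript_table("t", "chrA", list(ex), strand = "+", tpm = 1)
  exonic <- tibble::tibble(read_id = c("r1", "r2", "r2"), chrom = "chrA",
                           start = c(10, 80, 200), end = c(60, 100, 230),
                           spliced = c(FALSE, TRUE, TRUE))
  expect_equal(unspliced_fraction(exonic, tx)$fraction, 0)

  intronic <- tibble::tibble(read_id = c("r1", "r2"), chrom = "chrA",
                             start = c(110, 150), end = c(160, 199),
                             spliced = FALSE)
  expect_equal(unspliced_fraction(intronic, tx)$fraction, 1)

  outside <- tibble::tibble(read_id = "r", chrom = "chrA",
                            start = 5000, end = 5100, spliced = FALSE)
  out <- unspliced_fraction(outside, tx)
  expect_true(is.nan(out$fraction))
  expect_equal(out$n_unassigned, 1)

  expect_error(unspliced_fraction(exonic[0, ], tx),
               class = "dinotad_config_error")
})

test_that("reads below the intron-overlap threshold are not intronic", {
  ex <- tibble::tibble(start = c(0, 200), end = c(100, 300))
  tx <- transcript_table("t", "chrA", list(ex), strand = "+", tpm = 1)
  # 5 bp into the intron only
  graze <- tibble::tibble(read_id = "r", chrom = "chrA", start = 60,
                          end = 105, spliced = FALSE)
  expect_equal(unspliced_fraction(graze, tx, min_intron_overlap = 10)$fraction, 0)
  expect_equal(unspliced_fraction(graze, tx, min_intron_overlap = 5)$fraction, 1)
})
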