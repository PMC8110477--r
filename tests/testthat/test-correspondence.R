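# an O/E map built directly from a value matrix
oe_from_matrix <- function(m, resolution = 5e4, chrom = "chrA") {
  g <- bin_grid(setNames(nrow(m) * resolution, chrom), resolution)
  contact_map(setNames(list(m), chrom), g, kind = "oe")
}

bset <- function(edges, resolution = 5e4, chrom = "chrA") {
  tibble::tibble(chrom = chrom, edge = as.integer(edges),
                 pos = edges * resolution)
}

test_that("boundaries match their nearest junction within the tolerance", {
  js <- tibble::tibble(chrom = "chrA", pos = c(2e5, 8e5),
                       type = c("convergent", "convergent"))
  bs <- tibble::tibble(chrom = "chrA", pos = c(2e5, 9.2e5))
  m1 <- match_boundaries_to_junctions(bs[1, ], js, max_dist = 1e5)
  expect_true(m1$matched)
  expect_equal(m1$distance, 0)
  m2 <- match_boundaries_to_junctions(bs[2, ], js, max_dist = 1e5)
  expect_false(m2$matched)

  expect_error(match_boundaries_to_junctions(bs, js[0, ], max_dist = 1e5),
               class = "dinotad_config_error")

  # only allowed types are eligible
  jd <- dplyr::mutate(js, type = "divergent")
  m3 <- match_boundaries_to_junctions(bs, jd, max_dist = 1e5,
                                      types = "convergent")
  expect_equal(attr(m3, "matched_fraction"), 0)
})

test_that("the enrichment test is maximal for perfect correspondence and deterministic", {
  g <- bin_grid(c(chrA = 1e7), 5e4)
  js <- tibble::tibble(chrom = "chrA", pos = seq(7e5, 9.5e6, by = 7e5),
                       type = "convergent")
  bs <- tibble::tibble(chrom = "chrA", pos = js$pos)
  e1 <- junction_enrichment_test(bs, js, g, max_dist = 5e4, n_perm = 999,
                                 seed = 9)
  expect_equal(e1$observed, 1)
  expect_equal(e1$p_value, 1 / 1000)
  e2 <- junction_enrichment_test(bs, js, g, max_dist = 5e4, n_perm = 999,
                                 seed = 9)
  expect_identical(e1$null, e2$null)
  e3 <- junction_enrichment_test(bs, js, g, max_dist = 5e4, n_perm = 999,
                                 seed = 10)
  expect_false(identical(e1$null, e3$null))
})

test_that("the enrichment test is calibrated under independence", {
  g <- bin_grid(c(chrA = 1e7), 5e4)
  js <- tibble::tibble(chrom = "chrA", pos = seq(7e5, 9.5e6, by = 7e5),
                       type = "convergent")
  withr::with_seed(123, {
    hits <- purrr::map_lgl(1:200, function(i) {
      bpos <- sort(sample(seq(5e4, 9.9e6, by = 5e4), 13))
      bs <- tibble::tibble(chrom = "chrA", pos = bpos)
      junction_enrichment_test(bs, js, g, max_dist = 5e4, n_perm = 199,
                               seed = i)$p_value < 0.05
    })
  })
  expect_gte(mean(hits), 0.02)
  expect_lte(mean(hits), 0.10)
})

test_that("Hi-C metaplots average O/E submatrices around boundaries", {
  flat <- oe_from_matrix(matrix(1, 40, 40))
  mp <- hic_boundary_metaplot(flat, bset(c(15, 25)), flank = 5)
  expect_equal(mp$profile, matrix(1, 10, 10))
  expect_equal(mp$n_boundaries, 2)

  # boundaries near the edge are dropped and counted
  mp2 <- hic_boundary_metaplot(flat, bset(c(2, 20)), flank = 5)
  expect_equal(mp2$n_boundaries, 1)
  expect_equal(mp2$n_dropped, 1)
  expect_error(hic_boundary_metaplot(flat, bset(2), flank = 5),
               class = "dinotad_config_error")

  # input symmetric about the boundary (distance-stationary Toeplitz map)
  # -> 180-degree rotational symmetry of the profile
  g <- withr::with_seed(4, runif(40, 0.5, 2))
  m0 <- matrix(0, 40, 40)
  m0[] <- g[abs(row(m0) - col(m0)) + 1]
  mp3 <- hic_boundary_metaplot(oe_from_matrix(m0), bset(20), flank = 6)
  rot <- mp3$profile[rev(seq_len(12)), rev(seq_len(12))]
  expect_equal(mp3$profile, rot, tolerance = 1e-12)
})

test_that("metaplots are linear in their O/E inputs", {
  a <- random_symmetric(40, seed = 1)
  b <- random_symmetric(40, seed = 2)
  bs <- bset(c(12, 20, 28))
  pa <- hic_boundary_metaplot(oe_from_matrix(a), bs, flank = 4)$profile
  pb <- hic_boundary_metaplot(oe_from_matrix(b), bs, flank = 4)$profile
  pab <- hic_boundary_metaplot(oe_from_matrix((a + b) / 2), bs, flank = 4)$profile
  expect_equal(pab, (pa + pb) / 2, tolerance = 1e-12)
})

test_that("planted domains depress the cross-boundary metaplot quadrant", {
  truth <- default_truth()
  map <- simulate_contact_map(truth)
  bal <- balance_map(map)
  bs <- call_boundaries(tad_separation_score(bal), bal)
  oe <- observed_over_expected(bal)
  mp <- hic_boundary_metaplot(oe, bs, flank = 10)
  f <- mp$flank
  cross <- mp$profile[seq_len(f), f + seq_len(f)]
  intra <- c(mp$profile[seq_len(f), seq_len(f)][upper.tri(diag(f))],
             mp$profile[f + seq_len(f), f + seq_len(f)][upper.tri(diag(f))])
  expect_lt(mean(cross, na.rm = TRUE), mean(intra, na.rm = TRUE))
})

test_that("RNA metaplots mirror strand dominance and handle trivial cases", {
  L <- c(chrA = 2e6)
  zero <- tracks_from_rle(list(chrA = S4Vectors::Rle(0, 2e6)),
                          list(chrA = S4Vectors::Rle(0, 2e6)), L)
  bs <- tibble::tibble(chrom = "chrA", edge = 20L, pos = 1e6)
  mp0 <- rna_boundary_metaplot(zero, bs, flank = 2e5, bin = 5e4)
  expect_true(all(mp0$forward == 0) && all(mp0$reverse == 0))

  # single boundary: the profile is that boundary's own windowed track
  fwd <- S4Vectors::Rle(seq_len(2e6) %% 7)
  tr <- tracks_from_rle(list(chrA = fwd), list(chrA = S4Vectors::Rle(0, 2e6)), L)
  mp1 <- rna_boundary_metaplot(tr, bs, flank = 1e5, bin = 5e4)
  offs <- seq(-1e5, 1e5 - 5e4, by = 5e4)
  own <- vapply(offs, function(o)
    mean(as.numeric(fwd[(1e6 + o + 1):(1e6 + o + 5e4)])), 1)
  expect_equal(mp1$forward, own, tolerance = 1e-12)

  expect_error(rna_boundary_metaplot(zero, bs, flank = 1.3e5, bin = 5e4),
               class = "dinotad_config_error")
})

test_that("boundary strength is 1 on flat maps and scales with intra signal", {
  flat <- oe_from_matrix(matrix(1, 30, 30))
  s <- boundary_strength(flat, bset(15), window = 5)
  expect_equal(s$strength, 1)

  m0 <- two_block_matrix(block = 10, intra = 5, inter = 1)
  oe <- oe_from_matrix(m0)
  s2 <- boundary_strength(oe, bset(10), window = 5)
  # hand computation: diamond is all inter, triangles all intra
  expect_equal(s2$inter, 1)
  expect_equal(s2$intra, 5)
  expect_equal(s2$strength, 5)

  # doubling intra-domain cells doubles A and strength
  m3 <- m0
  m3[1:10, 1:10] <- m3[1:10, 1:10] * 2
  m3[11:20, 11:20] <- m3[11:20, 11:20] * 2
  s3 <- boundary_strength(oe_from_matrix(m3), bset(10), window = 5)
  expect_equal(s3$intra, 10)
  expect_equal(s3$strength, 10)

  # global scaling leaves strength unchanged
  s4 <- boundary_strength(oe_from_matrix(m0 * 3.7), bset(10), window = 5)
  expect_equal(s4$strength, s2$strength)
})

test_that("condition comparison detects decompaction and respects the null", {
  truth <- default_truth()
  map <- simulate_contact_map(truth)
  bal <- balance_map(map)
  bs <- call_boundaries(tad_separation_score(bal), bal)

  series <- simulate_condition_series(truth, c(0, 0.5, 1))
  ct <- compare_conditions(series, bs, n_perm = 999, seed = 3)
  expect_true(all(diff(ct$summary$mean_strength) < 0))
  expect_lt(ct$p_value, 0.05)

  # reversed dose labels flip the trend sign
  rev_series <- series
  rev_series$dose_rank <- rev(series$dose_rank)
  ct_rev <- compare_conditions(rev_series, bs, n_perm = 199, seed = 3)
  expect_equal(ct_rev$rho, -ct$rho, tolerance = 1e-9)

  # identical maps: no trend
  same <- series
  same$map <- list(series$map[[1]], series$map[[1]], series$map[[1]])
  ct0 <- compare_conditions(same, bs, n_perm = 199, seed = 3)
  expect_gt(ct0$p_value, 0.05)
  expect_true(all(abs(ct0$per_boundary$delta_last) < 1e-12))

  expect_error(compare_conditions(series[1, ], bs),
               class = "dinotad_config_error")
})
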