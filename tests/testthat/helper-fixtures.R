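# Shared fixtures, all built in code.

# symmetric random matrix with positive entries (always balanceable)
random_symmetric <- function(n, seed, lo = 0.5, hi = 10) {
  withr::with_seed(seed, {
    a <- matrix(runif(n * n, lo, hi), n)
    (a + t(a)) / 2
  })
}

# single-chromosome contact map from a matrix
map_from_matrix <- function(m, resolution = 1e4, chrom = "chrA") {
  g <- bin_grid(setNames(nrow(m) * resolution, chrom), resolution)
  contact_map(setNames(list(m), chrom), g)
}

# two same-size blocks with uniform intra/inter contact levels
two_block_matrix <- function(block = 10, intra = 5, inter = 1) {
  n <- 2 * block
  m <- matrix(inter, n, n)
  m[1:block, 1:block] <- intra
  m[(block + 1):n, (block + 1):n] <- intra
  m
}

# independent Sinkhorn oracle: alternating row/column scaling run to a tight
# tolerance; returns the balanced matrix (row sums 1)
sinkhorn_oracle <- function(m, tol = 1e-10, max_iter = 1e5) {
  r <- rep(1, nrow(m)); s <- rep(1, ncol(m))
  for (i in seq_len(max_iter)) {
    r <- 1 / as.vector(m %*% s)
    s <- 1 / as.vector(t(m) %*% r)
    b <- m * outer(r, s)
    if (max(abs(rowSums(b) - 1)) < tol && max(abs(colSums(b) - 1)) < tol)
      break
  }
  # symmetrize the equivalent diagonal scaling
  w <- sqrt(r * s)
  m * outer(w, w)
}

# strand_tracks object built directly from per-chromosome Rle vectors
tracks_from_rle <- function(forward, reverse, lengths) {
  structure(list(
    forward = methods::as(S4Vectors::SimpleList(forward), "SimpleRleList"),
    reverse = methods::as(S4Vectors::SimpleList(reverse), "SimpleRleList"),
    lengths = lengths), class = "strand_tracks")
}

# small simulation config for fast end-to-end tests
small_sim <- function(seed = 11, ...) {
  sim_config(chrom_lengths = c(chr1 = 4e6), domain_size = 6e5, depth = 8e5,
             seed = seed, ...)
}

# the pinned default synthetic dataset, built once per test session
default_truth <- local({
  cache <- NULL
  function(with_sequence = FALSE) {
    if (is.null(cache) || (with_sequence && is.null(cache$genome)))
      cache <<- simulate_genome(sim_config(), with_sequence = with_sequence)
    cache
  }
})
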