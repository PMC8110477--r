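#' Knight-Ruiz balancing of a contact map
#'
#' Finds per-bin positive weights `w` such that the balanced matrix
#' `w_i * c_ij * w_j` has all unmasked row sums equal to 1, by damped
#' fixed-point iteration on the symmetric scaling equation
#' `x .* (A x) = 1` (square-root damping, the classical symmetric
#' Sinkhorn-Knopp/Knight-Ruiz scheme). Convergence is the maximum relative
#' deviation of unmasked row sums from 1.
#'
#' The map should be masked of zero-marginal bins first (see
#' [mask_sparse_bins()]); a matrix that cannot be balanced (e.g. a
#' disconnected zero block) raises a non-convergence error naming the worst
#' offending bins, and no partial weights are returned.
#'
#' @param map A raw [contact_map()].
#' @param tol Relative row-sum tolerance (default 1e-6).
#' @param max_iter Maximum iterations per chromosome (default 3000).
#' @return A `balancing_weights` object: per-chromosome weight vectors with NA
#'   at masked bins, plus iteration counts.
#' @examples
#' g <- bin_grid(c(chrA = 100), resolution = 50)
#' m <- contact_map(list(chrA = matrix(c(0, 2, 2, 0), 2)), g)
#' w <- kr_balance(m)
#' map_values(apply_weights(m, w), "chrA")  # row sums are 1
#' @export
kr_balance <- function(map, tol = 1e-6, max_iter = 3000) {
  if (tol <= 0) stop_config("tol must be > 0")
  weights <- list()
  iters <- integer(0)
  for (ch in map$grid$chroms) {
    keep <- !map$mask[[ch]]
    n <- map$grid$nbins[[ch]]
    w_full <- rep(NA_real_, n)
    if (sum(keep) > 0) {
      A <- map$counts[[ch]][keep, keep, drop = FALSE]
      zero <- which(rowSums(A) == 0)
      if (length(zero) > 0)
        stop_numeric(paste0(
          "cannot balance ", ch, ": zero-marginal unmasked bin(s) ",
          paste(head(which(keep)[zero], 5), collapse = ", "),
          " (mask sparse bins first)"))
      res <- kr_iterate(A, tol, max_iter)
      if (!res$converged)
        stop_numeric(paste0(
          "KR balancing did not converge on ", ch, " within ", max_iter,
          " iterations; worst bins: ",
          paste(head(which(keep)[order(-abs(res$dev))], 5), collapse = ", ")))
      w_full[keep] <- res$x
      iters <- c(iters, res$iter)
    } else {
      iters <- c(iters, 0L)
    }
    weights[[ch]] <- w_full
  }
  structure(list(weights = weights, grid = map$grid,
                 iterations = setNames(iters, map$grid$chroms), tol = tol),
            class = "balancing_weights")
}

# Damped symmetric scaling on a dense symmetric non-negative matrix.
kr_iterate <- function(A, tol, max_iter) {
  x <- 1 / sqrt(rowSums(A))
  for (it in seq_len(max_iter)) {
    r <- x * as.vector(A %*% x)          # row sums of diag(x) A diag(x)
    dev <- r - 1
    if (max(abs(dev)) < tol)
      return(list(x = x, iter = it, converged = TRUE, dev = dev))
    x <- x / sqrt(r)
  }
  list(x = x, iter = max_iter, converged = FALSE, dev = x * as.vector(A %*% x) - 1)
}

#' @export
print.balancing_weights <- function(x, ...) {
  cat(sprintf("<balancing_weights> %d chromosome(s), tol %g, iterations: %s\n",
              length(x$weights), x$tol, paste(x$iterations, collapse = ", ")))
  invisible(x)
}

#' @describeIn kr_balance Tidy the weights into a tibble
#'   (`chrom`, `bin`, `start`, `weight`).
#' @param x A `balancing_weights` object.
#' @param ... Unused.
#' @export
tidy.balancing_weights <- function(x, ...) {
  grid_bins(x$grid) |>
    mutate(weight = unlist(x$weights, use.names = FALSE)) |>
    select("chrom", "bin", "start", "weight")
}

#' Apply balancing weights to a contact map
#'
#' @param map A raw [contact_map()].
#' @param weights A `balancing_weights` from [kr_balance()].
#' @return A [contact_map()] of kind `"balanced"`; masked cells are NA.
#' @export
apply_weights <- function(map, weights) {
  if (map$kind != "raw") stop_config("weights apply to raw maps")
  for (ch in map$grid$chroms) {
    w <- weights$weights[[ch]]
    m <- map$counts[[ch]] * outer(w, w)
    map$counts[[ch]] <- m
    map$mask[[ch]] <- map$mask[[ch]] | is.na(w)
  }
  map$weights <- NULL
  map$kind <- "balanced"
  map
}

#' Mask and balance in one step
#'
#' Convenience wrapper: [mask_sparse_bins()] then [kr_balance()] then
#' [apply_weights()].
#'
#' @inheritParams kr_balance
#' @param min_marginal,marginal_quantile Passed to [mask_sparse_bins()].
#' @return A balanced [contact_map()].
#' @export
balance_map <- function(map, tol = 1e-6, max_iter = 3000,
                        min_marginal = 1, marginal_quantile = 0.005) {
  map <- mask_sparse_bins(map, min_marginal, marginal_quantile)
  apply_weights(map, kr_balance(map, tol, max_iter))
}

#' Write balancing weights as bedGraph
#' @param weights A `balancing_weights`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weights_bedgraph <- function(weights, path) {
  df <- tidy.balancing_weights(weights) |>
    mutate(end = .data$start + weights$grid$resolution) |>
    select("chrom", "start", "end", "weight")
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
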