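#' Fixed-resolution genome binning
#'
#' A `bin_grid` tiles each chromosome with fixed-size bins (the last bin of a
#' chromosome may be short). Coordinates are 0-based, half-open throughout the
#' package; bins are indexed 1..n within each chromosome.
#'
#' @param lengths Named numeric vector of chromosome lengths in bp.
#' @param resolution Bin size in bp.
#' @return An object of class `bin_grid`.
#' @examples
#' grid <- bin_grid(c(chr1 = 1e6), resolution = 5e4)
#' n_bins(grid)
#' @export
bin_grid <- function(lengths, resolution) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths))))
    stop_config("chromosome lengths must be named")
  if (any(lengths < 1)) stop_config("chromosome lengths must be >= 1 bp")
  if (resolution < 1) stop_config("resolution must be >= 1 bp")
  structure(
    list(
      chroms = names(lengths),
      lengths = setNames(as.numeric(lengths), names(lengths)),
      resolution = as.numeric(resolution),
      nbins = setNames(as.integer(ceiling(lengths / resolution)), names(lengths))
    ),
    class = "bin_grid"
  )
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("<bin_grid> %d chromosome(s), resolution %g bp, %d bins total\n",
              length(x$chroms), x$resolution, sum(x$nbins)))
  invisible(x)
}

#' Number of bins per chromosome
#' @param grid A [bin_grid()].
#' @return Named integer vector.
#' @export
n_bins <- function(grid) grid$nbins

#' Bin table for a grid
#'
#' @param grid A [bin_grid()].
#' @return A tibble with columns `chrom`, `bin` (1-based within chromosome),
#'   `start`, `end` (bp, 0-based half-open; last bin may be short).
#' @export
grid_bins <- function(grid) {
  purrr::map_dfr(grid$chroms, function(ch) {
    n <- grid$nbins[[ch]]
    start <- (seq_len(n) - 1) * grid$resolution
    tibble(chrom = ch, bin = seq_len(n), start = start,
           end = pmin(start + grid$resolution, grid$lengths[[ch]]))
  })
}

#' Read a chrom.sizes table
#'
#' Two tab-separated columns: chromosome name, length in bp.
#'
#' @param path Path to the file.
#' @return Named numeric vector of lengths, usable with [bin_grid()].
#' @export
read_chrom_sizes <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "length"),
                        col_types = "cd", progress = FALSE)
  if (any(is.na(df$length))) stop_parse("non-numeric length in chrom.sizes")
  setNames(df$length, df$chrom)
}

# bp position -> bin index (1-based); positions must lie on the grid when
# `on_grid` is TRUE (bin starts), otherwise any position inside the chromosome.
pos_to_bin <- function(grid, chrom, pos, on_grid = FALSE) {
  if (!chrom %in% grid$chroms) stop_coord(paste0("unknown chromosome: ", chrom))
  if (on_grid && any(pos %% grid$resolution != 0))
    stop_coord("position not a multiple of the grid resolution")
  bin <- as.integer(pos %/% grid$resolution) + 1L
  if (any(bin < 1L | bin > grid$nbins[[chrom]]))
    stop_coord(paste0("position outside chromosome ", chrom))
  bin
}
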