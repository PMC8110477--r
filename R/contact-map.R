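#' Binned cis contact maps
#'
#' A `contact_map` holds one symmetric non-negative matrix per chromosome on a
#' shared [bin_grid()], a per-bin exclusion mask, and optionally Knight-Ruiz
#' balancing weights. Only intra-chromosomal (cis) matrices are modeled; the
#' domain analysis this package implements is strictly cis.
#'
#' `kind` records what the stored values are: raw counts (`"raw"`), balanced
#' values (`"balanced"`), or observed/expected ratios (`"oe"`).
#'
#' @param counts Named list of symmetric numeric matrices, one per chromosome.
#' @param grid The [bin_grid()] the matrices live on.
#' @param mask Optional named list of logical vectors (TRUE = excluded bin).
#' @param weights Optional named list of per-bin balancing weights (NA at
#'   masked bins).
#' @param kind One of `"raw"`, `"balanced"`, `"oe"`.
#' @return A `contact_map`.
#' @export
contact_map <- function(counts, grid, mask = NULL, weights = NULL,
                        kind = c("raw", "balanced", "oe")) {
  kind <- match.arg(kind)
  if (!all(names(counts) %in% grid$chroms))
    stop_coord("count matrices name chromosomes absent from the grid")
  for (ch in grid$chroms) {
    n <- grid$nbins[[ch]]
    m <- counts[[ch]]
    if (is.null(m)) {
      counts[[ch]] <- matrix(0, n, n)
      next
    }
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != n)
      stop_coord(paste0("matrix for ", ch, " is not ", n, "x", n))
    if (max(abs(m - t(m)), na.rm = TRUE) > 1e-8)
      stop_numeric(paste0("matrix for ", ch, " is not symmetric"))
    if (any(m < 0, na.rm = TRUE) && kind == "raw")
      stop_numeric(paste0("negative counts on ", ch))
  }
  counts <- counts[grid$chroms]
  if (is.null(mask))
    mask <- purrr::map(setNames(grid$chroms, grid$chroms),
                       ~ rep(FALSE, grid$nbins[[.x]]))
  structure(list(grid = grid, counts = counts, mask = mask[grid$chroms],
                 weights = if (is.null(weights)) NULL else weights[grid$chroms],
                 kind = kind, trans_pairs = 0L),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map:%s> %d chromosome(s), %g bp bins, total %g\n",
              x$kind, length(x$grid$chroms), x$grid$resolution,
              map_total(x)))
  invisible(x)
}

#' Current values of a contact map for one chromosome
#'
#' Returns the stored matrix with balancing weights applied (if present and
#' `kind == "raw"`) and masked rows/columns set to NA. Balanced and O/E maps
#' already store final values.
#'
#' @param map A [contact_map()].
#' @param chrom Chromosome name.
#' @return A symmetric numeric matrix with NA at masked bins.
#' @export
map_values <- function(map, chrom) {
  m <- map$counts[[chrom]]
  msk <- map$mask[[chrom]]
  if (map$kind == "raw" && !is.null(map$weights)) {
    w <- map$weights[[chrom]]
    m <- m * outer(w, w)
  }
  if (any(msk)) {
    m[msk, ] <- NA_real_
    m[, msk] <- NA_real_
  }
  m
}

#' Total contact sum of a map
#' @param map A [contact_map()].
#' @param unmasked Only count unmasked cells.
#' @return Sum over all cells of all chromosomes (each pair counted twice,
#'   matching the symmetric storage).
#' @export
map_total <- function(map, unmasked = FALSE) {
  sum(purrr::map_dbl(map$grid$chroms, function(ch) {
    m <- map$counts[[ch]]
    if (unmasked && any(map$mask[[ch]])) {
      keep <- !map$mask[[ch]]
      m <- m[keep, keep, drop = FALSE]
    }
    sum(m, na.rm = TRUE)
  }))
}

#' Load a contact map from text
#'
#' Two layouts are supported. COO text: five tab-separated columns
#' `chrom1 start1 chrom2 start2 count` (header optional), one line per
#' non-zero upper- or lower-triangle cell; bin starts must be multiples of the
#' grid resolution. Dense text: a whitespace-separated square matrix, allowed
#' only for single-chromosome grids. Trans (inter-chromosomal) entries are
#' counted and reported via the `trans_pairs` field but not stored.
#'
#' @param path File path.
#' @param grid A [bin_grid()].
#' @param format `"auto"` (default), `"coo"`, or `"dense"`.
#' @return A raw [contact_map()].
#' @export
load_contact_map <- function(path, grid, format = c("auto", "coo", "dense")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1)
    k <- length(strsplit(trimws(first), "[ \t]+")[[1]])
    format <- if (k == 5) "coo" else "dense"
  }
  if (format == "dense") {
    if (length(grid$chroms) != 1)
      stop_parse("dense matrix text requires a single-chromosome grid")
    m <- as.matrix(utils::read.table(path))
    dimnames(m) <- NULL
    return(contact_map(setNames(list((m + t(m)) / 2), grid$chroms), grid))
  }
  df <- readr::read_tsv(path,
                        col_names = c("chrom1", "start1", "chrom2", "start2", "count"),
                        col_types = "cdcdd", progress = FALSE,
                        show_col_types = FALSE)
  # tolerate a header row
  if (nrow(df) > 0 && is.na(df$start1[1]) && is.na(df$count[1])) df <- df[-1, ]
  bad <- which(!complete.cases(df))
  if (length(bad) > 0)
    stop_parse(paste0("malformed contact line at line ", bad[1]))
  off <- which(df$start1 %% grid$resolution != 0 | df$start2 %% grid$resolution != 0)
  if (length(off) > 0)
    stop_coord(paste0("bin start not on the grid at line ", off[1]))
  unknown <- which(!(df$chrom1 %in% grid$chroms) | !(df$chrom2 %in% grid$chroms))
  if (length(unknown) > 0)
    stop_coord(paste0("unknown chromosome at line ", unknown[1]))
  if (any(df$count < 0)) stop_numeric("negative contact count")
  trans <- df$chrom1 != df$chrom2
  n_trans <- sum(trans)
  df <- df[!trans, , drop = FALSE]
  counts <- purrr::map(setNames(grid$chroms, grid$chroms), function(ch) {
    n <- grid$nbins[[ch]]
    m <- matrix(0, n, n)
    sub <- df[df$chrom1 == ch, , drop = FALSE]
    if (nrow(sub) > 0) {
      i <- pos_to_bin(grid, ch, sub$start1, on_grid = TRUE)
      j <- pos_to_bin(grid, ch, sub$start2, on_grid = TRUE)
      for (k in seq_along(i)) {
        m[i[k], j[k]] <- m[i[k], j[k]] + sub$count[k]
        if (i[k] != j[k]) m[j[k], i[k]] <- m[j[k], i[k]] + sub$count[k]
      }
    }
    m
  })
  out <- contact_map(counts, grid)
  out$trans_pairs <- n_trans
  out
}

#' Write a contact map as COO text
#'
#' Upper-triangle non-zero cells (including the diagonal) as
#' `chrom1 start1 chrom2 start2 count`, the layout [load_contact_map()] reads.
#'
#' @param map A [contact_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(map, path) {
  grid <- map$grid
  rows <- purrr::map_dfr(grid$chroms, function(ch) {
    m <- map$counts[[ch]]
    idx <- which(upper.tri(m, diag = TRUE) & m != 0 & !is.na(m), arr.ind = TRUE)
    if (nrow(idx) == 0) return(tibble())
    tibble(chrom1 = ch, start1 = (idx[, 1] - 1) * grid$resolution,
           chrom2 = ch, start2 = (idx[, 2] - 1) * grid$resolution,
           count = m[idx])
  })
  readr::write_tsv(rows, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Mask low-coverage bins
#'
#' Bins whose raw marginal (row sum of counts) is below `min_marginal` are
#' masked, plus optionally bins below a per-chromosome quantile of the
#' positive marginals. Masking is idempotent: marginals are always computed on
#' the stored raw counts.
#'
#' @param map A raw [contact_map()].
#' @param min_marginal Mask bins with marginal strictly below this count.
#' @param marginal_quantile Additionally mask bins below this quantile of the
#'   positive marginals (0 disables; the pipeline default is 0.005).
#' @return The map with an updated mask (weights invalidated).
#' @export
mask_sparse_bins <- function(map, min_marginal = 1, marginal_quantile = 0) {
  if (min_marginal < 0) stop_config("min_marginal must be >= 0")
  for (ch in map$grid$chroms) {
    marg <- rowSums(map$counts[[ch]])
    msk <- marg < min_marginal
    if (marginal_quantile > 0 && any(marg > 0))
      msk <- msk | marg < q_at(marg[marg > 0], marginal_quantile)
    map$mask[[ch]] <- map$mask[[ch]] | msk
  }
  map$weights <- NULL
  map
}

#' Scale a set of maps to the smallest total
#'
#' Each map's counts are multiplied by a constant so every total equals the
#' smallest input total; within-map structure is untouched. This is the joint
#' depth normalization applied before comparing conditions.
#'
#' @param maps List of raw [contact_map()]s on identical grids.
#' @return List of scaled maps, in input order.
#' @export
normalize_to_smallest <- function(maps) {
  if (length(maps) < 2) stop_config("need >= 2 maps to normalize")
  g1 <- maps[[1]]$grid
  same <- purrr::map_lgl(maps, function(m)
    identical(m$grid$lengths, g1$lengths) && m$grid$resolution == g1$resolution)
  if (!all(same)) stop_config("maps are on different grids")
  totals <- purrr::map_dbl(maps, map_total)
  target <- min(totals)
  purrr::map2(maps, totals, function(m, tot) {
    f <- target / tot
    m$counts <- purrr::map(m$counts, ~ .x * f)
    m
  })
}
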