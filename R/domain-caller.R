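#' Multi-window TAD-separation score
#'
#' For every bin edge `e` (between bins `e` and `e+1`) and window size `w`,
#' the diamond `D(e, w)` is the balanced submatrix rows `(e-w, e]` by columns
#' `(e, e+w]`: the contacts crossing that edge within `w` bins. Its unmasked
#' mean `s_w` is z-transformed per chromosome per window, and the aggregate
#' score `S` is the mean of the per-window z-scores where defined. Minima of
#' `S` mark insulation points: candidate domain boundaries.
#'
#' A per-chromosome standard deviation of zero yields z = 0 (degenerate
#' constant chromosomes score flat, not NaN).
#'
#' @param map A balanced (or O/E) [contact_map()].
#' @param windows Sorted integer window sizes in bins, each >= 2. The default
#'   `c(2, 4, 6, 10)` corresponds to 100-500 kb at 50-kb resolution, the
#'   calling scale used for dinoTADs.
#' @return A `separation_track` tibble (`chrom`, `edge`, `pos`, `score`,
#'   `n_windows`, `interior`) with the per-window scores in the
#'   `window_scores` attribute. `interior` flags edges where every window fits
#'   inside the chromosome (the only edges eligible as boundary candidates).
#' @export
tad_separation_score <- function(map, windows = c(2L, 4L, 6L, 10L)) {
  if (map$kind == "raw") stop_config("score a balanced map, not raw counts")
  windows <- as.integer(sort(windows))
  if (any(windows < 2)) stop_config("windows must each be >= 2 bins")
  w_max <- max(windows)
  res <- map$grid$resolution
  long <- list()
  for (ch in map$grid$chroms) {
    n <- map$grid$nbins[[ch]]
    if (n <= min(windows)) {
      warn(paste0("chromosome ", ch, " shorter than the smallest window; ",
                  "empty track"))
      next
    }
    v <- map_values(map, ch)
    for (w in windows) {
      edges <- seq_len(n - 1L)
      s <- rep(NA_real_, n - 1L)
      for (e in edges) {
        if (e - w < 0 || e + w > n) next
        d <- v[(e - w + 1L):e, (e + 1L):(e + w), drop = FALSE]
        if (all(is.na(d))) next
        s[e] <- mean(d, na.rm = TRUE)
      }
      mu <- mean(s, na.rm = TRUE)
      sg <- sd(s, na.rm = TRUE)
      z <- if (is.na(sg) || sg == 0) ifelse(is.na(s), NA_real_, 0) else (s - mu) / sg
      long[[paste(ch, w)]] <- tibble(chrom = ch, edge = edges,
                                     window = w, s = s, z = z)
    }
  }
  ws <- bind_rows(long)
  if (nrow(ws) == 0) {
    out <- tibble(chrom = character(), edge = integer(), pos = numeric(),
                  score = numeric(), n_windows = integer(), interior = logical())
  } else {
    out <- ws |>
      group_by(.data$chrom, .data$edge) |>
      summarise(score = if (all(is.na(.data$z))) NA_real_
                        else mean(.data$z, na.rm = TRUE),
                n_windows = sum(!is.na(.data$z)), .groups = "drop") |>
      mutate(pos = .data$edge * res,
             interior = purrr::map2_lgl(.data$chrom, .data$edge, function(ch, e)
               e - w_max >= 0 && e + w_max <= map$grid$nbins[[ch]])) |>
      select("chrom", "edge", "pos", "score", "n_windows", "interior") |>
      arrange(.data$chrom, .data$edge)
  }
  structure(out, windows = windows, resolution = res,
            window_scores = ws, class = c("separation_track", class(out)))
}

# unmasked cells of the window-w diamond at edge e (used by the
# boundary significance test)
diamond_cells <- function(v, e, w) {
  n <- nrow(v)
  if (e - w < 0 || e + w > n) return(numeric(0))
  d <- v[(e - w + 1L):e, (e + 1L):(e + w), drop = FALSE]
  d[!is.na(d)]
}

# pooled diamonds across all windows at edge e, and the pooled flanking
# reference diamonds at e +- w per window (which never cross the edge, so
# they sample intra-domain territory at matched distances)
pooled_diamonds <- function(v, e, windows) {
  here <- unlist(purrr::map(windows, ~ diamond_cells(v, e, .x)))
  ref <- unlist(purrr::map(windows, function(w)
    c(diamond_cells(v, e - w, w), diamond_cells(v, e + w, w))))
  list(here = here, ref = ref)
}

#' Call domain boundaries from a separation track
#'
#' Candidates are strict local minima of the aggregate score `S` among
#' interior edges whose prominence (the smaller of the left/right maximum of
#' `S` within the largest window, minus `S` at the minimum) is at least
#' `delta`. Each candidate receives a p-value from a one-sided Wilcoxon
#' rank-sum test of its diamond values (pooled over all window sizes)
#' against the pooled flanking diamonds one window away on either side at
#' each size -- flanking diamonds never cross the candidate edge, so they
#' sample intra-domain territory at matched distances (insulation should
#' make the boundary diamonds stochastically smaller).
#' Benjamini-Hochberg correction is applied over all candidates genome-wide
#' and calls with `q <= fdr` are retained. Finally, among calls closer than
#' `min_boundary_distance` the one with the lower score wins (ties go to the
#' lower coordinate), which suppresses twin minima and the weaker minima at
#' intra-domain (divergent, sub-domain) junctions.
#'
#' @param track A [tad_separation_score()] result.
#' @param map The balanced map the track was computed from.
#' @param delta Minimum prominence of a minimum (score units; default 0.01).
#' @param fdr Benjamini-Hochberg threshold (default 0.05).
#' @param min_boundary_distance Minimum separation in bp; default the largest
#'   window.
#' @return A `boundary_set` tibble (`chrom`, `edge`, `pos`, `score`,
#'   `prominence`, `p_value`, `q_value`), sorted by position.
#' @export
call_boundaries <- function(track, map, delta = 0.01, fdr = 0.05,
                            min_boundary_distance = NULL) {
  if (delta < 0) stop_config("delta must be >= 0")
  if (fdr <= 0 || fdr >= 1) stop_config("fdr must be in (0, 1)")
  windows <- attr(track, "windows")
  w_max <- max(windows)
  res <- map$grid$resolution
  if (is.null(min_boundary_distance)) min_boundary_distance <- w_max * res
  empty <- tibble(chrom = character(), edge = integer(), pos = numeric(),
                  score = numeric(), prominence = numeric(),
                  p_value = numeric(), q_value = numeric())
  if (nrow(track) == 0)
    return(structure(empty, class = c("boundary_set", class(empty))))

  cands <- list()
  for (ch in unique(track$chrom)) {
    tr <- track[track$chrom == ch, ]
    S <- tr$score
    n_e <- nrow(tr)
    v <- map_values(map, ch)
    for (k in seq_len(n_e)) {
      if (!tr$interior[k] || is.na(S[k])) next
      if (k == 1 || k == n_e) next
      if (is.na(S[k - 1]) || is.na(S[k + 1])) next
      if (!(S[k] < S[k - 1] && S[k] < S[k + 1])) next      # strict local minimum
      li <- max(1, k - w_max):(k - 1)
      ri <- (k + 1):min(n_e, k + w_max)
      lmax <- suppressWarnings(max(S[li], na.rm = TRUE))
      rmax <- suppressWarnings(max(S[ri], na.rm = TRUE))
      if (!is.finite(lmax) || !is.finite(rmax)) next
      prom <- min(lmax, rmax) - S[k]
      if (prom < delta) next
      e <- tr$edge[k]
      pd <- pooled_diamonds(v, e, windows)
      p <- if (length(pd$here) == 0 || length(pd$ref) == 0) NA_real_
           else suppressWarnings(
             wilcox.test(pd$here, pd$ref, alternative = "less",
                         exact = FALSE)$p.value)
      cands[[paste(ch, e)]] <- tibble(chrom = ch, edge = e, pos = e * res,
                                      score = S[k], prominence = prom,
                                      p_value = p)
    }
  }
  cands <- bind_rows(cands)
  if (nrow(cands) == 0)
    return(structure(empty, class = c("boundary_set", class(empty))))
  cands$q_value <- p.adjust(cands$p_value, method = "BH")
  kept <- cands |> filter(!is.na(.data$q_value), .data$q_value <= fdr)
  # greedy pruning: lowest score first, ties at lower coordinate
  kept <- kept |> arrange(.data$score, .data$chrom, .data$pos)
  sel <- rep(TRUE, nrow(kept))
  for (i in seq_len(nrow(kept))) {
    if (!sel[i]) next
    if (i < nrow(kept)) {
      later <- (i + 1):nrow(kept)
      clash <- kept$chrom[later] == kept$chrom[i] &
        abs(kept$pos[later] - kept$pos[i]) < min_boundary_distance
      sel[later][clash] <- FALSE
    }
  }
  out <- kept[sel, ] |> arrange(.data$chrom, .data$pos)
  structure(out, class = c("boundary_set", class(out)))
}

#' Assemble domains from boundaries
#'
#' Domains are the half-open intervals between consecutive boundaries on each
#' chromosome, with the chromosome start prepended and the chromosome end
#' appended; they tile the genome exactly.
#'
#' @param boundaries A `boundary_set` (or any tibble with `chrom` and `pos`).
#' @param grid The [bin_grid()].
#' @return A tibble (`chrom`, `start`, `end`) of domains.
#' @export
assemble_domains <- function(boundaries, grid) {
  purrr::map_dfr(grid$chroms, function(ch) {
    pos <- sort(boundaries$pos[boundaries$chrom == ch])
    L <- grid$lengths[[ch]]
    if (any(pos <= 0 | pos >= L))
      stop_coord(paste0("boundary outside chromosome ", ch))
    if (any(pos %% grid$resolution != 0))
      stop_coord(paste0("boundary off the bin grid on ", ch))
    edges <- c(0, pos, L)
    tibble(chrom = ch, start = head(edges, -1), end = tail(edges, -1))
  })
}

#' Domain-scale summary statistics
#'
#' Size percentiles, per-chromosome domain counts, and the correlation
#' between domain count and chromosome length (the scaling the dinoTAD
#' analysis reports: longer chromosomes carry proportionally more domains).
#' Correlations are flagged undefined with fewer than 3 chromosomes.
#'
#' @param domains A domain tibble from [assemble_domains()].
#' @param grid The [bin_grid()].
#' @return A `domain_stats` object; see [tidy.domain_stats()] and
#'   [glance.domain_stats()].
#' @export
domain_stats <- function(domains, grid) {
  if (is.null(domains) || nrow(domains) == 0) stop_config("no domains")
  sizes <- domains$end - domains$start
  pct <- q_at(sizes, c(0.05, 0.25, 0.5, 0.75, 0.95))
  per_chrom <- tibble(chrom = grid$chroms,
                      length = unname(grid$lengths[grid$chroms])) |>
    left_join(dplyr::count(domains, .data$chrom, name = "n_domains"),
              by = "chrom") |>
    mutate(n_domains = tidyr::replace_na(.data$n_domains, 0L))
  defined <- nrow(per_chrom) >= 3
  pearson <- spearman <- NA_real_
  if (defined) {
    pearson <- cor(per_chrom$n_domains, per_chrom$length, method = "pearson")
    spearman <- cor(per_chrom$n_domains, per_chrom$length, method = "spearman")
  }
  structure(list(
    n_domains = nrow(domains),
    size_percentiles = setNames(pct, c("p05", "p25", "p50", "p75", "p95")),
    per_chrom = per_chrom,
    cor_pearson = pearson, cor_spearman = spearman,
    cor_defined = defined
  ), class = "domain_stats")
}

#' @export
print.domain_stats <- function(x, ...) {
  cat(sprintf("<domain_stats> %d domains; median size %g bp; count-length r = %s\n",
              x$n_domains, x$size_percentiles[["p50"]],
              if (x$cor_defined) sprintf("%.3f", x$cor_pearson) else "undefined"))
  invisible(x)
}

#' @describeIn domain_stats Per-chromosome counts as a tibble.
#' @param x A `domain_stats` object.
#' @param ... Unused.
#' @export
tidy.domain_stats <- function(x, ...) x$per_chrom

#' @describeIn domain_stats One-row summary (counts, size percentiles,
#'   correlations).
#' @export
glance.domain_stats <- function(x, ...) {
  tibble(n_domains = x$n_domains,
         size_p05 = x$size_percentiles[["p05"]],
         size_p25 = x$size_percentiles[["p25"]],
         size_p50 = x$size_percentiles[["p50"]],
         size_p75 = x$size_percentiles[["p75"]],
         size_p95 = x$size_percentiles[["p95"]],
         cor_pearson = x$cor_pearson, cor_spearman = x$cor_spearman,
         cor_defined = x$cor_defined)
}

#' Write boundaries as BED6
#'
#' Columns: chrom, start, end (one bin edge, zero-width interval widened to
#' one bp), name = q-value, score = S, strand = ".".
#'
#' @param boundaries A `boundary_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_boundaries_bed <- function(boundaries, path) {
  df <- tibble(chrom = boundaries$chrom,
               start = as.integer(boundaries$pos),
               end = as.integer(boundaries$pos) + 1L,
               name = signif(boundaries$q_value, 4),
               score = signif(boundaries$score, 4),
               strand = ".")
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write domains as BED3
#' @param domains Domain tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domains_bed <- function(domains, path) {
  readr::write_tsv(domains[, c("chrom", "start", "end")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write a separation track as bedGraph
#' @param track A `separation_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track_bedgraph <- function(track, path) {
  res <- attr(track, "resolution")
  df <- track |>
    filter(!is.na(.data$score)) |>
    mutate(start = .data$pos - res / 2, end = .data$pos + res / 2) |>
    select("chrom", "start", "end", "score")
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
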