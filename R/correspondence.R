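#' Match boundaries to gene-array junctions
#'
#' Each called boundary is matched to the nearest junction of an allowed type
#' on its chromosome within `max_dist` (ties go to the lower coordinate). The
#' central correspondence of the dinoTAD analysis is that domain boundaries
#' fall at *convergent* junctions.
#'
#' @param boundaries A `boundary_set` (or tibble with `chrom`, `pos`).
#' @param junctions A junction tibble from [classify_junctions()].
#' @param max_dist Maximum matching distance in bp.
#' @param types Junction types eligible for matching
#'   (default `"convergent"`).
#' @return A `junction_match` tibble, one row per boundary: `chrom`, `pos`,
#'   `junction_pos`, `junction_type`, `distance` (signed,
#'   junction - boundary), `matched`; the matched fraction is in the
#'   `matched_fraction` attribute (see [glance.junction_match()]).
#' @export
match_boundaries_to_junctions <- function(boundaries, junctions,
                                          max_dist = 5e4,
                                          types = "convergent") {
  if (max_dist < 0) stop_config("max_dist must be >= 0")
  if (is.null(junctions) || nrow(junctions) == 0)
    stop_config("empty junction list")
  js <- filter(junctions, .data$type %in% types)
  rows <- purrr::map_dfr(seq_len(nrow(boundaries)), function(i) {
    b <- boundaries[i, ]
    cand <- js[js$chrom == b$chrom, ]
    if (nrow(cand) == 0)
      return(tibble(chrom = b$chrom, pos = b$pos, junction_pos = NA_real_,
                    junction_type = NA_character_, distance = NA_real_,
                    matched = FALSE))
    d <- cand$pos - b$pos
    best <- order(abs(d), cand$pos)[1]
    ok <- abs(d[best]) <= max_dist
    tibble(chrom = b$chrom, pos = b$pos,
           junction_pos = if (ok) cand$pos[best] else NA_real_,
           junction_type = if (ok) cand$type[best] else NA_character_,
           distance = if (ok) d[best] else NA_real_, matched = ok)
  })
  structure(rows,
            matched_fraction = if (nrow(rows) > 0) mean(rows$matched) else NA_real_,
            max_dist = max_dist, types = types,
            class = c("junction_match", class(rows)))
}

#' @describeIn match_boundaries_to_junctions One-row summary of a match
#'   table.
#' @param x A `junction_match`.
#' @param ... Unused.
#' @export
glance.junction_match <- function(x, ...) {
  tibble(n_boundaries = nrow(x), n_matched = sum(x$matched),
         matched_fraction = attr(x, "matched_fraction"),
         max_dist = attr(x, "max_dist"))
}

#' Permutation test for boundary-junction enrichment
#'
#' Statistic: the fraction of boundaries matching an allowed junction within
#' `max_dist`. Null: the whole boundary set is circularly shifted within each
#' chromosome by a random offset, preserving boundary spacing and chromosome
#' structure (a uniform resampling null would overstate significance for
#' regularly spaced boundaries). Offsets within `2 * max_dist` of the
#' identity (mod chromosome length) are excluded: they reproduce the observed
#' configuration rather than an independent placement.
#' `p = (1 + #{null >= observed}) / (1 + n_perm)`.
#'
#' @inheritParams match_boundaries_to_junctions
#' @param grid The [bin_grid()] (chromosome lengths for the circular shift).
#' @param n_perm Number of permutations (>= 100; default 999).
#' @param seed Seed; identical seeds give identical null distributions.
#' @return An `enrichment_test` object (observed statistic, null vector,
#'   p-value).
#' @export
junction_enrichment_test <- function(boundaries, junctions, grid,
                                     max_dist = 5e4, types = "convergent",
                                     n_perm = 999, seed = 1) {
  if (n_perm < 100) stop_config("n_perm must be >= 100")
  if (nrow(boundaries) == 0 || nrow(junctions) == 0)
    stop_config("empty boundaries or junctions")
  js <- filter(junctions, .data$type %in% types)
  frac_matched <- function(bpos_by_chrom) {
    tot <- 0L; hit <- 0L
    for (ch in names(bpos_by_chrom)) {
      bp <- bpos_by_chrom[[ch]]
      jp <- sort(js$pos[js$chrom == ch])
      tot <- tot + length(bp)
      if (length(jp) == 0 || length(bp) == 0) next
      lo <- findInterval(bp, jp)
      d_lo <- ifelse(lo >= 1, bp - jp[pmax(lo, 1)], Inf)
      d_hi <- ifelse(lo < length(jp), jp[pmin(lo + 1, length(jp))] - bp, Inf)
      hit <- hit + sum(pmin(d_lo, d_hi) <= max_dist)
    }
    if (tot == 0) return(NA_real_)
    hit / tot
  }
  bpos <- split(boundaries$pos, boundaries$chrom)
  obs <- frac_matched(bpos)
  null <- withr::with_seed(seed, {
    purrr::map_dbl(seq_len(n_perm), function(i) {
      shifted <- purrr::imap(bpos, function(p, ch) {
        L <- grid$lengths[[ch]]
        (p + runif(1, 2 * max_dist, L - 2 * max_dist)) %% L
      })
      frac_matched(shifted)
    })
  })
  p <- (1 + sum(null >= obs)) / (1 + n_perm)
  structure(list(observed = obs, null = null, p_value = p, n_perm = n_perm,
                 max_dist = max_dist, types = types, seed = seed),
            class = "enrichment_test")
}

#' @export
print.enrichment_test <- function(x, ...) {
  cat(sprintf("<enrichment_test> matched fraction %.3f vs null mean %.3f; p = %.4g (%d perms)\n",
              x$observed, mean(x$null), x$p_value, x$n_perm))
  invisible(x)
}

#' @describeIn junction_enrichment_test One-row summary.
#' @param x An `enrichment_test`.
#' @param ... Unused.
#' @export
glance.enrichment_test <- function(x, ...) {
  tibble(observed = x$observed, null_mean = mean(x$null),
         null_q95 = q_at(x$null, 0.95), p_value = x$p_value,
         n_perm = x$n_perm)
}

#' Average Hi-C signal around boundaries (2-D metaplot)
#'
#' Element-wise mean of the O/E submatrices of size `2*flank` by `2*flank`
#' centered on each boundary edge; boundaries whose window crosses a
#' chromosome end are dropped and counted. Insulated boundaries show a
#' depleted cross-boundary quadrant against enriched intra-domain corners.
#'
#' @param oe An O/E [contact_map()] (see [observed_over_expected()]).
#' @param boundaries A `boundary_set`.
#' @param flank Half-width in bins (default 10, i.e. +-500 kb at 50 kb).
#' @return A `hic_metaplot`: list with `profile` (mean matrix), `n` (per-cell
#'   contributing counts), `offsets` (bins), `n_boundaries`, `n_dropped`.
#' @export
hic_boundary_metaplot <- function(oe, boundaries, flank = 10) {
  if (flank < 1) stop_config("flank must be >= 1")
  sz <- 2 * flank
  acc <- matrix(0, sz, sz)
  nmat <- matrix(0, sz, sz)
  used <- 0L; dropped <- 0L
  for (ch in unique(boundaries$chrom)) {
    v <- map_values(oe, ch)
    n <- nrow(v)
    for (e in boundaries$edge[boundaries$chrom == ch]) {
      if (e - flank < 0 || e + flank > n) { dropped <- dropped + 1L; next }
      sub <- v[(e - flank + 1L):(e + flank), (e - flank + 1L):(e + flank)]
      ok <- !is.na(sub)
      acc[ok] <- acc[ok] + sub[ok]
      nmat <- nmat + ok
      used <- used + 1L
    }
  }
  if (used == 0) stop_config("no usable boundary for the metaplot")
  structure(list(profile = ifelse(nmat > 0, acc / nmat, NA_real_), n = nmat,
                 offsets = seq(-flank + 1L, flank), n_boundaries = used,
                 n_dropped = dropped, flank = flank),
            class = "hic_metaplot")
}

#' @export
print.hic_metaplot <- function(x, ...) {
  cat(sprintf("<hic_metaplot> %d boundaries (+%d dropped), flank %d bins\n",
              x$n_boundaries, x$n_dropped, x$flank))
  invisible(x)
}

#' @describeIn hic_boundary_metaplot Long-format tibble
#'   (`offset_row`, `offset_col`, `mean_oe`, `n`).
#' @param x A `hic_metaplot`.
#' @param ... Unused.
#' @export
tidy.hic_metaplot <- function(x, ...) {
  sz <- nrow(x$profile)
  tibble(offset_row = rep(x$offsets, sz),
         offset_col = rep(x$offsets, each = sz),
         mean_oe = as.vector(x$profile), n = as.vector(x$n))
}

#' Average strand-track signal around boundaries (1-D metaplot)
#'
#' Per-offset mean of forward and reverse track values across boundaries,
#' in `bin`-sized steps from `-flank` to `+flank`; boundaries whose window
#' crosses a chromosome end are dropped. At convergent-junction boundaries
#' the forward strand dominates upstream and the reverse strand downstream.
#'
#' @param tracks A [build_strand_tracks()] result.
#' @param boundaries A `boundary_set`.
#' @param flank Half-width in bp (must be a multiple of `bin`).
#' @param bin Averaging bin in bp.
#' @return A tibble (`offset`, `forward`, `reverse`, `n`), `offset` the bin
#'   center relative to the boundary.
#' @export
rna_boundary_metaplot <- function(tracks, boundaries, flank = 5e5, bin = 5e4) {
  if (flank %% bin != 0) stop_config("flank must be a multiple of bin")
  offs <- seq(-flank, flank - bin, by = bin)
  accF <- accR <- rep(0, length(offs))
  nn <- rep(0L, length(offs))
  used <- 0L
  for (i in seq_len(nrow(boundaries))) {
    ch <- boundaries$chrom[i]; p <- boundaries$pos[i]
    L <- tracks$lengths[[ch]]
    if (is.null(L) || is.na(L) || p - flank < 0 || p + flank > L) next
    st <- p + offs
    vf <- IRanges::viewMeans(IRanges::Views(tracks$forward[[ch]], st + 1, st + bin))
    vr <- IRanges::viewMeans(IRanges::Views(tracks$reverse[[ch]], st + 1, st + bin))
    accF <- accF + vf; accR <- accR + vr; nn <- nn + 1L
    used <- used + 1L
  }
  if (used == 0) stop_config("no usable boundary for the metaplot")
  tibble(offset = offs + bin / 2, forward = accF / nn, reverse = accR / nn,
         n = nn)
}

#' Boundary strength: intra/inter contact ratio
#'
#' For each boundary edge and window `w`, `I` is the mean O/E of the boundary
#' diamond (contacts crossing the edge within `w` bins) and `A` the mean O/E
#' of the two flanking intra-domain triangles (off-diagonal cells within `w`
#' bins on either side). `strength = A / I`: 1 on structureless maps, > 1 at
#' insulated boundaries, decreasing as domains decompact.
#'
#' @param oe An O/E [contact_map()].
#' @param boundaries A `boundary_set`.
#' @param window Window in bins (default 10).
#' @return A tibble, one row per boundary: `chrom`, `pos`, `intra`, `inter`,
#'   `strength` (NA where the window does not fit).
#' @export
boundary_strength <- function(oe, boundaries, window = 10) {
  purrr::map_dfr(seq_len(nrow(boundaries)), function(i) {
    ch <- boundaries$chrom[i]
    e <- boundaries$edge[i]
    v <- map_values(oe, ch)
    n <- nrow(v)
    if (e - window < 0 || e + window > n)
      return(tibble(chrom = ch, pos = boundaries$pos[i], intra = NA_real_,
                    inter = NA_real_, strength = NA_real_))
    dia <- v[(e - window + 1L):e, (e + 1L):(e + window), drop = FALSE]
    left <- v[(e - window + 1L):e, (e - window + 1L):e, drop = FALSE]
    right <- v[(e + 1L):(e + window), (e + 1L):(e + window), drop = FALSE]
    tri <- c(left[upper.tri(left)], right[upper.tri(right)])
    A <- mean(tri, na.rm = TRUE)
    I <- mean(dia, na.rm = TRUE)
    tibble(chrom = ch, pos = boundaries$pos[i], intra = A, inter = I,
           strength = A / I)
  })
}

#' Compare boundary insulation across conditions
#'
#' Implements the decompaction readout for transcription-inhibition series:
#' maps are jointly depth-scaled ([normalize_to_smallest()]), balanced and
#' O/E-transformed, and [boundary_strength()] is evaluated at the *control*
#' boundaries in every condition, so insulation loss is measured at common
#' positions. The dose trend is Spearman's rank correlation between dose rank
#' and strength over all (boundary, condition) paired observations; its
#' one-sided (decreasing) p-value comes from permuting condition labels
#' independently within each boundary's paired strengths and recomputing the
#' trend statistic, which preserves between-boundary strength differences
#' under the null.
#'
#' @param series A tibble with columns `condition`, `dose_rank` and a `map`
#'   list-column of raw [contact_map()]s (see [simulate_condition_series()]);
#'   O/E maps are accepted as-is.
#' @param boundaries Boundaries called on the control (lowest dose) map.
#' @param window Strength window in bins.
#' @param n_perm Trend permutations (default 9999).
#' @param seed Seed for the permutation null.
#' @return A `condition_trend` object; see [tidy.condition_trend()] /
#'   [glance.condition_trend()].
#' @export
compare_conditions <- function(series, boundaries, window = 10,
                               n_perm = 9999, seed = 1) {
  if (nrow(series) < 2) stop_config("need >= 2 conditions")
  maps <- series$map
  if (all(purrr::map_chr(maps, "kind") == "raw")) {
    maps <- normalize_to_smallest(maps)
    maps <- purrr::map(maps, function(m)
      observed_over_expected(balance_map(m)))
  } else if (!all(purrr::map_chr(maps, "kind") == "oe")) {
    stop_config("series maps must be all raw or all O/E")
  }
  S <- purrr::map(maps, ~ boundary_strength(.x, boundaries, window)$strength)
  smat <- do.call(cbind, S)                # boundaries x conditions
  keep <- rowSums(is.na(smat)) == 0
  smat <- smat[keep, , drop = FALSE]
  if (nrow(smat) == 0) stop_config("no boundary with defined strength everywhere")
  dose <- series$dose_rank
  means <- colMeans(smat)
  dose_vec <- rep(dose, each = nrow(smat))
  rho_of <- function(m) {
    r <- suppressWarnings(cor(dose_vec, as.vector(m), method = "spearman"))
    if (is.na(r)) 0 else r                 # constant strengths: no trend
  }
  rho <- rho_of(smat)
  null <- withr::with_seed(seed, {
    purrr::map_dbl(seq_len(n_perm), function(i) {
      perm <- t(apply(smat, 1, sample))
      rho_of(perm)
    })
  })
  p <- (1 + sum(null <= rho)) / (1 + n_perm)   # one-sided: decreasing trend
  per_boundary <- tibble(
    chrom = boundaries$chrom[keep], pos = boundaries$pos[keep]) |>
    dplyr::bind_cols(as_tibble(smat, .name_repair = ~ as.character(series$condition))) |>
    mutate(delta_last = smat[, which.max(dose)] - smat[, which.min(dose)])
  structure(list(
    summary = tibble(condition = series$condition, dose_rank = dose,
                     mean_strength = means, n_boundaries = nrow(smat)),
    per_boundary = per_boundary, rho = rho, p_value = p, n_perm = n_perm,
    window = window
  ), class = "condition_trend")
}

#' @export
print.condition_trend <- function(x, ...) {
  cat(sprintf("<condition_trend> %d conditions; rho = %.3f, one-sided p = %.4g\n",
              nrow(x$summary), x$rho, x$p_value))
  print(x$summary)
  invisible(x)
}

#' @describeIn compare_conditions Per-condition mean strengths.
#' @param x A `condition_trend`.
#' @param ... Unused.
#' @export
tidy.condition_trend <- function(x, ...) x$summary

#' @describeIn compare_conditions One-row summary (rho, p, sizes).
#' @export
glance.condition_trend <- function(x, ...) {
  tibble(rho = x$rho, p_value = x$p_value, n_perm = x$n_perm,
         n_conditions = nrow(x$summary),
         n_boundaries = x$summary$n_boundaries[1])
}
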