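#' Segment strand tracks into gene arrays
#'
#' A gene array is a maximal run of one strand's transcription: per strand,
#' bases with signal `>= min_signal` are taken, internal zero gaps up to
#' `gap_tolerance` are bridged, and runs shorter than `min_array_length` are
#' dropped. Where a `+` and a `-` run overlap, the overlap goes to the strand
#' with the greater integrated signal there and the other run is truncated.
#'
#' @param tracks A [build_strand_tracks()] result.
#' @param min_array_length Minimum array span in bp (default 100 kb).
#' @param gap_tolerance Maximum internal signal gap bridged, bp (default 25 kb).
#' @param min_signal Minimum summed TPM counted as transcribed (default 0.1).
#' @return A `gene_array` tibble (`chrom`, `start`, `end`, `strand`), sorted
#'   and non-overlapping.
#' @export
segment_gene_arrays <- function(tracks, min_array_length = 1e5,
                                gap_tolerance = 2.5e4, min_signal = 0.1) {
  if (min_array_length <= 0 || gap_tolerance <= 0 || min_signal <= 0)
    stop_config("segmentation parameters must be > 0")
  runs_for <- function(rl) {
    IRanges::reduce(
      IRanges::slice(rl, lower = min_signal, rangesOnly = TRUE),
      min.gapwidth = gap_tolerance + 1)
  }
  out <- list()
  for (ch in names(tracks$lengths)) {
    fr <- runs_for(tracks$forward[[ch]])
    rr <- runs_for(tracks$reverse[[ch]])
    ov <- IRanges::findOverlaps(fr, rr)
    if (length(ov) > 0) {
      isect <- IRanges::pintersect(fr[S4Vectors::queryHits(ov)],
                                   rr[S4Vectors::subjectHits(ov)])
      for (k in seq_along(ov)) {
        reg <- isect[k]
        sf <- sum(as.numeric(IRanges::Views(tracks$forward[[ch]], reg)[[1]]))
        sr <- sum(as.numeric(IRanges::Views(tracks$reverse[[ch]], reg)[[1]]))
        if (sf >= sr) {
          rr <- IRanges::setdiff(rr, reg)
        } else {
          fr <- IRanges::setdiff(fr, reg)
        }
      }
    }
    mk <- function(ir, st) {
      ir <- ir[IRanges::width(ir) >= min_array_length]
      if (length(ir) == 0) return(NULL)
      tibble(chrom = ch, start = IRanges::start(ir) - 1,
             end = IRanges::end(ir), strand = st)
    }
    out[[ch]] <- bind_rows(mk(fr, "+"), mk(rr, "-"))
  }
  res <- bind_rows(out)
  if (nrow(res) == 0)
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  strand = character()))
  arrange(res, .data$chrom, .data$start)
}

#' Classify junctions between consecutive gene arrays
#'
#' One junction per consecutive array pair on a chromosome, at the midpoint
#' of the inter-array gap: `+` then `-` is convergent (transcription pointing
#' together -- the configuration at dinoTAD boundaries), `-` then `+` is
#' divergent (the configuration interior to a domain), same strands are
#' tandem.
#'
#' @param arrays A sorted, non-overlapping `gene_array` tibble.
#' @return A tibble (`chrom`, `pos`, `type`, `upstream_strand`,
#'   `downstream_strand`).
#' @export
classify_junctions <- function(arrays) {
  if (nrow(arrays) > 1) {
    byc <- split(seq_len(nrow(arrays)), arrays$chrom)
    for (idx in byc) {
      a <- arrays[idx, ]
      if (is.unsorted(a$start) || any(a$start[-1] < a$end[-nrow(a)]))
        stop_coord("arrays must be sorted and non-overlapping")
    }
  }
  arrays |>
    arrange(.data$chrom, .data$start) |>
    group_by(.data$chrom) |>
    dplyr::reframe(pos = (head(.data$end, -1) + tail(.data$start, -1)) / 2,
                   upstream_strand = head(.data$strand, -1),
                   downstream_strand = tail(.data$strand, -1)) |>
    mutate(type = dplyr::case_when(
      .data$upstream_strand == "+" & .data$downstream_strand == "-" ~ "convergent",
      .data$upstream_strand == "-" & .data$downstream_strand == "+" ~ "divergent",
      .data$upstream_strand == "+" ~ "tandem_forward",
      TRUE ~ "tandem_reverse")) |>
    select("chrom", "pos", "type", "upstream_strand", "downstream_strand")
}

#' Write gene arrays as BED6
#' @param arrays A `gene_array` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_arrays_bed <- function(arrays, path) {
  df <- tibble(chrom = arrays$chrom, start = as.integer(arrays$start),
               end = as.integer(arrays$end), name = "array", score = 0,
               strand = arrays$strand)
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write junctions as BED6 (name = type)
#' @param junctions A junction tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_junctions_bed <- function(junctions, path) {
  df <- tibble(chrom = junctions$chrom, start = as.integer(junctions$pos),
               end = as.integer(junctions$pos) + 1L, name = junctions$type,
               score = 0, strand = ".")
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Unspliced-read (nascent RNA) fraction
#'
#' The proxy for ongoing transcription: a read is *intronic* if its alignment
#' contains no intron-spanning gap and overlaps an annotated intron by at
#' least `min_intron_overlap` bp; the fraction is intronic over
#' (intronic + exonic-assigned), where reads touching no transcript are
#' excluded from the denominator.
#'
#' @param reads A read tibble, one row per aligned block: `read_id`, `chrom`,
#'   `start`, `end`, `spliced` (per-read logical: alignment has an
#'   intron-spanning gap).
#' @param transcripts A transcript tibble (annotation source for introns and
#'   spans).
#' @param min_intron_overlap Minimum intron overlap in bp (default 10).
#' @return A one-row tibble: `fraction`, `n_intronic`, `n_exonic`,
#'   `n_unassigned`, `n_reads`.
#' @export
unspliced_fraction <- function(reads, transcripts, min_intron_overlap = 10) {
  if (is.null(reads) || nrow(reads) == 0) stop_config("empty read set")
  blocks <- GenomicRanges::GRanges(reads$chrom,
                                   IRanges::IRanges(reads$start + 1, reads$end))
  ex <- tidyr::unnest(select(transcripts, "transcript_id", "chrom", "exons"),
                      "exons")
  spans <- ex |>
    group_by(.data$transcript_id, .data$chrom) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  span_gr <- GenomicRanges::GRanges(spans$chrom,
                                    IRanges::IRanges(spans$start + 1, spans$end))
  introns <- purrr::map2_dfr(transcripts$chrom, transcripts$exons,
                             function(ch, e) mutate(intron_intervals(e), chrom = ch))
  intron_gr <- if (nrow(introns) > 0)
    GenomicRanges::GRanges(introns$chrom,
                           IRanges::IRanges(introns$start + 1, introns$end))
  else GenomicRanges::GRanges()

  touches <- GenomicRanges::countOverlaps(blocks, span_gr) > 0
  iov <- GenomicRanges::findOverlaps(blocks, intron_gr, minoverlap = min_intron_overlap)
  hits_intron <- seq_along(blocks) %in% S4Vectors::queryHits(iov)

  per_read <- tibble(read_id = reads$read_id, spliced = reads$spliced,
                     touches = touches, hits_intron = hits_intron) |>
    group_by(.data$read_id) |>
    summarise(spliced = dplyr::first(.data$spliced),
              touches = any(.data$touches),
              hits_intron = any(.data$hits_intron), .groups = "drop")
  intronic <- !per_read$spliced & per_read$hits_intron
  assigned <- per_read$touches
  n_intronic <- sum(intronic & assigned)
  n_exonic <- sum(assigned & !(intronic))
  tibble(fraction = n_intronic / (n_intronic + n_exonic),
         n_intronic = n_intronic, n_exonic = n_exonic,
         n_unassigned = sum(!assigned), n_reads = nrow(per_read))
}
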