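#' Transcript tables
#'
#' Transcripts are tibbles with one row per transcript: `transcript_id`,
#' `chrom`, `strand` (`"+"`, `"-"` or `"*"` for unknown), `tpm`, optionally
#' `orf_aa`, and an `exons` list-column of tibbles (`start`, `end`; 0-based
#' half-open, sorted, non-overlapping). Introns are the gaps between
#' consecutive exons.
#'
#' @param transcript_id,chrom,strand,tpm Per-transcript vectors.
#' @param exons List of exon tibbles.
#' @return A transcript tibble.
#' @export
transcript_table <- function(transcript_id, chrom, exons, strand = "*",
                             tpm = NA_real_) {
  tb <- tibble(transcript_id = transcript_id, chrom = chrom,
               strand = strand, tpm = tpm, exons = exons)
  bad <- purrr::map_lgl(tb$exons, function(e)
    nrow(e) < 1 || is.unsorted(e$start) || any(e$end <= e$start) ||
      (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)])))
  if (any(bad))
    stop_coord(paste0("malformed exons for transcript(s): ",
                      paste(head(tb$transcript_id[bad], 5), collapse = ", ")))
  tb
}

# intron tibble (start, end) for one exon table
intron_intervals <- function(exons) {
  if (nrow(exons) < 2) return(tibble(start = numeric(0), end = numeric(0)))
  tibble(start = exons$end[-nrow(exons)], end = exons$start[-1])
}

#' Infer transcript strand from splice-junction orientation
#'
#' Unstranded assemblies carry no orientation, but splice junctions do: an
#' intron whose genomic ends read `GT..AG` on the forward strand votes `+`,
#' one reading `CT..AC` (the reverse complement) votes `-`; non-canonical
#' ends abstain. Under `mode = "strict"` (default) any conflict between
#' introns yields `"*"` (unknown); under `"majority"` the majority vote wins,
#' with ties unknown. Single-exon transcripts are always unknown.
#'
#' @param transcripts A transcript tibble (see [transcript_table()]).
#' @param genome A [Biostrings::DNAStringSet] covering all introns.
#' @param mode `"strict"` or `"majority"`.
#' @return The tibble with the `strand` column filled in.
#' @export
infer_transcript_strand <- function(transcripts, genome,
                                    mode = c("strict", "majority")) {
  mode <- match.arg(mode)
  strands <- purrr::map2_chr(transcripts$chrom, transcripts$exons, function(ch, ex) {
    introns <- intron_intervals(ex)
    if (nrow(introns) == 0) return("*")
    if (any(introns$end - introns$start < 4))
      abort("intron shorter than 4 nt", class = "dinotad_model_error")
    seq <- genome[[ch]]
    votes <- purrr::map_chr(seq_len(nrow(introns)), function(i) {
      don <- as.character(Biostrings::subseq(seq, introns$start[i] + 1,
                                             introns$start[i] + 2))
      acc <- as.character(Biostrings::subseq(seq, introns$end[i] - 1,
                                             introns$end[i]))
      if (don == "GT" && acc == "AG") "+"
      else if (don == "CT" && acc == "AC") "-"
      else "*"
    })
    votes <- votes[votes != "*"]
    if (length(votes) == 0) return("*")
    np <- sum(votes == "+"); nm <- sum(votes == "-")
    if (mode == "strict") {
      if (np > 0 && nm > 0) "*" else if (np > 0) "+" else "-"
    } else {
      if (np > nm) "+" else if (nm > np) "-" else "*"
    }
  })
  mutate(transcripts, strand = strands)
}

#' Longest open reading frame of a spliced transcript
#'
#' The spliced (mature) sequence is the concatenation of exon sequences,
#' reverse-complemented for `-`-strand transcripts. The longest ORF is the
#' longest ATG-initiated, in-frame-stop-terminated frame on the sense strand;
#' the reported length counts the codons strictly between the initiator and
#' the stop (so `ATG` + 63 codons + `TAA` scores 63). 0 if no complete ORF.
#'
#' @param transcripts A transcript tibble with known strands.
#' @param genome A [Biostrings::DNAStringSet].
#' @return The tibble with an `orf_aa` column added.
#' @export
longest_orf_aa <- function(transcripts, genome) {
  if (any(transcripts$strand == "*"))
    stop_config("ORFs need a known strand; filter unknown-strand transcripts first")
  orf <- purrr::pmap_dbl(
    list(transcripts$chrom, transcripts$exons, transcripts$strand),
    function(ch, ex, st) {
      s <- spliced_sequence(genome, ch, ex, st)
      longest_orf_in(s)
    })
  mutate(transcripts, orf_aa = orf)
}

# spliced sense-strand sequence of a transcript, as character
spliced_sequence <- function(genome, chrom, exons, strand) {
  seq <- genome[[chrom]]
  parts <- purrr::map_chr(seq_len(nrow(exons)), function(i)
    as.character(Biostrings::subseq(seq, exons$start[i] + 1, exons$end[i])))
  s <- paste(parts, collapse = "")
  if (strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

# longest ORF (codons between ATG and stop) in one sequence
longest_orf_in <- function(s) {
  L <- nchar(s)
  if (L < 6) return(0)
  best <- 0
  stops <- c("TAA", "TAG", "TGA")
  for (f in 1:3) {
    starts <- seq(f, L - 2, by = 3)
    codons <- substring(s, starts, starts + 2)
    open <- NA_integer_  # index of earliest ATG since the last stop
    for (k in seq_along(codons)) {
      if (codons[k] %in% stops) {
        if (!is.na(open)) best <- max(best, k - open - 1L)
        open <- NA_integer_
      } else if (is.na(open) && codons[k] == "ATG") {
        open <- k
      }
    }
  }
  best
}

#' Drop transcripts with short ORFs
#'
#' Transcripts whose longest ORF is shorter than `min_aa` amino acids are
#' removed (the dinoflagellate track-building procedure filters assemblies
#' with ORFs shorter than 60 aa); order is preserved.
#'
#' @param transcripts A transcript tibble with `orf_aa` computed.
#' @param min_aa Minimum ORF length in amino acids (default 60).
#' @return The filtered tibble.
#' @export
filter_short_orf <- function(transcripts, min_aa = 60) {
  if (!"orf_aa" %in% names(transcripts))
    stop_config("run longest_orf_aa() first")
  filter(transcripts, .data$orf_aa >= min_aa)
}

#' Strand-specific summed-TPM coverage tracks
#'
#' Every base pair covered by at least one exon of a retained transcript
#' receives the sum of the TPM values of all transcripts whose exons include
#' it, accumulated on that transcript's strand. Intronic and intergenic bases
#' are 0. Unknown-strand transcripts are dropped with a warning (junction
#' orientation gives them no signal).
#'
#' @param transcripts A transcript tibble with strands and `tpm`.
#' @param lengths Named chromosome lengths (or a [bin_grid()]).
#' @return A `strand_tracks` object: per-bp [S4Vectors::Rle] coverage per
#'   strand per chromosome.
#' @export
build_strand_tracks <- function(transcripts, lengths) {
  if (inherits(lengths, "bin_grid")) lengths <- lengths$lengths
  unknown <- transcripts$strand == "*"
  if (any(unknown)) {
    warn(sprintf("dropping %d unknown-strand transcript(s) from tracks",
                 sum(unknown)))
    transcripts <- transcripts[!unknown, ]
  }
  ex <- tidyr::unnest(select(transcripts, "transcript_id", "chrom", "strand",
                             "tpm", "exons"), "exons")
  over <- ex$end > lengths[ex$chrom] | !(ex$chrom %in% names(lengths))
  if (any(is.na(over)) || any(over))
    stop_coord("exon beyond chromosome end")
  cov_for <- function(sub) {
    gr <- GenomicRanges::GRanges(
      sub$chrom, IRanges::IRanges(sub$start + 1, sub$end),
      seqlengths = lengths)
    GenomicRanges::coverage(gr, weight = sub$tpm)
  }
  empty <- GenomicRanges::coverage(
    GenomicRanges::GRanges(seqlengths = lengths))
  fwd <- if (any(ex$strand == "+")) cov_for(ex[ex$strand == "+", ]) else empty
  rev <- if (any(ex$strand == "-")) cov_for(ex[ex$strand == "-", ]) else empty
  structure(list(forward = fwd, reverse = rev, lengths = lengths),
            class = "strand_tracks")
}

#' @export
print.strand_tracks <- function(x, ...) {
  cat(sprintf("<strand_tracks> %d chromosome(s); mass +%g / -%g\n",
              length(x$lengths), track_mass(x, "+"), track_mass(x, "-")))
  invisible(x)
}

#' Total mass of a strand track
#' @param tracks A `strand_tracks` object.
#' @param strand `"+"` or `"-"`.
#' @return Sum over all bases of the track (TPM x bp).
#' @export
track_mass <- function(tracks, strand = "+") {
  rl <- if (strand == "+") tracks$forward else tracks$reverse
  sum(purrr::map_dbl(as.list(rl), ~ sum(as.numeric(S4Vectors::runValue(.x)) *
                                          S4Vectors::runLength(.x))))
}

#' Binned materialization of strand tracks
#'
#' Mean track value per fixed-size bin, for metaplots and plotting.
#'
#' @param tracks A `strand_tracks` object.
#' @param bin Bin size in bp.
#' @return A tibble (`chrom`, `start`, `end`, `forward`, `reverse`).
#' @export
bin_strand_tracks <- function(tracks, bin) {
  purrr::map_dfr(names(tracks$lengths), function(ch) {
    L <- tracks$lengths[[ch]]
    starts <- seq(0, L - 1, by = bin)
    ends <- pmin(starts + bin, L)
    vf <- IRanges::Views(tracks$forward[[ch]], starts + 1, ends)
    vr <- IRanges::Views(tracks$reverse[[ch]], starts + 1, ends)
    tibble(chrom = ch, start = starts, end = ends,
           forward = IRanges::viewMeans(vf), reverse = IRanges::viewMeans(vr))
  })
}

#' Write strand tracks as a bedGraph pair
#'
#' @param tracks A `strand_tracks` object.
#' @param prefix Output path prefix; writes `<prefix>.fwd.bedgraph` and
#'   `<prefix>.rev.bedgraph` (run-length encoded, zero runs skipped).
#' @return The two paths, invisibly.
#' @export
write_tracks_bedgraph <- function(tracks, prefix) {
  one <- function(rl_list, path) {
    df <- purrr::map_dfr(names(tracks$lengths), function(ch) {
      r <- rl_list[[ch]]
      v <- as.numeric(S4Vectors::runValue(r))
      len <- S4Vectors::runLength(r)
      end <- cumsum(as.numeric(len))
      start <- end - len
      keep <- v != 0
      tibble(chrom = ch, start = start[keep], end = end[keep], value = v[keep])
    })
    readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
    path
  }
  p1 <- one(tracks$forward, paste0(prefix, ".fwd.bedgraph"))
  p2 <- one(tracks$reverse, paste0(prefix, ".rev.bedgraph"))
  invisible(c(p1, p2))
}

#' Read transcripts from GFF3
#'
#' Expects `mRNA`/`transcript` features with `exon` children (standard
#' `Parent` attributes). TPM is taken from a `tpm` attribute when present.
#'
#' @param path GFF3 file.
#' @return A transcript tibble.
#' @export
read_transcripts_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  ex <- gr[gr$type == "exon"]
  parent <- as.character(ex$Parent)
  tx <- gr[gr$type %in% c("mRNA", "transcript")]
  ids <- as.character(tx$ID)
  tpm <- if (!is.null(tx$tpm)) suppressWarnings(as.numeric(tx$tpm)) else rep(NA_real_, length(tx))
  strand_tx <- as.character(GenomicRanges::strand(tx))
  strand_tx[strand_tx == "?"] <- "*"
  exl <- purrr::map(ids, function(id) {
    e <- ex[parent == id]
    e <- e[order(GenomicRanges::start(e))]
    tibble(start = GenomicRanges::start(e) - 1, end = GenomicRanges::end(e))
  })
  transcript_table(ids, as.character(GenomicRanges::seqnames(tx)), exl,
                   strand = strand_tx, tpm = tpm)
}

#' Write transcripts as GFF3
#'
#' @param transcripts A transcript tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcripts_gff3 <- function(transcripts, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(transcripts))) {
    ex <- transcripts$exons[[i]]
    st <- transcripts$strand[i]
    if (st == "*") st <- "."
    id <- transcripts$transcript_id[i]
    lines <- c(lines, sprintf(
      "%s\tdinotad\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;tpm=%g",
      transcripts$chrom[i], min(ex$start) + 1, max(ex$end), st, id,
      transcripts$tpm[i]))
    lines <- c(lines, sprintf(
      "%s\tdinotad\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
      transcripts$chrom[i], ex$start + 1, ex$end, st, id))
  }
  writeLines(lines, path)
  invisible(path)
}
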