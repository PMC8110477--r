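#' Simulation configuration
#'
#' Defines the generative model the analysis assumes: each chromosome is
#' partitioned into domains, each domain is a divergent pair of gene arrays
#' (a reverse-strand array then a forward-strand array), so that domain
#' boundaries coincide exactly with convergent array junctions. Contact maps
#' follow a power-law distance decay multiplied by a block-domain enrichment,
#' with Poisson depth noise and a mixing parameter `m` interpolating towards
#' pure decay (transcription-inhibition decompaction).
#'
#' The pinned default emulates the dinoTAD study conditions at desk scale:
#' one 10-Mb chromosome at 50-kb bins, domain enrichment `E = 3`, sub-domain
#' (between arrays of one domain) enrichment `e = 2`, decay exponent
#' `alpha = 1`, 2e6 cis contacts, seed 1. Domain sizes are 750 kb +- 20%
#' (600-900 kb), inside the reported dinoTAD size range, and are rounded to
#' whole bins so planted boundaries sit on bin edges.
#'
#' @param chrom_lengths Named chromosome lengths in bp.
#' @param resolution Bin size in bp.
#' @param domain_size Expected domain size in bp.
#' @param domain_jitter Fractional uniform jitter of domain sizes.
#' @param alpha Distance-decay exponent.
#' @param enrichment Intra-array contact enrichment `E >= 1`.
#' @param sub_enrichment Cross-array (same domain) enrichment `e`, `1 <= e <= E`.
#' @param mixing Mixing parameter `m` in `[0, 1]`; 0 = full domains,
#'   1 = pure decay.
#' @param depth Expected cis contacts per chromosome.
#' @param transcripts_per_array Transcripts per array, or NULL to fill each
#'   array densely (the dinoflagellate regime: arrays are near-contiguous
#'   runs of genes).
#' @param exon_meanlog,exon_sdlog Log-normal exon length parameters (bp).
#' @param intron_meanlog,intron_sdlog Log-normal intron length parameters (bp).
#' @param n_exons_range Inclusive range of exons per transcript (>= 2 so
#'   every transcript carries splice-junction orientation signal).
#' @param orf_aa Length of the ORF embedded in each transcript (aa).
#' @param tpm_meanlog,tpm_sdlog Log-normal TPM parameters (scaled to sum 1e6).
#' @param intergenic_gap Mean gap between consecutive transcripts in an
#'   array (bp).
#' @param nascent_fraction Fraction of reads drawn from unspliced pre-mRNA.
#' @param read_length Read length in bp.
#' @param seed Root seed; all generators are pure functions of
#'   (config, seed).
#' @return A `sim_config` list.
#' @export
sim_config <- function(chrom_lengths = c(chr1 = 10e6),
                       resolution = 5e4,
                       domain_size = 7.5e5,
                       domain_jitter = 0.2,
                       alpha = 1.0,
                       enrichment = 3,
                       sub_enrichment = 2,
                       mixing = 0,
                       depth = 2e6,
                       transcripts_per_array = NULL,
                       exon_meanlog = log(400), exon_sdlog = 0.4,
                       intron_meanlog = log(400), intron_sdlog = 0.3,
                       n_exons_range = c(3L, 7L),
                       orf_aa = 120L,
                       tpm_meanlog = log(10), tpm_sdlog = 1,
                       intergenic_gap = 1000,
                       nascent_fraction = 0.3,
                       read_length = 100L,
                       seed = 1L) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (is.null(names(chrom_lengths))) stop_config("chrom_lengths must be named")
    if (enrichment < 1) stop_config("enrichment must be >= 1")
    if (sub_enrichment < 1 || sub_enrichment > enrichment)
      stop_config("sub_enrichment must satisfy 1 <= e <= E")
    if (mixing < 0 || mixing > 1) stop_config("mixing must be in [0, 1]")
    if (nascent_fraction < 0 || nascent_fraction > 1)
      stop_config("nascent_fraction must be in [0, 1]")
    if (depth <= 0) stop_config("depth must be > 0")
    if (domain_size < 2 * resolution)
      stop_config("domain_size must span at least 2 bins")
  })
  invisible(cfg)
}

#' Simulate a genome with planted domains, arrays and transcripts
#'
#' Each chromosome is partitioned into domains of jittered size (rounded to
#' whole bins, so boundaries sit on bin edges); each domain is split at its
#' middle bin edge into a reverse-strand array followed by a forward-strand
#' array. Arrays tile domains exactly, so the junction between two domains is
#' convergent (`+` then `-`) and coincides with the planted boundary, while
#' the mid-domain junction is divergent. Transcripts are placed sequentially
#' within arrays with canonical `GT..AG` splice sites on the sense strand and
#' an embedded ORF; the rest of the genome is uniform random sequence.
#'
#' @param cfg A [sim_config()].
#' @param with_sequence Generate the actual DNA (set FALSE for large genomes
#'   when only coordinates/maps are needed; transcripts then carry their true
#'   strand but no sequence-derived features can be computed).
#' @return A `synthetic_truth` object: `genome` ([Biostrings::DNAStringSet]
#'   or NULL), `grid`, `boundaries`, `domains`, `arrays`, `junctions`,
#'   `transcripts` (with true strand and TPM), `config`.
#' @export
simulate_genome <- function(cfg, with_sequence = TRUE) {
  validate_sim_config(cfg)
  withr::with_seed(derive_seed(cfg$seed, 1L), {
    grid <- bin_grid(cfg$chrom_lengths, cfg$resolution)
    res <- cfg$resolution
    doms <- purrr::map_dfr(names(cfg$chrom_lengths), function(ch) {
      L <- cfg$chrom_lengths[[ch]]
      min_size <- max(2, round(cfg$domain_size * (1 - cfg$domain_jitter) / res)) * res
      edges <- 0
      while (tail(edges, 1) < L) {
        size <- cfg$domain_size * (1 + runif(1, -cfg$domain_jitter, cfg$domain_jitter))
        size <- max(2, round(size / res)) * res
        edges <- c(edges, min(tail(edges, 1) + size, L))
      }
      # the terminal domain absorbs a trailing segment below the jitter
      # minimum, so every planted domain respects the size distribution
      if (length(edges) > 2 &&
          tail(edges, 1) - edges[length(edges) - 1] < min_size)
        edges <- edges[-(length(edges) - 1)]
      tibble(chrom = ch, start = head(edges, -1), end = tail(edges, -1))
    })
    boundaries <- doms |>
      group_by(.data$chrom) |>
      dplyr::reframe(pos = head(.data$end, -1))
    arrays <- doms |>
      mutate(mid = floor((.data$start + .data$end) / (2 * res)) * res) |>
      (\(d) bind_rows(
        tibble(chrom = d$chrom, start = d$start, end = d$mid, strand = "-"),
        tibble(chrom = d$chrom, start = d$mid, end = d$end, strand = "+")
      ))() |>
      arrange(.data$chrom, .data$start)
    junctions <- classify_junctions(arrays)

    tx <- purrr::map_dfr(seq_len(nrow(arrays)), function(ai) {
      a <- arrays[ai, ]
      make_array_transcripts(a, cfg, ai)
    })
    tpm <- rlnorm(nrow(tx), cfg$tpm_meanlog, cfg$tpm_sdlog)
    tx$tpm <- tpm / sum(tpm) * 1e6

    genome <- NULL
    if (with_sequence) genome <- assemble_genome_sequence(tx, cfg)

    structure(list(genome = genome, grid = grid, boundaries = boundaries,
                   domains = doms, arrays = arrays, junctions = junctions,
                   transcripts = tx, config = cfg),
              class = "synthetic_truth")
  })
}

# Plan transcripts for one array: exon/intron layouts and genomic placement.
# Each transcript records its sense-strand spliced/intron structure so the
# sequence can be assembled later.
make_array_transcripts <- function(a, cfg, array_index) {
  span <- a$end - a$start
  margin <- min(2000, span * 0.05)
  lo <- a$start + margin
  hi <- a$end - margin
  out <- list()
  cursor <- lo
  k <- 0L
  limit <- cfg$transcripts_per_array %||% Inf
  while (k < limit) {
    n_ex <- sample(cfg$n_exons_range[1]:cfg$n_exons_range[2], 1)
    ex_len <- pmax(50, round(rlnorm(n_ex, cfg$exon_meanlog, cfg$exon_sdlog)))
    in_len <- pmax(20, round(rlnorm(n_ex - 1, cfg$intron_meanlog, cfg$intron_sdlog)))
    # spliced length must hold the ORF (+ stop + some UTR)
    need <- (cfg$orf_aa + 2) * 3 + 40
    while (sum(ex_len) < need) ex_len <- ex_len + 50
    span_len <- sum(ex_len) + sum(in_len)
    if (cursor + span_len > hi) break
    k <- k + 1L
    gap <- max(100, round(cfg$intergenic_gap * runif(1, 0.5, 1.5)))
    # exon offsets within the sense-strand pre-mRNA
    off <- cumsum(c(0, head(ex_len, -1) + in_len))
    sense_exons <- tibble(start = off, end = off + ex_len)
    g_start <- cursor
    if (a$strand == "+") {
      exons <- tibble(start = g_start + sense_exons$start,
                      end = g_start + sense_exons$end)
    } else {
      # genomic image is the reverse complement: mirror the layout
      exons <- tibble(start = g_start + span_len - sense_exons$end,
                      end = g_start + span_len - sense_exons$start) |>
        arrange(.data$start)
    }
    out[[k]] <- tibble(
      transcript_id = sprintf("tx_%s_a%d_%d", a$chrom, array_index, k),
      chrom = a$chrom, strand = a$strand, tpm = NA_real_,
      exons = list(exons),
      g_start = g_start, span_len = span_len,
      exon_lens = list(ex_len), intron_lens = list(in_len))
    cursor <- cursor + span_len + gap
  }
  bind_rows(out)
}

# Build the chromosome sequences: random background with each transcript's
# pre-mRNA (canonical splice sites, embedded ORF) written at its locus.
assemble_genome_sequence <- function(tx, cfg) {
  seqs <- purrr::map(names(cfg$chrom_lengths), function(ch) {
    L <- cfg$chrom_lengths[[ch]]
    sub <- tx[tx$chrom == ch, ]
    sub <- sub[order(sub$g_start), ]
    parts <- character(0)
    cursor <- 0
    for (i in seq_len(nrow(sub))) {
      pre <- make_pre_mrna(sub$exon_lens[[i]], sub$intron_lens[[i]], cfg$orf_aa)
      if (sub$strand[i] == "-")
        pre <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(pre)))
      parts <- c(parts, rand_dna(sub$g_start[i] - cursor), pre)
      cursor <- sub$g_start[i] + sub$span_len[i]
    }
    parts <- c(parts, rand_dna(L - cursor))
    paste(parts, collapse = "")
  })
  Biostrings::DNAStringSet(setNames(unlist(seqs), names(cfg$chrom_lengths)))
}

# sense-strand pre-mRNA: exons concatenated carry a clean ORF; introns are
# GT ... AG
make_pre_mrna <- function(ex_len, in_len, orf_aa) {
  total_ex <- sum(ex_len)
  spliced <- rand_dna(total_ex)
  # embed ATG + orf_aa stop-free codons + TAA at a fixed offset
  orf_nt <- (orf_aa + 2) * 3
  at <- 10
  codons <- c("ATG", sample(safe_codons(), orf_aa, replace = TRUE), "TAA")
  substr(spliced, at + 1, at + orf_nt) <- paste(codons, collapse = "")
  # guard the frame upstream: avoid an in-frame ATG immediately before
  exons <- character(length(ex_len))
  pos <- 0
  for (i in seq_along(ex_len)) {
    exons[i] <- substr(spliced, pos + 1, pos + ex_len[i])
    pos <- pos + ex_len[i]
  }
  introns <- purrr::map_chr(in_len, function(l)
    paste0("GT", rand_dna(l - 4), "AG"))
  pre <- character(0)
  for (i in seq_along(exons)) {
    pre <- c(pre, exons[i])
    if (i <= length(introns)) pre <- c(pre, introns[i])
  }
  paste(pre, collapse = "")
}

# codons that are neither stops nor ATG (keeps the embedded ORF unambiguous)
safe_codons <- function() {
  all3 <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            c("A", "C", "G", "T")), 1, paste, collapse = "")
  setdiff(all3, c("TAA", "TAG", "TGA", "ATG"))
}

#' Simulate a Hi-C contact map from planted truth
#'
#' Expected intensity `lambda_ij` is proportional to
#' `d(|i-j|)^(-alpha) * ((1 - m) * F_ij + m)`, where `F_ij = E` for bins in
#' the same array, `e` for bins in the same domain but different arrays, and
#' 1 otherwise (`d(0)` is taken as `d(1)`). Intensities are scaled so the
#' expected total equals `depth` per chromosome and counts are drawn Poisson,
#' then symmetrized.
#'
#' @param truth A [simulate_genome()] result.
#' @param cfg Optional config override (defaults to `truth$config`).
#' @param mixing Optional mixing override of `cfg$mixing`.
#' @param seed_offset Offset added to the derived stage seed (used by
#'   condition series to draw independent maps).
#' @return A raw [contact_map()].
#' @export
simulate_contact_map <- function(truth, cfg = NULL, mixing = NULL,
                                 seed_offset = 0L) {
  cfg <- cfg %||% truth$config
  validate_sim_config(cfg)
  m <- mixing %||% cfg$mixing
  if (cfg$depth <= 0) stop_config("depth must be > 0")
  grid <- truth$grid
  withr::with_seed(derive_seed(cfg$seed, 2L + seed_offset), {
    counts <- purrr::map(setNames(grid$chroms, grid$chroms), function(ch) {
      n <- grid$nbins[[ch]]
      res <- grid$resolution
      centers <- (seq_len(n) - 0.5) * res
      dom <- truth$domains[truth$domains$chrom == ch, ]
      arr <- truth$arrays[truth$arrays$chrom == ch, ]
      dom_id <- findInterval(centers, dom$start)
      arr_id <- findInterval(centers, sort(arr$start))
      d <- abs(outer(seq_len(n), seq_len(n), "-"))
      decay <- pmax(d, 1)^(-cfg$alpha)
      FF <- matrix(1, n, n)
      same_dom <- outer(dom_id, dom_id, "==")
      same_arr <- outer(arr_id, arr_id, "==")
      FF[same_dom] <- cfg$sub_enrichment
      FF[same_dom & same_arr] <- cfg$enrichment
      lam <- decay * ((1 - m) * FF + m)
      # scale upper triangle (with diagonal) to the target depth
      ut <- upper.tri(lam, diag = TRUE)
      lam <- lam * (cfg$depth / sum(lam[ut]))
      x <- matrix(0, n, n)
      x[ut] <- rpois(sum(ut), lam[ut])
      x + t(x) - diag(diag(x))
    })
    contact_map(counts, grid)
  })
}

#' Simulate RNA-seq reads with a controlled nascent fraction
#'
#' Each read is drawn from a transcript with probability proportional to its
#' TPM. With probability `nascent_fraction` the read comes from unspliced
#' pre-mRNA: a single gapless block placed uniformly among positions that
#' overlap an intron by at least 10 bp (nascent signal is intronic by
#' definition). Otherwise the read comes from the mature mRNA: a position
#' uniform on the spliced sequence, mapped back to genomic blocks (spanning
#' junctions yields multiple blocks and sets the `spliced` flag).
#'
#' @param truth A [simulate_genome()] result.
#' @param n_reads Number of reads (>= 1).
#' @param cfg Optional config override.
#' @return A read tibble, one row per aligned block: `read_id`, `chrom`,
#'   `start`, `end`, `spliced`, plus truth labels `source_id` and `nascent`.
#' @export
simulate_reads <- function(truth, n_reads, cfg = NULL) {
  cfg <- cfg %||% truth$config
  if (n_reads < 1) stop_config("n_reads must be >= 1")
  tx <- truth$transcripts
  rl <- cfg$read_length
  withr::with_seed(derive_seed(cfg$seed, 3L), {
    pick <- sample.int(nrow(tx), n_reads, replace = TRUE, prob = tx$tpm)
    nascent <- runif(n_reads) < cfg$nascent_fraction
    rows <- purrr::map_dfr(seq_len(n_reads), function(r) {
      t <- tx[pick[r], ]
      ex <- t$exons[[1]]
      rid <- sprintf("read_%06d", r)
      if (nascent[r]) {
        introns <- intron_intervals(ex)
        sp0 <- min(ex$start); sp1 <- max(ex$end)
        # start positions whose read overlaps some intron by >= 10 bp
        lo <- pmax(sp0, introns$start - rl + 10)
        hi <- pmin(sp1 - rl, introns$end - 10)
        ok <- which(hi >= lo)
        if (length(ok) == 0) {          # pathological tiny intron: fall back
          st <- sp0
        } else {
          i <- ok[sample.int(length(ok), 1)]
          st <- floor(runif(1, lo[i], hi[i] + 1))
        }
        tibble(read_id = rid, chrom = t$chrom, start = st, end = st + rl,
               spliced = FALSE, source_id = t$transcript_id, nascent = TRUE)
      } else {
        sl <- sum(ex$end - ex$start)
        st_s <- floor(runif(1, 0, max(1, sl - rl)))
        blocks <- spliced_to_genomic(ex, st_s, min(rl, sl))
        tibble(read_id = rid, chrom = t$chrom, start = blocks$start,
               end = blocks$end, spliced = nrow(blocks) > 1,
               source_id = t$transcript_id, nascent = FALSE)
      }
    })
    rows
  })
}

# map an interval [s, s+len) in spliced coordinates to genomic blocks
spliced_to_genomic <- function(exons, s, len) {
  w <- exons$end - exons$start
  cum <- cumsum(c(0, w))
  out <- list()
  left <- len
  pos <- s
  while (left > 0) {
    i <- findInterval(pos, cum, rightmost.closed = FALSE)
    in_ex <- pos - cum[i]
    take <- min(left, w[i] - in_ex)
    out[[length(out) + 1]] <- tibble(start = exons$start[i] + in_ex,
                                     end = exons$start[i] + in_ex + take)
    pos <- pos + take
    left <- left - take
  }
  bind_rows(out)
}

#' Simulate a transcription-inhibition condition series
#'
#' One contact map per mixing value, sharing the planted truth but with
#' independent Poisson sampling; dose rank is the index in `mixings`.
#' Optionally pairs each condition with a nascent fraction scaled by
#' `(1 - m)`, mirroring inhibition reducing nascent RNA.
#'
#' @param truth A [simulate_genome()] result.
#' @param mixings Sorted ascending mixing values in `[0, 1]`.
#' @param cfg Optional config override.
#' @return A tibble (`condition`, `dose_rank`, `mixing`, `nascent_fraction`,
#'   `map` list-column), compatible with [compare_conditions()].
#' @export
simulate_condition_series <- function(truth, mixings = c(0, 0.5, 1),
                                      cfg = NULL) {
  cfg <- cfg %||% truth$config
  if (length(mixings) == 0) stop_config("empty mixing list")
  if (is.unsorted(mixings)) stop_config("mixings must be sorted ascending")
  tibble(
    condition = sprintf("m%.2f", mixings),
    dose_rank = seq_along(mixings),
    mixing = mixings,
    nascent_fraction = cfg$nascent_fraction * (1 - mixings),
    map = purrr::map(seq_along(mixings), function(i)
      simulate_contact_map(truth, cfg, mixing = mixings[i],
                           seed_offset = 100L * i))
  )
}

#' Write the synthetic truth to disk
#'
#' FASTA genome (if present), GFF3 transcripts, BED boundaries/arrays/
#' junction tables, and a JSON config echo.
#'
#' @param truth A [simulate_genome()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  if (!is.null(truth$genome)) {
    p <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(truth$genome, p)
    paths["genome"] <- p
  }
  p <- file.path(dir, "transcripts.gff3")
  write_transcripts_gff3(truth$transcripts, p); paths["transcripts"] <- p
  p <- file.path(dir, "boundaries.tsv")
  readr::write_tsv(truth$boundaries, p, progress = FALSE); paths["boundaries"] <- p
  p <- file.path(dir, "arrays.bed")
  write_arrays_bed(truth$arrays, p); paths["arrays"] <- p
  p <- file.path(dir, "junctions.bed")
  write_junctions_bed(truth$junctions, p); paths["junctions"] <- p
  p <- file.path(dir, "sim_config.json")
  cfgl <- unclass(truth$config)
  cfgl$chrom_lengths <- as.list(cfgl$chrom_lengths)
  jsonlite::write_json(cfgl, p, auto_unbox = TRUE, digits = NA, null = "null")
  paths["config"] <- p
  invisible(paths)
}
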