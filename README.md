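# dinotad

Topological domain analysis for dinoflagellate Hi-C data.

Dinoflagellate genomes are built from long unidirectional tandem gene
arrays, and their chromatin-contact maps partition into large
self-interacting domains — **dinoTADs** — whose boundaries coincide with
**convergent** gene-array junctions (arrays transcribed towards each other)
and which decompact under transcription inhibition, consistent with
transcription-induced supercoiling shaping the chromosome. `dinotad` is an
R package for researchers analysing such maps: it implements the full
computational pipeline from raw binned contact counts to called domains,
strand-resolved transcription tracks, boundary–junction correspondence
statistics, and cross-condition decompaction readouts, together with a
seeded synthetic-data generator so the whole pipeline is testable end to
end.

## The core quantities

* **Knight–Ruiz balancing.** Per-bin weights \(w\) with
  \(w_i c_{ij} w_j\) having equal (unit) row sums, via damped symmetric
  fixed-point iteration on \(x \odot (Ax) = 1\).
* **TAD-separation score.** For bin edge \(i\) and window \(w\), the
  *diamond* mean
  \(s_w(i) = \mathrm{mean}\, B[(i-w,i] \times (i,i+w]]\) of balanced
  contacts crossing the edge, z-scored per chromosome and averaged over
  windows into \(S(i)\); local minima of \(S\) with sufficient prominence,
  a significant one-sided rank test against flanking diamonds, and
  Benjamini–Hochberg \(q \le\) FDR become boundaries.
* **O/E transform and boundary strength.** Each balanced cell divided by
  the mean at its genomic distance; boundary strength
  \(= A/I\), intra-domain triangle mean over boundary diamond mean, equal
  to 1 on structureless maps and decreasing under decompaction.
* **Strand tracks and junctions.** Transcript strand inferred from splice
  junctions (`GT..AG` forward / `CT..AC` reverse), transcripts with ORFs
  under 60 aa removed, per-bp summed-TPM tracks per strand, maximal
  same-strand runs segmented into gene arrays, junctions classified
  convergent / divergent / tandem.
* **Nascent proxy.** Fraction of gapless reads overlapping annotated
  introns, a proxy for ongoing transcription.

## A worked example

```r
library(dinotad)

# a synthetic genome under the pinned study conditions:
# one 10-Mb chromosome, 50-kb bins, domain enrichment 3, depth 2e6, seed 1
cfg   <- sim_config()
truth <- simulate_genome(cfg)
map   <- simulate_contact_map(truth)

bal   <- balance_map(map)                       # mask + KR + unit row sums
track <- tad_separation_score(bal)              # windows 2,4,6,10 bins
bs    <- call_boundaries(track, bal, fdr = 0.05)
nrow(bs)
#> [1] 12
boundary_recovery(bs, truth)
#> # A tibble: 1 x 4
#>   recall precision n_true n_called
#>    <dbl>     <dbl>  <int>    <int>
#> 1      1         1     12       12

# transcription side: strand inference -> ORF filter -> tracks -> arrays
tx     <- infer_transcript_strand(truth$transcripts, truth$genome)
tx     <- filter_short_orf(longest_orf_aa(tx, truth$genome), min_aa = 60)
tracks <- build_strand_tracks(tx, truth$grid)
jx     <- classify_junctions(segment_gene_arrays(tracks))

mt <- match_boundaries_to_junctions(bs, jx, max_dist = 5e4)
glance(mt)$matched_fraction
#> [1] 1
junction_enrichment_test(bs, jx, truth$grid, n_perm = 999, seed = 42)
#> <enrichment_test> matched fraction 1.000 vs null mean 0.112; p = 0.001 (999 perms)

# decompaction: mean boundary strength falls with the mixing dose
series <- simulate_condition_series(truth, mixings = c(0, 0.5, 1))
compare_conditions(series, bs, seed = 5)
#> <condition_trend> 3 conditions; rho = -0.943, one-sided p = 0.0001
#> # A tibble: 3 x 4
#>   condition dose_rank mean_strength n_boundaries
#>   <chr>         <int>         <dbl>        <int>
#> 1 m0.00             1         1.63            12
#> 2 m0.50             2         1.34            12
#> 3 m1.00             3         0.993           12
```

All 12 called boundaries land exactly on planted convergent junctions
(matched fraction 1, permutation p = 0.001, the smallest attainable with
999 shifts), and boundary insulation decays monotonically towards 1 — the
structureless value — as the domain signal is mixed out, the in-silico
image of inhibitor-induced decompaction.

`run_analysis(validate_config(...))` chains all stages and writes BED /
bedGraph / TSV / JSON outputs plus a manifest;
`inst/scripts/dinotad.R` wraps it for the shell. Each result type has
`autoplot()` / `plot_*()` figures and broom-style `tidy()` / `glance()`
methods.

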