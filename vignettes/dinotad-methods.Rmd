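---
title: "Calling and probing dinoTADs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and probing dinoTADs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Dinoflagellate genomes are organized unlike those of other eukaryotes: genes
sit in long unidirectional tandem arrays, and chromatin-contact (Hi-C) maps
show the genome partitioned into large self-interacting topological domains
— *dinoTADs* — whose boundaries fall where two gene arrays transcribed
*towards* each other meet (convergent junctions), and which decompact when
transcription is chemically inhibited. The mechanistic reading is
transcription-induced supercoiling: elongating polymerases generate negative
supercoiling behind and positive supercoiling ahead, so a divergent pair of
arrays inside one domain accumulates torsional structure that physically
associates the pair, while convergent junctions act as topological
insulation points.

`dinotad` implements the complete computational arc of that analysis as a
reusable, tested pipeline: contact-map numerics, domain-boundary calling,
strand-resolved transcription tracks, gene-array segmentation, the
boundary–junction correspondence tests, and the cross-condition
decompaction comparison. A seeded synthetic-data generator embodies the
generative structure the analysis assumes, so every stage is verifiable end
to end without any external download.

## Contact-map numerics

Contact maps are strictly cis (the domain analysis is intra-chromosomal),
stored per chromosome as symmetric count matrices on a fixed-resolution bin
grid (0-based half-open coordinates; the last bin of a chromosome may be
short and participates normally).

**Masking.** Bins with raw marginal below a count threshold are excluded,
plus optionally bins below a per-chromosome quantile of positive marginals
(pipeline default 0.5%). The quantile default is an explicit knob, not a
claim about any particular external tool's behavior, which is unpublished
at this level of detail.

**Balancing.** `kr_balance()` finds per-bin weights \(w\) such that
\(w_i c_{ij} w_j\) has all unmasked row sums equal, by damped fixed-point
iteration on the symmetric scaling equation \(x \odot (Ax) = 1\) with
square-root damping — the classical symmetric Sinkhorn–Knopp/Knight–Ruiz
scheme. Convergence is the maximum relative row-sum deviation (default
`tol = 1e-6`, `max_iter = 3000`); balanced maps are normalized to unit row
sums so all downstream scores are sequencing-depth independent. A matrix
without total support (e.g. a disconnected zero block) cannot be balanced;
the iteration then fails loudly, naming the worst bins, rather than
returning partial weights. The test suite cross-checks the fixed point
against an independent alternating-scaling oracle.

**Distance decay and O/E.** `expected_by_distance()` pools the per-distance
mean of balanced values across chromosomes and fits the decay exponent
\(\alpha\) by least squares on \(\log E(d)\) vs \(\log d\) (default fit
range: 1 bin to a quarter of the longest chromosome). In
`observed_over_expected()`, distances with no defined expectation borrow
the nearest defined distance's value, so map edges do not create division
holes.

**Cross-sample scaling.** `normalize_to_smallest()` rescales a set of maps
so every total equals the smallest input total, leaving within-map
structure untouched — the joint normalization used before comparing
conditions.

## Boundary calling

The TAD-separation score generalizes insulation profiling: for every bin
edge and window size \(w\) (default \(\{2,4,6,10\}\) bins, i.e. 100–500 kb
at the 50-kb calling resolution used for dinoTADs), the *diamond* — the
submatrix of contacts crossing the edge within \(w\) bins — is averaged,
z-transformed per chromosome per window, and the per-window z-scores are
averaged into the aggregate score \(S\). The window set is the caller's
scale parameter and should be matched to the expected domain size: the
largest window ought to stay below roughly half to two-thirds of it,
otherwise the boundary diamonds of neighboring domains overlap and the
rank test below loses power (for a genome with ~500-kb domains at 50-kb
bins, windows \(\{2,3,4,5\}\) are appropriate). A zero per-chromosome
standard deviation defines \(z = 0\), so degenerate constant chromosomes
score flat rather than undefined. Edges where any window crosses a chromosome end are
excluded from candidacy.

Candidates are strict local minima of \(S\) with prominence at least
`delta` (default 0.01). Each candidate is tested with a one-sided Wilcoxon
rank-sum test: its diamond cells, pooled over all window sizes, against the
pooled *flanking* diamonds one window away on either side at each size.
Flanking diamonds never cross the candidate edge and sample matched
distances, so under insulation the candidate's cells are stochastically
smaller. We deliberately pool across window sizes rather than using only
the largest window: with a single reference offset, the reference
occasionally lands on a neighboring boundary or sub-domain junction and the
test loses power precisely at real boundaries. Benjamini–Hochberg
correction is applied genome-wide and calls with \(q \le\) `fdr` (default
0.05) are kept. Finally, calls closer than `min_boundary_distance` (default
= the largest window) are pruned keeping the lower score — this suppresses
twin minima and, importantly, the weaker minima at *divergent* junctions
inside domains (the "sub-domain" structure), which sit roughly half a
domain away from true boundaries.

The rank test is an emulation of the insulation-caller family's behavior,
not a bit-compatible reimplementation; no published description pins the
exact variant. For the same reason the printed dinoTAD count from the
original genome-scale analysis is configuration-dependent and is not a
target the package tries to reproduce.

## Transcription tracks, arrays, junctions

Dinoflagellate RNA-seq is typically unstranded, so transcript orientation is
inferred from splice-junction dinucleotides: an intron reading `GT..AG` on
the forward genomic strand votes `+`, `CT..AC` votes `-`; non-canonical
sites abstain. The default mode is strict unanimity (any conflict →
unknown); a majority mode is available. Whether non-canonical dinoflagellate
splice sites should vote is unknowable from published methods, so
canonical-only is the default and a documented choice. Single-exon
transcripts carry no orientation signal and are excluded from tracks.

ORFs are sought on the sense strand of the spliced sequence,
ATG-initiated with an in-frame stop required; the reported length counts
the codons strictly between initiator and stop. Transcripts with longest
ORF under 60 aa are dropped, matching the filtering applied in the original
track-building procedure.

Strand tracks assign each exonic base the sum of TPM values of all retained
transcripts covering it, on the transcript's strand (run-length encoded;
exact per-bp semantics with an optional binned materialization for
metaplots). Gene arrays are maximal per-strand runs with signal at least
`min_signal` (0.1 TPM), bridging internal gaps up to `gap_tolerance`
(25 kb), dropping runs under `min_array_length` (100 kb; domain halves are
at least that large given the observed domain size range); overlapping
opposite-strand runs are resolved to the strand with more integrated signal
in the overlap. Junctions between consecutive arrays are classified
convergent (`+` then `-`), divergent (`-` then `+`), or tandem, positioned
at the gap midpoint.

The unspliced-read fraction — the nascent-transcription proxy — counts a
read as intronic if its alignment has no intron-spanning gap and overlaps
an annotated intron by at least `min_intron_overlap` (10 bp), over all
reads assigned to transcripts. The exact operational definition used on the
original data is unpublished; the threshold is exposed.

## Correspondence and decompaction

`match_boundaries_to_junctions()` pairs each called boundary with its
nearest convergent junction within `max_dist`. Significance comes from a
circular permutation null: the boundary set is rotated within each
chromosome by a random offset, preserving spacing (a uniform resampling
null would overstate significance for regularly spaced boundaries). Offsets
within twice the matching tolerance of the identity are excluded — they
reproduce the observed configuration, not an independent placement, and
would otherwise floor the attainable p-value at roughly the ratio of the
tolerance to the chromosome length.

Boundary strength scalarizes the insulation metaplot: at window \(w\),
`strength = A / I` with \(A\) the mean O/E of the two flanking intra-domain
triangles and \(I\) the mean O/E of the boundary diamond; it is 1 on
structureless maps and invariant to global scaling. For condition series,
boundaries are fixed from the control map so decompaction is measured at
common positions; maps are jointly depth-scaled first. The dose trend is
Spearman's \(\rho\) between dose rank and strength over all (boundary,
condition) paired observations, with a one-sided p-value from permuting
condition labels independently within each boundary. Two notes on this
design: permuting *condition-level* labels alone admits only \(k!\)
arrangements (6 for a three-dose series, flooring p at 1/6), and a rank
statistic of the \(k\) condition means discards effect magnitude; the
per-boundary paired permutation avoids both while preserving
between-boundary heterogeneity under the null.

## The synthetic-data generator

The generator realizes the domain structure the supercoiling model
predicts, with truth tables for every stage:

* **Layout.** Each chromosome is tiled with domains of expected size 750 kb
  jittered ±20% (uniform), rounded to whole bins so planted boundaries sit
  on bin edges. Each domain is a reverse-strand array followed by a
  forward-strand array (a divergent pair), so inter-domain junctions are
  convergent and coincide exactly with planted boundaries. A trailing
  segment shorter than the jitter minimum is absorbed by the terminal
  domain: dinoTADs tile chromosomes end to end, and no planted domain
  violates the configured size distribution. The 750-kb default reflects
  the observed scale of dinoTADs (a few hundred kb to a few Mb, roughly
  1 Mb on average genome-wide); it also keeps array spans (half domains)
  below the caller's minimum boundary separation, which is what lets the
  caller distinguish domain boundaries from sub-domain junctions.
* **Contacts.** Expected intensity
  \(\lambda_{ij} \propto d^{-\alpha}\,[(1-m)F_{ij} + m]\) with
  \(F_{ij} = E\) (default 3) within an array, \(e\) (default 2, the more
  diffuse sub-domain level) across arrays of one domain, 1 otherwise;
  \(d(0)\) is taken as \(d(1)\). The mixing parameter \(m \in [0,1]\)
  interpolates to pure decay — a one-parameter decompaction family suitable
  for monotonicity tests. Counts are Poisson at a target cis depth per
  chromosome (default 2×10⁶) and symmetrized.
* **Transcripts and sequence.** Arrays are filled with multi-exon
  transcripts (canonical `GT..AG` sense splice sites, an embedded 120-aa
  ORF, log-normal TPMs scaled to one million) over uniform random
  background sequence. Reverse-strand transcripts are written as reverse
  complements, so their introns read `CT..AC` on the forward strand.
* **Reads.** Each read is drawn from a transcript proportionally to TPM.
  With probability `nascent_fraction` it is an unspliced pre-mRNA read,
  placed uniformly among positions overlapping an intron by at least 10 bp
  — nascent signal is intronic by construction, so the planted fraction is
  exactly the quantity the unspliced-read estimator measures and the
  estimate concentrates binomially around truth. Otherwise the read is
  mature: uniform on the spliced sequence, mapped back to genomic blocks
  (junction-spanning reads get multiple blocks).

All generators are pure functions of (config, seed); every source of
randomness derives from one root seed with fixed per-stage offsets.

**What the generator does not emulate.** Realistic base composition and
sequence evolution; non-canonical splice sites; trans contacts;
hierarchical domain nesting beyond the single sub-domain level; biological
variability between replicates; mappability and coverage artifacts of real
Hi-C. Passing tests therefore demonstrate the pipeline's correctness under
its stated model — planted structure in, same structure out through every
stage — not performance on any particular real dataset.

## Numerical choices and degenerate inputs

* Balancing tolerance 1e-6 (relative row-sum deviation), 3000 iterations;
  non-convergence is an error, never silent partial output.
* Score z-transforms define \(z = 0\) when the per-chromosome spread is
  zero; candidate ties in the distance pruning go to the lower coordinate.
* O/E at distances with undefined expectation uses the nearest defined
  distance's value.
* Chromosomes shorter than the smallest window yield empty score tracks
  with a warning; empty read sets, empty junction lists and empty domain
  sets are errors, not silent empties.
* Problem sizes in the test-suite simulations (a 10-Mb default genome at
  50-kb bins, a 10-chromosome 2–10 Mb genome for the scaling analysis,
  10,000-read samples, 50–200 replicate calibrations) were chosen so each
  stage's statistical targets are comfortably resolvable at desk scale.

## Known limitations

* The caller emulates, but does not bit-match, any external TAD caller; no
  loop/stripe detection or nested domain decomposition is attempted (the
  dinoflagellate maps show no loop or stripe features).
* Sub-domain (divergent-junction) structure is modeled in the simulator
  but deliberately *not* called as boundaries; how such sub-domains were
  delineated originally is unpublished.
* Genome-scale printed figures from the original study (pseudochromosome
  counts, the 583-domain census, genome-wide size medians) depend on
  manual scaffold curation and tool configuration and are outside what a
  desk-scale synthetic analysis can or should reproduce.
* Only cis analysis is supported; compartment/eigenvector analysis and
  read-level Hi-C processing are out of scope.
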