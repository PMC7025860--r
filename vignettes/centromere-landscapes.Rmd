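---
title: "Centromere landscapes and karyotype evolution: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centromere landscapes and karyotype evolution: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(censcape)
```

# The biological model

Short regional centromeres in compact fungal genomes — the *Malassezia*
yeasts are the motivating system — have a characteristic two-layer
architecture: a kinetochore-bound region of roughly 3–5 kb, inside which an
AT-rich core of under a kilobase sits at the global GC minimum of its
chromosome. The core is depleted of canonical histone H3 (replaced by the
centromeric variant CENP-A) and is enriched for a 12-bp AT-rich sequence
motif. Because each chromosome is monocentric and the genomic background is
GC-rich (near 58% GC in these genomes), the GC landscape alone is a strong
centromere predictor, and the motif and ChIP layers provide orthogonal
confirmation.

Centromeres also mark where karyotypes change. Comparing gene synteny around
centromeres between related genomes distinguishes two mechanisms of
chromosome-number reduction:

* **loss by breakage** — the chromosome breaks at the centromere, the
  centromere DNA is lost, and the two acentric arms fuse to the ends of
  other chromosomes. Signature: the genes flanking the lost centromere map
  to *two different* chromosomes of the derived genome, with no homologous
  region for the centromere itself.
* **inactivation after fusion** — two chromosomes fuse end to end, and one
  of the two centromeres subsequently diverges in sequence, losing its
  AT-richness and motif content. Signature: the flanking genes remain
  contiguous on *one* derived chromosome, but the intervening interval no
  longer draws a GC-trough centromere call.

Counting chromosomes across a species tree and minimising state changes
(Fitch parsimony, with counts treated as unordered states) then infers the
ancestral chromosome number.

# Stage by stage

## GC landscape (`gc_profile`, `find_gc_trough`, `delineate_core`)

GC content is computed in windows of 250 bp (the scale at which sub-kilobase
cores remain visible while sampling noise stays tolerable), non-overlapping
by default; `step` can be reduced for sliding profiles used in plots. N
bases are excluded from both numerator and denominator, and windows more
than 50% N (assembly gaps) are masked so they cannot masquerade as AT-rich
troughs. The trough is the strict window minimum, leftmost on ties, making
the call deterministic.

Two delineation rules turn a 250-bp trough into a core interval, and both
are reported with a `method` label:

* **intergenic** (used when a gene annotation is supplied): the core is the
  intergenic interval containing the trough. This mirrors how published
  core coordinates of *M. sympodialis* were obtained, where the trough lies
  in an annotated intergenic gap. If the trough falls inside an annotated
  gene the function warns and falls back to extension.
* **trough_extension** (annotation-free): the trough window is extended
  symmetrically in step-sized increments for as long as each added window
  stays at or below `gc_ceiling`.

`gc_ceiling` defaults to the genome mean GC minus 15 percentage points. In
the nine published genomes, cores run 13–38% GC against 52–66% GC
backgrounds, so a 15-point margin cleanly separates the two populations
without tuning. Cores are capped at `max_core_len = 1500` bp (published
cores are 81–1200 bp), trimming symmetrically around the trough.

## Motif scanning (`build_pwm`, `llr`, `count_windows`, `shuffle_pwm`)

The motif is a 12-column position weight matrix. Column probabilities are
estimated from aligned instances with a pseudocount (default 0.5 per base
per column), which keeps every probability positive with the few training
instances a small genome provides. A k-mer's score is the natural-log
likelihood ratio of the PWM model to a background composition model;
background defaults to the scanned genome's own mononucleotide frequencies
rather than a uniform model, because in a 58%-GC genome an AT-rich word is
already surprising under composition alone and the LLR should measure
enrichment beyond that.

Sites scoring above 7.5 are counted in 500-bp windows sliding by 100 bp;
both strands are scanned by default (the motif shows no orientation bias),
and a site contributes to every window that fully contains its k-mer. The
control is a **column-shuffled PWM**: a seeded uniform permutation of the
columns (identity redrawn once), which preserves each column's weight
vector — hence the matrix's overall AT appetite — while destroying the
positional arrangement. Enrichment surviving the shuffle is attributable to
composition; the margin lost to it is attributable to the motif.

Two routes provide the PWM itself. When instances are supplied (the output
of an external motif-discovery step, or planted truth in simulations),
`build_pwm` estimates the matrix directly. The annotation-free fallback
`train_pwm` seeds one instance per called core (its most AT-rich 12-mer)
and runs one refinement pass keeping each core's best-LLR 12-mer. This
fallback is deliberately modest: on cores whose non-motif positions are
close to exchangeable AT noise, AT-richness seeding converges towards a
generic AT-rich matrix with little positional information, and the shuffled
control then shows little contrast. Full Gibbs-sampling motif discovery is
out of scope; where the contrast matters, supply instances.

## ChIP quantification (`subtract_input`, `call_full_region`, qPCR helpers)

The kinetochore-bound ("full-length") region is called from coverage by the
same arithmetic the original analysis used: scale the input track to the IP
library size, subtract per bin, floor negatives at zero (reads cannot be
negative evidence of binding). The enriched region is delineated by a
fraction-of-peak rule: bins at or above 10% of the chromosome peak,
merged across gaps of up to 500 bp, returning the run containing the
summit. The published analysis does not state its boundary criterion; the
10%/500-bp rule is this package's declared stand-in, chosen because it
reproduces 3–5-kb calls on simulated tracks emulating the observed
enrichment profiles, and both values are exposed as parameters.

qPCR arithmetic uses the standard delta-Ct model with amplification
efficiency fixed at 2.0: `percent_input = 100 * input_fraction *
2^(ct_input - ct_ip)`. Depletion of histone H3 at cores is expressed as the
H3:H4 percent-of-input ratio (`relative_ratio`), and enrichment over a
centromere-unlinked locus as a fold difference (`fold_vs_control`).

## Synteny and fate (`build_blocks`, `classify_fate`)

Ortholog pairs (one-to-one, from any external orthology pipeline) are
chained into collinear blocks, same or inverted orientation, tolerating up
to 3 unmatched genes between consecutive anchors. Fate classification takes
`k_flank = 5` genes on each side of a query centromere — published synteny
figures resolve a handful of flanking ORFs, and the parameter is exposed
for sensitivity checks — and locates their orthologs in the target genome:

| flanks land on | called centromere nearby? | status |
|---|---|---|
| one chromosome | yes, in the intervening interval | `conserved` |
| one chromosome | no | `inactivated` |
| two chromosomes | — | `breakpoint` |
| only one flank syntenic | yes, near it | `partial` |

Target-genome spans within 50 kb are treated as one syntenic context,
absorbing small local rearrangements. One reading of "partial" had to be
fixed: this package requires *exactly one* syntenic flank for `partial`;
when both flanks map to two different chromosomes the call is `breakpoint`
even if a target centromere happens to lie near one junction. The
alternative (letting an incidental centromere near a junction soften a
breakpoint to partial) makes the breakpoint signature depend on where the
acceptor chromosome's own centromere sits, which is unrelated evidence.

## Ancestral karyotype (`ancestral_chromosome_number`)

Chromosome counts are unordered character states; no stepwise 9 → 8 → 7
ordering is imposed, because a single fusion or breakage event moves the
count by one regardless of direction and the data contain no evidence for
ordering costs. The Fitch bottom-up pass returns the root's minimal-change
state set and the change count; the packaged species tree and counts
(`malassezia_karyotype()`) resolve to a nine-chromosome ancestor with two
changes (one origin of the eight-chromosome state, one of the
seven-chromosome state). The packaged topology is a transcription of the
published clade structure, not a reconstruction performed here.

# The synthetic-genome generator

`synthetic_spec()` defaults define the simulated study conditions: nine
chromosomes of 300 kb, i.i.d. background at 58.5% GC, one 800-bp core per
chromosome drawn i.i.d. at 80% AT, carrying 7–13 motif instances sampled
from the default PWM at non-overlapping positions and random strands, and
genes with lognormal lengths (median 1.4 kb) separated by lognormal
intergenic gaps (median 350 bp) tiling both arms. Cores are placed at least
10% of the chromosome length from either end so that rearrangement
junctions are never ambiguous with a core's own neighbourhood. Chromosome
length is scaled down from the megabase-scale originals to keep simulation
batteries fast; all the statistics the pipeline relies on (window GC
contrast, motif density contrast, coverage contrast) are local, so the
scaling does not change what passing means.

The default PWM (`default_motif_pwm()`) has consensus `ATTAATTTTAAT` with
0.88 on the consensus base, 0.02 on the complementary AT base and 0.05 per
G/C. The published motif exists only as a logo, so exact reproduction is
not claimed; this matrix was designed from its score distributions so that
the simulation reproduces the *reported behaviour* of the real motif:
planted instances clear the 7.5 LLR threshold against a 58.5%-GC background
in about 90% of draws, i.i.d. 80%-AT core sequence clears it rarely enough
that centromere windows count a handful of chance matches beside the
planted ones, GC-rich background windows almost never exceed three matches,
and a column permutation destroys most planted-site detections. The columns
are individually sharp but compositionally alike — which is precisely the
property that makes the shuffled-PWM control informative.

What the generator does **not** emulate: dinucleotide structure and repeats
(background is mononucleotide i.i.d.; a Markov-1 extension is a natural
robustness probe), rDNA and mitochondrial contigs, transcribed ORFs inside
centromere regions, assembly gaps, and read-level artefacts (coverage is
simulated per bin as Poisson, not per read). Passing the simulation battery
therefore demonstrates correctness of the inference logic under the stated
statistical model, not robustness to every artefact of real assemblies.

`simulate_chip` draws input bins as Poisson(depth) and IP bins as
Poisson(depth × f), f = 20 over a 4-kb window centred on each core.
`apply_breakage` and `apply_fusion_inactivation` implement the two
mechanisms exactly as modelled — breakage deletes the core sequence and
fuses the arms to other chromosomes' ends without scar sequence (no
interstitial telomere repeats, matching the observation that none were
found); fusion-inactivation concatenates two chromosomes and replaces one
core with a background-composition draw — and both keep gene coordinates
tracked so that ortholog tables between ancestral and derived genomes are
exact.

# Numerical and interface choices

* **Coordinates.** All public coordinates are 0-based half-open; reports
  print 1-based inclusive coordinates (the convention of published
  centromere tables), with BED output remaining 0-based. The published core
  table is internally inconsistent by one base between its core rows
  (length = end − start) and full-length rows (length = end − start + 1);
  the converters treat printed coordinates as 1-based with the printed
  length authoritative, and `paper_to_internal`/`internal_to_paper` are
  exact inverses.
* **Ties and determinism.** Trough ties break leftmost; the summit bin of
  an enrichment profile ties leftmost; every generator takes an explicit
  seed and restores the caller's RNG state. Identical inputs give identical
  outputs everywhere outside the explicitly seeded simulators.
* **Degenerate inputs.** All-N sequences, fully masked profiles, all-zero
  enrichment profiles, empty FASTA files and zero-length intervals raise
  informative errors rather than propagating NaN; a trough inside an
  annotated gene degrades gracefully to the extension method with a
  warning.
* **Problem sizes.** The shipped test battery runs 50-genome recovery
  sweeps, 20-seed mechanism recoveries, 50 paired shuffle comparisons and
  50 ChIP simulations at the default specification, and checks the window
  counter against a naive double-loop oracle on 50 random 10-kb sequences
  and the parsimony pass against exhaustive enumeration over all rooted
  binary topologies with up to six leaves. These sizes give binomial
  confidence tight enough for the 90–100% acceptance bands while keeping a
  full run in minutes on one CPU.

# Known limitations

* The intergenic delineation rule depends on annotation quality; fragmented
  annotations inflate cores up to the length cap.
* `train_pwm` is not a motif finder (see above); genuine de novo discovery
  should be done externally and its instances supplied.
* Fate classification assumes one-to-one orthologs; paralog-rich families
  should be filtered before block building.
* The fraction-of-peak ChIP boundary rule is a declared stand-in for an
  unstated published criterion; calls are parameter-dependent at the
  margins, and both parameters are exposed.
* Fitch parsimony requires a rooted binary tree and returns the root state
  set only; it does not weight events or date them.
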