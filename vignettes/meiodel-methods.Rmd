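---
title: "Models and methods behind meiodel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind meiodel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meiodel)
```

`meiodel` implements the computational chain used to study mutagenic end
joining at meiotic DSB hotspots: a generator of ground-truth double-cut and
end-joining events with their two assay readouts, an amplicon split-read
junction caller, and the statistics used to compare end-joining spectra
between genotypes. This vignette records the models, the numerical
conventions, and the design decisions — including the ones that were
genuinely open — in one place.

## Coordinates and conventions

All genomic coordinates are 0-based, half-open, everywhere: a deletion
`[left, right)` removes `right - left` bases. A junction is reported once,
at its *leftmost* equivalent placement. These conventions are applied
identically to simulated ground truth and to caller output, so recovery can
be asserted at exact coordinates.

**Junction microhomology** is the longest sequence that is simultaneously a
suffix of the retained left flank and a prefix of the resumed right flank —
equivalently, the length of the interval over which the junction can slide
without changing the joined sequence. Microhomology and inserted bases are
mutually exclusive at a junction: if the read carries bases matching neither
flank they are reported as an insertion and the microhomology is 0.

## The hotspot signal model

SPO11-oligo maps (`spo_map`) carry per-base read counts (or RPM;
`rpm()` converts using counts × 10⁶ / library size). Three primitives
serve both the simulator and the statistics:

* `smooth_hann(values, width)` — convolution with a Hann kernel
  `w[n] = sin²(πn/(width−1))`, `n = 0..width−1`, normalized to sum 1; at
  the edges the kernel is truncated and renormalized, so the output length
  equals the input length. The kernel's endpoints are zero, so a width-3
  filter is the identity. Widths of 21 bp (fine structure near peaks) and
  151 bp (broad profile shape) are the working conventions.
* `local_normalize(values, window = 3001)` — divides each base's signal by
  the mean within the centered window (truncated at the edges), putting
  hotspots of different strength on a common scale before averaging.
  Zero-mean windows yield 0 with a warning rather than an error, because
  flat zero stretches are routine at the borders of real tracks.
* `flip_and_average(profiles, flip_flags)` — mirrors flagged
  (left-hotspot) profiles about the hotspot center before taking the
  pointwise mean, so "toward the partner hotspot" points the same way in
  every profile of a hotspot-pair set.

`call_hotspot` defines a hotspot center as the argmax of the 151-bp
Hann-smoothed signal within the given bounds (leftmost on ties — a
deterministic, order-independent rule) and its strength as the *raw* count
sum, which makes strength invariant to the smoothing width. How a "hotspot
center" is best defined is genuinely open; argmax-of-smoothed-signal is this
package's stand-in, and every statistic that consumes centers takes them as
explicit arguments so an alternative definition can be substituted.

## The synthetic-data generator

The generator's defaults encode the study conditions; they are not tuning
knobs.

**Hotspot shape** (`simulate_spo11_map`): a major Gaussian peak at the
center with secondary peaks at +34 and +55 bp (weights 1 / 0.35 / 0.5, sd
5–6 bp) over a diffuse sd-150-bp background, with counts drawn
multinomially at 50,000 reads so maps carry sampling noise. The offsets
match the inter-peak distances that recur under the ~30-bp and ~60-bp
deletion classes.

**Double cuts** (`make_double_cuts`): the left cut is sampled from the map;
the spacing between the two cuts follows a mixture on the 10-bp lattice
{21, 31, 41, 51} with weights 0.25/0.35/0.25/0.15, integer jitter (sd
1.5 bp, truncated at ±4) and a hard 21-bp minimum — about two helical
turns, the smallest spacing at which two SPO11 complexes can co-occupy a
duplex. When the jitter pushes a draw below the minimum, only the jitter is
resampled (the mixture component is kept), so component weights are
reproduced exactly. Sub-minimum deletion classes observed in real data
(< 18 bp) have no mechanism with calibratable rates, so the generator does
not emit them by default.

**End joining** (`join_ends`, `repair_model`):

* *unresected* mode (NHEJ at SPO11 ends, the 2-nt 5′ overhangs treated as
  filled in before ligation): the junction stays at the cut positions up to
  a drawn microhomology offset m ∈ {0, 1, 2} (probabilities follow the
  chance model truncated at 2), giving deletions of size `spacing − m`.
* *resected* mode (MMEJ): per-end resection lengths are gamma distributed
  with mean 1100 nt — the mean meiotic resection length in mouse — and
  shape 4 (the shape is this package's choice; only the mean is
  constrained). Exact repeats of ≥ 3 bp shared between the resected flanks
  are enumerated and one is chosen at random as the junction, widening the
  deletion; when none exists the event falls back to a 0-bp joint and is
  tagged. Inside `run_pipeline` the search span is additionally capped so
  junctions stay within the amplicon — which mirrors the real assay, where
  the amplicon bounds what is observable.

**Insertions** (`make_insertion_event`): ectopic insertions splice a
double-cut fragment from another hotspot into the junction in either
orientation (donors 15–967 bp in the real data, median under 100 bp);
inverted insertions reinsert a local segment in inverted orientation, with
≥ 1 bp of microhomology at exactly one side — the signature that
distinguishes foldback-mediated events.

**Assay readouts**: `simulate_well_assay` draws per-well event counts from
Poisson(rate × genomes per well), with 16,000 haploid genomes per well as
the default seeding; planting a fixed number of events expresses
detection-limit arithmetic exactly. `simulate_amplicon_reads` amplifies
each molecule by a branching process (every copy duplicates per cycle with
probability 0.9, 22 cycles) and subsamples to the requested depth, giving
PCR-duplicate multiplicities a realistic spread without modeling polymerase
chemistry. Reads are 300-bp pairs from the molecule ends; substitutions are
added at the configured rate (0.001/bp default); base qualities are a
constant Q33 with error positions written as Q12 so the mean-quality filter
is exercisable. Read names encode molecule and event ids for truth
tracking.

What the simulator does *not* emulate: indel sequencing errors, chimeric
PCR artifacts (the balanced-indel artifact class is injected directly in
caller tests instead), quality-score correlation along reads, and S1-seq
readouts. Passing tests therefore demonstrate correctness of the
computational chain under substitution noise and PCR duplication — not
robustness to every artifact of a real sequencer.

## The junction caller

`call_junctions` runs: merge → assign/infer amplicons → collapse →
align → extract → filter → infer junction bases → dedup → quality filter,
logging every stage count.

* **Merging**: best ungapped overlap (≥ 20 bp, ≤ 10% mismatches) between R1
  and the reverse complement of R2; the consensus takes the higher-quality
  base at disagreements and the maximum quality per overlap position.
  Unmerged pairs are excluded from calling and counted.
* **Amplicon inference**: read outer endpoints are located by exact
  terminal 20-mer seeding (a second seed offset tolerates one error in the
  terminus) and clustered with ±5 bp tolerance; clusters with ≥ 10 reads
  become amplicons. Seed-and-extend against the reference replaces full
  alignment here because endpoints, not junctions, are all that matters at
  this stage.
* **Collapsing**: exact-sequence groups per amplicon keep the per-position
  maximum quality and the group size — identical reads are potential PCR
  duplicates of one molecule.
* **Alignment**: a built-in affine-gap aligner (Rcpp), global in the read
  and local in the reference (free reference end gaps), scores match +1,
  mismatch −4, gap open −6, gap extend −1, so a several-hundred-bp deletion
  remains one operation. A read is *unaligned* when its identity
  (matches/read length) falls below 0.8 — with these scores a legitimate
  large deletion drives the raw score negative, so identity, not raw
  score, separates real molecules from foreign sequence. Mapping
  confidence is a 0–60 margin: `min(60, S1 − S2)` with S2 the best score
  over alignment end columns more than half a read length from the best
  end; a unique full-length alignment scores 60 and two equal placements
  score 0. The 55 threshold mirrors conventional uniqueness filters without
  claiming equivalence to any specific external aligner. The margin is
  computed per alignment (each unique sequence yields one), which resolves
  the open question of per-segment versus per-read filtering in favor of
  per-alignment.
* **Junction extraction**: indel operations within 30 bp of each other on
  the read are clustered, together with short aligned segments between
  them, into one composite junction. The cluster's deletion length is the
  reference span it consumes and its insertion length the read span, so
  the net size is invariant to how the aligner fragmented the junction —
  inserted or low-quality bases frequently re-align piecewise against the
  deleted reference. Clusters with deletion span ≥ 10 bp become
  candidates.
* **Artifact filter**: candidates with net deletion (deletion − insertion)
  < 10 bp are discarded; an insertion and deletion of roughly equal length
  is the signature of a low-quality segment that failed to align, not a
  structural variant. "Roughly equal" is implemented exactly as
  net < 10 bp.
* **Junction bases**: deletions are canonicalized leftmost with maximal
  microhomology; insertion-carrying junctions report the read bases
  verbatim and microhomology 0. Flanks are checked against the read (10 bp
  each side, 20% mismatch tolerance for sequencing error); inconsistent
  calls are flagged invalid and dropped.
* **Dedup and filters**: calls with identical (amplicon, ordered junction
  list, inserted bases) collapse to one unique event — conservative,
  because two independent molecules with the same junction are counted
  once. The surviving event must have a best read with mean base quality
  ≥ 25 and mapping confidence ≥ 55.

## Statistics

* `microhomology_chance(x) = (x+1)(1/4)^x (3/4)²`: the junction's shared
  sequence extends independently left and right, each extension geometric
  with per-base probability 1/4; x+1 counts the splits. At x = 0 this is
  0.5625 — 56% of chance junctions show no microhomology. The formula is
  exact for every x smaller than the flank length, which the tests verify
  by exhaustive enumeration of all flank pairs up to length 6.
* `fisher_exact`: two-sided p by summing hypergeometric probabilities of
  all tables (margins fixed) no more probable than the observed one, with
  1e-12 relative slack for floating-point ties. This is the conventional
  two-sided rule; alternative two-sided rules exist and give different
  values on extreme tables, which is documented here because one published
  comparison (8/29 vs 0/33, printed p = 0.0045) is not reproduced by the
  conventional rule (enumeration gives ≈ 0.0013) — the variant or counts
  behind that figure differ, and the package does not guess.
* `spread_test`: Levene's test in the Brown–Forsythe variant (ANOVA on
  absolute deviations from group *medians*) — the robust default when only
  "Levene's test" is specified. Degenerate all-constant groups return p = 1
  with a warning.
* `shift_test`: Wilcoxon rank-sum with normal approximation and tie
  correction, reported with the difference of medians.
* `stratify_sizes`: bins at 11/18/25/46/76/200 bracket the recurring size
  classes (~13, ~21, ~30, ~60 bp, and ≥ 200 bp); per-stratum profiles are
  21-bp Hann smoothed and size densities use a Gaussian kernel with 2-bp
  bandwidth (density plots in this field are shown without parameters; 2 bp
  resolves the 10-bp lattice without over-smoothing).
* `adjusted_frequency`: the expected double-cutting weight of a hotspot
  pair is the *product* of its two hotspot strengths — an independence
  assumption, flagged as such; the published adjustment does not state its
  formula. The adjustment is invariant to rescaling all strengths by a
  common factor, which the tests assert.

## Determinism and problem sizes

Every stochastic stage takes an explicit seed; `run_pipeline` derives
per-stage seeds from the master seed and the stage name, so a configuration
determines its outputs byte for byte. The test suite exercises the full
chain at moderate scale — for example, exact-recovery runs use 150–250
events sequenced to 4,000–10,000 read pairs, calibration runs use 2,000
null replicates — sizes chosen so the whole suite completes in about a
minute while keeping standard errors far below the tested margins.

## Known limitations

* The caller handles deletions (with or without inserted bases); tandem
  duplications, inversions and translocations are out of scope, as is
  paired-end rescue of unmerged reads.
* Composite junctions closer than 30 bp on one read merge into a single
  candidate by construction.
* The resected-mode microhomology search is bounded by the amplicon in
  pipeline context, so simulated resection tails longer than the amplicon
  are unobservable — as they are in the real assay.
* Published genotype-specific event counts cannot be reproduced without the
  underlying sequencing data; the package instead proves its machinery by
  parameter recovery on synthetic data and reproduces the published
  closed-form and contingency-table values exactly.
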