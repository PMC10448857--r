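---
title: "Methods: HEG landscape analysis on synthetic phage communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HEG landscape analysis on synthetic phage communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hegscape)
```

This vignette is the package's own account of its models and procedures:
what each stage assumes, which parameters matter and why their defaults are
what they are, what the synthetic-data generator does and does not emulate,
and where the genuinely open design choices were decided.

## Coordinates and records

All internal coordinates are 0-based half-open on the forward strand; strand
is a feature attribute, never a coordinate transform. GenBank's 1-based
inclusive locations (including `complement()` and origin-spanning `join()`
locations) are converted at the reading boundary and nowhere else. A feature
crossing the origin of a circular replicon is stored once with
`wraps_origin = TRUE` and interpreted modulo the genome length; consumers
unwrap with `unwrap_interval()`. This follows from the circularity
assumption of the neighborhood analysis: windows near the origin need
modular arithmetic anyway, so one representation serves everywhere.
`N` bases are legal in sequences; they never count as matches anywhere
identity is computed.

## HEG calling and allele states

A CDS is called a HEG iff it carries at least one nuclease-class domain hit
with independent e-value at most `heg_domain_evalue` (1e-3). The
accession-to-family map (`domain_family_map()`) is plain data the user can
extend; MUG113 hits are relabeled to the T5orf172 family because the two
profiles are closely related, and an HNH-class hit co-occurring with an AP2
hit on the same or an immediately adjacent CDS yields the composite IPA-HNH
family (N-terminal HNH nuclease, C-terminal AP2 DNA-binding domain).
Calling is monotone in the threshold: relaxing it never removes a call.

Allele-state classification works per homologous locus group across
genomes. The reference length of a group is its **longest observed allele**
(single CDS, or a reconstituted split pair rounded to the codon grid),
not the modal length: frameshifts and in-frame deletions only shorten a
locus, and with small groups the modal length flips to the deleted form
whenever deleted alleles happen to dominate, inverting the calls. The
states:

* **absent** — no CDS with a nuclease hit at the locus;
* **frameshifted** — two or more CDSs cover the locus and either restore
  one domain architecture between them (nuclease class on one fragment,
  DNA-binding class on another — the primary test) or concatenate to the
  reference length within 2 bp. Variable-stop alleles are reported under
  this state too, with the evidence string saying so, since coverage-level
  data cannot distinguish the two;
* **in-frame deletion** — a single CDS shorter than the reference by a
  multiple of 3 of at least `min_inframe_del_bp` (30 bp);
* **intact** — otherwise.

Split pairs are additionally emitted as one `fused` record so downstream
architecture analyses can treat the reconstituted protein as a unit.

Locus groups come either from a user-supplied locus map or from
flank anchoring (`group_heg_loci()`): two calls are the same locus only
when **both** 2 kb flanks share qualifying identity blocks. Requiring both
flanks is deliberate: when an intervening HEG is absent in one genome, the
neighbor's single flank window reaches the next gene over and one-flank
linking merges adjacent loci.

## Identity blocks

`find_identity_blocks()` is a self-contained seed-and-extend local aligner:
exact k-mer seeds (k = 11, both strands), ungapped X-drop extension
(match +1, mismatch −2, X = 20), banded stitching of collinear extensions
across small indels (gap open −5, extend −2, band 32), and an exact
per-diagonal refinement pass (maximum subarray over the whole diagonal,
triggered when a diagonal's best extension scores ≥ k + 2) that closes the
gap between the X-drop heuristic and the Smith–Waterman optimum on
substitution-dominated inputs. Identity is matches over alignment columns,
gap columns included — the convention the 60% threshold is calibrated
against. Reported blocks satisfy identity > 60%, length ≥ 125 bp and
e-value ≤ 1e-5; the e-value is the ungapped Karlin–Altschul formula
`E = K·m·n·exp(−λS)` with the published (λ, K) = (1.33271, 0.620991) for
the +1/−2 system, applied to stitched blocks as well — a documented
approximation that is acceptable because the e-value is only an acceptance
filter, never a reported statistic.

The engine's sensitivity bound is the seed: an alignment whose longest
exact match run is shorter than 11 bases cannot be found at word size 11
(the same bound applies to BLASTN at this word size). The oracle tests
assert exactly this contract: every reported block is within the X-drop
margin of the Smith–Waterman optimum, and misses occur only for seedless
alignments.

`cluster_sequences()` provides longest-first greedy clustering (CD-HIT
style): a sequence joins the first cluster whose representative shares at
least the threshold identity over the shorter sequence's length, computed
by global-local alignment; representatives are founding members.

## Neighborhoods

The neighborhood of a HEG is the ±3250 bp window around it, extended once
(single pass, deliberately not transitive — transitive closure over a
gene-dense genome would swallow it whole) to the full extent of every ORF
overlapping the window, wrapping the origin on circular replicons. Overlap
means ≥1 shared base and ignores strand. Marker flags (terminase, capsid,
TMP, RNR, replicase) are set per neighborhood — presence/absence, not gene
counts — from configurable accession lists at annotation e-value ≤ 0.1.
The extraction is validated against a brute-force doubled-sequence overlap
scan on 1000 random circular cases.

## HEG-islands

Qualifying blocks between a genome pair are chained when collinear within
`chain_gap_bp` (2000 bp, tolerating HEG-sized unconserved gaps inside
cargo). A chain becomes an island iff its span is at least
`island_min_span_bp` (10 kb), the cargo contains at least one marker gene,
and a HEG CDS lies within `heg_bracket_bp` (1000 bp — "flanked by" has no
canonical distance, so this default is an explicit, configurable choice) of
each end. The island interval is trimmed to exclude the flanking HEG CDSs,
and the partner coverage and length-weighted identity are computed over
blocks clipped to the trimmed interval, with identity recounted on the
clipped segment — otherwise the 100%-identical flanking HEGs inflate the
cargo identity estimate. Regions failing only the bracket test are emitted
separately as unbracketed conserved regions. Islands are called per ordered
pair and deduplicated at ≥50% interval overlap. Cognate flanking HEGs of
matched islands classify as homologous (shared qualifying block), same
class without homology, different class, or absent.

## Domain architecture and repeats

HEG nuclease domains sit at one protein terminus, so each protein is
bisected by trimming from the nuclease domain to the nearest terminus
(fewer residues outside the domain; exact ties go to the C-terminal side —
a documented tie-break, not a biological claim). The DNA-binding fragment
is classified by a fixed decision tree: CapR at e ≤ 1e-10 (Zn-finger count
= maximal greedy set of non-overlapping qualifying hits), else
DUF723/DUF4397 at e ≤ 1e-3 (the fallback threshold is not stated by the
source analysis and is surfaced in config), else a remote-homology
annotation table (RepA_N or DUF723/DUF4397; counts deliberately not
quantified, since remote-homology sensitivity is not comparable to
hmmsearch).

Degenerate intragenic repeats are found by an exhaustive ungapped diagonal
scan of the DBD-coding region against itself: for every start-to-start
offset, the maximum-scoring segment under breakeven scoring
(match +(1−t), mismatch −t for t = 60% identity) — which makes the optimum
the longest segment above the identity threshold rather than a short
perfect run. Seeded extension is the wrong tool here: 30-90 bp repeats at
~70% identity sit at its noise floor, while the region is small enough
(≤ a few kb) for the exact scan. Repeat pairs report start-to-start
spacing and frame status; a recombination product between a pair shortens
the CDS by the spacing, which for the designed 228 bp spacing is in-frame.
Domain swaps between any two genes (including phage HEG versus
satellite-encoded genes) are classified by whether blocks cover ≥50% of
the shorter DBD-coding and nuclease-coding regions.

## Splice detection

Intron candidates come from coverage dips: the per-base depth is smoothed
with a centered running mean (`smooth_bp` = 51 — overdispersed RNA-seq
counts put the raw median far below the mean, so the expression check and
reference level use the smoothed track), the exonic reference level is the
median outside candidate dips (iterated once), and a dip qualifies iff its
mean raw depth is below `dip_ratio` (0.3) times the reference and it runs
at least `min_intron_bp` (100 bp). Boundaries are refined at base
resolution by a maximum-likelihood changepoint under a negative binomial
with dispersion estimated from the exonic background by method of moments,
fitting a three-segment mean profile (exon | 5 bp linear ramp | dip) that
matches the boundary transition the coverage model assumes.

Exon chaining then uses whichever evidence is available. With a
junction-support table (the hook for spliced-read evidence), each boundary
snaps to the max-support junction within `snap_bp` (10 bp), widened to
`snap_bp + smooth_bp/2` for junctions whose intron interval overlaps the
detected dip — boundary uncertainty scales with the smoothing window.
Without junction evidence, boundary offsets within ±10 bp are searched for
the assignment making the spliced CDS a valid ORF (start codon, terminal
stop, no internal stop, length divisible by 3 — so fragment-internal
start/stop codons land inside the introns and are removed); the search is
iterative deepening over the total offset (smallest total first, caps
20/10/7 for 1/2/3 junctions; per-junction greedy beyond three), returning
`orf_valid = FALSE` rather than an error when nothing validates. Coverage
alone cannot always identify junctions uniquely — frame-consistent
alternatives that splice a whole codon in or out can be valid ORFs — which
is why the junction-evidence path is the pipeline's reported boundary
source, mirroring the two-step practice of dip inspection followed by
spliced-read/RT-PCR confirmation. On the default synthetic conditions the
full evidence path recovers intron counts, boundaries within ±5 bp, and
the byte-exact pre-fragmentation CDS.

## Satellites

The candidate locus is the seed homology interval plus 12.5 kb on each
side. Attachment-site repeats of at least 15 bp at ≥90% identity are
searched between the 3 kb windows outside each end of the core span, in
both direct and inverted orientation — att cores of integrase systems are
conventionally direct repeats, but bound-adjacent inverted repeats are
also reported; the package records the orientation and does not suppress
either. Element bounds are the inner edges of the best pair. The homology
support against a reference element is the total length of a
maximum-weight set of non-overlapping qualifying blocks, computed exactly
by dynamic programming ("non-contiguous": blocks need not chain); greedy
selection is shipped only as a comparison baseline. A call passes iff
support reaches `satellite_min_homology_bp` (10 kb). The integrase class
(tyrosine/serine, configurable accession lists) comes from any
integrase-annotated gene within 2 kb of either att site.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, not
phage biology in general. A community is one template genome (default
60 kb, GC 0.42, circular) — a gene grid interleaving the five essential
markers with HEG loci of alternating families, filler ORFs (30% of which
carry decoy nuclease hits *above* the calling threshold), and a flexible
background region — from which member genomes derive with background
substitutions (default 1% — ICP1-like isolates are nearly identical) and
independently drawn HEG allele states (frameshift = 1 bp insertion
splitting the CDS at the inter-domain linker; in-frame deletion = excision
between the starts of the designed 90 bp degenerate repeats spaced 228 bp
apart; absent = clean excision). Domain hits are emitted directly with
e-values drawn log-uniform below the calling threshold for true domains
and above it for decoys — decoupling all tests from external HMMER
binaries while preserving every downstream decision. Islands are implanted
between *unrelated* genomes (high-identity cargo against a dissimilar
background is what defines them); coverage is negative binomial
(`depth_dispersion` is the NB size, 0.3 by default — strongly
overdispersed, the realistic stressor for dip detection; size → ∞
recovers Poisson) with 5 bp linear boundary ramps; satellite loci get
exact att repeats with junction bases forced to mismatch so the designed
repeat length is the truth, and a reference element at 95% identity.
A self-audit (`audit_truth_consistency()`) re-extracts every truth entry
from the emitted sequence after generation.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: no indel evolution inside shared cargo (the
island identity statistic is exact on substitutions only), no repeat-rich
backgrounds (the designed repeats are the only long repeats, which is what
makes detector false-positive rates measurable), no annotation errors
beyond the designed frameshift splits, no read-level artifacts (coverage
is drawn per base, not from mapped reads), and no phylogenetic structure
among genomes beyond one template.

## Problem sizes and determinism

The shipped experiments use communities of 6 genomes × ~59 kb, 20-50
island pairs with 12 kb cargo, 40-100 fragmented genes and 25-50 satellite
loci — sizes at which every stage's behavior is already asymptotic while a
full run of the test suite and acceptance script completes in minutes.
Every stochastic step is seeded; `run_pipeline()` writes a manifest
(config snapshot, input digests, seed, outputs) and two runs from the same
seed are byte-identical.

## Known limitations

* Allele-state classification needs at least one full-length allele (or a
  reconstituted split pair) in the locus group; a group consisting
  entirely of deleted alleles is indistinguishable from intact.
* The aligner's word-size-11 seeding misses qualifying alignments whose
  longest exact run is under 11 bp (~70% identity over short cores).
* Coverage-only splice boundaries are information-limited at NB size 0.3
  (roughly 75-90% within ±5 bp); exact recovery needs junction evidence.
* `block_evalue()` applies ungapped (λ, K) to stitched blocks.
* Frameshifts and variable-stop alleles are reported under one state.
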