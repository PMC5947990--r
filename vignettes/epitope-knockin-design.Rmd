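---
title: "Designing guides and ssODN donors for C-terminal epitope knock-in"
author: "knocktag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing guides and ssODN donors for C-terminal epitope knock-in}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knocktag)
```

## The design problem

Tagging an endogenous protein at its C-terminus by homology-directed
repair (HDR) needs three reagents designed together: an SpCas9 guide RNA
cutting as close as possible to the stop codon, a single-stranded oligo
donor (ssODN) that carries the tag coding sequence flanked by homology
arms, and donor mutations that stop Cas9 from re-cutting the repaired
allele. knocktag automates this design, one transcript at a time or for a
96-well plate of targets.

The guide is placed in the 3'UTR rather than the coding sequence: an
unrepaired cut there produces small indels in untranslated sequence
instead of frameshifts, so failed HDR events are usually silent. Because
HDR efficiency falls off with the distance between the cut and the
insertion point, and because typical Cas9 indels are a few bases wide,
guides cutting 8-15 nt downstream of the stop codon are preferred: far
enough that end-joining indels rarely reach the stop codon, close enough
that HDR stays efficient.

## Coordinates and the design window

All internal coordinates are 0-based half-open; GTF/GFF3 input (1-based
inclusive) is converted at the boundary. GTF dialects disagree on whether
the CDS includes the stop codon, so `load_annotation()` treats an
explicit `stop_codon` feature as authoritative and otherwise checks the
last 3 CDS bases against TAA/TAG/TGA, falling back to the 3 exonic bases
just after the CDS. Transcripts with no 3'UTR (no insertion site exists),
a coding length not divisible by 3, or a stop codon split across a splice
junction (the correct handling is ambiguous, so we refuse to guess) are
skipped with a warning.

`extract_design_region()` returns a window of spliced transcript-
orientation sequence centred on the stop codon - 100 nt before the first
stop base and 100 nt from it onwards by default (`window_nt = 200`,
configurable; at least 46 so one 23-nt Cas9 site fits on either side).
The window is truncated, never padded, at transcript ends, and each base
carries a CDS/UTR3/FLANK label and its genomic coordinate so designs map
back to the genome exactly. N bases are kept in the sequence but poison
any overlapping guide candidate.

## Guide enumeration and geometry

Every 23-nt window on both strands matching N20-NGG yields a candidate.
The blunt SpCas9 cut sits 3 nt 5' of the PAM, between protospacer
positions 17 and 18. Distance is measured from the bond: `cut_to_stop =
cut_offset - (stop_offset + 3)`, so 0 means the cut bond abuts the last
stop-codon base and positive values run into the 3'UTR. The convention
matters - published "8-15 bp downstream" statements rarely define their
measuring points - and is recorded in every output table.

## Ranking policy

The selection policy layers one stated preference over two unstated ones,
and the choices are deliberately exposed in `design_config()`:

* **Hard filters.** The cut bond must fall on a UTR3-labelled base
  (guides whose protospacer overlaps the CDS are fine; only the cut
  position is constrained). Aggregate specificity must reach
  `specificity_floor` (default 50 of 100). In batch mode the cut may be
  at most `batch_max_distance = 30` nt from the stop.
* **Tiered ordering.** Candidates cutting inside `preferred_window =
  c(8, 15)` precede all others; within a tier higher on-target score
  wins, ties broken by smaller distance, then protospacer lexicographic
  order so ranking is a total order independent of input order.
* **Output.** The first `top_k = 2` survivors are reported, each with a
  36-mer crRNA ordering oligo (20-nt target transliterated to RNA + a
  16-nt repeat) and the 67-mer tracrRNA constant as metadata. Zero
  survivors is data, not an error: the bundle carries a machine-readable
  failure reason.

How efficiency and specificity scores combine into one ranking is a
genuinely open design point (the models come from different scales); we
chose window membership as the first-tier key, on-target score as the
second, and specificity as a hard floor rather than a sort key, since
off-target burden is a veto-style criterion in practice.

## On-target scoring

`ruleset2_features()` implements the published gradient-boosting
featurization over the 30-nt context (4 nt upstream + protospacer + PAM +
3 nt downstream): position-specific nucleotide (30 x 4) and adjacent
dinucleotide (29 x 16) indicators, position-independent mono- and
dinucleotide counts, protospacer GC count with low/high flags, and the 16
NGGN PAM-variant indicators - 623 named features, stable across calls.
The trained model itself is an externally distributed artefact and is not
bundled; `ontarget_model()` plugs in any linear model over these feature
names (predictions clipped to [0, 1]).

Without a model the package uses a documented deterministic fallback so
the pipeline stays self-contained: `0.5 * gc_term + 0.5 * run_term`,
where `gc_term = max(0, 1 - |GC20 - 10| / 10)` rewards mid-range GC
content and `run_term` zeroes out protospacers containing a
homonucleotide run of 5 or more. This is a coarse heuristic standing in
the same [0, 1] slot as a trained model, not a re-implementation of one;
rankings produced with the fallback should be read as
proximity-dominated.

## Off-target search and specificity

`find_offtargets()` reports every 20-nt window, on either strand of every
chromosome, within 3 mismatches of the protospacer and flanked by an NGG
or NAG PAM. The scan is exhaustive (Biostrings pattern matching over a
concatenated genome), which at this mismatch radius is equivalent to an
unrestricted Bowtie-style 3-mismatch search and strictly more sensitive
than seed-restricted alignment modes; there is no index to build and no
sensitivity caveat. The on-target locus is reported but flagged `self`
and excluded from aggregation.

Each hit is scored with the MIT single-hit formula using the published
Hsu et al. (2013) per-position weights W (position 20 PAM-proximal):

    score = 100 * prod(1 - W[p]) * 1 / (((19 - dbar)/19) * 4 + 1) * 1/m^2

with `dbar` the mean pairwise distance between mismatch positions. Two
conventions the formula's source leaves implicit are fixed here: a
perfect match scores 100, and a single mismatch takes `dbar = 19` so its
distance term is 1. The aggregate specificity is
`100 * 100 / (100 + sum(single-hit scores))`, 100 when no off-targets
exist, monotonically decreasing as hits accumulate. NAG hits are weighted
like NGG in the aggregate (their PAM class is reported so users can
down-weight downstream); CFD scoring and bulge-tolerant search are out of
scope.

## Donor layout and arm arithmetic

The donor is `5' arm | tag | stop codon | rest of 3' arm`, with the tag
inserted immediately 5' of the stop so the translated junction reads
...last-residue-tag-stop in frame. Both arms get
`floor((cap - tag_len)/2)` nt under the `ssodn_cap = 200` total; the stop
codon is budgeted inside the 3' arm - the only convention under which a
66-nt tag leaves exactly 67-nt arms in a 200-mer, which also fixes the
odd-remainder rule (a 27-nt tag gives 86/86 and a 199-mer donor, one nt
of the cap unused). Arms shorter than `min_arm = 30` nt are refused;
regions too short for full arms truncate both arms symmetrically with a
warning. The oligo is emitted on the PAM strand (the guide's strand) by
default, reverse-complemented when the guide sits on the region's minus
strand, with `emit_strand = "nonPAM"` available since both strands have
been reported to work as donors.

The bundled tag catalogue carries standard published coding sequences for
V5 (42 nt), 3XFLAG (66), Myc (30) and HA (27); custom tags are accepted
as in-frame coding sequences and validated (length divisible by 3, no
internal stop).

## Blocking re-cutting

`plan_pam_block()` decides how the donor escapes re-cleavage, in order:

1. If the insertion point falls strictly inside the protospacer/PAM
   footprint, the insertion itself destroys the site and no edit is made
   (`none_needed`). This inference is controllable: `always_block = TRUE`
   forces an edit anyway.
2. PAM wholly in the 3'UTR: the terminal G is rewritten, NGG to NGC by
   default (NGT optional) - one base, no coding consequence.
3. PAM G inside the CDS: the alphabetically first synonymous codon change
   at that position that also avoids leaving an NGG or NAG at the
   register (an NGG-to-NAG "block" would barely block).
4. No synonymous option (Trp/Met codons): the single-base substitution
   minimising, lexicographically, the absolute Kyte-Doolittle hydropathy
   change then the charge-class change (D/E negative; K/R/H positive;
   others neutral) of the altered residue, flagged `conservative_CDS` in
   the output. The scale and classes are recorded in run metadata.
5. A PAM G on the stop codon is never edited; if its partner G sits in
   the UTR that one is edited instead.

Every accepted donor is finally re-scanned for an intact
protospacer+NGG match on the guide strand; assembly fails rather than
emit a re-cuttable donor (pathological repeats can make blocking
impossible). Failed guides are dropped from the bundle with a note.

## Batch mode and plate layout

`batch_design()` activates the 30-nt distance cap, designs each target
once, and assigns targets to wells A1-H12 in row-major order (A1..A12,
B1..), spilling past 96 onto further plates. Control targets can be
pinned to chosen wells on every plate; repeated positive controls across
a plate expose positional artefacts in downstream screens. Design
failures are rows carrying a reason, not process errors - only I/O and
validation faults abort a run. `predict_genotyping_amplicons()` adds the
tag length to a wild-type amplicon and warns when the wild-type product
leaves the 400-600 bp band genotyping PCRs are designed into.

## The synthetic fixture generator

`generate_fixtures()` builds deterministic test genomes: one single-exon
gene per chromosome, guide sites planted at exact cut-to-stop distances,
and off-target decoys planted at exact Hamming distances with chosen PAM
classes, all recorded in a truth table. Three construction choices make
the truth table exact rather than probabilistic:

* The background alphabet is {A, C, T} with CC dinucleotides forbidden,
  so no PAM (NGG or its reverse complement) can occur by chance - the
  planted GG dinucleotides are the only Cas9 sites, while 3^20
  protospacer diversity keeps spurious protospacer matches negligible.
* Guides are planted by writing only the PAM's GG; the protospacer is
  whatever sequence is already there, so planting never disturbs the
  CDS, stop codon or reading frame.
* Decoy mutations swap within {A-T, C-A, G-T}, never creating G or C, so
  a decoy is at its intended Hamming distance and nothing else; mismatch
  positions are the PAM-proximal ones, where the MIT weights keep
  single-hit scores low.

The generator emulates design *geometry*, not genome composition: base
content is unrealistic, genes are single-exon, and there are no repeats
or pseudogenes. Passing the fixture suite therefore validates coordinate
arithmetic, enumeration, scoring formulas, selection policy and donor
assembly - it says nothing about on-target score accuracy on real
genomes (use a trained model for that) and does not exercise
splice-junction windows, which have their own dedicated tests.

## Determinism and problem sizes

Every stochastic step is seeded: the fixture generator takes an explicit
seed and restores the caller's RNG state, and the design pipeline itself
is deterministic (total-order ranking, alphabetical tie-breaks). The test
suite runs on fixtures of 1-10 genes with 150-300 nt CDS and 120-240 nt
UTRs; the off-target scanner is cross-checked against a literal
brute-force scan on a genome padded to ~100 kb, and the re-cut-protection
property is checked over ~200 assembled donors across seeds and all four
catalogue tags - sizes chosen to exercise every code path while keeping
the suite quick on a laptop.

## Known limitations

* SpCas9/NGG only; no Cas12a or SaCas9, no N-terminal or internal
  tagging sites.
* The fallback on-target score is a stand-in heuristic; supply a trained
  linear model over the provided features for real campaigns.
* Donors are short ssODNs; long dsDNA/plasmid donors with 100-500 bp
  arms are out of scope.
* Amplicon prediction assumes the primers are given; primer design
  itself is delegated to standard tools.
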