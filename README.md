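# knocktag

Design of CRISPR-Cas9 guides and single-stranded oligo (ssODN) donors for
scarless knock-in of short epitope tags (V5, 3XFLAG, Myc, HA) at the
C-terminus of protein-coding genes — for labs running RNP-based tagging
experiments, one gene at a time or as a 96-well batch.

## What it computes

Given a genome (FASTA) and a transcript annotation (GTF/GFF3), for each
target transcript the package:

1. extracts a 200-nt window of spliced coding-strand sequence centred on
   the stop codon;
2. enumerates every SpCas9 site (N20-NGG, both strands), with the blunt
   cut placed 3 nt 5′ of the PAM and distance measured as
   `cut_to_stop = cut_offset − (stop_offset + 3)`;
3. scores each candidate for on-target efficiency (Rule Set 2
   featurization of the 30-nt context, with a pluggable linear model and
   a documented deterministic fallback) and for specificity (exhaustive
   ≤3-mismatch off-target search against NGG/NAG PAMs, scored with the
   MIT mismatch-weight model:
   `100 · Π(1−W[p]) · 1/(((19−d̄)/19)·4+1) · 1/m²` per hit, aggregated as
   `100·100/(100+Σ)`);
4. selects the top two guides, preferring cuts 8–15 nt into the 3′UTR
   (hard filters: cut in the UTR, specificity ≥ 50, and ≤30 nt from the
   stop in batch mode);
5. assembles one ≤200-mer ssODN per guide — symmetric homology arms of
   `⌊(200 − tag)/2⌋` nt (67/79/85/86 nt for the 66/42/30/27-nt catalogue
   tags, stop codon budgeted inside the 3′ arm), tag inserted in frame
   immediately before the stop, and a PAM-blocking mutation (NGG→NGC in
   the UTR; synonymous or, failing that, hydropathy-conservative
   substitutions in coding sequence), emitted on the PAM strand — plus
   the matching 36-mer crRNA ordering oligo (20-nt target + 16-nt
   repeat) and the 67-mer tracrRNA constant.

A deterministic fixture generator (`generate_fixtures()`) builds
synthetic genomes with planted guide sites and off-target decoys plus a
truth table, so the whole pipeline is testable offline.

## Worked example

```r
library(knocktag)

dir <- file.path(tempdir(), "fix")
fx <- generate_fixtures(fixture_spec(seed = 5, n_transcripts = 3), dir = dir)
genome  <- load_genome(fx$paths$fasta)
catalog <- load_annotation(fx$paths$gtf, genome)

bundle <- design_for_target("FIXT0001", "V5", genome, catalog)
bundle
#> design_bundle for FIXT0001 (tag V5)
#>   #1 ATAAATCTCTTCAATCTAGG TGG+ cut+13 nt from stop, on-target 0.80, specificity 100.0, donor 200 nt
#>   #2 AATATAAATCTCTTCAATCT AGG+ cut+10 nt from stop, on-target 0.70, specificity 70.2, donor 200 nt
```

Both selected guides cut inside the preferred 8–15 nt band downstream of
the stop codon (`cut+13`, `cut+10`). The second guide has planted
off-target decoys at 1–3 mismatches, so its aggregate specificity drops
to 70.2 (still above the floor of 50); the first sees no off-targets and
scores 100.

```r
bundle$donors[[1]]
#> ssodn_design: 200 nt on the PAM strand; arms 79/79 nt; tag V5 (42 nt)
#>   blocking edits: none (none_needed)
#>   junction: ...TLQQIGKPIPNPLLGLDST*
```

The donor is exactly 200 nt: 79-nt arms around the 42-nt V5 tag. For
this guide the tag insertion point falls inside the protospacer, which
by itself destroys the target site, so no blocking edit is needed
(`none_needed`); the junction translates as ...native residues, the V5
peptide `GKPIPNPLLGLDST`, then the stop. Guides whose site survives the
insertion get an explicit edit (`pos:ref>alt:rationale` in the output
table).

```r
predict_genotyping_amplicons(c(-125L, 325L), bundle)
#> wt_len ki_len
#>    450    492
```

A 450-bp wild-type genotyping amplicon becomes 492 bp after V5 knock-in
(+42 nt), an easily resolved gel shift.

For plates: `batch_design(targets, "V5", genome, catalog)` applies the
30-nt distance cap, fills wells A1–H12 row-major (97+ targets spill to
plate 2), pins control wells on every plate, and writes TSV/FASTA/BED
outputs via `write_design_table()`, `write_ssodn_fasta()`,
`write_crrna_fasta()` and `write_guides_bed()`.

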