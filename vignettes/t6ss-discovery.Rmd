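---
title: "Discovering and classifying Bacteroidales T6SS loci: methods and design"
author: "t6finder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and classifying Bacteroidales T6SS loci: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Type VI secretion systems (T6SS) are contact-dependent toxin-injection
machines widespread in gut Bacteroidales. Their structural genes (TssB/C
sheath, Hcp tube, VgrG spike, ClpV ATPase, and the associated Tag
proteins) cluster in chromosomal loci that segregate into three conserved
genetic architectures, GA1-GA3, two of which ride on integrative
conjugative elements (ICE) and move horizontally between co-resident gut
strains. `t6finder` implements the complete in-silico side of that
analysis for annotated (often draft, multi-contig) genomes:

1. **Sentinel co-localization (pass 1).** Proteomes are scanned with
   position-specific profiles for the two sentinel families, VgrG and
   ClpV. A genome seeds a candidate locus when both sentinels hit on one
   contig with an E-value of at most `1e-3` and at most fifteen genes
   between them; 25 genes flanking the outermost sentinels are retrieved
   (truncated at contig ends).
2. **Clustering and annotation.** All window proteins are clustered
   greedily at 30% identity over 70% of *both* lengths; a pseudo-randomly
   chosen representative of each cluster is scored against the curated
   family profiles and the winning label propagates to all members.
3. **Trimming and orientation.** Each window is trimmed to the minimal
   gene interval containing every locus-family gene (Tss*, Tag*, TetR,
   Hcp, VgrG, ClpV, PAAR, Rhs, effector/immunity), and mirrored so that
   vgrG is transcribed left to right.
4. **Second pass.** Profiles are rebuilt from the cluster alignments and,
   together with the curated family set, used to re-scan all genomes. A
   new locus is called where a 30-gene window holds threshold-passing
   hits of at least 4 distinct core Tss families and does not overlap a
   pass-1 locus. This recovers loci whose vgrG and clpV fell on different
   contigs of a draft assembly; isolated hits (standalone ClpV-like
   genes, lone Hcp/TetR/Rhs) are reported as orphans, never as loci.
5. **Architecture classification.** TagC implies GA3; TagB implies GA1;
   TagA without TagB plus an evolved Hcp (Hcp domain in the N-terminal
   half of an over-length protein) or at least four distinct Hcp clusters
   implies GA2; otherwise the locus is scored against each architecture's
   signature feature set and called `other` below a 0.7 score floor.
6. **ICE association and DNA relatedness.** The nine tra families of the
   conjugation machinery are detected genome-wide; a locus is
   ICE-associated when a tra gene lies within 50 kb on the same contig,
   and the in-window tra roster is compared with the characteristic GA1
   (TraG-TraK-TraM-TraN-TraD, at least 4 of 5) and GA2 (9-family, at
   least 7 of 9) flanking patterns in consistent order. DNA relatedness
   between strains is profiled with a blastn-like seed-and-extend scan
   (word 11, +1/-2, X-drop 40, ungapped) whose HSPs below 1000 bp are
   discarded; ICE extents are refined by iteratively trimming the query
   to the outermost HSP boundaries.

A worked arithmetic example carried through the package: a shared segment
of 109,805 bp differing at three positions is
`percent_identity_from_mismatches(109805, 3)` = 99.997% identical — the
scale of identity that flags intra-ecosystem transfer of a T6SS-bearing
ICE.

## Profile scoring, E-values and thresholds

Profiles are plain position-specific log-odds matrices (bits) over the 20
amino acids; scanning is local Smith-Waterman over profile columns versus
residues with affine gaps (BLAST convention, open 11 / extend 1). `X`
residues score zero in every column. There are no insert/delete state
probabilities as in a full Plan7 HMM; at the divergences involved the
simpler model is sufficient and far easier to verify (the test suite
checks it cell-for-cell against a brute-force dynamic-programming
oracle).

**E-values** are empirical: each profile's null distribution is the score
sample of `n_shuffles` random length-matched proteins drawn from its
background distribution, and `E(s) = decoy_db_size * (k+1)/(n+1)` where
`k` counts null scores at or above `s`. Beyond the largest null score the
exceedance decays exponentially from the pseudo-count floor at a rate
fitted to the null sample by Gumbel moments (`lambda = pi/(sd * sqrt 6)`).
This keeps `E(s)` monotone and continuous, saturates at `decoy_db_size`
for hopeless scores, leaves near-null scores above any practical cutoff,
and sends genuine family matches (hundreds of bits above the null) to
vanishingly small values. A pure empirical count could never certify
`E <= 1e-3` at desk-scale null sizes; the fitted tail is what makes the
published cutoff meaningful here.

**Inclusion thresholds** follow the self-scan rule: after building a
profile from its training members, the threshold is the *minimum*
training-member score, so rescanning the training corpus recalls every
member by construction while random decoys pass at a rate below 1%.
(Taking the maximum instead would exclude all but the single best member
on rescan and could never have recovered additional loci.) One practical
caveat discovered during development: with only a handful of training
members, each member's idiosyncratic residues are part of the profile, so
fresh family members systematically score 10-30 bits below the training
minimum. The second pass therefore scans with the union of the rebuilt
cluster profiles and the curated family profiles — the former capture
corpus-specific variants, the latter carry thresholds that generalize.

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `sentinel_evalue_max` | 1e-3 | sentinel/tra/toxin profile hit cutoff |
| `max_sentinel_gene_gap` | 15 genes | vgrG-clpV co-localization rule |
| `flank_genes` | 25 genes | window flank around outermost sentinels |
| `cluster_identity_min` / `cluster_coverage_min` | 0.30 / 0.70 | clustering cutoffs, coverage on both sequences |
| `hsp_min_len` | 1000 bp | HSP length filter |
| `ice_window_bp` | 50 kb | tra proximity window |
| `pass2_window` / `pass2_min_core` | 30 genes / 4 families | second-pass trigger |
| `max_label_gap` | 3 genes | decoy isolation rule during trimming |
| `gap_open` / `gap_ext` | 11 / 1 | affine gap penalties (all protein alignments) |
| `hsp_word`, `hsp_match`, `hsp_mismatch`, `hsp_xdrop` | 11, +1, -2, 40 | DNA seed-and-extend scoring |
| `decoy_db_size` / `n_shuffles` | 1e4 / 200 | E-value calibration |

Gene *distance* is always measured on ordinals (per-contig gene rank),
not base pairs: "within fifteen genes" means at most 15 annotated genes
strictly between the two sentinels. Internal coordinates are 0-based
half-open; GFF3 I/O is 1-based inclusive.

The `max_label_gap` rule is this package's own addition to the trimming
step: labelled genes separated from the locus run by more than 3
intervening genes (standalone decoy hcp/clpV/tetR/rhs genes that happen
to fall inside the 25-gene flank) are treated as outside the locus.
Without it, a single decoy near a contig edge can stretch a trimmed locus
across dozens of unrelated genes. The unrestricted trimming semantics
(every labelled window gene kept) are recovered with
`max_label_gap = Inf`.

## The synthetic genome generator

Real corpora of two-hundred-odd genomes and the TIGRFAM/Pfam profile
databases are not reproducible at desk scale, so every stage is exercised
against seeded synthetic genomes with ground-truth records. The generator
emulates exactly the features the pipeline's logic depends on:

* **Family structure.** Each of 35 families (11 Tss, Hcp, VgrG, ClpV, 3
  Tags, TetR, PAAR, Rhs, 9 Tra, 3 toxin + 3 immunity) gets a random
  consensus at a fixed, realistic length (80-600 aa; Hcp is pinned at
  160 aa so the evolved-Hcp length rule is well defined). Independent
  random consensuses sit far below the 30%/70% clustering cutoffs, so
  family identity is unambiguous by construction. Curated profiles are
  log-odds of a 90% consensus / 10% background emission; their
  thresholds are calibrated on 8 members mutated at rate 0.25 — a
  deliberately broad family envelope.
* **Loci.** GA1/GA2/GA3 templates fix gene content and order (TagB only
  in GA1, TagC only in GA3, TagA in GA1+GA2, two cluster-1 Hcp genes in
  GA1, five Hcp copies plus an evolved Hcp in GA2, two variable
  effector/immunity regions in GA3). Implanted genes are per-family
  mutated consensuses (default rate 0.05), back-translated with uniform
  synonymous codons and separated by random 20-200 bp spacers; loci land
  on either strand. GA1/GA2 loci carry an adjacent tra flank in the
  architecture's characteristic order — the generator's model of the ICE.
* **Draft-assembly artifacts.** With probability 0.2 a locus is split
  between vgrG and clpV onto a second contig (the mechanism that makes
  pass 2 necessary); standalone decoy clpV/hcp/tetR/rhs genes are
  sprinkled at rate 0.05 per background gene.
* **Reference conditions.** The default set is 30 genomes: 10 GA1, 5
  GA2, 10 GA3 and 5 with no locus, at the rates above, seed 1. These
  sizes keep the full pipeline under a few minutes on one core while
  leaving every decision rule load-bearing.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: no phylogenetic correlation between genomes, no
indel mutations, no codon bias or GC skew, no promoters or operon
structure, no partial gene calls, and inter-family sequence space far
sparser than Pfam's. In particular, back-translating the same protein
twice with uniform synonymous codons yields only ~80-85% DNA identity, so
within-architecture DNA-identity fixtures use direct DNA-level point
mutation (`mutate_dna`) instead of independent back-translations; the
published within-architecture identity floors (GA1/GA3 above 95%, GA2
above 80%) are checked on such fixtures. The GA2 template also relaxes
"five Hcp of four distinct clusters" to five moderately diverged copies
plus the evolved Hcp: paralogs diverged below 30% identity could no
longer be recognized as Hcp by any single curated profile, and the GA2
decision rule's evolved-Hcp branch carries the classification instead.

## Numerical and design choices

* **Tie-breaks.** All alignments are deterministic: state priority
  diagonal > gap-in-subject > gap-in-query during traceback, and among
  co-optimal free-end endpoints the one consuming the most residues wins
  (this is what makes `AAAA` vs `AAAT` report identity 0.75 at coverage
  1.0 rather than a shorter perfect prefix match). Clustering sorts by
  descending length then ascending gene id before greedy seed
  recruitment, so the partition is invariant to input order. Equal-score
  family assignments resolve lexicographically and are logged.
* **Seeding.** One run seed; every stochastic step (null draws per
  profile, representative choice per cluster, generator stages) derives
  its own substream by hashing a stage name into the seed, so stage
  reordering never silently shifts downstream randomness, and no two
  stages can replay each other's streams.
* **Degenerate inputs.** Ambiguous nucleotides are preserved and
  translate to `X`, which scores zero against every profile column and
  never seeds a DNA word; CDS lengths not divisible by three are skipped
  with a warning; a window with no labelled genes refuses to trim; a
  locus without vgrG cannot be oriented and is left flagged; tra hits on
  a different contig than the locus never satisfy the proximity window;
  ICE extents with no HSP fall back to the locus span, flagged.
* **Open design points.** The two-pass trigger (4 distinct core families
  in a 30-gene window), the architecture score floor (0.7), the
  conserved-region rules (80% coverage, merge below 200 bp, number gaps
  of at least 500 bp) and the decoy isolation gap (3 genes) are this
  package's explicit choices where the published analysis was manual or
  silent; all are configurable.
* **Orientation of split loci.** Pass 2 calls the clpV-side fragment of
  a split locus (the vgrG-side fragment rarely carries four core
  families); fragments are not re-joined across contigs — scaffolding is
  out of scope — and evaluation counts a split implant as recovered when
  the fragment covers at least half of the truth locus (gene-set Jaccard
  at least 0.5).

## Problem sizes and runtime

The shipped test suite and the acceptance script run the full pipeline on
the 30-genome reference set (~1600 genes, ~300 protein clusters) in a few
minutes on a single core; unit tests exercise each operation on small
fixtures, and brute-force R oracles cross-check the compiled alignment
kernels on inputs up to length 40. These sizes are the package's chosen
desk-scale study conditions; all thresholds are the published analysis
values, never tuned to the synthetic data.

## Known limitations

* Profile scoring is profile-versus-sequence only; the profile-profile
  and profile-structure comparisons used to annotate the hardest families
  in the original analysis have no equivalent here — a user can drop in
  externally built profiles through the documented text format instead.
* Percent-identity clustering is greedy seed-recruitment, not
  blastclust's neighbor-joining; partitions can differ near the cutoffs.
* The HSP scanner is ungapped; long gapped homologies fragment into
  multiple HSPs (harmless for identity profiling, which is
  length-weighted).
* Corpus-scale headline counts from the original study (numbers of loci,
  clusters, architecture tallies across 205 genomes) depend on the real
  genome collection and are not reproduction targets of the synthetic
  conditions.
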