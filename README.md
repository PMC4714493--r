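# t6finder

Discovery, annotation and classification of type VI secretion system
(T6SS) loci in annotated bacterial genomes, with a focus on the gut
Bacteroidales, where T6SS loci fall into three conserved genetic
architectures (GA1–GA3) and the GA1/GA2 classes ride on integrative
conjugative elements (ICE) that transfer between co-resident strains.

The package is aimed at comparative genomicists working with draft,
multi-contig assemblies. It implements the full in-silico pipeline:

* **Pass 1 — sentinel co-localization.** Proteomes are scanned with
  position-specific profiles for VgrG and ClpV; a candidate locus needs
  both on one contig at E ≤ 1e−3 within fifteen genes, and is extracted
  with 25 flanking genes per side.
* **Clustering & annotation.** Window proteins are clustered greedily at
  ≥30 % identity over ≥70 % of both lengths (the blastclust criterion);
  cluster representatives are scored against a curated family-profile
  set and labels propagate to members.
* **Pass 2 — self-trained rescan.** Profiles rebuilt from the cluster
  alignments (plus the curated set) re-scan all genomes with
  self-calibrated score thresholds, recovering loci split across contigs
  and reporting orphan Tss-like genes.
* **Architecture calls.** TagC ⇒ GA3, TagB ⇒ GA1, TagA + evolved Hcp (or
  ≥4 Hcp clusters) ⇒ GA2, otherwise a signature score with an "other"
  fallback.
* **ICE analysis.** tra genes of the nine conjugation families are
  mapped; a locus is ICE-associated when tra genes lie within 50 kb, and
  their order is matched to the characteristic GA1/GA2 flanking
  patterns. DNA relatedness between ICEs uses a blastn-like
  seed-and-extend HSP scan (word 11, +1/−2, X-drop 40; HSPs < 1000 bp
  discarded) with length-weighted identity
  `Σ(len·id)/Σ(len)`, and the mismatch arithmetic
  `100·(L−m)/L` for near-identical segments.

Because the real 205-genome corpus and the TIGRFAM/Pfam databases are
external, the package ships a first-class seeded synthetic-genome
generator (`generate_genome_set`) that implants GA1/GA2/GA3 loci with
mutational divergence, ICE tra flanks, decoy standalone genes and
contig splits, together with ground-truth records and an evaluation
harness (`evaluate_run`).

## Worked example

```r
library(t6finder)

cfg     <- pipeline_config(rng_seed = 1)
curated <- curated_profile_set(1, cfg)            # stand-in family profiles
gset    <- generate_genome_set(synth_config(seed = 1), curated)

run <- run_pipeline(gset$genomes, curated, cfg)
run
#> t6_run: 30 genomes; 21 pass-1 + 4 pass-2 loci; 297 protein clusters

evaluate_run(run, gset$truth)
#> t6_evaluation: recall 1.000, precision 1.000, architecture accuracy 1.000,
#>   ICE accuracy 1.000, family accuracy 1.000 (25 truth loci, 25 detected)

head(run$ice[, c("locus_id", "architecture", "verdict", "pattern")])
# GA1/GA2 loci come back ICE-associated with the GA1-/GA2-pattern tra
# rosters; GA3 loci are not associated.

percent_identity_from_mismatches(109805, 3)
#> [1] 99.997
```

The numbers read as follows: of 25 implanted loci, 21 were seeded by
vgrG–clpV co-localization and the 4 loci split across contigs were
recovered by the second, profile-trained pass; every locus was assigned
its generator architecture; tra-flank proximity reproduced the
ICE association of GA1/GA2 but not GA3; and a 109,805-bp shared segment
with three mismatches is 99.997 % identical — the level of identity that
indicates recent horizontal transfer of a T6SS-bearing ICE.

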