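# Seeded synthetic Bacteroidales-like genome sets with implanted T6SS loci,
# ICE tra flanks, decoy standalone genes and ground-truth records, so every
# downstream stage is testable without downloading real genomes.

# fixed per-family consensus lengths (aa), emulating typical sizes of the
# corresponding real families; Hcp is fixed short enough that an evolved
# Hcp (Hcp domain + toxin tail) exceeds 1.5x the family median length
family_lengths <- function() {
  c(TssB = 170L, TssC = 480L, TssE = 140L, TssF = 580L, TssG = 330L,
    TssK = 440L, TssN = 250L, TssO = 120L, TssP = 390L, TssQ = 210L,
    TssR = 360L, Hcp = 160L, VgrG = 560L, ClpV = 470L,
    TagA = 420L, TagB = 310L, TagC = 520L,
    TetR = 200L, PAAR = 95L, Rhs = 600L,
    TraD = 450L, TraG = 320L, TraI = 400L, TraJ = 250L, TraK = 230L,
    TraM = 180L, TraN = 290L, TraO = 140L, TrbJ = 110L,
    ToxNuc = 150L, ToxDea = 120L, ToxPor = 180L,
    ImmNuc = 130L, ImmDea = 110L, ImmPor = 140L)
}

#' Generate per-family consensus sequences and profiles
#'
#' Each family receives a random, fixed-length amino-acid consensus
#' (independent draws keep inter-family identity far below the 30\%/70\%
#' clustering cutoffs) and a position-specific profile whose per-column
#' emission is 90\% consensus residue / 10\% background, expressed as
#' log-odds (bits) against a uniform background.
#'
#' @param seed integer seed; the same seed reproduces the identical set.
#' @return list with `consensus` (named character vector) and `profiles`
#'   (named list of `t6_profile`, each carrying its family label).
#' @export
generate_family_consensus <- function(seed = 1L) {
  lens <- family_lengths()
  with_seed(seed, {
    consensus <- vapply(names(lens), function(f)
      random_protein(lens[[f]]), character(1))
    profiles <- lapply(names(lens), function(f) {
      cons <- strsplit(consensus[[f]], "")[[1]]
      emit <- matrix(0.1 / 20, nrow = 20, ncol = length(cons),
                     dimnames = list(AA20, NULL))
      emit[cbind(match(cons, AA20), seq_along(cons))] <-
        0.9 + 0.1 / 20
      make_profile(f, log2(emit / (1 / 20)), family = f)
    })
    names(profiles) <- names(lens)
    list(consensus = consensus, profiles = profiles)
  })
}

#' Build the calibrated curated profile set used by the pipeline
#'
#' Stands in for an external curated family-profile database: consensus
#' profiles from [generate_family_consensus()], E-value calibration against
#' shuffled decoys, and inclusion thresholds calibrated as the minimum
#' score of a training set of diverged family members (substitution rate
#' 0.25), emulating a family-wide score envelope.
#'
#' @param seed integer seed.
#' @param config a [pipeline_config()].
#' @param n_train training members per family for threshold calibration.
#' @param train_rate per-residue substitution rate of the training members.
#' @return list with `consensus` and calibrated `profiles`.
#' @export
curated_profile_set <- function(seed = 1L, config = pipeline_config(),
                                n_train = 8L, train_rate = 0.25) {
  fam <- generate_family_consensus(stage_seed(seed, "consensus"))
  fam$profiles <- lapply(fam$profiles, function(p) {
    p <- calibrate_evalues(p, config$decoy_db_size, config$n_shuffles,
                           seed = stage_seed(seed, paste0("cal_", p$name)),
                           gap_open = config$gap_open,
                           gap_ext = config$gap_ext)
    members <- with_seed(stage_seed(seed, paste0("train_", p$name)),
      vapply(seq_len(n_train), function(i)
        mutate_protein(fam$consensus[[p$name]], train_rate), character(1)))
    p <- calibrate_threshold(p, members, config$gap_open, config$gap_ext)
    p$training <- members
    p
  })
  fam
}

#' Substitute residues of a protein at a fixed per-site rate
#'
#' Each position is independently replaced with probability `rate` by a
#' residue drawn uniformly from the 20 amino acids (so expected identity to
#' the input is `1 - rate * 19/20`). Length is preserved. Uses the current
#' RNG stream unless `seed` is given.
#'
#' @param protein amino-acid string.
#' @param rate substitution probability in `[0, 1]`.
#' @param seed optional seed.
#' @return the mutated protein.
#' @export
mutate_protein <- function(protein, rate, seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  run <- function() {
    ch <- strsplit(protein, "")[[1]]
    hit <- runif(length(ch)) < rate
    if (any(hit)) ch[hit] <- sample(AA20, sum(hit), replace = TRUE)
    paste(ch, collapse = "")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Substitute nucleotides of a DNA string at a fixed per-site rate
#'
#' The DNA analogue of [mutate_protein()] (uniform replacement over ACGT,
#' expected identity `1 - rate * 3/4`); used to build within-architecture
#' DNA-divergence fixtures.
#'
#' @param dna nucleotide string.
#' @param rate substitution probability.
#' @param seed optional seed.
#' @return the mutated sequence.
#' @export
mutate_dna <- function(dna, rate, seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  run <- function() {
    ch <- strsplit(dna, "")[[1]]
    hit <- runif(length(ch)) < rate
    if (any(hit)) ch[hit] <- sample(c("A", "C", "G", "T"), sum(hit),
                                    replace = TRUE)
    paste(ch, collapse = "")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# uniform synonymous back-translation (bacterial code, stops excluded from
# the codon pool; a TAA stop codon is appended); uses the current RNG
back_translate <- function(protein) {
  if (is.null(.t6_env$codon_map)) {
    gc <- Biostrings::getGeneticCode("11")
    gc <- gc[gc != "*"]
    .t6_env$codon_map <- split(names(gc), gc)
  }
  cm <- .t6_env$codon_map
  ch <- strsplit(protein, "")[[1]]
  codons <- vapply(ch, function(a) {
    opts <- cm[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  paste0(paste(codons, collapse = ""), "TAA")
}

#' Architecture templates of the three Bacteroidales T6SS locus classes
#'
#' Gene orders of the GA1/GA2/GA3 architectures as implanted by the
#' generator: every template carries vgrG and clpV exactly once; TagB
#' appears only in GA1, TagC only in GA3, TagA in GA1 and GA2; GA1 carries
#' two same-cluster Hcp genes, GA2 multiple Hcp copies plus an evolved Hcp,
#' GA3 two variable effector/immunity regions. `TOX1/IMM1/TOX2/IMM2` mark
#' the variable slots filled per locus.
#'
#' @return named list of templates (`name`, `gene_order`, `variable_slots`).
#' @export
architecture_templates <- function() {
  ga1 <- c("TetR", "TssB", "TssC", "Hcp", "Hcp", "TssE", "TssF", "TssG",
           "TssK", "TssN", "TssO", "TssP", "TssQ", "TssR", "TagA", "TagB",
           "ClpV", "VgrG", "PAAR", "Rhs", "TOX1", "IMM1")
  ga2 <- c("TetR", "TssB", "TssC", "Hcp", "Hcp", "Hcp", "Hcp", "Hcp",
           "EvolvedHcp", "TssE", "TssF", "TssG", "TssK", "TssN", "TssO",
           "TssP", "TssQ", "TssR", "TagA", "ClpV", "VgrG", "TOX1", "IMM1")
  ga3 <- c("TetR", "TssB", "TssC", "Hcp", "TssE", "TssF", "TssG", "TssK",
           "TagC", "TOX1", "IMM1", "TssN", "TssO", "TssP", "TssQ", "TssR",
           "ClpV", "VgrG", "TOX2", "IMM2")
  mk <- function(name, order)
    list(name = name, gene_order = order,
         variable_slots = which(grepl("^(TOX|IMM)", order)))
  list(GA1 = mk("GA1", ga1), GA2 = mk("GA2", ga2), GA3 = mk("GA3", ga3))
}

#' Synthetic genome-set configuration
#'
#' Defaults describe the reference study conditions used throughout the
#' package: 30 genomes (10 GA1, 5 GA2, 10 GA3, 5 without a locus),
#' per-residue substitution rate 0.05 within families, a 0.2 probability
#' that a locus is split between vgrG and clpV onto two contigs, and
#' decoy standalone clpV/hcp/tetR/rhs genes at rate 0.05 per background
#' gene.
#'
#' @param n_genomes number of genomes.
#' @param architecture_mix named counts over GA1/GA2/GA3/none summing to
#'   `n_genomes`.
#' @param mutation_rate per-residue substitution probability of implanted
#'   family members.
#' @param contig_split_prob probability that an implanted locus is split
#'   across two contigs between vgrG and clpV.
#' @param decoy_rate per-background-gene probability of being a decoy
#'   standalone clpV/hcp/tetR/rhs gene.
#' @param background_genes background genes per contig (length-2 vector).
#' @param seed integer seed.
#' @return a `t6_synth_config` list.
#' @export
synth_config <- function(n_genomes = 30L,
                         architecture_mix = c(GA1 = 10L, GA2 = 5L,
                                              GA3 = 10L, none = 5L),
                         mutation_rate = 0.05,
                         contig_split_prob = 0.2,
                         decoy_rate = 0.05,
                         background_genes = c(18L, 14L),
                         seed = 1L) {
  if (sum(architecture_mix) != n_genomes)
    stop("architecture_mix must sum to n_genomes")
  if (any(c(mutation_rate, contig_split_prob, decoy_rate) < 0) ||
      any(c(mutation_rate, contig_split_prob, decoy_rate) > 1))
    stop("rates must lie in [0, 1]")
  structure(list(n_genomes = as.integer(n_genomes),
                 architecture_mix = architecture_mix,
                 mutation_rate = mutation_rate,
                 contig_split_prob = contig_split_prob,
                 decoy_rate = decoy_rate,
                 background_genes = as.integer(background_genes),
                 seed = as.integer(seed)),
            class = "t6_synth_config")
}

spacer_dna <- function() {
  n <- sample(20:200, 1L)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# materialize an ordered cassette list (family/protein/gene_id) as a DNA
# segment with random intergenic spacers; on "-" the physical gene order is
# reversed so that template transcription order is preserved
build_segment <- function(cassettes, strand) {
  if (strand == "-") cassettes <- rev(cassettes)
  seq <- spacer_dna()
  rows <- vector("list", length(cassettes))
  for (i in seq_along(cassettes)) {
    cs <- cassettes[[i]]
    cds <- back_translate(cs$protein)
    if (strand == "-") cds <- revcomp(cds)
    start <- nchar(seq)
    seq <- paste0(seq, cds, spacer_dna())
    rows[[i]] <- data.frame(gene_id = cs$gene_id, start = start,
                            end = start + nchar(cds), strand = strand,
                            protein = cs$protein, family = cs$family,
                            stringsAsFactors = FALSE)
  }
  list(dna = seq, genes = do.call(rbind, rows))
}

# splice a segment into a contig at a random intergenic boundary
insert_segment <- function(ct, seg) {
  g <- ct$genes
  k <- sample.int(nrow(g) + 1L, 1L) - 1L
  pos <- if (k == 0L) 0L else g$end[k]
  shift <- nchar(seg$dna)
  newseq <- paste0(substr(ct$sequence, 1L, pos), seg$dna,
                   substring(ct$sequence, pos + 1L))
  segg <- seg$genes
  segg$start <- segg$start + pos
  segg$end <- segg$end + pos
  sel <- g$start >= pos
  g$start[sel] <- g$start[sel] + shift
  g$end[sel] <- g$end[sel] + shift
  cols <- c("gene_id", "start", "end", "strand", "protein")
  ct2 <- make_contig(ct$contig_id, newseq, rbind(g[, cols], segg[, cols]))
  list(contig = ct2, gene_ids = segg$gene_id)
}

gene_span <- function(ct, ids) {
  g <- ct$genes[ct$genes$gene_id %in% ids, , drop = FALSE]
  c(min(g$start), max(g$end))
}

#' Implant a T6SS locus (and its ICE tra flank) into a genome
#'
#' Emits the template's genes in order, each a per-family mutated consensus
#' back-translated with uniform synonymous codons and separated by random
#' 20-200 bp spacers. GA1/GA2 loci receive an upstream tra-gene flank in
#' the architecture's characteristic order. With probability
#' `contig_split_prob` the locus is split between vgrG and clpV onto the
#' genome's second contig, emulating draft-assembly breaks. Uses the
#' current RNG stream.
#'
#' @param genome a `t6_genome` with at least one (for splitting: two)
#'   contig carrying background genes.
#' @param template an entry of [architecture_templates()].
#' @param consensus named consensus vector from
#'   [generate_family_consensus()].
#' @param config a `t6_synth_config`.
#' @param locus_tag identifier fragment used in generated gene ids.
#' @return list with the modified `genome` and a ground-truth fragment
#'   (`contig_ids`, `spans`, `architecture`, `families`, `gene_ids`,
#'   `split`, `ice`).
#' @export
implant_locus <- function(genome, template, consensus, config,
                          locus_tag = "L1") {
  rate <- config$mutation_rate
  order <- template$gene_order
  # resolve variable effector/immunity slots
  picks <- list()
  for (i in seq_along(order)) {
    if (grepl("^TOX", order[i])) {
      slot <- sub("TOX", "", order[i])
      tox <- sample(names(TOXIN_FAMILIES), 1L)
      picks[[paste0("TOX", slot)]] <- tox
      picks[[paste0("IMM", slot)]] <- sub("Tox", "Imm", tox)
    }
  }
  resolved <- vapply(order, function(f)
    if (!is.null(picks[[f]])) picks[[f]] else f, character(1))
  prot_for <- function(f) {
    if (f == "EvolvedHcp")
      mutate_protein(paste0(consensus[["Hcp"]], consensus[["ToxDea"]]), rate)
    else mutate_protein(consensus[[f]], rate)
  }
  gid <- function(i, f) sprintf("%s_%s_%02d_%s", genome$genome_id,
                                locus_tag, i, f)
  cassettes <- lapply(seq_along(resolved), function(i)
    list(family = resolved[i], gene_id = gid(i, resolved[i]),
         protein = prot_for(resolved[i])))
  tra_fams <- switch(template$name, GA1 = TRA_PATTERN_GA1,
                     GA2 = TRA_PATTERN_GA2, NULL)
  tra_cassettes <- if (!is.null(tra_fams))
    lapply(seq_along(tra_fams), function(i)
      list(family = tra_fams[i],
           gene_id = sprintf("%s_%s_tra%02d_%s", genome$genome_id,
                             locus_tag, i, tra_fams[i]),
           protein = mutate_protein(consensus[[tra_fams[i]]], rate)))
    else list()

  split <- runif(1) < config$contig_split_prob &&
    length(genome$contigs) >= 2L
  strand <- sample(c("+", "-"), 1L)
  vg <- which(resolved == "VgrG")

  cids <- names(genome$contigs)
  if (!split) {
    seg <- build_segment(c(tra_cassettes, cassettes), strand)
    ins <- insert_segment(genome$contigs[[cids[1]]], seg)
    genome$contigs[[cids[1]]] <- ins$contig
    locus_ids <- vapply(cassettes, `[[`, character(1), "gene_id")
    spans <- setNames(list(gene_span(ins$contig, locus_ids)), cids[1])
    contig_ids <- cids[1]
  } else {
    partA <- cassettes[seq_len(vg - 1L)]
    partB <- cassettes[seq(vg, length(cassettes))]
    segA <- build_segment(c(tra_cassettes, partA), strand)
    segB <- build_segment(partB, strand)
    insA <- insert_segment(genome$contigs[[cids[1]]], segA)
    genome$contigs[[cids[1]]] <- insA$contig
    insB <- insert_segment(genome$contigs[[cids[2]]], segB)
    genome$contigs[[cids[2]]] <- insB$contig
    idsA <- vapply(partA, `[[`, character(1), "gene_id")
    idsB <- vapply(partB, `[[`, character(1), "gene_id")
    locus_ids <- c(idsA, idsB)
    spans <- setNames(list(gene_span(insA$contig, idsA),
                           gene_span(insB$contig, idsB)),
                      cids[1:2])
    contig_ids <- cids[1:2]
  }
  ice <- if (length(tra_cassettes)) {
    tra_ids <- vapply(tra_cassettes, `[[`, character(1), "gene_id")
    onA <- if (split) c(tra_ids,
                        vapply(cassettes[seq_len(vg - 1L)], `[[`,
                               character(1), "gene_id"))
           else c(tra_ids, locus_ids)
    list(contig_id = cids[1],
         span = gene_span(genome$contigs[[cids[1]]], onA),
         tra_families = tra_fams, tra_gene_ids = tra_ids)
  } else NULL
  truth <- list(contig_ids = contig_ids, spans = spans,
                architecture = template$name,
                families = unname(resolved), gene_ids = unname(locus_ids),
                split = split, strand = strand, ice = ice)
  list(genome = genome, truth = truth)
}

#' Generate a seeded synthetic genome set with ground truth
#'
#' Per genome: two contigs of random background genes, decoy standalone
#' clpV/hcp/tetR/rhs genes at `decoy_rate`, and one implanted T6SS locus
#' according to `architecture_mix` (genomes in the `none` class carry no
#' locus). Fully deterministic given `config$seed`.
#'
#' @param config a [synth_config()].
#' @param curated optional result of [curated_profile_set()] sharing the
#'   run's consensus set; if absent, consensus sequences are generated from
#'   the config seed.
#' @return list with `genomes` (list of `t6_genome`) and `truth` (list of
#'   per-genome truth records).
#' @export
generate_genome_set <- function(config = synth_config(), curated = NULL) {
  consensus <- if (!is.null(curated)) curated$consensus
    else generate_family_consensus(stage_seed(config$seed, "consensus"))$consensus
  templates <- architecture_templates()
  mix <- config$architecture_mix
  if (any(mix < 0)) stop("infeasible architecture mix")
  archs <- rep(names(mix), mix)
  with_seed(stage_seed(config$seed, "genomes"), {
    archs <- sample(archs)
    genomes <- vector("list", config$n_genomes)
    truth <- vector("list", config$n_genomes)
    decoy_pool <- c("ClpV", "Hcp", "TetR", "Rhs")
    for (gi in seq_len(config$n_genomes)) {
      gid <- sprintf("g%02d", gi)
      decoys <- character(0)
      contigs <- lapply(seq_along(config$background_genes), function(ci) {
        nb <- config$background_genes[ci]
        cass <- lapply(seq_len(nb), function(bi) {
          if (runif(1) < config$decoy_rate) {
            fam <- sample(decoy_pool, 1L)
            list(family = fam,
                 gene_id = sprintf("%s_c%d_d%02d_%s", gid, ci, bi, fam),
                 protein = mutate_protein(consensus[[fam]],
                                          config$mutation_rate))
          } else {
            list(family = "background",
                 gene_id = sprintf("%s_c%d_b%02d", gid, ci, bi),
                 protein = random_protein(sample(80:400, 1L)))
          }
        })
        strand_per <- sample(c("+", "-"), nb, replace = TRUE)
        seq <- spacer_dna()
        rows <- vector("list", nb)
        for (i in seq_len(nb)) {
          cds <- back_translate(cass[[i]]$protein)
          if (strand_per[i] == "-") cds <- revcomp(cds)
          start <- nchar(seq)
          seq <- paste0(seq, cds, spacer_dna())
          rows[[i]] <- data.frame(gene_id = cass[[i]]$gene_id, start = start,
                                  end = start + nchar(cds),
                                  strand = strand_per[i],
                                  protein = cass[[i]]$protein,
                                  stringsAsFactors = FALSE)
        }
        decoys <<- c(decoys, vapply(cass[vapply(cass, function(x)
          x$family != "background", logical(1))], `[[`, character(1),
          "gene_id"))
        make_contig(sprintf("%s_c%d", gid, ci), seq, do.call(rbind, rows))
      })
      gn <- make_genome(gid, species_label = sprintf("synthetic sp. %02d", gi),
                        contigs = contigs)
      loci <- list()
      if (archs[gi] != "none") {
        imp <- implant_locus(gn, templates[[archs[gi]]], consensus, config)
        gn <- imp$genome
        loci <- list(imp$truth)
      }
      genomes[[gi]] <- gn
      truth[[gi]] <- list(genome_id = gid, loci = loci,
                          decoy_gene_ids = decoys)
    }
    names(genomes) <- vapply(genomes, `[[`, character(1), "genome_id")
    names(truth) <- names(genomes)
    list(genomes = genomes, truth = truth)
  })
}

#' Write a synthetic genome set to disk
#'
#' Emits per-genome nucleotide FASTA and GFF3 plus a single ground-truth
#' JSON document.
#'
#' @param gset result of [generate_genome_set()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_genome_set <- function(gset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (gn in gset$genomes) {
    write_genome_fasta(gn, file.path(dir, paste0(gn$genome_id, ".fna")))
    write_gff(gn, file.path(dir, paste0(gn$genome_id, ".gff3")))
  }
  jsonlite::write_json(gset$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
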