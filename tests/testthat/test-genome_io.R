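test_that("GFF round-trip preserves coordinates, strands and proteins", {
  gs <- generate_genome_set(synth_config(n_genomes = 1,
                                         architecture_mix = c(GA1 = 1, GA2 = 0,
                                                              GA3 = 0, none = 0),
                                         seed = 7))
  gn <- gs$genomes[[1]]
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fna")
  gff <- file.path(dir, "g.gff3")
  write_genome_fasta(gn, fa)
  write_gff(gn, gff)
  gn2 <- read_genome_bundle(fa, gff, genome_id = gn$genome_id)
  g1 <- t6finder:::genome_genes(gn)
  g2 <- t6finder:::genome_genes(gn2)
  g2 <- g2[match(g1$gene_id, g2$gene_id), ]
  expect_equal(g1$start, g2$start)
  expect_equal(g1$end, g2$end)
  expect_equal(g1$strand, g2$strand)
  expect_equal(g1$protein, g2$protein)
  # generator truth: locus genes all present after the round trip
  expect_true(all(gs$truth[[1]]$loci[[1]]$gene_ids %in% g2$gene_id))
})

test_that("GFF 1-based inclusive converts to 0-based half-open", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fna")
  gff <- file.path(dir, "g.gff3")
  writeLines(c(">ctg", strrep("ATG", 20)), fa)
  writeLines(c("##gff-version 3",
               paste("ctg", "src", "CDS", "1", "3", ".", "+", "0",
                     "ID=gene1", sep = "\t")), gff)
  gn <- read_genome_bundle(fa, gff)
  g <- gn$contigs$ctg$genes
  expect_equal(g$start, 0L)
  expect_equal(g$end, 3L)
  expect_equal(g$protein, "M")
})

test_that("minus-strand proteins equal translation of the reverse complement", {
  gs <- generate_genome_set(synth_config(n_genomes = 1,
                                         architecture_mix = c(GA1 = 0, GA2 = 0,
                                                              GA3 = 1, none = 0),
                                         seed = 3))
  gn <- gs$genomes[[1]]
  for (ct in gn$contigs) {
    minus <- ct$genes[ct$genes$strand == "-", ]
    for (i in seq_len(min(nrow(minus), 5L))) {
      cds <- Biostrings::reverseComplement(Biostrings::DNAString(
        substr(ct$sequence, minus$start[i] + 1L, minus$end[i])))
      aa <- sub("\\*$", "", as.character(Biostrings::translate(
        cds, genetic.code = Biostrings::getGeneticCode("11"),
        no.init.codon = TRUE, if.fuzzy.codon = "X")))
      expect_equal(aa, minus$protein[i])
    }
  }
})

test_that("GFF referencing a missing contig is a hard error; bad CDS length is skipped", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fna")
  gff <- file.path(dir, "g.gff3")
  writeLines(c(">ctg", strrep("ATGAAA", 20)), fa)
  writeLines(c("##gff-version 3",
               paste("nope", "src", "CDS", "1", "6", ".", "+", "0",
                     "ID=gene1", sep = "\t")), gff)
  expect_error(read_genome_bundle(fa, gff), "nope")
  writeLines(c("##gff-version 3",
               paste("ctg", "src", "CDS", "1", "5", ".", "+", "0",
                     "ID=bad1", sep = "\t"),
               paste("ctg", "src", "CDS", "7", "12", ".", "+", "0",
                     "ID=ok1", sep = "\t")), gff)
  expect_warning(gn <- read_genome_bundle(fa, gff), "bad1")
  expect_equal(gn$contigs$ctg$genes$gene_id, "ok1")
})

test_that("profile set text format round-trips with scores preserved", {
  fam <- generate_family_consensus(5)
  ps <- fam$profiles[c("Hcp", "VgrG", "TetR")]
  ps$Hcp$threshold_score <- 123.456789
  path <- withr::local_tempfile(fileext = ".prof")
  write_profile_set(ps, path)
  back <- read_profile_set(path)
  expect_equal(names(back), names(ps))
  expect_equal(back$Hcp$length, ps$Hcp$length)
  expect_equal(back$Hcp$threshold_score, 123.456789, tolerance = 1e-6)
  # rescoring a fixed peptide is preserved to 6 decimals
  pep <- substr(fam$consensus[["Hcp"]], 1, 60)
  s1 <- score_protein(ps$Hcp, pep)$score
  s2 <- score_protein(back$Hcp, pep)$score
  expect_equal(s1, s2, tolerance = 1e-5)
  # empty file -> empty list; malformed row -> error with line number
  empty <- withr::local_tempfile()
  writeLines(character(0), empty)
  expect_length(read_profile_set(empty), 0)
  bad <- withr::local_tempfile()
  writeLines(c(">p 2 ACDEFGHIKLMNPQRSTVWY",
               paste(rep("0.1", 20), collapse = " "),
               "not numbers at all"), bad)
  expect_error(read_profile_set(bad), "line 3")
})

test_that("locus report has one row per locus and is deterministic", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_locus_report(list(), path)
  expect_length(readLines(path), 1L)
  mini <- fx_mini()
  loci <- mini$run$loci[1:3]
  write_locus_report(loci, path)
  expect_length(readLines(path), 4L)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_locus_report(loci, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("ORF maps orient vgrG left-to-right with per-family color keys", {
  mini <- fx_mini()
  loci <- Filter(function(lc) isTRUE(lc$oriented), mini$run$loci)
  ga3 <- Filter(function(lc) identical(lc$architecture, "GA3"), loci)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_orf_map(ga3[[1]], p1)
  write_orf_map(ga3[[2]], p2)
  j1 <- jsonlite::read_json(p1)
  j2 <- jsonlite::read_json(p2)
  vg1 <- Filter(function(a) a$family == "VgrG", j1$arrows)
  expect_true(length(vg1) >= 1)
  expect_true(all(vapply(vg1, function(a) a$strand == "+", logical(1))))
  expect_equal(j1$arrows[[1]]$offset, 0)
  key <- function(j) {
    fams <- vapply(j$arrows, function(a) a$family, character(1))
    cols <- vapply(j$arrows, function(a) a$color, character(1))
    setNames(cols, fams)[!duplicated(fams)]
  }
  k1 <- key(j1)
  k2 <- key(j2)
  shared <- intersect(names(k1), names(k2))
  expect_true(length(shared) > 5)
  expect_identical(k1[shared], k2[shared])
})

test_that("protein FASTA plus coordinate table loads to the same model", {
  gs <- generate_genome_set(synth_config(n_genomes = 1,
                                         architecture_mix = c(GA1 = 0, GA2 = 0,
                                                              GA3 = 0, none = 1),
                                         seed = 11))
  gn <- gs$genomes[[1]]
  genes <- t6finder:::genome_genes(gn)
  dir <- withr::local_tempdir()
  pfa <- file.path(dir, "p.faa")
  tab <- file.path(dir, "coords.tsv")
  Biostrings::writeXStringSet(
    setNames(Biostrings::AAStringSet(genes$protein), genes$gene_id), pfa)
  write.table(data.frame(genes$contig_id, genes$start + 1L, genes$end,
                         genes$strand),
              tab, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  gn2 <- read_protein_bundle(pfa, tab, genome_id = gn$genome_id)
  g2 <- t6finder:::genome_genes(gn2)
  g2 <- g2[match(genes$gene_id, g2$gene_id), ]
  expect_equal(genes$start, g2$start)
  expect_equal(genes$end, g2$end)
  expect_equal(genes$protein, g2$protein)
})
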