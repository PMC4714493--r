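test_that("family consensus generation is deterministic and well separated", {
  a <- generate_family_consensus(1)
  b <- generate_family_consensus(1)
  d <- generate_family_consensus(2)
  expect_identical(a$consensus, b$consensus)
  expect_false(identical(a$consensus, d$consensus))
  # consensus achieves the profile's maximum attainable score
  for (f in c("Hcp", "VgrG", "TraD")) {
    r <- score_protein(a$profiles[[f]], a$consensus[[f]])
    expect_equal(r$score, sum(apply(a$profiles[[f]]$match_scores, 2, max)),
                 tolerance = 1e-9)
    expect_equal(r$span, c(1L, nchar(a$consensus[[f]])))
  }
  # no two families come close to the clustering thresholds
  cfg <- fx_config()
  fams <- names(a$consensus)
  set.seed(1)
  pairs <- t(combn(fams, 2))
  pairs <- pairs[sample(nrow(pairs), 60), , drop = FALSE]
  for (k in seq_len(nrow(pairs))) {
    r <- pairwise_identity(a$consensus[[pairs[k, 1]]],
                           a$consensus[[pairs[k, 2]]], cfg)
    expect_false(r$identity >= 0.30 && r$coverage_a >= 0.70 &&
                   r$coverage_b >= 0.70)
  }
})

test_that("mutate_protein has the stated identity law", {
  p <- t6finder:::random_protein(200)
  expect_identical(mutate_protein(p, 0, seed = 1), p)
  long <- t6finder:::random_protein(10000)
  m1 <- mutate_protein(long, 1, seed = 2)
  id1 <- mean(strsplit(long, "")[[1]] == strsplit(m1, "")[[1]])
  expect_lt(abs(id1 - 1 / 20), 4 * sqrt(0.05 * 0.95 / 10000))
  # expected identity 1 - r * 19/20 at r = 0.3, within 3 sigma over 200 sims
  r <- 0.3
  set.seed(3)
  ids <- replicate(200, {
    m <- mutate_protein(p, r)
    mean(strsplit(p, "")[[1]] == strsplit(m, "")[[1]])
  })
  expected <- 1 - r * 19 / 20
  se <- sd(ids) / sqrt(length(ids))
  expect_lt(abs(mean(ids) - expected), 3 * se + 1e-12)
  expect_equal(nchar(m1), nchar(long))
})

test_that("architecture templates satisfy the marker invariants", {
  tpl <- architecture_templates()
  for (t in tpl) {
    expect_equal(sum(t$gene_order == "VgrG"), 1L)
    expect_equal(sum(t$gene_order == "ClpV"), 1L)
  }
  expect_true("TagB" %in% tpl$GA1$gene_order)
  expect_false("TagB" %in% tpl$GA2$gene_order)
  expect_false("TagB" %in% tpl$GA3$gene_order)
  expect_true("TagC" %in% tpl$GA3$gene_order)
  expect_false("TagC" %in% tpl$GA1$gene_order)
  expect_false("TagC" %in% tpl$GA2$gene_order)
  expect_true(all(c("TagA" %in% tpl$GA1$gene_order,
                    "TagA" %in% tpl$GA2$gene_order)))
  expect_false("TagA" %in% tpl$GA3$gene_order)
})

test_that("implanted loci honor co-localization and tra rosters", {
  gs <- generate_genome_set(synth_config(
    n_genomes = 3, architecture_mix = c(GA1 = 1, GA2 = 1, GA3 = 1),
    contig_split_prob = 0, seed = 9))
  for (tr in gs$truth) {
    tl <- tr$loci[[1]]
    expect_false(tl$split)
    expect_length(tl$contig_ids, 1L)
    gn <- gs$genomes[[tr$genome_id]]
    genes <- gn$contigs[[tl$contig_ids]]$genes
    vg <- genes$ordinal[genes$gene_id == tl$gene_ids[tl$families == "VgrG"]]
    cp <- genes$ordinal[genes$gene_id == tl$gene_ids[tl$families == "ClpV"]]
    expect_lte(abs(vg - cp) - 1L, 15L)
    if (tl$architecture == "GA1")
      expect_identical(tl$ice$tra_families,
                       c("TraG", "TraK", "TraM", "TraN", "TraD"))
    if (tl$architecture == "GA2")
      expect_identical(tl$ice$tra_families,
                       c("TraO", "TraN", "TraM", "TraK", "TraJ", "TrbJ",
                         "TraG", "TraI", "TraD"))
    if (tl$architecture == "GA3")
      expect_null(tl$ice)
  }
})

test_that("genome sets are deterministic under seed with faithful truth", {
  cfg <- synth_config(n_genomes = 2,
                      architecture_mix = c(GA1 = 1, GA2 = 0, GA3 = 0,
                                           none = 1), seed = 4)
  a <- generate_genome_set(cfg)
  b <- generate_genome_set(cfg)
  expect_identical(vapply(a$genomes, function(g) g$contigs[[1]]$sequence,
                          character(1)),
                   vapply(b$genomes, function(g) g$contigs[[1]]$sequence,
                          character(1)))
  # every truth gene id maps to a real gene of the emitted genome
  for (tr in a$truth) {
    gn <- a$genomes[[tr$genome_id]]
    ids <- t6finder:::genome_genes(gn)$gene_id
    for (tl in tr$loci) expect_true(all(tl$gene_ids %in% ids))
  }
  # all-"none" mix lists no loci
  none <- generate_genome_set(synth_config(
    n_genomes = 2, architecture_mix = c(GA1 = 0, GA2 = 0, GA3 = 0,
                                        none = 2), seed = 5))
  expect_true(all(vapply(none$truth, function(t) length(t$loci) == 0L,
                         logical(1))))
  # decoys never place a vgrG next to a clpV (no vgrG decoys exist)
  expect_false(any(grepl("VgrG", unlist(lapply(none$truth,
                                               `[[`, "decoy_gene_ids")))))
})

test_that("written genome sets round-trip with the truth gene counts", {
  gs <- generate_genome_set(synth_config(
    n_genomes = 1, architecture_mix = c(GA1 = 1, GA2 = 0, GA3 = 0,
                                        none = 0),
    contig_split_prob = 1, seed = 6))
  dir <- withr::local_tempdir()
  write_genome_set(gs, dir)
  gn <- read_genome_bundle(file.path(dir, "g01.fna"),
                           file.path(dir, "g01.gff3"), genome_id = "g01")
  expect_equal(nrow(t6finder:::genome_genes(gn)),
               nrow(t6finder:::genome_genes(gs$genomes$g01)))
  tl <- gs$truth$g01$loci[[1]]
  expect_true(tl$split)
  expect_length(tl$contig_ids, 2L)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(length(truth$g01$loci), 1L)
})
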