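test_that("HSP finding handles identity, randomness and the length filter", {
  cfg <- fx_config()
  set.seed(31)
  s <- fx_random_dna(5000)
  h <- find_hsps(s, s, cfg)
  plus <- h[h$strand == "+", ]
  expect_equal(nrow(plus), 1L)
  expect_equal(plus$qstart, 1L)
  expect_equal(plus$qend, 5000L)
  expect_equal(plus$identity, 1)
  # unrelated random sequences never reach the 1000-bp floor
  for (k in 1:20) {
    set.seed(100 + k)
    expect_equal(nrow(find_hsps(fx_random_dna(5000), fx_random_dna(5000),
                                cfg)), 0L)
  }
})

test_that("the 1000-bp filter keeps exactly the long homology blocks", {
  cfg <- fx_config()
  set.seed(32)
  b800 <- fx_random_dna(800)
  b1200 <- fx_random_dna(1200)
  b3000 <- fx_random_dna(3000)
  q <- paste0(fx_random_dna(300), b800, fx_random_dna(250), b1200,
              fx_random_dna(400), b3000, fx_random_dna(200))
  s <- paste0(fx_random_dna(500), b800, fx_random_dna(700), b1200,
              fx_random_dna(350), b3000, fx_random_dna(600))
  h <- find_hsps(q, s, cfg)
  expect_equal(nrow(h), 2L)
  expect_false(is.unsorted(h$qstart))
  expect_equal(sort(h$length), c(1200L, 3000L), tolerance = 0.02)
  # removing the filter only adds HSPs below the floor
  h0 <- find_hsps(q, s, cfg, min_len = 0)
  expect_true(all(h$length >= cfg$hsp_min_len))
  extra <- setdiff(paste(h0$qstart, h0$send), paste(h$qstart, h$send))
  expect_true(all(h0$length[paste(h0$qstart, h0$send) %in% extra] <
                    cfg$hsp_min_len))
})

test_that("HSPs are strand symmetric", {
  cfg <- fx_config()
  set.seed(33)
  q <- fx_random_dna(4000)
  s <- paste0(fx_random_dna(800), substr(q, 1001, 3200), fx_random_dna(500))
  h1 <- find_hsps(q, s, cfg)
  h2 <- find_hsps(q, t6finder:::revcomp(s), cfg)
  expect_equal(nrow(h1), nrow(h2))
  expect_setequal(h1$strand, "+")
  expect_setequal(h2$strand, "-")
  expect_equal(h1$qstart, h2$qstart)
  expect_equal(h1$qend, h2$qend)
  expect_equal(h1$sstart, nchar(s) - h2$send + 1L)
  expect_equal(h1$send, nchar(s) - h2$sstart + 1L)
  expect_equal(h1$identity, h2$identity)
})

test_that("tra detection finds the implanted rosters and nothing else", {
  mini <- fx_mini()
  tra <- mini$cur$profiles[t6finder:::TRA_FAMILIES]
  counts <- list(GA1 = 5L, GA2 = 9L)
  for (tr in mini$gs$truth) {
    hits <- detect_tra_genes(mini$gs$genomes[[tr$genome_id]], tra, mini$cfg)
    if (length(tr$loci) && tr$loci[[1]]$architecture %in% names(counts)) {
      expect_equal(nrow(hits), counts[[tr$loci[[1]]$architecture]])
      expect_setequal(hits$gene_id, tr$loci[[1]]$ice$tra_gene_ids)
    } else {
      expect_equal(nrow(hits), 0L)
    }
  }
})

test_that("tra proximity applies the 50-kb window and the flank patterns", {
  mini <- fx_mini()
  run <- mini$run
  for (i in seq_along(run$loci)) {
    lc <- run$loci[[i]]
    row <- run$ice[run$ice$locus_id == lc$locus_id, ]
    if (lc$architecture == "GA1") {
      expect_identical(row$verdict, "ICE-associated")
      expect_identical(row$pattern, "GA1-pattern")
    }
    if (lc$architecture == "GA2") {
      expect_identical(row$verdict, "ICE-associated")
      expect_identical(row$pattern, "GA2-pattern")
    }
    if (lc$architecture == "GA3") {
      expect_identical(row$verdict, "not-associated")
      expect_identical(row$pattern, "none")
    }
  }
  # a tra gene far down the same contig never counts
  gn <- fx_fake_genome(3)
  lc <- t6finder:::make_locus("L", "fake", gn$contigs$c1$genes,
                              list(c1 = c(0L, 30L)), 1L)
  far <- data.frame(gene_id = "t1", contig_id = "c1", ordinal = 99L,
                    family = "TraG", score = 50, evalue = 1e-9,
                    start = 200000L, end = 201000L, strand = "+",
                    stringsAsFactors = FALSE)
  a <- tra_proximity(lc, far, mini$cfg)
  expect_identical(a$verdict, "not-associated")
  near <- far
  near$start <- 10000L
  near$end <- 11000L
  a2 <- tra_proximity(lc, near, mini$cfg)
  expect_identical(a2$verdict, "ICE-associated")
  expect_identical(a2$pattern, "inconsistent")   # one family, no roster
  a3 <- tra_proximity(lc, far[0, ], mini$cfg)
  expect_identical(a3$verdict, "not-associated")
  expect_identical(a3$pattern, "none")
})

test_that("ICE extent converges onto the shared element", {
  cfg <- fx_config()
  set.seed(34)
  ice <- fx_random_dna(20000)
  mk <- function(id, flankL, flankR) {
    seqs <- paste0(fx_random_dna(flankL), ice, fx_random_dna(flankR))
    make_genome(id, "", list(make_contig("c1", seqs, NULL)))
  }
  gA <- mk("A", 30000, 15000)
  gB <- mk("B", 8000, 22000)
  # the "locus" is a 6-kb window inside the ICE of genome A
  lc <- t6finder:::make_locus("L", "A",
                              data.frame(gene_id = "x", contig_id = "c1",
                                         start = 36000L, end = 42000L,
                                         strand = "+", ordinal = 0L,
                                         protein = "M", family = "VgrG",
                                         stringsAsFactors = FALSE),
                              list(c1 = c(36000L, 42000L)), 1L)
  ext <- ice_extent(gA, lc, gB, cfg)
  expect_false(ext$flagged)
  expect_lt(abs(ext$span[1] - 30000), 100)
  expect_lt(abs(ext$span[2] - 50000), 100)
  # monotone: the refined span stays within locus +/- window
  expect_gte(ext$span[1], 36000 - cfg$ice_window_bp)
  expect_lte(ext$span[2], 42000 + cfg$ice_window_bp)
  # an unrelated genome is flagged with the locus-only fallback
  gC <- make_genome("C", "", list(make_contig("c1", fx_random_dna(60000),
                                              NULL)))
  ext2 <- ice_extent(gA, lc, gC, cfg)
  expect_true(ext2$flagged)
  expect_equal(ext2$span, c(36000L, 42000L))
})

test_that("percent identity from mismatches reproduces the worked example", {
  expect_equal(percent_identity_from_mismatches(109805, 3), 99.997)
  expect_equal(percent_identity_from_mismatches(123456, 0), 100)
  expect_equal(percent_identity_from_mismatches(1000, 10), 99.000)
  expect_error(percent_identity_from_mismatches(0, 0), "positive")
  expect_error(percent_identity_from_mismatches(10, 11), "mismatches")
})

test_that("pairwise ICE identity is weighted, near-symmetric and honest about divergence", {
  cfg <- fx_config()
  set.seed(35)
  base <- fx_random_dna(15000)
  seqs <- c(a = base, b = base)
  M <- pairwise_ice_identity(seqs, cfg)
  expect_equal(M["a", "b"], 1)
  expect_equal(M["b", "a"], 1)
  seqs2 <- c(a = base, b = mutate_dna(base, 0.01, seed = 1),
             c = mutate_dna(base, 0.01, seed = 2))
  M2 <- pairwise_ice_identity(seqs2, cfg)
  off <- M2[upper.tri(M2)]
  expect_true(all(abs(off - 0.99) < 0.006 | abs(off - 0.98) < 0.006))
  expect_true(all(abs(M2 - t(M2)) < 0.005, na.rm = TRUE))
  # unrelated pairs are reported missing
  M3 <- pairwise_ice_identity(c(a = base, z = fx_random_dna(15000)), cfg)
  expect_true(is.na(M3["a", "z"]))
})
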