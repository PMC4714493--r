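mk_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(gene_id = r[[1]], contig_id = r[[2]],
               ordinal = as.integer(r[[3]]), profile_name = r[[4]],
               family = r[[4]], score = 100, evalue = 1e-9,
               qstart = 1L, qend = 10L, stringsAsFactors = FALSE)))
}

test_that("sentinel pairing enforces contig and the fifteen-gene rule", {
  cfg <- fx_config()
  gn <- fx_fake_genome(60)
  p1 <- find_sentinel_pairs(mk_hits(list("g004", "c1", 3, "VgrG"),
                                    list("g011", "c1", 10, "ClpV")), gn, cfg)
  expect_equal(nrow(p1), 1L)
  p2 <- find_sentinel_pairs(mk_hits(list("g004", "c1", 3, "VgrG"),
                                    list("g026", "c1", 25, "ClpV")), gn, cfg)
  expect_equal(nrow(p2), 0L)
  p3 <- find_sentinel_pairs(mk_hits(list("g004", "c1", 3, "VgrG"),
                                    list("g011", "c2", 10, "ClpV")), gn, cfg)
  expect_equal(nrow(p3), 0L)
  # boundary: exactly 15 intervening genes still pairs, 16 does not
  p4 <- find_sentinel_pairs(mk_hits(list("g001", "c1", 0, "VgrG"),
                                    list("g017", "c1", 16, "ClpV")), gn, cfg)
  expect_equal(nrow(p4), 1L)
  p5 <- find_sentinel_pairs(mk_hits(list("g001", "c1", 0, "VgrG"),
                                    list("g018", "c1", 17, "ClpV")), gn, cfg)
  expect_equal(nrow(p5), 0L)
})

test_that("window extraction adds 25 flanking genes and truncates at ends", {
  cfg <- fx_config()
  gn <- fx_fake_genome(100)
  w <- extract_region(gn, list(contig_id = "c1",
                               sentinel_ordinals = c(30L, 40L)), cfg)
  expect_equal(range(w$genes$ordinal), c(5L, 65L))
  w2 <- extract_region(gn, list(contig_id = "c1",
                                sentinel_ordinals = c(3L, 10L)), cfg)
  expect_equal(min(w2$genes$ordinal), 0L)
  # bound: window size never exceeds gap + 2 + 2 * flank
  expect_lte(nrow(w$genes), (40 - 30 - 1) + 2 + 50)
})

test_that("trimming keeps the labelled interval and interior genes only", {
  gn <- fx_fake_genome(46)
  w <- list(contig_id = "c1", genes = gn$contigs$c1$genes)
  lab <- function(ords, fams) data.frame(
    gene_id = sprintf("g%03d", ords + 1L), family = fams,
    stringsAsFactors = FALSE)
  lc <- trim_region(w, lab(7:20, rep("TssB", 14)))
  expect_equal(range(lc$genes$ordinal), c(7L, 20L))
  # an effector two ordinals past the last tss gene extends the interval
  lc2 <- trim_region(w, lab(c(7:20, 22L), c(rep("TssB", 14), "ToxNuc")))
  expect_equal(max(lc2$genes$ordinal), 22L)
  expect_true("g022" %in% lc2$genes$gene_id)   # interior unlabelled kept
  # all genes labelled -> the whole window survives
  lc3 <- trim_region(w, lab(0:45, rep("Hcp", 46)))
  expect_equal(nrow(lc3$genes), 46L)
  expect_error(trim_region(w, lab(3L, "not-a-family")), "cannot trim")
  # a far-away labelled decoy is dropped under the label-gap rule
  lc4 <- trim_region(w, lab(c(2L, 7:20), c("ClpV", rep("TssB", 14))),
                     max_label_gap = 3, anchors = "g010")
  expect_equal(range(lc4$genes$ordinal), c(7L, 20L))
})

test_that("orientation mirrors minus-strand vgrG loci and is idempotent", {
  genes <- data.frame(gene_id = c("a", "b", "c"),
                      contig_id = "c1",
                      start = c(0L, 100L, 220L),
                      end = c(90L, 200L, 300L),
                      strand = c("-", "-", "+"),
                      ordinal = 0:2,
                      protein = "M",
                      family = c("TetR", "VgrG", "Hcp"),
                      stringsAsFactors = FALSE)
  lc <- t6finder:::make_locus("L", "g", genes,
                              list(c1 = c(0L, 300L)), 1L)
  o <- orient_region(lc)
  expect_true(o$oriented)
  vg <- o$genes[o$genes$family == "VgrG", ]
  expect_equal(vg$strand, "+")
  expect_equal(o$genes$gene_id, c("c", "b", "a"))   # order mirrored
  expect_equal(o$genes$start[o$genes$gene_id == "c"], 0L)
  o2 <- orient_region(o)
  expect_identical(o2$genes, o$genes)
  # plus-strand vgrG is left untouched
  genes$strand <- c("+", "+", "-")
  lc2 <- t6finder:::make_locus("L2", "g", genes, list(c1 = c(0L, 300L)), 1L)
  expect_identical(orient_region(lc2)$genes, genes)
  genes$family <- c("TetR", "TssB", "Hcp")
  lc3 <- t6finder:::make_locus("L3", "g", genes, list(c1 = c(0L, 300L)), 1L)
  expect_error(orient_region(lc3), "vgrG")
})

test_that("the second pass recovers split loci and reports orphans", {
  mini <- fx_mini()
  run <- mini$run
  split_ids <- names(which(vapply(mini$gs$truth, function(t)
    length(t$loci) && t$loci[[1]]$split, logical(1))))
  expect_gt(length(split_ids), 0)
  for (sid in split_ids) {
    p1 <- Filter(function(lc) lc$genome_id == sid &&
                   lc$discovery_pass == 1L, run$loci)
    p2 <- Filter(function(lc) lc$genome_id == sid &&
                   lc$discovery_pass == 2L, run$loci)
    expect_length(p1, 0)
    expect_length(p2, 1)
  }
  # standalone decoy hits become orphans, never loci
  orph <- run$orphans
  expect_true(any(grepl("_d[0-9]+_", orph$gene_id)))
  locus_genes <- unlist(lapply(run$loci, function(lc) lc$genes$gene_id))
  expect_length(intersect(orph$gene_id, locus_genes), 0)
  # pass-1 and pass-2 loci are disjoint in gene membership
  keys <- unlist(lapply(run$loci, function(lc)
    paste(lc$genome_id, lc$genes$gene_id)))
  expect_false(any(duplicated(keys)))
})

test_that("a genome without any T6SS gene yields neither loci nor orphans", {
  mini <- fx_mini()
  gs <- generate_genome_set(synth_config(
    n_genomes = 1, architecture_mix = c(GA1 = 0, GA2 = 0, GA3 = 0,
                                        none = 1),
    decoy_rate = 0, seed = 13), mini$cur)
  profs <- c(mini$run$cluster_profiles,
             mini$cur$profiles[c(t6finder:::CORE_TSS_FAMILIES,
                                 t6finder:::TAG_FAMILIES,
                                 "TetR", "PAAR", "Rhs")])
  res <- second_pass_scan(profs, gs$genomes, mini$cfg)
  expect_length(res$loci, 0)
  expect_equal(nrow(res$orphans), 0L)
})
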