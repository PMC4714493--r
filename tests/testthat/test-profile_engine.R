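test_that("profile scoring matches a brute-force DP oracle", {
  set.seed(11)
  for (k in 1:30) {
    L <- sample(5:30, 1)
    emit <- matrix(rnorm(20 * L, sd = 2), nrow = 20,
                   dimnames = list(t6finder:::AA20, NULL))
    p <- make_profile(sprintf("p%d", k), emit)
    prot <- oracle_random_protein(sample(5:30, 1))
    got <- score_protein(p, prot)$score
    want <- oracle_profile_sw(emit, prot)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("degenerate proteins and invalid characters are handled", {
  fam <- fx_curated()
  p <- fam$profiles$Hcp
  expect_equal(score_protein(p, strrep("X", 40))$score, 0)
  expect_error(score_protein(p, "ACDEF*"), "non-amino-acid")
  # provenance of the protein does not matter, only its sequence
  expect_equal(score_protein(p, fam$consensus[["Hcp"]])$score,
               score_protein(p, paste(fam$consensus[["Hcp"]]))$score)
})

test_that("empirical E-values saturate, decay monotonically and reward true members", {
  fam <- generate_family_consensus(1)
  p <- calibrate_evalues(fam$profiles$TssB, decoy_db_size = 1e4,
                         n_shuffles = 200, seed = 1)
  expect_equal(profile_evalue(p, 0), 1e4)
  expect_lte(profile_evalue(p, max(p$null_scores) + 1e-6), 1e4 / 201 + 1e-9)
  grid <- seq(0, 2 * max(p$null_scores), length.out = 80)
  ev <- vapply(grid, function(s) profile_evalue(p, s), numeric(1))
  expect_true(all(diff(ev) <= 1e-12))
  # an implanted family member is overwhelmingly significant
  member <- mutate_protein(fam$consensus[["TssB"]], 0.05, seed = 2)
  expect_lt(profile_evalue(p, score_protein(p, member)$score), 1e-3)
  expect_error(calibrate_evalues(p, n_shuffles = 50), ">= 100")
})

test_that("proteome scanning is deterministic, sorted and specific", {
  mini <- fx_mini()
  gn <- mini$gs$genomes[[1]]
  sent <- mini$cur$profiles[c("VgrG", "ClpV")]
  h1 <- scan_proteome(sent, gn, 1e-3, mini$cfg)
  h2 <- scan_proteome(sent, gn, 1e-3, mini$cfg)
  expect_identical(h1, h2)
  expect_false(is.unsorted(order(h1$contig_id, h1$ordinal)))
  expect_true(all(h1$evalue <= 1e-3))
  # one best hit per (gene, profile)
  expect_false(any(duplicated(paste(h1$gene_id, h1$profile_name))))
  # a genome with no implants yields no sentinel hits at this cutoff
  none_id <- names(which(vapply(mini$gs$truth, function(t)
    length(t$loci) == 0L, logical(1))))[1]
  h0 <- scan_proteome(sent, mini$gs$genomes[[none_id]], 1e-3, mini$cfg)
  expect_true(all(grepl("ClpV", h0$gene_id) | !nrow(h0)))
})

test_that("dedupe collapses exact duplicates in stable order", {
  expect_identical(dedupe_members(c(a = "AAA", b = "AAA")), c(a = "AAA"))
  v <- c(x = "AB", y = "CD", z = "EF")
  expect_identical(dedupe_members(v), v)
  set.seed(3)
  base <- replicate(5, oracle_random_protein(8))
  dup <- sample(rep(base, times = c(1, 2, 3, 1, 4)))
  names(dup) <- sprintf("m%02d", seq_along(dup))
  expect_length(dedupe_members(dup), length(unique(dup)))
})

test_that("star alignments keep all members at equal width", {
  one <- build_msa(c(s1 = "MKLV"))
  expect_identical(unname(one$alignment), "MKLV")
  same <- build_msa(c(a = "MKLVW", b = "MKLVW", c = "MKLVW"))
  expect_true(all(!grepl("-", same$alignment)))
  set.seed(4)
  for (k in 1:10) {
    mem <- vapply(seq_len(sample(2:6, 1)), function(i)
      oracle_random_protein(sample(10:40, 1)), character(1))
    names(mem) <- sprintf("m%d", seq_along(mem))
    al <- build_msa(mem)
    w <- unique(nchar(al$alignment))
    expect_length(w, 1L)
    expect_gte(w, max(nchar(mem)))
    expect_identical(vapply(al$alignment, function(r)
      gsub("-", "", r), character(1), USE.NAMES = FALSE), unname(mem))
  }
})

test_that("profiles built from alignments rescore their consensus and drop gap columns", {
  al <- c(a = "MK-LV", b = "MK-LV", c = "MK-LV")
  p <- build_profile(al, "toy")
  expect_equal(p$length, 4L)
  expect_equal(score_protein(p, "MKLV")$score,
               sum(apply(p$match_scores, 2, max)), tolerance = 1e-9)
  # a profile from mutated copies separates consensus from shuffles
  fam <- generate_family_consensus(2)
  cons <- fam$consensus[["TssO"]]
  set.seed(5)
  copies <- vapply(1:20, function(i) mutate_protein(cons, 0.05),
                   character(1))
  names(copies) <- sprintf("c%02d", 1:20)
  prof <- build_profile(build_msa(copies), "TssO_rebuilt")
  cons_score <- score_protein(prof, cons)$score
  null <- replicate(200, score_protein(prof,
    oracle_random_protein(nchar(cons)))$score)
  expect_gt(cons_score, quantile(null, 0.99))
})

test_that("self-scan thresholds recall the training set and reject decoys", {
  fam <- generate_family_consensus(3)
  p <- fam$profiles$TssQ
  same <- rep(fam$consensus[["TssQ"]], 4)
  p1 <- calibrate_threshold(p, same)
  expect_equal(p1$threshold_score, score_protein(p, same[1])$score)
  set.seed(6)
  members <- vapply(1:8, function(i)
    mutate_protein(fam$consensus[["TssQ"]], 0.25), character(1))
  p2 <- calibrate_threshold(p, members)
  scores <- vapply(members, function(m) score_protein(p2, m)$score,
                   numeric(1))
  expect_true(all(scores >= p2$threshold_score))
  decoys <- replicate(100, score_protein(p2,
    oracle_random_protein(nchar(fam$consensus[["TssQ"]])))$score)
  expect_lte(mean(decoys >= p2$threshold_score), 0.01)
})
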