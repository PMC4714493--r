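# End-to-end orchestration: sentinel scan -> pass-1 loci -> clustering ->
# family annotation -> self-trained profiles -> pass-2 rescan ->
# classification -> ICE analysis, with an evaluation harness against
# synthetic ground truth.

#' Run the full T6SS discovery pipeline
#'
#' Executes both detection passes, clusters the pass-1 window proteins,
#' assigns family labels via cluster representatives, rebuilds family
#' profiles from the clusters for the second pass, scans locus proteins
#' for toxin/immunity domains, classifies every locus into a genetic
#' architecture and decides ICE association from tra-gene proximity.
#' Fully deterministic given `config$rng_seed`.
#'
#' @param genomes named list of `t6_genome` objects.
#' @param curated curated profile set (e.g. [curated_profile_set()] or
#'   [read_profile_set()] output wrapped as `list(profiles = ...)`).
#' @param config a [pipeline_config()].
#' @param enable_pass2 run the self-trained profile rescan.
#' @param out_dir optional directory receiving TSV/JSON reports and the
#'   run manifest.
#' @return list (class `t6_run`): loci, arch (calls data.frame), ice
#'   (data.frame), clusters, assignments, annotations, effectors, orphans,
#'   manifest.
#' @export
run_pipeline <- function(genomes, curated, config = pipeline_config(),
                         enable_pass2 = TRUE, out_dir = NULL) {
  seed <- config$rng_seed
  names(genomes) <- vapply(genomes, `[[`, character(1), "genome_id")
  profiles <- curated$profiles
  profiles <- lapply(profiles, function(p) {
    if (is.null(p$null_scores))
      calibrate_evalues(p, config$decoy_db_size, config$n_shuffles,
                        seed = stage_seed(seed, paste0("cal_", p$name)),
                        gap_open = config$gap_open, gap_ext = config$gap_ext)
    else p
  })
  names(profiles) <- vapply(profiles, `[[`, character(1), "name")
  if (!all(c("VgrG", "ClpV") %in% names(profiles)))
    stop("curated set must contain VgrG and ClpV sentinel profiles")

  # ---- pass 1: sentinel co-localization ----
  windows <- list()
  n_hits <- 0L
  n_pairs <- 0L
  for (gn in genomes) {
    hits <- scan_proteome(profiles[c("VgrG", "ClpV")], gn,
                          config$sentinel_evalue_max, config)
    n_hits <- n_hits + nrow(hits)
    pairs <- find_sentinel_pairs(hits, gn, config)
    n_pairs <- n_pairs + nrow(pairs)
    for (cd in sentinel_candidates(pairs))
      windows[[length(windows) + 1L]] <-
        c(list(genome_id = gn$genome_id, anchors = cd$gene_ids),
          extract_region(gn, cd, config))
  }

  # ---- clustering of all window proteins ----
  wg <- if (length(windows)) do.call(rbind, lapply(windows, function(w)
    data.frame(genome_id = w$genome_id, gene_id = w$genes$gene_id,
               protein = w$genes$protein, stringsAsFactors = FALSE)))
    else data.frame(genome_id = character(), gene_id = character(),
                    protein = character(), stringsAsFactors = FALSE)
  wg <- wg[!duplicated(paste(wg$genome_id, wg$gene_id)), , drop = FALSE]
  proteins <- setNames(wg$protein, paste(wg$genome_id, wg$gene_id,
                                         sep = "|"))
  clusters <- greedy_cluster(proteins, config)
  reps <- vapply(clusters, function(cl)
    pick_representative(cl, stage_seed(seed, paste0("rep", cl$cluster_id))),
    character(1))
  rep_seqs <- setNames(proteins[reps], reps)
  assignments <- if (length(clusters))
    assign_families(clusters, rep_seqs, profiles, config)
    else data.frame(cluster_id = integer(), representative = character(),
                    family = character(), profile = character(),
                    score = numeric(), evalue = numeric(),
                    stringsAsFactors = FALSE)

  # per-gene annotation (label propagated from the cluster representative)
  key_fam <- character(0)
  key_cl <- integer(0)
  for (i in seq_along(clusters)) {
    key_fam[clusters[[i]]$members] <- assignments$family[i]
    key_cl[clusters[[i]]$members] <- assignments$cluster_id[i]
  }
  ann_all <- data.frame(key = names(proteins),
                        genome_id = wg$genome_id, gene_id = wg$gene_id,
                        family = unname(key_fam[names(proteins)]),
                        cluster_id = unname(key_cl[names(proteins)]),
                        stringsAsFactors = FALSE)
  # evolved-Hcp flags against the curated Hcp profile
  ann_all$evolved_hcp <- rep(FALSE, nrow(ann_all))
  hcp_rows <- which(!is.na(ann_all$family) & ann_all$family == "Hcp")
  if (length(hcp_rows) && "Hcp" %in% names(profiles)) {
    med <- median(nchar(proteins[ann_all$key[hcp_rows]]))
    ann_all$evolved_hcp[hcp_rows] <- vapply(hcp_rows, function(i)
      flag_evolved_hcp(proteins[[ann_all$key[i]]], profiles$Hcp, med,
                       config), logical(1))
  }

  # ---- trim + orient pass-1 loci ----
  pass1 <- list()
  for (w in windows) {
    ann <- ann_all[ann_all$genome_id == w$genome_id, , drop = FALSE]
    lc <- trim_region(w, ann,
                      locus_id = sprintf("%s_p1_%02d", w$genome_id,
                                         length(pass1) + 1L),
                      genome_id = w$genome_id, discovery_pass = 1L,
                      max_label_gap = config$max_label_gap,
                      anchors = w$anchors)
    if (any(!is.na(lc$genes$family) & lc$genes$family == "VgrG"))
      lc <- orient_region(lc)
    pass1[[length(pass1) + 1L]] <- lc
  }

  # ---- pass 2: profiles rebuilt from clusters ----
  pass2 <- list()
  orphans <- data.frame()
  cluster_profiles <- list()
  if (enable_pass2 && length(clusters)) {
    rebuild_fams <- c(CORE_TSS_FAMILIES, TAG_FAMILIES, "TetR", "PAAR",
                      "Rhs")
    for (i in seq_along(clusters)) {
      fam <- assignments$family[i]
      if (is.na(fam) || !fam %in% rebuild_fams) next
      mem <- dedupe_members(proteins[clusters[[i]]$members])
      prof <- build_profile(build_msa(mem, config$gap_open, config$gap_ext),
                            name = sprintf("cluster%03d",
                                           clusters[[i]]$cluster_id),
                            family = fam)
      prof <- calibrate_threshold(prof, mem, config$gap_open,
                                  config$gap_ext)
      prof <- calibrate_evalues(prof, config$decoy_db_size,
                                config$n_shuffles,
                                seed = stage_seed(seed,
                                  paste0("calc", clusters[[i]]$cluster_id)),
                                gap_open = config$gap_open,
                                gap_ext = config$gap_ext)
      cluster_profiles[[prof$name]] <- prof
    }
    # scan with the corpus-trained cluster profiles plus the curated
    # family profiles: the rebuilt profiles capture corpus-specific
    # variants while the curated set keeps thresholds that generalize
    # when a cluster has only a handful of training members
    pass2_profiles <- c(cluster_profiles,
                        profiles[intersect(names(profiles), rebuild_fams)])
    p2 <- second_pass_scan(pass2_profiles, genomes, config, pass1)
    pass2 <- p2$loci
    orphans <- p2$orphans
  }
  loci <- c(pass1, pass2)

  # ---- effector / immunity scan over locus proteins ----
  tox_profiles <- profiles[intersect(names(profiles),
                                     c(names(TOXIN_FAMILIES),
                                       names(IMMUNITY_FAMILIES)))]
  effectors <- do.call(rbind, c(lapply(loci, function(lc) {
    ps <- setNames(lc$genes$protein, lc$genes$gene_id)
    eh <- scan_effectors(ps, tox_profiles, config)
    if (nrow(eh)) cbind(locus_id = lc$locus_id, eh) else NULL
  }), list(make.row.names = FALSE)))
  if (is.null(effectors))
    effectors <- data.frame(locus_id = character(), gene_id = character(),
                            profile = character(), class = character(),
                            score = numeric(), evalue = numeric(),
                            qstart = integer(), qend = integer(),
                            stringsAsFactors = FALSE)

  # ---- architecture classification ----
  cls <- if (length(loci)) classify_loci(loci, config)
    else list(loci = loci,
              calls = data.frame(locus_id = character(), call = character(),
                                 score = numeric(), stringsAsFactors = FALSE),
              detail = list())
  loci <- cls$loci

  # ---- ICE association ----
  tra_profiles <- profiles[intersect(names(profiles), TRA_FAMILIES)]
  tra_by_genome <- lapply(genomes, function(gn)
    if (length(tra_profiles)) detect_tra_genes(gn, tra_profiles, config)
    else data.frame())
  ice_rows <- lapply(loci, function(lc) {
    assoc <- tra_proximity(lc, tra_by_genome[[lc$genome_id]], config)
    data.frame(locus_id = lc$locus_id, genome_id = lc$genome_id,
               architecture = lc$architecture, verdict = assoc$verdict,
               pattern = assoc$pattern,
               n_tra_within = sum(assoc$tra$within_window),
               min_distance = if (nrow(assoc$tra))
                 min(assoc$tra$distance) else NA_real_,
               stringsAsFactors = FALSE)
  })
  ice <- if (length(ice_rows)) do.call(rbind, ice_rows) else
    data.frame(locus_id = character(), genome_id = character(),
               architecture = character(), verdict = character(),
               pattern = character(), n_tra_within = integer(),
               min_distance = numeric(), stringsAsFactors = FALSE)

  manifest <- list(
    seed = seed, config = unclass(config),
    versions = list(package = as.character(utils::packageVersion("t6finder")),
                    r = R.version.string),
    counts = list(genomes = length(genomes), sentinel_hits = n_hits,
                  sentinel_pairs = n_pairs, windows = length(windows),
                  clusters = length(clusters),
                  pass1_loci = length(pass1), pass2_loci = length(pass2),
                  loci = length(loci), orphans = nrow(orphans),
                  calls = as.list(table(cls$calls$call)),
                  ice_associated = sum(ice$verdict == "ICE-associated")))

  res <- structure(list(loci = loci, arch = cls$calls, ice = ice,
                        clusters = clusters, assignments = assignments,
                        annotations = ann_all, effectors = effectors,
                        orphans = orphans,
                        cluster_profiles = cluster_profiles,
                        manifest = manifest),
                   class = "t6_run")
  if (!is.null(out_dir)) write_run_reports(res, out_dir)
  res
}

#' @export
print.t6_run <- function(x, ...) {
  cat("t6_run:", x$manifest$counts$genomes, "genomes;",
      x$manifest$counts$pass1_loci, "pass-1 +",
      x$manifest$counts$pass2_loci, "pass-2 loci;",
      x$manifest$counts$clusters, "protein clusters\n")
  invisible(x)
}

# write the stage reports plus a manifest with file checksums
write_run_reports <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_locus_report(res$loci, file.path(out_dir, "loci.tsv"))
  tsv <- function(df, f) write.table(df, file.path(out_dir, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE,
                                     eol = "\n")
  tsv(res$arch, "architecture.tsv")
  tsv(res$ice, "ice.tsv")
  tsv(res$assignments, "clusters.tsv")
  tsv(res$annotations[, setdiff(names(res$annotations), "key")],
      "annotations.tsv")
  tsv(res$effectors, "effectors.tsv")
  tsv(res$orphans, "orphans.tsv")
  md <- dir.create(file.path(out_dir, "orf_maps"), showWarnings = FALSE)
  for (lc in res$loci)
    write_orf_map(lc, file.path(out_dir, "orf_maps",
                                paste0(lc$locus_id, ".json")))
  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.json")
  res$manifest$checksums <- as.list(
    tools::md5sum(file.path(out_dir, files)))
  names(res$manifest$checksums) <- files
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Evaluate a pipeline run against synthetic ground truth
#'
#' A detected locus matches a truth locus when their gene-set Jaccard
#' index is at least 0.5 within the same genome. Locus-level precision
#' and recall are computed on matches; architecture accuracy and the
#' confusion matrix on matched loci; ICE verdict accuracy against the
#' generator's design (GA1/GA2 loci carry tra flanks, GA3 do not); and
#' family-assignment accuracy over truth genes present in matched loci.
#'
#' @param run a `t6_run`.
#' @param truth truth records from [generate_genome_set()].
#' @return list (class `t6_evaluation`) of metrics, all in `[0, 1]`.
#' @export
evaluate_run <- function(run, truth) {
  truth_loci <- list()
  for (tr in truth) {
    for (tl in tr$loci)
      truth_loci[[length(truth_loci) + 1L]] <-
        c(tl, list(genome_id = tr$genome_id))
  }
  det <- run$loci
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  match_of <- rep(NA_integer_, length(truth_loci))
  used <- logical(length(det))
  for (i in seq_along(truth_loci)) {
    tl <- truth_loci[[i]]
    best <- 0
    for (j in seq_along(det)) {
      if (det[[j]]$genome_id != tl$genome_id) next
      jj <- jac(tl$gene_ids, det[[j]]$genes$gene_id)
      if (jj >= 0.5 && jj > best) {
        best <- jj
        match_of[i] <- j
      }
    }
    if (!is.na(match_of[i])) used[match_of[i]] <- TRUE
  }
  recall <- if (length(truth_loci)) mean(!is.na(match_of)) else 1
  precision <- if (length(det)) mean(used) else 1

  archs <- c("GA1", "GA2", "GA3", "other")
  confusion <- matrix(0L, length(archs), length(archs),
                      dimnames = list(truth = archs, called = archs))
  arch_ok <- logical(0)
  ice_ok <- logical(0)
  fam_ok <- 0L
  fam_tot <- 0L
  for (i in seq_along(truth_loci)) {
    j <- match_of[i]
    if (is.na(j)) next
    tl <- truth_loci[[i]]
    call <- det[[j]]$architecture
    if (is.null(call)) call <- "other"
    confusion[tl$architecture, call] <- confusion[tl$architecture, call] + 1L
    arch_ok <- c(arch_ok, identical(call, tl$architecture))
    verdict <- run$ice$verdict[run$ice$locus_id == det[[j]]$locus_id]
    expect <- if (tl$architecture %in% c("GA1", "GA2")) "ICE-associated"
              else "not-associated"
    ice_ok <- c(ice_ok, length(verdict) == 1L && verdict == expect)
    expected_fam <- ifelse(tl$families == "EvolvedHcp", "Hcp", tl$families)
    g <- det[[j]]$genes
    common <- intersect(tl$gene_ids, g$gene_id)
    if (length(common)) {
      got <- g$family[match(common, g$gene_id)]
      want <- expected_fam[match(common, tl$gene_ids)]
      fam_ok <- fam_ok + sum(!is.na(got) & got == want)
      fam_tot <- fam_tot + length(common)
    }
  }
  structure(list(
    n_truth = length(truth_loci), n_detected = length(det),
    recall = recall, precision = precision,
    architecture_accuracy = if (length(arch_ok)) mean(arch_ok) else NA_real_,
    architecture_confusion = confusion,
    ice_accuracy = if (length(ice_ok)) mean(ice_ok) else NA_real_,
    family_accuracy = if (fam_tot) sum(fam_ok) / fam_tot else NA_real_,
    matched = match_of), class = "t6_evaluation")
}

#' @export
print.t6_evaluation <- function(x, ...) {
  cat(sprintf(paste0("t6_evaluation: recall %.3f, precision %.3f, ",
                     "architecture accuracy %.3f, ICE accuracy %.3f, ",
                     "family accuracy %.3f (%d truth loci, %d detected)\n"),
              x$recall, x$precision, x$architecture_accuracy,
              x$ice_accuracy, x$family_accuracy, x$n_truth, x$n_detected))
  invisible(x)
}
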