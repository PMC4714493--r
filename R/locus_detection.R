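# Two-pass T6SS locus discovery: sentinel (VgrG + ClpV) co-localization
# seeds pass 1; self-trained family profiles recover split/truncated loci
# in pass 2. Gene distance is measured on ordinals (per-contig gene rank).

make_locus <- function(locus_id, genome_id, genes, spans, discovery_pass,
                       oriented = FALSE, flipped = FALSE) {
  structure(list(locus_id = locus_id, genome_id = genome_id,
                 contig_ids = names(spans), genes = genes, spans = spans,
                 discovery_pass = discovery_pass, oriented = oriented,
                 flipped = flipped, architecture = NULL),
            class = "t6_locus")
}

#' @export
print.t6_locus <- function(x, ...) {
  cat("t6_locus", x$locus_id, "-", x$genome_id, "pass", x$discovery_pass,
      "-", nrow(x$genes), "genes on", paste(x$contig_ids, collapse = "+"),
      if (!is.null(x$architecture)) paste0("[", x$architecture, "]") else "",
      "\n")
  invisible(x)
}

#' Find co-localized sentinel pairs
#'
#' All (vgrG gene, clpV gene) pairs residing on the same contig with at
#' most `max_sentinel_gene_gap` genes lying strictly between them.
#'
#' @param hits motif hits from [scan_proteome()] with the two sentinel
#'   profiles.
#' @param genome the scanned `t6_genome`.
#' @param config a [pipeline_config()].
#' @return data.frame of pairs (contig_id, vgrg_gene, vgrg_ordinal,
#'   clpv_gene, clpv_ordinal).
#' @export
find_sentinel_pairs <- function(hits, genome, config = pipeline_config()) {
  empty <- data.frame(contig_id = character(), vgrg_gene = character(),
                      vgrg_ordinal = integer(), clpv_gene = character(),
                      clpv_ordinal = integer(), stringsAsFactors = FALSE)
  if (!nrow(hits)) return(empty)
  fam <- ifelse(is.na(hits$family), hits$profile_name, hits$family)
  v <- hits[fam == "VgrG", , drop = FALSE]
  cp <- hits[fam == "ClpV", , drop = FALSE]
  rows <- list()
  for (cid in intersect(unique(v$contig_id), unique(cp$contig_id))) {
    vv <- v[v$contig_id == cid, , drop = FALSE]
    cc <- cp[cp$contig_id == cid, , drop = FALSE]
    for (i in seq_len(nrow(vv))) {
      for (j in seq_len(nrow(cc))) {
        if (vv$gene_id[i] == cc$gene_id[j]) next
        gap <- abs(vv$ordinal[i] - cc$ordinal[j]) - 1L
        if (gap <= config$max_sentinel_gene_gap)
          rows[[length(rows) + 1L]] <- data.frame(
            contig_id = cid, vgrg_gene = vv$gene_id[i],
            vgrg_ordinal = vv$ordinal[i], clpv_gene = cc$gene_id[j],
            clpv_ordinal = cc$ordinal[j], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

# collapse pairs sharing genes into one candidate per gene neighborhood
sentinel_candidates <- function(pairs) {
  if (!nrow(pairs)) return(list())
  out <- list()
  for (cid in unique(pairs$contig_id)) {
    pp <- pairs[pairs$contig_id == cid, , drop = FALSE]
    sets <- lapply(seq_len(nrow(pp)), function(i)
      list(genes = c(pp$vgrg_gene[i], pp$clpv_gene[i]),
           ords = c(pp$vgrg_ordinal[i], pp$clpv_ordinal[i])))
    merged <- list()
    for (s in sets) {
      hit <- which(vapply(merged, function(m)
        length(intersect(m$genes, s$genes)) > 0L, logical(1)))
      if (length(hit)) {
        keep <- setdiff(seq_along(merged), hit)
        un <- s
        for (h in hit) {
          un$genes <- union(un$genes, merged[[h]]$genes)
          un$ords <- union(un$ords, merged[[h]]$ords)
        }
        merged <- c(merged[keep], list(un))
      } else merged <- c(merged, list(s))
    }
    for (m in merged)
      out[[length(out) + 1L]] <- list(contig_id = cid,
                                      gene_ids = sort(m$genes),
                                      sentinel_ordinals = sort(m$ords))
  }
  out
}

#' Extract the raw gene window around a sentinel candidate
#'
#' All genes between the outermost sentinel hits plus `flank_genes` genes
#' on each side, truncated at the contig ends (if fewer genes are
#' available, all available genes are included).
#'
#' @param genome a `t6_genome`.
#' @param candidate an element of the merged sentinel candidate list (or a
#'   one-row pair from [find_sentinel_pairs()]).
#' @param config a [pipeline_config()].
#' @return list with `contig_id` and the window `genes` data.frame.
#' @export
extract_region <- function(genome, candidate, config = pipeline_config()) {
  if (is.data.frame(candidate))
    candidate <- list(contig_id = candidate$contig_id[1],
                      sentinel_ordinals = c(candidate$vgrg_ordinal[1],
                                            candidate$clpv_ordinal[1]))
  genes <- genome$contigs[[candidate$contig_id]]$genes
  lo <- max(0L, min(candidate$sentinel_ordinals) - config$flank_genes)
  hi <- min(max(genes$ordinal),
            max(candidate$sentinel_ordinals) + config$flank_genes)
  w <- genes[genes$ordinal >= lo & genes$ordinal <= hi, , drop = FALSE]
  rownames(w) <- NULL
  list(contig_id = candidate$contig_id, genes = w)
}

#' Trim a raw window to the annotated locus
#'
#' The locus is the minimal contiguous ordinal interval containing every
#' gene labelled with a locus family (Tss*, Tag*, TetR, Hcp, VgrG, ClpV,
#' PAAR, Rhs, effector or immunity families); unlabelled genes interior to
#' the interval are retained, exterior ones dropped.
#'
#' @param window result of [extract_region()].
#' @param annotations data.frame with columns gene_id, family and
#'   optionally cluster_id, score, evolved_hcp.
#' @param locus_id,genome_id identifiers for the resulting locus.
#' @param discovery_pass 1 or 2.
#' @param max_label_gap labelled genes separated from the locus run by
#'   more than this many intervening genes are left out (draft genomes
#'   scatter decoy standalone hcp/clpV/tetR genes across contigs);
#'   `Inf` keeps every labelled gene in the window.
#' @param anchors gene ids that must lie inside the chosen run (e.g. the
#'   sentinel genes); when none is given the run with the most labelled
#'   genes wins.
#' @return a `t6_locus`.
#' @export
trim_region <- function(window, annotations, locus_id = "locus",
                        genome_id = "", discovery_pass = 1L,
                        max_label_gap = Inf, anchors = NULL) {
  g <- window$genes
  m <- match(g$gene_id, annotations$gene_id)
  g$family <- annotations$family[m]
  g$cluster_id <- if ("cluster_id" %in% names(annotations))
    annotations$cluster_id[m] else NA_integer_
  g$score <- if ("score" %in% names(annotations))
    annotations$score[m] else NA_real_
  g$evolved_hcp <- if ("evolved_hcp" %in% names(annotations))
    annotations$evolved_hcp[m] else NA
  labelled <- which(!is.na(g$family) & g$family %in% LOCUS_FAMILIES)
  if (!length(labelled))
    stop("window contains no genes labelled with locus families; cannot trim")
  if (is.finite(max_label_gap) && length(labelled) > 1L) {
    gaps <- g$ordinal[labelled[-1]] - g$ordinal[labelled[-length(labelled)]] - 1L
    run <- cumsum(c(0L, gaps > max_label_gap))
    counts <- tabulate(run + 1L)
    anchor_runs <- if (is.null(anchors)) integer(0)
      else unique(run[g$gene_id[labelled] %in% anchors])
    pick <- if (length(anchor_runs))
      anchor_runs[which.max(counts[anchor_runs + 1L])]
    else which.max(counts) - 1L
    labelled <- labelled[run == pick]
  }
  g <- g[min(labelled):max(labelled), , drop = FALSE]
  rownames(g) <- NULL
  spans <- setNames(list(c(min(g$start), max(g$end))), window$contig_id)
  make_locus(locus_id, genome_id, g, spans, discovery_pass)
}

#' Orient a locus so that vgrG is transcribed left to right
#'
#' If the anchoring vgrG gene (the highest-scoring one when scores are
#' available) lies on the minus strand, gene order and strands are
#' mirrored within the locus span. Idempotent.
#'
#' @param locus a `t6_locus` containing at least one vgrG gene.
#' @return the oriented locus.
#' @export
orient_region <- function(locus) {
  g <- locus$genes
  v <- which(!is.na(g$family) & g$family == "VgrG")
  if (!length(v)) stop("locus has no vgrG gene to orient by")
  anchor <- if ("score" %in% names(g) && !all(is.na(g$score[v])))
    v[which.max(g$score[v])] else v[1]
  if (g$strand[anchor] == "+") {
    locus$oriented <- TRUE
    return(locus)
  }
  for (cid in names(locus$spans)) {
    sel <- g$contig_id == cid
    sp <- locus$spans[[cid]]
    ns <- sp[1] + (sp[2] - g$end[sel])
    ne <- sp[1] + (sp[2] - g$start[sel])
    g$start[sel] <- ns
    g$end[sel] <- ne
    g$strand[sel] <- ifelse(g$strand[sel] == "+", "-", "+")
  }
  g <- g[order(match(g$contig_id, names(locus$spans)), g$start), ,
         drop = FALSE]
  rownames(g) <- NULL
  locus$genes <- g
  locus$flipped <- !isTRUE(locus$flipped)
  locus$oriented <- TRUE
  locus
}

#' Second-pass locus discovery with self-trained family profiles
#'
#' Slides an ordinal window along every contig; a new locus is called
#' where at least `pass2_min_core` distinct core Tss families score at or
#' above their profile thresholds and the region does not overlap a
#' pass-1 locus. Threshold-passing hits outside any locus are returned as
#' orphan genes (e.g. the numerous standalone ClpV-like genes of draft
#' genomes).
#'
#' @param profiles self-trained (cluster) profiles with calibrated
#'   thresholds and family labels.
#' @param genomes named list of `t6_genome`.
#' @param config a [pipeline_config()].
#' @param pass1_loci list of pass-1 `t6_locus` objects.
#' @return list with `loci` (pass-2 `t6_locus` list) and `orphans`
#'   (data.frame).
#' @export
second_pass_scan <- function(profiles, genomes, config = pipeline_config(),
                             pass1_loci = list()) {
  profiles <- Filter(function(p) !is.null(p$threshold_score), profiles)
  pass1_ids <- unlist(lapply(pass1_loci, function(lc)
    paste(lc$genome_id, lc$genes$gene_id)))
  loci <- list()
  orphan_rows <- list()
  nl <- 0L
  for (gn in genomes) {
    genes <- genome_genes(gn)
    if (!nrow(genes)) next
    best_fam <- rep(NA_character_, nrow(genes))
    best_score <- rep(NA_real_, nrow(genes))
    for (i in seq_len(nrow(genes))) {
      for (p in profiles) {
        r <- .cpp_profile_sw(p$match_scores, genes$protein[i],
                             config$gap_open, config$gap_ext)
        if (r$score >= p$threshold_score &&
            (is.na(best_score[i]) || r$score > best_score[i])) {
          best_score[i] <- r$score
          best_fam[i] <- if (is.na(p$family)) p$name else p$family
        }
      }
    }
    hit <- which(!is.na(best_fam))
    W <- config$pass2_window
    for (cid in unique(genes$contig_id)) {
      rows <- which(genes$contig_id == cid)
      h <- intersect(rows, hit)
      if (!length(h)) next
      h <- h[order(genes$ordinal[h])]
      # runs of hit genes separated by at most max_label_gap other genes
      gaps <- diff(genes$ordinal[h]) - 1L
      grp <- cumsum(c(0L, gaps > config$max_label_gap))
      for (gidx in unique(grp)) {
        mg <- h[grp == gidx]
        # trigger rule: some window of pass2_window genes within the run
        # holds hits of at least pass2_min_core distinct core families
        qualifies <- FALSE
        for (s in unique(genes$ordinal[mg])) {
          win <- mg[genes$ordinal[mg] >= s & genes$ordinal[mg] < s + W]
          fams <- intersect(unique(best_fam[win]), CORE_TSS_FAMILIES)
          if (length(fams) >= config$pass2_min_core) {
            qualifies <- TRUE
            break
          }
        }
        if (!qualifies) next
        sel <- rows[genes$ordinal[rows] >= min(genes$ordinal[mg]) &
                      genes$ordinal[rows] <= max(genes$ordinal[mg])]
        if (any(paste(gn$genome_id, genes$gene_id[sel]) %in% pass1_ids))
          next                                  # overlaps a pass-1 locus
        ann <- data.frame(gene_id = genes$gene_id[mg],
                          family = best_fam[mg], score = best_score[mg],
                          stringsAsFactors = FALSE)
        window <- list(contig_id = cid,
                       genes = genes[sel, , drop = FALSE])
        nl <- nl + 1L
        lc <- trim_region(window, ann,
                          locus_id = sprintf("%s_p2_%02d", gn$genome_id, nl),
                          genome_id = gn$genome_id, discovery_pass = 2L,
                          max_label_gap = config$max_label_gap,
                          anchors = genes$gene_id[mg])
        if (any(!is.na(lc$genes$family) & lc$genes$family == "VgrG"))
          lc <- orient_region(lc)
        loci[[length(loci) + 1L]] <- lc
      }
    }
    locus_gene_ids <- c(
      unlist(lapply(loci, function(lc)
        if (lc$genome_id == gn$genome_id) lc$genes$gene_id else NULL)),
      unlist(lapply(pass1_loci, function(lc)
        if (lc$genome_id == gn$genome_id) lc$genes$gene_id else NULL)))
    orph <- setdiff(genes$gene_id[hit], locus_gene_ids)
    if (length(orph)) {
      oi <- match(orph, genes$gene_id)
      orphan_rows[[length(orphan_rows) + 1L]] <- data.frame(
        genome_id = gn$genome_id, gene_id = orph,
        contig_id = genes$contig_id[oi], ordinal = genes$ordinal[oi],
        family = best_fam[oi], score = best_score[oi],
        stringsAsFactors = FALSE)
    }
  }
  orphans <- if (length(orphan_rows)) do.call(rbind, orphan_rows) else
    data.frame(genome_id = character(), gene_id = character(),
               contig_id = character(), ordinal = integer(),
               family = character(), score = numeric(),
               stringsAsFactors = FALSE)
  list(loci = loci, orphans = orphans)
}
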