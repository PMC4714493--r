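# ICE (integrative conjugative element) association of T6SS loci: tra-gene
# detection and proximity patterns, blastn-like HSP profiling of DNA
# relatedness between strains, and the near-identity computation used as
# evidence of intra-ecosystem horizontal transfer.

#' Detect conjugative transfer (tra) genes in a genome
#'
#' Scans the proteome with the nine curated tra family profiles (TraD,
#' TraG, TraI, TraJ, TraK, TraM, TraN, TraO, TrbJ) and keeps the best
#' qualifying hit per gene, with nucleotide coordinates attached.
#'
#' @param genome a `t6_genome`.
#' @param tra_profiles calibrated tra profiles.
#' @param config a [pipeline_config()].
#' @return data.frame of tra hits (gene_id, contig_id, ordinal, family,
#'   score, evalue, start, end, strand).
#' @export
detect_tra_genes <- function(genome, tra_profiles,
                             config = pipeline_config()) {
  hits <- scan_proteome(tra_profiles, genome, config$sentinel_evalue_max,
                        config)
  if (nrow(hits)) {
    hits <- hits[order(hits$gene_id, -hits$score), , drop = FALSE]
    hits <- hits[!duplicated(hits$gene_id), , drop = FALSE]
  }
  genes <- genome_genes(genome)
  m <- match(hits$gene_id, genes$gene_id)
  hits$family <- ifelse(is.na(hits$family), hits$profile_name, hits$family)
  hits$start <- genes$start[m]
  hits$end <- genes$end[m]
  hits$strand <- genes$strand[m]
  hits <- hits[order(hits$contig_id, hits$ordinal), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# is `x` a subsequence of `template` (same relative order)?
is_subseq <- function(x, template) {
  pos <- 0L
  for (f in x) {
    nxt <- which(template == f & seq_along(template) > pos)
    if (!length(nxt)) return(FALSE)
    pos <- nxt[1]
  }
  TRUE
}

#' Decide ICE association of a locus from tra proximity and pattern
#'
#' Distance is the minimum bp gap between the locus span and a tra gene on
#' the same contig (0 when overlapping; tra hits on other contigs never
#' satisfy the window). A locus is ICE-associated when at least one tra
#' gene lies within `ice_window_bp`. The in-window tra roster is compared,
#' after orientation, to the characteristic GA1 (>= 4 of 5 families) and
#' GA2 (>= 7 of 9 families) flanking patterns in consistent relative
#' order; GA2 is tested first as the more specific pattern.
#'
#' @param locus a `t6_locus`.
#' @param tra_hits result of [detect_tra_genes()] on the locus genome.
#' @param config a [pipeline_config()].
#' @return list (class `t6_ice_association`): locus_id, tra (data.frame
#'   with distances and within-window flags), pattern, verdict.
#' @export
tra_proximity <- function(locus, tra_hits, config = pipeline_config()) {
  tt <- tra_hits[tra_hits$contig_id %in% names(locus$spans), , drop = FALSE]
  if (nrow(tt)) {
    sp <- do.call(rbind, lapply(seq_len(nrow(tt)), function(i) {
      s <- locus$spans[[tt$contig_id[i]]]
      d <- max(0L, tt$start[i] - s[2], s[1] - tt$end[i])
      c(distance = d, within = d <= config$ice_window_bp)
    }))
    tt$distance <- sp[, "distance"]
    tt$within_window <- as.logical(sp[, "within"])
  } else {
    tt$distance <- numeric(0)
    tt$within_window <- logical(0)
  }
  inwin <- tt[tt$within_window, , drop = FALSE]
  pattern <- "none"
  if (nrow(inwin)) {
    inwin <- inwin[order(inwin$start), , drop = FALSE]
    fams <- inwin$family[!duplicated(inwin$family)]
    if (isTRUE(locus$flipped)) fams <- rev(fams)
    ok <- function(template, min_n) {
      pres <- fams[fams %in% template]
      length(pres) >= min_n &&
        (is_subseq(pres, template) || is_subseq(rev(pres), template))
    }
    pattern <- if (ok(TRA_PATTERN_GA2, 7L)) "GA2-pattern"
      else if (ok(TRA_PATTERN_GA1, 4L)) "GA1-pattern"
      else "inconsistent"
  }
  verdict <- if (nrow(inwin)) "ICE-associated" else "not-associated"
  structure(list(locus_id = locus$locus_id, tra = tt, pattern = pattern,
                 verdict = verdict),
            class = "t6_ice_association")
}

#' Find high-scoring segment pairs between two DNA sequences
#'
#' Exact-word seed (default 11) match-and-extend on both strands with
#' ungapped X-drop extension (match +1, mismatch -2, X-drop 40 by
#' default); overlapping HSPs on one diagonal are merged, HSPs shorter
#' than `min_len` are removed, and the result is sorted by query start.
#'
#' @param query,subject nucleotide strings.
#' @param config a [pipeline_config()].
#' @param min_len length filter in bp (default `config$hsp_min_len`; use 0
#'   to keep everything).
#' @param both_strands scan the reverse complement of the subject as well.
#' @return data.frame of HSPs: qstart, qend, sstart, send (1-based
#'   inclusive, on the forward subject), strand, length, matches,
#'   identity, score.
#' @export
find_hsps <- function(query, subject, config = pipeline_config(),
                      min_len = config$hsp_min_len, both_strands = TRUE) {
  if (!nzchar(query) || !nzchar(subject)) stop("empty sequence")
  plus <- .cpp_find_hsps(query, subject, config$hsp_word, config$hsp_match,
                         config$hsp_mismatch, config$hsp_xdrop)
  plus$strand <- rep("+", nrow(plus))
  if (both_strands) {
    ns <- nchar(subject)
    minus <- .cpp_find_hsps(query, revcomp(subject), config$hsp_word,
                            config$hsp_match, config$hsp_mismatch,
                            config$hsp_xdrop)
    if (nrow(minus)) {
      tmp <- ns - minus$send + 1L
      minus$send <- ns - minus$sstart + 1L
      minus$sstart <- tmp
      minus$strand <- "-"
      plus <- rbind(plus, minus)
    }
  }
  plus <- plus[plus$length >= min_len, , drop = FALSE]
  plus <- plus[order(plus$qstart, plus$sstart), , drop = FALSE]
  rownames(plus) <- NULL
  plus
}

#' Refine the homologous ICE extent shared by two genomes
#'
#' Starting from the locus span extended by `window` bp on each side, the
#' query is compared to the other genome's contigs; after each HSP round
#' the query is trimmed to the outermost HSP boundaries, iterating until
#' the boundaries are stable. The span never grows after the first trim.
#'
#' @param anchor_genome genome providing the query.
#' @param locus a `t6_locus` of `anchor_genome` (first contig is used).
#' @param other_genome genome searched for the homologous region.
#' @param config a [pipeline_config()].
#' @param window initial flank in bp (default `config$ice_window_bp`).
#' @param max_iter iteration cap.
#' @return list: `span` (0-based half-open on the anchor contig),
#'   `contig`, `subject_contig`, `hsps`, `flagged` (TRUE when no HSP was
#'   found and the span fell back to the locus itself).
#' @export
ice_extent <- function(anchor_genome, locus, other_genome,
                       config = pipeline_config(),
                       window = config$ice_window_bp, max_iter = 5L) {
  cid <- locus$contig_ids[1]
  ctseq <- anchor_genome$contigs[[cid]]$sequence
  sp <- locus$spans[[cid]]
  lo <- max(0L, sp[1] - window)
  hi <- min(nchar(ctseq), sp[2] + window)
  subj <- vapply(other_genome$contigs, function(ct) ct$sequence,
                 character(1))
  best <- NULL
  best_contig <- NA_character_
  for (it in seq_len(max_iter)) {
    q <- substr(ctseq, lo + 1L, hi)
    hs <- lapply(subj, function(s) find_hsps(q, s, config))
    tot <- vapply(hs, function(h) sum(h$length), numeric(1))
    if (!length(tot) || max(tot) == 0) {
      return(list(span = sp, contig = cid, subject_contig = NA_character_,
                  hsps = NULL, flagged = TRUE))
    }
    bi <- which.max(tot)
    best <- hs[[bi]]
    best_contig <- names(subj)[bi]
    newlo <- lo + min(best$qstart) - 1L
    newhi <- lo + max(best$qend)
    if (newlo == lo && newhi == hi) break
    lo <- newlo
    hi <- newhi
  }
  list(span = c(lo, hi), contig = cid, subject_contig = best_contig,
       hsps = best, flagged = FALSE)
}

#' Percent identity of a segment from its mismatch count
#'
#' `100 * (length - mismatches) / length`, reported to three decimal
#' places — the computation behind statements such as a 109,805 bp shared
#' segment with three mismatches being 99.997\% identical.
#'
#' @param length_bp segment length in bp (> 0).
#' @param mismatches mismatch count in `[0, length_bp]`.
#' @return percentage rounded to 3 decimals.
#' @export
percent_identity_from_mismatches <- function(length_bp, mismatches) {
  if (length_bp <= 0) stop("length_bp must be positive")
  if (mismatches < 0 || mismatches > length_bp)
    stop("mismatches must lie in [0, length_bp]")
  round(100 * (length_bp - mismatches) / length_bp, 3)
}

#' Pairwise length-weighted ICE identity matrix
#'
#' For each ordered pair of resolved ICE spans, identity is the HSP-length
#' weighted mean identity over qualifying HSPs; pairs with no qualifying
#' HSP are `NA` (missing).
#'
#' @param seqs named character vector of ICE DNA sequences (>= 2).
#' @param config a [pipeline_config()].
#' @return square numeric matrix with 1.0 on the diagonal.
#' @export
pairwise_ice_identity <- function(seqs, config = pipeline_config()) {
  if (length(seqs) < 2L) stop("need at least two ICE spans")
  n <- length(seqs)
  M <- matrix(NA_real_, n, n, dimnames = list(names(seqs), names(seqs)))
  diag(M) <- 1
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      h <- find_hsps(seqs[[i]], seqs[[j]], config)
      if (nrow(h)) M[i, j] <- sum(h$length * h$identity) / sum(h$length)
    }
  }
  M
}
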