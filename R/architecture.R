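# Classification of loci into the three conserved genetic architectures
# (GA1/GA2/GA3) from family content and synteny signatures, and
# delineation of conserved vs variable regions by DNA identity.

# signature feature sets scored when no exclusive tag marker decides
arch_features <- function() {
  list(GA1 = c(CORE_TSS_FAMILIES, "TagA", "TagB", "TetR", "PAAR", "Rhs"),
       GA2 = c(CORE_TSS_FAMILIES, "TagA", "TetR"),
       GA3 = c(CORE_TSS_FAMILIES, "TagC", "TetR"))
}

#' Classify a locus into a genetic architecture
#'
#' Decision rules in order: TagC present implies GA3; TagB present implies
#' GA1; TagA without TagB together with an evolved Hcp or at least four
#' distinct Hcp clusters implies GA2. Otherwise the locus is scored
#' against each architecture's signature feature set and assigned to the
#' best match if the fraction of features present reaches
#' `arch_score_min`, else called "other". A locus carrying both mutually
#' exclusive markers (TagB and TagC) is called "other" with a warning.
#'
#' @param locus an annotated (and preferably oriented) `t6_locus`.
#' @param config a [pipeline_config()].
#' @return list (class `t6_arch_call`): locus_id, call, matched, missing,
#'   score.
#' @export
signature_match <- function(locus, config = pipeline_config()) {
  g <- locus$genes
  if (is.null(g$family) || all(is.na(g$family)))
    stop("locus ", locus$locus_id, " is unannotated")
  fams <- unique(g$family[!is.na(g$family)])
  hcp <- !is.na(g$family) & g$family == "Hcp"
  n_hcp_clusters <- length(unique(g$cluster_id[hcp & !is.na(g$cluster_id)]))
  evolved <- any(!is.na(g$evolved_hcp) & g$evolved_hcp)
  has <- function(f) f %in% fams
  feats <- arch_features()
  score_for <- function(a) mean(feats[[a]] %in% fams)
  call <- NULL
  if (has("TagB") && has("TagC")) {
    warning("locus ", locus$locus_id,
            " carries both TagB and TagC; calling 'other'")
    call <- "other"
  } else if (has("TagC")) call <- "GA3"
  else if (has("TagB")) call <- "GA1"
  else if (has("TagA") && (evolved || n_hcp_clusters >= 4L)) call <- "GA2"
  if (is.null(call)) {
    sc <- vapply(names(feats), score_for, numeric(1))
    best <- names(which.max(sc))
    call <- if (max(sc) >= config$arch_score_min) best else "other"
  }
  ref <- if (call %in% names(feats)) call else
    names(which.max(vapply(names(feats), score_for, numeric(1))))
  structure(list(locus_id = locus$locus_id, call = call,
                 matched = intersect(feats[[ref]], fams),
                 missing = setdiff(feats[[ref]], fams),
                 score = score_for(ref)),
            class = "t6_arch_call")
}

#' Classify a list of loci
#'
#' @param loci list of annotated `t6_locus` objects.
#' @param config a [pipeline_config()].
#' @return list with `loci` (with `$architecture` attached) and `calls`
#'   (data.frame locus_id, call, score).
#' @export
classify_loci <- function(loci, config = pipeline_config()) {
  calls <- lapply(loci, signature_match, config = config)
  for (i in seq_along(loci)) loci[[i]]$architecture <- calls[[i]]$call
  data <- data.frame(locus_id = vapply(calls, `[[`, character(1), "locus_id"),
                     call = vapply(calls, `[[`, character(1), "call"),
                     score = vapply(calls, `[[`, numeric(1), "score"),
                     stringsAsFactors = FALSE)
  list(loci = loci, calls = data, detail = calls)
}

#' Nucleotide sequence of a locus
#'
#' Concatenates the locus spans from the parent genome; if the locus was
#' mirrored by [orient_region()], the sequence is reverse-complemented so
#' loci of one architecture are compared in a common orientation.
#'
#' @param locus a `t6_locus`.
#' @param genome its parent `t6_genome`.
#' @param pad extra flanking bases to include on each side.
#' @return nucleotide string.
#' @export
locus_dna <- function(locus, genome, pad = 0L) {
  parts <- vapply(names(locus$spans), function(cid) {
    sp <- locus$spans[[cid]]
    L <- nchar(genome$contigs[[cid]]$sequence)
    substr(genome$contigs[[cid]]$sequence, max(1L, sp[1] + 1L - pad),
           min(L, sp[2] + pad))
  }, character(1))
  if (isTRUE(locus$flipped))
    parts <- rev(vapply(parts, revcomp, character(1)))
  paste(parts, collapse = "")
}

#' Conserved and variable regions across loci of one architecture
#'
#' Each non-reference locus sequence is compared to the reference with the
#' HSP scan; reference positions covered by qualifying HSPs in at least
#' `conserved_cov` of the loci form conserved segments (segments separated
#' by less than `conserved_merge_gap` bp are merged), and remaining
#' internal gaps of at least `variable_min_gap` bp are numbered variable
#' regions, left to right.
#'
#' @param seqs named character vector of locus DNA sequences (>= 2).
#' @param reference name of the reference sequence (default: first).
#' @param config a [pipeline_config()].
#' @return list (class `t6_region_comparison`): reference, conserved
#'   (data.frame start/end, 1-based), variable (data.frame number,
#'   start/end), pair_identities (per non-reference locus, length-weighted
#'   HSP identity within conserved segments), hsps (per-locus list).
#' @export
conserved_regions <- function(seqs, reference = names(seqs)[1],
                              config = pipeline_config()) {
  if (length(seqs) < 2L)
    stop("conserved_regions needs at least two loci")
  if (is.null(names(seqs)) || !reference %in% names(seqs))
    stop("named sequences with a valid reference are required")
  ref <- seqs[[reference]]
  others <- seqs[setdiff(names(seqs), reference)]
  hsps <- lapply(others, function(s) find_hsps(ref, s, config))
  L <- nchar(ref)
  covered <- rep(0L, L)
  for (h in hsps) {
    if (!nrow(h)) next
    r <- IRanges::reduce(IRanges::IRanges(h$qstart, h$qend))
    for (k in seq_along(r)) {
      i1 <- IRanges::start(r)[k]
      i2 <- min(IRanges::end(r)[k], L)
      covered[i1:i2] <- covered[i1:i2] + 1L
    }
  }
  need <- ceiling(config$conserved_cov * length(others))
  cons <- IRanges::reduce(IRanges::IRanges(covered >= need),
                          min.gapwidth = config$conserved_merge_gap)
  conserved <- data.frame(start = IRanges::start(cons),
                          end = IRanges::end(cons))
  variable <- data.frame(number = integer(), start = integer(),
                         end = integer())
  if (nrow(conserved) > 1L) {
    gs <- conserved$end[-nrow(conserved)] + 1L
    ge <- conserved$start[-1L] - 1L
    keep <- (ge - gs + 1L) >= config$variable_min_gap
    if (any(keep))
      variable <- data.frame(number = seq_len(sum(keep)),
                             start = gs[keep], end = ge[keep])
  }
  pair_identity <- vapply(hsps, function(h) {
    if (!nrow(h) || !nrow(conserved)) return(NA_real_)
    ir <- IRanges::IRanges(h$qstart, h$qend)
    ov <- IRanges::intersect(ir, IRanges::IRanges(conserved$start,
                                                  conserved$end))
    # weight whole-HSP identities by their overlap with conserved segments
    w <- numeric(nrow(h))
    for (k in seq_len(nrow(h))) {
      o <- IRanges::intersect(IRanges::IRanges(h$qstart[k], h$qend[k]),
                              IRanges::IRanges(conserved$start,
                                               conserved$end))
      w[k] <- sum(IRanges::width(o))
    }
    if (sum(w) == 0) return(NA_real_)
    sum(w * h$identity) / sum(w)
  }, numeric(1))
  structure(list(reference = reference, conserved = conserved,
                 variable = variable, pair_identities = pair_identity,
                 hsps = hsps),
            class = "t6_region_comparison")
}

#' Check within-architecture DNA identity against the published floors
#'
#' Mean length-weighted HSP identity within conserved segments is compared
#' per locus pair to the architecture's floor: above 0.95 for GA1 and GA3,
#' above 0.80 for GA2.
#'
#' @param comparison a [conserved_regions()] result.
#' @param architecture "GA1", "GA2" or "GA3".
#' @return list: architecture, floor, per_pair identities, pass (logical).
#' @export
ga_identity_check <- function(comparison, architecture) {
  floors <- c(GA1 = 0.95, GA2 = 0.80, GA3 = 0.95)
  if (!architecture %in% names(floors))
    stop("unknown architecture '", architecture, "'")
  v <- comparison$pair_identities
  list(architecture = architecture, floor = floors[[architecture]],
       per_pair = v,
       pass = length(v) > 0 && !anyNA(v) && all(v > floors[[architecture]]))
}
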