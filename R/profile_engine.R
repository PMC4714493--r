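# Position-specific profile scoring with empirical E-values and
# self-calibrated inclusion thresholds: the package's internal substitute
# for the rpsblast / hmmbuild / hmmsearch stages of T6SS locus mining.

#' Construct a profile model
#'
#' @param name profile (family) name.
#' @param match_scores 20 x L matrix of per-column log-odds scores (bits),
#'   rows in the order `ACDEFGHIKLMNPQRSTVWY`.
#' @param null_freqs background residue distribution (length 20, sums to 1).
#' @param family optional family label carried by self-trained cluster
#'   profiles.
#' @return an object of class `t6_profile`.
#' @export
make_profile <- function(name, match_scores, null_freqs = rep(1 / 20, 20),
                         family = NA_character_) {
  if (!is.matrix(match_scores) || nrow(match_scores) != 20L ||
      ncol(match_scores) < 1L)
    stop("match_scores must be a 20 x L matrix with L >= 1")
  if (abs(sum(null_freqs) - 1) > 1e-9)
    stop("null_freqs must sum to 1")
  rownames(match_scores) <- AA20
  structure(list(name = name, length = ncol(match_scores),
                 match_scores = match_scores,
                 null_freqs = setNames(as.numeric(null_freqs), AA20),
                 family = family,
                 threshold_score = NULL, null_scores = NULL,
                 decoy_db_size = NULL, gumbel = NULL),
            class = "t6_profile")
}

#' @export
print.t6_profile <- function(x, ...) {
  cat("t6_profile", x$name, "-", x$length, "columns",
      if (!is.null(x$threshold_score))
        sprintf("(threshold %.1f bits)", x$threshold_score) else "",
      "\n")
  invisible(x)
}

# the consensus (per-column argmax residue) of a profile
profile_consensus <- function(profile) {
  paste(AA20[apply(profile$match_scores, 2, which.max)], collapse = "")
}

check_protein <- function(protein) {
  bad <- setdiff(unique(strsplit(protein, "")[[1]]), c(AA20, "X"))
  if (length(bad))
    stop("protein contains non-amino-acid characters: ",
         paste(bad, collapse = ""))
  invisible(protein)
}

#' Score a protein against a profile
#'
#' Best local segment score (Smith-Waterman over profile columns versus
#' residues, affine gaps) in bits, together with its span on the protein
#' and on the profile. `X` residues score 0 in every column; any other
#' non-amino-acid character is an error. By the local-alignment convention
#' the score is never negative.
#'
#' @param profile a `t6_profile`.
#' @param protein amino-acid string.
#' @param gap_open,gap_ext affine gap penalties (BLAST convention).
#' @return list with `score` (bits), `span` (protein start/end, 1-based) and
#'   `profile_span`.
#' @export
score_protein <- function(profile, protein, gap_open = 11, gap_ext = 1) {
  if (nchar(protein) < 1L) stop("protein must have length >= 1")
  check_protein(protein)
  r <- .cpp_profile_sw(profile$match_scores, protein, gap_open, gap_ext)
  list(score = r$score, span = c(r$qstart, r$qend),
       profile_span = c(r$pstart, r$pend))
}

#' Calibrate empirical E-values for a profile
#'
#' Builds an empirical null from the scores of random length-matched
#' proteins drawn from the profile's background distribution. The E-value
#' of a score s is `decoy_db_size` times the null exceedance fraction with
#' a +1 pseudo-count; beyond the largest null score the exceedance is
#' extrapolated with a Gumbel (extreme-value) tail fitted to the null by
#' the method of moments, so that strongly matching sequences obtain
#' E-values far below the pseudo-count floor. E(s) is monotone
#' non-increasing in s.
#'
#' @param profile a `t6_profile`.
#' @param decoy_db_size effective database size multiplying the exceedance
#'   probability.
#' @param n_shuffles null-sample size (>= 100).
#' @param seed integer seed for the null draws.
#' @param gap_open,gap_ext affine gap penalties.
#' @return the profile with null calibration attached.
#' @export
calibrate_evalues <- function(profile, decoy_db_size = 1e4,
                              n_shuffles = 200L, seed = 1L,
                              gap_open = 11, gap_ext = 1) {
  if (n_shuffles < 100L) stop("n_shuffles must be >= 100")
  # fold the profile name into the seed so the null stream can never
  # replay the stream of another seeded generation step
  seed <- stage_seed(seed, paste0("null_", profile$name))
  scores <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      p <- random_protein(profile$length, profile$null_freqs)
      .cpp_profile_sw(profile$match_scores, p, gap_open, gap_ext)$score
    }, numeric(1))
  })
  profile$null_scores <- sort(scores)
  profile$decoy_db_size <- decoy_db_size
  s <- stats::sd(scores)
  lambda <- if (s > 0) pi / (s * sqrt(6)) else Inf
  mu <- mean(scores) - 0.57721566 / lambda
  profile$gumbel <- c(mu = mu, lambda = lambda)
  profile
}

#' E-value of a score under a calibrated profile
#'
#' @param profile a calibrated `t6_profile`.
#' @param score score in bits.
#' @return the E-value (expected number of decoy hits at or above `score`).
#' @export
profile_evalue <- function(profile, score) {
  ns <- profile$null_scores
  if (is.null(ns)) stop("profile '", profile$name, "' is not calibrated")
  n <- length(ns)
  emp <- (sum(ns >= score) + 1) / (n + 1)
  p <- emp
  if (score > ns[n] && !is.null(profile$gumbel) &&
      is.finite(profile$gumbel[["lambda"]])) {
    # exponential tail decaying from the pseudo-count floor at the largest
    # null score, with the extreme-value rate fitted to the null sample:
    # continuous and monotone at the seam, vanishing for strong matches
    lam <- profile$gumbel[["lambda"]]
    p <- emp * exp(-lam * (score - ns[n]))
  }
  profile$decoy_db_size * p
}

#' Scan a genome's proteome with a set of calibrated profiles
#'
#' Scores every annotated protein against every profile and keeps the best
#' hit per (gene, profile) with E-value at or below `evalue_max`. Hits are
#' sorted by contig then gene ordinal.
#'
#' @param profiles list of calibrated `t6_profile` objects.
#' @param genome a `t6_genome`.
#' @param evalue_max inclusion E-value (hits at exactly this value are
#'   retained).
#' @param config a [pipeline_config()] (gap penalties).
#' @return data.frame of motif hits.
#' @export
scan_proteome <- function(profiles, genome, evalue_max = 1e-3,
                          config = pipeline_config()) {
  genes <- genome_genes(genome)
  out <- vector("list", length(profiles) * max(nrow(genes), 1L))
  k <- 0L
  for (i in seq_len(nrow(genes))) {
    prot <- genes$protein[i]
    for (p in profiles) {
      r <- .cpp_profile_sw(p$match_scores, prot, config$gap_open,
                           config$gap_ext)
      if (r$score <= 0) next
      ev <- profile_evalue(p, r$score)
      if (ev <= evalue_max) {
        k <- k + 1L
        out[[k]] <- data.frame(
          gene_id = genes$gene_id[i], contig_id = genes$contig_id[i],
          ordinal = genes$ordinal[i], profile_name = p$name,
          family = p$family, score = r$score, evalue = ev,
          qstart = r$qstart, qend = r$qend, stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (k) do.call(rbind, out[seq_len(k)]) else
    data.frame(gene_id = character(), contig_id = character(),
               ordinal = integer(), profile_name = character(),
               family = character(), score = numeric(), evalue = numeric(),
               qstart = integer(), qend = integer(), stringsAsFactors = FALSE)
  hits <- hits[order(hits$contig_id, hits$ordinal, hits$profile_name), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Collapse exact duplicate sequences
#'
#' Members identical at 100\% identity over 100\% of their length are
#' collapsed to the first representative in stable input order.
#'
#' @param proteins character vector (optionally named).
#' @return the non-redundant vector.
#' @export
dedupe_members <- function(proteins) {
  proteins[!duplicated(proteins)]
}

#' Star multiple alignment of a protein family
#'
#' Every member is globally aligned (BLOSUM62, affine gaps 11/1) to the
#' longest member and the pairwise alignments are merged on the center's
#' columns; insertions relative to the center open gap columns in all other
#' rows. All members are present and all aligned rows have equal length
#' (at least the center length).
#'
#' @param members character vector of protein sequences (>= 1).
#' @param gap_open,gap_ext affine gap penalties.
#' @return list with `alignment` (named character vector of equal-length
#'   rows) and `center` (index of the center member).
#' @export
build_msa <- function(members, gap_open = 11, gap_ext = 1) {
  if (length(members) < 1L) stop("build_msa needs at least one member")
  if (is.null(names(members)))
    names(members) <- paste0("seq", seq_along(members))
  center <- which.max(nchar(members))
  cseq <- members[[center]]
  Lc <- nchar(cseq)
  if (length(members) == 1L)
    return(list(alignment = setNames(cseq, names(members)), center = center))
  bl <- blosum62()
  alns <- lapply(seq_along(members), function(i) {
    if (i == center) return(list(a = cseq, b = cseq))
    r <- .cpp_pair_align(cseq, members[[i]], bl, paste(colnames(bl),
                         collapse = ""), gap_open, gap_ext, FALSE)
    list(a = r$aligned_a, b = r$aligned_b)
  })
  # slot k (0..Lc) holds member insertions before center residue k+1
  ins_len <- function(al) {
    a <- strsplit(al$a, "")[[1]]
    counts <- integer(Lc + 1L)
    pos <- 0L
    for (ch in a) {
      if (ch == "-") counts[pos + 1L] <- counts[pos + 1L] + 1L
      else pos <- pos + 1L
    }
    counts
  }
  slots <- lapply(alns, ins_len)
  maxins <- Reduce(pmax, slots)
  width <- Lc + sum(maxins)
  rowify <- function(al, ins) {
    a <- strsplit(al$a, "")[[1]]
    b <- strsplit(al$b, "")[[1]]
    out <- character(0)
    pos <- 0L
    buf <- character(0)
    flush <- function(slot, buf)
      c(buf, rep("-", maxins[slot + 1L] - length(buf)))
    for (k in seq_along(a)) {
      if (a[k] == "-") buf <- c(buf, b[k])
      else {
        out <- c(out, flush(pos, buf), b[k])
        buf <- character(0)
        pos <- pos + 1L
      }
    }
    out <- c(out, flush(pos, buf))
    paste(out, collapse = "")
  }
  rows <- vapply(seq_along(alns), function(i) rowify(alns[[i]], slots[[i]]),
                 character(1))
  stopifnot(all(nchar(rows) == width))
  list(alignment = setNames(rows, names(members)), center = center)
}

#' Build a profile from a family alignment
#'
#' Columns occupied by residues in at least half of the rows become match
#' columns; per-column emissions are residue frequencies with Laplace +0.1
#' pseudo-counts, converted to log-odds (bits) against the null. The
#' inclusion threshold is left unset (see [calibrate_threshold()]).
#'
#' @param alignment result of [build_msa()] or a named character vector of
#'   equal-length aligned rows.
#' @param name profile name.
#' @param null_freqs background distribution (default uniform).
#' @param family optional family label.
#' @return an uncalibrated `t6_profile`.
#' @export
build_profile <- function(alignment, name, null_freqs = rep(1 / 20, 20),
                          family = NA_character_) {
  rows <- if (is.list(alignment)) alignment$alignment else alignment
  if (!length(rows)) stop("empty alignment")
  mat <- do.call(rbind, strsplit(rows, ""))
  occ <- colMeans(mat != "-")
  keep <- which(occ >= 0.5)
  if (!length(keep)) stop("alignment has no match columns")
  scores <- vapply(keep, function(j) {
    col <- mat[, j]
    counts <- table(factor(col[col %in% AA20], levels = AA20))
    p <- (as.numeric(counts) + 0.1) / (sum(counts) + 0.1 * 20)
    log2(p / null_freqs)
  }, numeric(20))
  make_profile(name, matrix(scores, nrow = 20), null_freqs, family = family)
}

#' Calibrate a profile's inclusion threshold from its training members
#'
#' The threshold is the minimum score attained by any training member, so
#' that rescanning the training set recalls every member by construction.
#' (Using the maximum training score would exclude all but the single best
#' member on rescan.)
#'
#' @param profile a `t6_profile`.
#' @param members training-set protein sequences.
#' @param gap_open,gap_ext affine gap penalties.
#' @return the profile with `threshold_score` set.
#' @export
calibrate_threshold <- function(profile, members, gap_open = 11,
                                gap_ext = 1) {
  if (!length(members)) stop("no training members")
  scores <- vapply(members, function(m)
    .cpp_profile_sw(profile$match_scores, m, gap_open, gap_ext)$score,
    numeric(1))
  profile$threshold_score <- min(scores)
  profile
}
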