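# Greedy percent-identity/coverage protein clustering: a deterministic
# stand-in for the blastclust stage (30% identity over 70% of both
# sequence lengths).

#' Identity and coverage of two proteins
#'
#' Global alignment with free end gaps (BLOSUM62, affine gaps 11/1 by
#' default). Identity is identical columns over aligned columns with
#' terminal gap runs excluded (internal gap columns count as mismatches);
#' each coverage is the aligned span on that sequence divided by its
#' length. Among co-optimal alignments the one consuming the most residues
#' is preferred, with a fixed diagonal-first traceback, so results are
#' deterministic.
#'
#' @param a,b protein sequences (non-empty).
#' @param config a [pipeline_config()] (gap penalties).
#' @return list with `identity`, `coverage_a`, `coverage_b` and `score`.
#' @export
pairwise_identity <- function(a, b, config = pipeline_config()) {
  if (!nzchar(a) || !nzchar(b)) stop("empty protein sequence")
  bl <- blosum62()
  r <- .cpp_pair_align(a, b, bl, paste(colnames(bl), collapse = ""),
                       config$gap_open, config$gap_ext, TRUE)
  list(identity = r$identity, coverage_a = r$coverage_a,
       coverage_b = r$coverage_b, score = r$score)
}

#' Greedy seed-recruitment clustering of proteins
#'
#' Proteins are sorted by descending length, ties broken by ascending
#' gene id; each still-unassigned protein seeds a new cluster and recruits
#' every remaining unassigned protein matching the seed at or above the
#' identity floor over at least the coverage floor of BOTH lengths. The
#' canonical internal ordering makes the partition invariant to input
#' order.
#'
#' @param proteins named character vector (names are gene ids).
#' @param config a [pipeline_config()] (`cluster_identity_min`,
#'   `cluster_coverage_min`).
#' @return list of clusters, each with `cluster_id`, `members` (gene ids)
#'   and `seed` (the seeding gene id).
#' @export
greedy_cluster <- function(proteins, config = pipeline_config()) {
  if (!length(proteins)) return(list())
  if (is.null(names(proteins)) || anyDuplicated(names(proteins)))
    stop("proteins must carry unique names")
  ord <- order(-nchar(proteins), names(proteins))
  proteins <- proteins[ord]
  n <- length(proteins)
  assigned <- logical(n)
  clusters <- list()
  cid <- 0L
  for (i in seq_len(n)) {
    if (assigned[i]) next
    cid <- cid + 1L
    members <- i
    assigned[i] <- TRUE
    if (i < n) {
      for (j in seq(i + 1L, n)) {
        if (assigned[j]) next
        pi <- pairwise_identity(proteins[[i]], proteins[[j]], config)
        if (pi$identity >= config$cluster_identity_min &&
            pi$coverage_a >= config$cluster_coverage_min &&
            pi$coverage_b >= config$cluster_coverage_min) {
          members <- c(members, j)
          assigned[j] <- TRUE
        }
      }
    }
    clusters[[cid]] <- list(cluster_id = cid,
                            members = names(proteins)[members],
                            seed = names(proteins)[i])
  }
  clusters
}

#' Pseudo-random cluster representative
#'
#' Uniform seeded choice among the members; reproducible for a fixed seed
#' and independent of the caller's RNG state.
#'
#' @param cluster a cluster from [greedy_cluster()].
#' @param rng_seed integer seed.
#' @return the chosen member gene id.
#' @export
pick_representative <- function(cluster, rng_seed = 1L) {
  m <- cluster$members
  if (!length(m)) stop("empty cluster")
  if (length(m) == 1L) return(m)
  with_seed(rng_seed, m[sample.int(length(m), 1L)])
}
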