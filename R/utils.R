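#' @useDynLib t6finder, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median runif setNames
#' @importFrom utils head read.table write.table
NULL

# canonical amino-acid order shared with the C++ kernels
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# controlled family vocabulary -----------------------------------------------
CORE_TSS_FAMILIES <- c("TssB", "TssC", "TssE", "TssF", "TssG", "TssK",
                       "TssN", "TssO", "TssP", "TssQ", "TssR",
                       "Hcp", "VgrG", "ClpV")
TAG_FAMILIES   <- c("TagA", "TagB", "TagC")
TRA_FAMILIES   <- c("TraD", "TraG", "TraI", "TraJ", "TraK", "TraM",
                    "TraN", "TraO", "TrbJ")
TOXIN_FAMILIES <- c(ToxNuc = "nuclease", ToxDea = "deaminase",
                    ToxPor = "pore-forming")
IMMUNITY_FAMILIES <- c(ImmNuc = "immunity-nuclease",
                       ImmDea = "immunity-deaminase",
                       ImmPor = "immunity-pore-forming")
# families whose genes are retained when a candidate window is trimmed
LOCUS_FAMILIES <- c(CORE_TSS_FAMILIES, TAG_FAMILIES, "TetR", "PAAR", "Rhs",
                    names(TOXIN_FAMILIES), names(IMMUNITY_FAMILIES))
# characteristic ICE tra-gene rosters flanking GA1/GA2 loci, left to right
TRA_PATTERN_GA1 <- c("TraG", "TraK", "TraM", "TraN", "TraD")
TRA_PATTERN_GA2 <- c("TraO", "TraN", "TraM", "TraK", "TraJ", "TrbJ",
                     "TraG", "TraI", "TraD")

.t6_env <- new.env(parent = emptyenv())

# BLOSUM62 with gap penalties 11/1: the standard protein-search scoring used
# by every pairwise protein alignment in the package
blosum62 <- function() {
  if (is.null(.t6_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .t6_env$blosum62 <- e$BLOSUM62
  }
  .t6_env$blosum62
}

# derive a per-stage seed from the run seed so stage order never silently
# shifts downstream randomness; kept below 2^31
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

# run code under a temporary seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_protein <- function(len, freqs = NULL) {
  if (is.null(freqs)) freqs <- rep(1 / 20, 20)
  paste(sample(AA20, len, replace = TRUE, prob = freqs), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Reverse-complement one contig of a genome in place
#'
#' Mirrors the contig sequence and all gene coordinates, flips strands and
#' reverses ordinals. Used to check that detection is invariant to the
#' arbitrary orientation of draft-assembly contigs.
#'
#' @param genome a `t6_genome`.
#' @param contig_id contig to flip.
#' @return the modified genome.
#' @export
revcomp_contig <- function(genome, contig_id) {
  ct <- genome$contigs[[contig_id]]
  if (is.null(ct)) stop("no contig '", contig_id, "' in genome")
  L <- nchar(ct$sequence)
  ct$sequence <- revcomp(ct$sequence)
  g <- ct$genes
  if (nrow(g)) {
    new_start <- L - g$end
    new_end <- L - g$start
    g$start <- new_start
    g$end <- new_end
    g$strand <- ifelse(g$strand == "+", "-", "+")
    g <- g[order(g$start), , drop = FALSE]
    g$ordinal <- seq_len(nrow(g)) - 1L
    rownames(g) <- NULL
    ct$genes <- g
  }
  genome$contigs[[contig_id]] <- ct
  genome
}
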