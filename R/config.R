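#' Pipeline configuration
#'
#' Collects every tunable threshold of the T6SS discovery pipeline in one
#' validated list. Defaults reproduce the published analysis settings:
#' sentinel hits must reach E-value 1e-3 and lie within fifteen genes of
#' each other on one contig; 25 genes flank each candidate window; proteins
#' cluster at 30\% identity over 70\% of both lengths; HSPs shorter than
#' 1000 bp are discarded; tra genes count as ICE evidence within 50 kb.
#'
#' @param sentinel_evalue_max maximum E-value for a sentinel (VgrG/ClpV) or
#'   tra profile hit.
#' @param max_sentinel_gene_gap maximum number of genes lying strictly
#'   between a vgrG and a clpV hit on the same contig.
#' @param flank_genes genes retrieved on each side of the outermost sentinel
#'   hits when a candidate window is extracted.
#' @param cluster_identity_min,cluster_coverage_min percent-identity and
#'   per-sequence coverage floors for protein clustering (both sequences
#'   must satisfy the coverage floor).
#' @param hsp_min_len minimum HSP length (bp) retained by [find_hsps()].
#' @param ice_window_bp distance (bp) within which a tra gene counts as
#'   evidence of ICE association.
#' @param toxin_evalue_max maximum E-value for toxin/immunity profile hits.
#' @param rng_seed integer seed governing every stochastic step of a run.
#' @param gap_open,gap_ext affine gap penalties (BLAST convention: a gap of
#'   length k costs `gap_open + k * gap_ext`) used by all protein
#'   alignments and profile scans.
#' @param hsp_word,hsp_match,hsp_mismatch,hsp_xdrop seed word size, match
#'   reward, mismatch penalty and ungapped X-drop of the blastn-like HSP
#'   scan.
#' @param pass2_window,pass2_min_core sliding ordinal window (genes) of the
#'   second detection pass and the number of distinct core Tss families
#'   required inside it to call a locus.
#' @param max_label_gap when trimming a candidate region, labelled genes
#'   separated from the locus run by more than this many intervening genes
#'   (e.g. decoy standalone hcp/clpV genes elsewhere on the contig) are
#'   treated as outside the locus; `Inf` disables the rule.
#' @param arch_score_min fraction of an architecture's signature features
#'   that must be present before a tag-less locus is assigned to it.
#' @param conserved_cov,conserved_merge_gap,variable_min_gap conserved-region
#'   delineation: fraction of loci that must cover a reference position,
#'   the gap size (bp) below which conserved segments merge, and the
#'   minimum gap (bp) reported as a numbered variable region.
#' @param decoy_db_size,n_shuffles effective database size and null-sample
#'   size used for empirical E-value calibration.
#' @return an object of class `t6_config` (a named list).
#' @export
pipeline_config <- function(sentinel_evalue_max = 1e-3,
                            max_sentinel_gene_gap = 15L,
                            flank_genes = 25L,
                            cluster_identity_min = 0.30,
                            cluster_coverage_min = 0.70,
                            hsp_min_len = 1000L,
                            ice_window_bp = 50000L,
                            toxin_evalue_max = 1e-3,
                            rng_seed = 1L,
                            gap_open = 11,
                            gap_ext = 1,
                            hsp_word = 11L,
                            hsp_match = 1,
                            hsp_mismatch = -2,
                            hsp_xdrop = 40,
                            pass2_window = 30L,
                            pass2_min_core = 4L,
                            max_label_gap = 3L,
                            arch_score_min = 0.7,
                            conserved_cov = 0.8,
                            conserved_merge_gap = 200L,
                            variable_min_gap = 500L,
                            decoy_db_size = 1e4,
                            n_shuffles = 200L) {
  cfg <- list(sentinel_evalue_max = sentinel_evalue_max,
              max_sentinel_gene_gap = as.integer(max_sentinel_gene_gap),
              flank_genes = as.integer(flank_genes),
              cluster_identity_min = cluster_identity_min,
              cluster_coverage_min = cluster_coverage_min,
              hsp_min_len = as.integer(hsp_min_len),
              ice_window_bp = as.integer(ice_window_bp),
              toxin_evalue_max = toxin_evalue_max,
              rng_seed = as.integer(rng_seed),
              gap_open = gap_open, gap_ext = gap_ext,
              hsp_word = as.integer(hsp_word), hsp_match = hsp_match,
              hsp_mismatch = hsp_mismatch, hsp_xdrop = hsp_xdrop,
              pass2_window = as.integer(pass2_window),
              pass2_min_core = as.integer(pass2_min_core),
              max_label_gap = as.integer(max_label_gap),
              arch_score_min = arch_score_min,
              conserved_cov = conserved_cov,
              conserved_merge_gap = as.integer(conserved_merge_gap),
              variable_min_gap = as.integer(variable_min_gap),
              decoy_db_size = decoy_db_size,
              n_shuffles = as.integer(n_shuffles))
  thr <- c("sentinel_evalue_max", "max_sentinel_gene_gap", "flank_genes",
           "cluster_identity_min", "cluster_coverage_min", "hsp_min_len",
           "ice_window_bp", "toxin_evalue_max")
  for (f in thr)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
      stop("config field '", f, "' must be a positive scalar")
  for (f in c("cluster_identity_min", "cluster_coverage_min"))
    if (cfg[[f]] > 1) stop("config field '", f, "' must lie in (0, 1]")
  structure(cfg, class = "t6_config")
}
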