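# Family labelling of protein clusters via their representatives, and
# toxin/immunity profile scanning of locus proteins.

#' Assign family labels to clusters
#'
#' Each cluster representative is scored against every curated family
#' profile; the best profile with E-value at or below the sentinel cutoff
#' AND score at or above the profile's calibrated threshold (when one is
#' set) labels the whole cluster. Ties are broken by higher score, then
#' lexicographic profile name. Clusters without a qualifying hit are
#' labelled "unknown".
#'
#' @param clusters list from [greedy_cluster()].
#' @param representatives named character vector mapping cluster seeds /
#'   gene ids to protein sequences, one per cluster (names are gene ids;
#'   order parallel to `clusters`).
#' @param profiles calibrated curated family profiles.
#' @param config a [pipeline_config()].
#' @return data.frame: cluster_id, representative, family, profile, score,
#'   evalue.
#' @export
assign_families <- function(clusters, representatives, profiles,
                            config = pipeline_config()) {
  stopifnot(length(representatives) == length(clusters))
  rows <- lapply(seq_along(clusters), function(i) {
    prot <- representatives[[i]]
    best <- NULL
    for (p in profiles) {
      r <- .cpp_profile_sw(p$match_scores, prot, config$gap_open,
                           config$gap_ext)
      if (r$score <= 0) next
      ev <- profile_evalue(p, r$score)
      if (ev > config$sentinel_evalue_max) next
      if (!is.null(p$threshold_score) && r$score < p$threshold_score) next
      cand <- list(name = p$name,
                   family = if (is.na(p$family)) p$name else p$family,
                   score = r$score, evalue = ev)
      if (is.null(best) || cand$score > best$score ||
          (cand$score == best$score && cand$name < best$name))
        best <- cand
    }
    data.frame(cluster_id = clusters[[i]]$cluster_id,
               representative = names(representatives)[i],
               family = if (is.null(best)) "unknown" else best$family,
               profile = if (is.null(best)) NA_character_ else best$name,
               score = if (is.null(best)) NA_real_ else best$score,
               evalue = if (is.null(best)) NA_real_ else best$evalue,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Scan proteins for toxin and immunity domains
#'
#' All hits with full E-value at or below the toxin cutoff are retained
#' (a protein may legitimately hit both a toxin and an immunity profile;
#' every qualifying hit is reported) and annotated with the profile's
#' functional class tag.
#'
#' @param proteins named character vector (names are gene ids).
#' @param profiles calibrated toxin/immunity profiles.
#' @param config a [pipeline_config()] (`toxin_evalue_max`).
#' @return data.frame: gene_id, profile, class, score, evalue, qstart,
#'   qend.
#' @export
scan_effectors <- function(proteins, profiles, config = pipeline_config()) {
  class_tags <- c(TOXIN_FAMILIES, IMMUNITY_FAMILIES)
  rows <- list()
  for (g in names(proteins)) {
    for (p in profiles) {
      r <- .cpp_profile_sw(p$match_scores, proteins[[g]], config$gap_open,
                           config$gap_ext)
      if (r$score <= 0) next
      ev <- profile_evalue(p, r$score)
      if (ev <= config$toxin_evalue_max) {
        cls <- if (p$name %in% names(class_tags)) class_tags[[p$name]]
               else "effector"
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = g, profile = p$name, class = cls, score = r$score,
          evalue = ev, qstart = r$qstart, qend = r$qend,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(gene_id = character(), profile = character(),
                      class = character(), score = numeric(),
                      evalue = numeric(), qstart = integer(),
                      qend = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Flag an "evolved" Hcp protein
#'
#' An Hcp-labelled protein is flagged as evolved when the Hcp profile hit
#' lies in its N-terminal half (span midpoint at or before half the
#' protein length) and the protein is longer than 1.5 times the Hcp family
#' median length, i.e. an Hcp domain fused to a C-terminal effector
#' extension.
#'
#' @param protein amino-acid sequence of an Hcp-labelled gene.
#' @param hcp_profile the curated Hcp profile.
#' @param median_length median length of Hcp-labelled proteins in the set.
#' @param config a [pipeline_config()].
#' @return logical.
#' @export
flag_evolved_hcp <- function(protein, hcp_profile, median_length,
                             config = pipeline_config()) {
  r <- .cpp_profile_sw(hcp_profile$match_scores, protein, config$gap_open,
                       config$gap_ext)
  if (r$score <= 0 || is.na(r$qstart)) return(FALSE)
  len <- nchar(protein)
  mid <- (r$qstart + r$qend) / 2
  mid <= len / 2 && len > 1.5 * median_length
}
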