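# Internal coordinate convention: 0-based half-open nucleotide intervals;
# GFF3 I/O converts to/from 1-based inclusive. Gene "distance" elsewhere in
# the package is measured on ordinals (per-contig gene rank by start).

#' Assemble a genome record
#'
#' @param genome_id genome identifier (unique within a set).
#' @param species_label free-text species designation.
#' @param contigs named list of contig records from [make_contig()].
#' @return an object of class `t6_genome`.
#' @export
make_genome <- function(genome_id, species_label = "", contigs = list()) {
  ids <- vapply(contigs, function(ct) ct$contig_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate contig_ids in genome ", genome_id)
  names(contigs) <- ids
  gids <- unlist(lapply(contigs, function(ct) ct$genes$gene_id))
  if (anyDuplicated(gids)) stop("duplicate gene_ids in genome ", genome_id)
  structure(list(genome_id = genome_id, species_label = species_label,
                 contigs = contigs), class = "t6_genome")
}

#' Assemble a contig record
#'
#' Genes are re-sorted by start and assigned 0-based ordinals.
#'
#' @param contig_id contig identifier.
#' @param sequence nucleotide sequence (character scalar; may contain N).
#' @param genes data.frame with columns gene_id, start, end, strand, protein
#'   (start/end 0-based half-open).
#' @return a list with class `t6_contig`.
#' @export
make_contig <- function(contig_id, sequence, genes) {
  if (is.null(genes) || nrow(genes) == 0L) {
    genes <- data.frame(gene_id = character(), contig_id = character(),
                        start = integer(), end = integer(),
                        strand = character(), ordinal = integer(),
                        protein = character(), stringsAsFactors = FALSE)
  } else {
    stopifnot(all(genes$start < genes$end))
    if (any(genes$end > nchar(sequence)))
      stop("gene coordinates exceed contig length on ", contig_id)
    if (any(!nzchar(genes$protein)))
      stop("empty protein sequence on ", contig_id)
    genes <- genes[order(genes$start), , drop = FALSE]
    genes$contig_id <- contig_id
    genes$ordinal <- seq_len(nrow(genes)) - 1L
    genes <- genes[, c("gene_id", "contig_id", "start", "end", "strand",
                       "ordinal", "protein")]
    rownames(genes) <- NULL
  }
  structure(list(contig_id = contig_id, sequence = toupper(sequence),
                 genes = genes), class = "t6_contig")
}

#' @export
print.t6_genome <- function(x, ...) {
  ng <- sum(vapply(x$contigs, function(ct) nrow(ct$genes), integer(1)))
  cat("t6_genome", x$genome_id,
      if (nzchar(x$species_label)) paste0("(", x$species_label, ")") else "",
      "-", length(x$contigs), "contig(s),", ng, "genes\n")
  invisible(x)
}

# all genes of a genome as one data.frame (ordered by contig then ordinal)
genome_genes <- function(genome) {
  do.call(rbind, c(lapply(genome$contigs, function(ct) ct$genes),
                   make.row.names = FALSE))
}

# translate a CDS (already on the coding strand) with the bacterial code;
# fuzzy codons (N) yield X; the stop codon is stripped
translate_cds <- function(dna) {
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(dna),
    genetic.code = Biostrings::getGeneticCode("11"),
    no.init.codon = TRUE,
    if.fuzzy.codon = "X"))
  sub("\\*$", "", aa)
}

#' Read a genome from nucleotide FASTA plus GFF3
#'
#' CDS features are translated with the standard bacterial genetic code
#' (table 11, stop codon stripped); 1-based inclusive GFF coordinates are
#' converted to the internal 0-based half-open convention and ordinals are
#' assigned per contig. A CDS whose length is not divisible by 3 is skipped
#' with a warning; a GFF contig missing from the FASTA is a hard error.
#'
#' @param fasta_path nucleotide FASTA of the contigs.
#' @param gff_path GFF3 with CDS features carrying ID attributes.
#' @param genome_id,species_label identifiers for the record (default: the
#'   FASTA file stem).
#' @return a `t6_genome`.
#' @export
read_genome_bundle <- function(fasta_path, gff_path,
                               genome_id = NULL, species_label = "") {
  if (is.null(genome_id))
    genome_id <- sub("\\.(fa|fasta|fna)$", "", basename(fasta_path))
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gr <- rtracklayer::import(gff_path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "CDS"]
  feat <- data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr),
                     end = GenomicRanges::end(gr),
                     strand = as.character(GenomicRanges::strand(gr)),
                     gene_id = as.character(S4Vectors::mcols(gr)$ID),
                     stringsAsFactors = FALSE)
  missing <- setdiff(unique(feat$contig), names(seqs))
  if (length(missing))
    stop("GFF references contig(s) absent from FASTA: ",
         paste(missing, collapse = ", "))
  contigs <- lapply(names(seqs), function(cid) {
    fc <- feat[feat$contig == cid, , drop = FALSE]
    keep <- (fc$end - fc$start + 1L) %% 3L == 0L
    if (any(!keep))
      warning("skipping CDS with length not divisible by 3: ",
              paste(fc$gene_id[!keep], collapse = ", "))
    fc <- fc[keep, , drop = FALSE]
    seq <- as.character(seqs[[cid]])
    prot <- vapply(seq_len(nrow(fc)), function(i) {
      cds <- substr(seq, fc$start[i], fc$end[i])
      if (fc$strand[i] == "-") cds <- revcomp(cds)
      translate_cds(cds)
    }, character(1))
    make_contig(cid, seq,
                data.frame(gene_id = fc$gene_id, start = fc$start - 1L,
                           end = fc$end, strand = fc$strand,
                           protein = prot, stringsAsFactors = FALSE))
  })
  make_genome(genome_id, species_label, contigs)
}

#' Read a genome from protein FASTA plus a gene-coordinate table
#'
#' For annotation bundles without GFF3: a 4-column whitespace-separated
#' table (contig, start, end, strand; 1-based inclusive, rows in the order
#' of the protein FASTA) yields the same internal model. Contig nucleotide
#' sequences may be supplied as an optional FASTA; otherwise they are left
#' empty and DNA-level analyses are unavailable.
#'
#' @param protein_fasta protein FASTA (one record per gene).
#' @param coord_table path to the coordinate table.
#' @param fasta_path optional nucleotide FASTA.
#' @param genome_id,species_label record identifiers.
#' @return a `t6_genome`.
#' @export
read_protein_bundle <- function(protein_fasta, coord_table, fasta_path = NULL,
                                genome_id = "genome", species_label = "") {
  prots <- Biostrings::readAAStringSet(protein_fasta)
  names(prots) <- sub("\\s.*$", "", names(prots))
  tab <- read.table(coord_table, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("contig", "start", "end", "strand"))
  if (nrow(tab) != length(prots))
    stop("coordinate table rows do not match protein FASTA records")
  seqs <- if (!is.null(fasta_path)) {
    s <- Biostrings::readDNAStringSet(fasta_path)
    names(s) <- sub("\\s.*$", "", names(s))
    s
  } else NULL
  contigs <- lapply(unique(tab$contig), function(cid) {
    rows <- which(tab$contig == cid)
    seq <- if (!is.null(seqs) && cid %in% names(seqs))
      as.character(seqs[[cid]]) else strrep("N", max(tab$end[rows]))
    make_contig(cid, seq,
                data.frame(gene_id = names(prots)[rows],
                           start = tab$start[rows] - 1L, end = tab$end[rows],
                           strand = tab$strand[rows],
                           protein = as.character(prots)[rows],
                           stringsAsFactors = FALSE))
  })
  make_genome(genome_id, species_label, contigs)
}

#' Write a genome as nucleotide FASTA
#' @param genome a `t6_genome`.
#' @param path output path.
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- Biostrings::DNAStringSet(
    vapply(genome$contigs, function(ct) ct$sequence, character(1)))
  names(seqs) <- names(genome$contigs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write a genome's gene models as GFF3
#'
#' Internal 0-based half-open coordinates are emitted 1-based inclusive as
#' CDS features with ID attributes and phase 0.
#'
#' @param genome a `t6_genome`.
#' @param path output path.
#' @export
write_gff <- function(genome, path) {
  genes <- genome_genes(genome)
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig_id,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand)
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  S4Vectors::mcols(gr)$phase <- 0L
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# --- profile set text format ------------------------------------------------
# per record:
#   >name length ACDEFGHIKLMNPQRSTVWY
#   one whitespace-separated log-odds row per column (20 values, bits)
#   #null  <20 background frequencies>
#   #threshold <bits>                  (optional)
#   #calibration <decoy_db_size>       (optional)
#   #null_scores <s1> ... <sn>         (optional, sorted or not)

#' Read a profile set
#'
#' Parses the plain-text profile format documented in the package vignette
#' into a list of profile models. A malformed matrix row is a hard error
#' reporting the offending line number.
#'
#' @param path profile set file.
#' @return list of `t6_profile` objects.
#' @export
read_profile_set <- function(path) {
  lines <- readLines(path)
  profiles <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) { i <- i + 1L; next }
    if (!startsWith(ln, ">"))
      stop("expected profile header at line ", i)
    hdr <- strsplit(sub("^>", "", ln), "\\s+")[[1]]
    if (length(hdr) < 2L) stop("malformed profile header at line ", i)
    name <- hdr[1]
    L <- as.integer(hdr[2])
    rows <- matrix(NA_real_, nrow = 20L, ncol = L)
    for (k in seq_len(L)) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i + k]), "\\s+")[[1]]))
      if (length(v) != 20L || anyNA(v))
        stop("malformed profile matrix row at line ", i + k)
      rows[, k] <- v
    }
    i <- i + L + 1L
    null_freqs <- NULL; threshold <- NULL; null_scores <- NULL
    decoy_db_size <- NULL
    while (i <= length(lines) && startsWith(trimws(lines[i]), "#")) {
      parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      val <- suppressWarnings(as.numeric(parts[-1]))
      switch(parts[1],
             "#null" = { null_freqs <- val },
             "#threshold" = { threshold <- val },
             "#calibration" = { decoy_db_size <- val },
             "#null_scores" = { null_scores <- val },
             stop("unknown profile annotation '", parts[1], "' at line ", i))
      i <- i + 1L
    }
    if (is.null(null_freqs)) stop("profile '", name, "' lacks a #null line")
    p <- make_profile(name, rows, null_freqs)
    p$threshold_score <- threshold
    if (!is.null(null_scores)) {
      p$null_scores <- sort(null_scores)
      p$decoy_db_size <- if (is.null(decoy_db_size)) 1e4 else decoy_db_size
    }
    profiles[[name]] <- p
  }
  profiles
}

#' Write a profile set
#'
#' @param profiles list of `t6_profile` objects.
#' @param path output path.
#' @export
write_profile_set <- function(profiles, path) {
  fmt <- function(x) sprintf("%.6f", x)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in profiles) {
    writeLines(sprintf(">%s %d %s", p$name, p$length,
                       paste(AA20, collapse = "")), con)
    for (k in seq_len(p$length))
      writeLines(paste(fmt(p$match_scores[, k]), collapse = " "), con)
    writeLines(paste("#null", paste(fmt(p$null_freqs), collapse = " ")), con)
    if (!is.null(p$threshold_score))
      writeLines(paste("#threshold", fmt(p$threshold_score)), con)
    if (!is.null(p$null_scores)) {
      writeLines(paste("#calibration", fmt(p$decoy_db_size)), con)
      writeLines(paste("#null_scores",
                       paste(fmt(p$null_scores), collapse = " ")), con)
    }
  }
  invisible(path)
}

# --- reports ----------------------------------------------------------------

#' Write a per-locus TSV report
#'
#' One row per locus: genome, contigs, nucleotide spans, architecture call
#' (if attached to the locus), discovery pass, gene count, family roster.
#'
#' @param loci list of `t6_locus` objects.
#' @param path output path.
#' @export
write_locus_report <- function(loci, path) {
  rows <- lapply(loci, function(lc) {
    fams <- sort(unique(lc$genes$family[!is.na(lc$genes$family) &
                                          lc$genes$family != "unknown"]))
    spans <- paste(vapply(names(lc$spans), function(cid)
      sprintf("%s:%d-%d", cid, lc$spans[[cid]][1], lc$spans[[cid]][2]),
      character(1)), collapse = ";")
    data.frame(locus_id = lc$locus_id, genome_id = lc$genome_id,
               contig_ids = paste(lc$contig_ids, collapse = ","),
               spans = spans,
               architecture = if (is.null(lc$architecture)) NA_character_
                              else lc$architecture,
               discovery_pass = lc$discovery_pass,
               n_genes = nrow(lc$genes),
               families = paste(fams, collapse = ","),
               stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus_id = character(), genome_id = character(),
               contig_ids = character(), spans = character(),
               architecture = character(), discovery_pass = integer(),
               n_genes = integer(), families = character(),
               stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  invisible(path)
}

# fixed palette: each family name maps to one color, identically in every map
.orf_palette <- c("#1f77b4", "#ff7f0e", "#2ca02c", "#d62728", "#9467bd",
                  "#8c564b", "#e377c2", "#7f7f7f", "#bcbd22", "#17becf",
                  "#aec7e8", "#ffbb78", "#98df8a", "#ff9896", "#c5b0d5",
                  "#c49c94", "#f7b6d2", "#dbdb8d", "#9edae5", "#393b79",
                  "#637939", "#8c6d31", "#843c39", "#7b4173", "#5254a3",
                  "#bd9e39", "#ad494a", "#a55194", "#6b6ecf", "#b5cf6b",
                  "#e7ba52", "#d6616b", "#ce6dbd", "#9c9ede", "#cedb9c")

family_color <- function(family) {
  fams <- c(LOCUS_FAMILIES, TRA_FAMILIES, "TetR")
  idx <- match(family, fams)
  idx[is.na(idx)] <- (vapply(family[is.na(idx)], function(f)
    sum(utf8ToInt(f)), numeric(1)) %% length(.orf_palette)) + 1L
  .orf_palette[((idx - 1L) %% length(.orf_palette)) + 1L]
}

#' Write an ORF-map JSON for one locus
#'
#' Emits per-gene arrows (offset from the locus start, length, strand,
#' family label, cluster id and a color key consistent per family) suitable
#' for drawing gene-arrow tracks of a locus.
#'
#' @param locus an oriented `t6_locus`.
#' @param path output path.
#' @export
write_orf_map <- function(locus, path) {
  g <- locus$genes
  origin <- min(g$start)
  arrows <- lapply(seq_len(nrow(g)), function(i) {
    fam <- if (is.na(g$family[i])) "unknown" else g$family[i]
    list(id = g$gene_id[i], offset = g$start[i] - origin,
         length = g$end[i] - g$start[i], strand = g$strand[i],
         family = fam,
         cluster = if ("cluster_id" %in% names(g)) g$cluster_id[i] else NA,
         color = unname(family_color(fam)))
  })
  doc <- list(locus_id = locus$locus_id, genome_id = locus$genome_id,
              oriented = isTRUE(locus$oriented), arrows = arrows)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
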