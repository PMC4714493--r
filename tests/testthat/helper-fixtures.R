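# Shared fixtures, built once per test run and memoized. The "mini" set
# (6 genomes) backs most integration checks; the full reference
# conditions (30 genomes) back the acceptance suite.

.fx <- new.env(parent = emptyenv())

fx_config <- function() pipeline_config(rng_seed = 1)

fx_curated <- function() {
  if (is.null(.fx$curated))
    .fx$curated <- curated_profile_set(1, fx_config())
  .fx$curated
}

fx_mini <- function() {
  if (is.null(.fx$mini)) {
    cfg <- fx_config()
    cur <- fx_curated()
    gs <- generate_genome_set(
      synth_config(n_genomes = 6,
                   architecture_mix = c(GA1 = 2, GA2 = 1, GA3 = 2,
                                        none = 1),
                   seed = 1), cur)
    run <- run_pipeline(gs$genomes, cur, cfg)
    .fx$mini <- list(cfg = cfg, cur = cur, gs = gs, run = run,
                     eval = evaluate_run(run, gs$truth))
  }
  .fx$mini
}

fx_full <- function() {
  if (is.null(.fx$full)) {
    cfg <- fx_config()
    cur <- fx_curated()
    gs <- generate_genome_set(synth_config(seed = 1), cur)
    run <- run_pipeline(gs$genomes, cur, cfg)
    .fx$full <- list(cfg = cfg, cur = cur, gs = gs, run = run,
                     eval = evaluate_run(run, gs$truth))
  }
  .fx$full
}

# a quick fake genome: k tiny genes on one contig (no translation needed)
fx_fake_genome <- function(n_genes, contig_id = "c1", genome_id = "fake") {
  genes <- data.frame(gene_id = sprintf("g%03d", seq_len(n_genes)),
                      start = (seq_len(n_genes) - 1L) * 10L,
                      end = (seq_len(n_genes) - 1L) * 10L + 3L,
                      strand = "+",
                      protein = rep("M", n_genes),
                      stringsAsFactors = FALSE)
  make_genome(genome_id, "",
              list(make_contig(contig_id, strrep("A", n_genes * 10L + 10L),
                               genes)))
}

fx_random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
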