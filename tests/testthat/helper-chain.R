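# The default synthetic analysis chain (transcriptome -> counts ->
# normalization -> contrasts -> targetome -> network gates), computed once
# per test run and cached: several tests probe different properties of the
# same study-scale dataset.

.chain_cache <- new.env(parent = emptyenv())

default_chain <- function(seed = 1L) {
  key <- paste0("seed_", seed)
  if (!is.null(.chain_cache[[key]])) return(.chain_cache[[key]])
  cfg <- sim_config(seed = seed)
  sim <- generate_transcriptome(cfg)
  cm <- simulate_counts(sim$truth, cfg)

  rna_rows <- cm$features$biotype %in% c("mRNA", "lncRNA", "circRNA")
  lib_rna <- colSums(cm$counts[rna_rows, , drop = FALSE])
  fl <- subset_biotype(cm, c("mRNA", "lncRNA")); fl$library_size <- lib_rna
  circ <- subset_biotype(cm, "circRNA"); circ$library_size <- lib_rna
  mir <- subset_biotype(cm, "miRNA", recompute_library = TRUE)
  fpkm <- normalize_counts(fl, "FPKM")
  rpm <- normalize_counts(circ, "RPM")
  tpm <- normalize_counts(mir, "TPM")

  contrasts <- do.call(rbind, lapply(stage_contrasts(cfg$stage_labels),
    function(ctr) {
      ab <- strsplit(ctr, "/", fixed = TRUE)[[1]]
      rbind(contrast_stages(fpkm, cm$samples, ab[1], ab[2]),
            contrast_stages(rpm, cm$samples, ab[1], ab[2]),
            contrast_stages(tpm, cm$samples, ab[1], ab[2]))
    }))

  tr <- sim$transcripts
  mre <- predict_targetome(tr[tr$biotype == "miRNA", c("id", "sequence")],
                           tr[tr$biotype != "miRNA", , drop = FALSE])
  expr <- rbind(stage_means(fpkm, cm$samples, cfg$stage_labels),
                stage_means(rpm, cm$samples, cfg$stage_labels),
                stage_means(tpm, cm$samples, cfg$stage_labels))
  pairs <- shared_mre_pairs(mre)
  corr <- correlation_filter(pairs, expr, r_min = 0.8)
  triads <- assemble_triads(corr, contrasts, de_threshold = 1)

  out <- list(cfg = cfg, sim = sim, cm = cm, fpkm = fpkm, rpm = rpm,
              tpm = tpm, contrasts = contrasts, mre = mre, expr = expr,
              pairs = pairs, corr = corr, triads = triads)
  .chain_cache[[key]] <- out
  out
}
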