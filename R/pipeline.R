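# End-to-end orchestration: synthetic data -> family identification ->
# physicochemical profiles -> phylogeny -> normalization and contrasts ->
# target prediction -> ceRNA network, with structured per-stage record
# counts, a run summary and a provenance manifest.

#' Pipeline configuration
#'
#' Collects every tunable parameter of the pipeline in one resolved list so
#' that defaulted values are auditable in the manifest.
#'
#' @param synthetic A [sim_config()] (or list of arguments for one)
#'   describing the synthetic dataset.
#' @param identity_min,evalue_max Homology screen thresholds.
#' @param domain_score_min Domain-scan score cutoff.
#' @param scheme A [penalty_scheme()].
#' @param pseudocount Pseudocount for [contrast_stages()].
#' @param r_min Correlation threshold for [correlation_filter()].
#' @param de_threshold Minimum |log2fc| for triad membership.
#' @param require_mirna_de Enforce the opposite-direction miRNA gate.
#' @param n_bootstrap Bootstrap replicates for the phylogeny (default 1000).
#' @param seed Master seed; stage-specific streams are derived from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = sim_config(), identity_min = 0.80,
                            evalue_max = 1e-5, domain_score_min = 0,
                            scheme = penalty_scheme(), pseudocount = 1,
                            r_min = 0.8, de_threshold = 1,
                            require_mirna_de = TRUE, n_bootstrap = 1000L,
                            seed = NULL) {
  if (!inherits(synthetic, "sim_config")) {
    synthetic <- do.call(sim_config, as.list(synthetic))
  }
  if (!is.null(seed)) synthetic$seed <- as.integer(seed)
  check_scalar_number(r_min, "r_min", min = 1e-12)
  check_scalar_number(de_threshold, "de_threshold", min = 0)
  check_scalar_number(n_bootstrap, "n_bootstrap", min = 1)
  structure(list(
    synthetic = synthetic, identity_min = identity_min,
    evalue_max = evalue_max, domain_score_min = domain_score_min,
    scheme = scheme, pseudocount = pseudocount, r_min = r_min,
    de_threshold = de_threshold, require_mirna_de = require_mirna_de,
    n_bootstrap = as.integer(n_bootstrap), seed = synthetic$seed
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML may contain a `synthetic` block (arguments to [sim_config()]),
#' a `scheme` block (arguments to [penalty_scheme()]) and any top-level
#' [pipeline_config()] parameter.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$synthetic)) args$synthetic <- do.call(sim_config, y$synthetic)
  if (!is.null(y$scheme)) args$scheme <- do.call(penalty_scheme, y$scheme)
  for (f in c("identity_min", "evalue_max", "domain_score_min", "pseudocount",
              "r_min", "de_threshold", "require_mirna_de", "n_bootstrap",
              "seed")) {
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  }
  do.call(pipeline_config, args)
}

#' All later-vs-earlier stage contrasts
#'
#' @param stage_labels Ordered stage labels.
#' @return Character vector of labels `"later/earlier"` (e.g. `"Bo/Li"`).
#' @export
stage_contrasts <- function(stage_labels) {
  out <- character(0)
  for (i in seq_along(stage_labels)) {
    for (j in seq_along(stage_labels)) {
      if (j > i) out <- c(out, paste0(stage_labels[j], "/", stage_labels[i]))
    }
  }
  out
}

#' Run the full pipeline
#'
#' Executes: simulate -> identify -> physchem -> tree -> quantify (normalize
#' + contrasts) -> targets -> network, writing all artifacts under `outdir`
#' together with a run summary and a provenance manifest. A stage failure
#' aborts with the failing stage named and leaves a `FAILED` marker next to
#' the partial outputs. Record counts at every filtering step are logged
#' and returned, so the intersection structure of the network construction
#' is inspectable on any dataset.
#'
#' @param config A [pipeline_config()] (or path to a YAML file).
#' @param outdir Output directory.
#' @param stages Run the chain up to and including this stage (default
#'   `"network"`, i.e. everything). One of `"simulate"`, `"identify"`,
#'   `"physchem"`, `"tree"`, `"quantify"`, `"targets"`, `"network"`.
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a list with the run `summary`, the `manifest`, and
#'   the in-memory stage results.
#' @export
run_pipeline <- function(config, outdir,
                         stages = c("network", "simulate", "identify",
                                    "physchem", "tree", "quantify",
                                    "targets"),
                         quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  last_stage <- match.arg(stages)
  order_all <- c("simulate", "identify", "physchem", "tree", "quantify",
                 "targets", "network")
  to_run <- order_all[seq_len(match(last_stage, order_all))]
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  note <- function(...) if (!quiet) message(sprintf(...))
  res <- list()
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      writeLines(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                 file.path(outdir, "FAILED"))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  scfg <- config$synthetic
  summary <- list(seed = scfg$seed)

  ## --- simulate -----------------------------------------------------------
  run_stage("simulate", function() {
    sim <- generate_transcriptome(scfg)
    prot <- generate_protein_set(scfg)
    cm <- simulate_counts(sim$truth, scfg)
    res$transcripts <<- sim$transcripts
    res$truth <<- sim$truth
    res$proteins <<- prot
    res$counts <<- cm
    write_fixtures(file.path(outdir, "fixtures"), sim$transcripts, cm,
                   sim$truth, prot, seed = scfg$seed)
    summary$n_transcripts <<- nrow(sim$transcripts)
    summary$n_features <<- nrow(cm$counts)
    summary$n_proteins <<- nrow(prot$proteins)
    summary$n_planted_sites <<- nrow(sim$truth$planted_sites)
    summary$n_planted_triads <<- nrow(sim$truth$planted_triads)
    note("simulate: %d transcripts, %d proteins, %d planted sites",
         nrow(sim$transcripts), nrow(prot$proteins),
         nrow(sim$truth$planted_sites))
  })
  if (!"identify" %in% to_run) return(finish_run(config, res, summary, outdir))

  ## --- identify ------------------------------------------------------------
  run_stage("identify", function() {
    ident <- identify_spl(res$proteins$proteins, res$proteins$references,
                          identity_min = config$identity_min,
                          evalue_max = config$evalue_max,
                          score_min = config$domain_score_min)
    res$identification <<- ident
    utils::write.table(ident$canonical[, setdiff(names(ident$canonical),
                                                 "sequence")],
                       file.path(outdir, "spl_canonical.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$n_screen_retained <<- sum(ident$screen$retained)
    summary$n_full_domain <<- sum(ident$domain$full_length)
    summary$n_spl_canonical <<- nrow(ident$canonical)
    note("identify: %d retained by screen, %d with full-length domain, %d canonical",
         sum(ident$screen$retained), sum(ident$domain$full_length),
         nrow(ident$canonical))
  })
  if (!"physchem" %in% to_run) return(finish_run(config, res, summary, outdir))

  ## --- physchem ------------------------------------------------------------
  run_stage("physchem", function() {
    pc <- physchem_table(res$identification$canonical)
    pc <- merge(pc, res$identification$canonical[, c("id", "domain_start",
                                                     "domain_end",
                                                     "full_length")],
                by = "id", sort = TRUE)
    res$physchem <<- pc
    utils::write.table(pc, file.path(outdir, "spl_physchem.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note("physchem: %d profiles", nrow(pc))
  })
  if (!"tree" %in% to_run) return(finish_run(config, res, summary, outdir))

  ## --- tree ----------------------------------------------------------------
  run_stage("tree", function() {
    aln <- domain_alignment(res$identification$canonical)
    tree <- bootstrap_supports(aln, n_reps = config$n_bootstrap,
                               seed = scfg$seed + 3000L)
    # map canonical SPL proteins onto planted triad mRNAs (in order), so the
    # leaf MRE flag reflects the planted miR156 regulation
    canon <- sort(res$identification$canonical$id)
    triad_mrna <- res$truth$planted_triads$mrna_id
    map <- setNames(rep(NA_character_, length(canon)), canon)
    n_map <- min(length(canon), length(triad_mrna))
    map[seq_len(n_map)] <- triad_mrna[seq_len(n_map)]
    res$protein_mrna_map <<- map
    mre_ids <- unique(res$truth$planted_sites$target_id)
    tree <- annotate_mre_class(tree, mre_ids, map = map)
    res$tree <<- tree
    write_newick(tree, file.path(outdir, "spl_tree.nwk"))
    supports <- suppressWarnings(as.numeric(tree$node.label))
    summary$mean_bootstrap_support <<- mean(supports, na.rm = TRUE)
    note("tree: %d leaves, mean support %.1f", length(tree$tip.label),
         mean(supports, na.rm = TRUE))
  })
  if (!"quantify" %in% to_run) return(finish_run(config, res, summary, outdir))

  ## --- quantify ------------------------------------------------------------
  run_stage("quantify", function() {
    cm <- res$counts
    rna_rows <- cm$features$biotype %in% c("mRNA", "lncRNA", "circRNA")
    lib_rna <- colSums(cm$counts[rna_rows, , drop = FALSE])
    fl <- subset_biotype(cm, c("mRNA", "lncRNA"))
    fl$library_size <- lib_rna
    circ <- subset_biotype(cm, "circRNA")
    circ$library_size <- lib_rna
    mir <- subset_biotype(cm, "miRNA", recompute_library = TRUE)

    fpkm <- normalize_counts(fl, "FPKM")
    rpm <- normalize_counts(circ, "RPM")
    tpm <- normalize_counts(mir, "TPM")
    res$normalized <<- list(FPKM = fpkm, RPM = rpm, TPM = tpm)

    contrasts <- stage_contrasts(scfg$stage_labels)
    all_ctr <- list()
    for (ctr in contrasts) {
      ab <- strsplit(ctr, "/", fixed = TRUE)[[1]]
      for (mat in list(fpkm, rpm, tpm)) {
        all_ctr[[length(all_ctr) + 1L]] <-
          contrast_stages(mat, cm$samples, ab[1], ab[2],
                          pseudocount = config$pseudocount)
      }
    }
    ctab <- do.call(rbind, all_ctr)
    res$contrasts <<- ctab
    utils::write.table(ctab, file.path(outdir, "contrasts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    sm <- rbind(stage_means(fpkm, cm$samples, scfg$stage_labels),
                stage_means(rpm, cm$samples, scfg$stage_labels),
                stage_means(tpm, cm$samples, scfg$stage_labels))
    res$stage_expr <<- sm
    note("quantify: %d contrast rows over %s", nrow(ctab),
         paste(contrasts, collapse = ", "))
  })
  if (!"targets" %in% to_run) return(finish_run(config, res, summary, outdir))

  ## --- targets -------------------------------------------------------------
  run_stage("targets", function() {
    tr <- res$transcripts
    mirnas <- tr[tr$biotype == "miRNA", c("id", "sequence")]
    if (nrow(mirnas) == 0L) stop("no miRNA input available", call. = FALSE)
    targets <- tr[tr$biotype %in% c("mRNA", "lncRNA", "circRNA"), ,
                  drop = FALSE]
    mre <- predict_targetome(mirnas, targets, config$scheme)
    res$mre <<- mre
    utils::write.table(mre, file.path(outdir, "mre_sites.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    summary$n_mre_sites <<- nrow(mre)
    note("targets: %d MRE sites", nrow(mre))
  })
  if (!"network" %in% to_run) return(finish_run(config, res, summary, outdir))

  ## --- network -------------------------------------------------------------
  run_stage("network", function() {
    pairs <- shared_mre_pairs(res$mre)
    summary$n_shared_mre_pairs <<- nrow(pairs)
    corr <- correlation_filter(pairs, res$stage_expr, r_min = config$r_min)
    summary$n_correlated_pairs <<- nrow(corr)
    triads <- assemble_triads(corr, res$contrasts,
                              de_threshold = config$de_threshold,
                              require_mirna_de = config$require_mirna_de)
    res$pairs <<- corr
    res$triads <<- triads
    tri_out <- triads
    tri_out$r <- round(tri_out$r, 10)
    utils::write.table(tri_out, file.path(outdir, "triads.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    bio <- setNames(res$truth$features$biotype, res$truth$features$id)
    net_files <- character(0)
    for (ctr in unique(triads$contrast)) {
      pfx <- paste0("network_", gsub("/", "_", ctr))
      net_files <- c(net_files,
                     export_network(triads[triads$contrast == ctr, ,
                                           drop = FALSE],
                                    file.path(outdir, "network"), pfx,
                                    biotypes = bio))
    }
    summary$n_triads_total <<- nrow(unique(triads[, c("cerna_id", "mirna_id",
                                                      "mrna_id")]))
    per_ctr <- table(triads$contrast)
    summary$n_triads_per_contrast <<- as.list(setNames(as.integer(per_ctr),
                                                       names(per_ctr)))
    main_ctr <- paste0(scfg$stage_labels[4], "/", scfg$stage_labels[1])
    rec <- evaluate_recovery(triads, res$truth$planted_triads,
                             contrast = main_ctr)
    summary$recovery <<- list(contrast = main_ctr,
                              precision = rec$precision,
                              recall = rec$recall,
                              n_predicted = rec$n_predicted,
                              n_truth = rec$n_truth)
    res$recovery <<- rec
    note("network: %d shared-MRE pairs -> %d correlated -> %d triads (%s: P=%.3f R=%.3f)",
         nrow(pairs), nrow(corr), nrow(triads), main_ctr, rec$precision,
         rec$recall)
  })

  finish_run(config, res, summary, outdir)
}

#' @noRd
finish_run <- function(config, res, summary, outdir) {
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- write_manifest(config, outdir)
  invisible(list(summary = summary, manifest = manifest, results = res))
}

#' Write the provenance manifest of a run
#'
#' Records the package version, the master seed, a hash of the fully
#' resolved configuration (so every defaulted parameter is auditable), the
#' resolved configuration itself -- including the penalty-scheme values --
#' and an MD5 checksum for every file under the output directory.
#'
#' @param config The `pipeline_config` of the run.
#' @param outdir The run's output directory.
#' @return The manifest list (also written to `manifest.json`).
#' @export
write_manifest <- function(config, outdir) {
  cfg <- unclass(config)
  cfg$synthetic <- unclass(cfg$synthetic)
  cfg$scheme <- unclass(cfg$scheme)
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(as.character(cfg_json), tmp)
  cfg_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)

  rel <- list.files(outdir, recursive = TRUE)
  rel <- rel[rel != "manifest.json"]
  files <- file.path(outdir, rel)
  sums <- unname(tools::md5sum(files))
  manifest <- list(
    tool = "splnet",
    version = as.character(utils::packageVersion("splnet")),
    seed = config$seed,
    config_hash = cfg_hash,
    config = cfg,
    files = as.list(setNames(sums, rel))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
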