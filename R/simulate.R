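# Seed-reproducible synthetic transcriptomes, protein sets and four-stage
# count matrices with planted miRNA response elements, planted regulatory
# triads and known isoform redundancy, so that every downstream stage of the
# pipeline can be validated against ground truth.

#' Simulation configuration
#'
#' Defines the synthetic study: four developmental leaf stages (linear,
#' lanceolate, ovate, broad-ovate) with replicated sequencing, a miR156
#' family whose expression declines monotonically across the stage series,
#' and SPL-like target mRNAs plus ceRNAs (lncRNA/circRNA) that rise in
#' parallel. Counts follow a negative-binomial model with a single global
#' dispersion.
#'
#' In addition to the miR156 family itself (`n_mirna` members, each a
#' distinct family member), the simulated small-RNA library contains
#' `n_mirna_background` unrelated miRNA features with stage-stable
#' expression. These emulate the bulk of a real small-RNA library and give
#' per-million normalization a stable denominator, without which a
#' family-wide decline would be invisible after TPM scaling.
#'
#' @param n_mrna,n_lncrna,n_circrna Number of features per biotype
#'   (defaults 300 / 100 / 30).
#' @param n_mirna miR156 family size (default 12).
#' @param n_mirna_background Stage-stable background miRNAs (default 188).
#' @param stage_labels Ordered labels of the 4 stages (default Li, La, Ov,
#'   Bo: linear through broad-ovate).
#' @param replicates_per_stage Biological replicates per stage (default 3).
#' @param mre_fraction Fraction of non-triad ceRNAs/mRNAs receiving a
#'   planted miR156 site (default 0.25).
#' @param n_triads Number of planted ceRNA-miR156-mRNA triads (default 12).
#' @param nb_dispersion Negative-binomial dispersion (variance = mu +
#'   dispersion * mu^2; default 0.05).
#' @param effect_size Multiplicative per-stage trend factor for miR156
#'   (declining) and triad members (rising); default 2.
#' @param isoform_fraction Fraction of mRNA loci carrying 2-3 splice
#'   isoforms (default 0.15).
#' @param seed Integer seed; all generator functions derive their random
#'   streams from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_mrna = 300L, n_lncrna = 100L, n_circrna = 30L,
                       n_mirna = 12L, n_mirna_background = 188L,
                       stage_labels = c("Li", "La", "Ov", "Bo"),
                       replicates_per_stage = 3L, mre_fraction = 0.25,
                       n_triads = 12L, nb_dispersion = 0.05,
                       effect_size = 2, isoform_fraction = 0.15,
                       seed = 1L) {
  if (length(stage_labels) != 4L || anyDuplicated(stage_labels)) {
    stop_config("stage_labels", "must be exactly 4 distinct stage names")
  }
  for (f in c("n_mrna", "n_lncrna", "n_circrna", "n_mirna",
              "replicates_per_stage")) {
    check_scalar_number(get(f), f, min = 1)
  }
  check_scalar_number(n_mirna_background, "n_mirna_background", min = 0)
  check_scalar_number(mre_fraction, "mre_fraction", min = 0, max = 1)
  check_scalar_number(isoform_fraction, "isoform_fraction", min = 0, max = 1)
  check_scalar_number(nb_dispersion, "nb_dispersion", min = 0)
  if (nb_dispersion == 0) {
    # Poisson limit is allowed; strictly positive dispersion is the NB case
  }
  check_scalar_number(effect_size, "effect_size", min = 1e-6)
  check_scalar_number(n_triads, "n_triads", min = 0)
  check_scalar_number(seed, "seed")
  structure(list(
    n_mrna = as.integer(n_mrna), n_lncrna = as.integer(n_lncrna),
    n_circrna = as.integer(n_circrna), n_mirna = as.integer(n_mirna),
    n_mirna_background = as.integer(n_mirna_background),
    stage_labels = stage_labels,
    replicates_per_stage = as.integer(replicates_per_stage),
    mre_fraction = mre_fraction, n_triads = as.integer(n_triads),
    nb_dispersion = nb_dispersion, effect_size = effect_size,
    isoform_fraction = isoform_fraction, seed = as.integer(seed)
  ), class = "sim_config")
}

#' @noRd
mir156_ids <- function(n) {
  suffix <- c(letters, paste0(rep(letters, each = 26), letters))[seq_len(n)]
  paste0("peu-miR156", suffix)
}

#' Generate a synthetic transcriptome with planted ground truth
#'
#' Produces mRNA, lncRNA, circRNA and miRNA records plus the planted truth:
#' miR156 response elements shared between designated ceRNAs and mRNAs
#' (the planted triads), isoform groups for deduplication tests, and the
#' expected per-stage means that encode the study design -- miR156 family
#' members strictly decreasing across the stage series, triad mRNAs and
#' ceRNAs strictly increasing with the same geometric trend (their
#' noise-free stage profiles are perfectly correlated).
#'
#' @param config A [sim_config()].
#' @return List with `transcripts` (`data.frame`: `id`, `biotype`, `locus`,
#'   `length`, `junction`, `sequence`) and `truth` (list with
#'   `planted_sites`, `planted_triads`, `isoform_groups`, `stage_means`,
#'   `features`).
#' @export
generate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  # --- miR156 family + background small-RNA features -----------------------
  mir_ids <- mir156_ids(config$n_mirna)
  mirnas <- data.frame(
    id = mir_ids, biotype = "miRNA", locus = mir_ids,
    length = 21L, junction = NA_integer_,
    sequence = vapply(seq_len(config$n_mirna), function(i) random_sequence(21),
                      character(1)),
    stringsAsFactors = FALSE
  )
  bg_ids <- if (config$n_mirna_background > 0) {
    sprintf("peu-miR-bg%03d", seq_len(config$n_mirna_background))
  } else character(0)

  # --- mRNA loci with optional splice isoforms -----------------------------
  mrna_rows <- list()
  isoform_groups <- list()
  locus_i <- 0L
  n_done <- 0L
  while (n_done < config$n_mrna) {
    locus_i <- locus_i + 1L
    locus <- sprintf("mLOC_%04d", locus_i)
    n_iso <- if (runif(1) < config$isoform_fraction) sample(2:3, 1) else 1L
    n_iso <- min(n_iso, config$n_mrna - n_done)
    len0 <- sample(600:1500, 1)
    seq0 <- random_sequence(len0)
    ids <- sprintf("%s.t%d", locus, seq_len(n_iso))
    lens <- c(len0, sort(sample(300:(len0 - 50L), n_iso - 1L), decreasing = TRUE))
    for (k in seq_len(n_iso)) {
      mrna_rows[[length(mrna_rows) + 1L]] <- data.frame(
        id = ids[k], biotype = "mRNA", locus = locus,
        length = lens[k], junction = NA_integer_,
        sequence = substr(seq0, 1L, lens[k]), stringsAsFactors = FALSE
      )
    }
    if (n_iso > 1L) isoform_groups[[locus]] <- ids
    n_done <- n_done + n_iso
  }
  mrnas <- do.call(rbind, mrna_rows)

  lncrnas <- data.frame(
    id = sprintf("lncRNA_%04d", seq_len(config$n_lncrna)),
    biotype = "lncRNA",
    locus = sprintf("lncLOC_%04d", seq_len(config$n_lncrna)),
    length = sample(300:1000, config$n_lncrna, replace = TRUE),
    junction = NA_integer_, sequence = NA_character_,
    stringsAsFactors = FALSE
  )
  lncrnas$sequence <- vapply(lncrnas$length, random_sequence, character(1))

  circ_len <- sample(300:600, config$n_circrna, replace = TRUE)
  circrnas <- data.frame(
    id = sprintf("circRNA_%04d", seq_len(config$n_circrna)),
    biotype = "circRNA",
    locus = sprintf("circLOC_%04d", seq_len(config$n_circrna)),
    length = circ_len,
    junction = circ_len,  # back-splice closes the circle end -> start
    sequence = vapply(circ_len, random_sequence, character(1)),
    stringsAsFactors = FALSE
  )

  transcripts <- rbind(mrnas, lncrnas, circrnas, mirnas)

  # --- choose planted triads ----------------------------------------------
  single_iso_mrna <- mrnas$id[!(mrnas$locus %in% names(isoform_groups))]
  n_triads <- min(config$n_triads, length(single_iso_mrna),
                  config$n_lncrna + config$n_circrna)
  triad_mirna <- if (n_triads <= config$n_mirna) {
    sample(mir_ids, n_triads)
  } else {
    sample(mir_ids, n_triads, replace = TRUE)
  }
  n_circ_ce <- min(round(n_triads / 3), config$n_circrna)
  triad_cerna <- c(sample(lncrnas$id, n_triads - n_circ_ce),
                   sample(circrnas$id, n_circ_ce))
  triad_mrna <- sample(single_iso_mrna, n_triads)
  planted_triads <- data.frame(
    cerna_id = triad_cerna, mirna_id = triad_mirna, mrna_id = triad_mrna,
    stringsAsFactors = FALSE
  )

  # --- MRE plan: triad members always, plus a fraction of the rest ---------
  plan <- data.frame(target_id = character(0), mirna_id = character(0),
                     n_edits = integer(0), span_junction = logical(0),
                     stringsAsFactors = FALSE)
  add_plan <- function(target, mirna, span = FALSE) {
    rbind(plan, data.frame(target_id = target, mirna_id = mirna,
                           n_edits = sample(0:2, length(target), replace = TRUE),
                           span_junction = span, stringsAsFactors = FALSE))
  }
  if (n_triads > 0L) {
    span_ce <- triad_cerna %in% circrnas$id & runif(n_triads) < 0.5
    plan <- add_plan(triad_cerna, triad_mirna, span_ce)
    plan <- add_plan(triad_mrna, triad_mirna, FALSE)
  }
  extra_pool <- setdiff(c(single_iso_mrna, lncrnas$id, circrnas$id),
                        c(triad_cerna, triad_mrna))
  n_extra <- round(config$mre_fraction * length(extra_pool))
  if (n_extra > 0L) {
    extra <- sample(extra_pool, n_extra)
    plan <- add_plan(extra, sample(mir_ids, n_extra, replace = TRUE), FALSE)
  }

  planted <- plant_mres(transcripts, mirnas, plan)
  transcripts <- planted$transcripts

  # --- expected per-stage means -------------------------------------------
  feat_ids <- c(transcripts$id, bg_ids)
  features <- data.frame(
    id = feat_ids,
    biotype = c(transcripts$biotype, rep("miRNA", length(bg_ids))),
    length = c(transcripts$length, rep(21L, length(bg_ids))),
    stringsAsFactors = FALSE
  )
  n_feat <- nrow(features)
  base <- rlnorm(n_feat, log(150), 0.7)
  names(base) <- feat_ids
  base[mir_ids] <- rlnorm(config$n_mirna, log(500), 0.4)
  trend_up <- unique(c(triad_cerna, triad_mrna))
  base[trend_up] <- rlnorm(length(trend_up), log(60), 0.4)

  s_idx <- seq_len(4L) - 1L
  stage_means <- outer(base, rep(1, 4))
  colnames(stage_means) <- config$stage_labels
  stage_means[mir_ids, ] <- base[mir_ids] %o% config$effect_size^(-s_idx)
  stage_means[trend_up, ] <- base[trend_up] %o% config$effect_size^(s_idx)

  truth <- list(
    planted_sites = planted$planted_sites,
    planted_triads = planted_triads,
    isoform_groups = isoform_groups,
    stage_means = stage_means,
    features = features
  )
  list(transcripts = transcripts, truth = truth)
}

#' Plant miRNA response elements into transcripts
#'
#' Each planted site is the reverse complement of its miRNA with 0-2
#' controlled edits (mismatch or G:U wobble) placed outside the seed range,
#' so its designed penalty is at most 2 x mismatch and always below the
#' default site-call cutoff. Sites for circRNAs may span the back-splice
#' junction, in which case the site wraps from the end of the linear
#' representation to its start.
#'
#' @param transcripts Transcript table (`id`, `biotype`, `junction`,
#'   `sequence`, ...).
#' @param mirnas miRNA table (`id`, `sequence`).
#' @param plan `data.frame` with columns `target_id`, `mirna_id`,
#'   `n_edits` (0-2) and `span_junction`.
#' @param scheme Penalty scheme defining seed range and edit penalties.
#' @return List with the modified `transcripts` and `planted_sites`
#'   (`mirna_id`, `target_id`, `start`, `end`, `score`, `spans_junction`).
#' @export
plant_mres <- function(transcripts, mirnas, plan, scheme = penalty_scheme()) {
  stopifnot(is.data.frame(plan),
            all(c("target_id", "mirna_id", "n_edits", "span_junction") %in%
                  names(plan)))
  seqs <- setNames(transcripts$sequence, transcripts$id)
  mir_seqs <- setNames(as_dna(mirnas$sequence), mirnas$id)

  sites <- vector("list", nrow(plan))
  for (r in seq_len(nrow(plan))) {
    tid <- plan$target_id[r]
    mid <- plan$mirna_id[r]
    mir <- mir_seqs[[mid]]
    m <- nchar(mir)
    tseq <- seqs[[tid]]
    L <- nchar(tseq)
    if (m > L) {
      stop(sprintf("miRNA '%s' (%d nt) is longer than target '%s' (%d nt)",
                   mid, m, tid, L), call. = FALSE)
    }
    edited <- edit_site(mir, plan$n_edits[r], scheme)
    site <- edited$site
    if (isTRUE(plan$span_junction[r])) {
      k <- sample(seq_len(m - 1L), 1)  # bases placed before the junction
      substr(tseq, L - k + 1L, L) <- substr(site, 1L, k)
      substr(tseq, 1L, m - k) <- substr(site, k + 1L, m)
      start <- L - k + 1L
      end <- m - k
      spans <- TRUE
    } else {
      start <- sample(seq_len(L - m + 1L), 1)
      end <- start + m - 1L
      substr(tseq, start, end) <- site
      spans <- FALSE
    }
    seqs[[tid]] <- tseq
    sites[[r]] <- data.frame(
      mirna_id = mid, target_id = tid, start = start, end = end,
      score = edited$score, spans_junction = spans, stringsAsFactors = FALSE
    )
  }
  transcripts$sequence <- unname(seqs[transcripts$id])
  planted_sites <- if (nrow(plan) > 0L) do.call(rbind, sites) else
    data.frame(mirna_id = character(0), target_id = character(0),
               start = integer(0), end = integer(0), score = numeric(0),
               spans_junction = logical(0))
  list(transcripts = transcripts, planted_sites = planted_sites)
}

# Build a site sequence for one miRNA: reverse complement plus n_edits
# controlled edits outside the seed range. Returns the site and its
# designed penalty under `scheme`.
#' @noRd
edit_site <- function(mir, n_edits, scheme) {
  m <- nchar(mir)
  site <- revcomp(mir)
  score <- 0
  if (n_edits > 0L) {
    outside <- setdiff(seq_len(m), scheme$seed_start:scheme$seed_end)
    pos <- sample(outside, min(n_edits, length(outside)))
    mir_chars <- strsplit(mir, "", fixed = TRUE)[[1]]
    site_chars <- strsplit(site, "", fixed = TRUE)[[1]]
    for (i in pos) {
      p <- m - i + 1L  # site position pairing miRNA position i
      a <- mir_chars[i]
      wobble_partner <- switch(a, G = "T", "T" = "G", NA_character_)
      if (!is.na(wobble_partner) && runif(1) < 0.5) {
        site_chars[p] <- wobble_partner
        score <- score + scheme$gu_wobble
      } else {
        wc <- revcomp(a)
        forbidden <- c(wc, wobble_partner)
        site_chars[p] <- sample(setdiff(c("A", "C", "G", "T"), forbidden), 1)
        score <- score + scheme$mismatch
      }
    }
    site <- paste(site_chars, collapse = "")
  }
  list(site = site, score = score)
}

#' Simulate a four-stage count matrix from planted truth
#'
#' Counts are drawn feature-by-feature from a negative binomial with mean
#' `stage_mean x library-size factor` and the configured dispersion
#' (variance = mu + dispersion * mu^2); dispersion 0 gives the Poisson
#' limit. Library-size factors are drawn once per sample from
#' Uniform(0.85, 1.15).
#'
#' @param truth Truth list from [generate_transcriptome()] (needs
#'   `stage_means` and `features`).
#' @param config The [sim_config()] used to generate the truth.
#' @return A [count_matrix()] with `4 x replicates_per_stage` samples.
#' @export
simulate_counts <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1000L)
  stages <- config$stage_labels
  reps <- config$replicates_per_stage
  samples <- data.frame(
    sample = paste(rep(stages, each = reps), seq_len(reps), sep = "_"),
    stage = rep(stages, each = reps),
    replicate = rep(seq_len(reps), times = 4L),
    stringsAsFactors = FALSE
  )
  sf <- runif(nrow(samples), 0.85, 1.15)
  mu <- truth$stage_means[, samples$stage, drop = FALSE] %*% diag(sf)
  n <- length(mu)
  counts <- if (config$nb_dispersion > 0) {
    rnbinom(n, mu = mu, size = 1 / config$nb_dispersion)
  } else {
    stats::rpois(n, lambda = mu)
  }
  counts <- matrix(counts, nrow = nrow(mu),
                   dimnames = list(rownames(truth$stage_means), samples$sample))
  count_matrix(counts, truth$features, samples)
}

#' Generate a synthetic protein set with planted SPL domains
#'
#' Emits (i) true SPL proteins carrying a full-length (mutated) copy of the
#' SBP-domain consensus inside random flanks, some loci with 2-3 redundant
#' isoforms differing by terminal extensions; (ii) decoys whose domain copy
#' is truncated by the sequence end (they pass the homology screen but must
#' fail the full-length domain criterion); (iii) decoys with no domain at
#' all; and a small homology reference set. The truth table labels every
#' record.
#'
#' @param config A [sim_config()] (only the seed is used, plus fixed
#'   desk-scale set sizes).
#' @param n_spl_loci,n_truncated,n_random Set sizes (defaults 12 / 4 / 8).
#' @param domain_mutation_rate,flank_mutation_rate Per-residue substitution
#'   rates applied to the domain and flank portions of true SPL proteins
#'   (defaults 0.05 and 0.12: the DNA-binding domain is more conserved than
#'   the flanks, and the overall identity to the references stays
#'   comfortably above the 80% screen threshold).
#' @return List with `proteins` (`id`, `locus`, `sequence`), `references`
#'   and `truth` (`id`, `locus`, `class`, `is_spl`, `is_canonical`).
#' @export
generate_protein_set <- function(config, n_spl_loci = 12L, n_truncated = 4L,
                                 n_random = 8L, domain_mutation_rate = 0.05,
                                 flank_mutation_rate = 0.12) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2000L)
  profile <- sbp_profile()
  consensus <- profile$consensus
  W <- profile$width

  # Two reference homologs: same domain, distinct flanks. True SPL proteins
  # are derived from a reference by point substitution, so they share flank
  # homology with it -- as real family members from related species do.
  ref_flank_n <- c(50L, 65L)
  ref_flank_c <- c(70L, 40L)
  references <- data.frame(
    id = c("refSPL_1", "refSPL_2"),
    sequence = c(
      paste0(random_sequence(ref_flank_n[1], AA_ALPHABET), consensus,
             random_sequence(ref_flank_c[1], AA_ALPHABET)),
      paste0(random_sequence(ref_flank_n[2], AA_ALPHABET), consensus,
             random_sequence(ref_flank_c[2], AA_ALPHABET))
    ),
    stringsAsFactors = FALSE
  )

  proteins <- list()
  truth <- list()
  add <- function(id, locus, seq, class, is_spl, canonical) {
    proteins[[length(proteins) + 1L]] <<- data.frame(
      id = id, locus = locus, sequence = seq, stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <<- data.frame(
      id = id, locus = locus, class = class, is_spl = is_spl,
      is_canonical = canonical, stringsAsFactors = FALSE)
  }

  derive_spl <- function() {
    k <- sample(1:2, 1)
    fn <- mutate_protein(substr(references$sequence[k], 1L, ref_flank_n[k]),
                         flank_mutation_rate)
    dom <- mutate_protein(consensus, domain_mutation_rate)
    fc <- mutate_protein(substr(references$sequence[k],
                                ref_flank_n[k] + W + 1L,
                                nchar(references$sequence[k])),
                         flank_mutation_rate)
    paste0(fn, dom, fc)
  }

  for (i in seq_len(n_spl_loci)) {
    locus <- sprintf("pLOC_%03d", i)
    core <- derive_spl()
    n_iso <- if (i %% 3 == 0) sample(2:3, 1) else 1L
    exts <- c(0L, sample(10:40, n_iso - 1L))
    lens <- nchar(core) + exts
    # the longest isoform is canonical; extensions make lengths distinct
    for (k in seq_len(n_iso)) {
      seq_k <- if (exts[k] == 0L) core else
        paste0(core, random_sequence(exts[k], AA_ALPHABET))
      add(sprintf("%s.p%d", locus, k), locus, seq_k, "spl", TRUE,
          lens[k] == max(lens))
    }
  }
  for (i in seq_len(n_truncated)) {
    # N-flank plus a domain copy cut short by the sequence end: passes the
    # homology screen but can never yield a full-length domain window
    locus <- sprintf("pTRUNC_%02d", i)
    cut <- W - sample(5:15, 1)
    seq_i <- paste0(
      random_sequence(sample(20:50, 1), AA_ALPHABET),
      mutate_protein(substr(consensus, 1L, cut), domain_mutation_rate)
    )
    add(sprintf("%s.p1", locus), locus, seq_i, "truncated_domain", FALSE, FALSE)
  }
  for (i in seq_len(n_random)) {
    locus <- sprintf("pRAND_%02d", i)
    add(sprintf("%s.p1", locus), locus,
        random_sequence(sample(150:300, 1), AA_ALPHABET),
        "no_domain", FALSE, FALSE)
  }

  list(proteins = do.call(rbind, proteins),
       references = references,
       truth = do.call(rbind, truth))
}

#' @noRd
mutate_protein <- function(seq, rate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(AA_ALPHABET, chars[i]), 1)
  }
  paste(chars, collapse = "")
}

#' Write synthetic fixtures to disk
#'
#' Writes per-biotype FASTA files (circRNA back-splice position encoded in
#' the description as `junction=<int>`), the TSV count table, a JSON truth
#' file and a manifest listing the seed and an MD5 checksum for every file
#' written.
#'
#' @param dir Output directory (created if needed).
#' @param transcripts Transcript table from [generate_transcriptome()].
#' @param counts A [count_matrix()].
#' @param truth Truth list.
#' @param proteins Optional protein set from [generate_protein_set()].
#' @param seed Seed recorded in the manifest.
#' @return The manifest (invisibly), also written as `manifest.json`.
#' @export
write_fixtures <- function(dir, transcripts, counts, truth, proteins = NULL,
                           seed = NA_integer_) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create directory '%s'", dir), call. = FALSE)
  }
  files <- character(0)
  for (bt in unique(transcripts$biotype)) {
    sub <- transcripts[transcripts$biotype == bt, , drop = FALSE]
    x <- Biostrings::DNAStringSet(sub$sequence)
    names(x) <- ifelse(is.na(sub$junction), sub$id,
                       paste0(sub$id, " junction=", sub$junction))
    path <- file.path(dir, paste0(tolower(bt), ".fasta"))
    Biostrings::writeXStringSet(x, path)
    files <- c(files, path)
  }
  counts_path <- file.path(dir, "counts.tsv")
  write_count_table(counts, counts_path)
  files <- c(files, counts_path)

  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(list(
    planted_sites = truth$planted_sites,
    planted_triads = truth$planted_triads,
    isoform_groups = truth$isoform_groups,
    stage_means = as.data.frame(truth$stage_means)
  ), truth_path, digits = NA, auto_unbox = FALSE, pretty = TRUE)
  files <- c(files, truth_path)

  if (!is.null(proteins)) {
    pa <- Biostrings::AAStringSet(setNames(proteins$proteins$sequence,
                                           proteins$proteins$id))
    pr <- Biostrings::AAStringSet(setNames(proteins$references$sequence,
                                           proteins$references$id))
    pp <- file.path(dir, "proteins.fasta")
    rp <- file.path(dir, "references.fasta")
    Biostrings::writeXStringSet(pa, pp)
    Biostrings::writeXStringSet(pr, rp)
    files <- c(files, pp, rp)
  }

  manifest <- list(seed = seed, files = as.list(md5_of_files(files)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Write / read a count table as TSV
#'
#' Columns: `feature_id`, `biotype`, `length`, then one column per sample
#' named `<stage>_<replicate>`.
#'
#' @param cm A [count_matrix()].
#' @param path File path.
#' @return `write_count_table` invisibly returns `path`;
#'   `read_count_table` returns a [count_matrix()].
#' @export
write_count_table <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  tab <- cbind(
    data.frame(feature_id = cm$features$id, biotype = cm$features$biotype,
               length = cm$features$length, stringsAsFactors = FALSE),
    as.data.frame(cm$counts, check.names = FALSE)
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  meta <- c("feature_id", "biotype", "length")
  sample_cols <- setdiff(names(tab), meta)
  parts <- strsplit(sample_cols, "_", fixed = TRUE)
  samples <- data.frame(
    sample = sample_cols,
    stage = vapply(parts, function(p) paste(p[-length(p)], collapse = "_"),
                   character(1)),
    replicate = as.integer(vapply(parts, function(p) p[length(p)],
                                  character(1))),
    stringsAsFactors = FALSE
  )
  counts <- as.matrix(tab[, sample_cols, drop = FALSE])
  features <- data.frame(id = tab$feature_id, biotype = tab$biotype,
                         length = tab$length, stringsAsFactors = FALSE)
  count_matrix(counts, features, samples)
}

#' Read a transcript FASTA written by [write_fixtures()]
#'
#' @param path FASTA path.
#' @param biotype Biotype label to attach.
#' @return `data.frame` with `id`, `biotype`, `length`, `junction`,
#'   `sequence`.
#' @export
read_transcripts_fasta <- function(path, biotype) {
  x <- Biostrings::readDNAStringSet(path)
  desc <- names(x)
  id <- sub("\\s.*$", "", desc)
  junction <- ifelse(grepl("junction=", desc),
                     as.integer(sub(".*junction=(\\d+).*", "\\1", desc)),
                     NA_integer_)
  data.frame(id = id, biotype = biotype, length = Biostrings::width(x),
             junction = junction, sequence = as.character(x),
             stringsAsFactors = FALSE, row.names = NULL)
}
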