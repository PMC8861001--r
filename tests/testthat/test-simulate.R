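small_cfg <- function(seed = 1L, ...) {
  args <- list(n_mrna = 40, n_lncrna = 15, n_circrna = 6, n_triads = 5,
               n_mirna_background = 30, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

test_that("the generator is deterministic for a fixed config and seed", {
  cfg <- small_cfg(seed = 71)
  a <- generate_transcriptome(cfg)
  b <- generate_transcriptome(cfg)
  expect_identical(a, b)
  expect_identical(simulate_counts(a$truth, cfg), simulate_counts(b$truth, cfg))
  expect_identical(generate_protein_set(cfg), generate_protein_set(cfg))
})

test_that("the miR156 family has the configured size and 21-nt members", {
  sim <- generate_transcriptome(small_cfg(seed = 72))
  fam <- sim$transcripts[grepl("^peu-miR156", sim$transcripts$id), ]
  expect_equal(nrow(fam), 12L)
  expect_true(all(nchar(fam$sequence) == 21L))
  expect_true(all(fam$biotype == "miRNA"))
})

test_that("no sites are planted when mre_fraction is 0 and no triads exist", {
  cfg <- small_cfg(seed = 73, mre_fraction = 0, n_triads = 0)
  sim <- generate_transcriptome(cfg)
  expect_equal(nrow(sim$truth$planted_sites), 0L)
  expect_equal(nrow(sim$truth$planted_triads), 0L)
})

test_that("invalid configurations are rejected naming the offending field", {
  expect_error(sim_config(stage_labels = c("Li", "La")), "stage_labels")
  expect_error(sim_config(n_mrna = 0), "n_mrna")
  expect_error(sim_config(mre_fraction = 1.5), "mre_fraction")
  expect_error(sim_config(nb_dispersion = -1), "nb_dispersion")
  expect_error(sim_config(replicates_per_stage = 0), "replicates_per_stage")
})

test_that("planted truth is internally consistent", {
  sim <- generate_transcriptome(small_cfg(seed = 74))
  truth <- sim$truth
  # every triad's ceRNA and mRNA carry a site for the triad's miRNA
  for (i in seq_len(nrow(truth$planted_triads))) {
    tri <- truth$planted_triads[i, ]
    ps <- truth$planted_sites
    expect_true(any(ps$target_id == tri$cerna_id & ps$mirna_id == tri$mirna_id))
    expect_true(any(ps$target_id == tri$mrna_id & ps$mirna_id == tri$mirna_id))
  }
  # designed scores stay below the default site-call cutoff
  expect_true(all(truth$planted_sites$score <= penalty_scheme()$cutoff))
  # miR156 means strictly decreasing, triad mRNA means strictly increasing
  fam <- grep("^peu-miR156", rownames(truth$stage_means), value = TRUE)
  for (f in fam) expect_true(all(diff(truth$stage_means[f, ]) < 0))
  for (mr in truth$planted_triads$mrna_id) {
    expect_true(all(diff(truth$stage_means[mr, ]) > 0))
  }
  # noise-free profiles of triad partners are perfectly correlated
  for (i in seq_len(nrow(truth$planted_triads))) {
    tri <- truth$planted_triads[i, ]
    expect_equal(cor(truth$stage_means[tri$cerna_id, ],
                     truth$stage_means[tri$mrna_id, ]), 1)
  }
})

test_that("planted sites are recovered by the target scanner", {
  sim <- generate_transcriptome(small_cfg(seed = 75))
  tr <- sim$transcripts
  seqs <- setNames(tr$sequence, tr$id)
  mirs <- setNames(tr$sequence[tr$biotype == "miRNA"],
                   tr$id[tr$biotype == "miRNA"])
  ps <- sim$truth$planted_sites
  lin <- ps[!ps$spans_junction, ]
  for (i in seq_len(nrow(lin))) {
    sites <- find_sites(mirs[[lin$mirna_id[i]]], seqs[[lin$target_id[i]]])
    j <- which(sites$start == lin$start[i] & sites$end == lin$end[i])
    expect_length(j, 1L)
    expect_equal(sites$score[j], lin$score[i])
  }
})

test_that("count matrix has the expected dimensions and NB noise", {
  cfg <- small_cfg(seed = 76)
  sim <- generate_transcriptome(cfg)
  cm <- simulate_counts(sim$truth, cfg)
  expect_equal(dim(cm$counts),
               c(nrow(sim$truth$features), 4L * cfg$replicates_per_stage))
  expect_true(all(cm$counts >= 0))
  expect_true(all(cm$library_size >= colSums(cm$counts) - 1e-9))
})

test_that("the dispersion-to-zero limit approaches Poisson noise", {
  # Monte Carlo: 10,000 draws of a high-mean feature
  cfg <- small_cfg(seed = 77, nb_dispersion = 1e-8)
  set.seed(1)
  mu <- 500
  draws <- rnbinom(10000, mu = mu, size = 1 / cfg$nb_dispersion)
  expect_equal(var(draws) / mean(draws), 1, tolerance = 0.05)
  # and a clearly super-Poisson case for contrast
  draws2 <- rnbinom(10000, mu = mu, size = 1 / 0.1)
  expect_gt(var(draws2) / mean(draws2), 5)
})

test_that("empirical miR156 stage means decrease across the series", {
  cfg <- small_cfg(seed = 78, effect_size = 2)
  sim <- generate_transcriptome(cfg)
  fam <- grep("^peu-miR156", rownames(sim$truth$stage_means), value = TRUE)[1:3]
  acc <- matrix(0, 3, 4)
  for (r in 1:50) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + r
    cm <- simulate_counts(sim$truth, cfg_r)
    acc <- acc + t(apply(cm$counts[fam, ], 1, function(x) {
      tapply(x, cm$samples$stage, mean)[cfg$stage_labels]
    }))
  }
  emp <- acc / 50
  for (i in 1:3) expect_true(all(diff(emp[i, ]) < 0))
})

test_that("fixtures round-trip through disk with a faithful manifest", {
  cfg <- small_cfg(seed = 79)
  sim <- generate_transcriptome(cfg)
  cm <- simulate_counts(sim$truth, cfg)
  prot <- generate_protein_set(cfg)
  dir <- file.path(tempfile(), "fx")
  man <- write_fixtures(dir, sim$transcripts, cm, sim$truth, prot,
                        seed = cfg$seed)
  # sequences round-trip, including the circRNA junction annotation
  circ <- read_transcripts_fasta(file.path(dir, "circrna.fasta"), "circRNA")
  orig <- sim$transcripts[sim$transcripts$biotype == "circRNA", ]
  expect_equal(circ$id, orig$id)
  expect_equal(circ$sequence, orig$sequence)
  expect_equal(circ$junction, orig$junction)
  # counts round-trip
  cm2 <- read_count_table(file.path(dir, "counts.tsv"))
  expect_equal(cm2$counts, cm$counts)
  expect_equal(cm2$samples, cm$samples)
  # the truth file enumerates exactly the planted triads
  truth_back <- jsonlite::read_json(file.path(dir, "truth.json"),
                                    simplifyVector = TRUE)
  expect_equal(truth_back$planted_triads[order(truth_back$planted_triads$cerna_id), ],
               sim$truth$planted_triads[order(sim$truth$planted_triads$cerna_id), ],
               ignore_attr = TRUE)
  # manifest checksums change iff file content changes
  expect_setequal(names(man$files), basename(list.files(dir))[
    basename(list.files(dir)) != "manifest.json"])
  man2 <- jsonlite::read_json(file.path(dir, "manifest.json"),
                              simplifyVector = TRUE)
  expect_equal(unlist(man2$files), unlist(man$files))
  writeLines("tampered", file.path(dir, "counts.tsv"))
  tampered <- unname(tools::md5sum(file.path(dir, "counts.tsv")))
  expect_false(tampered == man$files[["counts.tsv"]])
  # rewriting the same content restores the same checksums
  man3 <- write_fixtures(dir, sim$transcripts,
                         cm, sim$truth, prot, seed = cfg$seed)
  expect_equal(unname(unlist(man3$files)), unname(unlist(man$files)))
})

test_that("protein truth labels match the construction", {
  prot <- generate_protein_set(small_cfg(seed = 80))
  truth <- prot$truth
  expect_true(all(!truth$is_spl[truth$class == "truncated_domain"]))
  expect_true(all(!truth$is_spl[truth$class == "no_domain"]))
  # exactly one canonical per SPL locus, and it is the longest isoform
  spl <- merge(truth[truth$is_spl, ], prot$proteins, by = c("id", "locus"))
  for (loc in unique(spl$locus)) {
    grp <- spl[spl$locus == loc, ]
    expect_equal(sum(grp$is_canonical), 1L)
    expect_equal(grp$id[grp$is_canonical],
                 grp$id[which.max(nchar(grp$sequence))])
  }
})
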