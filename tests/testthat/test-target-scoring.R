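# Helper: build a target window that pairs a given miRNA perfectly, then
# introduce controlled defects opposite chosen miRNA positions.
perfect_site <- function(mirna) revcomp_rna(mirna)

defect_at <- function(site, mirna, pos, type = c("mismatch", "wobble")) {
  type <- match.arg(type)
  m <- nchar(mirna)
  p <- m - pos + 1L  # site position pairing miRNA position `pos`
  mir_base <- substr(chartr("U", "T", mirna), pos, pos)
  if (type == "wobble") {
    new <- switch(mir_base, G = "T", "T" = "G",
                  stop("no wobble partner for ", mir_base))
  } else {
    wc <- revcomp_rna(mir_base)
    wobble <- switch(mir_base, G = "T", "T" = "G", NA_character_)
    new <- setdiff(c("A", "C", "G", "T"), c(wc, wobble))[1]
  }
  substr(site, p, p) <- new
  site
}

test_that("a perfect reverse-complement duplex scores 0", {
  set.seed(51)
  for (i in 1:5) {
    mir <- random_dna(21)
    d <- duplex_penalty(mir, perfect_site(mir))
    expect_equal(d$score, 0)
    expect_false(grepl("-", d$mirna_aligned))
  }
})

test_that("penalties follow position, type and seed doubling", {
  set.seed(52)
  mir <- "TGACAGAAGAGAGTGAGCACA"  # miR156-like, 21 nt
  s <- penalty_scheme()
  # mismatch opposite position 16 (outside seed): 1.0
  site16 <- defect_at(perfect_site(mir), mir, 16, "mismatch")
  expect_equal(duplex_penalty(mir, site16, s)$score, 1.0)
  # same defect opposite position 5 (in seed): doubled
  site5 <- defect_at(perfect_site(mir), mir, 5, "mismatch")
  expect_equal(duplex_penalty(mir, site5, s)$score, 2.0)
  # G:U wobble at position 3 (seed): 0.5 x 2
  wpos <- which(strsplit(mir, "")[[1]] %in% c("G", "T"))
  wpos3 <- wpos[wpos >= s$seed_start & wpos <= s$seed_end][1]
  sitew <- defect_at(perfect_site(mir), mir, wpos3, "wobble")
  expect_equal(duplex_penalty(mir, sitew, s)$score, 1.0)
  # wobble outside the seed: 0.5
  wout <- wpos[wpos > s$seed_end | wpos < s$seed_start][1]
  sitewo <- defect_at(perfect_site(mir), mir, wout, "wobble")
  expect_equal(duplex_penalty(mir, sitewo, s)$score, 0.5)
})

test_that("duplex DP equals the gap-placement enumeration oracle", {
  set.seed(53)
  s <- penalty_scheme()
  for (i in 1:60) {
    mir <- random_dna(21)
    len <- sample(20:22, 1)
    win <- random_dna(len)
    expect_equal(duplex_penalty(mir, win, s)$score,
                 oracle_duplex_penalty(mir, win, s),
                 info = paste(mir, win))
  }
})

test_that("scores are invariant to T/U representation", {
  set.seed(54)
  mir <- random_dna(21)
  win <- random_dna(21)
  mir_u <- chartr("T", "U", mir)
  win_u <- chartr("T", "U", win)
  expect_equal(duplex_penalty(mir, win)$score,
               duplex_penalty(mir_u, win_u)$score)
})

test_that("window length bounds are enforced", {
  mir <- random_dna(21)
  expect_error(duplex_penalty(mir, random_dna(25)), "window length")
  expect_error(duplex_penalty(mir, random_dna(18)), "window length")
})

test_that("find_sites recovers a planted perfect site at its coordinates", {
  set.seed(55)
  mir <- random_dna(21)
  flank1 <- random_dna(100)
  flank2 <- random_dna(80)
  tr <- paste0(flank1, perfect_site(mir), flank2)
  sites <- find_sites(mir, tr, mirna_id = "m", target_id = "t")
  exact <- sites[sites$score == 0, ]
  expect_equal(nrow(exact), 1L)
  expect_equal(exact$start, 101L)
  expect_equal(exact$end, 121L)
})

test_that("find_sites equals exhaustive window enumeration", {
  set.seed(56)
  s <- penalty_scheme(cutoff = Inf)
  for (i in 1:8) {
    mir <- random_dna(21)
    tr <- random_dna(45)
    mine <- find_sites(mir, tr, s, keep_overlaps = TRUE)
    oracle <- oracle_all_windows(mir, tr, s)
    key <- function(d) d[order(d$start, d$end), c("start", "end", "score")]
    expect_equal(key(mine), key(oracle), ignore_attr = TRUE)
  }
  # at the default cutoff, random transcripts contain no sites, matching
  # the enumeration
  s3 <- penalty_scheme()
  for (i in 1:5) {
    mir <- random_dna(21)
    tr <- random_dna(300)
    expect_equal(nrow(find_sites(mir, tr, s3)), 0L)
    oracle <- oracle_all_windows(mir, tr, s3)
    expect_equal(sum(oracle$score <= s3$cutoff), 0L)
  }
})

test_that("two disjoint planted sites are returned sorted by start", {
  set.seed(57)
  mir <- random_dna(21)
  tr <- paste0(random_dna(30), perfect_site(mir), random_dna(40),
               perfect_site(mir), random_dna(30))
  sites <- find_sites(mir, tr)
  perf <- sites[sites$score == 0, ]
  expect_equal(nrow(perf), 2L)
  expect_equal(perf$start, c(31L, 92L))
  expect_true(!is.unsorted(sites$start))
})

test_that("lowering the cutoff never adds sites", {
  set.seed(58)
  mir <- random_dna(21)
  tr <- paste0(random_dna(50), defect_at(perfect_site(mir), mir, 16),
               random_dna(50))
  for (cut in c(3, 2, 1, 0.5)) {
    loose <- find_sites(mir, tr, penalty_scheme(cutoff = cut))
    tight <- find_sites(mir, tr, penalty_scheme(cutoff = cut - 0.5))
    expect_lte(nrow(tight), nrow(loose))
    if (nrow(tight) > 0) {
      expect_true(all(paste(tight$start, tight$end) %in%
                        paste(loose$start, loose$end)))
    }
  }
})

test_that("circRNA junction pseudo-sequence follows its definition", {
  circ <- "ACGTTGCA"  # junction closes H -> A, i.e. position 8 -> 1
  pj <- circ_junction_sequence(circ, flank = 3)
  expect_equal(pj$sequence, paste0("GCA", "ACG"))
  expect_equal(pj$map, c(6L, 7L, 8L, 1L, 2L, 3L))
  # coordinate map is a bijection onto valid circular positions
  expect_true(all(pj$map >= 1 & pj$map <= 8))
  expect_equal(anyDuplicated(pj$map), 0L)
  expect_error(circ_junction_sequence(circ, flank = 8), "flank")
})

test_that("junction-spanning sites are found on the pseudo-sequence only", {
  set.seed(59)
  mir <- random_dna(21)
  site <- perfect_site(mir)
  L <- 200L
  k <- 8L  # split: last 8 nt of the circle, then the first 13
  circ <- random_dna(L)
  substr(circ, L - k + 1L, L) <- substr(site, 1L, k)
  substr(circ, 1L, 21L - k) <- substr(site, k + 1L, 21L)
  # not present on the linear sequence
  expect_equal(nrow(find_sites(mir, circ)[find_sites(mir, circ)$score == 0, ]),
               0L)
  # found via the junction pseudo-sequence with circular coordinates
  transcripts <- data.frame(id = "c1", biotype = "circRNA", sequence = circ)
  mirnas <- data.frame(id = "m1", sequence = mir)
  tab <- predict_targetome(mirnas, transcripts)
  hit <- tab[tab$score == 0, ]
  expect_equal(nrow(hit), 1L)
  expect_true(hit$spans_junction)
  expect_equal(hit$start, L - k + 1L)
  expect_equal(hit$end, 21L - k)
})

test_that("the targetome has no duplicate (miRNA, target, start) records", {
  set.seed(60)
  cfg <- sim_config(n_mrna = 30, n_lncrna = 10, n_circrna = 6, n_triads = 4,
                    seed = 61)
  sim <- generate_transcriptome(cfg)
  tr <- sim$transcripts
  tab <- predict_targetome(tr[tr$biotype == "miRNA", c("id", "sequence")],
                           tr[tr$biotype != "miRNA", ])
  expect_equal(anyDuplicated(tab[, c("mirna_id", "target_id", "start")]), 0L)
  # empty miRNA set gives an empty table
  empty <- predict_targetome(tr[0, c("id", "sequence")],
                             tr[tr$biotype != "miRNA", ])
  expect_equal(nrow(empty), 0L)
})
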