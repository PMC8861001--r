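mre_row <- function(mirna, target, biotype) {
  data.frame(mirna_id = mirna, target_id = target, biotype = biotype,
             start = 1L, end = 21L, score = 0, spans_junction = FALSE)
}

test_that("shared-MRE pairs enumerate ceRNA x mRNA combinations", {
  tab <- rbind(mre_row("miR156a", "lnc1", "lncRNA"),
               mre_row("miR156a", "lnc2", "lncRNA"),
               mre_row("miR156a", "m1", "mRNA"),
               mre_row("miR156a", "m2", "mRNA"))
  pairs <- shared_mre_pairs(tab)
  expect_equal(nrow(pairs), 4L)
  expect_true(all(pairs$n_shared == 1L))

  # disjoint miRNA sets give no pair
  tab2 <- rbind(mre_row("miR156a", "lnc1", "lncRNA"),
                mre_row("miR156b", "m1", "mRNA"))
  expect_equal(nrow(shared_mre_pairs(tab2)), 0L)
  expect_equal(nrow(shared_mre_pairs(tab2[0, ])), 0L)

  # shared sets are intersections
  tab3 <- rbind(mre_row("miR156a", "circ1", "circRNA"),
                mre_row("miR156b", "circ1", "circRNA"),
                mre_row("miR156b", "m1", "mRNA"),
                mre_row("miR156c", "m1", "mRNA"))
  p3 <- shared_mre_pairs(tab3)
  expect_equal(p3$shared_mirnas[[1]], "miR156b")
})

test_that("correlation filter keeps co-varying pairs only", {
  pairs <- shared_mre_pairs(rbind(mre_row("miR156a", "lnc1", "lncRNA"),
                                  mre_row("miR156a", "lnc2", "lncRNA"),
                                  mre_row("miR156a", "m1", "mRNA")))
  expr <- rbind(lnc1 = c(1, 2, 4, 8), lnc2 = c(8, 4, 2, 1),
                m1 = c(2, 4, 8, 16))
  out <- correlation_filter(pairs, expr, r_min = 0.8)
  expect_equal(out$cerna_id, "lnc1")
  expect_equal(out$r, 1)
  expect_error(correlation_filter(pairs, expr, r_min = 0), "r_min")

  # monotonicity: a stricter threshold keeps a subset
  set.seed(91)
  expr_r <- matrix(runif(40), 10, 4,
                   dimnames = list(c(paste0("lnc", 1:5), paste0("m", 1:5)),
                                   NULL))
  tab <- do.call(rbind, lapply(1:5, function(i)
    rbind(mre_row("miR156a", paste0("lnc", i), "lncRNA"),
          mre_row("miR156a", paste0("m", i), "mRNA"))))
  pr <- shared_mre_pairs(tab)
  strict <- correlation_filter(pr, expr_r, r_min = 0.8)
  loose <- correlation_filter(pr, expr_r, r_min = 0.5)
  expect_true(all(paste(strict$cerna_id, strict$mrna_id) %in%
                    paste(loose$cerna_id, loose$mrna_id)))
})

make_contrast <- function(feature, lfc, contrast = "Bo/Li") {
  data.frame(feature = feature, contrast = contrast, log2fc = lfc,
             direction = ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "flat")),
             fold_bin = fold_bin(lfc))
}

test_that("triads require same-direction pair DE and opposite miRNA DE", {
  pairs <- correlation_filter(
    shared_mre_pairs(rbind(mre_row("miR156a", "lnc1", "lncRNA"),
                           mre_row("miR156b", "lnc1", "lncRNA"),
                           mre_row("miR156a", "m1", "mRNA"),
                           mre_row("miR156b", "m1", "mRNA"))),
    rbind(lnc1 = c(1, 2, 4, 8), m1 = c(2, 4, 8, 16)), r_min = 0.8)
  ctr <- make_contrast(c("lnc1", "m1", "miR156a", "miR156b"),
                       c(2, 1.5, -1.2, -3))
  tri <- assemble_triads(pairs, ctr)
  expect_equal(nrow(tri), 2L)  # both shared miRNAs opposite-DE
  expect_setequal(tri$mirna_id, c("miR156a", "miR156b"))
  expect_equal(unique(tri$cerna_bin), "Up B")

  # miRNA moving with the pair blocks the triad
  ctr_up <- make_contrast(c("lnc1", "m1", "miR156a", "miR156b"),
                          c(2, 1.5, 1.2, -3))
  tri_up <- assemble_triads(pairs, ctr_up)
  expect_equal(tri_up$mirna_id, "miR156b")

  # relaxing the miRNA gate restores both
  tri_relaxed <- assemble_triads(pairs, ctr_up, require_mirna_de = FALSE)
  expect_equal(nrow(tri_relaxed), 2L)

  # opposite pair directions block the triad entirely
  ctr_mixed <- make_contrast(c("lnc1", "m1", "miR156a"), c(2, -1.5, -1.2))
  expect_equal(nrow(assemble_triads(pairs, ctr_mixed)), 0L)
})

test_that("every emitted triad satisfies all three gates (re-validation)", {
  ch <- default_chain()
  tri <- ch$triads
  expect_gt(nrow(tri), 0)
  for (i in seq_len(nrow(tri))) {
    pr <- ch$corr[ch$corr$cerna_id == tri$cerna_id[i] &
                    ch$corr$mrna_id == tri$mrna_id[i], ]
    expect_equal(nrow(pr), 1L)
    expect_true(tri$mirna_id[i] %in% pr$shared_mirnas[[1]])
    expect_gte(pr$r, 0.8)
    expect_gte(abs(tri$cerna_log2fc[i]), 1)
    expect_gte(abs(tri$mrna_log2fc[i]), 1)
    expect_gte(abs(tri$mirna_log2fc[i]), 1)
    expect_equal(sign(tri$cerna_log2fc[i]), sign(tri$mrna_log2fc[i]))
    expect_equal(sign(tri$mirna_log2fc[i]), -sign(tri$mrna_log2fc[i]))
  }
})

test_that("network export writes consistent SIF, node table and GraphML", {
  tri <- data.frame(cerna_id = "lnc1", mirna_id = "miR156a", mrna_id = "m1",
                    contrast = "Bo/Li", cerna_log2fc = 2, mirna_log2fc = -2,
                    mrna_log2fc = 1.5, cerna_bin = "Up B", mirna_bin = "Down B",
                    mrna_bin = "Up B", r = 0.99)
  dir <- tempfile()
  paths <- export_network(tri, dir, "net1")
  sif <- readLines(paths[["sif"]])
  expect_length(sif, 2L)
  expect_equal(sif[1], "lnc1\tcerna_mirna\tmiR156a")
  nodes <- read.delim(paths[["nodes"]])
  expect_equal(nrow(nodes), 3L)
  expect_equal(nodes$bin[nodes$node == "m1"], "Up B")
  g <- igraph::read_graph(paths[["graphml"]], format = "graphml")
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
})

test_that("node fold-bin labels agree with the contrast computation", {
  ch <- default_chain()
  tri <- ch$triads[ch$triads$contrast == "Bo/Li", ]
  dir <- tempfile()
  paths <- export_network(tri, dir, "boLi")
  nodes <- read.delim(paths[["nodes"]])
  ctr <- ch$contrasts[ch$contrasts$contrast == "Bo/Li", ]
  for (i in seq_len(nrow(nodes))) {
    row <- ctr[ctr$feature == nodes$node[i], ]
    lab <- paste(ifelse(row$direction == "up", "Up", "Down"), row$fold_bin)
    expect_equal(nodes$bin[i], lab)
  }
})

test_that("recovery evaluation handles perfect, empty and shuffled input", {
  truth <- data.frame(cerna_id = c("l1", "l2"), mirna_id = c("a", "b"),
                      mrna_id = c("m1", "m2"))
  tri <- data.frame(cerna_id = truth$cerna_id, mirna_id = truth$mirna_id,
                    mrna_id = truth$mrna_id, contrast = "Bo/Li")
  r <- evaluate_recovery(tri, truth)
  expect_equal(r$precision, 1)
  expect_equal(r$recall, 1)

  r0 <- evaluate_recovery(tri[0, ], truth)
  expect_equal(r0$recall, 0)
  expect_equal(r0$precision, 0)
  expect_false(r0$precision_defined)

  shuffled <- tri
  shuffled$mrna_id <- rev(shuffled$mrna_id)
  rs <- evaluate_recovery(shuffled, truth)
  expect_equal(rs$recall, 0)
})
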