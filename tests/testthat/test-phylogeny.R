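test_that("p-distances count differing columns with pairwise gap deletion", {
  aln <- c(a = "AAAA", b = "AAAT", c = "AAAA")
  d <- p_distance_matrix(aln)
  expect_equal(d["a", "b"], 0.25)
  expect_equal(d["a", "c"], 0)
  expect_equal(d, t(d))

  # gap columns are excluded pairwise
  d2 <- p_distance_matrix(c(a = "A-AA", b = "ATAA", c = "TTAA"))
  expect_equal(d2["a", "b"], 0)       # 3 comparable columns, all equal
  expect_equal(d2["b", "c"], 0.25)

  expect_error(p_distance_matrix(c(a = "AAA", b = "AAAA", c = "AAAA")),
               "ragged")
  expect_error(p_distance_matrix(c(a = "A---", b = "-TTT", c = "ATTT")),
               "no comparable columns between 'a' and 'b'")
})

test_that("NJ recovers additive 4-taxon trees exactly", {
  # tree ((A:1,B:2):1,(C:3,D:1)) -> additive distances
  D <- matrix(c(0, 3, 5, 3,
                3, 0, 6, 4,
                5, 6, 0, 4,
                3, 4, 4, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tree <- neighbor_joining(D)
  expect_s3_class(tree, "phylo")
  # path lengths reproduce the input distances exactly
  patristic <- stats::cophenetic(tree)[rownames(D), colnames(D)]
  expect_equal(patristic, D, tolerance = 1e-10)
  # AB|CD is the single internal split
  sp <- deepest_split(tree)
  expect_true(setequal(sp$clade1, c("A", "B")) ||
                setequal(sp$clade1, c("C", "D")))
})

test_that("3-taxon branch lengths solve the three-point formulas", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- neighbor_joining(D)
  len <- setNames(tree$edge.length[match(seq_len(3), tree$edge[, 2])],
                  tree$tip.label)
  expect_equal(unname(len["A"]), (3 + 4 - 5) / 2)  # = 1
  expect_equal(unname(len["B"]), (3 + 5 - 4) / 2)  # = 2
  expect_equal(unname(len["C"]), (4 + 5 - 3) / 2)  # = 3
})

test_that("NJ on random additive matrices matches the generating tree", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(4:5, 1)
    gen <- ape::rtree(n, rooted = FALSE)
    gen$edge.length <- runif(nrow(gen$edge), 0.2, 2)
    D <- stats::cophenetic(gen)
    tree <- neighbor_joining(D)
    expect_equal(as.numeric(ape::dist.topo(tree, gen)), 0)
    expect_equal(stats::cophenetic(tree)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
  }
})

test_that("bootstrap supports are 100 when every column induces one split", {
  aln <- c(A = strrep("A", 20), B = strrep("A", 20),
           C = strrep("R", 20), D = strrep("R", 20))
  # add distinguishing columns? no: identical rows within groups keep the
  # AB|CD split in every resample
  tree <- bootstrap_supports(aln, n_reps = 100, seed = 3)
  sup <- suppressWarnings(as.numeric(tree$node.label))
  expect_true(all(sup[!is.na(sup)] == 100))
})

test_that("bootstrap supports are reproducible and bounded", {
  set.seed(32)
  aln <- setNames(vapply(1:5, function(i) random_protein(30), character(1)),
                  LETTERS[1:5])
  t1 <- bootstrap_supports(aln, n_reps = 50, seed = 9)
  t2 <- bootstrap_supports(aln, n_reps = 50, seed = 9)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  sup <- suppressWarnings(as.numeric(t1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
})

test_that("a dominant split gets support above 95", {
  # 30 columns support AB|CDE, 2 discordant columns support AC, plus a few
  # taxon-specific columns for resolution
  block <- function(res) {
    c(A = res[1], B = res[2], C = res[3], D = res[4], E = res[5])
  }
  concordant <- replicate(30, block(c("A", "A", "R", "R", "R")))
  discordant <- replicate(2, block(c("W", "K", "W", "K", "K")))
  ident <- cbind(block(c("C", "D", "E", "F", "G")),
                 block(c("D", "E", "F", "G", "H")),
                 block(c("E", "F", "G", "H", "I")))
  m <- cbind(concordant, discordant, ident)
  aln <- setNames(apply(m, 1, paste, collapse = ""), rownames(m))
  tree <- bootstrap_supports(aln, n_reps = 200, seed = 4)
  # locate the AB|CDE bipartition's support
  sup <- support_of_split(tree, c("A", "B"))
  expect_gt(sup, 95)
})

test_that("Newick I/O round-trips topology, lengths and supports", {
  txt <- "(A:1,B:2,(C:1,D:1)90:0.5);"
  f <- tempfile(fileext = ".nwk")
  writeLines(txt, f)
  tree <- read_newick(f)
  expect_equal(sort(tree$tip.label), c("A", "B", "C", "D"))
  expect_true("90" %in% tree$node.label)
  f2 <- tempfile(fileext = ".nwk")
  write_newick(tree, f2)
  expect_identical(ape::write.tree(read_newick(f2)), ape::write.tree(tree))

  set.seed(33)
  for (i in 1:20) {
    tr <- ape::rtree(sample(4:12, 1), rooted = FALSE)
    p1 <- tempfile(); p2 <- tempfile()
    write_newick(tr, p1)
    back <- read_newick(p1)
    write_newick(back, p2)
    expect_identical(readLines(p1), readLines(p2))
    expect_equal(as.numeric(ape::dist.topo(back, tr)), 0)
    expect_equal(sort(back$edge.length), sort(tr$edge.length),
                 tolerance = 1e-9)
  }
  expect_error(read_newick({p <- tempfile(); writeLines("((A,B);", p); p}))
})

test_that("leaf sets and MRE flags are preserved through annotation", {
  aln <- setNames(vapply(1:4, function(i) random_protein(25), character(1)),
                  c("p1", "p2", "p3", "p4"))
  set.seed(34)
  tree <- bootstrap_supports(aln, n_reps = 10, seed = 2)
  tree <- annotate_mre_class(tree, mre_ids = c("mA"),
                             map = c(p1 = "mA", p2 = "mB"))
  expect_equal(unname(tree$mre_class), c(TRUE, FALSE, FALSE, FALSE)[
    match(tree$tip.label, c("p1", "p2", "p3", "p4"))])
})
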