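test_that("nested event sets yield a perfect-phylogeny chain", {
  em <- event_matrix_from_sets(list(
    p = "A", q = c("A", "B"), r = c("A", "B", "C")
  ))
  tr <- max_parsimony_tree(em)
  expect_equal(tr$score, 3) # one change per event
  expect_equal(tr$newick, "((q,r),p);") # chain matching containment order
  expect_true(glance(tr)$perfect_phylogeny)
  expect_equal(sum(detect_homoplasy(tr, em)$parallel), 0)
  # every acquisition sits on one edge; A on the root edge
  ee <- tidy(tr)
  expect_true(all(ee$change == "acquired"))
  expect_equal(ee$parent[ee$event == "A"], "root")
})

test_that("a single conflicting event costs exactly one extra change", {
  # A and B are clean; X is carried by two leaves on incompatible branches
  em <- event_matrix_from_sets(list(
    L1 = c("A", "X"), L2 = "A", L3 = c("B", "X"), L4 = "B"
  ))
  tr <- max_parsimony_tree(em, search = "exhaustive")
  expect_equal(tr$score, 3 + 1)
  expect_equal(tr$score, phangorn_min_score(em$matrix)) # independent oracle
  hp <- detect_homoplasy(tr, em)
  expect_equal(hp$origins[hp$event == "X"], 2L)
  expect_true(hp$parallel[hp$event == "X"])
})

test_that("single-column matrices give a one-leaf tree scoring its events", {
  em <- event_matrix_from_sets(list(only = c("A", "B", "C", "D")))
  tr <- max_parsimony_tree(em)
  expect_equal(tr$score, 4)
  expect_equal(tr$n_leaves, 1)
  expect_error(
    max_parsimony_tree(matrix(0L, 2, 0)),
    "no columns"
  )
})

test_that("exhaustive trees agree with the phangorn oracle on random matrices", {
  for (i in 1:25) {
    n_leaves <- sample(3:6, 1)
    m <- random_event_matrix(100 + i, n_leaves, sample(4:10, 1))
    tr <- max_parsimony_tree(m, search = "exhaustive")
    expect_equal(tr$score, phangorn_min_score(m))
    # the returned tree itself scores what it claims, per the oracle
    expect_equal(phangorn_score(tr$newick, m), tr$score)
  }
})

test_that("parsimony score is invariant under row and column permutation", {
  m <- random_event_matrix(7, 5, 8)
  tr <- max_parsimony_tree(m)
  set.seed(1)
  mp <- m[sample(nrow(m)), sample(ncol(m))]
  expect_equal(max_parsimony_tree(mp)$score, tr$score)
  expect_equal(max_parsimony_tree(mp)$newick, tr$newick)
})

test_that("heuristic search matches the exhaustive optimum on small matrices", {
  for (i in 1:30) {
    n_leaves <- sample(4:7, 1)
    m <- random_event_matrix(300 + i, n_leaves, sample(4:12, 1))
    ex <- max_parsimony_tree(m, search = "exhaustive")
    he <- max_parsimony_tree(m, search = "heuristic", seed = i)
    expect_equal(he$score, ex$score)
  }
})

test_that("heuristic search is deterministic for a fixed seed", {
  m <- random_event_matrix(55, 9, 10)
  a <- max_parsimony_tree(m, search = "heuristic", seed = 42)
  b <- max_parsimony_tree(m, search = "heuristic", seed = 42)
  expect_identical(a$newick, b$newick)
  expect_identical(a$score, b$score)
})

test_that("stem identification is plain intersection", {
  expect_setequal(
    identify_stem(list(c("A", "B"), c("A", "B", "C"), c("A", "B", "D"))),
    c("A", "B")
  )
  expect_length(identify_stem(list(c("A"), c("B"))), 0)
  expect_setequal(identify_stem(list(c("X", "Y"))), c("X", "Y"))
  expect_error(identify_stem(list()), "At least one")
})

test_that("homoplasy counting on a fixed chain flags the split event", {
  # Z sits in A and C; the laminar companions X, Y force a topology on which
  # Z cannot be a single clade
  m2 <- rbind(
    X = c(A = 1L, B = 1L, C = 0L),
    Y = c(A = 1L, B = 0L, C = 0L),
    Z = c(A = 1L, B = 0L, C = 1L)
  )
  tr <- max_parsimony_tree(m2, search = "exhaustive")
  hp <- detect_homoplasy(tr, m2)
  expect_gte(hp$origins[hp$event == "Z"], 1L)
  expect_error(
    detect_homoplasy(tr, m2[, c("A", "B"), drop = FALSE]),
    "do not match"
  )
})

test_that("events on a clade need a single origin", {
  em <- event_matrix_from_sets(list(
    a = c("S", "E"), b = c("S", "E"), c = "S", d = "S"
  ))
  tr <- max_parsimony_tree(em, search = "exhaustive")
  hp <- detect_homoplasy(tr, em)
  expect_equal(hp$origins, c(1L, 1L))
  expect_false(any(hp$parallel))
})

test_that("cross-dataset convergence requires reciprocal overlap and direction", {
  d1 <- tibble::tibble(chrom = "chr3", start = 10e6, end = 20e6,
                       direction = "loss")
  d2 <- tibble::tibble(
    chrom = c("chr3", "chr3", "chr5"),
    start = c(12e6, 12e6, 10e6), end = c(21e6, 13e6, 20e6),
    direction = c("loss", "loss", "loss")
  )
  conv <- cross_dataset_convergence(list(m1 = d1, m2 = d2))
  expect_equal(nrow(conv), 1) # the 12-21 Mb loss; 12-13 Mb fails reciprocity
  expect_equal(conv$chrom, "chr3")
  gain <- d2
  gain$direction <- "gain"
  expect_equal(nrow(cross_dataset_convergence(list(m1 = d1, m2 = gain))), 0)
})

test_that("clone trees export as newick plus an edge table", {
  em <- event_matrix_from_sets(list(p = "A", q = c("A", "B")))
  tr <- max_parsimony_tree(em)
  tmp <- withr::local_tempdir()
  paths <- export_clone_tree(tr, file.path(tmp, "tree"))
  expect_true(all(file.exists(paths)))
  reread <- ape::read.tree(paths[1])
  expect_setequal(reread$tip.label, c("p", "q"))
  edges <- readr::read_tsv(paths[2], show_col_types = FALSE)
  expect_setequal(edges$event, c("A", "B"))
})
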