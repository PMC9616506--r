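make_matrix <- function(profiles, chrom_len = 40L, chroms = "chr1",
                        baseline = 2L) {
  bins <- dplyr::bind_rows(lapply(seq_along(chroms), function(i) {
    tibble::tibble(
      chrom = chroms[i],
      start = as.numeric(0:(chrom_len - 1)) * 1e6,
      end = as.numeric(1:chrom_len) * 1e6
    )
  }))
  m <- vapply(profiles, identity, integer(chrom_len * length(chroms)))
  colnames(m) <- names(profiles)
  cell_bin_matrix(bins, m, baseline)
}

profile_with_run <- function(len, state, at = 10L, n_bins = 40L,
                             baseline = 2L) {
  p <- rep(baseline, n_bins)
  if (len > 0) p[at:(at + len - 1)] <- state
  as.integer(p)
}

test_that("event calling honors the run-length curation cutoffs", {
  mat <- make_matrix(list(
    c4 = profile_with_run(4, 3L),
    c5 = profile_with_run(5, 3L),
    amp2 = profile_with_run(2, 10L),
    amp1 = profile_with_run(1, 10L)
  ))
  expect_equal(nrow(call_cell_events(mat, "c4")), 0) # below 5-bin cutoff
  ev5 <- call_cell_events(mat, "c5")
  expect_equal(nrow(ev5), 1)
  expect_equal(ev5$length_bins, 5L)
  expect_equal(ev5$grade, "imbalance")
  expect_equal(ev5$direction, "gain")
  amp <- call_cell_events(mat, "amp2")
  expect_equal(nrow(amp), 1)
  expect_equal(amp$grade, "high_grade_amplification")
  expect_equal(nrow(call_cell_events(mat, "amp1")), 0) # 1 bin: below both
  expect_error(call_cell_events(mat, "nope"), "Unknown cell")
})

test_that("a long high-state run is emitted once, as amplification", {
  mat <- make_matrix(list(x = profile_with_run(8, 9L)))
  ev <- call_cell_events(mat, "x")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$grade, "high_grade_amplification")
})

test_that("a dissenting bin breaks a run and losses are called", {
  p <- profile_with_run(9, 1L)
  p[14] <- 2L # interrupts a 9-bin loss into 4 + 4
  mat <- make_matrix(list(x = p, y = profile_with_run(6, 1L)))
  expect_equal(nrow(call_cell_events(mat, "x")), 0)
  ev <- call_cell_events(mat, "y")
  expect_equal(ev$direction, "loss")
})

test_that("calling is translation invariant and respects chromosome bounds", {
  for (at in c(1L, 17L, 36L)) {
    mat <- make_matrix(list(x = profile_with_run(5, 3L, at = at)))
    ev <- call_cell_events(mat, "x")
    expect_equal(nrow(ev), 1)
    expect_equal(ev$start_bin, at)
    expect_equal(ev$length_bins, 5L)
  }
  # a deviation straddling the chr1/chr2 boundary must split (3 + 3 bins)
  p <- rep(2L, 80)
  p[38:43] <- 3L
  mat2 <- make_matrix(list(x = p), chrom_len = 40L,
                      chroms = c("chr1", "chr2"))
  expect_equal(nrow(call_cell_events(mat2, "x")), 0)
  # and per-chromosome calling agrees with joint calling
  p2 <- rep(2L, 80)
  p2[10:17] <- 1L
  p2[55:62] <- 3L
  joint <- make_matrix(list(x = p2), 40L, c("chr1", "chr2"))
  ev_joint <- call_cell_events(joint, "x")
  ev_split <- dplyr::bind_rows(
    call_cell_events(make_matrix(list(x = p2[1:40]), 40L, "chr1"), "x"),
    call_cell_events(make_matrix(list(x = p2[41:80]), 40L, "chr2"), "x") |>
      dplyr::mutate(
        start_bin = start_bin + 40L, end_bin = end_bin + 40L
      )
  )
  expect_equal(
    ev_joint[c("chrom", "direction", "copy_state", "length_bins")],
    ev_split[c("chrom", "direction", "copy_state", "length_bins")]
  )
})

test_that("WGD cells are called against their own baseline ploidy", {
  mat <- make_matrix(list(w = profile_with_run(6, 5L, baseline = 4L)),
                     baseline = 4L)
  ev <- call_cell_events(mat, "w")
  expect_equal(ev$direction, "gain")
  expect_equal(ev$grade, "imbalance") # threshold is baseline + 3 = 7
})

test_that("clone grouping partitions cells by exact event-set equality", {
  mat <- make_matrix(list(
    c1 = profile_with_run(5, 3L),
    c2 = profile_with_run(5, 3L),
    c3 = as.integer(`[<-`(profile_with_run(5, 3L), 25:30, 1L)),
    c4 = profile_with_run(0, 2L)
  ))
  asg <- group_cells_into_clones(call_all_cells(mat))
  expect_equal(nrow(asg$clones), 3)
  expect_setequal(asg$cells$clone[asg$cells$cell %in% c("c1", "c2")], "C1")
  # the {gain, loss} cell and the event-free cell are both single-cell clones
  expect_equal(sum(asg$clones$is_singleton), 2)
  expect_true("baseline" %in% asg$clones$clone)
  expect_equal(sum(asg$clones$frequency), 1)
  expect_error(group_cells_into_clones(list()), "At least one")
})

test_that("all-distinct cells become singleton clones at equal frequency", {
  mat <- make_matrix(list(
    a = profile_with_run(5, 3L, at = 1L),
    b = profile_with_run(5, 3L, at = 10L),
    c = profile_with_run(5, 1L, at = 20L),
    d = profile_with_run(6, 3L, at = 30L)
  ))
  asg <- group_cells_into_clones(call_all_cells(mat))
  expect_equal(nrow(asg$clones), 4)
  expect_true(all(asg$clones$is_singleton))
  expect_equal(asg$clones$frequency, rep(0.25, 4))
})

test_that("clone labels are invariant to cell input order", {
  truth <- simulate_clone_tree(42, n_clones = 3)
  sim <- simulate_cell_matrix(truth, 30, uniform_mixture_named(truth),
                              flip_noise = 0, seed = 7)
  ev <- call_all_cells(sim$matrix)
  a <- group_cells_into_clones(ev)
  b <- group_cells_into_clones(rev(ev))
  expect_equal(a$clones, b$clones)
  expect_equal(a$cells, b$cells)
})

test_that("noise-free simulation round-trips the true clone partition", {
  truth <- simulate_clone_tree(11, n_clones = 3)
  mix <- setNames(c(0.5, 0.3, 0.2), names(truth$parents))
  sim <- simulate_cell_matrix(truth, 20, mix, flip_noise = 0, seed = 3)
  asg <- group_cells_into_clones(call_all_cells(sim$matrix))
  inferred <- asg$cells$clone[match(sim$truth_assignment$cell,
                                    asg$cells$cell)]
  expect_equal(
    length(unique(paste(inferred, sim$truth_assignment$clone))),
    length(unique(inferred))
  ) # one-to-one mapping between inferred and true clones
})

test_that("clone recovery stays accurate under per-bin flip noise", {
  skip_if_not_installed("mclust")
  ok <- 0L
  n_rep <- 60L
  for (i in seq_len(n_rep)) {
    truth <- simulate_clone_tree(5000 + i, n_clones = 3,
                                 events_per_branch = 2)
    mix <- setNames(c(0.4, 0.35, 0.25), names(truth$parents))
    sim <- simulate_cell_matrix(truth, 20, mix, flip_noise = 0.01,
                                seed = 6000 + i)
    asg <- group_cells_into_clones(
      call_all_cells(sim$matrix, max_gap_bins = 1),
      match_mode = "overlap"
    )
    inferred <- asg$cells$clone[match(sim$truth_assignment$cell,
                                      asg$cells$cell)]
    ari <- mclust::adjustedRandIndex(inferred, sim$truth_assignment$clone)
    if (ari >= 0.9) ok <- ok + 1L
  }
  expect_gte(ok / n_rep, 0.9)
})

test_that("event matrix construction conserves cells and orders rows genomically", {
  truth <- simulate_clone_tree(8, n_clones = 3)
  sim <- simulate_cell_matrix(truth, 25, uniform_mixture_named(truth),
                              flip_noise = 0, seed = 5)
  asg <- group_cells_into_clones(call_all_cells(sim$matrix))
  em <- build_event_matrix(asg, "clones")
  expect_equal(sum(em$weights), 25)
  expect_true(all(rowSums(em$matrix) >= 1))
  expect_true(all(em$matrix %in% c(0L, 1L)))
  em_cells <- build_event_matrix(asg, "cells")
  expect_equal(sum(em_cells$weights), 25)
  expect_equal(sort(colnames(em_cells$matrix)), colnames(em_cells$matrix))
})

test_that("baseline-only input yields an empty event matrix with one column", {
  mat <- make_matrix(list(a = profile_with_run(0, 2L)))
  asg <- group_cells_into_clones(call_all_cells(mat))
  em <- build_event_matrix(asg)
  expect_equal(dim(em$matrix), c(0L, 1L))
  expect_equal(unname(em$weights), 1)
})
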