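test_that("generators are pure functions of seed and config", {
  a <- simulate_clone_tree(101, n_clones = 4)
  b <- simulate_clone_tree(101, n_clones = 4)
  expect_identical(a, b)
  sa <- simulate_bulk_segments(a, uniform_mixture_named(a), 0.8, seed = 5)
  sb <- simulate_bulk_segments(b, uniform_mixture_named(b), 0.8, seed = 5)
  expect_identical(sa, sb)
  ca <- simulate_cell_matrix(a, 10, uniform_mixture_named(a), seed = 5)
  cb <- simulate_cell_matrix(b, 10, uniform_mixture_named(b), seed = 5)
  expect_identical(ca, cb)
  ea <- simulate_expression_cohort(77, n_genes = 40, n_patients = 30)
  eb <- simulate_expression_cohort(77, n_genes = 40, n_patients = 30)
  expect_identical(ea, eb)
  va <- simulate_volume_series(9, "PR")
  vb <- simulate_volume_series(9, "PR")
  expect_identical(va, vb)
})

test_that("clone trees nest event sets along every lineage", {
  for (i in 1:100) {
    truth <- simulate_clone_tree(i, n_clones = sample(2:6, 1),
                                 events_per_branch = sample(1:3, 1))
    for (cl in names(truth$parents)) {
      p <- truth$parents[[cl]]
      if (!is.na(p)) {
        expect_true(all(truth$clone_events[[p]] %in%
                          truth$clone_events[[cl]]))
        expect_gt(
          length(truth$clone_events[[cl]]),
          length(truth$clone_events[[p]])
        )
      }
    }
    # no within-lineage overlap: each clone's events are disjoint intervals
    for (cl in names(truth$parents)) {
      evs <- truth$branch_events[
        truth$branch_events$event %in% truth$clone_events[[cl]],
      ]
      by_chr <- split(evs, evs$chrom)
      for (g in by_chr) {
        g <- g[order(g$start_bin), ]
        if (nrow(g) > 1) {
          expect_true(all(g$start_bin[-1] > g$end_bin[-nrow(g)]))
        }
      }
    }
  }
  expect_error(simulate_clone_tree(1, 0), "at least 1")
})

test_that("single-clone trees are a lone stem", {
  truth <- simulate_clone_tree(3, n_clones = 1)
  expect_equal(length(truth$parents), 1)
  expect_true(is.na(truth$parents[[1]]))
})

test_that("noise-free bulk forward model is the exact inverse of the MSF formulas", {
  truth <- simulate_clone_tree(17, n_clones = 3, events_per_branch = 2)
  freqs <- setNames(c(0.5, 0.3, 0.2), names(truth$parents))
  for (purity in c(0.4, 0.7, 1)) {
    segs <- simulate_bulk_segments(truth, freqs, purity,
      sigma_log2r = 0, sigma_baf = 0, seed = 3,
      frac_below_filter = 0
    )
    for (i in seq_len(nrow(segs))) {
      s <- segs[i, ]
      msf <- if (s$kind == "cnni") {
        msf_from_mbaf(s$mbaf, s$n_minor, s$n_major)
      } else {
        msf_from_log2r(s$log2r, s$n_minor + s$n_major, s$background_ploidy)
      }
      expect_equal(as.numeric(msf), s$msf_true, tolerance = 1e-9)
    }
  }
})

test_that("a fully clonal gain in a pure sample sits at log2(1.5)", {
  truth <- simulate_clone_tree(23, n_clones = 1, events_per_branch = 6)
  segs <- simulate_bulk_segments(
    truth, setNames(1, names(truth$parents)), 1,
    sigma_log2r = 0, sigma_baf = 0, seed = 2, frac_cnni = 0,
    frac_below_filter = 0
  )
  gains <- segs[segs$kind == "gain", ]
  expect_true(nrow(gains) > 0)
  expect_equal(gains$log2r, rep(log2(1.5), nrow(gains)), tolerance = 1e-12)
})

test_that("segments planted below the curation filter are removed by it", {
  truth <- simulate_clone_tree(31, n_clones = 2, events_per_branch = 3)
  segs <- simulate_bulk_segments(
    truth, uniform_mixture_named(truth), 0.9,
    seed = 8, frac_below_filter = 0.5
  )
  kept <- filter_segments(segs)
  small <- segs$end - segs$start + 1 < 50000 | segs$marker_count < 50
  expect_equal(nrow(kept), sum(!small))
})

test_that("cell counts per clone stay within binomial 99% bounds", {
  truth <- simulate_clone_tree(41, n_clones = 3)
  mix <- setNames(c(0.5, 0.3, 0.2), names(truth$parents))
  sim <- simulate_cell_matrix(truth, 100, mix, flip_noise = 0, seed = 11)
  counts <- table(factor(sim$truth_assignment$clone, levels = names(mix)))
  for (cl in names(mix)) {
    bounds <- qbinom(c(0.0005, 0.9995), 100, mix[[cl]])
    expect_gte(counts[[cl]], bounds[1])
    expect_lte(counts[[cl]], bounds[2])
  }
  expect_error(simulate_cell_matrix(truth, 0, mix), "at least 1")
})

test_that("null expression cohorts carry no signature structure", {
  sim <- simulate_expression_cohort(67, n_genes = 300, n_patients = 80,
                                    effect_size = 0, beta = 0)
  top <- top_variable_genes(sim$expr, 50)
  overlap <- length(intersect(top, sim$truth$signature_genes))
  # hypergeometric: expect ~ 50 * 20/300 = 3.3 by chance
  expect_lte(overlap, 12)
  expect_equal(dim(sim$expr), c(300, 80))
  expect_true(all(sim$cohort$time_days > 0))
  expect_true(all(sim$cohort$event %in% c(0, 1)))
})

test_that("censoring rate lands near its target", {
  sim <- simulate_expression_cohort(71, n_genes = 20, n_patients = 2000,
                                    censor_rate = 0.3)
  expect_lt(abs(mean(sim$cohort$event == 0) - 0.3), 0.06)
})

test_that("volume archetypes round-trip through classification without noise", {
  archetypes <- c("PD", "SD", "PR", "CR", "CR_relapse",
                  "surgery_cured", "surgery_relapse")
  for (a in archetypes) {
    s <- simulate_volume_series(13, a, noise = 0)
    call <- classify_response(s$series, window = s$window,
                              surgery_day = s$surgery_day)
    expect_equal(as.character(call$response), s$truth$expected$response,
                 info = a)
    expect_equal(call$relapse, s$truth$expected$relapse, info = a)
  }
})

test_that("truth records serialize losslessly to JSON", {
  truth <- simulate_clone_tree(87, n_clones = 4, stem_wgd = TRUE)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth_json(truth, path)
  back <- read_truth_json(path)
  expect_equal(back$parents, truth$parents)
  expect_equal(back$branch_events, truth$branch_events)
  expect_equal(back$clone_events, truth$clone_events)
  expect_equal(back$baseline_ploidy, truth$baseline_ploidy)
  expect_true(back$stem_wgd)
})
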