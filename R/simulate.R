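# Synthetic-data generators with planted ground truth. Every generator is a
# pure function of (seed, config): regeneration with the same arguments is
# bit-identical.

#' Simulate a random clone tree with copy-number events
#'
#' Grows a rooted clone phylogeny by attaching each new clone to a uniformly
#' chosen existing clone, then plants copy-number events (contiguous bin
#' spans with an integer copy change) on each branch, avoiding overlap with
#' events already carried by the lineage, so parent event sets are strict
#' subsets of their descendants'. An optional whole-genome duplication at
#' the stem doubles the baseline ploidy of every clone.
#'
#' @param seed Integer seed.
#' @param n_clones Number of clones (>= 1). The first clone is the stem and
#'   carries the stem events shared by all others.
#' @param events_per_branch Events planted on each branch (default 2).
#' @param chroms Chromosomes to draw events on (default: all autosomes).
#' @param span_bins Range of event lengths in 1-Mb bins (default 8-30).
#' @param stem_wgd Plant a whole-genome duplication at the stem
#'   (default FALSE).
#' @param p_gain Probability an event is a gain (+1) rather than a loss (-1);
#'   default 0.5. A small fraction (`p_amp`, default 0.1) of gains are
#'   high-grade amplifications (+6).
#' @param p_amp See `p_gain`.
#' @return An object of class `simulated_truth`: list with `seed`, `parents`
#'   (named vector, stem maps to NA), `branch_events` (tibble: clone, event,
#'   chrom, start_bin, end_bin, copy_change), `clone_events` (named list of
#'   cumulative event ids per clone), `events` (tibble of distinct events
#'   with genomic coordinates), `baseline_ploidy`, `stem_wgd`.
#' @export
simulate_clone_tree <- function(seed, n_clones, events_per_branch = 2L,
                                chroms = names(autosome_mb),
                                span_bins = c(8L, 30L), stem_wgd = FALSE,
                                p_gain = 0.5, p_amp = 0.1) {
  if (n_clones < 1) abort("`n_clones` must be at least 1.")
  set.seed(as.integer(seed))
  clones <- sprintf("clone_%02d", seq_len(n_clones))
  parents <- setNames(c(NA_character_, if (n_clones > 1) {
    vapply(2:n_clones, function(i) clones[sample.int(i - 1, 1)], character(1))
  }), clones)

  chrom_sizes <- autosome_mb[chroms]
  lineage_events <- setNames(vector("list", n_clones), clones)
  branch_rows <- list()
  ev_id <- 0L
  for (cl in clones) {
    inherited <- if (is.na(parents[[cl]])) {
      tibble(chrom = character(0), start_bin = integer(0),
             end_bin = integer(0))
    } else {
      lineage_events[[parents[[cl]]]]
    }
    new_rows <- list()
    taken <- inherited
    attempts <- 0L
    while (length(new_rows) < events_per_branch) {
      attempts <- attempts + 1L
      if (attempts > 200L * events_per_branch) {
        abort("Could not place events without within-lineage overlap; reduce events_per_branch or widen the genome.")
      }
      ch <- sample(chroms, 1)
      len <- sample(span_bins[1]:span_bins[2], 1)
      if (len >= chrom_sizes[[ch]]) next
      st <- sample.int(chrom_sizes[[ch]] - len + 1L, 1)
      en <- st + len - 1L
      clash <- taken |>
        filter(.data$chrom == ch, .data$start_bin <= en, .data$end_bin >= st)
      if (nrow(clash) > 0) next
      ev_id <- ev_id + 1L
      is_gain <- runif(1) < p_gain
      change <- if (is_gain) {
        if (runif(1) < p_amp) 6L else 1L
      } else {
        -1L
      }
      row <- tibble(
        clone = cl,
        event = sprintf("ev%03d", ev_id),
        chrom = ch, start_bin = st, end_bin = en,
        copy_change = change
      )
      new_rows[[length(new_rows) + 1]] <- row
      taken <- bind_rows(taken, row[, c("chrom", "start_bin", "end_bin")])
    }
    branch <- bind_rows(new_rows)
    branch_rows[[cl]] <- branch
    lineage_events[[cl]] <- taken
  }
  branch_events <- bind_rows(branch_rows)

  # cumulative event sets along the tree
  clone_events <- setNames(vector("list", n_clones), clones)
  for (cl in clones) {
    own <- branch_events$event[branch_events$clone == cl]
    clone_events[[cl]] <- if (is.na(parents[[cl]])) {
      own
    } else {
      c(clone_events[[parents[[cl]]]], own)
    }
  }

  structure(
    list(
      seed = as.integer(seed),
      parents = parents,
      branch_events = branch_events,
      clone_events = clone_events,
      events = branch_events |>
        select("event", "chrom", "start_bin", "end_bin", "copy_change"),
      baseline_ploidy = if (stem_wgd) 4L else 2L,
      stem_wgd = stem_wgd
    ),
    class = "simulated_truth"
  )
}

#' @export
print.simulated_truth <- function(x, ...) {
  cat(sprintf(
    "simulated_truth: %d clone(s), %d planted event(s), baseline ploidy %d\n",
    length(x$parents), nrow(x$events), x$baseline_ploidy
  ))
  invisible(x)
}

#' Simulate curated allele-specific bulk segments from a clone tree
#'
#' Forward model inverted by [msf_from_log2r()] / [msf_from_mbaf()]: for each
#' planted aberration the true mutated sample fraction is
#' `MSF = purity * sum of frequencies of clones carrying it`; the intensity
#' ratio is `log2((MSF * N_t + (1 - MSF) * N_p) / N_p)` plus Gaussian noise,
#' and for copy-neutral imbalances the mirrored B-allele frequency follows
#' the allele-mixture model with truncated Gaussian noise folded back into
#' \[0.5, 1\]. Segment lengths and marker counts are sampled so that a stated
#' fraction of segments falls below the curation filter.
#'
#' @param truth A `simulated_truth` from [simulate_clone_tree()].
#' @param clone_freqs Named numeric vector of clone frequencies (over the
#'   truth's clones, summing to 1).
#' @param purity Tumor cell fraction in (0, 1].
#' @param sigma_log2r Gaussian noise SD on log2R (default 0.02).
#' @param sigma_baf Gaussian noise SD on mBAF (default 0.01).
#' @param seed Integer seed.
#' @param sample_id Sample identifier.
#' @param frac_cnni Fraction of loss events converted to copy-neutral
#'   imbalances (default 0.2).
#' @param frac_below_filter Fraction of segments planted below the 50-kb /
#'   50-marker curation filter (default 0.1).
#' @return A tibble of segments in the bulk-pipeline input layout plus truth
#'   columns `msf_true` and `event`.
#' @export
simulate_bulk_segments <- function(truth, clone_freqs, purity,
                                   sigma_log2r = 0.02, sigma_baf = 0.01,
                                   seed = 1L, sample_id = "sim_sample",
                                   frac_cnni = 0.2,
                                   frac_below_filter = 0.1) {
  stopifnot(inherits(truth, "simulated_truth"))
  check_frequencies(clone_freqs, what = "clone_freqs")
  if (!setequal(names(clone_freqs), names(truth$parents))) {
    abort("`clone_freqs` must be named by the truth's clones.")
  }
  if (purity <= 0 || purity > 1) abort("`purity` must be in (0, 1].")
  set.seed(as.integer(seed))

  np <- truth$baseline_ploidy
  events <- truth$events
  rows <- purrr::map_dfr(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    carriers <- names(truth$clone_events)[
      purrr::map_lgl(truth$clone_events, function(s) ev$event %in% s)
    ]
    msf_true <- purity * sum(clone_freqs[carriers])
    as_cnni <- ev$copy_change == -1L && runif(1) < frac_cnni
    if (as_cnni) {
      # copy-neutral LOH: N_A = 0, N_B = N_p
      n_minor <- 0L
      n_major <- np
      mbaf_true <- (msf_true * n_major + (1 - msf_true) * (np / 2)) /
        (msf_true * (n_minor + n_major) + (1 - msf_true) * np)
      mbaf <- mbaf_true + rnorm(1, 0, sigma_baf)
      mbaf <- min(max(mbaf, 0), 1)
      if (mbaf < 0.5) mbaf <- 1 - mbaf # mirrored convention
      log2r <- rnorm(1, 0, sigma_log2r) # copy neutral: flat intensity
      kind <- "cnni"
      nt <- np
    } else {
      nt <- np + ev$copy_change
      kind <- if (ev$copy_change >= 6L) {
        "high_grade_amplification"
      } else if (ev$copy_change > 0) "gain" else "loss"
      mean_copy <- msf_true * nt + (1 - msf_true) * np
      log2r <- log2(mean_copy / np) + rnorm(1, 0, sigma_log2r)
      if (ev$copy_change > 0) {
        n_minor <- np %/% 2L
        n_major <- nt - n_minor
      } else {
        n_minor <- max(np %/% 2L - 1L, 0L)
        n_major <- nt - n_minor
      }
      mbaf <- NA_real_
    }
    below <- runif(1) < frac_below_filter
    length_bp <- if (below) {
      round(runif(1, 10e3, 49e3))
    } else {
      round(runif(1, 60e3, (ev$end_bin - ev$start_bin + 1) * 1e6))
    }
    markers <- if (below) {
      sample(10:49, 1)
    } else {
      sample(60:5000, 1)
    }
    start_bp <- ev$start_bin * 1e6 + 1
    tibble(
      sample_id = sample_id, chrom = ev$chrom,
      start = start_bp, end = start_bp + length_bp - 1,
      kind = kind, log2r = log2r, mbaf = mbaf,
      n_minor = as.integer(n_minor), n_major = as.integer(n_major),
      background_ploidy = np, marker_count = markers,
      event = ev$event, msf_true = msf_true
    )
  })
  rows
}

#' Simulate a single-cell bin-by-cell copy-number matrix
#'
#' Draws cells independently from the clone mixture, writes each clone's
#' cumulative events onto the 1-Mb bin grid as integer copy states over the
#' baseline ploidy, and applies independent per-bin flip noise (each bin is
#' shifted by +/-1 copy with probability `flip_noise`).
#'
#' @param truth A `simulated_truth`.
#' @param n_cells Number of cells (>= 1).
#' @param clone_mixture Named numeric vector of clone sampling probabilities
#'   (summing to 1).
#' @param flip_noise Per-bin state-flip probability (default 0.01).
#' @param seed Integer seed.
#' @param chroms Chromosomes for the bin grid (default: chromosomes carrying
#'   planted events, so matrices stay compact).
#' @return A list with `matrix` (a [cell_bin_matrix()]) and `truth_assignment`
#'   (tibble cell/clone).
#' @export
simulate_cell_matrix <- function(truth, n_cells, clone_mixture,
                                 flip_noise = 0.01, seed = 1L,
                                 chroms = NULL) {
  stopifnot(inherits(truth, "simulated_truth"))
  if (n_cells < 1) abort("`n_cells` must be at least 1.")
  check_frequencies(clone_mixture, what = "clone_mixture")
  if (!all(names(clone_mixture) %in% names(truth$parents))) {
    abort("`clone_mixture` names must be clones of the truth record.")
  }
  set.seed(as.integer(seed))

  chroms <- chroms %||% sort(unique(truth$branch_events$chrom))
  if (length(chroms) == 0) chroms <- names(autosome_mb)[1]
  bins <- genome_bins(chroms)
  bin_index <- split(seq_len(nrow(bins)), bins$chrom)

  clone_profile <- function(cl) {
    prof <- rep(truth$baseline_ploidy, nrow(bins))
    evs <- truth$branch_events |>
      filter(.data$event %in% truth$clone_events[[cl]],
             .data$chrom %in% chroms)
    for (i in seq_len(nrow(evs))) {
      idx <- bin_index[[evs$chrom[i]]]
      sel <- idx[evs$start_bin[i]:min(evs$end_bin[i], length(idx))]
      prof[sel] <- prof[sel] + evs$copy_change[i]
    }
    pmax(prof, 0L)
  }
  profiles <- purrr::map(setNames(names(clone_mixture),
                                  names(clone_mixture)), clone_profile)

  assign <- sample(names(clone_mixture), n_cells, replace = TRUE,
                   prob = clone_mixture)
  cells <- sprintf("cell_%03d", seq_len(n_cells))
  m <- vapply(seq_len(n_cells), function(i) {
    prof <- profiles[[assign[i]]]
    flip <- runif(length(prof)) < flip_noise
    if (any(flip)) {
      prof[flip] <- pmax(
        prof[flip] + sample(c(-1L, 1L), sum(flip), replace = TRUE), 0L
      )
    }
    prof
  }, integer(nrow(bins)))
  colnames(m) <- cells

  list(
    matrix = cell_bin_matrix(bins, m,
                             baseline_ploidy = truth$baseline_ploidy),
    truth_assignment = tibble(cell = cells, clone = assign)
  )
}

#' Simulate an expression matrix and a survival cohort with planted effects
#'
#' Baseline expression is Gaussian per gene (gene-specific means and SDs).
#' Signature genes are co-expressed: they share a per-patient latent state
#' with correlation `gene_correlation` — the structure of lineage-state
#' signatures, whose member genes rise and fall together. Samples in the
#' second group additionally receive an additive shift of `effect_size` on
#' the signature genes. Survival times are exponential with hazard
#' `h0 * exp(beta * score)` where the score is each patient's standardized
#' mean z over the signature genes (unit variance, so `beta` converts to a
#' hazard ratio of `exp(beta * 2 * sqrt(2 / pi))` between score halves);
#' censoring is independent exponential calibrated to the requested rate.
#'
#' @param seed Integer seed.
#' @param n_genes Gene universe size.
#' @param n_patients Number of patients.
#' @param signature_genes Character vector of planted signature genes
#'   (subset of the universe; default: first 20 genes).
#' @param effect_size Additive group shift on signature genes (default 1).
#' @param beta Log-hazard coefficient on the standardized signature score
#'   (default 0).
#' @param gene_correlation Share of each signature gene's variance carried
#'   by the latent state (default 0.7).
#' @param censor_rate Target censoring fraction (default 0.3).
#' @param base_hazard Baseline exponential hazard per day (default 1/1000).
#' @param cohort_genes Genes whose expression is copied into the cohort
#'   table as per-patient columns (default: the signature genes).
#' @return A list with `expr` (genes x patients matrix), `cohort` (tibble:
#'   patient, time_days, event, group, plus one column per `cohort_genes`),
#'   `truth` (list: signature genes, beta, effect size, per-patient score
#'   and latent state).
#' @export
simulate_expression_cohort <- function(seed, n_genes = 500,
                                       n_patients = 200,
                                       signature_genes = NULL,
                                       effect_size = 1,
                                       beta = 0,
                                       gene_correlation = 0.7,
                                       censor_rate = 0.3,
                                       base_hazard = 1 / 1000,
                                       cohort_genes = NULL) {
  set.seed(as.integer(seed))
  genes <- sprintf("g%04d", seq_len(n_genes))
  signature_genes <- signature_genes %||% genes[seq_len(min(20, n_genes))]
  if (!all(signature_genes %in% genes)) {
    abort("`signature_genes` must be a subset of the gene universe.")
  }
  if (gene_correlation < 0 || gene_correlation >= 1) {
    abort("`gene_correlation` must be in [0, 1).")
  }
  cohort_genes <- cohort_genes %||% signature_genes
  if (!all(cohort_genes %in% genes)) {
    abort("`cohort_genes` must be a subset of the gene universe.")
  }
  patients <- sprintf("p%04d", seq_len(n_patients))
  group <- rep(c("A", "B"), length.out = n_patients)

  mu <- rnorm(n_genes, 8, 2)
  sigma <- runif(n_genes, 0.5, 1.5)
  expr <- matrix(
    rnorm(n_genes * n_patients, mean = mu, sd = sigma),
    nrow = n_genes, dimnames = list(genes, patients)
  )
  # latent co-expression of the signature genes
  latent <- rnorm(n_patients)
  sig_idx <- match(signature_genes, genes)
  if (gene_correlation > 0) {
    shared <- outer(sigma[sig_idx], latent) * sqrt(gene_correlation)
    own <- (expr[sig_idx, , drop = FALSE] - mu[sig_idx]) *
      sqrt(1 - gene_correlation)
    expr[sig_idx, ] <- mu[sig_idx] + shared + own
  }
  expr[sig_idx, group == "B"] <- expr[sig_idx, group == "B"] + effect_size

  score <- rowMeans(scale(t(expr[sig_idx, , drop = FALSE])))
  score <- as.numeric(scale(score))
  hazard <- base_hazard * exp(beta * score)
  t_event <- rexp(n_patients, rate = hazard)
  # independent censoring calibrated to the requested overall rate
  c_rate <- base_hazard * censor_rate / max(1 - censor_rate, 1e-6)
  t_cens <- if (censor_rate > 0) {
    rexp(n_patients, rate = c_rate)
  } else {
    rep(Inf, n_patients)
  }
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  cohort <- tibble(
    patient = patients,
    time_days = time,
    event = event,
    group = group
  )
  for (g in cohort_genes) cohort[[g]] <- expr[g, ]

  list(
    expr = expr,
    cohort = cohort,
    truth = list(
      signature_genes = signature_genes, beta = beta,
      effect_size = effect_size, score = setNames(score, patients),
      latent = setNames(latent, patients)
    )
  )
}

#' Simulate a mouse tumor-volume trajectory for a response archetype
#'
#' Piecewise-exponential growth/regression shaped by the archetype, with
#' multiplicative log-normal measurement noise. Trajectories start at
#' ~500 mm^3 (the randomization size), are observed twice weekly over a
#' 6-week treatment window plus 4 follow-up weeks, and are built so that
#' [classify_response()] recovers the archetype:
#' `PD` grows steadily; `SD` stays flat; `PR` regresses to ~40% without
#' dropping below the measurable minimum; `CR` regresses below the
#' measurable minimum but re-emerges to ~130 mm^3 by the end of the window
#' (call: CR); `CR_relapse` does the same and then regrows past the relapse
#' threshold (call: CR + relapse); `surgery_cured` is resected mid-window
#' and stays down (call: MCR); `surgery_relapse` is resected and regrows
#' (call: MCR + relapse).
#'
#' @param seed Integer seed.
#' @param archetype One of `"PD"`, `"SD"`, `"PR"`, `"CR"`, `"CR_relapse"`,
#'   `"surgery_cured"`, `"surgery_relapse"`.
#' @param noise SD of the multiplicative log-normal noise (default 0.05).
#' @param baseline_volume Starting volume, mm^3 (default 500).
#' @return A list with `series` (tibble day/volume), `surgery_day` (NA when
#'   not applicable), `window` (c(0, 42)) and `truth` (the archetype and the
#'   expected classification).
#' @export
simulate_volume_series <- function(seed,
                                   archetype = c("PD", "SD", "PR", "CR",
                                                 "CR_relapse",
                                                 "surgery_cured",
                                                 "surgery_relapse"),
                                   noise = 0.05,
                                   baseline_volume = 500) {
  archetype <- match.arg(archetype)
  set.seed(as.integer(seed))
  days <- seq(0, 70, by = 3.5)
  window <- c(0, 42)

  # relative-volume trajectories as piecewise-exponential segments
  # (log-linear interpolation between knots); margins are wide enough that
  # 3-sigma multiplicative noise at the default 0.05 cannot cross a
  # classification threshold
  knots <- switch(archetype,
    PD = list(d = c(0, 70), r = c(1, 2.3)),
    SD = list(d = c(0, 70), r = c(1, 1)),
    PR = list(d = c(0, 21, 42, 70), r = c(1, 0.38, 0.38, 0.6)),
    CR = list(d = c(0, 25, 42, 70), r = c(1, 0.06, 0.27, 0.27)),
    CR_relapse = list(d = c(0, 25, 42, 49, 70),
                      r = c(1, 0.06, 0.27, 0.5, 1.6)),
    surgery_cured = list(d = c(0, 21, 24.5, 70),
                         r = c(1, 0.4, 0.004, 0.004)),
    surgery_relapse = list(d = c(0, 21, 24.5, 49, 70),
                           r = c(1, 0.4, 0.004, 0.004, 0.9))
  )
  shape <- function(d) {
    exp(stats::approx(knots$d, log(knots$r), xout = d, rule = 2)$y)
  }
  surgery_day <- if (archetype %in% c("surgery_cured", "surgery_relapse")) {
    21
  } else {
    NA_real_
  }
  v <- baseline_volume * shape(days) *
    exp(rnorm(length(days), 0, noise))
  expected <- switch(archetype,
    PD = list(response = "PD", relapse = FALSE),
    SD = list(response = "SD", relapse = FALSE),
    PR = list(response = "PR", relapse = FALSE),
    CR = list(response = "CR", relapse = FALSE),
    CR_relapse = list(response = "CR", relapse = TRUE),
    surgery_cured = list(response = "MCR", relapse = FALSE),
    surgery_relapse = list(response = "MCR", relapse = TRUE)
  )
  list(
    series = tibble(day = days, volume = v),
    surgery_day = surgery_day,
    window = window,
    truth = list(archetype = archetype, expected = expected)
  )
}

#' Expected classification for a simulated archetype
#'
#' The archetype-to-call contract used by round-trip accuracy checks: the
#' response class and relapse flag [classify_response()] should produce on a
#' noiseless trajectory of that archetype.
#'
#' @param archetype Archetype name, see [simulate_volume_series()].
#' @return List with `response` and `relapse`.
#' @export
expected_response_call <- function(archetype) {
  simulate_volume_series(1L, archetype, noise = 0)$truth$expected
}

#' Serialise a simulated truth record to JSON (and back)
#'
#' @param truth A `simulated_truth`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "simulated_truth"))
  payload <- list(
    seed = truth$seed,
    parents = as.list(truth$parents),
    branch_events = truth$branch_events,
    clone_events = truth$clone_events,
    baseline_ploidy = truth$baseline_ploidy,
    stem_wgd = truth$stem_wgd
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  parents <- unlist(lapply(x$parents, function(p) {
    if (is.null(p)) NA_character_ else p
  }))
  branch_events <- as_tibble(x$branch_events)
  structure(
    list(
      seed = as.integer(x$seed),
      parents = parents,
      branch_events = branch_events,
      clone_events = lapply(x$clone_events, as.character),
      events = branch_events |>
        select("event", "chrom", "start_bin", "end_bin", "copy_change"),
      baseline_ploidy = as.integer(x$baseline_ploidy),
      stem_wgd = isTRUE(x$stem_wgd)
    ),
    class = "simulated_truth"
  )
}
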