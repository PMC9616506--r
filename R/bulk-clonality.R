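#' Filter curated allele-specific segments by length and marker support
#'
#' Keeps only aberrations long enough and supported by enough array probes to
#' be trusted: segments spanning at least `min_length_bp` (coordinates are
#' 1-based inclusive, so length = end - start + 1) and carrying at least
#' `min_markers` probes. Both boundaries are inclusive. Input row order is
#' preserved.
#'
#' @param segments A data frame of allele-specific segments with at least
#'   columns `start`, `end` (1-based inclusive base-pair positions) and
#'   `marker_count`.
#' @param min_length_bp Minimum segment length in base pairs (default 50 kb).
#' @param min_markers Minimum probe count supporting the call (default 50).
#' @return A tibble containing the retained rows of `segments`.
#' @examples
#' segs <- tibble::tibble(
#'   sample_id = "s1", chrom = "1",
#'   start = c(1e6, 2e6, 3e6), end = c(1e6 + 39999, 2e6 + 59999, 3e6 + 49999),
#'   marker_count = c(60, 49, 50)
#' )
#' filter_segments(segs) # only the third row survives
#' @export
filter_segments <- function(segments, min_length_bp = 50000L,
                            min_markers = 50L) {
  check_columns(segments, c("start", "end", "marker_count"), "segments")
  as_tibble(segments) |>
    filter(
      (.data$end - .data$start + 1) >= min_length_bp,
      .data$marker_count >= min_markers
    )
}

#' Mutated sample fraction from the log2 intensity ratio
#'
#' Inverts the two-population intensity mixture: a fraction m of cells carry
#' the aberration at total copy number `n_total` while the remaining cells sit
#' at `background_ploidy` copies, so the observed median intensity ratio is
#' `2^log2r = (m * n_total + (1 - m) * background_ploidy) / background_ploidy`.
#' Solving for m gives
#' `MSF = (background_ploidy * 2^log2r - background_ploidy) /
#'        (n_total - background_ploidy)`.
#'
#' Copy-neutral events (`n_total == background_ploidy`) leave the intensity
#' ratio flat and are not identifiable from `log2r`; use [msf_from_mbaf()].
#'
#' Estimates within `tol` of \[0, 1\] are clamped into the unit interval;
#' estimates further outside are returned unclamped and flagged through the
#' `"flagged"` attribute (a logical vector), signalling a likely
#' mis-specified allelic composition rather than noise.
#'
#' @param log2r Log2 median probe intensity ratio (vectorised).
#' @param n_total Total copy number of the aberration in aberrant cells.
#' @param background_ploidy Copy number in non-aberrant cells (default 2).
#' @param tol Absolute clamping tolerance (default 0.05).
#' @return Numeric vector of MSF estimates with attribute `flagged`.
#' @examples
#' msf_from_log2r(log2(1.5), n_total = 3)  # fully clonal single-copy gain
#' msf_from_log2r(log2(1.25), n_total = 3) # the same gain in half the cells
#' @export
msf_from_log2r <- function(log2r, n_total, background_ploidy = 2L,
                           tol = 0.05) {
  # -Inf is a legitimate reading: a homozygous deletion carried by every
  # cell zeroes the intensity ratio
  check_numeric(log2r, "log2r", finite = FALSE)
  if (any(is.na(log2r) | log2r == Inf)) {
    abort("`log2r` contains NA or +Inf values.")
  }
  if (any(n_total == background_ploidy)) {
    abort(paste(
      "MSF is not identifiable from the intensity ratio when the aberration",
      "is copy neutral (n_total == background_ploidy); use msf_from_mbaf()."
    ))
  }
  msf <- (background_ploidy * 2^log2r - background_ploidy) /
    (n_total - background_ploidy)
  out <- clamp_fraction(msf, tol)
  structure(out$value, flagged = out$flagged)
}

#' Mutated sample fraction from the mirrored B-allele frequency
#'
#' For allelic imbalances — in particular copy-neutral ones, invisible to the
#' intensity ratio — the mirrored B-allele frequency (mBAF, the frequency of
#' the major allele folded into \[0.5, 1\]) determines the mutated sample
#' fraction through
#' `MSF = (1 - 2 * mbaf) / (mbaf * (n_minor + n_major - 2) - n_major + 1)`,
#' where `n_minor` (N_A) and `n_major` (N_B) are the minor- and major-allele
#' copy numbers in aberrant cells, on a diploid heterozygous background.
#'
#' By convention `n_major` is the more abundant allele (`n_minor <= n_major`);
#' inputs violating the convention are swapped with a warning. Allelically
#' balanced genotypes (`n_minor == n_major`) pin mBAF at 0.5 and are not
#' identifiable. The clamping contract matches [msf_from_log2r()].
#'
#' @param mbaf Mirrored B-allele frequency in \[0.5, 1\] (vectorised).
#' @param n_minor Minor-allele copy number in aberrant cells.
#' @param n_major Major-allele copy number in aberrant cells.
#' @param tol Absolute clamping tolerance (default 0.05).
#' @return Numeric vector of MSF estimates with attribute `flagged`.
#' @examples
#' msf_from_mbaf(1.0, 0, 2)  # fully clonal copy-neutral LOH
#' msf_from_mbaf(0.75, 0, 2) # the same event in half the cells
#' @export
msf_from_mbaf <- function(mbaf, n_minor, n_major, tol = 0.05) {
  check_numeric(mbaf, "mbaf")
  if (any(mbaf < 0.5 - 1e-9 | mbaf > 1 + 1e-9)) {
    abort("`mbaf` must lie in [0.5, 1] (mirrored convention).")
  }
  swap <- n_minor > n_major
  if (any(swap)) {
    warn("Swapping n_minor/n_major where n_minor > n_major (orientation convention).")
    tmp <- n_minor
    n_minor <- ifelse(swap, n_major, n_minor)
    n_major <- ifelse(swap, tmp, n_major)
  }
  if (any(n_minor == n_major)) {
    abort(paste(
      "Allelically balanced genotypes (n_minor == n_major) keep mBAF at 0.5;",
      "MSF is not identifiable from allele frequencies."
    ))
  }
  denom <- mbaf * (n_minor + n_major - 2) - n_major + 1
  if (any(abs(denom) < 1e-12)) {
    abort("Degenerate mBAF/allelic composition: zero denominator.")
  }
  msf <- (1 - 2 * mbaf) / denom
  out <- clamp_fraction(msf, tol)
  structure(out$value, flagged = out$flagged)
}

#' Estimate tumor cell fraction (purity) from clonal MSF values
#'
#' The tumor cell fraction (TCF) of a sample is the mean mutated sample
#' fraction of its clonal aberrations; the spread of those values defines the
#' interval of clonal events, `TCF +/- 2 * SD_MSF` on the MSF scale, inside
#' which an aberration is called clonal by [classify_clonality()].
#'
#' @param clonal_msfs Numeric vector of MSF values of aberrations designated
#'   clonal (at least one).
#' @param sample_id Optional sample identifier carried into the result.
#' @return An object of class `purity_estimate`: a list with `sample_id`,
#'   `tcf`, `sd_msf`, `clonal_msf_interval` (length-2 numeric) and `n_clonal`.
#' @examples
#' estimate_tcf(c(1.0, 0.9, 0.95))
#' @export
estimate_tcf <- function(clonal_msfs, sample_id = NA_character_) {
  check_numeric(clonal_msfs, "clonal_msfs")
  if (length(clonal_msfs) == 0) {
    abort("At least one clonal MSF value is required to estimate purity.")
  }
  tcf <- mean(clonal_msfs)
  sd_msf <- if (length(clonal_msfs) == 1) 0 else sd(clonal_msfs)
  structure(
    list(
      sample_id = sample_id,
      tcf = tcf,
      sd_msf = sd_msf,
      clonal_msf_interval = c(tcf - 2 * sd_msf, tcf + 2 * sd_msf),
      n_clonal = length(clonal_msfs)
    ),
    class = "purity_estimate"
  )
}

#' @export
print.purity_estimate <- function(x, ...) {
  cat(sprintf(
    "Purity estimate%s: TCF = %.3f (SD of clonal MSF = %.3f, n = %d)\n",
    if (is.na(x$sample_id)) "" else paste0(" for ", x$sample_id),
    x$tcf, x$sd_msf, x$n_clonal
  ))
  cat(sprintf(
    "Interval of clonal events (MSF scale): [%.3f, %.3f]\n",
    x$clonal_msf_interval[1], x$clonal_msf_interval[2]
  ))
  invisible(x)
}

#' Classify aberrations as clonal or subclonal
#'
#' An aberration whose MSF falls inside the sample's interval of clonal
#' events is clonal and its mutated clone fraction (MCF) is set to 1 exactly;
#' otherwise it is subclonal with `mcf = msf / tcf` (clamped into \[0, 1\]).
#' Interval boundaries count as clonal. MSF values flagged out-of-range by the
#' estimators propagate their flag.
#'
#' @param msf Numeric vector of mutated sample fractions (may carry a
#'   `flagged` attribute from [msf_from_log2r()] / [msf_from_mbaf()]).
#' @param purity A `purity_estimate` from [estimate_tcf()].
#' @return A tibble with columns `msf`, `mcf`, `status` (factor
#'   clonal/subclonal) and `flagged`.
#' @examples
#' p <- estimate_tcf(c(0.92, 0.95, 0.98))
#' classify_clonality(c(0.93, 0.40), p)
#' @export
classify_clonality <- function(msf, purity) {
  stopifnot(inherits(purity, "purity_estimate"))
  if (purity$tcf <= 0) abort("Purity (TCF) must be positive.")
  flagged <- attr(msf, "flagged") %||% rep(FALSE, length(msf))
  msf <- as.numeric(msf)
  lo <- purity$clonal_msf_interval[1]
  hi <- purity$clonal_msf_interval[2]
  clonal <- msf >= lo & msf <= hi
  tibble(
    msf = msf,
    mcf = ifelse(clonal, 1, pmin(pmax(msf / purity$tcf, 0), 1)),
    status = factor(ifelse(clonal, "clonal", "subclonal"),
      levels = c("clonal", "subclonal")
    ),
    flagged = flagged
  )
}

# Clonal-designation proxy: the densest cluster of MSF values inside a
# window-wide band containing the maximum MSF. Any such band is maximised by
# anchoring its upper edge at the maximum, so the proxy reduces to
# msf >= max(msf) - window.
auto_clonal_designation <- function(msf, window = 0.1) {
  msf >= max(msf) - window
}

#' Run the bulk clonality pipeline on a segment table
#'
#' For each sample: computes per-segment MSF (from the mirrored B-allele
#' frequency for copy-neutral imbalances, from the log2 intensity ratio
#' otherwise), estimates purity from the clonal aberrations, and classifies
#' every aberration as clonal (MCF set to 1) or subclonal (MCF = MSF / TCF).
#'
#' Which aberrations anchor the purity estimate is controlled by
#' `clonal_mode`: `"designated"` (default) expects a logical `is_clonal`
#' column marking curated clonal calls; `"auto"` uses the densest cluster of
#' MSF values within a 0.1-wide window containing the maximum MSF.
#'
#' @param segments Data frame with columns `sample_id`, `chrom`, `start`,
#'   `end`, `kind` (gain/loss/cnni/high_grade_amplification), `log2r`,
#'   `mbaf` (may be NA), `n_minor`, `n_major`, `background_ploidy`,
#'   `marker_count`, plus `is_clonal` when `clonal_mode = "designated"`.
#' @param clonal_mode `"designated"` or `"auto"`.
#' @param min_length_bp,min_markers Curation filter, see [filter_segments()].
#' @param tol MSF clamping tolerance.
#' @return A tibble: the filtered segments plus `msf`, `mcf`, `status`,
#'   `flagged`, `tcf`, `sd_msf`. High-grade amplifications keep their MSF but
#'   are marked `flagged` (their total ploidy is poorly determined, making the
#'   estimate low-confidence).
#' @export
bulk_clonality <- function(segments,
                           clonal_mode = c("designated", "auto"),
                           min_length_bp = 50000L, min_markers = 50L,
                           tol = 0.05) {
  clonal_mode <- match.arg(clonal_mode)
  check_columns(segments, c(
    "sample_id", "chrom", "start", "end", "kind", "log2r", "mbaf",
    "n_minor", "n_major", "background_ploidy", "marker_count"
  ), "segments")
  if (clonal_mode == "designated") {
    check_columns(segments, "is_clonal", "segments")
  }
  segs <- filter_segments(segments, min_length_bp, min_markers)
  if (nrow(segs) == 0) {
    return(segs |> mutate(
      msf = numeric(0), mcf = numeric(0),
      status = factor(character(0), levels = c("clonal", "subclonal")),
      flagged = logical(0), tcf = numeric(0), sd_msf = numeric(0)
    ))
  }

  msf_one <- function(row) {
    n_total <- row$n_minor + row$n_major
    if (row$kind == "cnni" || n_total == row$background_ploidy) {
      msf_from_mbaf(row$mbaf, row$n_minor, row$n_major, tol = tol)
    } else {
      msf_from_log2r(row$log2r, n_total, row$background_ploidy, tol = tol)
    }
  }

  segs |>
    group_by(.data$sample_id) |>
    dplyr::group_modify(function(df, key) {
      vals <- purrr::map(seq_len(nrow(df)), function(i) msf_one(df[i, ]))
      msf <- purrr::map_dbl(vals, as.numeric)
      flg <- purrr::map_lgl(vals, function(v) isTRUE(attr(v, "flagged")))
      flg <- flg | df$kind == "high_grade_amplification"
      clonal_sel <- if (clonal_mode == "designated") {
        sel <- df$is_clonal %in% TRUE
        if (!any(sel)) {
          warn(sprintf(
            "Sample %s has no designated clonal segment; falling back to the automatic proxy.",
            key$sample_id
          ))
          auto_clonal_designation(msf)
        } else {
          sel
        }
      } else {
        auto_clonal_designation(msf)
      }
      purity <- estimate_tcf(msf[clonal_sel], key$sample_id)
      calls <- classify_clonality(structure(msf, flagged = flg), purity)
      df |>
        mutate(
          msf = calls$msf, mcf = calls$mcf, status = calls$status,
          flagged = calls$flagged,
          tcf = purity$tcf, sd_msf = purity$sd_msf
        )
    }) |>
    ungroup()
}
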