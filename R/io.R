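# Tabular readers/writers for the pipeline's plain-text interchange formats.
# All are thin readr wrappers pinned to the column types each module expects.

#' Read / write allele-specific segment tables
#'
#' Tab-separated with a header row; columns `sample_id`, `chrom`, `start`,
#' `end`, `kind`, `log2r`, `mbaf` (may be empty), `n_minor`, `n_major`,
#' `background_ploidy`, `marker_count`, and optionally `is_clonal`.
#'
#' @param path File path.
#' @return A tibble of segments.
#' @export
read_segments_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    chrom = readr::col_character(),
    start = readr::col_double(),
    end = readr::col_double(),
    kind = readr::col_character(),
    log2r = readr::col_double(),
    mbaf = readr::col_double(),
    n_minor = readr::col_integer(),
    n_major = readr::col_integer(),
    background_ploidy = readr::col_integer(),
    marker_count = readr::col_integer(),
    .default = readr::col_guess()
  ))
}

#' @rdname read_segments_tsv
#' @param x Segment (or call) tibble to write.
#' @export
write_segments_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' Read a single-cell copy-number matrix from BED bins + TSV matrix
#'
#' `bins_path` is a 3-column BED (chrom, start, end, no header); the matrix
#' TSV has one row per bin and one named column per cell.
#'
#' @param bins_path BED file of bins.
#' @param matrix_path TSV of integer copy states.
#' @param baseline_ploidy Baseline copy number (scalar or per cell).
#' @return A [cell_bin_matrix()].
#' @export
read_cell_matrix <- function(bins_path, matrix_path, baseline_ploidy = 2L) {
  bins <- readr::read_tsv(
    bins_path,
    col_names = c("chrom", "start", "end"),
    col_types = "cdd"
  )
  m <- as.matrix(readr::read_tsv(matrix_path, col_types = readr::cols(
    .default = readr::col_integer()
  )))
  cell_bin_matrix(bins, m, baseline_ploidy)
}

#' Read / write clone-frequency tables
#'
#' Tab-separated with columns `tumor_id`, `time`, `clone`, `frequency` and
#' `events` (semicolon-joined event tokens; may be empty).
#'
#' @param path File path.
#' @return A tibble with `events` parsed into a list column.
#' @export
read_clone_frequencies_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    tumor_id = readr::col_character(),
    time = readr::col_double(),
    clone = readr::col_character(),
    frequency = readr::col_double(),
    events = readr::col_character()
  )) |>
    mutate(events = purrr::map(.data$events, function(s) {
      if (is.na(s) || s == "") character(0) else strsplit(s, ";")[[1]]
    }))
}

#' @rdname read_clone_frequencies_tsv
#' @param x Clone-frequency tibble (with `events` list column) to write.
#' @export
write_clone_frequencies_tsv <- function(x, path) {
  x |>
    mutate(events = purrr::map_chr(.data$events, paste, collapse = ";")) |>
    readr::write_tsv(path)
  invisible(path)
}

#' Read a gene signature from a two-column TSV
#'
#' Columns `gene` and `source`; one row per (gene, contributing source).
#'
#' @param path File path.
#' @param name Signature name (default: file name).
#' @param prognosis Passed to [gene_signature()].
#' @return A `gene_signature`.
#' @export
read_signature_tsv <- function(path, name = NULL,
                               prognosis = NA_character_) {
  tb <- readr::read_tsv(path, col_types = "cc")
  check_columns(tb, c("gene", "source"), "signature file")
  gene_signature(tb$gene,
    name = name %||% sub("\\.tsv$", "", basename(path)),
    sources = tb$source, prognosis = prognosis
  )
}
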