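# 1-Mb bin grid over the 22 human autosomes (GRCh38 lengths, rounded down to
# whole megabases). Sex chromosomes are omitted: the copy-number aberrations
# modelled here are autosome-dominated.
autosome_mb <- c(
  chr1 = 248L, chr2 = 242L, chr3 = 198L, chr4 = 190L, chr5 = 181L,
  chr6 = 170L, chr7 = 159L, chr8 = 145L, chr9 = 138L, chr10 = 133L,
  chr11 = 135L, chr12 = 133L, chr13 = 114L, chr14 = 107L, chr15 = 101L,
  chr16 = 90L, chr17 = 83L, chr18 = 80L, chr19 = 58L, chr20 = 64L,
  chr21 = 46L, chr22 = 50L
)

#' Genome bin grid at 1-Mb resolution
#'
#' Returns the bin scaffold used by the single-cell machinery and the
#' simulators: the 22 human autosomes tiled into 1-Mb bins, BED-style
#' (0-based half-open coordinates).
#'
#' @param chroms Character vector of chromosome names to include
#'   (default: all 22 autosomes).
#' @return A tibble with columns `chrom`, `start`, `end` (bp) sorted by
#'   chromosome then start.
#' @export
genome_bins <- function(chroms = names(autosome_mb)) {
  stopifnot(all(chroms %in% names(autosome_mb)))
  purrr::map_dfr(chroms, function(ch) {
    n <- autosome_mb[[ch]]
    tibble(
      chrom = ch,
      start = as.numeric(0:(n - 1)) * 1e6,
      end = as.numeric(1:n) * 1e6
    )
  })
}
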