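#' Construct a gene signature
#'
#' A directional gene set with provenance: which source lists contributed
#' each gene, and (optionally) the prognosis the signature is expected to
#' carry when highly expressed.
#'
#' @param genes Character vector of gene identifiers (duplicates collapsed).
#' @param name Signature name.
#' @param sources Optional character vector or list parallel to `genes`
#'   naming the contributing source list(s) per gene; defaults to `name`.
#' @param prognosis Expected direction of the survival association for
#'   high expression: `"favorable"`, `"adverse"` or `NA` (unknown).
#' @return An object of class `gene_signature`: a tibble with columns
#'   `gene`, `sources` (list column) and attributes `name`, `prognosis`.
#' @export
gene_signature <- function(genes, name = "signature", sources = NULL,
                           prognosis = NA_character_) {
  if (length(genes) == 0) abort("A signature needs at least one gene.")
  if (!is.na(prognosis) &&
      !prognosis %in% c("favorable", "adverse")) {
    abort('`prognosis` must be "favorable", "adverse" or NA.')
  }
  src <- if (is.null(sources)) {
    rep(list(name), length(genes))
  } else if (is.list(sources)) {
    sources
  } else {
    as.list(sources)
  }
  tb <- tibble(gene = genes, sources = src) |>
    group_by(.data$gene) |>
    summarise(
      sources = list(sort(unique(unlist(.data$sources)))),
      .groups = "drop"
    )
  structure(tb, class = c("gene_signature", class(tb)),
            name = name, prognosis = prognosis)
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf(
    "gene_signature \"%s\": %d gene(s)%s\n",
    attr(x, "name"), nrow(x),
    if (is.na(attr(x, "prognosis"))) "" else
      paste0(", expected prognosis when high: ", attr(x, "prognosis"))
  ))
  invisible(x)
}

#' Per-sample average z-score of a gene signature
#'
#' Standardises every gene across samples (mean 0, sd 1) and scores each
#' sample as the mean z over the signature genes present in the matrix.
#' Genes with zero variance carry no information and are dropped with a
#' warning.
#'
#' @param expr Numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns; or a data frame with a `gene` column followed by sample
#'   columns.
#' @param signature A `gene_signature` or plain character vector of genes.
#' @return A tibble with columns `sample`, `score` and attribute
#'   `n_genes_used`.
#' @export
zscore_signature_score <- function(expr, signature) {
  m <- as_expression_matrix(expr)
  genes <- if (inherits(signature, "gene_signature")) {
    signature$gene
  } else {
    as.character(signature)
  }
  present <- intersect(genes, rownames(m))
  if (length(present) == 0) {
    abort("No signature gene is present in the expression matrix.")
  }
  if (ncol(m) < 2) abort("At least two samples are required for z-scores.")
  sub <- m[present, , drop = FALSE]
  sds <- apply(sub, 1, sd)
  constant <- sds == 0 | is.na(sds)
  if (any(constant)) {
    warn(sprintf(
      "Dropping %d constant gene(s) from the signature score.",
      sum(constant)
    ))
    sub <- sub[!constant, , drop = FALSE]
    if (nrow(sub) == 0) abort("All overlapping signature genes are constant.")
  }
  z <- t(scale(t(sub)))
  out <- tibble(sample = colnames(m), score = unname(colMeans(z)))
  attr(out, "n_genes_used") <- nrow(sub)
  out
}

as_expression_matrix <- function(expr) {
  if (is.matrix(expr)) {
    if (is.null(rownames(expr))) abort("Expression matrix needs gene rownames.")
    return(expr)
  }
  check_columns(expr, "gene", "expr")
  genes <- expr$gene
  if (anyDuplicated(genes)) abort("Duplicate gene identifiers in `expr`.")
  m <- as.matrix(expr[setdiff(names(expr), "gene")])
  rownames(m) <- genes
  m
}

#' Top variance-ranked genes
#'
#' Ranks genes by their sample variance across samples (descending) and
#' returns the first `n`. Ties at the selection boundary are broken by the
#' lexicographically smaller gene identifier; if fewer than `n` genes exist,
#' all are returned with a warning.
#'
#' @param expr Expression matrix or data frame (see
#'   [zscore_signature_score()]).
#' @param n Number of genes to keep (default 1000).
#' @return Character vector of gene identifiers, most variable first.
#' @export
top_variable_genes <- function(expr, n = 1000L) {
  if (n < 1) abort("`n` must be at least 1.")
  m <- as_expression_matrix(expr)
  if (nrow(m) == 0) abort("The expression matrix has no genes.")
  v <- apply(m, 1, var)
  ord <- order(-v, rownames(m))
  if (n > nrow(m)) {
    warn(sprintf(
      "Requested %d genes but the matrix has only %d; returning all.",
      n, nrow(m)
    ))
    n <- nrow(m)
  }
  rownames(m)[ord[seq_len(n)]]
}

#' Merge gene signatures with provenance and disjointness resolution
#'
#' Unions the member genes of several source signatures, tracking which
#' sources support each gene. When an opposing signature set is supplied
#' (e.g. merging adrenergic sources against mesenchymal ones), genes claimed
#' by both sides are resolved by majority of supporting sources; ties are
#' dropped from both sides and reported.
#'
#' @param sources List of `gene_signature` objects (or character vectors) to
#'   merge.
#' @param opposing Optional list of signatures for the opposing side.
#' @param name Name for the merged signature.
#' @param prognosis Passed to [gene_signature()].
#' @return A `gene_signature`; genes dropped by the tie rule are recorded in
#'   attribute `dropped`.
#' @export
merge_signatures <- function(sources, opposing = NULL, name = "merged",
                             prognosis = NA_character_) {
  if (length(sources) == 0) abort("At least one source signature is required.")
  as_sig_list <- function(x, prefix) {
    purrr::imap(x, function(s, i) {
      nm <- if (is.character(i) && nzchar(i)) i else paste0(prefix, i)
      if (inherits(s, "gene_signature")) s else gene_signature(s, name = nm)
    })
  }
  src <- as_sig_list(sources, "source")
  support <- bind_rows(purrr::map(src, function(s) {
    tibble(gene = s$gene, source = attr(s, "name"))
  })) |>
    distinct() |>
    group_by(.data$gene) |>
    summarise(sources = list(sort(unique(.data$source))),
              n = dplyr::n(), .groups = "drop")

  dropped <- character(0)
  if (!is.null(opposing) && length(opposing) > 0) {
    opp <- as_sig_list(opposing, "opposing")
    opp_support <- bind_rows(purrr::map(opp, function(s) {
      tibble(gene = s$gene, source = attr(s, "name"))
    })) |>
      distinct() |>
      group_by(.data$gene) |>
      summarise(n_opp = dplyr::n(), .groups = "drop")
    support <- support |>
      left_join(opp_support, by = "gene") |>
      mutate(n_opp = dplyr::coalesce(.data$n_opp, 0L))
    dropped <- support$gene[support$n == support$n_opp & support$n_opp > 0]
    keep <- support$n > support$n_opp
    if (length(dropped) > 0) {
      inform(sprintf(
        "Dropping %d gene(s) tied between the two sides: %s",
        length(dropped),
        paste(head(dropped, 5), collapse = ", ")
      ))
    }
    support <- support[keep, ]
  }
  if (nrow(support) == 0) abort("No genes survive the merge.")
  out <- gene_signature(support$gene, name = name,
                        sources = support$sources, prognosis = prognosis)
  attr(out, "dropped") <- dropped
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity; input
#' order is preserved. Thin validated wrapper over
#' `stats::p.adjust(method = "BH")`.
#'
#' @param pvalues Numeric p-values in \[0, 1\].
#' @return Adjusted q-values, same order as the input.
#' @export
bh_fdr <- function(pvalues) {
  check_numeric(pvalues, "pvalues")
  if (any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(pvalues, method = "BH")
}
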