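# independent forward models and oracles used across the suite

# two-population mixture: mean copy number relative to background ploidy
forward_log2r <- function(m, n_total, background_ploidy = 2) {
  log2((m * n_total + (1 - m) * background_ploidy) / background_ploidy)
}

# allele mixture on a diploid heterozygous background: aberrant cells carry
# n_major copies of the B allele out of n_minor + n_major; normal cells 1/2
forward_mbaf <- function(m, n_minor, n_major) {
  (m * n_major + (1 - m)) / (m * (n_minor + n_major) + 2 * (1 - m))
}

# phangorn-based parsimony oracle: the rooted problem with an all-zero
# ancestor is equivalent to unrooted parsimony with an extra all-zero tip
phangorn_phydat <- function(m) {
  m2 <- cbind(m, ROOT = 0L)
  phangorn::phyDat(t(m2), type = "USER", levels = c(0L, 1L))
}

phangorn_score <- function(newick, m) {
  core <- sub(";*$", "", newick)
  tr <- ape::read.tree(text = paste0("(", core, ",ROOT);"))
  phangorn::parsimony(tr, phangorn_phydat(m))
}

# minimum parsimony score over every unrooted topology (leaves + ROOT tip)
phangorn_min_score <- function(m) {
  labs <- c(colnames(m), "ROOT")
  trees <- phangorn::allTrees(length(labs), rooted = FALSE,
                              tip.label = labs)
  dat <- phangorn_phydat(m)
  min(vapply(trees, phangorn::parsimony, numeric(1), data = dat))
}

random_event_matrix <- function(seed, n_leaves, n_events) {
  set.seed(seed)
  repeat {
    m <- matrix(rbinom(n_leaves * n_events, 1, 0.4),
      nrow = n_events,
      dimnames = list(
        sprintf("e%02d", seq_len(n_events)),
        sprintf("L%d", seq_len(n_leaves))
      )
    )
    if (all(rowSums(m) > 0)) return(m)
  }
}

uniform_mixture_named <- function(truth) {
  cl <- names(truth$parents)
  setNames(rep(1 / length(cl), length(cl)), cl)
}
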