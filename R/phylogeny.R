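# ---- nested-list tree machinery -------------------------------------------
#
# Rooted binary trees are built as nested lists (leaf = label string,
# internal node = list(left, right)); for scoring they are flattened to a
# postorder edge matrix with ape-style numbering (tips 1..n, root n+1).

tree_leaves <- function(tree) {
  if (is.character(tree)) return(tree)
  c(tree_leaves(tree[[1]]), tree_leaves(tree[[2]]))
}

tree_to_edges <- function(tree, tip_labels) {
  n <- length(tip_labels)
  if (is.character(tree)) {
    return(matrix(integer(0), ncol = 2))
  }
  next_internal <- n + 1L
  edges <- matrix(integer(0), ncol = 2)
  assign_ids <- function(node) {
    # preorder internal numbering so the root is always n + 1
    if (is.character(node)) {
      return(list(id = match(node, tip_labels), rows = NULL))
    }
    me <- next_internal
    next_internal <<- next_internal + 1L
    l <- assign_ids(node[[1]])
    r <- assign_ids(node[[2]])
    rows <- rbind(l$rows, r$rows, c(me, l$id), c(me, r$id))
    list(id = me, rows = rows)
  }
  res <- assign_ids(tree)
  res$rows
}

canonical_newick <- function(tree) {
  if (is.character(tree)) return(tree)
  kids <- sort(c(canonical_newick(tree[[1]]), canonical_newick(tree[[2]])))
  paste0("(", kids[1], ",", kids[2], ")")
}

canonicalize_tree <- function(tree) {
  if (is.character(tree)) return(tree)
  a <- canonicalize_tree(tree[[1]])
  b <- canonicalize_tree(tree[[2]])
  if (canonical_newick(a) <= canonical_newick(b)) list(a, b) else list(b, a)
}

# all rooted binary trees on the given labels, by recursive leaf insertion
# above every node ((2n - 3)!! trees)
enumerate_rooted_trees <- function(labels) {
  n <- length(labels)
  if (n == 1) return(list(labels[1]))
  trees <- list(list(labels[1], labels[2]))
  if (n == 2) return(trees)
  for (i in 3:n) {
    x <- labels[i]
    trees <- unlist(lapply(trees, function(tr) insert_above_each(tr, x)),
                    recursive = FALSE)
  }
  trees
}

insert_above_each <- function(tree, x) {
  out <- list(list(tree, x)) # above the root
  if (is.character(tree)) return(out)
  for (side in 1:2) {
    for (sub in insert_above_each(tree[[side]], x)) {
      t2 <- tree
      t2[[side]] <- sub
      out[[length(out) + 1]] <- t2
    }
  }
  out
}

# rooted nearest-neighbor interchanges: for every internal node with an
# internal child (X,(B,C)), the two regraftings (B,(X,C)) and (C,(B,X))
nni_neighbors <- function(tree) {
  out <- list()
  replace_at <- function(tr, path, value) {
    if (length(path) == 0) return(value)
    tr[[path[1]]] <- replace_at(tr[[path[1]]], path[-1], value)
    tr
  }
  # neighbors are generated per internal node, replacing that node wholesale
  walk2 <- function(node, path) {
    if (is.character(node)) return(invisible(NULL))
    x <- node[[1]]; s <- node[[2]]
    if (!is.character(s)) {
      out[[length(out) + 1]] <<- replace_at(tree, path,
                                            list(s[[1]], list(x, s[[2]])))
      out[[length(out) + 1]] <<- replace_at(tree, path,
                                            list(s[[2]], list(s[[1]], x)))
    }
    if (!is.character(x)) {
      out[[length(out) + 1]] <<- replace_at(tree, path,
                                            list(x[[1]], list(x[[2]], s)))
      out[[length(out) + 1]] <<- replace_at(tree, path,
                                            list(x[[2]], list(x[[1]], s)))
    }
    walk2(x, c(path, 1))
    walk2(s, c(path, 2))
  }
  walk2(tree, integer(0))
  out
}

# subtree prune and regraft: every (pruned subtree, remainder) pair,
# reinserted above every node of the remainder; strictly larger than the
# NNI neighborhood and the standard escape from its local optima
spr_neighbors <- function(tree) {
  if (is.character(tree)) return(list())
  prunings <- list()
  walk <- function(node, path) {
    if (is.character(node)) return(invisible(NULL))
    for (side in 1:2) {
      sub <- node[[side]]
      rest <- remove_at(tree, c(path, side))
      prunings[[length(prunings) + 1]] <<- list(sub = sub, rest = rest)
      walk(sub, c(path, side))
    }
  }
  # removing a child promotes its sibling into the parent's place
  remove_at <- function(tr, path) {
    if (length(path) == 1) return(tr[[3 - path[1]]])
    tr[[path[1]]] <- remove_at(tr[[path[1]]], path[-1])
    tr
  }
  walk(tree, integer(0))
  out <- list()
  for (p in prunings) {
    for (cand in insert_above_each(p$rest, p$sub)) {
      out[[length(out) + 1]] <- cand
    }
  }
  out
}

# per-event Fitch change counts for a nested tree and a binary event matrix
# (events x leaves); root anchored in the all-zero ancestral state
fitch_tree_counts <- function(tree, em_matrix) {
  labels <- colnames(em_matrix)
  if (nrow(em_matrix) == 0) return(integer(0))
  tips <- t(em_matrix[, labels, drop = FALSE])
  storage.mode(tips) <- "integer"
  if (length(labels) == 1) {
    return(as.integer(tips[1, ] != 0L))
  }
  edges <- tree_to_edges(tree, labels)
  .fitch_counts(edges, length(labels), tips)
}

fitch_tree_score <- function(tree, em_matrix) {
  sum(fitch_tree_counts(tree, em_matrix))
}

# topology cache (generic edge matrices + nested trees per leaf count)
.topology_cache <- new.env(parent = emptyenv())

cached_topologies <- function(n) {
  key <- as.character(n)
  if (is.null(.topology_cache[[key]])) {
    labels <- paste0(".t", seq_len(n))
    trees <- enumerate_rooted_trees(labels)
    edges <- lapply(trees, tree_to_edges, tip_labels = labels)
    .topology_cache[[key]] <- list(trees = trees, edges = edges,
                                   labels = labels)
  }
  .topology_cache[[key]]
}

relabel_tree <- function(tree, from, to) {
  if (is.character(tree)) return(to[match(tree, from)])
  list(relabel_tree(tree[[1]], from, to), relabel_tree(tree[[2]], from, to))
}

# ---- user-facing operations -----------------------------------------------

#' Maximum-parsimony clone tree from a binary event matrix
#'
#' Finds a rooted tree over the matrix columns (clones, cells or samples)
#' minimising the total number of character state changes under binary
#' unordered (Fitch) parsimony, with the root anchored at the unaberrated
#' all-zero ancestor — gains and losses of an event both count one change.
#'
#' With up to `exhaustive_max` leaves every rooted binary topology is scored,
#' guaranteeing the optimum; larger matrices use restarted seeded stepwise
#' addition followed by steepest-descent hill climbing over
#' subtree-prune-regraft rearrangements, with bounded sideways moves across
#' equal-score plateaus. Among equally parsimonious trees the
#' lexicographically smallest canonical (sorted) newick is returned, so
#' results are reproducible for a fixed seed.
#'
#' @param em An `event_matrix` (binary), or a plain 0/1 matrix with events in
#'   rows and named columns.
#' @param search `"auto"` (exhaustive up to `exhaustive_max` leaves, else
#'   heuristic), `"exhaustive"` or `"heuristic"`.
#' @param seed Integer seed for the heuristic's addition order.
#' @param exhaustive_max Leaf count up to which exhaustive search runs
#'   (default 7).
#' @return An object of class `clone_tree`: list with `newick` (canonical),
#'   `tree` (nested-list form), `labels`, `score` (total changes),
#'   `per_event_changes` (named integer), `edge_events` (tibble of per-edge
#'   acquired/lost events; parent `"root"` denotes the edge from the all-zero
#'   ancestor), `search` and `n_leaves`.
#' @examples
#' em <- event_matrix_from_sets(list(
#'   p = c("A"), q = c("A", "B"), r = c("A", "B", "C")
#' ))
#' tr <- max_parsimony_tree(em)
#' tr$score # 3: one change per event, a perfect phylogeny
#' @export
max_parsimony_tree <- function(em, search = c("auto", "exhaustive",
                                              "heuristic"),
                               seed = 1L, exhaustive_max = 7L) {
  search <- match.arg(search)
  m <- if (inherits(em, "event_matrix")) em$matrix else as.matrix(em)
  if (ncol(m) == 0) abort("The event matrix has no columns (clones/samples).")
  if (nrow(m) > 0 && !all(m %in% c(0L, 1L))) {
    abort("The event matrix must be binary for parsimony reconstruction.")
  }
  labels <- colnames(m)
  if (is.null(labels)) abort("The event matrix must have column names.")
  if (is.null(rownames(m)) && nrow(m) > 0) {
    rownames(m) <- sprintf("E%d", seq_len(nrow(m)))
  }
  n <- length(labels)

  if (n == 1) {
    tree <- labels[1]
  } else if (search == "exhaustive" ||
             (search == "auto" && n <= exhaustive_max)) {
    if (n > 9) {
      abort("Exhaustive search is limited to 9 leaves; use search = \"heuristic\".")
    }
    topo <- cached_topologies(n)
    tips <- t(m)
    storage.mode(tips) <- "integer"
    scores <- vapply(
      topo$edges,
      function(ed) sum(.fitch_counts(ed, n, tips)),
      numeric(1)
    )
    best <- which(scores == min(scores))
    cands <- lapply(topo$trees[best], relabel_tree, from = topo$labels,
                    to = labels)
    nwk <- vapply(cands, canonical_newick, character(1))
    tree <- cands[[match(min(nwk), nwk)]]
  } else {
    tree <- stepwise_nni_search(m, labels, seed)
  }

  finalize_clone_tree(tree, m, labels, search)
}

# Seeded stepwise addition followed by hill climbing over NNI and SPR
# rearrangements, restarted from several random addition orders; the best
# local optimum (ties broken by canonical newick) is returned.
stepwise_nni_search <- function(m, labels, seed, n_starts = 5L) {
  best_tree <- NULL
  best_score <- Inf
  best_nwk <- ""
  for (s in seq_len(n_starts)) {
    set.seed(derive_seed(seed, s))
    ord <- sample(labels)
    tree <- list(ord[1], ord[2])
    if (length(ord) > 2) {
      for (x in ord[-(1:2)]) {
        cands <- insert_above_each(tree, x)
        scores <- vapply(cands, fitch_tree_score, numeric(1), em_matrix = m)
        best <- which(scores == min(scores))
        nwk <- vapply(cands[best], canonical_newick, character(1))
        tree <- cands[best][[match(min(nwk), nwk)]]
      }
    }
    # steepest-descent hill climbing over SPR rearrangements (a superset of
    # NNI), with a bounded number of sideways moves across equal-score
    # plateaus — parsimony landscapes are plateau-rich and pure descent
    # stalls on them
    score <- fitch_tree_score(tree, m)
    visited <- new.env(parent = emptyenv())
    assign(canonical_newick(tree), TRUE, envir = visited)
    sideways_left <- 10L * length(labels)
    repeat {
      nbs <- spr_neighbors(tree)
      ss <- vapply(nbs, fitch_tree_score, numeric(1), em_matrix = m)
      if (length(ss) == 0) break
      if (min(ss) < score) {
        hits <- which(ss == min(ss))
        nwk <- vapply(nbs[hits], canonical_newick, character(1))
        tree <- nbs[hits][[match(min(nwk), nwk)]]
        score <- min(ss)
        assign(canonical_newick(tree), TRUE, envir = visited)
        next
      }
      if (min(ss) > score || sideways_left <= 0L) break
      hits <- which(ss == score)
      nwk <- vapply(nbs[hits], canonical_newick, character(1))
      fresh <- !vapply(nwk, exists, logical(1), envir = visited)
      if (!any(fresh)) break
      pick <- which(fresh)[match(min(nwk[fresh]), nwk[fresh])]
      tree <- nbs[hits][[pick]]
      assign(nwk[fresh][match(min(nwk[fresh]), nwk[fresh])], TRUE,
             envir = visited)
      sideways_left <- sideways_left - 1L
    }
    nwk <- canonical_newick(tree)
    if (score < best_score ||
        (score == best_score && nwk < best_nwk)) {
      best_tree <- tree
      best_score <- score
      best_nwk <- nwk
    }
  }
  best_tree
}

finalize_clone_tree <- function(tree, m, labels, search) {
  tree <- canonicalize_tree(tree)
  counts <- fitch_tree_counts(tree, m)
  names(counts) <- rownames(m)
  structure(
    list(
      newick = paste0(canonical_newick(tree), ";"),
      tree = tree,
      labels = sort(labels),
      score = sum(counts),
      per_event_changes = counts,
      edge_events = edge_event_assignment(tree, m),
      search = search,
      n_leaves = length(labels)
    ),
    class = "clone_tree"
  )
}

#' @export
print.clone_tree <- function(x, ...) {
  cat(sprintf(
    "Maximum-parsimony clone tree: %d leaves, %d event(s), score %d\n",
    x$n_leaves, length(x$per_event_changes), x$score
  ))
  cat(x$newick, "\n")
  invisible(x)
}

# Fitch ancestral reconstruction with deterministic top-down refinement
# (a node keeps its parent's state whenever its Fitch set allows it), then
# per-edge acquired/lost event labels. The edge from the all-zero ancestor to
# the root is reported with parent "root".
edge_event_assignment <- function(tree, m) {
  events <- rownames(m) %||% character(nrow(m))
  node_name <- function(node) {
    if (is.character(node)) node else canonical_newick(node)
  }
  rows <- list()
  assign_event <- function(ev) {
    states <- setNames(as.numeric(m[ev, ]), colnames(m))
    down <- function(node) { # returns Fitch set as bitmask (1={0},2={1},3=both)
      if (is.character(node)) return(if (states[[node]] == 1) 2L else 1L)
      a <- down(node[[1]]); b <- down(node[[2]])
      if (bitwAnd(a, b) > 0) bitwAnd(a, b) else bitwOr(a, b)
    }
    sets <- new.env()
    annotate <- function(node) {
      key <- node_name(node)
      if (is.character(node)) {
        val <- if (states[[node]] == 1) 2L else 1L
      } else {
        a <- annotate(node[[1]]); b <- annotate(node[[2]])
        val <- if (bitwAnd(a, b) > 0) bitwAnd(a, b) else bitwOr(a, b)
      }
      assign(key, val, envir = sets)
      val
    }
    annotate(tree)
    walk <- function(node, parent_state, parent_name) {
      set <- get(node_name(node), envir = sets)
      state <- if (bitwAnd(set, bitwShiftL(1L, parent_state)) > 0) {
        parent_state
      } else if (set == 2L) 1L else 0L
      if (state != parent_state) {
        rows[[length(rows) + 1]] <<- tibble(
          parent = parent_name, child = node_name(node), event = ev,
          change = if (state == 1L) "acquired" else "lost"
        )
      }
      if (!is.character(node)) {
        walk(node[[1]], state, node_name(node))
        walk(node[[2]], state, node_name(node))
      }
    }
    walk(tree, 0L, "root")
  }
  for (ev in events) assign_event(ev)
  if (length(rows) == 0) {
    return(tibble(parent = character(0), child = character(0),
                  event = character(0), change = character(0)))
  }
  bind_rows(rows)
}

#' Stem event set of a collection of samples or clones
#'
#' The stem is the set of aberrations shared by every sample (or clone or
#' organoid) of a model: the intersection of all their event sets.
#'
#' @param event_sets A list of character vectors (one event set per sample).
#' @return Character vector of stem events.
#' @examples
#' identify_stem(list(c("A", "B"), c("A", "B", "C"), c("A", "B", "D")))
#' @export
identify_stem <- function(event_sets) {
  if (length(event_sets) == 0) abort("At least one event set is required.")
  Reduce(intersect, event_sets)
}

#' Detect homoplasy (parallel evolution) on a fixed clone tree
#'
#' For each event, counts the minimum number of state changes required on the
#' given tree (Fitch counting, root anchored at the all-zero ancestor). An
#' event needing two or more changes cannot be explained by a single origin
#' on that tree and is flagged as parallel evolution.
#'
#' @param tree A `clone_tree`.
#' @param em The `event_matrix` (or binary matrix) the tree was built from;
#'   columns must match the tree's leaves.
#' @return An object of class `homoplasy_report`: a tibble with columns
#'   `event`, `origins` (minimum changes) and `parallel`.
#' @export
detect_homoplasy <- function(tree, em) {
  stopifnot(inherits(tree, "clone_tree"))
  m <- if (inherits(em, "event_matrix")) em$matrix else as.matrix(em)
  if (!setequal(colnames(m), tree$labels)) {
    abort("Tree leaves and event-matrix columns do not match.")
  }
  counts <- fitch_tree_counts(tree$tree, m)
  out <- tibble(
    event = rownames(m) %||% as.character(seq_len(nrow(m))),
    origins = as.integer(counts),
    parallel = counts >= 2
  )
  class(out) <- c("homoplasy_report", class(out))
  out
}

#' Convergent events across independent datasets
#'
#' Finds aberrations observed in two or more independently analysed datasets
#' (e.g. different xenograft models). Two events match when they sit on the
#' same chromosome, share the same direction and overlap reciprocally by at
#' least `min_reciprocal_overlap` of each event's span.
#'
#' @param datasets Named list of event tibbles, each with columns `chrom`,
#'   `start`, `end`, `direction`.
#' @param min_reciprocal_overlap Minimum reciprocal overlap fraction
#'   (default 0.5).
#' @return A tibble of matched event pairs: dataset and span of each side.
#' @export
cross_dataset_convergence <- function(datasets,
                                      min_reciprocal_overlap = 0.5) {
  if (length(datasets) < 2 || is.null(names(datasets))) {
    abort("`datasets` must be a named list with at least two datasets.")
  }
  all_ev <- purrr::imap_dfr(datasets, function(ev, nm) {
    check_columns(ev, c("chrom", "start", "end", "direction"), nm)
    as_tibble(ev) |> mutate(dataset = nm)
  })
  rows <- list()
  nms <- names(datasets)
  for (i in seq_along(nms)) {
    for (j in seq_along(nms)) {
      if (j <= i) next
      a <- all_ev |> filter(.data$dataset == nms[i])
      b <- all_ev |> filter(.data$dataset == nms[j])
      for (ia in seq_len(nrow(a))) {
        for (ib in seq_len(nrow(b))) {
          if (a$chrom[ia] != b$chrom[ib]) next
          if (a$direction[ia] != b$direction[ib]) next
          ov <- min(a$end[ia], b$end[ib]) - max(a$start[ia], b$start[ib])
          if (ov <= 0) next
          la <- a$end[ia] - a$start[ia]
          lb <- b$end[ib] - b$start[ib]
          if (ov >= min_reciprocal_overlap * la &&
              ov >= min_reciprocal_overlap * lb) {
            rows[[length(rows) + 1]] <- tibble(
              dataset_a = nms[i], chrom = a$chrom[ia],
              start_a = a$start[ia], end_a = a$end[ia],
              dataset_b = nms[j], start_b = b$start[ib], end_b = b$end[ib],
              direction = a$direction[ia]
            )
          }
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble(
      dataset_a = character(0), chrom = character(0), start_a = numeric(0),
      end_a = numeric(0), dataset_b = character(0), start_b = numeric(0),
      end_b = numeric(0), direction = character(0)
    ))
  }
  bind_rows(rows)
}

#' Export a clone tree as newick plus an edge-event table
#'
#' Writes the canonical newick string to `<prefix>.nwk` and the per-edge
#' acquired/lost event assignments to `<prefix>_edges.tsv`.
#'
#' @param tree A `clone_tree`.
#' @param prefix Output path prefix.
#' @return Invisibly, the two paths written.
#' @export
export_clone_tree <- function(tree, prefix) {
  stopifnot(inherits(tree, "clone_tree"))
  nwk <- paste0(prefix, ".nwk")
  writeLines(tree$newick, nwk)
  tsv <- paste0(prefix, "_edges.tsv")
  readr::write_tsv(tree$edge_events, tsv)
  invisible(c(nwk, tsv))
}
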