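# Species-tree-aware rooting.  Every edge of the unrooted gene-tree
# topology is a candidate root position (2n-3 of them for a binary tree
# with n leaves); candidates are scored by
#   * the unicity score U(T) = sum over internal nodes of ln(u_i), where
#     u_i is the product of per-species sequence counts in the subtree --
#     minimised, so duplications are pushed toward the root; and
#   * the taxonomic distance score D(T) = sum over internal nodes of the
#     depth of the node's LCA assignment on the species tree restricted
#     to the species present in the gene tree -- maximised, so the
#     rooted tree agrees with the reference taxonomy as finely as
#     possible.

#' Unicity score of one subtree
#'
#' Product over species of the number of sequences of that species at or
#' below the node; equals 1 exactly when the subtree is unicopy.
#'
#' @param species character vector of the species (with repeats) of the
#'   sequences under the node.
#' @return positive number.
#' @export
node_unicity <- function(species) {
  prod(as.numeric(table(species)))
}

entry_species_vector <- function(entry) unname(entry$map[entry$tree$label[leaf_ids(entry$tree)]])

unicity_score_tree <- function(tree, map) {
  tips <- tips_under(tree)
  internal <- which(!is_leaf(tree))
  sum(vapply(internal, function(v)
    log(node_unicity(unname(map[tree$label[tips[[v]]]]))), numeric(1)))
}

#' Unicity score U(T) of a rooted gene tree
#'
#' Sum of \code{ln(u_i)} over the n-1 internal nodes; 0 exactly when
#' every subtree is unicopy.
#'
#' @param entry a \code{tq_gene_entry} (rooted binary).
#' @return non-negative number (nats).
#' @export
unicity_score <- function(entry) {
  unicity_score_tree(entry$tree, entry$map)
}

distance_score_tree <- function(tree, map, st) {
  tips <- tips_under(tree)
  lv <- leaf_ids(tree)
  sp_of_leaf <- rep(NA_integer_, n_nodes(tree))
  sp_of_leaf[lv] <- vapply(unname(map[tree$label[lv]]), lookup_taxon,
                           integer(1), st = st)
  info <- restriction_info(unique(sp_of_leaf[lv]), st)
  internal <- which(!is_leaf(tree))
  sum(vapply(internal, function(v) {
    l <- lca_ids(unique(sp_of_leaf[tips[[v]]]), st)
    restricted_depth_id(l, info, st)
  }, integer(1)))
}

#' Taxonomic distance score D(T) of a rooted gene tree
#'
#' Each internal node is assigned the LCA of its species on the
#' reference tree; its distance d_i is the depth of that taxon on the
#' species tree restricted to the species present in the gene tree.
#' D(T) is the sum over internal nodes.
#'
#' @param entry a \code{tq_gene_entry}.
#' @param st a \code{tq_species_tree}.
#' @return non-negative integer.
#' @export
distance_score <- function(entry, st) {
  distance_score_tree(entry$tree, entry$map, st)
}

#' Enumerate and score every candidate root
#'
#' One candidate per edge of the unrooted topology.  Each candidate is
#' rescored from scratch: unicity score, taxonomic distance score (when
#' a species tree is given), and the length of the branch the root sits
#' on (the full edge length; missing lengths count as 0 with a warning
#' at selection time).
#'
#' @param entry a \code{tq_gene_entry}.
#' @param st a \code{tq_species_tree}, or \code{NULL} to skip D.
#' @return object of class \code{tq_rootings}: a data frame
#'   (\code{edge}, \code{split}, \code{U}, \code{D}, \code{root_branch})
#'   plus the re-rooted trees.
#' @export
enumerate_rootings <- function(entry, st = NULL) {
  ut <- as_unrooted(entry$tree)
  m <- nrow(ut$edges)
  trees <- lapply(seq_len(m), function(i) root_on_edge(ut, i))
  U <- vapply(trees, unicity_score_tree, numeric(1), map = entry$map)
  D <- if (is.null(st)) rep(NA_integer_, m)
       else vapply(trees, distance_score_tree, integer(1),
                   map = entry$map, st = st)
  tab <- data.frame(edge = seq_len(m),
                    split = edge_splits(ut),
                    U = U, D = D,
                    root_branch = ut$edges$len,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, trees = trees, entry = entry),
            class = "tq_rootings")
}

#' @export
print.tq_rootings <- function(x, ...) {
  cat("Candidate rootings of ", sQuote(x$entry$name), " (",
      nrow(x$table), " edges):\n", sep = "")
  print(x$table[, c("edge", "U", "D", "root_branch")], ...)
  invisible(x)
}

#' Choose the best root of a gene tree
#'
#' Strategies: \code{"unicity"} keeps the candidates minimising U(T);
#' \code{"taxonomy"} keeps those maximising D(T); \code{"combined"}
#' applies them in sequence (unicity first).  Remaining ties are broken
#' by the longest root branch, then deterministically by the first edge
#' in the canonical post-order edge numbering ("arbitrary" placement
#' made reproducible).
#'
#' @param entry a \code{tq_gene_entry}.
#' @param st a \code{tq_species_tree} (required unless
#'   \code{strategy = "unicity"}).
#' @param strategy one of \code{"unicity"}, \code{"taxonomy"},
#'   \code{"combined"}.
#' @param tol candidates within \code{tol} of the optimal U are tied.
#' @return object of class \code{tq_rooted}: the re-rooted
#'   \code{tq_gene_entry}, the chosen edge and its scores, the stage at
#'   which the tie resolved (\code{"unicity"}, \code{"taxonomy"},
#'   \code{"branch"} or \code{"arbitrary"}), the surviving candidate set
#'   at each stage, and the full candidate table.
#' @export
best_root <- function(entry, st = NULL,
                      strategy = c("combined", "unicity", "taxonomy"),
                      tol = 1e-9) {
  strategy <- match.arg(strategy)
  if (is.null(st) && strategy != "unicity")
    stop("strategy ", sQuote(strategy), " needs a species tree", call. = FALSE)
  cand <- enumerate_rootings(entry, st)
  tab <- cand$table
  alive <- seq_len(nrow(tab))
  stages <- list()
  stage <- NA_character_

  if (strategy %in% c("unicity", "combined")) {
    alive <- alive[tab$U[alive] <= min(tab$U[alive]) + tol]
    stages$unicity <- alive
    stage <- "unicity"
  }
  if (length(alive) > 1L && strategy %in% c("taxonomy", "combined")) {
    alive <- alive[tab$D[alive] == max(tab$D[alive])]
    stages$taxonomy <- alive
    stage <- "taxonomy"
  } else if (strategy == "taxonomy") {
    alive <- alive[tab$D[alive] == max(tab$D[alive])]
    stages$taxonomy <- alive
    stage <- "taxonomy"
  }
  if (length(alive) > 1L) {
    bl <- tab$root_branch[alive]
    if (anyNA(bl)) {
      warning("missing branch lengths treated as 0 during root tie-break",
              call. = FALSE)
      bl[is.na(bl)] <- 0
    }
    alive <- alive[bl >= max(bl) - tol]
    stages$branch <- alive
    stage <- "branch"
  }
  if (length(alive) > 1L) {
    alive <- alive[1L] # canonical post-order edge numbering
    stages$arbitrary <- alive
    stage <- "arbitrary"
  }
  chosen <- alive[1L]
  rooted <- structure(list(name = entry$name, tree = cand$trees[[chosen]],
                           map = entry$map),
                      class = "tq_gene_entry")
  structure(list(entry = rooted, edge = chosen,
                 U = tab$U[chosen], D = tab$D[chosen],
                 root_branch = tab$root_branch[chosen],
                 tie_stage = stage, stages = stages,
                 candidates = tab, strategy = strategy),
            class = "tq_rooted")
}

#' @export
print.tq_rooted <- function(x, ...) {
  cat("Root of ", sQuote(x$entry$name), ": edge ", x$edge,
      " (strategy ", x$strategy, ", resolved at stage ", sQuote(x$tie_stage),
      ")\n  U = ", format(x$U, digits = 6),
      if (!is.na(x$D)) paste0(", D = ", x$D),
      ", root branch = ", format(x$root_branch, digits = 6), "\n", sep = "")
  invisible(x)
}
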