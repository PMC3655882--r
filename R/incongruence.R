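# Taxonomic incongruency screening.  Exploration of a rooted gene tree
# goes from the leaves to the root; masking the subtree under a node and
# recomputing the LCA assignment of its *grandfather* reveals clades
# whose placement perturbs the taxonomy.  A detected clade is pruned,
# scored with a perturbation index (species-tree path length between the
# grandfather's old and new assignments, on the tree restricted to the
# species of the full gene tree), and the scan restarts until a fixpoint.

#' Perturbation index between two taxonomic assignments
#'
#' Path length (edge count) between the two taxa on the species tree
#' restricted to the given species set; for nested assignments this is
#' the difference of their restricted depths.
#'
#' @param old,new taxon names (or synonyms).
#' @param present character vector of the species present in the gene
#'   tree (the restriction set).
#' @param st a \code{tq_species_tree}.
#' @return non-negative integer.
#' @export
perturbation_index <- function(old, new, present, st) {
  ids <- unique(vapply(present, lookup_taxon, integer(1), st = st))
  info <- restriction_info(ids, st)
  perturbation_index_id(lookup_taxon(old, st), lookup_taxon(new, st), info, st)
}

perturbation_index_id <- function(old, new, info, st) {
  r1 <- restricted_node(old, info, st)
  r2 <- restricted_node(new, info, st)
  if (r1 == r2) return(0L)
  l <- lca_ids(c(st$tips[[r1]][1], st$tips[[r2]][1]), st)
  # the full-tree LCA of two distinct surviving nodes always survives
  restricted_depth_id(r1, info, st) + restricted_depth_id(r2, info, st) -
    2L * restricted_depth_id(l, info, st)
}

#' Detect taxonomic incongruencies in a rooted gene tree
#'
#' Post-order scan: for every node with a grandfather, tentatively mask
#' the subtree it generates and recompute the grandfather's LCA
#' assignment over the remaining leaves.  If the assignment changes and
#' the support of the implicated branch (the father of the masked
#' subtree -- the clade asserting the conflicting grouping) is at least
#' \code{support_threshold}, the subtree is pruned and a record emitted;
#' the scan then restarts on the pruned tree until no further
#' incongruency is found.  Depths and path lengths are measured on the
#' species tree restricted to the species of the \emph{full} original
#' gene tree.  Pruning never reduces the tree below 2 leaves.
#'
#' @param entry a rooted binary \code{tq_gene_entry}.
#' @param st a \code{tq_species_tree}.
#' @param support_threshold minimal support of the implicated branch
#'   (same scale as the collection's supports); branches without a
#'   support value never pass.
#' @return data frame of class \code{tq_incongruencies}: one row per
#'   record with columns \code{entry}, \code{pruned} (comma-separated
#'   sequence names), \code{n_pruned}, \code{old}, \code{d_old},
#'   \code{new}, \code{d_new}, \code{perturbation}, \code{support}.
#' @export
detect_incongruencies <- function(entry, st, support_threshold = 90) {
  full_present <- unique(vapply(unname(entry$map), lookup_taxon,
                                integer(1), st = st))
  info <- restriction_info(full_present, st)
  tree <- entry$tree
  rec <- list()

  repeat {
    if (sum(is_leaf(tree)) <= 2L) break
    tips <- tips_under(tree)
    lv <- leaf_ids(tree)
    sp_of_leaf <- rep(NA_integer_, n_nodes(tree))
    sp_of_leaf[lv] <- vapply(entry$map[tree$label[lv]], lookup_taxon,
                             integer(1), st = st)
    pruned_this_pass <- FALSE
    for (v in tree_postorder(tree)) {
      f <- tree$parent[v]
      if (is.na(f)) next
      g <- tree$parent[f]
      if (is.na(g)) next
      remaining <- setdiff(tips[[g]], tips[[v]])
      if (!length(remaining)) next
      if (sum(is_leaf(tree)) - length(tips[[v]]) < 2L) next
      old_id <- lca_ids(unique(sp_of_leaf[tips[[g]]]), st)
      new_id <- lca_ids(unique(sp_of_leaf[remaining]), st)
      if (old_id == new_id) next
      # the implicated branch is the father of the masked subtree (the
      # clade uniting it with its alien sibling); a masked *clade* must
      # additionally be supported itself, or masking it just relitigates
      # a conflict already rejected at its own leaves
      sup <- tree$support[f]
      if (is.na(sup) || sup < support_threshold) next
      if (length(tree$kids[[v]]) &&
          (is.na(tree$support[v]) || tree$support[v] < support_threshold))
        next
      rec[[length(rec) + 1L]] <- data.frame(
        entry = entry$name,
        pruned = paste(sort(tree$label[intersect(tips[[v]], lv)]),
                       collapse = ","),
        n_pruned = length(tips[[v]]),
        pruned_lca = st$primary[lca_ids(unique(sp_of_leaf[intersect(tips[[v]], lv)]), st)],
        old = st$primary[old_id],
        d_old = restricted_depth_id(old_id, info, st),
        new = st$primary[new_id],
        d_new = restricted_depth_id(new_id, info, st),
        perturbation = perturbation_index_id(old_id, new_id, info, st),
        support = sup,
        stringsAsFactors = FALSE)
      tree <- prune_leaves(tree, intersect(tips[[v]], lv))
      pruned_this_pass <- TRUE
      break
    }
    if (!pruned_this_pass) break
  }
  out <- if (length(rec)) do.call(rbind, rec)
         else data.frame(entry = character(0), pruned = character(0),
                         n_pruned = integer(0), pruned_lca = character(0),
                         old = character(0),
                         d_old = integer(0), new = character(0),
                         d_new = integer(0), perturbation = integer(0),
                         support = numeric(0), stringsAsFactors = FALSE)
  class(out) <- c("tq_incongruencies", "data.frame")
  out
}

#' Classify an incongruency as an intra- or inter-domain switch
#'
#' Domains are the children of the species-tree root (e.g. Archaea,
#' Bacteria, Eukaryota).  The switch goes from the domain of the pruned
#' clade's own LCA to the domain of the grandfather's post-masking
#' assignment; a clade or assignment spanning the root is
#' unclassifiable.
#'
#' @param record one row of a \code{tq_incongruencies} data frame.
#' @param st a \code{tq_species_tree}.
#' @param domains taxon names to treat as the domains; defaults to the
#'   species-tree root's children.
#' @return list with \code{kind} (\code{"intra"}, \code{"inter"} or
#'   \code{"unclassifiable"}), \code{from}, \code{to} (domain primary
#'   names or \code{NA}).
#' @export
classify_switch <- function(record, st, domains = NULL) {
  domains <- if (is.null(domains)) st$tree$kids[[st$tree$root]]
             else vapply(domains, lookup_taxon, integer(1), st = st)
  domain_of <- function(node_id) {
    while (!(node_id %in% domains)) {
      node_id <- st$tree$parent[node_id]
      if (is.na(node_id)) return(NA_integer_)
    }
    node_id
  }
  from_id <- domain_of(lookup_taxon(record$pruned_lca, st))
  to_id <- domain_of(lookup_taxon(record$new, st))
  from <- if (is.na(from_id)) NA_character_ else st$primary[from_id]
  to <- if (is.na(to_id)) NA_character_ else st$primary[to_id]
  kind <- if (is.na(from_id) || is.na(to_id)) "unclassifiable"
          else if (from_id == to_id) "intra" else "inter"
  list(kind = kind, from = from, to = to)
}

#' Summary statistics for a set of incongruency records
#'
#' @param records a \code{tq_incongruencies} data frame (rows may come
#'   from several entries of a collection).
#' @param n_trees number of trees scanned (for the per-tree mean).
#' @param st optional species tree; when given, records are classified
#'   into the intra/inter domain-switch matrix.
#' @param domains taxon names to treat as the domains; defaults to the
#'   species-tree root's children.
#' @return list with \code{total}, \code{n_trees}, \code{mean_per_tree},
#'   and (with \code{st}) \code{n_intra}, \code{n_inter},
#'   \code{n_unclassifiable} and the \code{switches} from-by-to matrix.
#' @export
summarize_incongruencies <- function(records, n_trees, st = NULL,
                                     domains = NULL) {
  out <- list(total = nrow(records), n_trees = n_trees,
              mean_per_tree = if (n_trees > 0) nrow(records) / n_trees else NA_real_)
  if (!is.null(st)) {
    dom_names <- if (is.null(domains))
      st$primary[st$tree$kids[[st$tree$root]]] else
      st$primary[vapply(domains, lookup_taxon, integer(1), st = st)]
    mat <- matrix(0L, length(dom_names), length(dom_names),
                  dimnames = list(from = dom_names, to = dom_names))
    n_un <- 0L
    if (nrow(records)) for (i in seq_len(nrow(records))) {
      cl <- classify_switch(records[i, ], st, domains)
      if (cl$kind == "unclassifiable") n_un <- n_un + 1L
      else mat[cl$from, cl$to] <- mat[cl$from, cl$to] + 1L
    }
    out$n_intra <- sum(diag(mat))
    out$n_inter <- sum(mat) - sum(diag(mat))
    out$n_unclassifiable <- n_un
    out$switches <- mat
  }
  class(out) <- "tq_incongruency_summary"
  out
}

#' @export
print.tq_incongruency_summary <- function(x, ...) {
  cat("Incongruencies: ", x$total, " over ", x$n_trees, " trees (",
      format(x$mean_per_tree, digits = 3), " per tree)\n", sep = "")
  if (!is.null(x$switches)) {
    cat("  intra-domain: ", x$n_intra, ", inter-domain: ", x$n_inter,
        if (x$n_unclassifiable > 0)
          paste0(", unclassifiable: ", x$n_unclassifiable),
        "\n", sep = "")
    print(x$switches)
  }
  invisible(x)
}
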