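# Seeded synthetic collections: random species trees, congruent gene
# trees, and controlled duplication / transfer events with ground-truth
# labels, so every algorithm in the package can be exercised and scored
# without external data.

#' Generate a random species tree
#'
#' Sequential leaf attachment: starting from a two-species cherry, each
#' new species is grafted onto a uniformly chosen branch.  Leaves are
#' named \code{S1...Sn}, internal nodes \code{G1...G(n-1)}; the result is
#' rooted and binary.
#'
#' @param n_species number of species (>= 2).
#' @param seed RNG seed (optional; the caller may manage the RNG).
#' @return a \code{tq_species_tree}.
#' @export
gen_species_tree <- function(n_species, seed = NULL) {
  if (n_species < 2) stop("need at least 2 species", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  # grow as nested label structure over leaf indices
  parent <- c(NA_integer_, 1L, 1L)
  kids <- list(c(2L, 3L), integer(0), integer(0))
  leaves <- c(2L, 3L)
  for (i in seq_len(n_species - 2)) {
    target <- sample(setdiff(seq_along(parent), 1L), 1L)
    p <- parent[target]
    mid <- length(parent) + 1L
    leaf <- length(parent) + 2L
    parent <- c(parent, p, mid)
    parent[target] <- mid
    kids[[mid]] <- c(target, leaf)
    kids[[leaf]] <- integer(0)
    kids[[p]][kids[[p]] == target] <- mid
    leaves <- c(leaves, leaf)
  }
  label <- rep(NA_character_, length(parent))
  is_lf <- lengths(kids) == 0L
  label[which(is_lf)] <- paste0("S", seq_len(sum(is_lf)))
  label[which(!is_lf)] <- paste0("G", seq_len(sum(!is_lf)))
  tree <- tq_tree(parent, kids, label,
                  rep(NA_real_, length(parent)), rep(NA_real_, length(parent)),
                  rep(NA_character_, length(parent)), 1L)
  parse_species_tree(nw_write(tree, function(t, v) t$label[v]))
}

# congruent unicopy copy of the species tree, as a gene tq_tree with
# sequence names "<species>_1"
congruent_tree <- function(st, support = 100, brlen_rate = 1) {
  tree <- st$tree
  gene <- tq_tree(tree$parent, tree$kids,
                  ifelse(is_leaf(tree), paste0(st$primary, "_1"), NA_character_),
                  ifelse(is_leaf(tree), NA_real_, support),
                  stats::rexp(n_nodes(tree), brlen_rate),
                  rep(NA_character_, n_nodes(tree)), tree$root)
  gene$support[gene$root] <- NA_real_
  gene$brlen[gene$root] <- NA_real_
  gene
}

# graft subtree `sub` (a tq_tree) as sister of node `v` of `tree`
graft_sister <- function(tree, v, sub, support = 100, brlen = 0.1) {
  off <- n_nodes(tree)
  nn <- off + n_nodes(sub) + 1L
  mid <- nn
  parent <- c(tree$parent, sub$parent + off, NA_integer_)
  kids <- c(tree$kids, lapply(sub$kids, function(k) k + off), list(integer(0)))
  label <- c(tree$label, sub$label, NA_character_)
  supv <- c(tree$support, sub$support, NA_real_)
  brl <- c(tree$brlen, sub$brlen, NA_real_)
  event <- c(tree$event, sub$event, NA_character_)
  subroot <- sub$root + off
  p <- tree$parent[v]
  parent[mid] <- p
  if (!is.na(p)) kids[[p]][kids[[p]] == v] <- mid
  kids[[mid]] <- c(v, subroot)
  parent[v] <- mid
  parent[subroot] <- mid
  supv[mid] <- support
  brl[mid] <- brlen
  brl[subroot] <- if (is.na(brl[subroot])) brlen else brl[subroot]
  root <- if (is.na(p)) mid else tree$root
  tq_tree(parent, kids, label, supv, brl, event, root)
}

extract_subtree <- function(tree, v) {
  ids <- integer(0)
  stack <- v
  while (length(stack)) {
    x <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    ids <- c(ids, x)
    stack <- c(stack, tree$kids[[x]])
  }
  ids <- sort(ids)
  remap <- integer(n_nodes(tree)); remap[ids] <- seq_along(ids)
  tq_tree(parent = ifelse(ids == v, NA_integer_, remap[tree$parent[ids]]),
          kids = lapply(tree$kids[ids], function(k) remap[k]),
          label = tree$label[ids], support = tree$support[ids],
          brlen = tree$brlen[ids], event = tree$event[ids],
          root = remap[v])
}

renumber_copies <- function(tree) {
  lv <- leaf_ids(tree)
  base <- sub("_[0-9]+$", "", tree$label[lv])
  for (b in unique(base)) {
    hit <- lv[base == b]
    tree$label[hit] <- paste0(b, "_", seq_along(hit))
  }
  tree
}

#' Generate a gene tree with controlled events
#'
#' Starts from a unicopy gene tree congruent with the (binary) species
#' tree, then applies duplications (a clade is copied and grafted as its
#' own sister) and single-leaf transfers (a leaf is pruned and regrafted
#' inside a foreign clade, i.e. one whose LCA assignment changes when
#' the leaf joins it -- the topological signature of an HGT).  All
#' supports are set by \code{support}; branch lengths are exponential
#' with rate \code{brlen_rate}.
#'
#' @param st a binary \code{tq_species_tree}.
#' @param name entry name.
#' @param n_dup number of duplication events (0 or more); the first one
#'   is root-adjacent (the whole tree is copied), emulating an ancient
#'   duplication.
#' @param n_transfer number of single-leaf transfer events.
#' @param support support value written on every internal branch.
#' @param brlen_rate rate of the exponential branch-length model.
#' @param seed RNG seed (optional).
#' @return list with \code{entry} (a \code{tq_gene_entry}) and
#'   \code{truth}: \code{root_split} (canonical leaf bipartition of the
#'   true root edge), \code{transferred} (sequence names moved by
#'   transfers), \code{duplicated_clades} (leaf sets copied).
#' @export
gen_gene_tree <- function(st, name = "tree1", n_dup = 0, n_transfer = 0,
                          support = 100, brlen_rate = 1, seed = NULL) {
  if (!tree_is_binary(st$tree))
    stop("the generator needs a binary species tree", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  gene <- congruent_tree(st, support, brlen_rate)
  dup_clades <- list()
  if (n_dup > 0) {
    for (i in seq_len(n_dup)) {
      v <- if (i == 1) gene$root
           else sample(setdiff(which(!is_leaf(gene)), gene$root), 1L)
      sub <- extract_subtree(gene, v)
      dup_clades[[i]] <- sub("_[0-9]+$", "", sub$label[leaf_ids(sub)])
      gene <- renumber_copies(graft_sister(gene, v, sub, support,
                                           stats::rexp(1, brlen_rate)))
    }
  }
  transferred <- character(0)
  if (n_transfer > 0) {
    for (i in seq_len(n_transfer)) {
      pick <- transfer_leaf(gene, st, support, brlen_rate)
      gene <- pick$tree
      transferred <- c(transferred, pick$moved)
    }
  }
  map <- stats::setNames(sub("_[0-9]+$", "", gene$label[leaf_ids(gene)]),
                         gene$label[leaf_ids(gene)])
  entry <- gene_entry(name, gene, map, st)
  split <- root_split_key(gene)
  list(entry = entry,
       truth = list(root_split = split, transferred = transferred,
                    duplicated_clades = dup_clades))
}

root_split_key <- function(tree) {
  rk <- tree$kids[[tree$root]]
  tips <- tips_under(tree)
  all_leaves <- sort(tree$label[leaf_ids(tree)])
  got <- sort(tree$label[tips[[rk[1]]]])
  other <- setdiff(all_leaves, got)
  k1 <- paste(got, collapse = "|"); k2 <- paste(other, collapse = "|")
  if (length(got) < length(other) ||
      (length(got) == length(other) && k1 <= k2))
    paste(k1, k2, sep = " // ") else paste(k2, k1, sep = " // ")
}

# SPR of one random leaf into a foreign clade: the recipient clade's LCA
# assignment must change once the leaf joins it, otherwise the move is
# taxonomically silent and undetectable by definition.
transfer_leaf <- function(gene, st, support, brlen_rate) {
  lv <- leaf_ids(gene)
  sp_of_leaf <- rep(NA_integer_, n_nodes(gene))
  sp_of_leaf[lv] <- vapply(sub("_[0-9]+$", "", gene$label[lv]), lookup_taxon,
                           integer(1), st = st)
  tips <- tips_under(gene)
  cands <- list()
  for (x in lv) {
    for (v in seq_len(n_nodes(gene))) {
      if (v == gene$root || v == x) next
      if (x %in% tips[[v]]) next
      p <- gene$parent[v]
      if (is.na(p)) next           # the regrafted leaf needs a grandfather
      if (p == gene$parent[x]) next # sibling move is a no-op
      # the move must be taxonomically visible at the future grandfather:
      # masking the leaf there must change the LCA assignment back
      gp_tips <- setdiff(tips[[p]], c(x))
      lca_without <- lca_ids(unique(sp_of_leaf[gp_tips]), st)
      lca_with <- lca_ids(unique(c(sp_of_leaf[gp_tips], sp_of_leaf[x])), st)
      if (lca_without == lca_with) next
      cands[[length(cands) + 1L]] <- c(x, v)
    }
  }
  if (!length(cands))
    stop("no taxonomically visible transfer is possible on this tree",
         call. = FALSE)
  pick <- cands[[sample.int(length(cands), 1L)]]
  x <- pick[1]; v <- pick[2]
  moved <- gene$label[x]
  # prune x, then graft it as sister of v
  leafsub <- extract_subtree(gene, x)
  pruned <- prune_leaves(gene, x)
  v_new <- which(pruned$label == gene$label[v])
  if (!length(v_new)) {
    # v is internal: relocate it by its leaf set
    tips_p <- tips_under(pruned)
    key <- paste(sort(gene$label[intersect(tips[[v]], lv)]), collapse = "|")
    v_new <- which(vapply(seq_len(n_nodes(pruned)), function(w)
      paste(sort(pruned$label[intersect(tips_p[[w]], leaf_ids(pruned))]),
            collapse = "|") == key, logical(1)))[1]
  }
  list(tree = graft_sister(pruned, v_new, leafsub, support,
                           stats::rexp(1, brlen_rate)),
       moved = moved)
}

#' Generate a whole synthetic collection
#'
#' @param n_species species-tree size.
#' @param n_trees number of gene-tree entries.
#' @param seed master seed; entry i uses \code{seed + i} so collections
#'   are reproducible entry by entry.
#' @param n_dup,n_transfer,support,brlen_rate passed to
#'   \code{\link{gen_gene_tree}} for every entry.
#' @return list with \code{collection} (a \code{tq_collection}) and
#'   \code{truth} (per-entry ground-truth list).
#' @export
gen_collection <- function(n_species, n_trees, seed = 1, n_dup = 0,
                           n_transfer = 0, support = 100, brlen_rate = 1) {
  st <- gen_species_tree(n_species, seed)
  entries <- vector("list", n_trees)
  truth <- vector("list", n_trees)
  for (i in seq_len(n_trees)) {
    g <- gen_gene_tree(st, sprintf("fam%03d", i), n_dup = n_dup,
                       n_transfer = n_transfer, support = support,
                       brlen_rate = brlen_rate, seed = seed + i)
    entries[[i]] <- g$entry
    truth[[i]] <- g$truth
  }
  list(collection = new_collection(st, entries),
       truth = stats::setNames(truth, vapply(entries, `[[`, "", "name")))
}
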