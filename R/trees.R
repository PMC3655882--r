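# Core rooted-tree container used by every module.
#
# A tq_tree is a flat, index-addressed rooted tree: node i has parent[i]
# (NA at the root), an ordered integer vector of children kids[[i]], an
# optional text label, an optional support value and branch length (the
# value attached to a node always describes the edge above it, following
# the usual Newick convention), and an optional event letter ("D"/"S").

tq_tree <- function(parent, kids, label, support, brlen, event, root) {
  structure(list(parent = as.integer(parent), kids = kids,
                 label = label, support = support, brlen = brlen,
                 event = event, root = as.integer(root)),
            class = "tq_tree")
}

n_nodes <- function(tree) length(tree$parent)

is_leaf <- function(tree) lengths(tree$kids) == 0L

leaf_ids <- function(tree) which(is_leaf(tree))

#' @noRd
tree_postorder <- function(tree, from = tree$root) {
  out <- integer(0)
  stack <- from
  seen <- integer(0)
  # iterative post-order (children before parent), preserving child order
  while (length(stack)) {
    v <- stack[[length(stack)]]
    kids <- tree$kids[[v]]
    if (length(kids) && !(v %in% seen)) {
      seen <- c(seen, v)
      stack <- c(stack, rev(kids))
    } else {
      out <- c(out, v)
      stack <- stack[-length(stack)]
      seen <- setdiff(seen, v)
    }
  }
  out
}

# list, per node, of the leaf ids beneath it (a leaf lists itself)
tips_under <- function(tree) {
  tips <- vector("list", n_nodes(tree))
  for (v in tree_postorder(tree)) {
    k <- tree$kids[[v]]
    tips[[v]] <- if (!length(k)) v else unlist(tips[k], use.names = FALSE)
  }
  tips
}

tree_is_binary <- function(tree) {
  all(lengths(tree$kids)[!is_leaf(tree)] == 2L)
}

node_depths <- function(tree) {
  d <- integer(n_nodes(tree))
  for (v in rev(tree_postorder(tree)))
    d[v] <- if (is.na(tree$parent[v])) 0L else d[tree$parent[v]] + 1L
  d
}

## ---- Newick dialect parsing -------------------------------------------

# Labels may contain spaces, slashes, +/- signs and dots; they end at one
# of the structural characters "(" ")" "," ":" ";".  Single-quoted labels
# are accepted and may contain structural characters.
nw_parse <- function(text) {
  s <- trimws(text)
  if (!nzchar(s)) stop("empty Newick string", call. = FALSE)
  n <- nchar(s)
  pos <- 1L
  peek <- function() if (pos <= n) substr(s, pos, pos) else ""
  advance <- function() pos <<- pos + 1L
  skip_ws <- function() while (pos <= n && grepl("^\\s$", substr(s, pos, pos))) pos <<- pos + 1L

  parent <- integer(0); kids <- list(); label <- character(0)
  support <- numeric(0); brlen <- numeric(0); event <- character(0)
  new_node <- function() {
    parent[length(parent) + 1L] <<- NA_integer_
    kids[[length(kids) + 1L]] <<- integer(0)
    label[length(label) + 1L] <<- NA_character_
    support[length(support) + 1L] <<- NA_real_
    brlen[length(brlen) + 1L] <<- NA_real_
    event[length(event) + 1L] <<- NA_character_
    length(parent)
  }

  read_label <- function() {
    skip_ws()
    if (peek() == "'") {
      advance()
      start <- pos
      while (pos <= n && substr(s, pos, pos) != "'") advance()
      if (pos > n) stop("unterminated quoted label at position ", start, call. = FALSE)
      lab <- substr(s, start, pos - 1L)
      advance()
      return(lab)
    }
    start <- pos
    while (pos <= n && !substr(s, pos, pos) %in% c("(", ")", ",", ":", ";")) advance()
    trimws(substr(s, start, pos - 1L))
  }

  read_number <- function() {
    skip_ws()
    start <- pos
    while (pos <= n && grepl("[0-9eE+.\\-]", substr(s, pos, pos))) advance()
    num <- suppressWarnings(as.numeric(substr(s, start, pos - 1L)))
    if (is.na(num)) stop("invalid branch length at position ", start, call. = FALSE)
    num
  }

  read_clade <- function() {
    skip_ws()
    v <- new_node()
    if (peek() == "(") {
      advance()
      repeat {
        child <- read_clade()
        parent[child] <<- v
        kids[[v]] <<- c(kids[[v]], child)
        skip_ws()
        if (peek() == ",") { advance(); next }
        if (peek() == ")") { advance(); break }
        stop("expected ',' or ')' at position ", pos, call. = FALSE)
      }
    }
    lab <- read_label()
    if (nzchar(lab)) label[v] <<- lab
    skip_ws()
    if (peek() == ":") { advance(); brlen[v] <<- read_number() }
    v
  }

  root <- read_clade()
  skip_ws()
  if (peek() == ";") advance()
  skip_ws()
  if (pos <= n) stop("trailing characters after ';' at position ", pos, call. = FALSE)
  tq_tree(parent, kids, label, support, brlen, event, root)
}

# Internal gene-tree labels are supports (numeric) or explicit event
# letters ("D"/"S"); this moves them out of `label` into their slots.
interpret_gene_labels <- function(tree) {
  for (v in which(!is_leaf(tree))) {
    lab <- tree$label[v]
    if (is.na(lab)) next
    if (lab %in% c("D", "S")) {
      tree$event[v] <- lab
    } else {
      num <- suppressWarnings(as.numeric(lab))
      if (is.na(num))
        stop("internal node label ", sQuote(lab),
             " is neither a support value nor an event letter (D/S)",
             call. = FALSE)
      tree$support[v] <- num
    }
    tree$label[v] <- NA_character_
  }
  tree
}

fmt_num <- function(x) sprintf("%.6g", x)

# Serialize to Newick.  label_fun(tree, v) must return the label text for
# node v (or NA for none); gene trees print supports/events on internal
# nodes, species trees print "primary/synonym/..." labels.
nw_write <- function(tree, label_fun) {
  rec <- function(v) {
    k <- tree$kids[[v]]
    core <- if (length(k))
      paste0("(", paste(vapply(k, rec, character(1)), collapse = ","), ")")
    else ""
    lab <- label_fun(tree, v)
    if (!is.na(lab) && grepl("[(),:;]", lab)) lab <- paste0("'", lab, "'")
    out <- paste0(core, if (!is.na(lab)) lab else "")
    if (!is.na(tree$brlen[v])) out <- paste0(out, ":", fmt_num(tree$brlen[v]))
    out
  }
  paste0(rec(tree$root), ";")
}

gene_label_fun <- function(tree, v) {
  if (length(tree$kids[[v]])) {
    if (!is.na(tree$event[v])) tree$event[v]
    else if (!is.na(tree$support[v])) fmt_num(tree$support[v])
    else NA_character_
  } else tree$label[v]
}

## ---- unrooted view and re-rooting -------------------------------------

# Unrooted view of a rooted tree: nodes keep their original ids; a binary
# root is dissolved, its two incident edges merging into one (lengths
# summed, support taken from either child -- they describe the same
# bipartition).  Edges are listed in the post-order of the source tree,
# which fixes the canonical edge numbering used for tie-breaks.
as_unrooted <- function(tree) {
  root <- tree$root
  rk <- tree$kids[[root]]
  merge_root <- length(rk) == 2L
  a <- integer(0); b <- integer(0); len <- numeric(0); sup <- numeric(0)
  for (v in tree_postorder(tree)) {
    p <- tree$parent[v]
    if (is.na(p)) next
    if (merge_root && p == root) next
    a <- c(a, p); b <- c(b, v)
    len <- c(len, tree$brlen[v]); sup <- c(sup, tree$support[v])
  }
  if (merge_root) {
    l1 <- tree$brlen[rk[1]]; l2 <- tree$brlen[rk[2]]
    l <- if (is.na(l1) && is.na(l2)) NA_real_ else sum(c(l1, l2), na.rm = TRUE)
    s1 <- tree$support[rk[1]]; s2 <- tree$support[rk[2]]
    s <- if (!is.na(s1)) s1 else s2
    a <- c(a, rk[1]); b <- c(b, rk[2]); len <- c(len, l); sup <- c(sup, s)
  }
  structure(list(edges = data.frame(a = a, b = b, len = len, sup = sup),
                 label = tree$label, dropped_root = if (merge_root) root else NA_integer_,
                 n_orig = n_nodes(tree)),
            class = "tq_unrooted")
}

# Root an unrooted view on edge `ei`, yielding a tq_tree.  The edge's
# length is split evenly between the two root-adjacent branches; its
# support is reported on both (one bipartition).
root_on_edge <- function(ut, ei) {
  ed <- ut$edges
  m <- nrow(ed)
  nodes <- sort(unique(c(ed$a, ed$b)))
  if (m == 0L) stop("cannot root a single-node tree", call. = FALSE)
  # adjacency: neighbour node and incident edge index
  adj <- vector("list", ut$n_orig)
  for (i in seq_len(m)) {
    adj[[ed$a[i]]] <- rbind(adj[[ed$a[i]]], c(ed$b[i], i))
    adj[[ed$b[i]]] <- rbind(adj[[ed$b[i]]], c(ed$a[i], i))
  }
  N <- ut$n_orig + 1L
  rootid <- N
  parent <- rep(NA_integer_, N); kids <- rep(list(integer(0)), N)
  label <- c(ut$label, NA_character_)
  length(label) <- N
  support <- rep(NA_real_, N); brlen <- rep(NA_real_, N)
  event <- rep(NA_character_, N)

  half <- if (is.na(ed$len[ei])) NA_real_ else ed$len[ei] / 2
  attach_side <- function(top) {
    parent[top] <<- rootid
    kids[[rootid]] <<- c(kids[[rootid]], top)
    support[top] <<- ed$sup[ei]; brlen[top] <<- half
    # orient everything below `top` away from the root edge
    queue <- list(c(top, ei))
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      v <- cur[1]; via <- cur[2]
      nb <- adj[[v]]
      if (is.null(nb)) next
      for (r in seq_len(nrow(nb))) {
        w <- nb[r, 1]; e <- nb[r, 2]
        if (e == via) next
        parent[w] <<- v
        kids[[v]] <<- c(kids[[v]], w)
        support[w] <<- ed$sup[e]; brlen[w] <<- ed$len[e]
        queue[[length(queue) + 1L]] <- c(w, e)
      }
    }
  }
  attach_side(ed$a[ei])
  attach_side(ed$b[ei])
  # drop slots not reachable from the new root (e.g. the dissolved
  # original root) and compact indices
  keep <- logical(N); keep[rootid] <- TRUE
  for (v in c(ed$a, ed$b)) keep[v] <- TRUE
  idx <- which(keep)
  remap <- integer(N); remap[idx] <- seq_along(idx)
  tq_tree(parent = ifelse(is.na(parent[idx]), NA_integer_, remap[parent[idx]]),
          kids = lapply(kids[idx], function(k) remap[k]),
          label = label[idx], support = support[idx], brlen = brlen[idx],
          event = event[idx], root = remap[rootid])
}

# Leaf-name bipartition of each unrooted edge (the side containing the
# edge's `b` endpoint), as a canonical sorted character key.
edge_splits <- function(ut) {
  ed <- ut$edges
  adj <- vector("list", ut$n_orig)
  for (i in seq_len(nrow(ed))) {
    adj[[ed$a[i]]] <- c(adj[[ed$a[i]]], list(c(ed$b[i], i)))
    adj[[ed$b[i]]] <- c(adj[[ed$b[i]]], list(c(ed$a[i], i)))
  }
  all_leaves <- sort(ut$label[!is.na(ut$label)])
  vapply(seq_len(nrow(ed)), function(i) {
    # collect leaves on the b-side of edge i
    got <- character(0)
    queue <- list(c(ed$b[i], i))
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      v <- cur[1]; via <- cur[2]
      if (!is.na(ut$label[v])) got <- c(got, ut$label[v])
      for (nb in adj[[v]]) if (nb[2] != via) queue[[length(queue) + 1L]] <- nb
    }
    got <- sort(got)
    other <- setdiff(all_leaves, got)
    # canonical: smaller side first, ties by first element
    k1 <- paste(got, collapse = "|"); k2 <- paste(other, collapse = "|")
    if (length(got) < length(other) || (length(got) == length(other) && k1 <= k2))
      paste(k1, k2, sep = " // ") else paste(k2, k1, sep = " // ")
  }, character(1))
}

# Drop the listed leaves and suppress the resulting degree-2 nodes; a
# spliced-out chain keeps the surviving child's own support, branch
# lengths along the chain are summed.
prune_leaves <- function(tree, drop) {
  keep_leaf <- setdiff(leaf_ids(tree), drop)
  if (length(keep_leaf) < 1L) stop("cannot prune every leaf", call. = FALSE)
  keep <- logical(n_nodes(tree))
  for (v in tree_postorder(tree)) {
    k <- tree$kids[[v]]
    keep[v] <- if (!length(k)) v %in% keep_leaf else any(keep[k])
  }
  parent <- tree$parent; kids <- tree$kids
  # detach dropped children
  for (v in which(keep)) kids[[v]] <- kids[[v]][keep[kids[[v]]]]
  # splice out degree-2 internals (and a single-child root) top-down
  newlen <- tree$brlen
  repeat {
    deg2 <- which(keep & !vapply(seq_along(kids), function(v) length(kids[[v]]) != 1L, logical(1)))
    if (!length(deg2)) break
    v <- deg2[1]
    child <- kids[[v]][1]
    p <- parent[v]
    if (!is.na(newlen[child]) || !is.na(newlen[v]))
      newlen[child] <- sum(c(newlen[child], newlen[v]), na.rm = TRUE)
    parent[child] <- p
    if (!is.na(p)) kids[[p]][kids[[p]] == v] <- child
    keep[v] <- FALSE
  }
  root <- tree$root
  while (!keep[root]) root <- kids[[root]][1]
  if (is.na(parent[root]) || !keep[parent[root]]) parent[root] <- NA_integer_
  # compact indices
  idx <- which(keep)
  remap <- integer(n_nodes(tree)); remap[idx] <- seq_along(idx)
  tq_tree(parent = ifelse(is.na(parent[idx]), NA_integer_, remap[parent[idx]]),
          kids = lapply(kids[idx], function(k) remap[k]),
          label = tree$label[idx],
          support = tree$support[idx],
          brlen = newlen[idx],
          event = tree$event[idx],
          root = remap[root])
}
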