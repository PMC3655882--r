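# Extended-Newick tree patterns and the matching engine.
#
# Pattern grammar (whitespace-tolerant; taxon names may contain spaces):
#   node      := "!"? ( "(" node "," node ")" fields? | leafspec ) modifiers
#   leafspec  := field1 "/" field2 "/" field3
#   fields    := field1 ( "/" field2 )?          (internal nodes)
#   modifiers := ( "$" int )? ( "D" | "S" )? "!"?
# field1 constrains the matched node's own LCA assignment, field2 is the
# path constraint (taxa allowed between the matched parent and the
# matched node), field3 (leaves only) is the set of taxa allowed at the
# leaf.  "$N" requires branch support >= N, "D"/"S" requires a
# duplication/speciation node, "!" (prefix or postfix) requires the
# matched node to be a *direct* child of its matched parent's image.

#' Parse a tree pattern
#'
#' @param text pattern string, e.g.
#'   \code{"((//Homo sapiens,//Pan troglodytes),//Rodentia)"} or
#'   \code{"(//Homo sapiens,//Mus musculus)$90"}.
#' @return a \code{tq_pattern} (recursive constraint tree).
#' @export
parse_pattern <- function(text) {
  s <- text
  n <- nchar(s)
  pos <- 1L
  peek <- function() if (pos <= n) substr(s, pos, pos) else ""
  peek2 <- function() if (pos + 1L <= n) substr(s, pos + 1L, pos + 1L) else ""
  skip_ws <- function() while (pos <= n && grepl("^\\s$", substr(s, pos, pos))) pos <<- pos + 1L
  fail <- function(msg) stop("pattern syntax error at position ", pos, ": ",
                             msg, call. = FALSE)

  read_field <- function(stop_slash = TRUE) {
    start <- pos
    stops <- c("(", ")", ",", "$", "!", ";")
    if (stop_slash) stops <- c(stops, "/")
    while (pos <= n && !substr(s, pos, pos) %in% stops) pos <<- pos + 1L
    trimws(substr(s, start, pos - 1L))
  }

  is_event_letter <- function() {
    peek() %in% c("D", "S") &&
      (peek2() %in% c("", "$", "!", ",", ")", ";") || grepl("^\\s$", peek2()))
  }

  read_modifiers <- function(node) {
    repeat {
      skip_ws()
      ch <- peek()
      if (ch == "$") {
        pos <<- pos + 1L
        skip_ws()
        start <- pos
        while (pos <= n && grepl("[0-9.]", substr(s, pos, pos))) pos <<- pos + 1L
        val <- suppressWarnings(as.numeric(substr(s, start, pos - 1L)))
        if (is.na(val)) fail("'$' must be followed by a support threshold")
        node$support_min <- val
      } else if (is_event_letter()) {
        node$event <- ch
        pos <<- pos + 1L
      } else if (ch == "!") {
        node$direct <- TRUE
        pos <<- pos + 1L
      } else break
    }
    node
  }

  expr_or_null <- function(txt) if (nzchar(txt)) parse_taxon_expression(txt) else NULL

  read_node <- function() {
    skip_ws()
    node <- list(node_expr = NULL, path_expr = NULL, leaf_expr = NULL,
                 support_min = NULL, event = NULL, direct = FALSE,
                 children = NULL)
    if (peek() == "!") { node$direct <- TRUE; pos <<- pos + 1L; skip_ws() }
    if (peek() == "(") {
      pos <<- pos + 1L
      kids <- list(read_node())
      repeat {
        skip_ws()
        if (peek() == ",") {
          pos <<- pos + 1L
          kids[[length(kids) + 1L]] <- read_node()
        } else if (peek() == ")") { pos <<- pos + 1L; break }
        else fail("expected ',' or ')'")
      }
      if (length(kids) != 2L)
        fail(paste0("pattern nodes must have exactly 2 children, found ",
                    length(kids), " (binary patterns only)"))
      node$children <- kids
      skip_ws()
      if (!peek() %in% c("", "$", "!", ",", ")", ";") && !is_event_letter()) {
        node$node_expr <- expr_or_null(read_field())
        if (peek() == "/") {
          pos <<- pos + 1L
          node$path_expr <- expr_or_null(read_field())
        }
      }
    } else {
      f1 <- read_field()
      if (peek() != "/") fail("expected a 'field1/field2/field3' leaf")
      pos <<- pos + 1L
      f2 <- read_field()
      if (peek() != "/") fail("expected the third (taxa) field of a leaf")
      pos <<- pos + 1L
      f3 <- read_field()
      if (!nzchar(f3)) fail("a pattern leaf must name its allowed taxa")
      node$node_expr <- expr_or_null(f1)
      node$path_expr <- expr_or_null(f2)
      node$leaf_expr <- parse_taxon_expression(f3)
    }
    read_modifiers(node)
  }

  root <- read_node()
  skip_ws()
  if (peek() == ";") pos <- pos + 1L
  skip_ws()
  if (pos <= n) fail("trailing characters")
  structure(root, class = "tq_pattern")
}

#' @export
print.tq_pattern <- function(x, ...) {
  fmt <- function(p) {
    mods <- paste0(if (!is.null(p$support_min)) paste0("$", p$support_min),
                   if (!is.null(p$event)) p$event,
                   if (isTRUE(p$direct)) "!")
    if (is.null(p$children)) {
      paste0(if (!is.null(p$node_expr)) format_taxon_expression(p$node_expr),
             "/",
             if (!is.null(p$path_expr)) format_taxon_expression(p$path_expr),
             "/", format_taxon_expression(p$leaf_expr), mods)
    } else {
      paste0("(", fmt(p$children[[1]]), ",", fmt(p$children[[2]]), ")",
             if (!is.null(p$node_expr)) format_taxon_expression(p$node_expr),
             if (!is.null(p$path_expr))
               paste0("/", format_taxon_expression(p$path_expr)),
             mods)
    }
  }
  cat("Tree pattern: ", fmt(x), "\n", sep = "")
  invisible(x)
}

# -- binding: flatten the pattern and resolve its taxa against a species
#    tree.  Nodes are numbered in pre-order; each gets resolved species-id
#    sets and (for field1) the base taxon's node id.
bind_pattern <- function(p, st) {
  nodes <- list()
  rec <- function(q) {
    id <- length(nodes) + 1L
    nodes[id] <<- list(NULL) # reserve the slot (keeps pre-order ids stable)
    b <- list(
      is_leaf = is.null(q$children),
      leaf_set = if (!is.null(q$leaf_expr)) taxon_expression_ids(q$leaf_expr, st),
      node_base = if (!is.null(q$node_expr)) lookup_taxon(q$node_expr$base, st),
      node_set = if (!is.null(q$node_expr) && length(q$node_expr$mods))
        taxon_expression_ids(q$node_expr, st),
      path_set = if (!is.null(q$path_expr)) taxon_expression_ids(q$path_expr, st),
      support_min = q$support_min,
      event = q$event,
      direct = isTRUE(q$direct),
      children = integer(0))
    if (!is.null(q$children))
      b$children <- c(rec(q$children[[1]]), rec(q$children[[2]]))
    nodes[[id]] <<- b
    id
  }
  rec(p)
  nodes
}

# -- gene-tree matching context ------------------------------------------

# Precomputed per-node facts about one gene tree against the species
# tree: leaf ids below, species-leaf ids below, LCA assignment, events.
gene_context <- function(entry, st) {
  tree <- entry$tree
  lv <- leaf_ids(tree)
  sp_of_leaf <- rep(NA_integer_, n_nodes(tree))
  sp_of_leaf[lv] <- vapply(entry$map[tree$label[lv]], lookup_taxon,
                           integer(1), st = st)
  tips <- tips_under(tree)
  species <- lapply(tips, function(t) sort(unique(sp_of_leaf[t])))
  po <- tree_postorder(tree)
  lca <- rep(NA_integer_, n_nodes(tree))
  for (v in po) lca[v] <- lca_ids(species[[v]], st)
  ev <- annotate_events_ids(tree, species)
  list(entry = entry, tree = tree, st = st, tips = tips,
       sp_of_leaf = sp_of_leaf, species = species, lca = lca,
       event = ev, postorder = po)
}

annotate_events_ids <- function(tree, species) {
  ev <- tree$event
  for (v in which(!is_leaf(tree))) {
    if (!is.na(ev[v])) next # explicit annotation wins
    k <- tree$kids[[v]]
    overlap <- length(intersect(species[[k[1]]], species[[k[2]]])) > 0L
    ev[v] <- if (overlap) "D" else "S"
  }
  ev
}

#' Label gene-tree nodes as duplication or speciation
#'
#' Applies the species-overlap rule: an internal node is a duplication
#' iff the species sets of its two children intersect, else a
#' speciation.  Explicit \code{D}/\code{S} labels present in the input
#' (reconciled collections) take precedence.
#'
#' @param entry a \code{tq_gene_entry}.
#' @param st a \code{tq_species_tree}.
#' @return character vector over nodes: \code{"D"}, \code{"S"}, or
#'   \code{NA} for leaves.
#' @export
annotate_events <- function(entry, st) {
  gene_context(entry, st)$event
}

# per-pattern-node check of a single gene node, shared by the DP and the
# match enumerator
node_ok <- function(b, g, ctx) {
  if (b$is_leaf) {
    if (length(ctx$tree$kids[[g]])) return(FALSE)
    if (!(ctx$sp_of_leaf[g] %in% b$leaf_set)) return(FALSE)
  } else {
    if (!length(ctx$tree$kids[[g]])) return(FALSE)
    if (!is.null(b$support_min)) {
      sup <- ctx$tree$support[g]
      if (is.na(sup) || sup < b$support_min) return(FALSE)
    }
    if (!is.null(b$event) && ctx$event[g] != b$event) return(FALSE)
  }
  if (!is.null(b$node_base)) {
    # the node's LCA assignment must fall within the base taxon ...
    anc <- ctx$lca[g]
    ok <- FALSE
    while (!is.na(anc)) {
      if (anc == b$node_base) { ok <- TRUE; break }
      anc <- ctx$st$tree$parent[anc]
    }
    if (!ok) return(FALSE)
    # ... and, with +/- modifiers, inside the evaluated set
    if (!is.null(b$node_set) && !all(ctx$species[[g]] %in% b$node_set))
      return(FALSE)
  }
  TRUE
}

#' Does a gene leaf satisfy a pattern leaf?
#'
#' @param pattern a \code{tq_pattern} that is a single leaf (or the text
#'   of one, e.g. \code{"//Rodentia"}).
#' @param entry a \code{tq_gene_entry}.
#' @param sequence the gene-leaf sequence name to test.
#' @param st a \code{tq_species_tree}.
#' @return logical.
#' @export
leaf_matches <- function(pattern, entry, sequence, st) {
  if (is.character(pattern)) pattern <- parse_pattern(pattern)
  if (!is.null(pattern$children))
    stop("leaf_matches expects a single-leaf pattern", call. = FALSE)
  ctx <- gene_context(entry, st)
  g <- which(ctx$tree$label == sequence & is_leaf(ctx$tree))
  if (!length(g))
    stop("no leaf named ", sQuote(sequence), " in entry ",
         sQuote(entry$name), call. = FALSE)
  node_ok(bind_pattern(pattern, st)[[1]], g, ctx)
}

# -- the DP matcher -------------------------------------------------------

# count[bi, g]: number of distinct pattern-to-gene maps rooted at
# pattern node bi matching at gene node g.  S(bi, c) aggregates, for a
# pattern child bi under a gene child c, the counts over all admissible
# descendants g' of c (g' = c only, when direct), where admissible means
# every leaf of subtree(c) outside subtree(g') carries a species allowed
# by bi's path constraint.
match_counts <- function(bp, ctx) {
  nb <- length(bp)
  nn <- n_nodes(ctx$tree)
  cnt <- matrix(0, nrow = nb, ncol = nn)
  # bad-leaf counts per pattern node with a path constraint
  bad <- vector("list", nb)
  for (bi in seq_len(nb)) {
    if (is.null(bp[[bi]]$path_set)) next
    badleaf <- !(ctx$sp_of_leaf %in% bp[[bi]]$path_set) & is_leaf(ctx$tree)
    bc <- numeric(nn)
    for (v in ctx$postorder) {
      k <- ctx$tree$kids[[v]]
      bc[v] <- if (!length(k)) as.numeric(badleaf[v]) else sum(bc[k])
    }
    bad[[bi]] <- bc
  }
  # pattern nodes in reverse pre-order = children before parents
  for (bi in rev(seq_len(nb))) {
    b <- bp[[bi]]
    for (g in ctx$postorder) {
      if (!node_ok(b, g, ctx)) next
      if (b$is_leaf) { cnt[bi, g] <- 1; next }
      k <- ctx$tree$kids[[g]]
      S <- function(ci, c) {
        child <- bp[[ci]]
        if (child$direct) {
          cnt[ci, c] # path constraint trivially satisfied: no off-path leaves
        } else {
          tot <- 0
          for (gp in descendants(ctx, c))
            if (is.null(bad[[ci]]) || bad[[ci]][c] == bad[[ci]][gp])
              tot <- tot + cnt[ci, gp]
          tot
        }
      }
      c1 <- b$children[1]; c2 <- b$children[2]
      cnt[bi, g] <- S(c1, k[1]) * S(c2, k[2]) + S(c1, k[2]) * S(c2, k[1])
    }
  }
  cnt
}

descendants <- function(ctx, v) {
  out <- integer(0)
  stack <- v
  while (length(stack)) {
    x <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    out <- c(out, x)
    stack <- c(stack, ctx$tree$kids[[x]])
  }
  out
}

# enumerate the actual maps (pattern node id -> gene node id)
enumerate_maps <- function(bp, ctx, cnt) {
  nb <- length(bp)
  expand <- function(bi, g) {
    b <- bp[[bi]]
    if (cnt[bi, g] == 0) return(list())
    if (b$is_leaf) {
      m <- rep(NA_integer_, nb); m[bi] <- g
      return(list(m))
    }
    k <- ctx$tree$kids[[g]]
    out <- list()
    pathok <- function(ci, c, gp) {
      ps <- bp[[ci]]$path_set
      if (is.null(ps)) return(TRUE)
      off <- setdiff(ctx$tips[[c]], ctx$tips[[gp]])
      all(ctx$sp_of_leaf[off] %in% ps)
    }
    targets <- function(ci, c) {
      if (bp[[ci]]$direct) return(c)
      ds <- descendants(ctx, c)
      ds[vapply(ds, function(gp) cnt[ci, gp] > 0 && pathok(ci, c, gp), logical(1))]
    }
    for (ord in list(c(1L, 2L), c(2L, 1L))) {
      c1 <- b$children[ord[1]]; c2 <- b$children[ord[2]]
      for (g1 in targets(c1, k[1])) for (g2 in targets(c2, k[2])) {
        for (m1 in expand(c1, g1)) for (m2 in expand(c2, g2)) {
          m <- pmax(m1, m2, na.rm = TRUE)
          m[is.na(m1) & is.na(m2)] <- NA_integer_
          m[bi] <- g
          out[[length(out) + 1L]] <- m
        }
      }
    }
    out
  }
  function(g) expand(1L, g)
}

#' Find all matches of a pattern in one gene tree
#'
#' An internal pattern node matches a gene node when its support, event
#' and taxon constraints hold there and its two children match gene
#' nodes lying in two \emph{different} child subtrees; the matched child
#' need not be a direct child of the gene node (unless flagged
#' \code{!}), but any leaf hanging off the connecting path must satisfy
#' the child's path constraint.  The pattern root may match at any gene
#' node; maps differing at any pattern node are distinct matches.
#'
#' @param pattern a \code{tq_pattern} or pattern text.
#' @param entry a \code{tq_gene_entry}.
#' @param st a \code{tq_species_tree}.
#' @param list_matches when \code{TRUE} (default) return the individual
#'   matches; otherwise only the count is computed.
#' @return a list of class \code{tq_matches}: \code{count}, and
#'   \code{matches} (each a named integer map pattern-node -> gene-node,
#'   pre-order numbering) when requested.
#' @export
match_pattern <- function(pattern, entry, st, list_matches = TRUE) {
  if (is.character(pattern)) pattern <- parse_pattern(pattern)
  bp <- bind_pattern(pattern, st)
  ctx <- gene_context(entry, st)
  cnt <- match_counts(bp, ctx)
  total <- sum(cnt[1L, ])
  matches <- NULL
  if (list_matches) {
    exp1 <- enumerate_maps(bp, ctx, cnt)
    matches <- list()
    for (g in ctx$postorder)
      if (cnt[1L, g] > 0) matches <- c(matches, exp1(g))
  }
  structure(list(entry = entry$name, count = total, matches = matches),
            class = "tq_matches")
}

#' @export
print.tq_matches <- function(x, ...) {
  cat("Entry ", sQuote(x$entry), ": ", x$count, " match(es)\n", sep = "")
  invisible(x)
}

#' Query every tree of a collection with a pattern
#'
#' @param pattern a \code{tq_pattern} or pattern text.
#' @param collection a \code{tq_collection}.
#' @return data frame (class \code{tq_query}) with one row per entry
#'   having at least one match, in collection order: \code{entry},
#'   \code{matches}.  Attributes \code{total_matches} and
#'   \code{total_trees} carry the collection-wide tallies (the paper-style
#'   "trees matching" count is \code{nrow}).
#' @export
query_collection <- function(pattern, collection) {
  if (is.character(pattern)) pattern <- parse_pattern(pattern)
  st <- collection$species_tree
  counts <- vapply(collection$entries, function(e)
    match_pattern(pattern, e, st, list_matches = FALSE)$count, numeric(1))
  out <- data.frame(entry = names(collection$entries), matches = unname(counts),
                    stringsAsFactors = FALSE)
  out <- out[out$matches > 0, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total_matches") <- sum(counts)
  attr(out, "total_trees") <- nrow(out)
  class(out) <- c("tq_query", "data.frame")
  out
}
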