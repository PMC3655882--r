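# Independent oracles, written directly from the matching semantics and
# elementary definitions; they share only the tree containers and the
# pattern *parser* with the package, never its matching, scoring or
# masking code paths.

# LCA by intersecting root-to-leaf ancestor paths
oracle_lca <- function(species, st) {
  path_of <- function(name) {
    v <- st$index[[normalize_name(name)]]
    path <- integer(0)
    while (!is.na(v)) { path <- c(v, path); v <- st$tree$parent[v] }
    path
  }
  paths <- lapply(species, path_of)
  shared <- Reduce(intersect, paths)
  st$primary[shared[length(shared)]]
}

# --- brute-force pattern matcher ----------------------------------------

# Enumerates every structurally admissible assignment of pattern nodes to
# gene nodes (leaves to leaves, internal to internal, the two children
# inside two different child subtrees of the parent's image) and keeps
# those satisfying the full semantics, checked predicate-style.
oracle_matches <- function(pattern, entry, st) {
  if (is.character(pattern)) pattern <- parse_pattern(pattern)
  # flatten pattern in pre-order
  pn <- list()
  flat <- function(q) {
    id <- length(pn) + 1L
    pn[id] <<- list(q)
    if (!is.null(q$children)) {
      c1 <- flat(q$children[[1]]); c2 <- flat(q$children[[2]])
      pn[[id]]$kid_ids <<- c(c1, c2)
    }
    id
  }
  flat(pattern)
  tree <- entry$tree
  nn <- length(tree$parent)
  kids <- tree$kids
  leafq <- lengths(kids) == 0L
  species_of_leaf <- rep(NA_character_, nn)
  species_of_leaf[leafq] <- unname(entry$map[tree$label[leafq]])
  under <- vector("list", nn) # leaf ids below each node
  fill_under <- function(v) {
    under[[v]] <<- if (leafq[v]) v else {
      for (k in kids[[v]]) fill_under(k)
      unlist(under[kids[[v]]])
    }
    invisible(NULL)
  }
  fill_under(tree$root)
  # on a tree, a is descendant-or-self of b iff leaves(a) is a subset of
  # leaves(b)
  desc_or_self <- function(a, b) all(under[[a]] %in% under[[b]])
  sub_list <- lapply(seq_len(nn), function(v)
    which(vapply(seq_len(nn), desc_or_self, logical(1), b = v)))

  # species-overlap events, computed locally
  ev <- rep(NA_character_, nn)
  for (v in which(!leafq)) {
    if (!is.na(tree$event[v])) { ev[v] <- tree$event[v]; next }
    s1 <- species_of_leaf[under[[kids[[v]][1]]]]
    s2 <- species_of_leaf[under[[kids[[v]][2]]]]
    ev[v] <- if (length(intersect(s1, s2))) "D" else "S"
  }

  expr_set <- function(e) eval_taxon_expression(e, st)
  # lca is base or a descendant of it iff lca's species are a subset of
  # base's species
  in_taxon <- function(lca_name, base_name)
    all(resolve_taxon(lca_name, st) %in% resolve_taxon(base_name, st))

  ok_node <- function(q, g) {
    if (is.null(q$children)) {
      if (!leafq[g]) return(FALSE)
      if (!(species_of_leaf[g] %in% suppressWarnings(expr_set(q$leaf_expr))))
        return(FALSE)
    } else {
      if (leafq[g]) return(FALSE)
      if (!is.null(q$support_min)) {
        if (is.na(tree$support[g]) || tree$support[g] < q$support_min)
          return(FALSE)
      }
      if (!is.null(q$event) && ev[g] != q$event) return(FALSE)
    }
    if (!is.null(q$node_expr)) {
      lca <- oracle_lca(species_of_leaf[under[[g]]], st)
      if (!in_taxon(lca, q$node_expr$base)) return(FALSE)
      if (length(q$node_expr$mods) &&
          !all(species_of_leaf[under[[g]]] %in%
                 suppressWarnings(expr_set(q$node_expr))))
        return(FALSE)
    }
    TRUE
  }

  # generate structurally admissible maps rooted at (pattern id, gene g)
  gen <- function(pi, g) {
    q <- pn[[pi]]
    if (is.null(q$children)) {
      if (!leafq[g]) return(list())
      m <- rep(NA_integer_, length(pn)); m[pi] <- g
      return(list(m))
    }
    if (leafq[g]) return(list())
    out <- list()
    k <- kids[[g]]
    for (ord in list(1:2, 2:1)) {
      q1 <- q$kid_ids[ord[1]]; q2 <- q$kid_ids[ord[2]]
      for (g1 in sub_list[[k[1]]]) for (g2 in sub_list[[k[2]]]) {
        for (m1 in gen(q1, g1)) for (m2 in gen(q2, g2)) {
          m <- ifelse(is.na(m1), m2, m1)
          m[pi] <- g
          out[[length(out) + 1L]] <- m
        }
      }
    }
    out
  }

  # full predicate over a complete map
  predicate <- function(m) {
    for (pi in seq_along(pn)) {
      q <- pn[[pi]]
      if (!ok_node(q, m[pi])) return(FALSE)
      if (is.null(q$children)) next
      g <- m[pi]; k <- kids[[g]]
      holding <- vapply(k, function(c) desc_or_self(m[q$kid_ids[1]], c),
                        logical(1))
      holding2 <- vapply(k, function(c) desc_or_self(m[q$kid_ids[2]], c),
                         logical(1))
      # each child image inside a child subtree, and different ones
      c1 <- k[holding]; c2 <- k[holding2]
      if (length(c1) != 1 || length(c2) != 1 || c1 == c2) return(FALSE)
      for (j in 1:2) {
        qc <- pn[[q$kid_ids[j]]]
        ci <- if (j == 1) c1 else c2
        gi <- m[q$kid_ids[j]]
        if (isTRUE(qc$direct) && gi != ci) return(FALSE)
        if (!is.null(qc$path_expr)) {
          off <- setdiff(under[[ci]], under[[gi]])
          if (!all(species_of_leaf[off] %in%
                     suppressWarnings(expr_set(qc$path_expr))))
            return(FALSE)
        }
      }
    }
    TRUE
  }

  res <- list()
  for (g in seq_len(nn))
    for (m in gen(1L, g)) if (predicate(m)) res[[length(res) + 1L]] <- m
  res
}

# canonical string form of a set of maps, for set comparison
map_keys <- function(maps) sort(vapply(maps, function(m)
  paste(ifelse(is.na(m), ".", m), collapse = "-"), character(1)))
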