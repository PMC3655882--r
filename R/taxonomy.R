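# Taxon resolution and species-tree geometry: name / synonym lookup,
# +/- set expressions, LCA assignment of gene-tree nodes, and depths on
# the species tree restricted to the species actually present in a gene
# tree.

lookup_taxon <- function(name, st) {
  hit <- st$index[[normalize_name(name)]]
  if (is.null(hit)) {
    all_names <- c(st$primary, unlist(st$synonyms))
    near <- utils::head(all_names[order(utils::adist(normalize_name(name),
                                                     normalize_name(all_names)))], 3)
    stop("unknown taxon ", sQuote(name), "; closest names: ",
         paste(sQuote(near), collapse = ", "), call. = FALSE)
  }
  hit
}

#' Resolve a taxon name to its species set
#'
#' Looks the name (or any of its synonyms) up in the species tree and
#' returns the species leaves under the matching node; a species leaf
#' resolves to itself.
#'
#' @param name taxon name or synonym.
#' @param st a \code{tq_species_tree}.
#' @return character vector of species primary names (sorted).
#' @export
resolve_taxon <- function(name, st) {
  sort(st$primary[st$tips[[lookup_taxon(name, st)]]])
}

#' Parse a +/- taxon expression
#'
#' Expressions start from a base taxon and add or remove taxa
#' left-to-right, e.g. \code{"Mammalia -Primates"} is every mammal
#' species that is not a primate.  Both ASCII \code{-} and the minus sign
#' \code{U+2212} are accepted.
#'
#' @param text the expression.
#' @return a \code{tq_taxon_expression}: base name plus ordered
#'   (sign, name) modifiers.
#' @export
parse_taxon_expression <- function(text) {
  text <- gsub("−", "-", text)
  toks <- regmatches(text, gregexpr("[+-]", text))[[1]]
  parts <- strsplit(text, "[+-]")[[1]]
  parts <- trimws(parts)
  if (!length(parts) || !nzchar(parts[1]))
    stop("taxon expression must start with a base taxon: ", sQuote(text),
         call. = FALSE)
  mods <- list()
  for (i in seq_along(toks)) {
    nm <- if (i + 1 <= length(parts)) parts[i + 1] else ""
    if (!nzchar(nm))
      stop("dangling ", sQuote(toks[i]), " in taxon expression ",
           sQuote(text), call. = FALSE)
    mods[[i]] <- list(sign = toks[i], name = nm)
  }
  structure(list(base = parts[1], mods = mods),
            class = "tq_taxon_expression")
}

# species-leaf *ids* for an expression (internal workhorse)
taxon_expression_ids <- function(e, st) {
  if (is.character(e)) e <- parse_taxon_expression(e)
  ids <- st$tips[[lookup_taxon(e$base, st)]]
  for (m in e$mods) {
    s <- st$tips[[lookup_taxon(m$name, st)]]
    ids <- if (m$sign == "+") union(ids, s) else setdiff(ids, s)
  }
  if (!length(ids))
    warning("taxon expression ", sQuote(format_taxon_expression(e)),
            " resolves to the empty species set and can match nothing",
            call. = FALSE)
  sort(ids)
}

format_taxon_expression <- function(e) {
  paste0(e$base, paste(vapply(e$mods, function(m)
    paste0(" ", m$sign, m$name), character(1)), collapse = ""))
}

#' Evaluate a +/- taxon expression to a species set
#'
#' @param e a \code{tq_taxon_expression} or the expression text.
#' @param st a \code{tq_species_tree}.
#' @return character vector of species primary names (sorted).
#' @export
eval_taxon_expression <- function(e, st) {
  sort(st$primary[taxon_expression_ids(e, st)])
}

# -- LCA assignment -------------------------------------------------------

# ids variant: species-leaf ids -> species-tree node id
lca_ids <- function(ids, st) {
  if (!length(ids)) stop("empty species set has no LCA", call. = FALSE)
  v <- ids[1]
  while (!all(ids %in% st$tips[[v]])) v <- st$tree$parent[v]
  v
}

#' Lowest common ancestor of a species set
#'
#' The deepest species-tree node whose leaf set contains every given
#' species; this is the taxonomic group assigned to a gene-tree node
#' containing sequences from exactly those species.
#'
#' @param species character vector of species names (synonyms allowed).
#' @param st a \code{tq_species_tree}.
#' @return the primary name of the LCA node.
#' @export
assign_lca <- function(species, st) {
  if (!length(species)) stop("empty species set has no LCA", call. = FALSE)
  ids <- vapply(species, lookup_taxon, integer(1), st = st)
  st$primary[lca_ids(unique(ids), st)]
}

# -- restricted depths ----------------------------------------------------

# Nodes that survive restriction of the species tree to `present` leaf
# ids: present leaves, plus internal nodes with >= 2 children holding
# present descendants.  Degree-2 chains collapse onto their deepest
# surviving member.
restriction_info <- function(present, st) {
  nn <- n_nodes(st$tree)
  pc <- integer(nn) # present leaves below (or self)
  for (v in tree_postorder(st$tree)) {
    k <- st$tree$kids[[v]]
    pc[v] <- if (!length(k)) as.integer(v %in% present) else sum(pc[k])
  }
  surv <- logical(nn)
  for (v in seq_len(nn)) {
    k <- st$tree$kids[[v]]
    surv[v] <- if (!length(k)) pc[v] > 0L
               else sum(pc[k] > 0L) >= 2L
  }
  list(pc = pc, surv = surv)
}

# representative of `v` in the restricted tree (deepest surviving member
# of its chain), and its restricted depth (# surviving strict ancestors)
restricted_node <- function(v, info, st) {
  if (info$pc[v] == 0L)
    stop("taxon ", sQuote(st$primary[v]),
         " is disjoint from the species present in the gene tree",
         call. = FALSE)
  while (!info$surv[v]) {
    k <- st$tree$kids[[v]]
    v <- k[info$pc[k] > 0L][1]
  }
  v
}

restricted_depth_id <- function(v, info, st) {
  r <- restricted_node(v, info, st)
  d <- 0L
  p <- st$tree$parent[r]
  while (!is.na(p)) {
    if (info$surv[p]) d <- d + 1L
    p <- st$tree$parent[p]
  }
  d
}

#' Depth of a taxon on the restricted species tree
#'
#' Restricts the species tree to the species present in a gene tree,
#' suppresses the resulting degree-2 nodes (a collapsed chain is
#' represented by its deepest surviving member), and returns the number
#' of edges from the restricted root down to the node representing the
#' taxon.  With every species present this is the plain root-to-node
#' edge count.
#'
#' @param taxon taxon name (or synonym).
#' @param present character vector of species names present in the gene
#'   tree.
#' @param st a \code{tq_species_tree}.
#' @return non-negative integer depth.
#' @export
restricted_depth <- function(taxon, present, st) {
  v <- lookup_taxon(taxon, st)
  ids <- unique(vapply(present, lookup_taxon, integer(1), st = st))
  if (!length(ids)) stop("`present` must name at least one species", call. = FALSE)
  restricted_depth_id(v, restriction_info(ids, st), st)
}
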