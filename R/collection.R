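# Collection format: one text file bundling a reference species tree
# (taxon names, with "/"-separated synonyms, on every node) and a list of
# gene-tree entries, each carrying its own sequence-to-species map.
#
# Layout:
#   <species-tree Newick>;
#
#   >ENTRY_NAME
#   <gene-tree Newick>;
#   sequence<TAB>species      (one line per leaf)
#
# entries separated by blank lines.

#' Normalize a taxon or species name
#'
#' Case-insensitive matching with underscores equivalent to spaces and
#' runs of whitespace collapsed, so that variants such as
#' \code{"Rattus Norvegicus"}, \code{"rattus_norvegicus"} and
#' \code{"Rattus  norvegicus"} all address the same taxon.
#'
#' @param x character vector of names.
#' @return character vector of normalized keys.
#' @export
normalize_name <- function(x) {
  x <- gsub("_", " ", x, fixed = TRUE)
  x <- gsub("\\s+", " ", x)
  tolower(trimws(x))
}

#' Parse a reference species tree
#'
#' Reads a Newick string in which every node (leaves and internal nodes)
#' carries a taxon label; synonyms are separated by slashes, e.g.
#' \code{"ECOLI/Escherichia coli K12 W3110"}.  Multifurcations are
#' allowed.  The full set of names and synonyms must be collision-free
#' after normalization (see \code{\link{normalize_name}}).
#'
#' @param text a Newick string.
#' @return an object of class \code{tq_species_tree}: the tree plus, per
#'   node, the primary name, synonyms, leaf set, and depth, and a
#'   normalized name index.
#' @export
parse_species_tree <- function(text) {
  tree <- nw_parse(text)
  nn <- n_nodes(tree)
  unlabeled <- which(is.na(tree$label))
  if (length(unlabeled)) {
    d <- node_depths(tree)
    stop("species tree has an unlabeled node (internal node at depth ",
         d[unlabeled[1]], "); every node must carry a taxon name",
         call. = FALSE)
  }
  primary <- character(nn)
  synonyms <- vector("list", nn)
  idx <- new.env(parent = emptyenv())
  for (v in seq_len(nn)) {
    parts <- trimws(strsplit(tree$label[v], "/", fixed = TRUE)[[1]])
    parts <- parts[nzchar(parts)]
    if (!length(parts))
      stop("species tree node ", v, " has an empty name", call. = FALSE)
    primary[v] <- parts[1]
    synonyms[[v]] <- parts[-1]
    for (p in parts) {
      key <- normalize_name(p)
      if (!is.null(idx[[key]]))
        stop("duplicate taxon name after normalization: ", sQuote(p),
             " (nodes ", idx[[key]], " and ", v, ")", call. = FALSE)
      idx[[key]] <- v
    }
  }
  structure(list(tree = tree, primary = primary, synonyms = synonyms,
                 index = idx, tips = tips_under(tree),
                 depth = node_depths(tree)),
            class = "tq_species_tree")
}

#' @export
print.tq_species_tree <- function(x, ...) {
  nl <- sum(is_leaf(x$tree))
  cat("Reference species tree: ", nl, " species, ",
      n_nodes(x$tree) - nl, " higher groups (root: ",
      x$primary[x$tree$root], ")\n", sep = "")
  invisible(x)
}

species_tree_newick <- function(st) {
  nw_write(st$tree, function(tree, v)
    paste(c(st$primary[v], st$synonyms[[v]]), collapse = "/"))
}

# -- gene-tree entries ----------------------------------------------------

#' Create a validated gene-tree entry
#'
#' @param name entry name (unique within a collection).
#' @param tree a \code{tq_tree} as returned by the internal Newick reader;
#'   most users build entries through \code{\link{build_collection}} or
#'   \code{\link{parse_collection}}.
#' @param map named character vector: sequence name -> species name.
#' @param st the \code{tq_species_tree} the species must resolve in.
#' @return an object of class \code{tq_gene_entry}.
#' @export
gene_entry <- function(name, tree, map, st) {
  if (!tree_is_binary(tree))
    stop("gene tree ", sQuote(name), " is not binary: ",
         "the pattern-matching machinery only supports binary trees",
         call. = FALSE)
  lv <- leaf_ids(tree)
  seqs <- tree$label[lv]
  if (anyNA(seqs) || any(!nzchar(seqs)))
    stop("gene tree ", sQuote(name), " has an unnamed leaf", call. = FALSE)
  if (anyDuplicated(seqs))
    stop("gene tree ", sQuote(name), " repeats sequence name ",
         sQuote(seqs[duplicated(seqs)][1]), call. = FALSE)
  missing <- setdiff(seqs, names(map))
  if (length(missing))
    stop("entry ", sQuote(name), ": no species association for sequence ",
         sQuote(missing[1]), call. = FALSE)
  species_leaves <- leaf_ids(st$tree)
  sp_id <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    key <- normalize_name(map[[seqs[i]]])
    hit <- st$index[[key]]
    if (is.null(hit) || !(hit %in% species_leaves))
      stop("entry ", sQuote(name), ": sequence ", sQuote(seqs[i]),
           " maps to ", sQuote(unname(map[[seqs[i]]])),
           ", which is not a species leaf of the reference tree",
           call. = FALSE)
    sp_id[i] <- hit
  }
  # store the resolved primary species names, in leaf order
  resolved <- stats::setNames(st$primary[sp_id], seqs)
  structure(list(name = name, tree = tree, map = resolved),
            class = "tq_gene_entry")
}

#' @export
print.tq_gene_entry <- function(x, ...) {
  cat("Gene tree ", sQuote(x$name), ": ", sum(is_leaf(x$tree)),
      " sequences from ", length(unique(x$map)), " species\n", sep = "")
  invisible(x)
}

# -- collection -----------------------------------------------------------

new_collection <- function(st, entries) {
  nm <- vapply(entries, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop("duplicate entry name in collection: ",
         sQuote(nm[duplicated(nm)][1]), call. = FALSE)
  structure(list(species_tree = st, entries = stats::setNames(entries, nm)),
            class = "tq_collection")
}

#' @export
print.tq_collection <- function(x, ...) {
  print(x$species_tree)
  cat(length(x$entries), "gene-tree entries\n")
  invisible(x)
}

#' Parse a tree collection
#'
#' Reads the single-file collection format: a header species tree in
#' Newick (synonyms separated by slashes) followed by gene-tree entries,
#' each introduced by a \code{">NAME"} line, holding one Newick line
#' (internal-node labels are branch supports, or explicit \code{D}/\code{S}
#' event letters for reconciled trees) and one \code{sequence<TAB>species}
#' line per leaf.  Every entry is validated: gene trees must be binary and
#' every sequence must map to a species leaf of the header tree.
#'
#' @param text collection text, or a length-one path readable by
#'   \code{readLines} when \code{file = TRUE}.
#' @param file whether \code{text} is a file path.
#' @return a \code{tq_collection}.
#' @seealso \code{\link{write_collection}}, \code{\link{build_collection}}
#' @export
parse_collection <- function(text, file = FALSE) {
  lines <- if (file) readLines(text, warn = FALSE)
           else strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- sub("\\s+$", "", lines)
  i <- 1L
  while (i <= length(lines) && !nzchar(lines[i])) i <- i + 1L
  if (i > length(lines)) stop("empty collection", call. = FALSE)
  if (startsWith(lines[i], ">"))
    stop("collection must start with the species-tree header, ",
         "found entry ", sQuote(lines[i]), call. = FALSE)
  st <- parse_species_tree(lines[i])
  i <- i + 1L
  entries <- list()
  while (i <= length(lines)) {
    if (!nzchar(lines[i])) { i <- i + 1L; next }
    if (!startsWith(lines[i], ">"))
      stop("expected '>NAME' entry header at line ", i,
           ", found ", sQuote(lines[i]), call. = FALSE)
    name <- trimws(substring(lines[i], 2))
    i <- i + 1L
    if (i > length(lines) || !nzchar(lines[i]))
      stop("entry ", sQuote(name), " has no tree line", call. = FALSE)
    tree <- interpret_gene_labels(nw_parse(lines[i]))
    i <- i + 1L
    map <- character(0)
    while (i <= length(lines) && nzchar(lines[i]) && !startsWith(lines[i], ">")) {
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      if (length(f) != 2L)
        stop("entry ", sQuote(name), ": malformed association line ",
             sQuote(lines[i]), " (expected sequence<TAB>species)",
             call. = FALSE)
      map[f[1]] <- f[2]
      i <- i + 1L
    }
    entries[[length(entries) + 1L]] <- gene_entry(name, tree, map, st)
  }
  new_collection(st, entries)
}

#' Serialize a tree collection
#'
#' Deterministic inverse of \code{\link{parse_collection}}: stable entry
#' order, association lines in leaf order, numbers printed with
#' \code{"\%.6g"}, so that write-parse-write is byte-stable.
#'
#' @param collection a \code{tq_collection}.
#' @param path optional file path; when given the text is also written
#'   there.
#' @return the collection text, invisibly when \code{path} is given.
#' @export
write_collection <- function(collection, path = NULL) {
  out <- c(species_tree_newick(collection$species_tree), "")
  for (e in collection$entries) {
    seqs <- sort(e$tree$label[leaf_ids(e$tree)], method = "radix")
    out <- c(out,
             paste0(">", e$name),
             nw_write(e$tree, gene_label_fun),
             paste0(seqs, "\t", unname(e$map[seqs])),
             "")
  }
  txt <- paste(out, collapse = "\n")
  if (!is.null(path)) { writeLines(out, path); return(invisible(txt)) }
  txt
}

#' Build a collection from raw inputs
#'
#' The \emph{mkdb} step: assemble a species tree, a set of named gene
#' trees and a fully filled sequence-to-species association table into a
#' validated collection.
#'
#' @param st a \code{tq_species_tree} (or a Newick string).
#' @param gene_trees named character vector (or list) of Newick strings.
#' @param assoc data frame with columns \code{sequence} and
#'   \code{species} (no blanks allowed), as produced by
#'   \code{\link{extract_sequence_names}} once completed.
#' @return a \code{tq_collection}.
#' @export
build_collection <- function(st, gene_trees, assoc) {
  if (is.character(st) && !inherits(st, "tq_species_tree"))
    st <- parse_species_tree(st)
  if (is.null(names(gene_trees)) || any(!nzchar(names(gene_trees))))
    stop("gene_trees must be a named vector of Newick strings", call. = FALSE)
  blanks <- !nzchar(trimws(as.character(assoc$species))) |
    is.na(assoc$species)
  if (any(blanks))
    stop("association table has unfilled species for sequence(s): ",
         paste(sQuote(assoc$sequence[blanks]), collapse = ", "),
         call. = FALSE)
  map <- stats::setNames(as.character(assoc$species),
                         as.character(assoc$sequence))
  entries <- lapply(names(gene_trees), function(nm) {
    tree <- interpret_gene_labels(nw_parse(gene_trees[[nm]]))
    gene_entry(nm, tree, map, st)
  })
  new_collection(st, entries)
}

#' List the sequence names used in a set of gene trees
#'
#' Returns a ready-to-complete association template: one row per distinct
#' sequence name found at the leaves of the input trees, sorted
#' lexicographically, with an empty species column for the user to fill.
#'
#' @param gene_trees character vector (or list) of Newick strings.
#' @return data frame with columns \code{sequence} and \code{species}.
#' @export
extract_sequence_names <- function(gene_trees) {
  seqs <- character(0)
  for (nw in gene_trees) {
    tree <- nw_parse(nw)
    seqs <- c(seqs, tree$label[leaf_ids(tree)])
  }
  seqs <- sort(unique(seqs), method = "radix")
  data.frame(sequence = seqs, species = rep("", length(seqs)),
             stringsAsFactors = FALSE)
}
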