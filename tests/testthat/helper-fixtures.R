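# Shared fixtures: the two worked-example species trees and entry
# builders.  All fixtures are built in code; nothing is read from disk.

leaf_ids <- function(tree) which(lengths(tree$kids) == 0L)

bacteria_st <- function() parse_species_tree(paste0(
  "(Staphylococcus_aureus/SA,(Pseudomonas_aeruginosa/PA,",
  "(Escherichia_coli/EC,Shigella_dysenteriae/SD)Enterobacteria)",
  "Gammaproteobacteria)Bacteria;"))

mammal_st <- function() parse_species_tree(paste0(
  "((Homo_sapiens/Hs,Pan_troglodytes/Pt)Primates,",
  "((Mus_musculus/Mm,Rattus_norvegicus/Rn)Rodentia,Bos_taurus/Bt)",
  "NonPrimates)Mammalia;"))

abc_st <- function() parse_species_tree("(A,(B,C)BC)Root;")

# entry from a bare Newick (internal labels = supports or D/S letters)
mk_entry <- function(name, newick, map, st) {
  gene_entry(name,
             treequery:::interpret_gene_labels(treequery:::nw_parse(newick)),
             map, st)
}

fig2_map <- function() stats::setNames(c("A", "A", "B", "B", "B", "C"),
                                       c("a1", "a2", "b1", "b2", "b3", "c"))

bact_map <- function() stats::setNames(c("SA", "PA", "EC", "SD"),
                                       c("sa", "pa", "ec", "sd"))

# a small, valid collection as text, for I/O and CLI tests
toy_collection_text <- function() {
  st <- bacteria_st()
  e1 <- mk_entry("fam001", "((ec,sd)95,(pa,sa)80);", bact_map(), st)
  e2 <- mk_entry("fam002", "((ec,sa)99,(pa,sd)70);", bact_map(), st)
  write_collection(treequery:::new_collection(st, list(e1, e2)))
}

# random binary gene tree over a species tree: k leaves, species drawn
# with replacement, supports uniform on [0, 100], lengths exponential
rand_gene_entry <- function(st, k, name = "rand", multicopy = TRUE) {
  species <- st$primary[which(lengths(st$tree$kids) == 0)]
  picks <- if (multicopy) sample(species, k, replace = TRUE)
           else sample(species, k)
  seqs <- paste0("q", seq_len(k))
  # random topology by sequential joining
  nodes <- as.list(seqs)
  while (length(nodes) > 1) {
    i <- sample.int(length(nodes), 2)
    joined <- sprintf("(%s,%s)%d", nodes[[i[1]]], nodes[[i[2]]],
                      sample(0:100, 1))
    nodes <- c(nodes[-i], joined)
  }
  nw <- paste0(nodes[[1]], ";")
  mk_entry(name, nw, stats::setNames(picks, seqs), st)
}

# random pattern with at most `max_leaves` leaves over taxa of `st`
rand_pattern_text <- function(st, max_leaves = 4) {
  taxa <- st$primary
  rand_expr <- function() {
    base <- sample(taxa, 1)
    if (stats::runif(1) < 0.25) paste0(base, " -", sample(taxa, 1)) else base
  }
  rand_node <- function(n_leaves) {
    if (n_leaves == 1) {
      f2 <- if (stats::runif(1) < 0.3) rand_expr() else ""
      bang <- if (stats::runif(1) < 0.25) "!" else ""
      paste0(bang, "/", f2, "/", rand_expr())
    } else {
      nl <- sample(seq_len(n_leaves - 1), 1)
      mods <- paste0(
        if (stats::runif(1) < 0.3) paste0("$", sample(c(50, 80, 90), 1)),
        if (stats::runif(1) < 0.25) sample(c("D", "S"), 1),
        if (stats::runif(1) < 0.2) "!")
      paste0("(", rand_node(nl), ",", rand_node(n_leaves - nl), ")", mods)
    }
  }
  rand_node(sample(2:max_leaves, 1))
}
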