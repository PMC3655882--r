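test_that("pattern parsing builds the expected constraint trees", {
  p <- parse_pattern("((//Homo sapiens,//Pan troglodytes),//Rodentia)")
  expect_null(p$children[[1]]$children[[1]]$children)
  expect_equal(p$children[[1]]$children[[1]]$leaf_expr$base, "Homo sapiens")
  expect_null(p$children[[1]]$children[[1]]$path_expr)
  expect_equal(p$children[[2]]$leaf_expr$base, "Rodentia")

  p90 <- parse_pattern("(//Homo sapiens, //Mus musculus)$90")
  expect_equal(p90$support_min, 90)

  pd <- parse_pattern("(!//Homo sapiens, //Mus musculus)")
  expect_true(pd$children[[1]]$direct)
  expect_false(pd$children[[2]]$direct)
  # postfix "!" is the same constraint
  ppost <- parse_pattern("((//A,//B)!,//C)")
  expect_true(ppost$children[[1]]$direct)

  pev <- parse_pattern("(//Homo sapiens,//Mus musculus)D")
  expect_equal(pev$event, "D")
  pfield <- parse_pattern("(/Primates/Pan troglodytes,//Mus musculus)")
  expect_equal(pfield$children[[1]]$path_expr$base, "Primates")

  expect_error(parse_pattern("((//A,//B,//C),//D)"), "binary patterns")
  expect_error(parse_pattern("(//A,//B"), "syntax error")
})

test_that("leaf matching respects taxon sets and exclusions", {
  st <- mammal_st()
  e <- mk_entry("e", "((hs,pt),(mm,bt));",
                stats::setNames(c("Hs", "Pt", "Mm", "Bt"),
                                c("hs", "pt", "mm", "bt")), st)
  expect_true(leaf_matches("//Rodentia", e, "mm", st))
  expect_false(leaf_matches("//Rodentia", e, "hs", st))
  expect_false(leaf_matches("//Mammalia -Primates", e, "pt", st))
  expect_true(leaf_matches("//Mammalia -Primates", e, "bt", st))
  expect_true(leaf_matches("//Homo sapiens", e, "hs", st))
})

test_that("subtree path constraints reproduce the accept/reject pair", {
  st <- mammal_st()
  p <- parse_pattern("(/Primates/Pan troglodytes,//Mus musculus)")
  rejected <- mk_entry("A", "((pt,bt),mm);",
                       stats::setNames(c("Pt", "Bt", "Mm"),
                                       c("pt", "bt", "mm")), st)
  accepted <- mk_entry("B", "((pt,hs),mm);",
                       stats::setNames(c("Pt", "Hs", "Mm"),
                                       c("pt", "hs", "mm")), st)
  expect_equal(match_pattern(p, rejected, st)$count, 0)
  expect_equal(match_pattern(p, accepted, st)$count, 1)
})

test_that("support, event and direct-link constraints filter matches", {
  st <- mammal_st()
  map3 <- stats::setNames(c("Hs", "Mm", "Bt"), c("hs", "mm", "bt"))
  strong <- mk_entry("s", "((hs,mm)95,bt);", map3, st)
  weak <- mk_entry("w", "((hs,mm)80,bt);", map3, st)
  p90 <- "(//Homo sapiens,//Mus musculus)$90"
  expect_equal(match_pattern(p90, strong, st)$count, 1)
  expect_equal(match_pattern(p90, weak, st)$count, 0)
  # a node with no support value fails any $ constraint
  nosup <- mk_entry("n", "((hs,mm),bt);", map3, st)
  expect_equal(match_pattern(p90, nosup, st)$count, 0)

  dup <- mk_entry("d", "((hs1,mm1),(hs2,mm2));",
                  stats::setNames(c("Hs", "Mm", "Hs", "Mm"),
                                  c("hs1", "mm1", "hs2", "mm2")), st)
  ev <- annotate_events(dup, st)
  expect_equal(ev[dup$tree$root], "D") # children share species
  expect_equal(match_pattern("(//Homo sapiens,//Mus musculus)D", dup, st)$count,
               2) # hs1+mm2 and hs2+mm1, through the duplication root
  expect_equal(match_pattern("(//Homo sapiens,//Mus musculus)S", dup, st)$count,
               2) # the two speciation cherries
  # explicit event letters in the input override the overlap rule
  forced <- mk_entry("f", "((hs,mm)D,bt);", map3, st)
  expect_equal(annotate_events(forced, st)[
    which(!lengths(forced$tree$kids) == 0)[2]], "D")

  direct <- "(!//Homo sapiens,//Mus musculus)"
  gapped <- mk_entry("g", "((hs,bt),mm);", map3, st)
  flush <- mk_entry("h", "(hs,(mm,bt));", map3, st)
  expect_equal(match_pattern(direct, gapped, st)$count, 0)
  expect_equal(match_pattern(direct, flush, st)$count, 1)
})

test_that("events under a duplicated cherry follow species overlap", {
  st <- gen_species_tree(5, seed = 7)
  g <- gen_gene_tree(st, n_dup = 0, seed = 8)$entry
  # duplicate one species by hand: cherry of two same-species sequences
  nw <- treequery:::nw_write(g$tree, treequery:::gene_label_fun)
  sp <- g$map[[1]]; sq <- names(g$map)[1]
  nw2 <- sub(sq, sprintf("(%s,%s_b)", sq, sq), nw, fixed = TRUE)
  map2 <- c(g$map, stats::setNames(sp, paste0(sq, "_b")))
  e2 <- mk_entry("dup", nw2, map2, st)
  ev <- annotate_events(e2, st)
  cherry <- e2$tree$parent[which(e2$tree$label == sq)]
  expect_equal(ev[cherry], "D")
  # brute-force check of every node
  tips <- treequery:::tips_under(e2$tree)
  for (v in which(lengths(e2$tree$kids) == 2)) {
    k <- e2$tree$kids[[v]]
    sp1 <- e2$map[e2$tree$label[tips[[k[1]]]]]
    sp2 <- e2$map[e2$tree$label[tips[[k[2]]]]]
    expect_equal(ev[v], if (length(intersect(sp1, sp2))) "D" else "S")
  }
})

test_that("query_collection preserves order and counts totals", {
  coll <- parse_collection(toy_collection_text())
  # (EC,SD) grouping with SA outside: only fam001 has it
  res <- query_collection("((//EC,//SD),//SA)", coll)
  expect_equal(res$entry, "fam001")
  expect_true(attr(res, "total_matches") >= 1)
  none <- query_collection("((//SA,//SD),//EC)$99", coll)
  expect_equal(nrow(none), 0)
})

test_that("the matcher agrees with the brute-force oracle on random cases", {
  set.seed(2024)
  for (rep in 1:40) {
    st <- gen_species_tree(sample(4:8, 1))
    e <- rand_gene_entry(st, sample(4:10, 1))
    ptxt <- rand_pattern_text(st, 4)
    got <- suppressWarnings(match_pattern(ptxt, e, st))
    want <- suppressWarnings(oracle_matches(ptxt, e, st))
    expect_equal(got$count, length(want), label = sprintf(
      "count for pattern %s (rep %d)", ptxt, rep))
    expect_identical(map_keys(got$matches), map_keys(want))
  }
})

test_that("relaxing constraints never removes matches", {
  set.seed(515)
  st <- mammal_st()
  tight <- parse_pattern("((//Homo sapiens,//Pan troglodytes),//Rodentia)")
  loose <- parse_pattern("((//Homo sapiens,//Pan troglodytes),//Mammalia -Primates)")
  for (rep in 1:25) {
    e <- rand_gene_entry(st, sample(4:10, 1))
    n_tight <- match_pattern(tight, e, st, list_matches = FALSE)$count
    n_loose <- match_pattern(loose, e, st, list_matches = FALSE)$count
    expect_gte(n_loose, n_tight)
  }
})

test_that("tightening the support threshold shrinks match counts monotonically", {
  set.seed(808)
  st <- gen_species_tree(6)
  entries <- lapply(1:15, function(i) rand_gene_entry(st, 8, paste0("e", i)))
  coll <- treequery:::new_collection(st, entries)
  base <- sprintf("((//%s,//%s),//%s)", st$primary[leaf_ids(st$tree)[1]],
                  st$primary[leaf_ids(st$tree)[2]],
                  st$primary[st$tree$root])
  counts <- vapply(c(0, 80, 85, 90, 95), function(thr) {
    p <- treequery:::tighten_support(parse_pattern(base), thr)
    sum(query_collection(p, coll)$matches)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})
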