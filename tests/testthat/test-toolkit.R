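test_that("species-tree generation is deterministic and well-formed", {
  expect_error(gen_species_tree(1), "at least 2")
  st2 <- gen_species_tree(2, seed = 3)
  expect_length(leaf_ids(st2$tree), 2) # a cherry
  a <- gen_species_tree(17, seed = 42)
  b <- gen_species_tree(17, seed = 42)
  expect_identical(treequery:::species_tree_newick(a),
                   treequery:::species_tree_newick(b))
  big <- gen_species_tree(50, seed = 9)
  expect_true(treequery:::tree_is_binary(big$tree))
  expect_length(big$primary, 50 + 49) # 49 internal nodes when binary
})

test_that("generated gene trees are congruent copies unless events are seeded", {
  st <- gen_species_tree(8, seed = 12)
  g <- gen_gene_tree(st, seed = 13)
  expect_equal(unicity_score(g$entry), 0)
  expect_equal(nrow(detect_incongruencies(g$entry, st, 0)), 0)
  # one ancient duplication doubles the leaves and keeps species counts = 2
  gd <- gen_gene_tree(st, n_dup = 1, seed = 14)
  expect_length(leaf_ids(gd$entry$tree), 16)
  expect_true(all(table(gd$entry$map) == 2))
  # one transfer is recorded in the truth and detectable at threshold 0
  gt <- gen_gene_tree(st, n_transfer = 1, seed = 15)
  expect_length(gt$truth$transferred, 1)
  rec <- detect_incongruencies(gt$entry, st, 0)
  expect_true(gt$truth$transferred %in% unlist(strsplit(rec$pruned, ",")))
})

test_that("generated collections always satisfy the collection invariants", {
  g <- gen_collection(7, 5, seed = 21, n_transfer = 1)
  # a parse of the serialized collection revalidates every invariant
  coll <- parse_collection(write_collection(g$collection))
  expect_length(coll$entries, 5)
  expect_identical(write_collection(coll), write_collection(g$collection))
})

test_that("the CLI dispatches, reports usage errors and round-trips files", {
  tmp <- withr::local_tempdir()
  coll_file <- file.path(tmp, "coll.txt")
  out_file <- file.path(tmp, "out.tsv")
  writeLines(strsplit(toy_collection_text(), "\n")[[1]], coll_file)

  expect_equal(tq_cli(character(0)), 2L) # usage
  expect_equal(tq_cli(c("query", "--collection", coll_file)), 2L) # no pattern
  expect_equal(tq_cli(c("query", "--collection", coll_file,
                        "--pattern", "((//EC,//SD),//SA)",
                        "--out", out_file)), 0L)
  res <- read.delim(out_file)
  expect_equal(res$entry, "fam001")
  # empty result is still success with a header-only file
  expect_equal(tq_cli(c("query", "--collection", coll_file,
                        "--pattern", "((//SA,//PA)$99,//EC)",
                        "--out", out_file)), 0L)
  expect_equal(nrow(read.delim(out_file)), 0)

  expect_equal(tq_cli(c("root", "--collection", coll_file,
                        "--strategy", "taxonomy", "--out", out_file)), 0L)
  rep <- read.delim(out_file)
  expect_named(rep, c("entry", "edge", "U", "D", "root_branch",
                      "tie_stage", "rooted_tree"))
  expect_true(all(rep$tie_stage %in%
                    c("unicity", "taxonomy", "branch", "arbitrary")))

  expect_equal(tq_cli(c("incongruencies", "--collection", coll_file,
                        "--support-min", "90", "--out", out_file)), 0L)
  expect_true(file.exists(out_file))

  # fixtures subcommand emits a parseable collection, deterministically
  fix1 <- file.path(tmp, "fix1.txt"); fix2 <- file.path(tmp, "fix2.txt")
  expect_equal(tq_cli(c("fixtures", "--n-species", "6", "--n-trees", "3",
                        "--seed", "5", "--out", fix1)), 0L)
  expect_equal(tq_cli(c("fixtures", "--n-species", "6", "--n-trees", "3",
                        "--seed", "5", "--out", fix2)), 0L)
  expect_identical(readLines(fix1), readLines(fix2))
  expect_length(parse_collection(fix1, file = TRUE)$entries, 3)
})

test_that("mkdb builds templates and collections, and flags blanks", {
  tmp <- withr::local_tempdir()
  trees_file <- file.path(tmp, "genes.nwk")
  writeLines(c(">famA", "((ec,sd)90,(pa,sa)80);",
               ">famB", "((ec,pa)70,(sd,sa)60);"), trees_file)
  st_file <- file.path(tmp, "species.nwk")
  writeLines(paste0("(Staphylococcus_aureus/SA,(Pseudomonas_aeruginosa/PA,",
                    "(Escherichia_coli/EC,Shigella_dysenteriae/SD)",
                    "Enterobacteria)Gammaproteobacteria)Bacteria;"), st_file)

  tmpl_file <- file.path(tmp, "template.tsv")
  expect_equal(tq_cli(c("mkdb", "--gene-trees", trees_file, "--template",
                        "--out", tmpl_file)), 0L)
  tmpl <- read.delim(tmpl_file)
  expect_equal(tmpl$sequence, c("ec", "pa", "sa", "sd"))

  assoc_file <- file.path(tmp, "assoc.tsv")
  writeLines(c("sequence\tspecies", "ec\tEC", "sd\tSD", "pa\tPA", "sa\tSA"),
             assoc_file)
  coll_file <- file.path(tmp, "built.txt")
  expect_equal(tq_cli(c("mkdb", "--gene-trees", trees_file,
                        "--species-tree", st_file, "--assoc", assoc_file,
                        "--out", coll_file)), 0L)
  expect_length(parse_collection(coll_file, file = TRUE)$entries, 2)

  # incomplete association table: data error (exit 1) naming the blank
  writeLines(c("sequence\tspecies", "ec\tEC", "sd\tSD", "pa\tPA", "sa\t"),
             assoc_file)
  msgs <- capture.output(
    code <- tq_cli(c("mkdb", "--gene-trees", trees_file,
                     "--species-tree", st_file, "--assoc", assoc_file,
                     "--out", coll_file)), type = "message")
  expect_equal(code, 1L)
  expect_true(any(grepl("sa", msgs)))
})

test_that("the installed CLI script runs end to end", {
  script <- system.file("cli", "treequery.R", package = "treequery")
  skip_if(script == "", "CLI script not installed")
  tmp <- withr::local_tempdir()
  coll_file <- file.path(tmp, "coll.txt")
  writeLines(strsplit(toy_collection_text(), "\n")[[1]], coll_file)
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(system2(
    rscript, c(script, "query", "--collection", shQuote(coll_file),
               "--pattern", shQuote("((//EC,//SD),//SA)")),
    stdout = TRUE, stderr = FALSE))
  expect_equal(out[1], "entry\tmatches")
  expect_true(any(grepl("fam001", out)))
})
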