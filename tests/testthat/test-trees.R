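test_that("newick parsing derives node ages from path sums", {
  tr <- read_dated_tree("(A:1.0,B:1.0):0.0;")
  expect_setequal(tr$tip.label, c("A", "B"))
  expect_equal(tree_height(tr), 1.0)
  expect_equal(unname(tr$node_age[1:2]), c(0, 0))

  tr2 <- read_dated_tree("((A:1,B:1):2,(C:2,D:2):1);")
  ages <- node_ages(tr2)
  expect_equal(tree_height(tr2), 3)
  keys <- clade_set(tr2)
  expect_equal(ages[as.integer(names(keys)[keys == "A;B"])], 1)
  expect_equal(ages[as.integer(names(keys)[keys == "C;D"])], 2)
})

test_that("non-ultrametric and malformed inputs fail with informative errors", {
  expect_error(read_dated_tree("((A:1,B:2):1,C:3);"), "not ultrametric.*'A'")
  expect_error(read_dated_tree("((A:1,B:1:2,C:2);"), "offset")
  expect_error(read_dated_tree("(A:1,B:1))(;"), "unmatched '\\)' at character offset 10")
  expect_error(read_dated_tree("(A:1,B:1)"), "missing ';'")
  # polytomies are rejected: DIVA needs strict bifurcation
  expect_error(read_dated_tree("(A:1,B:1,C:1);"), "polytom")
  # rounded branch lengths within relative tolerance still pass
  expect_s3_class(read_dated_tree("((A:1.0000001,B:1):2,C:3);"), "dated_tree")
})

test_that("write/read round trip preserves topology and ages", {
  set.seed(42)
  for (i in 1:5) {
    tr <- random_dated_tree(8)
    tr2 <- read_dated_tree(write_dated_tree(tr))
    expect_true(setequal(clade_set(tr2), clade_set(tr)))
    k1 <- clade_set(tr); k2 <- clade_set(tr2)
    expect_equal(unname(tr2$node_age[match(k1, k2)]), unname(tr$node_age),
                 tolerance = 1e-9)
  }
})

test_that("clade sets have 2n - 1 keys on bifurcating trees", {
  expect_setequal(clade_set(read_dated_tree("(A:1,B:1);")),
                  c("A", "B", "A;B"))
  expect_length(clade_set(read_dated_tree("((A:1,B:1):2,(C:2,D:2):1);")), 7)
  caterpillar <- read_dated_tree(
    "((((A:1,B:1):1,C:2):1,D:3):1,E:4);")
  expect_length(clade_set(caterpillar), 9)
  set.seed(7)
  for (n in c(4, 11, 32)) {
    expect_length(clade_set(random_dated_tree(n)), 2 * n - 1)
  }
})

test_that("mrca_clade returns the smallest enclosing clade", {
  tr <- read_dated_tree("((A:1,B:1):2,(C:2,D:2):1);")
  expect_equal(mrca_clade(tr, tr$tip.label), "A;B;C;D")
  expect_equal(mrca_clade(tr, c("A", "C")), "A;B;C;D")
  expect_equal(mrca_clade(tr, c("C", "D")), "C;D")
  expect_equal(mrca_age(tr, c("C", "D")), 2)
  expect_error(mrca_clade(tr, c("A", "Z")), "unknown taxa: Z")
  # exhaustive check against clade enumeration on random trees
  set.seed(3)
  tr2 <- random_dated_tree(8)
  keys <- clade_set(tr2)
  for (i in 1:10) {
    taxa <- sample(tr2$tip.label, sample(2:6, 1))
    containing <- keys[vapply(keys, function(k) {
      all(taxa %in% clade_key_taxa(k))
    }, logical(1))]
    smallest <- containing[which.min(vapply(containing, function(k) {
      length(clade_key_taxa(k))
    }, integer(1)))]
    expect_equal(mrca_clade(tr2, taxa), unname(smallest))
  }
})

test_that("identical topologies have no discordant taxa", {
  set.seed(11)
  for (i in 1:20) {
    tr <- random_dated_tree(sample(4:12, 1))
    tr2 <- perturb_node_ages(tr, sd = 0.2, seed = i)
    expect_identical(discordant_taxa(tr, tr2), character(0))
  }
})

test_that("a single moved tip is identified by name", {
  t1 <- read_dated_tree(
    "(((A:1,B:1):1,(C:1.5,X:1.5):0.5):1,(D:2,E:2):1);")
  t2 <- read_dated_tree(
    "((((A:1,X:1):0.5,B:1.5):0.5,C:2):1,(D:2,E:2):1);")
  # leave-one-out oracle: only removing X reconciles the clade sets
  reconciles <- function(tax) {
    keep1 <- setdiff(t1$tip.label, tax); keep2 <- setdiff(t2$tip.label, tax)
    p1 <- as_dated_tree(ape::keep.tip(t1, keep1))
    p2 <- as_dated_tree(ape::keep.tip(t2, keep2))
    setequal(clade_set(p1), clade_set(p2))
  }
  singles <- vapply(t1$tip.label, reconciles, logical(1))
  expect_identical(names(singles)[singles], "X")
  expect_identical(discordant_taxa(t1, t2), "X")
})

test_that("two independent tip moves are both found", {
  t1 <- read_dated_tree(paste0(
    "(((A:1,B:1):1,(C:1,D:1):1):1,((E:1,F:1):1,(G:1,H:1):1):1);"))
  t2 <- read_dated_tree(paste0(
    "(((A:2,(C:1,B:1):1):1,D:3):1,((E:2,(G:1,F:1):1):1,H:3):1);"))
  got <- discordant_taxa(t1, t2)
  # exhaustive oracle over all taxon subsets of size <= 2
  reconciles <- function(tax) {
    p1 <- as_dated_tree(ape::keep.tip(t1, setdiff(t1$tip.label, tax)))
    p2 <- as_dated_tree(ape::keep.tip(t2, setdiff(t2$tip.label, tax)))
    setequal(clade_set(p1), clade_set(p2))
  }
  sizes <- c(lapply(t1$tip.label, identity),
             combn(t1$tip.label, 2, simplify = FALSE))
  min_size <- min(vapply(sizes[vapply(sizes, reconciles, logical(1))],
                         length, integer(1)))
  expect_length(got, min_size)
  expect_true(reconciles(got))
})

test_that("removing the discordant taxa always reconciles random tree pairs", {
  set.seed(23)
  for (i in 1:10) {
    n <- sample(5:10, 1)
    t1 <- random_dated_tree(n)
    t2 <- random_dated_tree(n)
    d <- discordant_taxa(t1, t2)
    expect_lt(length(d), n - 1)
    keep <- setdiff(t1$tip.label, d)
    if (length(keep) >= 2) {
      p1 <- as_dated_tree(ape::keep.tip(t1, keep))
      p2 <- as_dated_tree(ape::keep.tip(t2, keep))
      expect_true(setequal(clade_set(p1), clade_set(p2)))
    }
  }
  expect_error(
    discordant_taxa(read_dated_tree("(A:1,B:1);"),
                    read_dated_tree("(A:1,C:1);")),
    "tip sets differ")
})

test_that("tree samples apply fractional burn-in by count", {
  set.seed(5)
  trees <- replicate(8, random_dated_tree(5), simplify = FALSE)
  f <- tempfile(fileext = ".nwk")
  writeLines(vapply(trees, write_dated_tree, character(1)), f)
  kept <- read_tree_sample(f, burnin = 0.25)
  expect_length(kept, 6)
  expect_equal(attr(kept, "n_discarded"), 2)
  # the first floor(0.25 * 8) = 2 trees are gone
  expect_equal(write_dated_tree(kept[[1]]), write_dated_tree(trees[[3]]))
  kept0 <- read_tree_sample(trees, burnin = 0)
  expect_length(kept0, 8)
})

test_that("NEXUS trees blocks with translate tables are honored", {
  nx <- c("#NEXUS", "BEGIN TREES;",
          "  TRANSLATE", "    1 A,", "    2 B,", "    3 C;",
          "  TREE one = ((1:1,2:1):1,3:2);",
          "  TREE two = ((1:2,3:2):1,2:3);",
          "END;")
  f <- tempfile(fileext = ".nex")
  writeLines(nx, f)
  kept <- read_tree_sample(f, burnin = 0)
  expect_length(kept, 2)
  expect_setequal(kept[[1]]$tip.label, c("A", "B", "C"))
  expect_true("A;B" %in% clade_set(kept[[1]]))
  expect_true("A;C" %in% clade_set(kept[[2]]))
})
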