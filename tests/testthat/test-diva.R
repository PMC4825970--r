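test_that("uniform tip ranges need no events", {
  tr <- read_dated_tree("((t1:1,t2:1):2,(t3:2,t4:2):1);")
  ab <- make_alphabet("AB")
  tips <- tips_tbl(tr$tip.label, rep(1L, 4), ab)
  rec <- diva_optimize(tr, tips)
  expect_equal(rec$cost, 0L)
  internal <- rec$ranges[grepl(";", rec$ranges$clade), ]
  expect_true(all(internal$range == "A"))
  expect_true(all(rec$events$event == "duplication"))
})

test_that("disjoint two-tip ranges force free vicariance at the root", {
  tr <- read_dated_tree("(t1:1,t2:1);")
  tips <- tips_tbl(tr$tip.label, c(1L, 2L), make_alphabet("AB"))
  rec <- diva_optimize(tr, tips)
  expect_equal(rec$cost, 0L)
  root <- rec$ranges[rec$ranges$clade == "t1;t2", ]
  expect_equal(root$range, "AB")
  expect_equal(rec$events$event, "vicariance")
  expect_equal(rec$routes$route, "AB|A^B")
})

test_that("the three-tip splitting example has cost 1 and a root tie", {
  tr <- read_dated_tree("((t1:1,t2:1):1,t3:2);")
  tips <- tips_tbl(tr$tip.label, c(1L, 2L, 1L), make_alphabet("AB"))
  rec <- diva_optimize(tr, tips)
  expect_equal(rec$cost, 1L)
  root <- rec$ranges[rec$ranges$clade == "t1;t2;t3", ]
  expect_setequal(root$range, c("A", "AB"))
  expect_equal(root$weight, c(0.5, 0.5))
  # frozen from the exhaustive oracle
  orc <- diva_oracle(tr, c(1L, 2L, 1L), 2)
  expect_equal(rec$cost, as.integer(orc$cost))
  expect_setequal(root$range, mask_range(orc$root_ranges, make_alphabet("AB")))
})

test_that("DIVA equals exhaustive enumeration on random small instances", {
  set.seed(101)
  n_cases <- 60
  for (i in seq_len(n_cases)) {
    n <- sample(3:6, 1)
    k <- sample(2:3, 1)
    tr <- random_dated_tree(n)
    tips <- random_tips(tr, k)
    rec <- diva_optimize(tr, tips)
    orc <- diva_oracle(tr, tips$mask[match(tr$tip.label, tips$taxon)], k)
    expect_equal(rec$cost, as.integer(orc$cost),
                 info = sprintf("case %d: cost mismatch", i))
    root_key <- clade_key(tr$tip.label)
    got_root <- sort(rec$ranges$mask[rec$ranges$clade == root_key])
    expect_equal(got_root, orc$root_ranges,
                 info = sprintf("case %d: root range set mismatch", i))
    # per-node optimal sets agree too
    keys <- clade_set(tr)
    for (v in names(orc$per_node)) {
      got <- sort(rec$ranges$mask[rec$ranges$clade == keys[v]])
      expect_equal(got, orc$per_node[[v]],
                   info = sprintf("case %d node %s", i, v))
    }
  }
})

test_that("adding one area to a tip moves the optimal cost by at most 1", {
  set.seed(202)
  for (i in 1:25) {
    n <- sample(3:6, 1)
    k <- 3
    tr <- random_dated_tree(n)
    tips <- random_tips(tr, k)
    base <- diva_optimize(tr, tips)$cost
    j <- sample.int(n, 1)
    free <- which(bitwAnd(bitwShiftR(tips$mask[j], 0:(k - 1)), 1L) == 0L)
    if (length(free) == 0) next
    tips2 <- tips
    tips2$mask[j] <- tips$mask[j] + bitwShiftL(1L, sample(free, 1) - 1L)
    tips2$range <- mask_range(tips2$mask, attr(tips, "alphabet"))
    expect_lte(abs(diva_optimize(tr, tips2)$cost - base), 1)
  }
})

test_that("per-clade weights are normalized and ranges respect max_areas", {
  set.seed(303)
  tr <- random_dated_tree(6)
  tips <- random_tips(tr, 3)
  rec <- diva_optimize(tr, tips, max_areas = 2)
  sums <- tapply(rec$ranges$weight, rec$ranges$clade, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  internal <- rec$ranges[grepl(";", rec$ranges$clade), ]
  expect_true(all(nchar(internal$range) <= 2))
})

test_that("exact mode is capped at 8 areas", {
  tr <- read_dated_tree("(t1:1,t2:1);")
  ab <- area_alphabet(LETTERS[1:9])
  tips <- tips_tbl(tr$tip.label, c(1L, 2L), ab)
  expect_error(diva_optimize(tr, tips, mode = "exact"), "capped at 8 areas")
  expect_warning(rec <- diva_optimize(tr, tips), "restricted")
  expect_equal(rec$cost, 0L)
})

test_that("sdiva averages uniform tie-weights over trees containing a clade", {
  set.seed(404)
  trees <- replicate(3, random_dated_tree(5), simplify = FALSE)
  tips <- random_tips(trees[[1]], 2)
  # single tree: identical to diva_optimize weights
  single <- sdiva(trees[1], tips)
  rec1 <- diva_optimize(trees[[1]], tips)
  merged <- merge(as.data.frame(single), as.data.frame(rec1$ranges),
                  by = c("clade", "range"))
  expect_equal(merged$frequency, merged$weight)
  expect_true(all(single$occupancy == 1))

  # multi-tree: equals a manual average computed with independent base-R code
  freqs <- sdiva(trees, tips)
  per_tree <- lapply(trees, function(tr) diva_optimize(tr, tips)$ranges)
  for (row in sample(nrow(freqs), 10)) {
    cl <- freqs$clade[row]; rg <- freqs$range[row]
    w <- vapply(per_tree, function(df) {
      if (!cl %in% df$clade) return(NA_real_)
      sum(df$weight[df$clade == cl & df$range == rg])
    }, numeric(1))
    expect_equal(freqs$frequency[row], mean(w, na.rm = TRUE), tolerance = 1e-12)
    expect_equal(freqs$occupancy[row], mean(!is.na(w)))
  }
  # frequencies normalize within every clade
  sums <- tapply(freqs$frequency, freqs$clade, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_error(sdiva(list(), tips), "empty")
})
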