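test_that("printed windows and intervals reproduce the recorded decisions", {
  # GAARlandia vs the Antillean colonisation node: B1 already disjoint
  expect_equal(congruence_test(
    list(B1 = c(8.14, 19.72), B2 = c(9.29, 22.29), B3 = c(9.22, 23.16)),
    c(35, 33))$decision, "rejected")
  # Bering land bridge: every analysis overlaps
  expect_equal(congruence_test(
    list(B1 = c(11.92, 31.64), B2 = c(16.71, 28.34), B3 = c(14.18, 26.05)),
    c(25, 10))$decision, "not_rejected")
  # Acre system: only the middle analysis is disjoint, still rejected
  res <- congruence_test(
    list(B1 = c(9.51, 20.88), B2 = c(14.76, 28.37), B3 = c(8.83, 18.27)),
    c(10.0, 7.0))
  expect_equal(res$decision, "rejected")
  expect_equal(res$flags$overlaps, c(TRUE, FALSE, TRUE))
  # full overlap is trivially not rejected
  expect_equal(congruence_test(
    list(B1 = c(5, 10), B2 = c(5, 10)), c(10, 5))$decision, "not_rejected")
  # a shared endpoint counts as overlap (closed intervals)
  expect_equal(congruence_test(list(B1 = c(10, 20)), c(25, 20))$decision,
               "not_rejected")
})

test_that("alternative decision rules are selectable", {
  ivs <- list(B1 = c(9.51, 20.88), B2 = c(14.76, 28.37), B3 = c(8.83, 18.27))
  expect_equal(congruence_test(ivs, c(10, 7), rule = "any-run-overlap")$decision,
               "not_rejected")
  expect_equal(congruence_test(list(B1 = c(11, 12)), c(10, 7),
                               rule = "any-run-overlap")$decision, "rejected")
  expect_equal(congruence_test(list(B1 = c(6, 10)), c(10, 7),
                               rule = "mean-in-window")$decision, "not_rejected")
  expect_equal(congruence_test(list(B1 = c(6, 20)), c(10, 7),
                               rule = "mean-in-window")$decision, "rejected")
})

test_that("overlap is symmetric in interval and window roles", {
  set.seed(88)
  for (i in 1:1000) {
    a <- sort(runif(2, 0, 50)); b <- sort(runif(2, 0, 50))
    f1 <- congruence_test(list(X = a), b)$flags$overlaps
    f2 <- congruence_test(list(X = b), a)$flags$overlaps
    expect_identical(f1, f2)
  }
})

test_that("widening an interval never flips not_rejected to rejected", {
  set.seed(99)
  for (i in 1:200) {
    ivs <- list(B1 = sort(runif(2, 0, 40)), B2 = sort(runif(2, 0, 40)),
                B3 = sort(runif(2, 0, 40)))
    w <- sort(runif(2, 0, 40))
    d1 <- congruence_test(ivs, w)$decision
    j <- sample(3, 1)
    ivs[[j]] <- c(ivs[[j]][1] - runif(1, 0, 5), ivs[[j]][2] + runif(1, 0, 5))
    d2 <- congruence_test(ivs, w)$decision
    if (d1 == "not_rejected") expect_equal(d2, "not_rejected")
  }
})

test_that("the packaged hypothesis table reproduces all recorded decisions", {
  tbl <- load_fixture("table3")
  rep <- run_hypothesis_table(tbl, rule = "all-runs-overlap")
  expect_equal(nrow(rep$decisions), 14)
  expect_equal(nrow(rep$mismatches), 0)
  expect_equal(rep$counts$n_cladogenetic_events, 11)
  expect_equal(rep$counts$n_geological_hypotheses, 13)
  expect_equal(rep$counts$n_rejected, 2)
  expect_equal(sum(rep$decisions$decision == "not_rejected"), 12)
  rejected <- rep$decisions[rep$decisions$decision == "rejected", ]
  expect_setequal(rejected$geological_event, c("Acre System", "GAARlandia"))
})

test_that("hypothesis-table validation catches malformed input", {
  tbl <- load_fixture("table3")
  expect_error(run_hypothesis_table(rbind(tbl, tbl[1, ])), "duplicate")
  bad <- tbl
  bad$B1_lower[1] <- bad$B1_upper[1] + 1
  expect_error(run_hypothesis_table(bad), "lower >= upper")
  empty <- tbl[0, ]
  rep0 <- run_hypothesis_table(empty)
  expect_equal(rep0$counts$n_cladogenetic_events, 0)
  expect_equal(rep0$counts$n_rejected, 0)
  one <- tbl[11, ]  # GAARlandia row: disjoint in at least one analysis
  expect_equal(run_hypothesis_table(one)$counts$n_rejected, 1)
})

test_that("decimal commas in transcribed tables are normalized", {
  tbl <- load_fixture("table3")
  raw <- as.data.frame(tbl)
  raw$older_ma <- as.character(raw$older_ma)
  raw$older_ma[3] <- "23,0"
  parsed <- read_hypothesis_table(raw)
  expect_equal(parsed$older_ma[3], 23)
})

test_that("report and posterior plots build without error", {
  rep <- run_hypothesis_table(load_fixture("table3"))
  expect_s3_class(ggplot2::autoplot(rep), "ggplot")
  post <- tibble::tibble(label = rep(c("B1", "B2"), each = 50),
                         clade = "x;y", age = rlnorm(100, 2, 0.3))
  expect_s3_class(plot_age_posterior(post, window = c(10, 5)), "ggplot")
})
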