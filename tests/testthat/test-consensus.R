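# minimal stand-in reconstruction carrying only what the consensus needs
fake_recon <- function(vic_clades, topology) {
  structure(list(events = tibble::tibble(clade = vic_clades,
                                         event = "vicariance"),
                 topology = topology),
            class = "ancestral_recon")
}

four_topologies <- function() {
  t1 <- read_dated_tree("(((a:1,b:1):1,c:2):1,d:3);")
  t2 <- read_dated_tree("(((a:1,b:1):2,c:3):1,d:4);")
  t3 <- read_dated_tree("(((a:2,b:2):1,c:3):2,d:5);")
  t4 <- read_dated_tree("((a:1,b:1):1,(c:1,d:1):1);")  # c;d instead of a;b;c
  list(ML = t1, B1 = t2, B2 = t3, B3 = t4)
}

test_that("the 50%-of-grid criterion is inclusive and support is reported", {
  topos <- four_topologies()
  # a;b occurs in all four topologies; vicariant in 9 of 16 reconstructions
  grid <- c(lapply(1:9, function(i) fake_recon("a;b", names(topos)[(i %% 4) + 1])),
            lapply(1:7, function(i) fake_recon(character(0),
                                               names(topos)[(i %% 4) + 1])))
  calls <- consensus_vicariance(grid, topos)
  expect_equal(calls$clade, "a;b")
  expect_equal(calls$support, 9 / 16)
  expect_equal(calls$n_topologies_present, 4)

  # exactly 8 of 16 still passes ("at least 50%")
  grid8 <- c(lapply(1:8, function(i) fake_recon("a;b", names(topos)[(i %% 4) + 1])),
             lapply(1:8, function(i) fake_recon(character(0),
                                                names(topos)[(i %% 4) + 1])))
  expect_equal(consensus_vicariance(grid8, topos)$support, 0.5)
  # 7 of 16 fails
  grid7 <- c(lapply(1:7, function(i) fake_recon("a;b", names(topos)[(i %% 4) + 1])),
             lapply(1:9, function(i) fake_recon(character(0),
                                                names(topos)[(i %% 4) + 1])))
  expect_equal(nrow(consensus_vicariance(grid7, topos)), 0)
})

test_that("clades absent from any topology are excluded despite full support", {
  topos <- four_topologies()
  # a;b;c is in the first three topologies but not the balanced fourth
  grid <- lapply(rep(names(topos), 4), function(tag) fake_recon("a;b;c", tag))
  expect_equal(nrow(consensus_vicariance(grid, topos)), 0)
  expect_error(consensus_vicariance(list(fake_recon("a;b", "nope")), topos),
               "unknown topology tag")
})

test_that("implanted vicariance is recovered through the full grid", {
  set.seed(61)
  recovered <- numeric(0)
  for (r in 1:3) {
    cfg0 <- sim_config(n_tips = 12, death = 0, gain = 0.005, loss = 0.005,
                       root_range = "ABC", seed = 500 + r)
    tree <- simulate_dated_tree(cfg0)
    implants <- cherry_nodes(tree)[1:2]
    cfg <- sim_config(n_tips = 12, death = 0, gain = 0.005, loss = 0.005,
                      root_range = "ABC", implant_vicariance = implants,
                      seed = 500 + r)
    sim <- simulate_range_evolution(tree, cfg)
    keys <- clade_set(tree)
    topos <- list(ML = tree,
                  B1 = perturb_node_ages(tree, 0.1, seed = 10 * r + 1),
                  B2 = perturb_node_ages(tree, 0.1, seed = 10 * r + 2),
                  B3 = perturb_node_ages(tree, 0.1, seed = 10 * r + 3))
    grid <- run_reconstruction_grid(topos, sim$tips, custom_root = "ABC",
                                    n_generations = 2000, seed = 600 + r)
    calls <- consensus_vicariance(grid, topos)
    recovered <- c(recovered,
                   mean(unname(keys[as.character(implants)]) %in% calls$clade))
  }
  expect_gte(mean(recovered), 0.5)
})

test_that("per-topology support scope is selectable", {
  topos <- four_topologies()
  # vicariant in every ML reconstruction but nowhere else: grid support 0.25
  grid <- c(lapply(1:4, function(i) fake_recon("a;b", "ML")),
            lapply(rep(c("B1", "B2", "B3"), each = 4),
                   function(tag) fake_recon(character(0), tag)))
  expect_equal(nrow(consensus_vicariance(grid, topos)), 0)
  expect_equal(nrow(consensus_vicariance(grid, topos, scope = "per-topology")), 0)
  # vicariant in at least half the reconstructions of every topology
  grid2 <- lapply(rep(names(topos), each = 4), function(tag) {
    fake_recon(if (runif(1) < 2) "a;b" else character(0), tag)
  })
  calls <- consensus_vicariance(grid2, topos, scope = "per-topology")
  expect_equal(calls$clade, "a;b")
})
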