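#' Run the reconstruction grid (methods x topologies)
#'
#' Runs every requested reconstruction method on every topology — the
#' replication grid behind consensus vicariance calls. With the default four
#' methods (S-DIVA and BBM under null, wide and custom root priors) and four
#' topologies this yields 16 reconstructions. Each output is tagged with its
#' method, topology and the seed used, so the grid is fully reproducible.
#'
#' @param trees Named list of `dated_tree`s (the topologies; names are the
#'   topology tags, e.g. `ML`, `B1`, `B2`, `B3`).
#' @param tips A tip distribution covering the shared tip set.
#' @param methods Character vector drawn from `"sdiva"`, `"bbm-null"`,
#'   `"bbm-wide"`, `"bbm-custom"`. Default: S-DIVA plus the two parameter-free
#'   BBM modes, plus `"bbm-custom"` when `custom_root` is supplied.
#' @param custom_root Root range for the custom BBM prior; required iff
#'   `"bbm-custom"` is requested.
#' @param n_generations,n_runs BBM chain settings (see [bbm_reconstruct()]).
#' @param max_areas Maximum ancestral range size for DIVA.
#' @param seed Integer master seed; each grid cell derives its own.
#' @param out_dir Optional directory; when given, every reconstruction is
#'   written as a tab-separated table (clade, range, weight, method,
#'   topology) with a route-string sidecar, plus a JSON manifest with seeds
#'   and content hashes and a run log.
#' @return A list of `ancestral_recon` objects (grid cells), invisibly tagged
#'   with attribute `manifest` when `out_dir` is used.
#' @export
run_reconstruction_grid <- function(trees, tips, methods = NULL,
                                    custom_root = NULL,
                                    n_generations = 50000L, n_runs = 2L,
                                    max_areas = 12L, seed, out_dir = NULL) {
  if (missing(seed)) stop("`seed` is mandatory.", call. = FALSE)
  if (is.null(names(trees))) names(trees) <- paste0("T", seq_along(trees))
  if (is.null(methods)) {
    methods <- c("sdiva", "bbm-null", "bbm-wide",
                 if (!is.null(custom_root)) "bbm-custom")
  }
  bad <- setdiff(methods, c("sdiva", "bbm-null", "bbm-wide", "bbm-custom"))
  if (length(bad) > 0) stop("unknown method(s): ", paste(bad, collapse = ", "),
                            call. = FALSE)
  if ("bbm-custom" %in% methods && is.null(custom_root)) {
    stop("method \"bbm-custom\" requires `custom_root`.", call. = FALSE)
  }
  cells <- tidyr::expand_grid(topology = names(trees), method = methods)
  grid <- purrr::pmap(cells, function(topology, method) {
    cell_seed <- seed + which(cells$topology == topology &
                                cells$method == method)
    rec <- if (method == "sdiva") {
      diva_optimize(trees[[topology]], tips, max_areas = max_areas)
    } else {
      mode <- sub("^bbm-", "", method)
      bbm_reconstruct(trees[[topology]], tips, prior_mode = mode,
                      custom_root = custom_root,
                      n_generations = n_generations, n_runs = n_runs,
                      seed = cell_seed)
    }
    rec$topology <- topology
    rec$seed <- cell_seed
    rec
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- purrr::map2_chr(grid, seq_along(grid), function(rec, i) {
      f <- file.path(out_dir, sprintf("recon_%02d_%s_%s.tsv", i,
                                      rec$topology, rec$method))
      readr::write_tsv(tidy(rec), f, progress = FALSE)
      fr <- sub("\\.tsv$", "_routes.txt", f)
      readr::write_tsv(rec$routes, fr, progress = FALSE)
      f
    })
    md5 <- tools::md5sum(files)
    names(md5) <- basename(files)
    manifest <- list(
      stage = "reconstruct", seed = seed,
      methods = methods, topologies = names(trees),
      grid_size = length(grid),
      outputs = as.list(md5))
    jsonlite::write_json(manifest, file.path(out_dir, "reconstruct_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    write_run_log(out_dir, "reconstruct",
                  c(sprintf("seed=%d", seed),
                    sprintf("grid=%d (%d methods x %d topologies)",
                            length(grid), length(methods), length(trees)),
                    sprintf("output %s md5=%s", basename(files),
                            tools::md5sum(files))))
    attr(grid, "manifest") <- manifest
  }
  grid
}

#' Run the congruence stage and write a decision report
#'
#' Wraps [run_hypothesis_table()]: computes a decision for every hypothesis
#' row, writes the decision table (TSV) and a JSON summary with the counts,
#' rule and any mismatches against recorded decisions. Mismatches are
#' findings, not errors.
#'
#' @param rows Hypothesis table (tibble or path; see
#'   [read_hypothesis_table()]).
#' @param rule Decision rule (see [congruence_test()]).
#' @param out_dir Optional output directory.
#' @return The `congruence_report` (see [run_hypothesis_table()]).
#' @export
run_congruence_report <- function(rows, rule = "all-runs-overlap",
                                  out_dir = NULL) {
  rep <- run_hypothesis_table(rows, rule = rule)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    f <- file.path(out_dir, "decisions.tsv")
    readr::write_tsv(rep$decisions, f, progress = FALSE)
    jsonlite::write_json(
      c(as.list(rep$counts),
        list(rule = rep$rule, n_mismatches = nrow(rep$mismatches),
             mismatches = rep$mismatches$cladogenetic_event)),
      file.path(out_dir, "congruence_summary.json"),
      auto_unbox = TRUE, pretty = TRUE)
    write_run_log(out_dir, "congruence",
                  c(sprintf("rule=%s", rep$rule),
                    sprintf("rows=%d rejected=%d mismatches=%d",
                            nrow(rep$decisions), rep$counts$n_rejected,
                            nrow(rep$mismatches)),
                    sprintf("output %s md5=%s", basename(f), tools::md5sum(f))))
  }
  rep
}

#' Write a full synthetic scenario to disk
#'
#' Simulates a dated tree, range evolution (with any implanted vicariance)
#' and pseudo-posterior node ages from one [sim_config()], and writes them in
#' the same formats the pipeline readers consume: Newick tree, tab-separated
#' presence/absence matrix, long-format age-posterior table, truth tables,
#' and a JSON manifest recording the seed.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the simulated objects and file paths.
#' @export
run_simulation_scenario <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tree <- simulate_dated_tree(config)
  ranges <- simulate_range_evolution(tree, config)
  post <- simulate_age_posteriors(tree, config)
  paths <- list(
    tree = file.path(out_dir, "tree.nwk"),
    tips = file.path(out_dir, "tip_distribution.tsv"),
    posteriors = file.path(out_dir, "age_posteriors.tsv"),
    truth_ranges = file.path(out_dir, "truth_ranges.tsv"),
    truth_events = file.path(out_dir, "truth_events.tsv"))
  write_dated_tree(tree, paths$tree)
  write_tip_distribution(ranges$tips, paths$tips)
  readr::write_tsv(post, paths$posteriors, progress = FALSE)
  readr::write_tsv(ranges$truth, paths$truth_ranges, progress = FALSE)
  readr::write_tsv(ranges$events, paths$truth_events, progress = FALSE)
  manifest <- list(
    stage = "simulate", seed = config$seed,
    n_tips = config$n_tips, birth = config$birth, death = config$death,
    areas = paste(config$alphabet, collapse = ""),
    gain = config$gain, loss = config$loss,
    root_range = config$root_range,
    implant_vicariance = config$implant_vicariance,
    posterior_n = config$posterior_n, noise = as.list(config$noise),
    n_suppressed_losses = ranges$n_suppressed_losses,
    outputs = as.list(stats::setNames(tools::md5sum(unlist(paths)),
                                      basename(unlist(paths)))))
  jsonlite::write_json(manifest, file.path(out_dir, "simulate_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  write_run_log(out_dir, "simulate",
                c(sprintf("seed=%d n_tips=%d", config$seed, config$n_tips),
                  sprintf("output %s md5=%s", basename(unlist(paths)),
                          tools::md5sum(unlist(paths)))))
  invisible(list(tree = tree, ranges = ranges, posteriors = post,
                 paths = paths, manifest = manifest))
}

write_run_log <- function(out_dir, stage, lines) {
  f <- file.path(out_dir, "run_log.txt")
  con <- file(f, open = "a")
  on.exit(close(con))
  writeLines(c(sprintf("[%s] stage=%s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                       stage), paste0("  ", lines)), con)
  invisible(f)
}
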