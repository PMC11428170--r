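#' Full-pipeline run configuration
#'
#' Bundles every stage setting of the end-to-end workflow: native-structure
#' search, ensemble generation, reconstruction, FSM/NEB refinement and
#' order-parameter analysis. Every stochastic stage derives its seed
#' deterministically from the master seed.
#'
#' @param protein either `NULL` (the default two-hairpin toy protein), a
#'   path to a bead sequence file, or a list as returned by
#'   [make_toy_protein()].
#' @param n_paths number of GDS paths.
#' @param M intermediates per path (`NULL` = heuristic).
#' @param n_updates,T_start annealing schedule.
#' @param k_cont transition-size threshold.
#' @param correct `"per_update"` or `"none"` (final-only reconstruction).
#' @param refine run FSM+NEB refinement of each path.
#' @param n_select paths kept for clustering (lowest floored energy); only
#'   applies when `refine = TRUE`.
#' @param min_cluster_size HDBSCAN minimum cluster size.
#' @param native_restarts,native_stop annealing-restart budget of the
#'   native search.
#' @param seed master seed.
#' @param out_dir output directory.
#' @return An object of class `run_config`.
#' @export
run_config <- function(protein = NULL, n_paths = 50, M = 3,
                       n_updates = 1000, T_start = 1e-3, k_cont = 0.15,
                       correct = "none", refine = FALSE, n_select = 100,
                       min_cluster_size = 5, native_restarts = 30,
                       native_stop = 10, seed = 1, out_dir = NULL) {
  structure(list(protein = protein, n_paths = n_paths, M = M,
                 n_updates = n_updates, T_start = T_start, k_cont = k_cont,
                 correct = correct, refine = refine, n_select = n_select,
                 min_cluster_size = min_cluster_size,
                 native_restarts = native_restarts,
                 native_stop = native_stop, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

resolve_protein <- function(protein) {
  if (is.null(protein)) return(make_toy_protein())
  if (is.character(protein)) {
    bs <- read_bead_sequence(protein)
    return(list(seq = bs, hairpins = list()))
  }
  protein
}

#' Run the full graph-driven sampling pipeline
#'
#' Executes: native-structure search (annealing with restarts) ->
#' path-ensemble generation by simulated annealing in contact-map space ->
#' back-mapping of intermediates -> optional FSM+NEB refinement and
#' floored-energy ranking -> order-parameter tracks -> Frechet distance
#' matrix -> density-based clustering -> occupancy summaries. Per-path
#' failures are isolated and recorded, never aborting the run. All outputs
#' are written under `cfg$out_dir` when set.
#'
#' @param cfg a [run_config()].
#' @param params a [bln_parameters()] set.
#' @return A list with `native`, `ensemble`, `tracks`, `frechet`,
#'   `labels`, `paths` (refined, when requested), `occupancy`, `config`.
#' @export
run_full_pipeline <- function(cfg = run_config(), params = bln_parameters()) {
  set.seed(cfg$seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 4L)
  prot <- resolve_protein(cfg$protein)
  bseq <- prot$seq
  n <- length(bseq)

  db <- build_minima_database(bseq, params,
                              n_restarts = cfg$native_restarts,
                              stop_after = cfg$native_stop,
                              seed = stage_seeds[1])
  if (length(db) == 0L) stop("native-structure search found no minima")
  native <- db[[1]]
  unfolded <- extended_chain(n)

  ensemble <- generate_ensemble(
    unfolded, native$conformation, bseq, params,
    n_paths = cfg$n_paths, M = cfg$M,
    schedule = anneal_schedule(cfg$n_updates, cfg$T_start),
    k_cont = cfg$k_cont, correct = cfg$correct,
    seed = stage_seeds[2])

  paths <- NULL
  keep <- seq_along(ensemble)
  if (isTRUE(cfg$refine)) {
    paths <- lapply(ensemble, function(p)
      tryCatch(refine_path(p$sequence$conformations, bseq, params),
               error = function(e) NULL))
    ok <- !vapply(paths, is.null, logical(1))
    paths <- paths[ok]
    ensemble <- ensemble[ok]
    sel <- select_low_energy_paths(paths, min(cfg$n_select, length(paths)))
    keep <- match(sel, paths)
    paths <- sel
    ensemble <- ensemble[keep]
    keep <- seq_along(ensemble)
  }

  tracks <- NULL
  labels <- NULL
  Dm <- NULL
  occupancy <- NULL
  if (length(prot$hairpins) >= 2L && length(ensemble) > 0) {
    p1 <- native_pair_set(native$conformation, prot$hairpins[[1]])
    p2 <- native_pair_set(native$conformation, prot$hairpins[[2]])
    track_confs <- lapply(ensemble, function(p) p$sequence$conformations)
    tracks <- lapply(track_confs, function(cs)
      chi_track(cs, native$conformation, p1, p2))
    Dm <- frechet_matrix(tracks)
    labels <- cluster_paths(Dm, cfg$min_cluster_size)
    occupancy <- chi_occupancy_grid(tracks)
  }

  out <- list(native = native, minima = db, ensemble = ensemble,
              paths = paths, tracks = tracks, frechet = Dm,
              labels = labels, occupancy = occupancy, config = cfg,
              stage_seeds = stage_seeds)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_xyz(native$conformation, file.path(cfg$out_dir, "native.xyz"),
              seq = bseq)
    write_ensemble(ensemble, file.path(cfg$out_dir, "ensemble"), seq = bseq)
    if (!is.null(labels)) {
      write.table(data.frame(path = seq_along(labels), cluster = labels),
                  file.path(cfg$out_dir, "clusters.tsv"),
                  row.names = FALSE, sep = "\t", quote = FALSE)
      write.table(unclass(Dm), file.path(cfg$out_dir, "frechet.tsv"),
                  row.names = FALSE, col.names = FALSE, sep = "\t")
      write.table(occupancy, file.path(cfg$out_dir, "occupancy.tsv"),
                  row.names = FALSE, sep = "\t", quote = FALSE)
    }
    writeLines(c(sprintf("seed %d", cfg$seed),
                 sprintf("n_paths %d", cfg$n_paths),
                 sprintf("n_updates %d", cfg$n_updates),
                 sprintf("package gdsfold %s",
                         as.character(utils::packageVersion("gdsfold")))),
               file.path(cfg$out_dir, "run-config.txt"))
  }
  out
}

parse_cli_args <- function(argv) {
  opts <- list()
  pos <- character(0)
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i == length(argv) || startsWith(argv[i + 1L], "--")) {
        opts[[key]] <- TRUE
        i <- i + 1L
      } else {
        opts[[key]] <- argv[i + 1L]
        i <- i + 2L
      }
    } else {
      pos <- c(pos, a)
      i <- i + 1L
    }
  }
  list(opts = opts, pos = pos)
}

cli_help <- function() {
  cat("gdsfold: graph-driven sampling of protein-folding pathways\n\n",
      "usage: gdsfold <command> [--seed N] [--out DIR] [options]\n\n",
      "commands:\n",
      "  find-native              anneal to the native structure\n",
      "  sample-paths             generate a GDS path ensemble\n",
      "  reconstruct              back-map a contact map to coordinates\n",
      "  refine                   FSM+NEB refinement of a path\n",
      "  analyze                  chi tracks, Frechet matrix, clusters\n",
      "  benchmark-reconstruction Table-style reconstruction benchmark\n",
      "  validate-metric          SCH/Hamming vs TM-score comparison\n",
      "  run-all                  full pipeline\n\n",
      "common options: --seed, --out, --sequence FILE, --params FILE,\n",
      "  --trials N, --method new-grp|crankshaft|old-grp, --paths N,\n",
      "  --updates N, --pairs N\n", sep = "")
}

#' Command-line dispatcher
#'
#' Thin command-line surface over the package functions; used by the
#' `exec/gdsfold` script. Unknown commands print usage and return a
#' non-zero status.
#'
#' @param argv character vector of command-line arguments.
#' @return Integer exit status (0 on success), invisibly.
#' @export
cli_dispatch <- function(argv = character(0)) {
  if (length(argv) == 0L || argv[1] %in% c("help", "--help", "-h")) {
    cli_help()
    return(invisible(0L))
  }
  cmd <- argv[1]
  parsed <- parse_cli_args(argv[-1])
  o <- parsed$opts
  seed <- as.integer(if (!is.null(o$seed)) o$seed else 1L)
  out <- if (!is.null(o$out)) o$out else "gdsfold-out"
  params <- if (!is.null(o$params))
    read_parameter_overrides(o$params) else bln_parameters()
  prot <- if (!is.null(o$sequence)) o$sequence else NULL
  num <- function(x, d) if (!is.null(x)) as.numeric(x) else d
  log_line <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), "gdsfold", cmd, ":",
        ..., "\n")
  }
  status <- tryCatch({
    switch(cmd,
      "find-native" = {
        p <- resolve_protein(prot)
        db <- build_minima_database(p$seq, params, seed = seed,
                                    n_restarts = num(o$restarts, 30),
                                    stop_after = num(o$stop, 10))
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        write_xyz(db[[1]]$conformation, file.path(out, "native.xyz"),
                  seq = p$seq)
        log_line("native energy", format(db[[1]]$energy, digits = 8),
                 "->", file.path(out, "native.xyz"))
        0L
      },
      "sample-paths" = ,
      "run-all" = {
        cfg <- run_config(protein = prot, seed = seed, out_dir = out,
                          n_paths = num(o$paths, 50),
                          n_updates = num(o$updates, 1000),
                          refine = identical(cmd, "run-all") &&
                            !isTRUE(o[["no-refine"]]))
        res <- run_full_pipeline(cfg, params)
        log_line(length(res$ensemble), "paths written to", out)
        0L
      },
      "reconstruct" = {
        p <- resolve_protein(prot)
        G <- read_contact_map(o$map)
        start <- read_xyz(o$start)[[1]]
        res <- reconstruct_minimize(start, G, p$seq, params)
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        write_xyz(res$conformation, file.path(out, "reconstructed.xyz"),
                  seq = p$seq)
        log_line("failed:", res$failed, " SCH to target:",
                 format(res$sch_to_target, digits = 4))
        if (res$failed) 1L else 0L
      },
      "refine" = {
        p <- resolve_protein(prot)
        confs <- read_xyz(o$path)
        fp <- refine_path(confs, p$seq, params)
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        write_xyz(fp$images, file.path(out, "refined.xyz"), seq = p$seq)
        write.table(data.frame(image = seq_along(fp$energies),
                               energy = fp$energies),
                    file.path(out, "energies.tsv"), row.names = FALSE,
                    sep = "\t", quote = FALSE)
        log_line("floored energy", format(fp$floored_energy, digits = 6))
        0L
      },
      "analyze" = {
        cfg <- run_config(protein = prot, seed = seed, out_dir = out,
                          n_paths = num(o$paths, 50),
                          n_updates = num(o$updates, 1000))
        res <- run_full_pipeline(cfg, params)
        log_line("clusters:",
                 paste(sort(unique(res$labels)), collapse = " "))
        0L
      },
      "benchmark-reconstruction" = {
        p <- resolve_protein(prot)
        set.seed(seed)
        db <- build_minima_database(p$seq, params,
                                    n_restarts = num(o$restarts, 30),
                                    stop_after = num(o$stop, 10))
        method <- gsub("-", "_", if (!is.null(o$method)) o$method
                       else "new-grp")
        bm <- benchmark_reconstruction(db, p$seq, params,
                                       n_trials = num(o$trials, 500),
                                       method = method)
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        write_benchmark_report(bm, file.path(out, "benchmark.tsv"))
        print(bm)
        0L
      },
      "validate-metric" = {
        p <- resolve_protein(prot)
        set.seed(seed)
        db <- build_minima_database(p$seq, params,
                                    n_restarts = num(o$restarts, 30),
                                    stop_after = num(o$stop, 10))
        v <- validate_sch_metric(db, p$seq, params,
                                 n_pairs = num(o$pairs, 200))
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        write.table(v$table, file.path(out, "metric-validation.tsv"),
                    row.names = FALSE, sep = "\t", quote = FALSE)
        log_line("Spearman rho: SCH", format(v$spearman["sch"], digits = 3),
                 " Hamming", format(v$spearman["hamming"], digits = 3))
        0L
      },
      {
        cli_help()
        1L
      })
  }, error = function(e) {
    message("gdsfold error: ", conditionMessage(e))
    1L
  })
  invisible(as.integer(status))
}
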