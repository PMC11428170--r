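#' Graph sequence: a folding path in contact-map space
#'
#' An ordered list of contact maps `[G^0, G^1, ..., G^(M+1)]` whose first
#' and last elements are the designated unfolded and folded maps. The M
#' interior maps are the folding intermediates that the simulated-annealing
#' search optimizes. Hop matrices are cached per map, and reconstructed
#' conformations may be carried alongside.
#'
#' @param maps list of contact maps sharing one size.
#' @param conformations optional parallel list of N x 3 conformations.
#' @param endpoints_fixed flag marking the first and last maps immutable.
#' @return An object of class `graph_sequence`.
#' @export
graph_sequence <- function(maps, conformations = NULL,
                           endpoints_fixed = TRUE) {
  stopifnot(length(maps) >= 2L)
  maps <- lapply(maps, check_map)
  sizes <- vapply(maps, nrow, integer(1))
  if (length(unique(sizes)) != 1L) stop("all maps must share one size")
  if (!is.null(conformations)) {
    stopifnot(length(conformations) == length(maps))
    conformations <- lapply(conformations, function(cf)
      if (is.null(cf)) NULL else as_conformation(cf, sizes[1]))
  }
  structure(list(maps = maps,
                 hops = lapply(maps, shortest_hop_matrix),
                 conformations = conformations,
                 endpoints_fixed = isTRUE(endpoints_fixed)),
            class = "graph_sequence")
}

#' @export
print.graph_sequence <- function(x, ...) {
  cat("graph sequence:", length(x$maps), "maps (",
      length(x$maps) - 2L, "intermediates ) on",
      nrow(x$maps[[1]]), "beads\n")
  cat("  consecutive SCH:",
      paste(format(consecutive_sch(x), digits = 3), collapse = " "), "\n")
  invisible(x)
}

# SCH distances between consecutive maps, using cached hop matrices
consecutive_sch <- function(gs) {
  m <- length(gs$maps)
  vapply(seq_len(m - 1L), function(j)
    sch_from_hops(gs$hops[[j]], gs$hops[[j + 1L]]), numeric(1))
}

obj_from_d <- function(d, k_cont, lambda, penalty) {
  equid <- if (length(d) >= 2) sum(abs(diff(d))) else 0
  pen <- switch(penalty,
                step = sum(d > k_cont),
                hinge = sum(pmax(0, d - k_cont)))
  equid + lambda * pen
}

#' Simulated-annealing objective of a graph sequence
#'
#' \deqn{F = \sum_{i=1}^{M} |d(G^{i-1},G^i) - d(G^i,G^{i+1})| +
#'   \lambda \sum_{j=1}^{M+1} H(d(G^{j-1},G^j) - k_{cont})}
#' with `d` the SCH distance and `H` the Heaviside step (`H(0) = 0`). The
#' first term drives every intermediate to be equidistant between its
#' neighbours; the second penalizes any single transition larger than
#' `k_cont`. A hinge variant `H(d - k)(d - k)` is available via
#' `penalty = "hinge"`.
#'
#' @param gs a [graph_sequence()] with at least one intermediate.
#' @param k_cont transition-size threshold, default 0.15.
#' @param lambda penalty weight.
#' @param penalty `"step"` (pure Heaviside) or `"hinge"`.
#' @return Non-negative objective value.
#' @export
sequence_objective <- function(gs, k_cont = 0.15, lambda = 1,
                               penalty = c("step", "hinge")) {
  penalty <- match.arg(penalty)
  if (length(gs$maps) < 3L)
    stop("sequence objective needs at least one intermediate")
  obj_from_d(consecutive_sch(gs), k_cont, lambda, penalty)
}

#' Annealing schedule for the graph-sequence search
#'
#' @param n_updates number of Monte Carlo updates.
#' @param T_start initial temperature (objective units); the schedule
#'   decreases linearly to zero.
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @return An object of class `anneal_schedule`.
#' @export
anneal_schedule <- function(n_updates = 1e4, T_start = 1e-3, seed = NULL) {
  stopifnot(n_updates >= 1, T_start > 0)
  structure(list(n_updates = as.integer(n_updates), T_start = T_start,
                 seed = seed),
            class = "anneal_schedule")
}

#' Propose a bit-flip move on a graph sequence
#'
#' Picks an intermediate uniformly at random, draws `n_b` uniformly from
#' `{1, ..., max_flips}`, and samples that many mutable pairs without
#' replacement.
#'
#' @param gs a [graph_sequence()].
#' @param max_flips largest number of simultaneous bit flips.
#' @param min_sep mutable-pair separation rule.
#' @return A list with `t` (intermediate index, 1-based among
#'   intermediates) and `flips` (two-column pair matrix).
#' @export
propose_move <- function(gs, max_flips = 5L, min_sep = 3L) {
  m_int <- length(gs$maps) - 2L
  if (m_int < 1L) stop("no intermediates to perturb")
  t <- if (m_int == 1L) 1L else sample.int(m_int, 1L)
  n <- nrow(gs$maps[[1]])
  pairs <- mutable_pairs(n, min_sep)
  nb <- sample.int(max_flips, 1L)
  nb <- min(nb, nrow(pairs))
  flips <- pairs[sample.int(nrow(pairs), nb), , drop = FALSE]
  list(t = t, flips = flips)
}

#' Apply a move, correct it through reconstruction, and score the sequence
#'
#' Applies the proposed bit flips to intermediate `t`. With a reconstructor,
#' the flipped map is back-mapped to a conformation (starting from the
#' stored conformation of that intermediate) and replaced by the contact map
#' of the reconstructed structure -- so a nonphysical flipped map is
#' corrected to the nearest physically realized map, and it is the corrected
#' map that enters the sequence on acceptance. Reconstruction failure scores
#' the move as rejected (infinite objective).
#'
#' @param gs a [graph_sequence()].
#' @param move a proposal from [propose_move()].
#' @param reconstructor `NULL` for pure-graph mode, or a
#'   `function(conf0, G)` returning a `reconstruction_result` (see
#'   [make_reconstructor()]).
#' @param k_cont,lambda,penalty objective settings, see
#'   [sequence_objective()].
#' @param r_c contact cutoff used to re-map reconstructed conformations.
#' @return A list with `map`, `hops`, `conformation`, `objective`, `failed`.
#' @export
correct_and_score <- function(gs, move, reconstructor = NULL, k_cont = 0.15,
                              lambda = 1, penalty = "step", r_c = 8) {
  idx <- move$t + 1L  # position in the maps list
  flipped <- apply_bit_flips(gs$maps[[idx]], move$flips)
  conf <- NULL
  if (is.null(reconstructor)) {
    corrected <- flipped
  } else {
    conf0 <- gs$conformations[[idx]]
    res <- tryCatch(reconstructor(conf0, flipped), error = function(e) NULL)
    if (is.null(res) || res$failed) {
      return(list(map = NULL, hops = NULL, conformation = NULL,
                  objective = Inf, failed = TRUE))
    }
    corrected <- res$achieved_map
    conf <- res$conformation
  }
  hops <- shortest_hop_matrix(corrected)
  d <- consecutive_sch(gs)
  d[idx - 1L] <- sch_from_hops(gs$hops[[idx - 1L]], hops)
  d[idx] <- sch_from_hops(hops, gs$hops[[idx + 1L]])
  list(map = corrected, hops = hops, conformation = conf,
       objective = obj_from_d(d, k_cont, lambda, penalty), failed = FALSE)
}

#' Build a reconstructor callable for the sequence search
#'
#' @param seq,params the BLN system.
#' @param method `"new_grp"` (restrained minimization) or `"crankshaft"`.
#' @param ... passed to [reconstruct_minimize()] or
#'   [reconstruct_crankshaft()].
#' @return A `function(conf0, G) -> reconstruction_result`.
#' @export
make_reconstructor <- function(seq, params = bln_parameters(),
                               method = c("new_grp", "crankshaft"), ...) {
  method <- match.arg(method)
  if (method == "new_grp") {
    function(conf0, G) reconstruct_minimize(conf0, G, seq, params, ...)
  } else {
    function(conf0, G) reconstruct_crankshaft(conf0, G, seq, params, ...)
  }
}

#' Optimize a graph sequence by simulated annealing
#'
#' Metropolis acceptance `exp(-dF/T)` of bit-flip moves under a linearly
#' decreasing temperature schedule. With a reconstructor, every candidate
#' map is corrected through back-mapping before scoring (`correct =
#' "per_update"`); `correct = "none"` searches in pure contact-map space.
#' Deterministic given `schedule$seed`; the best-seen sequence is returned.
#'
#' @param gs0 starting [graph_sequence()] with fixed endpoints.
#' @param schedule an [anneal_schedule()].
#' @param k_cont,lambda,penalty objective settings.
#' @param reconstructor see [correct_and_score()].
#' @param correct `"per_update"` or `"none"`.
#' @param max_flips largest move size.
#' @return A list with `sequence` (best-seen `graph_sequence`),
#'   `objective`, `trace` (objective after every update), `accepted`.
#' @export
sa_optimize_sequence <- function(gs0, schedule = anneal_schedule(),
                                 k_cont = 0.15, lambda = 1,
                                 penalty = "step", reconstructor = NULL,
                                 correct = c("per_update", "none"),
                                 max_flips = 5L) {
  correct <- match.arg(correct)
  if (correct == "none") reconstructor <- NULL
  if (!is.null(schedule$seed)) set.seed(schedule$seed)
  stopifnot(inherits(gs0, "graph_sequence"), length(gs0$maps) >= 3L)
  cur <- gs0
  if (!is.null(reconstructor)) {
    # reconcile the starting sequence: every stored intermediate map must
    # be the contact map of its stored conformation before the search runs
    for (idx in 2:(length(cur$maps) - 1L)) {
      res <- reconstructor(cur$conformations[[idx]], cur$maps[[idx]])
      if (res$failed)
        stop("reconstruction of initial intermediate ", idx - 1L,
             " failed: ", res$diagnostics)
      cur$maps[[idx]] <- res$achieved_map
      cur$hops[[idx]] <- shortest_hop_matrix(res$achieved_map)
      cur$conformations[[idx]] <- res$conformation
    }
  }
  f_cur <- sequence_objective(cur, k_cont, lambda, penalty)
  best <- cur
  f_best <- f_cur
  nup <- schedule$n_updates
  trace <- numeric(nup)
  acc <- 0L
  for (u in seq_len(nup)) {
    temp <- schedule$T_start * (1 - u / nup)
    move <- propose_move(cur, max_flips)
    cand <- correct_and_score(cur, move, reconstructor, k_cont, lambda,
                              penalty)
    if (!cand$failed) {
      dF <- cand$objective - f_cur
      if (dF <= 0 || (temp > 0 && runif(1) < exp(-dF / temp))) {
        idx <- move$t + 1L
        cur$maps[[idx]] <- cand$map
        cur$hops[[idx]] <- cand$hops
        if (!is.null(cand$conformation))
          cur$conformations[[idx]] <- cand$conformation
        f_cur <- cand$objective
        acc <- acc + 1L
        if (f_cur < f_best) {
          best <- cur
          f_best <- f_cur
        }
      }
    }
    trace[u] <- f_cur
  }
  list(sequence = best, objective = f_best, trace = trace, accepted = acc)
}

#' Initialize the intermediates of a graph sequence
#'
#' Intermediate `i` starts as the unfolded map with
#' `ceiling(i * n_diff / (M + 1))` of the contacts present in the folded but
#' not the unfolded map toggled on. The default `"growth"` ordering adds
#' contacts cooperatively: a random nucleus contact is drawn and the
#' contact set then grows preferentially through contacts that share a bead
#' with (or lie close in sequence to) those already formed, mimicking the
#' cooperative, spatially clustered contact formation of real folding
#' events -- and seeding genuine mechanistic diversity across random
#' nuclei. `"subset"` draws a plain random subset per intermediate
#' (uncorrelated, typically far from evenly spaced in SCH).
#'
#' @param unfolded_map,folded_map endpoint contact maps.
#' @param M number of intermediates.
#' @param conformations optional endpoint conformations to carry.
#' @param method `"growth"` or `"subset"`.
#' @param p_adjacent probability that the next contact is drawn from the
#'   adjacency frontier rather than uniformly (growth method).
#' @return A [graph_sequence()] of length `M + 2`.
#' @export
initialize_sequence <- function(unfolded_map, folded_map, M,
                                conformations = NULL,
                                method = c("growth", "subset"),
                                p_adjacent = 0.9) {
  method <- match.arg(method)
  U <- check_map(unfolded_map); F_ <- check_map(folded_map)
  n <- nrow(U)
  gain_idx <- which(upper.tri(U) & F_ == 1L & U == 0L, arr.ind = TRUE)
  K <- nrow(gain_idx)
  maps <- vector("list", M + 2L)
  maps[[1]] <- U
  maps[[M + 2L]] <- F_
  order_of <- integer(0)
  if (method == "growth" && K > 0) {
    remaining <- seq_len(K)
    touched <- rep(FALSE, n)
    order_of <- integer(K)
    for (q in seq_len(K)) {
      frontier <- remaining[touched[gain_idx[remaining, 1]] |
                            touched[gain_idx[remaining, 2]]]
      pool <- if (q > 1L && length(frontier) > 0 &&
                  runif(1) < p_adjacent) frontier else remaining
      pick <- pool[sample.int(length(pool), 1L)]
      order_of[q] <- pick
      touched[gain_idx[pick, ]] <- TRUE
      remaining <- remaining[remaining != pick]
    }
  }
  for (i in seq_len(M)) {
    k <- min(ceiling(i * K / (M + 1L)), K)
    Gi <- U
    if (k > 0) {
      sel <- if (method == "growth") order_of[seq_len(k)]
             else sample.int(K, k)
      pick <- gain_idx[sel, , drop = FALSE]
      Gi[pick] <- 1L
      Gi[pick[, c(2, 1), drop = FALSE]] <- 1L
    }
    maps[[i + 1L]] <- Gi
  }
  confs <- NULL
  if (!is.null(conformations)) {
    confs <- vector("list", M + 2L)
    confs[[1]] <- conformations[[1]]
    confs[[M + 2L]] <- conformations[[2]]
    for (i in seq_len(M)) confs[[i + 1L]] <- conformations[[1]]
  }
  graph_sequence(maps, confs)
}

#' Generate an ensemble of folding paths
#'
#' Runs `n_paths` independent seeded simulated-annealing searches between
#' the contact maps of an unfolded and a folded conformation. Each run
#' carries its own seed and objective trace. When the search itself operates
#' in pure contact-map space (`correct = "none"`), the intermediates of the
#' best sequence can be back-mapped once at the end
#' (`reconstruct_final = TRUE`). Individual run failures are logged and
#' skipped, never aborting the ensemble.
#'
#' @param unfolded,folded endpoint conformations.
#' @param seq,params the BLN system.
#' @param n_paths number of independent paths.
#' @param M number of intermediates; `NULL` uses the heuristic
#'   `ceiling(d_SCH(unfolded, folded) / k_cont) - 1`.
#' @param schedule an [anneal_schedule()] (its seed is ignored; per-path
#'   seeds derive from `seed`).
#' @param r_c contact cutoff.
#' @param k_cont,lambda,penalty,correct,max_flips search settings.
#' @param reconstructor see [sa_optimize_sequence()]; also used for final
#'   back-mapping.
#' @param reconstruct_final back-map intermediates of the final sequence.
#' @param init_method,init_p_adjacent initialization settings, see
#'   [initialize_sequence()].
#' @param seed master seed for the ensemble.
#' @return A list of per-path results (`sequence`, `objective`, `trace`,
#'   `seed`), with failed runs recorded in `attr(, "failures")`.
#' @export
generate_ensemble <- function(unfolded, folded, seq,
                              params = bln_parameters(), n_paths,
                              M = NULL, schedule = anneal_schedule(),
                              r_c = 8, k_cont = 0.15, lambda = 1,
                              penalty = "step",
                              reconstructor = NULL,
                              correct = c("per_update", "none"),
                              reconstruct_final = TRUE, max_flips = 5L,
                              init_method = "growth", init_p_adjacent = 0.9,
                              seed = NULL) {
  correct <- match.arg(correct)
  unfolded <- as_conformation(unfolded, length(seq))
  folded <- as_conformation(folded, length(seq))
  GU <- map_from_conformation(unfolded, r_c)
  GF <- map_from_conformation(folded, r_c)
  if (is.null(M)) {
    d_if <- sch_distance(GU, GF)
    M <- max(1L, as.integer(ceiling(d_if / k_cont)) - 1L)
  }
  if (!is.null(seed)) set.seed(seed)
  path_seeds <- sample.int(.Machine$integer.max - 1L, n_paths)
  if (is.null(reconstructor) &&
      (correct == "per_update" || reconstruct_final)) {
    reconstructor <- make_reconstructor(seq, params)
  }
  out <- vector("list", n_paths)
  failures <- list()
  for (p in seq_len(n_paths)) {
    res <- tryCatch({
      set.seed(path_seeds[p])
      gs0 <- initialize_sequence(GU, GF, M, list(unfolded, folded),
                                 method = init_method,
                                 p_adjacent = init_p_adjacent)
      sched <- anneal_schedule(schedule$n_updates, schedule$T_start,
                               seed = NULL)
      sa <- sa_optimize_sequence(gs0, sched, k_cont, lambda, penalty,
                                 reconstructor, correct, max_flips)
      gs <- sa$sequence
      if (reconstruct_final && correct == "none") {
        for (i in seq_len(M)) {
          rr <- reconstructor(gs$conformations[[i]], gs$maps[[i + 1L]])
          if (rr$failed) stop("final reconstruction failed at intermediate ",
                              i)
          gs$conformations[[i + 1L]] <- rr$conformation
          gs$maps[[i + 1L]] <- rr$achieved_map
          gs$hops[[i + 1L]] <- shortest_hop_matrix(rr$achieved_map)
        }
      }
      list(sequence = gs, objective = sa$objective, trace = sa$trace,
           seed = path_seeds[p])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        list(path = p, seed = path_seeds[p],
             message = conditionMessage(res))
      out[p] <- list(NULL)
    } else {
      out[[p]] <- res
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  attr(out, "failures") <- failures
  out
}
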