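ladder_sequence <- function(n = 8, M = 2, seed = 60) {
  # a small random sequence with fixed endpoints for objective tests
  set.seed(seed)
  U <- map_from_conformation(extended_chain(n))
  F_ <- apply_bit_flips(U, mutable_pairs(n)[sample(nrow(mutable_pairs(n)),
                                                   4), ])
  initialize_sequence(U, F_, M)
}

test_that("sequence objective equals a term-by-term oracle", {
  gs <- ladder_sequence(8, 3)
  d <- sapply(1:4, function(j) sch_distance(gs$maps[[j]], gs$maps[[j + 1]]))
  for (pen in c("step", "hinge")) {
    for (k_cont in c(0.05, 0.15, 0.9)) {
      expected <- sum(abs(diff(d))) +
        if (pen == "step") sum(d > k_cont) else sum(pmax(0, d - k_cont))
      expect_equal(sequence_objective(gs, k_cont = k_cont, penalty = pen),
                   expected, tolerance = 1e-12)
    }
  }
  # identical maps everywhere: equidistant (all zero) and below threshold
  U <- map_from_conformation(extended_chain(6))
  gs0 <- graph_sequence(list(U, U, U))
  expect_equal(sequence_objective(gs0), 0)
})

test_that("move proposals cover intermediates uniformly and are seeded", {
  gs <- ladder_sequence(8, 3)
  set.seed(61)
  ts <- replicate(3000, propose_move(gs)$t)
  counts <- table(factor(ts, levels = 1:3))
  # binomial 3 sigma around 1000
  expect_true(all(abs(counts - 1000) < 3 * sqrt(3000 * (1/3) * (2/3))))
  nb <- replicate(2000, nrow(propose_move(gs)$flips))
  expect_setequal(sort(unique(nb)), 1:5)
  gs1 <- ladder_sequence(8, 1)
  expect_true(all(replicate(50, propose_move(gs1)$t) == 1L))
  set.seed(62); m1 <- replicate(20, propose_move(gs), simplify = FALSE)
  set.seed(62); m2 <- replicate(20, propose_move(gs), simplify = FALSE)
  expect_identical(m1, m2)
})

test_that("correction leaves physically consistent maps untouched and fails safely", {
  gs <- ladder_sequence(8, 2)
  set.seed(63)
  move <- propose_move(gs)
  # pure-graph mode: corrected map is exactly the flipped map
  cand <- correct_and_score(gs, move)
  expect_identical(cand$map,
                   apply_bit_flips(gs$maps[[move$t + 1]], move$flips))
  expect_false(cand$failed)
  # a reconstructor that aborts scores the move as rejected
  bad <- function(conf0, G) stop("boom")
  cand2 <- correct_and_score(gs, move, reconstructor = bad)
  expect_true(cand2$failed)
  expect_identical(cand2$objective, Inf)
  # a reconstructor reproducing the map exactly is a fixed point
  fx <- fix_small10()
  G0 <- map_from_conformation(fx$min$conformation)
  gs10 <- graph_sequence(list(G0, G0, G0),
                         rep(list(fx$min$conformation), 3))
  rec <- make_reconstructor(fx$seq, tol = 1e-5, max_iter = 5000)
  cand3 <- correct_and_score(gs10, list(t = 1L,
                                        flips = matrix(numeric(0), 0, 2)),
                             reconstructor = rec)
  expect_identical(cand3$map, G0)
})

test_that("SA finds the exhaustive-enumeration optimum on a 6-bead system", {
  # mutable pairs on 6 beads: (1,4) (1,5) (1,6) (2,5) (2,6) (3,6)
  n <- 6
  U <- map_from_conformation(extended_chain(n))
  set.seed(64)
  F_ <- apply_bit_flips(U, rbind(c(1, 4), c(2, 5), c(3, 6)))
  pairs <- mutable_pairs(n)
  # enumerate all 2^6 reachable intermediates
  best_f <- Inf
  for (mask in 0:63) {
    Gi <- U
    on <- which(bitwAnd(mask, 2^(0:5)) > 0)
    if (length(on) > 0) Gi <- apply_bit_flips(U, pairs[on, , drop = FALSE])
    gs <- graph_sequence(list(U, Gi, F_))
    best_f <- min(best_f, sequence_objective(gs))
  }
  hits <- 0
  for (sd in 1:20) {
    set.seed(sd)
    gs0 <- initialize_sequence(U, F_, 1)
    sa <- sa_optimize_sequence(gs0, anneal_schedule(1000, 1e-3),
                               correct = "none")
    if (abs(sa$objective - best_f) < 1e-12) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("SA traces are monotone in best-seen objective and seeded", {
  gs0 <- ladder_sequence(10, 3, seed = 65)
  sa1 <- sa_optimize_sequence(gs0, anneal_schedule(400, 1e-3, seed = 66),
                              correct = "none")
  sa2 <- sa_optimize_sequence(gs0, anneal_schedule(400, 1e-3, seed = 66),
                              correct = "none")
  expect_identical(sa1$sequence$maps, sa2$sequence$maps)
  expect_identical(sa1$trace, sa2$trace)
  expect_lte(sa1$objective, sequence_objective(gs0))
  expect_equal(sa1$objective, min(sa1$trace), tolerance = 1e-12)
  # endpoints never move
  expect_identical(sa1$sequence$maps[[1]], gs0$maps[[1]])
  expect_identical(sa1$sequence$maps[[5]], gs0$maps[[5]])
})

test_that("ensembles are seeded, endpoint-faithful and self-consistent", {
  fx <- fix_small10()
  unf <- extended_chain(10)
  rec <- make_reconstructor(fx$seq, tol = 1e-4, max_iter = 3000)
  e1 <- generate_ensemble(unf, fx$min$conformation, fx$seq, n_paths = 2,
                          M = 2, schedule = anneal_schedule(30, 1e-3),
                          correct = "per_update", reconstructor = rec,
                          seed = 67)
  e2 <- generate_ensemble(unf, fx$min$conformation, fx$seq, n_paths = 2,
                          M = 2, schedule = anneal_schedule(30, 1e-3),
                          correct = "per_update", reconstructor = rec,
                          seed = 67)
  expect_identical(lapply(e1, function(p) p$sequence$maps),
                   lapply(e2, function(p) p$sequence$maps))
  GU <- map_from_conformation(unf)
  GF <- map_from_conformation(fx$min$conformation)
  for (p in e1) {
    maps <- p$sequence$maps
    expect_identical(maps[[1]], GU)
    expect_identical(maps[[length(maps)]], GF)
    # with correction, every stored intermediate map is the map of its
    # stored conformation
    for (i in 2:(length(maps) - 1)) {
      expect_identical(maps[[i]],
                       map_from_conformation(p$sequence$conformations[[i]]))
    }
  }
  e3 <- generate_ensemble(unf, fx$min$conformation, fx$seq, n_paths = 2,
                          M = 2, schedule = anneal_schedule(30, 1e-3),
                          correct = "per_update", reconstructor = rec,
                          seed = 68)
  expect_false(identical(lapply(e1, function(p) p$sequence$maps),
                         lapply(e3, function(p) p$sequence$maps)))
})
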