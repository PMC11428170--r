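test_that("contact maps follow the strict-cutoff convention", {
  # straight chain with 3.8 A bonds: contacts exactly |i-j| <= 2
  chain <- cbind(3.8 * (0:9), 0, 0)
  G <- map_from_conformation(chain)
  sep <- abs(outer(1:10, 1:10, "-"))
  expect_identical(G, (sep <= 2 & sep > 0) * 1L)
  # ties at exactly r_c are non-contacts
  G2 <- map_from_conformation(rbind(c(0, 0, 0), c(8, 0, 0)))
  expect_identical(G2, matrix(0L, 2, 2))
  # random conformation agrees with a brute-force double loop
  set.seed(50)
  conf <- matrix(rnorm(60, sd = 6), 20, 3)
  G3 <- map_from_conformation(conf)
  for (i in 1:20) for (j in 1:20) {
    expect_identical(G3[i, j],
                     as.integer(i != j &&
                                sqrt(sum((conf[i, ] - conf[j, ])^2)) < 8))
  }
})

test_that("hamming distance counts flipped unordered pairs", {
  set.seed(51)
  A <- random_contact_map(10)
  expect_identical(hamming_distance(A, A), 0L)
  B <- apply_bit_flips(A, cbind(2, 7))
  expect_identical(hamming_distance(A, B), 1L)
  # arbitrary edit scripts: distance equals the number of distinct pairs
  for (rep in 1:20) {
    pairs <- mutable_pairs(10)
    k <- sample(1:8, 1)
    fl <- pairs[sample(nrow(pairs), k), , drop = FALSE]
    expect_identical(hamming_distance(A, apply_bit_flips(A, fl)),
                     as.integer(k))
  }
  # empty vs complete on 4 beads
  empty <- matrix(0L, 4, 4)
  full <- matrix(1L, 4, 4); diag(full) <- 0L
  expect_identical(hamming_distance(empty, full), 6L)
  expect_error(hamming_distance(empty, matrix(0L, 5, 5)), "size")
})

test_that("shortest hop matrices match path-graph arithmetic and BFS", {
  path5 <- matrix(0L, 5, 5)
  for (i in 1:4) { path5[i, i + 1] <- 1L; path5[i + 1, i] <- 1L }
  expect_identical(shortest_hop_matrix(path5),
                   matrix(as.integer(abs(outer(1:5, 1:5, "-"))), 5, 5))
  chord <- apply_bit_flips(path5, cbind(1, 5))
  S <- shortest_hop_matrix(chord)
  expect_identical(S[1, 5], 1L)
  expect_identical(S[1, 4], 2L)
  expect_identical(S[2, 5], 2L)
  expect_identical(S[2, 4], 2L)
  # disconnected components take the cap value N
  two <- matrix(0L, 6, 6)
  for (i in c(1, 2, 4, 5)) { two[i, i + 1] <- 1L; two[i + 1, i] <- 1L }
  S2 <- shortest_hop_matrix(two)
  expect_true(all(S2[1:3, 4:6] == 6L))
})

test_that("hop matrices agree with independent oracles on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(52)
  for (rep in 1:25) {
    n <- sample(5:30, 1)
    G <- random_contact_map(n, p = runif(1, 0.05, 0.4))
    S <- shortest_hop_matrix(G)
    expect_identical(S, oracle_hops(G))
    ig <- igraph::graph_from_adjacency_matrix(G, mode = "undirected")
    Sig <- igraph::distances(ig)
    Sig[is.infinite(Sig)] <- n
    expect_equal(matrix(as.numeric(S), n, n), unname(Sig))
  }
})

test_that("SCH distance satisfies the metric axioms and its worked value", {
  path5 <- matrix(0L, 5, 5)
  for (i in 1:4) { path5[i, i + 1] <- 1L; path5[i + 1, i] <- 1L }
  chord <- apply_bit_flips(path5, cbind(1, 5))
  expect_equal(sch_distance(path5, path5), 0)
  expect_equal(sch_distance(path5, chord), 17 / 120)
  expect_equal(sch_distance(path5, chord), oracle_sch(path5, chord))
  set.seed(53)
  for (rep in 1:60) {
    n <- sample(5:14, 1)
    A <- random_contact_map(n); B <- random_contact_map(n)
    C <- random_contact_map(n)
    fab <- sch_distance(A, B)
    expect_equal(fab, sch_distance(B, A))
    expect_gte(fab, 0)
    expect_lt(fab, 1)
    expect_equal(fab, oracle_sch(A, B), tolerance = 1e-12)
    expect_lte(sch_distance(A, C), fab + sch_distance(B, C) + 1e-12)
  }
})

test_that("bit flips toggle symmetrically and respect the mutable rule", {
  set.seed(54)
  G <- random_contact_map(8)
  expect_identical(apply_bit_flips(G, NULL), G)
  expect_identical(apply_bit_flips(G, matrix(numeric(0), 0, 2)), G)
  fl <- rbind(c(1, 5), c(2, 8))
  expect_identical(apply_bit_flips(apply_bit_flips(G, fl), fl), G)
  flipped <- apply_bit_flips(G, fl)
  expect_identical(flipped, t(flipped))
  expect_error(apply_bit_flips(G, cbind(1, 2)), "immutable")
  expect_error(apply_bit_flips(G, cbind(3, 5)), "immutable")
  expect_identical(nrow(mutable_pairs(5)), 3L)  # (1,4) (1,5) (2,5)
})

test_that("contact maps round-trip through both text dialects", {
  set.seed(55)
  G <- random_contact_map(12)
  fe <- withr::local_tempfile(fileext = ".tsv")
  fd <- withr::local_tempfile(fileext = ".txt")
  write_contact_map(G, fe, format = "edges")
  write_contact_map(G, fd, format = "dense")
  expect_identical(read_contact_map(fe), G)
  expect_identical(read_contact_map(fd), G)
  # empty map round-trips in the sparse dialect too
  E <- matrix(0L, 7, 7)
  write_contact_map(E, fe, format = "edges")
  expect_identical(read_contact_map(fe), E)
})
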