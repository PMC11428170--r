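# Fixtures built in code and cached for the whole test run (several test
# files share the 56-bead system and its minima database).

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# a small 10-bead mixed system with one annealed minimum
fix_small10 <- function() fixture("small10", function() {
  seq10 <- bead_sequence(strsplit("BLNBBLNBLB", "")[[1]],
                         strsplit("HETHETH", "")[[1]])
  minres <- anneal_to_minimum(extended_chain(10), seq10, seed = 301)
  list(seq = seq10, min = minres)
})

# the 56-bead two-hairpin + helix protein with a seeded minima database
fix_toy56 <- function() fixture("toy56", function() {
  toy <- make_toy_protein()
  db <- build_minima_database(toy$seq, n_restarts = 12, stop_after = 6,
                              seed = 101)
  list(toy = toy, seq = toy$seq, db = db,
       native = db[[1]]$conformation)
})
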