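# SMILES -> graph and sequence -> token featurization.

scheme <- atom_feature_scheme()
n_el <- length(scheme$element_vocabulary)

block_sums <- function(row) {
  c(
    element = sum(row[1:n_el]),
    degree = sum(row[n_el + 1:(scheme$max_degree + 1)]),
    hydrogens = sum(row[n_el + scheme$max_degree + 1 + 1:(scheme$max_hydrogens + 1)]),
    valence = sum(row[n_el + scheme$max_degree + scheme$max_hydrogens + 2 +
      1:(scheme$max_implicit_valence + 1)]),
    aromatic = row[scheme$n_features]
  )
}

test_that("benzene parses to a 6-ring of aromatic carbons", {
  g <- smiles_to_graph("c1ccccc1")
  expect_equal(g$n_nodes, 6)
  expect_equal(nrow(g$edges), 12)
  expect_equal(g$node_features[, scheme$n_features], rep(1, 6))
  # edge symmetry, no self-pairs
  expect_true(all(g$edges[, 1] != g$edges[, 2]))
  key <- paste(g$edges[, 1], g$edges[, 2])
  rev_key <- paste(g$edges[, 2], g$edges[, 1])
  expect_setequal(key, rev_key)
})

test_that("single heavy atom molecules work and one-hot blocks each fire once", {
  g <- smiles_to_graph("C")
  expect_equal(g$n_nodes, 1)
  expect_equal(nrow(g$edges), 0)
  s <- block_sums(g$node_features[1, ])
  expect_equal(unname(s[c("element", "degree", "hydrogens", "valence")]), rep(1, 4))
  expect_equal(unname(s["aromatic"]), 0)
  # methane: 4 hydrogens, degree 0
  expect_equal(g$node_features[1, n_el + 1], 1) # degree bucket 0
})

test_that("ethane gives two nodes and one symmetric edge pair", {
  g <- smiles_to_graph("CC")
  expect_equal(g$n_nodes, 2)
  expect_setequal(paste(g$edges[, 1], g$edges[, 2]), c("0 1", "1 0"))
})

test_that("unparseable SMILES raise an invalid-input error carrying the string", {
  err <- expect_error(smiles_to_graph("not_a_smiles(("), class = "dta_invalid_input")
  expect_match(conditionMessage(err), "not_a_smiles", fixed = TRUE)
})

test_that("one-hot integrity holds across a random SMILES corpus", {
  withr::with_seed(55, {
    for (i in 1:25) {
      g <- smiles_to_graph(generate_smiles())
      sums <- t(apply(g$node_features, 1, block_sums))
      expect_true(all(sums[, "element"] == 1))
      expect_true(all(sums[, "degree"] == 1))
      expect_true(all(sums[, "hydrogens"] == 1))
      expect_true(all(sums[, "valence"] == 1))
      expect_true(all(sums[, "aromatic"] %in% c(0, 1)))
      # every row sums to 4 or 5 (aromatic flag optional)
      expect_true(all(rowSums(g$node_features) %in% c(4, 5)))
      # symmetric edge list implies an even directed-edge count
      expect_equal(nrow(g$edges) %% 2, 0)
    }
  })
})

test_that("protein encoding indexes, truncates and zero-pads", {
  tk <- encode_protein("ACD", L = 6)
  expect_equal(tk$tokens, c(1L, 3L, 4L, 0L, 0L, 0L))
  expect_equal(tk$original_length, 3)

  # exactly-L sequence has no padding
  vocab <- protein_vocabulary()
  full <- paste(vocab$symbols[1:10], collapse = "")
  expect_false(any(encode_protein(full, L = 10)$tokens == 0))

  # 2L sequence truncates to the first L
  long <- strrep("ACDEF", 4) # 20 chars
  t10 <- encode_protein(long, L = 10)
  expect_equal(t10$tokens, encode_protein(substr(long, 1, 10), L = 10)$tokens)
  expect_equal(t10$original_length, 20)
})

test_that("re-encoding a decoded prefix is idempotent", {
  vocab <- protein_vocabulary()
  tk <- encode_protein("MKVLAW", vocab, L = 12)
  prefix <- paste(vocab$symbols[tk$tokens[tk$tokens > 0]], collapse = "")
  tk2 <- encode_protein(prefix, vocab, L = 12)
  expect_equal(tk2$tokens, tk$tokens)
})

test_that("unknown residues follow the vocabulary policy", {
  mapped <- encode_protein("AJA", protein_vocabulary(), L = 4) # no 'J'
  expect_equal(mapped$tokens[2], match("X", protein_vocabulary()$symbols))
  expect_error(
    encode_protein("AJA", protein_vocabulary(unknown_policy = "error"), L = 4),
    class = "dta_invalid_input"
  )
})

test_that("featurize_dataset preserves order and aggregates failures", {
  recs <- tibble::tibble(
    smiles = c("CC", "CCO", "CCN"),
    target_id = "T1",
    sequence = c("ACD", "MKV", "WYF"),
    pic50 = c(5, 6, 7)
  )
  fz <- featurize_dataset(recs, L = 10)
  expect_length(fz$graphs, 3)
  expect_equal(fz$graphs[[2]]$smiles, "CCO")
  expect_equal(fz$labels, c(5, 6, 7))

  bad <- recs
  bad$smiles[2] <- "(((("
  err <- expect_error(featurize_dataset(bad, L = 10), class = "dta_invalid_input")
  expect_equal(err$indices, 2L)

  empty <- featurize_dataset(recs[0, ], L = 10)
  expect_length(empty$graphs, 0)
})

test_that("FASTA headers map to target identifiers and wrapped lines join", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(
    ">T001 some description", "ACDEF", "GHIKL",
    ">T002", "MNPQR"
  ), path)
  fa <- read_fasta_sequences(path)
  expect_equal(fa$target_id, c("T001", "T002"))
  expect_equal(fa$sequence, c("ACDEFGHIKL", "MNPQR"))
})
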