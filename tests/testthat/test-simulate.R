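test_that("site_probability multiplies normalized subsite weights", {
  m <- protease_model("uniform", efficiency = 0.5)
  expect_equal(site_probability(m, c(P2 = "A", P1 = "C", P1p = "D",
                                     P2p = "E")), 0.5)
  m2 <- protease_model("noA", P2 = c(A = 0), efficiency = 0.5)
  expect_equal(site_probability(m2, c(P2 = "A", P1 = "C", P1p = "D",
                                      P2p = "E")), 0)
  trp <- trp_p2p_model(efficiency = 1)
  expect_equal(site_probability(trp, c(P2 = "A", P1 = "C", P1p = "D",
                                       P2p = "W")), 1)
  expect_equal(site_probability(trp, c(P2 = "A", P1 = "C", P1p = "D",
                                       P2p = "A")), 0.1)
  # display-style subsite names are accepted; X kills the window
  expect_equal(site_probability(trp, c(P2 = "A", P1 = "C", "P1'" = "D",
                                       "P2'" = "X")), 0)
})

test_that("protease_model validates and normalizes preference vectors", {
  m <- protease_model("t", P2p = c(W = 10))
  expect_equal(m$subsite_weights$P2p[["W"]], 1)
  expect_equal(m$subsite_weights$P2p[["A"]], 0.1)
  expect_equal(unname(m$subsite_weights$P1), rep(1, 20))
  expect_error(protease_model("bad", P1 = c(Z = 2)), "unknown residue")
  expect_error(protease_model("bad", P1 = setNames(rep(0, 20), AA_ALPHABET)),
               "all-zero")
  expect_error(protease_model("bad", efficiency = 1.5))
})

test_that("digestion limiting cases behave as expected", {
  seqn <- paste(rep("ACDEFGHIK", 4), collapse = "")
  set.seed(1)
  all_cut <- digest_protein(seqn, protease_model("max", efficiency = 1),
                            digest_params(min_length = 5))
  expect_equal(nrow(all_cut), 0)   # every interior bond cut -> tiny fragments

  no_cut <- digest_protein(seqn, protease_model("none", efficiency = 0),
                           digest_params(max_length = 100))
  expect_equal(no_cut$peptide, seqn)
  expect_equal(no_cut$start, 0L)
  expect_length(attr(no_cut, "cuts"), 0)

  # whole protein dropped when outside length/mass limits
  no_cut2 <- digest_protein(seqn, protease_model("none", efficiency = 0),
                            digest_params(max_length = 10))
  expect_equal(nrow(no_cut2), 0)
  heavy <- digest_protein(seqn, protease_model("none", efficiency = 0),
                          digest_params(max_length = 100, max_mass = 500))
  expect_equal(nrow(heavy), 0)
})

test_that("every interior bond with a full window can be cut, edges cannot", {
  set.seed(2)
  seqn <- paste(rep("A", 30), collapse = "")
  d <- digest_protein(seqn, protease_model("max", efficiency = 1),
                      digest_params(min_length = 1))
  cuts <- attr(d, "cuts")
  expect_equal(cuts, 2:28)   # bonds 1 and 29 lack a P2/P2' residue
})

test_that("peptide masses match reference monoisotopic values", {
  # reference values computed independently with pyteomics.mass
  expect_equal(peptide_mass("PEPTIDE"), 799.35996, tolerance = 1e-7)
  expect_equal(peptide_mass("G"), 75.03203, tolerance = 1e-7)
  expect_error(peptide_mass("AXA"), "non-canonical")
})

test_that("simulation is deterministic given the seed", {
  ps <- within_seed <- NULL
  set.seed(99); ps <- random_proteins(5, 150)
  s1 <- simulate_experiment(ps, list(A = trp_p2p_model(),
                                     B = cys_p1_model()),
                            digest_params(decoy_fraction = 0.2), seed = 42)
  s2 <- simulate_experiment(ps, list(A = trp_p2p_model(),
                                     B = cys_p1_model()),
                            digest_params(decoy_fraction = 0.2), seed = 42)
  expect_identical(s1$table, s2$table)
  s3 <- simulate_experiment(ps, list(A = trp_p2p_model(),
                                     B = cys_p1_model()),
                            digest_params(decoy_fraction = 0.2), seed = 43)
  expect_false(identical(s1$table, s3$table))
})

test_that("true peptides are substrings of the inputs; decoys are not", {
  set.seed(4)
  ps <- random_proteins(6, 200)
  sim <- simulate_experiment(ps, list(A = trp_p2p_model()),
                             digest_params(decoy_fraction = 0.5), seed = 4)
  tab <- sim$table
  truth_peps <- unlist(lapply(sim$truth$per_condition,
                              function(x) names(x$abundance)))
  is_true <- tab$peptide %in% truth_peps
  expect_true(all(tab$confidence[is_true] >= 0.95))
  expect_true(all(tab$confidence[!is_true] < 0.95))
  # decoy count ~ n_true (decoy fraction one half of the table)
  expect_gt(sum(!is_true), 0.7 * sum(is_true))
  in_proteome <- vapply(tab$peptide, function(p)
    any(grepl(p, ps$sequence, fixed = TRUE)), logical(1))
  expect_true(all(in_proteome[is_true]))
  expect_true(all(!in_proteome[!is_true]))

  # the emitted table passes the loader and the 0.95 filter removes decoys
  q <- read_sim_table(tab, 0.95)
  expect_setequal(quant_peptides(q), tab$peptide[is_true])
})

test_that("fragment coordinates are consistent with realized cuts", {
  set.seed(6)
  ps <- random_proteins(3, 120)
  sim <- simulate_experiment(ps, list(A = protease_model("u", efficiency = 0.1)),
                             digest_params(min_length = 1, max_length = 200),
                             seed = 6)
  fr <- sim$truth$per_condition$A$fragments
  for (i in seq_len(nrow(fr))) {
    prot <- ps$sequence[ps$id == fr$protein_id[i]]
    expect_identical(substr(prot, fr$start[i] + 1, fr$end[i]),
                     fr$peptide[i])
    bounds <- c(0L, sim$truth$per_condition$A$cuts[[fr$protein_id[i]]],
                nchar(prot))
    expect_true(fr$start[i] %in% bounds)
    expect_true(fr$end[i] %in% bounds)
  }
})

test_that("P1 composition at cut sites converges to the generative model", {
  skew <- protease_model("p1skew", P1 = c(F = 5, L = 5, W = 5, Y = 5),
                         efficiency = 0.3)
  gen <- generative_subsite_distribution(skew, "P1")
  set.seed(8)
  ps <- random_proteins(300, 300)
  sim <- simulate_experiment(ps, list(A = skew), digest_params(), seed = 8)
  cuts <- sim$truth$per_condition$A$cuts
  p1 <- unlist(lapply(ps$id, function(id) {
    k <- cuts[[id]]
    substring(ps$sequence[ps$id == id], k, k)   # P1 residue of cut k
  }))
  freq <- table(factor(p1, levels = AA_ALPHABET)) / length(p1)
  tv <- 0.5 * sum(abs(as.numeric(freq) - gen[AA_ALPHABET]))
  expect_gt(length(p1), 5000)
  expect_lt(tv, 0.05)
})

test_that("condition label collisions and unnamed conditions error", {
  ps <- protein_set("P1", "ACDEFGHIKLMNPQRSTVWY")
  expect_error(simulate_experiment(ps, list(trp_p2p_model())), "named")
  cond <- list(A = trp_p2p_model(), A = cys_p1_model())
  expect_error(simulate_experiment(ps, cond), "collision")
})
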