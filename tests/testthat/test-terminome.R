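# Toy setting: protein "ACDEFGHIKLMNPQRSTVWY", every residue unique, so
# subsite residues can be read off the sequence directly.

located_at <- function(ps, peptide, start, end, weight = 1, n_sites = 1L) {
  out <- data.frame(peptide = peptide, protein_id = ps$id[1],
                    start = as.integer(start), end = as.integer(end),
                    weight = weight, n_sites = n_sites,
                    stringsAsFactors = FALSE)
  structure(out, unmatched = character(), discarded = character(),
            policy = "split_weight", match_mode = "exact",
            weight_sum_valid = TRUE,
            class = c("located_peptides", "data.frame"))
}

test_that("cleavage events carry the correct P2-P2' windows and weights", {
  ps <- toy_proteins()
  pep <- substr(ps$sequence, 5, 9)                  # [4, 9)
  q <- quant_from_list(pep, 0.99, list(list(raw = c(2, 2, 2))))
  ev <- extract_cleavage_events(located_at(ps, pep, 4, 9), ps, q, "raw")
  expect_equal(nrow(ev), 2)
  nev <- ev[ev$side == "N", ]; cev <- ev[ev$side == "C", ]
  expect_equal(unlist(nev[c("P2", "P1", "P1p", "P2p")], use.names = FALSE),
               c("D", "E", "F", "G"))
  expect_equal(unlist(cev[c("P2", "P1", "P1p", "P2p")], use.names = FALSE),
               c("I", "K", "L", "M"))
  expect_equal(ev$weight, c(2, 2))
  expect_equal(ev$cut, c(4L, 9L))
})

test_that("native protein termini never produce events", {
  ps <- toy_proteins()
  pep <- substr(ps$sequence, 1, 5)                  # [0, 5): native N-term
  q <- quant_from_list(pep, 0.99, list(list(raw = 1)))
  ev <- extract_cleavage_events(located_at(ps, pep, 0, 5), ps, q, "raw")
  expect_equal(ev$side, "C")
  # C-terminal peptide: [15, 20) ends at the native C-terminus
  pep2 <- substr(ps$sequence, 16, 20)
  q2 <- quant_from_list(pep2, 0.99, list(list(raw = 1)))
  ev2 <- extract_cleavage_events(located_at(ps, pep2, 15, 20), ps, q2, "raw")
  expect_equal(ev2$side, "N")
  # window overrun: C-cut at L-1 has no P2' residue
  pep3 <- substr(ps$sequence, 6, 19)                # [5, 19), cut 19 > L-2
  q3 <- quant_from_list(pep3, 0.99, list(list(raw = 1)))
  ev3 <- extract_cleavage_events(located_at(ps, pep3, 5, 19), ps, q3, "raw")
  expect_equal(ev3$side, "N")
})

test_that("Met-excision exclusion drops early N-side cuts only when enabled", {
  ps <- toy_proteins()
  pep <- substr(ps$sequence, 3, 7)                  # [2, 7): N-cut at 2
  q <- quant_from_list(pep, 0.99, list(list(raw = 1)))
  loc <- located_at(ps, pep, 2, 7)
  off <- extract_cleavage_events(loc, ps, q, "raw")
  expect_setequal(off$side, c("N", "C"))
  on <- extract_cleavage_events(loc, ps, q, "raw",
                                exclude_met_excision = TRUE)
  expect_equal(on$side, "C")
})

test_that("windows containing X are skipped", {
  ps <- protein_set("PX", "AAAAXAAAAAAA")
  pep <- "AAAAAA"                                   # matches at [5, 11)
  q <- quant_from_list(pep, 0.99, list(list(raw = 1)))
  loc <- suppressMessages(map_peptidome(q, ps))
  ev <- extract_cleavage_events(loc, ps, q, "raw")
  # N-cut at 5 has P2 = X -> dropped; only interior C-cuts survive
  expect_false(any(ev$cut == 5 & ev$side == "N"))
  expect_true(all(ev[c("P2", "P1", "P1p", "P2p")] != "X"))
})

test_that("missing condition is a hard error; zero intensity yields no event", {
  ps <- toy_proteins()
  pep <- substr(ps$sequence, 5, 9)
  q <- quant_from_list(pep, 0.99, list(list(raw = 1)))
  loc <- located_at(ps, pep, 4, 9)
  expect_error(extract_cleavage_events(loc, ps, q, "SV-80"), "condition")
  q0 <- quant_from_list(pep, 0.99, list(list(raw = 0)))
  expect_equal(nrow(extract_cleavage_events(loc, ps, q0, "raw")), 0)
})

test_that("dedupe_cuts collapses shared cut positions, summing weights", {
  ps <- toy_proteins()
  p1 <- substr(ps$sequence, 5, 9)                   # [4, 9)
  p2 <- substr(ps$sequence, 10, 14)                 # [9, 14): shares cut 9
  q <- quant_from_list(c(p1, p2), c(0.99, 0.99),
                       list(list(raw = 3), list(raw = 5)))
  loc <- rbind(located_at(ps, p1, 4, 9), located_at(ps, p2, 9, 14))
  class(loc) <- c("located_peptides", "data.frame")
  plain <- extract_cleavage_events(loc, ps, q, "raw")
  expect_equal(sum(plain$cut == 9), 2)
  ded <- extract_cleavage_events(loc, ps, q, "raw", dedupe_cuts = TRUE)
  at9 <- ded[ded$cut == 9, ]
  expect_equal(nrow(at9), 1)
  expect_equal(at9$weight, 8)
  expect_equal(at9$side, "C+N")
})

test_that("background_composition matches hand counts and ignores X", {
  expect_equal(background_composition(protein_set("A", "AAAA"))[["A"]], 1)
  u <- background_composition(toy_proteins())
  expect_equal(unname(u), rep(0.05, 20))
  two <- background_composition(protein_set(c("a", "b"), c("AA", "CC")))
  expect_equal(two[["A"]], 0.5)
  expect_equal(two[["C"]], 0.5)
  expect_error(background_composition(protein_set("x", "XXX")),
               "no canonical residues")
})

make_events <- function(P1p, weight,
                        P2 = "A", P1 = "C", P2p = "D") {
  out <- data.frame(protein_id = "P1", cut = seq_along(P1p) + 1L,
                    side = "C", P2 = P2, P1 = P1, P1p = P1p, P2p = P2p,
                    weight = weight, peptide = "x",
                    stringsAsFactors = FALSE)
  structure(out, condition = "raw",
            class = c("cleavage_events", "data.frame"))
}

test_that("specificity matrix cells follow the weighted-frequency definition", {
  ev <- make_events(c("F", "F"), c(1, 3))
  m <- compute_specificity_matrix(ev, "intensity", "frequency")
  expect_equal(m$values["F", "P1'"], 1)
  expect_equal(sum(m$values[, "P1'"]), 1)
  mc <- compute_specificity_matrix(ev, "count", "frequency")
  expect_equal(mc$values, m$values)

  ev2 <- make_events(c("F", "G"), c(1, 3))
  m2 <- compute_specificity_matrix(ev2)
  expect_equal(m2$values["F", "P1'"], 0.25)
  expect_equal(m2$values["G", "P1'"], 0.75)
  expect_equal(m2$n_events, 2L)
  expect_equal(m2$total_weight, 4)

  empty <- compute_specificity_matrix(ev2[0, , drop = FALSE])
  expect_true(all(empty$values == 0))
  expect_equal(empty$n_events, 0L)
})

test_that("frequency columns sum to one and are scale invariant", {
  set.seed(21)
  ps <- random_proteins(10, 200)
  sim <- simulate_experiment(ps, list(A = trp_p2p_model()),
                             digest_params(), seed = 21)
  q <- read_sim_table(sim$table)
  loc <- suppressMessages(map_peptidome(q, ps))
  ev <- extract_cleavage_events(loc, ps, q, "A")
  m <- compute_specificity_matrix(ev)
  expect_equal(unname(colSums(m$values)), rep(1, 4), tolerance = 1e-9)

  ev2 <- ev; ev2$weight <- ev$weight * 7.3
  m2 <- compute_specificity_matrix(ev2)
  expect_equal(m2$values, m$values, tolerance = 1e-12)

  bg <- background_composition(ps)
  e1 <- compute_specificity_matrix(ev, normalization = "enrichment",
                                   background = bg)
  e2 <- compute_specificity_matrix(ev2, normalization = "enrichment",
                                   background = bg)
  expect_equal(e2$values, e1$values, tolerance = 1e-12)
})

test_that("equal intensities make intensity and count weighting identical", {
  set.seed(22)
  ps <- random_proteins(5, 150)
  peps <- unique(vapply(1:30, function(i) {
    row <- sample(5, 1); st <- sample(140, 1)
    substr(ps$sequence[row], st, st + 6)
  }, character(1)))
  q <- quant_from_list(peps, rep(0.99, length(peps)),
                       rep(list(list(raw = c(5, 5, 5))), length(peps)))
  loc <- suppressMessages(map_peptidome(q, ps, "keep_all_unit"))
  loc$weight <- 1
  ev <- extract_cleavage_events(loc, ps, q, "raw")
  mi <- compute_specificity_matrix(ev, "intensity")
  mc <- compute_specificity_matrix(ev, "count")
  expect_identical(mi$values, mc$values)
})

test_that("enrichment requires a background covering observed residues", {
  ev <- make_events("F", 1)
  expect_error(compute_specificity_matrix(ev, normalization = "enrichment"),
               "background")
  bg <- stats::setNames(rep(0.05, 20), AA_ALPHABET)
  bg["F"] <- 0; bg <- bg / sum(bg)
  expect_error(compute_specificity_matrix(ev, normalization = "enrichment",
                                          background = bg), "F")
  bg2 <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  e <- compute_specificity_matrix(ev, normalization = "enrichment",
                                  background = bg2)
  expect_equal(e$values["F", "P1'"], 20)   # frequency 1 over background .05
})

test_that("condition contrasts rank the divergent cells first", {
  ev <- make_events(c("F", "G"), c(1, 3))
  m <- compute_specificity_matrix(ev)
  self <- compare_conditions(m, m)
  expect_true(all(self$difference == 0))

  a <- m; b <- m
  a$values["W", "P2'"] <- 0.4; b$values["W", "P2'"] <- 0.1
  ctr <- compare_conditions(a, b)
  top <- ctr$ranking[1, ]
  expect_equal(top$residue, "W")
  expect_equal(top$subsite, "P2'")
  expect_equal(top$delta, 0.3)

  cnt <- compute_specificity_matrix(ev, weighting = "count")
  expect_error(compare_conditions(m, cnt), "mode")
})

test_that("per-protein matrices pool into the global matrix by total weight", {
  set.seed(23)
  ps <- random_proteins(6, 150)
  sim <- simulate_experiment(ps, list(A = trp_p2p_model()),
                             digest_params(), seed = 23)
  q <- read_sim_table(sim$table)
  loc <- suppressMessages(map_peptidome(q, ps))
  ev <- extract_cleavage_events(loc, ps, q, "A")
  pooled <- compute_specificity_matrix(ev)
  ids <- unique(ev$protein_id)
  per <- lapply(ids, function(id) per_protein_specificity(ev, id))
  w <- vapply(per, function(m) m$total_weight, numeric(1))
  avg <- Reduce(`+`, lapply(seq_along(per), function(i)
    per[[i]]$values * w[i])) / sum(w)
  expect_equal(avg, pooled$values, tolerance = 1e-9)
  expect_equal(sum(vapply(per, function(m) m$n_events, integer(1))),
               pooled$n_events)

  expect_error(per_protein_specificity(ev, "nope"), "unknown protein")
  zero <- per_protein_specificity(ev[0, , drop = FALSE], ps$id[1],
                                  proteins = ps)
  expect_true(all(zero$values == 0))
})

test_that("recovered P1 distribution approaches the generative one with size", {
  skew <- protease_model("p1skew", P1 = c(F = 5, L = 5, W = 5, Y = 5),
                         efficiency = 0.3)
  gen <- generative_subsite_distribution(skew, "P1")
  jsd_at <- function(n_prot, seed) {
    set.seed(seed)
    ps <- random_proteins(n_prot, 300)
    sim <- simulate_experiment(ps, list(A = skew), digest_params(),
                               seed = seed)
    fr <- sim$truth$per_condition$A$fragments
    loc <- structure(
      data.frame(peptide = fr$peptide, protein_id = fr$protein_id,
                 start = fr$start, end = fr$end, weight = 1,
                 n_sites = 1L, stringsAsFactors = FALSE),
      unmatched = character(), discarded = character(),
      policy = "split_weight", match_mode = "exact",
      weight_sum_valid = TRUE,
      class = c("located_peptides", "data.frame"))
    q <- read_sim_table(sim$table)
    ev <- extract_cleavage_events(loc, ps, q, "A")
    m <- compute_specificity_matrix(ev, weighting = "count")
    js_divergence(m$values[, "P1"], gen[AA_ALPHABET])
  }
  worse <- vapply(1:10, function(s) jsd_at(3, s), numeric(1))   # ~50 peptides
  better <- vapply(1:10, function(s) jsd_at(300, s + 100), numeric(1)) # ~5000
  expect_true(all(better <= worse))
  expect_lt(mean(better), mean(worse))
})
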