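# Shared fixtures and independent oracles, built in code at test time.

# Toy protein with all 20 residues exactly once: window residues can be
# read off by eye.
toy_proteins <- function() protein_set("P1", "ACDEFGHIKLMNPQRSTVWY")

# Naive O(n*m) sliding-window substring oracle, independent of the
# package's search path.
naive_locate <- function(peptide, proteins, match_mode = "exact") {
  rows <- list()
  for (i in order(proteins$id)) {
    s <- proteins$sequence[i]
    p <- toupper(peptide)
    if (match_mode == "IL") {
      s <- chartr("I", "L", s)
      p <- chartr("I", "L", p)
    }
    n <- nchar(s); k <- nchar(p)
    if (k <= n) {
      starts <- which(substring(s, 1:(n - k + 1), k:n) == p)
      for (st in starts)
        rows[[length(rows) + 1]] <- data.frame(
          protein_id = proteins$id[i], start = st - 1L,
          end = st + k - 1L, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(protein_id = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Build a peptide_quant directly from peptide -> per-condition replicate
# intensity lists.
quant_from_list <- function(peptides, confidence, intensities) {
  rows <- list()
  for (i in seq_along(peptides)) {
    for (cn in names(intensities[[i]])) {
      v <- intensities[[i]][[cn]]
      rows[[length(rows) + 1]] <- data.frame(
        peptide = peptides[i], confidence = confidence[i],
        condition = cn, replicate = seq_along(v), intensity = v,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  peptide_quant(df$peptide, df$confidence, df$condition, df$replicate,
                df$intensity)
}

# Write a wide quant data frame (as produced by simulate_experiment) to a
# temp TSV and read it back through the package's loader.
read_sim_table <- function(table, confidence_threshold = 0.95) {
  tf <- tempfile(fileext = ".tsv")
  utils::write.table(table, tf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  suppressMessages(read_peptide_quant(tf, confidence_threshold))
}

# Analytic two-triangle TPA curve: cycle 1 peak h1 over d1 seconds
# (symmetric), cycle 2 peak h2 over d2, separated by `rest` seconds of
# zero force, sampled at `rate` Hz with the knots included.
two_triangle_curve <- function(h1 = 100, d1 = 20, h2 = 50, d2 = 10,
                               rest = 2, rate = 1000, noise_sd = 0) {
  kt <- c(0, rest, rest + d1 / 2, rest + d1,
          rest + d1 + rest, rest + d1 + rest + d2 / 2,
          rest + d1 + rest + d2, 2 * rest + d1 + rest + d2)
  kf <- c(0, 0, h1, 0, 0, h2, 0, 0)
  tt <- sort(unique(c(seq(0, max(kt), by = 1 / rate), kt)))
  ff <- stats::approx(kt, kf, xout = tt)$y
  if (noise_sd > 0) ff <- ff + stats::rnorm(length(ff), 0, noise_sd)
  tpa_curve(tt, ff, contact_threshold = 6 * noise_sd)
}

# Jensen-Shannon divergence between two discrete distributions.
js_divergence <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log(a[nz] / b[nz]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

# Standard simulation models used across tests.
trp_p2p_model <- function(efficiency = 1)
  protease_model("trpP2p", P2p = c(W = 10), efficiency = efficiency)

cys_p1_model <- function(efficiency = 1)
  protease_model("cysP1", P1 = c(C = 10), efficiency = efficiency)
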