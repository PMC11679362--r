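#' Define a protease subsite-preference model
#'
#' A generative cleavage model in the PSSM spirit: one non-negative
#' preference weight per residue at each of the four P2-P2' subsites,
#' combined multiplicatively, times a base efficiency. Each subsite
#' vector is rescaled so its maximum is 1, making `efficiency` the
#' cleavage probability at a maximally preferred site.
#'
#' Subsite arguments may be `NULL` (uniform preference), a full named
#' 20-vector, or a partial named vector of overrides with all remaining
#' residues at weight 1 — `protease_model("trpP2p", P2p = c(W = 10))`
#' describes an enzyme with a 10-fold tryptophan preference at P2'
#' (cathepsin-B-like S2' pocket behaviour).
#'
#' @param name Model name.
#' @param P2,P1,P1p,P2p Subsite preference weights (see above).
#' @param efficiency Cleavage probability in \[0, 1\] at a maximally
#'   preferred site.
#' @return A `protease_model`.
#' @export
protease_model <- function(name, P2 = NULL, P1 = NULL, P1p = NULL,
                           P2p = NULL, efficiency = 0.1) {
  stopifnot(is.numeric(efficiency), length(efficiency) == 1,
            efficiency >= 0, efficiency <= 1)
  expand <- function(w, subsite) {
    full <- stats::setNames(rep(1, 20), AA_ALPHABET)
    if (!is.null(w)) {
      if (is.null(names(w)) && length(w) == 20) {
        names(w) <- AA_ALPHABET
      }
      bad <- setdiff(names(w), AA_ALPHABET)
      if (length(bad) > 0)
        stop("unknown residue(s) in ", subsite, " weights: ",
             paste(bad, collapse = ", "))
      full[names(w)] <- w
    }
    if (any(full < 0)) stop("negative preference weight at ", subsite)
    if (all(full == 0)) stop("all-zero preference vector at ", subsite)
    full / max(full)
  }
  structure(list(name = name,
                 subsite_weights = list(P2 = expand(P2, "P2"),
                                        P1 = expand(P1, "P1"),
                                        P1p = expand(P1p, "P1'"),
                                        P2p = expand(P2p, "P2'")),
                 efficiency = efficiency),
            class = "protease_model")
}

#' @export
print.protease_model <- function(x, ...) {
  cat("protease_model '", x$name, "', efficiency ", x$efficiency, "\n",
      sep = "")
  for (s in names(x$subsite_weights)) {
    w <- x$subsite_weights[[s]]
    pref <- names(w)[w > min(w)]
    cat("  ", s, ": ",
        if (length(pref) == 0 || length(pref) == 20) "uniform"
        else paste0(paste(pref, collapse = ","), " preferred"), "\n",
        sep = "")
  }
  invisible(x)
}

#' Cleavage probability of one P2-P2' window
#'
#' `p = efficiency x w_P2(r) x w_P1(r) x w_P1'(r) x w_P2'(r)` with each
#' subsite vector max-normalized; windows containing `X` have
#' probability 0. Independence across subsites makes the cut-site
#' residue composition an unbiased image of the preference vectors,
#' which is what recovery tests rely on.
#'
#' @param model A [protease_model()].
#' @param window Named character vector with elements `P2`, `P1`, `P1p`
#'   (or `P1'`), `P2p` (or `P2'`).
#' @return Probability in \[0, 1\].
#' @export
site_probability <- function(model, window) {
  stopifnot(inherits(model, "protease_model"))
  nm <- names(window)
  nm[nm == "P1'"] <- "P1p"; nm[nm == "P2'"] <- "P2p"
  names(window) <- nm
  if (!all(c("P2", "P1", "P1p", "P2p") %in% nm))
    stop("window must name residues at P2, P1, P1', P2'")
  res <- as.character(window[c("P2", "P1", "P1p", "P2p")])
  if (any(res == "X")) return(0)
  if (any(!res %in% AA_ALPHABET))
    stop("non-canonical residue in window: ",
         paste(setdiff(res, AA_ALPHABET), collapse = ", "))
  w <- model$subsite_weights
  unname(model$efficiency * w$P2[res[1]] * w$P1[res[2]] *
           w$P1p[res[3]] * w$P2p[res[4]])
}

#' Digestion parameters for the simulator
#'
#' Length limits reflect the peptidome observation window of a typical
#' nano-LC-MS/MS setup; the 10 kDa mass ceiling mirrors the
#' ultrafiltration step used to isolate free peptides.
#'
#' @param min_length,max_length Kept fragment length range in residues.
#' @param max_mass Maximum monoisotopic fragment mass, Da.
#' @param abundance_log_sigma SD of log-normal abundance/replicate noise.
#' @param replicates Replicate injections per condition.
#' @param decoy_fraction Fraction of the emitted table made of shuffled
#'   decoy rows with sub-threshold confidence (0 disables).
#' @return A `digest_params` list.
#' @export
digest_params <- function(min_length = 5L, max_length = 30L,
                          max_mass = 10000, abundance_log_sigma = 0.5,
                          replicates = 3L, decoy_fraction = 0) {
  stopifnot(min_length >= 1, min_length <= max_length, max_mass > 0,
            replicates >= 1, abundance_log_sigma >= 0,
            decoy_fraction >= 0, decoy_fraction < 1)
  structure(list(min_length = as.integer(min_length),
                 max_length = as.integer(max_length),
                 max_mass = max_mass,
                 abundance_log_sigma = abundance_log_sigma,
                 replicates = as.integer(replicates),
                 decoy_fraction = decoy_fraction),
            class = "digest_params")
}

# Per-bond cleavage probabilities for one protein under one model.
# Cuts are 0-based: cut k severs the bond after the k-th residue; only
# k in [2, L-2] carries a full P2-P2' window, all other bonds get p = 0.
bond_probabilities <- function(chars, model) {
  L <- length(chars)
  p <- numeric(max(L - 1, 0))       # p[k] = probability of cut k, k = 1..L-1
  if (L < 4) return(p)
  ks <- 2:(L - 2)
  w <- model$subsite_weights
  look <- function(wv, idx) {
    v <- wv[chars[idx]]
    v[is.na(v)] <- 0                # X or unknown -> impossible window
    v
  }
  p[ks] <- model$efficiency *
    look(w$P2, ks - 1) * look(w$P1, ks) * look(w$P1p, ks + 1) *
    look(w$P2p, ks + 2)
  p
}

#' Stochastically digest one protein
#'
#' Each interior peptide bond is cut independently with probability
#' [site_probability()] under one protease model drawn from
#' `models` by `proportions` (one draw per protein realization — a
#' protein molecule meets one enzyme). Fragments between consecutive
#' realized cuts (protein termini included as boundaries) are kept when
#' their length is within `[min_length, max_length]` and their
#' monoisotopic mass is at most `max_mass`. Each kept fragment receives
#' a log-normal base abundance. Missed cleavages emerge naturally from
#' the Bernoulli sampling; there is no separate parameter.
#'
#' Consumes the current RNG stream; call `set.seed()` beforehand for
#' reproducibility.
#'
#' @param sequence One protein sequence.
#' @param models A [protease_model()] or list of them.
#' @param params A [digest_params()].
#' @param proportions Mixing proportions over `models` (default uniform).
#' @return Data frame `peptide`, `start`, `end` (0-based half-open),
#'   `abundance`, plus attributes `cuts` (realized 0-based cut
#'   positions) and `model` (name of the model drawn).
#' @export
digest_protein <- function(sequence, models, params = digest_params(),
                           proportions = NULL) {
  if (inherits(models, "protease_model")) models <- list(models)
  stopifnot(length(models) >= 1,
            all(vapply(models, inherits, logical(1), "protease_model")))
  if (is.null(proportions)) proportions <- rep(1, length(models))
  stopifnot(length(proportions) == length(models), all(proportions >= 0),
            sum(proportions) > 0)
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  mi <- sample.int(length(models), 1, prob = proportions)
  model <- models[[mi]]
  p <- bond_probabilities(chars, model)
  cut <- which(stats::runif(length(p)) < p)   # 0-based cut positions
  bounds <- c(0L, cut, L)
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1]
  frags <- substring(sequence, starts + 1L, ends)
  len <- ends - starts
  keep <- len >= params$min_length & len <= params$max_length
  if (any(keep)) {
    has_x <- grepl("X", frags[keep], fixed = TRUE)
    mass <- rep(Inf, sum(keep))
    mass[!has_x] <- peptide_mass(frags[keep][!has_x])
    keep[keep] <- !has_x & mass <= params$max_mass
  }
  out <- data.frame(peptide = frags[keep], start = starts[keep],
                    end = ends[keep],
                    abundance = stats::rlnorm(sum(keep), meanlog = 0,
                                              sdlog = params$abundance_log_sigma),
                    stringsAsFactors = FALSE)
  attr(out, "cuts") <- cut
  attr(out, "model") <- model$name
  out
}

# Shuffle a peptide until it no longer occurs in any protein (decoys
# must exercise the unmatched-peptide report).
shuffle_decoy <- function(pep, sequences, max_tries = 20L) {
  for (i in seq_len(max_tries)) {
    dec <- paste(sample(strsplit(pep, "")[[1]]), collapse = "")
    if (!any(grepl(dec, sequences, fixed = TRUE))) return(dec)
  }
  NA_character_
}

#' Simulate a multi-condition peptide quantification experiment
#'
#' Digests every protein under each condition's protease mixture and
#' assembles the union of fragments into one wide quantification table
#' emulating a SWATH export: per-condition replicate intensities equal
#' the realized abundance times independent log-normal replicate noise,
#' and are 0 where the peptide was not generated in that condition.
#' True peptides receive identification confidence Uniform(0.95, 1);
#' optional decoy rows (shuffled sequences mapping to no protein) get
#' Uniform(0, 0.95) and are removed by the default confidence filter.
#'
#' @param proteins A [protein_set()].
#' @param conditions Named list: condition label to either a
#'   [protease_model()] or `list(models = <list>, proportions = <vec>)`.
#' @param params A [digest_params()].
#' @param seed Integer seed; the run is fully reproducible given
#'   (inputs, seed).
#' @return List with `table` (wide data frame: `peptide`, `confidence`,
#'   `<condition>_r<k>` columns), `quant` (the same data as a filtered
#'   [peptide_quant()] would see, unfiltered here), and `truth`
#'   (per-condition realized cuts, fragment abundances, model names and
#'   the generative models).
#' @export
simulate_experiment <- function(proteins, conditions,
                                params = digest_params(), seed = 1L) {
  stopifnot(inherits(proteins, "protein_set"), length(conditions) >= 1)
  labels <- names(conditions)
  if (is.null(labels) || any(!nzchar(labels)))
    stop("conditions must be a named list of protease models")
  if (anyDuplicated(labels)) stop("condition label collision")
  set.seed(as.integer(seed))

  norm_cond <- lapply(conditions, function(cs) {
    if (inherits(cs, "protease_model"))
      list(models = list(cs), proportions = 1)
    else {
      stopifnot(is.list(cs), !is.null(cs$models))
      if (is.null(cs$proportions))
        cs$proportions <- rep(1, length(cs$models))
      cs
    }
  })

  per_cond <- lapply(labels, function(lab) {
    cs <- norm_cond[[lab]]
    digs <- lapply(seq_len(nrow(proteins)), function(i) {
      d <- digest_protein(proteins$sequence[i], cs$models, params,
                          cs$proportions)
      if (nrow(d) > 0) d$protein_id <- proteins$id[i]
      list(frags = d, cuts = attr(d, "cuts"), model = attr(d, "model"))
    })
    frags <- do.call(rbind, lapply(digs, function(d)
      if (nrow(d$frags) > 0) d$frags else NULL))
    if (is.null(frags))
      frags <- data.frame(peptide = character(), start = integer(),
                          end = integer(), abundance = numeric(),
                          protein_id = character(),
                          stringsAsFactors = FALSE)
    # identical sequences generated more than once in one condition pool
    ab <- if (nrow(frags) == 0) stats::setNames(numeric(0), character(0))
          else tapply(frags$abundance, frags$peptide, sum)
    list(abundance = ab,
         frags = frags,
         cuts = stats::setNames(lapply(digs, `[[`, "cuts"), proteins$id),
         models_drawn = stats::setNames(vapply(digs, `[[`, character(1),
                                               "model"), proteins$id))
  })
  names(per_cond) <- labels

  all_peps <- sort(unique(unlist(lapply(per_cond, function(x)
    names(x$abundance)))))
  n_true <- length(all_peps)

  wide <- data.frame(peptide = all_peps,
                     confidence = stats::runif(n_true, 0.95, 1),
                     stringsAsFactors = FALSE, check.names = FALSE)
  for (lab in labels) {
    ab <- per_cond[[lab]]$abundance
    base <- as.numeric(ab[all_peps])
    base[is.na(base)] <- 0
    for (r in seq_len(params$replicates)) {
      noise <- exp(stats::rnorm(n_true, 0, params$abundance_log_sigma))
      wide[[paste0(lab, "_r", r)]] <- base * noise
    }
  }

  if (params$decoy_fraction > 0 && n_true > 0) {
    n_decoy <- round(params$decoy_fraction / (1 - params$decoy_fraction) *
                       n_true)
    src <- sample(all_peps, n_decoy, replace = TRUE)
    dec <- vapply(src, shuffle_decoy, character(1),
                  sequences = proteins$sequence)
    keep <- !is.na(dec) & !dec %in% wide$peptide & !duplicated(dec)
    dec <- dec[keep]
    if (length(dec) > 0) {
      drows <- data.frame(peptide = dec,
                          confidence = stats::runif(length(dec), 0, 0.95),
                          stringsAsFactors = FALSE, check.names = FALSE)
      for (cl in setdiff(names(wide), c("peptide", "confidence")))
        drows[[cl]] <- stats::rlnorm(length(dec), 0,
                                     params$abundance_log_sigma)
      wide <- rbind(wide, drows)
    }
  }
  rownames(wide) <- NULL

  truth <- list(conditions = norm_cond,
                params = params, seed = as.integer(seed),
                n_true_peptides = n_true,
                per_condition = lapply(per_cond, function(x)
                  list(abundance = x$abundance, cuts = x$cuts,
                       models_drawn = x$models_drawn,
                       fragments = x$frags)))
  list(table = wide, truth = truth)
}

#' Model-implied residue distribution at a subsite
#'
#' The expected residue composition observed at cut sites under a
#' protease model acting on substrate with residue composition
#' `background` (uniform by default, matching [random_proteins()]):
#' preference weights times background, renormalized. The comparison
#' target for specificity-recovery checks.
#'
#' @param model A [protease_model()].
#' @param subsite One of `"P2"`, `"P1"`, `"P1'"`, `"P2'"`.
#' @param background Named 20-vector of substrate residue frequencies.
#' @return Named 20-vector summing to 1.
#' @export
generative_subsite_distribution <- function(model, subsite,
                                            background = NULL) {
  stopifnot(inherits(model, "protease_model"))
  key <- c("P2" = "P2", "P1" = "P1", "P1'" = "P1p", "P1p" = "P1p",
           "P2'" = "P2p", "P2p" = "P2p")[subsite]
  if (is.na(key)) stop("unknown subsite: ", subsite)
  if (is.null(background))
    background <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  w <- model$subsite_weights[[key]] * background[AA_ALPHABET]
  w / sum(w)
}
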