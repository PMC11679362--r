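#' Reconstruct cleavage events from mapped peptide termini
#'
#' Every terminus of a mapped free peptide that is not a native protein
#' terminus witnesses one scissile-bond hydrolysis. For a peptide at
#' `[s, e)` the N-side event sits at cut `c = s` and the C-side event at
#' `c = e`; a cut at `c` severs the bond between residues `c - 1` and `c`
#' and its Schechter-Berger window is `P2 = protein[c-2]`,
#' `P1 = protein[c-1]`, `P1' = protein[c]`, `P2' = protein[c+1]`
#' (0-based). Events are weighted by mapping weight times the
#' replicate-aggregated intensity of the peptide in `condition`.
#'
#' No event is produced when:
#' * the cut coincides with a protein terminus (`s = 0` or `e = L`) — a
#'   native terminus, not a cleavage;
#' * the P2-P2' window would run past a protein end (`c < 2` or
#'   `c > L - 2`);
#' * any window residue is `X`;
#' * `exclude_met_excision` is on and the N-side cut falls at position 1
#'   or 2 (initiator-Met removal is co-translational, not proteolysis);
#' * the peptide has zero aggregated intensity in `condition` (it was not
#'   observed there, so it is no evidence of cleavage there).
#'
#' @param located A `located_peptides` from [map_peptidome()].
#' @param proteins The [protein_set()] used for mapping.
#' @param quant The [peptide_quant()] providing intensities.
#' @param condition Condition label whose intensities weight the events.
#' @param aggregate Replicate summary passed to
#'   [aggregate_condition_intensity()].
#' @param exclude_met_excision Drop N-side cuts at positions 1-2.
#' @param dedupe_cuts Collapse events sharing (protein, cut position),
#'   summing weights. By default each peptide terminus is kept as
#'   independent evidence of its cut.
#' @return A `cleavage_events` data frame: `protein_id`, `cut`, `side`
#'   (`"N"`/`"C"`), `P2`, `P1`, `P1p`, `P2p`, `weight`, `peptide`;
#'   attribute `condition`.
#' @export
extract_cleavage_events <- function(located, proteins, quant, condition,
                                    aggregate = "mean",
                                    exclude_met_excision = FALSE,
                                    dedupe_cuts = FALSE) {
  stopifnot(inherits(located, "located_peptides"),
            inherits(proteins, "protein_set"))
  intens <- aggregate_condition_intensity(quant, condition,
                                          method = aggregate)
  unknown <- setdiff(unique(located$peptide), names(intens))
  if (length(unknown) > 0)
    stop("located peptide(s) absent from the quantification table: ",
         paste(utils::head(unknown, 5), collapse = ", "))

  empty <- data.frame(protein_id = character(), cut = integer(),
                      side = character(), P2 = character(),
                      P1 = character(), P1p = character(),
                      P2p = character(), weight = numeric(),
                      peptide = character(), stringsAsFactors = FALSE)
  if (nrow(located) == 0)
    return(structure(empty, condition = condition,
                     class = c("cleavage_events", "data.frame")))

  plen <- stats::setNames(nchar(proteins$sequence), proteins$id)
  pseq <- stats::setNames(proteins$sequence, proteins$id)
  L <- plen[located$protein_id]
  w_base <- located$weight * intens[located$peptide]

  # candidate cuts: N side at start, C side at end
  cand <- rbind(
    data.frame(protein_id = located$protein_id, cut = located$start,
               side = "N", weight = w_base, peptide = located$peptide,
               L = L, stringsAsFactors = FALSE),
    data.frame(protein_id = located$protein_id, cut = located$end,
               side = "C", weight = w_base, peptide = located$peptide,
               L = L, stringsAsFactors = FALSE))
  keep <- cand$cut > 0 & cand$cut < cand$L &      # not a native terminus
    cand$cut >= 2 & cand$cut <= cand$L - 2        # full P2-P2' window
  if (exclude_met_excision)
    keep <- keep & !(cand$side == "N" & cand$cut <= 2)
  keep <- keep & cand$weight > 0
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0)
    return(structure(empty, condition = condition,
                     class = c("cleavage_events", "data.frame")))

  # window residues (cut c is 0-based: P2 at string position c - 1)
  win <- function(offset) substring(pseq[cand$protein_id],
                                    cand$cut + offset, cand$cut + offset)
  cand$P2 <- win(-1L); cand$P1 <- win(0L)
  cand$P1p <- win(1L); cand$P2p <- win(2L)
  has_x <- cand$P2 == "X" | cand$P1 == "X" | cand$P1p == "X" |
    cand$P2p == "X"
  cand <- cand[!has_x, , drop = FALSE]
  cand$L <- NULL
  rownames(cand) <- NULL

  if (dedupe_cuts && nrow(cand) > 0) {
    key <- paste(cand$protein_id, cand$cut)
    agg_w <- tapply(cand$weight, key, sum)
    first <- !duplicated(key)
    ded <- cand[first, , drop = FALSE]
    ded$weight <- as.numeric(agg_w[paste(ded$protein_id, ded$cut)])
    ded$side <- vapply(paste(ded$protein_id, ded$cut), function(k)
      paste(sort(unique(cand$side[key == k])), collapse = "+"),
      character(1))
    ded$peptide <- NA_character_
    cand <- ded
    rownames(cand) <- NULL
  }
  cand <- cand[, c("protein_id", "cut", "side", "P2", "P1", "P1p", "P2p",
                   "weight", "peptide")]
  cand <- cand[order(cand$protein_id, cand$cut, cand$side), , drop = FALSE]
  rownames(cand) <- NULL
  structure(cand, condition = condition,
            class = c("cleavage_events", "data.frame"))
}

# Internal constructor for the 20 x 4 specificity matrix object.
new_specificity_matrix <- function(values, condition, weighting,
                                   normalization, n_events, total_weight) {
  dimnames(values) <- list(AA_ALPHABET, SUBSITES)
  structure(list(values = values, condition = condition,
                 weighting = weighting, normalization = normalization,
                 n_events = n_events, total_weight = total_weight),
            class = "specificity_matrix")
}

#' Compute a P2-P2' cleavage-site specificity matrix
#'
#' Summarizes cleavage events as a 20 residues x 4 subsites matrix, the
#' terminome fingerprint of the proteases active in one condition.
#'
#' Weighting: `"intensity"` uses each event's weight (mapping weight x
#' aggregated peptide intensity); `"count"` gives every event weight 1.
#' Normalization: `"frequency"` divides each subsite column by the total
#' event weight, making columns sum to 1; `"enrichment"` further divides
#' each row by the background residue frequency of the parent proteome,
#' so 1 means "no preference".
#'
#' @param events A `cleavage_events` data frame.
#' @param weighting `"intensity"` or `"count"`.
#' @param normalization `"frequency"` or `"enrichment"`.
#' @param background Named 20-vector from [background_composition()];
#'   required for enrichment.
#' @param condition Condition label stored in the result (defaults to the
#'   events' condition).
#' @return A `specificity_matrix` object.
#' @export
compute_specificity_matrix <- function(events,
                                       weighting = c("intensity", "count"),
                                       normalization = c("frequency",
                                                         "enrichment"),
                                       background = NULL,
                                       condition = attr(events, "condition")) {
  weighting <- match.arg(weighting)
  normalization <- match.arg(normalization)
  if (normalization == "enrichment" && is.null(background))
    stop("enrichment normalization requires a background composition")
  if (is.null(condition)) condition <- NA_character_

  w <- if (weighting == "count") rep(1, nrow(events)) else events$weight
  vals <- matrix(0, nrow = 20, ncol = 4,
                 dimnames = list(AA_ALPHABET, SUBSITES))
  total <- sum(w)
  if (nrow(events) > 0 && total > 0) {
    for (j in seq_along(SUBSITE_COLS)) {
      res <- factor(events[[SUBSITE_COLS[j]]], levels = AA_ALPHABET)
      vals[, j] <- as.numeric(tapply(w, res, sum, default = 0)) / total
    }
    if (normalization == "enrichment") {
      occ <- rowSums(vals) > 0
      zero_bg <- AA_ALPHABET[occ & background[AA_ALPHABET] == 0]
      if (length(zero_bg) > 0)
        stop("residue(s) observed at a subsite but absent from the ",
             "background: ", paste(zero_bg, collapse = ", "))
      vals <- vals / background[AA_ALPHABET]
      vals[!occ, ] <- 0
    }
  }
  new_specificity_matrix(vals, condition, weighting, normalization,
                         n_events = nrow(events),
                         total_weight = total)
}

#' Specificity matrix restricted to one parent protein
#'
#' Same computation as [compute_specificity_matrix()] on the subset of
#' events belonging to `protein_id`; lets cleavage signatures of
#' individual substrates (actin, troponin, myosin heavy chain, ...) be
#' compared across conditions.
#'
#' @inheritParams compute_specificity_matrix
#' @param protein_id Protein to keep.
#' @param proteins Optional [protein_set()]; when given, `protein_id`
#'   must exist there (a protein without events then yields a zero
#'   matrix).
#' @return A `specificity_matrix`.
#' @export
per_protein_specificity <- function(events, protein_id, proteins = NULL,
                                    weighting = c("intensity", "count"),
                                    normalization = c("frequency",
                                                      "enrichment"),
                                    background = NULL,
                                    condition = attr(events, "condition")) {
  known <- unique(events$protein_id)
  if (!is.null(proteins)) known <- union(known, proteins$id)
  if (!protein_id %in% known)
    stop("unknown protein id: ", protein_id)
  sub <- events[events$protein_id == protein_id, , drop = FALSE]
  class(sub) <- class(events)
  attr(sub, "condition") <- attr(events, "condition")
  compute_specificity_matrix(sub, weighting = weighting,
                             normalization = normalization,
                             background = background,
                             condition = condition)
}

#' Contrast two specificity matrices
#'
#' Cellwise difference `a - b` plus a ranking of (residue, subsite) cells
#' by absolute change — the view in which condition-specific protease
#' signatures (e.g. Trp at P2' after cooking, Cys at P1 only at 80 degC)
#' stand out. Both matrices must share weighting and normalization.
#'
#' @param a,b `specificity_matrix` objects.
#' @return A `specificity_contrast`: list with `difference` (20 x 4
#'   matrix), `ranking` (data frame `residue`, `subsite`, `delta`, sorted
#'   by `|delta|` descending, ties broken by subsite order then residue),
#'   and the two condition labels.
#' @export
compare_conditions <- function(a, b) {
  stopifnot(inherits(a, "specificity_matrix"),
            inherits(b, "specificity_matrix"))
  if (a$weighting != b$weighting || a$normalization != b$normalization)
    stop("matrices differ in weighting/normalization mode")
  d <- a$values - b$values
  rank_df <- data.frame(
    residue = rep(AA_ALPHABET, times = 4),
    subsite = rep(SUBSITES, each = 20),
    delta = as.numeric(d),
    stringsAsFactors = FALSE)
  ord <- order(-abs(rank_df$delta),
               match(rank_df$subsite, SUBSITES),
               rank_df$residue)
  rank_df <- rank_df[ord, , drop = FALSE]
  rownames(rank_df) <- NULL
  structure(list(difference = d, ranking = rank_df,
                 condition_a = a$condition, condition_b = b$condition,
                 weighting = a$weighting,
                 normalization = a$normalization),
            class = "specificity_contrast")
}

#' Export cleavage events as TSV
#'
#' @param events A `cleavage_events` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cleavage_events <- function(events, path) {
  df <- as.data.frame(events)
  names(df)[names(df) == "P1p"] <- "P1'"
  names(df)[names(df) == "P2p"] <- "P2'"
  df$condition <- attr(events, "condition")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a condition contrast as TSV
#'
#' @param contrast A `specificity_contrast` from [compare_conditions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contrast <- function(contrast, path) {
  stopifnot(inherits(contrast, "specificity_contrast"))
  utils::write.table(contrast$ranking, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.specificity_matrix <- function(x, ...) {
  cat("specificity_matrix [", x$condition, "] ", x$weighting, "/",
      x$normalization, ", ", x$n_events, " events, total weight ",
      format(x$total_weight, digits = 6), "\n", sep = "")
  print(round(x$values, 3))
  invisible(x)
}

#' @export
print.specificity_contrast <- function(x, ...) {
  cat("specificity_contrast:", x$condition_a, "-", x$condition_b, "(",
      x$weighting, "/", x$normalization, ")\n")
  print(utils::head(x$ranking, 8))
  invisible(x)
}
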