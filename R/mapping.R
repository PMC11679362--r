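#' Locate every occurrence of a peptide in a protein collection
#'
#' Exhaustive substring search including overlapping occurrences, with an
#' optional I/L-equivalent mode (MS cannot distinguish leucine from
#' isoleucine, so both letters are collapsed before matching). `X`
#' positions in a parent sequence match nothing.
#'
#' Coordinates are 0-based, half-open `[start, end)` — the cut position
#' convention used by the terminome module, where a cut at `c` severs the
#' bond between residues `c - 1` and `c`.
#'
#' @param sequence A single peptide sequence.
#' @param proteins A [protein_set()].
#' @param match_mode `"exact"` or `"IL"` (I/L-equivalent).
#' @return Data frame with columns `protein_id`, `start`, `end`, ordered
#'   by protein id then start; zero rows when the peptide does not occur.
#' @export
locate_peptide <- function(sequence, proteins,
                           match_mode = c("exact", "IL")) {
  match_mode <- match.arg(match_mode)
  stopifnot(inherits(proteins, "protein_set"))
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("empty peptide sequence")
  locate_many(sequence, proteins, match_mode)[[1]]
}

# Vectorized exhaustive substring search: for each peptide, every
# (overlapping) occurrence in every protein. Returns a list of data
# frames parallel to `peptides`.
locate_many <- function(peptides, proteins, match_mode = "exact") {
  subj <- proteins$sequence
  pats <- toupper(peptides)
  if (match_mode == "IL") {
    subj <- chartr("I", "L", subj)
    pats <- chartr("I", "L", pats)
  }
  # X denotes an unknown residue and matches nothing, not even another X:
  # map it to distinct sentinels on the two sides
  subj <- chartr("X", "!", subj)
  pats <- chartr("X", "?", pats)
  per_protein <- lapply(seq_along(subj), function(i)
    stringi::stri_locate_all_fixed(subj[i], pats, overlap = TRUE))
  lapply(seq_along(pats), function(j) {
    hits <- lapply(order(proteins$id), function(i) {
      m <- per_protein[[i]][[j]]
      if (is.na(m[1, 1])) return(NULL)
      data.frame(protein_id = proteins$id[i],
                 start = as.integer(m[, 1]) - 1L,
                 end = as.integer(m[, 2]),
                 stringsAsFactors = FALSE)
    })
    hits <- hits[!vapply(hits, is.null, logical(1))]
    if (length(hits) == 0)
      return(data.frame(protein_id = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE))
    out <- do.call(rbind, hits)
    out <- out[order(out$protein_id, out$start), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Map a peptidome onto its parent proteins
#'
#' Places each quantified peptide at every matching position and assigns
#' a mapping weight per site. Salmonid reference proteomes contain many
#' near-identical paralogs, so shared (multi-mapping) peptides are common;
#' the default `split_weight` policy apportions each peptide's intensity
#' equally over its sites, conserving total signal.
#'
#' Policies:
#' * `split_weight` — weight `1 / n_sites` per site (total weight 1);
#' * `discard_ambiguous` — drop peptides with more than one site;
#' * `keep_all_unit` — weight 1 at every site (diagnostics only: total
#'   intensity is inflated for shared peptides; flagged in the metadata).
#'
#' @param quant A [peptide_quant()] or character vector of peptide
#'   sequences.
#' @param proteins A [protein_set()].
#' @param policy Multi-mapping policy (see above).
#' @param match_mode `"exact"` or `"IL"` (see [locate_peptide()]).
#' @return A `located_peptides` data frame with columns `peptide`,
#'   `protein_id`, `start`, `end`, `weight`, `n_sites` and attributes
#'   `unmatched` (peptides with no site), `discarded` (ambiguous peptides
#'   dropped under `discard_ambiguous`), `policy`, `match_mode`,
#'   `weight_sum_valid`.
#' @export
map_peptidome <- function(quant, proteins,
                          policy = c("split_weight", "discard_ambiguous",
                                     "keep_all_unit"),
                          match_mode = c("exact", "IL")) {
  policy <- match.arg(policy)
  match_mode <- match.arg(match_mode)
  if (!inherits(proteins, "protein_set") || nrow(proteins) == 0)
    stop("empty protein collection")
  peptides <- if (inherits(quant, "peptide_quant"))
    quant_peptides(quant) else unique(as.character(quant))
  if (length(peptides) == 0)
    stop("no peptides to map")

  locs <- locate_many(peptides, proteins, match_mode)
  per_pep <- lapply(seq_along(peptides), function(i) {
    loc <- locs[[i]]
    if (nrow(loc) == 0) return(NULL)
    loc$peptide <- peptides[i]
    loc$n_sites <- nrow(loc)
    loc
  })
  unmatched <- peptides[vapply(per_pep, is.null, logical(1))]
  per_pep <- per_pep[!vapply(per_pep, is.null, logical(1))]
  if (length(unmatched) > 0)
    message(length(unmatched), " peptide(s) did not map to any protein")

  discarded <- character()
  if (length(per_pep) > 0 && policy == "discard_ambiguous") {
    ambig <- vapply(per_pep, function(d) d$n_sites[1] > 1L, logical(1))
    discarded <- vapply(per_pep[ambig], function(d) d$peptide[1], character(1))
    if (length(discarded) > 0)
      message(length(discarded),
              " ambiguous peptide(s) discarded (discard_ambiguous policy)")
    per_pep <- per_pep[!ambig]
  }

  if (length(per_pep) == 0) {
    out <- data.frame(peptide = character(), protein_id = character(),
                      start = integer(), end = integer(),
                      weight = numeric(), n_sites = integer(),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, per_pep)
    out$weight <- switch(policy,
                         split_weight = 1 / out$n_sites,
                         discard_ambiguous = 1,
                         keep_all_unit = 1)
    out <- out[, c("peptide", "protein_id", "start", "end", "weight",
                   "n_sites")]
    rownames(out) <- NULL
  }
  structure(out,
            unmatched = unmatched,
            discarded = discarded,
            policy = policy,
            match_mode = match_mode,
            weight_sum_valid = policy != "keep_all_unit",
            class = c("located_peptides", "data.frame"))
}

#' Export a mapped peptidome as TSV
#'
#' Columns: peptide, protein_id, start (0-based), end (exclusive),
#' weight, n_sites.
#'
#' @param located A `located_peptides` from [map_peptidome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_located_peptides <- function(located, path) {
  stopifnot(inherits(located, "located_peptides"))
  utils::write.table(as.data.frame(located), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.located_peptides <- function(x, ...) {
  cat("located_peptides:", nrow(x), "site(s) for",
      length(unique(x$peptide)), "peptide(s) on",
      length(unique(x$protein_id)), "protein(s)\n")
  cat("  policy:", attr(x, "policy"), "| match mode:",
      attr(x, "match_mode"), "| unmatched:", length(attr(x, "unmatched")),
      "\n")
  if (!isTRUE(attr(x, "weight_sum_valid")))
    cat("  NOTE: keep_all_unit weights do not sum to 1 per peptide\n")
  invisible(x)
}
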