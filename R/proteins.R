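#' Construct a validated protein collection
#'
#' A `protein_set` is a data frame with columns `id`, `description` and
#' `sequence` holding the parent proteins against which free peptides are
#' mapped (e.g. a Salmonidae reference proteome slice). Sequences are
#' upper-cased and must use the 20 canonical one-letter codes, plus `X`
#' for positions of unknown identity.
#'
#' @param id Character vector of unique, non-empty protein identifiers.
#' @param sequence Character vector of sequences, same length as `id`.
#' @param description Optional character vector of free-text descriptions.
#' @return A `protein_set` data frame.
#' @seealso [read_fasta()]
#' @export
protein_set <- function(id, sequence, description = "") {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(id) != length(sequence))
    stop("`id` and `sequence` must have the same length")
  if (length(id) == 0)
    stop("empty protein collection")
  if (any(!nzchar(id)))
    stop("protein ids must be non-empty")
  dup <- unique(id[duplicated(id)])
  if (length(dup) > 0)
    stop("duplicate protein id(s): ", paste(dup, collapse = ", "))
  if (any(!nzchar(sequence)))
    stop("empty sequence for protein(s): ",
         paste(id[!nzchar(sequence)], collapse = ", "))
  allowed <- c(AA_ALPHABET, "X")
  for (i in seq_along(sequence)) {
    chars <- unique(strsplit(sequence[i], "")[[1]])
    bad <- setdiff(chars, allowed)
    if (length(bad) > 0)
      stop("invalid residue(s) ", paste(bad, collapse = ", "),
           " in protein '", id[i], "'")
  }
  description <- rep_len(as.character(description), length(id))
  out <- data.frame(id = id, description = description,
                    sequence = sequence, stringsAsFactors = FALSE)
  class(out) <- c("protein_set", "data.frame")
  out
}

#' Read parent proteins from a FASTA file
#'
#' Headers are split at the first whitespace into an identifier and a
#' description. Lower-case sequence is accepted and normalized to upper
#' case. Duplicate identifiers, empty sequences and residues outside the
#' canonical alphabet (plus `X`) are hard errors.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return A [protein_set()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aas <- Biostrings::readBStringSet(path)
  if (length(aas) == 0) stop("no records in FASTA file: ", path)
  headers <- names(aas)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  protein_set(id = ids, sequence = as.character(aas), description = desc)
}

#' Write a protein collection to FASTA
#'
#' @param proteins A [protein_set()].
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  stopifnot(inherits(proteins, "protein_set"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(proteins))) {
    hdr <- if (nzchar(proteins$description[i]))
      paste(proteins$id[i], proteins$description[i]) else proteins$id[i]
    writeLines(paste0(">", hdr), con)
    s <- proteins$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Background residue composition of a proteome
#'
#' Frequencies of the 20 canonical residues over the (optionally
#' restricted) parent proteins, the denominator for enrichment-normalized
#' specificity matrices. `X` positions are ignored.
#'
#' @param proteins A [protein_set()].
#' @param restrict_to_ids Optional character vector of protein ids to pool.
#' @return Named numeric vector over [AA_ALPHABET], summing to 1.
#' @export
background_composition <- function(proteins, restrict_to_ids = NULL) {
  stopifnot(inherits(proteins, "protein_set"))
  if (!is.null(restrict_to_ids)) {
    missing_ids <- setdiff(restrict_to_ids, proteins$id)
    if (length(missing_ids) > 0)
      stop("unknown protein id(s): ", paste(missing_ids, collapse = ", "))
    proteins <- proteins[proteins$id %in% restrict_to_ids, , drop = FALSE]
  }
  chars <- unlist(seq_chars(proteins$sequence), use.names = FALSE)
  chars <- chars[chars != "X"]
  if (length(chars) == 0)
    stop("no canonical residues in the selected proteins")
  counts <- table(factor(chars, levels = AA_ALPHABET))
  freq <- as.numeric(counts) / length(chars)
  names(freq) <- AA_ALPHABET
  freq
}

#' Generate random parent proteins
#'
#' Draws sequences with residues sampled uniformly over the 20 canonical
#' amino acids — the neutral substrate used by simulation-based recovery
#' tests, where any compositional bias at reconstructed cut sites must
#' come from the protease model, not the substrate.
#'
#' @param n Number of proteins.
#' @param length Protein length in residues (recycled to `n`).
#' @param prefix Identifier prefix; ids are `prefix1 ... prefixN`.
#' @return A [protein_set()]. Uses the current RNG stream.
#' @export
random_proteins <- function(n, length = 300L, prefix = "prot") {
  length <- rep_len(as.integer(length), n)
  seqs <- vapply(length, function(L)
    paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = ""),
    character(1))
  protein_set(id = paste0(prefix, seq_len(n)), sequence = seqs,
              description = "synthetic random protein")
}

#' @export
print.protein_set <- function(x, ...) {
  cat("protein_set with", nrow(x), "sequence(s),",
      sum(nchar(x$sequence)), "residues total\n")
  utils::str(utils::head(data.frame(id = x$id, length = nchar(x$sequence))))
  invisible(x)
}
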