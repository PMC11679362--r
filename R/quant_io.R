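#' Build a peptide quantification table
#'
#' The in-memory representation of a DIA/SWATH-style peptide
#' quantification export: one row per (peptide, condition, replicate)
#' with a single identification confidence per peptide. Intensities are
#' label-free areas in arbitrary units; a peptide not detected in a
#' replicate carries intensity 0 (DIA non-detection is treated as
#' below-limit, not missing at random, so downstream sums stay defined).
#'
#' @param peptide,confidence,condition,replicate,intensity Parallel
#'   vectors in long format.
#' @param conditions Optional ordered condition labels (defaults to order
#'   of first appearance).
#' @return A `peptide_quant` data frame (long format) with attributes
#'   `conditions` and `n_filtered`.
#' @export
peptide_quant <- function(peptide, confidence, condition, replicate,
                          intensity, conditions = NULL) {
  df <- data.frame(peptide = as.character(peptide),
                   confidence = as.numeric(confidence),
                   condition = as.character(condition),
                   replicate = as.integer(replicate),
                   intensity = as.numeric(intensity),
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0) {
    if (any(!nzchar(df$peptide))) stop("empty peptide sequence")
    if (any(is.na(df$confidence)))
      stop("non-numeric or missing confidence value")
    if (any(df$confidence < 0 | df$confidence > 1))
      stop("confidence must lie in [0, 1]")
    df$intensity[is.na(df$intensity)] <- 0
    if (any(df$intensity < 0)) stop("negative intensity value")
    conf_by_pep <- tapply(df$confidence, df$peptide,
                          function(v) length(unique(v)))
    if (any(conf_by_pep > 1))
      stop("a peptide must carry a single confidence value")
  }
  if (is.null(conditions)) conditions <- unique(df$condition)
  if (anyDuplicated(conditions)) stop("duplicate condition labels")
  structure(df,
            conditions = conditions,
            n_filtered = 0L,
            class = c("peptide_quant", "data.frame"))
}

#' Conditions present in a peptide quantification table
#' @param quant A `peptide_quant`.
#' @return Character vector of condition labels in report order.
#' @export
quant_conditions <- function(quant) attr(quant, "conditions")

#' Distinct peptides in a quantification table
#' @param quant A `peptide_quant`.
#' @return Character vector of peptide sequences.
#' @export
quant_peptides <- function(quant) unique(quant$peptide)

# Guess field separator from the file extension.
guess_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a peptide quantification table and apply the confidence filter
#'
#' Reads a PeakView-style wide export (columns `peptide`, `confidence`,
#' then one intensity column per condition x replicate named
#' `<condition>_r<k>`) or an equivalent long table (columns `peptide`,
#' `confidence`, `condition`, `replicate`, `intensity`); the layout is
#' detected from the column names. Peptides with identification
#' confidence below `confidence_threshold` are removed on load, the
#' standard quality gate for SWATH quantification. Confidence given in
#' percent (max value > 1) is rescaled to a fraction with a warning.
#'
#' @param path Path to a TSV/CSV file (separator guessed from extension).
#' @param confidence_threshold Minimum retained confidence, fraction in
#'   \[0, 1\]. Default 0.95.
#' @return A [peptide_quant()]; attribute `n_filtered` records how many
#'   peptides the confidence filter removed.
#' @export
read_peptide_quant <- function(path, confidence_threshold = 0.95) {
  if (!file.exists(path)) stop("quantification table not found: ", path)
  stopifnot(is.numeric(confidence_threshold),
            confidence_threshold >= 0, confidence_threshold <= 1)
  raw <- utils::read.table(path, sep = guess_sep(path), header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "\"", comment.char = "")
  cols <- names(raw)
  long_cols <- c("peptide", "confidence", "condition", "replicate",
                 "intensity")
  if (all(long_cols %in% cols)) {
    df <- raw[long_cols]
  } else {
    if (!"peptide" %in% cols) stop("missing required column: peptide")
    if (!"confidence" %in% cols) stop("missing required column: confidence")
    int_cols <- grep("^.+_r[0-9]+$", cols, value = TRUE)
    int_cols <- setdiff(int_cols, c("peptide", "confidence"))
    if (length(int_cols) == 0)
      stop("no intensity columns of the form <condition>_r<k> found")
    ignored <- setdiff(cols, c("peptide", "confidence", int_cols))
    if (length(ignored) > 0)
      warning("ignoring unrecognized column(s): ",
              paste(ignored, collapse = ", "))
    condition <- sub("_r[0-9]+$", "", int_cols)
    replicate <- as.integer(sub("^.*_r([0-9]+)$", "\\1", int_cols))
    blocks <- lapply(seq_along(int_cols), function(j) {
      v <- raw[[int_cols[j]]]
      if (!is.numeric(v)) {
        v2 <- suppressWarnings(as.numeric(v))
        if (any(is.na(v2) & !is.na(v) & nzchar(trimws(as.character(v)))))
          stop("non-numeric intensity in column ", int_cols[j])
        v <- v2
      }
      data.frame(peptide = raw$peptide, confidence = raw$confidence,
                 condition = condition[j], replicate = replicate[j],
                 intensity = v, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, blocks)
    attr(df, "condition_order") <- unique(condition)
  }
  conf <- df$confidence
  if (!is.numeric(conf)) {
    conf2 <- suppressWarnings(as.numeric(conf))
    if (any(is.na(conf2)))
      stop("non-numeric confidence value(s) in table")
    conf <- conf2
  }
  if (any(is.na(conf))) stop("missing confidence value(s) in table")
  if (max(conf) > 1) {
    warning("confidence appears to be in percent (max > 1); rescaling by 1/100")
    conf <- conf / 100
  }
  df$confidence <- conf
  if (any(df$intensity < 0, na.rm = TRUE)) stop("negative intensity value")

  keep_pep <- unique(df$peptide[df$confidence >= confidence_threshold])
  n_total <- length(unique(df$peptide))
  n_drop <- n_total - length(keep_pep)
  if (n_drop > 0)
    message(n_drop, " of ", n_total,
            " peptide(s) removed by confidence filter (threshold ",
            confidence_threshold, ")")
  df <- df[df$peptide %in% keep_pep, , drop = FALSE]
  cond_order <- attr(df, "condition_order")
  if (is.null(cond_order)) cond_order <- unique(df$condition)
  out <- peptide_quant(df$peptide, df$confidence, df$condition,
                       df$replicate, df$intensity,
                       conditions = cond_order)
  attr(out, "n_filtered") <- n_drop
  attr(out, "n_read") <- n_total
  out
}

#' Write a peptide quantification table in wide (PeakView-like) layout
#'
#' @param quant A [peptide_quant()].
#' @param path Output path; `.csv` writes comma-separated, else tabs.
#' @return `path`, invisibly.
#' @export
write_peptide_quant <- function(quant, path) {
  stopifnot(inherits(quant, "peptide_quant"))
  conds <- quant_conditions(quant)
  key <- paste0(quant$condition, "_r", quant$replicate)
  col_order <- unlist(lapply(conds, function(cn) {
    reps <- sort(unique(quant$replicate[quant$condition == cn]))
    paste0(cn, "_r", reps)
  }))
  peps <- quant_peptides(quant)
  wide <- data.frame(peptide = peps,
                     confidence = quant$confidence[match(peps, quant$peptide)],
                     stringsAsFactors = FALSE, check.names = FALSE)
  for (cl in col_order) {
    v <- numeric(length(peps))
    sel <- key == cl
    v[match(quant$peptide[sel], peps)] <- quant$intensity[sel]
    wide[[cl]] <- v
  }
  utils::write.table(wide, path, sep = guess_sep(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Aggregate replicate intensities of each peptide within one condition
#'
#' The three SWATH injections are technical replicates of one sample per
#' condition, so the default summary is their mean.
#'
#' @param quant A [peptide_quant()].
#' @param condition Condition label.
#' @param method One of `"mean"`, `"median"`, `"sum"`.
#' @return Named numeric vector, one non-negative value per peptide
#'   present in `quant` (peptides never observed in `condition` get 0).
#' @export
aggregate_condition_intensity <- function(quant, condition,
                                          method = c("mean", "median", "sum")) {
  stopifnot(inherits(quant, "peptide_quant"))
  method <- match.arg(method)
  if (!condition %in% quant_conditions(quant))
    stop("condition '", condition, "' not present in quantification table")
  fun <- switch(method, mean = mean, median = stats::median, sum = sum)
  peps <- quant_peptides(quant)
  sel <- quant$condition == condition
  agg <- tapply(quant$intensity[sel], factor(quant$peptide[sel], levels = peps),
                fun)
  out <- as.numeric(agg)
  out[is.na(out)] <- 0
  names(out) <- peps
  out
}

#' @export
print.peptide_quant <- function(x, ...) {
  cat("peptide_quant:", length(quant_peptides(x)), "peptide(s) x",
      length(quant_conditions(x)), "condition(s) [",
      paste(quant_conditions(x), collapse = ", "), "]\n")
  cat("  confidence-filtered on load:", attr(x, "n_filtered"), "\n")
  invisible(x)
}
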