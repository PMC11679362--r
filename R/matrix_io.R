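#' Write a specificity matrix to TSV
#'
#' Serializes the 20 x 4 matrix with residues in the fixed alphabetical
#' row order and subsite columns P2, P1, P1', P2'. Metadata (condition,
#' weighting, normalization, event count, total weight) is stored in
#' `#`-prefixed header lines so the file round-trips losslessly through
#' [read_specificity_matrix()]. Values are written with 15 significant
#' digits.
#'
#' @param matrix A `specificity_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_specificity_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "specificity_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(condition = matrix$condition,
            weighting = matrix$weighting,
            normalization = matrix$normalization,
            n_events = as.character(matrix$n_events),
            total_weight = sprintf("%.15g", matrix$total_weight))
  writeLines(paste0("# ", names(meta), "=", meta), con)
  writeLines(paste(c("residue", SUBSITES), collapse = "\t"), con)
  for (i in seq_len(20)) {
    writeLines(paste(c(AA_ALPHABET[i],
                       sprintf("%.15g", matrix$values[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a specificity matrix written by [write_specificity_matrix()]
#'
#' @param path Path to a matrix TSV.
#' @return A `specificity_matrix`.
#' @export
read_specificity_matrix <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ml), "=", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- paste(kv[-1], collapse = "=")
  }
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.table(text = body, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "")   # P1'/P2' contain an apostrophe
  if (!identical(df$residue, AA_ALPHABET))
    stop("matrix file does not contain the 20 canonical residues in ",
         "the expected order")
  vals <- as.matrix(df[, SUBSITES])
  rownames(vals) <- AA_ALPHABET
  new_specificity_matrix(vals,
                         condition = meta$condition %||% NA_character_,
                         weighting = meta$weighting %||% "intensity",
                         normalization = meta$normalization %||% "frequency",
                         n_events = as.integer(meta$n_events %||% NA),
                         total_weight = as.numeric(meta$total_weight %||% NA))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render a specificity matrix as a heatmap
#'
#' 20 rows (residues, alphabetical top to bottom) by 4 columns (P2-P2'),
#' the standard terminome display. Frequency-mode matrices are shown on a
#' column-stochastic scale (columns renormalized to sum to 1, a no-op for
#' valid input), so the rendering is invariant to rescaling all
#' intensities. The fill legend is labelled with the normalization mode.
#'
#' @param matrix A `specificity_matrix`.
#' @param path Output image path (`.png` or `.svg` by extension).
#' @param width,height,dpi Device geometry passed to [ggplot2::ggsave()].
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(matrix, path, width = 3.2, height = 6,
                           dpi = 150) {
  stopifnot(inherits(matrix, "specificity_matrix"))
  vals <- matrix$values
  if (matrix$normalization == "frequency") {
    cs <- colSums(vals)
    nz <- cs > 0
    vals[, nz] <- sweep(vals[, nz, drop = FALSE], 2, cs[nz], "/")
  }
  df <- data.frame(
    residue = factor(rep(rownames(vals), times = 4), levels = rev(AA_ALPHABET)),
    subsite = factor(rep(SUBSITES, each = 20), levels = SUBSITES),
    value = as.numeric(vals))
  ttl <- if (is.na(matrix$condition)) "specificity" else matrix$condition
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$subsite,
                                        y = .data$residue,
                                        fill = .data$value)) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::scale_fill_gradient(low = "white", high = "#b2182b",
                                 name = matrix$normalization) +
    ggplot2::labs(title = ttl, x = "subsite", y = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
  ggplot2::ggsave(path, p, width = width, height = height, dpi = dpi)
  invisible(path)
}
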