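#' Expression matrix with transcript metadata
#'
#' Container for a transcripts x tissues matrix of non-negative expression
#' values (FPKM/TPM scale) together with per-transcript metadata. This is the
#' object every downstream stage (specificity, categorization, orthology,
#' TSS profiling) consumes.
#'
#' @param values Numeric matrix, transcripts in rows, tissues in columns.
#'   Row names are transcript identifiers, column names tissue names.
#' @param meta Data frame with one row per transcript and columns
#'   `transcript_id`, `gene_id`, `exon_count`, `biotype`
#'   (`"coding"`/`"noncoding"`). Rows are matched to `values` by
#'   `transcript_id`.
#' @param species Single character tag carried through cross-species joins.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `meta` and `species`.
#' @export
ExpressionMatrix <- function(values, meta, species = NA_character_) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have transcript row names and tissue column names")
  if (ncol(values) < 2L)
    stop("an expression matrix needs at least 2 tissues")
  if (anyDuplicated(rownames(values)))
    stop("duplicate transcript ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate tissue names")
  if (any(values < 0, na.rm = TRUE))
    stop("expression values must be non-negative")
  if (anyNA(values)) {
    n_na <- sum(is.na(values))
    message(n_na, " missing expression cells treated as 0")
    values[is.na(values)] <- 0
  }
  meta <- as.data.frame(meta)
  required <- c("transcript_id", "gene_id")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols))
    stop("meta lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (!all(rownames(values) %in% meta$transcript_id))
    stop("every transcript needs a meta row with a gene_id")
  meta <- meta[match(rownames(values), meta$transcript_id), , drop = FALSE]
  rownames(meta) <- NULL
  if (is.null(meta$exon_count)) meta$exon_count <- NA_integer_
  if (is.null(meta$biotype)) meta$biotype <- NA_character_
  if (any(stats::na.omit(meta$exon_count) < 1L))
    stop("exon_count must be >= 1")
  structure(list(values = values, meta = meta, species = species),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d transcripts x %d tissues (species: %s)\n",
              nrow(x$values), ncol(x$values), x$species))
  cat("tissues:", paste(utils::head(colnames(x$values), 8), collapse = ", "),
      if (ncol(x$values) > 8) "...\n" else "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Tissue names of an expression matrix
#' @param x An `ExpressionMatrix`.
#' @return Character vector of tissue names.
#' @export
tissue_names <- function(x) colnames(x$values)

#' Transcript identifiers of an expression matrix
#' @param x An `ExpressionMatrix`.
#' @return Character vector of transcript ids, in row order.
#' @export
transcript_ids <- function(x) rownames(x$values)

# Subset an ExpressionMatrix by transcript (rows kept in given order).
subset_transcripts <- function(x, keep) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  values <- x$values[keep, , drop = FALSE]
  meta <- x$meta[match(rownames(values), x$meta$transcript_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(values = values, meta = meta, species = x$species),
            class = "ExpressionMatrix")
}
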