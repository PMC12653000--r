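#' Raw tissue-specificity index
#'
#' For each transcript, the expression value in each tissue is standardized
#' against that transcript's own cross-tissue distribution:
#' \deqn{x_i = \frac{e_i - \bar e}{\sqrt{\frac{1}{n-1}\sum_j (e_j - \bar e)^2}}}
#' where \eqn{e_i} is the expression in tissue \eqn{i}, \eqn{\bar e} the mean
#' over the \eqn{n} tissues and the denominator the sample standard
#' deviation. A transcript expressed in a single tissue attains the maximal
#' value \eqn{(n-1)/\sqrt{n}} there. Constant rows (sd = 0, including all
#' zeros) are defined as 0 in every tissue: such transcripts are maximally
#' non-specific, and the convention avoids 0/0.
#'
#' @param expr An [ExpressionMatrix] with at least 2 tissues.
#' @return An object of class `SpecificityMatrix`: list with `raw`
#'   (transcripts x tissues), `normalized` (`NULL` until
#'   [normalize_maxabs()] is applied), `transcript_ids`, `tissue_names`,
#'   `species`.
#' @export
specificity_raw <- function(expr) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  E <- expr$values
  if (ncol(E) < 2L) stop("specificity needs at least 2 tissues")
  mu <- rowMeans(E)
  sdv <- apply(E, 1, stats::sd)
  raw <- (E - mu) / sdv
  raw[sdv == 0, ] <- 0
  structure(list(raw = raw, normalized = NULL,
                 transcript_ids = rownames(E),
                 tissue_names = colnames(E),
                 species = expr$species),
            class = "SpecificityMatrix")
}

#' @export
print.SpecificityMatrix <- function(x, ...) {
  cat(sprintf("SpecificityMatrix: %d transcripts x %d tissues (%s)\n",
              length(x$transcript_ids), length(x$tissue_names),
              if (is.null(x$normalized)) "raw only" else "normalized"))
  invisible(x)
}

#' Scale raw specificity indices to [-1, 1]
#'
#' Max-abs scaling: each value is divided by the largest absolute raw index
#' of its tissue column (the default, matching feature-wise scaling where
#' each tissue is a feature), so 1 marks the most specific transcript of
#' that tissue. `scope = "global"` divides the whole matrix by its single
#' largest absolute value instead. Columns (or matrices) that are entirely
#' zero stay zero.
#'
#' @param spec A `SpecificityMatrix` from [specificity_raw()].
#' @param scope `"column"` (default) or `"global"`.
#' @return The `SpecificityMatrix` with `normalized` filled.
#' @export
normalize_maxabs <- function(spec, scope = c("column", "global")) {
  stopifnot(inherits(spec, "SpecificityMatrix"))
  scope <- match.arg(scope)
  raw <- spec$raw
  if (scope == "column") {
    mx <- apply(abs(raw), 2, max)
    mx[mx == 0] <- 1
    spec$normalized <- sweep(raw, 2, mx, "/")
  } else {
    mx <- max(abs(raw))
    spec$normalized <- if (mx == 0) raw else raw / mx
  }
  spec$scope <- scope
  spec
}

#' Convenience wrapper: raw index plus max-abs normalization
#' @inheritParams specificity_raw
#' @inheritParams normalize_maxabs
#' @return A normalized `SpecificityMatrix`.
#' @export
specificity <- function(expr, scope = "column")
  normalize_maxabs(specificity_raw(expr), scope = scope)

#' Per-transcript specificity summaries
#'
#' @param spec A normalized `SpecificityMatrix`.
#' @return Data frame with `transcript_id`, `max_specificity`,
#'   `median_specificity` and `top_tissue` (the argmax tissue; ties broken
#'   by lexicographic tissue-name order for reproducibility).
#' @export
summarize_transcripts <- function(spec) {
  N <- need_normalized(spec)
  ord <- order(spec$tissue_names)      # lexicographic tie-break
  No <- N[, ord, drop = FALSE]
  top <- spec$tissue_names[ord][max.col(No, ties.method = "first")]
  data.frame(
    transcript_id = spec$transcript_ids,
    max_specificity = apply(N, 1, max),
    median_specificity = apply(N, 1, stats::median),
    top_tissue = top,
    stringsAsFactors = FALSE
  )
}

#' Category boundaries on the normalized specificity scale
#'
#' Defaults reproduce the four-way split used throughout the package:
#' underrepresented (below -0.20), general (-0.20 to 0.00), enriched
#' (above 0 up to 0.80) and highly enriched (above 0.80).
#'
#' @param under_max,general_max,enriched_max Strictly increasing boundaries,
#'   all below 1.
#' @return List of class `category_thresholds`.
#' @export
category_thresholds <- function(under_max = -0.20, general_max = 0.00,
                                enriched_max = 0.80) {
  if (!(under_max < general_max && general_max < enriched_max &&
        enriched_max < 1))
    stop("thresholds must satisfy under_max < general_max < enriched_max < 1")
  structure(list(under_max = under_max, general_max = general_max,
                 enriched_max = enriched_max),
            class = "category_thresholds")
}

#' Specificity category labels
#' @return The four labels in increasing-specificity order.
#' @export
specificity_categories <- function()
  c("underrepresented", "general", "enriched", "highly_enriched")

#' Assign each (transcript, tissue) cell to a specificity category
#'
#' Boundary handling mirrors the category wording: underrepresented is
#' strictly below `under_max`; general is the closed interval
#' `[under_max, general_max]`; enriched is `(general_max, enriched_max]`;
#' highly enriched is strictly above `enriched_max`.
#'
#' @param spec A normalized `SpecificityMatrix`.
#' @param thresholds A [category_thresholds()] object.
#' @return A character matrix (transcripts x tissues) of class
#'   `category_assignment` with the thresholds attached as an attribute.
#' @export
assign_categories <- function(spec, thresholds = category_thresholds()) {
  N <- need_normalized(spec)
  lab <- matrix(specificity_categories()[2], nrow(N), ncol(N),
                dimnames = dimnames(N))
  lab[N < thresholds$under_max] <- "underrepresented"
  lab[N > thresholds$general_max] <- "enriched"
  lab[N > thresholds$enriched_max] <- "highly_enriched"
  structure(lab, class = c("category_assignment", class(lab)),
            thresholds = thresholds)
}

#' Count transcripts enriched above a threshold in one tissue
#'
#' @param spec A normalized `SpecificityMatrix`.
#' @param tissue Tissue name (must exist in the matrix).
#' @param threshold Normalized specificity cut; strictly exceeded values
#'   count. Default 0.8, the highly-enriched boundary.
#' @return List with `count` and `fraction` (of all transcripts).
#' @export
count_enriched <- function(spec, tissue, threshold = 0.8) {
  N <- need_normalized(spec)
  if (!tissue %in% spec$tissue_names)
    stop("unknown tissue: ", tissue)
  cnt <- sum(N[, tissue] > threshold)
  list(count = cnt, fraction = cnt / nrow(N))
}

#' Recompute specificity after excluding tissues
#'
#' Drops the given tissue columns and recomputes the raw index and the
#' normalization from scratch on the reduced matrix, so `n` in the formula
#' becomes the remaining tissue count. Used to probe how much redundant
#' tissues (e.g. head/eye alongside brain) dilute the index.
#'
#' @param expr An [ExpressionMatrix].
#' @param excluded Character vector of tissue names to drop (all must
#'   exist); at least two tissues must remain.
#' @param scope Normalization scope, see [normalize_maxabs()].
#' @return A normalized `SpecificityMatrix` over the remaining tissues.
#' @export
exclude_tissues_recompute <- function(expr, excluded, scope = "column") {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  unknown <- setdiff(excluded, colnames(expr$values))
  if (length(unknown))
    stop("unknown tissue(s): ", paste(unknown, collapse = ", "))
  keep <- setdiff(colnames(expr$values), excluded)
  if (length(keep) < 2L)
    stop("fewer than 2 tissues would remain")
  sub <- ExpressionMatrix(expr$values[, keep, drop = FALSE], expr$meta,
                          species = expr$species)
  specificity(sub, scope = scope)
}

#' Drop low-expressing transcripts
#'
#' Keeps transcripts whose maximum expression across tissues is at least
#' `min_value`. The maximum (rather than the mean) is used so that
#' tissue-restricted transcripts, which are near zero almost everywhere,
#' are not penalized for their restriction.
#'
#' @param expr An [ExpressionMatrix].
#' @param min_value Expression floor on the FPKM/TPM scale (default 5).
#' @return The filtered [ExpressionMatrix] (possibly with zero rows).
#' @export
filter_by_expression <- function(expr, min_value = 5) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  keep <- apply(expr$values, 1, max) >= min_value
  subset_transcripts(expr, which(keep))
}

#' Export the per-transcript specificity table as TSV
#'
#' One row per transcript: gene id, per-tissue normalized specificity,
#' max/median summaries, argmax tissue, and per-tissue category labels.
#'
#' @param spec A normalized `SpecificityMatrix`.
#' @param expr The source [ExpressionMatrix] (for gene ids).
#' @param assign Optional `category_assignment` for the same matrix.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
export_specificity_table <- function(spec, expr, assign = NULL, path) {
  smry <- summarize_transcripts(spec)
  out <- data.frame(transcript_id = spec$transcript_ids,
                    gene_id = expr$meta$gene_id[
                      match(spec$transcript_ids, expr$meta$transcript_id)],
                    stringsAsFactors = FALSE)
  N <- need_normalized(spec)
  colnames_spec <- paste0("spec_", spec$tissue_names)
  out[colnames_spec] <- as.data.frame(N)
  out$max_specificity <- smry$max_specificity
  out$median_specificity <- smry$median_specificity
  out$top_tissue <- smry$top_tissue
  if (!is.null(assign))
    out[paste0("category_", spec$tissue_names)] <-
      as.data.frame(unclass(assign))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

need_normalized <- function(spec) {
  stopifnot(inherits(spec, "SpecificityMatrix"))
  if (is.null(spec$normalized))
    stop("normalized specificity missing; run normalize_maxabs() first")
  spec$normalized
}
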