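#' Filter ortholog links by database-support score
#'
#' Keeps pairs supported by at least `min_score` of the ortholog-prediction
#' databases (DIOPT-style integer support counts; the default 12 of 14 is a
#' strict cutoff). The cutoff is inclusive.
#'
#' @param links `pair_table` of kind `"ortholog"` (or any data frame with
#'   `id_a`, `id_b`, `score`).
#' @param min_score Minimum support count retained.
#' @return The filtered links, same class.
#' @export
filter_orthologs <- function(links, min_score = 12) {
  stopifnot(all(c("id_a", "id_b", "score") %in% names(links)))
  if (any(is.na(links$score))) stop("ortholog links must carry scores")
  out <- links[links$score >= min_score, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-gene summary for a focal tissue
#'
#' Collapses transcripts to genes for cross-species joining. By default a
#' gene is represented by its transcript with maximal normalized
#' specificity in the focal tissue (preserving the enrichment signal);
#' `aggregate = "mean"` averages across the gene's transcripts instead.
#'
#' @param expr An [ExpressionMatrix].
#' @param spec The matching normalized `SpecificityMatrix`.
#' @param tissue Focal tissue name.
#' @param aggregate `"top_transcript"` (default) or `"mean"`.
#' @return Data frame with `gene_id`, `expression` (in the tissue),
#'   `specificity`, `exon_count`, `transcript_count`.
#' @export
gene_tissue_summary <- function(expr, spec, tissue,
                                aggregate = c("top_transcript", "mean")) {
  aggregate <- match.arg(aggregate)
  N <- need_normalized(spec)
  if (!tissue %in% colnames(N)) stop("unknown tissue: ", tissue)
  s <- N[, tissue]
  e <- expr$values[, tissue]
  meta <- expr$meta
  split_idx <- split(seq_along(s), meta$gene_id)
  rows <- lapply(names(split_idx), function(g) {
    idx <- split_idx[[g]]
    if (aggregate == "top_transcript") {
      top <- idx[which.max(s[idx])]
      data.frame(gene_id = g, expression = e[top], specificity = s[top],
                 exon_count = meta$exon_count[top],
                 transcript_count = length(idx), stringsAsFactors = FALSE)
    } else {
      data.frame(gene_id = g, expression = mean(e[idx]),
                 specificity = mean(s[idx]),
                 exon_count = mean(meta$exon_count[idx]),
                 transcript_count = length(idx), stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Join two species' gene summaries across ortholog links
#'
#' One output row per surviving ortholog pair; many-to-many links produce
#' one row per pair. Links whose gene is absent from either summary are
#' dropped, with the counts reported via message.
#'
#' @param summary_a,summary_b Outputs of [gene_tissue_summary()] for
#'   species A and B.
#' @param links Ortholog `pair_table` (`id_a` in species A, `id_b` in B),
#'   typically pre-filtered with [filter_orthologs()].
#' @return Data frame with columns `gene_a`, `gene_b`, `score` and the
#'   summary columns suffixed `_a` / `_b`.
#' @export
join_cross_species <- function(summary_a, summary_b, links) {
  la <- links$id_a %in% summary_a$gene_id
  lb <- links$id_b %in% summary_b$gene_id
  if (any(!la | !lb))
    message("dropped ", sum(!la), " link(s) missing in species A and ",
            sum(!lb), " missing in species B")
  kept <- links[la & lb, , drop = FALSE]
  a <- summary_a[match(kept$id_a, summary_a$gene_id), , drop = FALSE]
  b <- summary_b[match(kept$id_b, summary_b$gene_id), , drop = FALSE]
  out <- data.frame(gene_a = kept$id_a, gene_b = kept$id_b,
                    score = kept$score, stringsAsFactors = FALSE)
  for (col in c("expression", "specificity", "exon_count",
                "transcript_count")) {
    out[[paste0(col, "_a")]] <- a[[col]]
    out[[paste0(col, "_b")]] <- b[[col]]
  }
  rownames(out) <- NULL
  out
}

#' Genes owning at least one highly enriched transcript, per tissue
#'
#' @param assign A `category_assignment`.
#' @param meta Per-transcript metadata with `transcript_id` and `gene_id`
#'   (e.g. `expr$meta`).
#' @return Named list: for each tissue, the character set of genes with
#'   >= 1 transcript labelled `highly_enriched` there.
#' @export
highly_enriched_gene_sets <- function(assign, meta) {
  stopifnot(inherits(assign, "category_assignment"))
  genes <- meta$gene_id[match(rownames(assign), meta$transcript_id)]
  sets <- lapply(colnames(assign), function(tis)
    sort(unique(genes[assign[, tis] == "highly_enriched"])))
  names(sets) <- colnames(assign)
  sets
}

#' Exact region decomposition of 2 or 3 named sets
#'
#' Computes the disjoint Venn regions (exclusive parts, pairwise-only
#' intersections, and for three sets the center), with counts and, for
#' each region, the percentage it represents of every participating set
#' (the style of "22 (18.64%) of the brain set also in the testis set").
#'
#' @param sets Named list of 2 or 3 character vectors (deduplicated
#'   internally).
#' @return List of class `venn_result`: `regions` (named list of members;
#'   region names join set names with `&`), `counts`, `set_sizes`, and
#'   `percent` (region x set matrix, `NA` for non-participating sets).
#' @export
venn_overlap <- function(sets) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == ""))
    stop("`sets` must be a named list")
  if (length(sets) < 2L || length(sets) > 3L)
    stop("venn_overlap supports 2 or 3 sets")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  nm <- names(sets)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1,
                                               dimnames = list(NULL, nm))
  pattern <- apply(member, 1, function(row) paste(nm[row], collapse = "&"))
  all_patterns <- unlist(lapply(seq_along(nm), function(k)
    utils::combn(nm, k, paste, collapse = "&")))
  regions <- lapply(all_patterns, function(p) universe[pattern == p])
  names(regions) <- all_patterns
  counts <- lengths(regions)
  set_sizes <- lengths(sets)
  percent <- matrix(NA_real_, length(all_patterns), length(nm),
                    dimnames = list(all_patterns, nm))
  for (p in all_patterns) {
    involved <- strsplit(p, "&", fixed = TRUE)[[1]]
    for (s in involved)
      percent[p, s] <- round_half_up(100 * counts[[p]] / set_sizes[[s]], 2)
  }
  structure(list(regions = regions, counts = counts,
                 set_sizes = set_sizes, percent = percent),
            class = "venn_result")
}

#' @export
print.venn_result <- function(x, ...) {
  cat("venn_result:\n")
  print(x$counts)
  invisible(x)
}

#' Disease association summary for a gene set
#'
#' A gene counts as disease-associated once, regardless of how many
#' disease terms it maps to. The percentage is rounded half-up to one
#' decimal (318-gene set with 118 associated genes prints 37.1).
#'
#' @param gene_set Character vector of genes.
#' @param disease_table `pair_table` of kind `"disease"` (`id_a` = gene,
#'   `id_b` = disease term) or an equivalent data frame.
#' @return List of class `disease_summary`: `size`, `n_associated`,
#'   `percent`, `per_disease` (genes of the set per term) and
#'   `associated_genes`.
#' @export
disease_summary <- function(gene_set, disease_table) {
  gene_set <- unique(as.character(gene_set))
  hits <- disease_table[disease_table$id_a %in% gene_set, , drop = FALSE]
  assoc <- unique(hits$id_a)
  per_disease <- if (nrow(hits))
    sort(vapply(split(hits$id_a, hits$id_b),
                function(g) length(unique(g)), integer(1)),
         decreasing = TRUE)
  else integer(0)
  pct <- if (length(gene_set) == 0) 0
         else round_half_up(100 * length(assoc) / length(gene_set), 1)
  structure(list(size = length(gene_set), n_associated = length(assoc),
                 percent = pct, per_disease = per_disease,
                 associated_genes = sort(assoc)),
            class = "disease_summary")
}

#' @export
print.disease_summary <- function(x, ...) {
  cat(sprintf("disease_summary: %.1f%% (%d out of %d genes)\n",
              x$percent, x$n_associated, x$size))
  invisible(x)
}

# round() uses banker's rounding; printed percentages use half-up.
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  floor(x * scale + 0.5) / scale
}
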