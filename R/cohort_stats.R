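#' Per-category cohort summary for one tissue
#'
#' Summarizes each specificity category of a tissue: gene and transcript
#' counts, mean/median expression in the tissue and of the transcript's
#' maximum across tissues, mean/median exon count, the median number of
#' transcripts per gene, and 95% confidence-interval half-widths for the
#' means (t-distribution, `qt(0.975, m-1) * sd / sqrt(m)` for group size m).
#' Empty categories yield `NA` statistics (0 counts), singletons a defined
#' mean with an `NA` half-width.
#'
#' @param assign A `category_assignment` from [assign_categories()].
#' @param expr The source [ExpressionMatrix].
#' @param tissue Tissue to summarize.
#' @return Data frame with one row per category, class `group_summary`.
#' @export
group_summary <- function(assign, expr, tissue) {
  stopifnot(inherits(assign, "category_assignment"),
            inherits(expr, "ExpressionMatrix"))
  if (!tissue %in% colnames(assign)) stop("unknown tissue: ", tissue)
  cats <- specificity_categories()
  lab <- assign[, tissue]
  expr_tissue <- expr$values[, tissue]
  expr_max <- apply(expr$values, 1, max)
  meta <- expr$meta

  ci_half <- function(v) {
    m <- length(v)
    if (m < 2L) return(NA_real_)
    stats::qt(0.975, m - 1L) * stats::sd(v) / sqrt(m)
  }
  one <- function(cat) {
    idx <- which(lab == cat)
    m <- length(idx)
    if (m == 0L)
      return(data.frame(category = cat, n_genes = 0L, n_transcripts = 0L,
                        mean_expr = NA_real_, median_expr = NA_real_,
                        ci_expr = NA_real_, mean_max_expr = NA_real_,
                        median_max_expr = NA_real_, ci_max_expr = NA_real_,
                        mean_exons = NA_real_, median_exons = NA_real_,
                        ci_exons = NA_real_,
                        median_tx_per_gene = NA_real_,
                        stringsAsFactors = FALSE))
    genes <- meta$gene_id[idx]
    exons <- meta$exon_count[idx]
    tx_per_gene <- as.numeric(table(genes))
    data.frame(
      category = cat,
      n_genes = length(unique(genes)),
      n_transcripts = m,
      mean_expr = mean(expr_tissue[idx]),
      median_expr = stats::median(expr_tissue[idx]),
      ci_expr = ci_half(expr_tissue[idx]),
      mean_max_expr = mean(expr_max[idx]),
      median_max_expr = stats::median(expr_max[idx]),
      ci_max_expr = ci_half(expr_max[idx]),
      mean_exons = mean(exons),
      median_exons = stats::median(exons),
      ci_exons = if (all(is.na(exons))) NA_real_ else ci_half(exons),
      median_tx_per_gene = stats::median(tx_per_gene),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, lapply(cats, one))
  attr(out, "tissue") <- tissue
  class(out) <- c("group_summary", "data.frame")
  out
}

#' Welch's two-tailed t-test
#'
#' Unequal-variance two-sample location test:
#' t = (mean(a) - mean(b)) / sqrt(s2a/na + s2b/nb) with Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value. Used to compare statistics
#' (expression, exon counts) between specificity categories; p-values are
#' reported uncorrected.
#'
#' @param a,b Numeric samples, each of length >= 2; at least one must have
#'   nonzero variance.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("both samples need at least 2 observations")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("both samples have zero variance; Welch statistic undefined")
  ht <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' All pairwise Welch tests between categories
#'
#' @param values Numeric vector (e.g. tissue expression per transcript).
#' @param labels Category label per value.
#' @return Data frame with one row per unordered category pair that has
#'   >= 2 observations on both sides; `NA` statistics where the test is
#'   undefined (both groups constant).
#' @export
pairwise_welch <- function(values, labels) {
  cats <- intersect(specificity_categories(), unique(labels))
  if (length(cats) < 2L)
    return(data.frame(group1 = character(), group2 = character(),
                      t = numeric(), df = numeric(), p = numeric(),
                      stars = character(), stringsAsFactors = FALSE))
  combs <- utils::combn(cats, 2)
  rows <- lapply(seq_len(ncol(combs)), function(k) {
    g1 <- combs[1, k]; g2 <- combs[2, k]
    a <- values[labels == g1]; b <- values[labels == g2]
    res <- if (length(a) >= 2 && length(b) >= 2 &&
               (stats::var(a) > 0 || stats::var(b) > 0))
      welch_t_test(a, b)
    else list(t = NA_real_, df = NA_real_, p = NA_real_)
    data.frame(group1 = g1, group2 = g2, t = res$t, df = res$df, p = res$p,
               stars = signif_stars(res$p), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Significance stars
#' @param p P-value(s).
#' @return `"***"` below 0.001, `"**"` below 0.01, `"*"` below 0.05,
#'   otherwise `""` (`NA` input gives `""`).
#' @export
signif_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*", ""))))
}

#' Pairwise correlation matrix over named feature vectors
#'
#' Computes all pairwise coefficients (with p-values from [stats::cor.test])
#' over a shared observation set, e.g. maximum expression, tissue
#' specificity, exon count and transcripts-per-gene across transcripts.
#' Missing values are removed pairwise; Spearman uses average ranks for
#' ties. With `method = "auto"`, Spearman is chosen whenever any feature
#' name marks an expression or specificity vector (heavy-tailed scales),
#' Pearson otherwise.
#'
#' @param features Named list of equal-length numeric vectors.
#' @param method `"auto"`, `"pearson"` or `"spearman"`.
#' @return List of class `correlation_matrix` with symmetric matrices `r`,
#'   `p`, `n` (pairwise observation counts) and the `method` used.
#'   Pairs involving a constant vector get `NA` coefficients and are listed
#'   in `$degenerate`.
#' @export
correlation_matrix <- function(features,
                               method = c("auto", "pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(is.list(features), !is.null(names(features)))
  len <- unique(lengths(features))
  if (length(len) != 1L) stop("feature vectors must have equal length")
  if (method == "auto") {
    marked <- grepl("exp|spec|tpm|fpkm", names(features), ignore.case = TRUE)
    method <- if (any(marked)) "spearman" else "pearson"
  }
  k <- length(features)
  nm <- names(features)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  nmat <- matrix(0L, k, k, dimnames = list(nm, nm))
  diag(r) <- 1; diag(p) <- 0
  degenerate <- character()
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    x <- features[[i]]; y <- features[[j]]
    ok <- !is.na(x) & !is.na(y)
    nmat[i, j] <- nmat[j, i] <- sum(ok)
    if (sum(ok) < 3L) next
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      degenerate <- c(degenerate, paste(nm[i], nm[j], sep = "~"))
      next
    }
    ht <- suppressWarnings(
      stats::cor.test(x[ok], y[ok], method = method, exact = FALSE))
    r[i, j] <- r[j, i] <- unname(ht$estimate)
    p[i, j] <- p[j, i] <- ht$p.value
  }
  diag(nmat) <- len
  structure(list(r = r, p = p, n = nmat, method = method,
                 degenerate = degenerate),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("correlation_matrix (", x$method, ")\n", sep = "")
  print(round(x$r, 3))
  invisible(x)
}
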