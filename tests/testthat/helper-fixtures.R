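# Shared in-code fixtures for the test suite.

# Small expression matrix with hand-chosen values.
make_expr <- function(values, tissues = NULL, species = "test") {
  if (is.null(tissues)) tissues <- paste0("t", seq_len(ncol(values)))
  ids <- paste0("tx", seq_len(nrow(values)))
  dimnames(values) <- list(ids, tissues)
  meta <- data.frame(transcript_id = ids,
                     gene_id = paste0("g", seq_len(nrow(values))),
                     exon_count = rep(2L, nrow(values)),
                     biotype = rep("coding", nrow(values)),
                     stringsAsFactors = FALSE)
  ExpressionMatrix(values, meta, species = species)
}

# Direct evaluation of the specificity formula for one expression row:
# the independent oracle for closed-form and vectorized paths.
spec_row_oracle <- function(e) {
  n <- length(e)
  m <- mean(e)
  s <- sqrt(sum((e - m)^2) / (n - 1))
  if (s == 0) rep(0, n) else (e - m) / s
}

# Write a tiny TSV and return its path.
write_tsv_fixture <- function(df, ...) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     ...)
  path
}

# Breadth-first all-pairs shortest-path distances: oracle for centrality.
bfs_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- unique(unlist(lapply(frontier, function(v) which(adj[v, ] > 0))))
      nxt <- nxt[d[s, nxt] == Inf]
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}

# Shortest-path counts sigma[s, t] from BFS distances (DAG recursion).
path_counts <- function(adj, d) {
  n <- nrow(adj)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    for (t in order(d[s, ])) {
      if (t == s || !is.finite(d[s, t])) next
      preds <- which(adj[t, ] > 0 & d[s, ] == d[s, t] - 1)
      sigma[s, t] <- sum(sigma[s, preds])
    }
  }
  sigma
}

# Normalized betweenness/closeness oracle matching the package's
# conventions: per connected component, betweenness / ((m-1)(m-2)/2),
# closeness = (m-1) / sum of distances, isolated nodes 0.
centrality_oracle <- function(adj) {
  n <- nrow(adj)
  d <- bfs_distances(adj)
  sigma <- path_counts(adj, d)
  btw <- numeric(n)
  for (v in seq_len(n)) {
    tot <- 0
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s >= t || s == v || t == v) next
      if (!is.finite(d[s, t])) next
      if (d[s, v] + d[v, t] == d[s, t] && sigma[s, t] > 0)
        tot <- tot + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
    btw[v] <- tot
  }
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (s in seq_len(n)) if (is.na(comp[s])) {
    cid <- cid + 1
    comp[is.finite(d[s, ])] <- cid
  }
  clo <- numeric(n)
  for (v in seq_len(n)) {
    members <- which(comp == comp[v])
    m <- length(members)
    if (m < 2) next
    denom <- (m - 1) * (m - 2) / 2
    btw[v] <- if (denom > 0) btw[v] / denom else 0
    clo[v] <- (m - 1) / sum(d[v, members])
  }
  list(degree = rowSums(adj), betweenness = btw, closeness = clo)
}

# Build a TypedGraph from a plain adjacency matrix (single species, one
# tissue containing every node).
graph_from_adj <- function(adj, species = "sp") {
  n <- nrow(adj)
  genes <- sprintf("g%02d", seq_len(n))
  pairs <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  pt <- data.frame(id_a = genes[pairs[, 1]], id_b = genes[pairs[, 2]],
                   stringsAsFactors = FALSE)
  gs <- list(list(all = genes))
  names(gs) <- species
  phys <- list(pt)
  names(phys) <- species
  build_network(gs, phys)
}
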