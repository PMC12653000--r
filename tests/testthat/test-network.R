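test_that("network construction restricts edges to present nodes", {
  gs <- list(human = list(brain = c("a", "b")),
             fly = list(brain = "x"))
  phys <- list(human = data.frame(id_a = c("a", "a", "b"),
                                  id_b = c("b", "b", "z")),
               fly = data.frame(id_a = character(), id_b = character()))
  orth <- data.frame(id_a = "a", id_b = "x", score = 13L)
  g <- build_network(gs, phys, orth)
  expect_equal(igraph::vcount(g), 3L)
  types <- igraph::E(g)$type
  expect_equal(sum(types == "physical"), 1L)  # duplicate a-b collapsed; b-z dropped
  expect_equal(sum(types == "ortholog"), 1L)
  expect_true(all(igraph::V(g)$has_ortholog ==
                    (igraph::V(g)$name %in% c("human|a", "fly|x"))))
})

test_that("ortholog edges never connect nodes of the same species", {
  set.seed(61)
  for (rep in 1:5) {
    genes_a <- sprintf("a%02d", 1:20)
    genes_b <- sprintf("b%02d", 1:20)
    gs <- list(s1 = list(t1 = sample(genes_a, 12)),
               s2 = list(t1 = sample(genes_b, 12)))
    phys <- list(s1 = data.frame(id_a = sample(genes_a, 15, TRUE),
                                 id_b = sample(genes_a, 15, TRUE)),
                 s2 = data.frame(id_a = sample(genes_b, 15, TRUE),
                                 id_b = sample(genes_b, 15, TRUE)))
    orth <- data.frame(id_a = sample(genes_a, 8),
                       id_b = sample(genes_b, 8), score = 13L)
    g <- build_network(gs, phys, orth)
    oe <- igraph::E(g)[igraph::E(g)$type == "ortholog"]
    if (length(oe)) {
      endp <- igraph::ends(g, oe)
      sp_of <- function(v) igraph::V(g)$species[match(v, igraph::V(g)$name)]
      expect_true(all(sp_of(endp[, 1]) != sp_of(endp[, 2])))
    }
    pe <- igraph::E(g)[igraph::E(g)$type == "physical"]
    if (length(pe)) {
      endp <- igraph::ends(g, pe)
      sp_of <- function(v) igraph::V(g)$species[match(v, igraph::V(g)$name)]
      expect_true(all(sp_of(endp[, 1]) == sp_of(endp[, 2])))
    }
  }
})

test_that("centralities on a 3-node path match hand computation", {
  adj <- matrix(0, 3, 3)
  adj[1, 2] <- adj[2, 1] <- 1
  adj[2, 3] <- adj[3, 2] <- 1
  g <- graph_from_adj(adj)
  ct <- centrality(g)
  ct <- ct[order(ct$gene), ]
  expect_equal(ct$degree, c(1, 2, 1))
  expect_equal(ct$betweenness, c(0, 1, 0))
  expect_equal(ct$closeness, c(2 / 3, 1, 2 / 3))
})

test_that("triangle has zero betweenness; isolated nodes score zero", {
  adj <- matrix(0, 4, 4)
  adj[1, 2] <- adj[2, 1] <- adj[2, 3] <- adj[3, 2] <- adj[1, 3] <- adj[3, 1] <- 1
  g <- graph_from_adj(adj)   # node 4 isolated
  ct <- centrality(g)
  ct <- ct[order(ct$gene), ]
  expect_equal(ct$betweenness, rep(0, 4))
  expect_equal(ct$degree[4], 0)
  expect_equal(ct$closeness[4], 0)
})

test_that("centralities match a brute-force shortest-path oracle", {
  set.seed(71)
  for (rep in 1:6) {
    n <- sample(8:20, 1)
    adj <- matrix(0, n, n)
    for (k in seq_len(round(n * 1.4))) {
      ij <- sample(n, 2)
      adj[ij[1], ij[2]] <- adj[ij[2], ij[1]] <- 1
    }
    g <- graph_from_adj(adj)
    ct <- centrality(g)
    ct <- ct[order(ct$gene), ]
    oracle <- centrality_oracle(adj)
    expect_equal(ct$degree, unname(oracle$degree))
    expect_equal(ct$betweenness, oracle$betweenness, tolerance = 1e-9)
    expect_equal(ct$closeness, oracle$closeness, tolerance = 1e-9)
  }
})

test_that("hub filter is strict at the cutoff and idempotent", {
  # star with 21 leaves: hub degree 21 kept, leaves dropped
  star <- matrix(0, 22, 22)
  star[1, 2:22] <- star[2:22, 1] <- 1
  g <- graph_from_adj(star)
  hubs <- filter_hubs(g, min_degree = 20)
  expect_equal(igraph::vcount(hubs), 1L)
  expect_equal(igraph::V(hubs)$gene, "g01")
  # degree exactly 20 dropped
  star20 <- matrix(0, 21, 21)
  star20[1, 2:21] <- star20[2:21, 1] <- 1
  expect_equal(igraph::vcount(filter_hubs(graph_from_adj(star20),
                                          min_degree = 20)), 0L)
  # idempotent, empty-safe
  hubs2 <- filter_hubs(hubs, min_degree = 20)
  expect_equal(igraph::vcount(hubs2), 0L)  # isolated survivor has degree 0
  empty <- build_network(list(s = list(t = character())), list())
  expect_equal(igraph::vcount(filter_hubs(empty)), 0L)
})

test_that("hub subgraph retains ortholog edges between surviving hubs", {
  genes_a <- c("hubA", sprintf("a%02d", 1:25))
  genes_b <- c("hubB", sprintf("b%02d", 1:25))
  gs <- list(s1 = list(t = genes_a), s2 = list(t = genes_b))
  phys <- list(s1 = data.frame(id_a = "hubA", id_b = genes_a[-1]),
               s2 = data.frame(id_a = "hubB", id_b = genes_b[-1]))
  orth <- data.frame(id_a = "hubA", id_b = "hubB", score = 14L)
  g <- build_network(gs, phys, orth)
  hubs <- filter_hubs(g, min_degree = 20)
  expect_equal(sort(igraph::V(hubs)$gene), c("hubA", "hubB"))
  expect_equal(igraph::E(hubs)$type, "ortholog")
})

test_that("ortholog-pair subnetworks keep only paired members of the tissue", {
  gs <- list(s1 = list(testis = c("a1", "a2", "a3"), brain = "a9"),
             s2 = list(testis = c("b1", "b2")))
  phys <- list(s1 = data.frame(id_a = "a1", id_b = "a2"),
               s2 = data.frame(id_a = character(), id_b = character()))
  orth <- data.frame(id_a = "a1", id_b = "b1", score = 13L)
  g <- build_network(gs, phys, orth)
  sub <- ortholog_pair_subnetwork(g, "testis")
  expect_equal(sort(igraph::V(sub)$gene), c("a1", "b1"))
  expect_error(ortholog_pair_subnetwork(g, "kidney"), "unknown tissue")
  sub_brain <- ortholog_pair_subnetwork(g, "brain")
  expect_equal(igraph::vcount(sub_brain), 0L)
})

test_that("planted hub ortholog pairs survive the degree filter together", {
  set.seed(81)
  genes_a <- sprintf("a%03d", 1:200)
  genes_b <- sprintf("b%03d", 1:200)
  links <- gen_links(genes_a, genes_b,
                     hubs = list(a = 10, b = 10, degree = 25), seed = 82)
  # pair the planted hubs across species and put everything in one tissue
  orth <- data.frame(id_a = links$truth$hubs_a, id_b = links$truth$hubs_b,
                     score = 14L)
  gs <- list(s1 = list(testis = genes_a), s2 = list(testis = genes_b))
  g <- build_network(gs, stats::setNames(links$physical, c("s1", "s2")),
                     orth)
  hubs <- filter_hubs(g, min_degree = 20)
  expect_setequal(igraph::V(hubs)$gene,
                  c(links$truth$hubs_a, links$truth$hubs_b))
  sub <- ortholog_pair_subnetwork(hubs, "testis")
  expect_equal(igraph::vcount(sub), 20L)
  expect_equal(sum(igraph::E(sub)$type == "ortholog"), 10L)
})

test_that("network export writes GraphML plus node and edge TSVs", {
  gs <- list(s1 = list(t = c("a", "b")))
  phys <- list(s1 = data.frame(id_a = "a", id_b = "b"))
  g <- build_network(gs, phys)
  stem <- file.path(withr::local_tempdir(), "net")
  files <- export_network(g, stem, centrality(g))
  expect_true(all(file.exists(files)))
  ed <- read.delim(files[2])
  expect_equal(ed$edge_type, "physical")
  nd <- read.delim(files[3])
  expect_true(all(c("species", "degree", "closeness") %in% names(nd)))
})
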