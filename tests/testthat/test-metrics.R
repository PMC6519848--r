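two_block <- function() {
  # a--b, b--c, c--d as directed edges with modules {a,b} and {c,d}
  g <- annotated_graph(
    data.frame(id = letters[1:4], vtype = "compound", compartment = "c"),
    data.frame(source = c("a", "b", "c"), target = c("b", "c", "d"),
               etype = "product", logic = "disjunct"))
  p <- domain_partition(c(a = "RD", b = "RD", c = "MD", d = "MD"),
                        "functional", 2)
  list(g = g, p = p)
}

test_that("inter-module edge fraction follows the external/(external+internal) formula", {
  tb <- two_block()
  res <- inter_module_edge_fraction(tb$g, tb$p)
  # each block: 1 internal, 1 external
  expect_equal(res$c_d, c(0.5, 0.5))

  # an isolated clique as its own domain has c_D = 0
  v <- data.frame(id = c("x", "y", "z", "o"), vtype = "compound", compartment = "c")
  e <- data.frame(source = c("x", "y", "z"), target = c("y", "z", "x"),
                  etype = "product", logic = "disjunct")
  p <- domain_partition(c(x = "MD", y = "MD", z = "MD", o = "RD"), "functional", 2)
  res2 <- inter_module_edge_fraction(annotated_graph(v, e), p)
  expect_equal(res2$c_d[res2$domain == "MD"], 0)
  expect_true(is.na(res2$c_d[res2$domain == "RD"]))
})

test_that("modularity matches the hand value 1/6 on the 3-edge toy and 0 for one module", {
  tb <- two_block()
  m <- modularity_partition(tb$g, tb$p)
  expect_equal(m$total, 1 / 6)
  expect_equal(m$per_module$term, c(1 / 12, 1 / 12))

  one <- domain_partition(stats::setNames(rep("MD", 4), letters[1:4]), "functional", 2)
  expect_equal(modularity_partition(tb$g, one)$total, 0)

  expect_error(modularity_partition(annotated_graph(tb$g$vertices), tb$p), "L_G = 0")
})

test_that("modularity agrees with igraph on random graphs and collapses reciprocals", {
  for (seed in c(4, 13, 29)) {
    g <- random_digraph(12, 0.2, seed)
    p <- random_partition3(g, seed + 500)
    m <- modularity_partition(g, p)
    ug <- igraph::as_undirected(as_igraph(g), mode = "collapse")
    ug <- igraph::simplify(ug)
    ref <- igraph::modularity(ug, factor(p$labels[igraph::V(ug)$name]))
    expect_equal(m$total, ref, tolerance = 1e-12)
    expect_lte(m$total, 1)
  }
})

test_that("degree centrality counts in- and out-edges and sums to 2|E|", {
  path <- annotated_graph(
    data.frame(id = c("a", "b", "c"), vtype = "compound", compartment = "c"),
    data.frame(source = c("a", "b"), target = c("b", "c"),
               etype = "product", logic = "disjunct"))
  dc <- degree_centrality(path)
  expect_equal(dc$dc[dc$id == "b"], 2)

  toy <- toy8_graph()
  dct <- degree_centrality(toy)
  expect_equal(dct$dc[dct$id == "pc1"], 4)   # in: c2, p2; out: g1, g2
  expect_equal(sum(dct$dc), 2 * n_edges(toy))

  expect_equal(nrow(degree_centrality(annotated_graph())), 0)
})

test_that("embeddedness is the intra-domain degree fraction and decomposes to 1", {
  toy <- toy8_graph()
  p3 <- affiliate_functional(toy, 3)
  emb <- embeddedness(toy, p3)
  # p1 sits in PI with neighbours g1 (RD) and r1 (MD): xi_PI(p1) = 0
  expect_equal(emb$xi[emb$id == "p1"], 0)

  # all neighbours inside the own domain -> 1; all outside -> 0
  v <- data.frame(id = c("m1", "m2", "r1"),
                  vtype = c("protein-monomer", "protein-monomer", "gene"),
                  compartment = c("c", "c", NA))
  e <- data.frame(source = c("m1", "r1"), target = c("m2", "m2"),
                  etype = c("complex-formation", "regulation"),
                  logic = c("conjunct", NA), regulation_mode = c(NA, 1L))
  g <- annotated_graph(v, e)
  p <- domain_partition(c(m1 = "PI", m2 = "PI", r1 = "RD"), "functional", 3)
  emb2 <- embeddedness(g, p)
  expect_equal(emb2$xi[emb2$id == "m1"], 1)
  expect_true(is.na(embeddedness(
    annotated_graph(rbind(v, data.frame(id = "iso", vtype = "gene", compartment = NA)),
                    e),
    domain_partition(c(m1 = "PI", m2 = "PI", r1 = "RD", iso = "RD"),
                     "functional", 3))$xi[4]))

  # per-vertex decomposition: domain-restricted fractions sum to 1
  sim <- generate_network(generator_params(n_genes = 14, n_compounds = 10,
                                           n_reactions = 7, seed = 3))
  p3s <- affiliate_functional(sim$graph, 3)
  tot <- rowSums(vapply(c("MD", "PI", "RD"), function(d)
    embeddedness(sim$graph, p3s, domain = d)$xi, numeric(n_vertices(sim$graph))))
  dc <- degree_centrality(sim$graph)$dc
  expect_equal(tot[dc > 0], rep(1, sum(dc > 0)))
})

test_that("betweenness matches closed forms and the exhaustive oracle", {
  path <- annotated_graph(
    data.frame(id = c("a", "b", "c"), vtype = "compound", compartment = "c"),
    data.frame(source = c("a", "b"), target = c("b", "c"),
               etype = "product", logic = "disjunct"))
  bc <- betweenness_centrality(path, directed = TRUE)
  expect_equal(unname(bc[c("a", "b", "c")]), c(0, 1, 0))

  # undirected star: centre scores k(k-1) ordered pairs
  k <- 5
  star <- annotated_graph(
    data.frame(id = c("hub", paste0("l", 1:k)), vtype = "compound",
               compartment = "c"),
    data.frame(source = "hub", target = paste0("l", 1:k),
               etype = "product", logic = "disjunct"))
  bs <- betweenness_centrality(star, directed = FALSE)
  expect_equal(unname(bs["hub"]), k * (k - 1))
  expect_true(all(bs[paste0("l", 1:k)] == 0))

  # complete digraph: every shortest path is direct
  ids <- c("u", "v", "w")
  pairs <- expand.grid(source = ids, target = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  complete <- annotated_graph(
    data.frame(id = ids, vtype = "compound", compartment = "c"),
    data.frame(pairs, etype = "product", logic = "disjunct"))
  expect_true(all(betweenness_centrality(complete) == 0))

  # exhaustive-oracle agreement on 50 random digraphs
  for (seed in 1:50) {
    g <- random_digraph(sample(5:9, 1), 0.25, seed)
    expect_equal(betweenness_centrality(g, directed = TRUE),
                 oracle_betweenness(g, directed = TRUE), tolerance = 1e-10)
  }
})

test_that("hub detection uses a strict threshold", {
  make_star <- function(k) {
    annotated_graph(
      data.frame(id = c("hub", sprintf("l%03d", 1:k)), vtype = "compound",
                 compartment = "c"),
      data.frame(source = "hub", target = sprintf("l%03d", 1:k),
                 etype = "product", logic = "disjunct"))
  }
  expect_length(find_hubs(make_star(50)), 0)   # DC = 50 is not a hub
  expect_equal(find_hubs(make_star(51)), "hub")
  expect_length(find_hubs(toy8_graph()), 0)
  expect_equal(find_hubs(make_star(6), threshold = 5), "hub")
})

test_that("the betweenness null is seeded, degenerate at |V|, and centred correctly", {
  sim <- generate_network(generator_params(n_genes = 12, n_compounds = 8,
                                           n_reactions = 6, seed = 8))
  g <- sim$graph
  null_all <- betweenness_null(g, subset_size = n_vertices(g), n_draws = 5, seed = 3)
  expect_true(all(abs(null_all$draws - mean(null_all$bc)) < 1e-9))

  none <- betweenness_null(g, subset_size = 3, n_draws = 0, seed = 3)
  expect_error(null_quantile(none, 1), "empty null distribution")
  expect_error(betweenness_null(g, subset_size = n_vertices(g) + 1, n_draws = 1),
               "exceeds")

  # reproducibility and sampling theory: the mean of subset means stays
  # within 3 standard errors of the global mean
  a <- betweenness_null(g, subset_size = 10, n_draws = 1000, seed = 7)
  b <- betweenness_null(g, subset_size = 10, n_draws = 1000, seed = 7)
  expect_identical(a$draws, b$draws)
  se <- stats::sd(a$draws) / sqrt(length(a$draws))
  expect_lt(abs(mean(a$draws) - mean(a$bc)), 3 * se + 1e-9)
})

test_that("rank report is deterministic with id tie-breaks and total at top_k = |V|", {
  g <- toy8_graph()
  p3 <- affiliate_functional(g, 3)
  full <- rank_report(g, p3, top_k = n_vertices(g))
  expect_setequal(full$table$id, g$vertices$id)
  expect_equal(sum(full$domain_counts), n_vertices(g))

  # tied scores order lexicographically by id
  v <- data.frame(id = c("b", "a", "c"), vtype = "compound", compartment = "c")
  e <- data.frame(source = c("b", "a"), target = c("a", "b"),
                  etype = "product", logic = "disjunct")
  gt <- annotated_graph(v, e)
  pt <- domain_partition(c(b = "MD", a = "MD", c = "MD"), "functional", 2)
  tab <- rank_report(gt, pt, top_k = 3, metric = "degree")$table
  expect_equal(tab$id, c("a", "b", "c"))
})
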