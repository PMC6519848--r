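test_that("TOY-8 traversing paths match the exhaustive hand enumeration", {
  g <- toy8_graph()
  p3 <- affiliate_functional(g, 3)
  down <- enumerate_traversing_paths(g, p3, "downwards")
  expect_equal(down$n, 1)
  expect_equal(down$paths[[1]], c("g1", "p1", "r1"))

  up <- enumerate_traversing_paths(g, p3, "upwards")
  expect_equal(up$n, 2)
  expect_equal(path_keys(up), c("c2>pc1>g1", "c2>pc1>g2"))

  # a graph with no RD-PI boundary edges has no traversing paths
  v <- data.frame(id = c("g", "c"), vtype = c("gene", "compound"),
                  compartment = c(NA, "c"))
  e <- data.frame(source = "c", target = "g", etype = "regulation",
                  regulation_mode = 1L)
  lonely <- annotated_graph(v, e)
  pl <- domain_partition(c(g = "RD", c = "PI"), "functional", 3)
  expect_equal(enumerate_traversing_paths(lonely, pl, "downwards")$n, 0)

  # a partition without a PI domain is rejected
  p2 <- affiliate_functional(g, 2)
  expect_error(enumerate_traversing_paths(g, p2, "downwards"), "no PI domain")
})

test_that("enumeration agrees with the brute-force Eq-2 oracle on 50 random graphs", {
  for (seed in 1:50) {
    g <- random_digraph(sample(8:12, 1), 0.18, seed + 3000)
    p <- random_partition3(g, seed + 4000)
    for (dir in c("downwards", "upwards")) {
      got <- enumerate_traversing_paths(g, p, dir)
      ref <- oracle_traversing_paths(g, p$labels, dir)
      expect_equal(path_keys(got), path_keys(ref))
      # deterministic lexicographic output order
      keys <- vapply(got$paths, paste, character(1), collapse = "\001")
      expect_equal(keys, sort(keys, method = "radix"))
    }
  }
})

test_that("every emitted path satisfies the traversing-path invariants", {
  for (seed in c(6, 16)) {
    sim <- generate_network(generator_params(seed = seed))
    g <- sim$graph
    p <- affiliate_functional(g, 3)
    for (dir in c("downwards", "upwards")) {
      from <- if (dir == "downwards") "RD" else "MD"
      to <- if (dir == "downwards") "MD" else "RD"
      edge_set <- paste(g$edges$source, g$edges$target)
      for (pp in enumerate_traversing_paths(g, p, dir)$paths) {
        expect_gte(length(pp), 3)   # minimum length 2 edges
        expect_equal(unname(p$labels[pp[1]]), from)
        expect_equal(unname(p$labels[pp[length(pp)]]), to)
        interior <- pp[-c(1, length(pp))]
        expect_true(all(p$labels[interior] == "PI"))
        expect_false(anyDuplicated(interior) > 0)
        expect_true(all(paste(pp[-length(pp)], pp[-1]) %in% edge_set))
      }
    }
  }
})

test_that("relabeling invariance and up/down symmetry under edge reversal", {
  sim <- generate_network(generator_params(n_genes = 16, n_compounds = 10,
                                           n_reactions = 8, seed = 12))
  g <- sim$graph
  p <- affiliate_functional(g, 3)
  down <- enumerate_traversing_paths(g, p, "downwards")
  up <- enumerate_traversing_paths(g, p, "upwards")

  # permute ids: path multiset maps through the permutation
  set.seed(99)
  perm <- stats::setNames(sample(sprintf("x%04d", seq_len(n_vertices(g)))),
                          g$vertices$id)
  g2 <- g
  g2$vertices$id <- unname(perm[g2$vertices$id])
  g2$edges$source <- unname(perm[g2$edges$source])
  g2$edges$target <- unname(perm[g2$edges$target])
  p2 <- domain_partition(stats::setNames(unname(p$labels),
                                         unname(perm[names(p$labels)])),
                         "functional", 3)
  down2 <- enumerate_traversing_paths(g2, p2, "downwards")
  expect_setequal(path_keys(down2),
                  vapply(down$paths, function(pp) paste(perm[pp], collapse = ">"),
                         character(1)))

  # reverse all edges and swap RD<->MD: downwards become reversed upwards
  g3 <- g
  g3$edges$source <- g$edges$target
  g3$edges$target <- g$edges$source
  swapped <- c(MD = "RD", PI = "PI", RD = "MD")[p$labels]
  p3 <- domain_partition(stats::setNames(unname(swapped), names(p$labels)),
                         "functional", 3)
  down3 <- enumerate_traversing_paths(g3, p3, "downwards")
  expect_setequal(path_keys(down3),
                  vapply(down$paths, function(pp) paste(rev(pp), collapse = ">"),
                         character(1)))
})

test_that("the enumeration cap raises a hard error when exceeded", {
  g <- toy8_graph()
  p3 <- affiliate_functional(g, 3)
  expect_error(enumerate_traversing_paths(g, p3, "upwards", max_paths = 1),
               "exceeded max_paths")
  expect_equal(enumerate_traversing_paths(g, p3, "upwards", max_depth = 1)$n, 0)
})

test_that("direct links count single edges between the stated domains", {
  g <- toy8_graph()
  p3 <- affiliate_functional(g, 3)
  expect_equal(count_direct_links(g, p3, "RD", "MD"), 0)
  expect_equal(count_direct_links(g, p3, "MD", "RD"), 0)
  # D -> D equals the internal directed edge count of D
  expect_equal(count_direct_links(g, p3, "MD", "MD"),
               sum(p3$labels[g$edges$source] == "MD" &
                     p3$labels[g$edges$target] == "MD"))
})

test_that("path statistics: histogram, participation fractions, interior counts", {
  g <- toy8_graph()
  p3 <- affiliate_functional(g, 3)
  up <- enumerate_traversing_paths(g, p3, "upwards")
  st <- path_statistics(up)
  expect_equal(st$n_paths, 2)
  expect_equal(st$length_hist, c(`2` = 2L))
  expect_equal(unname(st$vertex_participation["pc1"]), 1.0)  # 2 of 2 paths
  expect_equal(st$n_distinct_interior, 1)

  down <- enumerate_traversing_paths(g, p3, "downwards")
  expect_equal(path_statistics(down)$n_distinct_interior, 1)  # p1 only

  single <- list(c("a", "x", "y", "z", "b"))
  st4 <- path_statistics(single)
  expect_equal(st4$length_hist, c(`4` = 1L))
  expect_equal(unname(st4$triple_participation["x|y|z"]), 1.0)

  empty <- path_statistics(list())
  expect_equal(empty$n_paths, 0L)
  expect_length(empty$vertex_participation, 0)
  expect_equal(empty$n_distinct_interior, 0L)
})

test_that("SCC containment fractions follow membership", {
  g <- toy8_graph()
  p3 <- affiliate_functional(g, 3)
  down <- enumerate_traversing_paths(g, p3, "downwards")
  expect_equal(scc_containment(down, g$vertices$id), 1.0)
  expect_equal(scc_containment(down, character(0)), 0.0)
  scc <- largest_strongly_connected_component(g)
  # hand check: g1, p1, r1 all sit in the SCC cycle
  expect_equal(scc_containment(down, scc),
               mean(vapply(down$paths, function(p) all(p %in% scc), logical(1))))
  expect_true(is.na(scc_containment(list(), g$vertices$id)))
})

test_that("TOY-8 yields exactly one feedback loop under identity/edge closure", {
  g <- toy8_graph()
  p3 <- affiliate_functional(g, 3)
  up <- enumerate_traversing_paths(g, p3, "upwards")
  down <- enumerate_traversing_paths(g, p3, "downwards")
  loops <- find_feedback_loops(g, p3, up, down,
                               rd_closure = "identity", md_closure = "edge")
  expect_length(loops, 1)
  expect_equal(loops[[1]]$down, c("g1", "p1", "r1"))
  expect_equal(loops[[1]]$up, c("c2", "pc1", "g1"))
  expect_equal(loops[[1]]$md_closure, c("r1", "c2"))

  # bounded-path closure at length 0 reduces to identity
  loops0 <- find_feedback_loops(g, p3, up, down,
                                rd_closure = "path", md_closure = "edge",
                                rd_max_len = 0)
  expect_equal(loops0, loops)

  # removing the MD edge between the downwards end and upwards start
  # breaks the metabolic closure
  g2 <- g
  g2$edges <- g2$edges[!(g2$edges$source == "r1" & g2$edges$target == "c2"), ]
  p32 <- domain_partition(p3$labels, "functional", 3)
  up2 <- enumerate_traversing_paths(g2, p32, "upwards")
  down2 <- enumerate_traversing_paths(g2, p32, "downwards")
  expect_length(find_feedback_loops(g2, p32, up2, down2, md_closure = "edge"), 0)

  # a two-step metabolic detour is found by the bounded-path closure only
  v3 <- rbind(g2$vertices,
              data.frame(id = "cmid", vtype = "compound", compartment = "c",
                         name = NA, covert_map = NA, affiliation3 = NA,
                         affiliation2 = NA))
  e3 <- rbind(g2$edges,
              data.frame(source = c("r1", "cmid"), target = c("cmid", "c2"),
                         etype = "product", stoichiometry = 1L,
                         regulation_mode = NA_integer_, logic = "disjunct",
                         reg_id = NA, reg_name = NA))
  g3 <- annotated_graph(v3, e3, validate = FALSE)
  p33 <- domain_partition(c(p3$labels, cmid = "MD"), "functional", 3)
  up3 <- enumerate_traversing_paths(g3, p33, "upwards")
  down3 <- enumerate_traversing_paths(g3, p33, "downwards")
  expect_length(find_feedback_loops(g3, p33, up3, down3, md_closure = "edge"), 0)
  loops2 <- find_feedback_loops(g3, p33, up3, down3,
                                md_closure = "path", md_max_len = 2)
  expect_length(loops2, 1)
  expect_equal(loops2[[1]]$md_closure, c("r1", "cmid", "c2"))
})
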