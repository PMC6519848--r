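# Brute-force oracles and fixture builders shared across the suite.
# The oracles are deliberately naive (exhaustive enumeration, boolean
# reachability, union-find) and independent of the package's code paths.

# random directed annotated graph; vertex ids are zero-padded so that
# lexicographic and numeric orders coincide
random_digraph <- function(n, p_edge, seed) {
  set.seed(seed)
  ids <- sprintf("v%02d", seq_len(n))
  pairs <- expand.grid(source = ids, target = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  pairs <- pairs[stats::runif(nrow(pairs)) < p_edge, ]
  annotated_graph(
    data.frame(id = ids, vtype = "compound", compartment = "c"),
    data.frame(pairs, etype = "product", stoichiometry = 1L, logic = "disjunct"))
}

# union-find weak components
oracle_wcc <- function(g) {
  ids <- g$vertices$id
  parent <- stats::setNames(ids, ids)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (i in seq_len(nrow(g$edges))) {
    a <- find(g$edges$source[i]); b <- find(g$edges$target[i])
    if (a != b) parent[[a]] <- b
  }
  split(ids, vapply(ids, find, character(1)))
}

# boolean reachability matrix by repeated squaring-ish expansion
oracle_reachability <- function(g) {
  ids <- g$vertices$id
  n <- length(ids)
  A <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  A[cbind(g$edges$source, g$edges$target)] <- TRUE
  diag(A) <- TRUE
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A)) break
    A <- A2
  }
  A
}

# SCCs as mutual-reachability classes
oracle_scc_sets <- function(g) {
  R <- oracle_reachability(g)
  mutual <- R & t(R)
  ids <- rownames(R)
  key <- apply(mutual, 1, function(row) paste(ids[row], collapse = ","))
  unname(split(ids, key))
}

oracle_largest_scc <- function(g) {
  sets <- oracle_scc_sets(g)
  sizes <- lengths(sets)
  top <- sets[sizes == max(sizes)]
  mins <- vapply(top, function(s) sort(s, method = "radix")[1], character(1))
  sort(top[[order(mins, method = "radix")[1]]], method = "radix")
}

# all simple directed paths between every ordered pair, as id vectors
oracle_all_simple_paths <- function(g) {
  succ <- split(g$edges$target, g$edges$source)
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    for (w in succ[[v]]) {
      if (w %in% path) next
      out[[length(out) + 1L]] <<- c(path, w)
      walk(c(path, w))
    }
  }
  for (s in g$vertices$id) walk(s)
  out
}

# unnormalized ordered-pair betweenness by exhaustive shortest-path count
oracle_betweenness <- function(g, directed = TRUE) {
  e <- g$edges
  if (!directed) {
    a <- pmin(e$source, e$target); b <- pmax(e$source, e$target)
    keep <- !duplicated(paste(a, b)) & a != b
    e <- data.frame(source = c(a[keep], b[keep]), target = c(b[keep], a[keep]))
  }
  paths <- oracle_all_simple_paths(
    annotated_graph(g$vertices,
                    data.frame(e[c("source", "target")], etype = "product",
                               stoichiometry = 1L, logic = "disjunct"),
                    validate = FALSE))
  ids <- g$vertices$id
  bc <- stats::setNames(numeric(length(ids)), ids)
  for (s in ids) for (t in ids) {
    if (s == t) next
    st <- paths[vapply(paths, function(p) p[1] == s && p[length(p)] == t, logical(1))]
    if (!length(st)) next
    lens <- vapply(st, length, integer(1))
    short <- st[lens == min(lens)]
    sigma <- length(short)
    for (v in setdiff(ids, c(s, t))) {
      through <- sum(vapply(short, function(p) v %in% p, logical(1)))
      bc[v] <- bc[v] + through / sigma
    }
  }
  bc
}

# Eq-2 filter over the exhaustive simple-path list
oracle_traversing_paths <- function(g, labels, direction) {
  from <- if (direction == "downwards") "RD" else "MD"
  to <- if (direction == "downwards") "MD" else "RD"
  paths <- oracle_all_simple_paths(g)
  keep <- Filter(function(p) {
    length(p) >= 3 &&
      labels[[p[1]]] == from && labels[[p[length(p)]]] == to &&
      all(labels[p[-c(1, length(p))]] == "PI")
  }, paths)
  keep[order(vapply(keep, paste, character(1), collapse = "\001"), method = "radix")]
}

# sorted canonical form for path-set comparison
path_keys <- function(paths) {
  if (inherits(paths, "traversing_paths")) paths <- paths$paths
  sort(vapply(paths, paste, character(1), collapse = ">"), method = "radix")
}

# random total 3-domain labelling with every domain inhabited
random_partition3 <- function(g, seed) {
  set.seed(seed)
  n <- n_vertices(g)
  labs <- sample(c("MD", "PI", "RD", sample(c("MD", "PI", "RD"), n - 3, replace = TRUE)))
  domain_partition(stats::setNames(labs, g$vertices$id), "functional", 3)
}

# schema-column comparison up to row order (ids preserved)
expect_graph_identical <- function(a, b) {
  vc <- c("id", "vtype", "compartment", "name")
  ec <- c("source", "target", "etype", "stoichiometry", "regulation_mode", "logic")
  va <- a$vertices[order(a$vertices$id), vc]
  vb <- b$vertices[order(b$vertices$id), vc]
  ea <- a$edges[order(a$edges$source, a$edges$target, a$edges$etype), ec]
  eb <- b$edges[order(b$edges$source, b$edges$target, b$edges$etype), ec]
  rownames(va) <- rownames(vb) <- rownames(ea) <- rownames(eb) <- NULL
  expect_equal(va, vb)
  expect_equal(ea, eb)
}

# locate the deposited annotated E. coli graph, if a copy is available
s1_graph_path <- function() {
  getOption("regmetnet.s1_file", Sys.getenv("REGMETNET_S1_FILE", ""))
}
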