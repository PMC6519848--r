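.check_total_partition <- function(g, partition) {
  ids <- g$vertices$id
  if (!all(ids %in% names(partition$labels)))
    stop("partition does not cover every vertex of the graph", call. = FALSE)
  partition$labels[ids]
}

#' Inter-module edge fraction per domain
#'
#' For each domain D, edges joining a D vertex to a vertex of another
#' domain are *external*, edges between two D vertices *internal*, and
#' `c_D = external / (external + internal)`. The classification ignores
#' edge direction; each directed edge is counted once (an external edge
#' counts for both incident domains).
#'
#' @param g An `annotated_graph`.
#' @param partition A total `domain_partition`.
#' @return Data frame with columns `domain`, `internal`, `external`, `c_d`.
#' @export
inter_module_edge_fraction <- function(g, partition) {
  lab <- .check_total_partition(g, partition)
  doms <- sort(unique(unname(lab)))
  e <- g$edges
  ls <- lab[e$source]; lt <- lab[e$target]
  res <- lapply(doms, function(d) {
    touch <- ls == d | lt == d
    internal <- sum(ls == d & lt == d)
    external <- sum(touch) - internal
    data.frame(domain = d, internal = internal, external = external,
               c_d = if (internal + external > 0) external / (external + internal) else NA_real_)
  })
  do.call(rbind, res)
}

# Collapse the directed multigraph to a simple undirected link set:
# reciprocal and parallel edges count once, self-links are excluded.
.undirected_links <- function(g) {
  e <- g$edges
  e <- e[e$source != e$target, , drop = FALSE]
  if (!nrow(e)) return(data.frame(a = character(), b = character()))
  a <- pmin(e$source, e$target)
  b <- pmax(e$source, e$target)
  keep <- !duplicated(paste(a, b, sep = "\r"))
  data.frame(a = a[keep], b = b[keep], stringsAsFactors = FALSE)
}

#' Newman modularity of a partition
#'
#' Modularity on the undirected view of the network (every directed edge
#' contributes one undirected link; reciprocal/parallel duplicates
#' collapse, self-links are excluded):
#' \deqn{M = \sum_j \left( \frac{L(M_j, M_j)}{L_G} -
#'   \left(\frac{\deg(M_j)}{2 L_G}\right)^2 \right)}
#' with \eqn{L(M_j,M_j)} the number of links internal to module j,
#' \eqn{L_G} the total number of links and \eqn{\deg(M_j)} the summed
#' degree of the module's vertices.
#'
#' @param g An `annotated_graph` with at least one edge.
#' @param partition A total `domain_partition`.
#' @return List with `total` (M) and `per_module` (data frame of the
#'   per-module summands as `domain`, `internal_links`, `degree_sum`,
#'   `term`).
#' @export
modularity_partition <- function(g, partition) {
  lab <- .check_total_partition(g, partition)
  links <- .undirected_links(g)
  lg <- nrow(links)
  if (!lg) stop("modularity undefined on an empty link set (L_G = 0)", call. = FALSE)
  deg <- table(factor(c(links$a, links$b), levels = g$vertices$id))
  doms <- sort(unique(unname(lab)))
  per <- lapply(doms, function(d) {
    members <- names(lab)[lab == d]
    internal <- sum(links$a %in% members & links$b %in% members)
    dsum <- sum(deg[members])
    data.frame(domain = d, internal_links = internal, degree_sum = dsum,
               term = internal / lg - (dsum / (2 * lg))^2)
  })
  per <- do.call(rbind, per)
  list(total = sum(per$term), per_module = per)
}

#' Degree centrality table
#'
#' In-, out- and total degree DC(v) = k_in + k_out on the directed
#' multigraph. The total over all vertices equals twice the edge count.
#'
#' @param g An `annotated_graph`.
#' @return Data frame with `id`, `k_in`, `k_out`, `dc`.
#' @export
degree_centrality <- function(g) {
  ids <- g$vertices$id
  k_out <- as.integer(table(factor(g$edges$source, levels = ids)))
  k_in <- as.integer(table(factor(g$edges$target, levels = ids)))
  data.frame(id = ids, k_in = k_in, k_out = k_out, dc = k_in + k_out)
}

#' Embeddedness (intra-domain degree fraction)
#'
#' \eqn{\xi_D(v) = \frac{1}{k_v} \sum_{w \in D} (A_{vw} + A_{wv})}: the
#' fraction of a vertex's total degree formed by edges into domain D. With
#' `domain = NULL` each vertex is scored against its own domain. Vertices
#' with zero degree have undefined embeddedness and are reported as `NA`.
#'
#' @param g An `annotated_graph`.
#' @param partition A total `domain_partition`.
#' @param domain Domain label to score against, or `NULL` for each
#'   vertex's own domain.
#' @return Data frame with `id`, `domain` (the vertex's own domain),
#'   `dc`, `xi`.
#' @export
embeddedness <- function(g, partition, domain = NULL) {
  lab <- .check_total_partition(g, partition)
  dc <- degree_centrality(g)
  e <- g$edges
  ids <- g$vertices$id
  xi <- vapply(seq_along(ids), function(i) {
    v <- ids[i]
    k <- dc$dc[i]
    if (k == 0) return(NA_real_)
    d <- if (is.null(domain)) lab[[v]] else domain
    inward <- sum(e$source == v & lab[e$target] == d) +
      sum(e$target == v & lab[e$source] == d)
    inward / k
  }, numeric(1))
  data.frame(id = ids, domain = unname(lab[ids]), dc = dc$dc, xi = xi)
}

#' Betweenness centrality
#'
#' Unnormalized betweenness \eqn{BC(v) = \sum_{s \ne v \ne t}
#' \sigma_{st}(v) / \sigma_{st}} over ordered vertex pairs, with pairs that
#' have no connecting path contributing zero. Computed by Brandes'
#' algorithm on the directed graph by default; with `directed = FALSE` the
#' graph is collapsed to its undirected simple view but ordered pairs are
#' still counted (so a star centre with k leaves scores k(k-1)).
#'
#' @param g An `annotated_graph`.
#' @param directed Treat edge direction (default `TRUE`).
#' @return Named numeric vector of BC per vertex id.
#' @export
betweenness_centrality <- function(g, directed = TRUE) {
  if (!n_vertices(g)) return(setNames(numeric(0), character(0)))
  ig <- as_igraph(g)
  if (directed) {
    bc <- igraph::betweenness(ig, directed = TRUE, weights = NA, normalized = FALSE)
  } else {
    ug <- igraph::as_undirected(ig, mode = "collapse")
    # ordered-pair convention: undirected unordered-pair counts doubled
    bc <- 2 * igraph::betweenness(ug, directed = FALSE, weights = NA, normalized = FALSE)
  }
  bc[g$vertices$id]
}

#' Hub detection
#'
#' Hubs are vertices with total degree strictly greater than the
#' threshold (default 50).
#'
#' @param g An `annotated_graph`.
#' @param threshold Strict lower bound on DC (default 50).
#' @return Character vector of hub vertex ids (sorted).
#' @export
find_hubs <- function(g, threshold = 50) {
  dc <- degree_centrality(g)
  sort(dc$id[dc$dc > threshold], method = "radix")
}

#' Null distribution of mean betweenness over random vertex subsets
#'
#' Samples `n_draws` vertex subsets of size `subset_size` without
#' replacement and records the mean betweenness centrality of each subset,
#' as a null model against which the mean betweenness of a designated
#' vertex group (e.g. the protein interface) can be compared.
#'
#' @param g An `annotated_graph`.
#' @param subset_size Subset size (at most `|V|`).
#' @param n_draws Number of subsets to draw.
#' @param seed Integer seed for reproducible sampling.
#' @param directed Passed to [betweenness_centrality()].
#' @return Object of class `bc_null` with elements `draws` (numeric vector
#'   of subset means), `subset_size`, and `bc` (the per-vertex scores
#'   used).
#' @export
betweenness_null <- function(g, subset_size, n_draws, seed = 1L, directed = TRUE) {
  if (subset_size > n_vertices(g))
    stop("subset_size exceeds the number of vertices", call. = FALSE)
  bc <- betweenness_centrality(g, directed = directed)
  draws <- numeric(n_draws)
  if (n_draws > 0) {
    set.seed(seed)
    for (i in seq_len(n_draws))
      draws[i] <- mean(bc[sample.int(length(bc), subset_size)])
  }
  structure(list(draws = draws, subset_size = subset_size, bc = bc),
            class = "bc_null")
}

#' Empirical quantile of a value under a betweenness null
#'
#' Fraction of null draws lying at or below `value`.
#'
#' @param null A `bc_null` object from [betweenness_null()].
#' @param value Query value (e.g. observed mean interface betweenness).
#' @return Empirical quantile in \[0, 1\].
#' @export
null_quantile <- function(null, value) {
  if (!length(null$draws))
    stop("empty null distribution: no draws to compare against", call. = FALSE)
  mean(null$draws <= value)
}

#' Top-k centrality ranking with domain labels
#'
#' Ranks vertices by betweenness (or total degree), breaking ties by
#' lexicographic vertex id, and attaches each vertex's domain label.
#'
#' @param g An `annotated_graph`.
#' @param partition A total `domain_partition`.
#' @param top_k Number of top vertices to report.
#' @param metric `"betweenness"` or `"degree"`.
#' @param directed Passed to [betweenness_centrality()].
#' @return List with `table` (data frame `rank`, `id`, `score`, `domain`)
#'   and `domain_counts` (named count of top-k members per domain).
#' @export
rank_report <- function(g, partition, top_k = 25,
                        metric = c("betweenness", "degree"), directed = TRUE) {
  metric <- match.arg(metric)
  lab <- .check_total_partition(g, partition)
  score <- if (metric == "betweenness") betweenness_centrality(g, directed = directed)
           else setNames(degree_centrality(g)$dc, g$vertices$id)
  ord <- order(-score, names(score), method = "radix")
  k <- min(top_k, length(score))
  ids <- names(score)[ord][seq_len(k)]
  tab <- data.frame(rank = seq_len(k), id = ids, score = unname(score[ids]),
                    domain = unname(lab[ids]))
  counts <- table(factor(tab$domain, levels = sort(unique(unname(lab)))))
  list(table = tab, domain_counts = counts)
}
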