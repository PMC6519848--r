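#' Enumerate domain-traversing paths
#'
#' A traversing path of length k (edge count) is a directed path
#' `u, v_1, ..., v_{k-1}, w` whose endpoints u and w lie in the regulatory
#' and metabolic domains ("downwards", RD to MD) or vice versa
#' ("upwards"), and whose interior vertices are pairwise distinct members
#' of the protein interface. Single edges joining RD and MD directly are
#' *direct links*, tallied separately by [count_direct_links()]; the
#' minimum traversing-path length is therefore 2.
#'
#' Enumeration is a depth-first search seeded at the boundary edges from
#' the source domain into the interface, extended only through unvisited
#' interface vertices, and closed at the first successor in the target
#' domain. The output is complete and deterministically ordered
#' (lexicographic by vertex-id sequence, C collation).
#'
#' @param g An `annotated_graph`.
#' @param partition A total three-domain `domain_partition` containing a
#'   PI domain.
#' @param direction `"downwards"` (RD -> MD) or `"upwards"` (MD -> RD).
#' @param max_paths Hard cap on the number of enumerated paths; exceeding
#'   it raises an error (worst-case enumeration is exponential).
#' @param max_depth Cap on path length in edges (default unlimited).
#' @return Object of class `traversing_paths`: list with `paths` (list of
#'   character id vectors), `direction`, and `n`.
#' @export
enumerate_traversing_paths <- function(g, partition,
                                       direction = c("downwards", "upwards"),
                                       max_paths = 1e6, max_depth = Inf) {
  direction <- match.arg(direction)
  lab <- .check_total_partition(g, partition)
  if (!"PI" %in% lab)
    stop("partition has no PI domain; traversing paths need a three-domain partition",
         call. = FALSE)
  from_dom <- if (direction == "downwards") "RD" else "MD"
  to_dom <- if (direction == "downwards") "MD" else "RD"

  e <- g$edges
  succ <- split(e$target, e$source)
  acc <- new.env(parent = emptyenv())
  acc$paths <- vector("list", 256L)
  acc$n <- 0L
  push <- function(p) {
    acc$n <- acc$n + 1L
    if (acc$n > max_paths)
      stop("traversing-path enumeration exceeded max_paths = ", max_paths, call. = FALSE)
    if (acc$n > length(acc$paths)) length(acc$paths) <- 2L * length(acc$paths)
    acc$paths[[acc$n]] <- p
  }
  visit <- function(prefix, v, depth) {
    # v is an interface vertex already appended to prefix
    for (w in succ[[v]]) {
      lw <- lab[[w]]
      if (lw == to_dom) {
        push(c(prefix, w))
      } else if (lw == "PI" && !w %in% prefix && depth + 1 <= max_depth) {
        visit(c(prefix, w), w, depth + 1)
      }
    }
  }
  starts <- names(lab)[lab == from_dom]
  for (u in starts) {
    for (v in succ[[u]]) {
      if (lab[[v]] == "PI" && 2 <= max_depth)
        visit(c(u, v), v, 2)
    }
  }
  paths <- acc$paths[seq_len(acc$n)]
  if (length(paths)) {
    key <- vapply(paths, paste, character(1), collapse = "\001")
    paths <- paths[order(key, method = "radix")]
  }
  structure(list(paths = paths, direction = direction, n = length(paths)),
            class = "traversing_paths")
}

#' @export
print.traversing_paths <- function(x, ...) {
  cat(sprintf("<traversing_paths> %s, %d paths\n", x$direction, x$n))
  invisible(x)
}

#' Count direct links between two domains
#'
#' Number of single directed edges whose source lies in `from_domain` and
#' whose target lies in `to_domain`. With both arguments equal this is the
#' internal directed edge count of the domain.
#'
#' @param g An `annotated_graph`.
#' @param partition A total `domain_partition`.
#' @param from_domain,to_domain Domain labels.
#' @return Integer edge count.
#' @export
count_direct_links <- function(g, partition, from_domain, to_domain) {
  lab <- .check_total_partition(g, partition)
  e <- g$edges
  sum(lab[e$source] == from_domain & lab[e$target] == to_domain)
}

.interior <- function(p) p[-c(1L, length(p))]

#' Summary statistics of a traversing-path set
#'
#' Length histogram (by edge count), the fraction of paths whose interior
#' contains each single interface vertex, each unordered pair and each
#' unordered triple of interface vertices, and the number of distinct
#' interior vertices. Pair and triple identifiers join the member ids with
#' `"|"` in sorted order.
#'
#' @param paths A `traversing_paths` object (or bare list of id vectors).
#' @return Object of class `path_stats`: list with `n_paths`,
#'   `length_hist` (named integer vector), `vertex_participation`,
#'   `pair_participation`, `triple_participation` (named fractions, sorted
#'   decreasing) and `n_distinct_interior`.
#' @export
path_statistics <- function(paths) {
  if (inherits(paths, "traversing_paths")) paths <- paths$paths
  n <- length(paths)
  if (!n) {
    return(structure(list(n_paths = 0L, length_hist = setNames(integer(0), character(0)),
                          vertex_participation = numeric(0),
                          pair_participation = numeric(0),
                          triple_participation = numeric(0),
                          n_distinct_interior = 0L), class = "path_stats"))
  }
  lens <- vapply(paths, length, integer(1)) - 1L
  hist <- table(lens)
  length_hist <- setNames(as.integer(hist), names(hist))
  interiors <- lapply(paths, .interior)
  count_combos <- function(k) {
    per_path <- lapply(interiors, function(iv) {
      iv <- sort(unique(iv), method = "radix")
      if (length(iv) < k) return(character(0))
      if (k == 1) iv
      else apply(utils::combn(iv, k), 2, paste, collapse = "|")
    })
    tab <- table(unlist(per_path, use.names = FALSE))
    frac <- as.numeric(tab) / n
    names(frac) <- names(tab)
    sort(frac, decreasing = TRUE)
  }
  structure(list(
    n_paths = n,
    length_hist = length_hist,
    vertex_participation = count_combos(1),
    pair_participation = count_combos(2),
    triple_participation = count_combos(3),
    n_distinct_interior = length(unique(unlist(interiors, use.names = FALSE)))),
    class = "path_stats")
}

#' @export
print.path_stats <- function(x, ...) {
  cat(sprintf("<path_stats> %d paths, %d distinct interior vertices\n",
              x$n_paths, x$n_distinct_interior))
  if (length(x$length_hist))
    cat("  lengths: ", paste(sprintf("%s:%d", names(x$length_hist), x$length_hist),
                             collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Fraction of paths fully contained in a vertex set
#'
#' Fraction of traversing paths whose every vertex (endpoints included)
#' belongs to the given set, typically the largest strongly connected
#' component.
#'
#' @param paths A `traversing_paths` object (or bare list of id vectors).
#' @param scc Character vector of vertex ids.
#' @return Fraction in \[0, 1\]; `NA` for an empty path set.
#' @export
scc_containment <- function(paths, scc) {
  if (inherits(paths, "traversing_paths")) paths <- paths$paths
  if (!length(paths)) return(NA_real_)
  mean(vapply(paths, function(p) all(p %in% scc), logical(1)))
}

# shortest directed path from `from` to `to` with all vertices inside
# `members`, of length <= max_len; NULL when none exists
.bounded_domain_path <- function(succ, members, from, to, max_len) {
  if (max_len <= 0 || !from %in% members || !to %in% members) return(NULL)
  # BFS with predecessor tracking
  prev <- setNames(rep(NA_character_, length(members)), members)
  dist <- setNames(rep(Inf, length(members)), members)
  dist[[from]] <- 0
  frontier <- from
  while (length(frontier)) {
    nxt <- character(0)
    for (v in frontier) {
      if (dist[[v]] >= max_len) next
      for (w in succ[[v]]) {
        if (!w %in% members) next
        if (is.infinite(dist[[w]])) {
          dist[[w]] <- dist[[v]] + 1
          prev[[w]] <- v
          nxt <- c(nxt, w)
        }
      }
    }
    if (is.finite(dist[[to]])) break
    frontier <- nxt
  }
  if (!is.finite(dist[[to]]) || dist[[to]] > max_len) return(NULL)
  path <- to
  while (path[1L] != from) path <- c(prev[[path[1L]]], path)
  path
}

#' Compose regulatory-metabolic feedback loops from traversing paths
#'
#' Pairs every upwards path with every downwards path and keeps the pairs
#' closed at both ends: in the regulatory domain the regulator ending the
#' upwards path must coincide with the vertex starting the downwards path
#' (`rd_closure = "identity"`), or be connected to it by a directed path
#' inside RD of at most `rd_max_len` edges (`rd_closure = "path"`;
#' `rd_max_len = 0` reduces to identity). In the metabolic domain the
#' vertex ending the downwards path must reach the vertex starting the
#' upwards path by a single directed edge (`md_closure = "edge"`) or by a
#' directed path inside MD of at most `md_max_len` edges
#' (`md_closure = "path"`).
#'
#' @param g An `annotated_graph`.
#' @param partition A total three-domain `domain_partition`.
#' @param up,down `traversing_paths` objects (upwards and downwards).
#' @param rd_closure `"identity"` or `"path"`.
#' @param md_closure `"edge"` or `"path"`.
#' @param rd_max_len,md_max_len Length bounds for the path closure modes.
#' @return List of feedback loops, each a list with `up`, `down`,
#'   `rd_closure` and `md_closure` (the closure evidence: the shared
#'   vertex or the within-domain connecting path).
#' @export
find_feedback_loops <- function(g, partition, up, down,
                                rd_closure = c("identity", "path"),
                                md_closure = c("edge", "path"),
                                rd_max_len = 1, md_max_len = 1) {
  rd_closure <- match.arg(rd_closure)
  md_closure <- match.arg(md_closure)
  lab <- .check_total_partition(g, partition)
  up_paths <- if (inherits(up, "traversing_paths")) up$paths else up
  down_paths <- if (inherits(down, "traversing_paths")) down$paths else down
  e <- g$edges
  succ <- split(e$target, e$source)
  rd_members <- names(lab)[lab == "RD"]
  md_members <- names(lab)[lab == "MD"]
  edge_set <- paste(e$source, e$target, sep = "\r")

  loops <- list()
  for (u in up_paths) {
    u_end <- u[length(u)]; u_start <- u[1L]
    for (d in down_paths) {
      d_start <- d[1L]; d_end <- d[length(d)]
      # RD closure: upwards end regulates / reaches the downwards start
      if (rd_closure == "identity" || rd_max_len == 0) {
        if (u_end != d_start) next
        rd_ev <- u_end
      } else {
        if (u_end == d_start) rd_ev <- u_end
        else {
          rd_ev <- .bounded_domain_path(succ, rd_members, u_end, d_start, rd_max_len)
          if (is.null(rd_ev)) next
        }
      }
      # MD closure: downwards end feeds the upwards start
      if (md_closure == "edge") {
        if (!paste(d_end, u_start, sep = "\r") %in% edge_set) next
        md_ev <- c(d_end, u_start)
      } else {
        if (d_end == u_start) md_ev <- d_end
        else {
          md_ev <- .bounded_domain_path(succ, md_members, d_end, u_start, md_max_len)
          if (is.null(md_ev)) next
        }
      }
      loops[[length(loops) + 1L]] <- list(up = u, down = d,
                                          rd_closure = rd_ev, md_closure = md_ev)
    }
  }
  loops
}
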