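#' @importFrom stats setNames quantile aggregate
#' @importFrom utils head write.table
NULL

#' Closed vocabulary of vertex types
#'
#' The seven biological vertex classes of the integrated network:
#' biochemical reactions, small compounds, encoding genes, and the four
#' protein classes (monomers and protein-protein, protein-compound and
#' protein-RNA complexes).
#'
#' @return Character vector of the seven vertex type strings.
#' @export
vertex_types <- function() {
  c("reaction", "compound", "gene",
    "protein-monomer", "protein-protein-complex",
    "protein-compound-complex", "protein-RNA-complex")
}

#' Closed vocabulary of edge types
#'
#' Two encoding association types (transcription and translation), four
#' reaction/assembly association types (educt, product, catalysis, complex
#' formation) and one regulatory type.
#'
#' @return Character vector of the seven edge type strings.
#' @export
edge_types <- function() {
  c("transcription-encoding", "translation-encoding",
    "educt", "product", "catalysis", "complex-formation", "regulation")
}

#' Compartment codes
#'
#' Single-letter compartment codes: cytosol (c), extracellular space (e),
#' periplasmic space (p), inner membrane (i), outer membrane (o) and
#' membrane in general (m).
#'
#' @return Character vector of compartment codes.
#' @export
compartment_codes <- function() c("c", "e", "p", "i", "o", "m")

.v_cols <- c(id = "character", vtype = "character", compartment = "character",
             name = "character", covert_map = "character",
             affiliation3 = "character", affiliation2 = "character")
.e_cols <- c(source = "character", target = "character", etype = "character",
             stoichiometry = "integer", regulation_mode = "integer",
             logic = "character", reg_id = "character", reg_name = "character")

.coerce_frame <- function(df, spec) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (nm in names(spec)) {
    if (!nm %in% names(df)) {
      df[[nm]] <- vector(spec[[nm]], nrow(df))
      df[[nm]][] <- NA
    } else {
      df[[nm]] <- switch(spec[[nm]],
                         character = as.character(df[[nm]]),
                         integer = as.integer(df[[nm]]),
                         df[[nm]])
    }
  }
  # schema columns first, opaque extras after
  extra <- setdiff(names(df), names(spec))
  df[, c(names(spec), extra), drop = FALSE]
}

#' Construct an annotated graph
#'
#' An `annotated_graph` is a directed, typed multigraph: a vertex table with
#' the schema columns `id`, `vtype`, `compartment`, `name`, `covert_map`,
#' `affiliation3`, `affiliation2` and an edge table with `source`, `target`,
#' `etype`, `stoichiometry`, `regulation_mode`, `logic`, `reg_id`,
#' `reg_name`. Columns beyond the schema are preserved as opaque metadata.
#' Parallel edges between the same vertex pair are allowed as long as their
#' edge types differ (a transcription factor may both encode-relate to and
#' regulate the same partner).
#'
#' @param vertices Data frame of vertex records (at least `id`, `vtype`).
#' @param edges Data frame of edge records (at least `source`, `target`,
#'   `etype`). May be empty.
#' @param validate Validate the schema (default `TRUE`).
#' @return An object of class `annotated_graph`.
#' @export
annotated_graph <- function(vertices = NULL, edges = NULL, validate = TRUE) {
  if (is.null(vertices)) vertices <- data.frame(id = character(), vtype = character())
  if (is.null(edges)) edges <- data.frame(source = character(), target = character(),
                                          etype = character())
  vertices <- .coerce_frame(vertices, .v_cols)
  edges <- .coerce_frame(edges, .e_cols)
  edges$stoichiometry[is.na(edges$stoichiometry)] <- 0L
  if (!nrow(edges)) edges$stoichiometry <- integer(0)
  rownames(vertices) <- NULL
  rownames(edges) <- NULL
  g <- structure(list(vertices = vertices, edges = edges),
                 class = "annotated_graph")
  if (validate) {
    viol <- validate_annotated_graph(g)
    if (length(viol))
      stop("annotated_graph validation failed:\n  ",
           paste(viol, collapse = "\n  "), call. = FALSE)
  }
  g
}

#' Validate an annotated graph against the schema
#'
#' Checks id uniqueness, the closed vertex/edge type vocabularies,
#' compartment rules (genes and reactions carry none; other vertex classes
#' carry one of the six codes), edge endpoint existence, duplicate
#' `(source, target, etype)` triples, the regulation-mode rule
#' (`regulation_mode` in -1/0/+1 present iff the edge is a regulation edge)
#' and the logic rule (conjunct/disjunct defined for all non-regulation
#' edges).
#'
#' @param g An `annotated_graph` (or a bare list with `vertices`/`edges`).
#' @return Character vector of violations; empty when valid.
#' @export
validate_annotated_graph <- function(g) {
  v <- g$vertices; e <- g$edges
  viol <- character()
  dup <- v$id[duplicated(v$id)]
  if (length(dup))
    viol <- c(viol, paste0("duplicate vertex ids: ", paste(unique(dup), collapse = ", ")))
  bad <- unique(v$vtype[!v$vtype %in% vertex_types()])
  if (length(bad))
    viol <- c(viol, paste0("unknown vtype values: ", paste(bad, collapse = ", ")))
  no_comp <- v$vtype %in% c("gene", "reaction")
  offending <- v$id[no_comp & !is.na(v$compartment)]
  if (length(offending))
    viol <- c(viol, paste0("compartment set on gene/reaction vertices: ",
                           paste(offending, collapse = ", ")))
  bad_comp <- v$id[!no_comp & !is.na(v$compartment) &
                     !v$compartment %in% compartment_codes()]
  if (length(bad_comp))
    viol <- c(viol, paste0("invalid compartment codes on: ",
                           paste(bad_comp, collapse = ", ")))
  if (nrow(e)) {
    bad_e <- unique(e$etype[!e$etype %in% edge_types()])
    if (length(bad_e))
      viol <- c(viol, paste0("unknown etype values: ", paste(bad_e, collapse = ", ")))
    dangling <- unique(c(e$source[!e$source %in% v$id], e$target[!e$target %in% v$id]))
    if (length(dangling))
      viol <- c(viol, paste0("edges reference unknown vertices: ",
                             paste(dangling, collapse = ", ")))
    key <- paste(e$source, e$target, e$etype, sep = "\r")
    if (anyDuplicated(key))
      viol <- c(viol, paste0("duplicate (source, target, etype) triples: ",
                             paste(unique(key[duplicated(key)]), collapse = "; ")))
    is_reg <- e$etype == "regulation"
    if (any(is_reg & (is.na(e$regulation_mode) | !e$regulation_mode %in% c(-1L, 0L, 1L))))
      viol <- c(viol, "regulation edges must carry regulation_mode in {-1, 0, +1}")
    if (any(!is_reg & !is.na(e$regulation_mode)))
      viol <- c(viol, "regulation_mode set on non-regulation edges")
    if (any(!is_reg & (is.na(e$logic) | !e$logic %in% c("conjunct", "disjunct"))))
      viol <- c(viol, "non-regulation edges must carry logic conjunct|disjunct")
  }
  viol
}

#' @export
print.annotated_graph <- function(x, ...) {
  cat(sprintf("<annotated_graph> %d vertices, %d edges\n",
              nrow(x$vertices), nrow(x$edges)))
  if (nrow(x$vertices)) {
    tb <- table(x$vertices$vtype)
    cat("  vertex types: ",
        paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n", sep = "")
  }
  if (nrow(x$edges)) {
    tb <- table(x$edges$etype)
    cat("  edge types:   ",
        paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Number of vertices / edges
#' @param g An `annotated_graph`.
#' @return Integer count.
#' @export
n_vertices <- function(g) nrow(g$vertices)

#' @rdname n_vertices
#' @export
n_edges <- function(g) nrow(g$edges)

#' Convert an annotated graph to an igraph object
#'
#' All vertex and edge attributes are carried over; the igraph object is
#' directed. Views needed by undirected metrics are derived from it, never
#' stored.
#'
#' @param g An `annotated_graph`.
#' @return An [igraph::graph] object.
#' @export
as_igraph <- function(g) {
  v <- g$vertices
  # igraph reserves the vertex attribute "name" for the id; keep the
  # display string under display_name so it cannot clobber the ids
  names(v)[names(v) == "name"] <- "display_name"
  e <- g$edges
  names(e)[names(e) == "source"] <- "from"
  names(e)[names(e) == "target"] <- "to"
  igraph::graph_from_data_frame(e, directed = TRUE, vertices = v)
}

#' Induced subgraph on a set of vertex ids
#'
#' @param g An `annotated_graph`.
#' @param ids Character vector of vertex ids to keep.
#' @return The induced `annotated_graph` (edges with both endpoints kept).
#' @export
induced_annotated_subgraph <- function(g, ids) {
  v <- g$vertices[g$vertices$id %in% ids, , drop = FALSE]
  e <- g$edges[g$edges$source %in% ids & g$edges$target %in% ids, , drop = FALSE]
  annotated_graph(v, e, validate = FALSE)
}

.component_membership <- function(g, mode) {
  if (!n_vertices(g)) return(integer(0))
  comp <- igraph::components(as_igraph(g), mode = mode)
  setNames(comp$membership, g$vertices$id)
}

.largest_component_ids <- function(membership) {
  if (!length(membership)) return(character(0))
  sizes <- table(membership)
  top <- names(sizes)[sizes == max(sizes)]
  if (length(top) > 1L) {
    # deterministic tie-break: component holding the lexicographically
    # smallest member id (C collation)
    mins <- vapply(top, function(cc) {
      ids <- names(membership)[membership == as.integer(cc)]
      sort(ids, method = "radix")[1L]
    }, character(1))
    top <- top[order(mins, method = "radix")][1L]
  }
  names(membership)[membership == as.integer(top[1L])]
}

#' Largest weakly connected component
#'
#' Induced subgraph on the largest weak component of the directed graph.
#' Ties in component size are broken deterministically towards the
#' component containing the lexicographically smallest vertex id.
#'
#' @param g An `annotated_graph`.
#' @return The induced `annotated_graph`; the empty graph maps to itself.
#' @export
largest_weakly_connected_component <- function(g) {
  if (!n_vertices(g)) return(g)
  induced_annotated_subgraph(g, .largest_component_ids(.component_membership(g, "weak")))
}

#' Largest strongly connected component
#'
#' Vertex id set of the largest strongly connected component under edge
#' direction. In a DAG every SCC is a singleton and the lexicographically
#' smallest vertex id is returned.
#'
#' @param g An `annotated_graph`.
#' @return Character vector of vertex ids (sorted).
#' @export
largest_strongly_connected_component <- function(g) {
  if (!n_vertices(g)) return(character(0))
  sort(.largest_component_ids(.component_membership(g, "strong")), method = "radix")
}
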