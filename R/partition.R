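#' Domain partition object
#'
#' A total map from vertex id to domain label for one of the four
#' partitioning schemes: functional or vertex-driven, with two (MD--RD) or
#' three (MD--PI--RD) domains.
#'
#' @param labels Named character vector, vertex id -> label.
#' @param method `"functional"` or `"vertex_driven"`.
#' @param n_domains 2 or 3.
#' @param n_unresolved Number of vertices still ambiguous at the affiliation
#'   fixed point (functional partitions only).
#' @param trace Optional per-round trace data frame.
#' @return An object of class `domain_partition`.
#' @export
domain_partition <- function(labels, method, n_domains,
                             n_unresolved = NA_integer_, trace = NULL) {
  allowed <- if (n_domains == 3) c("MD", "PI", "RD") else c("MD", "RD")
  if (length(labels) && !all(labels %in% allowed))
    stop("labels outside the ", n_domains, "-domain scheme: ",
         paste(unique(labels[!labels %in% allowed]), collapse = ", "), call. = FALSE)
  structure(list(labels = labels, method = method, n_domains = as.integer(n_domains),
                 n_unresolved = as.integer(n_unresolved), trace = trace),
            class = "domain_partition")
}

#' @export
print.domain_partition <- function(x, ...) {
  cat(sprintf("<domain_partition> %s, %d domains, %d vertices\n",
              x$method, x$n_domains, length(x$labels)))
  if (length(x$labels)) {
    tb <- table(x$labels)
    cat("  ", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n", sep = "")
  }
  if (!is.na(x$n_unresolved))
    cat("  unresolved at fixed point: ", x$n_unresolved, "\n", sep = "")
  invisible(x)
}

#' Members of one domain
#' @param partition A `domain_partition`.
#' @param domain Domain label (`"MD"`, `"PI"` or `"RD"`).
#' @return Character vector of vertex ids.
#' @export
domain_members <- function(partition, domain) {
  names(partition$labels)[partition$labels == domain]
}

#' Write a partition as two-column TSV
#' @param partition A `domain_partition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition_tsv <- function(partition, path) {
  df <- data.frame(id = names(partition$labels), label = unname(partition$labels))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write partition labels back into the graph's affiliation attributes
#' @param g An `annotated_graph`.
#' @param partition A `domain_partition` covering `g`'s vertices.
#' @return The graph with `affiliation3` or `affiliation2` filled in.
#' @export
apply_partition <- function(g, partition) {
  col <- if (partition$n_domains == 3) "affiliation3" else "affiliation2"
  g$vertices[[col]] <- unname(partition$labels[g$vertices$id])
  g
}

# ---------------------------------------------------------------------------
# Functional affiliation (iterative fixed point)
# ---------------------------------------------------------------------------

.is_protein <- function(vtype) {
  vtype %in% c("protein-monomer", "protein-protein-complex",
               "protein-compound-complex", "protein-RNA-complex")
}

# Closure of regulatory involvement over the protein/gene layer:
# a protein is involved in regulation if it is endpoint of a regulation
# edge, if it is encoded by a regulation-incident gene, or if it shares a
# complex-formation edge with an involved protein (transitively).
.regulation_involved_proteins <- function(v, e) {
  prot <- v$id[.is_protein(v$vtype)]
  reg <- e[e$etype == "regulation", , drop = FALSE]
  reg_genes <- v$id[v$vtype == "gene" & (v$id %in% reg$source | v$id %in% reg$target)]
  enc <- e[e$etype %in% c("translation-encoding", "transcription-encoding"), , drop = FALSE]
  seeds <- unique(c(intersect(c(reg$source, reg$target), prot),
                    intersect(enc$target[enc$source %in% reg_genes], prot)))
  cf <- e[e$etype == "complex-formation", , drop = FALSE]
  # undirected complex adjacency restricted to proteins
  cf <- cf[cf$source %in% prot & cf$target %in% prot, , drop = FALSE]
  adj <- split(c(cf$target, cf$source), c(cf$source, cf$target))
  involved <- seeds
  frontier <- seeds
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), involved)
    involved <- c(involved, nxt)
    frontier <- nxt
  }
  involved
}

# Proteins that act as regulation sources, plus (transitively) the
# components assembling into such a regulator. Genes encoding a member of
# this closure count as regulatory genes.
.regulator_source_closure <- function(v, e) {
  prot <- v$id[.is_protein(v$vtype)]
  src <- intersect(unique(e$source[e$etype == "regulation"]), prot)
  cf <- e[e$etype == "complex-formation" & e$source %in% prot, , drop = FALSE]
  comp_of <- split(cf$source, cf$target)   # complex -> protein components
  closure <- src
  frontier <- src
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(comp_of[frontier], use.names = FALSE)), closure)
    closure <- c(closure, nxt)
    frontier <- nxt
  }
  closure
}

#' Functional domain affiliation (MD--PI--RD fixed point)
#'
#' Assigns every vertex to the metabolic domain (MD), protein interface
#' (PI) or regulatory domain (RD) by the biologically motivated rule set,
#' then optionally merges to the two-domain MD--RD scheme.
#'
#' Seeding: a reaction whose educts and products are all compounds is
#' purely metabolic (MD); all proteins makes it interface-related (PI);
#' mixed participation is deferred. A gene is RD when it takes part in a
#' regulation edge or encodes (possibly via complex assembly) a regulation
#' source, and MD otherwise. A compound or protein with no regulatory
#' involvement is MD. Remaining vertices are deferred and resolved in
#' synchronous rounds from the labels of their *influential* neighbours
#' (see [influence_table()]): agreement on MD or RD adopts that label, a
#' pull from both sides classifies the vertex as interface (PI), and
#' interface neighbours exert no directional pull. Mutually deferred
#' clusters remaining at the round fixed point are resolved from the labels
#' on their boundary; clusters with no labelled boundary at all stay
#' ambiguous and are assigned PI -- these are the vertices counted by
#' [count_unresolved()].
#'
#' Rounds are synchronous, so the fixed point does not depend on vertex
#' iteration order. A safety cap of `|V|` rounds guards the iteration (each
#' vertex can be relabelled at most once).
#'
#' @param g An `annotated_graph`.
#' @param n_domains 2 or 3. For `n_domains = 2` the PI vertices are merged
#'   onto the side holding the majority of their non-regulation edges
#'   (ties and isolated interface vertices fall to RD).
#' @param trace Record a per-round trace of (vertex, rule, label).
#' @return A `domain_partition`; `$n_unresolved` holds the count of
#'   vertices still ambiguous at the fixed point.
#' @export
affiliate_functional <- function(g, n_domains = 3, trace = FALSE) {
  stopifnot(n_domains %in% c(2, 3))
  v <- g$vertices
  e <- g$edges
  n <- nrow(v)
  labels <- setNames(rep(NA_character_, n), v$id)
  tr <- if (trace) list() else NULL
  note <- function(ids, rule, lab, round) {
    if (trace && length(ids))
      tr[[length(tr) + 1L]] <<- data.frame(round = round, id = ids,
                                           rule = rule, label = lab)
  }
  if (n) {
    vtype <- setNames(v$vtype, v$id)
    reg <- e[e$etype == "regulation", , drop = FALSE]
    ep <- e[e$etype %in% c("educt", "product"), , drop = FALSE]

    # --- seeds -------------------------------------------------------------
    # reactions, by educt/product participant composition
    rxn <- v$id[vtype == "reaction"]
    part_of <- lapply(setNames(rxn, rxn), function(r)
      unique(c(ep$source[ep$target == r & ep$etype == "educt"],
               ep$target[ep$source == r & ep$etype == "product"])))
    for (r in rxn) {
      p <- part_of[[r]]
      if (!length(p) || all(vtype[p] == "compound")) labels[r] <- "MD"
      else if (all(.is_protein(vtype[p]))) labels[r] <- "PI"
    }
    note(rxn[!is.na(labels[rxn])], "reaction-composition", labels[rxn[!is.na(labels[rxn])]], 0L)

    # genes
    genes <- v$id[vtype == "gene"]
    reg_closure <- .regulator_source_closure(v, e)
    enc <- e[e$etype %in% c("translation-encoding", "transcription-encoding"), , drop = FALSE]
    gene_rd <- genes[genes %in% c(reg$source, reg$target) |
                       genes %in% enc$source[enc$target %in% reg_closure]]
    labels[gene_rd] <- "RD"
    labels[setdiff(genes, gene_rd)] <- "MD"
    note(gene_rd, "gene-regulatory", "RD", 0L)
    note(setdiff(genes, gene_rd), "gene-no-regulation", "MD", 0L)

    # proteins with no regulatory involvement are metabolic
    prot <- v$id[.is_protein(vtype)]
    involved <- .regulation_involved_proteins(v, e)
    prot_md <- setdiff(prot, involved)
    labels[prot_md] <- "MD"
    note(prot_md, "protein-no-regulation", "MD", 0L)

    # --- influential neighbour sets for deferred vertices ------------------
    deferred <- names(labels)[is.na(labels)]
    infl <- .influential_sets(v, e, deferred, part_of)

    # compounds with no influential neighbours are metabolic by default
    cmpd_iso <- deferred[vtype[deferred] == "compound" &
                           !vapply(infl[deferred], length, integer(1))]
    labels[cmpd_iso] <- "MD"
    note(cmpd_iso, "compound-default", "MD", 0L)
    deferred <- setdiff(deferred, cmpd_iso)

    # --- synchronous rounds ------------------------------------------------
    round <- 0L
    repeat {
      round <- round + 1L
      if (round > n + 1L)
        stop("affiliation fixed point not reached within |V| rounds", call. = FALSE)
      prev <- labels
      changed <- FALSE
      for (u in deferred) {
        s <- infl[[u]]
        labs <- prev[s]
        pull <- unique(labs[!is.na(labs) & labs != "PI"])
        if (length(pull) >= 2L) {
          labels[u] <- "PI"            # conflicting pull is final
          note(u, "neighbour-conflict", "PI", round)
          changed <- TRUE
        } else if (!anyNA(labs)) {
          lab <- if (length(pull) == 1L) pull else "PI"
          labels[u] <- lab
          note(u, if (length(pull)) "neighbour-agreement" else "interface-surrounded",
               lab, round)
          changed <- TRUE
        }
      }
      deferred <- names(labels)[is.na(labels)]
      if (!changed || !length(deferred)) break
    }

    # --- residual mutually-deferred clusters -------------------------------
    n_unresolved <- 0L
    if (length(deferred)) {
      # undirected influence adjacency restricted to deferred vertices
      pairs <- do.call(rbind, lapply(deferred, function(u) {
        s <- intersect(infl[[u]], deferred)
        if (length(s)) cbind(u, s) else NULL
      }))
      dg <- igraph::graph_from_data_frame(
        if (is.null(pairs)) data.frame(from = character(), to = character())
        else data.frame(from = pairs[, 1], to = pairs[, 2]),
        directed = FALSE,
        vertices = data.frame(name = deferred))
      mem <- igraph::components(dg)$membership
      for (cc in unique(mem)) {
        cl <- deferred[mem == cc]
        boundary <- setdiff(unique(unlist(infl[cl], use.names = FALSE)), cl)
        pull <- unique(labels[boundary])
        pull <- pull[!is.na(pull) & pull != "PI"]
        if (length(pull) == 1L) {
          labels[cl] <- pull
          note(cl, "cluster-boundary", pull, round + 1L)
        } else if (length(pull) >= 2L) {
          labels[cl] <- "PI"
          note(cl, "cluster-conflict", "PI", round + 1L)
        } else {
          labels[cl] <- "PI"
          n_unresolved <- n_unresolved + length(cl)
          note(cl, "ambiguous", "PI", round + 1L)
        }
      }
    }
  } else n_unresolved <- 0L

  trace_df <- if (trace && length(tr)) do.call(rbind, tr) else NULL
  if (n_domains == 3)
    return(domain_partition(labels, "functional", 3, n_unresolved, trace_df))

  # --- two-domain merge ----------------------------------------------------
  lab2 <- labels
  pi_v <- names(labels)[labels == "PI"]
  if (length(pi_v)) {
    nonreg <- e[e$etype != "regulation", , drop = FALSE]
    for (u in pi_v) {
      nb <- c(nonreg$target[nonreg$source == u], nonreg$source[nonreg$target == u])
      side <- labels[nb]
      md <- sum(side == "MD", na.rm = TRUE)
      rd <- sum(side == "RD", na.rm = TRUE)
      lab2[u] <- if (md > rd) "MD" else "RD"
    }
  }
  domain_partition(lab2, "functional", 2, n_unresolved, trace_df)
}

# Influential neighbour sets, one declarative table of scopes per vertex
# class; see influence_table() for the documented summary.
.influential_sets <- function(v, e, deferred, part_of) {
  vtype <- setNames(v$vtype, v$id)
  reg <- e[e$etype == "regulation", , drop = FALSE]
  nonreg <- e[e$etype != "regulation", , drop = FALSE]
  ep <- e[e$etype %in% c("educt", "product"), , drop = FALSE]
  out <- setNames(vector("list", length(deferred)), deferred)
  for (u in deferred) {
    tu <- vtype[[u]]
    if (tu == "reaction") {
      # mixed reactions wait on their protein educt/product participants
      p <- part_of[[u]]
      out[[u]] <- p[.is_protein(vtype[p])]
    } else if (tu == "compound") {
      # reactions consuming/producing the compound, plus regulation sources
      rx <- unique(c(ep$target[ep$source == u & ep$etype == "educt"],
                     ep$source[ep$target == u & ep$etype == "product"]))
      out[[u]] <- unique(c(rx, reg$source[reg$target == u]))
    } else {
      # proteins: all neighbours via non-regulation edges + regulation sources
      nb <- unique(c(nonreg$target[nonreg$source == u],
                     nonreg$source[nonreg$target == u],
                     reg$source[reg$target == u]))
      out[[u]] <- nb
    }
  }
  out
}

#' Influential-neighbour scopes used by the affiliation rules
#'
#' The neighbour scope consulted when resolving a deferred vertex is a
#' fixed, declarative table per vertex class: mixed reactions wait on their
#' protein educt/product participants; compounds look at the reactions they
#' take part in plus any regulators targeting them (and default to MD when
#' that scope is empty); proteins look at all neighbours reached via
#' non-regulation edges plus regulation sources targeting them. Genes are
#' never deferred (they are seeded from their regulatory involvement).
#'
#' @return Data frame describing the scope per vertex class.
#' @export
influence_table <- function() {
  data.frame(
    vclass = c("reaction (mixed participants)", "compound", "protein", "gene"),
    scope = c("protein educt/product participants",
              "educt/product reaction partners + regulation sources; empty scope -> MD",
              "all non-regulation neighbours + regulation sources",
              "seeded: RD iff regulation-incident or encoding a regulation source, else MD"),
    stringsAsFactors = FALSE)
}

#' Vertex-driven domain partition
#'
#' Partition by vertex type alone: in the three-domain scheme genes form
#' the regulatory domain, all protein classes the interface, and reactions
#' plus compounds the metabolic domain. In the two-domain scheme genes and
#' proteins together form the regulatory side.
#'
#' @param g An `annotated_graph`.
#' @param n_domains 2 or 3.
#' @return A `domain_partition`.
#' @export
affiliate_vertex_driven <- function(g, n_domains = 3) {
  stopifnot(n_domains %in% c(2, 3))
  vtype <- g$vertices$vtype
  lab <- ifelse(vtype == "gene", "RD",
                ifelse(.is_protein(vtype), if (n_domains == 3) "PI" else "RD", "MD"))
  domain_partition(setNames(lab, g$vertices$id), "vertex_driven", n_domains)
}

#' Count vertices unresolved at the affiliation fixed point
#'
#' Number of vertices that the functional affiliation could not assign to a
#' domain even after cluster-boundary resolution; these ambiguous vertices
#' are assigned to the protein interface.
#'
#' @param g An `annotated_graph`.
#' @return Integer count.
#' @export
count_unresolved <- function(g) {
  affiliate_functional(g, n_domains = 3)$n_unresolved
}
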