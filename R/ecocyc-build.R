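.COMPARTMENT_ALIASES <- c("CCO-CYTOSOL" = "c", "CCO-PERI-BAC" = "p",
                          "CCO-PM-BAC-NEG" = "i", "CCO-EXTRACELLULAR" = "e",
                          "CCO-OUTER-MEM" = "o", "CCO-MEMBRANE" = "m")

.norm_compartment <- function(x, default = "c") {
  if (is.null(x) || !length(x) || is.na(x) || !nzchar(x)) return(default)
  if (x %in% names(.COMPARTMENT_ALIASES)) return(unname(.COMPARTMENT_ALIASES[x]))
  x
}

.first_value <- function(record, key) {
  v <- record_values(record, key)
  if (length(v)) v[1L] else NA_character_
}

#' Validate and classify vertex candidates from parsed flat files
#'
#' Classifies every database object into one of the seven vertex types:
#' compounds, genes, reactions (reversible ones split into a forward
#' vertex and a `_REV` twin), and proteins divided by composition into
#' monomer, protein-protein, protein-compound and protein-RNA complex.
#' Generic class terms (e.g. DIPEPTIDES) are substituted by their member
#' instances via the classes records and do not become vertices; double
#' annotations (`ALIAS-OF`) are decoded to one canonical id with the alias
#' logged. Reactions located outside the periplasm / inner membrane /
#' cytosol compartments are dropped with a report entry, as are candidates
#' matching no vertex type. Objects without a stated compartment default
#' to the cytosol, logged per vertex.
#'
#' @param raw A `raw_record_set` from [parse_flat_files()].
#' @return Object of class `vertex_candidates`: `$vertices` (vertex record
#'   data frame), `$report` (a `validation_report` with accepted counts,
#'   substitutions, aliases, dropped candidates and compartment defaults)
#'   and `$maps` (alias, class-member, RNA-to-gene, composition and
#'   reversible lookup tables used by [build_edges()]).
#' @export
build_candidate_vertices <- function(raw) {
  f <- raw$files
  aliases <- list()
  dropped <- list()
  defaulted <- character(0)

  # alias decoding (compounds and proteins)
  alias_map <- character(0)
  for (fn in c("compounds.dat", "proteins.dat")) {
    for (r in f[[fn]]) {
      canon <- .first_value(r, "ALIAS-OF")
      if (!is.na(canon)) {
        alias_map[r$id] <- canon
        aliases[[length(aliases) + 1L]] <- data.frame(alias = r$id, canonical = canon)
      }
    }
  }
  resolve <- function(id) if (id %in% names(alias_map)) unname(alias_map[id]) else id

  # generic class terms -> member instances
  class_map <- lapply(f[["classes.dat"]], function(r) record_values(r, "MEMBERS"))
  names(class_map) <- names(f[["classes.dat"]])
  substitutions <- if (length(class_map)) {
    do.call(rbind, lapply(names(class_map), function(cl)
      if (length(class_map[[cl]]))
        data.frame(class_term = cl, member = class_map[[cl]]) else NULL))
  } else NULL

  vertices <- list()
  add_vertex <- function(id, vtype, compartment = NA_character_, name = NA_character_) {
    vertices[[length(vertices) + 1L]] <<- data.frame(
      id = id, vtype = vtype, compartment = compartment, name = name,
      stringsAsFactors = FALSE)
  }

  # compounds (canonical records only; class members ensured present)
  compound_ids <- character(0)
  for (r in f[["compounds.dat"]]) {
    if (r$id %in% names(alias_map)) next
    comp <- .first_value(r, "COMPARTMENT")
    if (is.na(comp)) defaulted <- c(defaulted, r$id)
    add_vertex(r$id, "compound", .norm_compartment(comp), .first_value(r, "COMMON-NAME"))
    compound_ids <- c(compound_ids, r$id)
  }
  for (m in unique(unlist(class_map, use.names = FALSE))) {
    m <- resolve(m)
    if (!m %in% compound_ids) {
      add_vertex(m, "compound", "c", NA_character_)
      defaulted <- c(defaulted, m)
      compound_ids <- c(compound_ids, m)
    }
  }

  # genes
  gene_ids <- names(f[["genes.dat"]])
  for (r in f[["genes.dat"]])
    add_vertex(r$id, "gene", NA_character_, .first_value(r, "COMMON-NAME"))

  # RNAs are not vertices: they resolve to their encoding gene
  rna_map <- vapply(f[["rnas.dat"]], function(r) .first_value(r, "GENE"), character(1))

  # protein composition: proteins.dat COMPONENTS merged with protcplxs.col
  composition <- list()
  for (r in f[["proteins.dat"]]) {
    ent <- record_entries(r, "COMPONENTS")
    if (length(ent)) composition[[r$id]] <- ent
  }
  for (r in f[["protcplxs.col"]]) {
    ent <- record_entries(r, "COMPONENTS")
    if (length(ent)) composition[[r$id]] <- ent
  }

  protein_ids <- setdiff(names(f[["proteins.dat"]]), names(alias_map))
  classify_protein <- function(id) {
    comp <- composition[[id]]
    if (is.null(comp) || !length(comp)) return("protein-monomer")
    kinds <- vapply(comp, function(en) {
      ref <- resolve(en$value)
      if (ref %in% compound_ids) "compound"
      else if (ref %in% names(rna_map)) "rna"
      else if (ref %in% protein_ids) "protein"
      else "unknown"
    }, character(1))
    if (any(kinds == "unknown")) return(NA_character_)
    if (any(kinds == "compound")) "protein-compound-complex"
    else if (any(kinds == "rna")) "protein-RNA-complex"
    else "protein-protein-complex"
  }
  for (id in protein_ids) {
    r <- f[["proteins.dat"]][[id]]
    vt <- classify_protein(id)
    if (is.na(vt)) {
      dropped[[length(dropped) + 1L]] <- data.frame(
        id = id, stage = "vertex", reason = "complex with unidentified component")
      next
    }
    comp <- .first_value(r, "COMPARTMENT")
    if (is.na(comp)) defaulted <- c(defaulted, id)
    add_vertex(id, vt, .norm_compartment(comp), .first_value(r, "COMMON-NAME"))
  }

  # reactions: compartment restriction + reversible splitting
  reversible <- character(0)
  for (r in f[["reactions.dat"]]) {
    loc <- .norm_compartment(.first_value(r, "RXN-LOCATIONS"))
    if (!loc %in% c("c", "i", "p")) {
      dropped[[length(dropped) + 1L]] <- data.frame(
        id = r$id, stage = "vertex",
        reason = paste0("reaction outside periplasm/inner membrane/cytosol (", loc, ")"))
      next
    }
    nm <- .first_value(r, "EC-NUMBER")
    add_vertex(r$id, "reaction", NA_character_, nm)
    dir <- .first_value(r, "REACTION-DIRECTION")
    if (!is.na(dir) && dir == "REVERSIBLE") {
      add_vertex(paste0(r$id, "_REV"), "reaction", NA_character_, nm)
      reversible <- c(reversible, r$id)
    }
  }

  vdf <- if (length(vertices)) do.call(rbind, vertices) else
    data.frame(id = character(), vtype = character(),
               compartment = character(), name = character())
  report <- structure(list(
    accepted = table(factor(vdf$vtype, levels = vertex_types())),
    substitutions = substitutions,
    aliases = if (length(aliases)) do.call(rbind, aliases) else NULL,
    dropped = if (length(dropped)) do.call(rbind, dropped) else NULL,
    compartment_defaulted = unique(defaulted)), class = "validation_report")
  structure(list(vertices = vdf, report = report,
                 maps = list(alias = alias_map, classes = class_map,
                             rna_gene = rna_map, composition = composition,
                             reversible = reversible)),
            class = "vertex_candidates")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n  accepted: ",
      paste(sprintf("%s=%d", names(x$accepted), x$accepted), collapse = ", "), "\n",
      sep = "")
  cat("  substitutions: ", if (is.null(x$substitutions)) 0L else nrow(x$substitutions),
      "; aliases: ", if (is.null(x$aliases)) 0L else nrow(x$aliases),
      "; dropped: ", if (is.null(x$dropped)) 0L else nrow(x$dropped), "\n", sep = "")
  invisible(x)
}

#' Build the edge list from parsed records and validated vertices
#'
#' Emits the seven edge classes: translation-encoding edges from each gene
#' to its validated protein product; transcription-encoding edges standing
#' in for RNA components of protein-RNA complexes (the RNA is translated
#' into its encoding gene); complex-formation edges from each component to
#' its complex (conjunct, with coefficients as stoichiometry); educt and
#' product edges of every validated reaction (reversible reactions emit
#' the swapped edge set for their `_REV` twin); catalysis edges from
#' enzymes to reactions; and regulation edges. Regulation processes are
#' multiplied over the genes of the target transcription unit (the
#' multi-valued `REGULATED-ENTITY` attribute), RNA regulators and targets
#' are replaced by their encoding genes, and regulation of a split
#' reversible reaction applies to both direction twins. Any process citing
#' a participant absent from the validated vertex set is dropped entirely
#' and recorded in the report with the unidentified vertex named.
#'
#' @param raw A `raw_record_set`.
#' @param candidates A `vertex_candidates` from [build_candidate_vertices()].
#' @return List with `$edges` (edge record data frame) and
#'   `$dropped_processes` (data frame naming each dropped process and its
#'   unidentified participant or reason).
#' @export
build_edges <- function(raw, candidates) {
  f <- raw$files
  v <- candidates$vertices
  maps <- candidates$maps
  vid <- v$id
  edges <- list()
  dropped <- list()
  drop <- function(process, reason) {
    dropped[[length(dropped) + 1L]] <<- data.frame(process = process, reason = reason)
  }
  add_edge <- function(source, target, etype, stoichiometry = 0L,
                       regulation_mode = NA_integer_, logic = NA_character_,
                       reg_id = NA_character_, reg_name = NA_character_) {
    edges[[length(edges) + 1L]] <<- data.frame(
      source = source, target = target, etype = etype,
      stoichiometry = as.integer(stoichiometry),
      regulation_mode = regulation_mode, logic = logic,
      reg_id = reg_id, reg_name = reg_name, stringsAsFactors = FALSE)
  }
  resolve <- function(id) {
    if (id %in% names(maps$alias)) id <- unname(maps$alias[id])
    if (id %in% names(maps$rna_gene)) id <- unname(maps$rna_gene[id])
    id
  }
  expand_class <- function(id) {
    if (id %in% names(maps$classes)) vapply(maps$classes[[id]], resolve, character(1))
    else id
  }

  # encoding: gene -> protein product
  for (r in f[["genes.dat"]]) {
    prod <- .first_value(r, "PRODUCT")
    if (is.na(prod)) next
    prod_res <- if (prod %in% names(maps$alias)) unname(maps$alias[prod]) else prod
    if (prod_res %in% names(maps$rna_gene)) next   # RNA products surface via complexes
    if (!prod_res %in% vid) {
      drop(paste0("encoding:", r$id), paste0("unidentified product ", prod))
      next
    }
    add_edge(r$id, prod_res, "translation-encoding", logic = "disjunct")
  }

  # complex formation
  for (cx in names(maps$composition)) {
    if (!cx %in% vid) next
    comp <- maps$composition[[cx]]
    refs <- lapply(comp, function(en) {
      raw_ref <- if (en$value %in% names(maps$alias)) unname(maps$alias[en$value]) else en$value
      coeff <- en$annotations[["COEFFICIENT"]]
      list(ref = raw_ref, coeff = if (is.null(coeff)) 1L else as.integer(coeff))
    })
    unidentified <- vapply(refs, function(x)
      !(x$ref %in% vid || x$ref %in% names(maps$rna_gene)), logical(1))
    if (any(unidentified)) {
      drop(paste0("complex:", cx),
           paste0("unidentified component ",
                  paste(vapply(refs[unidentified], `[[`, character(1), "ref"),
                        collapse = ", ")))
      next
    }
    for (x in refs) {
      if (x$ref %in% names(maps$rna_gene)) {
        gene <- unname(maps$rna_gene[x$ref])
        if (!gene %in% vid) {
          drop(paste0("complex:", cx), paste0("unidentified encoding gene ", gene))
        } else {
          add_edge(gene, cx, "transcription-encoding", x$coeff, logic = "conjunct")
        }
      } else {
        add_edge(x$ref, cx, "complex-formation", x$coeff, logic = "conjunct")
      }
    }
  }

  # reactions: educt/product (+ swapped twin for reversible) and catalysis
  for (r in f[["reactions.dat"]]) {
    if (!r$id %in% vid) next  # dropped at vertex stage
    side <- function(key) {
      ent <- record_entries(r, key)
      out <- list()
      for (en in ent) {
        coeff <- en$annotations[["COEFFICIENT"]]
        coeff <- if (is.null(coeff)) 1L else as.integer(coeff)
        for (ref in expand_class(resolve(en$value)))
          out[[length(out) + 1L]] <- list(ref = ref, coeff = coeff)
      }
      out
    }
    lhs <- side("LEFT"); rhs <- side("RIGHT")
    refs <- vapply(c(lhs, rhs), `[[`, character(1), "ref")
    missing <- setdiff(refs, vid)
    if (length(missing)) {
      drop(paste0("reaction:", r$id),
           paste0("unidentified participant ", paste(missing, collapse = ", ")))
      next
    }
    twins <- r$id
    if (r$id %in% maps$reversible) twins <- c(twins, paste0(r$id, "_REV"))
    for (i in seq_along(twins)) {
      rx <- twins[i]
      el <- if (i == 1L) lhs else rhs
      pr <- if (i == 1L) rhs else lhs
      for (x in el) add_edge(x$ref, rx, "educt", x$coeff, logic = "conjunct")
      for (x in pr) add_edge(rx, x$ref, "product", x$coeff, logic = "disjunct")
    }
    for (enz in record_values(r, "ENZYMES")) {
      enz_res <- resolve(enz)
      if (!enz_res %in% vid) {
        drop(paste0("catalysis:", r$id), paste0("unidentified enzyme ", enz))
        next
      }
      for (rx in twins) add_edge(enz_res, rx, "catalysis", logic = "disjunct")
    }
  }

  # regulation: one edge per gene of the target transcription unit
  for (r in f[["regulation.dat"]]) {
    regulator <- .first_value(r, "REGULATOR")
    if (is.na(regulator)) { drop(paste0("regulation:", r$id), "no regulator"); next }
    regulator <- resolve(regulator)
    targets <- record_values(r, "REGULATED-ENTITY")
    if (!length(targets)) {
      drop(paste0("regulation:", r$id), "transcription unit with zero genes")
      next
    }
    targets <- vapply(targets, resolve, character(1), USE.NAMES = FALSE)
    missing <- setdiff(c(regulator, targets), vid)
    if (length(missing)) {
      drop(paste0("regulation:", r$id),
           paste0("unidentified participant ", paste(missing, collapse = ", ")))
      next
    }
    mode_raw <- .first_value(r, "MODE")
    mode <- if (is.na(mode_raw)) 0L else switch(mode_raw, "+" = 1L, "-" = -1L, 0L)
    nm <- .first_value(r, "COMMON-NAME")
    for (tg in targets) {
      expanded <- tg
      if (tg %in% maps$reversible) expanded <- c(tg, paste0(tg, "_REV"))
      for (tg2 in expanded)
        add_edge(regulator, tg2, "regulation", regulation_mode = mode,
                 reg_id = r$id, reg_name = nm)
    }
  }

  edf <- if (length(edges)) do.call(rbind, edges) else
    data.frame(source = character(), target = character(), etype = character())
  # class expansion can duplicate (source, target, etype); keep one
  if (nrow(edf)) {
    key <- paste(edf$source, edf$target, edf$etype, sep = "\r")
    edf <- edf[!duplicated(key), , drop = FALSE]
  }
  list(edges = edf,
       dropped_processes = if (length(dropped)) do.call(rbind, dropped) else NULL)
}

#' Assemble the annotated graph from validated vertices and edges
#'
#' Builds and validates the full graph, then extracts its largest weakly
#' connected component (the analysis graph); dropped processes can leave
#' isolated vertices behind, which the component extraction removes.
#'
#' @param vertices Vertex record data frame (or a `vertex_candidates`).
#' @param edges Edge record data frame (or the list from [build_edges()]).
#' @return List with `$full` (full `annotated_graph`) and `$wcc` (its
#'   largest weakly connected component).
#' @export
assemble_network <- function(vertices, edges) {
  if (inherits(vertices, "vertex_candidates")) vertices <- vertices$vertices
  if (is.list(edges) && !is.data.frame(edges) && !is.null(edges$edges))
    edges <- edges$edges
  full <- annotated_graph(vertices, edges, validate = TRUE)
  list(full = full, wcc = largest_weakly_connected_component(full))
}

#' One-call reconstruction from a flat-file directory
#'
#' Convenience wrapper chaining [parse_flat_files()],
#' [build_candidate_vertices()], [build_edges()] and [assemble_network()].
#'
#' @param directory Flat-file directory.
#' @param strict Passed to [parse_flat_files()].
#' @return List with `$full`, `$wcc`, `$report`, `$dropped_processes`.
#' @export
reconstruct_network <- function(directory, strict = FALSE) {
  raw <- parse_flat_files(directory, strict = strict)
  cand <- build_candidate_vertices(raw)
  ed <- build_edges(raw, cand)
  net <- assemble_network(cand, ed)
  c(net, list(report = cand$report, dropped_processes = ed$dropped_processes))
}
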