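.GRAPHML_NS <- "http://graphml.graphdrawing.org/xmlns"

# Attribute typing for GraphML <key> declarations.
.graphml_attr_type <- function(x) {
  if (is.integer(x)) "long" else if (is.numeric(x)) "double"
  else if (is.logical(x)) "boolean" else "string"
}

.parse_graphml_value <- function(x, type) {
  switch(type,
         long = as.integer(x),
         int = as.integer(x),
         double = as.numeric(x),
         float = as.numeric(x),
         boolean = as.logical(toupper(x) %in% c("TRUE", "1")),
         as.character(x))
}

#' Key-mapping table for the deposited annotated-graph XML dialect
#'
#' The deposited *E. coli* graph stores its annotation under attribute names
#' that differ from this package's schema column names. The mapping is kept
#' as an explicit, versioned configuration table rather than inferred ad
#' hoc: `type` carries the vertex/edge class, `affiliation` the three-domain
#' label, `metabolic` the two-domain side (1 = metabolic domain, 0 =
#' regulatory domain), `covert` the external-model identifier, and for
#' regulation edges the `stoichiometry` attribute carries the regulation
#' mode (+1 activation, -1 inhibition, 0 combined).
#'
#' @return Data frame with columns `element` ("node"/"edge"), `dialect_key`
#'   (attribute name in the file) and `column` (schema column).
#' @export
s1_key_map <- function() {
  data.frame(
    element = c(rep("node", 6), rep("edge", 5)),
    dialect_key = c("type", "name", "compartment", "covert", "affiliation", "metabolic",
                    "type", "stoichiometry", "logic", "id", "name"),
    column = c("vtype", "name", "compartment", "covert_map", "affiliation3", "affiliation2",
               "etype", "stoichiometry", "logic", "reg_id", "reg_name"),
    stringsAsFactors = FALSE)
}

.frame_to_xml <- function(doc_graph, df, element, id_cols, key_prefix, keymap = NULL) {
  # returns list(keys = data.frame(key_id, attr_name, attr_type, column))
  attr_cols <- setdiff(names(df), id_cols)
  keys <- data.frame(column = attr_cols, stringsAsFactors = FALSE)
  keys$attr_name <- keys$column
  if (!is.null(keymap)) {
    km <- keymap[keymap$element == element, ]
    hit <- match(keys$column, km$column)
    keys$attr_name[!is.na(hit)] <- km$dialect_key[stats::na.omit(hit)]
    keys <- keys[!is.na(hit) | !keys$column %in% .schema_cols(element), , drop = FALSE]
  }
  keys$attr_type <- vapply(df[keys$column], .graphml_attr_type, character(1))
  keys$key_id <- paste0(key_prefix, seq_len(nrow(keys)))
  keys
}

.schema_cols <- function(element) {
  if (element == "node") setdiff(names(.v_cols), "id") else
    setdiff(names(.e_cols), c("source", "target"))
}

#' Write an annotated graph to GraphML
#'
#' Writes standard GraphML with one `<key>` per attribute column. `NA`
#' values are encoded by omitting the `<data>` element, so optional
#' attributes round-trip exactly. With `dialect = "s1_xml"` the schema
#' columns are written under the deposited dialect's attribute names (see
#' [s1_key_map()]); in that dialect the regulation mode of regulation edges
#' is folded into the `stoichiometry` attribute and the two-domain
#' affiliation becomes the boolean-like `metabolic` flag.
#'
#' @param g An `annotated_graph`.
#' @param path Output file path.
#' @param dialect `"graphml"` (native schema column names) or `"s1_xml"`.
#' @return `path`, invisibly.
#' @export
save_graph <- function(g, path, dialect = c("graphml", "s1_xml")) {
  dialect <- match.arg(dialect)
  v <- g$vertices
  e <- g$edges
  keymap <- NULL
  if (dialect == "s1_xml") {
    keymap <- s1_key_map()
    # fold regulation mode into stoichiometry; 2-domain label into 0/1 flag
    is_reg <- e$etype == "regulation"
    e$stoichiometry[is_reg] <- e$regulation_mode[is_reg]
    e$regulation_mode <- NULL
    v$affiliation2 <- ifelse(is.na(v$affiliation2), NA_character_,
                             ifelse(v$affiliation2 == "MD", "1", "0"))
  }
  vkeys <- .frame_to_xml(NULL, v, "node", "id", "v", keymap)
  ekeys <- .frame_to_xml(NULL, e, "edge", c("source", "target"), "e", keymap)

  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  fmt_val <- function(x) {
    if (is.logical(x)) tolower(as.character(x)) else as.character(x)
  }
  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf("<graphml xmlns=\"%s\">", .GRAPHML_NS),
    sprintf("  <key id=\"%s\" for=\"node\" attr.name=\"%s\" attr.type=\"%s\"/>",
            vkeys$key_id, esc(vkeys$attr_name), vkeys$attr_type),
    sprintf("  <key id=\"%s\" for=\"edge\" attr.name=\"%s\" attr.type=\"%s\"/>",
            ekeys$key_id, esc(ekeys$attr_name), ekeys$attr_type),
    "  <graph id=\"G\" edgedefault=\"directed\">")
  node_lines <- character(0)
  if (nrow(v)) {
    node_lines <- vapply(seq_len(nrow(v)), function(i) {
      dat <- character(0)
      for (k in seq_len(nrow(vkeys))) {
        val <- v[[vkeys$column[k]]][i]
        if (!is.na(val))
          dat <- c(dat, sprintf("<data key=\"%s\">%s</data>",
                                vkeys$key_id[k], esc(fmt_val(val))))
      }
      sprintf("    <node id=\"%s\">%s</node>", esc(v$id[i]), paste(dat, collapse = ""))
    }, character(1))
  }
  edge_lines <- character(0)
  if (nrow(e)) {
    edge_lines <- vapply(seq_len(nrow(e)), function(i) {
      dat <- character(0)
      for (k in seq_len(nrow(ekeys))) {
        val <- e[[ekeys$column[k]]][i]
        if (!is.na(val))
          dat <- c(dat, sprintf("<data key=\"%s\">%s</data>",
                                ekeys$key_id[k], esc(fmt_val(val))))
      }
      sprintf("    <edge source=\"%s\" target=\"%s\">%s</edge>",
              esc(e$source[i]), esc(e$target[i]), paste(dat, collapse = ""))
    }, character(1))
  }
  out <- c(out, node_lines, edge_lines, "  </graph>", "</graphml>")
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Load an annotated graph from GraphML
#'
#' Reads the GraphML dialects produced by [save_graph()] as well as generic
#' GraphML with the same attribute names. Unknown attribute keys are
#' preserved as opaque extra columns. Parse failures name the offending
#' element; schema violations (unknown vertex type, dangling edge, ...) are
#' reported all at once as a validation error.
#'
#' @param path Input file path.
#' @param dialect `"graphml"` or `"s1_xml"` (deposited-graph attribute
#'   names, mapped onto the schema via [s1_key_map()]).
#' @param validate Run schema validation (default `TRUE`).
#' @return An `annotated_graph`.
#' @export
load_graph <- function(path, dialect = c("graphml", "s1_xml"), validate = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("GraphML parse failure in '", path,
                                           "': ", conditionMessage(e), call. = FALSE))
  ns <- c(g = .GRAPHML_NS)
  keys <- xml2::xml_find_all(doc, ".//g:key", ns)
  keytab <- data.frame(
    key_id = xml2::xml_attr(keys, "id"),
    for_ = xml2::xml_attr(keys, "for"),
    attr_name = xml2::xml_attr(keys, "attr.name"),
    attr_type = xml2::xml_attr(keys, "attr.type"),
    stringsAsFactors = FALSE)
  keytab$attr_type[is.na(keytab$attr_type)] <- "string"
  graph <- xml2::xml_find_first(doc, ".//g:graph", ns)
  if (inherits(graph, "xml_missing"))
    stop("GraphML format error: no <graph> element in '", path, "'", call. = FALSE)

  read_elems <- function(xpath, for_kind, fixed_attr) {
    elems <- xml2::xml_find_all(graph, xpath, ns)
    kt <- keytab[keytab$for_ %in% c(for_kind, "all"), , drop = FALSE]
    base <- lapply(fixed_attr, function(a) xml2::xml_attr(elems, a))
    names(base) <- fixed_attr
    cols <- lapply(seq_len(nrow(kt)), function(k) {
      d <- xml2::xml_find_first(elems, sprintf(".//g:data[@key='%s']", kt$key_id[k]), ns)
      raw <- xml2::xml_text(d)
      raw[vapply(d, inherits, logical(1), "xml_missing")] <- NA
      .parse_graphml_value(raw, kt$attr_type[k])
    })
    names(cols) <- kt$attr_name
    df <- c(base, cols)
    n <- length(elems)
    df <- lapply(df, function(x) if (length(x)) x else x[0])
    as.data.frame(df, stringsAsFactors = FALSE, check.names = FALSE,
                  optional = TRUE)[seq_len(n), , drop = FALSE]
  }

  v <- read_elems(".//g:node", "node", "id")
  e <- read_elems(".//g:edge", "edge", c("source", "target"))
  if (nrow(v) && anyNA(v$id))
    stop("GraphML format error: <node> without id attribute", call. = FALSE)
  if (nrow(e) && (anyNA(e$source) || anyNA(e$target)))
    stop("GraphML format error: <edge> without source/target", call. = FALSE)

  if (dialect == "s1_xml") {
    km <- s1_key_map()
    rn <- function(df, element) {
      kme <- km[km$element == element, ]
      hit <- match(names(df), kme$dialect_key)
      names(df)[!is.na(hit)] <- kme$column[stats::na.omit(hit)]
      df
    }
    v <- rn(v, "node"); e <- rn(e, "edge")
    if ("affiliation2" %in% names(v))
      v$affiliation2 <- ifelse(is.na(v$affiliation2), NA_character_,
                               ifelse(v$affiliation2 %in% c("1", "true", "TRUE"),
                                      "MD", "RD"))
    if (nrow(e)) {
      is_reg <- !is.na(e$etype) & e$etype == "regulation"
      e$regulation_mode <- NA_integer_
      if ("stoichiometry" %in% names(e)) {
        e$regulation_mode[is_reg] <- as.integer(e$stoichiometry[is_reg])
        e$stoichiometry[is_reg] <- 0L
      }
    }
  }
  g <- annotated_graph(v, e, validate = FALSE)
  if (validate) {
    viol <- validate_annotated_graph(g)
    if (length(viol))
      stop("GraphML schema validation failed for '", path, "':\n  ",
           paste(viol, collapse = "\n  "), call. = FALSE)
  }
  g
}
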