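.FLAT_FILES <- c("regulation.dat", "reactions.dat", "compounds.dat",
                 "proteins.dat", "genes.dat", "rnas.dat", "classes.dat",
                 "protcplxs.col")

#' Parse BioCyc-dialect attribute-value flat files
#'
#' Reads a directory in the BioCyc attribute-value dialect: records open
#' with a `UNIQUE-ID - <accession>` line, carry `ATTR - value` lines
#' (attributes may repeat, forming a multimap), use `/`-prefixed
#' continuation lines appended to the previous value, `^SUBATTR - value`
#' annotation lines attached to the preceding attribute (e.g.
#' `^COEFFICIENT`), `#`-prefixed comment lines, and close with `//`.
#' `protcplxs.col` is a tab-separated table (`UNIQUE-ID`, `COMPONENTS`
#' with ` // `-separated entries carrying optional `:coefficient`
#' suffixes) and is parsed into the same record form.
#'
#' @param directory Directory holding the flat files.
#' @param strict When `TRUE`, all eight files must be present and a
#'   malformed record (attribute line outside any record) is an error
#'   naming the line; otherwise missing files yield empty record lists and
#'   malformed lines are skipped and logged.
#' @return Object of class `raw_record_set`: per-file named lists of
#'   records (`$attrs` is a list of entries with `key`, `value`,
#'   `annotations`), plus a `log` of skipped lines.
#' @export
parse_flat_files <- function(directory, strict = FALSE) {
  out <- list()
  log <- character(0)
  for (f in .FLAT_FILES) {
    path <- file.path(directory, f)
    if (!file.exists(path)) {
      if (strict) stop("missing flat file: ", f, call. = FALSE)
      out[[f]] <- list()
      next
    }
    if (f == "protcplxs.col") {
      out[[f]] <- .parse_col_file(path)
    } else {
      parsed <- .parse_dat_file(path, strict = strict, fname = f)
      out[[f]] <- parsed$records
      log <- c(log, parsed$log)
    }
  }
  structure(list(files = out, log = log), class = "raw_record_set")
}

.parse_dat_file <- function(path, strict, fname) {
  lines <- readLines(path, warn = FALSE)
  records <- list()
  cur_id <- NULL
  cur_attrs <- list()
  log <- character(0)
  flush <- function() {
    if (!is.null(cur_id)) {
      if (cur_id %in% names(records))
        stop("duplicate accession '", cur_id, "' in ", fname, call. = FALSE)
      records[[cur_id]] <<- list(id = cur_id, attrs = cur_attrs)
    }
    cur_id <<- NULL
    cur_attrs <<- list()
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (ln == "//") { flush(); next }
    if (startsWith(ln, "/")) {
      # continuation of the previous attribute value
      if (length(cur_attrs)) {
        k <- length(cur_attrs)
        cur_attrs[[k]]$value <- paste(cur_attrs[[k]]$value, sub("^/", "", ln))
      } else {
        msg <- sprintf("%s:%d: continuation line outside a record", fname, i)
        if (strict) stop(msg, call. = FALSE) else log <- c(log, msg)
      }
      next
    }
    m <- regmatches(ln, regexec("^(\\^?)([A-Za-z0-9?_-]+) - (.*)$", ln))[[1]]
    if (!length(m)) {
      msg <- sprintf("%s:%d: malformed line: %s", fname, i, ln)
      if (strict) stop(msg, call. = FALSE) else log <- c(log, msg)
      next
    }
    is_anno <- m[2] == "^"
    key <- m[3]
    val <- m[4]
    if (!is_anno && key == "UNIQUE-ID") {
      flush()
      cur_id <- val
      next
    }
    if (is.null(cur_id)) {
      msg <- sprintf("%s:%d: attribute line before any UNIQUE-ID (no accession)", fname, i)
      if (strict) stop(msg, call. = FALSE) else log <- c(log, msg)
      next
    }
    if (is_anno) {
      if (length(cur_attrs)) {
        k <- length(cur_attrs)
        cur_attrs[[k]]$annotations[[key]] <- val
      } else {
        msg <- sprintf("%s:%d: annotation line with no preceding attribute", fname, i)
        if (strict) stop(msg, call. = FALSE) else log <- c(log, msg)
      }
    } else {
      cur_attrs[[length(cur_attrs) + 1L]] <- list(key = key, value = val,
                                                  annotations = list())
    }
  }
  flush()
  list(records = records, log = log)
}

.parse_col_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(list())
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  records <- list()
  for (ln in lines[-1L]) {
    cells <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    row <- setNames(as.list(cells), header[seq_along(cells)])
    id <- row[["UNIQUE-ID"]]
    if (is.null(id)) next
    attrs <- list()
    comps <- row[["COMPONENTS"]]
    if (!is.null(comps) && nzchar(comps)) {
      for (entry in strsplit(comps, " // ", fixed = TRUE)[[1L]]) {
        bits <- strsplit(entry, ":", fixed = TRUE)[[1L]]
        anno <- if (length(bits) > 1L) list(COEFFICIENT = bits[2L]) else list()
        attrs[[length(attrs) + 1L]] <- list(key = "COMPONENTS", value = bits[1L],
                                            annotations = anno)
      }
    }
    records[[id]] <- list(id = id, attrs = attrs)
  }
  records
}

# All values of one attribute key for a record.
record_values <- function(record, key) {
  vals <- vapply(record$attrs, function(a) if (a$key == key) a$value else NA_character_,
                 character(1))
  vals[!is.na(vals)]
}

# (value, annotation) pairs for one attribute key.
record_entries <- function(record, key) {
  record$attrs[vapply(record$attrs, function(a) a$key == key, logical(1))]
}
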