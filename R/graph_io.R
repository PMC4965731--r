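#' Read a network from a delimited edge list
#'
#' One edge per line, `#` comments and blank lines skipped.  Self-loops are
#' dropped with a logged count, parallel edges collapsed keeping the maximum
#' weight.
#'
#' @param path file path
#' @param delimiter field separator; the default splits on any run of
#'   whitespace (spaces or tabs)
#' @param weighted if `TRUE`, a numeric third column is read as edge weight
#' @return a [network()] object
#' @export
read_edge_list <- function(path, delimiter = "", weighted = FALSE) {
  lines <- read_network_lines(path)
  fields <- if (identical(delimiter, "")) {
    strsplit(trimws(lines), "[ \t]+")
  } else {
    strsplit(lines, delimiter, fixed = TRUE)
  }
  nf <- lengths(fields)
  bad <- which(nf < 2L | (weighted & nf < 3L))
  if (length(bad) > 0L) {
    stop(sprintf("malformed edge-list line %d in '%s': '%s'",
                 attr(lines, "lineno")[bad[1L]], path, lines[bad[1L]]))
  }
  from <- vapply(fields, `[[`, "", 1L)
  to <- vapply(fields, `[[`, "", 2L)
  w <- NULL
  if (weighted) {
    w <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
    if (anyNA(w)) {
      bad <- which(is.na(w))[1L]
      stop(sprintf("non-numeric weight on line %d in '%s'",
                   attr(lines, "lineno")[bad], path))
    }
  }
  network(cbind(from, to), weights = w)
}

#' Read a network in SIF (simple interaction format)
#'
#' Lines are `source relation target [target ...]`; the relation column is
#' ignored.  A line with only a source registers an isolated vertex.
#'
#' @inheritParams read_edge_list
#' @return a [network()] object
#' @export
read_sif <- function(path) {
  lines <- read_network_lines(path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf == 2L)) {
    bad <- which(nf == 2L)[1L]
    stop(sprintf("malformed SIF line %d in '%s': relation without target",
                 attr(lines, "lineno")[bad], path))
  }
  iso <- vapply(fields[nf == 1L], `[[`, "", 1L)
  from <- character(); to <- character()
  for (f in fields[nf >= 3L]) {
    targets <- f[-(1:2)]
    from <- c(from, rep(f[[1L]], length(targets)))
    to <- c(to, targets)
  }
  network(cbind(from, to), vertices = iso)
}

#' Read a network from a GraphML document
#'
#' Parsed with igraph's GraphML reader.  A directedness attribute, if
#' present, is coerced to undirected with a warning; reciprocal directed
#' edges collapse to a single undirected edge.
#'
#' @inheritParams read_edge_list
#' @return a [network()] object
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  g <- igraph::read_graph(path, format = "graphml")
  if (igraph::is_directed(g)) {
    warning("directed GraphML coerced to undirected")
    g <- igraph::as_undirected(g, mode = "collapse",
                               edge.attr.comb = list(weight = "max",
                                                     "ignore"))
  }
  nm <- igraph::vertex_attr(g, "name")
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(g)))
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::edge_attr(g, "weight")
  network(cbind(nm[el[, 1L]], nm[el[, 2L]]), vertices = nm, weights = w)
}

#' Read a gene set (one identifier per line)
#'
#' Identifiers are whitespace-trimmed, blank lines skipped, duplicates
#' removed.  Matching against network vertices is exact and case-sensitive;
#' no alias resolution is attempted.
#'
#' @param path file path
#' @return character vector of unique identifiers
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  ids <- trimws(readLines(path, warn = FALSE))
  ids <- unique(ids[nzchar(ids)])
  if (length(ids) == 0L) {
    stop(sprintf("gene set '%s' contains no identifiers", path))
  }
  ids
}

#' Write / read a feature table
#'
#' Tab-separated with a header: `vertex`, the 13 feature columns in the
#' fixed order of [feature_names()], then any extra columns (e.g. `label`,
#' `provenance`).  Values are written with 15 significant digits so a
#' write-read round trip reproduces them to better than 1e-12 relative
#' error.
#'
#' @param table a feature table data.frame (first column `vertex`)
#' @param path file path
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns the data.frame.
#' @export
write_feature_table <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop("feature table must be a non-empty data.frame")
  }
  out <- table
  num <- vapply(out, is.numeric, logical(1L))
  out[num] <- lapply(out[num], function(x) sprintf("%.15g", x))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = NA, stringsAsFactors = FALSE,
                          check.names = FALSE)
  df$vertex <- as.character(df$vertex)
  if ("provenance" %in% names(df)) {
    df$provenance <- as.character(df$provenance)
  }
  df
}

# Shared line reader: drops comments/blanks, errors on empty input, and
# records original line numbers for error messages.
read_network_lines <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  raw <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(raw)) & !grepl("^\\s*#", raw))
  if (length(keep) == 0L) {
    stop(sprintf("'%s' contains no network data", path))
  }
  structure(raw[keep], lineno = keep)
}
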