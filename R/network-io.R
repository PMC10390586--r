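#' Read a network from a text file
#'
#' Two plain-text formats are supported and auto-detected (or forced with
#' `format`):
#' * **dense matrix** — a square numeric matrix, whitespace- or
#'   comma-separated, one row per line;
#' * **edge list** — three columns `source target weight` (tab- or
#'   whitespace-separated, optional header line), with *0-based* node
#'   indices. Each line sets `weights[target + 1, source + 1]`; for
#'   `directed = FALSE` the symmetric entry is set as well and conflicting
#'   duplicate entries are an error.
#'
#' Lines starting with `#` are ignored. Negative weights and nonzero
#' self-loops are format errors reported with their line number.
#'
#' @param path file to read.
#' @param format `"auto"`, `"matrix"` or `"edgelist"`.
#' @param directed logical flag stored on the returned network; a dense
#'   matrix read with `directed = FALSE` must be symmetric.
#' @param n_nodes required for edge lists whose isolated tail nodes would
#'   otherwise be dropped; optional.
#' @return a `weighted_network`.
#' @seealso [write_network()], [read_parcellation()]
#' @export
read_network <- function(path, format = c("auto", "matrix", "edgelist"),
                         directed = FALSE, n_nodes = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  if (length(keep) == 0L) stop("no data lines in ", path)
  first <- strsplit(trimws(gsub(",", " ", raw[keep[1L]])), "\\s+")[[1L]]
  if (format == "auto") {
    format <- if (length(first) == 3L && length(keep) != 3L) "edgelist" else "matrix"
    if (length(first) == 3L && length(keep) == 3L) {
      # ambiguous 3x3: treat numeric square block as matrix
      format <- "matrix"
    }
  }
  if (format == "matrix") {
    rows <- lapply(keep, function(ln) {
      vals <- suppressWarnings(as.numeric(
        strsplit(trimws(gsub(",", " ", raw[ln])), "\\s+")[[1L]]
      ))
      if (anyNA(vals)) stop("line ", ln, ": non-numeric matrix entry")
      vals
    })
    ncols <- lengths(rows)
    if (length(unique(ncols)) != 1L || ncols[1L] != length(rows)) {
      stop("non-square matrix: ", length(rows), " rows, ",
           paste(unique(ncols), collapse = "/"), " columns")
    }
    w <- do.call(rbind, rows)
    for (r in seq_along(keep)) {
      if (any(rows[[r]] < 0)) stop("line ", keep[r], ": negative weight")
      if (rows[[r]][r] != 0) stop("line ", keep[r], ": nonzero self-loop weight")
    }
    return(weighted_network(w, directed = directed))
  }
  # edge list
  src <- integer(0); dst <- integer(0); wts <- numeric(0)
  start <- keep[1L]
  if (anyNA(suppressWarnings(as.numeric(first)))) start <- keep[2L]  # header
  for (ln in keep[keep >= start]) {
    f <- strsplit(trimws(raw[ln]), "\\s+")[[1L]]
    if (length(f) != 3L) stop("line ", ln, ": expected 3 columns, got ", length(f))
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v)) stop("line ", ln, ": non-numeric entry")
    if (v[1L] < 0 || v[2L] < 0) stop("line ", ln, ": negative node index")
    if (v[3L] < 0) stop("line ", ln, ": negative weight")
    if (v[1L] == v[2L] && v[3L] != 0) stop("line ", ln, ": self-loop with nonzero weight")
    src <- c(src, as.integer(v[1L])); dst <- c(dst, as.integer(v[2L]))
    wts <- c(wts, v[3L])
  }
  n <- max(c(src, dst)) + 1L
  if (!is.null(n_nodes)) {
    if (n_nodes < n) stop("n_nodes smaller than largest node index + 1")
    n <- as.integer(n_nodes)
  }
  sel <- wts > 0
  i <- dst[sel] + 1L; j <- src[sel] + 1L; x <- wts[sel]
  if (!directed) {
    i2 <- c(i, j); j2 <- c(j, i); x2 <- c(x, x)
    key <- paste(i2, j2)
    if (anyDuplicated(key)) {
      agg <- tapply(x2, key, function(v) length(unique(v)))
      if (any(agg > 1L)) stop("conflicting duplicate undirected edges in ", path)
      dedup <- !duplicated(key)
      i2 <- i2[dedup]; j2 <- j2[dedup]; x2 <- x2[dedup]
    }
    w <- Matrix::sparseMatrix(i = i2, j = j2, x = x2, dims = c(n, n))
  } else {
    w <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
  }
  weighted_network(w, directed = directed)
}

#' Write a network to a text file
#'
#' @param net a `weighted_network`.
#' @param path output file.
#' @param format `"matrix"` writes the dense weight matrix (space-separated,
#'   full precision); `"edgelist"` writes tab-separated
#'   `source target weight` with 0-based indices and a header line
#'   (undirected networks list each edge once).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("matrix", "edgelist")) {
  stopifnot_network(net)
  format <- match.arg(format)
  if (format == "matrix") {
    m <- as.matrix(net$weights)
    lines <- apply(m, 1L, function(r) paste(format(r, digits = 17), collapse = " "))
    writeLines(lines, path)
  } else {
    s <- Matrix::summary(net$weights)  # i = target, j = source
    if (!net$directed) s <- s[s$i <= s$j, , drop = FALSE]
    lines <- c("source\ttarget\tweight",
               sprintf("%d\t%d\t%.17g", s$j - 1L, s$i - 1L, s$x))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read / write a node parcellation table
#'
#' Tab-separated two-column format `node_index<TAB>label` with 0-based node
#' indices, optional header, `#` comments ignored. Every node index from 0 to
#' the maximum must appear exactly once.
#'
#' @param path file path.
#' @return a `parcellation`.
#' @export
read_parcellation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  if (length(keep) == 0L) stop("no data lines in ", path)
  f1 <- strsplit(trimws(raw[keep[1L]]), "\\s+")[[1L]]
  if (is.na(suppressWarnings(as.integer(f1[1L])))) keep <- keep[-1L]  # header
  idx <- integer(0); lab <- character(0)
  for (ln in keep) {
    f <- strsplit(trimws(raw[ln]), "\\s+")[[1L]]
    if (length(f) != 2L) stop("line ", ln, ": expected 2 columns")
    v <- suppressWarnings(as.integer(f[1L]))
    if (is.na(v) || v < 0) stop("line ", ln, ": bad node index '", f[1L], "'")
    idx <- c(idx, v); lab <- c(lab, f[2L])
  }
  n <- max(idx) + 1L
  if (anyDuplicated(idx)) stop("duplicate node index in ", path)
  if (length(idx) != n) stop("missing node indices in ", path)
  parcellation(lab[order(idx)])
}

#' @rdname read_parcellation
#' @param parc a `parcellation` to write.
#' @export
write_parcellation <- function(parc, path) {
  if (!inherits(parc, "parcellation")) stop("expected a parcellation")
  writeLines(c("node_index\tlabel",
               sprintf("%d\t%s", seq_along(parc) - 1L, unclass(parc))), path)
  invisible(path)
}
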