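#' Read a network from Pajek (.net) format
#'
#' Parses the Pajek dialect used for undirected weighted networks: a
#' `*Vertices N` section with optional quoted labels, followed by one or
#' more `*Edges` and/or `*Arcs` sections. `*Arcs` entries are symmetrized
#' into undirected edges (all supported case-study networks are
#' undirected). A missing edge weight defaults to 1.0. Duplicate or
#' reciprocal entries collapse to a single edge keeping the first weight
#' seen; self-loops are dropped with a warning.
#'
#' @param file path to a `.net` file. Ignored when `text` is given.
#' @param text optional character scalar (or vector of lines) holding the
#'   document itself, for programmatic use.
#' @return a [network()] object.
#' @seealso [write_pajek()]
#' @export
#' @examples
#' net <- read_pajek(text = "*Vertices 2\n1 \"a\"\n2 \"b\"\n*Edges\n1 2")
#' edge_table(net, labels = TRUE)
read_pajek <- function(file, text = NULL) {
  lines <- if (!is.null(text)) {
    unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  } else {
    readLines(file, warn = FALSE)
  }
  perr <- function(i, msg) stop(sprintf("Pajek parse error at line %d: %s", i, msg),
                                call. = FALSE)
  strip <- function(s) sub("\\s+$", "", sub("^\\s+", "", s))
  # locate sections
  is_header <- grepl("^\\s*\\*", lines)
  headers <- which(is_header)
  if (!length(headers)) stop("Pajek parse error: no *Vertices section", call. = FALSE)
  hdr_kind <- tolower(sub("^\\s*\\*(\\S+).*$", "\\1", lines[headers]))
  vert_at <- headers[hdr_kind == "vertices"]
  if (!length(vert_at))
    stop("Pajek parse error: no *Vertices section", call. = FALSE)
  vi <- vert_at[1]
  m <- regmatches(lines[vi], regexec("^\\s*\\*\\S+\\s+(\\d+)\\s*$", lines[vi]))[[1]]
  if (length(m) < 2) perr(vi, "malformed *Vertices header")
  nv <- as.integer(m[2])

  labels <- as.character(seq_len(nv))
  disp <- rep(NA_character_, nv)
  seen_label <- rep(FALSE, nv)

  section_end <- function(start) {
    nxt <- headers[headers > start]
    if (length(nxt)) nxt[1] - 1L else length(lines)
  }

  # vertex lines
  if (section_end(vi) >= vi + 1L) {
    for (i in (vi + 1L):section_end(vi)) {
      ln <- strip(lines[i])
      if (!nzchar(ln) || startsWith(ln, "%")) next
      m <- regmatches(ln, regexec('^(\\d+)(?:\\s+"([^"]*)"|\\s+(\\S+))?.*$', ln))[[1]]
      if (length(m) < 2 || !nzchar(m[2])) perr(i, "malformed vertex line")
      id <- as.integer(m[2])
      if (is.na(id) || id < 1L || id > nv) perr(i, "vertex index out of range")
      lab <- if (nzchar(m[3])) m[3] else if (length(m) >= 4 && nzchar(m[4])) m[4] else NA
      if (!is.na(lab)) { labels[id] <- lab; disp[id] <- lab }
      seen_label[id] <- TRUE
    }
  }
  if (anyDuplicated(labels))
    labels <- make.unique(labels, sep = "_")

  # edge / arc sections
  ef <- integer(); et <- integer(); ew <- numeric()
  for (h in headers[hdr_kind %in% c("edges", "arcs")]) {
    lo <- h + 1L; hi <- section_end(h)
    if (lo > hi) next
    for (i in lo:hi) {
      ln <- strip(lines[i])
      if (!nzchar(ln) || startsWith(ln, "%")) next
      parts <- strsplit(ln, "\\s+")[[1]]
      if (length(parts) < 2) perr(i, "malformed edge line")
      u <- suppressWarnings(as.integer(parts[1]))
      v <- suppressWarnings(as.integer(parts[2]))
      if (is.na(u) || is.na(v)) perr(i, "malformed edge line")
      if (u < 1L || u > nv || v < 1L || v > nv)
        perr(i, "vertex index out of range")
      w <- 1
      if (length(parts) >= 3) {
        w <- suppressWarnings(as.numeric(parts[3]))
        if (is.na(w)) perr(i, "malformed edge weight")
        if (w <= 0) perr(i, "non-positive edge weight")
      }
      ef <- c(ef, u); et <- c(et, v); ew <- c(ew, w)
    }
  }
  unknown <- setdiff(hdr_kind, c("vertices", "edges", "arcs"))
  if (length(unknown))
    warning("ignoring Pajek section(s): ",
            paste(unique(unknown), collapse = ", "))
  network(labels, from = ef, to = et, weight = ew,
          names = if (any(!is.na(disp))) disp else NULL,
          collapse = "first", drop_loops = TRUE)
}

#' Write a network in Pajek (.net) format
#'
#' The output round-trips: `read_pajek(text = write_pajek(net))`
#' reproduces `net` exactly (labels, edges, weights).
#'
#' @param net a [network()] object.
#' @param file optional path; when `NULL` the document is returned as a
#'   character scalar.
#' @return the document text, invisibly when written to a file.
#' @export
write_pajek <- function(net, file = NULL) {
  stopifnot(inherits(net, "netgame_network"))
  out <- c(sprintf("*Vertices %d", n_nodes(net)),
           sprintf('%d "%s"', seq_len(n_nodes(net)), net$labels),
           "*Edges")
  if (n_edges(net)) {
    e <- net$edges
    out <- c(out, sprintf("%d %d %s", e$from, e$to,
                          formatC(e$weight, format = "g", digits = 17)))
  }
  doc <- paste0(paste(out, collapse = "\n"), "\n")
  if (is.null(file)) return(doc)
  writeLines(doc, file, sep = "")
  invisible(doc)
}

#' Read a node list file
#'
#' One node label per line; blank lines and `#` comments are ignored.
#'
#' @param file path to the list file.
#' @return character vector of labels.
#' @export
read_node_list <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}
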