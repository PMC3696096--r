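#' Read a protein structure for network construction
#'
#' Loads the ATOM records of a PDB file into a structure model suitable
#' for residue-interaction-network construction: heavy atoms only
#' (hydrogens and deuteriums are excluded from the contact search),
#' alternate locations resolved to the highest-occupancy copy (first on
#' ties), insertion codes kept as part of residue identity. HETATM
#' records (ligands, waters) are ignored.
#'
#' @param file path to a PDB file, or a character vector of PDB lines
#'   via `text`.
#' @param text optional PDB document text.
#' @param chain optional chain filter (character vector of chain ids).
#' @return object of class `structure_model`: `atoms` (data.frame with
#'   chain, resno, insert, resid, elety, x, y, z) and `residues`
#'   (one row per residue, in sequence order, with a `label`
#'   `chain:resno:resid`).
#' @export
read_structure <- function(file, text = NULL, chain = NULL) {
  if (!is.null(text)) {
    file <- tempfile(fileext = ".pdb")
    on.exit(unlink(file))
    writeLines(text, file)
  }
  pdb <- bio3d::read.pdb(file, multi = FALSE, rm.alt = FALSE,
                         verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop("no ATOM records found")
  if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
  if (!nrow(at)) stop("no ATOM records left after chain filter")
  # drop hydrogens/deuteriums (element symbol, falling back to atom name)
  elem <- toupper(trimws(at$elesy))
  noelem <- is.na(elem) | !nzchar(elem)
  if (any(noelem)) {
    nm <- sub("^[0-9]*", "", trimws(at$elety[noelem]))
    elem[noelem] <- substr(nm, 1, 1)
  }
  at <- at[!(elem %in% c("H", "D")), , drop = FALSE]
  if (!nrow(at)) stop("no heavy atoms found")
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  # resolve altlocs: keep the highest-occupancy copy of each named atom
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  if (anyDuplicated(key)) {
    ord <- order(key, -at$o)          # stable: first wins occupancy ties
    at <- at[ord, , drop = FALSE][!duplicated(sort(key)), , drop = FALSE]
    at <- at[order(at$eleno), , drop = FALSE]
  }
  rkey <- paste(at$chain, at$resno, at$insert, sep = "|")
  ridx <- match(rkey, unique(rkey))   # sequence order = file order
  first <- !duplicated(rkey)
  res <- data.frame(chain = at$chain[first], resno = at$resno[first],
                    insert = at$insert[first], resid = at$resid[first],
                    stringsAsFactors = FALSE)
  res$label <- paste0(res$chain, ":", res$resno,
                      ifelse(nzchar(res$insert), res$insert, ""),
                      ":", res$resid)
  at$res_index <- ridx
  structure(list(atoms = at[, c("res_index", "chain", "resno", "insert",
                                "resid", "elety", "x", "y", "z")],
                 residues = res),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d residues, %d heavy atoms (chains: %s)\n",
              nrow(x$residues), nrow(x$atoms),
              paste(unique(x$residues$chain), collapse = ", ")))
  invisible(x)
}

#' Build a protein structure network (residue interaction network)
#'
#' Nodes are amino-acid residues; an edge connects two residues when at
#' least one heavy-atom pair lies within the distance cutoff
#' (default 4.0 A, i.e. 0.4 nm), excluding the covalent backbone
#' peptide bond C(i)-N(i+1) between sequence-adjacent residues.
#' The edge weight is the inverse of the arithmetic mean distance over
#' the qualifying (within-cutoff) atom pairs, so all weights are at
#' least `1/cutoff`. Residues with no contacts are absent from the
#' network.
#'
#' @param model a [read_structure()] model.
#' @param cutoff contact distance cutoff in Angstrom (> 0).
#' @return a [network()] with residue labels `chain:resno:resid`.
#' @export
build_psn <- function(model, cutoff = 4.0) {
  stopifnot(inherits(model, "structure_model"))
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be > 0")
  at <- model$atoms
  res <- model$residues
  nr <- nrow(res)
  if (nr < 2) stop("need at least 2 residues")
  coords <- lapply(seq_len(nr), function(i) {
    a <- at[at$res_index == i, , drop = FALSE]
    list(xyz = cbind(a$x, a$y, a$z), name = trimws(a$elety))
  })
  cent <- t(vapply(coords, function(cc) colMeans(cc$xyz), numeric(3)))
  radius <- vapply(seq_len(nr), function(i)
    sqrt(max(rowSums((coords[[i]]$xyz - rep(cent[i, ], each = nrow(coords[[i]]$xyz)))^2))),
    numeric(1))
  ef <- integer(); et <- integer(); ew <- numeric()
  for (i in seq_len(nr - 1L)) {
    for (j in (i + 1L):nr) {
      reach <- radius[i] + radius[j] + cutoff
      if (sum((cent[i, ] - cent[j, ])^2) > reach^2) next
      a <- coords[[i]]; b <- coords[[j]]
      d2 <- outer(rowSums(a$xyz^2), rowSums(b$xyz^2), "+") -
        2 * a$xyz %*% t(b$xyz)
      d2[d2 < 0] <- 0
      d <- sqrt(d2)
      ok <- d <= cutoff
      # covalent exclusion: the peptide bond C(i)-N(i+1)
      if (j == i + 1L && res$chain[i] == res$chain[j]) {
        ci <- which(a$name == "C"); nj <- which(b$name == "N")
        if (length(ci) && length(nj)) ok[ci, nj] <- FALSE
      }
      if (any(ok)) {
        ef <- c(ef, i); et <- c(et, j); ew <- c(ew, 1 / mean(d[ok]))
      }
    }
  }
  used <- sort(unique(c(ef, et)))
  network(res$label[used],
          from = match(ef, used), to = match(et, used), weight = ew)
}
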