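#' Extract the interface residues of a complex model
#'
#' A residue is part of the interface iff its minimum heavy-atom distance to
#' any residue of the other subunit is at most `cutoff` (residue-residue
#' distance is the shortest distance over all heavy-atom pairs).  The
#' selection is computed symmetrically for both subunits.
#'
#' @param structure a [ComplexStructure-class].
#' @param cutoff interface residue cutoff in Angstrom (default 10).
#' @return list with character vectors `receptor` and `ligand` of residue
#'   keys ("chain|resno|icode"), and `cutoff`.
#' @export
extractInterface <- function(structure, cutoff = 10.0) {
  ra <- receptorAtoms(structure)
  la <- ligandAtoms(structure)
  ra <- ra[ra$heavy, , drop = FALSE]
  la <- la[la$heavy, , drop = FALSE]
  d <- .crossDistances(ra, la)
  close <- d <= cutoff
  if (!any(close)) stop("no interface: no residue pair within ",
                        cutoff, " A")
  rkey <- paste(ra$chain, ra$resno, ra$icode, sep = "|")
  lkey <- paste(la$chain, la$resno, la$icode, sep = "|")
  rsel <- unique(rkey[apply(close, 1, any)])
  lsel <- unique(lkey[apply(close, 2, any)])
  # preserve file order
  list(receptor = unique(rkey)[unique(rkey) %in% rsel],
       ligand = unique(lkey)[unique(lkey) %in% lsel],
       cutoff = cutoff)
}

# dense receptor-atom x ligand-atom distance matrix
.crossDistances <- function(ra, la) {
  A <- as.matrix(ra[, c("x", "y", "z")])
  B <- as.matrix(la[, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * (A %*% t(B))
  sqrt(pmax(d2, 0))
}

#' Build the interface graph pair of a complex model
#'
#' Nodes are all heavy atoms of the selected interface residues, receptor
#' block first.  The covalent adjacency `A1` has a 1 for bonded pairs
#' (template bonds plus peptide bonds between two selected residues) and on
#' the diagonal.  Cross-molecular heavy-atom distances up to `crossCutoff`
#' are stored so that the second adjacency can be assembled from the current
#' edge parameters at forward time (see [adjacencyPair()]).
#'
#' @param structure a [ComplexStructure-class].
#' @param selection result of [extractInterface()]; computed at `cutoff`
#'   when NULL.
#' @param cutoff interface residue cutoff (Angstrom), used when `selection`
#'   is NULL.
#' @param crossCutoff cross-edge distance cutoff (Angstrom).  Kept as a
#'   separate constant from the residue cutoff despite the equal default.
#' @return an [InterfaceGraph-class].
#' @export
buildInterfaceGraph <- function(structure, selection = NULL, cutoff = 10.0,
                                crossCutoff = 10.0) {
  if (is.null(selection)) selection <- extractInterface(structure, cutoff)
  if (length(selection$receptor) == 0 || length(selection$ligand) == 0)
    stop("empty interface selection")
  feats <- list(); nodesL <- list(); a1edges <- list(); offset <- 0L
  for (su in c("receptor", "ligand")) {
    bg <- inferBonds(structure, su)
    at <- bg$atoms
    key <- paste(at$chain, at$resno, at$icode, sep = "|")
    sel <- key %in% selection[[su]]
    idxMap <- rep(NA_integer_, nrow(at))
    idxMap[sel] <- seq_len(sum(sel)) + offset
    # bonds with both endpoints inside the selection survive
    e <- bg$edges
    keep <- sel[e[, 1]] & sel[e[, 2]]
    a1edges[[su]] <- cbind(idxMap[e[keep, 1]], idxMap[e[keep, 2]])
    feats[[su]] <- .featuresOfAtoms(at, bg$edges)[sel, , drop = FALSE]
    nd <- at[sel, c("name", "resname", "chain", "resno", "icode",
                    "element", "x", "y", "z"), drop = FALSE]
    nd$molecule <- su
    nodesL[[su]] <- nd
    offset <- offset + sum(sel)
  }
  nodes <- do.call(rbind, nodesL)
  rownames(nodes) <- NULL
  n <- nrow(nodes)
  A1 <- diag(1, n)
  ee <- do.call(rbind, a1edges)
  if (nrow(ee) > 0) {
    A1[ee] <- 1
    A1[ee[, c(2, 1), drop = FALSE]] <- 1
  }
  cross <- matrix(Inf, n, n)
  ir <- which(nodes$molecule == "receptor")
  il <- which(nodes$molecule == "ligand")
  d <- .crossDistances(nodes[ir, ], nodes[il, ])
  d[d > crossCutoff] <- Inf
  cross[ir, il] <- d
  cross[il, ir] <- t(d)
  g <- new("InterfaceGraph",
           nodes = nodes[, c("name", "resname", "chain", "resno", "icode",
                             "element")],
           features = do.call(rbind, feats), A1 = A1, crossDist = cross,
           molecule = nodes$molecule, crossCutoff = crossCutoff)
  validObject(g)
  g
}

#' Assemble the adjacency pair of an interface graph
#'
#' `A1` is the stored covalent adjacency.  `A2` equals `A1` on
#' within-molecule entries (including the diagonal) and holds the Gaussian
#' edge weight `exp(-(d - mu)^2 / sigma)` on cross-molecular pairs within
#' the cross cutoff, 0 beyond it.  `sigma` is clamped to at least 1e-6.
#'
#' @param graph an [InterfaceGraph-class].
#' @param mu,sigma learnable edge parameters (initial values 0 and 1).
#' @return list with matrices `A1`, `A2` and logical support masks
#'   `support1`, `support2` (structural nonzero patterns).
#' @export
adjacencyPair <- function(graph, mu = 0.0, sigma = 1.0) {
  if (sigma <= 0) {
    warning("sigma <= 0 clamped to 1e-6")
  }
  sigma <- max(sigma, 1e-6)
  A1 <- graph@A1
  crossOk <- is.finite(graph@crossDist)
  A2 <- A1
  A2[crossOk] <- exp(-(graph@crossDist[crossOk] - mu)^2 / sigma)
  list(A1 = A1, A2 = A2, support1 = A1 > 0, support2 = A1 > 0 | crossOk)
}

#' Serialize / read an interface graph as plain text
#'
#' Column-oriented text format (version tag, node table, feature rows, `A1`
#' rows, sparse cross-distance triplets at full precision); the round trip
#' is lossless and preserves node order.
#'
#' @param graph an [InterfaceGraph-class].
#' @param path output (input) file.
#' @return `serializeGraph` invisibly returns `path`; `readGraph` returns
#'   the reconstructed [InterfaceGraph-class].
#' @export
serializeGraph <- function(graph, path) {
  stopifnot(is(graph, "InterfaceGraph"))
  validObject(graph)
  n <- nodeCount(graph)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("graphdock-graph-1", paste("N", n),
               paste("crossCutoff", sprintf("%.17g", graph@crossCutoff))),
             con)
  writeLines(paste(graph@nodes$name, graph@nodes$resname,
                   ifelse(trimws(graph@nodes$chain) == "", ".",
                          graph@nodes$chain),
                   graph@nodes$resno,
                   ifelse(graph@nodes$icode == "", ".", graph@nodes$icode),
                   graph@nodes$element, graph@molecule), con)
  writeLines(apply(graph@features, 1, paste, collapse = " "), con)
  writeLines(apply(graph@A1, 1, paste, collapse = " "), con)
  ij <- which(is.finite(graph@crossDist) & upper.tri(graph@crossDist),
              arr.ind = TRUE)
  writeLines(paste("cross", nrow(ij)), con)
  if (nrow(ij) > 0)
    writeLines(sprintf("%d %d %.17g", ij[, 1], ij[, 2],
                       graph@crossDist[ij]), con)
  invisible(path)
}

#' @rdname serializeGraph
#' @export
readGraph <- function(path) {
  ln <- readLines(path)
  if (length(ln) < 3 || ln[1] != "graphdock-graph-1")
    stop("not a graphdock graph file: ", path)
  n <- as.integer(strsplit(ln[2], " ")[[1]][2])
  if (is.na(n) || n < 1) stop("corrupt graph file (bad node count)")
  cc <- as.numeric(strsplit(ln[3], " ")[[1]][2])
  at <- do.call(rbind, strsplit(ln[3 + seq_len(n)], " "))
  nodes <- data.frame(name = at[, 1], resname = at[, 2], chain = at[, 3],
                      resno = as.integer(at[, 4]),
                      icode = ifelse(at[, 5] == ".", "", at[, 5]),
                      element = at[, 6], stringsAsFactors = FALSE)
  molecule <- at[, 7]
  feat <- do.call(rbind, lapply(strsplit(ln[3 + n + seq_len(n)], " "),
                                as.numeric))
  A1 <- do.call(rbind, lapply(strsplit(ln[3 + 2 * n + seq_len(n)], " "),
                              as.numeric))
  hdr <- strsplit(ln[3 + 3 * n + 1], " ")[[1]]
  if (hdr[1] != "cross") stop("corrupt graph file (missing cross section)")
  ncross <- as.integer(hdr[2])
  cross <- matrix(Inf, n, n)
  if (ncross > 0) {
    tr <- do.call(rbind, lapply(strsplit(ln[3 + 3 * n + 1 + seq_len(ncross)],
                                         " "), as.numeric))
    cross[tr[, 1:2, drop = FALSE]] <- tr[, 3]
    cross[tr[, 2:1, drop = FALSE]] <- tr[, 3]
  }
  g <- new("InterfaceGraph", nodes = nodes, features = feat, A1 = A1,
           crossDist = cross, molecule = molecule, crossCutoff = cc)
  validObject(g)
  g
}
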