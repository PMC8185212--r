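#' Read a two-chain docking model from a PDB file
#'
#' Parses ATOM records of a PDB file (via bio3d) into a
#' [ComplexStructure-class].  HETATM records and waters are skipped,
#' alternate locations are resolved to the first-listed conformer, and
#' hydrogens are retained but flagged non-heavy.  Only the first MODEL of a
#' multi-model file is used.
#'
#' @param path PDB file.
#' @param receptorChains,ligandChains chain id character vectors.  When both
#'   are NULL, the first chain in the file is the receptor and all remaining
#'   chains form the ligand.
#' @return a [ComplexStructure-class].
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writeComplexPDB(makeNative(4, 3, seed = 1), pdb)
#' readComplexPDB(pdb, "A", "B")
#' @export
readComplexPDB <- function(path, receptorChains = NULL, ligandChains = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  a <- a[a$type == "ATOM" & !(a$resid %in% c("HOH", "WAT", "DOD")), ,
         drop = FALSE]
  if (nrow(a) == 0) stop("no ATOM records in ", path)
  bad <- !is.finite(a$x) | !is.finite(a$y) | !is.finite(a$z)
  if (any(bad))
    stop("malformed coordinate fields in ", path, " at atom serial ",
         paste(a$eleno[bad], collapse = ", "))
  a$insert[is.na(a$insert)] <- ""
  a$chain[is.na(a$chain)] <- " "
  # first-listed conformer wins for alternate locations
  a <- a[!duplicated(paste(a$chain, a$resno, a$insert, a$elety)), ,
         drop = FALSE]
  element <- .atomElement(a$elesy, a$elety)
  chains <- unique(a$chain)
  if (is.null(receptorChains) && is.null(ligandChains)) {
    receptorChains <- chains[1]
    ligandChains <- setdiff(chains, chains[1])
  }
  if (length(receptorChains) == 0 || length(ligandChains) == 0 ||
      length(intersect(receptorChains, ligandChains)) > 0)
    stop("receptor and ligand chain sets must be non-empty and disjoint")
  subunit <- ifelse(a$chain %in% receptorChains, "receptor",
                    ifelse(a$chain %in% ligandChains, "ligand", NA))
  keep <- !is.na(subunit)
  atoms <- data.frame(serial = a$eleno[keep], name = a$elety[keep],
                      resname = a$resid[keep], chain = a$chain[keep],
                      resno = a$resno[keep], icode = a$insert[keep],
                      x = a$x[keep], y = a$y[keep], z = a$z[keep],
                      element = element[keep],
                      heavy = element[keep] != "H",
                      subunit = subunit[keep],
                      stringsAsFactors = FALSE)
  if (!any(atoms$subunit == "receptor"))
    stop("no atoms in receptor chains (",
         paste(receptorChains, collapse = ","), ")")
  if (!any(atoms$subunit == "ligand"))
    stop("no atoms in ligand chains (",
         paste(ligandChains, collapse = ","), ")")
  rownames(atoms) <- NULL
  new("ComplexStructure", atoms = atoms,
      receptorChains = receptorChains, ligandChains = ligandChains,
      source = path)
}

# element from the PDB element column, with atom-name fallback
.atomElement <- function(elesy, elety) {
  e <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  fromName <- toupper(substring(gsub("^[0-9']+", "", elety), 1, 1))
  e[e == ""] <- fromName[e == ""]
  e[!(e %in% c("C", "N", "O", "S", "H", "P", "SE", "FE", "ZN"))] <-
    substring(e[!(e %in% c("C", "N", "O", "S", "H", "P", "SE", "FE", "ZN"))],
              1, 1)
  e
}

#' Write a complex model to a PDB file
#'
#' Round-trips through [readComplexPDB()] preserving atom count, names,
#' chains and coordinates to 3 decimals (PDB fixed width).
#'
#' @param structure a [ComplexStructure-class].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeComplexPDB <- function(structure, path) {
  stopifnot(is(structure, "ComplexStructure"))
  validObject(structure)
  a <- structure@atoms
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, type = "ATOM",
                   resno = a$resno, resid = a$resname, eleno = a$serial,
                   elety = a$name, chain = a$chain, insert = a$icode,
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)),
                   elesy = a$element)
  invisible(path)
}

#' Covalent bond graph of one subunit
#'
#' Intra-residue bonds come from the amino-acid template table; the
#' inter-residue peptide bond C(i)-N(i+1) is added when the two atoms are
#' closer than 2.0 Angstrom.  For residues outside the template table the
#' bonds degrade to a distance rule: heavy-atom pairs within the residue
#' closer than 1.9 Angstrom are bonded (logged via a message).
#'
#' @param structure a [ComplexStructure-class].
#' @param subunit "receptor" or "ligand".
#' @return list with `edges` (two-column integer matrix of heavy-atom row
#'   indices into the subunit atom table, `atoms`) and `atoms` (the subunit
#'   atom data frame, heavy atoms only).
#' @export
inferBonds <- function(structure, subunit = c("receptor", "ligand")) {
  subunit <- match.arg(subunit)
  at <- structure@atoms[structure@atoms$subunit == subunit &
                          structure@atoms$heavy, , drop = FALSE]
  rownames(at) <- NULL
  .bondsOfAtoms(at)
}

# core bond inference on a heavy-atom table (one subunit, file order)
.bondsOfAtoms <- function(at) {
  n <- nrow(at)
  reskey <- paste(at$chain, at$resno, at$icode, sep = "|")
  resIds <- unique(reskey)
  known <- .templateResidues()
  edges <- matrix(integer(0), ncol = 2)
  for (r in resIds) {
    idx <- which(reskey == r)
    resname <- at$resname[idx[1]]
    if (resname %in% known) {
      tb <- .templateBonds(resname)
      i1 <- idx[match(tb$atom1, at$name[idx])]
      i2 <- idx[match(tb$atom2, at$name[idx])]
      ok <- !is.na(i1) & !is.na(i2)
      edges <- rbind(edges, cbind(i1[ok], i2[ok]))
    } else {
      message("non-template residue ", resname, " ", r,
              ": using 1.9 A distance rule for bonds")
      if (length(idx) > 1) {
        co <- as.matrix(at[idx, c("x", "y", "z")])
        d <- as.matrix(stats::dist(co))
        pr <- which(upper.tri(d) & d < 1.9, arr.ind = TRUE)
        if (nrow(pr) > 0)
          edges <- rbind(edges, cbind(idx[pr[, 1]], idx[pr[, 2]]))
      }
    }
  }
  # peptide bonds between consecutive residues in file order, same chain
  if (length(resIds) > 1) {
    for (k in seq_len(length(resIds) - 1)) {
      i1 <- which(reskey == resIds[k])
      i2 <- which(reskey == resIds[k + 1])
      if (at$chain[i1[1]] != at$chain[i2[1]]) next
      ci <- i1[at$name[i1] == "C"][1]
      ni <- i2[at$name[i2] == "N"][1]
      if (is.na(ci) || is.na(ni)) next
      d <- sqrt(sum((c(at$x[ci], at$y[ci], at$z[ci]) -
                       c(at$x[ni], at$y[ni], at$z[ni]))^2))
      if (d < 2.0) edges <- rbind(edges, cbind(ci, ni))
    }
  }
  storage.mode(edges) <- "integer"
  list(edges = edges, atoms = at)
}

#' Atom feature layout
#'
#' The per-atom feature vector concatenates four one-hot blocks and an
#' aromatic flag: atom type over (C, N, O, S, H), heavy-atom degree 0-5,
#' attached hydrogens 0-4, implicit valence 0-5, aromatic 0/1 - a total of
#' 5 + 6 + 5 + 6 + 1 = 23 bits.
#'
#' @return named integer vector of block widths.
#' @export
featureBlocks <- function() {
  c(atomType = 5L, degree = 6L, hydrogens = 5L, implicitValence = 6L,
    aromatic = 1L)
}

# one 23-bit feature row
.featureRow <- function(element, degree, nH, valence, aromatic) {
  typeIdx <- match(element, c("C", "N", "O", "S", "H"))
  if (is.na(typeIdx)) typeIdx <- 1L   # non-CNOSH elements typed as carbon
  v <- numeric(23)
  v[typeIdx] <- 1
  v[5 + 1 + min(max(degree, 0L), 5L)] <- 1
  v[11 + 1 + min(max(nH, 0L), 4L)] <- 1
  iv <- min(max(valence - degree, 0L), 5L)
  v[16 + 1 + iv] <- 1
  v[23] <- as.numeric(aromatic)
  v
}

#' Per-atom feature vectors of the heavy atoms of a complex
#'
#' Computes the 23-dimensional binary feature vector of every heavy atom
#' (see [featureBlocks()]).  Degree is the number of bonded heavy atoms on
#' the full-chain covalent bond graph; attached hydrogens and aromaticity
#' come from the residue templates; implicit valence is the template valence
#' minus the observed heavy-atom degree.
#'
#' @param structure a [ComplexStructure-class].
#' @return matrix with one row per heavy atom (receptor block first, then
#'   ligand, file order) and 23 columns; row order matches
#'   `rbind(receptorAtoms(x), ligandAtoms(x))` restricted to heavy atoms.
#' @export
atomFeatureMatrix <- function(structure) {
  out <- lapply(c("receptor", "ligand"), function(su) {
    bg <- inferBonds(structure, su)
    .featuresOfAtoms(bg$atoms, bg$edges)
  })
  do.call(rbind, out)
}

.featuresOfAtoms <- function(at, edges) {
  n <- nrow(at)
  degree <- tabulate(c(edges[, 1], edges[, 2]), nbins = n)
  rows <- matrix(0, n, 23)
  for (i in seq_len(n)) {
    if (!at$heavy[i])
      stop("atom features are defined for heavy atoms only (got hydrogen)")
    tpl <- .templateAtom(at$resname[i], at$name[i])
    if (is.null(tpl)) {
      rows[i, ] <- .featureRow(at$element[i], degree[i], 0L,
                               .elementValence(at$element[i]), 0)
    } else {
      rows[i, ] <- .featureRow(at$element[i], degree[i], tpl$hydrogens,
                               tpl$valence, tpl$aromatic)
    }
  }
  rows
}

#' Feature vector of a single heavy atom
#'
#' @param structure a [ComplexStructure-class].
#' @param subunit "receptor" or "ligand".
#' @param index row index into the heavy-atom table of that subunit.
#' @return numeric vector of length 23.
#' @export
atomFeatures <- function(structure, subunit = c("receptor", "ligand"),
                         index) {
  subunit <- match.arg(subunit)
  bg <- inferBonds(structure, subunit)
  stopifnot(index >= 1, index <= nrow(bg$atoms))
  .featuresOfAtoms(bg$atoms, bg$edges)[index, ]
}
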