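#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of point set `P` onto `Q` (correspondence by
#' row index) with a proper rotation (det = +1 enforced through the SVD sign
#' correction).
#'
#' @param P,Q M x 3 coordinate matrices, M >= 3.
#' @return list with `rotation` (3x3, applied as `P %*% t(rotation)`),
#'   `translation` (length 3) and `rmsd` (Angstrom).
#' @export
kabschSuperpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  stopifnot(ncol(P) == 3, ncol(Q) == 3, nrow(P) == nrow(Q))
  if (nrow(P) < 3) stop("kabsch superposition needs at least 3 points")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  s <- svd(crossprod(Pc, Qc))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rmsd <- sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  list(rotation = R, translation = as.numeric(cq - R %*% cp), rmsd = rmsd)
}

.applyTransform <- function(X, fit) {
  sweep(as.matrix(X) %*% t(fit$rotation), 2, fit$translation, "+")
}

.residueKeys <- function(at) paste(at$chain, at$resno, at$icode, sep = "|")

#' Interface residues of a native complex
#'
#' Residues of either subunit whose minimum heavy-atom distance to any
#' residue of the other subunit is at most `cutoff`.
#'
#' @param native a [ComplexStructure-class].
#' @param cutoff Angstrom (default 10).
#' @return list of residue-key vectors `receptor` and `ligand`
#'   ("chain|resno|icode").
#' @export
nativeInterfaceResidues <- function(native, cutoff = 10.0) {
  sel <- extractInterface(native, cutoff)
  list(receptor = sel$receptor, ligand = sel$ligand)
}

# C-alpha coordinates of the given residue keys; residues without a CA are
# dropped with a warning; residues absent from the structure are an error.
.caCoords <- function(structure, keys, what) {
  at <- structure@atoms[structure@atoms$heavy, , drop = FALSE]
  rk <- .residueKeys(at)
  missing <- setdiff(keys, rk)
  if (length(missing) > 0)
    stop("unmatched residue in ", what, ": ",
         paste(missing, collapse = ", "))
  ca <- at[at$name == "CA", , drop = FALSE]
  cak <- .residueKeys(ca)
  noCa <- setdiff(keys, cak)
  if (length(noCa) > 0)
    warning("residues lacking CA dropped from RMSD set: ",
            paste(noCa, collapse = ", "))
  keep <- keys[keys %in% cak]
  i <- match(keep, cak)
  list(keys = keep, xyz = as.matrix(ca[i, c("x", "y", "z")]))
}

#' Interface C-alpha RMSD of a decoy against the native complex
#'
#' The interface set is defined on the native complex (`cutoff`, default
#' 10 Angstrom) and mapped to the decoy by residue key; the decoy interface
#' C-alphas are superposed onto the native ones (Kabsch over the interface
#' set) and the RMSD is reported.
#'
#' @param decoy,native [ComplexStructure-class] objects with matching
#'   residue numbering.
#' @param cutoff native interface cutoff (Angstrom).
#' @return iRMSD in Angstrom.
#' @export
irmsd <- function(decoy, native, cutoff = 10.0) {
  sel <- nativeInterfaceResidues(native, cutoff)
  keys <- c(sel$receptor, sel$ligand)
  nat <- .caCoords(native, keys, "native")
  dec <- .caCoords(decoy, nat$keys, "decoy")
  common <- intersect(nat$keys, dec$keys)
  if (length(common) < 3) stop("fewer than 3 matched interface C-alphas")
  kabschSuperpose(dec$xyz[match(common, dec$keys), , drop = FALSE],
                  nat$xyz[match(common, nat$keys), , drop = FALSE])$rmsd
}

#' Ligand C-alpha RMSD after receptor superposition
#'
#' The decoy receptor C-alphas are superposed onto the native receptor
#' C-alphas; the resulting transform is applied to the decoy ligand and the
#' ligand C-alpha RMSD is reported without further fitting.
#'
#' @inheritParams irmsd
#' @return lRMSD in Angstrom.
#' @export
lrmsd <- function(decoy, native) {
  natR <- receptorAtoms(native); natL <- ligandAtoms(native)
  rkeys <- unique(.residueKeys(natR))
  lkeys <- unique(.residueKeys(natL))
  natRca <- .caCoords(native, rkeys, "native receptor")
  decRca <- .caCoords(decoy, natRca$keys, "decoy receptor")
  common <- intersect(natRca$keys, decRca$keys)
  if (length(common) < 3) stop("fewer than 3 matched receptor C-alphas")
  fit <- kabschSuperpose(decRca$xyz[match(common, decRca$keys), ,
                                    drop = FALSE],
                         natRca$xyz[match(common, natRca$keys), ,
                                    drop = FALSE])
  natLca <- .caCoords(native, lkeys, "native ligand")
  decLca <- .caCoords(decoy, natLca$keys, "decoy ligand")
  common <- intersect(natLca$keys, decLca$keys)
  if (length(common) < 1) stop("no matched ligand C-alphas")
  moved <- .applyTransform(decLca$xyz[match(common, decLca$keys), ,
                                      drop = FALSE], fit)
  ref <- natLca$xyz[match(common, natLca$keys), , drop = FALSE]
  sqrt(mean(rowSums((moved - ref)^2)))
}

# cross-subunit residue contact pairs (min heavy-atom distance <= cutoff)
.contactPairs <- function(structure, cutoff) {
  ra <- receptorAtoms(structure); la <- ligandAtoms(structure)
  ra <- ra[ra$heavy, , drop = FALSE]; la <- la[la$heavy, , drop = FALSE]
  d <- .crossDistances(ra, la)
  close <- which(d <= cutoff, arr.ind = TRUE)
  if (nrow(close) == 0) return(character(0))
  unique(paste(.residueKeys(ra)[close[, 1]],
               .residueKeys(la)[close[, 2]], sep = "::"))
}

#' Fraction of native contacts preserved in a decoy
#'
#' Native contacts are cross-subunit residue pairs with any heavy-atom pair
#' within `contactCutoff` (default 5 Angstrom); fnat is the fraction of
#' those present in the decoy (residue correspondence by key).
#'
#' @inheritParams irmsd
#' @param contactCutoff contact distance cutoff (Angstrom).
#' @return fraction in \[0, 1\].
#' @export
fnat <- function(decoy, native, contactCutoff = 5.0) {
  natC <- .contactPairs(native, contactCutoff)
  if (length(natC) == 0)
    stop("native structure has no cross-subunit contacts; fnat undefined")
  decC <- .contactPairs(decoy, contactCutoff)
  length(intersect(natC, decC)) / length(natC)
}

#' CAPRI metrics of a decoy
#'
#' @inheritParams irmsd
#' @param contactCutoff fnat contact cutoff (Angstrom).
#' @return a [CapriMetrics-class].
#' @export
capriMetrics <- function(decoy, native, cutoff = 10.0, contactCutoff = 5.0) {
  new("CapriMetrics",
      irmsd = irmsd(decoy, native, cutoff),
      lrmsd = lrmsd(decoy, native),
      fnat = fnat(decoy, native, contactCutoff))
}

#' CAPRI quality threshold table
#'
#' The standard CAPRI combination table: a class is reached when its fnat
#' floor is met and either RMSD bound holds.  Supplied as data so alternate
#' tables can be tested.
#'
#' @return data.frame with columns `class`, `fnat`, `lrmsd`, `irmsd`,
#'   ordered best class first.
#' @export
capriThresholds <- function() {
  data.frame(class = c("high", "medium", "acceptable"),
             fnat = c(0.5, 0.3, 0.1),
             lrmsd = c(1.0, 5.0, 10.0),
             irmsd = c(1.0, 2.0, 4.0),
             stringsAsFactors = FALSE)
}

#' CAPRI quality class of a metrics triple
#'
#' @param m a [CapriMetrics-class], or the iRMSD when the three values are
#'   given separately.
#' @param lrmsd,fnat scalar metrics (when `m` is the iRMSD).
#' @param thresholds a threshold table, see [capriThresholds()].
#' @return ordered factor with levels incorrect < acceptable < medium <
#'   high.
#' @export
classifyQuality <- function(m, lrmsd = NULL, fnat = NULL,
                            thresholds = capriThresholds()) {
  if (is(m, "CapriMetrics")) {
    ir <- m@irmsd; lr <- m@lrmsd; fn <- m@fnat
  } else {
    ir <- m; lr <- lrmsd; fn <- fnat
  }
  lv <- c("incorrect", "acceptable", "medium", "high")
  cls <- "incorrect"
  for (i in seq_len(nrow(thresholds))) {
    t <- thresholds[i, ]
    if (fn >= t$fnat && (lr <= t$lrmsd || ir <= t$irmsd)) {
      cls <- t$class
      break
    }
  }
  factor(cls, levels = lv, ordered = TRUE)
}

#' Is a decoy "correct" (acceptable or better)?
#' @param quality result of [classifyQuality()].
#' @return logical.
#' @export
isCorrect <- function(quality) {
  as.character(quality) != "incorrect"
}
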