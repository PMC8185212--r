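# Desk-scale synthetic decoy sets: toy poly-alanine complexes plus
# rigid-body ligand perturbations with controllable quality, so that graph
# building, CAPRI metrics, training and evaluation are exercised end to end
# without any external download.

# idealized alanine heavy-atom geometry for residue index i (0-based) of an
# extended strand along x; C(i)-N(i+1) comes out at 1.33 A so the peptide
# bond rule applies.
.alaResidue <- function(i) {
  x0 <- 3.8 * i
  rbind(N  = c(x0, 0, 0),
        CA = c(x0 + 1.235, 1.0, 0),
        C  = c(x0 + 2.47, 0, 0),
        O  = c(x0 + 2.47, -1.23, 0),
        CB = c(x0 + 1.235, 1.7, 1.35))
}

.polyAlaChain <- function(nRes, chain, offset = c(0, 0, 0), serial0 = 0L,
                          jitter = 0) {
  rows <- list()
  for (i in seq_len(nRes) - 1L) {
    xyz <- .alaResidue(i)
    if (jitter > 0)
      xyz <- xyz + matrix(stats::runif(15, -jitter, jitter), 5, 3)
    xyz <- sweep(xyz, 2, offset, "+")
    rows[[i + 1L]] <- data.frame(
      serial = serial0 + i * 5L + 1:5,
      name = rownames(xyz), resname = "ALA", chain = chain,
      resno = i + 1L, icode = "", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      element = c("N", "C", "C", "O", "C"), heavy = TRUE,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Generate a toy native complex
#'
#' Two poly-alanine chains with idealized backbone geometry, placed in
#' contact (at least 3 cross-residue contacts within 5 Angstrom); chain A
#' is the receptor, chain B the ligand.  Deterministic given the seed
#' (small seeded coordinate jitter distinguishes targets).
#'
#' @param nResReceptor,nResLigand residues per chain (>= 3).
#' @param seed integer seed.
#' @return a [ComplexStructure-class].
#' @export
makeNative <- function(nResReceptor = 6L, nResLigand = 5L, seed = 1L) {
  stopifnot(nResReceptor >= 3, nResLigand >= 3)
  set.seed(seed)
  for (try in 1:25) {
    rec <- .polyAlaChain(nResReceptor, "A", jitter = 0.08)
    lig <- .polyAlaChain(nResLigand, "B",
                         offset = c(1.9 + stats::runif(1, -0.3, 0.3),
                                    stats::runif(1, -0.3, 0.3),
                                    5.2 + stats::runif(1, -0.2, 0.2)),
                         serial0 = nResReceptor * 5L, jitter = 0.08)
    lig$subunit <- "ligand"; rec$subunit <- "receptor"
    s <- new("ComplexStructure", atoms = rbind(rec, lig),
             receptorChains = "A", ligandChains = "B", source = "")
    if (length(.contactPairs(s, 5.0)) >= 3) return(s)
  }
  stop("failed to place chains in contact after bounded retries")
}

.rotationMatrix <- function(axis, angleDeg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angleDeg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rigid-body perturbation of the ligand
#'
#' The receptor is untouched; the ligand is rotated by `rotationAngle`
#' degrees about a seeded random axis through its centroid and then
#' translated.
#'
#' @param native a [ComplexStructure-class].
#' @param rotationAngle degrees.
#' @param translation length-3 vector (Angstrom).
#' @param seed seed for the random rotation axis.
#' @return the perturbed [ComplexStructure-class].
#' @export
perturbComplex <- function(native, rotationAngle = 0,
                           translation = c(0, 0, 0), seed = 1L) {
  set.seed(seed)
  axis <- stats::rnorm(3)
  a <- native@atoms
  il <- a$subunit == "ligand"
  xyz <- as.matrix(a[il, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  R <- .rotationMatrix(axis, rotationAngle)
  xyz <- sweep(sweep(xyz, 2, ctr) %*% t(R), 2, ctr + translation, "+")
  a[il, c("x", "y", "z")] <- xyz
  out <- native
  out@atoms <- a
  out
}

#' Generate a labeled synthetic decoy dataset
#'
#' For each target a toy native is built and `decoysPerTarget` rigid-body
#' decoys are drawn.  Each decoy aims at the correct class with probability
#' `positiveFraction`: candidate positives use small perturbations
#' (rotation up to 12 degrees, translation up to 0.8 Angstrom), candidate
#' negatives large ones (rotation 40-180 degrees plus 2.5-8 Angstrom
#' translation); a candidate is redrawn (bounded retries) until its
#' CAPRI class matches the aim and the decoy still has a non-empty
#' interface.  Labels always come from the recomputed metrics.
#'
#' @param nTargets number of targets.
#' @param decoysPerTarget decoys per target.
#' @param positiveFraction aimed fraction of correct decoys, in (0, 1).
#' @param seed master seed.
#' @param outDir when given, PDB files and a `manifest.tsv` are written
#'   there (columns target, decoy, path, label, irmsd, lrmsd, fnat, class).
#' @param nResReceptor,nResLigand chain sizes of the toy natives.
#' @return list of targets; each has `targetId`, `native`, and `decoys`
#'   (list of lists with `decoyId`, `structure`, `metrics`, `class`,
#'   `label`).
#' @export
makeDecoyDataset <- function(nTargets = 8L, decoysPerTarget = 60L,
                             positiveFraction = 0.1, seed = 1L,
                             outDir = NULL, nResReceptor = 6L,
                             nResLigand = 5L) {
  stopifnot(positiveFraction > 0, positiveFraction < 1)
  targets <- vector("list", nTargets)
  manifest <- list()
  for (t in seq_len(nTargets)) {
    tSeed <- (seed * 1013L + t) %% .Machine$integer.max
    native <- makeNative(nResReceptor, nResLigand, seed = tSeed)
    targetId <- sprintf("T%02d", t)
    decoys <- vector("list", decoysPerTarget)
    set.seed((tSeed + 555L) %% .Machine$integer.max)
    for (k in seq_len(decoysPerTarget)) {
      aim <- stats::runif(1) < positiveFraction
      dec <- NULL
      for (try in 1:80) {
        if (aim) {
          ang <- stats::runif(1, 0, 12)
          tr <- stats::rnorm(3)
          tr <- tr / sqrt(sum(tr^2)) * stats::runif(1, 0, 0.8)
        } else {
          ang <- stats::runif(1, 40, 180)
          dir <- c(stats::rnorm(2), stats::rnorm(1) * 0.3)
          tr <- dir / sqrt(sum(dir^2)) * stats::runif(1, 2.5, 8)
        }
        axSeed <- sample.int(1e6, 1)
        cand <- perturbComplex(native, ang, tr, seed = axSeed)
        ok <- tryCatch({
          m <- capriMetrics(cand, native)
          cls <- classifyQuality(m)
          if (isCorrect(cls) == aim &&
              length(.contactPairs(cand, 10.0)) > 0) {
            dec <- list(decoyId = sprintf("%s_D%03d", targetId, k),
                        structure = cand, metrics = m,
                        class = as.character(cls),
                        label = as.integer(isCorrect(cls)))
            TRUE
          } else FALSE
        }, error = function(e) FALSE)
        if (ok) break
      }
      if (is.null(dec))
        stop("could not realize requested class mix for ", targetId,
             " decoy ", k, " after bounded retries")
      decoys[[k]] <- dec
    }
    targets[[t]] <- list(targetId = targetId, native = native,
                         decoys = decoys)
    if (!is.null(outDir)) {
      dir.create(file.path(outDir, targetId), recursive = TRUE,
                 showWarnings = FALSE)
      natPath <- file.path(outDir, targetId, "native.pdb")
      writeComplexPDB(native, natPath)
      for (d in decoys) {
        p <- file.path(outDir, targetId, paste0(d$decoyId, ".pdb"))
        writeComplexPDB(d$structure, p)
        manifest[[length(manifest) + 1L]] <- data.frame(
          target = targetId, decoy = d$decoyId, path = p,
          native = natPath, label = d$label,
          irmsd = d$metrics@irmsd, lrmsd = d$metrics@lrmsd,
          fnat = d$metrics@fnat, class = d$class,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!is.null(outDir)) {
    mf <- do.call(rbind, manifest)
    utils::write.table(mf, file.path(outDir, "manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  targets
}

#' Turn a synthetic dataset into training records
#'
#' Builds the interface graph of every decoy of the selected targets.
#'
#' @param dataset result of [makeDecoyDataset()].
#' @param targetIdx indices of the targets to include (default all).
#' @param cutoff,crossCutoff graph cutoffs (Angstrom).
#' @return list of [decoyRecord()]s.
#' @export
datasetRecords <- function(dataset, targetIdx = seq_along(dataset),
                           cutoff = 10.0, crossCutoff = 10.0) {
  recs <- list()
  for (t in targetIdx) {
    for (d in dataset[[t]]$decoys) {
      g <- buildInterfaceGraph(d$structure, cutoff = cutoff,
                               crossCutoff = crossCutoff)
      recs[[length(recs) + 1L]] <-
        decoyRecord(d$decoyId, g, d$label, d$metrics)
    }
  }
  recs
}
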