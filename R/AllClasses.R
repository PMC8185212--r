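#' @import methods
NULL

#' Two-chain protein complex model
#'
#' Container for a parsed pairwise docking model (or native complex).  Atoms
#' are stored as a single data frame partitioned into a receptor and a ligand
#' subunit by chain identifier.  Hydrogens, if present in the file, are kept
#' but flagged non-heavy; HETATM records and waters are never stored.
#'
#' @slot atoms data.frame with one row per atom and columns `serial`, `name`,
#'   `resname`, `chain`, `resno`, `icode`, `x`, `y`, `z`, `element`, `heavy`,
#'   `subunit`.
#' @slot receptorChains character vector of receptor chain ids.
#' @slot ligandChains character vector of ligand chain ids.
#' @slot source path the structure was read from ("" if built in memory).
#'
#' @seealso [readComplexPDB()], [writeComplexPDB()], [makeNative()]
#' @export
setClass("ComplexStructure",
         representation(atoms = "data.frame",
                        receptorChains = "character",
                        ligandChains = "character",
                        source = "character"))

setValidity("ComplexStructure", function(object) {
  need <- c("serial", "name", "resname", "chain", "resno", "icode",
            "x", "y", "z", "element", "heavy", "subunit")
  a <- object@atoms
  if (!all(need %in% names(a)))
    return(paste("atoms is missing columns:",
                 paste(setdiff(need, names(a)), collapse = ", ")))
  if (length(intersect(object@receptorChains, object@ligandChains)) > 0)
    return("receptor and ligand chain sets overlap")
  if (!any(a$subunit == "receptor")) return("no atoms in receptor chains")
  if (!any(a$subunit == "ligand")) return("no atoms in ligand chains")
  if (!all(is.finite(c(a$x, a$y, a$z))))
    return("non-finite atom coordinates")
  TRUE
})

#' Interface graph pair of a docking model
#'
#' Heavy atoms of the interface residues of a complex model, their 23-bit
#' feature rows, the covalent adjacency matrix and the cross-molecular
#' distances from which the second (covalent + non-covalent) adjacency is
#' assembled at forward time.  Node order is receptor block first, then
#' ligand block, each in file order.
#'
#' The second adjacency `A2` is a function of the learnable edge parameters
#' (`mu`, `sigma`) and is therefore not stored: it is recomputed from
#' `crossDist` by [adjacencyPair()] so that gradients can flow to the edge
#' parameters during training.
#'
#' @slot nodes data.frame describing the atoms behind each node (`name`,
#'   `resname`, `chain`, `resno`, `icode`, `element`).
#' @slot features N x 23 binary feature matrix (see [atomFeatureMatrix()]).
#' @slot A1 N x N covalent adjacency, entries in \{0,1\}, unit diagonal.
#' @slot crossDist N x N matrix; finite entries hold cross-molecular
#'   heavy-atom distances within the cross cutoff, all other entries are Inf.
#' @slot molecule length-N character vector, "receptor" or "ligand".
#' @slot crossCutoff cross-edge distance cutoff in Angstrom (default 10).
#'
#' @seealso [buildInterfaceGraph()], [adjacencyPair()]
#' @export
setClass("InterfaceGraph",
         representation(nodes = "data.frame",
                        features = "matrix",
                        A1 = "matrix",
                        crossDist = "matrix",
                        molecule = "character",
                        crossCutoff = "numeric"))

setValidity("InterfaceGraph", function(object) {
  n <- nrow(object@features)
  if (n < 1) return("graph has no nodes")
  if (ncol(object@features) != 23) return("features must have 23 columns")
  if (!all(dim(object@A1) == c(n, n))) return("A1 dimension mismatch")
  if (!all(dim(object@crossDist) == c(n, n)))
    return("crossDist dimension mismatch")
  if (length(object@molecule) != n) return("molecule length mismatch")
  if (!all(object@molecule %in% c("receptor", "ligand")))
    return("molecule entries must be 'receptor' or 'ligand'")
  if (any(object@A1 != t(object@A1))) return("A1 is not symmetric")
  if (!all(object@A1 %in% c(0, 1))) return("A1 entries must be 0/1")
  if (any(diag(object@A1) != 1)) return("A1 diagonal must be 1")
  same <- outer(object@molecule, object@molecule, "==")
  if (any(is.finite(object@crossDist[same])))
    return("crossDist must be Inf within a molecule")
  TRUE
})

#' CAPRI quality metrics of a decoy
#'
#' @slot irmsd interface C-alpha RMSD (Angstrom).
#' @slot lrmsd ligand C-alpha RMSD after receptor superposition (Angstrom).
#' @slot fnat fraction of native cross-subunit residue contacts preserved.
#' @seealso [capriMetrics()], [classifyQuality()]
#' @export
setClass("CapriMetrics",
         representation(irmsd = "numeric", lrmsd = "numeric",
                        fnat = "numeric"))

setValidity("CapriMetrics", function(object) {
  if (length(object@irmsd) != 1 || object@irmsd < 0) return("bad irmsd")
  if (length(object@lrmsd) != 1 || object@lrmsd < 0) return("bad lrmsd")
  if (length(object@fnat) != 1 || object@fnat < 0 || object@fnat > 1)
    return("fnat must be in [0,1]")
  TRUE
})

#' Gated graph attention scoring network
#'
#' Holds the architecture description and all learnable parameters of the
#' scorer: the 23 -> F atom embedding, the shared gate-augmented attention
#' layers, the global edge parameters (mu, sigma) of the cross-molecular
#' Gaussian edges, and the fully connected head.
#'
#' @slot config list as returned by [networkConfig()].
#' @slot params flat named list of parameter arrays (see [initNetwork()]).
#' @seealso [initNetwork()], [scoreGraph()], [trainNetwork()]
#' @export
setClass("DockScorer",
         representation(config = "list", params = "list"))

setValidity("DockScorer", function(object) {
  if (!all(c("featureWidth", "nGatLayers", "fcDims", "dropout") %in%
           names(object@config)))
    return("incomplete network config")
  if (!all(vapply(object@params, function(p) all(is.finite(p)), logical(1))))
    return("non-finite network parameters")
  TRUE
})
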