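#' Number of nodes of an interface graph
#' @param x an object with a node dimension.
#' @return integer node count.
#' @export
setGeneric("nodeCount", function(x) standardGeneric("nodeCount"))

#' @rdname nodeCount
#' @export
setMethod("nodeCount", "InterfaceGraph", function(x) nrow(x@features))

#' Accessors for complex structures
#'
#' `receptorAtoms()` and `ligandAtoms()` return the atom table of one
#' subunit; `atomTable()` returns all atoms.
#'
#' @param x a [ComplexStructure-class].
#' @return a data.frame of atoms.
#' @export
setGeneric("receptorAtoms", function(x) standardGeneric("receptorAtoms"))

#' @rdname receptorAtoms
#' @export
setGeneric("ligandAtoms", function(x) standardGeneric("ligandAtoms"))

#' @rdname receptorAtoms
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname receptorAtoms
#' @export
setMethod("receptorAtoms", "ComplexStructure",
          function(x) x@atoms[x@atoms$subunit == "receptor", , drop = FALSE])

#' @rdname receptorAtoms
#' @export
setMethod("ligandAtoms", "ComplexStructure",
          function(x) x@atoms[x@atoms$subunit == "ligand", , drop = FALSE])

#' @rdname receptorAtoms
#' @export
setMethod("atomTable", "ComplexStructure", function(x) x@atoms)

setMethod("show", "ComplexStructure", function(object) {
  a <- object@atoms
  cat("ComplexStructure:",
      sum(a$subunit == "receptor"), "receptor atoms (chains",
      paste(object@receptorChains, collapse = ","), "),",
      sum(a$subunit == "ligand"), "ligand atoms (chains",
      paste(object@ligandChains, collapse = ","), ")\n")
  if (nzchar(object@source)) cat("  source:", object@source, "\n")
})

setMethod("show", "InterfaceGraph", function(object) {
  n <- nodeCount(object)
  cat("InterfaceGraph:", n, "interface heavy atoms (",
      sum(object@molecule == "receptor"), "receptor /",
      sum(object@molecule == "ligand"), "ligand )\n")
  cat("  covalent edges:", (sum(object@A1) - n) / 2,
      "; cross pairs <=", object@crossCutoff, "A:",
      sum(is.finite(object@crossDist)) / 2, "\n")
})

setMethod("show", "CapriMetrics", function(object) {
  cat(sprintf("CapriMetrics: iRMSD %.2f A, lRMSD %.2f A, fnat %.3f -> %s\n",
              object@irmsd, object@lrmsd, object@fnat,
              as.character(classifyQuality(object))))
})

setMethod("show", "DockScorer", function(object) {
  cfg <- object@config
  cat("DockScorer: 23 ->", cfg$featureWidth, "embedding,",
      cfg$nGatLayers, "shared gated attention layers, FC head",
      paste(cfg$fcDims, collapse = "-"), "\n")
  cat(sprintf("  edge params: mu = %.4f, sigma = %.4f; dropout %.2f\n",
              object@params$mu, object@params$sigma, cfg$dropout))
})
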