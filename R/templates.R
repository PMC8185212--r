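# Residue chemistry templates.
#
# The 20 standard amino acids fully determine heavy-atom connectivity,
# attached hydrogen counts, and side-chain aromaticity, so these are taken
# from a versioned template table shipped with the package rather than from
# a cheminformatics perception pass.  Docking decoys usually lack hydrogens,
# hence attached-H counts always come from the template, never from file
# content.

.tplEnv <- new.env(parent = emptyenv())

# per-atom "template valence": full heavy-atom degree inside an intact chain
# (intra-residue neighbours, plus one peptide partner for backbone N and C)
# plus the template hydrogen count.  The implicit-valence feature of an atom
# is this value minus its observed heavy-atom degree.
.loadTemplates <- function() {
  if (!is.null(.tplEnv$atoms)) return(invisible(NULL))
  atoms <- utils::read.csv(system.file("extdata", "residue_atoms.csv",
                                       package = "graphdock"),
                           stringsAsFactors = FALSE)
  bonds <- utils::read.csv(system.file("extdata", "residue_bonds.csv",
                                       package = "graphdock"),
                           stringsAsFactors = FALSE)
  deg <- stats::setNames(rep(0L, nrow(atoms)),
                         paste(atoms$residue, atoms$atom))
  for (i in seq_len(nrow(bonds))) {
    k1 <- paste(bonds$residue[i], bonds$atom1[i])
    k2 <- paste(bonds$residue[i], bonds$atom2[i])
    deg[k1] <- deg[k1] + 1L
    deg[k2] <- deg[k2] + 1L
  }
  key <- paste(atoms$residue, atoms$atom)
  peptide <- atoms$atom %in% c("N", "C")   # one partner across the link
  atoms$valence <- deg[key] + as.integer(peptide) + atoms$hydrogens
  .tplEnv$atoms <- atoms
  .tplEnv$bonds <- bonds
  .tplEnv$atomKey <- key
  invisible(NULL)
}

.templateResidues <- function() {
  .loadTemplates()
  unique(.tplEnv$atoms$residue)
}

# returns NULL for unknown (residue, atom) combinations
.templateAtom <- function(resname, atname) {
  .loadTemplates()
  i <- match(paste(resname, atname), .tplEnv$atomKey)
  if (is.na(i)) return(NULL)
  .tplEnv$atoms[i, ]
}

.templateBonds <- function(resname) {
  .loadTemplates()
  b <- .tplEnv$bonds
  b[b$residue == resname, c("atom1", "atom2"), drop = FALSE]
}

# fallback valence by element for atoms outside the template table (OXT,
# non-standard residues): standard organic valences.
.elementValence <- function(element) {
  v <- c(C = 4, N = 3, O = 2, S = 2, H = 1)
  out <- v[element]
  out[is.na(out)] <- 4
  unname(out)
}
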