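# Shared fixtures and independent reference implementations used as
# oracles.  Everything is generated in code; no binary fixtures.

# fixed-width PDB ATOM line
pdbLine <- function(serial, name, resname, chain, resno, x, y, z,
                    altloc = " ", icode = " ", element = "") {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
          altloc, resname, chain, resno, icode, x, y, z, 1, 0, element)
}

writePdbFixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# a minimal two-chain complex: chain A = 2 glycines, chain B = 1 glycine
tinyComplexPDB <- function(bGap = 4.0) {
  res <- function(serial0, chain, resno, x0, z0)
    c(pdbLine(serial0 + 1, "N", "GLY", chain, resno, x0, 0, z0, element = "N"),
      pdbLine(serial0 + 2, "CA", "GLY", chain, resno, x0 + 1.2, 1.0, z0, element = "C"),
      pdbLine(serial0 + 3, "C", "GLY", chain, resno, x0 + 2.47, 0, z0, element = "C"),
      pdbLine(serial0 + 4, "O", "GLY", chain, resno, x0 + 2.47, -1.23, z0, element = "O"))
  writePdbFixture(c(res(0, "A", 1, 0, 0), res(4, "A", 2, 3.8, 0),
                    res(8, "B", 1, 1.0, bGap)))
}

# random proper rotation + translation
randomRigidTransform <- function(seed) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  list(R = R, t = runif(3, -20, 20))
}

applyRigid <- function(structure, tf) {
  a <- structure@atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(tf$R)
  xyz <- sweep(xyz, 2, tf$t, "+")
  a[, c("x", "y", "z")] <- xyz
  out <- structure
  out@atoms <- a
  out
}

# straight-line double-loop reference of one gated attention layer
bruteGatLayer <- function(X, params, A) {
  n <- nrow(X); F <- ncol(X)
  Xp <- matrix(0, n, F)
  for (i in 1:n) Xp[i, ] <- as.numeric(params$W %*% X[i, ])
  e <- matrix(-Inf, n, n)
  for (i in 1:n) for (j in 1:n) if (A[i, j] > 0)
    e[i, j] <- as.numeric(t(Xp[i, ]) %*% params$E %*% Xp[j, ] +
                            t(Xp[j, ]) %*% params$E %*% Xp[i, ])
  e <- pmin(pmax(e, -50), 50)
  e[A <= 0] <- -Inf
  a <- matrix(0, n, n)
  for (i in 1:n) {
    Ni <- which(A[i, ] > 0)
    w <- exp(e[i, Ni] - max(e[i, Ni]))
    a[i, Ni] <- w / sum(w) * A[i, Ni]
  }
  out <- matrix(0, n, F)
  for (i in 1:n) {
    xagg <- numeric(F)
    for (j in 1:n) xagg <- xagg + a[i, j] * Xp[j, ]
    ci <- plogis(sum(params$D * c(X[i, ], xagg)) + params$b)
    out[i, ] <- ci * X[i, ] + (1 - ci) * xagg
  }
  out
}

# random layer params at width F
randomLayerParams <- function(F, seed = 1, scale = 0.3) {
  set.seed(seed)
  list(W = matrix(rnorm(F * F, sd = scale / sqrt(F)), F, F),
       E = matrix(rnorm(F * F, sd = scale / sqrt(F)), F, F),
       D = rnorm(2 * F, sd = scale / sqrt(F)),
       b = rnorm(1, sd = 0.2))
}

# permute the nodes of an InterfaceGraph
permuteGraph <- function(g, perm) {
  new("InterfaceGraph",
      nodes = g@nodes[perm, , drop = FALSE],
      features = g@features[perm, , drop = FALSE],
      A1 = g@A1[perm, perm, drop = FALSE],
      crossDist = g@crossDist[perm, perm, drop = FALSE],
      molecule = g@molecule[perm],
      crossCutoff = g@crossCutoff)
}

# small cached native + graph for network tests
toyGraph <- function(seedStruct = 3) {
  s <- makeNative(5, 4, seed = seedStruct)
  buildInterfaceGraph(s)
}
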