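# brute-force rotational search: minimize RMSD over Euler angles + centroid
bruteSuperposeRmsd <- function(P, Q) {
  obj <- function(par) {
    cx <- cos(par[1]); sx <- sin(par[1])
    cy <- cos(par[2]); sy <- sin(par[2])
    cz <- cos(par[3]); sz <- sin(par[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
    R <- Rz %*% Ry %*% Rx
    Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
    sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  }
  best <- Inf
  for (s in 1:8) {
    set.seed(s)
    r <- stats::optim(runif(3, -pi, pi), obj, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-14))
    best <- min(best, r$value)
  }
  best
}

test_that("Kabsch superposition is optimal and proper", {
  set.seed(1)
  P <- matrix(rnorm(15), 5, 3)
  # identity
  expect_equal(kabschSuperpose(P, P)$rmsd, 0, tolerance = 1e-12)
  # exact recovery of a known rigid transform
  tf <- randomRigidTransform(7)
  Q <- sweep(P %*% t(tf$R), 2, tf$t, "+")
  fit <- kabschSuperpose(P, Q)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  # matches the numerical rotation-search oracle on random point sets
  for (s in 1:3) {
    set.seed(s + 50)
    P4 <- matrix(rnorm(12), 4, 3)
    Q4 <- matrix(rnorm(12), 4, 3)
    expect_equal(kabschSuperpose(P4, Q4)$rmsd, bruteSuperposeRmsd(P4, Q4),
                 tolerance = 1e-6)
  }
  # and agrees with an independent library implementation
  set.seed(99)
  P5 <- matrix(rnorm(21), 7, 3); Q5 <- matrix(rnorm(21), 7, 3)
  # bio3d warns informatively when no fitting indices are given
  ref <- suppressWarnings(bio3d::fit.xyz(fixed = as.numeric(t(Q5)),
                                         mobile = as.numeric(t(P5))))
  refRmsd <- sqrt(mean(rowSums((matrix(ref, ncol = 3, byrow = TRUE) - Q5)^2)))
  expect_equal(kabschSuperpose(P5, Q5)$rmsd, refRmsd, tolerance = 1e-6)
  expect_error(kabschSuperpose(P[1:2, ], P[1:2, ]), "at least 3")
})

test_that("iRMSD is zero at the native and matches direct recomputation", {
  nat <- makeNative(6, 5, seed = 9)
  expect_equal(irmsd(nat, nat), 0, tolerance = 1e-9)
  dec <- perturbComplex(nat, 0, c(0, 0, 2), seed = 1)
  # independent recomputation: select interface residues on the native,
  # gather CA pairs, superpose with the brute-force optimizer
  sel <- nativeInterfaceResidues(nat, 10)
  keys <- c(sel$receptor, sel$ligand)
  caOf <- function(s) {
    a <- atomTable(s)
    a <- a[a$name == "CA", ]
    rk <- paste(a$chain, a$resno, a$icode, sep = "|")
    as.matrix(a[match(keys, rk), c("x", "y", "z")])
  }
  expect_equal(irmsd(dec, nat), bruteSuperposeRmsd(caOf(dec), caOf(nat)),
               tolerance = 1e-6)
  # renumbered decoy -> unmatched residue contract error
  bad <- dec
  bad@atoms$resno[bad@atoms$subunit == "ligand"] <-
    bad@atoms$resno[bad@atoms$subunit == "ligand"] + 100
  expect_error(irmsd(bad, nat), "unmatched residue")
})

test_that("lRMSD of a pure translation equals the translation norm", {
  nat <- makeNative(6, 5, seed = 10)
  expect_equal(lrmsd(nat, nat), 0, tolerance = 1e-9)
  tr <- c(1.2, -0.7, 2.2)
  dec <- perturbComplex(nat, 0, tr, seed = 1)
  expect_equal(lrmsd(dec, nat), sqrt(sum(tr^2)), tolerance = 1e-9)
  # rotated ligand matches a direct recomputation (receptor is identical,
  # so the superposition is the identity and lRMSD is the plain CA RMSD)
  rot <- perturbComplex(nat, 180, c(0, 0, 0), seed = 5)
  caL <- function(s) {
    a <- ligandAtoms(s)
    as.matrix(a[a$name == "CA", c("x", "y", "z")])
  }
  expect_equal(lrmsd(rot, nat),
               sqrt(mean(rowSums((caL(rot) - caL(nat))^2))),
               tolerance = 1e-6)
})

test_that("fnat counts preserved native residue contacts", {
  nat <- makeNative(6, 5, seed = 11)
  expect_equal(fnat(nat, nat), 1.0)
  far <- perturbComplex(nat, 0, c(0, 0, 100), seed = 1)
  expect_equal(fnat(far, nat), 0.0)
  # hand-enumerated toy: native has 4 contacts, decoy preserves 2.
  # receptor: 4 single-atom residues; ligand: 1 residue contacting all 4
  # in the native but only 2 after shifting it along x.
  mkPair <- function(lx) {
    rec <- do.call(c, lapply(1:4, function(i)
      pdbLine(i, "CA", "GLY", "A", i, i * 4, 0, 0, element = "C")))
    lig <- pdbLine(5, "CA", "GLY", "B", 1, lx, 0, 3, element = "C")
    readComplexPDB(writePdbFixture(c(rec, lig)), "A", "B")
  }
  # native ligand at x=10: distances to residues at 4,8,12,16 are
  # sqrt(36+9),sqrt(4+9),sqrt(4+9),sqrt(36+9) -> only residues 2,3 contact
  natT <- mkPair(10)
  expect_equal(length(graphdock:::.contactPairs(natT, 5)), 2)
  # widen the criterion instead: use contact cutoff 7.3 so all 4 contact
  expect_equal(length(graphdock:::.contactPairs(natT, 7.3)), 4)
  # decoy shifted to x=2: residues 1,2 within 7.3, residues 3,4 not
  decT <- mkPair(2)
  expect_equal(fnat(decT, natT, contactCutoff = 7.3), 0.5)
  # native without contacts is an explicit error
  apart <- mkPair(1000)
  expect_error(fnat(natT, apart), "no cross-subunit contacts")
})

test_that("all three metrics are invariant under common rigid transforms", {
  nat <- makeNative(6, 5, seed = 12)
  dec <- perturbComplex(nat, 25, c(1, 0.5, 0), seed = 3)
  m0 <- capriMetrics(dec, nat)
  for (sd in 1:3) {
    decT <- applyRigid(dec, randomRigidTransform(sd))
    m1 <- capriMetrics(decT, nat)
    expect_equal(m1@irmsd, m0@irmsd, tolerance = 1e-6)
    expect_equal(m1@lrmsd, m0@lrmsd, tolerance = 1e-6)
    expect_equal(m1@fnat, m0@fnat)
  }
})

test_that("quality classification reproduces reference worked examples", {
  expect_equal(as.character(classifyQuality(2.54, 2.93, 0.551)), "medium")
  expect_equal(as.character(classifyQuality(2.14, 3.86, 0.453)), "medium")
  expect_equal(as.character(classifyQuality(0.04, 100, 0.05)), "incorrect")
  expect_equal(as.character(classifyQuality(0.5, 0.8, 0.9)), "high")
  expect_equal(as.character(classifyQuality(3.5, 9.0, 0.15)), "acceptable")
})

test_that("quality classification is monotone in each metric", {
  set.seed(5)
  for (k in 1:200) {
    ir <- runif(1, 0, 12); lr <- runif(1, 0, 15); fn <- runif(1)
    q0 <- classifyQuality(ir, lr, fn)
    # improving any single metric never lowers the class
    expect_gte(as.integer(classifyQuality(ir * 0.5, lr, fn)),
               as.integer(q0))
    expect_gte(as.integer(classifyQuality(ir, lr * 0.5, fn)),
               as.integer(q0))
    expect_gte(as.integer(classifyQuality(ir, lr, min(1, fn * 1.5))),
               as.integer(q0))
  }
})
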