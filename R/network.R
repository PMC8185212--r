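#' Network architecture description
#'
#' Defaults follow the reference architecture of the method: a 23 -> 140 atom embedding,
#' four gate-augmented attention layers shared between the covalent and the
#' covalent+cross adjacency, sum pooling, and a four-layer fully connected
#' head (140, 128, 128, 128, 1) with rectifiers between layers and a
#' logistic output; dropout 0.3.
#'
#' @param featureWidth embedding width F.
#' @param nGatLayers number of shared attention layers.
#' @param fcDims dimensions of the fully connected head (input first,
#'   scalar output last).
#' @param dropout dropout rate used in training mode.
#' @return named list.
#' @export
networkConfig <- function(featureWidth = 140L, nGatLayers = 4L,
                          fcDims = c(140L, 128L, 128L, 128L, 1L),
                          dropout = 0.3) {
  stopifnot(featureWidth > 0, nGatLayers > 0, length(fcDims) >= 2,
            fcDims[1] == featureWidth, utils::tail(fcDims, 1) == 1,
            dropout >= 0, dropout < 1)
  list(featureWidth = as.integer(featureWidth),
       nGatLayers = as.integer(nGatLayers),
       fcDims = as.integer(fcDims), dropout = dropout)
}

#' Initialize a scoring network
#'
#' All weight matrices are Glorot-uniform, all biases 0; the edge parameters
#' are mu = 0.0 and sigma = 1.0.  Deterministic given the seed.
#'
#' @param config a [networkConfig()].
#' @param seed integer RNG seed.
#' @return a [DockScorer-class].
#' @export
initNetwork <- function(config = networkConfig(), seed = 1L) {
  set.seed(seed)
  F <- config$featureWidth
  p <- list(Wemb = .glorot(F, 23L), bemb = numeric(F))
  for (l in seq_len(config$nGatLayers)) {
    gp <- gatLayerParams(F)
    p[[paste0("W", l)]] <- gp$W
    p[[paste0("E", l)]] <- gp$E
    p[[paste0("D", l)]] <- gp$D
    p[[paste0("b", l)]] <- gp$b
  }
  p$mu <- 0.0
  p$sigma <- 1.0
  dims <- config$fcDims
  for (k in seq_len(length(dims) - 1)) {
    p[[paste0("Wf", k)]] <- .glorot(dims[k + 1], dims[k])
    p[[paste0("bf", k)]] <- numeric(dims[k + 1])
  }
  new("DockScorer", config = config, params = p)
}

.layerParams <- function(params, l) {
  list(W = params[[paste0("W", l)]], E = params[[paste0("E", l)]],
       D = params[[paste0("D", l)]], b = params[[paste0("b", l)]])
}

.dropMask <- function(dim1, dim2 = NULL, p) {
  if (p <= 0) return(NULL)
  n <- if (is.null(dim2)) dim1 else dim1 * dim2
  m <- (stats::runif(n) >= p) / (1 - p)
  if (is.null(dim2)) m else matrix(m, dim1, dim2)
}

# Full forward pass on one interface graph.  Returns probability, the
# pre-sigmoid logit, and (when keepCache) everything backprop needs.
# Dropout masks are drawn from the current RNG stream in training mode.
.forwardGraph <- function(graph, params, config, training = FALSE,
                          keepCache = FALSE) {
  adj <- adjacencyPair(graph, params$mu, params$sigma)
  p <- if (training) config$dropout else 0
  H <- graph@features %*% t(params$Wemb)
  H <- sweep(H, 2, params$bemb, "+")
  m0 <- if (training) .dropMask(nrow(H), ncol(H), p) else NULL
  if (!is.null(m0)) H <- H * m0
  caches <- vector("list", config$nGatLayers)
  masks <- vector("list", config$nGatLayers)
  for (l in seq_len(config$nGatLayers)) {
    lp <- .layerParams(params, l)
    c2 <- .gatForward(H, adj$A2, adj$support2, lp)
    c1 <- .gatForward(H, adj$A1, adj$support1, lp)
    H <- c2$out - c1$out
    ml <- if (training) .dropMask(nrow(H), ncol(H), p) else NULL
    if (!is.null(ml)) H <- H * ml
    caches[[l]] <- list(c1 = c1, c2 = c2)
    masks[l] <- list(ml)   # keeps NULL placeholders
  }
  g <- colSums(H)
  nfc <- length(config$fcDims) - 1
  acts <- vector("list", nfc)
  fcmasks <- vector("list", nfc)
  h <- g
  for (k in seq_len(nfc)) {
    zk <- as.numeric(params[[paste0("Wf", k)]] %*% h +
                       params[[paste0("bf", k)]])
    if (k < nfc) {
      h <- pmax(zk, 0)
      mk <- if (training) .dropMask(length(h), NULL, p) else NULL
      if (!is.null(mk)) h <- h * mk
      acts[[k]] <- list(z = zk, h = h)
      fcmasks[k] <- list(mk)
    } else {
      acts[[k]] <- list(z = zk, h = zk)
    }
  }
  z <- acts[[nfc]]$z
  prob <- stats::plogis(z)
  out <- list(prob = prob, logit = z)
  if (keepCache)
    out$cache <- list(adj = adj, m0 = m0, masks = masks, caches = caches,
                      g = g, acts = acts, fcmasks = fcmasks,
                      lastH = H)
  out
}

# Backward pass from d(loss)/d(logit); returns gradients in the same flat
# layout as the parameter list.
.backwardGraph <- function(dlogit, fw, graph, params, config) {
  ch <- fw$cache
  gr <- list()
  nfc <- length(config$fcDims) - 1
  dh <- dlogit
  for (k in rev(seq_len(nfc))) {
    hin <- if (k == 1) ch$g else ch$acts[[k - 1]]$h
    dz <- dh
    if (k < nfc) {
      if (!is.null(ch$fcmasks[[k]])) dz <- dz * ch$fcmasks[[k]]
      dz <- dz * (ch$acts[[k]]$z > 0)
    }
    gr[[paste0("Wf", k)]] <- outer(dz, hin)
    gr[[paste0("bf", k)]] <- dz
    dh <- as.numeric(crossprod(params[[paste0("Wf", k)]], dz))
  }
  # sum pooling: every node row receives the pooled gradient
  n <- nodeCount(graph)
  dH <- matrix(dh, n, config$featureWidth, byrow = TRUE)
  dmu <- 0; dsigma <- 0
  crossOk <- is.finite(graph@crossDist)
  sigma <- max(params$sigma, 1e-6)
  for (l in rev(seq_len(config$nGatLayers))) {
    if (!is.null(ch$masks[[l]])) dH <- dH * ch$masks[[l]]
    lp <- .layerParams(params, l)
    b2 <- .gatBackward(dH, ch$caches[[l]]$c2, lp)
    b1 <- .gatBackward(-dH, ch$caches[[l]]$c1, lp)
    gr[[paste0("W", l)]] <- b2$dW + b1$dW
    gr[[paste0("E", l)]] <- b2$dE + b1$dE
    gr[[paste0("D", l)]] <- b2$dD + b1$dD
    gr[[paste0("b", l)]] <- b2$db + b1$db
    if (any(crossOk)) {
      dA2 <- b2$dA[crossOk]
      A2v <- ch$caches[[l]]$c2$A[crossOk]
      dd <- graph@crossDist[crossOk] - params$mu
      dmu <- dmu + sum(dA2 * A2v * 2 * dd / sigma)
      dsigma <- dsigma + sum(dA2 * A2v * dd^2 / sigma^2)
    }
    dH <- b2$dH + b1$dH
  }
  if (!is.null(ch$m0)) dH <- dH * ch$m0
  gr$mu <- dmu
  gr$sigma <- dsigma
  gr$Wemb <- crossprod(dH, graph@features)
  gr$bemb <- colSums(dH)
  gr
}

# Compiled fast path (src/gnn.cpp): same computation as .forwardGraph /
# .backwardGraph, used by the training loop; the two are compared in tests.
.gdRun <- function(graph, params, config, training = FALSE,
                   label = NA_real_, wantGrad = FALSE) {
  cd <- graph@crossDist
  cd[!is.finite(cd)] <- -1
  out <- .gdRunC(graph@features, graph@A1, cd, params,
                 config$nGatLayers, length(config$fcDims) - 1L,
                 config$dropout, training,
                 if (is.na(label)) 0 else label, wantGrad)
  if (wantGrad) {
    # column vectors come back as n x 1 matrices; restore parameter shapes
    out$grads <- stats::setNames(lapply(names(out$grads), function(nm) {
      g <- out$grads[[nm]]
      if (is.null(dim(params[[nm]]))) as.numeric(g) else g
    }), names(out$grads))
  }
  out
}

#' Score an interface graph
#'
#' Runs the forward pass and returns the probability that the underlying
#' docking model is of acceptable quality.  With dropout disabled (the
#' default, `training = FALSE`) the forward pass is deterministic.
#'
#' @param graph an [InterfaceGraph-class].
#' @param network a [DockScorer-class].
#' @param training apply dropout (draws from the current RNG stream).
#' @return probability in (0, 1).
#' @export
scoreGraph <- function(graph, network, training = FALSE) {
  stopifnot(is(graph, "InterfaceGraph"), is(network, "DockScorer"))
  .forwardGraph(graph, network@params, network@config,
                training = training)$prob
}

#' Score a docking model from a PDB file or structure
#'
#' Parses (if needed), extracts the interface, builds the graph pair and
#' runs the network.
#'
#' @param x path to a PDB file or a [ComplexStructure-class].
#' @param network a [DockScorer-class].
#' @param receptorChains,ligandChains chain assignment (see
#'   [readComplexPDB()]); ignored when `x` is already a structure.
#' @param cutoff,crossCutoff interface and cross-edge cutoffs (Angstrom).
#' @return probability in (0, 1).
#' @export
scoreDecoy <- function(x, network, receptorChains = NULL,
                       ligandChains = NULL, cutoff = 10.0,
                       crossCutoff = 10.0) {
  s <- if (is(x, "ComplexStructure")) x
       else readComplexPDB(x, receptorChains, ligandChains)
  g <- buildInterfaceGraph(s, cutoff = cutoff, crossCutoff = crossCutoff)
  scoreGraph(g, network)
}

#' Save / load a network checkpoint
#'
#' Lossless round trip with an embedded version tag; loading validates the
#' tag and fails loudly on corrupt or missing files.
#'
#' @param network a [DockScorer-class].
#' @param path checkpoint file.
#' @return `loadCheckpoint` returns the restored [DockScorer-class].
#' @export
saveCheckpoint <- function(network, path) {
  stopifnot(is(network, "DockScorer"))
  saveRDS(list(version = "graphdock-ckpt-1", config = network@config,
               params = network@params), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("corrupt checkpoint ", path, ": ",
                                           conditionMessage(e),
                                           call. = FALSE))
  if (!is.list(obj) || !identical(obj$version, "graphdock-ckpt-1"))
    stop("checkpoint version mismatch in ", path)
  net <- new("DockScorer", config = obj$config, params = obj$params)
  validObject(net)
  net
}
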