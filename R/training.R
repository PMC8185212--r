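#' Training configuration
#'
#' Defaults follow the standard training schedule of the method: learning rate 0.002, weight
#' decay 0, 100 epochs, batch size 32, dropout 0.3.  `fineTuneLr` is the
#' reduced rate for fine-tuning from a checkpoint (a second-stage option of
#' 0.00002 is config-expressible).
#'
#' @param learningRate Adam learning rate.
#' @param weightDecay L2 weight decay added to the gradient.
#' @param epochs training epochs.
#' @param batchSize per-batch decoy count (even; half correct, half
#'   incorrect).
#' @param dropout dropout rate.
#' @param seed master seed; fans out to initialization, shuffling, dropout.
#' @param fineTuneLr learning rate used when fine-tuning from a checkpoint.
#' @return named list.
#' @export
trainingConfig <- function(learningRate = 0.002, weightDecay = 0,
                           epochs = 100L, batchSize = 32L, dropout = 0.3,
                           seed = 1L, fineTuneLr = 0.0002) {
  stopifnot(learningRate >= 0, epochs > 0, batchSize > 0,
            batchSize %% 2 == 0, weightDecay >= 0)
  list(learningRate = learningRate, weightDecay = weightDecay,
       epochs = as.integer(epochs), batchSize = as.integer(batchSize),
       dropout = dropout, seed = as.integer(seed), fineTuneLr = fineTuneLr)
}

#' Construct a labeled decoy record
#'
#' @param decoyId identifier string.
#' @param graph an [InterfaceGraph-class] (or a path to a serialized one).
#' @param label 1/TRUE for correct (acceptable or better), 0/FALSE for
#'   incorrect.
#' @param metrics optional [CapriMetrics-class]; when present the label
#'   must agree with its quality class.
#' @return list of class "decoyRecord".
#' @export
decoyRecord <- function(decoyId, graph, label, metrics = NULL) {
  label <- as.integer(as.logical(label))
  if (!is.null(metrics)) {
    stopifnot(is(metrics, "CapriMetrics"))
    if (label != as.integer(isCorrect(classifyQuality(metrics))))
      stop("label inconsistent with CAPRI metrics for ", decoyId)
  }
  structure(list(decoyId = decoyId, graph = graph, label = label,
                 metrics = metrics), class = "decoyRecord")
}

#' Class-balanced batch indices
#'
#' Every batch holds exactly `batchSize/2` correct and `batchSize/2`
#' incorrect records.  One epoch is one pass over all incorrect records
#' (shuffled); correct records are resampled with replacement when scarce.
#' Deterministic given the seed.
#'
#' @param labels integer/logical vector (1 = correct).
#' @param batchSize even batch size.
#' @param seed RNG seed.
#' @return list of integer index vectors.
#' @export
balancedBatches <- function(labels, batchSize, seed) {
  labels <- as.integer(as.logical(labels))
  pos <- which(labels == 1); neg <- which(labels == 0)
  if (length(pos) == 0) stop("no correct decoys in the training set")
  if (length(neg) == 0) stop("no incorrect decoys in the training set")
  stopifnot(batchSize %% 2 == 0)
  half <- batchSize / 2
  set.seed(seed)
  negSeq <- sample(neg)
  nBatches <- ceiling(length(negSeq) / half)
  pad <- nBatches * half - length(negSeq)
  if (pad > 0) negSeq <- c(negSeq, sample(neg, pad, replace = TRUE))
  posSeq <- sample(pos, nBatches * half,
                   replace = length(pos) < nBatches * half)
  lapply(seq_len(nBatches), function(b) {
    i <- (b - 1) * half + seq_len(half)
    sample(c(posSeq[i], negSeq[i]))
  })
}

# Adam update; state carries first/second moments and the step counter.
.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adamStep <- function(params, grads, state, lr, weightDecay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weightDecay > 0) g <- g + weightDecay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  params$sigma <- max(params$sigma, 1e-6)
  list(params = params, state = state)
}

# binary cross-entropy from the logit (numerically stable)
.bceFromLogit <- function(z, y) {
  pmax(z, 0) - z * y + log1p(exp(-abs(z)))
}

#' Train the scoring network
#'
#' Minimizes binary cross-entropy with Adam on class-balanced batches.
#' When validation records are given, per-epoch validation loss/accuracy is
#' logged and the parameters with the best validation accuracy are
#' returned; otherwise the final parameters are returned.  Supplying `init`
#' fine-tunes from an existing network at `config$fineTuneLr`.
#'
#' @param records list of [decoyRecord()]s with in-memory graphs.
#' @param config a [trainingConfig()].
#' @param init optional [DockScorer-class] to fine-tune from.
#' @param valRecords optional validation records.
#' @param networkConfig architecture used when `init` is NULL.
#' @param verbose print per-epoch progress.
#' @return list with `network` (a [DockScorer-class]) and `log`
#'   (data.frame, one row per epoch).
#' @export
trainNetwork <- function(records, config = trainingConfig(), init = NULL,
                         valRecords = NULL,
                         networkConfig = graphdock::networkConfig(
                           dropout = config$dropout),
                         verbose = FALSE) {
  stopifnot(length(records) > 0)
  labels <- vapply(records, function(r) r$label, integer(1))
  lr <- config$learningRate
  if (is.null(init)) {
    net <- initNetwork(networkConfig, seed = config$seed)
  } else {
    stopifnot(is(init, "DockScorer"))
    net <- init
    lr <- config$fineTuneLr
  }
  params <- net@params
  cfg <- net@config
  state <- .adamInit(params)
  set.seed(config$seed)
  logRows <- list()
  best <- list(acc = -Inf, params = params)
  for (epoch in seq_len(config$epochs)) {
    batchSeed <- (config$seed + 7919L * epoch) %% .Machine$integer.max
    batches <- balancedBatches(labels, config$batchSize, batchSeed)
    set.seed((batchSeed + 13L) %% .Machine$integer.max)  # dropout stream
    epochLoss <- 0; epochAcc <- 0; nSeen <- 0
    for (bi in batches) {
      gAcc <- NULL
      bLoss <- 0
      for (i in bi) {
        rec <- records[[i]]
        fw <- .gdRun(rec$graph, params, cfg, training = TRUE,
                     label = rec$label, wantGrad = TRUE)
        loss <- .bceFromLogit(fw$logit, rec$label)
        if (!is.finite(loss))
          stop("training diverged (non-finite loss) at epoch ", epoch)
        bLoss <- bLoss + loss
        epochAcc <- epochAcc + as.integer((fw$prob >= 0.5) == rec$label)
        gr <- fw$grads
        gAcc <- if (is.null(gAcc)) gr
                else mapply(function(a, b) a + b, gAcc, gr,
                            SIMPLIFY = FALSE)
      }
      # per-sample gradients are summed; normalize to the batch mean
      gAcc <- lapply(gAcc, function(g) g / length(bi))
      up <- .adamStep(params, gAcc, state, lr, config$weightDecay)
      params <- up$params
      state <- up$state
      epochLoss <- epochLoss + bLoss
      nSeen <- nSeen + length(bi)
    }
    row <- data.frame(epoch = epoch, trainLoss = epochLoss / nSeen,
                      trainAcc = epochAcc / nSeen,
                      valLoss = NA_real_, valAcc = NA_real_)
    if (!is.null(valRecords)) {
      vnet <- new("DockScorer", config = cfg, params = params)
      vm <- validateNetwork(valRecords, vnet)
      row$valLoss <- vm$loss; row$valAcc <- vm$accuracy
      if (vm$accuracy > best$acc) best <- list(acc = vm$accuracy,
                                               params = params)
    }
    logRows[[epoch]] <- row
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  acc %.3f%s", epoch,
                      row$trainLoss, row$trainAcc,
                      if (is.na(row$valAcc)) ""
                      else sprintf("  val acc %.3f", row$valAcc)))
  }
  finalParams <- if (!is.null(valRecords)) best$params else params
  list(network = new("DockScorer", config = cfg, params = finalParams),
       log = do.call(rbind, logRows))
}

#' Evaluate a network on labeled records
#'
#' Dropout is disabled.  Accuracy thresholds the probability at 0.5; AUC is
#' computed with pROC (NA when only one class is present).
#'
#' @param records list of [decoyRecord()]s.
#' @param network a [DockScorer-class].
#' @return list with `loss`, `accuracy`, `auc`, and the per-record `scores`.
#' @export
validateNetwork <- function(records, network) {
  stopifnot(length(records) > 0)
  labels <- vapply(records, function(r) r$label, integer(1))
  out <- vapply(records, function(r) {
    fw <- .gdRun(r$graph, network@params, network@config)
    c(fw$prob, fw$logit)
  }, numeric(2))
  probs <- out[1, ]; logits <- out[2, ]
  auc <- if (length(unique(labels)) < 2) NA_real_ else
    as.numeric(pROC::auc(pROC::roc(labels, probs, quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  list(loss = mean(.bceFromLogit(logits, labels)),
       accuracy = mean((probs >= 0.5) == labels),
       auc = auc,
       scores = data.frame(
         decoyId = vapply(records, function(r) r$decoyId, character(1)),
         score = probs, label = labels, stringsAsFactors = FALSE))
}
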