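# BCE training loop with Adam, plateau learning-rate decay, and per-epoch
# validation Dice model selection.

#' Binary cross-entropy loss
#'
#' Mean over all pixels of the negative log-likelihood
#' `-(y log p + (1-y) log(1-p))`. Probabilities are clipped to
#' `[1e-7, 1 - 1e-7]` so the loss stays finite at saturated predictions.
#'
#' @param pred numeric array of predicted probabilities.
#' @param target binary array of the same shape.
#' @param clip clipping bound (default 1e-7).
#' @return scalar loss (non-negative).
#' @examples
#' bceLoss(c(0.5, 0.5), c(1, 1))  # log(2)
#' @export
bceLoss <- function(pred, target, clip = 1e-7) {
  if (!identical(dim(pred) %||% length(pred),
                 dim(target) %||% length(target))) {
    stop("bceLoss: pred and target shapes differ", call. = FALSE)
  }
  if (!isBinary(target)) {
    stop("bceLoss: target must be binary (0/1)", call. = FALSE)
  }
  p <- pmin(pmax(pred, clip), 1 - clip)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

# One Adam step over the flat parameter list; weight decay enters as an L2
# gradient term. State (m, v, t) lives in `st`, an environment.
adamStep <- function(params, grads, st, lr, beta1, beta2, weightDecay,
                     eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weightDecay > 0) g <- g + weightDecay * params[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  params
}

# Stack a SliceSet into (H, W, 1, n) image and mask arrays.
setToArrays <- function(set, idx = seq_len(length(set))) {
  d <- dim(set[[idx[1]]]@image)
  n <- length(idx)
  x <- array(0, c(d[1], d[2], 1L, n))
  y <- array(0, c(d[1], d[2], 1L, n))
  for (j in seq_along(idx)) {
    r <- set[[idx[j]]]
    x[, , 1L, j] <- r@image
    y[, , 1L, j] <- r@mask
  }
  list(x = x, y = y)
}

#' Predict lesion probability maps for a slice set
#'
#' @param model a `segModel`.
#' @param set a [SliceSet-class] of preprocessed slices.
#' @param batchSize forward batch size (default 8).
#' @return list of probability matrices, one per slice.
#' @export
predictProbs <- function(model, set, batchSize = 8L) {
  n <- length(set)
  out <- vector("list", n)
  for (start in seq(1L, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1L, n)
    a <- setToArrays(set, idx)
    p <- forwardPass(model, a$x, mode = "eval")
    for (j in seq_along(idx)) out[[idx[j]]] <- p[, , 1L, j]
  }
  out
}

#' Train a segmentation model
#'
#' Optimizes the mean binary cross-entropy with Adam (`beta1 = 0.9`,
#' `beta2 = 0.999`), L2 weight decay, and a plateau learning-rate schedule
#' (multiply by `lrDecayFactor` when validation Dice has not improved for
#' `lrPatience` epochs). After every epoch the model is evaluated on the
#' validation set at the binarization threshold and the epoch with the best
#' validation mean Dice is kept. Fully deterministic under `config@seed`.
#'
#' @param model a `segModel` (its weights are the starting point).
#' @param trainSet,valSet [SliceSet-class] objects of preprocessed slices.
#' @param config a [TrainConfig-class].
#' @param verbose print a per-epoch progress line (default FALSE).
#' @param logFile optional path; per-epoch lines are appended when given.
#' @return list with `model` (best-epoch checkpoint) and `history`
#'   (a [TrainHistory-class]).
#' @export
trainModel <- function(model, trainSet, valSet, config, verbose = FALSE,
                       logFile = NULL) {
  if (length(trainSet) == 0L || length(valSet) == 0L) {
    stop("trainModel: training and validation sets must be non-empty",
         call. = FALSE)
  }
  cfg <- model$config
  n <- length(trainSet)
  withSeed(config@seed, {
    params <- model$params
    bufs <- buffersAsEnvs(model$buffers)
    st <- new.env(parent = emptyenv())
    st$t <- 0L
    st$m <- lapply(params, function(p) p * 0)
    st$v <- st$m
    lr <- config@initialLr
    bestDsc <- -Inf
    bestModel <- NULL
    bestEpoch <- 0L
    sinceBest <- 0L
    hist <- data.frame(epoch = integer(), lr = numeric(),
                       trainLoss = numeric(), valDsc = numeric())
    for (epoch in seq_len(config@epochs)) {
      ord <- sample.int(n)
      lossSum <- 0
      for (start in seq(1L, n, by = config@batchSize)) {
        idx <- ord[start:min(start + config@batchSize - 1L, n)]
        a <- setToArrays(trainSet, idx)
        tape <- agTape()
        pn <- lapply(params, function(v) agLeaf(tape, v))
        r <- .netForward(tape, pn, bufs, cfg, agLeaf(tape, a$x), "train")
        loss <- agBCE(tape, r$pred, a$y)
        if (!is.finite(loss$value)) {
          stop(sprintf(paste0("trainModel: non-finite loss at epoch %d ",
                              "(lr %.2e); training diverged"), epoch, lr),
               call. = FALSE)
        }
        lossSum <- lossSum + loss$value * length(idx)
        agBackward(tape, loss)
        grads <- lapply(pn, function(nd) nd$grad)
        params <- adamStep(params, grads, st, lr, config@beta1, config@beta2,
                           config@weightDecay)
      }
      trainLoss <- lossSum / n
      cur <- structure(list(params = params, buffers = envsAsBuffers(bufs),
                            config = cfg, seed = model$seed),
                       class = "segModel")
      valRep <- evaluateModel(cur, valSet, threshold = config@threshold,
                              prCurve = FALSE)
      valDsc <- metricMeans(valRep)[["dsc"]]
      hist <- rbind(hist, data.frame(epoch = epoch, lr = lr,
                                     trainLoss = trainLoss, valDsc = valDsc))
      line <- sprintf("epoch %3d  lr %.2e  train loss %.5f  val DSC %.4f",
                      epoch, lr, trainLoss, valDsc)
      if (verbose) message(line)
      if (!is.null(logFile)) cat(line, "\n", file = logFile, append = TRUE)
      if (valDsc > bestDsc) {
        bestDsc <- valDsc
        bestModel <- cur
        bestEpoch <- epoch
        sinceBest <- 0L
      } else {
        sinceBest <- sinceBest + 1L
        if (sinceBest >= config@lrPatience) {
          lr <- lr * config@lrDecayFactor
          sinceBest <- 0L
        }
      }
    }
    list(model = bestModel,
         history = new("TrainHistory", epochs = hist,
                       bestEpoch = bestEpoch))
  })
}

#' Evaluate a model on a test set
#'
#' Computes the per-slice confusion at the given threshold, averages the five
#' scalar metrics over slices (mean and standard deviation), and pools the
#' raw probabilities of all slices into one precision-recall curve.
#'
#' @param model a `segModel`.
#' @param testSet a [SliceSet-class].
#' @param threshold binarization threshold in (0, 1) (default 0.5).
#' @param batchSize forward batch size.
#' @param prCurve also compute the pooled PR curve (default TRUE; skipped
#'   during per-epoch validation for speed).
#' @return a [MetricsReport-class].
#' @export
evaluateModel <- function(model, testSet, threshold = 0.5, batchSize = 8L,
                          prCurve = TRUE) {
  if (length(testSet) == 0L) {
    stop("evaluateModel: empty test set", call. = FALSE)
  }
  if (threshold <= 0 || threshold >= 1) {
    stop("evaluateModel: threshold must lie in (0,1)", call. = FALSE)
  }
  probs <- predictProbs(model, testSet, batchSize)
  truths <- lapply(seq_len(length(testSet)),
                   function(i) testSet[[i]]@mask)
  metricsFromPredictions(probs, truths, threshold = threshold,
                         prCurve = prCurve)
}

# Shared by evaluateModel and oracle-model tests: metrics from explicit
# probability maps.
metricsFromPredictions <- function(probs, truths, threshold = 0.5,
                                   prCurve = TRUE) {
  per <- do.call(rbind, Map(function(p, y) {
    cc <- confusionCounts(p >= threshold, y)
    as.data.frame(scalarMetrics(cc))
  }, probs, truths))
  means <- vapply(per, mean, numeric(1))
  sds <- vapply(per, function(v) if (length(v) > 1L) sd(v) else 0, numeric(1))
  auc <- NA_real_
  pr <- data.frame(recall = numeric(), precision = numeric())
  if (prCurve && sum(vapply(truths, sum, numeric(1))) > 0) {
    crv <- attrunet::prCurve(unlist(probs), unlist(truths))
    auc <- crv$auc
    pr <- crv$points
  }
  new("MetricsReport", means = means, sds = sds, auc = auc,
      perSlice = per, prCurve = pr)
}
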