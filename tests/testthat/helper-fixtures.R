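# Shared fixtures and independent oracles for the test suite. Oracles are
# written as direct, naive arithmetic so they stay independent of the
# package's optimized implementations.

tinyPhantom <- function(seed = 3L, side = 64L, ...) {
  phantomSpec(imageSide = side, lesionAreaFraction = c(0.008, 0.06),
              seed = seed, ...)
}

tinyCohort <- function(nPatients = 6L, slices = c(2L, 3L), side = 32L,
                       seed = 5L) {
  generateCohort(cohortSpec(nPatients = nPatients, slicesPerPatient = slices,
                            phantom = tinyPhantom(seed = seed, side = side)))
}

makeRecord <- function(img, msk = NULL, id = "P1", idx = 0L) {
  if (is.null(msk)) msk <- matrix(0, nrow(img), ncol(img))
  SliceRecord(id, idx, img, msk)
}

# naive per-pixel 2-D "same" convolution (loop form)
naiveConv <- function(x, W, b) {
  d <- dim(x); dw <- dim(W)
  H <- d[1]; Wd <- d[2]; C <- d[3]; N <- d[4]
  kh <- dw[1]; kw <- dw[2]; oC <- dw[4]
  ph <- (kh - 1) / 2; pw <- (kw - 1) / 2
  y <- array(0, c(H, Wd, oC, N))
  for (n in 1:N) for (oc in 1:oC) for (w in 1:Wd) for (h in 1:H) {
    s <- b[oc]
    for (ic in 1:C) for (kx in 1:kw) for (ky in 1:kh) {
      sh <- h + ky - 1 - ph; sw <- w + kx - 1 - pw
      if (sh >= 1 && sh <= H && sw >= 1 && sw <= Wd) {
        s <- s + x[sh, sw, ic, n] * W[ky, kx, ic, oc]
      }
    }
    y[h, w, oc, n] <- s
  }
  y
}

# scalar attention-gate oracle for 1-channel maps with 1x1 weights: applies
# the gate equations independently at every pixel
scalarGateOracle <- function(xe, xd, we, wd, psi, bl, bm) {
  lam <- we * xe + wd * xd + bl
  mu <- psi * pmax(lam, 0) + bm
  alpha <- 1 / (1 + exp(-mu))
  list(gated = alpha * xe, alpha = alpha)
}

# scalar eval-mode BN with gamma 1, beta 0, running mean 0, running var 1
scalarBn <- function(v, eps = 1e-5) v / sqrt(1 + eps)

# hand-unrolled scalar RCL oracle (1x1 kernel, 1 channel, eval-mode BN)
scalarRclOracle <- function(x, wf, wr, b, t, eps = 1e-5) {
  o <- pmax(scalarBn(wf * x + b, eps), 0)
  if (t > 1) {
    for (tau in 2:t) {
      o <- pmax(scalarBn(wf * x + wr * o + b, eps), 0)
    }
  }
  o
}

# identity-scale eval-mode BN parameter set for a public RCL call
evalBnParams <- function(outC) {
  list(gamma = rep(1, outC), beta = rep(0, outC),
       runningMean = rep(0, outC), runningVar = rep(1, outC))
}

perSliceDsc <- function(set, probs, threshold = 0.5) {
  vapply(seq_len(length(set)), function(i) {
    cc <- confusionCounts((probs[[i]] >= threshold) * 1, sliceMask(set[[i]]))
    scalarMetrics(cc)$dsc
  }, numeric(1))
}

# best fixed-threshold segmenter on Z-scored intensities: the trivial
# baseline that similar-intensity distractors are supposed to defeat
thresholdBaselineDsc <- function(set, thresholds = seq(-1, 3, by = 0.1)) {
  nset <- normalizeSliceSet(set, computeDatasetStats(set))
  best <- 0
  for (th in thresholds) {
    d <- mean(vapply(seq_len(length(nset)), function(i) {
      cc <- confusionCounts((sliceImage(nset[[i]]) >= th) * 1,
                            sliceMask(nset[[i]]))
      scalarMetrics(cc)$dsc
    }, numeric(1)))
    best <- max(best, d)
  }
  best
}

zeroGateParams <- function(ce = 1L, cd = 1L, cint = 1L) {
  list(We = array(0, c(1, 1, ce, cint)), Wd = array(0, c(1, 1, cd, cint)),
       psi = array(0, c(1, 1, cint, 1)), b_lambda = rep(0, cint), b_mu = 0)
}

rclParams1 <- function(wf, wr, b) {
  c(list(Wf = array(wf, c(1, 1, 1, 1)), b = b,
         Wr = array(wr, c(1, 1, 1, 1))), evalBnParams(1L))
}

rrcbParams1 <- function(ws, bs, wf1, wr1, b1, wf2, wr2, b2) {
  list(short = list(W = array(ws, c(1, 1, 1, 1)), b = bs),
       rcl1 = rclParams1(wf1, wr1, b1),
       rcl2 = rclParams1(wf2, wr2, b2))
}

# exhaustive brute-force PR curve: every distinct score as threshold
bruteForcePr <- function(scores, truths) {
  th <- sort(unique(scores), decreasing = TRUE)
  rec <- prec <- numeric(length(th))
  for (i in seq_along(th)) {
    pred <- scores >= th[i]
    rec[i] <- sum(pred & truths == 1) / sum(truths)
    prec[i] <- sum(pred & truths == 1) / sum(pred)
  }
  r <- c(0, rec); p <- c(prec[1], prec)
  sum(diff(r) * (head(p, -1) + tail(p, -1)) / 2)
}
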