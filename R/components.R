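# Architectural mechanisms: soft spatial attention gate, recurrent
# convolutional layer (RCL) with in-loop batch normalization, and the
# residual recurrent convolution block (RRCB).
#
# Each mechanism exists at two levels: a tape-level builder (.ag*) used inside
# the assembled network so gradients flow end to end, and an exported
# array-level wrapper that runs the same builder on a throwaway tape for
# standalone use and testing. There is a single implementation of the math.

# ---- attention gate ----------------------------------------------------

# lambda = W_e * x_e + W_d * x_d + b_lambda            (1x1 convolutions)
# mu     = psi * ReLU(lambda) + b_mu                   (1x1 to one channel)
# alpha  = sigmoid(mu);  gated = alpha (.) x_e         (broadcast product)
.agAttentionGate <- function(tape, xe, xd, p) {
  lam_e <- agConv(tape, xe, p$We, p$b_lambda)
  lam_d <- agConv(tape, xd, p$Wd, agLeaf(tape, rep(0, length(p$b_lambda$value))))
  lam <- agAdd(tape, lam_e, lam_d)
  mu <- agConv(tape, agRelu(tape, lam), p$psi, p$b_mu)
  alpha <- agSigmoid(tape, mu)
  list(gated = agGateMul(tape, xe, alpha), coefficients = alpha)
}

#' Soft spatial attention gate on a skip connection
#'
#' Computes per-pixel attention coefficients from an encoder feature map and a
#' (spatially aligned) decoder guidance map via 1x1 convolutions, and returns
#' the encoder features reweighted by those coefficients. The coefficients
#' pass through a sigmoid, so they lie strictly in (0, 1); coarser-scale
#' decoder semantics thereby guide which encoder locations survive the skip
#' connection.
#'
#' @param x_e encoder feature map, 4-D array (H, W, C_e, N).
#' @param x_d decoder guidance map, 4-D array (H, W, C_d, N); must match
#'   `x_e` in height, width and batch size (upsample it first if needed, see
#'   [upsampleBilinear2x()]).
#' @param params named list of gate parameters: `We` (1,1,C_e,C_int) and `Wd`
#'   (1,1,C_d,C_int) 1x1 convolution weights, `psi` (1,1,C_int,1), bias
#'   vectors `b_lambda` (length C_int) and `b_mu` (length 1).
#' @return list with `gated` (same shape as `x_e`) and `coefficients`
#'   (H, W, 1, N) in (0, 1).
#' @examples
#' xe <- array(rnorm(2 * 2 * 1 * 1), c(2, 2, 1, 1))
#' xd <- array(rnorm(2 * 2 * 1 * 1), c(2, 2, 1, 1))
#' p <- list(We = array(0, c(1, 1, 1, 1)), Wd = array(0, c(1, 1, 1, 1)),
#'           psi = array(0, c(1, 1, 1, 1)), b_lambda = 0, b_mu = 0)
#' attentionGate(xe, xd, p)$coefficients[1, 1, 1, 1]  # sigmoid(0) = 0.5
#' @export
attentionGate <- function(x_e, x_d, params) {
  stopIfNot4d(x_e, "x_e"); stopIfNot4d(x_d, "x_d")
  de <- dim(x_e); dd <- dim(x_d)
  if (!identical(de[1:2], dd[1:2])) {
    stop("attentionGate: x_e and x_d spatial dimensions differ (",
         paste(de[1:2], collapse = "x"), " vs ",
         paste(dd[1:2], collapse = "x"),
         "); resample the guidance map first", call. = FALSE)
  }
  if (de[4] != dd[4]) stop("attentionGate: batch sizes differ", call. = FALSE)
  tape <- agTape()
  p <- lapply(params[c("We", "Wd", "psi", "b_lambda", "b_mu")],
              function(v) agLeaf(tape, v))
  r <- .agAttentionGate(tape, agLeaf(tape, x_e), agLeaf(tape, x_d), p)
  list(gated = r$gated$value, coefficients = r$coefficients$value)
}

# ---- recurrent convolutional layer -------------------------------------

# One RCL: t total Conv+BN+ReLU passes over a constant input X.
#   I(0) = Wf*X + b                      (no recurrent term on the first pass)
#   I(tau) = Wf*X + Wr*O(tau-1) + b      for tau = 1 .. t-1
# each pass applies conv -> batch norm -> ReLU; output is O(t-1).
# Conv weights are tied across passes; batch-norm state is shared by default
# (bnList of length 1) or per-step (length t).
.agRCL <- function(tape, x, p, tSteps, mode, cfg, bnPrefix, buffers) {
  bn <- function(h, step) {
    i <- if (cfg@bnPerStep) step else 1L
    g <- p$gamma[[i]]; b <- p$beta[[i]]
    key <- paste0(bnPrefix, if (cfg@bnPerStep) paste0(".s", i) else "")
    buf <- buffers[[key]]
    if (mode == "train") {
      agBNTrain(tape, h, g, b, buf, eps = cfg@bnEpsilon,
                momentum = cfg@bnMomentum)
    } else {
      agBNEval(tape, h, g, b, buf, eps = cfg@bnEpsilon)
    }
  }
  ff <- agConv(tape, x, p$Wf, p$b)   # constant across steps; node reused
  o <- agRelu(tape, bn(ff, 1L))
  if (tSteps > 1L) {
    zeroB <- agLeaf(tape, rep(0, dim(p$Wf$value)[4]))
    for (step in 2:tSteps) {
      rec <- agConv(tape, o, p$Wr, zeroB)
      o <- agRelu(tape, bn(agAdd(tape, ff, rec), step))
    }
  }
  o
}

#' Recurrent convolutional layer
#'
#' Applies `t` successive Conv+BN+ReLU passes in which the original input
#' enters every pass through the feed-forward weights while the previous
#' pass's output re-enters through the recurrent weights. The first pass uses
#' the feed-forward term alone. With `t = 1` the layer reduces to a plain
#' convolution + batch norm + ReLU; with zero recurrent weights the output
#' equals the `t = 1` result for any `t`.
#'
#' @param x input feature map (H, W, inC, N).
#' @param params named list: `Wf` (kh, kw, inC, outC) feed-forward weights,
#'   `b` (outC) bias, `Wr` (kh, kw, outC, outC) recurrent weights (required
#'   when `t > 1`), `gamma`/`beta` (outC) batch-norm affine parameters, and in
#'   eval mode `runningMean`/`runningVar` (outC).
#' @param t number of total convolution passes (>= 1).
#' @param mode `"train"` (batch statistics) or `"eval"` (running statistics).
#' @param bnEpsilon batch-norm variance floor (default 1e-5).
#' @param bnMomentum running-statistics momentum used in train mode.
#' @return output feature map (H, W, outC, N), non-negative (terminal ReLU);
#'   in train mode the updated running statistics are attached as attributes
#'   `runningMean` and `runningVar`.
#' @export
recurrentConvLayer <- function(x, params, t = 3L,
                               mode = c("train", "eval"),
                               bnEpsilon = 1e-5, bnMomentum = 0.1) {
  mode <- match.arg(mode)
  stopIfNot4d(x, "x")
  dw <- dim(params$Wf)
  if (dim(x)[3] != dw[3]) {
    stop("recurrentConvLayer: input has ", dim(x)[3],
         " channels but Wf expects ", dw[3], call. = FALSE)
  }
  if (t > 1L && is.null(params$Wr)) {
    stop("recurrentConvLayer: recurrent weights Wr required for t > 1",
         call. = FALSE)
  }
  if (mode == "eval" &&
      (is.null(params$runningMean) || is.null(params$runningVar))) {
    stop("recurrentConvLayer: eval mode requires running statistics",
         call. = FALSE)
  }
  tape <- agTape()
  cfg <- networkConfig(baseChannels = 1L, bnEpsilon = bnEpsilon,
                       bnMomentum = bnMomentum, dropoutRate = 0)
  buf <- new.env(parent = emptyenv())
  buf$mean <- params$runningMean %||% rep(0, dw[4])
  buf$var <- params$runningVar %||% rep(1, dw[4])
  p <- list(Wf = agLeaf(tape, params$Wf), b = agLeaf(tape, params$b),
            Wr = if (!is.null(params$Wr)) agLeaf(tape, params$Wr),
            gamma = list(agLeaf(tape, params$gamma)),
            beta = list(agLeaf(tape, params$beta)))
  buffers <- list(rcl = buf)
  o <- .agRCL(tape, agLeaf(tape, x), p, as.integer(t), mode, cfg, "rcl",
              buffers)
  out <- o$value
  if (mode == "train") {
    attr(out, "runningMean") <- buf$mean
    attr(out, "runningVar") <- buf$var
  }
  out
}

# ---- residual recurrent convolution block ------------------------------

# shortcut = 1x1 conv matching channels; body = two RCLs; output =
# modulatingScalar * shortcut + body(shortcut). The outer combine is the
# identity.
.agRRCB <- function(tape, x, p, tSteps, mode, cfg, prefix, buffers) {
  s <- agConv(tape, x, p$short$W, p$short$b)
  h <- .agRCL(tape, s, p$rcl1, tSteps, mode, cfg, paste0(prefix, ".rcl1"),
              buffers)
  h <- .agRCL(tape, h, p$rcl2, tSteps, mode, cfg, paste0(prefix, ".rcl2"),
              buffers)
  agAdd(tape, agScaleConst(tape, s, cfg@modulatingScalar), h)
}

#' Residual recurrent convolution block
#'
#' A 1x1 convolution maps the input to the block's output width; two
#' [recurrentConvLayer()]s form the body; the block output is
#' `modulatingScalar * shortcut + body(shortcut)` (identity outer combine).
#'
#' @param x input feature map (H, W, inC, N).
#' @param params named list with `short` (list `W` (1,1,inC,outC), `b`),
#'   `rcl1` and `rcl2` (each a [recurrentConvLayer()] parameter list mapping
#'   outC -> outC).
#' @param t recurrence steps for both body layers.
#' @param mode `"train"` or `"eval"`.
#' @param modulatingScalar weighting of the shortcut term (default 1, plain
#'   residual addition).
#' @param bnEpsilon,bnMomentum batch-norm settings.
#' @return output feature map (H, W, outC, N).
#' @export
rrcb <- function(x, params, t = 3L, mode = c("train", "eval"),
                 modulatingScalar = 1, bnEpsilon = 1e-5, bnMomentum = 0.1) {
  mode <- match.arg(mode)
  stopIfNot4d(x, "x")
  if (dim(x)[3] != dim(params$short$W)[3]) {
    stop("rrcb: input has ", dim(x)[3], " channels but the block expects ",
         dim(params$short$W)[3], call. = FALSE)
  }
  tape <- agTape()
  cfg <- networkConfig(baseChannels = 1L, modulatingScalar = modulatingScalar,
                       bnEpsilon = bnEpsilon, bnMomentum = bnMomentum,
                       dropoutRate = 0)
  outC <- dim(params$short$W)[4]
  mkrcl <- function(q) {
    list(Wf = agLeaf(tape, q$Wf), b = agLeaf(tape, q$b),
         Wr = if (!is.null(q$Wr)) agLeaf(tape, q$Wr),
         gamma = list(agLeaf(tape, q$gamma)),
         beta = list(agLeaf(tape, q$beta)))
  }
  mkbuf <- function(q) {
    buf <- new.env(parent = emptyenv())
    buf$mean <- q$runningMean %||% rep(0, outC)
    buf$var <- q$runningVar %||% rep(1, outC)
    buf
  }
  p <- list(short = list(W = agLeaf(tape, params$short$W),
                         b = agLeaf(tape, params$short$b)),
            rcl1 = mkrcl(params$rcl1), rcl2 = mkrcl(params$rcl2))
  buffers <- list("blk.rcl1" = mkbuf(params$rcl1),
                  "blk.rcl2" = mkbuf(params$rcl2))
  .agRRCB(tape, agLeaf(tape, x), p, as.integer(t), mode, cfg, "blk",
          buffers)$value
}

# ---- closed-form multi-layer residual expansion ------------------------

#' Closed-form input of a deep stack of residual layers
#'
#' For stacked residual layers `x_{k+1} = alpha_k * x_k + f_k(x_k)`, evaluates
#' the telescoped closed form
#' `x_I = (prod alpha_k) x_i + sum_k (prod_{h>k} alpha_h) f_k(x_k)`
#' rather than the recursion itself. A verification utility: tests cross-check
#' it against sequential application of the one-layer rule.
#'
#' @param x input of the first layer (array or numeric).
#' @param alphas numeric vector of per-layer modulating scalars (length >= 1).
#' @param fs list of per-layer functions `f_k` (same length as `alphas`).
#' @return the closed-form input of layer `I = i + length(alphas)`.
#' @export
unrolledResidualInput <- function(x, alphas, fs) {
  nl <- length(alphas)
  if (nl < 1L || length(fs) != nl) {
    stop("unrolledResidualInput: need matching non-empty alphas and fs",
         call. = FALSE)
  }
  # layer inputs are needed as arguments of f_k; build them sequentially,
  # then assemble the closed form from scratch.
  xs <- vector("list", nl)
  xs[[1]] <- x
  if (nl > 1L) {
    for (k in seq_len(nl - 1L)) {
      xs[[k + 1]] <- alphas[k] * xs[[k]] + fs[[k]](xs[[k]])
    }
  }
  out <- prod(alphas) * x
  for (k in seq_len(nl)) {
    coef <- if (k < nl) prod(alphas[(k + 1):nl]) else 1
    out <- out + coef * fs[[k]](xs[[k]])
  }
  out
}

#' Bilinear 2x upsampling of a feature map
#'
#' Half-pixel-center bilinear interpolation used to align decoder guidance
#' maps with encoder resolution before attention gating.
#' @param x 4-D array (H, W, C, N).
#' @return array (2H, 2W, C, N).
#' @export
upsampleBilinear2x <- function(x) {
  stopIfNot4d(x)
  .c_upsample2_bilinear_fwd(x)
}
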