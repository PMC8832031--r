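# Minimal reverse-mode autodiff tape.
#
# Nodes are environments carrying a value, an optional vector-Jacobian product
# closure, and references to parent nodes. Operations append nodes in
# evaluation order, so the tape itself is a topological order and the backward
# sweep is a single reverse pass with gradient accumulation at shared nodes
# (weight sharing across recurrence steps relies on this).
#
# Feature maps are dense (H, W, C, N) arrays; parameters are arrays/vectors.
# Heavy kernels (convolution, pooling, resampling) are implemented in C++.

agTape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

agNode <- function(tape, value, parents = list(), vjp = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$vjp <- vjp
  if (!is.null(tape)) {
    n <- tape$n + 1L
    if (n > length(tape$nodes)) {
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    }
    tape$nodes[[n]] <- nd
    tape$n <- n
  }
  nd
}

agLeaf <- function(tape, value) agNode(tape, value)

# Backward sweep from a scalar loss node. Gradients of leaves are left on
# their $grad fields; intermediate gradients are dropped as soon as consumed.
agBackward <- function(tape, loss) {
  loss$grad <- 1
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad)) next
    if (!is.null(nd$vjp)) {
      gs <- nd$vjp(nd$grad)
      ps <- nd$parents
      for (j in seq_along(ps)) {
        g <- gs[[j]]
        if (is.null(g)) next
        p <- ps[[j]]
        p$grad <- if (is.null(p$grad)) g else p$grad + g
      }
    }
    if (length(nd$parents)) nd$grad <- NULL
  }
  invisible(NULL)
}

# ---- broadcasting helpers (per-channel vectors over (H, W, C, N) arrays) ----

bcChannel <- function(v, d) {
  rep(rep(v, each = d[1] * d[2]), times = d[4])
}

sumChannel <- function(a, d) {
  m <- colSums(array(a, c(d[1] * d[2], d[3], d[4])))  # C x N
  if (is.matrix(m)) rowSums(m) else m
}

# ---- primitive ops ----

agConv <- function(tape, x, W, b) {
  y <- .c_conv2d_fwd(x$value, W$value, b$value)
  xv <- x$value; Wv <- W$value
  agNode(tape, y, list(x, W, b), function(g) {
    r <- .c_conv2d_bwd(xv, Wv, g)
    list(r$dx, r$dW, r$db)
  })
}

agAdd <- function(tape, a, b) {
  agNode(tape, a$value + b$value, list(a, b), function(g) list(g, g))
}

agScaleConst <- function(tape, x, s) {
  agNode(tape, x$value * s, list(x), function(g) list(g * s))
}

agRelu <- function(tape, x) {
  m <- x$value > 0
  agNode(tape, x$value * m, list(x), function(g) list(g * m))
}

agSigmoid <- function(tape, x) {
  # clamped away from 0/1 so saturated logits keep the open-interval contract
  v <- pmin(pmax(1 / (1 + exp(-x$value)), 1e-12), 1 - 1e-12)
  agNode(tape, v, list(x), function(g) list(g * v * (1 - v)))
}

# Batch norm, training mode: biased batch statistics normalize; running
# buffers (env with $mean, $var) are updated with momentum and the unbiased
# variance, following the usual deep-learning convention.
agBNTrain <- function(tape, x, gamma, beta, buf, eps = 1e-5, momentum = 0.1) {
  d <- dim(x$value)
  m <- d[1] * d[2] * d[4]
  mu <- sumChannel(x$value, d) / m
  xc <- x$value - bcChannel(mu, d)
  varb <- sumChannel(xc * xc, d) / m
  invstd <- 1 / sqrt(varb + eps)
  xhat <- xc * bcChannel(invstd, d)
  y <- xhat * bcChannel(gamma$value, d) + bcChannel(beta$value, d)
  dim(y) <- d
  if (!is.null(buf)) {
    ub <- if (m > 1) varb * m / (m - 1) else varb
    buf$mean <- (1 - momentum) * buf$mean + momentum * mu
    buf$var <- (1 - momentum) * buf$var + momentum * ub
  }
  gv <- gamma$value
  agNode(tape, y, list(x, gamma, beta), function(g) {
    dxhat <- g * bcChannel(gv, d)
    s1 <- sumChannel(dxhat, d)
    s2 <- sumChannel(dxhat * xhat, d)
    dx <- (dxhat - bcChannel(s1 / m, d) - xhat * bcChannel(s2 / m, d)) *
      bcChannel(invstd, d)
    dim(dx) <- d
    list(dx, sumChannel(g * xhat, d), sumChannel(g, d))
  })
}

agBNEval <- function(tape, x, gamma, beta, buf, eps = 1e-5) {
  if (is.null(buf) || is.null(buf$mean)) {
    stop("batch norm in eval mode requires running statistics", call. = FALSE)
  }
  d <- dim(x$value)
  invstd <- 1 / sqrt(buf$var + eps)
  xhat <- (x$value - bcChannel(buf$mean, d)) * bcChannel(invstd, d)
  y <- xhat * bcChannel(gamma$value, d) + bcChannel(beta$value, d)
  dim(y) <- d
  gv <- gamma$value
  agNode(tape, y, list(x, gamma, beta), function(g) {
    dx <- g * bcChannel(gv * invstd, d)
    dim(dx) <- d
    list(dx, sumChannel(g * xhat, d), sumChannel(g, d))
  })
}

agMaxPool <- function(tape, x) {
  r <- .c_maxpool2_fwd(x$value)
  din <- dim(x$value)
  agNode(tape, r$out, list(x), function(g) {
    list(.c_maxpool2_bwd(g, r$argmax, din))
  })
}

agUpNearest <- function(tape, x) {
  agNode(tape, .c_upsample2_nearest_fwd(x$value), list(x), function(g) {
    list(.c_upsample2_nearest_bwd(g))
  })
}

agUpBilinear <- function(tape, x) {
  agNode(tape, .c_upsample2_bilinear_fwd(x$value), list(x), function(g) {
    list(.c_upsample2_bilinear_bwd(g))
  })
}

agConcatChannels <- function(tape, a, b) {
  da <- dim(a$value); db <- dim(b$value)
  d <- c(da[1], da[2], da[3] + db[3], da[4])
  y <- array(0, d)
  y[, , seq_len(da[3]), ] <- a$value
  y[, , da[3] + seq_len(db[3]), ] <- b$value
  agNode(tape, y, list(a, b), function(g) {
    list(array(g[, , seq_len(da[3]), , drop = FALSE], da),
         array(g[, , da[3] + seq_len(db[3]), , drop = FALSE], db))
  })
}

# Broadcast multiply of a single-channel coefficient map over all channels.
agGateMul <- function(tape, x, alpha) {
  d <- dim(x$value)
  av <- array(alpha$value[, , rep(1L, d[3]), , drop = FALSE], d)
  agNode(tape, x$value * av, list(x, alpha), function(g) {
    s <- g * x$value
    da <- s[, , 1L, , drop = FALSE]
    if (d[3] > 1L) {
      for (cc in 2:d[3]) da <- da + s[, , cc, , drop = FALSE]
    }
    list(g * av, array(da, dim(alpha$value)))
  })
}

agDropout <- function(tape, x, rate) {
  if (rate <= 0) return(x)
  keep <- (array(runif(length(x$value)), dim(x$value)) >= rate) / (1 - rate)
  agNode(tape, x$value * keep, list(x), function(g) list(g * keep))
}

# Mean binary cross-entropy with probability clipping; scalar-valued node.
agBCE <- function(tape, pred, target, clip = 1e-7) {
  p <- pmin(pmax(pred$value, clip), 1 - clip)
  n <- length(p)
  val <- -sum(target * log(p) + (1 - target) * log(1 - p)) / n
  inside <- (pred$value > clip) & (pred$value < 1 - clip)
  agNode(tape, val, list(pred), function(g) {
    dp <- ((1 - target) / (1 - p) - target / p) / n
    list(g * dp * inside)
  })
}
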