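# Attention gate, recurrent convolutional layer, residual recurrent block,
# and the closed-form residual expansion, against scalar brute-force oracles.

test_that("attention gate degenerates correctly and matches the per-pixel oracle", {
  set.seed(1)
  xe <- array(rnorm(2 * 2 * 1), c(2, 2, 1, 1))
  xd <- array(rnorm(2 * 2 * 1), c(2, 2, 1, 1))

  # all-zero parameters: sigmoid(0) = 0.5 everywhere
  r0 <- attentionGate(xe, xd, zeroGateParams())
  expect_equal(as.numeric(r0$coefficients), rep(0.5, 4))
  expect_equal(r0$gated, 0.5 * xe)

  # saturated bias: coefficients ~ 0
  psat <- zeroGateParams(); psat$b_mu <- -1000
  rs <- attentionGate(xe, xd, psat)
  expect_lt(max(rs$coefficients), 1e-10)
  expect_lt(max(abs(rs$gated)), 1e-10)

  # random scalar weights vs the hand-computed oracle
  for (rep in 1:5) {
    we <- rnorm(1); wd <- rnorm(1); psi <- rnorm(1)
    bl <- rnorm(1); bm <- rnorm(1)
    p <- list(We = array(we, c(1, 1, 1, 1)), Wd = array(wd, c(1, 1, 1, 1)),
              psi = array(psi, c(1, 1, 1, 1)), b_lambda = bl, b_mu = bm)
    r <- attentionGate(xe, xd, p)
    o <- scalarGateOracle(xe, xd, we, wd, psi, bl, bm)
    expect_lt(max(abs(r$gated - o$gated)), 1e-6)
    expect_lt(max(abs(r$coefficients - array(o$alpha, c(2, 2, 1, 1)))), 1e-6)
  }

  expect_error(attentionGate(xe, array(0, c(4, 4, 1, 1)), zeroGateParams()),
               "spatial")
  expect_error(attentionGate(xe, array(0, c(2, 2, 1, 3)), zeroGateParams()),
               "batch")
})

test_that("attention coefficients lie strictly in (0,1) and never amplify", {
  set.seed(2)
  for (rep in 1:10) {
    xe <- array(rnorm(4 * 4 * 3 * 2, sd = 3), c(4, 4, 3, 2))
    xd <- array(rnorm(4 * 4 * 2 * 2, sd = 3), c(4, 4, 2, 2))
    p <- list(We = array(rnorm(3 * 2), c(1, 1, 3, 2)),
              Wd = array(rnorm(2 * 2), c(1, 1, 2, 2)),
              psi = array(rnorm(2), c(1, 1, 2, 1)),
              b_lambda = rnorm(2), b_mu = rnorm(1))
    r <- attentionGate(xe, xd, p)
    expect_true(all(r$coefficients > 0 & r$coefficients < 1))
    expect_true(all(abs(r$gated) <= abs(xe) + 1e-12))
  }
})

test_that("recurrent conv layer honours its degenerate and unrolled forms", {
  set.seed(3)
  x <- array(rnorm(4), c(2, 2, 1, 1))
  wf <- 0.7; wr <- -0.4; b <- 0.1

  # t = 1: one plain conv + BN + ReLU
  o1 <- recurrentConvLayer(x, rclParams1(wf, wr, b), t = 1L, mode = "eval")
  expect_equal(as.numeric(o1),
               as.numeric(pmax(scalarBn(wf * x + b), 0)), tolerance = 1e-12)

  # zero recurrent weights: any t reproduces the t = 1 output
  o3 <- recurrentConvLayer(x, rclParams1(wf, 0, b), t = 3L, mode = "eval")
  expect_equal(o3, o1, tolerance = 1e-12)

  # t = 3 vs hand-unrolled scalar oracle
  o <- recurrentConvLayer(x, rclParams1(wf, wr, b), t = 3L, mode = "eval")
  expect_lt(max(abs(o - scalarRclOracle(x, wf, wr, b, 3))), 1e-6)

  # output is non-negative (terminal ReLU) and spatial dims preserved
  expect_true(all(o >= 0))
  expect_equal(dim(o), dim(x))

  bad <- array(rnorm(8), c(2, 2, 2, 1))
  expect_error(recurrentConvLayer(bad, rclParams1(wf, wr, b), t = 2L,
                                  mode = "eval"), "channels")
  noStats <- rclParams1(wf, wr, b)
  noStats$runningMean <- NULL
  expect_error(recurrentConvLayer(x, noStats, t = 2L, mode = "eval"),
               "running statistics")
})

test_that("RRCB residual path and composition match oracles", {
  set.seed(4)
  x <- array(rnorm(4), c(2, 2, 1, 1))

  # zero body: output = shortcut exactly
  p0 <- rrcbParams1(0.8, 0.2, 0, 0, 0, 0, 0, 0)
  out0 <- rrcb(x, p0, t = 2L, mode = "eval", modulatingScalar = 1)
  expect_equal(out0, array(0.8 * x + 0.2, dim(x)), tolerance = 1e-12)

  # zero modulating scalar: body path only
  wf1 <- 0.5; wr1 <- 0.3; b1 <- -0.1; wf2 <- -0.6; wr2 <- 0.2; b2 <- 0.05
  p <- rrcbParams1(1.1, 0.1, wf1, wr1, b1, wf2, wr2, b2)
  s <- 1.1 * x + 0.1
  body <- scalarRclOracle(scalarRclOracle(s, wf1, wr1, b1, 2),
                          wf2, wr2, b2, 2)
  outB <- rrcb(x, p, t = 2L, mode = "eval", modulatingScalar = 0)
  expect_lt(max(abs(outB - body)), 1e-6)

  # full composition oracle: alpha * shortcut + RCL(RCL(shortcut))
  out <- rrcb(x, p, t = 2L, mode = "eval", modulatingScalar = 1.3)
  expect_lt(max(abs(out - (1.3 * s + body))), 1e-6)

  expect_error(rrcb(array(0, c(2, 2, 3, 1)), p, t = 2L, mode = "eval"),
               "channels")
})

test_that("with a zeroed body, gradients flow through the shortcut alone", {
  # d(sum(output))/dx must equal modulatingScalar * shortcut weight at every
  # pixel, checked by central finite differences on a 2x2 instance
  p0 <- rrcbParams1(0.8, 0.0, 0, 0, 0, 0, 0, 0)
  x <- array(c(0.3, -0.2, 0.5, 0.1), c(2, 2, 1, 1))
  eps <- 1e-6
  for (i in 1:4) {
    xp <- x; xp[i] <- x[i] + eps
    xm <- x; xm[i] <- x[i] - eps
    fd <- (sum(rrcb(xp, p0, t = 2L, mode = "eval")) -
           sum(rrcb(xm, p0, t = 2L, mode = "eval"))) / (2 * eps)
    expect_equal(fd, 0.8, tolerance = 1e-5)
  }
})

test_that("closed-form residual expansion telescopes and matches iteration", {
  set.seed(5)
  x <- 1.7

  # all alphas 1, all f zero: telescoping identity
  fs0 <- replicate(3, function(v) 0)
  expect_equal(unrolledResidualInput(x, c(1, 1, 1), fs0), x)

  # single layer: reduces to the one-layer residual rule
  f1 <- function(v) pmax(0.4 * v + 0.1, 0)
  expect_equal(unrolledResidualInput(x, 0.9, list(f1)),
               0.9 * x + f1(x))

  # three layers, random scalar weights: closed form == sequential iteration
  for (rep in 1:5) {
    alphas <- runif(3, 0.5, 1.5)
    ws <- rnorm(3); bs <- rnorm(3)
    fs <- lapply(1:3, function(k) {
      force(k); function(v) pmax(ws[k] * v + bs[k], 0)
    })
    seqv <- x
    for (k in 1:3) seqv <- alphas[k] * seqv + fs[[k]](seqv)
    expect_equal(unrolledResidualInput(x, alphas, fs), seqv,
                 tolerance = 1e-9)
  }

  expect_error(unrolledResidualInput(x, numeric(0), list()), "non-empty")
})

test_that("components preserve spatial dimensions for any H, W >= 1", {
  set.seed(6)
  for (d in list(c(1, 1), c(1, 5), c(3, 2))) {
    x <- array(rnorm(prod(d) * 2), c(d, 1, 2))
    o <- recurrentConvLayer(x, rclParams1(0.3, 0.2, 0), t = 2L, mode = "eval")
    expect_equal(dim(o)[1:2], d)
    xd <- array(rnorm(prod(d) * 2), c(d, 1, 2))
    g <- attentionGate(x, xd, zeroGateParams())
    expect_equal(dim(g$gated)[1:2], d)
  }
})
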