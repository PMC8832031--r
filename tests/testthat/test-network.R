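# Assembly of the full network and its ablation variants.

tinyCfg <- function(tSteps = 1L, ...) {
  networkConfig(baseChannels = 2L, tSteps = tSteps, dropoutRate = 0, ...)
}

test_that("building is deterministic under a fixed seed", {
  m1 <- buildModel(tinyCfg(), seed = 11)
  m2 <- buildModel(tinyCfg(), seed = 11)
  expect_identical(m1$params, m2$params)
  m3 <- buildModel(tinyCfg(), seed = 12)
  expect_false(identical(m1$params, m3$params))
})

test_that("the skeleton variant has plain double-conv blocks and no gates", {
  v <- makeVariant("Skeleton", baseChannels = 2L, dropoutRate = 0)
  m <- buildModel(v$config, seed = 1)
  nms <- names(m$params)
  expect_false(any(grepl("gate", nms)))           # no attention parameters
  expect_false(any(grepl("\\.Wr$", nms)))         # no recurrent weights
  expect_false(any(grepl("short", nms)))          # no residual shortcut
  # first decoder block consumes plain concatenation: 2x channels in
  expect_equal(dim(m$params[["dec1.blk.rcl1.Wf"]])[3], 4L)
  # forward still works end to end
  p <- forwardPass(m, array(rnorm(32 * 32), c(32, 32, 1, 1)))
  expect_equal(dim(p), c(32L, 32L, 1L, 1L))
})

test_that("forward output has the contracted shape and open-interval range", {
  m <- buildModel(tinyCfg(), seed = 2)
  x64 <- array(rnorm(64 * 64 * 2), c(64, 64, 1, 2))
  p <- forwardPass(m, x64)
  expect_equal(dim(p), c(64L, 64L, 1L, 2L))
  expect_true(all(p > 0 & p < 1))

  x256 <- array(rnorm(256 * 256), c(256, 256, 1, 1))
  p256 <- forwardPass(m, x256)
  expect_equal(dim(p256), c(256L, 256L, 1L, 1L))

  expect_error(forwardPass(m, array(0, c(63, 64, 1, 1))), "divisible")
  expect_error(forwardPass(m, array(0, c(64, 64, 2, 1))), "channel")
})

test_that("encoder levels halve spatial dims and double channels", {
  cfg <- tinyCfg()
  ch <- attrunet:::encoderChannels(cfg)
  expect_equal(ch, 2L * 2L^(0:4))
  m <- buildModel(cfg, seed = 3)
  for (l in 2:5) {
    expect_equal(dim(m$params[[paste0("enc", l, ".short.W")]])[3:4],
                 c(ch[l - 1], ch[l]))
  }
})

test_that("variant factory is a bijection onto distinct flag tuples", {
  nms <- variantNames()
  expect_length(nms, 9L)
  expect_setequal(nms, c("Att+Rec+Res", "Att+Rec", "Att+Res", "Rec+Res",
                         "Only Att", "Only Rec", "Only Res", "Skeleton",
                         "Without Norm"))
  tuples <- vapply(nms, function(n) {
    cfg <- makeVariant(n)$config
    paste(cfg@useAttention, cfg@useRecurrent, cfg@useResidual,
          cfg@useNormalization)
  }, character(1))
  expect_equal(anyDuplicated(tuples), 0L)

  full <- makeVariant("Att+Rec+Res")$config
  expect_true(full@useAttention && full@useRecurrent && full@useResidual &&
              full@useNormalization)
  onlyRes <- makeVariant("Only Res")$config
  expect_false(onlyRes@useAttention || onlyRes@useRecurrent)
  expect_true(onlyRes@useResidual)
  noNorm <- makeVariant("Without Norm")$config
  expect_true(noNorm@useAttention && noNorm@useRecurrent && noNorm@useResidual)
  expect_false(noNorm@useNormalization)

  expect_error(makeVariant("NotAVariant"), "Att\\+Rec\\+Res")
})

test_that("parameter count equals the layer-by-layer analytic sum", {
  cfg <- networkConfig(baseChannels = 2L, tSteps = 1L, dropoutRate = 0)
  m <- buildModel(cfg, seed = 1)

  # independent analytic count, written out mechanism by mechanism
  conv <- function(kh, kw, ci, co) kh * kw * ci * co + co
  bn <- function(co) 2 * co
  rcl <- function(ci, co) {
    conv(3, 3, ci, co) + 3 * 3 * co * co + bn(co)   # Wf+b, Wr (no bias), BN
  }
  block <- function(ci, co) conv(1, 1, ci, co) + rcl(co, co) + rcl(co, co)
  gate <- function(ce, cd) {
    cint <- max(1, ce %/% 2)
    (1 * 1 * ce * cint + cint) +    # We + b_lambda
      1 * 1 * cd * cint +           # Wd (bias shared with b_lambda)
      (1 * 1 * cint * 1 + 1)        # psi + b_mu
  }
  ch <- 2 * 2^(0:4)
  total <- block(1, ch[1])
  for (l in 2:5) total <- total + block(ch[l - 1], ch[l])
  for (i in 4:1) {
    total <- total + conv(3, 3, ch[i + 1], ch[i]) + bn(ch[i])  # Up-Conv
    total <- total + gate(ch[i], ch[i + 1])
    total <- total + block(2 * ch[i], ch[i])
  }
  total <- total + conv(1, 1, ch[1], 1)

  expect_equal(countParameters(m), total)
})

test_that("parameter count is invariant across recurrence steps t", {
  counts <- vapply(1:4, function(t) {
    countParameters(buildModel(networkConfig(baseChannels = 2L,
                                             tSteps = t, dropoutRate = 0),
                               seed = 1))
  }, numeric(1))
  expect_equal(length(unique(counts)), 1L)
})

test_that("attention maps come at encoder scales with values in (0,1)", {
  cfg <- networkConfig(baseChannels = 2L, tSteps = 1L, dropoutRate = 0)
  m <- buildModel(cfg, seed = 4)
  x <- array(rnorm(64 * 64 * 2), c(64, 64, 1, 2))
  maps <- extractAttentionMaps(m, x)
  expect_named(maps, paste0("level", 1:4))
  sides <- vapply(maps, function(a) dim(a)[1], integer(1))
  expect_equal(unname(sides), c(64L, 32L, 16L, 8L))
  expect_true(all(vapply(maps, function(a) all(a > 0 & a < 1), logical(1))))
  expect_true(all(vapply(maps, function(a) dim(a)[3] == 1L, logical(1))))

  # zero-weight gates: coefficients exactly 0.5
  m0 <- m
  for (nm in grep("^gate", names(m0$params), value = TRUE)) {
    m0$params[[nm]] <- m0$params[[nm]] * 0
  }
  maps0 <- extractAttentionMaps(m0, x)
  expect_true(all(vapply(maps0, function(a) all(a == 0.5), logical(1))))

  sk <- buildModel(makeVariant("Skeleton", baseChannels = 2L,
                               dropoutRate = 0)$config, seed = 1)
  expect_error(extractAttentionMaps(sk, x), "without attention")
})

test_that("checkpoints round-trip parameters, buffers, and config", {
  m <- buildModel(tinyCfg(tSteps = 2L), seed = 9)
  dir <- withr::local_tempdir()
  saveCheckpoint(m, dir)
  m2 <- loadCheckpoint(dir)
  expect_equal(m2$params, m$params)
  expect_equal(m2$buffers[order(names(m2$buffers))],
               m$buffers[order(names(m$buffers))])
  expect_equal(attrunet:::configAsList(m2$config),
               attrunet:::configAsList(m$config))
  x <- array(rnorm(32 * 32), c(32, 32, 1, 1))
  expect_equal(forwardPass(m2, x), forwardPass(m, x))
})
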