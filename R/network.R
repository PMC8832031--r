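# Full encoder-decoder assembly and the ablation-variant factory.
#
# Architecture: five encoder blocks with 2x2 max pooling between levels,
# a symmetric four-block decoder in which each level upsamples (Up-Conv =
# nearest 2x + 3x3 conv + BN + ReLU), gates the same-scale encoder features
# with a spatial attention block, concatenates, and fuses through an RRCB;
# a 1x1 convolution + sigmoid head emits the per-pixel lesion probability.
# Mechanism flags degrade blocks gracefully: recurrent off -> plain double
# conv (t = 1), residual off -> no shortcut path, attention off -> plain
# concatenation.

encoderChannels <- function(cfg) cfg@baseChannels * 2L^(0:4)

tEffective <- function(cfg) if (cfg@useRecurrent) cfg@tSteps else 1L

# ---- parameter initialization ------------------------------------------

kaimingConv <- function(kh, kw, inC, outC) {
  array(rnorm(kh * kw * inC * outC, 0, sqrt(2 / (kh * kw * inC))),
        c(kh, kw, inC, outC))
}

bnSteps <- function(cfg) if (cfg@bnPerStep) tEffective(cfg) else 1L

initRcl <- function(cfg, inC, outC, prefix, params, buffers) {
  params[[paste0(prefix, ".Wf")]] <- kaimingConv(3L, 3L, inC, outC)
  params[[paste0(prefix, ".b")]] <- rep(0, outC)
  # recurrent weights exist whenever the mechanism is on, independent of t:
  # recurrence reuses weights, so the t sweep is parameter-matched
  if (cfg@useRecurrent) {
    params[[paste0(prefix, ".Wr")]] <- kaimingConv(3L, 3L, outC, outC)
  }
  for (s in seq_len(bnSteps(cfg))) {
    params[[paste0(prefix, ".gamma", s)]] <- rep(1, outC)
    params[[paste0(prefix, ".beta", s)]] <- rep(0, outC)
    key <- if (cfg@bnPerStep) paste0(prefix, ".s", s) else prefix
    buffers[[key]] <- list(mean = rep(0, outC), var = rep(1, outC))
  }
  list(params = params, buffers = buffers)
}

initBlock <- function(cfg, inC, outC, prefix, params, buffers) {
  if (cfg@useResidual) {
    params[[paste0(prefix, ".short.W")]] <- kaimingConv(1L, 1L, inC, outC)
    params[[paste0(prefix, ".short.b")]] <- rep(0, outC)
    r <- initRcl(cfg, outC, outC, paste0(prefix, ".rcl1"), params, buffers)
  } else {
    r <- initRcl(cfg, inC, outC, paste0(prefix, ".rcl1"), params, buffers)
  }
  initRcl(cfg, outC, outC, paste0(prefix, ".rcl2"), r$params, r$buffers)
}

#' Build a segmentation network
#'
#' Initializes all parameters (Kaiming fan-in normal for convolutions, unit
#' scale / zero shift for batch norm) under the given seed, so two builds with
#' the same configuration and seed are parameter-identical.
#'
#' @param config a [NetworkConfig-class].
#' @param seed integer seed for weight initialization.
#' @return a `segModel` list with elements `params` (named parameter arrays),
#'   `buffers` (batch-norm running statistics), `config`, and `seed`.
#' @export
buildModel <- function(config, seed = 1L) {
  validObject(config)
  cfg <- config
  ch <- encoderChannels(cfg)
  withSeed(seed, {
    params <- list()
    buffers <- list()
    inC <- 1L
    for (l in 1:5) {
      r <- initBlock(cfg, inC, ch[l], paste0("enc", l), params, buffers)
      params <- r$params; buffers <- r$buffers
      inC <- ch[l]
    }
    for (i in 4:1) {
      up_in <- ch[i + 1]
      params[[paste0("dec", i, ".up.W")]] <- kaimingConv(3L, 3L, up_in, ch[i])
      params[[paste0("dec", i, ".up.b")]] <- rep(0, ch[i])
      params[[paste0("dec", i, ".up.gamma1")]] <- rep(1, ch[i])
      params[[paste0("dec", i, ".up.beta1")]] <- rep(0, ch[i])
      buffers[[paste0("dec", i, ".up")]] <-
        list(mean = rep(0, ch[i]), var = rep(1, ch[i]))
      if (cfg@useAttention) {
        cint <- max(1L, ch[i] %/% 2L)
        params[[paste0("gate", i, ".We")]] <- kaimingConv(1L, 1L, ch[i], cint)
        params[[paste0("gate", i, ".Wd")]] <- kaimingConv(1L, 1L, up_in, cint)
        params[[paste0("gate", i, ".psi")]] <- kaimingConv(1L, 1L, cint, 1L)
        params[[paste0("gate", i, ".b_lambda")]] <- rep(0, cint)
        params[[paste0("gate", i, ".b_mu")]] <- 0
      }
      r <- initBlock(cfg, 2L * ch[i], ch[i], paste0("dec", i, ".blk"),
                     params, buffers)
      params <- r$params; buffers <- r$buffers
    }
    params[["head.W"]] <- kaimingConv(1L, 1L, ch[1], 1L)
    params[["head.b"]] <- 0
    structure(list(params = params, buffers = buffers, config = cfg,
                   seed = as.integer(seed)),
              class = "segModel")
  })
}

#' @export
print.segModel <- function(x, ...) {
  cat(sprintf("segModel  %s parameters\n",
              format(countParameters(x), big.mark = ",")))
  print(x$config)
  invisible(x)
}

#' Total number of trainable parameters
#' @param model a `segModel`.
#' @return integer parameter count.
#' @export
countParameters <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

# Deep copy: parameters are copied by R value semantics; buffer lists too.
copyModel <- function(model) {
  list(params = model$params, buffers = model$buffers,
       config = model$config, seed = model$seed) |>
    structure(class = "segModel")
}

buffersAsEnvs <- function(buffers) {
  lapply(buffers, function(b) {
    e <- new.env(parent = emptyenv())
    e$mean <- b$mean; e$var <- b$var
    e
  })
}

envsAsBuffers <- function(envs) {
  lapply(envs, function(e) list(mean = e$mean, var = e$var))
}

# ---- forward pass -------------------------------------------------------

.blockForward <- function(tape, x, prefix, cfg, mode, pn, bufs) {
  tEff <- tEffective(cfg)
  getp <- function(nm) pn[[paste0(prefix, ".", nm)]]
  rclp <- function(r) {
    list(Wf = getp(paste0(r, ".Wf")), b = getp(paste0(r, ".b")),
         Wr = getp(paste0(r, ".Wr")),
         gamma = lapply(seq_len(bnSteps(cfg)),
                        function(s) getp(paste0(r, ".gamma", s))),
         beta = lapply(seq_len(bnSteps(cfg)),
                       function(s) getp(paste0(r, ".beta", s))))
  }
  if (cfg@useResidual) {
    p <- list(short = list(W = getp("short.W"), b = getp("short.b")),
              rcl1 = rclp("rcl1"), rcl2 = rclp("rcl2"))
    .agRRCB(tape, x, p, tEff, mode, cfg, prefix, bufs)
  } else {
    h <- .agRCL(tape, x, rclp("rcl1"), tEff, mode, cfg,
                paste0(prefix, ".rcl1"), bufs)
    .agRCL(tape, h, rclp("rcl2"), tEff, mode, cfg,
           paste0(prefix, ".rcl2"), bufs)
  }
}

.netForward <- function(tape, pn, bufs, cfg, x, mode,
                        collectAttention = FALSE) {
  enc <- vector("list", 5L)
  h <- x
  for (l in 1:5) {
    h <- .blockForward(tape, h, paste0("enc", l), cfg, mode, pn, bufs)
    if (mode == "train" && cfg@dropoutRate > 0 && l >= 4L) {
      h <- agDropout(tape, h, cfg@dropoutRate)
    }
    enc[[l]] <- h
    if (l < 5L) h <- agMaxPool(tape, h)
  }
  d <- enc[[5]]
  attn <- list()
  for (i in 4:1) {
    u <- agUpNearest(tape, d)
    u <- agConv(tape, u, pn[[paste0("dec", i, ".up.W")]],
                pn[[paste0("dec", i, ".up.b")]])
    u <- if (mode == "train") {
      agBNTrain(tape, u, pn[[paste0("dec", i, ".up.gamma1")]],
                pn[[paste0("dec", i, ".up.beta1")]],
                bufs[[paste0("dec", i, ".up")]],
                eps = cfg@bnEpsilon, momentum = cfg@bnMomentum)
    } else {
      agBNEval(tape, u, pn[[paste0("dec", i, ".up.gamma1")]],
               pn[[paste0("dec", i, ".up.beta1")]],
               bufs[[paste0("dec", i, ".up")]], eps = cfg@bnEpsilon)
    }
    u <- agRelu(tape, u)
    skip <- enc[[i]]
    if (cfg@useAttention) {
      guid <- agUpBilinear(tape, d)
      g <- .agAttentionGate(tape, skip, guid, list(
        We = pn[[paste0("gate", i, ".We")]],
        Wd = pn[[paste0("gate", i, ".Wd")]],
        psi = pn[[paste0("gate", i, ".psi")]],
        b_lambda = pn[[paste0("gate", i, ".b_lambda")]],
        b_mu = pn[[paste0("gate", i, ".b_mu")]]))
      skip <- g$gated
      if (collectAttention) attn[[paste0("level", i)]] <- g$coefficients
    }
    fused <- agConcatChannels(tape, skip, u)
    d <- .blockForward(tape, fused, paste0("dec", i, ".blk"), cfg, mode, pn,
                       bufs)
  }
  out <- agConv(tape, d, pn[["head.W"]], pn[["head.b"]])
  pred <- agSigmoid(tape, out)
  list(pred = pred, attention = attn)
}

checkForwardInput <- function(batch) {
  stopIfNot4d(batch, "batch")
  d <- dim(batch)
  if (d[1] %% 16L != 0L || d[2] %% 16L != 0L) {
    stop("forward: input height and width must be divisible by 16 ",
         "(four 2x2 poolings); got ", d[1], "x", d[2], call. = FALSE)
  }
  if (d[3] != 1L) {
    stop("forward: expected a single input channel, got ", d[3],
         call. = FALSE)
  }
  invisible(d)
}

#' Run the network forward
#'
#' @param model a `segModel` from [buildModel()].
#' @param batch 4-D array (H, W, 1, N); H and W must be divisible by 16.
#' @param mode `"eval"` (running batch-norm statistics; default) or
#'   `"train"` (batch statistics).
#' @return probability array (H, W, 1, N) with values strictly in (0, 1).
#' @export
forwardPass <- function(model, batch, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  checkForwardInput(batch)
  tape <- agTape()
  pn <- lapply(model$params, function(v) agLeaf(tape, v))
  bufs <- buffersAsEnvs(model$buffers)
  r <- .netForward(tape, pn, bufs, model$config, agLeaf(tape, batch), mode)
  r$pred$value
}

#' Extract attention coefficient maps
#'
#' Runs the model in eval mode and returns the attention coefficients of the
#' four gated skip connections, one single-channel map per decoder level at
#' the spatial size of the corresponding encoder level (finest first).
#'
#' @param model a `segModel` built with attention enabled.
#' @param batch input array (H, W, 1, N).
#' @return named list `level1..level4` of (h, w, 1, N) coefficient arrays,
#'   values in (0, 1).
#' @export
extractAttentionMaps <- function(model, batch) {
  if (!model$config@useAttention) {
    stop("extractAttentionMaps: model was built without attention gates",
         call. = FALSE)
  }
  checkForwardInput(batch)
  tape <- agTape()
  pn <- lapply(model$params, function(v) agLeaf(tape, v))
  bufs <- buffersAsEnvs(model$buffers)
  r <- .netForward(tape, pn, bufs, model$config, agLeaf(tape, batch), "eval",
                   collectAttention = TRUE)
  maps <- lapply(r$attention, function(nd) nd$value)
  maps[paste0("level", 1:4)]
}

# ---- variant factory ----------------------------------------------------

variantFlagTable <- function() {
  # name -> (attention, recurrent, residual, normalization)
  list(
    "Att+Rec+Res" = c(TRUE, TRUE, TRUE, TRUE),
    "Att+Rec" = c(TRUE, TRUE, FALSE, TRUE),
    "Att+Res" = c(TRUE, FALSE, TRUE, TRUE),
    "Rec+Res" = c(FALSE, TRUE, TRUE, TRUE),
    "Only Att" = c(TRUE, FALSE, FALSE, TRUE),
    "Only Rec" = c(FALSE, TRUE, FALSE, TRUE),
    "Only Res" = c(FALSE, FALSE, TRUE, TRUE),
    "Skeleton" = c(FALSE, FALSE, FALSE, TRUE),
    "Without Norm" = c(TRUE, TRUE, TRUE, FALSE)
  )
}

#' Ablation variant factory
#'
#' Maps a variant label to its mechanism flags. The nine labels cover the
#' full model (`"Att+Rec+Res"`), the seven reduced mechanism combinations
#' down to the plain-U-Net `"Skeleton"`, and `"Without Norm"` (full
#' mechanisms, input Z-score normalization disabled in preprocessing).
#'
#' @param name one of the nine variant labels; see [variantNames()].
#' @param ... further arguments passed to [networkConfig()] (e.g.
#'   `baseChannels`, `tSteps`, `dropoutRate`).
#' @return list with `name` and `config` (a [NetworkConfig-class]).
#' @export
makeVariant <- function(name, ...) {
  tab <- variantFlagTable()
  if (!name %in% names(tab)) {
    stop("unknown variant '", name, "'; valid names: ",
         paste(names(tab), collapse = ", "), call. = FALSE)
  }
  f <- tab[[name]]
  cfg <- networkConfig(useAttention = f[1], useRecurrent = f[2],
                       useResidual = f[3], useNormalization = f[4], ...)
  list(name = name, config = cfg)
}

#' Names of the ablation variants
#' @return character vector of the nine variant labels.
#' @export
variantNames <- function() names(variantFlagTable())

# ---- checkpoint serialization ------------------------------------------

#' Save model parameters as a flat named-tensor checkpoint
#'
#' Writes `params.bin` (all parameter and buffer tensors as little-endian
#' doubles) and `manifest.json` describing name, shape, and offset of each
#' entry plus the resolved network configuration and seed.
#'
#' @param model a `segModel`.
#' @param dir destination directory (created if missing).
#' @return `dir`, invisibly.
#' @export
saveCheckpoint <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tensors <- c(model$params,
               stats::setNames(
                 unlist(lapply(model$buffers, function(b) b), recursive = FALSE),
                 paste0(rep(names(model$buffers), each = 2), ".running.",
                        c("mean", "var"))))
  offsets <- cumsum(c(0, head(vapply(tensors, length, numeric(1)), -1)))
  manifest <- list(
    format = "attrunet-checkpoint-v1",
    config = configAsList(model$config),
    seed = model$seed,
    tensors = Map(function(nm, v, off) {
      list(name = nm, dim = as.integer(dim(v) %||% length(v)),
           dtype = "float64", offset = off)
    }, names(tensors), tensors, offsets)
  )
  con <- file(file.path(dir, "params.bin"), "wb")
  on.exit(close(con))
  for (v in tensors) writeBin(as.numeric(v), con, size = 8, endian = "little")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a model checkpoint written by [saveCheckpoint()]
#' @param dir checkpoint directory.
#' @return a `segModel`.
#' @export
loadCheckpoint <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  cfg <- do.call(networkConfig, manifest$config[setdiff(names(manifest$config),
                                                        "depth")])
  con <- file(file.path(dir, "params.bin"), "rb")
  on.exit(close(con))
  tensors <- list()
  for (tn in manifest$tensors) {
    d <- unlist(tn$dim)
    v <- readBin(con, "numeric", n = prod(d), size = 8, endian = "little")
    if (length(d) > 1L) dim(v) <- d
    tensors[[tn$name]] <- v
  }
  isRun <- grepl("\\.running\\.(mean|var)$", names(tensors))
  params <- tensors[!isRun]
  buffers <- list()
  for (nm in names(tensors)[isRun]) {
    key <- sub("\\.running\\.(mean|var)$", "", nm)
    field <- sub("^.*\\.running\\.", "", nm)
    if (is.null(buffers[[key]])) buffers[[key]] <- list()
    buffers[[key]][[field]] <- tensors[[nm]]
  }
  structure(list(params = params, buffers = buffers, config = cfg,
                 seed = as.integer(manifest$seed)),
            class = "segModel")
}

configAsList <- function(cfg) {
  list(baseChannels = cfg@baseChannels, tSteps = cfg@tSteps,
       useAttention = cfg@useAttention, useRecurrent = cfg@useRecurrent,
       useResidual = cfg@useResidual, useNormalization = cfg@useNormalization,
       dropoutRate = cfg@dropoutRate, modulatingScalar = cfg@modulatingScalar,
       bnEpsilon = cfg@bnEpsilon, bnMomentum = cfg@bnMomentum,
       bnPerStep = cfg@bnPerStep)
}
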