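`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded helpers never perturb
#' the global random stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Mix a root seed with stream labels into a new 31-bit seed. Deterministic,
# order-sensitive, keeps derived seeds inside the portable integer range.
deriveSeed <- function(root, ...) {
  parts <- c(as.numeric(root), as.numeric(c(...)))
  h <- 0
  for (p in parts) h <- (h * 69069 + (p %% 2147483647) + 1) %% 2147483647
  as.integer(h)
}

stopIfNot4d <- function(x, what = "feature map") {
  if (!is.array(x) || length(dim(x)) != 4L) {
    stop(what, " must be a 4-D array with dims (H, W, C, N)", call. = FALSE)
  }
  invisible(x)
}

isBinary <- function(x) all(x %in% c(0, 1))

# Format "mean +/- sd" the way results tables print it.
fmtPM <- function(mean, sd, digits = 4) {
  sprintf("%.*f ± %.*f", digits, mean, digits, sd)
}
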