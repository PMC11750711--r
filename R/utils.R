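# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible per-stage seed from a master seed
#'
#' All stochastic stages draw their seed from one master seed and a stage
#' name, so each stage is independently reproducible and stages do not
#' share RNG streams.
#'
#' @param seed Master seed (integer).
#' @param stage Stage name (character scalar).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647  # 2^31 - 1, keeps derived seeds valid R integers
  h <- as.double(seed %% m)
  for (ch in utf8ToInt(stage)) h <- (h * 69069 + ch) %% m
  as.integer(h)
}

# Evaluate `expr` under `set.seed(seed)` without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Normalize a benign/malignant encoding to logical (TRUE = malignant).
# Accepts logical, 0/1 numeric, or character/factor "benign"/"malignant".
as_malignant <- function(x, what = "calls") {
  if (is.logical(x)) return(x)
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1) | is.na(x))) {
      stop(sprintf("numeric %s must be 0/1", what))
    }
    return(x == 1)
  }
  if (is.character(x)) {
    bad <- !(x %in% c("benign", "malignant") | is.na(x))
    if (any(bad)) {
      stop(sprintf("%s must be 'benign' or 'malignant' (got '%s')",
                   what, x[which(bad)[1]]))
    }
    return(x == "malignant")
  }
  stop(sprintf("cannot interpret %s of class %s", what, class(x)[1]))
}

malignant_label <- function(flag) ifelse(flag, "malignant", "benign")

# Draw from a bivariate normal given mean (length 2) and covariance (2x2).
rbvnorm <- function(n, mean, sigma) {
  L <- chol(sigma)
  z <- matrix(stats::rnorm(2L * n), ncol = 2L)
  sweep(z %*% L, 2L, mean, `+`)
}

check_prob <- function(x, name) {
  if (any(!is.finite(x) | x < 0 | x > 1)) {
    stop(sprintf("%s must lie in [0, 1]", name))
  }
  invisible(x)
}
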