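#' @keywords internal
"_PACKAGE"

# Lightweight run log: messages to stderr, optionally mirrored to a file set by
# mc5LogFile(). Kept deliberately simple; structured logging is not the point.
.mc5_env <- new.env(parent = emptyenv())

#' Direct the package run log to a file
#'
#' All validation warnings and stage notes emitted through the package logger
#' go to `stderr`; when a path is set here they are appended to that file too.
#'
#' @param path File path, or `NULL` to disable file logging.
#' @return The previous path, invisibly.
#' @export
mc5LogFile <- function(path = NULL) {
  old <- .mc5_env$logfile
  .mc5_env$logfile <- path
  invisible(old)
}

mc5Log <- function(...) {
  msg <- paste0(...)
  message("[mc5score] ", msg)
  lf <- .mc5_env$logfile
  if (!is.null(lf)) cat("[mc5score] ", msg, "\n", sep = "", file = lf, append = TRUE)
  invisible(msg)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Deterministic per-replicate seed stream below 2^31, so resampling replicates
# are order-independent and reproducible from one master seed.
derivedSeed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 1000003) * 2017 + index * 7 + 1) %% 2147483587L
}

assertMatrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stopf("%s must be a numeric matrix", what)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stopf("%s must have row and column names", what)
  if (anyDuplicated(rownames(x)))
    stopf("%s has duplicated row ids", what)
  if (anyDuplicated(colnames(x)))
    stopf("%s has duplicated column ids", what)
  if (anyNA(x)) {
    idx <- which(is.na(x), arr.ind = TRUE)[1L, ]
    stopf("%s contains a missing value at row '%s', column '%s'",
          what, rownames(x)[idx[1L]], colnames(x)[idx[2L]])
  }
  invisible(TRUE)
}

#' Log2-transform a TPM expression matrix
#'
#' Expression is consumed on the log2(TPM+1) scale by clustering, differential
#' expression, scoring, and enrichment; the linear scale is kept for reporting.
#' Matrices already carrying the `"log2_tpm_plus1"` scale attribute are
#' returned unchanged.
#'
#' @param expr Gene-by-sample expression matrix (linear TPM unless its
#'   `scale` attribute says otherwise).
#' @return Matrix on the log2(TPM+1) scale with `scale` attribute set.
#' @export
logTPM <- function(expr) {
  assertMatrix(expr, "expression matrix")
  sc <- attr(expr, "scale")
  if (identical(sc, "log2_tpm_plus1")) return(expr)
  if (any(expr < 0)) {
    idx <- which(expr < 0, arr.ind = TRUE)[1L, ]
    stopf("negative TPM value at gene '%s', sample '%s'",
          rownames(expr)[idx[1L]], colnames(expr)[idx[2L]])
  }
  out <- log2(expr + 1)
  attr(out, "scale") <- "log2_tpm_plus1"
  out
}

# Inverse of trigamma by Newton iteration on the log scale (monotone,
# convex); used by the empirical-Bayes prior-df estimator.
trigammaInverse <- function(x) {
  if (!is.finite(x) || x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}
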