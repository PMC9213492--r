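#' Stop unless a condition holds
#' @noRd
.check <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

#' Coerce a data.frame of predictors to a numeric matrix, preserving names
#' @noRd
.as_matrix <- function(X) {
  if (is.data.frame(X)) {
    .check(all(vapply(X, is.numeric, logical(1))),
           "all predictor columns must be numeric")
    X <- as.matrix(X)
  }
  .check(is.matrix(X) && is.numeric(X), "X must be a numeric matrix or data.frame")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  X
}

#' Euclidean distance matrix from a 2-column coordinate matrix
#' @noRd
.distmat <- function(coords) {
  as.matrix(dist(coords[, 1:2, drop = FALSE]))
}

#' A short stable hash of an R object (used to stamp outputs with their config)
#' @noRd
.config_hash <- function(x) rlang::hash(x)

#' Append a timestamped line to a character log
#' @noRd
.log_line <- function(log, ...) c(log, paste0(...))
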