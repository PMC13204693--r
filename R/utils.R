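# internal helpers shared across modules

# add a row vector to every row of a matrix
.addrow <- function(x, v) x + rep(v, each = nrow(x))

# multiply every row of a matrix by a row vector
.mulrow <- function(x, v) x * rep(v, each = nrow(x))

# row-wise maximum (C-level, via max.col)
.row_max <- function(x) x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]

# numerically stable row-wise log-sum-exp
.row_logsumexp <- function(x) {
  m <- .row_max(x)
  m + log(rowSums(exp(x - m)))
}

# row-wise log-softmax
.row_logsoftmax <- function(x) x - .row_logsumexp(x)

# row-wise softmax
.row_softmax <- function(x) {
  e <- exp(x - .row_max(x))
  e / rowSums(e)
}

.is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == round(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
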