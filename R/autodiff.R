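# Minimal reverse-mode automatic differentiation on dense arrays.
#
# A global tape records operations in execution order (a valid topological
# order); ag_backward() walks it in reverse accumulating gradients.
# Values are plain numeric arrays (images H x W x C) or vectors; nodes are
# environments so gradients accumulate by reference. Parameters are nodes
# created off-tape whose gradients persist until zeroed by the optimizer.

.ag <- new.env(parent = emptyenv())
.ag$tape <- list()
.ag$n <- 0L
.ag$enabled <- TRUE

#' Start a fresh autodiff tape
#'
#' Discards all previously recorded operations. Call once before each
#' forward/backward pass.
#' @return Invisibly, `NULL`.
#' @keywords internal
#' @export
ag_tape_start <- function() {
  .ag$tape <- vector("list", 256L)
  .ag$n <- 0L
  .ag$enabled <- TRUE
  invisible(NULL)
}

#' Evaluate an expression without recording gradients
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @export
ag_no_grad <- function(expr) {
  old <- .ag$enabled
  .ag$enabled <- FALSE
  on.exit(.ag$enabled <- old)
  force(expr)
}

ag_new_node <- function(value, parents = NULL, backward = NULL,
                        is_param = FALSE) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backward <- backward
  e$is_param <- is_param
  class(e) <- "ag_node"
  e
}

tape_push <- function(node) {
  n <- .ag$n + 1L
  if (n > length(.ag$tape)) length(.ag$tape) <- 2L * length(.ag$tape)
  .ag$tape[[n]] <- node
  .ag$n <- n
  node
}

#' Create a trainable parameter node
#' @param value Initial numeric array.
#' @return An `ag_node` flagged as a parameter.
#' @keywords internal
#' @export
ag_param <- function(value) ag_new_node(value, is_param = TRUE)

#' Wrap a constant in an autodiff node
#' @param value Numeric array.
#' @return An `ag_node` that receives no gradient.
#' @keywords internal
#' @export
ag_const <- function(value) ag_new_node(value)

is_node <- function(x) inherits(x, "ag_node")

#' Extract the value of a node (or pass a plain array through)
#' @param x An `ag_node` or numeric array.
#' @return The underlying numeric array.
#' @keywords internal
#' @export
ag_value <- function(x) if (is_node(x)) x$value else x

as_node <- function(x) if (is_node(x)) x else ag_const(x)

# Record an operation. `backward` maps the output gradient to a list of
# gradients aligned with `parents` (NULL entries allowed).
ag_op <- function(value, parents, backward) {
  if (!.ag$enabled) return(ag_new_node(value))
  tape_push(ag_new_node(value, parents = parents, backward = backward))
}

#' Reverse-mode gradient accumulation from a scalar loss
#'
#' Seeds the loss gradient with 1 and walks the tape in reverse. Gradients
#' land in each parameter node's `$grad`.
#' @param loss Scalar `ag_node`.
#' @return Invisibly, `NULL`.
#' @keywords internal
#' @export
ag_backward <- function(loss) {
  stopifnot(is_node(loss), length(loss$value) == 1L)
  # clear any gradients from a previous backward over the same tape so
  # several losses can be differentiated from one recorded forward pass
  if (.ag$n > 0L) for (k in seq_len(.ag$n)) .ag$tape[[k]]$grad <- NULL
  loss$grad <- 1
  if (.ag$n == 0L) return(invisible(NULL))
  for (k in seq(.ag$n, 1L)) {
    node <- .ag$tape[[k]]
    if (is.null(node$grad) || is.null(node$backward)) next
    gs <- node$backward(node$grad)
    ps <- node$parents
    for (i in seq_along(ps)) {
      g <- gs[[i]]
      if (is.null(g)) next
      p <- ps[[i]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(NULL)
}

#' Zero the gradients of a list of parameter nodes
#' @param params List of `ag_node` parameters.
#' @return Invisibly, `NULL`.
#' @keywords internal
#' @export
ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- elementwise arithmetic ------------------------------------------------

ag_add <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  ag_op(a$value + b$value, list(a, b), function(g) list(g, g))
}

ag_sub <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  ag_op(a$value - b$value, list(a, b), function(g) list(g, -g))
}

ag_mul <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  av <- a$value; bv <- b$value
  ag_op(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

# Multiply by a fixed scalar.
ag_scale <- function(a, k) {
  a <- as_node(a)
  ag_op(a$value * k, list(a), function(g) list(g * k))
}

ag_neg <- function(a) ag_scale(a, -1)

# ---- activations -----------------------------------------------------------

ag_relu <- function(a) {
  a <- as_node(a)
  m <- a$value > 0
  ag_op(a$value * m, list(a), function(g) list(g * m))
}

ag_leaky_relu <- function(a, slope = 0.2) {
  a <- as_node(a)
  m <- ifelse(a$value > 0, 1, slope)
  ag_op(a$value * m, list(a), function(g) list(g * m))
}

ag_tanh <- function(a) {
  a <- as_node(a)
  y <- tanh(a$value)
  ag_op(y, list(a), function(g) list(g * (1 - y^2)))
}

ag_sigmoid <- function(a) {
  a <- as_node(a)
  y <- 1 / (1 + exp(-a$value))
  ag_op(y, list(a), function(g) list(g * y * (1 - y)))
}

# log(1 + exp(x)), numerically stable
ag_softplus <- function(a) {
  a <- as_node(a)
  v <- a$value
  y <- pmax(v, 0) + log1p(exp(-abs(v)))
  dim(y) <- dim(v)
  s <- 1 / (1 + exp(-v))
  ag_op(y, list(a), function(g) list(g * s))
}

ag_abs <- function(a) {
  a <- as_node(a)
  s <- sign(a$value)
  ag_op(abs(a$value), list(a), function(g) list(g * s))
}

ag_square <- function(a) {
  a <- as_node(a)
  av <- a$value
  ag_op(av^2, list(a), function(g) list(2 * g * av))
}

# ---- reductions ------------------------------------------------------------

ag_sum <- function(a) {
  a <- as_node(a)
  d <- dim(a$value); n <- length(a$value)
  ag_op(sum(a$value), list(a), function(g) {
    gr <- array(g, dim = if (is.null(d)) n else d)
    list(gr)
  })
}

ag_mean <- function(a) {
  a <- as_node(a)
  d <- dim(a$value); n <- length(a$value)
  ag_op(mean(a$value), list(a), function(g) {
    gr <- array(g / n, dim = if (is.null(d)) n else d)
    list(gr)
  })
}

# ---- shape utilities -------------------------------------------------------

# Concatenate H x W x C arrays along the channel axis.
ag_concat_c <- function(nodes) {
  nodes <- lapply(nodes, as_node)
  vals <- lapply(nodes, function(n) n$value)
  dims <- lapply(vals, dim)
  H <- dims[[1]][1]; W <- dims[[1]][2]
  cs <- vapply(dims, function(d) d[3], 0)
  out <- array(unlist(vals, use.names = FALSE), dim = c(H, W, sum(cs)))
  ends <- cumsum(cs); starts <- ends - cs + 1
  ag_op(out, nodes, function(g) {
    lapply(seq_along(nodes), function(i) {
      g[, , starts[i]:ends[i], drop = FALSE]
    })
  })
}

# Extract a spatial window (1-based inclusive bounds), all channels.
ag_crop <- function(a, r0, r1, c0, c1) {
  a <- as_node(a)
  d <- dim(a$value)
  ag_op(a$value[r0:r1, c0:c1, , drop = FALSE], list(a), function(g) {
    gr <- array(0, dim = d)
    gr[r0:r1, c0:c1, ] <- g
    list(gr)
  })
}

# Place a small map into a zero array of shape `shape` at (r0, c0) (1-based).
ag_embed <- function(a, shape, r0, c0) {
  a <- as_node(a)
  d <- dim(a$value)
  out <- array(0, dim = shape)
  out[r0:(r0 + d[1] - 1), c0:(c0 + d[2] - 1), ] <- a$value
  ag_op(out, list(a), function(g) {
    list(g[r0:(r0 + d[1] - 1), c0:(c0 + d[2] - 1), , drop = FALSE])
  })
}

# Insert zeros between pixels (stride-2 dilation), the first step of a
# fractionally-strided (transposed) convolution.
ag_dilate2 <- function(a) {
  a <- as_node(a)
  d <- dim(a$value)
  H2 <- 2L * d[1] - 1L; W2 <- 2L * d[2] - 1L
  out <- array(0, dim = c(H2, W2, d[3]))
  io <- seq(1L, H2, by = 2L); jo <- seq(1L, W2, by = 2L)
  out[io, jo, ] <- a$value
  ag_op(out, list(a), function(g) list(g[io, jo, , drop = FALSE]))
}

# Symmetric (mirror-with-edge) padding by r pixels on each spatial side.
ag_pad_reflect <- function(a, r) {
  a <- as_node(a)
  d <- dim(a$value)
  if (r >= d[1] || r >= d[2]) stop("reflect padding exceeds image size")
  ri <- c(rev(seq_len(r)), seq_len(d[1]), d[1] - seq_len(r) + 1L)
  ci <- c(rev(seq_len(r)), seq_len(d[2]), d[2] - seq_len(r) + 1L)
  ag_op(a$value[ri, ci, , drop = FALSE], list(a), function(g) {
    # fold contributions of mirrored rows/cols back onto their sources
    gr <- rowsum(matrix(g, nrow = length(ri)), ri)
    gr <- array(gr, dim = c(d[1], length(ci), d[3]))
    gc <- aperm(gr, c(2, 1, 3))
    gc <- rowsum(matrix(gc, nrow = length(ci)), ci)
    gc <- array(gc, dim = c(d[2], d[1], d[3]))
    list(aperm(gc, c(2, 1, 3)))
  })
}
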