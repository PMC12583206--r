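# Minimal reverse-mode automatic differentiation on a tape.
#
# Every differentiable operation accepts a mix of `advar` nodes and plain
# numeric arrays; when no argument is an advar the op just computes the value,
# so the same model code runs numerically (prediction) and symbolically
# (training). Gradients are exact; tests check them against central finite
# differences.

ad_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 256L)
  e$k <- 0L
  e
}

is_advar <- function(x) inherits(x, "advar")

# value of an advar or passthrough for numerics
vof <- function(x) if (is_advar(x)) x$value else x

ad_node <- function(tape, value, parents, back) {
  k <- tape$k + 1L
  if (k > length(tape$nodes)) length(tape$nodes) <- 2L * k
  tape$nodes[[k]] <- list(parents = parents, back = back)
  tape$k <- k
  structure(list(id = k, value = value, tape = tape), class = "advar")
}

# leaf variable (a parameter); gradient is collected for it
tape_var <- function(tape, value) ad_node(tape, value, integer(0), NULL)

# create advar leaves mirroring a (possibly nested) list of numeric arrays
tape_vars <- function(tape, params) {
  lapply(params, function(p) {
    if (is.list(p)) tape_vars(tape, p) else tape_var(tape, p)
  })
}

tape_of <- function(...) {
  for (a in list(...)) if (is_advar(a)) return(a$tape)
  NULL
}

pid <- function(x) if (is_advar(x)) x$id else 0L

# Backward pass from a scalar advar. Returns list of gradients indexed by
# node id (NULL where a node does not influence y).
ad_backward <- function(y) {
  stopifnot(is_advar(y), length(y$value) == 1L)
  tape <- y$tape
  grads <- vector("list", tape$k)
  grads[[y$id]] <- 1
  for (i in seq.int(y$id, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    node <- tape$nodes[[i]]
    if (!length(node$parents)) next
    pg <- node$back(g)
    for (j in seq_along(node$parents)) {
      p <- node$parents[[j]]
      if (p == 0L) next
      grads[[p]] <- if (is.null(grads[[p]])) pg[[j]] else grads[[p]] + pg[[j]]
    }
  }
  grads
}

# pull gradients for a nested list of leaf advars; zeros where unused
grads_for <- function(grads, vars) {
  lapply(vars, function(v) {
    if (is.list(v) && !is_advar(v)) return(grads_for(grads, v))
    g <- if (v$id <= length(grads)) grads[[v$id]] else NULL
    if (is.null(g)) 0 * v$value else g
  })
}

# ---- arithmetic ----

# a + b; shapes equal, or one operand is a length-1 scalar
ad_add <- function(a, b) {
  va <- vof(a); vb <- vof(b)
  val <- va + vb
  tape <- tape_of(a, b)
  if (is.null(tape)) return(val)
  ad_node(tape, val, c(pid(a), pid(b)), function(g) {
    list(if (length(va) == 1L && length(val) > 1L) sum(g) else g,
         if (length(vb) == 1L && length(val) > 1L) sum(g) else g)
  })
}

ad_sub <- function(a, b) {
  va <- vof(a); vb <- vof(b)
  val <- va - vb
  tape <- tape_of(a, b)
  if (is.null(tape)) return(val)
  ad_node(tape, val, c(pid(a), pid(b)), function(g) {
    list(if (length(va) == 1L && length(val) > 1L) sum(g) else g,
         if (length(vb) == 1L && length(val) > 1L) -sum(g) else -g)
  })
}

ad_neg <- function(a) ad_sub(0, a)

# elementwise product; scalar broadcast allowed on either side
ad_mul <- function(a, b) {
  va <- vof(a); vb <- vof(b)
  val <- va * vb
  tape <- tape_of(a, b)
  if (is.null(tape)) return(val)
  ad_node(tape, val, c(pid(a), pid(b)), function(g) {
    ga <- g * vb
    gb <- g * va
    list(if (length(va) == 1L && length(val) > 1L) sum(ga) else ga,
         if (length(vb) == 1L && length(val) > 1L) sum(gb) else gb)
  })
}

ad_div <- function(a, b) {
  va <- vof(a); vb <- vof(b)
  val <- va / vb
  tape <- tape_of(a, b)
  if (is.null(tape)) return(val)
  ad_node(tape, val, c(pid(a), pid(b)), function(g) {
    ga <- g / vb
    gb <- -g * va / (vb * vb)
    list(if (length(va) == 1L && length(val) > 1L) sum(ga) else ga,
         if (length(vb) == 1L && length(val) > 1L) sum(gb) else gb)
  })
}

ad_mm <- function(a, b) {
  va <- vof(a); vb <- vof(b)
  val <- va %*% vb
  tape <- tape_of(a, b)
  if (is.null(tape)) return(val)
  ad_node(tape, val, c(pid(a), pid(b)), function(g) {
    list(g %*% t(vb), t(va) %*% g)
  })
}

# add a length-ncol(X) vector to every row of X
ad_addrow <- function(X, b) {
  vX <- vof(X); vb <- vof(b)
  val <- sweep(vX, 2L, vb, "+")
  tape <- tape_of(X, b)
  if (is.null(tape)) return(val)
  ad_node(tape, val, c(pid(X), pid(b)), function(g) list(g, colSums(g)))
}

# ---- nonlinearities ----

ad_unary <- function(a, fval, fgrad) {
  va <- vof(a)
  val <- fval(va)
  if (!is_advar(a)) return(val)
  ad_node(a$tape, val, pid(a), function(g) list(g * fgrad(va, val)))
}

ad_tanh <- function(a) ad_unary(a, tanh, function(x, y) 1 - y * y)
ad_sigmoid <- function(a) ad_unary(a, plogis, function(x, y) y * (1 - y))
ad_relu <- function(a) ad_unary(a, function(x) pmax(x, 0), function(x, y) (x > 0) + 0)
ad_exp <- function(a) ad_unary(a, exp, function(x, y) y)
ad_log <- function(a) ad_unary(a, log, function(x, y) 1 / x)
ad_sqrt <- function(a) ad_unary(a, sqrt, function(x, y) 0.5 / y)
ad_square <- function(a) ad_unary(a, function(x) x * x, function(x, y) 2 * x)

# numerically stable softplus
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))
softplus_inv <- function(y) log(expm1(y))
ad_softplus <- function(a) ad_unary(a, softplus, function(x, y) plogis(x))

# ---- reductions / shape ----

ad_sum <- function(a) {
  va <- vof(a)
  val <- sum(va)
  if (!is_advar(a)) return(val)
  ad_node(a$tape, val, pid(a), function(g) list(g + 0 * va))
}

ad_mean <- function(a) {
  n <- length(vof(a))
  ad_div(ad_sum(a), n)
}

ad_rowsums <- function(a) {
  va <- vof(a)
  val <- matrix(rowSums(va), ncol = 1L)
  if (!is_advar(a)) return(val)
  ad_node(a$tape, val, pid(a), function(g) {
    list(matrix(g, nrow = nrow(va), ncol = ncol(va)))
  })
}

ad_colsums <- function(a) {
  va <- vof(a)
  val <- matrix(colSums(va), nrow = 1L)
  if (!is_advar(a)) return(val)
  ad_node(a$tape, val, pid(a), function(g) {
    list(matrix(g, nrow = nrow(va), ncol = ncol(va), byrow = TRUE))
  })
}

# column-bind any mix of advars / numeric matrices (equal row counts)
ad_cbind <- function(...) {
  args <- list(...)
  vals <- lapply(args, vof)
  vals <- lapply(vals, function(v) if (is.matrix(v)) v else matrix(v, nrow = 1L))
  val <- do.call(cbind, vals)
  tape <- do.call(tape_of, args)
  if (is.null(tape)) return(val)
  widths <- vapply(vals, ncol, 1L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_node(tape, val, vapply(args, pid, 1L), function(g) {
    lapply(seq_along(args), function(j) {
      gj <- g[, starts[j]:ends[j], drop = FALSE]
      if (is.matrix(vof(args[[j]]))) gj else as.numeric(gj)
    })
  })
}

# gather rows of a table by integer index (embedding lookup); scatter-add grad
ad_rows <- function(E, idx) {
  vE <- vof(E)
  val <- vE[idx, , drop = FALSE]
  if (!is_advar(E)) return(val)
  ad_node(E$tape, val, pid(E), function(g) {
    gE <- matrix(0, nrow(vE), ncol(vE))
    agg <- rowsum(g, group = idx)
    gE[as.integer(rownames(agg)), ] <- agg
    list(gE)
  })
}

# row-bind a list of advars / numeric matrices (equal column counts)
ad_rbind <- function(args) {
  vals <- lapply(args, vof)
  val <- do.call(rbind, vals)
  tape <- NULL
  for (a in args) if (is_advar(a)) { tape <- a$tape; break }
  if (is.null(tape)) return(val)
  heights <- vapply(vals, nrow, 1L)
  ends <- cumsum(heights)
  starts <- ends - heights + 1L
  ad_node(tape, val, vapply(args, pid, 1L), function(g) {
    lapply(seq_along(args), function(j) g[starts[j]:ends[j], , drop = FALSE])
  })
}

ad_transpose <- function(a) {
  va <- vof(a)
  val <- t(va)
  if (!is_advar(a)) return(val)
  ad_node(a$tape, val, pid(a), function(g) list(t(g)))
}

# multiply each row of X (B x m) by the matching entry of w (B x 1)
ad_mulcol <- function(X, w) {
  vX <- vof(X); vw <- vof(w)
  val <- vX * as.vector(vw)
  tape <- tape_of(X, w)
  if (is.null(tape)) return(val)
  ad_node(tape, val, c(pid(X), pid(w)), function(g) {
    list(g * as.vector(vw), matrix(rowSums(g * vX), ncol = 1L))
  })
}

# row-wise softmax with stable shift
ad_softmax_rows <- function(a) {
  va <- vof(a)
  sm <- function(x) {
    e <- exp(x - apply(x, 1L, max))
    e / rowSums(e)
  }
  val <- sm(va)
  if (!is_advar(a)) return(val)
  ad_node(a$tape, val, pid(a), function(g) {
    list(val * (g - rowSums(g * val)))
  })
}
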