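# Numerical primitives of the dual-branch network: GELU, layer
# normalization, row-wise softmax, patch extraction, and parameter-tree
# utilities. Forward passes cache intermediates; each primitive has a
# matching hand-derived backward pass used by the trainer.

LN_EPS <- 1e-6

gelu <- function(x) x * pnorm(x)
gelu_grad <- function(x) pnorm(x) + x * dnorm(x)
# backward variant reusing the forward pass's cached pnorm(x)
gelu_grad_cached <- function(x, px) px + x * dnorm(x)

# add a length-k bias to each row of an n x k matrix
add_bias <- function(M, b) M + rep(b, each = nrow(M))

# layer normalization over each row, with learnable affine (g, b)
ln_forward <- function(X, g, b) {
  mu <- rowMeans(X)
  d <- X - mu                       # length-n vector recycles per row
  s <- sqrt(rowMeans(d * d) + LN_EPS)
  xhat <- d / s
  list(out = add_bias(xhat * rep(g, each = nrow(X)), b), xhat = xhat, s = s)
}

ln_backward <- function(dY, cache, g) {
  xhat <- cache$xhat
  dxhat <- dY * rep(g, each = nrow(dY))
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  list(dX = (dxhat - m1 - xhat * m2) / cache$s,
       dg = colSums(dY * xhat), db = colSums(dY))
}

softmax_rows <- function(Z) {
  m <- Z[cbind(seq_len(nrow(Z)), max.col(Z, ties.method = "first"))]
  E <- exp(Z - m)
  E / rowSums(E)
}

softmax_rows_backward <- function(dP, P) P * (dP - rowSums(dP * P))

# extract non-overlapping p x p patches from a (3, R, R) grid, row-major
# over patch positions; each row of the result is one flattened patch
# (channel index varying fastest).
patchify <- function(grid, p) {
  R <- dim(grid)[2]
  if (R %% p != 0) stop("resolution must be divisible by the patch size")
  ns <- R %/% p
  # reshape (3, p, ns, p, ns) = (c, in-patch y, patch row, in-patch x,
  # patch col), reorder so each column enumerates one patch (patch col
  # fastest, matching row-major patch order after the transpose)
  A <- aperm(array(grid, c(3L, p, ns, p, ns)), c(1L, 2L, 4L, 5L, 3L))
  t(matrix(A, nrow = 3L * p * p))
}

# truncated-normal initializer (std 0.02, truncated at 2 sd)
trunc_normal <- function(n, std = 0.02) {
  u <- runif(n, pnorm(-2), pnorm(2))
  qnorm(u) * std
}

init_mat <- function(nr, nc, std = 0.02) matrix(trunc_normal(nr * nc, std), nr, nc)

# ---- parameter-tree utilities -------------------------------------------

# apply f leaf-wise across parallel parameter trees; children are aligned
# by name where the first tree is named (gradient lists may be built in a
# different order than the parameter tree)
tree_map <- function(f, ...) {
  trees <- list(...)
  t1 <- trees[[1]]
  if (is.list(t1)) {
    keys <- if (is.null(names(t1))) seq_along(t1) else names(t1)
    out <- lapply(keys, function(k)
      do.call(tree_map, c(list(f), lapply(trees, `[[`, k))))
    names(out) <- names(t1)
    out
  } else {
    do.call(f, trees)
  }
}

tree_zeros_like <- function(par) tree_map(function(x) x * 0, par)

# flatten a parameter tree to one numeric vector (and back), used by the
# finite-difference gradient checks
tree_flatten <- function(par) {
  leaves <- list()
  walk <- function(x, path) {
    if (is.list(x)) {
      for (i in seq_along(x))
        walk(x[[i]], c(path, if (!is.null(names(x))) names(x)[i] else as.character(i)))
    } else {
      leaves[[paste(path, collapse = "/")]] <<- x
    }
  }
  walk(par, character(0))
  leaves
}

tree_key <- function(x, key) {
  if (!is.null(names(x)) && key %in% names(x)) key else as.integer(key)
}

tree_get <- function(par, path) {
  for (p in strsplit(path, "/")[[1]]) par <- par[[tree_key(par, p)]]
  par
}

tree_set <- function(par, path, value) {
  keys <- strsplit(path, "/")[[1]]
  k <- tree_key(par, keys[1])
  if (length(keys) == 1) {
    par[[k]] <- value
  } else {
    par[[k]] <- tree_set(par[[k]], paste(keys[-1], collapse = "/"), value)
  }
  par
}
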