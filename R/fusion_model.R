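# The dual-branch global fusion network: a Mixer-style whole-map branch and
# a self-attention inter-patch branch, each reduced to a 128-length feature
# by token mean-pooling, concatenated with the survival-event scalar and
# mapped to a scalar risk by a fully connected head.

#' Mixer branch configuration
#'
#' The whole-map branch: non-overlapping patches are linearly embedded to
#' `channels` and passed through `depth` Mixer layers, each a token-mixing
#' MLP (communication across the `S = (resolution/patch_size)^2` spatial
#' tokens) and a channel-mixing MLP (communication across channels), both
#' residual.
#'
#' @param resolution input edge length (default 256).
#' @param patch_size patch edge (default 8).
#' @param depth number of Mixer layers (default 2).
#' @param channels channel dimension C, also the branch output length
#'   (default 128).
#' @param token_hidden,channel_hidden hidden widths of the two MLPs.
#' @return A `mixer_config` list (with derived token count `S`).
#' @export
mixer_config <- function(resolution = 256, patch_size = 8, depth = 2,
                         channels = 128, token_hidden = 256,
                         channel_hidden = 512) {
  if (resolution %% patch_size != 0)
    stop("resolution must be divisible by patch_size")
  stopifnot(depth >= 1, channels >= 1, token_hidden >= 1, channel_hidden >= 1)
  structure(list(resolution = resolution, patch_size = patch_size,
                 depth = depth, channels = channels,
                 token_hidden = token_hidden, channel_hidden = channel_hidden,
                 tokens = (resolution %/% patch_size)^2),
            class = "mixer_config")
}

#' Attention branch configuration
#'
#' The inter-patch branch: flattened patches are linearly projected and a
#' learned position embedding is added; `depth` pre-norm transformer layers
#' (multi-head self-attention + MLP, both residual) follow; tokens are
#' mean-pooled to the branch feature.
#'
#' @param resolution,patch_size,depth as in [mixer_config()].
#' @param embed_dim token embedding width, also the branch output length
#'   (default 128).
#' @param heads number of attention heads (must divide `embed_dim`).
#' @param mlp_hidden hidden width of the per-token MLP.
#' @return A `vit_config` list (with derived patch count `p`).
#' @export
vit_config <- function(resolution = 256, patch_size = 8, depth = 2,
                       embed_dim = 128, heads = 4, mlp_hidden = 256) {
  if (resolution %% patch_size != 0)
    stop("resolution must be divisible by patch_size")
  if (embed_dim %% heads != 0) stop("embed_dim must be divisible by heads")
  structure(list(resolution = resolution, patch_size = patch_size,
                 depth = depth, embed_dim = embed_dim, heads = heads,
                 mlp_hidden = mlp_hidden,
                 patches = (resolution %/% patch_size)^2),
            class = "vit_config")
}

init_mixer_par <- function(cfg) {
  P <- 3 * cfg$patch_size^2
  layers <- lapply(seq_len(cfg$depth), function(l) list(
    ln1g = rep(1, cfg$channels), ln1b = rep(0, cfg$channels),
    tW1 = init_mat(cfg$tokens, cfg$token_hidden), tb1 = rep(0, cfg$token_hidden),
    tW2 = init_mat(cfg$token_hidden, cfg$tokens), tb2 = rep(0, cfg$tokens),
    ln2g = rep(1, cfg$channels), ln2b = rep(0, cfg$channels),
    cW1 = init_mat(cfg$channels, cfg$channel_hidden), cb1 = rep(0, cfg$channel_hidden),
    cW2 = init_mat(cfg$channel_hidden, cfg$channels), cb2 = rep(0, cfg$channels)))
  list(W_embed = init_mat(P, cfg$channels), b_embed = rep(0, cfg$channels),
       layers = layers)
}

init_vit_par <- function(cfg) {
  P <- 3 * cfg$patch_size^2
  D <- cfg$embed_dim
  layers <- lapply(seq_len(cfg$depth), function(l) list(
    ln1g = rep(1, D), ln1b = rep(0, D),
    Wq = init_mat(D, D), bq = rep(0, D),
    Wk = init_mat(D, D), bk = rep(0, D),
    Wv = init_mat(D, D), bv = rep(0, D),
    Wo = init_mat(D, D), bo = rep(0, D),
    ln2g = rep(1, D), ln2b = rep(0, D),
    mW1 = init_mat(D, cfg$mlp_hidden), mb1 = rep(0, cfg$mlp_hidden),
    mW2 = init_mat(cfg$mlp_hidden, D), mb2 = rep(0, D)))
  list(W_embed = init_mat(P, D), b_embed = rep(0, D),
       E_pos = init_mat(cfg$patches, D), layers = layers)
}

#' Construct (and initialize) the dual global fusion model
#'
#' Weights are initialized from a seeded truncated normal (std 0.02,
#' truncated at 2 sd); biases and layer-norm offsets start at zero, norm
#' gains at one. Single-branch ablations are available through `branches`.
#'
#' @param mixer a [mixer_config()] (or `NULL` if the branch is ablated).
#' @param vit a [vit_config()] (or `NULL` if ablated).
#' @param branches character subset of `c("mixer", "vit")`.
#' @param mask_event if `TRUE`, the event scalar entering the fused vector
#'   is forced to 0 at every forward pass (for deployment settings where
#'   event status is unknowable; see the vignette's leakage discussion).
#' @param seed integer seed for weight initialization.
#' @return A `fusion_model` with elements `config` and `par`.
#' @export
fusion_model <- function(mixer = mixer_config(), vit = vit_config(),
                         branches = c("mixer", "vit"), mask_event = FALSE,
                         seed = 1L) {
  branches <- match.arg(branches, c("mixer", "vit"), several.ok = TRUE)
  feat_len <- 0
  if ("mixer" %in% branches) {
    stopifnot(inherits(mixer, "mixer_config"))
    feat_len <- feat_len + mixer$channels
  }
  if ("vit" %in% branches) {
    stopifnot(inherits(vit, "vit_config"))
    feat_len <- feat_len + vit$embed_dim
  }
  head_in <- feat_len + 1L
  par <- with_seed(seed, {
    p <- list()
    if ("mixer" %in% branches) p$mixer <- init_mixer_par(mixer)
    if ("vit" %in% branches) p$vit <- init_vit_par(vit)
    p$head <- list(w = trunc_normal(head_in), b = 0)
    p
  })
  structure(list(config = list(mixer = if ("mixer" %in% branches) mixer,
                               vit = if ("vit" %in% branches) vit,
                               branches = branches, mask_event = mask_event,
                               head_in = head_in, seed = as.integer(seed)),
                 par = par),
            class = "fusion_model")
}

#' @export
print.fusion_model <- function(x, ...) {
  np <- sum(vapply(tree_flatten(x$par), length, integer(1)))
  cat(sprintf("fusion_model: branches [%s], head input %d, %d parameters\n",
              paste(x$config$branches, collapse = ", "), x$config$head_in, np))
  invisible(x)
}

# ---- Mixer branch -------------------------------------------------------

#' One MLP block: FC -> GELU -> FC, applied row-wise
#'
#' @param x input matrix (rows are the independent units).
#' @param W1,b1,W2,b2 the two fully connected layers' weights.
#' @return Matrix of the same shape as `x` when `W2` maps back to the input
#'   width.
#' @export
mixer_mlp_block <- function(x, W1, b1, W2, b2) {
  add_bias(gelu(add_bias(x %*% W1, b1)) %*% W2, b2)
}

mixer_layer_fwd <- function(Z, lw) {
  # token mixing: LN, transpose to channels x tokens, MLP, transpose back
  ln1 <- ln_forward(Z, lw$ln1g, lw$ln1b)
  Yt <- t(ln1$out)
  A1 <- add_bias(Yt %*% lw$tW1, lw$tb1)
  P1 <- pnorm(A1)
  H1 <- A1 * P1
  O1 <- add_bias(H1 %*% lw$tW2, lw$tb2)
  U <- Z + t(O1)
  # channel mixing: LN, row-wise MLP
  ln2 <- ln_forward(U, lw$ln2g, lw$ln2b)
  A2 <- add_bias(ln2$out %*% lw$cW1, lw$cb1)
  P2 <- pnorm(A2)
  H2 <- A2 * P2
  O2 <- add_bias(H2 %*% lw$cW2, lw$cb2)
  list(out = U + O2,
       cache = list(Z = Z, ln1 = ln1, Yt = Yt, A1 = A1, P1 = P1, H1 = H1,
                    U = U, ln2 = ln2, A2 = A2, P2 = P2, H2 = H2))
}

mixer_layer_bwd <- function(dOut, cache, lw) {
  g <- list()
  # channel-mixing path
  dO2 <- dOut
  g$cb2 <- colSums(dO2)
  g$cW2 <- crossprod(cache$H2, dO2)
  dH2 <- tcrossprod(dO2, lw$cW2)
  dA2 <- dH2 * gelu_grad_cached(cache$A2, cache$P2)
  g$cb1 <- colSums(dA2)
  g$cW1 <- crossprod(cache$ln2$out, dA2)
  dY2 <- tcrossprod(dA2, lw$cW1)
  lb2 <- ln_backward(dY2, cache$ln2, lw$ln2g)
  g$ln2g <- lb2$dg; g$ln2b <- lb2$db
  dU <- dOut + lb2$dX
  # token-mixing path
  dO1t <- t(dU)                                   # grad wrt O1 (C x S)
  g$tb2 <- colSums(dO1t)
  g$tW2 <- crossprod(cache$H1, dO1t)
  dH1 <- tcrossprod(dO1t, lw$tW2)
  dA1 <- dH1 * gelu_grad_cached(cache$A1, cache$P1)
  g$tb1 <- colSums(dA1)
  g$tW1 <- crossprod(cache$Yt, dA1)
  dYt <- tcrossprod(dA1, lw$tW1)
  lb1 <- ln_backward(t(dYt), cache$ln1, lw$ln1g)
  g$ln1g <- lb1$dg; g$ln1b <- lb1$db
  list(dZ = dU + lb1$dX, grads = g)
}

#' One Mixer layer (token mixing then channel mixing, both residual)
#'
#' `U = Z + transpose(MLP_token(transpose(LN(Z))))`;
#' `out = U + MLP_channel(LN(U))`. With all MLP weights zero this is the
#' identity map (residual structure).
#'
#' @param Z token grid, `S x C`.
#' @param layer_weights one element of a mixer parameter tree's `layers`
#'   (see [fusion_model()]).
#' @return Token grid `S x C`.
#' @export
mixer_layer <- function(Z, layer_weights) mixer_layer_fwd(Z, layer_weights)$out

mixer_branch_fwd <- function(grid, par, cfg, X = NULL) {
  if (is.null(X)) X <- patchify(grid, cfg$patch_size)
  Z <- add_bias(X %*% par$W_embed, par$b_embed)
  caches <- vector("list", cfg$depth)
  for (l in seq_len(cfg$depth)) {
    r <- mixer_layer_fwd(Z, par$layers[[l]])
    caches[[l]] <- r$cache
    Z <- r$out
  }
  list(z = colMeans(Z), cache = list(X = X, layers = caches, S = nrow(Z)))
}

mixer_branch_bwd <- function(dz, cache, par, cfg) {
  S <- cache$S
  dZ <- matrix(rep(dz / S, each = S), S, length(dz))
  gl <- vector("list", cfg$depth)
  for (l in rev(seq_len(cfg$depth))) {
    r <- mixer_layer_bwd(dZ, cache$layers[[l]], par$layers[[l]])
    gl[[l]] <- r$grads
    dZ <- r$dZ
  }
  list(W_embed = crossprod(cache$X, dZ), b_embed = colSums(dZ), layers = gl)
}

#' Run the Mixer branch
#'
#' Patch embedding, `depth` Mixer layers, then mean-pooling over tokens to
#' a feature of length `channels`.
#'
#' @param grid model input array `3 x R x R`.
#' @param par mixer parameter tree (e.g. `model$par$mixer`).
#' @param config the [mixer_config()].
#' @return Numeric feature vector of length `config$channels`.
#' @export
mixer_branch_forward <- function(grid, par, config) {
  mixer_branch_fwd(grid, par, config)$z
}

# ---- Attention branch ---------------------------------------------------

#' Tokenize a model input for the attention branch
#'
#' Flattens non-overlapping patches, projects each by the linear embedding
#' `E` and adds the learned position embedding.
#'
#' @param grid model input array `3 x R x R`.
#' @param par vit parameter tree (needs `W_embed`, `b_embed`, `E_pos`).
#' @param config the [vit_config()].
#' @return Token matrix `p x embed_dim`.
#' @export
vit_tokenize <- function(grid, par, config) {
  X <- patchify(grid, config$patch_size)
  add_bias(X %*% par$W_embed, par$b_embed) + par$E_pos
}

msa_fwd <- function(Y, lw, heads) {
  D <- ncol(Y)
  p <- nrow(Y)
  dh <- D %/% heads
  Q <- add_bias(Y %*% lw$Wq, lw$bq)
  K <- add_bias(Y %*% lw$Wk, lw$bk)
  V <- add_bias(Y %*% lw$Wv, lw$bv)
  # stack all heads' score matrices and softmax them in one call
  Sc <- matrix(0, heads * p, p)
  for (h in seq_len(heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    Sc[((h - 1) * p + 1):(h * p), ] <-
      tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(dh)
  }
  A <- softmax_rows(Sc)
  H <- matrix(0, p, D)
  for (h in seq_len(heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    H[, cols] <- A[((h - 1) * p + 1):(h * p), , drop = FALSE] %*%
      V[, cols, drop = FALSE]
  }
  list(out = add_bias(H %*% lw$Wo, lw$bo),
       cache = list(Y = Y, Q = Q, K = K, V = V, H = H, A = A, dh = dh))
}

msa_bwd <- function(dOut, cache, lw, heads) {
  g <- list()
  g$bo <- colSums(dOut)
  g$Wo <- crossprod(cache$H, dOut)
  dH <- tcrossprod(dOut, lw$Wo)
  p <- nrow(dH)
  dQ <- dK <- dV <- matrix(0, p, ncol(dH))
  dh <- cache$dh
  dAall <- matrix(0, heads * p, p)
  for (h in seq_len(heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    rows <- ((h - 1) * p + 1):(h * p)
    dHh <- dH[, cols, drop = FALSE]
    dAall[rows, ] <- tcrossprod(dHh, cache$V[, cols, drop = FALSE])
    dV[, cols] <- crossprod(cache$A[rows, , drop = FALSE], dHh)
  }
  dS <- softmax_rows_backward(dAall, cache$A)
  for (h in seq_len(heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    rows <- ((h - 1) * p + 1):(h * p)
    dSh <- dS[rows, , drop = FALSE]
    dQ[, cols] <- dSh %*% cache$K[, cols, drop = FALSE] / sqrt(dh)
    dK[, cols] <- crossprod(dSh, cache$Q[, cols, drop = FALSE]) / sqrt(dh)
  }
  g$bq <- colSums(dQ); g$Wq <- crossprod(cache$Y, dQ)
  g$bk <- colSums(dK); g$Wk <- crossprod(cache$Y, dK)
  g$bv <- colSums(dV); g$Wv <- crossprod(cache$Y, dV)
  dY <- tcrossprod(dQ, lw$Wq) + tcrossprod(dK, lw$Wk) + tcrossprod(dV, lw$Wv)
  list(dY = dY, grads = g)
}

transformer_layer_fwd <- function(Z, lw, heads) {
  ln1 <- ln_forward(Z, lw$ln1g, lw$ln1b)
  msa <- msa_fwd(ln1$out, lw, heads)
  U <- msa$out + Z
  ln2 <- ln_forward(U, lw$ln2g, lw$ln2b)
  A <- add_bias(ln2$out %*% lw$mW1, lw$mb1)
  Pm <- pnorm(A)
  Hm <- A * Pm
  M <- add_bias(Hm %*% lw$mW2, lw$mb2)
  list(out = M + U,
       cache = list(ln1 = ln1, msa = msa$cache, U = U, ln2 = ln2,
                    A = A, Pm = Pm, Hm = Hm))
}

transformer_layer_bwd <- function(dOut, cache, lw, heads) {
  g <- list()
  dM <- dOut
  g$mb2 <- colSums(dM)
  g$mW2 <- crossprod(cache$Hm, dM)
  dHm <- tcrossprod(dM, lw$mW2)
  dA <- dHm * gelu_grad_cached(cache$A, cache$Pm)
  g$mb1 <- colSums(dA)
  g$mW1 <- crossprod(cache$ln2$out, dA)
  dY2 <- tcrossprod(dA, lw$mW1)
  lb2 <- ln_backward(dY2, cache$ln2, lw$ln2g)
  g$ln2g <- lb2$dg; g$ln2b <- lb2$db
  dU <- dOut + lb2$dX
  mb <- msa_bwd(dU, cache$msa, lw, heads)
  g <- c(g, mb$grads)
  lb1 <- ln_backward(mb$dY, cache$ln1, lw$ln1g)
  g$ln1g <- lb1$dg; g$ln1b <- lb1$db
  list(dZ = dU + lb1$dX, grads = g)
}

#' One pre-norm transformer layer
#'
#' `U = MSA(LN(Z)) + Z`; `out = MLP(LN(U)) + U`. With zero attention output
#' projection and zero second MLP weights this is the identity map.
#'
#' @param Z token matrix `p x embed_dim`.
#' @param layer_weights one element of a vit parameter tree's `layers`.
#' @param heads number of attention heads.
#' @return Token matrix of the same shape.
#' @export
transformer_layer <- function(Z, layer_weights, heads = 4) {
  transformer_layer_fwd(Z, layer_weights, heads)$out
}

vit_branch_fwd <- function(grid, par, cfg, X = NULL) {
  if (is.null(X)) X <- patchify(grid, cfg$patch_size)
  Z <- add_bias(X %*% par$W_embed, par$b_embed) + par$E_pos
  caches <- vector("list", cfg$depth)
  for (l in seq_len(cfg$depth)) {
    r <- transformer_layer_fwd(Z, par$layers[[l]], cfg$heads)
    caches[[l]] <- r$cache
    Z <- r$out
  }
  list(z = colMeans(Z), cache = list(X = X, layers = caches, S = nrow(Z)))
}

vit_branch_bwd <- function(dz, cache, par, cfg) {
  S <- cache$S
  dZ <- matrix(rep(dz / S, each = S), S, length(dz))
  gl <- vector("list", cfg$depth)
  for (l in rev(seq_len(cfg$depth))) {
    r <- transformer_layer_bwd(dZ, cache$layers[[l]], par$layers[[l]],
                               cfg$heads)
    gl[[l]] <- r$grads
    dZ <- r$dZ
  }
  list(W_embed = crossprod(cache$X, dZ), b_embed = colSums(dZ), E_pos = dZ,
       layers = gl)
}

#' Run the attention branch
#'
#' Tokenization, `depth` transformer layers, then mean-pooling over tokens
#' to a feature of length `embed_dim`.
#'
#' @inheritParams vit_tokenize
#' @return Numeric feature vector of length `config$embed_dim`.
#' @export
vit_branch_forward <- function(grid, par, config) {
  vit_branch_fwd(grid, par, config)$z
}

# ---- Fusion and head ----------------------------------------------------

#' Fuse branch features with the survival-event scalar
#'
#' Concatenates the branch features and appends the event indicator `mu`
#' (or 0 when `mask_event`), giving the head input of length
#' `sum of branch lengths + 1` (257 under the default dual-branch
#' configuration).
#'
#' @param z1,z2 branch feature vectors (either may be `NULL` for a
#'   single-branch ablation, but not both).
#' @param mu event scalar in \{0, 1\}.
#' @param mask_event force the appended scalar to 0.
#' @return The fused feature vector.
#' @export
fuse <- function(z1, z2, mu, mask_event = FALSE) {
  if (is.null(z1) && is.null(z2)) stop("at least one branch feature required")
  if (!mu %in% c(0, 1)) stop("mu must be 0 or 1")
  c(z1, z2, if (mask_event) 0 else mu)
}

#' Predict the scalar survival risk from a fused feature
#'
#' A single fully connected layer: `r = w . fused + b`, an unbounded value
#' on the Cox linear-predictor scale.
#'
#' @param fused fused feature vector.
#' @param head list with weight vector `w` and bias `b` (e.g.
#'   `model$par$head`).
#' @return Scalar risk.
#' @export
predict_risk <- function(fused, head) {
  if (length(fused) != length(head$w))
    stop("fused length ", length(fused), " does not match head input ",
         length(head$w))
  sum(head$w * fused) + head$b
}

#' Full forward pass of the fusion model
#'
#' @param model a [fusion_model()].
#' @param grid model input array `3 x R x R`.
#' @param mu event scalar.
#' @param keep_cache cache intermediates for [model_backward()].
#' @return list with `risk`, `z1`, `z2`, `fused` (and `cache` if requested).
#' @export
model_forward <- function(model, grid, mu, keep_cache = FALSE) {
  cfg <- model$config
  z1 <- z2 <- NULL
  c1 <- c2 <- NULL
  X <- NULL
  if (all(c("mixer", "vit") %in% cfg$branches) &&
      cfg$mixer$patch_size == cfg$vit$patch_size)
    X <- patchify(grid, cfg$mixer$patch_size)
  if ("mixer" %in% cfg$branches) {
    r <- mixer_branch_fwd(grid, model$par$mixer, cfg$mixer, X)
    z1 <- r$z; c1 <- r$cache
  }
  if ("vit" %in% cfg$branches) {
    r <- vit_branch_fwd(grid, model$par$vit, cfg$vit, X)
    z2 <- r$z; c2 <- r$cache
  }
  fused <- fuse(z1, z2, mu, cfg$mask_event)
  risk <- predict_risk(fused, model$par$head)
  out <- list(risk = risk, z1 = z1, z2 = z2, fused = fused)
  if (keep_cache) out$cache <- list(mixer = c1, vit = c2, fused = fused)
  out
}

#' Backward pass: parameter gradients of `drisk * risk`
#'
#' Propagates the scalar upstream gradient `drisk` (e.g. the Cox-loss
#' derivative for this patient) through the head and both branches.
#'
#' @param model a [fusion_model()].
#' @param fwd the result of `model_forward(..., keep_cache = TRUE)`.
#' @param drisk upstream gradient of the loss with respect to this
#'   patient's risk.
#' @return Gradient tree mirroring `model$par`.
#' @export
model_backward <- function(model, fwd, drisk) {
  cfg <- model$config
  fused <- fwd$cache$fused
  g <- list()
  g$head <- list(w = drisk * fused, b = drisk)
  dfused <- drisk * model$par$head$w
  off <- 0
  if ("mixer" %in% cfg$branches) {
    n1 <- cfg$mixer$channels
    g$mixer <- mixer_branch_bwd(dfused[(off + 1):(off + n1)],
                                fwd$cache$mixer, model$par$mixer, cfg$mixer)
    off <- off + n1
  }
  if ("vit" %in% cfg$branches) {
    n2 <- cfg$vit$embed_dim
    g$vit <- vit_branch_bwd(dfused[(off + 1):(off + n2)],
                            fwd$cache$vit, model$par$vit, cfg$vit)
  }
  g[names(model$par)]
}

#' Save / load a model checkpoint
#'
#' The checkpoint carries the full configuration, the initialization seed
#' and all weights, and round-trips exactly.
#'
#' @param model a [fusion_model()].
#' @param path checkpoint path (RDS).
#' @return `path` invisibly; `load_checkpoint` returns the model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "fusion_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "fusion_model"))
  model
}
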