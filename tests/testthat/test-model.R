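# Structural and numerical checks of the dual-branch network: shapes,
# residual identities, dual-implementation oracles and gradients.

test_that("MLP blocks equal a straight-line FC-GELU-FC re-implementation", {
  cellfuse:::with_seed(51, {
    x <- matrix(rnorm(16), 4, 4)
    W1 <- matrix(rnorm(20), 4, 5); b1 <- rnorm(5)
    W2 <- matrix(rnorm(20), 5, 4); b2 <- rnorm(4)
  })
  got <- mixer_mlp_block(x, W1, b1, W2, b2)
  # independent literal evaluation, row by row
  manual <- matrix(0, 4, 4)
  for (i in 1:4) {
    h <- as.vector(x[i, ] %*% W1) + b1
    h <- 0.5 * h * (1 + pracma::erf(h / sqrt(2)))   # exact erf-form GELU
    manual[i, ] <- as.vector(h %*% W2) + b2
  }
  expect_equal(got, manual, tolerance = 1e-6)

  # zero weights annihilate any input; identity-then-zero also annihilates
  expect_equal(mixer_mlp_block(x, W1 * 0, b1 * 0, W2 * 0, b2 * 0),
               matrix(0, 4, 4))
  expect_equal(mixer_mlp_block(x, diag(4), rep(0, 4),
                               matrix(0, 4, 4), rep(0, 4)),
               matrix(0, 4, 4))
})

test_that("mixer layer is the identity under zero MLP weights", {
  cfg <- mixer_config(resolution = 8, patch_size = 4, depth = 1,
                      channels = 3, token_hidden = 5, channel_hidden = 6)
  m <- fusion_model(cfg, vit = NULL, branches = "mixer", seed = 1)
  lw <- zero_leaves(m$par$mixer$layers[[1]], "^(t|c)[Wb]")
  cellfuse:::with_seed(52, Z <- matrix(rnorm(12), 4, 3))
  expect_equal(mixer_layer(Z, lw), Z, tolerance = 1e-12)

  # constant input + zero token mixing: all output tokens identical
  lw2 <- zero_leaves(m$par$mixer$layers[[1]], "^t[Wb]")
  Zc <- matrix(rep(c(1, 2, 3), each = 4), 4, 3)
  out <- mixer_layer(Zc, lw2)
  expect_equal(out[1, ], out[2, ])
  expect_equal(out[1, ], out[4, ])
})

test_that("mixer layer matches a literal two-residual transcription", {
  cfg <- mixer_config(resolution = 8, patch_size = 4, depth = 1,
                      channels = 3, token_hidden = 5, channel_hidden = 6)
  m <- fusion_model(cfg, vit = NULL, branches = "mixer", seed = 99)
  lw <- m$par$mixer$layers[[1]]
  cellfuse:::with_seed(53, Z <- matrix(rnorm(12), 4, 3))
  # independent evaluation: LN, transpose, MLP, residual; LN, MLP, residual
  ln <- function(X, g, b) {
    t(apply(X, 1, function(r) {
      (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-6)
    })) * rep(g, each = nrow(X)) + rep(b, each = nrow(X))
  }
  gelu_ref <- function(x) x * stats::pnorm(x)
  mlp <- function(X, W1, b1, W2, b2)
    t(apply(X, 1, function(r)
      as.vector(gelu_ref(as.vector(r %*% W1) + b1) %*% W2) + b2))
  MP <- t(mlp(t(ln(Z, lw$ln1g, lw$ln1b)), lw$tW1, lw$tb1, lw$tW2, lw$tb2))
  U <- Z + MP
  MC <- mlp(ln(U, lw$ln2g, lw$ln2b), lw$cW1, lw$cb1, lw$cW2, lw$cb2)
  expect_equal(mixer_layer(Z, lw), U + MC, tolerance = 1e-6)
})

test_that("branch outputs have the configured lengths and token counts", {
  # reference-scale arithmetic: S = (256/8)^2 tokens, feature length 128
  mc <- mixer_config()
  vc <- vit_config()
  expect_equal(mc$tokens, 1024)
  expect_equal(vc$patches, 1024)
  expect_equal(mc$channels, 128)
  expect_equal(vc$embed_dim, 128)

  prof <- tiny_profile()
  m <- fusion_model(prof$mixer, prof$vit, seed = 2)
  g <- array(abs(rnorm(3 * 16 * 16)), dim = c(3, 16, 16))
  z1 <- mixer_branch_forward(g, m$par$mixer, prof$mixer)
  z2 <- vit_branch_forward(g, m$par$vit, prof$vit)
  expect_length(z1, prof$mixer$channels)
  expect_length(z2, prof$vit$embed_dim)

  # zero-weight networks emit zero features
  mz <- m
  mz$par$mixer <- cellfuse:::tree_zeros_like(mz$par$mixer)
  mz$par$vit <- cellfuse:::tree_zeros_like(mz$par$vit)
  mz$par$mixer$layers <- lapply(mz$par$mixer$layers, function(l) {
    l$ln1g <- l$ln1g + 1; l$ln2g <- l$ln2g + 1; l
  })
  expect_equal(mixer_branch_forward(g, mz$par$mixer, prof$mixer),
               rep(0, 8))
  expect_error(cellfuse:::patchify(g, 5), "divisible")
})

test_that("tokenization projects patches and respects position embeddings", {
  prof <- tiny_profile()
  m <- fusion_model(prof$mixer, prof$vit, seed = 4)
  g <- array(rnorm(3 * 16 * 16), dim = c(3, 16, 16))
  tok <- vit_tokenize(g, m$par$vit, prof$vit)
  expect_equal(dim(tok), c(16, 8))   # p = (16/4)^2 patches

  # zero projection and zero positions give zero tokens
  pz <- m$par$vit
  pz$W_embed <- pz$W_embed * 0; pz$b_embed <- pz$b_embed * 0
  pz$E_pos <- pz$E_pos * 0
  expect_equal(vit_tokenize(g, pz, prof$vit), matrix(0, 16, 8))

  # with E_pos = 0, permuting input patches permutes tokens identically
  p0 <- m$par$vit
  p0$E_pos <- p0$E_pos * 0
  tok0 <- vit_tokenize(g, p0, prof$vit)
  # swap the two patch rows of the grid (patches 1..4 <-> 5..8)
  g2 <- g
  g2[, 1:4, ] <- g[, 5:8, ]
  g2[, 5:8, ] <- g[, 1:4, ]
  tok2 <- vit_tokenize(g2, p0, prof$vit)
  expect_equal(tok2[1:4, ], tok0[5:8, ])
  expect_equal(tok2[5:8, ], tok0[1:4, ])
})

test_that("transformer layer has the residual identity and 1-token closed form", {
  prof <- tiny_profile()
  m <- fusion_model(prof$mixer, prof$vit, seed = 5)
  lw <- m$par$vit$layers[[1]]
  cellfuse:::with_seed(54, Z <- matrix(rnorm(32), 4, 8))

  lw0 <- lw
  lw0$Wo <- lw0$Wo * 0; lw0$bo <- lw0$bo * 0
  lw0$mW2 <- lw0$mW2 * 0; lw0$mb2 <- lw0$mb2 * 0
  expect_equal(transformer_layer(Z, lw0, heads = 2), Z, tolerance = 1e-12)

  # single token: softmax over one key is 1, so MSA is a value pass
  z1 <- Z[1, , drop = FALSE]
  ln <- function(x, g, b) (x - mean(x)) / sqrt(mean((x - mean(x))^2) + 1e-6) * g + b
  y <- ln(as.vector(z1), lw$ln1g, lw$ln1b)
  v <- as.vector(y %*% lw$Wv) + lw$bv
  msa <- as.vector(v %*% lw$Wo) + lw$bo
  u <- msa + as.vector(z1)
  y2 <- ln(u, lw$ln2g, lw$ln2b)
  gelu_ref <- function(x) x * stats::pnorm(x)
  out_ref <- as.vector(gelu_ref(as.vector(y2 %*% lw$mW1) + lw$mb1) %*%
                         lw$mW2) + lw$mb2 + u
  expect_equal(as.vector(transformer_layer(z1, lw, heads = 2)), out_ref,
               tolerance = 1e-8)
})

test_that("attention matches an independent re-implementation", {
  prof <- tiny_profile()
  m <- fusion_model(prof$mixer, prof$vit, seed = 6)
  lw <- m$par$vit$layers[[1]]
  cellfuse:::with_seed(55, Z <- matrix(rnorm(32), 4, 8))
  heads <- 2; dh <- 4
  # literal pre-norm transformer block
  ln_rows <- function(X, g, b) t(apply(X, 1, function(r)
    (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-6) * g + b))
  Y <- ln_rows(Z, lw$ln1g, lw$ln1b)
  Q <- Y %*% lw$Wq + rep(lw$bq, each = 4)
  K <- Y %*% lw$Wk + rep(lw$bk, each = 4)
  V <- Y %*% lw$Wv + rep(lw$bv, each = 4)
  H <- matrix(0, 4, 8)
  for (h in 1:heads) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    S <- Q[, cols] %*% t(K[, cols]) / sqrt(dh)
    A <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
    H[, cols] <- A %*% V[, cols]
  }
  U <- H %*% lw$Wo + rep(lw$bo, each = 4) + Z
  Y2 <- ln_rows(U, lw$ln2g, lw$ln2b)
  gelu_ref <- function(x) x * stats::pnorm(x)
  OUT <- gelu_ref(Y2 %*% lw$mW1 + rep(lw$mb1, each = 4)) %*% lw$mW2 +
    rep(lw$mb2, each = 4) + U
  expect_equal(transformer_layer(Z, lw, heads = 2), OUT, tolerance = 1e-6)
})

test_that("fusion emits the documented head sizes and mask behavior", {
  # reference configuration: 128 + 128 + 1 = 257
  m <- fusion_model(seed = 1)
  expect_equal(m$config$head_in, 257)
  expect_length(fuse(rep(0, 128), rep(0, 128), 1), 257)

  f <- fuse(rep(0, 128), rep(0, 128), 1)
  expect_equal(which(f != 0), 257)

  expect_equal(fuse(rep(0, 4), rep(0, 4), 1, mask_event = TRUE)[9], 0)
  expect_error(fuse(NULL, NULL, 1), "at least one")
  expect_error(fuse(1:3, NULL, 0.5), "mu")

  # ablation head sizes at reference dims: 129 / 129 / 257
  m1 <- fusion_model(branches = "mixer", seed = 1)
  m2 <- fusion_model(branches = "vit", seed = 1)
  expect_equal(m1$config$head_in, 129)
  expect_equal(m2$config$head_in, 129)
})

test_that("the risk head is the documented affine map", {
  head <- list(w = c(0.5, -1, 2, 0, 0.25), b = 0.3)
  fused <- c(1, 2, 3, 4, 5)
  expect_equal(predict_risk(fused, head),
               0.5 * 1 - 1 * 2 + 2 * 3 + 0 + 0.25 * 5 + 0.3)
  expect_equal(predict_risk(rep(1, 5), list(w = rep(0, 5), b = -2)), -2)
  # affine: subtracting the bias makes it linear
  a <- 3.5
  expect_equal(predict_risk(a * fused, head) - head$b,
               a * (predict_risk(fused, head) - head$b))
  expect_error(predict_risk(1:3, head), "match")
})

test_that("forward passes are deterministic and zero-weight models are flat", {
  prof <- tiny_profile()
  m <- fusion_model(prof$mixer, prof$vit, seed = 8)
  g <- array(abs(rnorm(3 * 16 * 16)), dim = c(3, 16, 16))
  r1 <- model_forward(m, g, 1)
  r2 <- model_forward(m, g, 1)
  expect_identical(r1$risk, r2$risk)
  expect_identical(r1$fused, r2$fused)
  expect_length(r1$fused, 17)

  # same seed, same weights
  m2 <- fusion_model(prof$mixer, prof$vit, seed = 8)
  expect_identical(m$par, m2$par)
})

test_that("analytic gradients match central differences on a tiny batch", {
  prof <- tiny_profile()
  m <- fusion_model(prof$mixer, prof$vit, seed = 9)
  cellfuse:::with_seed(56, {
    grids <- lapply(1:6, function(i) array(rnorm(3 * 16 * 16),
                                           dim = c(3, 16, 16)))
  })
  times <- c(1, 2, 3, 4, 5, 6)
  events <- c(1, 1, 0, 1, 0, 1)
  G <- model_cox_grads(m, grids, times, events)
  err <- max_grad_rel_err(m, G, model_cox_loss_fn(grids, times, events),
                          per_leaf = 2)
  expect_lt(err, 1e-4)
})

test_that("checkpoints round-trip the model exactly", {
  prof <- tiny_profile()
  m <- fusion_model(prof$mixer, prof$vit, seed = 10)
  p <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, p)
  back <- load_checkpoint(p)
  expect_identical(back$par, m$par)
  expect_identical(back$config$head_in, m$config$head_in)
})
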