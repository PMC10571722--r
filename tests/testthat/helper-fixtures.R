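# Fixtures and independent oracles shared across the tests. Everything is
# built in code; no binary fixtures.

# a tiny dual-branch configuration for fast structural tests
tiny_profile <- function() {
  list(mixer = mixer_config(resolution = 16, patch_size = 4, depth = 2,
                            channels = 8, token_hidden = 12,
                            channel_hidden = 16),
       vit = vit_config(resolution = 16, patch_size = 4, depth = 2,
                        embed_dim = 8, heads = 2, mlp_hidden = 12),
       train = train_config(learning_rate = 3e-3, batch_size = 8,
                            epochs = 2, input_resolution = 16, seed = 1L))
}

# build a mapped nuclei table from coordinate/class vectors
toy_table <- function(x, y, cls, w = 8000, h = 8000) {
  rec <- data.frame(centroid_x = x, centroid_y = y,
                    merged_class = factor(cls, levels = c("neoplastic",
                                                          "inflammatory",
                                                          "miscellaneous")))
  nuclei_table(rec, w, h, mapped = TRUE)
}

# write a block JSON in the ingestion dialect; counts is named by type id
write_block_json <- function(path, centroids, types) {
  nuc <- list()
  for (i in seq_along(types))
    nuc[[as.character(i)]] <- list(centroid = centroids[[i]],
                                   type = types[[i]])
  jsonlite::write_json(list(nuc = nuc), path, auto_unbox = TRUE, digits = NA)
  path
}

# brute-force O(n^2) concordance oracle, independent of the implementation
cindex_bruteforce <- function(risks, times, events) {
  num <- 0; den <- 0
  n <- length(risks)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (events[i] == 1 && times[i] < times[j]) {
      den <- den + 1
      if (risks[i] > risks[j]) num <- num + 1
      else if (risks[i] == risks[j]) num <- num + 0.5
    }
  }
  num / den
}

# literal term-by-term negative Cox log partial likelihood (Breslow ties)
cox_loss_literal <- function(risks, times, events) {
  total <- 0
  for (i in seq_along(risks)) {
    if (events[i] == 1) {
      denom <- sum(exp(risks[times >= times[i]]))
      total <- total + (-risks[i] + log(denom))
    }
  }
  total
}

# independent log-rank chi-squared from the O-E hypergeometric table
logrank_literal <- function(times_a, events_a, times_b, events_b) {
  times <- c(times_a, times_b)
  events <- c(events_a, events_b)
  in_a <- rep(c(TRUE, FALSE), c(length(times_a), length(times_b)))
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(times[events == 1]))) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n_a <- sum(at_risk & in_a)
    d <- sum(events == 1 & times == t)
    d_a <- sum(events == 1 & times == t & in_a)
    o_minus_e <- o_minus_e + d_a - d * n_a / n
    if (n > 1) v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# numeric central-difference gradient of loss(model) at sampled coordinates;
# returns the worst relative discrepancy against the analytic gradient tree
max_grad_rel_err <- function(model, analytic, loss_fn, per_leaf = 2,
                             h = 1e-4, seed = 42) {
  flat <- cellfuse:::tree_flatten(analytic)
  worst <- 0
  cellfuse:::with_seed(seed, {
    for (path in names(flat)) {
      leaf <- flat[[path]]
      for (j in sample(seq_along(leaf), min(per_leaf, length(leaf)))) {
        m2 <- model
        v <- cellfuse:::tree_get(m2$par, path)
        v[j] <- v[j] + h
        m2$par <- cellfuse:::tree_set(m2$par, path, v)
        lp <- loss_fn(m2)
        v[j] <- v[j] - 2 * h
        m2$par <- cellfuse:::tree_set(m2$par, path, v)
        lm <- loss_fn(m2)
        gn <- (lp - lm) / (2 * h)
        ga <- leaf[j]
        worst <- max(worst, abs(ga - gn) / max(abs(ga), abs(gn), 1e-6))
      }
    }
  })
  worst
}

# Cox-loss gradient of the risks of a set of inputs, pushed through the
# model: the composite used by the gradient checks
model_cox_grads <- function(model, grids, times, events) {
  risks <- vapply(seq_along(grids), function(i)
    model_forward(model, grids[[i]], events[i])$risk, numeric(1))
  dr <- cox_loss_grad(risks, times, events)
  G <- cellfuse:::tree_zeros_like(model$par)
  for (i in seq_along(grids)) {
    fwd <- model_forward(model, grids[[i]], events[i], keep_cache = TRUE)
    G <- cellfuse:::tree_map(`+`, G, model_backward(model, fwd, dr[i]))
  }
  G
}

model_cox_loss_fn <- function(grids, times, events) {
  function(model) {
    risks <- vapply(seq_along(grids), function(i)
      model_forward(model, grids[[i]], events[i])$risk, numeric(1))
    cox_loss(risks, times, events)
  }
}

# set every leaf of a parameter subtree whose name matches `pattern` to zero
zero_leaves <- function(par, pattern) {
  flat <- cellfuse:::tree_flatten(par)
  for (path in names(flat)) {
    last <- utils::tail(strsplit(path, "/")[[1]], 1)
    if (grepl(pattern, last))
      par <- cellfuse:::tree_set(par, path, flat[[path]] * 0)
  }
  par
}
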