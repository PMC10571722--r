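# Training, evaluation, cross-validation and feature projection: the
# orchestration layer over the fusion model and the survival machinery.

#' Training configuration
#'
#' Defaults follow the reference training recipe: Adam with learning rate
#' 1e-4, weight decay 5e-3 and first-moment decay (beta1) 0.99, batch size
#' 64, 100 epochs, input resolution 256, training to the last epoch with no
#' early stopping. `beta2` is the conventional 0.999. Mini-batches are
#' event-stratified shuffles so each batch almost surely contains an event,
#' and the batch is the Cox risk set (a standard approximation to the
#' full-cohort partial likelihood).
#'
#' @param learning_rate,weight_decay,beta1,beta2 Adam settings.
#' @param batch_size,epochs training schedule.
#' @param seed integer seed for shuffling (and augmentation draws).
#' @param input_resolution model input edge length.
#' @param normalize count normalization applied upstream of the network.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, weight_decay = 5e-3,
                         beta1 = 0.99, beta2 = 0.999, batch_size = 64,
                         epochs = 100, seed = 1L, input_resolution = 256,
                         normalize = c("log1p", "none", "max_scale")) {
  normalize <- match.arg(normalize)
  stopifnot(learning_rate > 0, weight_decay >= 0, beta1 > 0, beta1 < 1,
            beta2 > 0, beta2 < 1, batch_size >= 1, epochs >= 0,
            input_resolution >= 1)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 beta1 = beta1, beta2 = beta2, batch_size = batch_size,
                 epochs = epochs, seed = as.integer(seed),
                 input_resolution = input_resolution, normalize = normalize),
            class = "train_config")
}

#' Named model/training profiles
#'
#' `"paper"` is the reference-scale configuration (resolution 256, patch 8,
#' 128-dim branches). `"desk"` is a reduced CPU-scale configuration
#' (resolution 64, patch 4, 32-dim branches) with a shorter, hotter
#' training schedule suited to the smaller model; it is the profile used
#' throughout the package's tests and simulations.
#'
#' @param name `"paper"` or `"desk"`.
#' @return list with elements `mixer`, `vit` and `train`.
#' @export
model_profile <- function(name = c("desk", "paper")) {
  name <- match.arg(name)
  if (name == "paper") {
    list(mixer = mixer_config(256, 8, 2, 128, 256, 512),
         vit = vit_config(256, 8, 2, 128, 4, 256),
         train = train_config())
  } else {
    # 64 tokens per branch: token count is the quadratic cost driver of
    # self-attention, so desk scale uses patch 8 at resolution 64
    list(mixer = mixer_config(64, 8, 2, 32, 64, 128),
         vit = vit_config(64, 8, 2, 32, 4, 64),
         train = train_config(learning_rate = 3e-3, beta1 = 0.9,
                              batch_size = 16, epochs = 15,
                              input_resolution = 64))
  }
}

#' Prepare model inputs from embedded maps
#'
#' Resizes each map to the configured resolution (area-weighted, mass
#' preserving) and applies the configured count normalization.
#'
#' @param maps list of `embedded_map` (or bare 3-channel arrays).
#' @param resolution model input edge length.
#' @param normalize normalization scheme (see [normalize_counts()]).
#' @return list of `3 x resolution x resolution` arrays.
#' @export
prepare_model_inputs <- function(maps, resolution = 256,
                                 normalize = "log1p") {
  lapply(maps, function(m)
    normalize_counts(resize_to_input(m, resolution), normalize))
}

# event-stratified batch assignment: events and censored are shuffled
# separately and dealt round-robin, so every batch gets its share of events
batch_assignment <- function(events, batch_size) {
  n <- length(events)
  nb <- max(1L, ceiling(n / batch_size))
  assign <- integer(n)
  slot <- 0L
  for (grp in list(which(events == 1), which(events == 0))) {
    for (i in grp[sample.int(length(grp))]) {
      assign[i] <- (slot %% nb) + 1L
      slot <- slot + 1L
    }
  }
  assign
}

adam_step <- function(par, grads, state, cfg) {
  state$t <- state$t + 1L
  gd <- tree_map(function(g, p) g + cfg$weight_decay * p, grads, par)
  state$m <- tree_map(function(m, g) cfg$beta1 * m + (1 - cfg$beta1) * g,
                      state$m, gd)
  state$v <- tree_map(function(v, g) cfg$beta2 * v + (1 - cfg$beta2) * g * g,
                      state$v, gd)
  c1 <- 1 - cfg$beta1^state$t
  c2 <- 1 - cfg$beta2^state$t
  par <- tree_map(function(p, m, v)
    p - cfg$learning_rate * (m / c1) / (sqrt(v / c2) + 1e-8),
    par, state$m, state$v)
  list(par = par, state = state)
}

#' Train the fusion model with the negative Cox log partial likelihood
#'
#' Mini-batch Adam for exactly `config$epochs` epochs (no early stopping);
#' each batch's risk set is the batch itself. The per-patient event scalar
#' is both the model's fused input `mu` and the loss's event indicator.
#'
#' @param model a [fusion_model()].
#' @param inputs list of prepared model input arrays (see
#'   [prepare_model_inputs()]).
#' @param times,events training survival data.
#' @param config a [train_config()].
#' @param augment_spec optional [augmentation_spec()] applied per sample
#'   per epoch.
#' @param verbose print per-epoch loss.
#' @return A `fusion_fit`: list with the trained `model`, `history`
#'   (per-epoch mean batch loss), `config` and `seed` - a reproducible run
#'   manifest.
#' @export
train_fusion <- function(model, inputs, times, events, config,
                         augment_spec = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "fusion_model"), inherits(config, "train_config"))
  n <- length(inputs)
  stopifnot(length(times) == n, length(events) == n)
  if (sum(events) == 0)
    stop("training data contains no events; the Cox loss is uninformative")
  par <- model$par
  state <- list(t = 0L, m = tree_zeros_like(par), v = tree_zeros_like(par))
  history <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    assign <- with_seed(child_seed(config$seed, 1000 + ep),
                        batch_assignment(events, config$batch_size))
    ep_losses <- c()
    for (b in sort(unique(assign))) {
      idx <- which(assign == b)
      model$par <- par
      fwds <- vector("list", length(idx))
      risks <- numeric(length(idx))
      for (k in seq_along(idx)) {
        g <- inputs[[idx[k]]]
        if (!is.null(augment_spec))
          g <- augment(g, augment_spec, draw = ep * n + idx[k])
        fwds[[k]] <- model_forward(model, g, events[idx[k]],
                                   keep_cache = TRUE)
        risks[k] <- fwds[[k]]$risk
      }
      if (sum(events[idx]) == 0) next  # no informative terms in this batch
      loss <- cox_loss(risks, times[idx], events[idx])
      dr <- cox_loss_grad(risks, times[idx], events[idx])
      grads <- tree_zeros_like(par)
      for (k in seq_along(idx))
        grads <- tree_map(`+`, grads,
                          model_backward(model, fwds[[k]], dr[k]))
      st <- adam_step(par, grads, state, config)
      par <- st$par
      state <- st$state
      ep_losses <- c(ep_losses, loss / sum(events[idx]))
    }
    history[ep] <- if (length(ep_losses)) mean(ep_losses) else NA_real_
    if (verbose)
      message(sprintf("epoch %3d  loss/event %.4f", ep, history[ep]))
  }
  model$par <- par
  structure(list(model = model,
                 history = data.frame(epoch = seq_len(config$epochs),
                                      loss = history),
                 config = config, seed = config$seed),
            class = "fusion_fit")
}

#' Predict risks for a set of patients
#'
#' @param model a `fusion_model` (or a `fusion_fit`).
#' @param inputs list of prepared input arrays.
#' @param mus per-patient event scalars fed to the fusion (ignored when the
#'   model masks the event).
#' @return Numeric risk vector.
#' @export
predict_risks <- function(model, inputs, mus) {
  if (inherits(model, "fusion_fit")) model <- model$model
  vapply(seq_along(inputs), function(i)
    model_forward(model, inputs[[i]], mus[i])$risk, numeric(1))
}

#' Evaluate a model on a patient set
#'
#' Emits risks, the concordance index, and - given (or after deriving) a
#' risk cutoff - the low/high stratification with its log-rank test and
#' per-group Kaplan-Meier curves. By default the cutoff should come from
#' training data (pass `cutoff`); if absent it is derived on the evaluated
#' set itself and flagged in the result.
#'
#' @param model a `fusion_model` or `fusion_fit`.
#' @param inputs,times,events the evaluation set.
#' @param cutoff optional risk cutoff carried over from training.
#' @param quantile_grid grid for [optimal_quantile_cutoff()] when `cutoff`
#'   is `NULL`.
#' @return list with `risks`, `cindex`, `cutoff`, `cutoff_source`,
#'   `stratification`, `km` (per-group curves).
#' @export
evaluate_fusion <- function(model, inputs, times, events, cutoff = NULL,
                            quantile_grid = seq(0.25, 0.75, by = 0.05)) {
  risks <- predict_risks(model, inputs, events)
  ci <- concordance_index(risks, times, events)
  source <- "training"
  if (is.null(cutoff)) {
    cc <- tryCatch(optimal_quantile_cutoff(risks, times, events,
                                           quantile_grid),
                   error = function(e) NULL)
    cutoff <- if (is.null(cc)) unname(quantile(risks, 0.5)) else cc$cutoff
    source <- "evaluation-set"
  }
  strat <- stratify(risks, times, events, cutoff)
  km <- lapply(split(seq_along(risks), strat$group), function(ix) {
    if (length(ix) == 0) return(NULL)
    km_estimate(times[ix], events[ix])
  })
  list(risks = risks, cindex = ci, cutoff = cutoff, cutoff_source = source,
       stratification = strat, km = km)
}

#' k-fold cross-validation of the pipeline
#'
#' Splits with [make_folds()] (half-year/event strata), trains per fold,
#' derives the risk cutoff on the training fold, and evaluates the held-out
#' fold. Ablations run the same protocol on a single branch.
#'
#' @param inputs list of prepared model inputs for the whole cohort.
#' @param times,events cohort survival data (times in years).
#' @param k number of folds.
#' @param profile a [model_profile()]-shaped list (`mixer`, `vit`, `train`).
#' @param variant `"fusion"` (both branches), `"mixer"` or `"vit"`.
#' @param mask_event mask the fused event scalar.
#' @return A `cv_result`: list with `per_fold` (data.frame of fold, cindex,
#'   logrank chi2/p, cutoff), `mean_cindex`, `sd_cindex`, `variant`.
#' @export
crossvalidate <- function(inputs, times, events, k = 5,
                          profile = model_profile("desk"),
                          variant = c("fusion", "mixer", "vit"),
                          mask_event = FALSE) {
  variant <- match.arg(variant)
  branches <- switch(variant, fusion = c("mixer", "vit"),
                     mixer = "mixer", vit = "vit")
  n <- length(inputs)
  ids <- seq_len(n)
  folds <- make_folds(ids, times, events, k = k, seed = profile$train$seed)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds[[f]]$train_ids
    te <- folds[[f]]$test_ids
    model <- fusion_model(profile$mixer, profile$vit, branches = branches,
                          mask_event = mask_event,
                          seed = child_seed(profile$train$seed, 500 + f))
    fit <- train_fusion(model, inputs[tr], times[tr], events[tr],
                        profile$train)
    tr_risks <- predict_risks(fit, inputs[tr], events[tr])
    cut <- tryCatch(
      optimal_quantile_cutoff(tr_risks, times[tr], events[tr])$cutoff,
      error = function(e) unname(quantile(tr_risks, 0.5)))
    ev <- evaluate_fusion(fit, inputs[te], times[te], events[te],
                          cutoff = cut)
    rows[[f]] <- data.frame(fold = f, cindex = ev$cindex,
                            logrank_chi2 = ev$stratification$logrank_chi2,
                            p_value = ev$stratification$p_value,
                            cutoff = cut)
  }
  per_fold <- do.call(rbind, rows)
  structure(list(per_fold = per_fold,
                 mean_cindex = mean(per_fold$cindex),
                 sd_cindex = sd(per_fold$cindex), variant = variant,
                 head_in = sum(vapply(branches, function(b)
                   if (b == "mixer") profile$mixer$channels
                   else profile$vit$embed_dim, numeric(1))) + 1),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result [%s]: C-index %.3f +/- %.3f over %d folds\n",
              x$variant, x$mean_cindex, x$sd_cindex, nrow(x$per_fold)))
  print(x$per_fold, row.names = FALSE)
  invisible(x)
}

#' Export fused features and a 2-D neighbour-graph projection
#'
#' Computes the fused feature of every patient, with and without the event
#' coordinate, and projects each variant to 2-D by classical scaling of
#' geodesic distances on the symmetrized k-nearest-neighbour graph
#' (an Isomap-style embedding; `neighbors` plays the usual local/global
#' trade-off role). Qualitative output for visual inspection.
#'
#' @param model a `fusion_model` or `fusion_fit`.
#' @param inputs,events the patient set.
#' @param neighbors neighbour count (>= 2, < number of patients).
#' @return list with `features_with`, `features_without` (matrices) and
#'   `projection_with`, `projection_without` (n x 2 matrices).
#' @export
project_features <- function(model, inputs, events, neighbors = 4) {
  if (inherits(model, "fusion_fit")) model <- model$model
  n <- length(inputs)
  if (neighbors < 2) stop("neighbors must be at least 2")
  if (n <= neighbors) stop("need more patients than neighbors")
  feats <- t(vapply(seq_len(n), function(i)
    model_forward(model, inputs[[i]], events[i])$fused,
    numeric(model$config$head_in)))
  fw <- feats
  fwo <- feats[, -ncol(feats), drop = FALSE]
  proj <- function(X) {
    D <- as.matrix(dist(X))
    edges <- NULL
    w <- NULL
    for (i in seq_len(n)) {
      nb <- order(D[i, ])[2:(neighbors + 1)]
      edges <- rbind(edges, cbind(i, nb))
      w <- c(w, D[i, nb])
    }
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    igraph::E(g)$weight <- w
    gd <- igraph::distances(g)
    fin <- gd[is.finite(gd)]
    gd[!is.finite(gd)] <- if (length(fin)) 2 * max(fin) else 1
    cmdscale(gd, k = 2)
  }
  list(features_with = fw, features_without = fwo,
       projection_with = proj(fw), projection_without = proj(fwo))
}
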