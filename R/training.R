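## Decoy labelling, mini-batch gradient-descent training, checkpoints.

#' Training configuration
#'
#' Defaults follow the published regime: initial learning rate 1e-4, batch
#' size 1, mean-squared-error objective, 20000 maximum steps (tests use toy
#' values).  Training stops early when the loss plateaus: the relative change
#' of the mean loss between two consecutive windows of `plateau_window` steps
#' falls below `plateau_tol`.
#'
#' @param learning_rate Positive step size (default 1e-4).
#' @param max_steps Maximum optimization steps (default 20000).
#' @param batch_size Decoys per step (default 1).
#' @param label_scheme `"irmsd_regression"` (label = interface RMSD in
#'   Angstrom; the native's label is 0) or `"native_binary"` (1 when
#'   interface RMSD <= 4 Angstrom).
#' @param seed Integer seed controlling initialization-independent sampling.
#' @param checkpoint_every Snapshot period in steps.
#' @param momentum SGD momentum coefficient (default 0 = plain SGD).
#' @param optimizer `"sgd"` (plain gradient descent, optionally with
#'   momentum) or `"adam"` (adaptive moments; recommended for the tiny
#'   overfitting runs used in tests, where the global-pooled representation
#'   makes the problem too ill-conditioned for plain SGD to memorize within
#'   a few hundred steps).
#' @param plateau_window,plateau_tol Plateau-stopping parameters; set
#'   `plateau_window = Inf` to disable.
#' @return A `training_config` list.
#' @export
training_config <- function(learning_rate = 1e-4, max_steps = 20000L,
                            batch_size = 1L,
                            label_scheme = c("irmsd_regression",
                                             "native_binary"),
                            seed = 1L, checkpoint_every = 100L,
                            momentum = 0, optimizer = c("sgd", "adam"),
                            plateau_window = 200L,
                            plateau_tol = 1e-4) {
  label_scheme <- match.arg(label_scheme)
  optimizer <- match.arg(optimizer)
  stopifnot(learning_rate >= 0, max_steps >= 1)  # lr 0 = frozen weights
  structure(list(learning_rate = learning_rate,
                 max_steps = as.integer(max_steps),
                 batch_size = as.integer(batch_size),
                 label_scheme = label_scheme, seed = as.integer(seed),
                 checkpoint_every = as.integer(checkpoint_every),
                 momentum = momentum, optimizer = optimizer,
                 plateau_window = plateau_window,
                 plateau_tol = plateau_tol),
            class = "training_config")
}

#' Label decoys against a native structure
#'
#' Featurizes every structure and attaches the training label: the interface
#' RMSD to the native (regression scheme) or the native-like indicator
#' (interface RMSD <= `threshold`, binary scheme).
#'
#' @param decoys Named list of `complex_structure` poses of the same complex
#'   (may include the native itself; its label is exactly 0 / 1).
#' @param native The native `complex_structure`.
#' @param scheme Label scheme, see [training_config()].
#' @param cutoff,L,grid_dim Featurization parameters.
#' @param rna_table,protein_table Atom type tables.
#' @param threshold Native-likeness threshold, 4.0 Angstrom.
#' @return List of `labeled_decoy` objects: `tensor`, `label`, `decoy_id`,
#'   `irmsd`.
#' @export
make_labels <- function(decoys, native,
                        scheme = c("irmsd_regression", "native_binary"),
                        cutoff = 6.0, L = 128L, grid_dim = 32L,
                        rna_table = atom_type_table("rna"),
                        protein_table = atom_type_table("protein"),
                        threshold = 4.0) {
  scheme <- match.arg(scheme)
  if (missing(native) || is.null(native))
    stop("a native structure is required for labelling", call. = FALSE)
  if (is.null(names(decoys)))
    names(decoys) <- sprintf("decoy_%03d", seq_along(decoys))
  native_t <- assign_types(native, rna_table, protein_table)
  lapply(names(decoys), function(id) {
    dec <- decoys[[id]]
    ir <- interface_rmsd(native_t, dec, cutoff = cutoff)
    dec_t <- assign_types(dec, rna_table, protein_table)
    tensor <- featurize_structure(dec_t, cutoff = cutoff, L = L,
                                  grid_dim = grid_dim)
    label <- if (scheme == "irmsd_regression") ir
             else as.numeric(ir <= threshold)
    structure(list(tensor = tensor, label = label, decoy_id = id, irmsd = ir),
              class = "labeled_decoy")
  })
}

opt_update <- function(model, config, state, step) {
  envs <- param_envs(model)
  lr <- config$learning_rate
  for (i in seq_along(envs)) {
    pe <- envs[[i]]
    for (p in intersect(names(grad_fields), ls(pe))) {
      g <- get(grad_fields[[p]], envir = pe)
      key <- paste0(i, ".", p)
      if (config$optimizer == "adam") {
        b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
        m <- b1 * (if (is.null(state[[key]]$m)) 0 else state[[key]]$m) +
          (1 - b1) * g
        v <- b2 * (if (is.null(state[[key]]$v)) 0 else state[[key]]$v) +
          (1 - b2) * g^2
        state[[key]] <- list(m = m, v = v)
        mhat <- m / (1 - b1^step)
        vhat <- v / (1 - b2^step)
        assign(p, get(p, envir = pe) - lr * mhat / (sqrt(vhat) + eps),
               envir = pe)
      } else if (config$momentum > 0) {
        v <- config$momentum *
          (if (is.null(state[[key]])) 0 else state[[key]]) - lr * g
        state[[key]] <- v
        assign(p, get(p, envir = pe) + v, envir = pe)
      } else {
        assign(p, get(p, envir = pe) - lr * g, envir = pe)
      }
    }
  }
  state
}

#' Train a scoring model
#'
#' Mini-batch gradient descent on the mean squared error between predicted
#' scores and labels.  Fully deterministic for a fixed `config$seed`.
#'
#' @param model An `rp_model` from [build_4dcnn()] or [build_3dcnn()].
#' @param dataset List of `labeled_decoy` objects (see [make_labels()]).
#' @param config A [training_config()].
#' @param checkpoint_dir Optional directory; periodic checkpoints are written
#'   there as `step_<n>.rds`.
#' @return List: `model` (trained, in place), `loss_trace` (data frame
#'   `step`, `loss`), `checkpoints` (data frame `step`, `eval_loss`, `path`),
#'   `selected_step` (checkpoint with the lowest full-dataset evaluation
#'   loss), `stopped_early`.
#' @export
train <- function(model, dataset, config = training_config(),
                  checkpoint_dir = NULL) {
  stopifnot(length(dataset) >= 1)
  set.seed(config$seed)
  if (!is.null(checkpoint_dir))
    dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
  losses <- numeric(0)
  opt_state <- list()
  ckpt <- list()
  eval_loss <- function() {
    mean(vapply(dataset, function(d)
      (model_forward(model, d$tensor, FALSE)$score - d$label)^2, 0))
  }
  take_checkpoint <- function(step) {
    el <- eval_loss()
    path <- NA_character_
    if (!is.null(checkpoint_dir)) {
      path <- file.path(checkpoint_dir, sprintf("step_%06d.rds", step))
      save_checkpoint(model, path)
    }
    ckpt[[length(ckpt) + 1L]] <<- list(step = step, eval_loss = el,
                                       path = path,
                                       state = model_state(model))
  }
  stopped_early <- FALSE
  for (step in seq_len(config$max_steps)) {
    idx <- sample.int(length(dataset), config$batch_size, replace = TRUE)
    zero_grads(model)
    step_loss <- 0
    for (i in idx) {
      fw <- model_forward(model, dataset[[i]]$tensor, training = TRUE)
      err <- fw$score - dataset[[i]]$label
      step_loss <- step_loss + err^2 / length(idx)
      model_backward(model, fw, 2 * err / length(idx))
    }
    if (!is.finite(step_loss)) {
      last <- if (length(ckpt)) ckpt[[length(ckpt)]]$step else NA_integer_
      stop("training diverged (non-finite loss) at step ", step,
           "; last good checkpoint: step ", last, call. = FALSE)
    }
    opt_state <- opt_update(model, config, opt_state, step)
    losses[step] <- step_loss
    if (step %% config$checkpoint_every == 0L) take_checkpoint(step)
    w <- config$plateau_window
    if (is.finite(w) && step >= 2 * w) {
      recent <- mean(losses[(step - w + 1):step])
      prev <- mean(losses[(step - 2 * w + 1):(step - w)])
      if (abs(prev - recent) < config$plateau_tol * max(prev, 1e-12)) {
        stopped_early <- TRUE
        break
      }
    }
  }
  if (length(ckpt) == 0L || ckpt[[length(ckpt)]]$step != length(losses))
    take_checkpoint(length(losses))
  cds <- data.frame(step = vapply(ckpt, `[[`, 0, "step"),
                    eval_loss = vapply(ckpt, `[[`, 0, "eval_loss"),
                    path = vapply(ckpt, `[[`, "", "path"))
  selected <- cds$step[which.min(cds$eval_loss)]
  list(model = model,
       loss_trace = data.frame(step = seq_along(losses), loss = losses),
       checkpoints = cds, checkpoint_states = lapply(ckpt, `[[`, "state"),
       selected_step = selected, stopped_early = stopped_early)
}

#' Save / load model checkpoints
#'
#' A checkpoint bundles the model kind, its configuration and all parameter
#' and batch-normalization state; loading rebuilds the model and restores the
#' weights bit-identically.
#'
#' @param model An `rp_model`.
#' @param path File path (`.rds`).
#' @return `save_checkpoint()`: `path` invisibly; `load_checkpoint()`: an
#'   `rp_model`.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(format = "rpscore_checkpoint", version = 1L,
              kind = model$kind, config = model$config,
              base_channels = if (model$kind == "3dcnn")
                model$channels[1] else NULL,
              state = model_state(model))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path))
    stop("checkpoint file not found: ", path, call. = FALSE)
  obj <- readRDS(path)
  if (!identical(obj$format, "rpscore_checkpoint"))
    stop("not an rpscore checkpoint: ", path, call. = FALSE)
  model <- if (obj$kind == "4dcnn") build_4dcnn(obj$config)
           else build_3dcnn(obj$config, base_channels = obj$base_channels)
  restore_state(model, obj$state)
  model
}

#' Score and rank a set of decoys
#'
#' Scores every tensor in evaluation mode and ranks them: ascending score for
#' a regression head (lower predicted interface RMSD is better), descending
#' for a classification head.  Ties are broken by `decoy_id` so rankings are
#' reproducible.
#'
#' @param model An `rp_model` or a checkpoint path.
#' @param tensors Named list of `complex_tensor` objects (names are decoy
#'   ids), or a list of `labeled_decoy` objects.
#' @return Data frame `decoy_id`, `score`, `rank`, ordered best-first.
#' @export
score_decoys <- function(model, tensors) {
  if (is.character(model)) model <- load_checkpoint(model)
  if (length(tensors) && inherits(tensors[[1]], "labeled_decoy")) {
    names(tensors) <- vapply(tensors, `[[`, "", "decoy_id")
    tensors <- lapply(tensors, `[[`, "tensor")
  }
  if (is.null(names(tensors)))
    names(tensors) <- sprintf("decoy_%03d", seq_along(tensors))
  scores <- vapply(tensors, function(tt) predict_score(model, tt), 0)
  out <- data.frame(decoy_id = names(tensors), score = unname(scores),
                    stringsAsFactors = FALSE)
  decreasing <- model$config$head == "classification"
  ord <- order(if (decreasing) -out$score else out$score, out$decoy_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
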