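## Sequence-spatial ("4D") convolutional scoring network and 3D baseline.
##
## Tensors are plain R arrays in channel-first, column-major layout:
##   4D network input: (C, L, H, W, D);  3D baseline per-unit input: (C, H, W, D).
## A "4D convolution" here is a genuine 4-axis kernel (3 along the sequence
## dimension and 3x3x3 spatially) realized by im2col + matrix multiply, with
## stride only on the sequence axis and same-padding everywhere; all spatial
## downsampling is delegated to 2x2x2 max-pooling.  Layers are functional:
## forward returns (y, cache); backward consumes (cache, dy), accumulates
## parameter gradients in the layer's environment and returns dx.

## ---- index machinery ------------------------------------------------------

# im2col indices for an n-d convolution, kernel 3 per axis, padding 1,
# stride s1 on the first axis and 1 elsewhere.  `dims` excludes the channel.
convnd_indices <- function(C, dims, s1) {
  nd <- length(dims)
  dp <- dims + 2L
  mult <- cumprod(c(1, dp[-nd]))          # per-axis multiplier after channel
  out_dims <- dims
  out_dims[1] <- (dims[1] - 1L) %/% s1 + 1L
  oc <- as.matrix(do.call(expand.grid,
                          lapply(out_dims, function(n) 0:(n - 1))))
  oc[, 1] <- oc[, 1] * s1                  # 0-based window start in padded axis
  posbase <- as.vector(C * (oc %*% mult))
  ko <- as.matrix(do.call(expand.grid,
                          c(list(ch = 1:C), rep(list(0:2), nd))))
  kerbase <- as.vector(ko[, 1] + C * (ko[, -1, drop = FALSE] %*% mult))
  list(idx = outer(posbase, kerbase, "+"), out_dims = out_dims,
       pad_dims = c(C, dp))
}

pad_input <- function(x) {
  d <- dim(x)
  out <- array(0, c(d[1], d[-1] + 2L))
  sub <- c(list(seq_len(d[1])), lapply(d[-1], function(n) 1L + seq_len(n)))
  do.call(`[<-`, c(list(out), sub, list(value = x)))
}

unpad_grad <- function(xp, dims) {
  C <- dim(xp)[1]
  sub <- c(list(seq_len(C)), lapply(dims, function(n) 1L + seq_len(n)))
  do.call(`[`, c(list(xp), sub, list(drop = FALSE)))
}

# max-pool (kernel 2, stride 2) indices over the axes flagged in `pool_axes`
pool_indices <- function(C, dims, pool_axes) {
  nd <- length(dims)
  mult <- C * cumprod(c(1, dims[-nd]))
  out_dims <- ifelse(pool_axes, dims %/% 2L, dims)
  oc <- as.matrix(do.call(expand.grid,
                          c(list(ch = 1:C),
                            lapply(out_dims, function(n) 0:(n - 1)))))
  base <- oc[, -1, drop = FALSE]
  base[, pool_axes] <- base[, pool_axes, drop = FALSE] * 2L
  posbase <- as.vector(oc[, 1] + base %*% mult)
  offs <- as.matrix(do.call(expand.grid,
                            lapply(pool_axes, function(p) if (p) 0:1 else 0L)))
  offs <- unique(offs)
  offbase <- as.vector(offs %*% mult)
  list(idx = outer(posbase, offbase, "+"), out_dims = out_dims)
}

## ---- layers ---------------------------------------------------------------

layer_conv <- function(C_in, C_out, stride1, nd) {
  pe <- new.env(parent = emptyenv())
  ksize <- 3L^nd
  fan_in <- C_in * ksize
  pe$W <- matrix(stats::rnorm(fan_in * C_out, sd = sqrt(2 / fan_in)),
                 fan_in, C_out)
  pe$b <- numeric(C_out)
  pe$gW <- pe$W * 0; pe$gb <- numeric(C_out)
  pe$C_in <- C_in; pe$C_out <- C_out; pe$stride <- stride1
  pe$idx_cache <- list()
  list(type = "conv", pe = pe)
}

conv_fwd <- function(lay, x, training) {
  pe <- lay$pe
  d <- dim(x)
  key <- paste(d, collapse = "x")
  ii <- pe$idx_cache[[key]]
  if (is.null(ii)) {
    ii <- convnd_indices(d[1], d[-1], pe$stride)
    pe$idx_cache[[key]] <- ii
  }
  xp <- pad_input(x)
  M <- matrix(xp[ii$idx], nrow(ii$idx), ncol(ii$idx))
  Y <- M %*% pe$W + rep(pe$b, each = nrow(ii$idx))
  y <- array(t(Y), c(pe$C_out, ii$out_dims))
  list(y = y, cache = list(M = M, ii = ii, dims = d[-1], C = d[1],
                           np = length(xp)))
}

conv_bwd <- function(lay, cache, dy) {
  pe <- lay$pe
  P <- nrow(cache$M)
  dYm <- t(matrix(dy, pe$C_out, P))
  pe$gW <- pe$gW + crossprod(cache$M, dYm)
  pe$gb <- pe$gb + colSums(dYm)
  dM <- tcrossprod(dYm, pe$W)
  rs <- rowsum(as.vector(dM), as.vector(cache$ii$idx))
  dxp <- numeric(cache$np)
  dxp[as.numeric(rownames(rs))] <- rs[, 1]
  unpad_grad(array(dxp, c(cache$C, cache$dims + 2L)), cache$dims)
}

layer_bn <- function(C, mode = "instance", momentum = 0.1, eps = 1e-5) {
  pe <- new.env(parent = emptyenv())
  pe$gamma <- rep(1, C); pe$beta <- numeric(C)
  pe$ggamma <- numeric(C); pe$gbeta <- numeric(C)
  pe$run_mean <- numeric(C); pe$run_var <- rep(1, C)
  pe$momentum <- momentum; pe$eps <- eps; pe$C <- C; pe$mode <- mode
  list(type = "bn", pe = pe)
}

bn_fwd <- function(lay, x, training) {
  pe <- lay$pe
  d <- dim(x)
  xm <- matrix(x, pe$C)
  # "instance" mode normalizes by the current sample's statistics in both
  # training and evaluation - the self-consistent choice for batch size 1;
  # "batch" mode uses running statistics at evaluation time
  use_current <- training || pe$mode == "instance"
  if (use_current) {
    mu <- rowMeans(xm)
    xc <- xm - mu
    v <- rowMeans(xc^2)
    if (training) {
      pe$run_mean <- (1 - pe$momentum) * pe$run_mean + pe$momentum * mu
      pe$run_var <- (1 - pe$momentum) * pe$run_var + pe$momentum * v
    }
  } else {
    mu <- pe$run_mean
    xc <- xm - mu
    v <- pe$run_var
  }
  inv <- 1 / sqrt(v + pe$eps)
  xhat <- xc * inv
  y <- array(pe$gamma * xhat + pe$beta, d)
  list(y = y, cache = list(xhat = xhat, inv = inv, d = d,
                           current = use_current))
}

bn_bwd <- function(lay, cache, dy) {
  pe <- lay$pe
  dym <- matrix(dy, pe$C)
  pe$ggamma <- pe$ggamma + rowSums(dym * cache$xhat)
  pe$gbeta <- pe$gbeta + rowSums(dym)
  dxhat <- dym * pe$gamma
  if (cache$current) {
    P <- ncol(dym)
    dx <- (cache$inv / P) *
      (P * dxhat - rowSums(dxhat) - cache$xhat * rowSums(dxhat * cache$xhat))
  } else {
    dx <- dxhat * cache$inv
  }
  array(dx, cache$d)
}

layer_relu <- function() list(type = "relu", pe = new.env(parent = emptyenv()))

relu_fwd <- function(lay, x, training) {
  m <- x > 0
  list(y = x * m, cache = m)
}

relu_bwd <- function(lay, cache, dy) dy * cache

layer_pool <- function(pool_axes) {
  pe <- new.env(parent = emptyenv())
  pe$pool_axes <- pool_axes
  pe$idx_cache <- list()
  list(type = "pool", pe = pe)
}

pool_fwd <- function(lay, x, training) {
  pe <- lay$pe
  d <- dim(x)
  key <- paste(d, collapse = "x")
  ii <- pe$idx_cache[[key]]
  if (is.null(ii)) {
    ii <- pool_indices(d[1], d[-1], pe$pool_axes)
    pe$idx_cache[[key]] <- ii
  }
  vals <- matrix(x[ii$idx], nrow(ii$idx), ncol(ii$idx))
  mc <- max.col(vals, ties.method = "first")
  sel <- ii$idx[cbind(seq_len(nrow(vals)), mc)]
  y <- array(x[sel], c(d[1], ii$out_dims))
  list(y = y, cache = list(sel = sel, n_in = length(x), d_in = d))
}

pool_bwd <- function(lay, cache, dy) {
  dx <- numeric(cache$n_in)
  dx[cache$sel] <- dy        # 2x2 windows are disjoint
  array(dx, cache$d_in)
}

run_fwd <- function(lay, x, training) {
  switch(lay$type,
         conv = conv_fwd(lay, x, training),
         bn = bn_fwd(lay, x, training),
         relu = relu_fwd(lay, x, training),
         pool = pool_fwd(lay, x, training))
}

run_bwd <- function(lay, cache, dy) {
  switch(lay$type,
         conv = conv_bwd(lay, cache, dy),
         bn = bn_bwd(lay, cache, dy),
         relu = relu_bwd(lay, cache, dy),
         pool = pool_bwd(lay, cache, dy))
}

layer_linear <- function(n_in) {
  pe <- new.env(parent = emptyenv())
  pe$w <- stats::rnorm(n_in, sd = sqrt(1 / n_in))
  pe$b <- 0
  pe$gw <- numeric(n_in); pe$gb <- 0
  list(type = "linear", pe = pe)
}

## ---- configuration and shape tracing --------------------------------------

#' Network configuration
#'
#' Bundles the architecture hyperparameters.  Defaults reproduce the printed
#' schedule: five sequence-spatial convolution blocks with channels
#' `[64, 128, 256, 512, 512]`, sequence strides `[2, 2, 2, 1, 1]` and kernel
#' size 3, spatial 2x2x2 max-pooling after blocks 1-4, a global spatial
#' average after block 5, and one linear output layer.
#'
#' @param conv_channels Integer vector of length 5: output channels per block.
#' @param seq_strides Integer vector of length 5: sequence-axis strides.
#' @param batch_norm Apply batch normalization after each convolution.
#' @param norm_mode `"instance"` (normalize by the current sample's
#'   statistics in both training and evaluation; the self-consistent choice
#'   for the batch-size-1 regime used throughout) or `"batch"` (running
#'   statistics at evaluation time).
#' @param head `"regression"` (score approximates interface RMSD, lower is
#'   better) or `"classification"` (native-likeness logit, higher is better).
#' @param in_channels Input feature channels (occupancy, mass, charge = 3).
#' @param L Maximum sequence length (interface units), default 128.
#' @param grid_dim Voxel grid edge, default 32.
#' @return A `network_config` list.
#' @export
network_config <- function(conv_channels = c(64L, 128L, 256L, 512L, 512L),
                           seq_strides = c(2L, 2L, 2L, 1L, 1L),
                           batch_norm = TRUE,
                           norm_mode = c("instance", "batch"),
                           head = c("regression", "classification"),
                           in_channels = 3L, L = 128L, grid_dim = 32L) {
  head <- match.arg(head)
  norm_mode <- match.arg(norm_mode)
  if (length(conv_channels) != 5L || length(seq_strides) != 5L)
    stop("conv_channels and seq_strides must have length 5", call. = FALSE)
  if (L %% prod(seq_strides) != 0L)
    stop("L must be divisible by the product of seq_strides", call. = FALSE)
  structure(list(conv_channels = as.integer(conv_channels),
                 seq_strides = as.integer(seq_strides),
                 seq_kernel = 3L, batch_norm = isTRUE(batch_norm),
                 norm_mode = norm_mode,
                 head = head, in_channels = as.integer(in_channels),
                 L = as.integer(L), grid_dim = as.integer(grid_dim)),
            class = "network_config")
}

#' Symbolic shape trace of the sequence-spatial network
#'
#' Computes every intermediate shape of [build_4dcnn()] without allocating
#' weights.  For the default configuration on input `(1, 3, 128, 32, 32, 32)`
#' the trace reproduces the printed progression: block 1 convolution gives
#' `(64, 64, 32, 32, 32)` then pooling `16^3`; block 2 `(128, 32, 16^3)` then
#' `8^3`; block 3 `(256, 16, 4^3)`; block 4 `(512, 16, 2^3)`; block 5 keeps
#' `(512, 16, 2^3)` and the global spatial average leaves `512 x 16`,
#' flattening to a vector of length 8192.
#'
#' @param config A [network_config()].
#' @param L,grid_dim Optional input-shape overrides.
#' @return Data frame with one row per stage: `block`, `stage`
#'   (`"conv"`/`"pool"`/`"global_avg"`), `channels`, `seq_len`, `spatial`,
#'   plus attribute `flat_len` (flattened representation length).
#' @export
trace_shapes <- function(config = network_config(), L = config$L,
                         grid_dim = config$grid_dim) {
  seq_len_ <- as.integer(L)
  spatial <- as.integer(grid_dim)
  if (seq_len_ %% prod(config$seq_strides) != 0L)
    stop("sequence length not divisible by the stride product", call. = FALSE)
  rows <- list()
  for (b in 1:5) {
    seq_len_ <- (seq_len_ - 1L) %/% config$seq_strides[b] + 1L
    ch <- config$conv_channels[b]
    rows[[length(rows) + 1L]] <-
      data.frame(block = b, stage = "conv", channels = ch,
                 seq_len = seq_len_, spatial = spatial)
    if (b < 5L) {
      if (spatial %% 2L == 0L && spatial > 1L) spatial <- spatial %/% 2L
      rows[[length(rows) + 1L]] <-
        data.frame(block = b, stage = "pool", channels = ch,
                   seq_len = seq_len_, spatial = spatial)
    } else {
      spatial <- 1L
      rows[[length(rows) + 1L]] <-
        data.frame(block = b, stage = "global_avg", channels = ch,
                   seq_len = seq_len_, spatial = spatial)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "flat_len") <- out$channels[nrow(out)] * out$seq_len[nrow(out)]
  out
}

## ---- model builders -------------------------------------------------------

#' Build the sequence-spatial ("4D") scoring network
#'
#' Five blocks of 4-axis convolution (kernel 3 on the sequence axis with the
#' block's stride, 3x3x3 spatially with stride 1, same-padding), optional
#' batch normalization, rectified-linear activation and spatial max-pooling
#' (blocks 1-4; block 5 instead takes the global spatial average), followed
#' by one linear layer mapping the flattened `channels x sequence`
#' representation (8192 for the default configuration) to a scalar score.
#' Weights use seeded fan-in (He) initialization; biases start at zero, so an
#' all-zero input scores exactly the head bias when batch_norm is off.
#'
#' @param config A [network_config()].
#' @return An `rp_model` (kind `"4dcnn"`).
#' @export
build_4dcnn <- function(config = network_config()) {
  tr <- trace_shapes(config)
  conv_rows <- tr[tr$stage == "conv", ]
  blocks <- vector("list", 5L)
  C_in <- config$in_channels
  spatial <- config$grid_dim
  for (b in 1:5) {
    C_out <- config$conv_channels[b]
    ls <- list(layer_conv(C_in, C_out, config$seq_strides[b], nd = 4L))
    # batch-norm statistics need more than one position; skipped on blocks
    # whose conv output is a single (seq, spatial) cell (only happens at
    # reduced test sizes, never for the default 128 x 32^3 input)
    n_pos <- conv_rows$seq_len[b] * conv_rows$spatial[b]^3
    if (config$batch_norm && n_pos > 1L)
      ls <- c(ls, list(layer_bn(C_out, mode = config$norm_mode)))
    ls <- c(ls, list(layer_relu()))
    if (b < 5L && spatial %% 2L == 0L && spatial > 1L) {
      ls <- c(ls, list(layer_pool(c(FALSE, TRUE, TRUE, TRUE))))
      spatial <- spatial %/% 2L
    }
    blocks[[b]] <- ls
    C_in <- C_out
  }
  head <- layer_linear(attr(tr, "flat_len"))
  structure(list(kind = "4dcnn", config = config, blocks = blocks,
                 head = head, trace = tr),
            class = "rp_model")
}

#' Build the 3D convolutional baseline
#'
#' Processes each unit's voxel grid independently with a stack of 3x3x3
#' convolutions that doubles the channel count per block (64, 128, ... for
#' the default) while 2x2x2 max-pooling halves the spatial extent from
#' `grid_dim` down to 1, giving a per-unit representation of
#' `base_channels * 2^(n_blocks - 1)` channels at 1x1x1 (1024 for the 32-grid
#' default).  A mask-aware mean over real units yields the global
#' representation fed to a single linear layer.  Batch normalization (when
#' enabled) is skipped on blocks whose output spatial extent is 1, where
#' single-sample statistics are degenerate.
#'
#' @param config A [network_config()]; `grid_dim` must be a power of 2.
#' @param base_channels Channels of the first block (default 64).
#' @return An `rp_model` (kind `"3dcnn"`).
#' @export
build_3dcnn <- function(config = network_config(), base_channels = 64L) {
  g <- config$grid_dim
  n_blocks <- as.integer(round(log2(g)))
  if (2L^n_blocks != g)
    stop("grid_dim must be a power of 2 for the 3D baseline", call. = FALSE)
  channels <- base_channels * 2L^(seq_len(n_blocks) - 1L)
  blocks <- vector("list", n_blocks)
  C_in <- config$in_channels
  spatial <- g
  for (b in seq_len(n_blocks)) {
    C_out <- channels[b]
    ls <- list(layer_conv(C_in, C_out, 1L, nd = 3L))
    if (config$batch_norm && spatial %/% 2L > 1L)
      ls <- c(ls, list(layer_bn(C_out, mode = config$norm_mode)))
    ls <- c(ls, list(layer_relu()), list(layer_pool(c(TRUE, TRUE, TRUE))))
    spatial <- spatial %/% 2L
    blocks[[b]] <- ls
    C_in <- C_out
  }
  head <- layer_linear(channels[n_blocks])
  structure(list(kind = "3dcnn", config = config, blocks = blocks,
                 head = head, channels = channels),
            class = "rp_model")
}

#' @export
print.rp_model <- function(x, ...) {
  cat(sprintf("<rp_model %s: %d blocks, %d parameters, head=%s>\n",
              x$kind, length(x$blocks), n_params(x), x$config$head))
  invisible(x)
}

#' Number of trainable parameters
#' @param model An `rp_model`.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  n <- length(model$head$pe$w) + 1L
  for (blk in model$blocks)
    for (lay in blk)
      n <- n + switch(lay$type,
                      conv = length(lay$pe$W) + length(lay$pe$b),
                      bn = 2L * lay$pe$C,
                      0L)
  n
}

## ---- forward / backward ---------------------------------------------------

check_tensor_shape <- function(model, tensor) {
  d <- dim(tensor$data)
  cfg <- model$config
  want <- c(cfg$in_channels, cfg$L, rep(cfg$grid_dim, 3))
  if (!identical(as.integer(d), as.integer(want)))
    stop(sprintf("tensor shape mismatch: expected (%s), got (%s)",
                 paste(want, collapse = ", "), paste(d, collapse = ", ")),
         call. = FALSE)
}

# global spatial average of a (C, L, H, W, D) array -> length C*L vector
global_avg_spatial <- function(x) {
  d <- dim(x)
  rowMeans(matrix(x, d[1] * d[2]))
}

forward_4dcnn <- function(model, tensor, training = FALSE) {
  x <- tensor$data
  caches <- list()
  k <- 0L
  for (blk in model$blocks)
    for (lay in blk) {
      r <- run_fwd(lay, x, training)
      x <- r$y
      k <- k + 1L
      caches[[k]] <- r$cache
    }
  d5 <- dim(x)
  flat <- global_avg_spatial(x)
  pe <- model$head$pe
  score <- sum(pe$w * flat) + pe$b
  list(score = score, caches = caches, flat = flat, d5 = d5)
}

backward_4dcnn <- function(model, fw, dscore) {
  pe <- model$head$pe
  pe$gw <- pe$gw + fw$flat * dscore
  pe$gb <- pe$gb + dscore
  dflat <- pe$w * dscore
  d5 <- fw$d5
  nsp <- prod(d5[3:5])
  dx <- array(rep(dflat, times = nsp) / nsp, d5)
  layers <- unlist(model$blocks, recursive = FALSE)
  for (i in rev(seq_along(layers)))
    dx <- run_bwd(layers[[i]], fw$caches[[i]], dx)
  invisible(NULL)
}

forward_3dcnn <- function(model, tensor, training = FALSE) {
  real <- which(tensor$mask == 1L)
  if (length(real) == 0L) stop("tensor has no real units", call. = FALSE)
  layers <- unlist(model$blocks, recursive = FALSE)
  unit_caches <- vector("list", length(real))
  reps <- matrix(0, length(model$head$pe$w), length(real))
  for (j in seq_along(real)) {
    x <- array(tensor$data[, real[j], , , ],
               c(model$config$in_channels, rep(model$config$grid_dim, 3)))
    caches <- vector("list", length(layers))
    for (i in seq_along(layers)) {
      r <- run_fwd(layers[[i]], x, training)
      x <- r$y
      caches[[i]] <- r$cache
    }
    reps[, j] <- as.vector(x)
    unit_caches[[j]] <- caches
  }
  rep_mean <- rowMeans(reps)
  pe <- model$head$pe
  score <- sum(pe$w * rep_mean) + pe$b
  list(score = score, unit_caches = unit_caches, rep_mean = rep_mean,
       real = real)
}

backward_3dcnn <- function(model, fw, dscore) {
  pe <- model$head$pe
  pe$gw <- pe$gw + fw$rep_mean * dscore
  pe$gb <- pe$gb + dscore
  drep <- pe$w * dscore / length(fw$real)
  layers <- unlist(model$blocks, recursive = FALSE)
  C_last <- length(drep)
  for (j in seq_along(fw$real)) {
    dx <- array(drep, c(C_last, 1L, 1L, 1L))
    caches <- fw$unit_caches[[j]]
    for (i in rev(seq_along(layers)))
      dx <- run_bwd(layers[[i]], caches[[i]], dx)
  }
  invisible(NULL)
}

model_forward <- function(model, tensor, training = FALSE) {
  check_tensor_shape(model, tensor)
  if (model$kind == "4dcnn") forward_4dcnn(model, tensor, training)
  else forward_3dcnn(model, tensor, training)
}

model_backward <- function(model, fw, dscore) {
  if (model$kind == "4dcnn") backward_4dcnn(model, fw, dscore)
  else backward_3dcnn(model, fw, dscore)
}

#' Score one complex tensor
#'
#' Runs a forward pass in evaluation mode (batch normalization uses running
#' statistics) and returns the scalar score.
#'
#' @param model An `rp_model`.
#' @param tensor A `complex_tensor` from [assemble_tensor()].
#' @return Finite numeric scalar.
#' @export
predict_score <- function(model, tensor) {
  model_forward(model, tensor, training = FALSE)$score
}

## ---- parameter state (checkpoints) ----------------------------------------

param_envs <- function(model) {
  envs <- list()
  for (blk in model$blocks)
    for (lay in blk)
      if (lay$type %in% c("conv", "bn")) envs[[length(envs) + 1L]] <- lay$pe
  envs[[length(envs) + 1L]] <- model$head$pe
  envs
}

param_fields <- c("W", "b", "gamma", "beta", "run_mean", "run_var", "w")
grad_fields <- c(W = "gW", b = "gb", gamma = "ggamma", beta = "gbeta",
                 w = "gw")

model_state <- function(model) {
  lapply(param_envs(model), function(pe)
    mget(intersect(param_fields, ls(pe)), envir = pe))
}

restore_state <- function(model, state) {
  envs <- param_envs(model)
  stopifnot(length(envs) == length(state))
  for (i in seq_along(envs))
    for (nm in names(state[[i]]))
      assign(nm, state[[i]][[nm]], envir = envs[[i]])
  invisible(model)
}

zero_grads <- function(model) {
  for (pe in param_envs(model)) {
    if (!is.null(pe$W)) { pe$gW <- pe$W * 0; pe$gb <- pe$b * 0 }
    if (!is.null(pe$gamma)) { pe$ggamma <- pe$gamma * 0
                              pe$gbeta <- pe$beta * 0 }
    if (!is.null(pe$w)) { pe$gw <- pe$w * 0; pe$gb <- 0 }
  }
  invisible(model)
}
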