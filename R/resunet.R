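#' Residual U-Net architecture configuration
#'
#' The network is an encoder-bridge-decoder with pre-activation residual
#' units and U-Net skip concatenations. Encoder level i works at
#' `base_filters * 2^(i-1)` channels and halves the spatial grid from
#' level 2 on (stride-2 first convolution); the bridge doubles once more;
#' each decoder level up-samples by 2 (nearest neighbour), concatenates the
#' mirror encoder output along channels, and convolves back down to the
#' mirror's channel count; a 1x1 convolution plus sigmoid produces the
#' per-pixel fluid probability.
#'
#' @param n_blocks Residual blocks per side (encoder depth, excluding the
#'   bridge), in 2..5; default 4.
#' @param convs_per_block Convolutions in each residual unit, in 2..4;
#'   default 2.
#' @param base_filters Filters at the first encoder level; default 32
#'   (doubling to 512 at the bridge for the default depth).
#' @param kernel_size Convolution kernel side, default 3.
#' @param input_size Input grid side, default 256; must be divisible by
#'   `2^n_blocks`.
#' @param in_channels Input channels, default 3 (replicated grayscale).
#' @param seed Seed for weight initialisation (He-uniform).
#' @return Object of class `resunet_config`.
#' @export
resunet_config <- function(n_blocks = 4, convs_per_block = 2,
                           base_filters = 32, kernel_size = 3,
                           input_size = 256, in_channels = 3, seed = 1L) {
  if (!n_blocks %in% 2:5)
    stop_user("`n_blocks` must be one of 2, 3, 4, 5 (got ", n_blocks, ")")
  if (!convs_per_block %in% 2:4)
    stop_user("`convs_per_block` must be one of 2, 3, 4 (got ",
              convs_per_block, ")")
  if (base_filters < 1) stop_user("`base_filters` must be positive")
  if (input_size %% 2^n_blocks != 0)
    stop_user("`input_size` must be divisible by 2^n_blocks = ", 2^n_blocks)
  structure(list(n_blocks = as.integer(n_blocks),
                 convs_per_block = as.integer(convs_per_block),
                 base_filters = as.integer(base_filters),
                 kernel_size = as.integer(kernel_size),
                 input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels),
                 seed = as.integer(seed)),
            class = "resunet_config")
}

# Per-block channel/stride/size arithmetic shared by layer_shapes() and the
# builder, so declared and realised shapes cannot drift apart.
block_plan <- function(config) {
  n <- config$n_blocks; f <- config$base_filters; S <- config$input_size
  enc <- lapply(seq_len(n), function(i) {
    list(part = "encoder", name = sprintf("residual block %d", i),
         cin = if (i == 1) config$in_channels else f * 2^(i - 2),
         cout = f * 2^(i - 1), stride = if (i == 1) 1L else 2L,
         size = S / 2^(i - 1))
  })
  bridge <- list(part = "bridge", name = sprintf("residual block %d", n + 1),
                 cin = f * 2^(n - 1), cout = f * 2^n, stride = 2L,
                 size = S / 2^n)
  dec <- lapply(rev(seq_len(n)), function(i) {
    prev_c <- if (i == n) f * 2^n else f * 2^i
    list(part = "decoder",
         name = sprintf("residual block %d", n + 1 + (n - i + 1)),
         cin = prev_c + f * 2^(i - 1),  # up-sampled previous + encoder skip
         cout = f * 2^(i - 1), stride = 1L, size = S / 2^(i - 1),
         mirror = i)
  })
  c(enc, list(bridge), dec)
}

#' Declared layer shapes of a configuration
#'
#' Pure arithmetic over the configuration — no weights are allocated. The
#' realised tensor shapes of a built model match these rows exactly.
#'
#' @param config A [resunet_config()].
#' @return Data frame with `part`, `name`, `height`, `width`, `channels`,
#'   one row per convolutional layer plus input/head/sigmoid rows.
#' @export
layer_shapes <- function(config) {
  stopifnot(inherits(config, "resunet_config"))
  S <- config$input_size
  rows <- list(data.frame(part = "input", name = "input", height = S,
                          width = S, channels = config$in_channels))
  li <- 0
  for (b in block_plan(config)) {
    for (j in seq_len(config$convs_per_block)) {
      li <- li + 1
      rows[[length(rows) + 1]] <-
        data.frame(part = b$part,
                   name = sprintf("%s conv %d (convolutional layer %d)",
                                  b$name, j, li),
                   height = b$size, width = b$size, channels = b$cout)
    }
  }
  rows[[length(rows) + 1]] <- data.frame(part = "output",
                                         name = sprintf("convolutional layer %d (1x1)", li + 1),
                                         height = S, width = S, channels = 1)
  rows[[length(rows) + 1]] <- data.frame(part = "output", name = "sigmoid",
                                         height = S, width = S, channels = 1)
  do.call(rbind, rows)
}

he_uniform <- function(k, cin, cout) {
  limit <- sqrt(6 / (k * k * cin))
  array(runif(k * k * cin * cout, -limit, limit), dim = c(k, k, cin, cout))
}

init_block <- function(b, convs, k) {
  p <- list(convs = vector("list", convs))
  st <- list(convs = vector("list", convs))
  cin <- b$cin
  for (j in seq_len(convs)) {
    p$convs[[j]] <- list(bn = list(gamma = rep(1, cin), beta = rep(0, cin)),
                         w = he_uniform(k, cin, b$cout), b = rep(0, b$cout))
    st$convs[[j]] <- list(mean = rep(0, cin), var = rep(1, cin))
    cin <- b$cout
  }
  if (b$stride != 1 || b$cin != b$cout)
    p$proj <- list(w = he_uniform(1, b$cin, b$cout), b = rep(0, b$cout))
  list(p = p, st = st)
}

#' Build an untrained residual U-Net
#'
#' Allocates and initialises all weights (He-uniform, seeded from
#' `config$seed`; batch-norm scale 1 / shift 0; running statistics 0/1).
#' Building twice from the same configuration yields identical weights.
#'
#' @param config A [resunet_config()].
#' @return Object of class `resunet` (untrained).
#' @export
resunet <- function(config = resunet_config()) {
  stopifnot(inherits(config, "resunet_config"))
  plan <- block_plan(config)
  withr::with_seed(config$seed, {
    blocks <- lapply(plan, init_block, convs = config$convs_per_block,
                     k = config$kernel_size)
    f <- config$base_filters
    head <- list(w = he_uniform(1, f, 1), b = 0)
    structure(list(config = config,
                   params = list(blocks = lapply(blocks, `[[`, "p"),
                                 head = head),
                   bn_state = lapply(blocks, `[[`, "st"),
                   plan = plan, trained = FALSE, epochs = 0L,
                   history = NULL, train_config = NULL),
              class = "resunet")
  })
}

# Full forward pass. training = TRUE caches intermediates for backprop and
# updates batch-norm running statistics (returned in $bn_state).
resunet_forward <- function(model, x, training = FALSE) {
  cfg <- model$config; plan <- model$plan
  n <- cfg$n_blocks; k <- cfg$kernel_size
  p <- model$params; st <- model$bn_state
  caches <- vector("list", length(plan))
  skips <- vector("list", n)
  shapes <- list(input = dim(x)[c(1, 2, 4)])
  cur <- x
  concat_c1 <- integer(length(plan))
  for (bi in seq_along(plan)) {
    b <- plan[[bi]]
    if (b$part == "decoder") {
      up <- upsample2_fwd(cur)
      concat_c1[bi] <- dim(up)[4]
      cur <- concat_channels(up, skips[[b$mirror]])
    }
    r <- res_block_fwd(cur, p$blocks[[bi]], st[[bi]], b$stride, k, training)
    st[[bi]] <- r$state
    if (training) caches[[bi]] <- c(r$cache, list(block_in = cur))
    cur <- r$out
    shapes[[b$name]] <- dim(cur)[c(1, 2, 4)]
    if (b$part == "encoder") skips[[bi]] <- cur
  }
  z <- conv_fwd(cur, p$head, 1, 0)
  prob <- sigmoid(z)
  shapes[["head"]] <- dim(prob)[c(1, 2, 4)]
  list(prob = prob, bn_state = st,
       cache = if (training) list(blocks = caches, head_in = cur,
                                  concat_c1 = concat_c1) else NULL,
       shapes = shapes)
}

# Backward pass from the loss gradient w.r.t. the pre-sigmoid logits.
resunet_backward <- function(model, cache, dz) {
  cfg <- model$config; plan <- model$plan; k <- cfg$kernel_size
  p <- model$params
  hb <- conv_bwd(cache$head_in, p$head, dz, 1, 0)
  grads <- list(blocks = vector("list", length(plan)),
                head = list(w = hb$dw, b = hb$db))
  dcur <- hb$dx
  dskips <- vector("list", cfg$n_blocks)
  for (bi in rev(seq_along(plan))) {
    b <- plan[[bi]]
    if (b$part == "encoder" && !is.null(dskips[[bi]]))
      dcur <- dcur + dskips[[bi]]
    bb <- res_block_bwd(dcur, p$blocks[[bi]], cache$blocks[[bi]], b$stride, k)
    grads$blocks[[bi]] <- bb$grads
    dcur <- bb$dx
    if (b$part == "decoder") {
      sp <- split_channels_bwd(dcur, cache$concat_c1[bi])
      dskips[[b$mirror]] <- sp$db
      dcur <- upsample2_bwd(sp$da)
    }
  }
  grads
}

#' Predict per-pixel fluid probabilities
#'
#' Inference runs with batch normalisation in evaluation mode (running
#' statistics), so repeated calls on the same input are bit-identical.
#'
#' @param object A `resunet` model (trained or not).
#' @param newdata A `seg_data` set, an H x W x N x 3 array, or a single
#'   H x W x 3 input.
#' @param type `"prob"` for probabilities, `"mask"` for binarised masks.
#' @param threshold Binarisation threshold when `type = "mask"`.
#' @param batch_size Slices per forward pass.
#' @param ... Unused.
#' @return H x W x N x 1 array of probabilities in (0, 1), or of 0/1 values
#'   when `type = "mask"`.
#' @export
predict.resunet <- function(object, newdata, type = c("prob", "mask"),
                            threshold = 0.5, batch_size = 16, ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "seg_data")) newdata$x else newdata
  if (length(dim(x)) == 3) x <- array(x, dim = c(dim(x)[1:2], 1, dim(x)[3]))
  d <- dim(x)
  if (length(d) != 4 || d[1] != object$config$input_size ||
      d[2] != object$config$input_size || d[4] != object$config$in_channels)
    stop_user("input must be ", object$config$input_size, " x ",
              object$config$input_size, " x n x ", object$config$in_channels,
              " (got ", paste(d, collapse = " x "), ")")
  out <- array(0, dim = c(d[1], d[2], d[3], 1))
  for (ix in split(seq_len(d[3]), ceiling(seq_len(d[3]) / batch_size))) {
    fw <- resunet_forward(object, x[, , ix, , drop = FALSE], training = FALSE)
    out[, , ix, 1] <- fw$prob
  }
  out <- pmin(pmax(out, 1e-7), 1 - 1e-7)
  dim(out) <- c(d[1], d[2], d[3], 1)
  if (type == "mask") out <- (out >= threshold) + 0L
  out
}

#' Count model parameters
#'
#' Trainable: convolution weights and biases plus batch-norm scale/shift.
#' Non-trainable: batch-norm running means and variances.
#'
#' @param model A `resunet` model.
#' @return List with `trainable` and `non_trainable` integer counts.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "resunet"))
  list(trainable = as.integer(tree_count(model$params)),
       non_trainable = as.integer(tree_count(model$bn_state)))
}

#' @export
print.resunet <- function(x, ...) {
  cfg <- x$config
  pc <- count_parameters(x)
  cat(sprintf("Residual U-Net: %d residual blocks/side + bridge, %d convs/block, base %d filters, input %d x %d x %d\n",
              cfg$n_blocks, cfg$convs_per_block, cfg$base_filters,
              cfg$input_size, cfg$input_size, cfg$in_channels))
  cat(sprintf("  parameters: %s trainable, %s non-trainable\n",
              format(pc$trainable, big.mark = ","),
              format(pc$non_trainable, big.mark = ",")))
  cat(if (x$trained)
        sprintf("  trained for %d epoch(s), final training cost %.4f\n",
                x$epochs, utils::tail(x$history$train_cost, 1))
      else "  untrained\n")
  invisible(x)
}

#' @export
summary.resunet <- function(object, ...) {
  print(object)
  cat("\nLayer shapes (output size per convolutional layer):\n")
  sh <- layer_shapes(object$config)
  sh$output <- sprintf("%d x %d x %d", sh$height, sh$width, sh$channels)
  print(sh[, c("part", "name", "output")], row.names = FALSE, right = FALSE)
  invisible(sh)
}

#' @export
coef.resunet <- function(object, ...) {
  flat <- list()
  walk <- function(tree, path) {
    if (is.list(tree)) {
      nm <- names(tree) %||% seq_along(tree)
      for (i in seq_along(tree))
        walk(tree[[i]], paste0(path, ".", nm[i]))
    } else flat[[sub("^\\.", "", path)]] <<- tree
  }
  walk(object$params, "")
  flat
}

#' @export
plot.resunet <- function(x, ...) {
  if (is.null(x$history)) stop_user("model has no training history to plot")
  h <- x$history
  ylim <- range(c(h$train_cost, h$val_cost), na.rm = TRUE)
  graphics::plot(h$epoch, h$train_cost, type = "b", ylim = ylim,
                 xlab = "epoch", ylab = "BCE + Dice cost", ...)
  if (!all(is.na(h$val_cost)))
    graphics::lines(h$epoch, h$val_cost, type = "b", lty = 2, col = 2)
  graphics::legend("topright", c("training", "validation"),
                   lty = 1:2, col = 1:2, bty = "n")
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint bundles the weights, batch-norm statistics,
#' configuration, training settings and history; loading restores a model
#' whose predictions are bit-identical to the saved one.
#'
#' @param model A `resunet` model.
#' @param path Checkpoint path (`.rds`).
#' @return `save_model()` the path invisibly; `load_model()` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "resunet"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "resunet")) stop_user(path, " is not a resunet checkpoint")
  m
}
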