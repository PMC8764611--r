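#' Training protocol settings
#'
#' Defaults follow the reference protocol: Adam with learning rate 1e-4,
#' batch size 16, equal-weight binary cross-entropy + Dice loss, 5-fold
#' stratified cross-validation, and epoch selection by the lowest mean
#' validation cost (no early stopping inside folds).
#'
#' @param learning_rate Adam learning rate, default 1e-4.
#' @param batch_size Images per optimisation step, default 16.
#' @param max_epochs Epochs per fold / final fit, default 50.
#' @param loss_weights Named vector `c(bce = , dice = )`, default both 1.
#' @param k_folds Folds for cross-validation, default 5 (>= 2).
#' @param seed Seed governing fold assignment, weight init offsets and
#'   per-epoch shuffling.
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 16,
                         max_epochs = 50, loss_weights = c(bce = 1, dice = 1),
                         k_folds = 5, seed = 1L) {
  if (learning_rate <= 0 || batch_size <= 0 || max_epochs <= 0)
    stop_user("learning rate, batch size and max_epochs must be positive")
  if (k_folds < 2) stop_user("`k_folds` must be at least 2")
  if (any(loss_weights < 0)) stop_user("loss weights must be non-negative")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 loss_weights = loss_weights,
                 k_folds = as.integer(k_folds), seed = as.integer(seed)),
            class = "train_config")
}

#' Combined binary cross-entropy and soft Dice loss
#'
#' loss = w_bce * mean pixelwise BCE +
#'        w_dice * (1 - (2 sum(p g) + eps) / (sum p + sum g + eps)).
#' The Dice term is computed over the whole batch; the smoothing constant
#' eps (default 1) keeps it defined and stable on empty masks.
#'
#' @param probabilities Predicted probabilities in (0, 1) (any array).
#' @param truth Binary ground truth of the same shape.
#' @param weights Named vector `c(bce = , dice = )`.
#' @param eps Dice smoothing constant.
#' @return Scalar loss with attributes `bce` and `dice` (the unweighted
#'   terms).
#' @export
bce_dice_loss <- function(probabilities, truth, weights = c(bce = 1, dice = 1),
                          eps = 1) {
  if (!identical(dim(probabilities), dim(truth)) &&
      length(probabilities) != length(truth))
    stop_user("probability and truth shapes differ")
  p <- pmin(pmax(probabilities, 1e-7), 1 - 1e-7)
  g <- truth
  bce <- -mean(g * log(p) + (1 - g) * log(1 - p))
  dice <- 1 - (2 * sum(p * g) + eps) / (sum(p) + sum(g) + eps)
  structure(weights[["bce"]] * bce + weights[["dice"]] * dice,
            bce = bce, dice = dice)
}

# Gradient of the combined loss w.r.t. the pre-sigmoid logits z
# (p = sigmoid(z)). BCE through sigmoid: (p - g)/n; Dice by quotient rule
# chained through p(1-p).
bce_dice_grad_z <- function(p, g, weights, eps = 1) {
  n <- length(p)
  dz <- weights[["bce"]] * (p - g) / n
  denom <- sum(p) + sum(g) + eps
  num <- 2 * sum(p * g) + eps
  ddice_dp <- -(2 * g * denom - num) / denom^2
  dz + weights[["dice"]] * ddice_dp * p * (1 - p)
}

#' Stratified k-fold assignment
#'
#' Every entry receives exactly one fold id in 0..k-1; within each class
#' the fold sizes differ by at most one. Deterministic given `seed`.
#'
#' @param labels Vector of class labels (one per entry), or a manifest data
#'   frame with a `has_ascites` column.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in 0..k-1.
#' @export
make_folds <- function(labels, k, seed = 1L) {
  if (is.data.frame(labels)) labels <- labels$has_ascites
  n <- length(labels)
  folds <- integer(n)
  withr::with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < k)
        stop_user("class `", cl, "` has ", length(idx),
                  " entries, fewer than k = ", k)
      folds[sample(idx)] <- rep_len(seq_len(k) - 1L, length(idx))
    }
  })
  folds
}

# --- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  zero <- function(x) array(0, dim = dim(x) %||% length(x))
  list(m = tree_zip(zero, params), v = tree_zip(zero, params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_zip(function(m, g) beta1 * m + (1 - beta1) * g,
                      state$m, grads)
  state$v <- tree_zip(function(v, g) beta2 * v + (1 - beta2) * g * g,
                      state$v, grads)
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  params <- tree_zip(function(p, m, v) p - lr * (m / c1) / (sqrt(v / c2) + eps),
                     params, state$m, state$v)
  list(params = params, state = state)
}

# One optimisation pass over (x, y); returns the updated model/opt state and
# the mean per-batch costs. Batch order reshuffles each epoch from a
# seed derived from (seed, epoch).
run_epoch <- function(model, opt, x, y, tc, epoch) {
  n <- dim(x)[3]
  order <- withr::with_seed(tc$seed + 131L * epoch,
                            sample.int(n))
  batches <- split(order, ceiling(seq_along(order) / tc$batch_size))
  costs <- bces <- dices <- numeric(length(batches))
  for (bi in seq_along(batches)) {
    ix <- batches[[bi]]
    xb <- x[, , ix, , drop = FALSE]; yb <- y[, , ix, , drop = FALSE]
    fw <- resunet_forward(model, xb, training = TRUE)
    model$bn_state <- fw$bn_state
    p <- pmin(pmax(fw$prob, 1e-7), 1 - 1e-7)
    loss <- bce_dice_loss(p, yb, tc$loss_weights)
    if (!is.finite(loss))
      stop_user("non-finite loss at epoch ", epoch, ", batch ", bi,
                "; aborting (bce = ", attr(loss, "bce"),
                ", dice = ", attr(loss, "dice"), ")")
    costs[bi] <- loss; bces[bi] <- attr(loss, "bce")
    dices[bi] <- attr(loss, "dice")
    dz <- bce_dice_grad_z(p, yb, tc$loss_weights)
    grads <- resunet_backward(model, fw$cache, dz)
    st <- adam_step(model$params, grads, opt, tc$learning_rate)
    model$params <- st$params; opt <- st$state
  }
  list(model = model, opt = opt, cost = mean(costs), bce = mean(bces),
       dice = mean(dices))
}

eval_cost <- function(model, x, y, tc, batch_size = 16) {
  p <- predict(model, x, batch_size = batch_size)
  as.numeric(bce_dice_loss(p, y, tc$loss_weights))
}

#' Fit a residual U-Net
#'
#' Trains a freshly initialised network on a preprocessed dataset with
#' Adam under the combined BCE + Dice loss. This is the final-fit stage:
#' run [resunet_cv()] first to pick `epochs`, then fit on the full
#' training set.
#'
#' @param data A `seg_data` set (see [preprocess_dataset()] /
#'   [balance_and_augment()]), or a list with arrays `x` (S x S x N x 3)
#'   and `y` (S x S x N x 1).
#' @param model_config A [resunet_config()].
#' @param train_config A [train_config()].
#' @param epochs Number of epochs; defaults to `train_config$max_epochs`
#'   (pass the best epoch from cross-validation).
#' @param validation Optional held-out `seg_data` monitored per epoch.
#' @param verbose Print per-epoch costs.
#' @return A trained `resunet` object with a `history` data frame
#'   (epoch, train_cost, train_bce, train_dice, val_cost).
#' @export
resunet_fit <- function(data, model_config = resunet_config(),
                        train_config = resunetCT::train_config(),
                        epochs = train_config$max_epochs,
                        validation = NULL, verbose = FALSE) {
  x <- data$x; y <- data$y
  if (is.null(x) || dim(x)[3] == 0) stop_user("no training data provided")
  if (dim(x)[1] != model_config$input_size)
    stop_user("data grid (", dim(x)[1], ") does not match model input_size (",
              model_config$input_size, ")")
  model <- resunet(model_config)
  opt <- adam_init(model$params)
  hist <- data.frame(epoch = seq_len(epochs), train_cost = NA_real_,
                     train_bce = NA_real_, train_dice = NA_real_,
                     val_cost = NA_real_)
  for (e in seq_len(epochs)) {
    r <- run_epoch(model, opt, x, y, train_config, e)
    model <- r$model; opt <- r$opt
    hist$train_cost[e] <- r$cost; hist$train_bce[e] <- r$bce
    hist$train_dice[e] <- r$dice
    if (!is.null(validation))
      hist$val_cost[e] <- eval_cost(model, validation$x, validation$y,
                                    train_config)
    if (verbose)
      message(sprintf("epoch %d/%d  train %.4f (bce %.4f, dice %.4f)%s",
                      e, epochs, r$cost, r$bce, r$dice,
                      if (!is.null(validation))
                        sprintf("  val %.4f", hist$val_cost[e]) else ""))
  }
  model$trained <- TRUE
  model$epochs <- as.integer(epochs)
  model$history <- hist
  model$train_config <- train_config
  model
}

#' Stratified k-fold cross-validation with epoch selection
#'
#' Splits the (already balanced/augmented) training set into k stratified
#' folds, trains one model per fold for `max_epochs`, averages the
#' per-epoch validation costs across folds, and selects the epoch with the
#' lowest mean validation cost (ties broken towards the smallest epoch).
#'
#' @param data A `seg_data` set.
#' @param model_config A [resunet_config()].
#' @param train_config A [train_config()].
#' @param by `"image"` folds individual (possibly augmented) images — the
#'   reference protocol; `"subject"` folds whole subjects, a stricter
#'   non-default that prevents augmented copies of one source slice from
#'   crossing folds.
#' @param verbose Print progress.
#' @return List of class `resunet_cv`: `history` (long data frame of fold
#'   x epoch costs), `mean_val_cost` (per epoch), `best_epoch`, `folds`.
#' @export
resunet_cv <- function(data, model_config = resunet_config(),
                       train_config = resunetCT::train_config(),
                       by = c("image", "subject"), verbose = FALSE) {
  by <- match.arg(by)
  stopifnot(inherits(data, "seg_data"))
  k <- train_config$k_folds
  folds <- if (by == "image") {
    make_folds(data$manifest$has_ascites, k, train_config$seed)
  } else {
    sub <- data$manifest$subject_id
    sub_cls <- tapply(data$manifest$has_ascites, sub, any)
    sf <- make_folds(as.vector(sub_cls), k, train_config$seed)
    sf[match(sub, names(sub_cls))]
  }
  hist <- list()
  for (fold in seq_len(k) - 1L) {
    tr <- subset_seg_data(data, which(folds != fold))
    va <- subset_seg_data(data, which(folds == fold))
    mc <- model_config
    mc$seed <- model_config$seed + fold  # independent init per fold
    tc <- train_config
    tc$seed <- train_config$seed + 1000L * fold
    if (verbose) message("fold ", fold + 1, "/", k)
    fit <- resunet_fit(tr, mc, tc, epochs = train_config$max_epochs,
                       validation = va, verbose = verbose)
    h <- fit$history
    h$fold <- fold
    hist[[fold + 1]] <- h
  }
  hist <- do.call(rbind, hist)
  mean_val <- tapply(hist$val_cost, hist$epoch, mean)
  best <- as.integer(names(mean_val)[which.min(mean_val)])
  structure(list(history = hist, mean_val_cost = as.numeric(mean_val),
                 best_epoch = best, folds = folds),
            class = "resunet_cv")
}

#' @export
print.resunet_cv <- function(x, ...) {
  k <- length(unique(x$history$fold))
  cat(sprintf("%d-fold cross-validation over %d epochs\n", k,
              max(x$history$epoch)))
  cat(sprintf("  best epoch: %d (mean validation cost %.4f)\n",
              x$best_epoch, min(x$mean_val_cost)))
  invisible(x)
}
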