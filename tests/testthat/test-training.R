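test_that("BCE + Dice loss matches closed forms", {
  # perfect prediction: loss tends to 0
  g <- array(rbinom(256, 1, 0.4), c(16, 16, 1, 1))
  p <- pmin(pmax(g, 1e-7), 1 - 1e-7)
  expect_lt(as.numeric(bce_dice_loss(p, g)), 1e-4)
  # truth half-positive, p = 0.5 everywhere: BCE ln 2, Dice 0.5 (eps -> 0)
  g <- array(rep(c(1, 0), each = 2048), c(64, 64, 1, 1))
  p <- array(0.5, c(64, 64, 1, 1))
  l <- bce_dice_loss(p, g, eps = 1e-9)
  expect_equal(attr(l, "bce"), log(2), tolerance = 1e-8)
  expect_equal(attr(l, "dice"), 0.5, tolerance = 1e-6)
  expect_equal(as.numeric(l), log(2) + 0.5, tolerance = 1e-6)
  # weights scale the two terms
  l2 <- bce_dice_loss(p, g, weights = c(bce = 2, dice = 0), eps = 1e-9)
  expect_equal(as.numeric(l2), 2 * log(2), tolerance = 1e-8)
  expect_error(bce_dice_loss(array(0.5, c(4, 4)), array(0, c(5, 5))),
               "shapes differ")
})

test_that("the loss decreases when any pixel moves towards its target", {
  withr::with_seed(14, {
    for (r in 1:20) {
      g <- array(rbinom(64, 1, 0.5), c(8, 8, 1, 1))
      p <- array(runif(64, 0.05, 0.95), c(8, 8, 1, 1))
      i <- sample(64, 1)
      l0 <- as.numeric(bce_dice_loss(p, g))
      p2 <- p
      p2[i] <- p2[i] + 0.01 * (g[i] - p[i])  # small step towards truth
      expect_lt(as.numeric(bce_dice_loss(p2, g)), l0)
    }
  })
})

test_that("the analytic loss gradient matches finite differences", {
  withr::with_seed(15, {
    z <- array(rnorm(128, sd = 2), c(8, 8, 2, 1))
    g <- array(rbinom(128, 1, 0.4), c(8, 8, 2, 1))
    w <- c(bce = 1, dice = 1)
    p <- resunetCT:::sigmoid(z)
    dz <- resunetCT:::bce_dice_grad_z(p, g, w)
    eps <- 1e-6
    for (i in sample(128, 20)) {
      zp <- z; zp[i] <- zp[i] + eps
      zm <- z; zm[i] <- zm[i] - eps
      fd <- (as.numeric(bce_dice_loss(resunetCT:::sigmoid(zp), g, w)) -
             as.numeric(bce_dice_loss(resunetCT:::sigmoid(zm), g, w))) / (2 * eps)
      expect_equal(dz[i], fd, tolerance = 1e-5)
    }
  })
})

test_that("backpropagation through the full network matches finite differences", {
  cfg <- resunet_config(n_blocks = 2, convs_per_block = 2, base_filters = 2,
                        input_size = 16, seed = 3)
  m <- resunet(cfg)
  m$params$head$w <- m$params$head$w * 0.02  # keep sigmoid unsaturated
  withr::with_seed(42, {
    x <- array(runif(16 * 16 * 2 * 3), c(16, 16, 2, 3))
    y <- array(rbinom(16 * 16 * 2, 1, 0.3), c(16, 16, 2, 1))
  })
  w <- c(bce = 1, dice = 1)
  fw <- resunetCT:::resunet_forward(m, x, training = TRUE)
  dz <- resunetCT:::bce_dice_grad_z(fw$prob, y, w)
  gr <- resunetCT:::resunet_backward(m, fw$cache, dz)
  loss_with <- function(params) {
    m2 <- m; m2$params <- params
    as.numeric(bce_dice_loss(
      resunetCT:::resunet_forward(m2, x, training = TRUE)$prob, y, w))
  }
  eps <- 1e-5
  leaves <- list(
    list(get = function(p) p$head$w,
         set = function(p, v) { p$head$w <- v; p }, an = gr$head$w),
    list(get = function(p) p$blocks[[1]]$convs[[1]]$w,
         set = function(p, v) { p$blocks[[1]]$convs[[1]]$w <- v; p },
         an = gr$blocks[[1]]$convs[[1]]$w),
    list(get = function(p) p$blocks[[3]]$proj$w,
         set = function(p, v) { p$blocks[[3]]$proj$w <- v; p },
         an = gr$blocks[[3]]$proj$w),
    list(get = function(p) p$blocks[[5]]$convs[[2]]$bn$gamma,
         set = function(p, v) { p$blocks[[5]]$convs[[2]]$bn$gamma <- v; p },
         an = gr$blocks[[5]]$convs[[2]]$bn$gamma))
  withr::with_seed(7, {
    for (lf in leaves) {
      leaf <- lf$get(m$params)
      for (i in sample(length(leaf), 2)) {
        lp <- leaf; lp[i] <- lp[i] + eps
        lm <- leaf; lm[i] <- lm[i] - eps
        fd <- (loss_with(lf$set(m$params, lp)) -
               loss_with(lf$set(m$params, lm))) / (2 * eps)
        expect_equal(lf$an[i], fd, tolerance = 1e-4)
      }
    }
  })
})

test_that("the fused BN+ReLU kernel matches a plain R reference", {
  withr::with_seed(16, {
    x <- array(rnorm(6 * 6 * 3 * 4), c(6, 6, 3, 4))
    gamma <- runif(4, 0.5, 1.5); beta <- rnorm(4)
    out <- resunetCT:::bnrelu_fwd_cpp(x, gamma, beta, rep(0, 4), rep(1, 4),
                                      0.9, 1e-3, TRUE)
    m <- matrix(x, 108, 4)
    mu <- colMeans(m)
    v <- colMeans(sweep(m, 2, mu)^2)
    ref <- sweep(sweep(m, 2, mu), 2, sqrt(v + 1e-3), "/")
    ref <- pmax(sweep(sweep(ref, 2, gamma, "*"), 2, beta, "+"), 0)
    expect_equal(as.vector(out$r), as.vector(ref), tolerance = 1e-12)
    expect_equal(out$mu, mu)
    expect_equal(out$rmean, 0.1 * mu)
    expect_equal(out$rvar, 0.9 + 0.1 * v)
  })
})

test_that("stratified folds cover the data exactly with balanced classes", {
  f <- make_folds(rep(c(TRUE, FALSE), 5), 5, seed = 1)
  expect_equal(sort(unique(f)), 0:4)
  expect_true(all(table(f) == 2))
  # classes (100, 300) with k = 5: every fold holds exactly (20, 60)
  labels <- rep(c(TRUE, FALSE), c(100, 300))
  f <- make_folds(labels, 5, seed = 2)
  tab <- table(f, labels)
  expect_true(all(tab[, "TRUE"] == 20))
  expect_true(all(tab[, "FALSE"] == 60))
  # random class sizes: exact cover and per-class balance <= 1
  withr::with_seed(17, {
    for (r in 1:30) {
      k <- sample(2:6, 1)
      n1 <- sample(k:40, 1); n0 <- sample(k:40, 1)
      labels <- sample(rep(c(TRUE, FALSE), c(n1, n0)))
      f <- make_folds(labels, k, seed = r)
      expect_length(f, n1 + n0)
      expect_true(all(f %in% 0:(k - 1)))
      for (cl in c(TRUE, FALSE)) {
        sizes <- tabulate(f[labels == cl] + 1, nbins = k)
        expect_lte(diff(range(sizes)), 1)
      }
    }
  })
  expect_error(make_folds(rep(c(TRUE, FALSE), c(3, 10)), 5), "fewer than k")
  expect_identical(make_folds(labels, 3, seed = 5),
                   make_folds(labels, 3, seed = 5))
})

test_that("fold balance matches an established stratified-fold routine", {
  skip_if_not_installed("caret")
  labels <- factor(rep(c("a", "b"), c(37, 91)))
  ours <- make_folds(labels == "a", 5, seed = 3)
  ref <- withr::with_seed(3, caret::createFolds(labels, k = 5))
  our_sizes <- sort(tabulate(ours + 1, nbins = 5))
  ref_sizes <- sort(lengths(ref))
  # identical assignments are not expected (different shuffles), but the
  # per-fold size profile of a stratified partition is
  expect_equal(our_sizes, unname(ref_sizes))
})

test_that("fitting is seed-deterministic and records its history", {
  data <- toy_seg_data(n = 8, size = 16)
  mc <- resunet_config(n_blocks = 2, base_filters = 2, input_size = 16,
                       seed = 5)
  tc <- train_config(learning_rate = 1e-3, batch_size = 4, max_epochs = 2,
                     seed = 9)
  f1 <- resunet_fit(data, mc, tc)
  f2 <- resunet_fit(data, mc, tc)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$history, f2$history)
  expect_equal(nrow(f1$history), 2)
  expect_true(all(is.finite(f1$history$train_cost)))
  expect_true(f1$trained)
  expect_error(resunet_fit(list(x = NULL, y = NULL), mc, tc), "no training data")
  expect_error(resunet_fit(data, resunet_config(n_blocks = 2, input_size = 64),
                           tc), "input_size")
})

test_that("training reduces the loss on a separable toy problem", {
  data <- toy_seg_data(n = 12, size = 16, seed = 3)
  mc <- resunet_config(n_blocks = 2, base_filters = 4, input_size = 16,
                       seed = 2)
  tc <- train_config(learning_rate = 3e-3, batch_size = 4, max_epochs = 8,
                     seed = 4)
  fit <- resunet_fit(data, mc, tc)
  h <- fit$history$train_cost
  expect_lt(h[length(h)], h[1] * 0.8)
})

test_that("cross-validation selects the epoch with lowest mean validation cost", {
  data <- toy_seg_data(n = 12, size = 16, seed = 5)
  mc <- resunet_config(n_blocks = 2, base_filters = 2, input_size = 16,
                       seed = 6)
  tc <- train_config(learning_rate = 2e-3, batch_size = 4, max_epochs = 3,
                     k_folds = 2, seed = 8)
  cv1 <- resunet_cv(data, mc, tc)
  cv2 <- resunet_cv(data, mc, tc)
  expect_identical(cv1$best_epoch, cv2$best_epoch)
  expect_identical(cv1$history, cv2$history)
  expect_length(cv1$mean_val_cost, 3)
  expect_equal(nrow(cv1$history), 2 * 3)  # k folds x epochs
  expect_equal(cv1$best_epoch, which.min(cv1$mean_val_cost))
  # recompute the mean validation curve from the per-fold history
  mv <- tapply(cv1$history$val_cost, cv1$history$epoch, mean)
  expect_equal(as.numeric(mv), cv1$mean_val_cost)
  # subject-level folding keeps subjects intact
  cv3 <- resunet_cv(data, mc, tc, by = "subject")
  sub_folds <- tapply(cv3$folds, data$manifest$subject_id,
                      function(f) length(unique(f)))
  expect_true(all(sub_folds == 1))
})
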