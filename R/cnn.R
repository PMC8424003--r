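#' Training configuration for the ECM classifier
#'
#' Defaults are the published optimization settings: stochastic gradient
#' descent with momentum 0.9, learning rate 0.01, L2 regularization factor
#' 1e-4 on weight matrices, 3 epochs with per-epoch reshuffling. The original
#' batch size of 3000 ECM-images suits multi-million-image datasets; the
#' desk-scale default here is 256 (set `batch_size = 3000` to match the
#' original).
#'
#' @param learning_rate SGD learning rate.
#' @param momentum momentum coefficient.
#' @param l2 L2 regularization factor applied to convolution and
#'   fully-connected weights.
#' @param epochs number of passes over the training data.
#' @param batch_size images per SGD step.
#' @param seed seed controlling initialization, shuffling and balancing.
#' @param balance equalize class counts by random exclusion before training.
#' @return list of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.01, momentum = 0.9, l2 = 1e-4,
                         epochs = 3L, batch_size = 256L, seed = 1L,
                         balance = TRUE) {
  assert_that(learning_rate > 0 && momentum >= 0 && l2 >= 0,
              "optimization constants must be non-negative (learning rate positive)")
  assert_that(is_count(epochs) && epochs >= 1, "epochs must be >= 1")
  assert_that(is_count(batch_size) && batch_size >= 1, "batch_size must be >= 1")
  structure(list(learning_rate = learning_rate, momentum = momentum, l2 = l2,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 seed = as.integer(seed), balance = isTRUE(balance)),
            class = "train_config")
}

ECM_CLASSES <- c("AF", "NONAF")
ECM_INPUT_DIM <- c(10L, 219L, 1L)

# Layer plan of the ECM network. Conv-2 uses stride (1,1): the published
# stride entry (1,2) is inconsistent with its own 10x110 output shape, and
# only stride (1,1) chains the activation shapes to the fully-connected
# input of 3*28*20 = 1680 features that fixes the 10,217-parameter total.
ecm_layer_plan <- function() {
  list(
    list(type = "conv", kh = 3L, kw = 9L, out_c = 10L, sh = 1L, sw = 1L),
    list(type = "bn"),
    list(type = "relu"),
    list(type = "pool", kh = 3L, kw = 3L, sh = 1L, sw = 2L),
    list(type = "conv", kh = 3L, kw = 9L, out_c = 15L, sh = 1L, sw = 1L),
    list(type = "bn"),
    list(type = "relu"),
    list(type = "pool", kh = 3L, kw = 3L, sh = 2L, sw = 2L),
    list(type = "conv", kh = 2L, kw = 4L, out_c = 20L, sh = 2L, sw = 2L),
    list(type = "bn"),
    list(type = "relu"),
    list(type = "fc", out = 2L),
    list(type = "softmax")
  )
}

#' Build the ECM convolutional network
#'
#' Instantiates the fixed architecture — three convolution + batch-norm +
#' ReLU stages (kernels 3x9x10, 3x9x15, 2x4x20), two max-pooling layers, and
#' a fully-connected softmax head — with seeded scaled-uniform (fan-in)
#' weight initialization. The activation shapes chain
#' 10x219x1 -> 10x219x10 -> 10x110x10 -> 10x110x15 -> 5x55x15 -> 3x28x20 -> 2,
#' and the network carries exactly 10,217 trainable parameters.
#'
#' @param seed integer seed for parameter initialization.
#' @return an object of class `ecm_cnn`.
#' @export
build_network <- function(seed = 1L) {
  plan <- ecm_layer_plan()
  shape <- ECM_INPUT_DIM
  layers <- vector("list", length(plan))
  with_seed(seed, {
    for (i in seq_along(plan)) {
      sp <- plan[[i]]
      l <- sp
      if (sp$type == "conv") {
        g <- conv_geometry(shape[1], shape[2], shape[3], sp$kh, sp$kw, sp$sh, sp$sw)
        fan_in <- g$K
        a <- sqrt(3 / fan_in)
        l$W <- matrix(runif(g$K * sp$out_c, -a, a), g$K, sp$out_c)
        l$b <- numeric(sp$out_c)
        l$geom <- g
        shape <- c(g$out_h, g$out_w, sp$out_c)
      } else if (sp$type == "bn") {
        C <- shape[3]
        l$gamma <- rep(1, C)
        l$beta <- numeric(C)
        l$running_mean <- numeric(C)
        l$running_var <- rep(1, C)
      } else if (sp$type == "pool") {
        g <- pool_geometry(shape[1], shape[2], sp$kh, sp$kw, sp$sh, sp$sw)
        l$geom <- g
        shape <- c(g$out_h, g$out_w, shape[3])
      } else if (sp$type == "fc") {
        d <- prod(shape)
        a <- sqrt(3 / d)
        l$W <- matrix(runif(sp$out * d, -a, a), sp$out, d)
        l$b <- numeric(sp$out)
        shape <- c(1L, 1L, sp$out)
      }
      l$out_shape <- shape
      layers[[i]] <- l
    }
  })
  structure(list(layers = layers, classes = ECM_CLASSES, seed = seed,
                 input_dim = ECM_INPUT_DIM, trained = FALSE, log = NULL),
            class = "ecm_cnn")
}

#' Count trainable parameters of a network
#'
#' Sums convolution weights and biases, batch-normalization scale and shift
#' (running statistics are not trainable and are excluded), and
#' fully-connected weights and biases.
#'
#' @param model an `ecm_cnn`, or a list of layers.
#' @return integer parameter count.
#' @export
count_parameters <- function(model) {
  layers <- if (inherits(model, "ecm_cnn")) model$layers else model
  tot <- 0L
  for (l in layers) {
    if (is.null(l$type)) next
    if (l$type %in% c("conv", "fc")) tot <- tot + length(l$W) + length(l$b)
    if (l$type == "bn") tot <- tot + length(l$gamma) + length(l$beta)
  }
  tot
}

#' Activation shape chain of a network
#'
#' @param model an `ecm_cnn`.
#' @return tibble with one row per layer: `layer`, `type`, `out_h`, `out_w`,
#'   `out_c`.
#' @export
network_shapes <- function(model) {
  tibble::tibble(
    layer = seq_along(model$layers),
    type = purrr::map_chr(model$layers, "type"),
    out_h = purrr::map_int(model$layers, ~ as.integer(.x$out_shape[1])),
    out_w = purrr::map_int(model$layers, ~ as.integer(.x$out_shape[2])),
    out_c = purrr::map_int(model$layers, ~ as.integer(.x$out_shape[3]))
  )
}

# full forward pass over a batch array (10,219,1,N)
net_forward <- function(model, x, mode = c("infer", "train"),
                        keep_cache = FALSE) {
  mode <- match.arg(mode)
  caches <- vector("list", length(model$layers))
  acts <- if (keep_cache) vector("list", length(model$layers)) else NULL
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    if (keep_cache) acts[[i]] <- x
    r <- switch(l$type,
      conv = conv_forward(l, x, keep_cache),
      bn = bn_forward(l, x, mode, keep_cache),
      relu = relu_forward(x, keep_cache),
      pool = pool_forward(l, x, keep_cache || mode == "train"),
      fc = fc_forward(l, x, keep_cache),
      softmax = list(out = softmax_cols(x), cache = list(z = x))
    )
    if (l$type == "bn" && mode == "train") model$layers[[i]] <- r$layer
    caches[[i]] <- r$cache
    x <- r$out
  }
  list(probs = x, caches = caches, acts = acts, model = model)
}

as_batch_array <- function(pixels) {
  if (is.matrix(pixels)) {
    assert_that(all(dim(pixels) == c(10L, 219L)), "ECM-image must be 10 x 219")
    return(array(pixels, c(10L, 219L, 1L, 1L)))
  }
  d <- dim(pixels)
  assert_that(length(d) == 3L && all(d[1:2] == c(10L, 219L)),
              "expected a 10 x 219 x N pixel array")
  array(pixels, c(10L, 219L, 1L, d[3]))
}

#' Forward-pass class probabilities for ECM-images
#'
#' Runs the network in inference mode (batch normalization uses running
#' statistics, so the output is deterministic).
#'
#' @param model a (trained) `ecm_cnn`.
#' @param pixels one 10 x 219 matrix or a 10 x 219 x N array.
#' @return tibble with columns `p_AF`, `p_NONAF`, `label`.
#' @export
forward <- function(model, pixels) {
  x <- as_batch_array(pixels)
  p <- net_forward(model, x, mode = "infer")$probs
  tibble::tibble(
    p_AF = p[1, ],
    p_NONAF = p[2, ],
    label = model$classes[apply(p, 2L, which.max)]
  )
}

#' Balance a two-class ECM dataset by random exclusion
#'
#' Randomly excludes the surplus of the majority class (seeded, without
#' replacement) so both classes end with the minority count; relative order
#' of the kept images is preserved.
#'
#' @param dataset an `ecm_dataset` with both classes present.
#' @param seed integer seed.
#' @return the balanced `ecm_dataset`.
#' @export
balance_classes <- function(dataset, seed = 1L) {
  labs <- dataset$meta$label
  n_af <- sum(labs == "AF")
  n_non <- sum(labs == "NONAF")
  if (n_af == 0L || n_non == 0L) {
    abort("balance_classes needs both classes present")
  }
  keep <- with_seed(seed, {
    if (n_af == n_non) {
      seq_along(labs)
    } else {
      major <- if (n_af > n_non) "AF" else "NONAF"
      excess <- abs(n_af - n_non)
      maj_idx <- which(labs == major)
      drop <- sample(maj_idx, excess)
      setdiff(seq_along(labs), drop)
    }
  })
  keep <- sort(keep)
  dataset$pixels <- dataset$pixels[, , keep, drop = FALSE]
  dataset$meta <- dataset$meta[keep, ]
  dataset
}

one_hot <- function(labels, classes = ECM_CLASSES) {
  y <- matrix(0, length(classes), length(labels))
  y[cbind(match(labels, classes), seq_along(labels))] <- 1
  y
}

#' Train the ECM network with SGD + momentum
#'
#' Minimizes binary cross-entropy on the two-class softmax output using
#' stochastic gradient descent with momentum and L2 weight decay, reshuffling
#' the data each epoch under the configured seed. Identical data, config and
#' seed give bit-identical parameter trajectories.
#'
#' @param model an `ecm_cnn` from [build_network()].
#' @param dataset an `ecm_dataset` with labels.
#' @param cfg a [train_config()].
#' @return the trained `ecm_cnn`; `$log` holds per-epoch loss and accuracy.
#' @export
train <- function(model, dataset, cfg = train_config()) {
  n <- dim(dataset$pixels)[3]
  assert_that(n > 0L, "cannot train on an empty dataset")
  if (cfg$balance) dataset <- balance_classes(dataset, seed = cfg$seed)
  n <- dim(dataset$pixels)[3]
  labs <- dataset$meta$label
  assert_that(length(unique(labs)) == 2L,
              "training requires both classes after balancing")
  y_all <- one_hot(labs, model$classes)
  vel <- purrr::map(model$layers, function(l) {
    switch(l$type,
      conv = , fc = list(W = l$W * 0, b = l$b * 0),
      bn = list(gamma = l$gamma * 0, beta = l$beta * 0),
      NULL)
  })
  log <- tibble::tibble(epoch = integer(), loss = numeric(), accuracy = numeric())
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(child_seed(cfg$seed, paste0("epoch", ep)), sample.int(n))
    ep_loss <- 0
    ep_correct <- 0L
    for (bs in seq(1L, n, by = cfg$batch_size)) {
      be <- min(bs + cfg$batch_size - 1L, n)
      sel <- ord[bs:be]
      x <- array(dataset$pixels[, , sel, drop = FALSE],
                 c(10L, 219L, 1L, length(sel)))
      y <- y_all[, sel, drop = FALSE]
      fwd <- net_forward(model, x, mode = "train", keep_cache = TRUE)
      model <- fwd$model
      p <- fwd$probs
      loss <- -mean(colSums(y * log(pmax(p, 1e-12))))
      if (!is.finite(loss)) {
        abort("training diverged (non-finite loss); lower the learning rate")
      }
      ep_loss <- ep_loss + loss * length(sel)
      ep_correct <- ep_correct + sum(apply(p, 2L, which.max) ==
                                       apply(y, 2L, which.max))
      grad <- (p - y) / length(sel)
      for (i in rev(seq_along(model$layers))) {
        l <- model$layers[[i]]
        if (l$type == "softmax") next
        bk <- switch(l$type,
          conv = conv_backward(l, grad, fwd$caches[[i]]),
          bn = bn_backward(l, grad, fwd$caches[[i]]),
          relu = list(dx = grad * fwd$caches[[i]]$mask),
          pool = pool_backward(l, grad, fwd$caches[[i]]),
          fc = fc_backward(l, grad, fwd$caches[[i]])
        )
        if (l$type %in% c("conv", "fc")) {
          dW <- bk$dW + cfg$l2 * l$W
          vel[[i]]$W <- cfg$momentum * vel[[i]]$W - cfg$learning_rate * dW
          vel[[i]]$b <- cfg$momentum * vel[[i]]$b - cfg$learning_rate * bk$db
          model$layers[[i]]$W <- l$W + vel[[i]]$W
          model$layers[[i]]$b <- l$b + vel[[i]]$b
        } else if (l$type == "bn") {
          vel[[i]]$gamma <- cfg$momentum * vel[[i]]$gamma -
            cfg$learning_rate * bk$dgamma
          vel[[i]]$beta <- cfg$momentum * vel[[i]]$beta -
            cfg$learning_rate * bk$dbeta
          model$layers[[i]]$gamma <- l$gamma + vel[[i]]$gamma
          model$layers[[i]]$beta <- l$beta + vel[[i]]$beta
        }
        grad <- bk$dx
      }
    }
    log <- dplyr::bind_rows(log, tibble::tibble(
      epoch = ep, loss = ep_loss / n, accuracy = ep_correct / n))
  }
  model <- calibrate_batchnorm(model, dataset$pixels)
  model$trained <- TRUE
  model$log <- log
  model$train_config <- cfg
  model
}

#' Recalibrate batch-normalization statistics on a reference set
#'
#' Replaces each batch-norm layer's running mean/variance with the exact
#' statistics of its inputs over the given images under the current
#' parameters, layer by layer. [train()] calls this on the training set after
#' the SGD loop: with few SGD steps the momentum-tracked running statistics
#' lag far behind the learned parameters, and inference-mode outputs would
#' not match training behavior.
#'
#' @param model an `ecm_cnn`.
#' @param pixels 10 x 219 x N training images.
#' @param chunk images processed per forward chunk.
#' @return the model with refreshed batch-norm statistics.
#' @export
calibrate_batchnorm <- function(model, pixels, chunk = 512L) {
  n <- dim(pixels)[3]
  if (n == 0L) return(model)
  idx <- split(seq_len(n), ceiling(seq_len(n) / chunk))
  acts <- purrr::map(idx, function(sel) {
    array(pixels[, , sel, drop = FALSE], c(10L, 219L, 1L, length(sel)))
  })
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    if (l$type == "bn") {
      C <- length(l$gamma)
      s1 <- numeric(C)
      s2 <- numeric(C)
      m <- 0
      for (a in acts) {
        d <- dim(a)
        am <- aperm(a, c(1L, 2L, 4L, 3L))
        dim(am) <- c(d[1] * d[2] * d[4], C)
        s1 <- s1 + colSums(am)
        s2 <- s2 + colSums(am^2)
        m <- m + nrow(am)
      }
      mu <- s1 / m
      model$layers[[i]]$running_mean <- mu
      model$layers[[i]]$running_var <- pmax(s2 / m - mu^2, 0)
      l <- model$layers[[i]]
    }
    acts <- purrr::map(acts, function(a) {
      switch(l$type,
        conv = conv_forward(l, a, keep_cache = FALSE)$out,
        bn = bn_forward(l, a, mode = "infer", keep_cache = FALSE)$out,
        relu = relu_forward(a, keep_cache = FALSE)$out,
        pool = pool_forward(l, a, keep_cache = FALSE)$out,
        fc = fc_forward(l, a, keep_cache = FALSE)$out,
        softmax = a)
    })
  }
  model
}

#' @export
print.ecm_cnn <- function(x, ...) {
  cat(sprintf("<ecm_cnn> %d layers, %s parameters, %s\n",
              length(x$layers), format(count_parameters(x), big.mark = ","),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}
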