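# Desk-scale CNN: backbone + global average pooling + dropout + softmax
# head, trained by backpropagation in plain R (im2col convolutions). The
# `tiny_stub` backbone (3 conv blocks, ~12k parameters) stands in for the
# eight ImageNet networks, which are not available offline; the head
# assembly, transfer-learning freeze ratio, loss functions, optimizer update
# rules and metrics all behave as they would on a real backbone.

BACKBONE_NAMES <- c("resnet50", "vgg16", "vgg19", "mobilenet", "mobilenet_v2",
                    "mobilenet_v3_small", "mobilenet_v3_large",
                    "inception_resnet_v2", "tiny_stub")

#' Backbone specification
#' @param name backbone name; only `"tiny_stub"` is available offline.
#' @param input_shape input `(H, W, C)`; default `c(100, 100, 3)`.
#' @param weights `"random"` or `"pretrained"`.
#' @export
backbone_spec <- function(name = "tiny_stub", input_shape = c(100, 100, 3),
                          weights = c("random", "pretrained")) {
  weights <- match.arg(weights)
  assert_that(name %in% BACKBONE_NAMES, "unknown backbone '%s'; valid: %s",
              name, paste(BACKBONE_NAMES, collapse = ", "))
  structure(list(name = name, input_shape = input_shape, weights = weights),
            class = "backbone_spec")
}

# im2col linear-index matrix for an (h, w, c) array and k x k kernels.
im2col_index <- function(h, w, c, k = 3L) {
  oh <- h - k + 1L; ow <- w - k + 1L
  starts <- as.vector(outer(seq_len(oh), (seq_len(ow) - 1L) * h, `+`))
  offs <- as.vector(outer(seq_len(k) - 1L, (seq_len(k) - 1L) * h, `+`))
  offs <- as.vector(outer(offs, (seq_len(c) - 1L) * h * w, `+`))
  list(idx = outer(starts, offs, `+`), oh = oh, ow = ow)
}

#' Assemble a classification model
#'
#' Backbone convolutions feed a global-average-pooling layer, a dropout
#' layer and a softmax output of `n_classes` units.
#'
#' @param backbone a [backbone_spec()].
#' @param n_classes number of classes (>= 2).
#' @param dropout dropout fraction in \[0, 0.6\].
#' @param seed seed for the random weight initialization.
#' @return a `pd_cnn_model`.
#' @export
assemble_model <- function(backbone = backbone_spec(), n_classes, dropout = 0,
                           seed = NULL) {
  assert_that(n_classes >= 2, "n_classes must be >= 2")
  assert_that(dropout >= 0 && dropout <= 0.6, "dropout must be in [0, 0.6]")
  if (backbone$name != "tiny_stub") {
    stop(sprintf(paste0("backbone '%s' needs pretrained ImageNet weights, which ",
                        "are unavailable offline; use backbone_spec('tiny_stub') ",
                        "or random weights at your own scale"), backbone$name))
  }
  channels <- c(backbone$input_shape[3], 8, 16, 32)
  with_seed_or_stream(seed, {
    layers <- lapply(seq_len(3), function(l) {
      fan_in <- 9 * channels[l]
      list(W = matrix(stats::rnorm(fan_in * channels[l + 1], sd = sqrt(2 / fan_in)),
                      fan_in, channels[l + 1]),
           b = numeric(channels[l + 1]),
           pool = l < 3)
    })
    head <- list(W = matrix(stats::rnorm(channels[4] * n_classes, sd = 0.1),
                            channels[4], n_classes),
                 b = numeric(n_classes))
    structure(list(backbone_name = backbone$name,
                   input_shape = backbone$input_shape,
                   layers = layers, head = head, n_classes = n_classes,
                   dropout = dropout, trainable = rep(TRUE, length(layers))),
              class = "pd_cnn_model")
  })
}

#' @export
print.pd_cnn_model <- function(x, ...) {
  n_par <- sum(vapply(x$layers, function(l) length(l$W) + length(l$b), 0)) +
    length(x$head$W) + length(x$head$b)
  cat(sprintf("<pd_cnn_model %s> %d backbone layers (%s trainable), %d classes, %d params\n",
              x$backbone_name, length(x$layers), sum(x$trainable),
              x$n_classes, n_par))
  invisible(x)
}

#' Trainable backbone layer count under a transfer-learning ratio
#'
#' @param n_layers total backbone layers.
#' @param ratio percentage 0-100 of layers left trainable, counted from the
#'   output end; rounded to the nearest layer.
#' @export
tl_trainable_layers <- function(n_layers, ratio) {
  assert_that(ratio >= 0 && ratio <= 100, "TL ratio must be in [0, 100]")
  round(ratio / 100 * n_layers)
}

#' Apply the transfer-learning freeze ratio
#'
#' Freezes all but the top `ratio` percent of backbone layers; the head is
#' always trainable.
#'
#' @param model a `pd_cnn_model`.
#' @param ratio percentage in \[0, 100\].
#' @return the model with updated trainable flags.
#' @export
apply_tl_ratio <- function(model, ratio) {
  n <- length(model$layers)
  k <- tl_trainable_layers(n, ratio)
  model$trainable <- rep(FALSE, n)
  if (k > 0) model$trainable[(n - k + 1):n] <- TRUE
  model
}

relu <- function(x) pmax(x, 0)

# Forward through the backbone for one (h, w, c) image array scaled to [0,1].
# Returns the GAP feature vector; with cache = TRUE also all intermediates.
cnn_forward <- function(model, x, cache = FALSE) {
  caches <- if (cache) vector("list", length(model$layers))
  for (l in seq_along(model$layers)) {
    layer <- model$layers[[l]]
    d <- dim(x)
    ic <- im2col_index(d[1], d[2], d[3])
    patches <- matrix(x[ic$idx], nrow(ic$idx))
    z <- sweep(patches %*% layer$W, 2, layer$b, `+`)
    a <- relu(z)
    out <- array(a, dim = c(ic$oh, ic$ow, ncol(layer$W)))
    pool_arg <- NULL
    if (layer$pool) {
      ph <- ic$oh %/% 2L; pw <- ic$ow %/% 2L
      i0 <- seq(1, 2 * ph, by = 2); j0 <- seq(1, 2 * pw, by = 2)
      a1 <- out[i0, j0, , drop = FALSE]; a2 <- out[i0 + 1, j0, , drop = FALSE]
      a3 <- out[i0, j0 + 1, , drop = FALSE]; a4 <- out[i0 + 1, j0 + 1, , drop = FALSE]
      m <- pmax(a1, a2, a3, a4)
      if (cache) {
        pool_arg <- ifelse(m == a1, 1L, ifelse(m == a2, 2L, ifelse(m == a3, 3L, 4L)))
      }
      pooled <- m
    } else pooled <- out
    if (cache) {
      caches[[l]] <- list(in_dim = d, idx = ic$idx, patches = patches, z = z,
                          out_dim = dim(out), pool_arg = pool_arg,
                          pooled_dim = dim(pooled))
    }
    x <- pooled
  }
  feat <- apply(x, 3, mean)
  if (cache) list(feat = feat, spatial = dim(x)[1:2], caches = caches) else feat
}

softmax <- function(z) { e <- exp(z - max(z)); e / sum(e) }

# loss value and gradient w.r.t. the softmax logits for one sample
loss_and_grad <- function(loss_name, p, y) {
  k <- length(p)
  chain <- function(dp) p * (dp - sum(dp * p))
  eps <- 1e-9
  switch(loss_name,
    categorical_crossentropy = list(loss = -sum(y * log(p + eps)),
                                    dlogits = p - y),
    kl_divergence = list(loss = sum(y * log((y + eps) / (p + eps))),
                         dlogits = chain(-y / (p + eps))),
    poisson = list(loss = mean(p - y * log(p + eps)),
                   dlogits = chain((1 - y / (p + eps)) / k)),
    hinge = {
      ys <- 2 * y - 1
      margin <- pmax(0, 1 - ys * p)
      list(loss = mean(margin), dlogits = chain(ifelse(margin > 0, -ys / k, 0)))
    },
    squared_hinge = {
      ys <- 2 * y - 1
      margin <- pmax(0, 1 - ys * p)
      list(loss = mean(margin^2), dlogits = chain(-2 * ys * margin / k))
    },
    categorical_hinge = {
      pos <- sum(y * p)
      negv <- (1 - y) * p
      j <- which.max(negv)
      L <- max(0, 1 - pos + negv[j])
      dp <- numeric(k)
      if (L > 0) { dp <- -y; dp[j] <- dp[j] + 1 }
      list(loss = L, dlogits = chain(dp))
    },
    abort_validation("unknown loss function '%s'", loss_name))
}

# backward through the backbone; returns gradients for trainable layers
cnn_backward <- function(model, fwd, dfeat) {
  grads <- vector("list", length(model$layers))
  # GAP backward
  sp <- fwd$spatial
  dpooled <- array(rep(dfeat / prod(sp), each = prod(sp)),
                   dim = c(sp, length(dfeat)))
  for (l in rev(seq_along(model$layers))) {
    cache <- fwd$caches[[l]]
    layer <- model$layers[[l]]
    if (layer$pool) {
      dout <- array(0, dim = cache$out_dim)
      ph <- dim(dpooled)[1]; pw <- dim(dpooled)[2]
      i0 <- seq(1, 2 * ph, by = 2); j0 <- seq(1, 2 * pw, by = 2)
      arg <- cache$pool_arg
      for (a in 1:4) {
        di <- (a == 2 || a == 4) * 1L; dj <- (a >= 3) * 1L
        mask <- arg == a
        sel <- dpooled * mask
        dout[i0 + di, j0 + dj, ] <- dout[i0 + di, j0 + dj, ] + sel
      }
    } else dout <- dpooled
    dz <- matrix(dout, nrow = prod(cache$out_dim[1:2])) * (cache$z > 0)
    if (model$trainable[l]) {
      grads[[l]] <- list(W = crossprod(cache$patches, dz), b = colSums(dz))
    }
    if (l > 1) {  # propagate into the previous activation
      dpatches <- tcrossprod(dz, layer$W)
      n_in <- prod(cache$in_dim)
      agg <- rowsum(as.vector(dpatches), as.vector(cache$idx))
      dxv <- numeric(n_in)
      dxv[as.integer(rownames(agg))] <- agg
      dpooled <- array(dxv, dim = cache$in_dim)
    }
  }
  grads
}

# optimizer update-rule families mapped from the 11 search-space tags
optimizer_family <- function(tag) {
  switch(tag,
    sgd = , ftrl = list(kind = "sgd", lr = 0.05),
    sgd_nesterov = list(kind = "momentum", lr = 0.05, beta = 0.9, nesterov = TRUE),
    adagrad = , adadelta = list(kind = "adagrad", lr = 0.05),
    rmsprop = , rmsprop_centered = list(kind = "rmsprop", lr = 0.005, rho = 0.9),
    adam = , nadam = , adamax = , amsgrad = list(kind = "adam", lr = 0.005,
                                                 b1 = 0.9, b2 = 0.999),
    abort_validation("unknown weights optimizer '%s'", tag))
}

make_updater <- function(fam) {
  state <- new.env()
  function(name, param, grad) {
    key <- name
    s <- get0(key, state)
    if (is.null(s)) s <- list(m = param * 0, v = param * 0, t = 0)
    s$t <- s$t + 1
    out <- switch(fam$kind,
      sgd = param - fam$lr * grad,
      momentum = {
        s$m <- fam$beta * s$m - fam$lr * grad
        param + (if (fam$nesterov) fam$beta * s$m - fam$lr * grad else s$m)
      },
      adagrad = {
        s$v <- s$v + grad^2
        param - fam$lr * grad / sqrt(s$v + 1e-8)
      },
      rmsprop = {
        s$v <- fam$rho * s$v + (1 - fam$rho) * grad^2
        param - fam$lr * grad / sqrt(s$v + 1e-8)
      },
      adam = {
        s$m <- fam$b1 * s$m + (1 - fam$b1) * grad
        s$v <- fam$b2 * s$v + (1 - fam$b2) * grad^2
        mh <- s$m / (1 - fam$b1^s$t); vh <- s$v / (1 - fam$b2^s$t)
        param - fam$lr * mh / (sqrt(vh) + 1e-8)
      })
    assign(key, s, state)
    out
  }
}

#' Predict class probabilities for a batch of images
#'
#' @param model a `pd_cnn_model`.
#' @param images list of `image_sample` objects (pixels in \[0, 255\]).
#' @param classes optional class names for the probability columns.
#' @return n x n_classes matrix, rows summing to 1.
#' @export
predict_model <- function(model, images, classes = NULL) {
  probs <- t(vapply(images, function(img) {
    feat <- cnn_forward(model, img$pixels / 255)
    softmax(as.numeric(feat %*% model$head$W + model$head$b))
  }, numeric(model$n_classes)))
  if (!is.null(classes)) colnames(probs) <- classes
  probs
}

#' Train the model under a decoded hyperparameter set and score the held-out split
#'
#' Stratified 85/15 train/test split; training uses the hyperparameter set's
#' loss function, batch size, weights optimizer, dropout, TL freeze ratio and
#' second-location augmentation ranges; the extended metric set is computed
#' on the test split.
#'
#' @param model a `pd_cnn_model`.
#' @param images list of `image_sample` objects.
#' @param hp a `hyperparameter_set` (see [decode_hyperparameters()]); any
#'   missing entry falls back to a plain-SGD/crossentropy default.
#' @param epochs training epochs (default 5).
#' @param seed seed controlling split, shuffling, dropout and augmentation.
#' @param test_frac held-out fraction (default 0.15).
#' @param augment apply the hp augmentation ranges to training images.
#' @return list: `metrics` (`extended_metrics` on the test split), `model`
#'   (trained), `epoch_losses`, `n_train`, `n_test`.
#' @export
train_and_score <- function(model, images, hp = NULL, epochs = 5, seed = NULL,
                            test_frac = 0.15, augment = TRUE) {
  labels <- vapply(images, `[[`, "", "class_label")
  classes <- sort(unique(labels))
  assert_that(length(classes) == model$n_classes,
              "model expects %d classes; data has %d", model$n_classes,
              length(classes))
  loss_name <- hp$loss_function %||% "categorical_crossentropy"
  batch_size <- hp$batch_size %||% 16
  opt_tag <- hp$weights_optimizer %||% "sgd"
  if (!is.null(hp$dropout)) model$dropout <- hp$dropout
  if (!is.null(hp$tl_learn_ratio)) model <- apply_tl_ratio(model, hp$tl_learn_ratio)
  aug_cfg <- if (augment && !is.null(hp$rotation)) hp_augmentation_config(hp) else NULL
  updater <- make_updater(optimizer_family(opt_tag))

  with_seed_or_stream(seed, {
    # stratified 85/15 split
    test_idx <- unlist(lapply(classes, function(cls) {
      idx <- which(labels == cls)
      sample(idx, max(1L, round(test_frac * length(idx))))
    }))
    if (!setequal(unique(labels[test_idx]), classes)) {
      abort_validation("a class is absent from the test split; use another seed/split")
    }
    train_idx <- setdiff(seq_along(images), test_idx)
    onehot <- function(lab) as.numeric(classes == lab)
    epoch_losses <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      order_ <- sample(train_idx)
      losses <- c()
      for (start in seq(1, length(order_), by = batch_size)) {
        batch <- order_[start:min(start + batch_size - 1, length(order_))]
        gW_layers <- vector("list", length(model$layers))
        gb_layers <- vector("list", length(model$layers))
        gW_head <- model$head$W * 0; gb_head <- model$head$b * 0
        for (bi in batch) {
          img <- images[[bi]]
          if (!is.null(aug_cfg)) img <- augment_image(img, aug_cfg)
          fwd <- cnn_forward(model, img$pixels / 255, cache = TRUE)
          feat <- fwd$feat
          if (model$dropout > 0) {
            mask <- (stats::runif(length(feat)) >= model$dropout) /
              (1 - model$dropout)
            feat <- feat * mask
          } else mask <- NULL
          p <- softmax(as.numeric(feat %*% model$head$W + model$head$b))
          lg <- loss_and_grad(loss_name, p, onehot(img$class_label))
          losses <- c(losses, lg$loss)
          gW_head <- gW_head + outer(feat, lg$dlogits)
          gb_head <- gb_head + lg$dlogits
          if (any(model$trainable)) {
            dfeat <- as.numeric(model$head$W %*% lg$dlogits)
            if (!is.null(mask)) dfeat <- dfeat * mask
            g <- cnn_backward(model, fwd, dfeat)
            for (l in seq_along(g)) {
              if (is.null(g[[l]])) next
              gW_layers[[l]] <- (gW_layers[[l]] %||% (g[[l]]$W * 0)) + g[[l]]$W
              gb_layers[[l]] <- (gb_layers[[l]] %||% (g[[l]]$b * 0)) + g[[l]]$b
            }
          }
        }
        nb <- length(batch)
        model$head$W <- updater("head.W", model$head$W, gW_head / nb)
        model$head$b <- updater("head.b", model$head$b, gb_head / nb)
        for (l in seq_along(model$layers)) {
          if (is.null(gW_layers[[l]])) next
          model$layers[[l]]$W <- updater(paste0("L", l, ".W"),
                                         model$layers[[l]]$W, gW_layers[[l]] / nb)
          model$layers[[l]]$b <- updater(paste0("L", l, ".b"),
                                         model$layers[[l]]$b, gb_layers[[l]] / nb)
        }
      }
      epoch_losses[ep] <- mean(losses)
    }
    probs <- predict_model(model, images[test_idx], classes)
    truth <- t(vapply(labels[test_idx], onehot, numeric(length(classes))))
    colnames(truth) <- classes
    test_loss <- mean(vapply(seq_len(nrow(probs)), function(i) {
      loss_and_grad(loss_name, probs[i, ], truth[i, ])$loss
    }, numeric(1)))
    list(metrics = extended_metrics(truth, probs, loss = test_loss),
         model = model, epoch_losses = epoch_losses,
         n_train = length(train_idx), n_test = length(test_idx))
  })
}
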