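# Classical classifiers behind the grid-search pipeline. No classifier
# package (e1071/kernlab/rpart/class) exists in the target environment, so
# the four algorithms are implemented here:
#   - KNN with the Minkowski metric (p = 1 or 2); leafSize is accepted for
#     interface parity but, as in the reference implementations, affects only
#     lookup speed, never predictions.
#   - CART decision tree (gini/entropy impurity, best/random splitter,
#     maxDepth).
#   - Gaussian naive Bayes; `alpha` acts as additive variance smoothing
#     (the features are real-valued, so Laplace count smoothing is undefined).
#   - Least-squares SVM (kernel ridge classification, one-vs-rest) with
#     linear / poly / rbf / sigmoid kernels honouring C, degree and gamma.
# All emit per-class probability matrices with columns in class order.

CLASSIFIER_KINDS <- c("KNN", "SVM", "DT", "NB")

#' Fit a classifier
#'
#' @param kind one of `"KNN"`, `"SVM"`, `"DT"`, `"NB"`.
#' @param x numeric feature matrix (rows = samples).
#' @param y label vector.
#' @param params named list of hyperparameters (see [build_grid()]).
#' @param seed optional seed (used by the DT random splitter).
#' @return a `pd_classifier` model object.
#' @export
fit_classifier <- function(kind, x, y, params = list(), seed = NULL) {
  assert_that(kind %in% CLASSIFIER_KINDS, "unknown classifier '%s'", kind)
  classes <- sort(unique(as.character(y)))
  y <- as.character(y)
  model <- switch(kind,
    KNN = list(x = x, y = y,
               k = params$nNeighbors %||% 5L,
               p = params$p %||% 2),
    NB = fit_gaussian_nb(x, y, classes, alpha = params$alpha %||% 1),
    DT = with_seed_or_stream(seed,
           fit_cart(x, y, classes,
                    criterion = params$criterion %||% "gini",
                    splitter = params$splitter %||% "best",
                    max_depth = params$maxDepth %||% 10L)),
    SVM = fit_lssvm(x, y, classes,
                    C = params$C %||% 1,
                    kernel = params$kernel %||% "rbf",
                    degree = params$degree %||% 3,
                    gamma = params$gamma %||% (1 / ncol(x)))
  )
  structure(list(kind = kind, model = model, classes = classes),
            class = "pd_classifier")
}

#' Predict class probabilities
#' @param object a `pd_classifier`.
#' @param newx numeric matrix of new samples.
#' @param ... unused.
#' @return matrix n x n_classes, rows summing to 1, columns named by class.
#' @export
predict.pd_classifier <- function(object, newx, ...) {
  if (is.null(dim(newx))) newx <- matrix(newx, nrow = 1)
  probs <- switch(object$kind,
    KNN = predict_knn(object$model, newx, object$classes),
    NB = predict_gaussian_nb(object$model, newx, object$classes),
    DT = predict_cart(object$model, newx, object$classes),
    SVM = predict_lssvm(object$model, newx, object$classes))
  colnames(probs) <- object$classes
  probs
}

# KNN ------------------------------------------------------------------------

minkowski_dist <- function(a, b, p) {
  # rows of a vs rows of b -> nrow(a) x nrow(b)
  if (p == 2) {
    d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
    sqrt(pmax(d2, 0))
  } else {
    out <- matrix(0, nrow(a), nrow(b))
    for (j in seq_len(nrow(b))) {
      out[, j] <- rowSums(abs(sweep(a, 2, b[j, ]))^p)^(1 / p)
    }
    out
  }
}

predict_knn <- function(model, newx, classes) {
  d <- minkowski_dist(newx, model$x, model$p)
  k <- min(model$k, ncol(d))
  probs <- matrix(0, nrow(newx), length(classes))
  for (i in seq_len(nrow(newx))) {
    nn <- order(d[i, ])[seq_len(k)]
    tab <- table(factor(model$y[nn], levels = classes))
    probs[i, ] <- as.numeric(tab) / k
  }
  probs
}

# Gaussian naive Bayes --------------------------------------------------------

fit_gaussian_nb <- function(x, y, classes, alpha = 1) {
  stats_by <- lapply(classes, function(cls) {
    xi <- x[y == cls, , drop = FALSE]
    list(mu = colMeans(xi),
         var = apply(xi, 2, stats::var) + alpha + 1e-9,
         prior = nrow(xi) / nrow(x))
  })
  names(stats_by) <- classes
  list(stats = stats_by)
}

predict_gaussian_nb <- function(model, newx, classes) {
  loglik <- sapply(classes, function(cls) {
    st <- model$stats[[cls]]
    v <- st$var
    ll <- -0.5 * colSums((t(newx) - st$mu)^2 / v) -
      0.5 * sum(log(2 * pi * v)) + log(st$prior)
    ll
  })
  if (is.null(dim(loglik))) loglik <- matrix(loglik, nrow = 1)
  m <- apply(loglik, 1, max)
  w <- exp(loglik - m)
  w / rowSums(w)
}

# CART decision tree ----------------------------------------------------------

node_impurity <- function(counts, criterion) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts / n
  p <- p[p > 0]
  if (criterion == "gini") 1 - sum(p^2) else -sum(p * log2(p))
}

best_split_feature <- function(xj, yf, criterion) {
  ord <- order(xj)
  xs <- xj[ord]; ys <- yf[ord]
  n <- length(xs)
  cut_pos <- which(diff(xs) > 0)
  if (!length(cut_pos)) return(NULL)
  lvls <- levels(yf)
  left_counts <- matrix(0, length(lvls), n)
  onehot <- sapply(lvls, function(l) cumsum(ys == l))
  total <- onehot[n, ]
  best <- NULL
  for (cp in cut_pos) {
    lc <- onehot[cp, ]; rc <- total - lc
    imp <- (cp * node_impurity(lc, criterion) +
            (n - cp) * node_impurity(rc, criterion)) / n
    if (is.null(best) || imp < best$impurity) {
      best <- list(threshold = (xs[cp] + xs[cp + 1]) / 2, impurity = imp)
    }
  }
  best
}

random_split_feature <- function(xj, yf, criterion) {
  rng <- range(xj)
  if (diff(rng) == 0) return(NULL)
  thr <- stats::runif(1, rng[1], rng[2])
  left <- xj <= thr
  if (!any(left) || all(left)) return(NULL)
  lc <- table(yf[left]); rc <- table(yf[!left])
  imp <- (sum(lc) * node_impurity(lc, criterion) +
          sum(rc) * node_impurity(rc, criterion)) / length(xj)
  list(threshold = thr, impurity = imp)
}

build_cart_node <- function(x, yf, criterion, splitter, max_depth, depth) {
  counts <- table(yf)
  leaf <- function() list(leaf = TRUE, probs = as.numeric(counts) / sum(counts))
  if (depth >= max_depth || length(unique(as.character(yf))) <= 1 ||
      nrow(x) < 2) {
    return(leaf())
  }
  split_fn <- if (splitter == "best") best_split_feature else random_split_feature
  best <- NULL
  for (j in seq_len(ncol(x))) {
    cand <- split_fn(x[, j], yf, criterion)
    if (!is.null(cand) && (is.null(best) || cand$impurity < best$impurity)) {
      best <- c(cand, feature = j)
    }
  }
  if (is.null(best)) return(leaf())
  parent_imp <- node_impurity(counts, criterion)
  if (best$impurity >= parent_imp - 1e-12) return(leaf())
  left <- x[, best$feature] <= best$threshold
  list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
       left = build_cart_node(x[left, , drop = FALSE], yf[left],
                              criterion, splitter, max_depth, depth + 1),
       right = build_cart_node(x[!left, , drop = FALSE], yf[!left],
                               criterion, splitter, max_depth, depth + 1))
}

fit_cart <- function(x, y, classes, criterion = "gini", splitter = "best",
                     max_depth = 10L) {
  assert_that(criterion %in% c("gini", "entropy"), "unknown criterion '%s'", criterion)
  assert_that(splitter %in% c("best", "random"), "unknown splitter '%s'", splitter)
  yf <- factor(y, levels = classes)
  list(root = build_cart_node(x, yf, criterion, splitter, max_depth, 0L))
}

predict_cart <- function(model, newx, classes) {
  one <- function(v) {
    node <- model$root
    while (!node$leaf) {
      node <- if (v[node$feature] <= node$threshold) node$left else node$right
    }
    node$probs
  }
  t(apply(newx, 1, one))
}

# Least-squares SVM -----------------------------------------------------------

svm_kernel <- function(a, b, kernel, degree, gamma) {
  switch(kernel,
    linear = tcrossprod(a, b),
    poly = (gamma * tcrossprod(a, b))^degree,
    rbf = {
      d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
      exp(-gamma * pmax(d2, 0))
    },
    sigmoid = tanh(gamma * tcrossprod(a, b)),
    abort_validation("unsupported SVM kernel '%s'", kernel))
}

fit_lssvm <- function(x, y, classes, C = 1, kernel = "rbf", degree = 3,
                      gamma = 1) {
  if (identical(kernel, "precomputed")) {
    abort_validation("precomputed kernel requires a user kernel matrix; none defined")
  }
  K <- svm_kernel(x, x, kernel, degree, gamma)
  n <- nrow(x)
  machines <- lapply(classes, function(cls) {
    t <- ifelse(y == cls, 1, -1)
    A <- rbind(c(0, rep(1, n)), cbind(1, K + diag(n) / C))
    sol <- tryCatch(solve(A, c(0, t)),
                    error = function(e) solve(A + diag(n + 1) * 1e-8, c(0, t)))
    list(b = sol[1], alpha = sol[-1])
  })
  names(machines) <- classes
  list(x = x, machines = machines, kernel = kernel, degree = degree, gamma = gamma)
}

predict_lssvm <- function(model, newx, classes) {
  Knew <- svm_kernel(newx, model$x, model$kernel, model$degree, model$gamma)
  dec <- sapply(classes, function(cls) {
    m <- model$machines[[cls]]
    as.numeric(Knew %*% m$alpha + m$b)
  })
  if (is.null(dim(dec))) dec <- matrix(dec, nrow = nrow(newx))
  w <- exp(dec - apply(dec, 1, max))
  w / rowSums(w)
}
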