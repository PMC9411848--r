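# Model assembly, transfer-learning freeze ratio, training and the extended
# metric set.

test_that("assembled model emits softmax probabilities of the right shape", {
  model <- assemble_model(backbone_spec("tiny_stub"), n_classes = 6, seed = 1)
  imgs <- lapply(1:8, function(i) make_synthetic_drawing("circle", 0, seed = i,
                                                         class_label = "c"))
  p <- predict_model(model, imgs)
  expect_equal(dim(p), c(8, 6))
  expect_equal(rowSums(p), rep(1, 8), tolerance = 1e-6)
  # dropout affects training only: evaluation is deterministic
  model2 <- assemble_model(backbone_spec("tiny_stub"), n_classes = 6,
                           dropout = 0.5, seed = 1)
  expect_identical(predict_model(model2, imgs), p)
})

test_that("backbone validation errors are explicit", {
  expect_error(backbone_spec("alexnet"), "unknown backbone")
  expect_error(assemble_model(backbone_spec("vgg19"), n_classes = 2),
               "unavailable offline")
  expect_error(assemble_model(backbone_spec("tiny_stub"), n_classes = 1), "n_classes")
  expect_error(assemble_model(backbone_spec("tiny_stub"), n_classes = 2,
                              dropout = 0.9), "dropout")
})

test_that("the TL freeze ratio controls trainable backbone layers", {
  expect_equal(tl_trainable_layers(10, 50), 5)
  expect_equal(tl_trainable_layers(10, 0), 0)
  expect_equal(tl_trainable_layers(10, 100), 10)
  expect_error(tl_trainable_layers(10, 120), "ratio")
  model <- assemble_model(backbone_spec("tiny_stub"), n_classes = 2, seed = 1)
  expect_equal(sum(apply_tl_ratio(model, 0)$trainable), 0)
  expect_equal(sum(apply_tl_ratio(model, 100)$trainable), 3)
  # monotone in the ratio
  counts <- vapply(seq(0, 100, by = 10),
                   function(r) sum(apply_tl_ratio(model, r)$trainable), 0)
  expect_true(all(diff(counts) >= 0))
  # the frozen layers are the bottom ones
  m67 <- apply_tl_ratio(model, 67)
  expect_equal(m67$trainable, c(FALSE, TRUE, TRUE))
})

test_that("training separates a linearly separable synthetic image set", {
  imgs <- c(lapply(1:14, function(i) make_synthetic_drawing("circle", 0,
                                                            class_label = "HC", seed = i)),
            lapply(1:14, function(i) make_synthetic_drawing("spiral", 3,
                                                            class_label = "PD", seed = 100 + i)))
  model <- assemble_model(backbone_spec("tiny_stub"), n_classes = 2, seed = 1)
  fit <- train_and_score(model, imgs, epochs = 5, seed = 2, augment = FALSE)
  expect_gte(fit$metrics$accuracy, 0.95)
  expect_true(all(unlist(fit$metrics[c("accuracy", "f1", "precision", "recall",
                                       "specificity", "auc", "iou_coef",
                                       "dice_coef")]) >= 0))
  expect_true(all(unlist(fit$metrics[c("accuracy", "f1", "precision", "recall",
                                       "specificity", "auc", "iou_coef",
                                       "dice_coef")]) <= 1))
  expect_equal(fit$n_train + fit$n_test, 28)
})

test_that("an untrained stub scores near chance on balanced data", {
  classes <- c("a", "b", "c")
  imgs <- unlist(lapply(classes, function(cl) {
    lapply(1:6, function(i) make_synthetic_drawing("circle", 1, class_label = cl,
                                                   seed = match(cl, classes) * 50 + i))
  }), recursive = FALSE)
  model <- assemble_model(backbone_spec("tiny_stub"), n_classes = 3, seed = 9)
  p <- predict_model(model, imgs, classes = classes)
  truth <- t(vapply(vapply(imgs, `[[`, "", "class_label"),
                    function(l) as.numeric(classes == l), numeric(3)))
  m <- extended_metrics(truth, p)
  expect_lt(abs(m$accuracy - 1 / 3), 0.35)  # untrained: near chance
})

test_that("training under a decoded hyperparameter set runs end to end", {
  imgs <- c(lapply(1:8, function(i) make_synthetic_drawing("circle", 0,
                                                           class_label = "HC", seed = i)),
            lapply(1:8, function(i) make_synthetic_drawing("spiral", 3,
                                                           class_label = "PD", seed = 60 + i)))
  hp <- decode_hyperparameters(rep(0.3, 14))
  model <- assemble_model(backbone_spec("tiny_stub"), n_classes = 2,
                          dropout = hp$dropout, seed = 3)
  fit <- train_and_score(model, imgs, hp = hp, epochs = 2, seed = 4)
  expect_s3_class(fit$metrics, "extended_metrics")
  expect_true(is.finite(fit$metrics$loss))
  expect_length(fit$epoch_losses, 2)
})

test_that("every loss function produces finite losses and gradients", {
  p <- c(0.6, 0.3, 0.1); y <- c(1, 0, 0)
  for (loss in pdscreen:::LOSS_FUNCTIONS) {
    lg <- pdscreen:::loss_and_grad(loss, p, y)
    expect_true(is.finite(lg$loss), label = loss)
    expect_true(all(is.finite(lg$dlogits)), label = loss)
    # gradients through softmax sum to ~0
    expect_lt(abs(sum(lg$dlogits)), 1e-8)
  }
})

test_that("extended metrics match a hand-computed 3-sample oracle", {
  # truth: classes 1, 2, 2; predictions: 1 (0.9), 1 (0.6), 2 (0.8)
  truth <- rbind(c(1, 0), c(0, 1), c(0, 1))
  probs <- rbind(c(0.9, 0.1), c(0.6, 0.4), c(0.2, 0.8))
  m <- extended_metrics(truth, probs)
  # confusion: TP(1)=1, TP(2)=1, one class-2 sample predicted class 1
  expect_equal(m$accuracy, 2 / 3)
  expect_equal(m$precision, 2 / 3)   # micro identity
  expect_equal(m$f1, 2 / 3)
  # specificity by hand: class1 ovr TN=1 FP=1; class2 ovr TN=1 FP=0 -> 2/3
  expect_equal(m$specificity, 2 / 3)
  # IOU by hand: thresholded predictions {1},{1},{2}; truth {1},{2},{2}
  # intersection 2, union 4 -> 0.5; dice 2*2/(3+3) = 2/3
  expect_equal(m$iou_coef, 0.5)
  expect_equal(m$dice_coef, 2 / 3)
  expect_gte(m$dice_coef, m$iou_coef)
})

test_that("perfect and uninformative predictions bound the metric set", {
  truth <- diag(3)[c(1, 2, 3, 1, 2, 3), ]
  m_perfect <- extended_metrics(truth, truth)
  for (k in c("accuracy", "f1", "precision", "recall", "specificity", "auc",
              "iou_coef", "dice_coef")) {
    expect_equal(m_perfect[[k]], 1, label = k)
  }
  uniform <- matrix(1 / 3, 6, 3)
  m_uniform <- extended_metrics(truth, uniform)
  expect_equal(m_uniform$auc, 0.5)
  expect_error(extended_metrics(truth, uniform[1:3, ]), "mismatch")
})

test_that("dice >= iou across random prediction matrices", {
  withr::with_seed(5, {
    for (i in 1:20) {
      k <- sample(2:5, 1); n <- sample(4:12, 1)
      truth <- diag(k)[sample(k, n, replace = TRUE), , drop = FALSE]
      raw <- matrix(runif(n * k), n)
      probs <- raw / rowSums(raw)
      m <- extended_metrics(truth, probs)
      expect_gte(m$dice_coef + 1e-12, m$iou_coef)
    }
  })
})
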