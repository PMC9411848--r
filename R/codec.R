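# The 14-dimensional solution codec: the optimizer searches [0,1]^14 and the
# codec maps each coordinate onto a CNN / augmentation hyperparameter.
# Continuous dimensions rescale linearly, stepped dimensions snap to the
# nearest grid point, categorical dimensions index by floor(value * n)
# (clamped), and the brightness pair is reordered so from <= to.

LOSS_FUNCTIONS <- c("categorical_crossentropy", "categorical_hinge",
                    "kl_divergence", "poisson", "squared_hinge", "hinge")

# the published optimizer list repeats Adam; deduplicated to 11 unique tags
WEIGHT_OPTIMIZERS <- c("adam", "nadam", "adagrad", "adadelta", "adamax",
                       "rmsprop", "sgd", "ftrl", "sgd_nesterov",
                       "rmsprop_centered", "amsgrad")

#' The 14-dimension CNN/augmentation search space
#'
#' Dimensions in order: loss function (6 options), batch size (8..64 step 8),
#' dropout \[0, 0.6\], TL learning ratio (0..100 step 1), weights optimizer
#' (11 options), rotation (0..45 step 1), width/height shift, shear, zoom
#' \[0, 0.25\], horizontal/vertical flip (TRUE/FALSE), brightness from/to
#' \[0.5, 2.0\].
#'
#' @return a `search_space` list of dimension descriptors.
#' @export
cnn_search_space <- function() {
  dims <- list(
    list(name = "loss_function", type = "categorical", options = LOSS_FUNCTIONS),
    list(name = "batch_size", type = "stepped", grid = seq(8, 64, by = 8)),
    list(name = "dropout", type = "continuous", range = c(0, 0.6)),
    list(name = "tl_learn_ratio", type = "stepped", grid = 0:100),
    list(name = "weights_optimizer", type = "categorical", options = WEIGHT_OPTIMIZERS),
    list(name = "rotation", type = "stepped", grid = 0:45),
    list(name = "width_shift", type = "continuous", range = c(0, 0.25)),
    list(name = "height_shift", type = "continuous", range = c(0, 0.25)),
    list(name = "shear", type = "continuous", range = c(0, 0.25)),
    list(name = "zoom", type = "continuous", range = c(0, 0.25)),
    list(name = "horizontal_flip", type = "categorical", options = c(TRUE, FALSE)),
    list(name = "vertical_flip", type = "categorical", options = c(TRUE, FALSE)),
    list(name = "brightness_from", type = "continuous", range = c(0.5, 2.0)),
    list(name = "brightness_to", type = "continuous", range = c(0.5, 2.0))
  )
  structure(dims, class = "search_space")
}

decode_dim <- function(value, dim) {
  value <- min(max(value, 0), 1)
  switch(dim$type,
    continuous = dim$range[1] + value * diff(dim$range),
    stepped = {
      target <- min(dim$grid) + value * (max(dim$grid) - min(dim$grid))
      dim$grid[which.min(abs(dim$grid - target))]
    },
    categorical = {
      n <- length(dim$options)
      dim$options[[min(floor(value * n) + 1, n)]]
    })
}

#' Decode a candidate vector into a hyperparameter set
#'
#' @param vector numeric vector in `[0,1]^14`.
#' @param space a [cnn_search_space()] (or compatible `search_space`).
#' @return named `hyperparameter_set` list; `brightness_from <=
#'   brightness_to` is enforced by reordering.
#' @export
decode_hyperparameters <- function(vector, space = cnn_search_space()) {
  assert_that(length(vector) == length(space),
              "candidate has dimension %d; search space expects %d",
              length(vector), length(space))
  hp <- stats::setNames(
    lapply(seq_along(space), function(i) decode_dim(vector[i], space[[i]])),
    vapply(space, `[[`, "", "name"))
  if (!is.null(hp$brightness_from) && !is.null(hp$brightness_to) &&
      hp$brightness_from > hp$brightness_to) {
    tmp <- hp$brightness_from
    hp$brightness_from <- hp$brightness_to
    hp$brightness_to <- tmp
  }
  structure(hp, class = "hyperparameter_set")
}

#' @export
print.hyperparameter_set <- function(x, ...) {
  cat("<hyperparameter_set>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Second-location augmentation config from a decoded hyperparameter set
#' @param hp a `hyperparameter_set`.
#' @return an [augmentation_config()].
#' @export
hp_augmentation_config <- function(hp) {
  augmentation_config(rotation_deg = hp$rotation,
                      width_shift = hp$width_shift, height_shift = hp$height_shift,
                      shear = hp$shear, zoom = hp$zoom,
                      horizontal_flip = hp$horizontal_flip,
                      vertical_flip = hp$vertical_flip,
                      brightness_range = c(hp$brightness_from, hp$brightness_to))
}

#' Epoch-logging stub objective for budget accounting
#'
#' Returns an objective over `[0,1]^14` that decodes the candidate, "runs"
#' `epochs` training epochs by bumping a counter, and returns a cheap
#' deterministic surrogate score. Used to verify the optimization budget
#' (population x iterations candidate evaluations, each costing `epochs`
#' epoch calls) without GPU-scale training.
#'
#' @param epochs epochs per candidate evaluation (default 5).
#' @param space search space for decoding.
#' @return list with `objective` (function) and `counter` (environment with
#'   `epoch_calls` and `evaluations`).
#' @export
make_stub_trainer <- function(epochs = 5, space = cnn_search_space()) {
  counter <- new.env()
  counter$epoch_calls <- 0L
  counter$evaluations <- 0L
  objective <- function(v) {
    hp <- decode_hyperparameters(v, space)
    for (e in seq_len(epochs)) counter$epoch_calls <- counter$epoch_calls + 1L
    counter$evaluations <- counter$evaluations + 1L
    # deterministic surrogate: smooth in the continuous dims
    hp$dropout^2 + (hp$zoom - 0.1)^2 + abs(hp$brightness_to - hp$brightness_from)
  }
  list(objective = objective, counter = counter)
}
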