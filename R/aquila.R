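# Aquila Optimizer (AO): a population metaheuristic with four update rules
# modelled on eagle hunting. Exploration (high soar; contour flight with Levy
# steps) runs for the first two thirds of the iterations, exploitation (low
# flight; walk-and-grab) for the rest. Constants the published equations
# leave open (Levy scale, spiral terms, QF, G1, G2, alpha, gamma) follow the
# original AO reference conventions and are exposed in the config.

#' Aquila Optimizer configuration
#'
#' @param dimension problem dimension D.
#' @param population_size number of solutions (>= 2); default 10.
#' @param iterations number of iterations T (>= 1); default 25.
#' @param lower,upper per-dimension bounds (scalars recycle).
#' @param alpha,gamma exploitation adjustment parameters (default 0.1).
#' @param levy_beta Levy stability index (default 1.5).
#' @param mode `"minimize"` or `"maximize"`.
#' @param seed optional integer seed for full determinism.
#' @return an `ao_config`.
#' @export
ao_config <- function(dimension, population_size = 10, iterations = 25,
                      lower = 0, upper = 1, alpha = 0.1, gamma = 0.1,
                      levy_beta = 1.5, mode = c("minimize", "maximize"),
                      seed = NULL) {
  mode <- match.arg(mode)
  lower <- rep_len(lower, dimension); upper <- rep_len(upper, dimension)
  assert_that(all(lower < upper), "lower bound must be < upper bound per dimension")
  assert_that(population_size >= 2, "population_size must be >= 2")
  assert_that(iterations >= 1, "iterations must be >= 1")
  structure(list(dimension = as.integer(dimension),
                 population_size = as.integer(population_size),
                 iterations = as.integer(iterations),
                 lower = lower, upper = upper, alpha = alpha, gamma = gamma,
                 levy_beta = levy_beta, mode = mode, seed = seed),
            class = "ao_config")
}

#' Levy flight step vector (Mantegna construction)
#'
#' Components are `0.01 * u * sigma / |v|^(1/beta)` with u, v standard
#' normal and sigma the beta-dependent Mantegna scale.
#'
#' @param D dimension.
#' @param beta stability index in (0, 2\].
#' @param seed optional seed.
#' @return numeric vector of length D with heavy-tailed components.
#' @export
levy_flight <- function(D, beta = 1.5, seed = NULL) {
  assert_that(beta > 0 && beta <= 2, "beta must be in (0, 2]")
  with_seed_or_stream(seed, {
    sigma <- (gamma(1 + beta) * sin(pi * beta / 2) /
              (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
    u <- stats::rnorm(D) * sigma
    v <- stats::rnorm(D)
    0.01 * u / abs(v)^(1 / beta)
  })
}

#' Select the AO hunting phase for an iteration
#'
#' Exploration phases (1, 2) while `t <= (2/3) T`, exploitation phases (3, 4)
#' afterwards; within each regime the two phases are equally likely.
#'
#' @param t current iteration (0-based).
#' @param T_total total iterations.
#' @param seed optional seed.
#' @return integer phase tag 1-4.
#' @export
select_phase <- function(t, T_total, seed = NULL) {
  assert_that(t >= 0 && t < T_total, "t must satisfy 0 <= t < T")
  with_seed_or_stream(seed, {
    explore <- t <= (2 / 3) * T_total
    base <- if (explore) 1L else 3L
    base + (stats::runif(1) >= 0.5)
  })
}

# Spiral terms of the contour flight: y = r cos(theta), x = r sin(theta) with
# r = r1 + 0.00565 D1, theta = -0.005 D1 + 3 pi / 2, D1 = 1..D, r1 ~ U(1, 20).
ao_spiral <- function(D) {
  D1 <- seq_len(D)
  r1 <- stats::runif(1, 1, 20)
  r <- r1 + 0.00565 * D1
  theta <- -0.005 * D1 + 3 * pi / 2
  list(y = r * cos(theta), x = r * sin(theta))
}

#' One AO position update
#'
#' Applies the published update rule of the given phase to one member and
#' clips the result into the bounds. `state` must carry `X` (population
#' matrix), `X_best`, `X_m` (column means), `t` and `T_total`.
#'
#' @param phase tag 1-4.
#' @param member current candidate vector.
#' @param state list with the population state (see above).
#' @param config an [ao_config()].
#' @param seed optional seed.
#' @return updated candidate vector inside `[lower, upper]`.
#' @export
update_position <- function(phase, member, state, config, seed = NULL) {
  assert_that(phase %in% 1:4, "unknown phase %s", as.character(phase))
  with_seed_or_stream(seed, {
    D <- config$dimension
    t <- state$t; T_total <- state$T_total
    LB <- config$lower; UB <- config$upper
    cand <- switch(phase,
      { # 1: high soar with vertical stoop
        state$X_best * (1 - t / T_total) +
          (state$X_m - state$X_best * stats::runif(1))
      },
      { # 2: contour flight with short glide attack
        X_R <- state$X[sample.int(nrow(state$X), 1), ]
        sp <- ao_spiral(D)
        state$X_best * levy_flight(D, config$levy_beta) + X_R +
          (sp$y - sp$x) * stats::runif(1)
      },
      { # 3: low flight with slow descent attack
        (state$X_best - state$X_m) * config$alpha - stats::runif(1) +
          ((UB - LB) * stats::runif(1) + LB) * config$gamma
      },
      { # 4: walking and grab prey
        QF <- (t + 1)^((2 * stats::runif(1) - 1) / (1 - T_total)^2)
        G1 <- 2 * stats::runif(1) - 1
        G2 <- 2 * (1 - t / T_total)
        QF * state$X_best - (G1 * member * stats::runif(1)) -
          G2 * levy_flight(D, config$levy_beta) + stats::runif(1) * G1
      })
    pmin(pmax(cand, LB), UB)
  })
}

#' Run the Aquila Optimizer
#'
#' The population is initialized uniformly inside the bounds with fitness
#' unset; every candidate generated across `iterations` iterations is
#' evaluated (exactly `population_size * iterations` objective calls), a
#' member is replaced only when its candidate improves its own objective
#' (greedy replacement), and the best-so-far trajectory is monotone.
#'
#' @param objective function mapping a vector in the bounds to a finite
#'   scalar; non-finite returns are scored as worst-possible with a warning.
#' @param config an [ao_config()].
#' @param decoder optional function applied to each candidate for the history
#'   log (e.g. [decode_hyperparameters()] bound to a search space).
#' @return list: `best` (vector), `best_value`, `history` (data frame with
#'   iteration, member, phase, value, candidate columns `x1..xD`),
#'   `trajectory` (best-so-far value per evaluation), `decoded_best`.
#' @export
ao_optimize <- function(objective, config, decoder = NULL) {
  with_seed_or_stream(config$seed, {
    pop <- config$population_size
    D <- config$dimension
    T_total <- config$iterations
    sign_ <- if (config$mode == "maximize") -1 else 1
    f <- function(v) {
      val <- sign_ * objective(v)
      if (!is.finite(val)) {
        warning("objective returned a non-finite value; scoring as worst")
        val <- Inf
      }
      val
    }
    X <- matrix(stats::runif(pop * D), pop, D)
    X <- sweep(sweep(X, 2, config$upper - config$lower, "*"), 2, config$lower, "+")
    fit <- rep(Inf, pop)          # unevaluated: first candidate always accepted
    X_best <- X[1, ]; best_val <- Inf
    n_rec <- pop * T_total
    hist_iter <- integer(n_rec); hist_member <- integer(n_rec)
    hist_phase <- integer(n_rec); hist_value <- numeric(n_rec)
    hist_cand <- matrix(NA_real_, n_rec, D)
    trajectory <- numeric(n_rec)
    decoded <- if (is.null(decoder)) NULL else vector("list", n_rec)
    r <- 0L
    for (t in 0:(T_total - 1L)) {
      X_m <- colMeans(X)
      state <- list(X = X, X_best = X_best, X_m = X_m, t = t, T_total = T_total)
      for (i in seq_len(pop)) {
        phase <- select_phase(t, T_total)
        cand <- update_position(phase, X[i, ], state, config)
        val <- f(cand)
        r <- r + 1L
        hist_iter[r] <- t; hist_member[r] <- i; hist_phase[r] <- phase
        hist_value[r] <- sign_ * val; hist_cand[r, ] <- cand
        if (!is.null(decoder)) decoded[[r]] <- decoder(cand)
        if (val < fit[i]) { X[i, ] <- cand; fit[i] <- val }
        if (val < best_val) { best_val <- val; X_best <- cand }
        trajectory[r] <- sign_ * best_val
      }
    }
    history <- data.frame(iteration = hist_iter, member = hist_member,
                          phase = hist_phase, value = hist_value)
    colnames(hist_cand) <- paste0("x", seq_len(D))
    history <- cbind(history, hist_cand)
    list(best = X_best, best_value = sign_ * best_val, history = history,
         trajectory = trajectory,
         decoded_best = if (is.null(decoder)) NULL else decoder(X_best),
         decoded_history = decoded)
  })
}

#' Write an AO history as JSON lines
#' @param result an [ao_optimize()] result.
#' @param path output path.
#' @export
write_ao_history <- function(result, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(result$history))) {
    rec <- as.list(result$history[i, ])
    if (!is.null(result$decoded_history)) {
      rec$decoded <- unclass(result$decoded_history[[i]])
    }
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
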