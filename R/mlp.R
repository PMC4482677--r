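#' Hidden-layer architecture of a multilayer perceptron
#'
#' Between one and three hidden layers with at most 500 neurons each; these
#' bounds define the structure search space.
#'
#' @param hidden_sizes Integer vector of 1 to 3 hidden-layer sizes, each in
#'   `[1, 500]`.
#' @return An object of class `architecture`.
#' @export
architecture <- function(hidden_sizes) {
  hidden_sizes <- as.integer(hidden_sizes)
  if (length(hidden_sizes) < 1 || length(hidden_sizes) > 3) {
    stopf("between 1 and 3 hidden layers allowed, got %d",
          length(hidden_sizes))
  }
  if (any(hidden_sizes < 1L | hidden_sizes > 500L)) {
    stopf("hidden-layer sizes must lie in [1, 500]")
  }
  structure(list(hidden_sizes = hidden_sizes), class = "architecture")
}

#' Training configuration for scaled-conjugate-gradient backpropagation
#'
#' @param max_iterations Maximum SCG iterations (default 500).
#' @param val_fraction Fraction of the training data held out as the
#'   internal validation set used for early stopping and as the fitness
#'   set (default 0.2).
#' @param patience Consecutive iterations without a validation-kappa
#'   improvement before stopping (default 6).
#' @param scg_sigma Finite-difference step scale of the SCG Hessian-vector
#'   approximation (default 5e-5).
#' @param scg_lambda0 Initial SCG scale/trust parameter (default 5e-7).
#' @param seed Seed for the internal stratified train/validation split.
#' @return A list of class `train_config`.
#' @export
train_config <- function(max_iterations = 500, val_fraction = 0.2,
                         patience = 6, scg_sigma = 5e-5,
                         scg_lambda0 = 5e-7, seed = 1) {
  stopifnot(max_iterations >= 1, val_fraction > 0, val_fraction < 1,
            patience >= 1, scg_sigma > 0, scg_lambda0 > 0)
  structure(list(max_iterations = as.integer(max_iterations),
                 val_fraction = val_fraction,
                 patience = as.integer(patience),
                 scg_sigma = scg_sigma, scg_lambda0 = scg_lambda0,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Initialize a multilayer perceptron
#'
#' Hidden layers use the hyperbolic tangent; the output layer is either
#' softmax trained with cross-entropy (`"SOFTMAX_XENT"`, default) or tanh
#' trained with sum-of-squares (`"TANH_SSE"`).  Weights are drawn from a
#' seeded uniform distribution scaled per layer as
#' `+/- sqrt(6 / (fan_in + fan_out))`; biases start at zero.
#'
#' @param input_dim Number of inputs (channels x samples per epoch).
#' @param arch An [architecture()] or a plain vector of hidden sizes.
#' @param n_classes Number of output classes (>= 2).
#' @param seed Integer seed; the same seed reproduces the same weights.
#' @param output_mode `"SOFTMAX_XENT"` or `"TANH_SSE"`.
#' @return An object of class `network_model`.
#' @export
init_network <- function(input_dim, arch, n_classes, seed = 1,
                         output_mode = c("SOFTMAX_XENT", "TANH_SSE")) {
  if (!inherits(arch, "architecture")) arch <- architecture(arch)
  output_mode <- match.arg(output_mode)
  if (input_dim < 1) stopf("input_dim must be >= 1")
  if (n_classes < 2) stopf("need at least 2 classes")
  sizes <- c(input_dim, arch$hidden_sizes, n_classes)
  weights <- vector("list", length(sizes) - 1)
  biases <- vector("list", length(sizes) - 1)
  with_seed(seed, {
    for (l in seq_along(weights)) {
      fan_in <- sizes[l]
      fan_out <- sizes[l + 1]
      r <- sqrt(6 / (fan_in + fan_out))
      weights[[l]] <- matrix(stats::runif(fan_in * fan_out, -r, r),
                             fan_in, fan_out)
      biases[[l]] <- numeric(fan_out)
    }
  })
  structure(list(input_dim = as.integer(input_dim),
                 hidden_sizes = arch$hidden_sizes,
                 n_classes = as.integer(n_classes),
                 weights = weights, biases = biases,
                 output_mode = output_mode, seed = as.integer(seed)),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("network_model: %d -> %s -> %d (%s), %d parameters\n",
              x$input_dim, paste(x$hidden_sizes, collapse = " -> "),
              x$n_classes, x$output_mode, length(pack_params(x))))
  invisible(x)
}

pack_params <- function(model) {
  unlist(c(model$weights, model$biases), use.names = FALSE)
}

unpack_params <- function(model, par) {
  pos <- 0L
  for (l in seq_along(model$weights)) {
    n <- length(model$weights[[l]])
    model$weights[[l]][] <- par[(pos + 1):(pos + n)]
    pos <- pos + n
  }
  for (l in seq_along(model$biases)) {
    n <- length(model$biases[[l]])
    model$biases[[l]][] <- par[(pos + 1):(pos + n)]
    pos <- pos + n
  }
  model
}

# Forward pass keeping activations (for backpropagation).
forward_all <- function(model, X) {
  acts <- vector("list", length(model$weights) + 1)
  acts[[1]] <- X
  L <- length(model$weights)
  for (l in seq_len(L)) {
    Z <- acts[[l]] %*% model$weights[[l]] +
      rep(model$biases[[l]], each = nrow(X))
    if (l < L) {
      acts[[l + 1]] <- tanh(Z)
    } else {
      acts[[l + 1]] <- switch(model$output_mode,
        SOFTMAX_XENT = {
          Zs <- Z - apply(Z, 1, max)
          E <- exp(Zs)
          E / rowSums(E)
        },
        TANH_SSE = tanh(Z))
    }
  }
  acts
}

#' Forward pass of a network
#'
#' @param model A [init_network()] model.
#' @param X Matrix of flattened epochs, one per row; width must equal
#'   `model$input_dim`.
#' @return Matrix of class scores (`n x n_classes`): softmax probabilities
#'   or tanh outputs depending on the model's output mode.
#' @export
mlp_forward <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$input_dim) {
    stopf("input width %d != network input_dim %d", ncol(X),
          model$input_dim)
  }
  if (nrow(X) == 0) return(matrix(numeric(0), 0, model$n_classes))
  acts <- forward_all(model, X)
  acts[[length(acts)]]
}

#' Predict class labels
#'
#' The class is the index of the maximum output neuron; exact ties go to
#' the lowest class index.
#'
#' @inheritParams mlp_forward
#' @return Integer labels in `1:n_classes`.
#' @export
predict_class <- function(model, X) {
  scores <- mlp_forward(model, X)
  if (nrow(scores) == 0) return(integer(0))
  max.col(scores, ties.method = "first")
}

# Mean loss and gradient w.r.t. the packed parameter vector.
loss_and_grad <- function(model, par, X, Y) {
  model <- unpack_params(model, par)
  n <- nrow(X)
  acts <- forward_all(model, X)
  L <- length(model$weights)
  out <- acts[[L + 1]]
  if (model$output_mode == "SOFTMAX_XENT") {
    loss <- -sum(Y * log(pmax(out, 1e-300))) / n
    dZ <- (out - Y) / n
  } else {
    target <- 2 * Y - 1  # +/- 1 coding
    loss <- sum((out - target)^2) / (2 * n)
    dZ <- (out - target) * (1 - out^2) / n
  }
  gW <- vector("list", L)
  gb <- vector("list", L)
  for (l in L:1) {
    gW[[l]] <- crossprod(acts[[l]], dZ)
    gb[[l]] <- colSums(dZ)
    if (l > 1) {
      dZ <- (dZ %*% t(model$weights[[l]])) * (1 - acts[[l]]^2)
    }
  }
  list(loss = loss, grad = unlist(c(gW, gb), use.names = FALSE))
}

# Moller's scaled conjugate gradient minimizer.
# fn(par) must return list(loss, grad).  Calls `monitor(k, par, loss)` after
# every accepted step; monitor returns TRUE to continue, FALSE to stop.
scg_minimize <- function(par, fn, max_iterations, sigma0 = 5e-5,
                         lambda0 = 5e-7, monitor = NULL) {
  N <- length(par)
  ev <- fn(par)
  if (!is.finite(ev$loss)) stopf("non-finite initial loss")
  f_old <- f_now <- ev$loss
  grad <- ev$grad
  d <- -grad
  lambda <- lambda0
  lambda_min <- 1e-15
  lambda_max <- 1e100
  success <- TRUE
  nsuccess <- 0L
  theta <- 0; mu <- 0; kap <- 0
  for (k in seq_len(max_iterations)) {
    if (success) {
      mu <- sum(d * grad)
      if (mu >= 0) {           # ensure a descent direction
        d <- -grad
        mu <- sum(d * grad)
      }
      kap <- sum(d * d)
      if (kap < 1e-300) break
      sigma <- sigma0 / sqrt(kap)
      gplus <- fn(par + sigma * d)$grad
      theta <- sum(d * (gplus - grad)) / sigma   # curvature along d
    }
    delta <- theta + lambda * kap                # scaled curvature
    if (delta <= 0) {                            # make delta positive
      delta <- lambda * kap
      lambda <- lambda - theta / kap
    }
    alpha <- -mu / delta
    ev_new <- fn(par + alpha * d)
    if (!is.finite(ev_new$loss)) stopf("non-finite loss during SCG")
    Delta <- 2 * (ev_new$loss - f_old) / (alpha * mu)  # >= 0 iff improved
    if (Delta >= 0) {
      success <- TRUE
      nsuccess <- nsuccess + 1L
      par <- par + alpha * d
      f_now <- ev_new$loss
    } else {
      success <- FALSE
      f_now <- f_old
    }
    if (success) {
      f_old <- f_now
      grad_old <- grad
      grad <- ev_new$grad
      keep_going <- is.null(monitor) || monitor(k, par, f_now)
      if (!keep_going) break
      if (sqrt(sum(grad * grad)) < 1e-9) break
      if (nsuccess %% N == 0L) {
        d <- -grad                               # periodic restart
      } else {
        gamma <- (sum(grad * grad) - sum(grad_old * grad)) / mu
        d <- gamma * d - grad
      }
    }
    if (Delta < 0.25) lambda <- min(4 * lambda, lambda_max)
    if (Delta > 0.75) lambda <- max(0.5 * lambda, lambda_min)
    if (lambda >= lambda_max) break
  }
  list(par = par, loss = f_now)
}

one_hot <- function(y, n_classes) {
  Y <- matrix(0, length(y), n_classes)
  Y[cbind(seq_along(y), y)] <- 1
  Y
}

#' Train a network by scaled-conjugate-gradient backpropagation
#'
#' Full-batch SCG on the training portion of `(X, y)`.  A stratified,
#' seeded fraction (`cfg$val_fraction`) is held out as an internal
#' validation set; after every accepted SCG step the validation Cohen's
#' kappa is computed, the best snapshot is kept, and training stops after
#' `cfg$patience` consecutive steps without improvement (or at
#' `cfg$max_iterations`).  Training loss is non-increasing across accepted
#' steps by construction.  When the data are too few to hold out at least
#' one epoch per class, the training set doubles as the validation set.
#'
#' @param model An [init_network()] model.
#' @param X Matrix of flattened epochs (rows).
#' @param y Integer labels in `1:n_classes`; at least two classes must be
#'   present.
#' @param cfg A [train_config()].
#' @return List with the best-validation-kappa `model`, its `val_kappa`,
#'   the validation indices `val_idx`, and a per-step `trace` data frame
#'   (iteration, train_loss, val_kappa).
#' @export
scg_train <- function(model, X, y, cfg = train_config()) {
  stopifnot(inherits(model, "network_model"))
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stopf("training labels contain a single class")
  if (nrow(X) != length(y)) stopf("nrow(X) != length(y)")
  split <- stratified_split(y, cfg$val_fraction, cfg$seed)
  if (length(split$val) == 0 ||
      length(unique(y[split$val])) < length(unique(y))) {
    # too little data for a representative held-out set
    split <- list(train = seq_along(y), val = seq_along(y))
  }
  Xtr <- X[split$train, , drop = FALSE]
  ytr <- y[split$train]
  Xval <- X[split$val, , drop = FALSE]
  yval <- y[split$val]
  Y <- one_hot(ytr, model$n_classes)

  val_kappa_of <- function(par) {
    m <- unpack_params(model, par)
    cohens_kappa(confusion_matrix(yval, predict_class(m, Xval),
                                  model$n_classes))
  }

  env <- new.env()
  env$best_par <- pack_params(model)
  env$best_kappa <- val_kappa_of(env$best_par)
  env$fails <- 0L
  env$trace <- list()
  monitor <- function(k, par, loss) {
    vk <- val_kappa_of(par)
    env$trace[[length(env$trace) + 1L]] <-
      data.frame(iteration = k, train_loss = loss, val_kappa = vk)
    if (vk > env$best_kappa + 1e-12) {
      env$best_kappa <- vk
      env$best_par <- par
      env$fails <- 0L
    } else {
      # ties keep the later snapshot: equal validation kappa at lower
      # training loss (loss is non-increasing across accepted steps)
      if (vk >= env$best_kappa - 1e-12) env$best_par <- par
      env$fails <- env$fails + 1L
    }
    env$fails < cfg$patience
  }

  fn <- function(par) loss_and_grad(model, par, Xtr, Y)
  scg_minimize(pack_params(model), fn, cfg$max_iterations,
               sigma0 = cfg$scg_sigma, lambda0 = cfg$scg_lambda0,
               monitor = monitor)

  trained <- unpack_params(model, env$best_par)
  list(model = trained, val_kappa = env$best_kappa, val_idx = split$val,
       trace = if (length(env$trace)) do.call(rbind, env$trace) else
         data.frame(iteration = integer(0), train_loss = numeric(0),
                    val_kappa = numeric(0)))
}
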