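#' Simulated-annealing configuration
#'
#' @param iterations Number of perturb/retrain cycles (default 10).
#' @param tau Decay constant of the exponential acceptance schedule
#'   (default 2): at cycle `k` (1-based) a worse retrained network is still
#'   adopted with probability `exp(-k / tau)`.
#' @param seed Integer seed for perturbations and acceptance draws.
#' @return A list of class `sa_config`.
#' @export
sa_config <- function(iterations = 10, tau = 2, seed = 1) {
  stopifnot(iterations >= 0, tau > 0)
  structure(list(iterations = as.integer(iterations), tau = tau,
                 seed = as.integer(seed)),
            class = "sa_config")
}

#' Randomly perturb every weight within its own magnitude
#'
#' Each weight `w` (biases included) is replaced by `w + u` with
#' `u ~ Uniform(-|w|, |w|)`, so the result stays within `[0, 2w]` for
#' positive `w` (mirrored for negative `w`) and zero weights stay zero.
#'
#' @param model A `network_model`.
#' @param seed Integer seed; the same seed reproduces the perturbation.
#' @return The perturbed `network_model`.
#' @export
perturb_weights <- function(model, seed = 1) {
  stopifnot(inherits(model, "network_model"))
  par <- pack_params(model)
  par <- with_seed(seed, par + stats::runif(length(par), -abs(par), abs(par)))
  unpack_params(model, par)
}

#' Acceptance probability of a degraded network at annealing cycle k
#'
#' `p(k) = exp(-k / tau)` for 1-based cycle index `k`: strictly decreasing
#' in `k`, approaching 1 as `tau` grows.
#'
#' @param k Cycle index, `1 <= k <= iterations`.
#' @param cfg An [sa_config()] (or anything with a `tau` field).
#' @return Probability in `(0, 1]`.
#' @export
acceptance_probability <- function(k, cfg = sa_config()) {
  stopifnot(all(k >= 1))
  exp(-k / cfg$tau)
}

#' Simulated-annealing-augmented network training
#'
#' Trains by [scg_train()], then repeats for `sa_cfg$iterations` cycles:
#' perturb the current weights ([perturb_weights()]), retrain by SCG, and
#' compare validation kappa on the same internal validation split.  An
#' improved network is always adopted; a degraded one is adopted with
#' [acceptance_probability()].  The returned model is the best (by
#' validation kappa) ever seen, even if a later cycle moved away from it.
#'
#' @inheritParams scg_train
#' @param train_cfg A [train_config()]; its seed fixes the validation
#'   split, which is shared by every cycle of one `sa_train()` call.
#' @param sa_cfg An [sa_config()].
#' @return List with the best `model`, its `val_kappa`, the plain-SCG
#'   baseline kappa `base_kappa`, and a per-cycle `trace` data frame
#'   (iteration, kappa_before, kappa_after, p_accept, adopted).
#' @export
sa_train <- function(model, X, y, train_cfg = train_config(),
                     sa_cfg = sa_config()) {
  base <- scg_train(model, X, y, train_cfg)
  current <- base
  best <- base
  n_iter <- sa_cfg$iterations
  trace <- vector("list", n_iter)
  if (n_iter > 0) {
    seeds <- derive_seeds(sa_cfg$seed, 2L * n_iter)
    for (k in seq_len(n_iter)) {
      perturbed <- perturb_weights(current$model, seeds[[2L * k - 1L]])
      cand <- scg_train(perturbed, X, y, train_cfg)
      p_acc <- acceptance_probability(k, sa_cfg)
      improved <- cand$val_kappa > current$val_kappa
      adopted <- improved ||
        with_seed(seeds[[2L * k]], stats::runif(1)) < p_acc
      trace[[k]] <- data.frame(iteration = k,
                               kappa_before = current$val_kappa,
                               kappa_after = cand$val_kappa,
                               p_accept = if (improved) 1 else p_acc,
                               adopted = adopted)
      if (adopted) current <- cand
      if (cand$val_kappa > best$val_kappa) best <- cand
    }
  }
  list(model = best$model, val_kappa = best$val_kappa,
       base_kappa = base$val_kappa, val_idx = base$val_idx,
       trace = if (n_iter > 0) do.call(rbind, trace) else
         data.frame(iteration = integer(0), kappa_before = numeric(0),
                    kappa_after = numeric(0), p_accept = numeric(0),
                    adopted = logical(0)))
}
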