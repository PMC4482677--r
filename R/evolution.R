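#' Genetic-algorithm configuration
#'
#' Defaults are the study conditions: population 30, 20 generations, one
#' elite, 2% mutation.
#'
#' @param population Population size (>= 2, default 30).
#' @param generations Number of generations (default 20).
#' @param elites Individuals carried over unchanged (default 1).
#' @param mutation_rate Per-individual probability that one random genome
#'   bit flips (default 0.02).
#' @param max_neurons Upper bound used when sampling initial neuron counts
#'   (default 500; lower it for desk-scale runs).
#' @param seed Integer seed for the whole GA run.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population = 30, generations = 20, elites = 1,
                      mutation_rate = 0.02, max_neurons = 500, seed = 1) {
  stopifnot(population >= 2, generations >= 0, elites >= 0,
            elites < population, mutation_rate >= 0, mutation_rate <= 1,
            max_neurons >= 1, max_neurons <= 500)
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 elites = as.integer(elites),
                 mutation_rate = mutation_rate,
                 max_neurons = as.integer(max_neurons),
                 seed = as.integer(seed)),
            class = "ga_config")
}

GENOME_BITS <- 29L   # 2 bits layer count + 3 x 9 bits neuron counts

bits_to_int <- function(bits) {
  sum(bits * 2^((length(bits) - 1):0))
}

int_to_bits <- function(x, width) {
  as.integer(rev(as.integer(intToBits(x))[seq_len(width)]))
}

check_genome <- function(g) {
  g <- as.integer(g)
  if (length(g) != GENOME_BITS || any(g != 0L & g != 1L)) {
    stopf("a genome is a binary vector of exactly %d bits", GENOME_BITS)
  }
  g
}

#' Decode a 29-bit genome into a network architecture
#'
#' Layout: 2 leading bits encode the hidden-layer count (00 -> 1, 01 -> 2,
#' 10 -> 3, 11 clamped to 3), followed by three 9-bit big-endian neuron
#' fields, each clamped into `[1, 500]`; fields beyond the layer count are
#' ignored.  Decoding is total: every bit pattern yields a valid
#' architecture.
#'
#' @param g Integer vector of 29 bits (0/1).
#' @return An [architecture()].
#' @export
decode_genome <- function(g) {
  g <- check_genome(g)
  n_layers <- min(bits_to_int(g[1:2]), 2L) + 1L
  sizes <- vapply(seq_len(n_layers), function(l) {
    field <- g[(3L + (l - 1L) * 9L):(2L + l * 9L)]
    min(max(bits_to_int(field), 1L), 500L)
  }, numeric(1))
  architecture(sizes)
}

#' Encode an architecture as a 29-bit genome
#'
#' Inverse of [decode_genome()]: `decode_genome(encode_architecture(a))`
#' recovers `a` exactly.  Unused neuron fields are zero.
#'
#' @param a An [architecture()] or plain vector of hidden sizes.
#' @return Integer vector of 29 bits.
#' @export
encode_architecture <- function(a) {
  if (!inherits(a, "architecture")) a <- architecture(a)
  sizes <- a$hidden_sizes
  g <- integer(GENOME_BITS)
  g[1:2] <- int_to_bits(length(sizes) - 1L, 2L)
  for (l in seq_along(sizes)) {
    g[(3L + (l - 1L) * 9L):(2L + l * 9L)] <- int_to_bits(sizes[l], 9L)
  }
  g
}

#' Mutate a genome
#'
#' With probability `rate`, exactly one uniformly chosen bit is flipped
#' (Hamming distance 1); otherwise the genome is returned unchanged.
#'
#' @param g 29-bit genome.
#' @param rate Mutation probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return The (possibly) mutated genome.
#' @export
mutate_genome <- function(g, rate, seed = 1) {
  g <- check_genome(g)
  with_seed(seed, {
    if (stats::runif(1) < rate) {
      i <- sample.int(GENOME_BITS, 1L)
      g[i] <- 1L - g[i]
    }
  })
  g
}

#' Single-point crossover of two genomes
#'
#' The crossover point `c` is drawn uniformly from `1..28`; the child takes
#' the first `c` bits from `a` and the rest from `b`.
#'
#' @param a,b Parent genomes (29 bits each).
#' @param seed Integer seed.
#' @return The child genome.
#' @export
crossover_genomes <- function(a, b, seed = 1) {
  a <- check_genome(a)
  b <- check_genome(b)
  cut <- with_seed(seed, sample.int(GENOME_BITS - 1L, 1L))
  c(a[seq_len(cut)], b[(cut + 1L):GENOME_BITS])
}

#' Roulette-wheel parent selection
#'
#' Selection probability is proportional to the shifted fitness
#' `f' = f - min(f) + 1e-6`, which stays valid for negative or all-equal
#' kappa values (all-equal fitness reduces to uniform selection).
#'
#' @param fitnesses Numeric fitness values (Cohen's kappa), length >= 1.
#' @param seed Integer seed.
#' @return The selected index.
#' @export
roulette_select <- function(fitnesses, seed = 1) {
  if (length(fitnesses) < 1) stopf("need at least one individual")
  w <- fitnesses - min(fitnesses) + 1e-6
  with_seed(seed, sample.int(length(fitnesses), 1L, prob = w))
}

#' Initialize a stratified population of genomes
#'
#' Hidden-layer counts are stratified so the numbers of one-, two- and
#' three-layer networks differ by at most one; neuron counts are uniform
#' on `[1, cfg$max_neurons]`.
#'
#' @param cfg A [ga_config()] with `population >= 3`.
#' @param seed Integer seed (default: `cfg$seed`).
#' @return List of genomes.
#' @export
init_population <- function(cfg = ga_config(), seed = cfg$seed) {
  if (cfg$population < 3) stopf("population must be >= 3 for stratification")
  layer_counts <- rep_len(1:3, cfg$population)
  with_seed(seed, {
    layer_counts <- sample(layer_counts)
    lapply(layer_counts, function(L) {
      encode_architecture(sample.int(cfg$max_neurons, L, replace = TRUE))
    })
  })
}

# Internal: train the genome's network and return both fitness and model.
fit_genome <- function(g, X, y, n_classes, train_cfg, sa_cfg, seed) {
  arch <- decode_genome(g)
  model <- init_network(ncol(X), arch, n_classes, seed = seed)
  fit <- sa_train(model, X, y, train_cfg, sa_cfg)
  list(fitness = fit$val_kappa, model = fit$model)
}

#' Fitness of a genome: validation kappa of its trained network
#'
#' Decodes the genome, initializes the network (seeded), trains it with
#' [sa_train()], and returns the Cohen's kappa on the internal validation
#' split.  Deterministic given the data and all seeds.
#'
#' @param g 29-bit genome.
#' @param X Matrix of flattened epochs.
#' @param y Integer labels in `1:n_classes` (>= 2 classes present).
#' @param n_classes Number of classes.
#' @param train_cfg A [train_config()].
#' @param sa_cfg An [sa_config()].
#' @param seed Seed for weight initialization.
#' @return Validation kappa (numeric scalar).
#' @export
evaluate_fitness <- function(g, X, y, n_classes = max(y),
                             train_cfg = train_config(),
                             sa_cfg = sa_config(), seed = 1) {
  fit_genome(g, X, y, n_classes, train_cfg, sa_cfg, seed)$fitness
}

#' Run the genetic algorithm over network structures
#'
#' Generational GA: the top `elites` individuals (with their fitness) are
#' carried over unchanged, and the remainder of each generation is filled
#' with `mutate(crossover(roulette, roulette))` offspring.  One internal
#' validation split (fixed by `train_cfg$seed`) is used for every fitness
#' evaluation of the run so fitnesses are comparable across genomes.  With
#' `generations = 0` the best of the initial population is returned.
#'
#' @inheritParams evaluate_fitness
#' @param ga_cfg A [ga_config()].
#' @return An object of class `ga_result`: `best_model`, `best_genome`,
#'   `best_fitness`, and a per-generation `history` data frame
#'   (generation, min, mean, max, elite).
#' @export
run_ga <- function(X, y, ga_cfg = ga_config(), train_cfg = train_config(),
                   sa_cfg = sa_config()) {
  X <- as.matrix(X)
  y <- as.integer(y)
  n_classes <- max(y)
  n_gen <- ga_cfg$generations
  seeds <- derive_seeds(ga_cfg$seed, 2L + n_gen)
  pop <- init_population(ga_cfg, seeds[[1L]])

  eval_pop <- function(genomes, gen_seed, keep = rep(FALSE, length(genomes))) {
    sub_seeds <- derive_seeds(gen_seed, length(genomes))
    lapply(seq_along(genomes), function(i) {
      if (keep[i]) return(NULL)  # placeholder; elite filled by caller
      fit_genome(genomes[[i]], X, y, n_classes, train_cfg, sa_cfg,
                 sub_seeds[[i]])
    })
  }

  evals <- eval_pop(pop, seeds[[2L]])
  fitness <- vapply(evals, `[[`, numeric(1), "fitness")
  best_i <- which.max(fitness)
  best <- list(genome = pop[[best_i]], fitness = fitness[best_i],
               model = evals[[best_i]]$model)
  history <- list(data.frame(generation = 0L, min = min(fitness),
                             mean = mean(fitness), max = max(fitness),
                             elite = max(fitness)))

  for (gen in seq_len(n_gen)) {
    gen_seeds <- derive_seeds(seeds[[2L + gen]], 3L * ga_cfg$population + 1L)
    elite_order <- order(fitness, decreasing = TRUE)
    elite_idx <- elite_order[seq_len(ga_cfg$elites)]
    new_pop <- pop[elite_idx]
    new_evals <- evals[elite_idx]
    new_fitness <- fitness[elite_idx]
    for (j in seq_len(ga_cfg$population - ga_cfg$elites)) {
      pa <- roulette_select(fitness, gen_seeds[[3L * j - 2L]])
      pb <- roulette_select(fitness, gen_seeds[[3L * j - 1L]])
      child <- crossover_genomes(pop[[pa]], pop[[pb]],
                                 gen_seeds[[3L * j]])
      child <- mutate_genome(child, ga_cfg$mutation_rate,
                             gen_seeds[[3L * j]] %% 1000003L + j)
      new_pop <- c(new_pop, list(child))
    }
    offspring_idx <- (ga_cfg$elites + 1L):ga_cfg$population
    off_evals <- eval_pop(new_pop[offspring_idx],
                          gen_seeds[[3L * ga_cfg$population + 1L]])
    pop <- new_pop
    evals <- c(new_evals, off_evals)
    fitness <- c(new_fitness,
                 vapply(off_evals, `[[`, numeric(1), "fitness"))
    gi <- which.max(fitness)
    if (fitness[gi] > best$fitness) {
      best <- list(genome = pop[[gi]], fitness = fitness[gi],
                   model = evals[[gi]]$model)
    }
    history[[gen + 1L]] <- data.frame(
      generation = gen, min = min(fitness), mean = mean(fitness),
      max = max(fitness), elite = best$fitness)
  }

  structure(list(best_model = best$model, best_genome = best$genome,
                 best_fitness = best$fitness,
                 history = do.call(rbind, history)),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf(
    "ga_result: best architecture [%s], validation kappa %.3f (%d generations)\n",
    paste(decode_genome(x$best_genome)$hidden_sizes, collapse = ", "),
    x$best_fitness, max(x$history$generation)))
  invisible(x)
}
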