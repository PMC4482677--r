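test_that("genome decoding clamps into the allowed structure space", {
  expect_equal(decode_genome(rep(0L, 29))$hidden_sizes, 1L)
  expect_equal(decode_genome(rep(1L, 29))$hidden_sizes, c(500L, 500L, 500L))
  # layer-count field: 00 -> 1, 01 -> 2, 10 -> 3, 11 -> 3 (clamped)
  g <- rep(0L, 29)
  g[11] <- 1L                       # second neuron field = 256 (unused)
  expect_length(decode_genome(g)$hidden_sizes, 1)
  g[2] <- 1L
  expect_length(decode_genome(g)$hidden_sizes, 2)
  g[1] <- 1L; g[2] <- 0L
  expect_length(decode_genome(g)$hidden_sizes, 3)
  g[2] <- 1L
  expect_length(decode_genome(g)$hidden_sizes, 3)
  expect_error(decode_genome(rep(0L, 28)), "29 bits")
})

test_that("architecture encoding round-trips through the genome", {
  expect_equal(encode_architecture(1)[1:2], c(0L, 0L))
  set.seed(2)
  for (rep in 1:100) {
    L <- sample(1:3, 1)
    sizes <- sample(1:500, L, replace = TRUE)
    g <- encode_architecture(sizes)
    expect_length(g, 29)
    expect_equal(decode_genome(g)$hidden_sizes, as.integer(sizes))
  }
  expect_equal(decode_genome(encode_architecture(c(120, 300)))$hidden_sizes,
               c(120L, 300L))
  expect_error(encode_architecture(c(600)), "\\[1, 500\\]")
})

test_that("mutation flips at most one bit at the configured rate", {
  g <- encode_architecture(c(37, 255))
  expect_identical(mutate_genome(g, 0, seed = 1), g)
  for (s in 1:20) {
    expect_equal(sum(mutate_genome(g, 1, seed = s) != g), 1)
  }
  flips <- vapply(1:10000, function(s) {
    any(mutate_genome(g, 0.02, seed = s) != g)
  }, logical(1))
  expect_gte(mean(flips), 0.015)
  expect_lte(mean(flips), 0.025)
})

test_that("single-point crossover recombines parent prefixes and suffixes", {
  a <- rep(0L, 29)
  b <- rep(1L, 29)
  expect_identical(crossover_genomes(a, a, seed = 1), a)
  for (s in 1:50) {
    child <- crossover_genomes(a, b, seed = s)
    # child is 0...0 1...1: exactly one switch point in 1..28
    switches <- which(diff(child) != 0)
    expect_length(switches, 1)
    expect_gte(switches, 1)
    expect_lte(switches, 28)
  }
  # every child bit comes from a parent at the same position
  set.seed(7)
  for (rep in 1:50) {
    pa <- sample(0:1, 29, replace = TRUE)
    pb <- sample(0:1, 29, replace = TRUE)
    child <- crossover_genomes(pa, pb, seed = rep)
    expect_true(all(child == pa | child == pb))
  }
  expect_error(crossover_genomes(a, rep(0L, 28), seed = 1), "29 bits")
})

test_that("roulette selection is fitness-proportional on shifted kappas", {
  expect_equal(roulette_select(0.4, seed = 1), 1)
  # [0, 0, 1]: the fit individual wins essentially always
  picks <- vapply(1:500, function(s) {
    roulette_select(c(0, 0, 1), seed = s)
  }, integer(1))
  expect_true(all(picks == 3))
  # all-equal (including negative) fitness -> uniform selection
  picks_eq <- vapply(1:10000, function(s) {
    roulette_select(c(-0.2, -0.2, -0.2, -0.2), seed = s)
  }, integer(1))
  freq <- tabulate(picks_eq, 4) / 10000
  expect_true(all(abs(freq - 0.25) < 3 * sqrt(0.25 * 0.75 / 10000) + 0.005))
})

test_that("initial populations stratify layer counts evenly", {
  pop30 <- init_population(ga_config(population = 30, seed = 1))
  layers <- vapply(pop30, function(g) length(decode_genome(g)$hidden_sizes),
                   integer(1))
  expect_equal(as.vector(table(layers)), c(10, 10, 10))
  pop31 <- init_population(ga_config(population = 31, seed = 1))
  layers31 <- vapply(pop31, function(g) length(decode_genome(g)$hidden_sizes),
                     integer(1))
  expect_equal(sort(as.vector(table(layers31))), c(10, 10, 11))
  expect_identical(init_population(ga_config(population = 30, seed = 1)),
                   pop30)
  # neuron sampling respects max_neurons
  pop <- init_population(ga_config(population = 9, max_neurons = 32, seed = 2))
  expect_true(all(unlist(lapply(pop, function(g)
    decode_genome(g)$hidden_sizes)) <= 32))
})

test_that("fitness is the validation kappa of the trained network", {
  es <- demean_epochs(synth_epochs(synth_config(
    n_epochs = 20, effect_amplitude = 20, seed = 5)))
  X <- flatten_epochs(es)
  g <- encode_architecture(8)
  tc <- train_config(max_iterations = 40, patience = 8, seed = 1)
  sc <- sa_config(iterations = 0)
  f1 <- evaluate_fitness(g, X, es$labels, 2, tc, sc, seed = 3)
  expect_gte(f1, 0.9)                       # separable data
  expect_identical(f1, evaluate_fitness(g, X, es$labels, 2, tc, sc, seed = 3))
})

test_that("chance-level data yields chance-level fitness", {
  g <- encode_architecture(8)
  set.seed(42)
  fits <- vapply(1:20, function(s) {
    es <- demean_epochs(synth_epochs(synth_config(
      n_epochs = 200, effect_amplitude = 4, seed = s)))
    X <- flatten_epochs(es)
    # shuffling the labels destroys the planted class structure
    evaluate_fitness(g, X, sample(es$labels), 2,
                     train_config(max_iterations = 30, patience = 6,
                                  val_fraction = 0.25, seed = s),
                     sa_config(iterations = 0), seed = s)
  }, numeric(1))
  expect_lt(abs(mean(fits)), 0.1)
})

test_that("the genetic algorithm improves and respects elitism", {
  es <- demean_epochs(synth_epochs(synth_config(
    n_epochs = 15, effect_amplitude = 6, seed = 3)))
  X <- flatten_epochs(es)
  tc <- train_config(max_iterations = 30, patience = 6, seed = 1)
  sc <- sa_config(iterations = 0)
  gc0 <- ga_config(population = 6, generations = 0, max_neurons = 32,
                   seed = 4)
  r0 <- run_ga(X, es$labels, gc0, tc, sc)
  expect_equal(nrow(r0$history), 1)           # best of initial population
  expect_equal(r0$best_fitness, r0$history$max[1])
  gc <- ga_config(population = 6, generations = 4, max_neurons = 32,
                  seed = 4)
  r <- run_ga(X, es$labels, gc, tc, sc)
  expect_false(is.unsorted(r$history$elite))  # elitism invariant
  expect_gte(r$best_fitness, median(r$history$max[1]))
  # all evaluated architectures respect the structural bounds
  arch <- decode_genome(r$best_genome)$hidden_sizes
  expect_lte(length(arch), 3)
  expect_true(all(arch >= 1 & arch <= 500))
  # determinism of a full run
  r2 <- run_ga(X, es$labels, gc, tc, sc)
  expect_identical(r$history, r2$history)
  expect_identical(r$best_genome, r2$best_genome)
})
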