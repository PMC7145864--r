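test_that("random genomes validate and respect a degenerate space", {
  space <- rt_search_space()
  set.seed(1)
  for (i in 1:20) expect_true(validate_genome(random_genome(space), space))
  single <- rt_search_space(conv_layers = c(2L, 2L), feature_maps = 16L,
                            activations = "relu", dropout_rates = 0.1,
                            dense_layers = c(1L, 1L), dense_units = 32L,
                            optimizers = "adam")
  g1 <- random_genome(single)
  g2 <- random_genome(single)
  # batch-norm/pool flags are always free; all other fields are pinned
  strip_flags <- function(g) {
    for (i in seq_along(g$conv))
      g$conv[[i]]$batch_norm <- g$conv[[i]]$max_pool <- NULL
    for (i in seq_along(g$dense)) g$dense[[i]]$batch_norm <- NULL
    g
  }
  expect_identical(strip_flags(g1), strip_flags(g2))
  # determinism under a fixed RNG state
  set.seed(42); a <- random_genome(space)
  set.seed(42); b <- random_genome(space)
  expect_identical(a, b)
})

test_that("sampled field values are uniform over their allowed sets", {
  space <- rt_search_space()
  set.seed(11)
  acts <- replicate(3000, random_genome(space)$conv[[1]]$activation)
  freq <- table(acts) / 3000
  k <- length(space$activations)
  sigma <- sqrt((1 / k) * (1 - 1 / k) / 3000)
  expect_true(all(abs(freq - 1 / k) < 4 * sigma))
})

test_that("mutation resamples fields at the requested rate", {
  space <- rt_search_space()
  set.seed(2)
  g <- random_genome(space)
  expect_identical(mutate_genome(g, space, rate = 0), g)
  single <- rt_search_space(conv_layers = c(1L, 1L), feature_maps = 16L,
                            activations = "relu", dropout_rates = 0.1,
                            dense_layers = c(1L, 1L), dense_units = 32L,
                            optimizers = "adam")
  gs <- random_genome(single)
  mut <- mutate_genome(gs, single, rate = 1)
  mut$conv[[1]]$batch_norm <- gs$conv[[1]]$batch_norm  # only free fields
  mut$conv[[1]]$max_pool <- gs$conv[[1]]$max_pool
  mut$dense[[1]]$batch_norm <- gs$dense[[1]]$batch_norm
  expect_identical(mut, gs)
  # change frequency of one 4-valued field at rate 0.1:
  # P(change) = 0.1 * (1 - 1/4)
  set.seed(3)
  changed <- mean(replicate(4000, {
    m <- mutate_genome(g, space, rate = 0.1)
    m$conv[[1]]$filters != g$conv[[1]]$filters
  }))
  p <- 0.1 * (1 - 1 / 4)
  expect_lt(abs(changed - p), 4 * sqrt(p * (1 - p) / 4000))
})

test_that("uniform crossover mixes aligned slots and fixes identical parents", {
  space <- rt_search_space()
  set.seed(4)
  a <- random_genome(space)
  kids <- crossover_genomes(a, a)
  expect_identical(kids[[1]], a)
  expect_identical(kids[[2]], a)
  # parents differing in one slot -> children differ at most there
  b <- a
  b$optimizer <- setdiff(space$optimizers, a$optimizer)[1]
  kids <- crossover_genomes(a, b)
  for (child in kids) {
    tmp <- child
    tmp$optimizer <- a$optimizer
    expect_identical(tmp, a)
  }
  # each slot inherited from parent a with frequency ~0.5
  b2 <- mutate_genome(a, space, rate = 1)
  set.seed(5)
  from_a <- replicate(2000, {
    k <- crossover_genomes(a, b2)[[1]]
    k$n_conv == a$n_conv
  })
  if (a$n_conv != b2$n_conv) {
    p <- mean(from_a)
    expect_lt(abs(p - 0.5), 4 * sqrt(0.25 / 2000))
  }
  for (child in kids) expect_true(validate_genome(child, space))
})

test_that("tournament selection favours low validation MSE as expected", {
  fitness <- (1:10) / 10  # rank i has fitness i/10
  # tournament of the whole population always returns the best
  set.seed(6)
  picks <- select_parents(fitness, 50, tournament_size = 10)
  expect_true(all(picks == 1L))
  # size-1 tournaments are uniform draws
  picks1 <- select_parents(fitness, 4000, tournament_size = 1)
  freq <- tabulate(picks1, 10) / length(picks1)
  expect_true(all(abs(freq - 0.1) < 4 * sqrt(0.1 * 0.9 / 8000)))
  # size-3 without replacement: P(winner is rank 1) = 1 - C(9,3)/C(10,3)
  picks3 <- select_parents(fitness, 4000, tournament_size = 3)
  p_best <- mean(picks3 == 1L)
  p_theory <- 1 - choose(9, 3) / choose(10, 3)  # = 0.3
  expect_lt(abs(p_best - p_theory), 4 * sqrt(0.3 * 0.7 / 8000))
  expect_error(select_parents(c(1, NA, 3), 1), "evaluated")
})

test_that("genomes survive JSON round-trips", {
  space <- rt_search_space()
  set.seed(7)
  g <- random_genome(space)
  g2 <- genome_from_json(genome_to_json(g))
  expect_true(validate_genome(g2, space))
  expect_equal(unclass(g2), unclass(g), tolerance = 0)
})
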