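test_that("half-life decay halves at every half-life period", {
  expect_equal(half_life_decay(0.8, 1.5, 0), 0.8)
  expect_equal(half_life_decay(0.8, 1.5, 1.5), 0.4, tolerance = 1e-12)
  expect_equal(half_life_decay(0.8, 1.5, 3.0), 0.2, tolerance = 1e-12)
  # strictly decreasing in t
  g <- half_life_decay(1, 1, seq(0, 10, by = 0.5))
  expect_true(all(diff(g) < 0))
  expect_error(half_life_decay(1, 0, 1), "t_half")
})

test_that("trail freshness is a strict threshold on the decay constant", {
  expect_identical(trail_is_new(1.5), 1L)
  expect_identical(trail_is_new(0.5), 0L)
  expect_identical(trail_is_new(1.0), 0L)
})

test_that("population initialization is seeded and sized", {
  p <- kestrel_params(population_size = 200, seed = 3)
  set.seed(3)
  pop <- init_population(p)
  expect_length(pop, 200)
  expect_true(all(vapply(pop, function(c) length(c$bits), integer(1)) == 256L))
  expect_true(all(vapply(pop, function(c) c$fitness, numeric(1)) >= 0))
  expect_true(all(vapply(pop, function(c) c$fitness, numeric(1)) <= 8))
  set.seed(3)
  pop2 <- init_population(p)
  expect_identical(pop, pop2)
  different <- 0L
  for (s in 1:20) {
    set.seed(s); a <- init_population(kestrel_params(population_size = 5), 64)
    set.seed(s + 1000); b <- init_population(kestrel_params(population_size = 5), 64)
    if (!identical(a, b)) different <- different + 1L
  }
  expect_identical(different, 20L)
})

test_that("the search is elitist and never crowns a degenerate key", {
  p <- kestrel_params(population_size = 20, iterations = 10, seed = 5)
  set.seed(5)
  pop <- init_population(p)
  init_best <- max(vapply(pop, function(c) c$fitness, numeric(1)))
  winner <- kestrel_search(pop, p)
  expect_gte(winner$fitness, init_best)

  # an all-zero-bit candidate (fitness 0) cannot win against random ones
  zero <- pop[[1]]
  zero$gamma <- rep(0, 256)
  zero$rand_bits <- rep(0L, 256)
  zero$bits <- rep(0L, 256)
  zero$fitness <- shannon_entropy(as.raw(rep(0, 32)))
  expect_equal(zero$fitness, 0)
  pop[[1]] <- zero
  winner2 <- kestrel_search(pop, p)
  expect_gt(winner2$fitness, 0)

  expect_error(kestrel_search(list(), p), "empty")
  # single candidate, zero iterations: returned unchanged
  p0 <- kestrel_params(population_size = 2, iterations = 0, seed = 1)
  w <- kestrel_search(pop[2], p0)
  expect_identical(w, pop[[2]])
})

test_that("unique feature key is deterministic with avalanche behaviour", {
  v <- c(0.1, 2.5, -3.25, 100)
  expect_identical(unique_feature_key(v), unique_feature_key(v))
  expect_length(unique_feature_key(v), 32L)
  expect_error(unique_feature_key(numeric(0)), "empty")
  expect_error(unique_feature_key(c(1, NaN)), "finite")

  set.seed(17)
  hd <- replicate(200, {
    x <- runif(30, -10, 10)
    y <- x
    i <- sample(30, 1)
    y[i] <- y[i] + 1e-6
    hamming_bits(unique_feature_key(x), unique_feature_key(y))
  })
  expect_gte(mean(hd), 0.4 * 256)
  expect_lte(mean(hd), 0.6 * 256)
})

test_that("final key assembly is 256-bit, deterministic, collision-free", {
  p <- kestrel_params(population_size = 10, iterations = 3, seed = 2)
  fused <- c(a = 1.5, b = -0.25, c = 10)
  k1 <- generate_biokey(fused, p)
  k2 <- generate_biokey(fused, p)
  expect_identical(k1$final_key, k2$final_key)
  expect_identical(k1$nonce, k2$nonce)
  expect_length(k1$final_key, 32L)
  expect_length(k1$nonce, 12L)

  # different winners (different seeds) never collide over 100 trials
  keys <- vapply(1:100, function(s) {
    raw_to_hex(generate_biokey(fused, kestrel_params(
      population_size = 4, iterations = 1, seed = s))$final_key)
  }, character(1))
  expect_identical(anyDuplicated(keys), 0L)

  # changing the fused vector changes the key
  k3 <- generate_biokey(fused + 1e-3, p)
  expect_false(identical(k1$final_key, k3$final_key))
})

test_that("key files round trip through disk", {
  k <- generate_biokey(c(x = 1, y = 2),
                       kestrel_params(population_size = 4,
                                      iterations = 1, seed = 9))
  path <- withr::local_tempfile(fileext = ".bin")
  write_key(k, path)
  back <- read_key(path)
  expect_identical(back$final_key, k$final_key)
  expect_identical(back$nonce, k$nonce)
  expect_identical(back$provenance$params$seed, 9L)
})

test_that("entropy estimators match the frequency-count oracle", {
  u <- as.raw(0:255)
  expect_equal(shannon_entropy(u), 8.0)
  expect_equal(min_entropy(u), 8.0)
  expect_equal(shannon_entropy(as.raw(rep(7, 100))), 0)
  expect_equal(min_entropy(as.raw(rep(7, 100))), 0)
  half <- as.raw(c(rep(0, 50), rep(255, 50)))
  expect_equal(shannon_entropy(half), 1.0)
  expect_equal(min_entropy(half), 1.0)
  expect_error(shannon_entropy(raw(0)), "empty")

  set.seed(23)
  for (i in 1:100) {
    b <- random_bytes(sample(10:500, 1))
    expect_equal(shannon_entropy(b), entropy_oracle(b), tolerance = 1e-12)
    expect_equal(min_entropy(b), min_entropy_oracle(b), tolerance = 1e-12)
  }
})
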