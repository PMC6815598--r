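test_that("construction heuristics follow their closed forms", {
  expect_equal(heuristic_select(2, 3), 0.5)
  expect_equal(heuristic_select(0, 7), 0)
  expect_equal(heuristic_select(1.3, 0), 1.3)
  # skip heuristic is the mean score under the same discount
  expect_equal(heuristic_skip(1, 0), 1)          # all F_k = 1, p = 10
  expect_equal(heuristic_skip(1, 4), 0.2)
  expect_equal(heuristic_skip(0, 3), 0)
})

test_that("transition probabilities normalize and weight as specified", {
  expect_equal(transition_probability(1, 1, 2, 2, 1.2, 0.2), c(0.5, 0.5))
  # beta = 0: heuristics drop out entirely
  expect_equal(transition_probability(0.3, 0.9, 5, 0.001, 1, 0),
               c(0.25, 0.75))
  # tau = (1, 1), eta = (1, 4), alpha = 1, beta = 0.5 -> p1 = 2/3
  expect_equal(transition_probability(1, 1, 1, 4, 1, 0.5)[2], 2 / 3)
  # both weighted terms zero -> unbiased coin
  expect_equal(transition_probability(1, 1, 0, 0, 1.2, 0.2), c(0.5, 0.5))
  # normalization holds across random parameterizations
  set.seed(51)
  for (i in 1:200) {
    pr <- transition_probability(runif(1, 0.05, 1.4), runif(1, 0.05, 1.4),
                                 runif(1, 0, 3), runif(1, 0, 3),
                                 runif(1, 0.5, 2), runif(1, 0, 1))
    expect_equal(sum(pr), 1, tolerance = 1e-12)
    expect_true(all(pr >= 0))
  }
})

test_that("path construction is seeded, forceable, and repairs empty draws", {
  params <- aco_params(alpha = 40)
  fisher <- runif(8, 0.5, 2)
  pher <- init_pheromone(8, params)
  pher[, 1] <- params$tau_min
  pher[, 2] <- params$tau_max
  set.seed(52)
  expect_equal(construct_path(pher, fisher, params), rep(1L, 8))

  set.seed(53)
  b1 <- construct_path(init_pheromone(8, params), fisher, aco_params())
  set.seed(53)
  b2 <- construct_path(init_pheromone(8, params), fisher, aco_params())
  expect_identical(b1, b2)

  # select-pathway mass squeezed to ~0: the repair rule must kick in
  pher0 <- init_pheromone(1, params)
  pher0[, 1] <- params$tau_max
  pher0[, 2] <- params$tau_min
  set.seed(54)
  expect_equal(construct_path(pher0, 1.0, params), 1L)
})

test_that("local update deposits on the used pathway and evaporates the rest", {
  params <- aco_params()
  pher <- init_pheromone(3, params)
  bits <- c(1L, 0L, 1L)
  # CA = 1, lambda = 1.6, 2 of 3 genes -> deposit = 1.6 - 2/3
  dep <- 1.6 - 2 / 3
  out <- local_pheromone_update(pher, bits, accuracy = 1, params)
  expect_equal(unname(out[1, "select"]), 0.998 * 1 + 0.002 * dep)
  expect_equal(unname(out[1, "skip"]), 0.998)            # pure evaporation
  expect_equal(unname(out[2, "skip"]), 0.998 * 1 + 0.002 * dep)
  expect_equal(unname(out[2, "select"]), 0.998)
})

test_that("global update touches only the best path and clamps", {
  params <- aco_params()
  pher <- init_pheromone(4, params)
  pher[, ] <- 1.2
  bits <- c(1L, 1L, 0L, 0L)
  out <- global_pheromone_update(pher, bits, accuracy = 1, params)
  dep <- 1.6 - 2 / 4
  expect_equal(unname(out[1, "select"]), 0.94 * 1.2 + 0.06 * dep)
  expect_equal(unname(out[1, "skip"]), 1.2)              # off-path: unchanged
  expect_equal(unname(out[3, "select"]), 1.2)
  expect_equal(unname(out[3, "skip"]), 0.94 * 1.2 + 0.06 * dep)

  pher[, ] <- params$tau_max
  out2 <- global_pheromone_update(pher, bits, accuracy = 1, params)
  expect_true(all(out2 <= params$tau_max))
})

test_that("pheromones stay clamped under long random update sequences", {
  params <- aco_params()
  pher <- init_pheromone(6, params)
  set.seed(55)
  for (i in 1:300) {
    bits <- rbinom(6, 1, 0.5)
    if (sum(bits) == 0) bits[1] <- 1L
    pher <- local_pheromone_update(pher, bits, runif(1), params)
    if (i %% 10 == 0) {
      pher <- global_pheromone_update(pher, bits, runif(1), params)
    }
    expect_true(all(pher >= params$tau_min - 1e-15))
    expect_true(all(pher <= params$tau_max + 1e-15))
  }
})

test_that("run_aco is deterministic and its best-so-far trajectory is monotone", {
  gen <- generate_dataset(synthetic_spec(M = 40, N = 30, c = 2,
                                         n_informative = 3, n_blocks = 2,
                                         block_size = 4, seed = 6))
  ds <- gen$dataset
  params <- aco_params(m = 5, n_max = 10, seed = 77)
  r1 <- run_aco(ds, params = params)
  r2 <- run_aco(ds, params = params)
  expect_identical(r1$best$bits, r2$best$bits)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_equal(nrow(r1$trajectory), 10L)
  expect_true(all(diff(r1$trajectory$fitness) >= 0))
  expect_true(all(r1$pheromone >= params$tau_min &
                    r1$pheromone <= params$tau_max))
  expect_equal(r1$best$selected, which(r1$best$bits == 1L))
  expect_gte(length(r1$best$selected), 1L)
})

test_that("with beta = 0 and uniform trails, first-iteration selection is a fair coin", {
  params <- aco_params(beta = 0)
  pher <- init_pheromone(40, params)
  fisher <- runif(40, 0, 2)
  set.seed(56)
  freq <- rowMeans(vapply(1:400, function(i) construct_path(pher, fisher, params),
                          integer(40)))
  # 400 draws per gene: a fair coin stays within +/- 5 SDs of 0.5
  expect_true(all(abs(freq - 0.5) < 5 * sqrt(0.25 / 400)))
})

test_that("n_max = 0 degenerates to the evaluated full candidate set", {
  gen <- generate_dataset(synthetic_spec(M = 20, N = 12, c = 2,
                                         n_informative = 2, n_blocks = 1,
                                         block_size = 3, seed = 8))
  res <- run_aco(gen$dataset, params = aco_params(n_max = 0))
  expect_equal(res$best$selected, seq_len(12))
  expect_equal(nrow(res$trajectory), 0L)
  expect_equal(res$best$evaluation$fitness,
               0.99 * res$best$evaluation$accuracy)
})

test_that("parameter invariants are enforced", {
  expect_error(aco_params(rho_loc = 0), "rho_loc")
  expect_error(aco_params(tau_min = 0.5, tau_init = 0.2), "tau_min")
  expect_error(aco_params(lambda = 0.5), "lambda")
  expect_error(aco_params(m = 0), "m")
})
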