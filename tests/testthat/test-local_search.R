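test_that("Add roulette prefers high scores and degrades to uniform", {
  expect_equal(add_probabilities(c(1, 2, 3)), c(1, 2, 3) / 6)
  expect_equal(add_probabilities(c(0, 0, 5)), c(0, 0, 1))
  expect_equal(add_probabilities(c(0, 0, 0)), rep(1 / 3, 3))
  expect_error(add_probabilities(numeric(0)), "Add")
})

test_that("Del roulette prefers low scores; the top gene is never drawn", {
  expect_equal(del_probabilities(c(1, 2, 3)), c(2 / 3, 1 / 3, 0))
  expect_equal(del_probabilities(c(5, 5)), c(0.5, 0.5))
  expect_equal(del_probabilities(c(0, 4)), c(1, 0))
  expect_error(del_probabilities(numeric(0)), "Del")
})

make_ls_fixture <- function(seed = 61, N = 10) {
  gen <- generate_dataset(synthetic_spec(M = 30, N = N, c = 2,
                                         n_informative = 2, n_blocks = 1,
                                         block_size = 3, seed = seed))
  ds <- gen$dataset
  list(ds = ds, fisher = fisher_scores(ds)$fisher,
       fit = fitness_params(ds$N), truth = gen$ground_truth)
}

as_start <- function(ds, bits, fit) {
  structure(list(bits = bits, selected = which(bits == 1L),
                 evaluation = evaluate_subset(ds, which(bits == 1L), fit)),
            class = "AntSolution")
}

test_that("local search never loses fitness and never empties the subset", {
  fx <- make_ls_fixture()
  set.seed(62)
  for (i in 1:10) {
    bits <- rbinom(fx$ds$N, 1, 0.5)
    if (sum(bits) == 0) bits[1] <- 1L
    start <- as_start(fx$ds, as.integer(bits), fx$fit)
    out <- local_search(start, fx$ds, fx$fisher, ls_params(), fx$fit)
    expect_gte(out$evaluation$fitness, start$evaluation$fitness)
    expect_gte(length(out$selected), 1L)
    expect_equal(out$evaluation$n_genes, length(out$selected))
  }
})

test_that("a single-flip optimum is returned unchanged", {
  fx <- make_ls_fixture(seed = 63, N = 6)
  fit <- fx$fit
  # find a subset no single flip can improve (a local optimum by brute force)
  n <- fx$ds$N
  all_bits <- expand.grid(rep(list(0:1), n))
  evals <- apply(all_bits, 1, function(b) {
    if (sum(b) == 0) return(-Inf)
    evaluate_subset(fx$ds, which(b == 1), fit)$fitness
  })
  best <- as.integer(all_bits[which.max(evals), ])
  start <- as_start(fx$ds, best, fit)
  set.seed(64)
  out <- local_search(start, fx$ds, fx$fisher, ls_params(), fit)
  expect_identical(out$bits, start$bits)
  expect_equal(out$evaluation$fitness, start$evaluation$fitness)
})

test_that("noise genes are pruned from a planted-plus-noise start", {
  fx <- make_ls_fixture(seed = 65, N = 12)
  bits <- integer(fx$ds$N)
  bits[fx$truth] <- 1L
  bits[8:12] <- 1L                       # five noise genes added
  start <- as_start(fx$ds, bits, fx$fit)
  set.seed(66)
  out <- local_search(start, fx$ds, fx$fisher, ls_params(it_max = 10), fx$fit)
  expect_gt(out$evaluation$fitness, start$evaluation$fitness)
  # brute-force optimum over all non-empty subsets bounds the result
  n <- fx$ds$N
  all_bits <- expand.grid(rep(list(0:1), n))
  opt <- max(apply(all_bits, 1, function(b) {
    if (sum(b) == 0) return(-Inf)
    evaluate_subset(fx$ds, which(b == 1), fx$fit)$fitness
  }))
  expect_lte(out$evaluation$fitness, opt + 1e-12)
})

test_that("backward generation only deletes and shrinks monotonically", {
  fx <- make_ls_fixture(seed = 67)
  bits <- rep(1L, fx$ds$N)
  start <- as_start(fx$ds, bits, fx$fit)
  set.seed(68)
  out <- local_search(start, fx$ds, fx$fisher, backward_params(), fx$fit)
  expect_lte(out$evaluation$n_genes, start$evaluation$n_genes)
  expect_gte(out$evaluation$fitness, start$evaluation$fitness)
  expect_true(all(out$bits <= start$bits))   # no gene was ever added
  expect_gte(length(out$selected), 1L)
})

test_that("ls_params validates its ranges", {
  expect_error(ls_params(it_max = 0), "it_max")
  expect_error(ls_params(n_add = 0, n_del = 0), "n_add")
  expect_equal(backward_params()$n_add, 0L)
})
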