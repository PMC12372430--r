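# oracle values below are frozen from direct logistic arithmetic:
# 1/(1+exp(-1.7)) = 0.84553473..., and the symmetric 4-category split at
# theta 0 for a=1.7, b=(-1,0,1)

test_that("cumulative probabilities match direct logistic evaluation", {
  it <- grm_item("q", a = 1.7, b = c(-1, 0, 1))
  expect_equal(grm_cumprob(grm_item("d", 1, 0), 1, 0), 0.5)
  expect_equal(grm_cumprob(it, 1, 0), 1 / (1 + exp(-1.7)), tolerance = 1e-12)
  expect_equal(grm_cumprob(it, 1, 10), 1, tolerance = 1e-6)
  expect_error(grm_cumprob(it, 4, 0), "out of range")
  # strictly increasing in theta, decreasing in k
  th <- seq(-3, 3, 0.5)
  expect_true(all(diff(grm_cumprob(it, 2, th)) > 0))
  expect_true(grm_cumprob(it, 1, 0.3) > grm_cumprob(it, 2, 0.3))
})

test_that("category probabilities are adjacent cumulative differences", {
  it <- grm_item("q", a = 1.7, b = c(-1, 0, 1))
  p <- grm_probs(it, 0)
  expect_equal(p, c(0.1544653, 0.3455347, 0.3455347, 0.1544653),
               tolerance = 1e-6)
  expect_equal(grm_probs(grm_item("d", 1, 0), 0), c(0.5, 0.5))
  # sum to 1 at machine precision over random items and thetas
  set.seed(1)
  for (i in 1:40) {
    it <- random_item()
    th <- runif(1, -5, 5)
    p <- grm_probs(it, th)
    expect_true(all(p >= 0))
    expect_lt(abs(sum(p) - 1), 1e-12)
  }
})

test_that("expected score is nondecreasing in theta for every item", {
  set.seed(2)
  th <- seq(-4, 4, 0.1)
  for (i in 1:20) {
    it <- random_item()
    es <- vapply(th, function(t) sum(grm_probs(it, t) * (0:(it$n_categories - 1))),
                 numeric(1))
    expect_true(all(diff(es) >= -1e-12))
  }
})

test_that("item information matches its closed form and a finite-difference oracle", {
  expect_equal(item_information(grm_item("d", 2, 0), 0), 1)  # a^2 / 4
  expect_lt(item_information(grm_item("d", 2, 0), 10), 1e-6)
  # oracle: I(theta) = sum_k P_k (d log P_k / d theta)^2, the variance of
  # the score function, with the derivative taken numerically
  set.seed(3)
  h <- 1e-5
  for (i in 1:40) {
    it <- random_item()
    th <- runif(1, -2.5, 2.5)
    p0 <- grm_probs(it, th)
    dlog <- (log(grm_probs(it, th + h)) - log(grm_probs(it, th - h))) / (2 * h)
    oracle <- sum(p0 * dlog^2)
    expect_equal(item_information(it, th), oracle, tolerance = 1e-4)
  }
})

test_that("test information is additive and SE is its inverse square root", {
  b2 <- item_bank(list(grm_item("a1", 1.3, c(-0.5, 0.5)),
                       grm_item("a2", 1.3, c(-0.5, 0.5))), "toy")
  expect_equal(test_information(b2, 0.7),
               2 * item_information(b2$items[[1]], 0.7), tolerance = 1e-12)
  expect_equal(test_information(toy_bank(), 1, items = character(0)), 0)
  expect_warning(se0 <- test_se(toy_bank(), 1, items = character(0)), "undefined")
  expect_true(is.na(se0))
  info <- test_information(toy_bank(), 0.3)
  expect_equal(test_se(toy_bank(), 0.3), 1 / sqrt(info))
  expect_error(test_information(toy_bank(), 0, items = "ghost"), "unknown")
})

test_that("information curve of a synthetic sleep bank has one dominant peak", {
  # a graded bank with spread thresholds can show minor secondary bumps,
  # so the shape property asserted is a single dominant interior peak:
  # any secondary local maximum has prominence < 20% of the global max
  for (seed in c(1, 9)) {
    bank <- generate_bank(sleep_bank_template(), seed = seed)
    cv <- information_curve(bank, from = -4, to = 4, by = 0.05)
    info <- cv$information
    imax <- which.max(info)
    expect_gt(imax, 1); expect_lt(imax, length(info))  # interior peak
    rise_viol <- max(0, max(cummax(info[1:imax]) - info[1:imax]))
    fall_viol <- max(0, max(rev(cummax(rev(info[imax:length(info)]))) -
                              info[imax:length(info)]))
    expect_lt(max(rise_viol, fall_viol), 0.2 * max(info))
    expect_equal(cv$se, 1 / sqrt(info))
  }
})

test_that("response log-likelihood equals the brute-force product of probabilities", {
  bank <- toy_bank()
  expect_equal(response_loglik(c(d1 = 1L), bank, 0), log(0.5))
  expect_equal(response_loglik(c(d1 = NA_integer_, p1 = NA_integer_), bank, 1.2), 0)
  set.seed(4)
  for (i in 1:20) {
    th <- runif(1, -3, 3)
    codes <- vapply(bank$items, function(it)
      sample(0:(it$n_categories - 1), 1), integer(1))
    oracle <- sum(log(vapply(seq_along(codes), function(j)
      grm_probs(bank$items[[j]], th)[codes[j] + 1], numeric(1))))
    expect_equal(response_loglik(codes, bank, th), oracle, tolerance = 1e-10)
  }
  expect_error(response_loglik(c(d1 = 5L), bank, 0), "out of range")
})

test_that("sampled responses reproduce the model's category distribution", {
  it <- grm_item("q", a = 1.7, b = c(-1, 0, 1))
  draws <- with_seed(10, sample_response(it, rep(0, 20000)))
  freq <- tabulate(draws + 1L, 4) / 20000
  expect_equal(freq, c(0.1544653, 0.3455347, 0.3455347, 0.1544653),
               tolerance = 0.015)
  expect_identical(with_seed(5, sample_response(it, c(0, 1))),
                   with_seed(5, sample_response(it, c(0, 1))))
  expect_equal(with_seed(6, sample_response(it, 10)), 3L)
})
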