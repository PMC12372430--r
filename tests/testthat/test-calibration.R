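# module-level calibration checks kept small; the full recovery study at
# the stated J=23 / N=1000 / 20-replicate scale runs in test-acceptance.R

test_that("EM increases the marginal likelihood monotonically and converges", {
  bank <- generate_bank(bank_template(8, category_counts = 4L), seed = 1)
  co <- generate_cohort(bank, n = 400, seed = 2)
  fit <- fit_grm(co)
  expect_true(fit$converged)
  expect_true(all(diff(fit$ll_trace) > -1e-6))
  # estimated thresholds strictly increasing everywhere
  for (it in fit$bank$items) {
    expect_gt(it$a, 0)
    if (it$n_categories > 2) expect_true(all(diff(it$b) > 0))
  }
})

test_that("calibration is invariant to response-matrix column order", {
  bank <- generate_bank(bank_template(6, category_counts = 3L), seed = 3)
  co <- generate_cohort(bank, n = 300, seed = 4)
  fit1 <- fit_grm(co)
  perm <- c(4, 1, 6, 2, 5, 3)
  co2 <- co
  co2$responses <- co$responses[, perm]
  co2$n_categories <- co$n_categories[perm]
  co2$reversed <- co$reversed[perm]
  fit2 <- fit_grm(co2)
  for (id in bank_ids(fit1$bank)) {
    # identical up to the EM stopping tolerance (summation order inside
    # the E-step is not associative in floating point)
    expect_equal(fit2$bank$items[[id]]$a, fit1$bank$items[[id]]$a,
                 tolerance = 1e-4)
    expect_equal(fit2$bank$items[[id]]$b, fit1$bank$items[[id]]$b,
                 tolerance = 1e-4)
  }
})

test_that("identical items get near-identical estimates (exchangeability)", {
  it <- grm_item("t", a = 1.4, b = c(-0.8, 0.6))
  bank <- item_bank(lapply(1:6, function(j)
    grm_item(paste0("t", j), a = 1.4, b = c(-0.8, 0.6))), "x")
  co <- generate_cohort(bank, n = 2000, seed = 5)
  fit <- fit_grm(co)
  a_hat <- vapply(fit$bank$items, `[[`, numeric(1), "a")
  expect_lt(diff(range(a_hat)), 0.45)
  expect_lt(abs(mean(a_hat) - 1.4), 0.2)
})

test_that("small samples are refused and empty categories collapse", {
  bank <- generate_bank(bank_template(5), seed = 6)
  tiny <- generate_cohort(bank, n = 100, seed = 7)
  expect_error(fit_grm(tiny), "below the minimum")
  # force an unobservable top category
  co <- generate_cohort(bank, n = 250, seed = 8)
  co$responses[co$responses[, 2] == 3L, 2] <- 2L
  co$n_categories[2] <- 4L
  expect_warning(fit <- fit_grm(co), "collapsed")
  expect_equal(fit$bank$items[[2]]$n_categories, 3L)
})

test_that("EAP scores match a dense-grid numerical-integration oracle", {
  bank <- toy_bank()
  set.seed(9)
  X <- sapply(bank$items, function(it) sample(0:(it$n_categories - 1), 12,
                                              replace = TRUE))
  X[1, ] <- NA  # all-missing respondent gets the prior
  rm_ <- response_matrix(X, n_categories = vapply(bank$items, `[[`,
                                                  integer(1), "n_categories"))
  sc <- eap_scores(rm_, bank)
  expect_equal(sc$theta[1], 0, tolerance = 0.01)
  expect_equal(sc$se[1], 1, tolerance = 0.01)
  expect_true(sc$prior_only[1])
  # dense trapezoid oracle on [-8, 8]
  grid <- seq(-8, 8, length.out = 10000)
  for (i in c(2, 5, 9)) {
    ll <- response_loglik(stats::setNames(X[i, ], colnames(X)), bank, grid)
    w <- exp(ll) * dnorm(grid)
    w <- w / sum(w)
    expect_equal(sc$theta[i], sum(w * grid), tolerance = 1e-4)
    expect_equal(sc$se[i], sqrt(sum(w * grid^2) - sum(w * grid)^2),
                 tolerance = 1e-3)
  }
  # monotonicity: all-highest beats all-lowest
  hi <- vapply(bank$items, function(it) it$n_categories - 1L, integer(1))
  lo <- rep(0L, length(bank))
  X2 <- rbind(hi, lo)
  colnames(X2) <- bank_ids(bank)
  sc2 <- eap_scores(response_matrix(X2, n_categories = hi + 1L), bank)
  expect_gt(sc2$theta[1], sc2$theta[2])
})

test_that("standard errors are positive and shrink roughly as 1/sqrt(N)", {
  bank <- generate_bank(bank_template(8, category_counts = 4L), seed = 10)
  co1 <- generate_cohort(bank, n = 250, seed = 11)
  co2 <- generate_cohort(bank, n = 1000, seed = 12)
  se1 <- grm_standard_errors(fit_grm(co1), "opg")
  se2 <- grm_standard_errors(fit_grm(co2), "opg")
  expect_true(all(se1$se$se > 0))
  expect_true(all(se2$se$se > 0))
  ratio <- median(se1$se$se / se2$se$se)  # expect about sqrt(4) = 2
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.7)
  # observed-information and OPG agree to first order
  so <- grm_standard_errors(fit_grm(co2), "observed")
  expect_equal(so$se$se, se2$se$se, tolerance = 0.25)
})
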