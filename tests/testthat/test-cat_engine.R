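test_that("the T-score transformation is exact", {
  expect_identical(t_score(0), 50)
  expect_identical(t_score(1), 60)
  expect_equal(t_score(-2.624), 23.76)
  expect_error(t_score(Inf), "finite")
})

test_that("session start is seeded, uniform over the bank, and validated", {
  bank <- generate_bank(sleep_bank_template(), seed = 1)
  s1 <- start_session(bank, cat_config(seed = 7))
  s2 <- start_session(bank, cat_config(seed = 7))
  expect_identical(s1$pending, s2$pending)
  expect_error(item_bank(list()), "at least one")
  firsts <- vapply(1:1000, function(k)
    start_session(bank, cat_config(seed = k))$pending, character(1))
  freq <- table(factor(firsts, levels = bank_ids(bank))) / 1000
  expect_true(all(abs(freq - 1 / 23) < 0.02))
  # deterministic alternative start
  s3 <- start_session(bank, cat_config(first_item = "max_info_at_prior"))
  bm <- paincat:::bank_matrices(bank)
  expect_identical(s3$pending, bank_ids(bank)[which.max(
    paincat:::bank_info_at(bm, 0))])
})

test_that("estimators behave per contract at zero and extreme patterns", {
  bank <- generate_bank(sleep_bank_template(), seed = 1)
  e0 <- estimate_theta(integer(0), bank, "EAP")
  expect_equal(e0$value, 0, tolerance = 0.01)
  expect_equal(e0$se, 1, tolerance = 0.01)
  expect_error(estimate_theta(integer(0), bank, "ML"), "at least one")
  set.seed(20)
  codes <- vapply(bank$items[1:20], function(it)
    sample_response(it, 0.5), integer(1))
  names(codes) <- bank_ids(bank)[1:20]
  ests <- vapply(c("ML", "EAP", "MAP", "WLE"), function(e)
    estimate_theta(codes, bank, e)$value, numeric(1))
  expect_lt(diff(range(ests)), 0.15)
  hi <- vapply(bank$items, function(it) it$n_categories - 1L, integer(1))
  names(hi) <- bank_ids(bank)
  ml <- estimate_theta(hi, bank, "ML")
  expect_true(ml$clamped)
  expect_equal(ml$value, 4)
  wle <- estimate_theta(hi, bank, "WLE")
  expect_false(wle$clamped)
  expect_true(is.finite(wle$value) && is.finite(wle$se))
})

test_that("item selection maximizes information and never repeats", {
  # equal-slope dichotomous items: information peaks at b
  bank <- item_bank(lapply(1:5, function(j)
    grm_item(paste0("d", j), a = 1.5, b = j - 3)), "x")  # b = -2..2
  s <- start_session(bank, cat_config(seed = 1))
  s <- step_session(s, 1L)  # theta estimate near 0 after one response
  cur <- s$theta_trajectory[[1]]$value
  remaining <- setdiff(bank_ids(bank), s$administered)
  bs <- vapply(bank$items[remaining], function(it) it$b, numeric(1))
  expect_identical(s$pending, remaining[which.min(abs(bs - cur))])
  # the already-administered best item is excluded
  expect_false(s$pending %in% s$administered)
})

test_that("MFI and KL usually agree on the next item", {
  bank <- generate_bank(sleep_bank_template(), seed = 2)
  agree <- 0L
  for (k in 1:25) {
    s <- start_session(bank, cat_config(seed = k))
    set.seed(1000 + k)
    for (st in 1:3)
      s <- step_session(s, sample_response(bank$items[[s$pending]], 0))
    if (s$finished) next
    mfi <- select_next_item(s, rule = "MFI")
    kl <- select_next_item(s, rule = "KL")
    agree <- agree + (mfi == kl)
  }
  expect_gte(agree / 25, 0.8)
})

test_that("stopping rule honors the SE cutoff and bank exhaustion", {
  bank <- generate_bank(sleep_bank_template(), seed = 3)
  config <- cat_config(seed = 5)
  set.seed(77)
  s <- start_session(bank, config)
  while (!s$finished)
    s <- step_session(s, sample_response(bank$items[[s$pending]], 0.2))
  est <- s$theta_trajectory[[length(s$theta_trajectory)]]
  expect_identical(s$stop_reason, "se_reached")
  expect_lte(est$se, 0.3)
  expect_equal(s$t_score, est$value * 10 + 50)
  # every earlier step had SE above the cutoff
  earlier <- vapply(head(s$theta_trajectory, -1), `[[`, numeric(1), "se")
  expect_true(all(earlier > 0.3))
  expect_error(step_session(s, 0L), "finished")
  # a tiny uninformative bank exhausts instead
  small <- item_bank(list(grm_item("w1", 0.4, 0), grm_item("w2", 0.4, 0.5)), "x")
  s2 <- start_session(small, cat_config(seed = 1))
  s2 <- step_session(s2, 0L); s2 <- step_session(s2, 1L)
  expect_identical(s2$stop_reason, "bank_exhausted")
  # with the cutoff at 0 the whole bank is administered
  s3 <- start_session(bank, cat_config(se_cutoff = 1e-9, seed = 2))
  set.seed(78)
  while (!s3$finished)
    s3 <- step_session(s3, sample_response(bank$items[[s3$pending]], 0))
  expect_identical(s3$stop_reason, "bank_exhausted")
  expect_identical(length(s3$administered), length(bank))
  expect_error(step_session(start_session(bank, cat_config(seed = 1)), 99L),
               "invalid code")
})

test_that("no item is ever administered twice across simulated sessions", {
  bank <- generate_bank(bank_template(10, category_counts = 3L), seed = 4)
  set.seed(6)
  for (k in 1:60) {
    th <- rnorm(1)
    s <- run_session(bank, function(id) sample_response(bank$items[[id]], th),
                     cat_config(seed = k))
    expect_false(anyDuplicated(s$administered) > 0)
    expect_true(s$finished)
    expect_true(s$stop_reason %in% c("se_reached", "bank_exhausted"))
  }
})

test_that("SE trajectory is mostly nonincreasing under EAP", {
  bank <- generate_bank(sleep_bank_template(), seed = 5)
  set.seed(7)
  drops <- c(); total <- 0L
  for (k in 1:20) {
    th <- rnorm(1)
    s <- run_session(bank, function(id) sample_response(bank$items[[id]], th),
                     cat_config(seed = 100 + k))
    se <- vapply(s$theta_trajectory, `[[`, numeric(1), "se")
    drops <- c(drops, diff(se) <= 1e-8)
  }
  expect_gte(mean(drops), 0.95)
})

test_that("endorsement table dichotomizes categories and filters by slope", {
  bank <- item_bank(list(grm_item("lo", 0.5, 0),
                         grm_item("m1", 1.0, c(-1, 1)),
                         grm_item("m2", 2.0, c(-0.5, 0.5))), "x")
  tab <- endorsement_table(bank, theta_levels = c(-1, 0, 1), top_n = 10)
  expect_false("lo" %in% tab$item)           # a = 0.5 < 0.65 excluded
  expect_equal(nrow(tab[tab$theta == 0, ]), 4)  # 2+2 categories survive
  # hand-computed oracle at theta 0: P* = plogis(a (0 - b))
  oracle <- sort(c(plogis(1 * 1), plogis(1 * -1), plogis(2 * 0.5),
                   plogis(2 * -0.5)), decreasing = TRUE)
  expect_equal(tab$endorsement[tab$theta == 0], oracle, tolerance = 1e-12)
  # endorsement probabilities nondecreasing in theta per category
  for (itc in split(tab, paste(tab$item, tab$category))) {
    itc <- itc[order(itc$theta), ]
    if (nrow(itc) > 1) expect_true(all(diff(itc$endorsement) > 0))
  }
  expect_error(endorsement_table(item_bank(list(grm_item("lo", 0.5, 0)), "x")),
               "no items")
})
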