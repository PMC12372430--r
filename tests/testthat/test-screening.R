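test_that("polychoric recovers the latent correlation of discretized normals", {
  set.seed(1)
  n <- 2000
  rho <- 0.6
  z1 <- rnorm(n); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  x <- cut(z1, c(-Inf, -0.5, 0.5, Inf), labels = FALSE) - 1
  y <- cut(z2, c(-Inf, -1, 0, 1, Inf), labels = FALSE) - 1
  expect_equal(polychoric_corr(x, y), rho, tolerance = 0.07)
  # independent ordinals stay near zero
  y0 <- cut(rnorm(n), c(-Inf, 0, Inf), labels = FALSE) - 1
  expect_lt(abs(polychoric_corr(x, y0)), 0.08)
})

test_that("polyserial recovers a mixed-pair latent correlation", {
  set.seed(2)
  n <- 2000
  z1 <- rnorm(n); z2 <- 0.5 * z1 + sqrt(0.75) * rnorm(n)
  y <- cut(z2, c(-Inf, -0.8, 0.8, Inf), labels = FALSE) - 1
  expect_equal(polyserial_corr(z1, y), 0.5, tolerance = 0.08)
})

test_that("mixed correlation matrix is symmetric with unit diagonal", {
  set.seed(3)
  n <- 300
  z <- rnorm(n)
  df <- data.frame(o1 = as.integer(z + rnorm(n) > 0),
                   o2 = cut(z + rnorm(n), c(-Inf, -1, 1, Inf), labels = FALSE) - 1L,
                   c1 = z + rnorm(n))
  R <- correlation_matrix(df, types = c("ordinal", "ordinal", "continuous"))
  expect_equal(R, t(R))
  expect_equal(unname(diag(R)), rep(1, 3))
  expect_true(all(abs(R) <= 1, na.rm = TRUE))
  # a pair with too few complete cases is flagged undefined
  df$o1[1:295] <- NA
  R2 <- correlation_matrix(df, types = c("ordinal", "ordinal", "continuous"))
  expect_true(is.na(R2["o1", "o2"]))
  expect_true(length(attr(R2, "undefined")) >= 1)
})

test_that("one-factor structure is recovered with the closed-form loading", {
  R <- matrix(0.49, 6, 6); diag(R) <- 1
  sol <- efa(R, 1)
  expect_equal(unname(sol$loadings[, 1]), rep(0.7, 6), tolerance = 1e-3)
  # identity matrix: unit eigenvalues, no dominant factor
  sol0 <- efa(diag(8), 1)
  expect_equal(sol0$eigenvalues, rep(1, 8))
  expect_true(all(abs(sol0$loadings) < 0.3))
})

test_that("oblimin separates a two-block structure with small cross-loadings", {
  R <- diag(1, 8)
  R[1:4, 1:4] <- 0.49; R[5:8, 5:8] <- 0.49
  R[1:4, 5:8] <- 0.15; R[5:8, 1:4] <- 0.15
  diag(R) <- 1
  sol <- efa(R, 2, rotation = "oblimin")
  primary <- apply(abs(sol$loadings), 1, max)
  cross <- apply(abs(sol$loadings), 1, min)
  expect_true(all(primary > 0.6))
  expect_true(all(cross < 0.30))
  # the implied factor correlation for this block structure is 0.15/0.49
  expect_equal(sol$factor_cor[1, 2], 0.15 / 0.49, tolerance = 0.02)
  # varimax also separates, with orthogonal factors
  solv <- efa(R, 2, rotation = "varimax")
  expect_equal(solv$factor_cor, diag(2))
})

test_that("loading filter keeps exactly-one-strong-loading items", {
  L <- matrix(c(0.8, 0.1,
                0.29, 0.05,
                0.5, 0.5), 3, 2, byrow = TRUE,
              dimnames = list(c("good", "weak", "cross"), NULL))
  lf <- loading_filter(L)
  expect_identical(lf$kept, "good")
  expect_setequal(lf$excluded$id, c("weak", "cross"))
  expect_match(lf$excluded$reason[lf$excluded$id == "weak"], "no loading")
  expect_match(lf$excluded$reason[lf$excluded$id == "cross"], "cross-loading")
  # boundary: 0.30 exactly is kept
  expect_identical(loading_filter(matrix(0.30, 1, 1))$kept, "item1")
})

test_that("Q3 centers at -1/(J-1) under independence and flags duplicates", {
  bank <- generate_bank(bank_template(10, category_counts = 4L), seed = 4)
  co <- generate_cohort(bank, n = 800, seed = 5)
  fit <- fit_grm(co)
  q3 <- q3_local_dependence(co, fit$bank)
  expect_lt(abs(mean(q3$q3) - (-1 / 9)), 0.05)
  expect_false(any(q3$flagged))
  expect_false(any(q3_local_dependence(co, fit$bank, cutoff = 1.0)$flagged))
  # inject a duplicate item: its pair must flag with q3 near 1
  co2 <- co
  co2$responses <- cbind(co$responses, dup = co$responses[, 1])
  colnames(co2$responses)[11] <- "dup"
  co2$n_categories <- c(co$n_categories, dup = co$n_categories[[1]])
  co2$reversed <- c(co$reversed, dup = FALSE)
  bank2 <- fit$bank
  bank2$items$dup <- grm_item("dup", a = fit$bank$items[[1]]$a,
                              b = fit$bank$items[[1]]$b)
  q32 <- q3_local_dependence(co2, bank2)
  pair <- q32[q32$item1 == colnames(co$responses)[1] & q32$item2 == "dup", ]
  expect_true(pair$flagged)
  expect_gt(pair$q3, 0.8)
})

test_that("discrimination bands follow the conventional scale", {
  expect_equal(as.character(classify_discrimination(
    c(0.1, 0.35, 0.64, 0.65, 1.34, 1.35, 1.69, 1.70, 2.5))),
    c("very_low", "low", "low", "moderate", "moderate", "high", "high",
      "very_high", "very_high"))
  expect_error(classify_discrimination(-0.1), "nonnegative")
})

test_that("DIF refuses a single group and runs on a small two-group null", {
  bank <- generate_bank(dif_template(), seed = 1)
  co <- generate_cohort(bank, n = 400, seed = 6)
  co$covariates$gender <- "F"
  expect_error(dif_wald(co), "2 groups")
  rm_ <- make_dif_cohort(1, dif_template(), n_per_group = 250L)
  res <- suppressWarnings(dif_wald(rm_))
  expect_equal(nrow(res), 12)
  expect_true(all(res$wald_statistic >= 0))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_identical(res$flagged, res$p_adjusted < 0.05)
})

test_that("hot-deck imputation is deterministic, complete, and harmless when complete", {
  bank <- generate_bank(bank_template(8), seed = 7)
  full <- generate_cohort(bank, n = 300, seed = 8)
  expect_identical(hotdeck_impute(full, seed = 1), full)
  holey <- full  # same responses, 10% MCAR mask
  holey$responses[with_seed(9, matrix(runif(300 * 8) < 0.1, 300, 8))] <- NA
  imp1 <- hotdeck_impute(holey, seed = 42)
  imp2 <- hotdeck_impute(holey, seed = 42)
  expect_false(anyNA(imp1$responses))
  expect_identical(imp1$responses, imp2$responses)
  # imputed calibration stays close to the complete-data calibration
  fit_full <- fit_grm(full)
  fit_imp <- fit_grm(imp1)
  a_full <- vapply(fit_full$bank$items, `[[`, numeric(1), "a")
  a_imp <- vapply(fit_imp$bank$items, `[[`, numeric(1), "a")
  expect_lt(max(abs(a_full - a_imp)), 0.5)
  too_holey <- holey
  too_holey$responses[1:150, 1] <- NA
  expect_error(hotdeck_impute(too_holey), "30%")
})
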