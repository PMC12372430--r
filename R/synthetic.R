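# Synthetic banks and cohorts emulating the study setting: a 23-item
# sleep bank (16 PSQI-like + 7 ISI-like items, 2-5 response categories)
# and a 41-item QoL bank, respondents with standard-normal trait levels,
# and 5000-simulee adaptive-testing burden simulations with the
# item-reduction arithmetic. Also the parameter-recovery harness used as
# the calibration acceptance surface.

band_ranges <- list(very_low = c(0.15, 0.35), low = c(0.35, 0.65),
                    moderate = c(0.65, 1.35), high = c(1.35, 1.70),
                    very_high = c(1.70, 2.80))

#' Bank template for synthetic item generation
#'
#' @param n_items number of items.
#' @param category_counts per-item K (recycled).
#' @param discrimination_mix named fractions over the bands
#'   `very_low, low, moderate, high, very_high`; must sum to 1.
#' @param threshold_spread range the thresholds are drawn in.
#' @param instruments per-item instrument labels (recycled).
#' @param construct construct label.
#' @return list of class `bank_template`.
#' @export
bank_template <- function(n_items, category_counts = 4L,
                          discrimination_mix = c(moderate = 0.5, high = 0.25,
                                                 very_high = 0.25),
                          threshold_spread = c(-2.5, 2.5),
                          instruments = "synthetic", construct = "trait") {
  mix <- rep(0, 5)
  names(mix) <- names(band_ranges)
  bad <- setdiff(names(discrimination_mix), names(mix))
  if (length(bad)) stop_pc("unknown band(s): ", paste(bad, collapse = ", "))
  mix[names(discrimination_mix)] <- discrimination_mix
  if (abs(sum(mix) - 1) > 1e-8) stop_pc("discrimination_mix must sum to 1")
  if (n_items < 1L) stop_pc("n_items must be >= 1")
  structure(list(n_items = as.integer(n_items),
                 category_counts = rep_len(as.integer(category_counts), n_items),
                 discrimination_mix = mix,
                 threshold_spread = threshold_spread,
                 instruments = rep_len(instruments, n_items),
                 construct = construct),
            class = "bank_template")
}

#' Template emulating the 23-item sleep bank
#'
#' 16 PSQI-like items (one dichotomous, a couple of 3-category items, the
#' bulk 4-category, three 5-category quantile-split-style items) and 7
#' ISI-like 5-category items. The discrimination mix follows the reported
#' banding of the calibrated sleep bank: 10 very high, 2 high, 10
#' moderate, 1 low of 23.
#'
#' @return a [bank_template()].
#' @export
sleep_bank_template <- function() {
  K <- c(2L, 3L, 3L, rep(4L, 10L), rep(5L, 3L), rep(5L, 7L))
  instr <- c(rep("PSQI", 16L), rep("ISI", 7L))
  bank_template(23L, category_counts = K,
                discrimination_mix = c(low = 1, moderate = 10, high = 2,
                                       very_high = 10) / 23,
                instruments = instr, construct = "sleep")
}

#' Template emulating the 41-item quality-of-life bank
#'
#' 11 SF-12-like items (3-5 categories), 25 WHOQOL-BREF-like 5-category
#' items and 5 EQ-5D-3L-like 3-category items; discrimination mix 15 very
#' high, 9 high, 14 moderate, 3 low of 41.
#'
#' @return a [bank_template()].
#' @export
qol_bank_template <- function() {
  K <- c(c(3L, 5L, 5L, 5L, 3L, 3L, 5L, 5L, 5L, 4L, 4L),
         rep(5L, 25L), rep(3L, 5L))
  instr <- c(rep("SF12", 11L), rep("WHOQOL", 25L), rep("EQ5D", 5L))
  bank_template(41L, category_counts = K,
                discrimination_mix = c(low = 3, moderate = 14, high = 9,
                                       very_high = 15) / 41,
                instruments = instr, construct = "qol")
}

# integer band counts from fractions by largest remainder
mix_counts <- function(mix, n) {
  raw <- mix * n
  cnt <- floor(raw)
  short <- n - sum(cnt)
  if (short > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(short)]] <- cnt[ord[seq_len(short)]] + 1
  }
  cnt
}

#' Generate a synthetic item bank from a template
#'
#' Discriminations are drawn uniformly inside each band's range according
#' to the template mix; thresholds are sorted uniform draws in the spread,
#' redrawn until a minimum gap of 0.25 holds (evenly spaced fallback), so
#' calibration targets are well separated. Deterministic under `seed`.
#'
#' @param template a [bank_template()].
#' @param seed integer seed.
#' @return an [item_bank()].
#' @export
generate_bank <- function(template, seed = 1L) {
  stopifnot(inherits(template, "bank_template"))
  with_seed(seed, {
    n <- template$n_items
    cnt <- mix_counts(template$discrimination_mix, n)
    bands <- rep(names(cnt), cnt)
    bands <- sample(bands, n)  # shuffle band assignment over items
    a <- vapply(bands, function(bd) stats::runif(1, band_ranges[[bd]][1],
                                                 band_ranges[[bd]][2]),
                numeric(1))
    items <- lapply(seq_len(n), function(j) {
      K <- template$category_counts[j]
      sp <- template$threshold_spread
      b <- NULL
      for (try in 1:100) {
        cand <- sort(stats::runif(K - 1L, sp[1], sp[2]))
        if (K == 2L || min(diff(cand)) >= 0.25) { b <- cand; break }
      }
      if (is.null(b))
        b <- seq(sp[1], sp[2], length.out = K + 1L)[2:K] +
          stats::runif(1, -0.1, 0.1)
      grm_item(sprintf("%s_%02d", template$instruments[j], j), a = a[j], b = b,
               instrument = template$instruments[j])
    })
    item_bank(items, construct = template$construct,
              provenance = sprintf("synthetic bank, seed %d", seed))
  })
}

#' Generate a synthetic respondent cohort from a bank
#'
#' Draws each respondent's trait from `theta_dist` (standard normal by
#' default), samples every response from the graded model at that trait,
#' and knocks out cells completely at random at `missing_rate`. True trait
#' values are attached for recovery studies.
#'
#' @param bank an [item_bank()].
#' @param n cohort size.
#' @param theta_dist function `n -> n` trait draws, default `rnorm`.
#' @param missing_rate MCAR missingness in \[0, 0.5\].
#' @param gender_prop proportion in the second gender stratum (covariate
#'   for DIF screening).
#' @param seed integer seed.
#' @return a [response_matrix()] with attribute `"theta_true"`.
#' @export
generate_cohort <- function(bank, n = 300L, theta_dist = stats::rnorm,
                            missing_rate = 0, gender_prop = 0.5, seed = 1L) {
  stopifnot(n >= 1L, missing_rate >= 0, missing_rate <= 0.5)
  bm <- bank_matrices(bank)
  with_seed(seed, {
    theta <- theta_dist(n)
    X <- matrix(NA_integer_, n, bm$J, dimnames = list(paste0("r", seq_len(n)),
                                                      bm$ids))
    for (i in seq_len(n)) {
      P <- bank_probs_at(bm, theta[i])          # J x Kmax
      u <- stats::runif(bm$J)
      X[i, ] <- as.integer(rowSums(u > t(apply(P, 1, cumsum))))
    }
    if (missing_rate > 0) {
      drop <- matrix(stats::runif(n * bm$J) < missing_rate, n, bm$J)
      X[drop] <- NA_integer_
    }
    gender <- sample(c("F", "M"), n, replace = TRUE,
                     prob = c(1 - gender_prop, gender_prop))
    out <- response_matrix(X, n_categories = bm$K,
                           covariates = data.frame(gender = gender))
    attr(out, "theta_true") <- theta
    out
  })
}

#' Item-reduction percentage
#'
#' `100 (total - mean_items) / total`: the percentage of items saved by the
#' adaptive test relative to a fixed-length total.
#'
#' @param mean_items average number of items administered.
#' @param total denominator item count (full instruments or bank size).
#' @return percentage in \[0, 100\].
#' @export
compute_reduction <- function(mean_items, total) {
  stopifnot(total > 0, mean_items >= 0, mean_items <= total)
  100 * (total - mean_items) / total
}

#' Simulated response-burden study
#'
#' Runs a full adaptive session for each of `n_simulees` simulated
#' respondents (traits standard normal), with responses drawn from the
#' graded model at the true trait, and summarizes the administered item
#' counts and reduction percentages against the full-instrument total and
#' the bank size. Reproducible bit-for-bit under `seed`.
#'
#' @param bank a calibrated [item_bank()].
#' @param n_simulees number of simulated respondents (default 5000).
#' @param config a [cat_config()]; its `seed` is ignored here (the
#'   simulation runs one seeded stream).
#' @param instrument_total full-instrument item count used as the
#'   reduction denominator (e.g. 34 for the sleep instruments, 43 for
#'   QoL); defaults by construct label, else the bank size.
#' @param seed integer seed.
#' @return list of class `burden_result`: `mean_items`,
#'   `per_instrument_mean`, `reduction_vs_instruments`,
#'   `reduction_vs_bank`, `records` (per-simulee data frame).
#' @export
simulate_burden <- function(bank, n_simulees = 5000L, config = cat_config(),
                            instrument_total = NULL, seed = 1L) {
  config$seed <- NULL  # one stream for the whole simulation
  total <- instrument_total %||%
    switch(bank$construct, sleep = 34L, qol = 43L, length(bank))
  J <- length(bank)
  with_seed(seed, {
    theta <- stats::rnorm(n_simulees)
    recs <- vector("list", n_simulees)
    for (i in seq_len(n_simulees)) {
      s <- run_session(bank, function(id)
        sample_response(bank$items[[id]], theta[i]), config)
      est <- s$theta_trajectory[[length(s$theta_trajectory)]]
      recs[[i]] <- list(theta_true = theta[i],
                        n_items = length(s$administered),
                        theta_hat = est$value, se = est$se,
                        stop_reason = s$stop_reason,
                        instruments = vapply(bank$items[s$administered], `[[`,
                                             character(1), "instrument"))
    }
    records <- data.frame(
      simulee = seq_len(n_simulees),
      theta_true = vapply(recs, `[[`, numeric(1), "theta_true"),
      n_items = vapply(recs, `[[`, numeric(1), "n_items"),
      theta_hat = vapply(recs, `[[`, numeric(1), "theta_hat"),
      se = vapply(recs, `[[`, numeric(1), "se"),
      stop_reason = vapply(recs, `[[`, character(1), "stop_reason"))
    instr_all <- unlist(lapply(recs, `[[`, "instruments"))
    per_instr <- tapply(rep(1, length(instr_all)), instr_all, sum) / n_simulees
    mean_items <- mean(records$n_items)
    structure(list(
      mean_items = mean_items,
      per_instrument_mean = as.list(per_instr),
      reduction_vs_instruments = compute_reduction(mean_items, total),
      reduction_vs_bank = compute_reduction(mean_items, J),
      instrument_total = total, bank_size = J, n_simulees = n_simulees,
      seed = seed, records = records), class = "burden_result")
  })
}

#' @export
print.burden_result <- function(x, ...) {
  cat(sprintf(paste0("<burden_result> %d simulees: mean %.2f items ",
                     "(reduction %.1f%% vs %d instrument items, %.1f%% vs ",
                     "%d-item bank)\n"),
              x$n_simulees, x$mean_items, x$reduction_vs_instruments,
              x$instrument_total, x$reduction_vs_bank, x$bank_size))
  cat("  stop reasons:", paste(names(table(x$records$stop_reason)),
                               table(x$records$stop_reason),
                               sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Parameter-recovery experiment for the calibrator
#'
#' Per replicate: generate a bank from the template, simulate a complete
#' cohort of size `n`, calibrate it, and compare estimates with the
#' generating truth: correlation of discriminations, bias and MAE/RMSE of
#' all parameters, and the coverage of the nominal 95% Wald intervals for
#' the thresholds.
#'
#' @param template a [bank_template()].
#' @param n cohort size per replicate.
#' @param replicates number of replicates.
#' @param seed integer seed; replicate r runs under `seed + r`.
#' @param control [grm_control()] for the fits.
#' @param coverage also compute SEs and CI coverage (slower).
#' @param se_method covariance estimator for the coverage intervals;
#'   OPG default (cheap, slightly conservative).
#' @return data frame with one row per replicate: `r_a`, `bias_a`,
#'   `mae_b`, `rmse_b`, `coverage_b`, `converged`.
#' @export
recovery_experiment <- function(template, n = 1000L, replicates = 20L,
                                seed = 1L, control = grm_control(),
                                coverage = TRUE, se_method = "opg") {
  stopifnot(replicates >= 1L)
  rows <- lapply(seq_len(replicates), function(r) {
    bank <- generate_bank(template, seed = seed + 1000L * r)
    rm_ <- generate_cohort(bank, n = n, seed = seed + 1000L * r + 1L)
    fit <- suppressWarnings(fit_grm(rm_, control, construct = template$construct))
    a_true <- vapply(bank$items, `[[`, numeric(1), "a")
    a_hat <- vapply(fit$bank$items, `[[`, numeric(1), "a")
    # items whose categories were collapsed (rare, empty extreme category)
    # are dropped from the threshold comparison: parameter vectors differ
    same_K <- vapply(bank_ids(bank), function(id)
      bank$items[[id]]$n_categories == fit$bank$items[[id]]$n_categories,
      logical(1))
    b_true <- unlist(lapply(bank$items[same_K], `[[`, "b"))
    b_hat <- unlist(lapply(fit$bank$items[same_K], `[[`, "b"))
    cov_b <- NA_real_
    if (coverage) {
      se <- grm_standard_errors(fit, se_method)
      bse <- se$se$se[grepl("\\.b[0-9]+$", se$se$parameter)]
      if (length(bse) == length(b_true))
        cov_b <- mean(abs(b_hat - b_true) <= 1.96 * bse)
    }
    data.frame(replicate = r, r_a = stats::cor(a_true, a_hat),
               bias_a = mean(a_hat - a_true),
               mae_b = mean(abs(b_hat - b_true)),
               rmse_b = sqrt(mean((b_hat - b_true)^2)),
               coverage_b = cov_b, converged = fit$converged)
  })
  do.call(rbind, rows)
}
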