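# shared fixtures, built in code at test time

# tiny deterministic 4-item bank with hand-set parameters
toy_bank <- function() {
  item_bank(list(
    grm_item("d1", a = 1.0, b = 0),
    grm_item("d2", a = 2.0, b = 0.5),
    grm_item("p1", a = 1.7, b = c(-1, 0, 1)),
    grm_item("p2", a = 0.9, b = c(-0.5, 0.8))
  ), construct = "toy")
}

# random item with K categories under the current RNG
random_item <- function(id = "r", K = sample(2:5, 1)) {
  b <- sort(stats::runif(K - 1, -2.5, 2.5))
  while (K > 2 && min(diff(b)) < 0.05) b <- sort(stats::runif(K - 1, -2.5, 2.5))
  grm_item(id, a = stats::runif(1, 0.4, 2.8), b = b)
}

# two-group cohort for DIF simulations: identical banks under the null,
# or one item's thresholds shifted in the focal group
make_dif_cohort <- function(seed, template, shift = 0, shift_item = 5L,
                            n_per_group = 500L, bank_seed = 1L) {
  b <- generate_bank(template, seed = bank_seed)
  bF <- b
  if (shift != 0) bF$items[[shift_item]]$b <- bF$items[[shift_item]]$b + shift
  cR <- generate_cohort(b, n = n_per_group, seed = seed)
  cF <- generate_cohort(bF, n = n_per_group, seed = seed + 50000L)
  X <- rbind(cR$responses, cF$responses)
  rownames(X) <- paste0("r", seq_len(2L * n_per_group))
  response_matrix(X, n_categories = pmax(cR$n_categories, cF$n_categories),
                  covariates = data.frame(gender = rep(c("F", "M"),
                                                       each = n_per_group)))
}

dif_template <- function() bank_template(12L, category_counts = 4L,
                                         construct = "dif")
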