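# The adaptive testing loop: a random first item, information- or
# Kullback-Leibler-based selection of subsequent items, trait estimation
# after every response (ML / EAP / MAP / WLE), a standard-error stopping
# rule, and the final T-score. The named multidimensional selection rules
# (determinant, trace, asymptotic-covariance, weighted-composite and
# eigenvalue rules) all reduce to maximum Fisher information in a
# unidimensional model, so the engine exposes MFI and KL.

#' Adaptive test configuration
#'
#' @param se_cutoff stop when the current SE of the trait estimate drops to
#'   this value or below (theta units; default 0.3, i.e. roughly reliability
#'   0.91 on the T-score scale).
#' @param estimator trait estimator used during the session: `"EAP"`
#'   (default; stable with few items), `"MAP"`, `"ML"` or `"WLE"`.
#' @param selection_rule `"MFI"` (maximum Fisher information at the current
#'   estimate, default), `"KL"` (posterior-weighted Kullback-Leibler
#'   index), or `"random"`.
#' @param first_item `"random"` (uniform over the bank, default) or
#'   `"max_info_at_prior"` (most informative item at theta 0).
#' @param seed optional integer; when given, the session's random choices
#'   run on a private stream seeded here, otherwise the current RNG is
#'   used.
#' @param theta_bounds search/clamp bounds for ML and WLE estimates.
#' @param max_items optional administration cap (default none: the test
#'   runs until the SE criterion is met or the bank is exhausted).
#' @param n_quad,quad_bounds quadrature settings for EAP/MAP/KL.
#' @return list of class `cat_config`.
#' @export
cat_config <- function(se_cutoff = 0.3, estimator = c("EAP", "MAP", "ML", "WLE"),
                       selection_rule = c("MFI", "KL", "random"),
                       first_item = c("random", "max_info_at_prior"),
                       seed = NULL, theta_bounds = c(-4, 4), max_items = NULL,
                       n_quad = 61L, quad_bounds = c(-6, 6)) {
  stopifnot(se_cutoff > 0, theta_bounds[1] < theta_bounds[2])
  structure(list(se_cutoff = se_cutoff, estimator = match.arg(estimator),
                 selection_rule = match.arg(selection_rule),
                 first_item = match.arg(first_item), seed = seed,
                 theta_bounds = theta_bounds, max_items = max_items,
                 n_quad = as.integer(n_quad), quad_bounds = quad_bounds),
            class = "cat_config")
}

#' Convert a trait estimate to the reporting T-score
#'
#' `T = theta * 10 + 50`: mean 50, SD 10 in the calibration population.
#'
#' @param theta finite trait value(s).
#' @return T-score(s).
#' @export
t_score <- function(theta) {
  if (any(!is.finite(theta))) stop_pc("theta must be finite")
  theta * 10 + 50
}

#' Estimate the latent trait from a partial response pattern
#'
#' * `ML`: likelihood maximizer within `theta_bounds`; clamped and flagged
#'   at a bound (all-extreme patterns diverge); SE = `1/sqrt(I(theta))`.
#' * `MAP`: posterior mode under N(0,1); SE = posterior SD.
#' * `EAP`: posterior mean; SE = posterior SD.
#' * `WLE`: maximizer of likelihood times `sqrt(I(theta))` (Warm's
#'   bias-corrected likelihood, finite even for extreme patterns);
#'   SE = `1/sqrt(I(theta))`.
#'
#' @param codes named integer vector of 0-based codes (names = item ids).
#' @param bank an [item_bank()].
#' @param estimator one of `"ML"`, `"EAP"`, `"MAP"`, `"WLE"`.
#' @param theta_bounds bounds for ML/WLE search and clamping.
#' @param n_quad,quad_bounds quadrature for EAP/MAP.
#' @return list: `value`, `se`, `estimator`, `clamped`.
#' @export
estimate_theta <- function(codes, bank, estimator = "EAP",
                           theta_bounds = c(-4, 4), n_quad = 61L,
                           quad_bounds = c(-6, 6)) {
  estimator <- match.arg(estimator, c("ML", "EAP", "MAP", "WLE"))
  codes <- codes[!is.na(codes)]
  n <- length(codes)
  if (n == 0L && estimator %in% c("ML", "WLE"))
    stop_pc(estimator, " estimation needs at least one response")
  clamped <- FALSE
  if (estimator %in% c("EAP", "MAP")) {
    grid <- theta_grid(n_quad, quad_bounds)
    ll <- response_loglik(codes, bank, grid$nodes)
    post <- ll + log(grid$weights)
    post <- exp(post - max(post)); post <- post / sum(post)
    if (estimator == "EAP") {
      value <- sum(post * grid$nodes)
      se <- sqrt(max(sum(post * grid$nodes^2) - value^2, 0))
    } else {
      # refine the grid argmax by continuous optimization of the posterior
      obj <- function(th) -(response_loglik(codes, bank, th) +
                              stats::dnorm(th, log = TRUE))
      value <- stats::optimize(obj, quad_bounds)$minimum
      mu <- sum(post * grid$nodes)
      se <- sqrt(max(sum(post * grid$nodes^2) - mu^2, 0))
    }
    return(list(value = value, se = se, estimator = estimator, clamped = FALSE))
  }
  ids <- names(codes)
  if (estimator == "ML") {
    obj <- function(th) -response_loglik(codes, bank, th)
    opt <- stats::optimize(obj, theta_bounds)
    value <- opt$minimum
    # detect boundary solutions (monotone likelihood for extreme patterns)
    eps <- 1e-3 * diff(theta_bounds)
    if (value <= theta_bounds[1] + eps || value >= theta_bounds[2] - eps) {
      lo <- obj(theta_bounds[1]); hi <- obj(theta_bounds[2])
      value <- theta_bounds[which.min(c(lo, hi))]
      clamped <- TRUE
    }
  } else {  # WLE
    obj <- function(th) -(response_loglik(codes, bank, th) +
                            0.5 * log(pmax(test_information(bank, th, ids), 1e-12)))
    value <- stats::optimize(obj, theta_bounds)$minimum
  }
  info <- test_information(bank, value, ids)
  se <- if (info > 0) 1 / sqrt(info) else Inf
  list(value = value, se = se, estimator = estimator, clamped = clamped)
}

#' Start an adaptive testing session
#'
#' Chooses the first item (uniformly at random by default) and initializes
#' the trait estimate at the prior mean 0.
#'
#' @param bank a calibrated [item_bank()].
#' @param config a [cat_config()].
#' @return An object of class `cat_session`; the item to administer next is
#'   in `$pending`.
#' @export
start_session <- function(bank, config = cat_config()) {
  if (length(bank) == 0L) stop_pc("cannot start a session on an empty bank")
  ids <- bank_ids(bank)
  first <- if (config$first_item == "random") {
    with_seed(config$seed, sample(ids, 1L))
  } else {
    bm <- bank_matrices(bank)
    ids[which.max(bank_info_at(bm, 0))]
  }
  structure(list(bank = bank, config = config, administered = character(0),
                 responses = integer(0), pending = first,
                 theta_trajectory = list(), finished = FALSE,
                 stop_reason = NULL, t_score = NULL, n_random_draws = 1L),
            class = "cat_session")
}

#' @export
print.cat_session <- function(x, ...) {
  cat(sprintf("<cat_session> %d administered, %s%s\n", length(x$administered),
              if (x$finished) paste0("finished (", x$stop_reason, "), T-score ",
                                     sprintf("%.1f", x$t_score))
              else paste0("pending item '", x$pending, "'"),
              ""))
  invisible(x)
}

#' Select the next item for a session
#'
#' `MFI` picks the unadministered item with maximum Fisher information at
#' the current trait estimate. `KL` picks the item maximizing the
#' posterior-weighted Kullback-Leibler divergence between the response
#' distributions at the current estimate and at each grid node. Ties break
#' to the lowest item index; an administered item is never re-selected.
#'
#' @param session a [start_session()] session.
#' @param rule override the configured selection rule.
#' @return an item id.
#' @export
select_next_item <- function(session, rule = NULL) {
  bank <- session$bank
  config <- session$config
  rule <- rule %||% config$selection_rule
  remaining <- setdiff(bank_ids(bank), c(session$administered, session$pending))
  if (!length(remaining)) stop_pc("no unadministered items remain")
  if (rule == "random")
    return(with_seed(if (is.null(config$seed)) NULL
                     else config$seed + session$n_random_draws,
                     sample(remaining, 1L)))
  cur <- session$theta_trajectory[[length(session$theta_trajectory)]]
  bm <- bank_matrices(bank)
  sel <- match(remaining, bm$ids)
  crit <- if (rule == "MFI") {
    bank_info_at(bm, cur$value)[sel]
  } else {
    kl_index(bank, remaining, cur$value, session)
  }
  remaining[which.max(crit)]  # which.max takes the first (lowest index) tie
}

# posterior-weighted KL index: sum_q w_q KL(P(.|theta_hat) || P(.|theta_q))
kl_index <- function(bank, ids, theta_hat, session) {
  config <- session$config
  grid <- theta_grid(config$n_quad, config$quad_bounds)
  codes <- stats::setNames(session$responses, session$administered)
  ll <- response_loglik(codes, bank, grid$nodes)
  post <- ll + log(grid$weights)
  post <- exp(post - max(post)); post <- post / sum(post)
  vapply(ids, function(id) {
    it <- bank$items[[id]]
    p0 <- pmax(grm_probs(it, theta_hat), P_FLOOR)
    kl <- vapply(grid$nodes, function(t) {
      pt <- pmax(grm_probs(it, t), P_FLOOR)
      sum(p0 * (log(p0) - log(pt)))
    }, numeric(1))
    sum(post * kl)
  }, numeric(1))
}

#' Record a response and advance the session
#'
#' Records `code` for the pending item, re-estimates theta, checks the
#' stopping rule (SE at or below `se_cutoff`, bank exhaustion, or the
#' optional item cap), and either selects the next item or finalizes the
#' session with a stop reason and T-score.
#'
#' @param session an unfinished `cat_session`.
#' @param code 0-based response code for the pending item.
#' @return the updated `cat_session`.
#' @export
step_session <- function(session, code) {
  if (session$finished) stop_pc("session is already finished")
  item <- session$bank$items[[session$pending]]
  code <- as.integer(code)
  if (is.na(code) || code < 0L || code >= item$n_categories)
    stop_pc("invalid code ", code, " for item '", item$id, "' (K = ",
            item$n_categories, ")")
  session$administered <- c(session$administered, session$pending)
  session$responses <- c(session$responses, code)
  session$pending <- NULL
  config <- session$config
  est <- estimate_theta(stats::setNames(session$responses, session$administered),
                        session$bank, config$estimator, config$theta_bounds,
                        config$n_quad, config$quad_bounds)
  session$theta_trajectory <- c(session$theta_trajectory, list(est))
  exhausted <- length(session$administered) >= length(session$bank)
  capped <- !is.null(config$max_items) &&
    length(session$administered) >= config$max_items
  if (est$se <= config$se_cutoff) {
    session$finished <- TRUE; session$stop_reason <- "se_reached"
  } else if (exhausted) {
    session$finished <- TRUE; session$stop_reason <- "bank_exhausted"
  } else if (capped) {
    session$finished <- TRUE; session$stop_reason <- "max_items"
  } else {
    session$n_random_draws <- session$n_random_draws + 1L
    session$pending <- select_next_item(session)
  }
  if (session$finished) session$t_score <- t_score(est$value)
  session
}

#' Run a whole session against a response-generating function
#'
#' Drives [step_session()] with codes produced by `answer(item_id)` until
#' the session finishes. Used by the burden simulator and handy for
#' scripted runs.
#'
#' @param bank a calibrated [item_bank()].
#' @param answer function taking an item id and returning a 0-based code.
#' @param config a [cat_config()].
#' @return the finished `cat_session`.
#' @export
run_session <- function(bank, answer, config = cat_config()) {
  s <- start_session(bank, config)
  while (!s$finished) s <- step_session(s, answer(s$pending))
  s
}

#' Most endorsed response categories per theta level
#'
#' For clinical interpretation, each polytomous category `k >= 1` is
#' dichotomized into the event "responds in category k or above", whose
#' endorsement probability at a theta level is the cumulative curve
#' `P*_k(theta)`. Items below the minimum discrimination are excluded
#' (default 0.65, the lower bound of the conventional "moderate" band),
#' and the `top_n` most endorsed categories are listed per level.
#'
#' @param bank an [item_bank()].
#' @param theta_levels trait levels to profile (default -2..2).
#' @param top_n categories per level.
#' @param min_a minimum discrimination for inclusion.
#' @return data frame: `theta`, `rank`, `item`, `instrument`, `category`
#'   (the dichotomized ">= k" event), `endorsement`.
#' @export
endorsement_table <- function(bank, theta_levels = c(-2, -1, 0, 1, 2),
                              top_n = 10L, min_a = 0.65) {
  stopifnot(all(is.finite(theta_levels)))
  keep <- vapply(bank$items, function(it) it$a >= min_a, logical(1))
  if (!any(keep))
    stop_pc("no items with discrimination >= ", min_a, " in the bank")
  items <- bank$items[keep]
  rows <- do.call(rbind, lapply(items, function(it)
    data.frame(item = it$id, instrument = it$instrument,
               category = seq_len(it$n_categories - 1L),
               a = it$a, b = it$b, row.names = NULL)))
  out <- do.call(rbind, lapply(theta_levels, function(th) {
    p <- stats::plogis(rows$a * (th - rows$b))
    ord <- order(-p, rows$item, rows$category)
    top <- utils::head(ord, top_n)
    data.frame(theta = th, rank = seq_along(top), item = rows$item[top],
               instrument = rows$instrument[top],
               category = rows$category[top], endorsement = p[top],
               row.names = NULL)
  }))
  out
}
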