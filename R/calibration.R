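# Marginal maximum-likelihood calibration of the graded response model by
# EM, with the latent scale identified by a standard-normal prior over a
# fixed quadrature grid. The E-step computes posterior weights for every
# respondent on the grid; the M-step maximizes each item's expected
# complete-data log-likelihood by BFGS on (log a, b1, log-gaps), which
# enforces a positive slope and strictly increasing thresholds.

#' Calibration settings
#'
#' @param n_quad number of quadrature nodes (equally spaced, N(0,1)
#'   weights). 61 nodes on \[-6, 6\] is the deterministic default.
#' @param bounds quadrature bounds.
#' @param tol EM convergence tolerance: maximum absolute parameter change
#'   (natural units) between cycles.
#' @param max_cycles maximum EM cycles.
#' @param mstep_maxit BFGS iteration cap per item per M-step; the partial
#'   M-step still increases the marginal likelihood (generalized EM).
#' @param min_gap minimum threshold gap, enforced on the log scale.
#' @param min_n sample size below which [fit_grm()] refuses to run; item
#'   calibration guidance calls for roughly 200-300 subjects, so fits with
#'   fewer than 200 warn.
#' @return list of class `grm_control`.
#' @export
grm_control <- function(n_quad = 61L, bounds = c(-6, 6), tol = 1e-4,
                        max_cycles = 500L, mstep_maxit = 30L,
                        min_gap = 1e-3, min_n = 150L) {
  structure(list(n_quad = as.integer(n_quad), bounds = bounds, tol = tol,
                 max_cycles = as.integer(max_cycles),
                 mstep_maxit = as.integer(mstep_maxit),
                 min_gap = min_gap, min_n = as.integer(min_n)),
            class = "grm_control")
}

# parameter transform: z = (log a, b1, log(gap_2 - min_gap), ...)
z_to_ab <- function(z, min_gap) {
  a <- exp(z[1])
  b <- numeric(length(z) - 1L)
  b[1] <- z[2]
  if (length(b) > 1L)
    for (m in 2:length(b)) b[m] <- b[m - 1L] + min_gap + exp(z[m + 1L])
  list(a = a, b = b)
}

ab_to_z <- function(a, b, min_gap) {
  z <- c(log(a), b[1])
  if (length(b) > 1L) {
    gaps <- diff(b)
    gaps[gaps <= min_gap] <- min_gap + 1e-6
    z <- c(z, log(gaps - min_gap))
  }
  z
}

# negative expected complete-data log-likelihood for one item and its
# analytic gradient; r is K x Q expected counts, t the quadrature nodes
mstep_obj <- function(z, r, t, min_gap) {
  ab <- z_to_ab(z, min_gap)
  ps <- stats::plogis(outer(ab$b, t, function(b, t) ab$a * (t - b)))  # (K-1) x Q
  P <- rbind(1, ps) - rbind(ps, 0)
  -sum(r * log(pmax(P, P_FLOOR)))
}

mstep_grad <- function(z, r, t, min_gap) {
  ab <- z_to_ab(z, min_gap)
  a <- ab$a; b <- ab$b
  Km1 <- length(b)
  ps <- stats::plogis(outer(b, t, function(b, t) a * (t - b)))
  P <- rbind(1, ps) - rbind(ps, 0)
  Rr <- r / pmax(P, P_FLOOR)                       # K x Q
  S <- ps * (1 - ps)                               # (K-1) x Q
  Dm <- Rr[2:(Km1 + 1L), , drop = FALSE] - Rr[1:Km1, , drop = FALSE]
  tb <- outer(b, t, function(b, t) t - b)
  dfa <- -sum(tb * S * Dm)                         # d(-Q)/da
  dfb <- a * rowSums(S * Dm)                       # d(-Q)/db_m
  g <- numeric(length(z))
  g[1] <- a * dfa
  g[2] <- sum(dfb)
  if (Km1 > 1L)
    for (m in 2:Km1) g[m + 1L] <- exp(z[m + 1L]) * sum(dfb[m:Km1])
  g
}

# per-respondent x node log-likelihood matrix for a parameter set
loglik_grid <- function(X, K, a, blist, nodes) {
  N <- nrow(X); Q <- length(nodes)
  LL <- matrix(0, N, Q)
  for (j in seq_len(ncol(X))) {
    obs <- which(!is.na(X[, j]))
    if (!length(obs)) next
    ps <- stats::plogis(outer(blist[[j]], nodes, function(b, t) a[j] * (t - b)))
    lp <- log(pmax(rbind(1, ps) - rbind(ps, 0), P_FLOOR))
    LL[obs, ] <- LL[obs, ] + lp[X[obs, j] + 1L, , drop = FALSE]
  }
  LL
}

# posterior weights + marginal log-likelihood from an LL grid
posterior_weights <- function(LL, logw) {
  M <- sweep(LL, 2, logw, "+")
  mx <- apply(M, 1, max)
  W <- exp(M - mx)
  den <- rowSums(W)
  list(W = W / den, marg_ll = sum(log(den) + mx))
}

collapse_empty <- function(X, K) {
  # merge unobserved categories into their lower neighbour (category 0
  # merges upward); returns recoded matrix, new K, and a note per item
  notes <- character(0)
  for (j in seq_len(ncol(X))) {
    obs <- tabulate(X[, j] + 1L, nbins = K[j])
    if (all(obs > 0L)) next
    keep <- which(obs > 0L) - 1L
    if (length(keep) < 2L)
      stop_pc("item '", colnames(X)[j],
              "': fewer than 2 observed categories; cannot calibrate")
    map <- cumsum(obs > 0L) - 1L  # old code -> new code (empty joins lower)
    map[map < 0L] <- 0L
    X[, j] <- map[X[, j] + 1L]
    K[j] <- max(map) + 1L
    notes <- c(notes, sprintf("item '%s': collapsed %d empty categor%s",
                              colnames(X)[j], sum(obs == 0L),
                              if (sum(obs == 0L) == 1L) "y" else "ies"))
  }
  list(X = X, K = K, notes = notes)
}

#' Calibrate a graded response model by marginal maximum likelihood
#'
#' Fits discrimination and threshold parameters for every item of an
#' ordinal response matrix under a standard-normal latent trait, using the
#' EM algorithm with fixed quadrature. Missing responses are ignored in
#' the likelihood (missing-at-random). Unobserved categories are collapsed
#' into their lower neighbour with a warning. The fit is deterministic
#' given the data and control settings.
#'
#' @param rm_ a [response_matrix()].
#' @param control a [grm_control()] list.
#' @param construct construct label for the estimated bank.
#' @param verbose print per-cycle progress.
#' @return An object of class `grm_fit`: `bank` (estimated [item_bank()]),
#'   `log_likelihood`, `n_iterations`, `converged`, `ll_trace`,
#'   `quadrature`, `collapse_notes`, plus internals used by
#'   [grm_standard_errors()] and [dif_wald()].
#' @export
fit_grm <- function(rm_, control = grm_control(), construct = "trait",
                    verbose = FALSE) {
  stopifnot(inherits(rm_, "response_matrix"))
  X <- rm_$responses
  N <- nrow(X); J <- ncol(X)
  if (N < control$min_n)
    stop_pc("N = ", N, " is below the minimum calibration sample (",
            control$min_n, ")")
  if (N < 200L)
    warning("N = ", N, " is below the recommended 200-300 calibration sample")
  cl <- collapse_empty(X, rm_$n_categories)
  for (msg in cl$notes) warning(msg)
  X <- cl$X; K <- cl$K
  grid <- theta_grid(control$n_quad, control$bounds)
  nodes <- grid$nodes; logw <- log(grid$weights)

  # deterministic starts: a = 1, thresholds at normal quantiles of the
  # observed cumulative category frequencies
  zs <- vector("list", J)
  for (j in seq_len(J)) {
    obs <- X[!is.na(X[, j]), j]
    cum <- cumsum(tabulate(obs + 1L, nbins = K[j]))[seq_len(K[j] - 1L)] / length(obs)
    b0 <- stats::qnorm(pmin(pmax(cum, 0.02), 0.98))
    b0 <- cummax(b0 + seq_along(b0) * 1e-6)  # guard exact ties
    zs[[j]] <- ab_to_z(1, b0, control$min_gap)
  }
  a <- rep(1, J)
  blist <- lapply(seq_len(J), function(j) z_to_ab(zs[[j]], control$min_gap)$b)

  ll_trace <- numeric(0)
  converged <- FALSE
  cyc <- 0L
  repeat {
    cyc <- cyc + 1L
    LL <- loglik_grid(X, K, a, blist, nodes)
    pw <- posterior_weights(LL, logw)
    ll_trace <- c(ll_trace, pw$marg_ll)
    if (verbose) message(sprintf("cycle %3d  logLik %.4f", cyc, pw$marg_ll))
    maxdelta <- 0
    for (j in seq_len(J)) {
      obsi <- which(!is.na(X[, j]))
      Wo <- pw$W[obsi, , drop = FALSE]
      g <- X[obsi, j]
      r <- matrix(0, K[j], control$n_quad)
      rs <- rowsum(Wo, group = g)
      r[as.integer(rownames(rs)) + 1L, ] <- rs
      op <- stats::optim(zs[[j]], mstep_obj, mstep_grad, r = r, t = nodes,
                         min_gap = control$min_gap, method = "BFGS",
                         control = list(maxit = control$mstep_maxit))
      ab_old <- c(a[j], blist[[j]])
      zs[[j]] <- op$par
      ab <- z_to_ab(op$par, control$min_gap)
      a[j] <- ab$a; blist[[j]] <- ab$b
      maxdelta <- max(maxdelta, max(abs(c(ab$a, ab$b) - ab_old)))
    }
    if (maxdelta < control$tol) { converged <- TRUE; break }
    if (cyc >= control$max_cycles) break
  }
  # final marginal log-likelihood at the converged parameters
  LL <- loglik_grid(X, K, a, blist, nodes)
  pw <- posterior_weights(LL, logw)
  ll_trace <- c(ll_trace, pw$marg_ll)

  instr <- if (!is.null(rm_$instrument)) rm_$instrument else
    rep("calibrated", J)
  items <- lapply(seq_len(J), function(j)
    grm_item(colnames(X)[j], a = a[j], b = blist[[j]],
             instrument = instr[j], reversed = rm_$reversed[[j]]))
  structure(list(
    bank = item_bank(items, construct = construct,
                     provenance = sprintf("MML-EM fit, N=%d, %d cycles", N, cyc)),
    log_likelihood = pw$marg_ll, n_iterations = cyc, converged = converged,
    ll_trace = ll_trace,
    quadrature = sprintf("%d equally spaced nodes on [%g, %g], N(0,1) weights",
                         control$n_quad, control$bounds[1], control$bounds[2]),
    collapse_notes = cl$notes, control = control,
    .X = X, .K = K, .nodes = nodes, .logw = logw, .W = pw$W
  ), class = "grm_fit")
}

#' @export
print.grm_fit <- function(x, ...) {
  cat(sprintf("<grm_fit> %d items, logLik %.2f, %d EM cycles, %s\n",
              length(x$bank), x$log_likelihood, x$n_iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
coef.grm_fit <- function(object, ...) {
  bm <- bank_matrices(object$bank)
  B <- bm$b; B[!is.finite(B)] <- NA
  colnames(B) <- paste0("b", seq_len(ncol(B)))
  data.frame(id = bm$ids, a = bm$a, B, row.names = NULL)
}

#' @export
logLik.grm_fit <- function(object, ...) {
  structure(object$log_likelihood, df = sum(object$.K), class = "logLik")
}

#' Parameter standard errors of a calibrated graded model
#'
#' `method = "observed"` (default) inverts the observed information matrix,
#' obtained as the numerical Jacobian of the analytic marginal score vector
#' (Fisher's identity: the marginal score is the posterior-expected
#' complete-data score). `method = "opg"` uses the empirical cross-product
#' of per-respondent score vectors (outer product of gradients / BHHH); it
#' is cheaper but overstates the covariance somewhat in finite samples,
#' which makes downstream Wald tests conservative.
#'
#' @param fit a converged [fit_grm()] result.
#' @param method `"observed"` or `"opg"`.
#' @return list with `se` (data frame of per-parameter SEs), `cov` (full
#'   covariance matrix) and `blocks` (per-item index ranges into `cov`).
#' @export
grm_standard_errors <- function(fit, method = c("observed", "opg")) {
  stopifnot(inherits(fit, "grm_fit"))
  method <- match.arg(method)
  if (method == "observed") return(observed_se(fit))
  X <- fit$.X; K <- fit$.K; nodes <- fit$.nodes; W <- fit$.W
  bm <- bank_matrices(fit$bank)
  N <- nrow(X); J <- ncol(X)
  pj <- K  # params per item: a + (K-1) thresholds
  P <- sum(pj)
  G <- matrix(0, N, P)
  cn <- character(P)
  blocks <- vector("list", J)
  pos <- 0L
  for (j in seq_len(J)) {
    a <- bm$a[j]; b <- fit$bank$items[[j]]$b
    Km1 <- K[j] - 1L
    ps <- stats::plogis(outer(b, nodes, function(b, t) a * (t - b)))
    Pm <- rbind(1, ps) - rbind(ps, 0)
    Pm <- pmax(Pm, P_FLOOR)
    S <- ps * (1 - ps)
    tb <- outer(b, nodes, function(b, t) t - b)
    dPsa <- tb * S                                  # dP*_m/da, (K-1) x Q
    # dlogP_c/da = (dP*_c/da - dP*_{c+1}/da) / P_c
    DA <- (rbind(0, dPsa) - rbind(dPsa, 0)) / Pm    # K x Q
    obs <- which(!is.na(X[, j]))
    xi <- X[obs, j] + 1L
    Wo <- W[obs, , drop = FALSE]
    idx <- pos + 1L
    G[obs, idx] <- rowSums(Wo * DA[xi, , drop = FALSE])
    cn[idx] <- paste0(bm$ids[j], ".a")
    for (m in seq_len(Km1)) {
      # b_m enters P*_m only: dP_{m-1}/db_m = +a S_m, dP_m/db_m = -a S_m
      DB <- matrix(0, K[j], length(nodes))
      DB[m, ] <- a * S[m, ] / Pm[m, ]
      DB[m + 1L, ] <- -a * S[m, ] / Pm[m + 1L, ]
      G[obs, pos + 1L + m] <- rowSums(Wo * DB[xi, , drop = FALSE])
      cn[pos + 1L + m] <- paste0(bm$ids[j], ".b", m)
    }
    blocks[[j]] <- (pos + 1L):(pos + pj[j])
    pos <- pos + pj[j]
  }
  names(blocks) <- bm$ids
  OPG <- crossprod(G)
  V <- tryCatch(solve(OPG), error = function(e) {
    dets <- vapply(blocks, function(ix) det(OPG[ix, ix, drop = FALSE]), numeric(1))
    stop_pc("singular information matrix; weakest item: '",
            bm$ids[which.min(abs(dets))], "'")
  })
  se <- sqrt(pmax(diag(V), 0))
  list(se = data.frame(parameter = cn, se = se, row.names = NULL),
       cov = structure(V, dimnames = list(cn, cn)), blocks = blocks)
}

# total marginal score vector at arbitrary parameters (a, blist); by
# Fisher's identity this is sum_j sum_{k,q} r_jkq dlogP_jk(theta_q)/d eta
marginal_score <- function(X, K, a, blist, nodes, logw) {
  LL <- loglik_grid(X, K, a, blist, nodes)
  pw <- posterior_weights(LL, logw)
  out <- numeric(sum(K))
  pos <- 0L
  for (j in seq_len(ncol(X))) {
    obs <- which(!is.na(X[, j]))
    Wo <- pw$W[obs, , drop = FALSE]
    g <- X[obs, j]
    r <- matrix(0, K[j], length(nodes))
    rs <- rowsum(Wo, group = g)
    r[as.integer(rownames(rs)) + 1L, ] <- rs
    b <- blist[[j]]; Km1 <- K[j] - 1L
    ps <- stats::plogis(outer(b, nodes, function(b, t) a[j] * (t - b)))
    Pm <- pmax(rbind(1, ps) - rbind(ps, 0), P_FLOOR)
    S <- ps * (1 - ps)
    dPsa <- outer(b, nodes, function(b, t) t - b) * S
    DA <- (rbind(0, dPsa) - rbind(dPsa, 0)) / Pm
    out[pos + 1L] <- sum(r * DA)
    for (m in seq_len(Km1))
      out[pos + 1L + m] <- a[j] * sum(S[m, ] * (r[m, ] / Pm[m, ] -
                                                  r[m + 1L, ] / Pm[m + 1L, ]))
    pos <- pos + K[j]
  }
  out
}

# observed-information SEs: central-difference Jacobian of marginal_score
observed_se <- function(fit, h = 1e-4) {
  X <- fit$.X; K <- fit$.K; nodes <- fit$.nodes; logw <- fit$.logw
  bm <- bank_matrices(fit$bank)
  a <- bm$a
  blist <- lapply(fit$bank$items, `[[`, "b")
  J <- ncol(X)
  P <- sum(K)
  cn <- character(P); blocks <- vector("list", J)
  pos <- 0L
  for (j in seq_len(J)) {
    cn[pos + 1L] <- paste0(bm$ids[j], ".a")
    if (K[j] > 1L)
      cn[pos + 1L + seq_len(K[j] - 1L)] <- paste0(bm$ids[j], ".b",
                                                  seq_len(K[j] - 1L))
    blocks[[j]] <- (pos + 1L):(pos + K[j])
    pos <- pos + K[j]
  }
  names(blocks) <- bm$ids
  perturb <- function(p, delta) {
    a2 <- a; b2 <- blist
    jj <- findInterval(p - 1L, cumsum(c(0, K))[seq_len(J)], rightmost.closed = FALSE)
    within <- p - sum(K[seq_len(jj - 1L)])
    if (within == 1L) a2[jj] <- a2[jj] + delta
    else b2[[jj]][within - 1L] <- b2[[jj]][within - 1L] + delta
    marginal_score(X, K, a2, b2, nodes, logw)
  }
  H <- matrix(0, P, P)
  for (p in seq_len(P))
    H[, p] <- (perturb(p, h) - perturb(p, -h)) / (2 * h)
  info <- -(H + t(H)) / 2
  V <- tryCatch(solve(info), error = function(e)
    stop_pc("singular observed information matrix"))
  d <- diag(V)
  if (any(d <= 0))
    warning("non-positive variance estimate for: ",
            paste(cn[d <= 0], collapse = ", "))
  se <- sqrt(pmax(d, 0))
  list(se = data.frame(parameter = cn, se = se, row.names = NULL),
       cov = structure(V, dimnames = list(cn, cn)), blocks = blocks)
}

#' Expected a posteriori trait scores
#'
#' EAP estimate (posterior mean) and SE (posterior SD) per respondent under
#' a standard-normal prior on a fixed quadrature grid. Respondents with no
#' answered items get the prior (theta 0, SE 1) and are flagged.
#'
#' @param rm_ a [response_matrix()] whose items are covered by `bank`.
#' @param bank a calibrated [item_bank()].
#' @param n_quad,bounds quadrature settings.
#' @return data frame: `respondent_id`, `theta`, `se`, `estimator`,
#'   `n_answered`, `prior_only`.
#' @export
eap_scores <- function(rm_, bank, n_quad = 61L, bounds = c(-6, 6)) {
  stopifnot(inherits(rm_, "response_matrix"))
  ids <- colnames(rm_$responses)
  bad <- setdiff(ids, bank_ids(bank))
  if (length(bad)) stop_pc("bank does not cover item(s): ",
                           paste(bad, collapse = ", "))
  grid <- theta_grid(n_quad, bounds)
  items <- bank$items[ids]
  a <- vapply(items, `[[`, numeric(1), "a")
  blist <- lapply(items, `[[`, "b")
  LL <- loglik_grid(rm_$responses, rm_$n_categories, a, blist, grid$nodes)
  pw <- posterior_weights(LL, log(grid$weights))
  theta <- as.numeric(pw$W %*% grid$nodes)
  m2 <- as.numeric(pw$W %*% grid$nodes^2)
  se <- sqrt(pmax(m2 - theta^2, 0))
  n_ans <- rowSums(!is.na(rm_$responses))
  data.frame(respondent_id = rownames(rm_$responses), theta = theta, se = se,
             estimator = "EAP", n_answered = n_ans, prior_only = n_ans == 0L,
             row.names = NULL)
}
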