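# Pre-calibration item screening: mixed-type correlation matrices,
# maximum-likelihood exploratory factor analysis with the 0.30
# single-factor loading rule, Yen's Q3 local-dependence diagnostic, Wald
# tests for differential item functioning across two groups, conventional
# discrimination banding, and a seeded hot-deck imputation surrogate.

# ---------------------------------------------------------------------------
# bivariate normal CDF (Gauss-Legendre on the correlation path):
# Phi2(h, k, rho) = Phi(h) Phi(k) + int_0^rho phi2(h, k; r) dr

pbivnorm <- function(h, k, rho) {
  if (!is.finite(h) && h > 0) return(stats::pnorm(min(k, Inf)))
  if (!is.finite(k) && k > 0) return(stats::pnorm(min(h, Inf)))
  if (!is.finite(h) || !is.finite(k)) return(0)  # either is -Inf
  if (abs(rho) < 1e-12) return(stats::pnorm(h) * stats::pnorm(k))
  rho <- max(min(rho, 0.9999), -0.9999)
  gl <- list(  # 16-point Gauss-Legendre on [0, 1]
    x = c(0.00529953250417503, 0.0277124884633837, 0.0671843988060841,
          0.122297795822498, 0.191061877798678, 0.270991611171386,
          0.359198224610371, 0.452493745081181, 0.547506254918819,
          0.640801775389629, 0.729008388828614, 0.808938122201322,
          0.877702204177502, 0.932815601193916, 0.972287511536616,
          0.994700467495825),
    w = c(0.0135762297058770, 0.0311267619693239, 0.0475792558412464,
          0.0623144856277669, 0.0747979944082884, 0.0845782596975013,
          0.0913017075224618, 0.0947253052275343, 0.0947253052275343,
          0.0913017075224618, 0.0845782596975013, 0.0747979944082884,
          0.0623144856277669, 0.0475792558412464, 0.0311267619693239,
          0.0135762297058770))
  r <- rho * gl$x
  dens <- exp(-(h^2 - 2 * r * h * k + k^2) / (2 * (1 - r^2))) /
    (2 * pi * sqrt(1 - r^2))
  stats::pnorm(h) * stats::pnorm(k) + rho * sum(gl$w * dens)
}

#' Polychoric correlation of two ordinal variables
#'
#' Two-step maximum likelihood: thresholds from the marginal cumulative
#' proportions, then the latent correlation maximizing the bivariate-normal
#' multinomial likelihood of the contingency table.
#'
#' @param x,y integer-coded ordinal vectors (pairwise-complete used).
#' @return estimated latent correlation, or `NA` (with a warning) when the
#'   contingency table has an empty margin.
#' @export
polychoric_corr <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  tab <- table(x, y)
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    warning("polychoric undefined: a margin has fewer than 2 observed categories")
    return(NA_real_)
  }
  n <- sum(tab)
  taux <- c(-Inf, stats::qnorm(cumsum(rowSums(tab) / n))[-nrow(tab)], Inf)
  tauy <- c(-Inf, stats::qnorm(cumsum(colSums(tab) / n))[-ncol(tab)], Inf)
  nll <- function(rho) {
    ll <- 0
    for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
      if (tab[i, j] == 0) next
      pij <- pbivnorm(taux[i + 1], tauy[j + 1], rho) -
        pbivnorm(taux[i], tauy[j + 1], rho) -
        pbivnorm(taux[i + 1], tauy[j], rho) +
        pbivnorm(taux[i], tauy[j], rho)
      ll <- ll + tab[i, j] * log(max(pij, 1e-12))
    }
    -ll
  }
  stats::optimize(nll, c(-0.999, 0.999))$minimum
}

#' Polyserial correlation of a continuous and an ordinal variable
#'
#' Two-step estimator: the Pearson correlation rescaled by the ratio of the
#' ordinal variable's SD to the total density at its normal thresholds.
#'
#' @param x continuous vector.
#' @param y integer-coded ordinal vector.
#' @return estimated latent correlation in \[-1, 1\].
#' @export
polyserial_corr <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  tab <- table(y)
  if (length(tab) < 2L) {
    warning("polyserial undefined: ordinal margin has fewer than 2 categories")
    return(NA_real_)
  }
  tau <- stats::qnorm(cumsum(tab / length(y)))[-length(tab)]
  r <- stats::cor(x, y)
  est <- r * stats::sd(y) * sqrt((length(y) - 1) / length(y)) /
    sum(stats::dnorm(tau))
  max(min(est, 1), -1)
}

#' Mixed-type correlation matrix
#'
#' Pearson for continuous pairs, polychoric for ordinal pairs, polyserial
#' for mixed pairs. Pairs with fewer than `min_pairs` complete observations
#' or an empty contingency margin are set to `NA` and flagged.
#'
#' @param data data frame or matrix of variables (columns).
#' @param types character vector per column: `"ordinal"` or `"continuous"`.
#'   Default: all ordinal.
#' @param min_pairs minimum pairwise-complete observations.
#' @return symmetric correlation matrix with unit diagonal; attribute
#'   `"undefined"` lists flagged pairs.
#' @export
correlation_matrix <- function(data, types = NULL, min_pairs = 10L) {
  data <- as.data.frame(data)
  p <- ncol(data)
  if (p < 2L) stop_pc("need at least 2 variables")
  types <- types %||% rep("ordinal", p)
  if (length(types) == 1L) types <- rep(types, p)
  if (length(types) != p || !all(types %in% c("ordinal", "continuous")))
    stop_pc("'types' must give 'ordinal' or 'continuous' per column")
  R <- diag(1, p)
  dimnames(R) <- list(colnames(data), colnames(data))
  undef <- character(0)
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    xi <- data[[i]]; xj <- data[[j]]
    ok <- !is.na(xi) & !is.na(xj)
    if (sum(ok) < min_pairs) {
      R[i, j] <- R[j, i] <- NA
      undef <- c(undef, paste(colnames(data)[c(i, j)], collapse = ":"))
      next
    }
    r <- withCallingHandlers({
      if (types[i] == "ordinal" && types[j] == "ordinal")
        polychoric_corr(xi, xj)
      else if (types[i] == "continuous" && types[j] == "continuous")
        stats::cor(xi[ok], xj[ok])
      else if (types[i] == "continuous")
        polyserial_corr(xi, xj)
      else
        polyserial_corr(xj, xi)
    }, warning = function(w) invokeRestart("muffleWarning"))
    if (is.na(r)) undef <- c(undef, paste(colnames(data)[c(i, j)], collapse = ":"))
    R[i, j] <- R[j, i] <- r
  }
  attr(R, "undefined") <- undef
  R
}

# ---------------------------------------------------------------------------
# exploratory factor analysis

# nearest-PSD smoothing: clip eigenvalues, rescale to unit diagonal
smooth_psd <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) > 1e-8) return(list(R = R, smoothed = FALSE))
  v <- pmax(e$values, 1e-6)
  S <- e$vectors %*% diag(v) %*% t(e$vectors)
  d <- sqrt(diag(S))
  list(R = S / tcrossprod(d), smoothed = TRUE)
}

# quartimin criterion and gradient for oblique gradient-projection rotation
vg_quartimin <- function(L) {
  L2 <- L^2
  Nm <- matrix(1, ncol(L), ncol(L)) - diag(ncol(L))
  list(f = sum(L2 * (L2 %*% Nm)) / 4, G = L * (L2 %*% Nm))
}

# oblique gradient projection (Jennrich-style) for the quartimin/oblimin
# criterion; returns the rotated pattern and factor correlations
gpf_oblimin <- function(A, maxit = 500L, tol = 1e-6) {
  m <- ncol(A)
  # start from the varimax rotation: deterministic, and steps off the
  # symmetric saddle point of the quartimin criterion at the ML solution
  # (an orthogonal T has unit-norm columns and T^{-T} = T, so the first
  # pattern below is exactly the varimax solution)
  Tm <- stats::varimax(A, normalize = FALSE)$rotmat
  al <- 1
  Ti <- solve(Tm)
  L <- A %*% t(Ti)
  vg <- vg_quartimin(L)
  f <- vg$f
  G <- -t(t(L) %*% vg$G %*% Ti)
  for (it in seq_len(maxit)) {
    Gp <- G - Tm %*% diag(colSums(Tm * G), m)
    s <- sqrt(sum(Gp^2))
    if (s < tol) break
    al <- 2 * al
    for (half in 1:20) {
      X <- Tm - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)), m)
      Ti <- solve(Tt)
      L <- A %*% t(Ti)
      vg <- vg_quartimin(L)
      if (vg$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tm <- Tt
    f <- vg$f
    G <- -t(t(L) %*% vg$G %*% Ti)
  }
  list(loadings = L, Phi = t(Tm) %*% Tm)
}

#' Exploratory factor analysis of a correlation matrix
#'
#' Maximum-likelihood extraction (via `stats::factanal` on the correlation
#' matrix, smoothed to positive definite if needed) followed by the
#' requested rotation: none, varimax (orthogonal) or oblimin (oblique,
#' quartimin criterion by gradient projection). Heywood cases
#' (communalities at the boundary) are flagged, not fatal.
#'
#' @param corr correlation matrix.
#' @param n_factors number of factors (must be < n_items / 2).
#' @param rotation `"none"`, `"varimax"` or `"oblimin"`.
#' @param n_obs optional number of observations behind `corr`.
#' @return object of class `factor_solution`: `loadings`, `rotation`,
#'   `eigenvalues`, `communalities`, `factor_cor`, `heywood`, `smoothed`.
#' @export
efa <- function(corr, n_factors = 1L, rotation = c("none", "varimax", "oblimin"),
                n_obs = NULL) {
  rotation <- match.arg(rotation)
  p <- ncol(corr)
  if (n_factors >= p / 2)
    stop_pc("n_factors must be below n_items / 2 for identification")
  if (anyNA(corr)) stop_pc("correlation matrix contains NA entries")
  sm <- smooth_psd(corr)
  if (sm$smoothed) message("correlation matrix smoothed to positive definite")
  fa <- stats::factanal(covmat = stats::cov2cor(sm$R), factors = n_factors,
                        rotation = "none",
                        n.obs = n_obs %||% NA_integer_)
  L <- unclass(fa$loadings)
  Phi <- diag(n_factors)
  if (rotation == "varimax" && n_factors > 1L) {
    L <- stats::varimax(L)$loadings
    L <- unclass(L)
  } else if (rotation == "oblimin" && n_factors > 1L) {
    ro <- gpf_oblimin(L)
    L <- ro$loadings
    Phi <- ro$Phi
  }
  dimnames(L) <- list(colnames(corr), paste0("F", seq_len(n_factors)))
  comm <- 1 - fa$uniquenesses
  structure(list(n_factors = n_factors, loadings = L, rotation = rotation,
                 extraction = "ml",
                 eigenvalues = eigen(sm$R, symmetric = TRUE,
                                     only.values = TRUE)$values,
                 communalities = comm, factor_cor = Phi,
                 heywood = any(comm > 0.998), smoothed = sm$smoothed),
            class = "factor_solution")
}

#' @export
print.factor_solution <- function(x, ...) {
  cat(sprintf("<factor_solution> %d factor(s), %s rotation%s\n", x$n_factors,
              x$rotation, if (x$heywood) " [Heywood case]" else ""))
  print(round(x$loadings, 3))
  invisible(x)
}

#' Apply the single-factor 0.30 loading rule
#'
#' An item is kept if and only if exactly one of its absolute loadings
#' reaches the threshold: items loading nowhere, and items cross-loading on
#' two or more factors, are excluded with the reason recorded.
#'
#' @param solution a [efa()] `factor_solution` (or a bare loading matrix).
#' @param threshold loading cutoff (default 0.30).
#' @return list: `kept` (ids), `excluded` (data frame id, reason).
#' @export
loading_filter <- function(solution, threshold = 0.30) {
  L <- if (inherits(solution, "factor_solution")) solution$loadings
       else as.matrix(solution)
  ids <- rownames(L) %||% paste0("item", seq_len(nrow(L)))
  nbig <- rowSums(abs(L) >= threshold)
  kept <- ids[nbig == 1L]
  excl <- data.frame(
    id = ids[nbig != 1L],
    reason = ifelse(nbig[nbig != 1L] == 0L,
                    sprintf("no loading >= %.2f", threshold),
                    sprintf("cross-loading on %d factors", nbig[nbig != 1L])),
    row.names = NULL)
  list(kept = kept, excluded = excl)
}

# ---------------------------------------------------------------------------
# local dependence

#' Yen's Q3 local-dependence diagnostic
#'
#' Correlates item residuals (observed code minus model-expected score at
#' the respondent's EAP theta). Under local independence Q3 values center
#' near `-1/(J-1)` (a known negative bias), so pairs are flagged when
#' `|Q3 - baseline|` exceeds the cutoff.
#'
#' @param rm_ a [response_matrix()].
#' @param bank the calibrated [item_bank()] for these items.
#' @param cutoff flagging cutoff above the baseline (default 0.2).
#' @return data frame of item pairs with `q3` and `flagged`; attribute
#'   `"baseline"` holds `-1/(J-1)`.
#' @export
q3_local_dependence <- function(rm_, bank, cutoff = 0.2) {
  stopifnot(inherits(rm_, "response_matrix"))
  X <- rm_$responses
  J <- ncol(X)
  if (J < 2L) stop_pc("need at least 2 items")
  th <- eap_scores(rm_, bank)$theta
  E <- matrix(NA_real_, nrow(X), J, dimnames = dimnames(X))
  for (j in seq_len(J)) {
    it <- bank$items[[colnames(X)[j]]]
    K <- it$n_categories
    ps <- stats::plogis(it$a * outer(th, it$b, "-"))
    P <- cbind(1, ps) - cbind(ps, 0)
    E[, j] <- as.numeric(P %*% (0:(K - 1L)))
  }
  Rres <- X - E
  sds <- apply(Rres, 2, stats::sd, na.rm = TRUE)
  if (any(sds < 1e-10, na.rm = TRUE))
    warning("item(s) with zero residual variance skipped: ",
            paste(colnames(X)[which(sds < 1e-10)], collapse = ", "))
  Q3 <- suppressWarnings(stats::cor(Rres, use = "pairwise.complete.obs"))
  baseline <- -1 / (J - 1)
  pairs <- which(upper.tri(Q3), arr.ind = TRUE)
  out <- data.frame(item1 = colnames(X)[pairs[, 1]],
                    item2 = colnames(X)[pairs[, 2]],
                    q3 = Q3[pairs], row.names = NULL)
  out <- out[!is.na(out$q3), ]
  out$flagged <- abs(out$q3 - baseline) > cutoff
  attr(out, "baseline") <- baseline
  out
}

# ---------------------------------------------------------------------------
# differential item functioning

#' Wald tests for differential item functioning across two groups
#'
#' Calibrates the graded model separately in the reference and focal
#' groups, links the focal scale to the reference with mean/sigma linking
#' on all other items' thresholds (anchor-all-other-items), and tests the
#' joint difference of the studied item's parameters with a Wald
#' chi-square (df = number of item parameters). P-values are
#' Benjamini-Hochberg adjusted across items; `flagged` applies `alpha` to
#' the adjusted values.
#'
#' @param rm_ a [response_matrix()] with a two-level grouping covariate.
#' @param group name of the covariate column (default `"gender"`).
#' @param alpha flagging level (default 0.05).
#' @param control [grm_control()] passed to the per-group calibrations.
#' @param se_method covariance estimator passed to
#'   [grm_standard_errors()]; the observed information (default) gives a
#'   well-calibrated Wald test, the cheaper OPG is conservative.
#' @return data frame: `item_id`, `wald_statistic`, `df`, `p_value`,
#'   `p_adjusted`, `flagged`.
#' @export
dif_wald <- function(rm_, group = "gender", alpha = 0.05,
                     control = grm_control(),
                     se_method = c("observed", "opg")) {
  se_method <- match.arg(se_method)
  stopifnot(inherits(rm_, "response_matrix"))
  if (is.null(rm_$covariates) || !group %in% names(rm_$covariates))
    stop_pc("grouping covariate '", group, "' not found")
  g <- as.factor(rm_$covariates[[group]])
  if (nlevels(g) != 2L)
    stop_pc("DIF requires exactly 2 groups; got ", nlevels(g))
  ns <- table(g)
  if (any(ns < 100)) warning("group size(s) below 100: ",
                             paste(ns, collapse = ", "))
  sub_rm <- function(keep) {
    r <- rm_
    r$responses <- r$responses[keep, , drop = FALSE]
    r$covariates <- r$covariates[keep, , drop = FALSE]
    r
  }
  fitR <- fit_grm(sub_rm(g == levels(g)[1]), control)
  fitF <- fit_grm(sub_rm(g == levels(g)[2]), control)
  seR <- grm_standard_errors(fitR, se_method)
  seF <- grm_standard_errors(fitF, se_method)
  ids <- bank_ids(fitR$bank)
  res <- lapply(ids, function(id) {
    itR <- fitR$bank$items[[id]]; itF <- fitF$bank$items[[id]]
    if (itR$n_categories != itF$n_categories) {
      warning("item '", id, "' skipped: category structures differ between ",
              "groups after collapsing")
      return(NULL)
    }
    anchors <- Filter(function(aid)
      fitR$bank$items[[aid]]$n_categories == fitF$bank$items[[aid]]$n_categories,
      setdiff(ids, id))
    # positions of the anchor thresholds inside each group's full
    # parameter vector (block layout: a, b1, ..., b_{K-1} per item)
    anc_R <- unlist(lapply(anchors, function(aid) seR$blocks[[aid]][-1]))
    anc_F <- unlist(lapply(anchors, function(aid) seF$blocks[[aid]][-1]))
    bR <- unlist(lapply(fitR$bank$items[anchors], `[[`, "b"))
    bF <- unlist(lapply(fitF$bank$items[anchors], `[[`, "b"))
    nA <- length(bR)
    mR <- mean(bR); sR <- stats::sd(bR)
    mF <- mean(bF); sF <- stats::sd(bF)
    A <- sR / sF
    B <- mR - A * mF
    Km1 <- itR$n_categories - 1L
    delta <- c(itR$a - itF$a / A, itR$b - (A * itF$b + B))
    # delta-method variance of delta, propagating the linking constants
    # (A, B) through both groups' full covariance matrices: the scale
    # error shared by the studied item and its anchors largely cancels in
    # the linked difference, and ignoring that makes the test conservative
    PR <- ncol(seR$cov); PF <- ncol(seF$cov)
    DR <- matrix(0, Km1 + 1L, PR)
    DF <- matrix(0, Km1 + 1L, PF)
    bix_R <- seR$blocks[[id]]; bix_F <- seF$blocks[[id]]
    DR[1L, bix_R[1L]] <- 1
    DR[cbind(1L + seq_len(Km1), bix_R[-1L])] <- 1
    DF[1L, bix_F[1L]] <- -1 / A
    DF[cbind(1L + seq_len(Km1), bix_F[-1L])] <- -A
    dA_dbR <- (bR - mR) / ((nA - 1) * sR * sF)          # per anchor threshold
    dB_dbR <- 1 / nA - mF * dA_dbR
    dA_dbF <- -A * (bF - mF) / ((nA - 1) * sF^2)
    dB_dbF <- -A / nA - mF * dA_dbF
    DR[1L, anc_R] <- (itF$a / A^2) * dA_dbR
    DF[1L, anc_F] <- (itF$a / A^2) * dA_dbF
    for (m in seq_len(Km1)) {
      DR[1L + m, anc_R] <- -itF$b[m] * dA_dbR - dB_dbR
      DF[1L + m, anc_F] <- -itF$b[m] * dA_dbF - dB_dbF
    }
    V <- DR %*% seR$cov %*% t(DR) + DF %*% seF$cov %*% t(DF)
    W <- tryCatch(drop(t(delta) %*% solve(V, delta)), error = function(e) NA)
    if (!is.finite(W)) {
      warning("item '", id, "' skipped: singular Wald covariance")
      return(NULL)
    }
    df <- length(delta)
    data.frame(item_id = id, wald_statistic = W, df = df,
               p_value = stats::pchisq(W, df, lower.tail = FALSE))
  })
  out <- do.call(rbind, res)
  if (is.null(out)) stop_pc("no testable items")
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out$flagged <- out$p_adjusted < alpha
  rownames(out) <- NULL
  out
}

#' Band a discrimination value on the conventional scale
#'
#' Very low `[0, 0.35)`, low `[0.35, 0.65)`, moderate `[0.65, 1.35)`, high
#' `[1.35, 1.70)`, very high `>= 1.70`. "At least moderate" (a >= 0.65) is
#' the usual inclusion rule for clinical interpretation tables.
#'
#' @param a nonnegative discrimination value(s).
#' @return factor with levels very_low .. very_high.
#' @export
classify_discrimination <- function(a) {
  if (any(a < 0)) stop_pc("discrimination must be nonnegative")
  cut(a, breaks = c(0, 0.35, 0.65, 1.35, 1.70, Inf), right = FALSE,
      labels = c("very_low", "low", "moderate", "high", "very_high"))
}

# ---------------------------------------------------------------------------
# imputation surrogate

#' Seeded hot-deck imputation within total-score deciles
#'
#' Fills each missing cell with the value of a donor respondent drawn from
#' the same decile of the rescaled observed total score; when no donor in
#' the decile has the item observed, the item mode is used (logged). A
#' deliberately simple, deterministic surrogate for chained-equations
#' multiple imputation, adequate for complete-synthetic acceptance runs.
#'
#' @param rm_ a [response_matrix()]; per-item missingness must be < 30%.
#' @param seed integer seed.
#' @return a completed [response_matrix()].
#' @export
hotdeck_impute <- function(rm_, seed = 1L) {
  stopifnot(inherits(rm_, "response_matrix"))
  X <- rm_$responses
  miss_rate <- colMeans(is.na(X))
  if (any(miss_rate >= 0.3))
    stop_pc("per-item missingness must be < 30%; worst item: ",
            colnames(X)[which.max(miss_rate)],
            sprintf(" (%.0f%%)", 100 * max(miss_rate)))
  if (!anyNA(X)) return(rm_)
  Km1 <- pmax(rm_$n_categories - 1L, 1L)
  prop <- sweep(X, 2, Km1, "/")
  tot <- rowMeans(prop, na.rm = TRUE)
  tot[is.nan(tot)] <- 0.5
  dec <- as.integer(cut(rank(tot, ties.method = "first"),
                        breaks = 10, labels = FALSE))
  with_seed(seed, {
    for (j in seq_len(ncol(X))) {
      nas <- which(is.na(X[, j]))
      for (i in nas) {
        pool <- which(dec == dec[i] & !is.na(X[, j]))
        if (length(pool)) {
          X[i, j] <- X[pool[sample.int(length(pool), 1L)], j]
        } else {
          obs <- X[!is.na(X[, j]), j]
          X[i, j] <- as.integer(names(which.max(table(obs))))
          message("item '", colnames(X)[j], "': empty donor pool, mode used")
        }
      }
    }
  })
  rm_$responses <- X
  rm_
}
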