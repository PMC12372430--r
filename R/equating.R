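# Single-group equipercentile equating between the raw total scores of two
# instruments, reduction of the concordance to a linear crosswalk
# (intercept + slope with spreadsheet rounding), and round-trip symmetry
# reporting.

#' Discrete score distribution
#'
#' @param scores integer vector of observed raw scores (`NA` dropped).
#' @param min,max score range; defaults to the observed range. Scores in
#'   the range with zero frequency are kept with count 0.
#' @return object of class `score_distribution`: `scores`, `freq`, `n`.
#' @export
score_distribution <- function(scores, min = NULL, max = NULL) {
  scores <- scores[!is.na(scores)]
  if (!length(scores)) stop_pc("empty score distribution")
  scores <- as.integer(round(scores))
  lo <- as.integer(min %||% base::min(scores))
  hi <- as.integer(max %||% base::max(scores))
  if (any(scores < lo | scores > hi))
    stop_pc("scores outside declared range ", lo, "..", hi)
  sup <- lo:hi
  freq <- as.integer(table(factor(scores, levels = sup)))
  structure(list(scores = sup, freq = freq, n = length(scores)),
            class = "score_distribution")
}

#' Percentile ranks of a discrete score distribution
#'
#' Plus-half convention: `PR(x) = 100 (F(x-1) + f(x)/2) / N`, strictly
#' increasing across scores with nonzero frequency.
#'
#' @param dist a [score_distribution()].
#' @return data frame: `score`, `percentile_rank`.
#' @export
percentile_ranks <- function(dist) {
  stopifnot(inherits(dist, "score_distribution"))
  cf <- cumsum(dist$freq)
  pr <- 100 * (c(0, cf[-length(cf)]) + dist$freq / 2) / dist$n
  data.frame(score = dist$scores, percentile_rank = pr)
}

#' Equipercentile equating of two score distributions
#'
#' Maps each score `x` of the source instrument to the (continuized)
#' score of the target instrument with the same percentile rank, by linear
#' interpolation within the target score interval holding that rank. The
#' equated function is monotone nondecreasing.
#'
#' @param x_dist source [score_distribution()].
#' @param y_dist target [score_distribution()].
#' @return data frame: `score`, `percentile_rank`, `equated` (continuous
#'   target-scale value).
#' @export
equipercentile_equate <- function(x_dist, y_dist) {
  stopifnot(inherits(x_dist, "score_distribution"),
            inherits(y_dist, "score_distribution"))
  if (sum(y_dist$freq > 0) == 1L) {
    warning("degenerate target distribution (single support point); constant map")
    cst <- y_dist$scores[y_dist$freq > 0]
    prx <- percentile_ranks(x_dist)
    return(data.frame(score = prx$score, percentile_rank = prx$percentile_rank,
                      equated = rep(as.numeric(cst), nrow(prx))))
  }
  prx <- percentile_ranks(x_dist)
  G <- cumsum(y_dist$freq) / y_dist$n        # cumulative rel. freq of target
  g <- y_dist$freq / y_dist$n
  ys <- y_dist$scores
  equate_one <- function(p) {                # p in [0, 1]
    if (p >= 1) return(ys[length(ys)] + 0.5)
    if (p <= 0) return(ys[1] - 0.5)
    u <- which(G > p)[1]                     # first score with G(y) > p
    Gl <- if (u == 1L) 0 else G[u - 1L]
    if (g[u] <= 0) return(ys[u] - 0.5)       # rank falls on a gap boundary
    ys[u] - 0.5 + (p - Gl) / g[u]
  }
  eq <- vapply(prx$percentile_rank / 100, equate_one, numeric(1))
  data.frame(score = prx$score, percentile_rank = prx$percentile_rank,
             equated = eq)
}

#' Fit a linear crosswalk to an equipercentile concordance
#'
#' Weighted least squares of the equated values on the source scores, with
#' the source frequencies as weights, giving the `ROUND(intercept + slope *
#' score)` conversion form. A residual summary is attached so users can
#' judge whether the concordance is close enough to linear.
#'
#' @param concordance output of [equipercentile_equate()].
#' @param weights per-score weights (default: source frequencies via
#'   `x_dist`; unweighted if neither given).
#' @param x_dist optional source [score_distribution()] providing weights.
#' @param source,target instrument labels.
#' @param target_range integer vector `c(min, max)` for clamping converted
#'   scores.
#' @param clamp clamp converted scores into `target_range`?
#' @return object of class `crosswalk`: `intercept`, `slope`, labels,
#'   ranges, `residuals` summary.
#' @export
fit_linear_crosswalk <- function(concordance, weights = NULL, x_dist = NULL,
                                 source = "X", target = "Y",
                                 target_range = NULL, clamp = TRUE) {
  keep <- is.finite(concordance$equated)
  x <- concordance$score[keep]; y <- concordance$equated[keep]
  w <- weights %||% (if (!is.null(x_dist)) x_dist$freq[keep] else rep(1, length(x)))
  pos <- w > 0
  if (length(unique(x[pos])) < 2L)
    stop_pc("need at least 2 distinct source scores with positive weight")
  fit <- stats::lm.wfit(cbind(1, x[pos]), y[pos], w[pos])
  co <- fit$coefficients
  if (abs(co[2]) < 1e-12) stop_pc("degenerate crosswalk: slope is zero")
  res <- y[pos] - (co[1] + co[2] * x[pos])
  structure(list(source = source, target = target,
                 source_range = range(concordance$score),
                 target_range = target_range %||%
                   c(floor(min(y)), ceiling(max(y))),
                 intercept = unname(co[1]), slope = unname(co[2]),
                 rounding = "half-away-from-zero", clamp = clamp,
                 residuals = c(max_abs = max(abs(res)),
                               rmse = sqrt(stats::weighted.mean(res^2, w[pos])))),
            class = "crosswalk")
}

#' Construct a crosswalk from known coefficients
#'
#' For applying published conversion functions directly.
#'
#' @inheritParams fit_linear_crosswalk
#' @param intercept,slope linear coefficients.
#' @param source_range valid integer input range `c(min, max)`.
#' @return a `crosswalk` object.
#' @export
crosswalk <- function(intercept, slope, source = "X", target = "Y",
                      source_range, target_range, clamp = TRUE) {
  if (slope == 0) stop_pc("crosswalk slope must be nonzero")
  structure(list(source = source, target = target,
                 source_range = source_range, target_range = target_range,
                 intercept = intercept, slope = slope,
                 rounding = "half-away-from-zero", clamp = clamp,
                 residuals = NULL),
            class = "crosswalk")
}

#' @export
print.crosswalk <- function(x, ...) {
  cat(sprintf("<crosswalk> %s -> %s: ROUND(%.4f + score x %.4f)%s\n",
              x$source, x$target, x$intercept, x$slope,
              if (x$clamp) sprintf(", clamped to [%d, %d]",
                                   x$target_range[1], x$target_range[2]) else ""))
  invisible(x)
}

#' Apply a linear crosswalk to raw scores
#'
#' `ROUND(intercept + slope * score)` with half-away-from-zero rounding
#' (spreadsheet `ROUND` semantics), then clamped into the target range when
#' the crosswalk says so.
#'
#' @param cw a `crosswalk`.
#' @param score integer score(s) within the source range.
#' @return converted integer score(s).
#' @export
apply_crosswalk <- function(cw, score) {
  stopifnot(inherits(cw, "crosswalk"))
  if (any(score < cw$source_range[1] | score > cw$source_range[2]))
    stop_pc("score outside source range ", cw$source_range[1], "..",
            cw$source_range[2])
  out <- round_half_away(cw$intercept + cw$slope * score)
  if (cw$clamp) out <- pmin(pmax(out, cw$target_range[1]), cw$target_range[2])
  as.integer(out)
}

#' Round-trip discrepancy of a crosswalk pair
#'
#' For each source score x, reports `|x - back(forward(x))|`; a mutually
#' consistent pair should round-trip within one raw-score point (rounding
#' error only), the practical check of equating symmetry.
#'
#' @param cw_xy forward crosswalk (X to Y).
#' @param cw_yx backward crosswalk (Y to X).
#' @param x_range optional integer range to scan (default: source range of
#'   `cw_xy`).
#' @return list: `table` (data frame x, forward, back, discrepancy),
#'   `max`, `mean`.
#' @export
round_trip_report <- function(cw_xy, cw_yx, x_range = NULL) {
  r <- x_range %||% cw_xy$source_range
  if (!is.null(x_range) &&
      (x_range[1] < cw_xy$source_range[1] || x_range[2] > cw_xy$source_range[2]))
    stop_pc("x_range exceeds the forward crosswalk's source range")
  xs <- r[1]:r[2]
  fwd <- apply_crosswalk(cw_xy, xs)
  fwd_in <- pmin(pmax(fwd, cw_yx$source_range[1]), cw_yx$source_range[2])
  back <- apply_crosswalk(cw_yx, fwd_in)
  d <- abs(xs - back)
  list(table = data.frame(x = xs, forward = fwd, back = back, discrepancy = d),
       max = max(d), mean = mean(d))
}

#' One-call equating pipeline on paired scores
#'
#' Builds the two score distributions from a paired single-group sample,
#' equates in both directions, and fits both linear crosswalks.
#'
#' @param x,y paired integer raw scores (same respondents).
#' @param source,target instrument labels.
#' @param x_range,y_range declared score ranges.
#' @return list: `concordance_xy`, `concordance_yx`, `cw_xy`, `cw_yx`,
#'   `round_trip`.
#' @export
equate_instruments <- function(x, y, source = "X", target = "Y",
                               x_range = NULL, y_range = NULL) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (sum(ok) < 20)
    warning("fewer than 20 paired observations; equated tables are for ",
            "group-level use and will be unstable here")
  dx <- score_distribution(x, min = x_range[1] %||% NULL, max = x_range[2] %||% NULL)
  dy <- score_distribution(y, min = y_range[1] %||% NULL, max = y_range[2] %||% NULL)
  cxy <- equipercentile_equate(dx, dy)
  cyx <- equipercentile_equate(dy, dx)
  cw_xy <- fit_linear_crosswalk(cxy, x_dist = dx, source = source,
                                target = target,
                                target_range = range(dy$scores))
  cw_yx <- fit_linear_crosswalk(cyx, x_dist = dy, source = target,
                                target = source,
                                target_range = range(dx$scores))
  list(concordance_xy = cxy, concordance_yx = cyx, cw_xy = cw_xy,
       cw_yx = cw_yx, round_trip = round_trip_report(cw_xy, cw_yx))
}
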