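# Domain types and file I/O for graded-response item banks and ordinal
# response matrices, plus the pre-analysis recoding rules (category
# inversion, numeric-rating-scale pain bands, quantile splits).

#' Construct a graded response model item
#'
#' An item is described by a logistic slope (discrimination) `a` and
#' `K - 1` strictly increasing thresholds `b` on the latent-trait scale.
#' The trait is oriented so that a higher theta means a better construct
#' level (better sleep quality / quality of life); `reversed` records
#' whether the item's raw categories were inverted to achieve that.
#'
#' @param id item label, unique within a bank.
#' @param a discrimination (slope), must be > 0.
#' @param b numeric vector of thresholds, strictly increasing.
#' @param instrument instrument label, e.g. `"PSQI"` or `"ISI"`.
#' @param reversed logical; were the response categories inverted?
#' @return An object of class `grm_item`.
#' @examples
#' it <- grm_item("q1", a = 1.7, b = c(-1, 0, 1))
#' it$n_categories  # 4
#' @export
grm_item <- function(id, a, b, instrument = "synthetic", reversed = FALSE) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop_pc("item 'id' must be a non-empty string")
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop_pc("item '", id, "': discrimination 'a' must be a positive finite number")
  a <- unname(as.numeric(a))
  b <- unname(as.numeric(b))
  if (length(b) < 1L || any(!is.finite(b)))
    stop_pc("item '", id, "': thresholds must be finite and non-empty")
  if (length(b) > 1L && any(diff(b) <= 0))
    stop_pc("item '", id, "': thresholds must be strictly increasing, got (",
            paste(signif(b, 6), collapse = ", "), ")")
  structure(
    list(id = id, instrument = instrument, n_categories = length(b) + 1L,
         a = a, b = b, reversed = isTRUE(reversed)),
    class = "grm_item"
  )
}

#' @export
print.grm_item <- function(x, ...) {
  cat(sprintf("<grm_item> %s [%s] K=%d a=%.3f b=(%s)%s\n", x$id, x$instrument,
              x$n_categories, x$a, paste(sprintf("%.3f", x$b), collapse = ", "),
              if (x$reversed) " reversed" else ""))
  invisible(x)
}

#' Construct an item bank
#'
#' @param items list of [grm_item()] objects with unique ids.
#' @param construct construct label, e.g. `"sleep"` or `"qol"`.
#' @param provenance free-text metadata recorded with the bank.
#' @return An object of class `item_bank`.
#' @export
item_bank <- function(items, construct = "sleep", provenance = "") {
  if (length(items) == 0L) stop_pc("item bank must contain at least one item")
  if (!all(vapply(items, inherits, logical(1), "grm_item")))
    stop_pc("all elements of 'items' must be grm_item objects")
  ids <- vapply(items, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop_pc("duplicate item ids: ",
                                  paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(items) <- ids
  structure(list(construct = construct, items = items, provenance = provenance),
            class = "item_bank")
}

#' @export
length.item_bank <- function(x) length(x$items)

#' @export
print.item_bank <- function(x, ...) {
  K <- vapply(x$items, `[[`, integer(1), "n_categories")
  a <- vapply(x$items, `[[`, numeric(1), "a")
  cat(sprintf("<item_bank> construct='%s', %d items, K in %d..%d, a in [%.2f, %.2f]\n",
              x$construct, length(x$items), min(K), max(K), min(a), max(a)))
  invisible(x)
}

#' Item ids of a bank
#' @param bank an [item_bank()].
#' @return character vector of item ids in bank order.
#' @export
bank_ids <- function(bank) names(bank$items)

# dense matrix view of a bank used by the vectorized GRM kernel:
# thresholds padded with +Inf so that padded categories carry zero
# probability and drop out of every sum
bank_matrices <- function(bank) {
  items <- bank$items
  J <- length(items)
  K <- vapply(items, `[[`, integer(1), "n_categories")
  a <- vapply(items, `[[`, numeric(1), "a")
  Km1 <- max(K) - 1L
  bmat <- matrix(Inf, J, Km1)
  for (j in seq_len(J)) bmat[j, seq_len(K[j] - 1L)] <- items[[j]]$b
  list(J = J, K = K, Kmax = max(K), a = a, b = bmat, ids = names(items))
}

#' Toggle an item's reverse-scoring flag
#' @param bank an [item_bank()].
#' @param id item id.
#' @return the bank with the item's `reversed` flag toggled.
#' @export
reverse_item <- function(bank, id) {
  if (!id %in% bank_ids(bank)) stop_pc("unknown item id '", id, "'")
  bank$items[[id]]$reversed <- !bank$items[[id]]$reversed
  bank
}

# ---------------------------------------------------------------------------
# bank serialization

#' Read an item bank from CSV or JSON
#'
#' CSV columns: `id, instrument, n_categories, a, b1..b{Kmax-1}, reversed`,
#' with trailing blanks for items with fewer categories. The JSON form is a
#' list with `construct`, `provenance` and an `items` array carrying explicit
#' threshold arrays. Banks with non-increasing thresholds are rejected.
#'
#' @param path file path.
#' @param format `"csv"`, `"json"`, or `"auto"` (by extension).
#' @return An [item_bank()].
#' @export
read_item_bank <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_pc("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "json") {
    raw <- jsonlite::read_json(path, simplifyVector = FALSE)
    items <- lapply(raw$items, function(it) {
      need <- c("id", "a", "b")
      miss <- setdiff(need, names(it))
      if (length(miss))
        stop_pc("malformed bank JSON: item missing field(s) ",
                paste(miss, collapse = ", "))
      grm_item(it$id, a = it$a, b = unlist(it$b),
               instrument = it$instrument %||% "unknown",
               reversed = isTRUE(it$reversed))
    })
    return(item_bank(items, construct = raw$construct %||% "unknown",
                     provenance = raw$provenance %||% ""))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "instrument", "n_categories", "a", "reversed")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_pc("malformed bank CSV '", path, "': missing column(s) ",
            paste(miss, collapse = ", "))
  bcols <- grep("^b[0-9]+$", names(df), value = TRUE)
  bcols <- bcols[order(as.integer(sub("^b", "", bcols)))]
  items <- lapply(seq_len(nrow(df)), function(i) {
    K <- df$n_categories[i]
    b <- as.numeric(df[i, bcols[seq_len(K - 1L)]])
    if (anyNA(b))
      stop_pc("malformed bank CSV row ", i, " (id '", df$id[i],
              "'): expected ", K - 1L, " thresholds")
    grm_item(df$id[i], a = df$a[i], b = b, instrument = df$instrument[i],
             reversed = isTRUE(as.logical(df$reversed[i])))
  })
  construct <- if ("construct" %in% names(df)) df$construct[1] else "unknown"
  item_bank(items, construct = construct)
}

#' Write an item bank to CSV or JSON
#' @param bank an [item_bank()].
#' @param path output file path.
#' @param format `"csv"`, `"json"`, or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_item_bank <- function(bank, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "json") {
    out <- list(
      construct = bank$construct, provenance = bank$provenance,
      items = lapply(unname(bank$items), function(it)
        list(id = it$id, instrument = it$instrument,
             n_categories = it$n_categories, a = it$a, b = as.list(it$b),
             reversed = it$reversed)))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(path))
  }
  bm <- bank_matrices(bank)
  df <- data.frame(id = bm$ids,
                   instrument = vapply(bank$items, `[[`, character(1), "instrument"),
                   n_categories = bm$K, a = bm$a,
                   construct = bank$construct,
                   stringsAsFactors = FALSE)
  B <- bm$b
  B[!is.finite(B)] <- NA
  colnames(B) <- paste0("b", seq_len(ncol(B)))
  df <- cbind(df, as.data.frame(B))
  df$reversed <- vapply(bank$items, `[[`, logical(1), "reversed")
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

# ---------------------------------------------------------------------------
# response matrices

#' Construct a response matrix container
#'
#' Holds an N x J matrix of 0-based ordinal codes (`NA` = missing), the
#' per-item category counts, per-respondent covariates (at minimum a
#' `gender` column when DIF screening is intended), and a per-item
#' `reversed` flag tracking category inversions applied to the data.
#'
#' @param responses integer matrix, respondents x items, codes in
#'   `0..K_j - 1` or `NA`. Column names are item ids.
#' @param n_categories per-item category counts; inferred as
#'   `max(code) + 1` when omitted.
#' @param covariates data frame of per-respondent covariates.
#' @param respondent_ids respondent labels.
#' @return An object of class `response_matrix`.
#' @export
response_matrix <- function(responses, n_categories = NULL, covariates = NULL,
                            respondent_ids = NULL) {
  responses <- as.matrix(responses)
  storage.mode(responses) <- "integer"
  if (is.null(colnames(responses)))
    colnames(responses) <- paste0("item", seq_len(ncol(responses)))
  if (is.null(respondent_ids))
    respondent_ids <- rownames(responses) %||% paste0("r", seq_len(nrow(responses)))
  rownames(responses) <- respondent_ids
  J <- ncol(responses)
  if (is.null(n_categories)) {
    n_categories <- apply(responses, 2, function(x) {
      x <- x[!is.na(x)]
      if (!length(x)) 2L else max(x) + 1L
    })
  }
  n_categories <- as.integer(n_categories)
  if (length(n_categories) != J)
    stop_pc("n_categories must have one entry per item")
  names(n_categories) <- colnames(responses)
  for (j in seq_len(J)) {
    x <- responses[, j]
    bad <- !is.na(x) & (x < 0L | x >= n_categories[j])
    if (any(bad))
      stop_pc("item '", colnames(responses)[j], "': response code(s) outside 0..",
              n_categories[j] - 1L, " (e.g. ", x[bad][1], ")")
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != nrow(responses))
      stop_pc("covariates must have one row per respondent")
  }
  structure(list(responses = responses, n_categories = n_categories,
                 covariates = covariates,
                 reversed = stats::setNames(rep(FALSE, J), colnames(responses))),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  nmiss <- sum(is.na(x$responses))
  cat(sprintf("<response_matrix> %d respondents x %d items, %.1f%% missing\n",
              nrow(x$responses), ncol(x$responses),
              100 * nmiss / length(x$responses)))
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$responses)

#' Read a response matrix from CSV
#'
#' One row per respondent; item columns are ordinal codes with empty cells
#' or `NA` for missing. A `respondent_id` column and covariate columns
#' (e.g. `gender`) are split off automatically. Instruments usually publish
#' 1-based scoring, so the file's code origin is declared and normalized to
#' the 0-based internal convention.
#'
#' @param path CSV path.
#' @param origin code origin used in the file: 0 or 1.
#' @param covariate_cols column names to treat as covariates rather than
#'   items (default: `"gender"` plus any non-numeric column).
#' @return A [response_matrix()].
#' @export
read_responses <- function(path, origin = 0L, covariate_cols = "gender") {
  if (!file.exists(path)) stop_pc("file not found: ", path)
  if (!origin %in% c(0L, 1L)) stop_pc("'origin' must be 0 or 1")
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  ids <- if ("respondent_id" %in% names(df)) as.character(df$respondent_id)
         else paste0("r", seq_len(nrow(df)))
  df$respondent_id <- NULL
  isnum <- vapply(df, is.numeric, logical(1))
  covs <- union(intersect(covariate_cols, names(df)), names(df)[!isnum])
  covariates <- if (length(covs)) df[covs] else NULL
  items <- df[setdiff(names(df), covs)]
  if (!ncol(items)) stop_pc("no item columns found in ", path)
  m <- as.matrix(items) - origin
  if (any(m < 0, na.rm = TRUE))
    stop_pc("negative codes after origin shift; is 'origin' correct?")
  response_matrix(m, covariates = covariates, respondent_ids = ids)
}

#' Write a response matrix to CSV
#' @param rm_ a [response_matrix()].
#' @param path output path.
#' @param origin code origin to write (0 or 1).
#' @return `path`, invisibly.
#' @export
write_responses <- function(rm_, path, origin = 0L) {
  df <- data.frame(respondent_id = rownames(rm_$responses),
                   stringsAsFactors = FALSE)
  if (!is.null(rm_$covariates)) df <- cbind(df, rm_$covariates)
  df <- cbind(df, as.data.frame(rm_$responses + as.integer(origin)))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

# ---------------------------------------------------------------------------
# recoding rules

#' Invert the response categories of one item
#'
#' Maps each non-missing code `c` to `K - 1 - c` (missing stays missing) and
#' toggles the container's `reversed` flag for that item. Applying the
#' function twice restores the original matrix. Used to align items whose
#' raw direction opposes the construct, so that after calibration a high
#' theta uniformly means a better construct level.
#'
#' @param rm_ a [response_matrix()].
#' @param item_id item to invert.
#' @return the modified [response_matrix()].
#' @export
invert_categories <- function(rm_, item_id) {
  stopifnot(inherits(rm_, "response_matrix"))
  if (!item_id %in% colnames(rm_$responses))
    stop_pc("unknown item id '", item_id, "'")
  K <- rm_$n_categories[[item_id]]
  x <- rm_$responses[, item_id]
  rm_$responses[, item_id] <- ifelse(is.na(x), NA_integer_, K - 1L - x)
  rm_$reversed[[item_id]] <- !rm_$reversed[[item_id]]
  rm_
}

#' Recode a 0-10 numeric rating scale for pain into four ordinal bands
#'
#' Bands: 0 = no pain, 1-3 = mild, 4-6 = moderate, 7+ = severe.
#'
#' @param values integer vector in 0..10 (`NA` allowed, passed through).
#' @return integer codes in 0..3.
#' @export
recode_nrs_pain <- function(values) {
  ok <- is.na(values) | (values >= 0 & values <= 10)
  if (!all(ok))
    stop_pc("NRS values must be in 0..10; got ", values[!ok][1])
  out <- ifelse(is.na(values), NA_integer_,
                ifelse(values == 0, 0L,
                       ifelse(values <= 3, 1L, ifelse(values <= 6, 2L, 3L))))
  as.integer(out)
}

#' Split a numeric variable into ordinal codes at empirical quantiles
#'
#' Bins are left-closed/right-open at the empirical quantiles, with ties
#' assigned to the lower bin, so codes are deterministic and monotone in
#' the input. With distinct values the bin populations differ by at most 1.
#'
#' @param values numeric vector (`NA` passed through).
#' @param q number of quantile bins (>= 2); 5 gives quintiles.
#' @return integer codes in `0..q-1`.
#' @export
quantile_split <- function(values, q = 5L) {
  q <- as.integer(q)
  if (q < 2L) stop_pc("'q' must be at least 2")
  obs <- values[!is.na(values)]
  if (!length(obs)) stop_pc("no non-missing values to split")
  if (length(unique(obs)) == 1L)
    stop_pc("degenerate split: all values identical")
  cuts <- stats::quantile(obs, probs = seq_len(q - 1L) / q, type = 7, names = FALSE)
  codes <- rowSums(outer(values, cuts, FUN = ">"))  # ties -> lower bin
  out <- ifelse(is.na(values), NA_integer_, as.integer(codes))
  as.integer(out)
}
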