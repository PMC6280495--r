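#' Construct and validate a left-censored dataset
#'
#' Bundles the observed response, the censoring indicator, per-row detection
#' limits and the predictor matrix into a validated `censored_data` object.
#' The convention follows the Tobit observation rule: `delta[i] = 1` means the
#' latent response exceeded its detection limit and `z[i]` is the true value;
#' `delta[i] = 0` means the response was below the limit and `z[i]` equals
#' `lod[i]` (the recorded placeholder).
#'
#' @param z numeric vector of observed responses (e.g. log10 copies/mL).
#' @param delta 0/1 vector, 1 = uncensored (above the limit), 0 = censored.
#' @param lod numeric vector of per-row detection limits, or a single value
#'   recycled to all rows. Heterogeneous limits (multicentric studies with
#'   different assays) are supported throughout.
#' @param X numeric predictor matrix with `length(z)` rows.
#' @param names optional predictor labels; defaults to `colnames(X)`.
#' @return an object of class `censored_data` with elements `z`, `delta`,
#'   `lod`, `X`, `names`.
#' @examples
#' ds <- censored_data(z = c(2, 1), delta = c(1, 0), lod = 1,
#'                     X = matrix(c(0, 1), ncol = 1))
#' censoring_rate(ds)
#' @export
censored_data <- function(z, delta, lod, X, names = NULL) {
  z <- as.numeric(z)
  delta <- as.numeric(delta)
  n <- length(z)
  if (length(lod) == 1L) lod <- rep(as.numeric(lod), n)
  lod <- as.numeric(lod)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(names)) names <- colnames(X)
  if (is.null(names)) names <- paste0("x", seq_len(ncol(X)))
  colnames(X) <- names
  ds <- structure(list(z = z, delta = delta, lod = lod, X = X, names = names),
                  class = "censored_data")
  validate_censored_data(ds)
}

#' Validate a censored dataset
#'
#' Checks every structural invariant of a [censored_data()] object: matching
#' lengths, `delta` in \{0, 1\}, no missing values, `z > lod` on uncensored
#' rows, and `z == lod` on censored rows (values within `1e-12` of the limit
#' are coerced to it, anything else is an error).
#'
#' @param ds a `censored_data` object (or a bare list with the same fields).
#' @return the validated (possibly coerced) `censored_data` object.
#' @export
validate_censored_data <- function(ds) {
  n <- length(ds$z)
  if (n < 2L) stop("need at least 2 observations")
  if (length(ds$delta) != n || length(ds$lod) != n || nrow(ds$X) != n)
    stop("dimension mismatch: z, delta, lod and rows of X must agree")
  if (ncol(ds$X) < 1L) stop("need at least one predictor column")
  if (anyNA(ds$z) || anyNA(ds$delta) || anyNA(ds$lod) || anyNA(ds$X) ||
      any(!is.finite(ds$z)) || any(!is.finite(ds$lod)) || any(!is.finite(ds$X)))
    stop("missing or non-finite values are not allowed")
  if (!all(ds$delta %in% c(0, 1))) stop("delta must contain only 0 and 1")
  cens <- ds$delta == 0
  if (any(ds$z[!cens] <= ds$lod[!cens]))
    stop("uncensored value below LOD: rows with delta = 1 must have z > lod")
  off <- abs(ds$z[cens] - ds$lod[cens])
  if (any(off > 1e-12))
    stop("censored rows must record z = lod (|z - lod| > 1e-12 found)")
  ds$z[cens] <- ds$lod[cens]
  class(ds) <- "censored_data"
  ds
}

#' @export
print.censored_data <- function(x, ...) {
  cat(sprintf("censored_data: n = %d, p = %d, censoring rate = %.3f\n",
              length(x$z), ncol(x$X), censoring_rate(x)))
  cat(sprintf("  response range [%.3g, %.3g], LOD range [%.3g, %.3g]\n",
              min(x$z), max(x$z), min(x$lod), max(x$lod)))
  invisible(x)
}

# Row subset, used by the cross-validation machinery.
subset_censored <- function(ds, idx) {
  structure(list(z = ds$z[idx], delta = ds$delta[idx], lod = ds$lod[idx],
                 X = ds$X[idx, , drop = FALSE], names = ds$names),
            class = "censored_data")
}

#' Fraction of censored observations
#'
#' @param ds a [censored_data()] object.
#' @return `mean(1 - delta)`, in `[0, 1]`.
#' @export
censoring_rate <- function(ds) mean(1 - ds$delta)

#' Flip a left-censored dataset to right-censoring
#'
#' Subtracts every observation and detection limit from a constant `M` that
#' equals or exceeds the largest observation, so methods for right-censored
#' data (Kaplan-Meier, Buckley-James) apply directly. `delta` keeps its value
#' but is reinterpreted as an event indicator. Flipping twice with the same
#' `M` recovers the original data exactly.
#'
#' @param ds a [censored_data()] object.
#' @param M the flip constant, or `"auto"` (the default) for `max(z)`, the
#'   smallest admissible value.
#' @return a `flipped_data` list with `y_flip = M - z`,
#'   `threshold_flip = M - lod`, `delta`, and `M`.
#' @export
flip_censoring <- function(ds, M = "auto") {
  if (identical(M, "auto")) M <- max(ds$z)
  M <- as.numeric(M)
  if (M < max(ds$z)) stop("M must equal or exceed the largest observation")
  structure(list(y_flip = M - ds$z, delta = ds$delta,
                 threshold_flip = M - ds$lod, M = M),
            class = "flipped_data")
}

#' Standardize predictor columns
#'
#' Centers each column to mean zero and scales to unit standard deviation,
#' using the n-denominator (population) standard deviation so the transform
#' can be undone exactly when reporting coefficients on the original scale.
#' Constant columns cannot be standardized; they are dropped with a warning
#' and recorded in the `dropped` element.
#'
#' @param X numeric matrix.
#' @return list with `X` (standardized, retained columns), `centers`,
#'   `scales`, `keep` (logical over original columns) and `dropped`
#'   (names of excluded columns).
#' @export
standardize_predictors <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  centers <- colMeans(X)
  Xc <- sweep(X, 2, centers, "-")
  scales <- sqrt(colSums(Xc^2) / n)
  keep <- scales > 0
  if (!any(keep)) stop("all predictor columns are constant")
  dropped <- colnames(X)[!keep]
  if (length(dropped))
    warning("dropping constant column(s): ", paste(dropped, collapse = ", "))
  Xs <- sweep(Xc[, keep, drop = FALSE], 2, scales[keep], "/")
  list(X = Xs, centers = centers[keep], scales = scales[keep],
       keep = keep, dropped = dropped)
}

#' Read a censored dataset from a delimited file
#'
#' Expects a column `response` and either a 0/1 column `censored`
#' (1 = below the limit) together with a scalar `lod`, or a per-row `lod`
#' column (in which case censoring is `response <= lod` unless a `censored`
#' column is also present). All remaining numeric columns are predictors.
#' Column names are overridable.
#'
#' @param path file path (CSV by default).
#' @param lod scalar detection limit, required when no `lod` column exists.
#' @param response,censored,lod_col column names to use.
#' @param sep field separator, `","` or `"\t"`.
#' @return a [censored_data()] object.
#' @export
read_censored_csv <- function(path, lod = NULL, response = "response",
                              censored = "censored", lod_col = "lod",
                              sep = ",") {
  df <- utils::read.csv(path, sep = sep, check.names = FALSE)
  if (!response %in% names(df)) stop("missing response column '", response, "'")
  z <- df[[response]]
  has_cens <- censored %in% names(df)
  has_lod <- lod_col %in% names(df)
  if (!has_lod && is.null(lod))
    stop("need a '", lod_col, "' column or a scalar `lod`")
  lodv <- if (has_lod) df[[lod_col]] else rep(lod, nrow(df))
  if (has_cens) delta <- 1 - df[[censored]]
  else if (has_lod) delta <- as.numeric(z > lodv)
  else stop("need a '", censored, "' column when `lod` is scalar")
  drop <- c(response, if (has_cens) censored, if (has_lod) lod_col)
  Xdf <- df[, setdiff(names(df), drop), drop = FALSE]
  if (!ncol(Xdf)) stop("no predictor columns found")
  censored_data(z, delta, lodv, as.matrix(Xdf))
}

#' Write a censored dataset to a delimited file
#'
#' Mirrors the layout read by [read_censored_csv()]: columns `response`,
#' `censored`, `lod`, then the predictors.
#'
#' @param ds a [censored_data()] object.
#' @param path output file path.
#' @param sep field separator.
#' @export
write_censored_csv <- function(ds, path, sep = ",") {
  df <- data.frame(response = ds$z, censored = 1 - ds$delta, lod = ds$lod,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(ds$X, check.names = FALSE))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
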