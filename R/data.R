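#' Right-censored dataset
#'
#' Bundle a covariate matrix `W`, follow-up times `Y = min(T, C)` and event
#' indicators `Delta = 1(T <= C)` into a validated container.  The event time
#' `T` itself is never stored: it is only observed when `Delta = 1`, in which
#' case `Y` equals it.  Censoring times `C` may optionally be attached for
#' diagnostics (e.g. Type-I censoring comparisons); they are never used by the
#' calibration machinery.
#'
#' @param W Numeric matrix (or vector / data frame coercible to one) of
#'   covariates, one row per subject.
#' @param Y Numeric vector of follow-up times, all finite and `>= 0`.
#' @param Delta Event indicator, `0`/`1` (or logical); `1` means the event was
#'   observed (`T <= C`).
#' @param C Optional numeric vector of censoring times.  When supplied,
#'   `Delta[i] == 1` requires `Y[i] <= C[i]`.
#'
#' @return An object of class `rc_data`: a list with elements `W` (matrix),
#'   `Y`, `Delta`, and optionally `C`.
#' @examples
#' d <- rc_data(W = c(0.5, 1, 2), Y = c(3, 1, 4), Delta = c(1, 0, 1))
#' nobs_rc(d)
#' @export
rc_data <- function(W, Y, Delta, C = NULL) {
  if (is.data.frame(W)) W <- as.matrix(W)
  if (!is.matrix(W)) W <- matrix(as.numeric(W), ncol = 1L)
  storage.mode(W) <- "double"
  Y <- as.numeric(Y)
  if (is.logical(Delta)) Delta <- as.numeric(Delta)
  Delta <- as.numeric(Delta)
  n <- nrow(W)
  if (length(Y) != n || length(Delta) != n)
    stop("W, Y and Delta must have matching lengths (rows)")
  if (anyNA(W) || anyNA(Y) || anyNA(Delta))
    stop("missing values are not allowed in W, Y or Delta")
  bad <- which(!is.finite(Y) | Y < 0)
  if (length(bad))
    stop("Y must be finite and >= 0; first offending row: ", bad[1])
  bad <- which(!(Delta %in% c(0, 1)))
  if (length(bad))
    stop("Delta must be 0/1; first offending row: ", bad[1])
  if (is.null(colnames(W))) colnames(W) <- paste0("w", seq_len(ncol(W)))
  out <- list(W = W, Y = Y, Delta = Delta)
  if (!is.null(C)) {
    C <- as.numeric(C)
    if (length(C) != n) stop("C must have length ", n)
    if (anyNA(C) || any(!is.finite(C) | C < 0))
      stop("C must be finite and >= 0")
    bad <- which(Delta == 1 & Y > C + 1e-12)
    if (length(bad))
      stop("Delta = 1 requires Y <= C; first offending row: ", bad[1])
    out$C <- C
  }
  structure(out, class = "rc_data")
}

#' Number of observations / covariates of a right-censored dataset
#' @param data An [rc_data] object.
#' @return Integer count.
#' @export
nobs_rc <- function(data) nrow(data$W)

#' @rdname nobs_rc
#' @export
ncov_rc <- function(data) ncol(data$W)

#' @export
print.rc_data <- function(x, ...) {
  cat(sprintf("Right-censored dataset: %d observations, %d covariate(s)\n",
              nobs_rc(x), ncov_rc(x)))
  cat(sprintf("  events: %d (%.1f%%), censored: %d\n",
              sum(x$Delta == 1), 100 * mean(x$Delta == 1), sum(x$Delta == 0)))
  if (!is.null(x$C)) cat("  censoring times attached\n")
  invisible(x)
}

#' Subset a right-censored dataset by row index
#'
#' @param data An [rc_data] object.
#' @param idx Integer vector of row indices.
#' @return An [rc_data] object with the selected rows.
#' @export
rc_subset <- function(data, idx) {
  rc_data(W = data$W[idx, , drop = FALSE], Y = data$Y[idx],
          Delta = data$Delta[idx], C = if (!is.null(data$C)) data$C[idx])
}

#' Split a dataset into training and calibration sets
#'
#' Draws a uniform random partition with `round(c * N)` calibration rows; the
#' remainder goes to training.  No stratification is applied.
#'
#' @param data An [rc_data] object with at least 4 rows.
#' @param c Calibration proportion in (0, 1).
#' @param seed Optional integer seed making the split reproducible without
#'   disturbing the caller's RNG stream.
#' @return An object of class `rc_split`: list with integer index vectors
#'   `train` and `cal` and the proportion `c`.
#' @examples
#' d <- rc_data(W = 1:10, Y = 1:10, Delta = rep(1, 10))
#' s <- rc_split(d, c = 0.5, seed = 1)
#' length(s$cal)
#' @export
rc_split <- function(data, c = 0.5, seed = NULL) {
  if (!is.numeric(c) || length(c) != 1L || c <= 0 || c >= 1)
    stop("split proportion c must lie strictly in (0, 1)")
  N <- nobs_rc(data)
  n_cal <- round(c * N)
  if (n_cal < 2L || N - n_cal < 2L)
    stop("degenerate split: both training and calibration sets need >= 2 rows")
  idx <- with_seed(seed, sample.int(N, n_cal))
  structure(list(train = sort(setdiff(seq_len(N), idx)), cal = sort(idx), c = c),
            class = "rc_split")
}

# Evaluate `expr` under an optional temporary seed, restoring the caller's
# RNG state afterwards so that seeded helpers do not perturb outer streams.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Read a right-censored dataset from a delimited text file
#'
#' @param path Path to a CSV (or TSV, for files ending in `.tsv`/`.txt`) file
#'   with a header row.
#' @param column_map Named list declaring column roles: `covariates`
#'   (character vector of column names), `time`, `event`, and optionally
#'   `censor`.  The event column may contain `0`/`1` or logicals.
#' @param sep Field separator; guessed from the file extension by default.
#' @return An [rc_data] object.
#' @seealso [write_rc_csv()]
#' @export
read_rc_csv <- function(path, column_map, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.csv(path, sep = sep, check.names = FALSE)
  need <- c(column_map$covariates, column_map$time, column_map$event,
            column_map$censor)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("column(s) not found in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  ev <- df[[column_map$event]]
  if (is.logical(ev) || all(ev %in% c("TRUE", "FALSE", "True", "False")))
    ev <- as.logical(ev)
  rc_data(W = as.matrix(df[, column_map$covariates, drop = FALSE]),
          Y = df[[column_map$time]], Delta = ev,
          C = if (!is.null(column_map$censor)) df[[column_map$censor]])
}

#' Write a right-censored dataset to CSV
#'
#' Column layout: the covariate columns (named as in `data$W`), then `time`,
#' `event`, and `censor` when present.  `read_rc_csv()` with the matching
#' `column_map` round-trips the object exactly.
#'
#' @param data An [rc_data] object.
#' @param path Output file path.
#' @return Invisibly, the `column_map` that reads the file back.
#' @export
write_rc_csv <- function(data, path) {
  df <- as.data.frame(data$W)
  df$time <- data$Y
  df$event <- data$Delta
  if (!is.null(data$C)) df$censor <- data$C
  utils::write.csv(df, path, row.names = FALSE)
  invisible(list(covariates = colnames(data$W), time = "time", event = "event",
                 censor = if (!is.null(data$C)) "censor"))
}
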