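#' Areal panel data
#'
#' Observed counts \code{y}, expected counts \code{e} and optional
#' covariates over a complete region-by-time grid.  Counts may be zero but
#' expected counts must be strictly positive wherever a count is modeled:
#' the expected count is the Poisson offset from indirect standardization,
#' and a zero offset makes the relative risk unidentifiable.
#'
#' @param y nonnegative integer matrix of observed counts, regions in rows,
#'   time periods in columns.
#' @param e positive matrix of expected counts, same shape as \code{y} (a
#'   vector of per-region values is recycled across time).
#' @param X optional covariate array of dimension
#'   \code{(n_regions, n_times, p)}, or \code{NULL} for the no-covariate
#'   model.
#' @param region_ids,times optional labels; default to the dimnames of
#'   \code{y} or to \code{1..n}.
#' @return an object of class \code{panel_data}.
#' @export
panel_data <- function(y, e, X = NULL, region_ids = NULL, times = NULL) {
  y <- as.matrix(y)
  if (is.matrix(e)) e <- as.matrix(e)
  else e <- matrix(e, nrow(y), ncol(y))
  if (!all(dim(e) == dim(y)))
    stop("'y' and 'e' must have the same region x time shape", call. = FALSE)
  if (any(!is.finite(y)) || any(y < 0) || any(y != round(y)))
    stop("'y' must contain nonnegative integer counts", call. = FALSE)
  if (any(!is.finite(e)) || any(e <= 0))
    stop("'e' must be strictly positive everywhere", call. = FALSE)
  if (is.null(region_ids))
    region_ids <- if (!is.null(rownames(y))) rownames(y) else as.character(seq_len(nrow(y)))
  if (is.null(times))
    times <- if (!is.null(colnames(y))) colnames(y) else as.character(seq_len(ncol(y)))
  if (length(region_ids) != nrow(y) || length(times) != ncol(y))
    stop("label lengths do not match the data shape", call. = FALSE)
  if (!is.null(X)) {
    X <- as.array(X)
    if (length(dim(X)) == 2) X <- array(X, c(dim(X), 1))
    if (length(dim(X)) != 3 || any(dim(X)[1:2] != dim(y)))
      stop("'X' must be an (n_regions, n_times, p) array", call. = FALSE)
  }
  dimnames(y) <- dimnames(e) <- list(region_ids, times)
  structure(list(y = y, e = e, X = X,
                 region_ids = region_ids, times = times,
                 n_regions = nrow(y), n_times = ncol(y),
                 n_covariates = if (is.null(X)) 0L else dim(X)[3]),
            class = "panel_data")
}

#' @export
print.panel_data <- function(x, ...) {
  cat("panel_data:", x$n_regions, "regions x", x$n_times, "periods,",
      x$n_covariates, "covariate(s);",
      "total count", sum(x$y), "(expected", round(sum(x$e), 1), ")\n")
  invisible(x)
}

#' Read panel data from a delimited file
#'
#' Expects a delimited text file with header columns \code{region_id},
#' \code{time}, \code{count}, \code{expected}; any further columns are
#' treated as covariates.  The file must define a complete region-by-time
#' grid with no duplicate keys; violations are reported with the offending
#' rows.  Time periods are ordered numerically when all labels are numeric,
#' otherwise lexically.
#'
#' @param path path to the file.
#' @param sep field separator (default comma).
#' @return a \code{\link{panel_data}}.
#' @export
read_panel <- function(path, sep = ",") {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = NA, stringsAsFactors = FALSE)
  need <- c("region_id", "time", "count", "expected")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("panel file is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  key <- paste(df$region_id, df$time, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (region, time) rows: ",
         paste(which(duplicated(key)) + 1, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(df$count) | df$count < 0 | df$count != round(df$count))
  if (length(bad))
    stop("nonnegative integer 'count' required; offending row(s): ",
         paste(bad + 1, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(df$expected) | df$expected <= 0)
  if (length(bad))
    stop("strictly positive 'expected' required; offending row(s): ",
         paste(bad + 1, collapse = ", "), call. = FALSE)
  regions <- unique(as.character(df$region_id))
  tlab <- unique(as.character(df$time))
  tnum <- suppressWarnings(as.numeric(tlab))
  times <- if (!any(is.na(tnum))) tlab[order(tnum)] else sort(tlab)
  if (nrow(df) != length(regions) * length(times))
    stop("panel is not a complete region x time grid: ", nrow(df),
         " rows for ", length(regions), " regions x ", length(times),
         " periods", call. = FALSE)
  ri <- match(as.character(df$region_id), regions)
  ti <- match(as.character(df$time), times)
  shape <- c(length(regions), length(times))
  y <- e <- matrix(NA_real_, shape[1], shape[2])
  y[cbind(ri, ti)] <- df$count
  e[cbind(ri, ti)] <- df$expected
  covs <- setdiff(names(df), need)
  X <- NULL
  if (length(covs)) {
    X <- array(NA_real_, c(shape, length(covs)), dimnames = list(NULL, NULL, covs))
    for (k in seq_along(covs)) {
      xk <- matrix(NA_real_, shape[1], shape[2])
      xk[cbind(ri, ti)] <- df[[covs[k]]]
      X[, , k] <- xk
    }
    if (any(!is.finite(X))) stop("covariate columns contain missing values",
                                 call. = FALSE)
  }
  panel_data(y, e, X, region_ids = regions, times = times)
}

#' Write panel data to a delimited file
#'
#' Inverse of \code{\link{read_panel}}: one row per (region, time) cell.
#'
#' @param panel a \code{\link{panel_data}}.
#' @param path output path.
#' @param sep field separator.
#' @export
write_panel <- function(panel, path, sep = ",") {
  grid <- expand.grid(ri = seq_len(panel$n_regions), ti = seq_len(panel$n_times))
  df <- data.frame(region_id = panel$region_ids[grid$ri],
                   time = panel$times[grid$ti],
                   count = panel$y[cbind(grid$ri, grid$ti)],
                   expected = panel$e[cbind(grid$ri, grid$ti)],
                   stringsAsFactors = FALSE)
  if (!is.null(panel$X))
    for (k in seq_len(panel$n_covariates)) {
      nm <- dimnames(panel$X)[[3]][k]
      if (is.null(nm) || !nzchar(nm)) nm <- paste0("x", k)
      df[[nm]] <- panel$X[, , k][cbind(grid$ri, grid$ti)]
    }
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
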