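#' Define a design factor
#'
#' A factor is described by the affine map between its coded level and its
#' actual value: `actual = center + coded * step`. The coded scale is the
#' package's internal currency; actual units appear only at I/O boundaries.
#'
#' @param name Factor name, e.g. `"agar_concentration"`.
#' @param symbol Short symbol, e.g. `"Y1"`.
#' @param unit Unit string, e.g. `"%"` or `"h/d"`.
#' @param center Actual value at coded level 0.
#' @param step Actual-unit change per coded unit; must be positive.
#' @return An object of class `factor_spec`.
#' @examples
#' agar <- factor_spec("agar_concentration", "Y1", "%", center = 0.6, step = 0.1)
#' decode_point(c(2), list(agar))  # 0.8
#' @export
factor_spec <- function(name, symbol, unit, center, step) {
  stopifnot(is.character(name), is.character(symbol), is.character(unit))
  if (!is.numeric(step) || length(step) != 1L || !is.finite(step) || step <= 0)
    stop("degenerate factor '", name, "': step must be a positive finite number")
  structure(
    list(name = name, symbol = symbol, unit = unit,
         center = as.numeric(center), step = as.numeric(step)),
    class = "factor_spec"
  )
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("<factor_spec> %s (%s, %s): actual = %g + coded * %g\n",
              x$name, x$symbol, x$unit, x$center, x$step))
  invisible(x)
}

#' The four culture-condition factors of the melon differentiation study
#'
#' Agar concentration (%), light duration (h/d), culture temperature (deg C)
#' and relative humidity (%), each on a five-level coded scale -2..2 with the
#' centers and steps of the shipped factor table.
#'
#' @return List of four `factor_spec` objects.
#' @export
melon_factors <- function() {
  path <- system.file("extdata", "table4_factors.csv", package = "cultopt",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i)
    factor_spec(tab$name[i], tab$symbol[i], tab$unit[i], tab$center[i], tab$step[i]))
}

#' Construct a CCD table object
#'
#' @param coded Numeric matrix of coded levels, one row per run.
#' @param factors List of `factor_spec`, one per column of `coded`.
#' @param observed Optional numeric vector of observed response (% scale).
#' @param paper_predicted Optional numeric vector of reference predictions (%).
#' @return An object of class `ccd_table` with fields `coded`, `factors`,
#'   `observed`, `paper_predicted`.
#' @export
ccd_table <- function(coded, factors, observed = NULL, paper_predicted = NULL) {
  coded <- as.matrix(coded)
  storage.mode(coded) <- "double"
  if (ncol(coded) != length(factors))
    stop("dimension error: coded matrix has ", ncol(coded),
         " columns but ", length(factors), " factors were given")
  for (v in list(observed = observed, paper_predicted = paper_predicted)) {
    if (!is.null(v) && length(v) != nrow(coded))
      stop("dimension error: response vector length does not match run count")
  }
  colnames(coded) <- vapply(factors, `[[`, "", "symbol")
  structure(
    list(coded = coded, factors = factors,
         observed = if (is.null(observed)) NULL else as.numeric(observed),
         paper_predicted = if (is.null(paper_predicted)) NULL else as.numeric(paper_predicted)),
    class = "ccd_table"
  )
}

#' @export
print.ccd_table <- function(x, ...) {
  k <- ncol(x$coded)
  cat(sprintf("<ccd_table> %d runs x %d factors%s\n", nrow(x$coded), k,
              if (is.null(x$observed)) "" else " (with observed response)"))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x$coded) > 6) cat("...\n")
  invisible(x)
}

#' @export
as.data.frame.ccd_table <- function(x, ...) {
  d <- as.data.frame(x$coded)
  if (!is.null(x$observed)) d$observed <- x$observed
  if (!is.null(x$paper_predicted)) d$paper_predicted <- x$paper_predicted
  d
}

#' Build a central composite design in coded units
#'
#' Rows are ordered canonically: the 2^k full factorial (+/-1) in
#' lexicographic order with -1 before +1 and the first factor slowest, then
#' 2k axial runs (-alpha before +alpha, in factor order), then `n_center`
#' center runs. This is a package convention chosen for diff-stable fixtures;
#' run order carries no statistical meaning here.
#'
#' @param factors List of `factor_spec` (length k >= 2).
#' @param alpha Axial distance in coded units (> 0); 2 for the melon design.
#' @param n_center Number of center-point replicates (>= 1).
#' @return A `ccd_table` with `2^k + 2k + n_center` rows and no responses.
#' @examples
#' d <- build_ccd(melon_factors(), alpha = 2, n_center = 7)
#' nrow(d$coded)  # 31
#' @export
build_ccd <- function(factors, alpha = 2, n_center = 1) {
  k <- length(factors)
  if (k < 2) stop("invalid design: need at least 2 factors, got ", k)
  if (!is.numeric(alpha) || alpha <= 0) stop("invalid design: alpha must be > 0")
  if (n_center < 1) stop("invalid design: n_center must be >= 1")
  # factorial block, first factor most significant
  fact <- as.matrix(rev(expand.grid(rev(rep(list(c(-1, 1)), k)))))
  dimnames(fact) <- NULL
  axial <- matrix(0, 2 * k, k)
  for (i in seq_len(k)) {
    axial[2 * i - 1, i] <- -alpha
    axial[2 * i, i] <- alpha
  }
  centers <- matrix(0, n_center, k)
  ccd_table(rbind(fact, axial, centers), factors)
}

#' Decode coded levels to actual units
#'
#' @param coded Numeric vector (one point) or matrix (one point per row).
#' @param factors List of `factor_spec`.
#' @return Actual-unit values, same shape as `coded`.
#' @export
decode_point <- function(coded, factors) {
  centers <- vapply(factors, `[[`, 0, "center")
  steps <- vapply(factors, `[[`, 0, "step")
  if (is.matrix(coded)) {
    if (ncol(coded) != length(factors))
      stop("dimension error: point has ", ncol(coded), " coordinates, expected ",
           length(factors))
    return(sweep(sweep(coded, 2, steps, `*`), 2, centers, `+`))
  }
  if (length(coded) != length(factors))
    stop("dimension error: point has ", length(coded), " coordinates, expected ",
         length(factors))
  centers + coded * steps
}

#' Encode actual-unit values to coded levels
#'
#' Inverse of [decode_point()]: `coded = (actual - center) / step`.
#'
#' @param actual Numeric vector or matrix in actual units.
#' @param factors List of `factor_spec`.
#' @return Coded values, same shape as `actual`.
#' @export
encode_point <- function(actual, factors) {
  centers <- vapply(factors, `[[`, 0, "center")
  steps <- vapply(factors, `[[`, 0, "step")
  if (any(steps == 0)) stop("degenerate factor: zero step")
  if (is.matrix(actual)) {
    if (ncol(actual) != length(factors))
      stop("dimension error: point has ", ncol(actual), " coordinates, expected ",
           length(factors))
    return(sweep(sweep(actual, 2, centers, `-`), 2, steps, `/`))
  }
  if (length(actual) != length(factors))
    stop("dimension error: point has ", length(actual), " coordinates, expected ",
         length(factors))
  (actual - centers) / steps
}

#' Load the 31-run melon differentiation CCD dataset
#'
#' The five-level four-factor central composite design (16 factorial, 8 axial
#' at +/-2, 7 center runs) with the observed differentiation rates and the
#' original study's network predictions, both in percent.
#'
#' @return A `ccd_table` with `observed` and `paper_predicted` filled in.
#' @examples
#' t1 <- load_table1()
#' rmse(t1$observed, t1$paper_predicted, scale = "percent")
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1_ccd.csv", package = "cultopt",
                      mustWork = TRUE)
  read_ccd_csv(path, factors = melon_factors(), validate_runs = 31L)
}

#' Read a CCD dataset from CSV
#'
#' Expected columns: `run`, one `<symbol>_coded` column per factor (lower
#' case), `actual_pct`, and optionally `paper_predicted_pct`. UTF-8, "."
#' decimal separator.
#'
#' @param path CSV file path.
#' @param factors List of `factor_spec` defining the coded-to-actual map.
#' @param validate_runs Optional expected row count; mismatch is an error.
#' @return A `ccd_table`.
#' @export
read_ccd_csv <- function(path, factors, validate_runs = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- paste0(tolower(vapply(factors, `[[`, "", "symbol")), "_coded")
  missing <- setdiff(c("run", cols, "actual_pct"), names(d))
  if (length(missing))
    stop("fixture error: ", path, " lacks column(s) ", paste(missing, collapse = ", "))
  if (!is.null(validate_runs) && nrow(d) != validate_runs)
    stop("fixture error: expected ", validate_runs, " runs, found ", nrow(d))
  if (anyNA(d[cols]) || anyNA(d$actual_pct))
    stop("fixture error: missing values in ", path)
  ccd_table(as.matrix(d[cols]), factors,
            observed = d$actual_pct,
            paper_predicted = if ("paper_predicted_pct" %in% names(d)) d$paper_predicted_pct)
}

#' Write a CCD dataset to CSV
#'
#' @param x A `ccd_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ccd_csv <- function(x, path) {
  stopifnot(inherits(x, "ccd_table"))
  d <- data.frame(run = seq_len(nrow(x$coded)))
  cols <- paste0(tolower(vapply(x$factors, `[[`, "", "symbol")), "_coded")
  for (i in seq_along(cols)) d[[cols[i]]] <- x$coded[, i]
  if (!is.null(x$observed)) d$actual_pct <- x$observed
  if (!is.null(x$paper_predicted)) d$paper_predicted_pct <- x$paper_predicted
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
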