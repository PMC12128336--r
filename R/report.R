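#' Round half-up
#'
#' Deterministic decimal rounding where exact halves round away from zero
#' (the convention used for all reported percentages), unlike base
#' [round()]'s round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Percentage of a count pair, rounded to one decimal
#'
#' @param num,den Nonnegative integer numerator and denominator.
#' @return `100 * num / den` rounded half-up to one decimal; `NA` with a
#'   warning when `den` is zero.
#' @examples
#' pct(25, 602)  # 4.2
#' @export
pct <- function(num, den) {
  if (length(den) == 1 && den == 0) {
    warn("Zero denominator; percentage omitted.")
    return(NA_real_)
  }
  round_half_up(100 * num / den, 1)
}

#' Assemble the pipeline summary report
#'
#' Collects stage counts and count/denominator pairs into a single
#' serializable report.  Every percentage is recomputed here from its
#' integer numerator and denominator and rounded half-up to one decimal,
#' so the printed percentages are always consistent with the printed
#' counts.
#'
#' @param counts Named list of nonnegative integer stage counts.
#' @param ratios Named list; each element a length-2 numeric
#'   `c(numerator, denominator)`.
#' @param cutoffs Named list of realized cutoffs (e.g. hub weight/degree
#'   cutoffs per group).
#' @param lambda The LASSO penalty used, or an [mb_lambda()] object.
#' @param config Configuration echo (a [pipeline_config()] or plain list),
#'   recorded for provenance.
#'
#' @return An object of class `summary_report`.
#' @examples
#' r <- build_report(counts = list(genes = 100, degs = 10),
#'                   ratios = list(deg_rate = c(10, 100)))
#' r$percentages$deg_rate
#' @export
build_report <- function(counts = list(), ratios = list(), cutoffs = list(),
                         lambda = NULL, config = list()) {
  stopifnot(is.list(counts), is.list(ratios), is.list(cutoffs))
  bad <- names(counts)[!vapply(counts, function(x) {
    is.numeric(x) && length(x) == 1 && x >= 0 && x == floor(x)
  }, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("Counts must be single nonnegative integers: ",
                 paste(bad, collapse = ", ")))
  }
  percentages <- list()
  for (nm in names(ratios)) {
    pair <- ratios[[nm]]
    if (length(pair) != 2 || any(pair < 0)) {
      abort(paste0("Ratio '", nm, "' must be c(numerator, denominator)."))
    }
    if (pair[2] == 0) {
      warn(paste0("Zero denominator for '", nm, "'; percentage omitted."))
      next
    }
    percentages[[nm]] <- pct(pair[1], pair[2])
  }
  if (inherits(lambda, "mb_penalty")) lambda <- lambda$lambda
  if (inherits(config, "pipeline_config")) config <- unclass(config)
  structure(list(counts = lapply(counts, as.integer),
                 ratios = lapply(ratios, function(x) as.integer(x)),
                 percentages = percentages,
                 cutoffs = cutoffs,
                 lambda = lambda,
                 config = config),
            class = "summary_report")
}

#' Write a summary report as JSON
#'
#' @param report A `summary_report` from [build_report()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "summary_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @export
print.summary_report <- function(x, ...) {
  cat("<summary_report>\n")
  for (nm in names(x$counts)) cat("  ", nm, ": ", x$counts[[nm]], "\n", sep = "")
  for (nm in names(x$percentages)) {
    pair <- x$ratios[[nm]]
    cat("  ", nm, ": ", x$percentages[[nm]], "% (", pair[1], "/", pair[2],
        ")\n", sep = "")
  }
  if (!is.null(x$lambda)) cat("  lambda: ", x$lambda, "\n", sep = "")
  invisible(x)
}
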