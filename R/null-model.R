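#' Fit an empirical null model to flow-through peptide log ratios
#'
#' Peptides in the lectin-column flow-through carry no glycosylation signal,
#' so their log10 mutant/control ratios estimate the technical null of the
#' isotope-doublet quantification. The null is modelled as a normal
#' distribution; the candidate cutoff is the half-width of the central
#' interval holding `coverage` of that normal, i.e. `z * sigma` with
#' `z = qnorm((1 + coverage) / 2)`. At the default `coverage = 0.9973`
#' (two-sided 3-sigma coverage, `2 * pnorm(3) - 1`) the cutoff is exactly
#' `3 * sigma`; on the embryo flow-through scale (`sigma ~ 0.55 / 3`) this
#' reproduces the working cutoff of +/-0.55 log10 units.
#'
#' @param flowthrough_log_ratios numeric vector of at least 30 log10 ratios.
#' @param coverage central probability mass the cutoff should enclose.
#' @return an object of class `null_ratio_model` with components `mu`
#'   (sample mean), `sigma` (sample sd), `cutoff` (`z * sigma`), `coverage`,
#'   `z` and `n`.
#' @examples
#' r <- simulate_flowthrough_ratios(10000, sigma = 0.55 / 3, seed = 7)
#' fit_null_model(r)
#' @seealso [select_candidates()]
#' @export
fit_null_model <- function(flowthrough_log_ratios, coverage = 0.9973) {
  x <- flowthrough_log_ratios
  if (!is.numeric(x)) stop_invalid("flowthrough_log_ratios must be numeric")
  x <- x[is.finite(x)]
  if (length(x) < 30L) {
    stop_degenerate("need at least 30 finite flow-through ratios to fit a null")
  }
  if (!is_prob(coverage) || coverage <= 0 || coverage >= 1) {
    stop_invalid("coverage must lie strictly in (0, 1)")
  }
  sigma <- stats::sd(x)
  if (!is.finite(sigma) || sigma <= 0) {
    stop_degenerate("flow-through ratios have zero variance")
  }
  z <- stats::qnorm((1 + coverage) / 2)
  structure(
    list(mu = mean(x), sigma = sigma, cutoff = z * sigma,
         coverage = coverage, z = z, n = length(x)),
    class = "null_ratio_model"
  )
}

#' @export
print.null_ratio_model <- function(x, digits = 4, ...) {
  cat("Empirical null of log10 M/L ratios (n =", x$n, ")\n")
  cat("  mu     =", signif(x$mu, digits), "\n")
  cat("  sigma  =", signif(x$sigma, digits), "\n")
  cat(sprintf("  cutoff = %s (encloses %.2f%% of the null, z = %.3f)\n",
              signif(x$cutoff, digits), 100 * x$coverage, x$z))
  invisible(x)
}

#' @export
coef.null_ratio_model <- function(object, ...) {
  c(mu = object$mu, sigma = object$sigma, cutoff = object$cutoff)
}

#' @export
summary.null_ratio_model <- function(object, ...) {
  out <- c(coef(object), coverage = object$coverage, z = object$z,
           n = object$n)
  class(out) <- "summary.null_ratio_model"
  out
}

#' @export
print.summary.null_ratio_model <- function(x, ...) {
  print(unclass(x))
  invisible(x)
}

#' Classify log ratios against a fitted null
#'
#' `predict()` on a null model labels each ratio as inside the null interval
#' (`"null"`) or beyond it (`"candidate"`); `NA` ratios stay `NA`.
#'
#' @param object a `null_ratio_model`.
#' @param newdata numeric vector of log10 ratios.
#' @param ... unused.
#' @export
predict.null_ratio_model <- function(object, newdata, ...) {
  if (missing(newdata)) stop_invalid("newdata (log ratios) is required")
  ifelse(is.na(newdata), NA_character_,
         ifelse(abs(newdata - object$mu) > object$cutoff,
                "candidate", "null"))
}
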