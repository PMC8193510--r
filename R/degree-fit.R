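#' Degree histogram of a tree
#'
#' @param tree a [spanning_tree()].
#' @return A `degree_histogram`: `data.frame` with columns `k` (observed
#'   degree values), `count` (nodes at each degree) and `p` (normalized
#'   frequency). Zero-count degrees are omitted.
#' @examples
#' degree_histogram(spanning_tree(cbind(1, 2:10)))
#' @export
degree_histogram <- function(tree) {
  deg <- tree_degrees(tree)
  tab <- table(deg)
  out <- data.frame(k = as.integer(names(tab)),
                    count = as.integer(tab))
  out$p <- out$count / sum(out$count)
  class(out) <- c("degree_histogram", "data.frame")
  out
}

#' Fit a degree-distribution family to a histogram
#'
#' Fits one of three classical degree-distribution forms by least squares:
#' power law `P(k) ~ k^-alpha`, exponential `P(k) ~ e^(-alpha k)`, and the
#' exponentially truncated power law `P(k) ~ k^(alpha - 1) e^(-k / kc)`,
#' the regime between scale-free and random-graph degree spectra. A free
#' proportionality constant is always estimated.
#'
#' On the default log scale every family is linear in its parameters
#' (`log p ~ log k`, `~ k`, `~ log k + k`) and the fit is exact least
#' squares via [stats::lm()]; `R^2 = 1 - SSres/SStot` is reported on the
#' fitted scale. On the linear scale the same model is refit by
#' [stats::nls()] started from the log-scale solution.
#'
#' @param h a [degree_histogram()].
#' @param family `"power_law"`, `"exponential"` or `"truncated_power_law"`.
#' @param scale fitting scale, `"log"` (default) or `"linear"`.
#' @return A `degree_fit`: list with `family`, `alpha`, `kc` (truncated
#'   family only), `r_squared`, `scale`, `fitted` (data.frame of k, observed
#'   and fitted p), `n_params`.
#' @export
fit_degree_distribution <- function(h, family = c("power_law", "exponential",
                                                  "truncated_power_law"),
                                    scale = c("log", "linear")) {
  family <- match.arg(family)
  scale <- match.arg(scale)
  stopifnot(inherits(h, "degree_histogram") || all(c("k", "p") %in% names(h)))
  k <- h$k; p <- h$p
  need <- if (family == "truncated_power_law") 3L else 2L
  if (length(unique(k)) < need)
    stop(sprintf("insufficient data: family '%s' needs at least %d distinct degrees",
                 family, need))
  lp <- log(p); lk <- log(k)
  fit <- switch(family,
    power_law = stats::lm(lp ~ lk),
    exponential = stats::lm(lp ~ k),
    truncated_power_law = stats::lm(lp ~ lk + k))
  cf <- stats::coef(fit)
  alpha <- switch(family,
    power_law = -cf[["lk"]],
    exponential = -cf[["k"]],
    truncated_power_law = cf[["lk"]] + 1)
  kc <- if (family == "truncated_power_law") -1 / cf[["k"]] else NULL
  pred_log <- stats::fitted(fit)
  if (scale == "log") {
    r2 <- 1 - sum(stats::residuals(fit)^2) / sum((lp - mean(lp))^2)
    fitted_p <- exp(pred_log)
  } else {
    form <- switch(family,
      power_law = p ~ exp(c0 - alpha * lk),
      exponential = p ~ exp(c0 - alpha * k),
      truncated_power_law = p ~ exp(c0 + (alpha - 1) * lk - k / kc))
    start <- c(list(c0 = cf[[1L]], alpha = alpha),
               if (!is.null(kc)) list(kc = kc))
    nl <- stats::nls(form, data = data.frame(k = k, p = p, lk = lk),
                     start = start, control = stats::nls.control(warnOnly = TRUE))
    cfn <- stats::coef(nl)
    alpha <- cfn[["alpha"]]
    if (!is.null(kc)) kc <- cfn[["kc"]]
    fitted_p <- stats::fitted(nl)
    r2 <- 1 - sum(stats::residuals(nl)^2) / sum((p - mean(p))^2)
  }
  structure(list(family = family, alpha = unname(alpha),
                 kc = if (is.null(kc)) NULL else unname(kc),
                 r_squared = r2, scale = scale,
                 fitted = data.frame(k = k, observed = p, fitted = unname(fitted_p)),
                 n_params = need - 1L),
            class = "degree_fit")
}

#' @export
print.degree_fit <- function(x, ...) {
  cat(sprintf("Degree-distribution fit: %s (scale: %s)\n", x$family, x$scale))
  cat(sprintf("  alpha = %.4f%s, R^2 = %.4f\n", x$alpha,
              if (!is.null(x$kc)) sprintf(", kc = %.4f", x$kc) else "",
              x$r_squared))
  invisible(x)
}

#' @export
plot.degree_fit <- function(x, ...) {
  plot(x$fitted$k, x$fitted$observed, log = "y", pch = 16,
       xlab = "degree k", ylab = "P(k)",
       main = sprintf("%s fit (R^2 = %.3f)", x$family, x$r_squared), ...)
  graphics::lines(x$fitted$k, x$fitted$fitted, col = 2)
  invisible(x)
}

#' Fit and rank all degree-distribution families
#'
#' Fits every family the histogram supports and ranks them by R-squared.
#' Because the truncated power law nests both one-parameter families, exact
#' ties (within `1e-8`) are broken in favor of the family with fewer
#' parameters.
#'
#' @inheritParams fit_degree_distribution
#' @return A `degree_fit_set`: list with `fits` (named list of [fit_degree_distribution()]
#'   results, best first), `best` (winning family name), and `partial`
#'   (`TRUE` if some family could not be fitted for lack of support points).
#' @export
compare_degree_fits <- function(h, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  families <- c("power_law", "exponential", "truncated_power_law")
  fits <- list()
  partial <- FALSE
  for (f in families) {
    fit <- tryCatch(fit_degree_distribution(h, f, scale = scale),
                    error = function(e) NULL)
    if (is.null(fit)) partial <- TRUE else fits[[f]] <- fit
  }
  if (!length(fits)) stop("no family could be fitted to this histogram")
  r2 <- vapply(fits, `[[`, numeric(1), "r_squared")
  np <- vapply(fits, `[[`, integer(1), "n_params")
  ord <- order(-round(r2 / 1e-8) * 1e-8, np)
  fits <- fits[ord]
  structure(list(fits = fits, best = names(fits)[1L], partial = partial),
            class = "degree_fit_set")
}

#' @export
print.degree_fit_set <- function(x, ...) {
  cat("Degree-distribution model comparison",
      if (x$partial) "(partial: some families lacked support)" else "", "\n")
  for (f in x$fits) {
    cat(sprintf("  %-22s R^2 = %.4f  alpha = %.4f%s%s\n", f$family,
                f$r_squared, f$alpha,
                if (!is.null(f$kc)) sprintf("  kc = %.4f", f$kc) else "",
                if (f$family == x$best) "  <- best" else ""))
  }
  invisible(x)
}
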