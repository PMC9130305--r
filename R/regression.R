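# Statistical primitives: standardization, polynomial design construction,
# OLS with adjusted R-squared and standardized coefficients, AICc.

#' Bioclimatic variables used throughout the package
#' @return Character vector `c("bio1","bio4","bio6","bio12","bio14","bio15")`.
#' @export
bioclim_vars <- function() c("bio1", "bio4", "bio6", "bio12", "bio14", "bio15")

#' The 12 candidate model terms (linear + quadratic per variable)
#'
#' Quadratic terms are named `<var>_sq`. A quadratic may enter a model
#' without its linear partner; no marginality constraint is imposed.
#' @return Character vector of 12 term names.
#' @export
climate_terms <- function() {
  v <- bioclim_vars()
  c(v, paste0(v, "_sq"))
}

#' Z-score columns to mean 0, SD 1
#'
#' Sample SD (n - 1 denominator). Centering/scaling parameters are kept as
#' attributes for reporting back on the original scale.
#'
#' @param x Numeric vector, matrix, or data frame of numeric columns.
#' @return Object of the same shape with each column standardized;
#'   attributes `center` and `scale` hold the removed means and SDs.
#' @export
standardize <- function(x) {
  if (is.vector(x) && is.numeric(x)) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) stop("cannot standardize a constant column")
    out <- (x - mean(x)) / s
    attr(out, "center") <- mean(x); attr(out, "scale") <- s
    return(out)
  }
  m <- as.matrix(x)
  if (!is.numeric(m)) stop("'x' must be numeric")
  ctr <- colMeans(m)
  scl <- apply(m, 2, stats::sd)
  bad <- !is.finite(scl) | scl == 0
  if (any(bad))
    stop("cannot standardize constant column(s): ",
         paste(colnames(m)[bad], collapse = ", "))
  out <- sweep(sweep(m, 2, ctr, "-"), 2, scl, "/")
  attr(out, "center") <- ctr; attr(out, "scale") <- scl
  out
}

#' Build a fully standardized polynomial design matrix
#'
#' Linear columns are z-scores of the raw variables. Quadratic columns are
#' the square of the z-scored variable, re-standardized, so that every
#' design column has mean 0 and SD 1 and coefficients are directly
#' comparable as standardized coefficients. An intercept column is
#' appended last.
#'
#' @param climate Data frame holding (at least) the variables named by the
#'   linear parts of `terms`.
#' @param terms Character vector of term names from [climate_terms()];
#'   empty gives an intercept-only design.
#' @return Numeric matrix `n x (length(terms) + 1)`; the final column is
#'   the intercept.
#' @export
build_design <- function(climate, terms = character()) {
  climate <- as.data.frame(climate)
  n <- nrow(climate)
  bad <- terms[!(terms %in% c(names(climate), paste0(names(climate), "_sq")))]
  if (length(bad)) stop("unknown term(s): ", paste(bad, collapse = ", "))
  cols <- lapply(terms, function(tm) {
    v <- sub("_sq$", "", tm)
    z <- standardize(climate[[v]])
    if (grepl("_sq$", tm)) standardize(as.numeric(z)^2) else as.numeric(z)
  })
  X <- if (length(cols)) do.call(cbind, cols) else matrix(numeric(0), nrow = n, ncol = 0)
  X <- cbind(X, 1)
  colnames(X) <- c(terms, "(Intercept)")
  X
}

#' Ordinary least squares on a standardized design
#'
#' Fits by QR decomposition; reports coefficients (standardized when the
#' design is, as from [build_design()]), residual sum of squares,
#' R-squared, adjusted R-squared, the AICc parameter count
#' `K = p + 2` (slopes + intercept + error variance) and the AICc score.
#'
#' @param design Design matrix whose last column is the intercept, as
#'   built by [build_design()].
#' @param y Response vector (standardized richness in this package's
#'   pipeline).
#' @param rank_tol Relative singular-value tolerance declaring the design
#'   rank-deficient.
#' @param check_rank Skip the rank check when the caller has already
#'   established full rank (e.g. the model search, which checks the full
#'   candidate design once: column subsets of a full-rank matrix stay
#'   full rank).
#' @return A `poly_fit` object.
#' @export
ols_fit <- function(design, y, rank_tol = 1e-10, check_rank = TRUE) {
  X <- as.matrix(design)
  n <- length(y)
  if (nrow(X) != n) stop("design and response lengths differ")
  p <- ncol(X) - 1L                       # slopes, intercept excluded
  if (n <= p + 1L)
    stop(sprintf("n = %d too small for %d terms", n, p))
  if (check_rank) {
    sv <- svd(X, nu = 0, nv = 0)$d
    if (sv[length(sv)] < rank_tol * sv[1]) {
      qr_x <- qr(X, tol = rank_tol)
      dropped <- colnames(X)[qr_x$pivot[seq.int(qr_x$rank + 1L, ncol(X))]]
      stop("rank-deficient design; collinear term(s): ",
           paste(dropped, collapse = ", "))
    }
  }
  fit <- stats::lm.fit(X, y)
  coefs <- fit$coefficients
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  # residuals at floating-point noise level are an exact fit: snap to zero
  # so AICc treats all noiseless supersets as ties (broken by model size)
  if (rss < 1e-20 * tss) rss <- 0
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  r2_adj <- if (tss > 0) 1 - (1 - r2) * (n - 1) / (n - p - 1) else NA_real_
  k <- p + 2L
  terms <- setdiff(colnames(X), "(Intercept)")
  structure(list(
    terms = terms, n = n,
    coefficients = coefs[terms],
    intercept = unname(coefs["(Intercept)"]),
    RSS = rss, R2 = r2, R2_adj = r2_adj,
    K = k, AICc = aicc_value(n, rss, k),
    sign = ifelse(coefs[terms] >= 0, "+", "-")
  ), class = "poly_fit")
}

# AICc from n, RSS and parameter count (Gaussian log-likelihood up to a
# constant shared by all models on the same data).
aicc_value <- function(n, rss, k) {
  if (n - k - 1 < 1) return(Inf)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Small-sample corrected Akaike information criterion of a fit
#'
#' `AICc = n log(RSS/n) + 2K + 2K(K+1)/(n-K-1)` with `K` = number of
#' slopes + intercept + error variance. Returns `Inf` when
#' `n - K - 1 < 1` (model infeasible at this sample size), so the score
#' stays usable inside a model search.
#'
#' @param fit A [ols_fit()] result.
#' @return The AICc score (lower is better).
#' @export
aicc <- function(fit) {
  stopifnot(inherits(fit, "poly_fit"))
  aicc_value(fit$n, fit$RSS, fit$K)
}

#' @export
print.poly_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Polynomial OLS fit: n = %d, %d term(s)\n", x$n, length(x$terms)))
  if (length(x$terms)) {
    cf <- format(round(x$coefficients, digits))
    cat("  standardized coefficients:\n")
    for (i in seq_along(x$terms))
      cat(sprintf("    %-10s %s\n", x$terms[i], cf[i]))
  }
  cat(sprintf("  R2 = %.4f, adj. R2 = %.4f, AICc = %.3f\n", x$R2, x$R2_adj, x$AICc))
  invisible(x)
}

#' @export
as.data.frame.poly_fit <- function(x, ...) {
  data.frame(term = x$terms,
             coefficient = unname(x$coefficients),
             n = x$n, R2 = x$R2, R2_adj = x$R2_adj, AICc = x$AICc,
             stringsAsFactors = FALSE)
}
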