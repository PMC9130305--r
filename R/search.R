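# Exhaustive all-subsets model selection over the candidate climate terms,
# ranked by AICc.

#' Enumerate all non-empty term subsets
#'
#' Deterministic order: by subset size, then lexicographically by term
#' name within a size. Refuses more than 20 candidate terms (2^20 - 1
#' models) as a combinatorial guard.
#'
#' @param candidate_terms Character vector of candidate term names.
#' @return List of character vectors, one per candidate model
#'   (`2^m - 1` of them for `m` terms).
#' @examples
#' length(enumerate_specs(climate_terms()))  # 4095
#' @export
enumerate_specs <- function(candidate_terms = climate_terms()) {
  m <- length(candidate_terms)
  if (m == 0) stop("no candidate terms")
  if (m > 20) stop("refusing to enumerate more than 20 candidate terms")
  sorted <- sort(candidate_terms, method = "radix")
  specs <- list()
  for (k in seq_len(m)) {
    idx <- utils::combn(m, k, simplify = FALSE)
    specs <- c(specs, lapply(idx, function(i) sorted[i]))
  }
  specs
}

#' Exhaustive AICc model search
#'
#' Fits every non-empty subset of the candidate terms by OLS on the fully
#' standardized design and ranks by AICc. Subsets infeasible at the sample
#' size (`n - K - 1 < 1`) or with a rank-deficient design are skipped and
#' counted, not raised. Ties in AICc (within `1e-9`) are broken by fewer
#' terms, then by enumeration order. The best model's terms, ordered by
#' absolute standardized coefficient, give the relative-importance
#' ranking.
#'
#' @param y Standardized response vector.
#' @param climate Per-band climate table.
#' @param candidate_terms Candidate term names (default the 12 linear +
#'   quadratic bioclim terms).
#' @param rank_tol Passed to [ols_fit()].
#' @return A `model_search` object: `ranking` data frame (`terms`, `k`,
#'   `AICc`, `R2_adj`), `best` ([ols_fit()] result), `importance`
#'   (best-model terms by decreasing `|coefficient|`), `n_skipped`,
#'   `n_candidates`.
#' @export
exhaustive_search <- function(y, climate, candidate_terms = climate_terms(),
                              rank_tol = 1e-10) {
  n <- length(y)
  if (n < 5) stop("need at least 5 observations")
  specs <- enumerate_specs(candidate_terms)
  full <- build_design(climate, sort(candidate_terms, method = "radix"))
  # column subsets of a full-rank design are full rank, so one check on the
  # full candidate design covers every subset
  sv <- svd(full, nu = 0, nv = 0)$d
  all_full_rank <- nrow(full) > ncol(full) && sv[length(sv)] >= rank_tol * sv[1]
  m <- length(specs)
  fits <- vector("list", m)
  aicc_v <- rep(NA_real_, m); r2adj_v <- rep(NA_real_, m); k_v <- integer(m)
  for (i in seq_len(m)) {
    tm <- specs[[i]]
    k_v[i] <- length(tm)
    if (n - (length(tm) + 2L) - 1L < 1L) next
    X <- full[, c(tm, "(Intercept)"), drop = FALSE]
    fit <- tryCatch(ols_fit(X, y, rank_tol = rank_tol, check_rank = !all_full_rank),
                    error = function(e) NULL)
    if (is.null(fit)) next
    fits[[i]] <- fit
    aicc_v[i] <- fit$AICc; r2adj_v[i] <- fit$R2_adj
  }
  fitted <- which(!is.na(aicc_v))
  skipped <- m - length(fitted)
  if (!length(fitted)) stop("all candidate models infeasible")
  ord <- fitted[order(aicc_v[fitted], k_v[fitted], fitted)]
  ranking <- data.frame(
    spec = ord,
    terms = vapply(specs[ord], paste, character(1), collapse = "+"),
    k = k_v[ord], AICc = aicc_v[ord], R2_adj = r2adj_v[ord],
    stringsAsFactors = FALSE, row.names = NULL)
  # best: AICc minimum with the 1e-9 tie window resolved by size then order
  near <- ranking[ranking$AICc <= ranking$AICc[1] + 1e-9, , drop = FALSE]
  near <- near[order(near$k, near$spec), , drop = FALSE]
  best <- fits[[near$spec[1]]]
  imp <- best$terms[order(abs(best$coefficients), decreasing = TRUE)]
  structure(list(ranking = ranking[, c("terms", "k", "AICc", "R2_adj")],
                 best = best, importance = imp,
                 n_skipped = skipped, n_candidates = length(specs)),
            class = "model_search")
}

#' @export
print.model_search <- function(x, ...) {
  cat(sprintf("Exhaustive AICc search: %d candidate models (%d fitted, %d skipped)\n",
              x$n_candidates, nrow(x$ranking), x$n_skipped))
  cat("Best model:\n")
  print(x$best)
  cat("Relative importance (|standardized coefficient|):",
      paste(x$importance, collapse = " > "), "\n")
  invisible(x)
}
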