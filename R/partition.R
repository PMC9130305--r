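# Variance partitioning by partial regression: unique and shared fractions
# of explained variation among 2 or 3 disjoint sets of climatic predictors,
# on the adjusted R-squared scale (the recommended currency when predictor
# sets differ in size). Fractions may be negative -- a known artefact of the
# adjustment -- and are reported as-is, which preserves the additivity
# identity.

# Expand a vector of variable names into model terms at the given
# polynomial order (order 2 adds the quadratic term of each variable).
expand_terms <- function(vars, order = 2) {
  stopifnot(order %in% c(1, 2))
  if (order == 1) vars else c(vars, paste0(vars, "_sq"))
}

# Adjusted R2 of y regressed on the expanded terms of one or more
# variable sets.
set_r2adj <- function(y, climate, vars, order) {
  ols_fit(build_design(climate, expand_terms(vars, order)), y)$R2_adj
}

#' Partition explained variation between two predictor sets
#'
#' With `R(.)` denoting the adjusted R-squared of the fit on the named
#' set(s): `unique_A = R(A+B) - R(B)`, `unique_B = R(A+B) - R(A)`,
#' `shared = R(A) + R(B) - R(A+B)`, `unexplained = 1 - R(A+B)`.
#'
#' @param y Standardized response (band richness).
#' @param set_a,set_b Character vectors of disjoint climatic variable
#'   names (each contributes its linear and, at `order = 2`, quadratic
#'   term).
#' @param climate Per-band climate table.
#' @param order Polynomial order, 1 or 2 (the analyses this mirrors use 2).
#' @param labels Length-2 labels for the sets in the output.
#' @return A `partition_result` data frame: `fraction` label, `value`
#'   (adjusted-R2 scale), `percent`.
#' @export
partition_two <- function(y, set_a, set_b, climate, order = 2,
                          labels = c("A", "B")) {
  if (length(intersect(set_a, set_b)))
    stop("predictor sets must be disjoint")
  r_a  <- set_r2adj(y, climate, set_a, order)
  r_b  <- set_r2adj(y, climate, set_b, order)
  r_ab <- set_r2adj(y, climate, c(set_a, set_b), order)
  out <- data.frame(
    fraction = c(paste0("unique_", labels[1]), paste0("unique_", labels[2]),
                 "shared", "unexplained"),
    value = c(r_ab - r_b, r_ab - r_a, r_a + r_b - r_ab, 1 - r_ab),
    stringsAsFactors = FALSE
  )
  out$percent <- 100 * out$value
  attr(out, "R2_adj") <- c(A = r_a, B = r_b, AB = r_ab)
  class(out) <- c("partition_result", "data.frame")
  out
}

#' Partition explained variation among three predictor sets
#'
#' Seven fractions from the adjusted R-squared of the 7 sub-models, by
#' inclusion--exclusion: three unique (`a`, `b`, `c`), three pairwise
#' shared (`d` = A&B, `e` = B&C, `f` = A&C) and one three-way shared
#' (`g`); they sum exactly to `R2_adj` of the combined model.
#'
#' @inheritParams partition_two
#' @param set_c Third disjoint variable set.
#' @param labels Length-3 labels.
#' @return A `partition_result` data frame with the seven fractions plus
#'   `unexplained`.
#' @export
partition_three <- function(y, set_a, set_b, set_c, climate, order = 2,
                            labels = c("A", "B", "C")) {
  if (length(intersect(set_a, set_b)) || length(intersect(set_a, set_c)) ||
      length(intersect(set_b, set_c)))
    stop("predictor sets must be pairwise disjoint")
  R <- function(...) set_r2adj(y, climate, c(...), order)
  r_a <- R(set_a); r_b <- R(set_b); r_c <- R(set_c)
  r_ab <- R(set_a, set_b); r_ac <- R(set_a, set_c); r_bc <- R(set_b, set_c)
  r_abc <- R(set_a, set_b, set_c)
  vals <- c(
    r_abc - r_bc,                       # a: unique A
    r_abc - r_ac,                       # b: unique B
    r_abc - r_ab,                       # c: unique C
    r_ac + r_bc - r_abc - r_c,          # d: shared A & B only
    r_ab + r_ac - r_abc - r_a,          # e: shared B & C only
    r_ab + r_bc - r_abc - r_b,          # f: shared A & C only
    r_a + r_b + r_c - r_ab - r_ac - r_bc + r_abc,  # g: three-way shared
    1 - r_abc
  )
  out <- data.frame(
    fraction = c(paste0("unique_", labels),
                 paste0("shared_", c(paste0(labels[1], labels[2]),
                                     paste0(labels[2], labels[3]),
                                     paste0(labels[1], labels[3]))),
                 paste0("shared_", paste(labels, collapse = "")),
                 "unexplained"),
    value = vals, stringsAsFactors = FALSE
  )
  out$percent <- 100 * out$value
  attr(out, "R2_adj") <- c(A = r_a, B = r_b, C = r_c,
                           AB = r_ab, AC = r_ac, BC = r_bc, ABC = r_abc)
  class(out) <- c("partition_result", "data.frame")
  out
}

#' @export
print.partition_result <- function(x, digits = 3, ...) {
  cat("Variance partition (adjusted R2 scale):\n")
  print(data.frame(fraction = x$fraction,
                   value = round(x$value, digits),
                   percent = round(x$percent, 1)), row.names = FALSE)
  invisible(x)
}
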