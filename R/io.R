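# CSV dialects shared by the generator and the pipeline.

#' Read a species elevational-range table
#'
#' Expects a UTF-8 CSV with header `species_id,group,elev_min_m,elev_max_m`;
#' `group` is `"lycophyte"` or `"fern"`.
#'
#' @param path CSV file path.
#' @return Validated data frame of species ranges.
#' @export
read_species_ranges <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  validate_ranges(df)
  df
}

#' Write a species range table
#' @param ranges Range data frame.
#' @param path Output CSV path.
#' @export
write_species_ranges <- function(ranges, path) {
  validate_ranges(ranges)
  utils::write.csv(ranges, path, row.names = FALSE)
  invisible(path)
}

#' Read a per-band climate/area table
#'
#' Expects one row per band with the six bioclim columns plus `area`
#' (km^2); a `band` label and `mid` elevation column are accepted and
#' preserved. Basic physical invariants are checked: `bio6 <= bio1`,
#' `bio12 >= bio14 >= 0`, no missing values, positive areas.
#'
#' @param path CSV file path.
#' @return Data frame with one row per band.
#' @export
read_climate_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  validate_climate(df)
  df
}

validate_climate <- function(df) {
  need <- c(bioclim_vars(), "area")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("climate table lacks column(s): ", paste(miss, collapse = ", "))
  num <- df[need]
  if (any(!vapply(num, is.numeric, logical(1))) || anyNA(num))
    stop("climate table has missing or non-numeric values")
  if (any(df$bio6 > df$bio1 + 1e-9))
    stop("invariant violated: bio6 must not exceed bio1")
  if (any(df$bio14 < 0) || any(df$bio12 < df$bio14 - 1e-9))
    stop("invariant violated: need bio12 >= bio14 >= 0")
  if (any(df$area <= 0)) stop("band areas must be positive")
  invisible(df)
}

#' Write a per-band climate table
#' @param climate Climate data frame.
#' @param path Output CSV path.
#' @export
write_climate_table <- function(climate, path) {
  validate_climate(climate)
  utils::write.csv(climate, path, row.names = FALSE)
  invisible(path)
}

#' Write a presence matrix as a wide 0/1 CSV
#'
#' Rows are band labels, columns species ids.
#' @param pm A presence matrix.
#' @param path Output CSV path.
#' @export
write_presence_matrix <- function(pm, path) {
  stopifnot(inherits(pm, "presence_matrix"))
  wide <- data.frame(band = rownames(pm$occupancy),
                     pm$occupancy * 1L, check.names = FALSE,
                     stringsAsFactors = FALSE)
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}
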