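#' Construct a scheme of fixed-width elevational bands
#'
#' Divides the gradient `[lo, hi)` into contiguous half-open bands
#' `[b, b + width)`. Bands are half-open so that a range endpoint lying
#' exactly on a band boundary belongs to one band only: a species recorded
#' up to 2000 m does not occupy the 2000--2100 m band.
#'
#' @param lo,hi Gradient limits in metres; `hi - lo` must be an exact
#'   multiple of `width`.
#' @param width Band width in metres (default 100).
#' @return A `band_scheme` object: a list with `lo`, `hi`, `width`,
#'   `n_bands`, and a data frame `bands` with columns `band` (label),
#'   `lower`, `upper`, `mid` (metres).
#' @examples
#' make_bands(0, 5000, 100)   # fifty 100-m bands
#' @export
make_bands <- function(lo, hi, width = 100) {
  stopifnot(is.numeric(lo), is.numeric(hi), is.numeric(width), length(width) == 1L)
  if (!is.finite(lo) || !is.finite(hi) || !is.finite(width))
    stop("band limits and width must be finite")
  if (width <= 0) stop("band width must be positive")
  if (hi <= lo) stop("'hi' must exceed 'lo'")
  rem <- (hi - lo) %% width
  if (abs(rem) > 1e-9 && abs(rem - width) > 1e-9)
    stop(sprintf("gradient span %g is not a multiple of width %g (remainder %g)",
                 hi - lo, width, rem))
  n <- as.integer(round((hi - lo) / width))
  lower <- lo + width * (seq_len(n) - 1L)
  upper <- lower + width
  bands <- data.frame(
    band  = sprintf("%g-%g", lower, upper),
    lower = lower, upper = upper, mid = (lower + upper) / 2,
    stringsAsFactors = FALSE
  )
  structure(list(lo = lo, hi = hi, width = width, n_bands = n, bands = bands),
            class = "band_scheme")
}

#' @export
print.band_scheme <- function(x, ...) {
  cat(sprintf("Elevational band scheme: %d bands of %g m covering [%g, %g) m\n",
              x$n_bands, x$width, x$lo, x$hi))
  invisible(x)
}

validate_ranges <- function(ranges) {
  need <- c("species_id", "group", "elev_min_m", "elev_max_m")
  miss <- setdiff(need, names(ranges))
  if (length(miss))
    stop("range table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(ranges$species_id))
    stop("duplicated species_id: ",
         paste(unique(ranges$species_id[duplicated(ranges$species_id)]), collapse = ", "))
  bad <- which(!is.finite(ranges$elev_min_m) | !is.finite(ranges$elev_max_m) |
                 ranges$elev_min_m > ranges$elev_max_m | ranges$elev_min_m < 0)
  if (length(bad))
    stop("invalid elevational range for species: ",
         paste(ranges$species_id[bad], collapse = ", "))
  badg <- which(!ranges$group %in% c("lycophyte", "fern"))
  if (length(badg))
    stop("unknown group (must be 'lycophyte' or 'fern') for species: ",
         paste(ranges$species_id[badg], collapse = ", "))
  invisible(ranges)
}

#' Interpolate species elevational ranges into band occupancy
#'
#' A species is marked present in every band its recorded range overlaps
#' with positive length (range interpolation). A point range
#' (`elev_min_m == elev_max_m`) occupies the single band whose half-open
#' interval contains the point. Ranges extending beyond the scheme are
#' clipped, not rejected; a range wholly outside contributes an all-FALSE
#' column.
#'
#' @param ranges Data frame with columns `species_id`, `group`
#'   (`"lycophyte"` or `"fern"`), `elev_min_m`, `elev_max_m`.
#' @param scheme A [make_bands()] scheme.
#' @return A `presence_matrix`: list with the `scheme`, `species` ids,
#'   `groups` (named character vector), and `occupancy`, a bands x species
#'   logical matrix.
#' @export
assign_species_to_bands <- function(ranges, scheme) {
  stopifnot(inherits(scheme, "band_scheme"))
  validate_ranges(ranges)
  b <- scheme$bands
  occ <- matrix(FALSE, nrow = scheme$n_bands, ncol = nrow(ranges),
                dimnames = list(b$band, ranges$species_id))
  for (i in seq_len(nrow(ranges))) {
    l <- ranges$elev_min_m[i]; u <- ranges$elev_max_m[i]
    if (u > l) {
      occ[, i] <- pmin(b$upper, u) - pmax(b$lower, l) > 0
    } else {
      occ[, i] <- b$lower <= l & l < b$upper
    }
  }
  structure(list(scheme = scheme, species = ranges$species_id,
                 groups = stats::setNames(ranges$group, ranges$species_id),
                 occupancy = occ),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("Presence matrix: %d bands x %d species (%d lycophytes, %d ferns)\n",
              nrow(x$occupancy), ncol(x$occupancy),
              sum(x$groups == "lycophyte"), sum(x$groups == "fern")))
  invisible(x)
}

#' Per-band richness by taxon group and area-corrected species density
#'
#' Species density is richness divided by the log10-transformed band
#' surface area in km^2, the usual species--area correction for bands of
#' unequal area. Bands where `log10(area) <= 0` (area at or below 1 km^2)
#' get `NA` density and are flagged.
#'
#' @param pm A [assign_species_to_bands()] presence matrix.
#' @param areas Numeric vector of band surface areas (km^2), one per band.
#' @param groups Optional species-to-group map overriding the one stored in
#'   `pm` (named character vector).
#' @return A `richness_profile` data frame: one row per band with `band`,
#'   `mid`, `S_all`, `S_lycophyte`, `S_fern`, `area`, `density`,
#'   `density_flagged`.
#' @export
richness_profile <- function(pm, areas, groups = NULL) {
  stopifnot(inherits(pm, "presence_matrix"))
  if (is.null(groups)) groups <- pm$groups
  miss <- setdiff(pm$species, names(groups))
  if (length(miss))
    stop("no group for species: ", paste(miss, collapse = ", "))
  groups <- groups[pm$species]
  if (length(areas) != nrow(pm$occupancy))
    stop("need one area per band")
  if (any(!is.finite(areas) | areas <= 0))
    stop("band areas must be positive and finite")
  occ <- pm$occupancy
  s_lyc <- as.integer(rowSums(occ[, groups == "lycophyte", drop = FALSE]))
  s_frn <- as.integer(rowSums(occ[, groups == "fern", drop = FALSE]))
  la <- log10(areas)
  flagged <- la <= 0
  out <- data.frame(
    band = pm$scheme$bands$band,
    mid  = pm$scheme$bands$mid,
    S_all = s_lyc + s_frn,
    S_lycophyte = s_lyc,
    S_fern = s_frn,
    area = areas,
    density = ifelse(flagged, NA_real_, (s_lyc + s_frn) / la),
    density_flagged = flagged,
    stringsAsFactors = FALSE
  )
  class(out) <- c("richness_profile", "data.frame")
  out
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper used for the density--richness coupling check.
#'
#' @param x,y Numeric vectors of equal length (>= 3) with nonzero variance.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance")
  stats::cor(x, y, method = "pearson")
}
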