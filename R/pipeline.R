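# Orchestration: taxon groups x gradient segments x the three analysis
# families (single-variable polynomial table, variance partitions, best
# AICc models), from two CSV inputs to the output bundle.

group_column <- function(group) {
  switch(group,
         pteridophytes = "S_all",
         lycophytes    = "S_lycophyte",
         ferns         = "S_fern",
         stop("unknown group: ", group))
}

#' Analysis configuration
#'
#' @param lo,hi,width Band scheme (m); defaults fifty 100-m bands over
#'   0--5000 m.
#' @param break_elev Elevation (m) splitting the lower and upper segments;
#'   must fall on a band edge. Default 2000 m (the richness peak).
#' @param groups Taxon groups to analyse, subset of
#'   `c("pteridophytes", "lycophytes", "ferns")`.
#' @param out_dir Output directory for [run_all()].
#' @param seed Seed echoed to the run log (used by synthetic runs).
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(lo = 0, hi = 5000, width = 100,
                            break_elev = 2000,
                            groups = c("pteridophytes", "lycophytes", "ferns"),
                            out_dir = ".", seed = NULL) {
  stopifnot(length(groups) >= 1)
  vapply(groups, group_column, character(1))   # validates names
  cfg <- list(lo = lo, hi = hi, width = width, break_elev = break_elev,
              groups = groups, out_dir = out_dir, seed = seed)
  scheme <- make_bands(lo, hi, width)
  if (!any(abs(c(scheme$bands$lower, hi) - break_elev) < 1e-9))
    stop("break_elev must coincide with a band edge")
  class(cfg) <- "analysis_config"
  cfg
}

#' Subset profile and climate to one gradient segment
#'
#' `"lower"` keeps the bands strictly below `break_elev`; `"upper"` the
#' bands at or above it; `"full"` keeps everything. With the default
#' scheme: lower = 20 bands (`[0,100)` .. `[1900,2000)`), upper = 30
#' bands. Standardization is re-done within the segment by the downstream
#' fits, which always z-score the data they are handed.
#'
#' @param profile A [richness_profile()].
#' @param climate Matching per-band climate table.
#' @param segment `"full"`, `"lower"` or `"upper"`.
#' @param break_elev Segment boundary (m); must fall on a band edge.
#' @return List with `profile`, `climate`, `n`.
#' @export
select_segment <- function(profile, climate, segment = c("full", "lower", "upper"),
                           break_elev = 2000) {
  segment <- match.arg(segment)
  if (nrow(profile) != nrow(climate))
    stop("profile and climate tables must have one row per band")
  if (nrow(profile) > 1) {
    width <- profile$mid[2] - profile$mid[1]
    edges <- c(profile$mid - width / 2, profile$mid[nrow(profile)] + width / 2)
    if (segment != "full" && !any(abs(edges - break_elev) < 1e-9))
      stop(sprintf("segment boundary %g m is not a band edge", break_elev))
  }
  keep <- switch(segment,
                 full  = rep(TRUE, nrow(profile)),
                 lower = profile$mid < break_elev,
                 upper = profile$mid > break_elev)
  list(profile = profile[keep, , drop = FALSE],
       climate = climate[keep, , drop = FALSE],
       n = sum(keep))
}

segment_richness <- function(profile, climate, group, segment, break_elev) {
  seg <- select_segment(profile, climate, segment, break_elev)
  list(y = standardize(as.numeric(seg$profile[[group_column(group)]])),
       climate = seg$climate, n = seg$n)
}

#' Single-variable polynomial regression table
#'
#' For each group x segment x bioclim variable x polynomial order (1, 2):
#' adjusted R-squared, with the sign of the first-order slope. Mirrors
#' the classic richness--climate summary table (3 groups x 3 segments x
#' 6 variables x 2 orders = 108 cells with the defaults).
#'
#' @param profile A [richness_profile()].
#' @param climate Matching climate table.
#' @param config An [analysis_config()].
#' @return Data frame with `group`, `segment`, `variable`, `order`,
#'   `R2_adj`, `sign` (first order only).
#' @export
run_table1 <- function(profile, climate, config = analysis_config()) {
  rows <- list()
  for (grp in config$groups) {
    for (seg in c("full", "lower", "upper")) {
      dat <- segment_richness(profile, climate, grp, seg, config$break_elev)
      for (v in bioclim_vars()) {
        for (ord in 1:2) {
          fit <- ols_fit(build_design(dat$climate, expand_terms(v, ord)), dat$y)
          rows[[length(rows) + 1L]] <- data.frame(
            group = grp, segment = seg, variable = v, order = ord,
            R2_adj = fit$R2_adj,
            sign = if (ord == 1) unname(fit$sign[v]) else NA_character_,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

# The partition schemes the pipeline runs, keyed by output file stem:
# temperature vs precipitation with the two main variables only (fig4a)
# and with all six (fig4b); extreme vs seasonality jointly (fig5a) and per
# climatic axis (fig5b temperature, fig5c precipitation); and the
# three-way general / extreme / seasonality split (fig6).
partition_schemes <- function() {
  list(
    fig4a = list(kind = 2, sets = list(temperature = "bio1",
                                       precipitation = "bio12")),
    fig4b = list(kind = 2, sets = list(temperature = c("bio1", "bio6", "bio4"),
                                       precipitation = c("bio12", "bio14", "bio15"))),
    fig5a = list(kind = 2, sets = list(extreme = c("bio6", "bio14"),
                                       seasonality = c("bio4", "bio15"))),
    fig5b = list(kind = 2, sets = list(extreme = "bio6", seasonality = "bio4")),
    fig5c = list(kind = 2, sets = list(extreme = "bio14", seasonality = "bio15")),
    fig6  = list(kind = 3, sets = list(general = c("bio1", "bio12"),
                                       extreme = c("bio6", "bio14"),
                                       seasonality = c("bio4", "bio15")))
  )
}

#' Run the variance-partitioning schemes
#'
#' Runs every scheme in [partition_schemes()] (or a named subset) for each
#' configured group on the full gradient, second-order designs throughout.
#'
#' @param profile A [richness_profile()].
#' @param climate Matching climate table.
#' @param config An [analysis_config()].
#' @param schemes Character vector of scheme names to run.
#' @return Named list (per scheme) of data frames with `group` plus the
#'   partition fractions.
#' @export
run_partitions <- function(profile, climate, config = analysis_config(),
                           schemes = names(partition_schemes())) {
  all_schemes <- partition_schemes()
  bad <- setdiff(schemes, names(all_schemes))
  if (length(bad)) stop("unknown scheme(s): ", paste(bad, collapse = ", "))
  out <- list()
  for (nm in schemes) {
    sch <- all_schemes[[nm]]
    per_group <- list()
    for (grp in config$groups) {
      dat <- segment_richness(profile, climate, grp, "full", config$break_elev)
      res <- if (sch$kind == 2) {
        partition_two(dat$y, sch$sets[[1]], sch$sets[[2]], dat$climate,
                      order = 2, labels = names(sch$sets))
      } else {
        partition_three(dat$y, sch$sets[[1]], sch$sets[[2]], sch$sets[[3]],
                        dat$climate, order = 2, labels = names(sch$sets))
      }
      per_group[[grp]] <- cbind(group = grp, as.data.frame(res),
                                stringsAsFactors = FALSE)
    }
    out[[nm]] <- do.call(rbind, per_group)
    rownames(out[[nm]]) <- NULL
  }
  out
}

#' Best AICc models for every group x segment
#'
#' Runs the exhaustive 12-term search per group and segment and lays the
#' standardized coefficients out as a wide table: one row per term plus a
#' final `R2_adj` row, one column per group x segment (blank where a term
#' is not retained).
#'
#' @param profile A [richness_profile()].
#' @param climate Matching climate table.
#' @param config An [analysis_config()].
#' @return List with `table` (wide coefficient data frame), `searches`
#'   (the raw [exhaustive_search()] results, named `group.segment`), and
#'   `skipped` (infeasible-model counts per cell).
#' @export
run_best_models <- function(profile, climate, config = analysis_config()) {
  terms <- climate_terms()
  cols <- list()
  searches <- list()
  skipped <- integer()
  for (grp in config$groups) {
    for (seg in c("full", "lower", "upper")) {
      dat <- segment_richness(profile, climate, grp, seg, config$break_elev)
      sr <- exhaustive_search(dat$y, dat$climate)
      key <- paste(grp, seg, sep = ".")
      searches[[key]] <- sr
      skipped[key] <- sr$n_skipped
      col <- rep(NA_real_, length(terms) + 1L)
      col[match(sr$best$terms, terms)] <- unname(sr$best$coefficients)
      col[length(terms) + 1L] <- sr$best$R2_adj
      cols[[key]] <- col
    }
  }
  tab <- data.frame(term = c(terms, "R2_adj"), cols,
                    check.names = FALSE, stringsAsFactors = FALSE)
  list(table = tab, searches = searches, skipped = skipped)
}

#' Run the full analysis from two CSV inputs
#'
#' Reads the range and climate tables, interpolates ranges into bands,
#' and writes the whole output bundle to `config$out_dir`:
#' `richness_profile.csv`, `table1_r2.csv`, `partition_fig4a.csv`,
#' `partition_fig4b.csv`, `partition_fig5a.csv`, `partition_fig5b.csv`,
#' `partition_fig5c.csv`, `partition_fig6.csv`, `table2_best_models.csv`
#' and `run_log.txt`. Outputs are deterministic: identical inputs and
#' configuration give byte-identical files.
#'
#' @param ranges_csv Path to the species range CSV.
#' @param climate_csv Path to the per-band climate CSV.
#' @param config An [analysis_config()].
#' @return Invisibly, a list with the in-memory results (`profile`,
#'   `table1`, `partitions`, `best_models`, `files`).
#' @export
run_all <- function(ranges_csv, climate_csv, config = analysis_config()) {
  ranges <- read_species_ranges(ranges_csv)
  climate <- read_climate_table(climate_csv)
  scheme <- make_bands(config$lo, config$hi, config$width)
  if (nrow(climate) != scheme$n_bands)
    stop(sprintf("stage band_assembly: climate table has %d rows, scheme %d bands",
                 nrow(climate), scheme$n_bands))
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage %s failed: %s", stage, conditionMessage(e)), call. = FALSE))
  }
  pm <- run_stage("band_assembly", assign_species_to_bands(ranges, scheme))
  profile <- run_stage("band_assembly", richness_profile(pm, climate$area))
  table1 <- run_stage("regression", run_table1(profile, climate, config))
  parts <- run_stage("variance_partitioning", run_partitions(profile, climate, config))
  best <- run_stage("model_search", run_best_models(profile, climate, config))

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  utils::write.csv(as.data.frame(profile), out("richness_profile.csv"), row.names = FALSE)
  utils::write.csv(table1, out("table1_r2.csv"), row.names = FALSE)
  for (nm in names(parts))
    utils::write.csv(parts[[nm]], out(sprintf("partition_%s.csv", nm)), row.names = FALSE)
  utils::write.csv(best$table, out("table2_best_models.csv"), row.names = FALSE)
  log_lines <- c(
    "elevrich run_all",
    sprintf("bands: %d x %g m over [%g, %g) m; segment break at %g m",
            scheme$n_bands, config$width, config$lo, config$hi, config$break_elev),
    sprintf("groups: %s", paste(config$groups, collapse = ", ")),
    sprintf("seed: %s", if (is.null(config$seed)) "none" else config$seed),
    sprintf("species: %d (%d lycophytes, %d ferns)", nrow(ranges),
            sum(ranges$group == "lycophyte"), sum(ranges$group == "fern")),
    sprintf("skipped models: %s",
            paste(sprintf("%s=%d", names(best$skipped), best$skipped), collapse = ", "))
  )
  writeLines(log_lines, out("run_log.txt"))
  files <- c("richness_profile.csv", "table1_r2.csv",
             sprintf("partition_%s.csv", names(parts)),
             "table2_best_models.csv", "run_log.txt")
  invisible(list(profile = profile, table1 = table1, partitions = parts,
                 best_models = best, files = file.path(config$out_dir, files)))
}

#' One-command synthetic demonstration run
#'
#' Generates the default synthetic gradient, writes the two input CSVs,
#' and runs the full analysis on them.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed for the generator.
#' @return Invisibly, the [run_all()] result.
#' @export
run_synthetic_demo <- function(out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- synthetic_config(seed = seed)
  ranges_csv <- file.path(out_dir, "synthetic_ranges.csv")
  climate_csv <- file.path(out_dir, "synthetic_climate.csv")
  write_species_ranges(generate_species_ranges(cfg), ranges_csv)
  write_climate_table(generate_climate_table(cfg), climate_csv)
  acfg <- analysis_config(cfg$gradient_lo, cfg$gradient_hi, cfg$band_width,
                          out_dir = out_dir, seed = seed)
  run_all(ranges_csv, climate_csv, acfg)
}
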