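#' Categorize a cattle-abundance raster
#'
#' Bins abundance (head per 10 km^2) into the reporting categories
#' {0-1, 1-5, 5-10, 10-20, 20-50, 50-100, >100}, using the half-open
#' convention [low, high) with a final open category [100, Inf).
#'
#' @param cattle Numeric matrix of abundance (>= 0; `NA` = no data).
#' @param breakpoints Strictly increasing lower bounds, starting at 0
#'   (default `c(0, 1, 5, 10, 20, 50, 100)`).
#' @return List of class `cattle_categories`: `categories` (integer
#'   matrix 1..K), `labels`, `breakpoints`.
#' @export
categorize_cattle <- function(cattle, breakpoints = c(0, 1, 5, 10, 20, 50,
                                                      100)) {
  if (any(diff(breakpoints) <= 0)) stop("breakpoints must be strictly increasing")
  if (any(cattle < 0, na.rm = TRUE))
    stop("cattle abundance values must be >= 0")
  k <- length(breakpoints)
  cat_m <- matrix(findInterval(cattle, breakpoints), nrow(cattle),
                  ncol(cattle))
  cat_m[is.na(cattle)] <- NA_integer_
  labels <- c(paste(breakpoints[-k], breakpoints[-1], sep = "-"),
              paste0(">", breakpoints[k]))
  structure(list(categories = cat_m, labels = labels,
                 breakpoints = breakpoints),
            class = "cattle_categories")
}

#' Region x cattle-category percent-modification table
#'
#' For each (scenario, region, abundance-category) stratum, the percent
#' modification is `100 x (# gain cells) / (# present-suitable cells)`,
#' where gain cells are strong-agreement gains (`gain-strong`), or all
#' gains (`gain-strong` + `gain-weak`) when `strong_only = FALSE`. The
#' `both` scenario is the union of the individual scenarios' gain cells,
#' which is why it can exceed each one. Strata with no present-suitable
#' cells are reported as `NA` (undefined), not 0; values can exceed 100
#' because the denominator is the present-suitable count. The final
#' column is the arithmetic mean of the category cells.
#'
#' @param present A `binary_map` of present-day suitability.
#' @param change_maps Named list of `change_map`s, one per scenario
#'   (e.g. `list(rcp45 = ..., rcp85 = ...)`).
#' @param categories A [categorize_cattle()] result.
#' @param regions Integer region raster (matrix, `NA` = no data), with
#'   optional attribute `"region_names"`.
#' @param strong_only Count only strong-agreement gains (default `TRUE`).
#' @return data.frame of class `exposure_table` with columns `scenario`,
#'   `region`, one column per category, and `average`.
#' @export
exposure_table <- function(present, change_maps, categories, regions,
                           strong_only = TRUE) {
  stopifnot(length(change_maps) >= 1)
  if (is.null(names(change_maps))) stop("change_maps must be named")
  dims <- dim(present$binary)
  if (!all(dim(categories$categories) == dims) ||
      !all(dim(regions) == dims))
    stop("rasters are on different grids")
  gain_codes <- if (strong_only) 4L else c(3L, 4L)
  gains <- lapply(change_maps, function(cm) {
    if (!all(dim(cm$classes) == dims))
      stop("rasters are on different grids")
    !is.na(cm$classes) & cm$classes %in% gain_codes
  })
  if (length(gains) > 1) gains$both <- Reduce(`|`, gains)
  region_ids <- sort(unique(regions[!is.na(regions)]))
  region_names <- attr(regions, "region_names") %||%
    paste0("region_", region_ids)
  k <- length(categories$labels)
  pres <- !is.na(present$binary) & present$binary
  rows <- list()
  for (sc in names(gains)) {
    for (ri in seq_along(region_ids)) {
      in_region <- !is.na(regions) & regions == region_ids[ri]
      vals <- rep(NA_real_, k)
      for (ci in seq_len(k)) {
        stratum <- in_region & !is.na(categories$categories) &
          categories$categories == ci
        denom <- sum(pres & stratum)
        if (denom > 0)
          vals[ci] <- 100 * sum(gains[[sc]] & stratum) / denom
      }
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sc, region = region_names[ri],
        t(vals), average = mean(vals, na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  names(out)[3:(2 + k)] <- categories$labels
  out$average[is.nan(out$average)] <- NA_real_
  class(out) <- c("exposure_table", "data.frame")
  out
}

#' Flag high-change table cells
#'
#' Marks percent-modification cells greater than `cutoff_percent`
#' (default 10, the reporting convention for italicized values).
#'
#' @param table An [exposure_table()].
#' @param cutoff_percent Flagging threshold.
#' @return The table with a logical flag matrix attached as attribute
#'   `"flags"` (same category columns, `NA` where undefined).
#' @export
flag_high <- function(table, cutoff_percent = 10) {
  value_cols <- setdiff(names(table), c("scenario", "region"))
  flags <- as.matrix(table[, value_cols, drop = FALSE]) > cutoff_percent
  attr(table, "flags") <- flags
  attr(table, "cutoff_percent") <- cutoff_percent
  table
}

#' Write an exposure table as CSV and formatted text
#'
#' The text rendering marks flagged cells with an asterisk.
#'
#' @param table A (possibly [flag_high()]-annotated) `exposure_table`.
#' @param csv_path,txt_path Output paths (either may be `NULL`).
#' @export
write_exposure_table <- function(table, csv_path = NULL, txt_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(as.data.frame(table), csv_path, row.names = FALSE)
  if (!is.null(txt_path)) {
    flags <- attr(table, "flags")
    value_cols <- setdiff(names(table), c("scenario", "region"))
    fmt <- as.data.frame(table)
    for (j in seq_along(value_cols)) {
      col <- value_cols[j]
      txt <- ifelse(is.na(fmt[[col]]), "",
                    sprintf("%.2f", fmt[[col]]))
      if (!is.null(flags))
        txt <- paste0(txt, ifelse(!is.na(flags[, j]) & flags[, j], "*", ""))
      fmt[[col]] <- txt
    }
    writeLines(c(utils::capture.output(print(fmt, row.names = FALSE)),
                 "* modification > cutoff"), txt_path)
  }
  invisible(table)
}
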