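#' @importFrom stats coef lm pnorm pt qnorm residuals rlnorm runif setNames
#' @importFrom rlang .data
NULL

# classed condition helper so callers can distinguish failure modes
hw_stop <- function(message, class) {
  stop(errorCondition(message, class = c(class, "hwequity_error")))
}

#' Canonical region partition of China's 31 provincial units
#'
#' Returns the National Health Commission's three-way health-region
#' partition of mainland China's 31 provincial-level units: 11 eastern,
#' 8 central and 12 western units.
#'
#' @return A named character vector mapping unit name to region label
#'   (`"eastern"`, `"central"` or `"western"`).
#' @examples
#' map <- default_region_map()
#' map[["Beijing"]]
#' table(map)
#' @export
default_region_map <- function() {
  eastern <- c("Beijing", "Tianjin", "Hebei", "Liaoning", "Shanghai",
               "Jiangsu", "Zhejiang", "Fujian", "Shandong", "Guangdong",
               "Hainan")
  central <- c("Shanxi", "Jilin", "Heilongjiang", "Anhui", "Jiangxi",
               "Henan", "Hubei", "Hunan")
  western <- c("Inner Mongolia", "Chongqing", "Guangxi", "Sichuan",
               "Guizhou", "Yunnan", "Tibet", "Shaanxi", "Gansu",
               "Qinghai", "Ningxia", "Xinjiang")
  c(setNames(rep("eastern", length(eastern)), eastern),
    setNames(rep("central", length(central)), central),
    setNames(rep("western", length(western)), western))
}

# spelling variants accepted on input, mapped to the canonical names used
# by default_region_map(); matching is case-insensitive
unit_name_aliases <- function() {
  c("heilong jiang"                    = "Heilongjiang",
    "xinjiang uygur autonomous region" = "Xinjiang",
    "nei mongol"                       = "Inner Mongolia",
    "inner mongolia autonomous region" = "Inner Mongolia",
    "tibet autonomous region"          = "Tibet",
    "ningxia hui autonomous region"    = "Ningxia",
    "guangxi zhuang autonomous region" = "Guangxi")
}

#' Normalize administrative-unit names
#'
#' Resolves common spelling variants (e.g. `"Heilong Jiang"`,
#' `"Xinjiang Uygur Autonomous Region"`) to the canonical names used by
#' [default_region_map()]. Matching is case-insensitive; unknown names
#' pass through unchanged.
#'
#' @param x Character vector of unit names.
#' @return Character vector of the same length with canonical spellings.
#' @export
normalize_unit_names <- function(x) {
  aliases <- unit_name_aliases()
  key <- tolower(trimws(x))
  hit <- key %in% names(aliases)
  x <- trimws(x)
  x[hit] <- unname(aliases[key[hit]])
  # case-insensitive match against the canonical map too
  canon <- names(default_region_map())
  idx <- match(key[!hit], tolower(canon))
  x[!hit][!is.na(idx)] <- canon[idx[!is.na(idx)]]
  x
}

panel_columns <- c("unit", "region", "year", "population", "gdp",
                   "area_km2", "staff", "health_professionals")

#' Construct and validate a workforce panel
#'
#' A workforce panel is a tibble with one row per (unit, year) and columns
#' `unit`, `region`, `year`, `population`, `gdp`, `area_km2`, `staff`,
#' `health_professionals`. Validation enforces: unique (unit, year) pairs,
#' one region per unit across all years, strictly positive population and
#' area, non-negative GDP and counts, `health_professionals <= staff`,
#' and (unless `allow_unbalanced = TRUE`) a balanced panel in which every
#' year carries the full unit set.
#'
#' @param x A data frame with the panel columns (`region` may be omitted
#'   when `region_map` is supplied).
#' @param region_map Optional named character vector mapping unit name to
#'   region label, used to fill or override the `region` column.
#' @param allow_unbalanced If `TRUE`, years may cover different unit
#'   subsets; per-year statistics then use the units available that year.
#' @return A validated tibble of class `workforce_panel`.
#' @export
workforce_panel <- function(x, region_map = NULL, allow_unbalanced = FALSE) {
  x <- tibble::as_tibble(x)
  names(x) <- tolower(names(x))
  if (!"region" %in% names(x) && !is.null(region_map)) x$region <- NA_character_

  missing_cols <- setdiff(panel_columns, names(x))
  if (length(missing_cols) > 0) {
    hw_stop(paste0("panel is missing required column(s): ",
                   paste(missing_cols, collapse = ", ")),
            "hw_schema_error")
  }
  x <- x[panel_columns]
  x$unit <- normalize_unit_names(as.character(x$unit))
  if (!is.null(region_map)) {
    names(region_map) <- normalize_unit_names(names(region_map))
    mapped <- unname(region_map[x$unit])
    x$region <- ifelse(is.na(x$region) | x$region == "", mapped, x$region)
  }
  if (anyNA(x$region)) {
    hw_stop("region is missing for some units and no region_map covers them",
            "hw_schema_error")
  }
  x$region <- tolower(trimws(as.character(x$region)))
  x$year <- as.integer(x$year)

  key <- paste(x$unit, x$year, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- x[duplicated(key), , drop = FALSE]
    hw_stop(paste0("duplicate (unit, year) pair: ", dup$unit[1], " ",
                   dup$year[1]),
            "hw_integrity_error")
  }
  regions_per_unit <- tapply(x$region, x$unit, function(r) length(unique(r)))
  if (any(regions_per_unit > 1)) {
    hw_stop(paste0("unit assigned to more than one region: ",
                   names(regions_per_unit)[regions_per_unit > 1][1]),
            "hw_integrity_error")
  }
  if (any(x$population <= 0) || any(x$area_km2 <= 0)) {
    hw_stop("population and area_km2 must be strictly positive",
            "hw_validation_error")
  }
  if (any(x$gdp < 0) || any(x$staff < 0) || any(x$health_professionals < 0)) {
    hw_stop("gdp and worker counts must be non-negative",
            "hw_validation_error")
  }
  bad <- x$health_professionals > x$staff
  if (any(bad)) {
    hw_stop(paste0("health_professionals exceeds staff for ",
                   x$unit[bad][1], " in ", x$year[bad][1]),
            "hw_validation_error")
  }
  if (!allow_unbalanced) {
    units_by_year <- tapply(x$unit, x$year, function(u) sort(unique(u)))
    full <- sort(unique(x$unit))
    ok <- vapply(units_by_year, function(u) identical(u, full), logical(1))
    if (!all(ok)) {
      hw_stop(paste0("panel is unbalanced (year ",
                     names(units_by_year)[!ok][1],
                     " does not cover all units); pass allow_unbalanced",
                     " = TRUE to accept"),
              "hw_integrity_error")
    }
  }
  x <- x[order(x$year, x$unit), ]
  class(x) <- c("workforce_panel", class(x))
  attr(x, "balanced") <- !allow_unbalanced
  x
}

#' Read a workforce panel from delimited text
#'
#' Reads a comma- or tab-delimited file with a named header (column order
#' and case are free) into a validated [workforce_panel()]. Expected
#' columns: `unit, region, year, population, gdp, area_km2, staff,
#' health_professionals`; `region` may be omitted when `region_map` is
#' supplied.
#'
#' @param path Path to the file.
#' @param region_map Optional unit-to-region mapping (see
#'   [default_region_map()]).
#' @param allow_unbalanced Accept panels whose years cover different unit
#'   subsets.
#' @param delim Field delimiter; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @return A `workforce_panel` tibble.
#' @export
read_panel <- function(path, region_map = NULL, allow_unbalanced = FALSE,
                       delim = NULL) {
  if (!file.exists(path)) hw_stop(paste0("file not found: ", path), "hw_io_error")
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  workforce_panel(raw, region_map = region_map,
                  allow_unbalanced = allow_unbalanced)
}

#' Read a national category-breakdown table
#'
#' Reads per-year composition percentages (gender, age bands, tenure
#' bands, professional share) from delimited text with columns
#' `year, category_group, category_label, percent`. Within each
#' (year, category_group) whose group is a full partition, percentages are
#' checked to sum to 100 within a 0.1-point rounding slack.
#'
#' @param path Path to the file.
#' @param check_sums Verify the 100% partition invariant for groups other
#'   than `professional_share`.
#' @return A tibble with the four breakdown columns.
#' @export
read_breakdown <- function(path, check_sums = TRUE) {
  if (!file.exists(path)) hw_stop(paste0("file not found: ", path), "hw_io_error")
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE)
  names(x) <- tolower(names(x))
  need <- c("year", "category_group", "category_label", "percent")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    hw_stop(paste0("breakdown is missing column(s): ",
                   paste(miss, collapse = ", ")), "hw_schema_error")
  }
  x <- tibble::as_tibble(x[need])
  x$year <- as.integer(x$year)
  if (any(x$percent < 0 | x$percent > 100)) {
    hw_stop("percent outside [0, 100]", "hw_validation_error")
  }
  if (check_sums) {
    part <- x[!x$category_group %in% "professional_share", , drop = FALSE]
    if (nrow(part) > 0) {
      sums <- tapply(part$percent,
                     paste(part$year, part$category_group), sum)
      off <- abs(sums - 100) > 0.1
      if (any(off)) {
        hw_stop(paste0("percentages do not sum to 100 for ",
                       names(sums)[off][1]), "hw_validation_error")
      }
    }
  }
  x
}

#' Write a rectangular result table as delimited text
#'
#' Writes rows as comma-delimited text with a stable column order and
#' the report's numeric formatting: inequality indices at 4 decimals,
#' percentages at 2 decimals. Columns are classified by name: names
#' containing `percent` or ending in `_pct` are percentages; other
#' non-integer numeric columns are indices unless listed in `raw_cols`.
#'
#' @param rows A data frame.
#' @param path Output path.
#' @param index_digits Decimals for index-valued columns (default 4).
#' @param percent_digits Decimals for percentage columns (default 2).
#' @param raw_cols Character vector of numeric columns to leave unformatted.
#' @return Invisibly, the formatted data frame that was written.
#' @export
write_table <- function(rows, path, index_digits = 4, percent_digits = 2,
                        raw_cols = character()) {
  rows <- as.data.frame(rows)
  out <- rows
  for (nm in names(out)) {
    v <- out[[nm]]
    if (!is.numeric(v) || nm %in% raw_cols) next
    if (grepl("percent|_pct$", nm, ignore.case = TRUE)) {
      out[[nm]] <- formatC(v, format = "f", digits = percent_digits)
    } else if (!all(is.na(v)) && all(v == round(v), na.rm = TRUE) &&
               max(abs(v), na.rm = TRUE) >= 1) {
      out[[nm]] <- formatC(v, format = "d")
    } else {
      out[[nm]] <- formatC(v, format = "f", digits = index_digits)
    }
    out[[nm]][is.na(v)] <- ""
  }
  con <- tryCatch(file(path, "w"), error = function(e)
    hw_stop(paste0("cannot open for writing: ", path), "hw_io_error"))
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' Write a workforce panel as delimited text
#'
#' Writes the panel in the schema accepted by [read_panel()]; integer
#' counts are written exactly so that a read/write cycle round-trips them
#' bit-identically.
#'
#' @param panel A `workforce_panel`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "workforce_panel"))
  df <- as.data.frame(panel)[panel_columns]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
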