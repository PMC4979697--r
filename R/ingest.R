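#' Default Darwin-Core-style column mapping
#'
#' Maps the internal record fields to the column names found in the input
#' file. Fields `species`, `latitude`, `longitude` and `year` are
#' mandatory; the rest are optional and filled with defaults when absent.
#'
#' @param ... Overrides, e.g. `latitude = "decimalLatitude"`.
#' @return Named character vector `internal_field = file_column`.
#' @export
occ_column_map <- function(...) {
  map <- c(species = "species",
           taxon_group = "taxon_group",
           latitude = "decimal_latitude",
           longitude = "decimal_longitude",
           year = "year",
           basis_of_record = "basis_of_record",
           coordinate_issue = "coordinate_issue_flag",
           taxon_rank = "taxon_rank",
           dataset = "dataset")
  ov <- c(...)
  if (length(ov)) {
    unknown <- setdiff(names(ov), names(map))
    if (length(unknown))
      stop("unknown record field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    map[names(ov)] <- ov
  }
  map
}

#' Read an occurrence table from delimited text
#'
#' Reads comma- or tab-separated occurrence records (UTF-8). Rows with
#' unparseable or out-of-range coordinates or years are retained but
#' flagged invalid; they are removed (and accounted for) only by
#' [filter_records()], so the filter report reflects every exclusion.
#'
#' @param path Path to the delimited file.
#' @param column_map Mapping from internal fields to file columns, see
#'   [occ_column_map()].
#' @param sep Field separator; `NULL` (default) sniffs tab vs comma from
#'   the header line.
#' @return Data frame with columns `species`, `taxon_group`,
#'   `decimal_latitude`, `decimal_longitude`, `year`, `basis_of_record`,
#'   `coordinate_issue`, `taxon_rank`, `dataset`, plus logical
#'   `invalid_coordinate` and `invalid_year` flags.
#' @export
read_occurrences <- function(path, column_map = occ_column_map(), sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L, warn = FALSE)
    sep <- if (grepl("\t", hdr, fixed = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", comment.char = "",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           encoding = "UTF-8")
  mandatory <- c("species", "latitude", "longitude", "year")
  for (f in mandatory) {
    if (!column_map[[f]] %in% names(raw))
      stop("missing mandatory column '", column_map[[f]], "' (field ", f, ")",
           call. = FALSE)
  }
  pick <- function(f, default) {
    col <- column_map[[f]]
    if (!is.na(col) && col %in% names(raw)) raw[[col]] else
      rep(default, nrow(raw))
  }
  suppressWarnings({
    lat <- as.numeric(pick("latitude", NA))
    lon <- as.numeric(pick("longitude", NA))
    yr <- as.numeric(pick("year", NA))
  })
  issue_raw <- tolower(trimws(pick("coordinate_issue", "false")))
  out <- data.frame(
    species = pick("species", NA_character_),
    taxon_group = pick("taxon_group", "unknown"),
    decimal_latitude = lat,
    decimal_longitude = lon,
    year = yr,
    basis_of_record = pick("basis_of_record", "specimen"),
    coordinate_issue = issue_raw %in% c("true", "t", "1", "yes"),
    taxon_rank = pick("taxon_rank", "species"),
    dataset = pick("dataset", "dataset"),
    stringsAsFactors = FALSE)
  out$invalid_coordinate <- !is.finite(out$decimal_latitude) |
    !is.finite(out$decimal_longitude) |
    abs(out$decimal_latitude) > 90 | abs(out$decimal_longitude) > 180
  out$invalid_year <- !is.finite(out$year) | out$year != round(out$year)
  out$year <- ifelse(out$invalid_year, NA_integer_, as.integer(round(out$year)))
  out
}

#' Record screening criteria
#'
#' The default criteria mirror the standard museum-record screen: no known
#' coordinate issues, sampling year 1800-2013 (inclusive on both ends),
#' taxonomic rank "species", and record type "specimen". Systematic survey
#' datasets (BBS/FFS style) lack the issue and record-type fields; use
#' `filter_criteria(require_no_coordinate_issue = FALSE,
#' allowed_record_types = NULL)` for those.
#'
#' @param require_no_coordinate_issue Drop records flagged with coordinate
#'   issues (and records with unparseable/out-of-range coordinates).
#' @param year_range Inclusive `c(min, max)` calendar-year window; records
#'   with unparseable years are dropped under this rule. `NULL` disables.
#' @param require_species_rank Keep only rows whose taxonomic rank is
#'   "species" (case-insensitive); rows lacking a rank column pass.
#' @param allowed_record_types Case-insensitive allow-list for
#'   `basis_of_record` (default `"specimen"`); `NULL` disables the rule.
#' @return Object of class `filter_criteria`.
#' @export
filter_criteria <- function(require_no_coordinate_issue = TRUE,
                            year_range = c(1800L, 2013L),
                            require_species_rank = TRUE,
                            allowed_record_types = "specimen") {
  if (!is.null(year_range)) {
    if (length(year_range) != 2L || year_range[1] > year_range[2])
      stop("'year_range' must be c(min, max) with min <= max", call. = FALSE)
  }
  structure(list(require_no_coordinate_issue = isTRUE(require_no_coordinate_issue),
                 year_range = if (is.null(year_range)) NULL else as.integer(year_range),
                 require_species_rank = isTRUE(require_species_rank),
                 allowed_record_types = allowed_record_types),
            class = "filter_criteria")
}

#' Screen occurrence records
#'
#' Applies the screening rules in a fixed order -- coordinate issue, year,
#' taxonomic rank, record type -- so removal counts are reproducible when
#' a record violates several rules. Retained + removed always equals the
#' input count.
#'
#' @param records Occurrence table from [read_occurrences()] or
#'   [simulate_records()].
#' @param criteria A [filter_criteria()] object.
#' @return List with `records` (the retained rows) and `report`, a named
#'   integer vector of removal counts per rule plus `input` and `retained`.
#' @export
filter_records <- function(records, criteria = filter_criteria()) {
  stopifnot(is.data.frame(records), inherits(criteria, "filter_criteria"))
  n0 <- nrow(records)
  alive <- rep(TRUE, n0)
  report <- c(coordinate_issue = 0L, year = 0L, rank = 0L, record_type = 0L)

  if (criteria$require_no_coordinate_issue) {
    bad <- alive & (isTRUE_col(records, "coordinate_issue") |
                    isTRUE_col(records, "invalid_coordinate"))
    report["coordinate_issue"] <- sum(bad)
    alive <- alive & !bad
  }
  if (!is.null(criteria$year_range)) {
    yr <- records$year
    bad <- alive & (is.na(yr) | yr < criteria$year_range[1] |
                    yr > criteria$year_range[2] |
                    isTRUE_col(records, "invalid_year"))
    report["year"] <- sum(bad)
    alive <- alive & !bad
  }
  if (criteria$require_species_rank && "taxon_rank" %in% names(records)) {
    bad <- alive & tolower(trimws(records$taxon_rank)) != "species"
    report["rank"] <- sum(bad)
    alive <- alive & !bad
  }
  if (!is.null(criteria$allowed_record_types) &&
      "basis_of_record" %in% names(records)) {
    allowed <- tolower(trimws(criteria$allowed_record_types))
    bad <- alive & !(tolower(trimws(records$basis_of_record)) %in% allowed)
    report["record_type"] <- sum(bad)
    alive <- alive & !bad
  }
  out <- records[alive, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out,
       report = c(input = n0, report, retained = nrow(out)))
}

isTRUE_col <- function(df, col) {
  if (col %in% names(df)) !is.na(df[[col]]) & df[[col]] else
    rep(FALSE, nrow(df))
}

#' Build per-cell, per-period survey inventories
#'
#' A survey is the set of all occurrence records within one grid cell and
#' one time period. A record contributes to every period whose (inclusive)
#' interval contains its year, so overlapping schemes (complete vs
#' contemporary) are built in one pass.
#'
#' @param records Occurrence table with `cell_id` (see [assign_cells()]).
#' @param scheme A [time_periods()] scheme, or a character scheme name.
#' @param dataset Dataset label; default takes the records' `dataset`
#'   column (one label per record allowed).
#' @return Long-format data frame of class `survey_inventories`: one row
#'   per (dataset, period, cell_id, species) with `record_count`.
#' @export
build_inventories <- function(records, scheme = "complete", dataset = NULL) {
  if (is.character(scheme) && length(scheme) == 1L) scheme <- time_periods(scheme)
  stopifnot(inherits(scheme, "time_period_scheme"))
  if (!nrow(records)) {
    out <- data.frame(dataset = character(), period = character(),
                      cell_id = character(), species = character(),
                      record_count = integer(), stringsAsFactors = FALSE)
    class(out) <- c("survey_inventories", "data.frame")
    return(out)
  }
  if (!"cell_id" %in% names(records))
    stop("records lack cell ids; run assign_cells() first", call. = FALSE)
  ds <- if (!is.null(dataset)) rep(as.character(dataset), nrow(records))
        else if ("dataset" %in% names(records)) as.character(records$dataset)
        else "dataset"
  pieces <- lapply(names(scheme), function(pn) {
    iv <- scheme[[pn]]
    in_p <- !is.na(records$year) & records$year >= iv[1] & records$year <= iv[2]
    if (!any(in_p)) return(NULL)
    r <- records[in_p, , drop = FALSE]
    agg <- stats::aggregate(
      list(record_count = rep(1L, nrow(r))),
      by = list(dataset = ds[in_p], cell_id = r$cell_id, species = r$species),
      FUN = sum)
    agg$period <- pn
    agg
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  out <- if (length(pieces)) do.call(rbind, pieces) else
    data.frame(dataset = character(), cell_id = character(),
               species = character(), record_count = integer(),
               period = character(), stringsAsFactors = FALSE)
  out <- out[, c("dataset", "period", "cell_id", "species", "record_count")]
  out <- out[order(out$dataset, out$period, out$cell_id, out$species), ]
  rownames(out) <- NULL
  class(out) <- c("survey_inventories", "data.frame")
  out
}

#' Per-inventory summary statistics
#'
#' Collapses a long inventory table to one row per survey (dataset,
#' period, cell) with the quantities the completeness metrics use:
#' total records n, observed richness S_obs, and the singleton/doubleton
#' counts Q1, Q2 (species with exactly one / two records).
#'
#' @param inventories A [build_inventories()] table.
#' @return Data frame with `dataset`, `period`, `cell_id`, `n`, `s_obs`,
#'   `q1`, `q2`.
#' @export
inventory_stats <- function(inventories) {
  stopifnot(is.data.frame(inventories))
  if (!nrow(inventories))
    return(data.frame(dataset = character(), period = character(),
                      cell_id = character(), n = integer(), s_obs = integer(),
                      q1 = integer(), q2 = integer(), stringsAsFactors = FALSE))
  key <- list(dataset = inventories$dataset, period = inventories$period,
              cell_id = inventories$cell_id)
  cnt <- inventories$record_count
  agg <- stats::aggregate(list(n = cnt, s_obs = rep(1L, length(cnt)),
                               q1 = as.integer(cnt == 1L),
                               q2 = as.integer(cnt == 2L)),
                          by = key, FUN = sum)
  agg <- agg[order(agg$dataset, agg$period, agg$cell_id), ]
  rownames(agg) <- NULL
  agg
}

#' Write an inventory table as delimited text
#'
#' Long format with the cell's south-west corner coordinates appended:
#' dataset, period, cell_id, cell_lon_min, cell_lat_min, species,
#' record_count.
#'
#' @param inventories A [build_inventories()] table.
#' @param path Output file path.
#' @param grid The [grid_spec()] the inventories were built on.
#' @return `path`, invisibly.
#' @export
write_inventories <- function(inventories, path, grid) {
  geo <- cell_geometry(unique(inventories$cell_id), grid)
  m <- match(inventories$cell_id, geo$cell_id)
  out <- data.frame(inventories[, c("dataset", "period", "cell_id")],
                    cell_lon_min = geo$lon_min[m], cell_lat_min = geo$lat_min[m],
                    inventories[, c("species", "record_count")],
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
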