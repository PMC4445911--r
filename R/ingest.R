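#' Body parts and colours used in plumage scoring
#'
#' Plumage colour is scored as presence/absence of each of 11 colour
#' categories on each of 14 body parts. Coverage of a colour is the fraction
#' of the 14 parts on which it is present; parts are equally weighted. The
#' pink category subsumes purple and violet.
#'
#' @return Character vector of part or colour names.
#' @export
body_part_names <- function() {
  c("bill", "face", "cheek", "head", "throat", "breast", "belly", "flank",
    "back", "wings", "tail", "rump", "vent", "legs")
}

#' @rdname body_part_names
#' @export
colour_names <- function() {
  c("blue", "green", "red", "orange", "brown", "pink", "yellow", "black",
    "grey", "white", "ivory")
}

required_trait_columns <- function() {
  c("species_id", "price_twd", "n_for_sale", "status", "realm", "iucn",
    "cites_listed", "body_mass_g", "range_km2", "song_count")
}

numeric_trait_columns <- function() {
  c("price_twd", "n_for_sale", "cites_listed", "body_mass_g", "range_km2",
    "song_count")
}

#' Read a species trait table from CSV
#'
#' One row per species. Required columns: `species_id`, `price_twd`,
#' `n_for_sale`, `status` (native/alien), `realm`, `iucn` (LC/NT/VU/EN),
#' `cites_listed` (0/1), `body_mass_g`, `range_km2`, `song_count`. Optional:
#' `family`, `order`, per-colour coverage columns `colour_<name>` (proportions
#' in \[0, 1\]), `colour_diversity`, `song_attractiveness`. Rows containing
#' missing values are retained and flagged in the logical column
#' `has_missing`; complete-case subsetting happens per fitted model
#' downstream.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @return A `trait_table`: a tibble with normalised `species_id` labels.
#' @export
read_species_table <- function(path) {
  if (!file.exists(path)) stopf("trait table not found: %s", path)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_trait_table(raw, source = path)
}

#' Validate a data frame as a species trait table
#'
#' @param x A data frame with the columns described in
#'   [read_species_table()].
#' @param source Optional provenance string stored as an attribute.
#' @return A validated `trait_table` tibble.
#' @export
as_trait_table <- function(x, source = NULL) {
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(required_trait_columns(), names(x))
  if (length(missing_cols) > 0) {
    stopf("trait table is missing required column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  for (col in intersect(numeric_trait_columns(), names(x))) {
    v <- x[[col]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(coerced))
      if (length(bad) > 0) {
        stopf("column '%s' is not numeric (first offending row: %d, value '%s')",
              col, bad[1], as.character(v[bad[1]]))
      }
      x[[col]] <- coerced
    }
  }
  x$species_id <- normalise_labels(as.character(x$species_id))
  if (anyDuplicated(x$species_id)) {
    stopf("duplicated species_id: %s",
          paste(unique(x$species_id[duplicated(x$species_id)]), collapse = ", "))
  }
  with_value <- !is.na(x$price_twd)
  if (any(x$price_twd[with_value] <= 0)) {
    stopf("price_twd must be positive (row %d)",
          which(with_value & x$price_twd <= 0)[1])
  }
  cov_cols <- grep("^colour_", names(x), value = TRUE)
  for (col in cov_cols) {
    v <- x[[col]]
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      stopf("colour coverage column '%s' has values outside [0, 1]", col)
    }
  }
  core <- setdiff(names(x), c("family", "order"))
  x$has_missing <- !complete.cases(x[core])
  attr(x, "source") <- source
  attr(x, "transform_log") <- character(0)
  class(x) <- c("trait_table", class(x))
  x
}

#' Drop listed species from a trait table
#'
#' Removes rows whose `species_id` matches `drop_ids` (after label
#' normalisation). Identifiers not present in the table produce a warning,
#' not an error, to tolerate taxonomy drift between data sources.
#'
#' @param table A `trait_table`.
#' @param drop_ids Character vector of species identifiers to remove; may be
#'   empty.
#' @return The filtered `trait_table`; the number of removals is reported.
#' @export
apply_exclusions <- function(table, drop_ids = character()) {
  drop_ids <- normalise_labels(as.character(drop_ids))
  if (length(drop_ids) == 0) return(table)
  absent <- setdiff(drop_ids, table$species_id)
  if (length(absent) > 0) {
    warn(sprintf("exclusion id(s) not present in table: %s",
                 paste(absent, collapse = ", ")))
  }
  keep <- !(table$species_id %in% drop_ids)
  out <- table[keep, , drop = FALSE]
  inform(sprintf("apply_exclusions: removed %d of %d rows (n = %d)",
                 sum(!keep), nrow(table), nrow(out)))
  out
}

#' Read a long-format colour score sheet from CSV
#'
#' Expected columns: `species_id`, `part`, `colour`, `present` (0/1), one row
#' per species x part x colour cell. Parts must be the 14 of
#' [body_part_names()] and colours the 11 of [colour_names()].
#'
#' @param path Path to a CSV file.
#' @return A tibble with one row per cell.
#' @export
read_colour_sheet <- function(path) {
  if (!file.exists(path)) stopf("colour sheet not found: %s", path)
  sheet <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("species_id", "part", "colour", "present")
  missing_cols <- setdiff(needed, names(sheet))
  if (length(missing_cols) > 0) {
    stopf("colour sheet is missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  sheet$species_id <- normalise_labels(as.character(sheet$species_id))
  sheet
}

validate_colour_sheet <- function(sheet) {
  parts <- body_part_names()
  cols <- colour_names()
  if (!all(sheet$present %in% c(0, 1))) {
    stopf("colour sheet 'present' must be 0 or 1")
  }
  bad_parts <- setdiff(unique(sheet$part), parts)
  if (length(bad_parts) > 0) {
    stopf("unknown body part(s): %s", paste(bad_parts, collapse = ", "))
  }
  bad_cols <- setdiff(unique(sheet$colour), cols)
  if (length(bad_cols) > 0) {
    stopf("unknown colour(s): %s", paste(bad_cols, collapse = ", "))
  }
  counts <- dplyr::count(sheet, .data$species_id, .data$part)
  by_sp <- dplyr::count(dplyr::distinct(sheet, .data$species_id, .data$part),
                        .data$species_id)
  if (any(by_sp$n != length(parts))) {
    stopf("each species must score exactly %d body parts (species '%s' has %d)",
          length(parts), by_sp$species_id[by_sp$n != length(parts)][1],
          by_sp$n[by_sp$n != length(parts)][1])
  }
  part_tot <- dplyr::summarise(
    dplyr::group_by(sheet, .data$species_id, .data$part),
    tot = sum(.data$present), .groups = "drop")
  if (any(part_tot$tot == 0)) {
    i <- which(part_tot$tot == 0)[1]
    stopf("every body part must carry at least one colour ('%s' / '%s' has none)",
          part_tot$species_id[i], part_tot$part[i])
  }
  invisible(sheet)
}

#' Colour coverage from a presence score sheet
#'
#' For each species and colour, coverage is the number of body parts on which
#' the colour is present divided by 14. A part may carry several colours, so
#' per-species coverages may sum to more than 1.
#'
#' @param sheet Long-format score sheet as returned by [read_colour_sheet()].
#' @return A tibble with `species_id` and one `colour_<name>` column per
#'   colour, values in \[0, 1\].
#' @export
colour_coverage <- function(sheet) {
  validate_colour_sheet(sheet)
  n_parts <- length(body_part_names())
  cov <- dplyr::summarise(
    dplyr::group_by(sheet, .data$species_id, .data$colour),
    coverage = sum(.data$present) / n_parts, .groups = "drop")
  wide <- tidyr::pivot_wider(cov, names_from = "colour",
                             values_from = "coverage", values_fill = 0,
                             names_prefix = "colour_")
  for (col in paste0("colour_", colour_names())) {
    if (!col %in% names(wide)) wide[[col]] <- 0
  }
  dplyr::select(wide, "species_id",
                dplyr::all_of(paste0("colour_", colour_names())))
}

#' Colour diversity of a species
#'
#' The number of distinct colours on a species, excluding colours that cover
#' less than 3% of the body (coverage below `threshold`).
#'
#' @param coverage A data frame with `colour_<name>` columns (as from
#'   [colour_coverage()]), or a numeric vector/matrix of coverages.
#' @param threshold Minimum coverage for a colour to count; default 0.03.
#' @return Integer count per row (a vector), 0 to 11.
#' @export
colour_diversity <- function(coverage, threshold = 0.03) {
  if (is.data.frame(coverage)) {
    cols <- grep("^colour_", names(coverage), value = TRUE)
    if (length(cols) == 0) stopf("no colour_* columns found")
    coverage <- as.matrix(coverage[cols])
  }
  if (is.vector(coverage)) coverage <- matrix(coverage, nrow = 1)
  if (any(coverage < 0 | coverage > 1, na.rm = TRUE)) {
    stopf("coverages must lie in [0, 1]")
  }
  as.integer(rowSums(coverage >= threshold, na.rm = TRUE))
}

#' Song attractiveness residuals
#'
#' Regresses ln(song recordings + 1) on ln(breeding range area) by ordinary
#' least squares across the supplied species and returns the residuals.
#' Species with more recordings than their range size predicts get positive
#' residuals; the count of public recordings, once range size is controlled
#' for, tracks how attractive a species' song is to recordists.
#'
#' @param song_count Non-negative recording counts.
#' @param range_km2 Positive breeding range areas (square kilometres).
#' @return Numeric residuals, one per species; they sum to zero.
#' @export
song_attractiveness <- function(song_count, range_km2) {
  if (length(song_count) != length(range_km2)) {
    stopf("song_count and range_km2 lengths differ")
  }
  if (any(song_count < 0, na.rm = TRUE)) stopf("song counts must be >= 0")
  if (any(range_km2 <= 0, na.rm = TRUE)) stopf("range areas must be > 0")
  lx <- log(range_km2)
  ly <- log1p(song_count)
  ok <- !is.na(lx) & !is.na(ly)
  if (diff(range(lx[ok])) < .Machine$double.eps^0.5) {
    stopf("all range areas identical: regression of songs on range is degenerate")
  }
  fit <- stats::lm(ly ~ lx, subset = ok)
  out <- rep(NA_real_, length(lx))
  out[ok] <- stats::residuals(fit)
  out
}

#' @rdname song_attractiveness
#' @param table A `trait_table` with `song_count` and `range_km2` columns.
#' @return For `add_song_attractiveness()`, the table with a
#'   `song_attractiveness` column appended.
#' @export
add_song_attractiveness <- function(table) {
  table$song_attractiveness <- song_attractiveness(table$song_count,
                                                   table$range_km2)
  table
}

#' Transform predictors for regression
#'
#' Applies the analysis transforms and appends the design-ready columns:
#' natural log of price (`log_price`, the response), body mass (`log_mass`),
#' number for sale (`log_n_for_sale`) and range area (`log_range`);
#' arcsine-square-root of every colour coverage proportion
#' (`asr_colour_<name>`); and encoded categorical predictors: `status` as a
#' factor with reference level "native", `cites_listed` as 0/1, `iucn` as a
#' 4-level factor with reference "LC" plus the binary recode `iucn_not_lc`
#' (0 = least concern, 1 = any threatened category) used in the multivariate
#' analysis, and `realm` as a factor with reference "Afrotropic". Species
#' counts for sale are at least 1 whenever a species was recorded, so a plain
#' log is used there; the +1 offset applies only to song counts inside
#' [song_attractiveness()].
#'
#' @param table A `trait_table`.
#' @return The table with transformed columns appended and the log-transform
#'   registry stored in `attr(, "transform_log")`.
#' @export
transform_predictors <- function(table) {
  cov_cols <- grep("^colour_", names(table), value = TRUE)
  for (col in cov_cols) {
    v <- table[[col]]
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      stopf("coverage column '%s' outside [0, 1]: cannot arcsine-transform", col)
    }
  }
  out <- dplyr::mutate(
    table,
    log_price = log(.data$price_twd),
    log_mass = log(.data$body_mass_g),
    log_n_for_sale = log(.data$n_for_sale),
    log_range = log(.data$range_km2))
  for (col in cov_cols) {
    out[[paste0("asr_", col)]] <- asin(sqrt(out[[col]]))
  }
  out$status <- factor(out$status, levels = c("native", "alien"))
  out$iucn <- factor(out$iucn, levels = c("LC", "NT", "VU", "EN"))
  out$iucn_not_lc <- as.integer(out$iucn != "LC")
  out$realm <- factor(out$realm,
                      levels = c("Afrotropic", "Australasia", "Indo-Malay",
                                 "Neotropic", "Palearctic", "none"))
  out$realm <- droplevels(out$realm)
  if (!"song_attractiveness" %in% names(out)) {
    out <- add_song_attractiveness(out)
  }
  attr(out, "transform_log") <- c(price_twd = "log_price",
                                  body_mass_g = "log_mass",
                                  n_for_sale = "log_n_for_sale",
                                  range_km2 = "log_range")
  out
}

#' Descriptive market tallies
#'
#' Totals and rankings of the market survey: total individuals for sale,
#' alien individuals and species, a per-species abundance ranking, the share
#' of individuals contributed by the `top_k` most abundant species, price
#' extrema in US dollars at a configurable exchange rate, and the total
#' displayed market value (sum of price times count).
#'
#' @param table A `trait_table`.
#' @param exchange_rate TWD per USD; default 30.
#' @param top_k Number of species in the top-abundance share; default 10.
#' @param grand_total Optional externally supplied total number of
#'   individuals (e.g. a published total when only the top species are
#'   tabulated); defaults to the column sum.
#' @return A list of class `market_tallies`.
#' @export
summary_tallies <- function(table, exchange_rate = 30, top_k = 10,
                            grand_total = NULL) {
  if (nrow(table) == 0) stopf("empty trait table: nothing to tally")
  n_total <- sum(table$n_for_sale, na.rm = TRUE)
  grand_total <- grand_total %||% n_total
  alien <- !is.na(table$status) & table$status == "alien"
  ranking <- dplyr::arrange(
    dplyr::select(tibble::as_tibble(table), "species_id", "n_for_sale",
                  "price_twd", "status"),
    dplyr::desc(.data$n_for_sale))
  top_k <- min(top_k, nrow(ranking))
  top_share <- sum(head(ranking$n_for_sale, top_k)) / grand_total
  value_twd <- sum(table$price_twd * table$n_for_sale, na.rm = TRUE)
  structure(list(
    n_species = nrow(table),
    total_individuals = n_total,
    grand_total = grand_total,
    alien_species = sum(alien),
    alien_individuals = sum(table$n_for_sale[alien], na.rm = TRUE),
    abundance_ranking = ranking,
    top_k = top_k,
    top_share = top_share,
    exchange_rate = exchange_rate,
    min_price_usd = min(table$price_twd, na.rm = TRUE) / exchange_rate,
    max_price_usd = max(table$price_twd, na.rm = TRUE) / exchange_rate,
    total_value_twd = value_twd,
    total_value_usd = value_twd / exchange_rate
  ), class = "market_tallies")
}

#' @export
print.market_tallies <- function(x, ...) {
  cat(sprintf("Market tallies: %d species, %d individuals for sale\n",
              x$n_species, x$total_individuals))
  cat(sprintf("  alien: %d species, %d individuals\n",
              x$alien_species, x$alien_individuals))
  cat(sprintf("  top %d species hold %.1f%% of individuals\n",
              x$top_k, 100 * x$top_share))
  cat(sprintf("  price range US$%.2f - US$%.2f (at %g TWD/USD)\n",
              x$min_price_usd, x$max_price_usd, x$exchange_rate))
  cat(sprintf("  displayed market value US$%.0f\n", x$total_value_usd))
  invisible(x)
}
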