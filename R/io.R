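#' Read field-survey input tables
#'
#' Readers for the four CSV schemas of a Type I resource-selection and
#' diet field study:
#'
#' * `quadrats.csv` — `site, quadrat_id, category, diameter1_m,
#'   diameter2_m`: one vegetation/substrate patch per row, with the two
#'   perpendicular crown diameters (metres) used by the crown-diameter
#'   coverage method. A row with an empty `category` declares a quadrat
#'   that was surveyed but contained no patches.
#' * `encounters.csv` — `site, quadrat_id, time_hhmm, microhabitat,
#'   activity`: one lizard observation; `activity` is `active` or
#'   `inactive`.
#' * `stomachs.csv` — `site, individual_id, sex, prey_category, count,
#'   dry_weight_g`: one prey category per individual per row; plant
#'   material rows carry a weight but no count.
#' * `pitfalls.csv` — `site, line_id, prey_category, count`: pitfall
#'   catches per trap line.
#'
#' Categories are checked against the closed vocabularies
#' ([microhabitat_categories()], [prey_categories()]) unless
#' `allow_new_categories = TRUE`.
#'
#' @param path Path to a CSV file.
#' @param categories Character vector of admissible categories.
#' @param allow_new_categories If `TRUE`, categories outside
#'   `categories` are accepted.
#' @param quadrat_area Quadrat area in square metres (default
#'   400, a 20 x 20 m quadrat), attached as the `quadrat_area`
#'   attribute.
#'
#' @return A tibble; `read_encounters()` adds a `time_h` column with
#'   the encounter time as decimal hours in \[0, 24).
#' @name readers
NULL

read_checked_csv <- function(path, col_types, required) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  header <- names(readr::read_csv(path, n_max = 0,
                                  col_types = readr::cols(.default = "c"),
                                  progress = FALSE))
  missing <- setdiff(required, header)
  if (length(missing) > 0) {
    abort(paste0("schema error in ", path, ": missing column(s) ",
                 paste(missing, collapse = ", ")))
  }
  readr::read_csv(path, col_types = col_types,
                  na = c("", "NA"), progress = FALSE)
}

check_categories <- function(x, vocabulary, allow_new, what) {
  bad <- setdiff(unique(x[!is.na(x)]), vocabulary)
  if (length(bad) > 0 && !allow_new) {
    abort(paste0("unknown ", what, " category: ",
                 paste(bad, collapse = ", "),
                 " (use allow_new_categories = TRUE to accept)"))
  }
  invisible(x)
}

#' @rdname readers
#' @export
read_quadrats <- function(path,
                          categories = microhabitat_categories(),
                          allow_new_categories = FALSE,
                          quadrat_area = 400) {
  x <- read_checked_csv(
    path,
    readr::cols(site = "c", quadrat_id = "c", category = "c",
                diameter1_m = "d", diameter2_m = "d"),
    c("site", "quadrat_id", "category", "diameter1_m", "diameter2_m")
  )
  check_categories(x$category, categories, allow_new_categories,
                   "microhabitat")
  bad <- which(x$diameter1_m < 0 | x$diameter2_m < 0)
  if (length(bad) > 0) {
    abort(paste0("negative diameter in row(s): ",
                 paste(bad, collapse = ", ")))
  }
  patch <- !is.na(x$category)
  if (any(patch & (is.na(x$diameter1_m) | is.na(x$diameter2_m)))) {
    abort("patch rows must have both diameters")
  }
  attr(x, "quadrat_area") <- quadrat_area
  x
}

parse_time_hhmm <- function(time_hhmm) {
  m <- regmatches(time_hhmm,
                  regexec("^([0-9]{1,2}):([0-9]{2})$", time_hhmm))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    abort(paste0("unparseable time(s): ",
                 paste(unique(time_hhmm[bad]), collapse = ", ")))
  }
  hh <- vapply(m, function(g) as.numeric(g[2]), 1)
  mm <- vapply(m, function(g) as.numeric(g[3]), 1)
  if (any(hh > 23 | mm > 59)) abort("time out of range [0:00, 23:59]")
  hh + mm / 60
}

#' @rdname readers
#' @export
read_encounters <- function(path,
                            categories = microhabitat_categories(),
                            allow_new_categories = FALSE) {
  x <- read_checked_csv(
    path,
    readr::cols(site = "c", quadrat_id = "c", time_hhmm = "c",
                microhabitat = "c", activity = "c"),
    c("site", "quadrat_id", "time_hhmm", "microhabitat", "activity")
  )
  check_categories(x$microhabitat, categories, allow_new_categories,
                   "microhabitat")
  bad <- setdiff(unique(x$activity), c("active", "inactive"))
  if (length(bad) > 0) {
    abort(paste0("activity must be active/inactive, got: ",
                 paste(bad, collapse = ", ")))
  }
  x$time_h <- parse_time_hhmm(x$time_hhmm)
  x
}

#' @rdname readers
#' @export
read_stomachs <- function(path,
                          categories = prey_categories(),
                          allow_new_categories = FALSE) {
  x <- read_checked_csv(
    path,
    readr::cols(site = "c", individual_id = "c", sex = "c",
                prey_category = "c", count = "d", dry_weight_g = "d"),
    c("site", "individual_id", "sex", "prey_category", "count",
      "dry_weight_g")
  )
  check_categories(x$prey_category, categories, allow_new_categories,
                   "prey")
  key <- paste(x$site, x$individual_id, x$prey_category, sep = "/")
  dup <- key[!is.na(x$prey_category)][duplicated(key[!is.na(x$prey_category)])]
  if (length(dup) > 0) {
    abort(paste0("duplicate (site, individual, prey) rows: ",
                 paste(unique(dup), collapse = "; ")))
  }
  plant <- !is.na(x$prey_category) & x$prey_category == "plant_material"
  if (any(plant & !is.na(x$count))) {
    abort("plant_material rows must have an empty count")
  }
  if (any(!plant & !is.na(x$prey_category) & is.na(x$count))) {
    abort("animal prey rows must have a count")
  }
  x
}

#' @rdname readers
#' @export
read_pitfalls <- function(path,
                          categories = prey_categories(),
                          allow_new_categories = FALSE) {
  x <- read_checked_csv(
    path,
    readr::cols(site = "c", line_id = "c", prey_category = "c",
                count = "d"),
    c("site", "line_id", "prey_category", "count")
  )
  check_categories(x$prey_category, categories, allow_new_categories,
                   "prey")
  if (any(x$count < 0 | x$count != round(x$count), na.rm = TRUE)) {
    abort("pitfall counts must be nonnegative integers")
  }
  x
}

#' Write display-rounded report tables
#'
#' Writes each table in `tables` as a TSV rounded for display
#' (percentages to `rounding$percentages` decimals, ratios and weights
#' to `rounding$ratios` decimals) alongside an `_unrounded` companion
#' file that retains machine precision, so display rounding can never
#' feed back into computation. Selection tables are laid out as
#' `category, available, used, wi, se, ci, p` with the confidence
#' interval rendered as `"lo-hi"` and p-values below the Bonferroni
#' level rendered as e.g. `"<0.007"`. Diet tables keep the standard
#' `n, pct_n, f, pct_f, w, pct_w, iri, pct_iri` column order.
#'
#' @param tables Named list of tibbles, typically produced by
#'   [selection_analysis()] and [diet_table()].
#' @param dir Output directory (created if needed).
#' @param rounding Named list with `percentages` and `ratios` decimal
#'   places.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(tables, dir,
                         rounding = list(percentages = 1, ratios = 3)) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    raw_path <- file.path(dir, paste0(nm, "_unrounded.tsv"))
    readr::write_tsv(tibble::as_tibble(tab), raw_path)
    disp <- format_report_table(tab, rounding)
    disp_path <- file.path(dir, paste0(nm, ".tsv"))
    readr::write_tsv(disp, disp_path)
    paths <- c(paths, disp_path, raw_path)
  }
  invisible(paths)
}

format_report_table <- function(tab, rounding) {
  pr <- rounding$percentages %||% 1
  rr <- rounding$ratios %||% 3
  if (inherits(tab, "selection_table")) {
    lev <- attr(tab, "bonferroni_level")
    p_disp <- ifelse(
      !is.na(tab$p) & !is.na(lev) & tab$p < lev,
      paste0("<", format(round(lev, rr), nsmall = rr)),
      format(round(tab$p, rr), nsmall = rr)
    )
    return(tibble::tibble(
      category = tab$category,
      available = round(tab$available, rr),
      used = round(tab$used, rr),
      wi = round(tab$wi, rr),
      se = round(tab$se, rr),
      ci = paste0(format(round(tab$ci_lo, rr), nsmall = rr), "-",
                  format(round(tab$ci_hi, rr), nsmall = rr)),
      p = p_disp
    ))
  }
  if (inherits(tab, "diet_table")) {
    return(tibble::tibble(
      prey_category = tab$prey_category,
      n = tab$n, pct_n = round(tab$pct_n, pr),
      f = tab$f, pct_f = round(tab$pct_f, pr),
      w = round(tab$w, 4), pct_w = round(tab$pct_w, pr),
      iri = round(tab$iri, pr), pct_iri = round(tab$pct_iri, pr),
      hierarchy = tab$hierarchy
    ))
  }
  # generic: round numeric columns to the ratio profile
  dplyr::mutate(tibble::as_tibble(tab),
                dplyr::across(dplyr::where(is.numeric), ~ round(.x, rr)))
}
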