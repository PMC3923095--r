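# Tabular input/output, schema validation, ICD-10 stay selection and the
# log-log correlation comparison used to choose between selection algorithms.

# ---- schemas -----------------------------------------------------------

hli_schemas <- function() {
  list(
    strata_counts = list(
      cols = c("hospital_id", "sex", "age_cat", "year", "hli_count",
               "stay_count"),
      key = c("hospital_id", "sex", "age_cat", "year"),
      counts = c("hli_count", "stay_count"),
      complete_grid = FALSE),
    strata_stays = list(
      cols = c("hospital_id", "sex", "age_cat", "year", "stay_count"),
      key = c("hospital_id", "sex", "age_cat", "year"),
      counts = "stay_count",
      complete_grid = FALSE),
    national_stays = list(
      cols = c("sex", "age_cat", "year", "national_stay_count"),
      key = c("sex", "age_cat", "year"),
      counts = "national_stay_count",
      complete_grid = TRUE),
    population = list(
      cols = c("sex", "age_cat", "year", "population"),
      key = c("sex", "age_cat", "year"),
      counts = character(),
      complete_grid = TRUE),
    standard_weights = list(
      cols = c("age_cat", "weight"),
      key = "age_cat",
      counts = character(),
      complete_grid = FALSE)
  )
}

#' Validate a table against one of the canonical schemas
#'
#' Checks column presence, value ranges, key uniqueness and (for national
#' stay and population tables) grid completeness, then tags the data frame
#' with its schema.  All reading functions and the simulator funnel their
#' outputs through this validator, so any table carrying an `hli_schema`
#' attribute satisfies the corresponding invariants.
#'
#' @param x A data frame.
#' @param schema One of `"strata_counts"`, `"strata_stays"`,
#'   `"national_stays"`, `"population"`, `"standard_weights"`.
#' @return The validated data frame (canonical column order) with
#'   attribute `hli_schema`.
#' @export
as_hli_table <- function(x, schema) {
  schemas <- hli_schemas()
  if (!schema %in% names(schemas))
    hli_error(sprintf("unknown schema '%s'", schema), "hli_schema_error")
  sc <- schemas[[schema]]
  x <- as.data.frame(x)

  missing_cols <- setdiff(sc$cols, names(x))
  extra_cols <- setdiff(names(x), sc$cols)
  if (length(missing_cols) || length(extra_cols))
    hli_error(sprintf(
      "schema '%s': missing columns [%s], unexpected columns [%s]",
      schema, paste(missing_cols, collapse = ", "),
      paste(extra_cols, collapse = ", ")), "hli_schema_error")
  x <- x[sc$cols]

  if ("sex" %in% sc$cols && !all(x$sex %in% c(1L, 2L)))
    hli_error("sex must be coded 1 (men) or 2 (women)",
              "hli_validation_error")
  if ("age_cat" %in% sc$cols && !all(x$age_cat %in% 1:15))
    hli_error("age_cat must be an integer in 1..15", "hli_validation_error")
  for (cc in sc$counts) {
    v <- x[[cc]]
    if (!is.numeric(v) || any(is.na(v)) || any(v < 0) ||
        any(v != round(v)))
      hli_error(sprintf("column '%s' must hold non-negative integers", cc),
                "hli_validation_error")
    x[[cc]] <- as.integer(round(v))
  }
  if ("population" %in% sc$cols &&
      (any(is.na(x$population)) || any(x$population <= 0)))
    hli_error("population must be strictly positive", "hli_validation_error")
  if ("weight" %in% sc$cols) {
    if (any(is.na(x$weight)) || any(x$weight <= 0))
      hli_error("weights must be strictly positive", "hli_validation_error")
    if (!setequal(x$age_cat, 1:15))
      hli_error("standard weights must cover age categories 1..15",
                "hli_validation_error")
    if (abs(sum(x$weight) - 1) > 1e-6)
      hli_error("standard weights must sum to 1", "hli_validation_error")
  }

  if (anyDuplicated(x[sc$key]))
    hli_error(sprintf("duplicate (%s) keys", paste(sc$key, collapse = ", ")),
              "hli_integrity_error")

  if (isTRUE(sc$complete_grid)) {
    years <- sort(unique(x$year))
    need <- 2L * 15L * length(years)
    if (nrow(x) != need)
      hli_error(sprintf(
        "schema '%s' requires the complete 2 sex x 15 age x %d year grid (%d rows, got %d)",
        schema, length(years), need, nrow(x)), "hli_integrity_error")
  }

  ord <- do.call(order, x[sc$key])
  x <- x[ord, , drop = FALSE]
  rownames(x) <- NULL
  attr(x, "hli_schema") <- schema
  x
}

#' Read a canonical CSV table
#'
#' @param path Path to a UTF-8 CSV file with a header matching the schema.
#' @param schema Schema name, see [as_hli_table()].
#' @return Validated table.
#' @export
#' @examples
#' w <- european_standard_weights()
#' f <- tempfile(fileext = ".csv")
#' write_hli_table(w, f)
#' identical(read_hli_table(f, "standard_weights")$weight, w$weight)
read_hli_table <- function(path, schema) {
  if (!file.exists(path))
    hli_error(sprintf("file not found: %s", path), "hli_io_error")
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_hli_table(x, schema)
}

#' Write a canonical CSV table
#'
#' Writes in canonical column order without quoting, so that
#' `write_hli_table(read_hli_table(path, s), path2)` reproduces the file
#' byte for byte.
#'
#' @param x A validated table (or a data frame matching a schema).
#' @param path Output path.
#' @param schema Schema to validate against; defaults to the table's own
#'   `hli_schema` attribute.
#' @return Invisibly, `path`.
#' @export
write_hli_table <- function(x, path, schema = attr(x, "hli_schema")) {
  if (is.null(schema))
    hli_error("no schema given and the table carries none", "hli_schema_error")
  x <- as_hli_table(x, schema)
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- bundled reference data -------------------------------------------

#' European Standard Population weights, truncated to ages 15 and over
#'
#' Five-year-band weights of the 1976 European Standard Population for the
#' bands 15-19, ..., 80-84, 85+, renormalized to sum to one over this
#' truncated age range.  Used for direct age standardization of incidence
#' rates in the adult population.
#'
#' @return A `standard_weights` table with columns `age_cat` (1..15) and
#'   `weight`.
#' @export
european_standard_weights <- function() {
  esp <- c(7000, 7000, 7000, 7000, 7000, 7000, 7000, 7000,
           6000, 5000, 4000, 3000, 2000, 1000, 1000)
  as_hli_table(
    data.frame(age_cat = 1:15, weight = esp / sum(esp)),
    "standard_weights")
}

# ---- ICD-10 selection algorithms --------------------------------------

#' ICD-10 three-character blocks defining the injury-stay selection
#' algorithms
#'
#' Algorithm 1 selects hospital stays with any diagnosis code (principal
#' or associated) in ICD-10 chapter 19, "injury, poisoning and certain
#' other consequences of external causes" (S00-T98).  Algorithm 2 extends
#' algorithm 1 with blocks for disorders strongly related to injuries:
#' eyes (H05, H16, H26, H27, H40), ears (H72), respiratory conditions
#' (J68-J70) and skin (L55-L59).  Membership of a full code is decided by
#' its three-character prefix after stripping the dot, so subdivisions are
#' included.
#'
#' @param algorithm 1 or 2.
#' @return Character vector of three-character blocks.
#' @export
icd10_code_set <- function(algorithm = 1) {
  alg1 <- c(sprintf("S%02d", 0:99), sprintf("T%02d", 0:98))
  extra <- c("H05", "H16", "H26", "H27", "H40", "H72",
             sprintf("J%02d", 68:70), sprintf("L%02d", 55:59))
  if (!length(algorithm) == 1 || !algorithm %in% c(1, 2))
    hli_error("algorithm must be 1 or 2", "hli_validation_error")
  if (algorithm == 1) alg1 else c(alg1, extra)
}

icd10_normalize <- function(codes) {
  up <- toupper(gsub(".", "", codes, fixed = TRUE))
  bad <- !grepl("^[A-Z][0-9]{2,}$", up)
  if (any(bad))
    hli_error(sprintf("malformed ICD-10 code(s): %s",
                      paste(unique(codes[bad]), collapse = ", ")),
              "hli_validation_error")
  up
}

age_to_band <- function(age) {
  pmin(15L, as.integer(floor((age - 15) / 5)) + 1L)
}

#' Select injury-related hospital stays and aggregate them into strata
#'
#' A stay is selected if any of its diagnosis codes (principal or
#' associated) falls in the chosen algorithm's ICD-10 code set; each stay
#' is counted once however many codes match.  Patients younger than 15
#' are excluded.  Selected stays are aggregated by hospital, sex,
#' five-year age band (85+ top band) and year; cells with no selected
#' stay are reported as zero for every hospital-year present in the
#' input.
#'
#' @param records Data frame of stays with columns `hospital_id`, `sex`,
#'   `age` (years), `year` and `diagnosis_codes`, a list column of ICD-10
#'   codes whose first element is the principal diagnosis.
#' @param algorithm 1 (chapter 19 only) or 2 (extended selection).
#' @return A `strata_stays` table.
#' @export
select_injury_stays <- function(records, algorithm = 1) {
  need <- c("hospital_id", "sex", "age", "year", "diagnosis_codes")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    hli_error(sprintf("records lack column(s): %s",
                      paste(missing_cols, collapse = ", ")),
              "hli_schema_error")
  if (any(lengths(records$diagnosis_codes) == 0))
    hli_error("every stay needs at least one diagnosis code",
              "hli_validation_error")
  if (any(records$age < 0))
    hli_error("age must be non-negative", "hli_validation_error")
  set <- icd10_code_set(algorithm)
  codes <- lapply(records$diagnosis_codes, icd10_normalize)
  hit <- vapply(codes, function(cs) any(substr(cs, 1, 3) %in% set),
                logical(1))
  keep <- hit & records$age >= 15

  grid <- merge(
    merge(unique(records[c("hospital_id", "year")]),
          data.frame(sex = 1:2)),
    data.frame(age_cat = 1:15))
  sel <- records[keep, c("hospital_id", "sex", "year"), drop = FALSE]
  if (nrow(sel)) {
    sel$age_cat <- age_to_band(records$age[keep])
    agg <- stats::aggregate(
      list(stay_count = rep(1L, nrow(sel))),
      by = sel[c("hospital_id", "sex", "age_cat", "year")], FUN = sum)
  } else {
    agg <- cbind(grid[0, ], stay_count = integer(0))
  }
  out <- merge(grid, agg,
               by = c("hospital_id", "sex", "age_cat", "year"),
               all.x = TRUE)
  out$stay_count[is.na(out$stay_count)] <- 0L
  as_hli_table(out, "strata_stays")
}

#' Compare stay-selection algorithms by log-log correlation with HLI
#' counts
#'
#' For each candidate algorithm, the observed HLI counts and the selected
#' stay counts are paired over hospital x sex x age x year cells and the
#' Pearson correlation of their logarithms is computed (log scaling
#' stabilizes the variance of Poisson counts).  Cells with a zero in
#' either count are dropped.  The algorithm with the largest correlation
#' is selected; ties go to the smaller (more restrictive) algorithm.
#'
#' @param hli A `strata_counts` table with the ED-recorded HLI counts.
#' @param stays_by_algorithm Named list (names "1", "2", ...) of
#'   `strata_stays` tables, one per algorithm.
#' @return A list with `correlations` (named numeric vector) and
#'   `selected` (integer algorithm id).
#' @export
compare_selection_algorithms <- function(hli, stays_by_algorithm) {
  hli <- as_hli_table(hli, "strata_counts")
  if (!is.list(stays_by_algorithm) || is.null(names(stays_by_algorithm)))
    hli_error("stays_by_algorithm must be a named list of stay tables",
              "hli_validation_error")
  key <- c("hospital_id", "sex", "age_cat", "year")
  cors <- vapply(stays_by_algorithm, function(st) {
    st <- as_hli_table(st, "strata_stays")
    m <- merge(hli[c(key, "hli_count")], st, by = key)
    ok <- m$hli_count > 0 & m$stay_count > 0
    if (sum(ok) < 3)
      hli_error("fewer than 3 non-zero paired cells",
                "hli_insufficient_data_error")
    stats::cor(log(m$hli_count[ok]), log(m$stay_count[ok]))
  }, numeric(1))
  algs <- as.integer(names(cors))
  selected <- min(algs[cors == max(cors)])
  list(correlations = cors, selected = selected)
}
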