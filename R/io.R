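#' Construct a cohort object
#'
#' A cohort holds one row per patient (`patient_id`, `age`, `region`,
#' optional `tige`, and one numeric sIgE column per panel molecule, kU/L)
#' plus the ordered molecule panel. The constructor enforces the invariants
#' that ingest relies on: unique patient ids, complete and non-negative
#' sIgE values, plausible ages.
#'
#' @param data A data.frame with columns `patient_id`, `age`, `region`,
#'   optionally `tige`, and one column per panel molecule.
#' @param panel Ordered character vector of molecule names
#'   (default [hdm_panel()]).
#' @return An object of class `hdm_cohort`: the data.frame with attributes
#'   `panel` (molecule order) and `region_set` (regions present).
#' @export
new_cohort <- function(data, panel = hdm_panel()) {
  validate_panel(panel)
  stopifnot(is.data.frame(data))
  required <- c("patient_id", "age", "region")
  missing_req <- setdiff(c(required, panel), names(data))
  if (length(missing_req) > 0L)
    stop("missing required column(s): ", paste(missing_req, collapse = ", "),
         call. = FALSE)

  data$patient_id <- as.character(data$patient_id)
  data$region <- as.character(data$region)
  dup <- data$patient_id[duplicated(data$patient_id)]
  if (length(dup) > 0L)
    stop("duplicate patient_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)

  if (anyNA(data$age) || any(!is.finite(data$age)))
    stop("age must be a finite number for every patient", call. = FALSE)
  if (any(data$age < 0))
    stop("negative age for patient_id: ",
         paste(data$patient_id[data$age < 0], collapse = ", "), call. = FALSE)
  if (any(data$age >= 150))
    stop("implausible age (>= 150) for patient_id: ",
         paste(data$patient_id[data$age >= 150], collapse = ", "),
         call. = FALSE)

  for (mol in panel) {
    v <- data[[mol]]
    if (!is.numeric(v)) stop("column '", mol, "' is not numeric", call. = FALSE)
    bad <- !is.finite(v) | v < 0
    if (any(bad))
      stop("invalid sIgE value in column '", mol, "' for patient_id: ",
           paste(data$patient_id[bad], collapse = ", "), call. = FALSE)
  }
  if (!is.null(data$tige)) {
    bad <- !is.na(data$tige) & (!is.finite(data$tige) | data$tige < 0)
    if (any(bad))
      stop("invalid tIgE value for patient_id: ",
           paste(data$patient_id[bad], collapse = ", "), call. = FALSE)
  }

  structure(data,
            panel = panel,
            region_set = sort(unique(data$region)),
            class = c("hdm_cohort", "data.frame"))
}

#' @export
print.hdm_cohort <- function(x, ...) {
  cat("<hdm_cohort> ", nrow(x), " patients, ",
      length(attr(x, "panel")), " panel molecules, ",
      length(attr(x, "region_set")), " regions\n", sep = "")
  utils::str(as.data.frame(utils::head(x, 3L)))
  invisible(x)
}

#' Molecule panel of a cohort
#' @param cohort An `hdm_cohort`.
#' @return Character vector of molecule names in canonical order.
#' @export
cohort_panel <- function(cohort) attr(cohort, "panel")

#' Regions present in a cohort
#' @param cohort An `hdm_cohort`.
#' @return Sorted character vector of region labels.
#' @export
cohort_regions <- function(cohort) attr(cohort, "region_set")

# parse a character vector as decimal reals; decimal commas are rejected
# (they are ambiguous with CSV field separators) unless decimal_comma = TRUE
.parse_numeric <- function(x, decimal_comma = FALSE) {
  x <- trimws(x)
  if (decimal_comma) x <- gsub(",", ".", x, fixed = TRUE)
  out <- suppressWarnings(as.numeric(x))
  out[!nzchar(x)] <- NA_real_
  attr(out, "unparseable") <- nzchar(x) & is.na(out)
  out
}

#' Read a multiplex sIgE cohort table
#'
#' Reads a delimited patient table (one row per patient) and validates it
#' into an [new_cohort()] object. The header must contain `patient_id`,
#' `age`, `region`, and one column per panel molecule (exact, case-sensitive
#' names); a `tige` column is optional. Rows are never silently dropped:
#' any malformed cell raises an error naming the patient and column.
#' Missing sIgE cells are rejected, not imputed, so prevalence denominators
#' always reflect complete panels.
#'
#' @param path Path to the CSV/TSV file.
#' @param panel Ordered molecule panel (default [hdm_panel()]).
#' @param dialect `"comma"` or `"tab"`; default guesses from the file
#'   extension (`.tsv`/`.tab` means tab, anything else comma).
#' @param decimal_comma If `TRUE`, accept a decimal comma (`"26,57"`) in
#'   numeric cells. Off by default because it is ambiguous with the CSV
#'   field separator.
#' @return An `hdm_cohort`; row order preserved from the file.
#' @export
read_cohort <- function(path, panel = hdm_panel(),
                        dialect = c("auto", "comma", "tab"),
                        decimal_comma = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "auto")
    dialect <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE))
      "tab" else "comma"
  sep <- if (dialect == "tab") "\t" else ","

  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "", fill = FALSE,
                           stringsAsFactors = FALSE)
  required <- c("patient_id", "age", "region", panel)
  missing_req <- setdiff(required, names(raw))
  if (length(missing_req) > 0L)
    stop("input lacks required column(s): ",
         paste(missing_req, collapse = ", "), call. = FALSE)

  out <- data.frame(patient_id = raw$patient_id,
                    region = raw$region,
                    stringsAsFactors = FALSE)

  age <- .parse_numeric(raw$age, decimal_comma)
  if (any(attr(age, "unparseable")))
    stop("non-numeric age for patient_id: ",
         paste(raw$patient_id[attr(age, "unparseable")], collapse = ", "),
         call. = FALSE)
  out$age <- as.numeric(age)

  if ("tige" %in% names(raw)) {
    tige <- .parse_numeric(raw$tige, decimal_comma)
    if (any(attr(tige, "unparseable")))
      stop("non-numeric tIgE for patient_id: ",
           paste(raw$patient_id[attr(tige, "unparseable")], collapse = ", "),
           call. = FALSE)
    out$tige <- as.numeric(tige)
  }

  for (mol in panel) {
    v <- .parse_numeric(raw[[mol]], decimal_comma)
    bad <- attr(v, "unparseable") | is.na(v)
    if (any(bad))
      stop("missing or non-numeric sIgE in column '", mol,
           "' for patient_id: ",
           paste(raw$patient_id[bad], collapse = ", "), call. = FALSE)
    if (any(v < 0))
      stop("negative sIgE in column '", mol, "' for patient_id: ",
           paste(raw$patient_id[v < 0], collapse = ", "), call. = FALSE)
    out[[mol]] <- as.numeric(v)
  }

  new_cohort(out, panel)
}

#' Write a delimited result table
#'
#' Serializes a data.frame to CSV or TSV with a fixed, documented numeric
#' precision so that write/read round-trips are exact at that precision.
#' Character fields (e.g. region labels with spaces) are preserved verbatim
#' via quoting when the dialect requires it.
#'
#' @param rows A data.frame (may have zero rows; the header is still
#'   written).
#' @param path Output file path.
#' @param dialect `"comma"` or `"tab"` (default).
#' @param digits Decimal places used for non-integer numeric columns
#'   (default 4).
#' @return Invisibly, the path written.
#' @export
write_table <- function(rows, path, dialect = c("tab", "comma"), digits = 4) {
  dialect <- match.arg(dialect)
  stopifnot(is.data.frame(rows))
  sep <- if (dialect == "tab") "\t" else ","
  fmt <- rows
  for (nm in names(fmt)) {
    v <- fmt[[nm]]
    if (is.numeric(v) && !is.integer(v)) {
      formatted <- formatC(v, format = "f", digits = digits)
      formatted[is.na(v)] <- NA_character_
      fmt[[nm]] <- formatted
    }
  }
  ok <- tryCatch({
    utils::write.table(fmt, file = path, sep = sep, quote = TRUE,
                       row.names = FALSE, col.names = TRUE, na = "")
    TRUE
  }, error = function(e) {
    stop("cannot write table to '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(path)
}
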