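# Canonical column names understood by the loader. `haz`, `weight`,
# `division`, `district` are mandatory; the rest feed apply_standard_codings()
# or pass through untouched.
.canonical_columns <- c(
  "haz", "weight", "division", "district", "cluster_id",
  "age_months", "sex", "mother_edu_years", "father_edu_years",
  "mother_bmi_kgm2", "mother_height_cm", "mother_age_at_birth_years",
  "delivery_place_code", "wealth_index", "wealth_index_ru",
  "residence_code", "other_under5_count"
)

#' Load a children's-recode-style table from delimited text
#'
#' Reads one row per child from a CSV or TSV extract, renames columns to the
#' package's canonical names via `column_map`, and applies the structural
#' filters: children older than 59 months are excluded, records with a
#' non-positive or missing sampling weight are rejected (with a reported
#' count), and records with a missing height-for-age z-score are retained
#' but flagged missing so that downstream complete-case selection can see
#' them.
#'
#' @param path Path to the delimited file (header row required, UTF-8,
#'   `.` decimal separator).
#' @param column_map Named character vector mapping canonical names (see
#'   Details) to the file's column names, e.g.
#'   `c(haz = "hw70", weight = "v005", ...)`. Defaults to the identity map
#'   over canonical columns found in the file. Must cover `haz`, `weight`,
#'   `division` and `district`.
#' @param dialect `"csv"` or `"tsv"`.
#' @param missing String used as the missing-value marker in the file
#'   (default: empty string).
#' @param survey_label Optional survey label stored on the dataset.
#'
#' @details Canonical column names: `haz`, `weight`, `division`, `district`,
#'   `cluster_id`, `age_months`, `sex`, `mother_edu_years`,
#'   `father_edu_years`, `mother_bmi_kgm2`, `mother_height_cm`,
#'   `mother_age_at_birth_years`, `delivery_place_code`, `wealth_index`,
#'   `wealth_index_ru`, `residence_code`, `other_under5_count`. Columns in
#'   the file whose (mapped) name matches an already-coded analysis variable
#'   (e.g. `residence` holding `"urban"`/`"rural"`) pass through and are
#'   validated by [apply_standard_codings()].
#'
#' @return A [coded_dataset()] (codebook filled in once
#'   [apply_standard_codings()] is applied).
#' @export
load_children_table <- function(path, column_map = NULL,
                                dialect = c("csv", "tsv"),
                                missing = "", survey_label = NA_character_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (dialect == "csv") "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           na.strings = missing, stringsAsFactors = FALSE,
                           check.names = FALSE, quote = "\"",
                           encoding = "UTF-8")
  n_in <- nrow(raw)

  if (is.null(column_map)) {
    present <- intersect(union(.canonical_columns, .derived_variable_names()),
                         names(raw))
    column_map <- stats::setNames(present, present)
  }
  for (col in c("haz", "weight", "division", "district")) {
    if (!col %in% names(column_map)) {
      stop("column_map must cover mandatory column '", col, "'", call. = FALSE)
    }
  }
  absent <- setdiff(unname(column_map), names(raw))
  if (length(absent) > 0L) {
    stop("mandatory column(s) not found in file: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }

  d <- raw[, unname(column_map), drop = FALSE]
  names(d) <- names(column_map)
  d$haz <- as.numeric(d$haz)
  d$weight <- as.numeric(d$weight)
  d$division <- as.character(d$division)
  d$district <- as.character(d$district)

  bad_w <- is.na(d$weight) | d$weight <= 0
  if (any(bad_w)) {
    message(sprintf("load_children_table: rejected %d record(s) with non-positive or missing weight",
                    sum(bad_w)))
    d <- d[!bad_w, , drop = FALSE]
  }
  if ("age_months" %in% names(d)) {
    over <- !is.na(d$age_months) & (d$age_months < 0 | d$age_months > 59)
    if (any(over)) {
      message(sprintf("load_children_table: excluded %d record(s) outside 0-59 months",
                      sum(over)))
      d <- d[!over, , drop = FALSE]
    }
  }
  n_miss_haz <- sum(is.na(d$haz))
  message(sprintf("load_children_table: read %d row(s), kept %d record(s) (%d with missing HAZ)",
                  n_in, nrow(d), n_miss_haz))
  if (nrow(d) == 0L) stop("no records remain after loading filters", call. = FALSE)
  coded_dataset(d, codebook = list(), survey_label = survey_label)
}

#' Write a coded dataset back to delimited text
#'
#' Numeric columns are written with 17 significant digits so that a
#' write/reload cycle reproduces every value exactly, and
#' reload-then-rewrite is byte-identical.
#'
#' @param ds A `coded_dataset`.
#' @param path Output path.
#' @param dialect `"csv"` or `"tsv"`.
#' @param missing Missing-value marker to write (default empty string).
#' @return `path`, invisibly.
#' @export
write_children_table <- function(ds, path, dialect = c("csv", "tsv"),
                                 missing = "") {
  dialect <- match.arg(dialect)
  stopifnot(inherits(ds, "coded_dataset"))
  sep <- if (dialect == "csv") "," else "\t"
  d <- as.data.frame(ds$data)
  for (col in names(d)) {
    if (is.numeric(d[[col]])) {
      txt <- sprintf("%.17g", d[[col]])
      txt[is.na(d[[col]])] <- NA_character_
      d[[col]] <- txt
    }
  }
  utils::write.table(d, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = missing, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a codebook to YAML
#' @param ds A `coded_dataset` with a non-empty codebook.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_codebook <- function(ds, path) {
  stopifnot(inherits(ds, "coded_dataset"))
  entries <- lapply(ds$codebook, function(vs) {
    list(name = vs$name, kind = vs$kind,
         categories = as.list(vs$categories),
         source_column = if (is.na(vs$source_column)) NULL else vs$source_column,
         coding_rule = if (is.na(vs$coding_rule)) NULL else vs$coding_rule)
  })
  yaml::write_yaml(list(variables = entries), path)
  invisible(path)
}

#' Read a codebook from YAML
#' @param path Path to a YAML codebook written by [write_codebook()].
#' @return A list of [variable_spec()] objects.
#' @export
read_codebook <- function(path) {
  y <- yaml::read_yaml(path)
  lapply(y$variables, function(e) {
    variable_spec(
      name = e$name,
      categories = unlist(e$categories),
      kind = if (is.null(e$kind)) "categorical" else e$kind,
      source_column = if (is.null(e$source_column)) NA_character_ else e$source_column,
      coding_rule = if (is.null(e$coding_rule)) NA_character_ else e$coding_rule
    )
  })
}
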