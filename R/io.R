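# Tab-separated interchange schemas shared by the analysis stages, plus
# config reading and a run manifest. All files are UTF-8 TSV with header,
# '.' decimal separator, times in seconds, money in integer JPY.

schema_check <- function(df, numeric_cols, required, what, file) {
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(what, " file ", file, " is missing columns: ",
         paste(miss, collapse = ", "))
  for (col in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop(what, " file ", file, ": non-numeric value in column '", col,
           "', row ", bad[1], " ('", df[[col]][bad[1]], "')")
    if (anyNA(v))
      stop(what, " file ", file, ": missing value in column '", col,
           "', row ", which(is.na(v))[1])
    df[[col]] <- v
  }
  df
}

#' Read and validate a choices table
#'
#' Schema: `trial_id`, `condition`, `a_low`, `a_mid`, `a_high`, `b_low`,
#' `b_mid`, `b_high`, `choice` (`a`/`b`), `rt_s`; optional `subject_id`.
#' Violations are reported with the offending row and column.
#'
#' @param path TSV file path.
#' @return Validated data frame.
#' @export
read_choices <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df <- schema_check(df,
                     c("a_low", "a_mid", "a_high", "b_low", "b_mid",
                       "b_high", "rt_s"),
                     c("trial_id", "condition", "a_low", "a_mid", "a_high",
                       "b_low", "b_mid", "b_high", "choice", "rt_s"),
                     "choices", path)
  bad <- which(!df$choice %in% c("a", "b"))
  if (length(bad))
    stop("choices file ", path, ": choice must be 'a' or 'b' (row ",
         bad[1], ")")
  if (any(df$rt_s <= 0))
    stop("choices file ", path, ": non-positive rt_s (row ",
         which(df$rt_s <= 0)[1], ")")
  df
}

#' Read and validate a view-events table
#'
#' Schema: `trial_id`, `condition`, `option`, `cell`, `onset_s`,
#' `offset_s`, `layout`; optional `subject_id`. Views with non-positive
#' duration are rejected.
#'
#' @param path TSV file path.
#' @return Validated data frame.
#' @export
read_views <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df <- schema_check(df, c("onset_s", "offset_s"),
                     c("trial_id", "option", "cell", "onset_s", "offset_s",
                       "layout"), "views", path)
  if (any(df$offset_s <= df$onset_s))
    stop("views file ", path, ": offset_s <= onset_s (row ",
         which(df$offset_s <= df$onset_s)[1], ")")
  df
}

#' Read and validate a gaze-samples table
#'
#' Schema: `trial_id`, `t_s`, `x_deg`, `y_deg`, `valid`; optional
#' `subject_id`.
#'
#' @param path TSV file path.
#' @return Validated data frame.
#' @export
read_gaze <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  schema_check(df, c("t_s", "x_deg", "y_deg"),
               c("trial_id", "t_s", "x_deg", "y_deg", "valid"),
               "gaze", path)
}

#' Write a table in the package's TSV dialect
#'
#' @param df Data frame.
#' @param path Output path (directories created as needed).
#' @export
write_tsv <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline/fit configuration from JSON or YAML
#'
#' @param path File ending in `.json`, `.yaml` or `.yml`.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else stop("config must be .json or .yaml/.yml: ", path)
}

#' Write a run manifest
#'
#' Records the seed and every emitted file so a stage's outputs are
#' reproducible and auditable.
#'
#' @param dir Output directory.
#' @param seed Integer seed used for the run.
#' @param files Character vector of emitted file paths.
#' @param extra Optional named list of additional fields.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, seed, files, extra = list()) {
  man <- c(list(seed = seed, files = as.character(files),
                package_version = as.character(utils::packageVersion("proxyrisk")),
                written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
           extra)
  path <- file.path(dir, "manifest.json")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
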