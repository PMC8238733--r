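## CSV contracts. All times are seconds; rates are pecks per 0.5-s bin;
## bin_index is 0-based over [0, 135 s) with half-open bins
## [i * 0.5, (i + 1) * 0.5).

schema_birds <- c(bird_id = "character", sex = "character",
                  family_id = "character", amount = "character",
                  effort = "character")
schema_rasters <- c(bird_id = "character", trial_id = "numeric",
                    day = "numeric", key = "character",
                    bin_index = "numeric", count = "numeric")
schema_choices <- c(bird_id = "character", n_choice_trials = "numeric",
                    n_ss_choices = "numeric", proportion_ss = "numeric")
schema_imprecision <- c(bird_id = "character", alpha_hat = "numeric",
                        beta_hat = "numeric", alpha_truncated = "numeric")

validate_schema <- function(df, schema, file) {
  missing <- setdiff(names(schema), names(df))
  if (length(missing)) {
    abort(sprintf("%s: missing column(s) %s.", file,
                  paste(missing, collapse = ", ")))
  }
  for (col in names(schema)) {
    ok <- switch(schema[[col]],
                 character = is.character(df[[col]]) || is.factor(df[[col]]),
                 numeric = is.numeric(df[[col]]))
    if (!ok) {
      abort(sprintf("%s: column `%s` must be %s.", file, col, schema[[col]]))
    }
    bad <- which(is.na(df[[col]]))
    if (length(bad)) {
      abort(sprintf("%s: column `%s` has a missing value at row %d.",
                    file, col, bad[1]))
    }
  }
  invisible(df)
}

read_contract <- function(path, schema) {
  if (!file.exists(path)) abort(sprintf("Input file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_schema(df, schema, basename(path))
  df
}

#' Read and write the pipeline's CSV contracts
#'
#' Plain-CSV readers and writers for the four tabular interfaces of the
#' pipeline (bird metadata, long-format probe rasters, choice summaries and
#' imprecision estimates). Readers validate the schema on load and fail
#' naming the file and offending column.
#'
#' @param path CSV file path.
#' @param data Tibble to write.
#' @return Readers return validated tibbles; writers return `path`
#'   invisibly.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_birds <- function(path) read_contract(path, schema_birds)

#' @rdname pipeline_io
#' @export
read_rasters <- function(path) {
  df <- read_contract(path, schema_rasters)
  if (any(df$count < 0)) abort(sprintf("%s: negative counts.", basename(path)))
  df
}

#' @rdname pipeline_io
#' @export
read_choices <- function(path) {
  df <- read_contract(path, schema_choices)
  if (any(df$proportion_ss < 0 | df$proportion_ss > 1)) {
    abort(sprintf("%s: proportion_ss outside [0, 1].", basename(path)))
  }
  df
}

#' @rdname pipeline_io
#' @export
read_imprecision <- function(path) read_contract(path, schema_imprecision)

write_contract <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
write_birds <- function(data, path) write_contract(data, path)

#' @rdname pipeline_io
#' @export
write_rasters <- function(data, path) write_contract(data, path)

#' @rdname pipeline_io
#' @export
write_choices <- function(data, path) write_contract(data, path)

#' @rdname pipeline_io
#' @export
write_imprecision <- function(data, path) write_contract(data, path)
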