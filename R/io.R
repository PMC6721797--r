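#' Read a YAML or JSON configuration file
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return a named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path),
          class = "sequestr_validation_error")
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

read_csv_checked <- function(path, required_cols) {
  if (!file.exists(path) || file.size(path) == 0) {
    abort(paste0("missing or empty input file: ", path),
          class = "sequestr_validation_error")
  }
  df <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort(paste0("cannot parse ", path, ": ",
                                     conditionMessage(e)),
                              class = "sequestr_validation_error")
  )
  missing <- setdiff(required_cols, names(df))
  if (length(missing)) {
    abort(paste0(path, " is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "sequestr_validation_error")
  }
  for (col in required_cols) {
    if (!is.numeric(df[[col]])) {
      coerced <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(coerced) & !is.na(df[[col]]))
      if (length(bad)) {
        abort(sprintf("%s: non-numeric value in `%s` at data row(s) %s",
                      path, col, paste(head(bad, 5), collapse = ", ")),
              class = "sequestr_validation_error")
      }
      df[[col]] <- coerced
    }
  }
  bad <- which(!stats::complete.cases(df[required_cols]))
  if (length(bad)) {
    abort(sprintf("%s: malformed or missing values at data row(s) %s",
                  path, paste(head(bad, 5), collapse = ", ")),
          class = "sequestr_validation_error")
  }
  df
}

#' Read a CD lipid-titration CSV
#'
#' Expects columns `dmps_uM, cd_mdeg`; converts ellipticity to bound
#' fraction with [cd_fraction_bound()] using the two calibration signals.
#'
#' @param path CSV path.
#' @param cd_free,cd_bound calibration ellipticities (mdeg).
#' @return a tibble: `dmps_uM`, `cd_mdeg`, `xb`, `out_of_range`.
#' @export
read_cd_titration <- function(path, cd_free, cd_bound) {
  df <- read_csv_checked(path, c("dmps_uM", "cd_mdeg"))
  xb <- cd_fraction_bound(df$cd_mdeg, cd_free, cd_bound)
  tibble(dmps_uM = df$dmps_uM, cd_mdeg = df$cd_mdeg,
         xb = as.numeric(xb), out_of_range = attr(xb, "out_of_range"))
}

#' Read an ITC injection-heat CSV
#'
#' Expects columns `injection_index, volume_uL, heat_uJ`.
#'
#' @param path CSV path.
#' @return a tibble sorted by injection index.
#' @export
read_itc_csv <- function(path) {
  read_csv_checked(path, c("injection_index", "volume_uL", "heat_uJ")) |>
    arrange(.data$injection_index)
}

#' Read a dose-response CSV
#'
#' Expects columns `binder_uM, response` (optionally
#' `tracer_concentration`).
#'
#' @param path CSV path.
#' @return a tibble sorted by binder concentration.
#' @export
read_dose_response_csv <- function(path) {
  read_csv_checked(path, c("binder_uM", "response")) |>
    arrange(.data$binder_uM)
}
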