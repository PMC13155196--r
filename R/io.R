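#' Read and write long-format recurrent-event tables
#'
#' The canonical on-disk layout is a UTF-8 CSV with a header and columns
#' `id`, `j` (recurrence index), `time` (gap), `status` (0/1) followed by
#' covariate columns. `column_map` renames nonstandard headers, e.g.
#' `c(id = "patient", time = "gap")` maps the file's `patient` column to
#' `id`. Validation reports the offending row numbers.
#'
#' @param path File path.
#' @param column_map Named character vector `c(standard = "file_column")`.
#' @return A tibble of validated records.
#' @export
read_long_csv <- function(path, column_map = NULL) {
  stopifnot(file.exists(path))
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(column_map)) {
    miss <- setdiff(unname(column_map), names(x))
    if (length(miss)) {
      stop("Mapped columns not in file: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    names(x)[match(unname(column_map), names(x))] <- names(column_map)
  }
  validate_records(x)
}

#' @rdname read_long_csv
#' @param records A records tibble (e.g. from [simulate_recurrent_cure()]).
#' @export
write_long_csv <- function(records, path) {
  readr::write_csv(as.data.frame(validate_records(records)), path)
  invisible(path)
}

validate_records <- function(x) {
  need <- c("id", "time", "status")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("Missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(x) == 0) return(tibble::as_tibble(x))
  bad <- which(!is.finite(x$time) | x$time <= 0)
  if (length(bad)) {
    stop("Non-positive gap time at rows: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  bad <- which(!x$status %in% c(0, 1))
  if (length(bad)) {
    stop("Event indicator not 0/1 at rows: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  if ("j" %in% names(x)) {
    chk <- tapply(x$j, x$id, function(jj) identical(as.integer(jj),
                                                    seq_along(jj)))
    if (!all(unlist(chk))) {
      warning("Recurrence index `j` is not contiguous from 1 within every ",
              "subject.")
    }
  }
  multi_cens <- tapply(x$status, x$id, function(s) sum(s == 0) > 1)
  if (any(unlist(multi_cens))) {
    warning("Some subjects have more than one censored record; expected at ",
            "most one (the last) in simulated data.")
  }
  tibble::as_tibble(x)
}

#' Adapt the colorectal readmission layout to the long gap-time format
#'
#' Converts a table in the layout of the colorectal cancer hospital
#' readmission data shipped with the `frailtypack` package (columns `id`,
#' `t.start`, `t.stop`, `event`, `chemo`, `sex`, `dukes`, `charlson`) into the
#' package's long format: gap time `t.stop - t.start`, reference-coded
#' indicator covariates (reference: male, non-treated, Dukes A-B, Charlson
#' index 0), the same covariates entering both the latency and incidence
#' design. Gap times are in days; the unit is carried as an attribute and
#' never converted.
#'
#' @param x Data frame in the readmission layout. `sex` may be coded
#'   `"Male"`/`"Female"` (or 1/2), `chemo` `"NonTreated"`/`"Treated"` (or
#'   0/1), `dukes` in \{1,2,3\} or \{"A-B","C","D"\}, `charlson` in
#'   \{0,1,3\} or \{"0","1-2",">=3"\}.
#' @return A long-format tibble with columns `id`, `j`, `time`, `status`,
#'   `female`, `chemo`, `dukesC`, `dukesD`, `charlson12`, `charlson3`, and
#'   attribute `unit = "days"`.
#' @export
adapt_readmission <- function(x) {
  need <- c("id", "t.start", "t.stop", "event")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("Missing readmission columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  gap <- x$t.stop - x$t.start
  bad <- which(!is.finite(gap) | gap <= 0)
  if (length(bad)) {
    stop("Non-positive computed gap at rows: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  code2 <- function(col, lev1) as.integer(as.character(col) %in% lev1)
  out <- tibble::tibble(
    id = x$id,
    time = as.numeric(gap),
    status = as.integer(x$event),
    female = code2(x$sex, c("Female", "female", "2")),
    chemo = code2(x$chemo, c("Treated", "treated", "1")),
    dukesC = code2(x$dukes, c("2", "C")),
    dukesD = code2(x$dukes, c("3", "D")),
    charlson12 = code2(x$charlson, c("1", "1-2")),
    charlson3 = code2(x$charlson, c("3", ">=3"))
  )
  out <- out |> dplyr::group_by(.data$id) |>
    dplyr::mutate(j = dplyr::row_number(), .after = "id") |>
    dplyr::ungroup()
  out <- validate_records(out)
  attr(out, "unit") <- "days"
  out
}
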