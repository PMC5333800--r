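# Canonical record layout shared by every stage of the pipeline.
# One row = one extracted t-test report.

litpower_cols <- c("paper_id", "journal_id", "df", "t", "p_cmp", "p", "d")

#' Construct a tibble of t-test records
#'
#' A *record* is a single full t-test report as it appears in an article:
#' degrees of freedom and t value, optionally a p value with its comparator
#' (`=`, `<` or `>`) and a reported Cohen's d. All pipeline stages consume
#' and produce this layout.
#'
#' @param df Integer degrees of freedom (>= 1).
#' @param t Reported t values (sign preserved).
#' @param p_cmp Comparator tag for the reported p: `"="`, `"<"` or `">"`,
#'   or `NA` when no p was reported.
#' @param p Reported p values in (0, 1], or `NA`.
#' @param d Reported Cohen's d, or `NA`.
#' @param paper_id,journal_id Opaque identifiers.
#' @param line_source Optional raw matched line, for audit.
#'
#' @return A tibble with columns `paper_id`, `journal_id`, `df`, `t`,
#'   `p_cmp`, `p`, `d` (and `line_source` when supplied).
#' @export
#' @examples
#' stat_records(df = 23, t = 2.45, p_cmp = "=", p = 0.022)
stat_records <- function(df, t, p_cmp = NA_character_, p = NA_real_,
                         d = NA_real_, paper_id = NA_character_,
                         journal_id = NA_character_, line_source = NULL) {
  out <- tibble::tibble(
    paper_id = as.character(paper_id),
    journal_id = as.character(journal_id),
    df = as.integer(df),
    t = as.numeric(t),
    p_cmp = as.character(p_cmp),
    p = as.numeric(p),
    d = as.numeric(d)
  )
  if (!is.null(line_source)) out$line_source <- as.character(line_source)
  validate_records(out)
}

#' Validate a records tibble
#'
#' Checks the invariants of the record layout: `df >= 1` and integer-valued,
#' `p` in (0, 1] where present, `p_cmp` one of `=`, `<`, `>` where present.
#' Violations raise an error; this function never drops rows silently
#' (cleaning with reasons is [clean_records()]'s job).
#'
#' With `strict = FALSE` only the structural checks run (mandatory columns,
#' comparator vocabulary); out-of-range `df` and `p` are tolerated. Freshly
#' parsed or imported corpora use this mode, because real literatures contain
#' impossible values (negative df, negative p) that [clean_records()] must be
#' able to see in order to drop them with a reason.
#'
#' @param records A tibble with at least `df` and `t` columns.
#' @param strict Enforce the value-range invariants (default `TRUE`).
#' @return `records`, invisibly unchanged, with canonical column types.
#' @export
validate_records <- function(records, strict = TRUE) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(c("df", "t"), names(records))
  if (length(missing_cols) > 0) {
    abort(sprintf("records are missing mandatory column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "litpower_format_error")
  }
  if (strict && (any(records$df < 1, na.rm = TRUE) ||
                 any(records$df != round(records$df), na.rm = TRUE))) {
    abort("df must be a positive integer for every record",
          class = "litpower_invariant_error")
  }
  if (strict && "p" %in% names(records)) {
    bad <- !is.na(records$p) & (records$p <= 0 | records$p > 1)
    if (any(bad)) {
      abort(sprintf("p must lie in (0, 1]; offending rows: %s",
                    paste(head(which(bad), 5), collapse = ", ")),
            class = "litpower_invariant_error")
    }
  }
  if ("p_cmp" %in% names(records)) {
    bad <- !is.na(records$p_cmp) & !records$p_cmp %in% c("=", "<", ">")
    if (any(bad)) {
      abort("p_cmp must be one of '=', '<', '>' or NA",
            class = "litpower_invariant_error")
    }
  }
  records
}

#' Read t-test records from CSV
#'
#' Reads the canonical record CSV (RFC-4180, header row mandatory, UTF-8).
#' Columns `df` and `t` are mandatory; `paper_id`, `journal_id`, `p_cmp`,
#' `p`, `d` are optional and preserved as `NA` when the cell is empty.
#' Row order is preserved.
#'
#' @param path Path to a CSV file.
#' @param strict Enforce value-range invariants on read (see
#'   [validate_records()]). Set to `FALSE` to read a raw, not-yet-cleaned
#'   corpus dump.
#' @return A tibble of records (see [stat_records()]).
#' @export
read_records <- function(path, strict = TRUE) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "litpower_io_error")
  }
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing_cols <- setdiff(c("df", "t"), header)
  if (length(missing_cols) > 0) {
    abort(sprintf("CSV %s is missing mandatory column(s): %s",
                  path, paste(missing_cols, collapse = ", ")),
          class = "litpower_format_error")
  }
  col_types <- list(
    paper_id = readr::col_character(),
    journal_id = readr::col_character(),
    df = readr::col_double(),
    t = readr::col_double(),
    p_cmp = readr::col_character(),
    p = readr::col_double(),
    d = readr::col_double(),
    line_source = readr::col_character()
  )
  spec <- do.call(readr::cols,
                  c(col_types[intersect(names(col_types), header)],
                    .default = list(readr::col_guess())))
  out <- suppressWarnings(
    readr::read_csv(path, col_types = spec, na = c("", "NA"),
                    progress = FALSE, show_col_types = FALSE))
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    abort(sprintf("unparseable cell in %s at row %d, column %s",
                  path, probs$row[1], probs$col[1]),
          class = "litpower_format_error")
  }
  for (col in setdiff(litpower_cols, names(out))) {
    out[[col]] <- if (col %in% c("df", "t", "p", "d")) NA_real_ else NA_character_
  }
  out$df <- as.integer(out$df)
  validate_records(out, strict = strict)
  out[, c(litpower_cols, setdiff(names(out), litpower_cols))]
}

#' Write t-test records to CSV
#'
#' Serializes records in the canonical column order with absent values as
#' empty cells. `read_records(write_records(x))` reproduces `x`
#' field-for-field, including comparator tags and absence markers.
#'
#' @param records A records tibble.
#' @param path Output path.
#' @return `records`, invisibly (so the call can sit inside a pipe).
#' @export
write_records <- function(records, path) {
  validate_records(records, strict = FALSE)
  keep <- c(litpower_cols, intersect("line_source", names(records)))
  for (col in setdiff(litpower_cols, names(records))) {
    records[[col]] <- if (col %in% c("df", "t", "p", "d")) NA_real_ else NA_character_
  }
  readr::write_csv(records[, keep], path, na = "", progress = FALSE)
  invisible(records)
}

#' Import records from a deposited MATLAB .mat file
#'
#' Adapter for supplementary data deposited as a MATLAB MAT-file. The MAT
#' layout of such deposits is not standardized, so the adapter converts the
#' file to CSV with a short Python/scipy.io helper (`python` must be on the
#' PATH), maps top-level numeric variables onto the canonical columns, and
#' messages the mapping it used.
#'
#' @param path Path to a `.mat` file.
#' @param var_map Named character vector mapping canonical column names to
#'   MAT variable names, e.g. `c(df = "df", t = "tvalue")`. Variables named
#'   exactly `df`, `t`, `p`, `d` are picked up by default.
#' @return A records tibble.
#' @export
read_records_mat <- function(path, var_map = c(df = "df", t = "t",
                                               p = "p", d = "d")) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "litpower_io_error")
  }
  py <- Sys.which("python")
  if (!nzchar(py)) {
    abort("python with scipy is required to read MAT files",
          class = "litpower_io_error")
  }
  tmp <- tempfile(fileext = ".csv")
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, csv",
    "from scipy.io import loadmat",
    "import numpy as np",
    "mat = loadmat(sys.argv[1], squeeze_me=True)",
    "cols = {k: np.atleast_1d(v).ravel() for k, v in mat.items()",
    "        if not k.startswith('__') and np.issubdtype(np.asarray(v).dtype, np.number)}",
    "n = max((len(v) for v in cols.values()), default=0)",
    "cols = {k: v for k, v in cols.items() if len(v) == n}",
    "with open(sys.argv[2], 'w', newline='') as fh:",
    "    w = csv.writer(fh)",
    "    w.writerow(list(cols))",
    "    for i in range(n):",
    "        w.writerow([cols[k][i] for k in cols])"
  ), script)
  status <- system2(py, c(script, shQuote(path), shQuote(tmp)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(tmp)) {
    abort(sprintf("MAT conversion failed for %s", path),
          class = "litpower_io_error")
  }
  raw <- readr::read_csv(tmp, show_col_types = FALSE, progress = FALSE)
  found <- var_map[var_map %in% names(raw)]
  if (!all(c("df", "t") %in% names(found))) {
    abort(sprintf(
      "MAT file %s has no variables mappable to df and t (top-level numeric variables: %s)",
      path, paste(names(raw), collapse = ", ")),
      class = "litpower_format_error")
  }
  message("read_records_mat: mapped ",
          paste(sprintf("%s <- '%s'", names(found), found), collapse = ", "),
          " from ", path)
  p_val <- if ("p" %in% names(found)) as.numeric(raw[[found[["p"]]]]) else
    rep(NA_real_, nrow(raw))
  out <- tibble::tibble(
    paper_id = NA_character_, journal_id = NA_character_,
    df = as.integer(round(raw[[found[["df"]]]])),
    t = as.numeric(raw[[found[["t"]]]]),
    p_cmp = ifelse(is.na(p_val), NA_character_, "="),
    p = p_val,
    d = if ("d" %in% names(found)) as.numeric(raw[[found[["d"]]]]) else NA_real_
  )
  validate_records(out, strict = FALSE)
}
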