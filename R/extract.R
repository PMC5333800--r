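# Two-phase extraction of full t-test records from article plain text.
# Phase 1 harvests 65-character candidate windows at "t(" / "t" anchors;
# phase 2 parses them with record templates. Cleaning applies the survey's
# exclusion rules with machine-readable reasons.

# number token: "2.45", ".022", "0.022", "2"; no thousands separators
.num_rx <- "(-?(?:\\d+\\.\\d*|\\.\\d+|\\d+))"

#' Harvest candidate t-test lines from article text
#'
#' Phase one of the extraction algorithm. Every occurrence of a `t(` anchor
#' (and of a bare `t` anchor directly followed by `=`) opens a candidate
#' window: the text from the anchor to the end of the physical line, with
#' all whitespace removed and lowercased, truncated to 65 characters. A
#' window is retained only if it contains one of `=`, `<`, `>` *and* a
#' `p=`, `p<` or `p>` token — the filter that keeps stand-alone t values
#' (e.g. "t < 1") out of the candidate set.
#'
#' The window stops at the end of the physical line, so a line break inside
#' a statistical record truncates its window; this is the mechanism by which
#' records broken across lines are missed, mirroring how such records defeat
#' text extraction in practice.
#'
#' @param body A character scalar (or vector of lines) of article plain text.
#' @return A tibble with columns `text` (the candidate window, no spaces,
#'   lowercase), `line` (physical line number) and `offset` (character
#'   position of the anchor within the line).
#' @export
#' @examples
#' harvest_candidate_lines("the effect was reliable, t(23) = 2.45, p = .022")
harvest_candidate_lines <- function(body) {
  stopifnot(is.character(body))
  lines <- tolower(unlist(strsplit(paste(body, collapse = "\n"), "\n",
                                   fixed = TRUE)))
  if (length(lines) == 0) {
    return(tibble::tibble(text = character(), line = integer(),
                          offset = integer()))
  }
  # anchor: "t(" (whitespace allowed before "("), or bare "t" followed by "="
  hits <- gregexpr("t\\s*[(=]", lines, perl = TRUE)
  n_hit <- vapply(hits, function(m) if (m[1] == -1L) 0L else length(m),
                  integer(1))
  if (sum(n_hit) == 0) {
    return(tibble::tibble(text = character(), line = integer(),
                          offset = integer()))
  }
  line_idx <- rep(seq_along(lines), n_hit)
  offsets <- unlist(lapply(hits, function(m) if (m[1] == -1L) integer() else
    as.integer(m)))
  windows <- substr(lines[line_idx], offsets, nchar(lines[line_idx]))
  windows <- gsub("[[:space:]]+", "", windows)
  windows <- substr(windows, 1L, 65L)
  keep <- grepl("[=<>]", windows) & grepl("p[=<>]", windows)
  tibble::tibble(text = windows[keep], line = line_idx[keep],
                 offset = offsets[keep])
}

#' Parse candidate lines into t-test records
#'
#' Phase two of the extraction algorithm. Applies the full-record templates
#' (`t(df) = x.xx`, `p = y.yy`, optional `d = z.zz`) to candidate windows.
#' Non-matching windows yield nothing, never a partial record. A window with
#' two numbers inside the parentheses (an F-style `t(2,45)` pattern) does not
#' match: the t template requires a single integer df. Unicode minus and
#' ASCII hyphen are both accepted; the sign of t is preserved.
#'
#' @param lines Character vector of candidate windows (as produced by
#'   [harvest_candidate_lines()]), or a tibble with a `text` column.
#' @return A records tibble (possibly zero rows) with `line_source` set to
#'   the matched window. Values are exactly as printed; no cleaning or range
#'   checks are applied here (see [clean_records()]).
#' @export
#' @examples
#' parse_t_record("t(23)=2.45,p=.022,d=0.51")
parse_t_record <- function(lines) {
  if (is.data.frame(lines)) lines <- lines$text
  stopifnot(is.character(lines))
  txt <- gsub("−", "-", lines)
  # a 65-char window can reach into the next record; clauses after a second
  # "t(" anchor belong to that record, so cut the window there
  nxt <- as.integer(regexpr("t\\(", substr(txt, 3L, nchar(txt))))
  txt <- ifelse(nxt > 0L, substr(txt, 1L, nxt + 1L), txt)

  t_rx <- paste0("^t\\((-?\\d+)\\)=", .num_rx)
  tm <- regmatches(txt, regexec(t_rx, txt, perl = TRUE))
  ok <- lengths(tm) == 3L
  if (!any(ok)) {
    return(stat_records(df = integer(), t = numeric(),
                        line_source = character()))
  }
  txt <- txt[ok]
  src <- lines[ok]
  tm <- tm[ok]
  df <- as.integer(vapply(tm, `[[`, "", 2L))
  t_val <- as.numeric(vapply(tm, `[[`, "", 3L))

  p_rx <- paste0("p([=<>])", .num_rx)
  pm <- regmatches(txt, regexec(p_rx, txt, perl = TRUE))
  p_ok <- lengths(pm) == 3L
  p_cmp <- ifelse(p_ok, vapply(pm, function(m) if (length(m) == 3L) m[[2L]]
                               else NA_character_, ""), NA_character_)
  p_val <- ifelse(p_ok, as.numeric(vapply(pm, function(m)
    if (length(m) == 3L) m[[3L]] else NA_character_, "")), NA_real_)

  # d clause must start a clause (not be the tail of another token)
  d_rx <- paste0("(?:^|[^a-z0-9])d=", .num_rx)
  dm <- regmatches(txt, regexec(d_rx, txt, perl = TRUE))
  d_val <- vapply(dm, function(m) if (length(m) == 2L) as.numeric(m[[2L]])
                  else NA_real_, numeric(1))

  tibble::tibble(
    paper_id = NA_character_, journal_id = NA_character_,
    df = df, t = t_val, p_cmp = p_cmp, p = p_val, d = d_val,
    line_source = src
  )
}

#' Extract all t-test records from a corpus of article bodies
#'
#' Runs both parsing phases over each body and tags records with the paper
#' they came from. Output is in document order (bodies in input order, lines
#' in reading order). The result is *raw*: pass it to [clean_records()]
#' before analysis.
#'
#' @param bodies Character vector of article plain texts.
#' @param paper_ids Identifiers, one per body (default `paper_1`, ...).
#' @param journal_ids Optional journal identifier per body.
#' @return A raw records tibble with `line_source`.
#' @export
extract_records <- function(bodies,
                            paper_ids = paste0("paper_", seq_along(bodies)),
                            journal_ids = NA_character_) {
  stopifnot(length(paper_ids) == length(bodies))
  journal_ids <- rep_len(journal_ids, length(bodies))
  res <- purrr::map(seq_along(bodies), function(i) {
    cand <- harvest_candidate_lines(bodies[[i]])
    rec <- parse_t_record(cand$text)
    if (nrow(rec) > 0) {
      rec$paper_id <- paper_ids[[i]]
      rec$journal_id <- journal_ids[[i]]
    }
    rec
  })
  dplyr::bind_rows(res)
}

#' Clean a raw record set with per-drop reasons
#'
#' Applies the survey's exclusion rules, in document order:
#' \describe{
#'   \item{`negative_df`}{df below 1 (impossible; typesetting artefacts).}
#'   \item{`negative_p`}{reported p below 0.}
#'   \item{`df_outlier`}{df above `df_max` (default 10,000).}
#'   \item{`duplicate`}{statistical fields (df, t, p comparator, p, d)
#'     identical to the immediately preceding *kept* record of the same
#'     paper — the double-detection artefact of anchor-based harvesting.}
#' }
#' Only adjacent duplicates are dropped: the same statistic legitimately
#' reappearing later in a paper is retained. The operation is idempotent.
#'
#' @param records A raw records tibble (document order).
#' @param df_max Outlier threshold on df.
#' @return A list with `kept` (clean records tibble) and `dropped` (the
#'   removed rows plus a `reason` column).
#' @export
clean_records <- function(records, df_max = 10000) {
  validate_records(records, strict = FALSE)
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  reason[!is.na(records$p) & records$p < 0] <- "negative_p"
  reason[records$df < 1] <- "negative_df"
  reason[is.na(reason) & records$df > df_max] <- "df_outlier"

  valid <- which(is.na(reason))
  if (length(valid) > 1) {
    v <- records[valid, ]
    key <- paste(v$df, v$t, v$p_cmp, v$p, v$d, sep = "|")
    pid <- dplyr::coalesce(v$paper_id, "")
    same_paper <- pid[-1] == pid[-nrow(v)]
    dup <- c(FALSE, key[-1] == key[-length(key)] & same_paper)
    # a run of identical records collapses to its first element: within a
    # run every element equals the preceding *kept* one
    reason[valid[dup]] <- "duplicate"
  }
  list(
    kept = records[is.na(reason), , drop = FALSE],
    dropped = dplyr::mutate(records[!is.na(reason), , drop = FALSE],
                            reason = reason[!is.na(reason)])
  )
}

#' Compare extracted records against a rendered ground truth
#'
#' Multiset comparison of a parsed record set with the records that were
#' rendered into a synthetic corpus: recovery is the fraction of rendered
#' records that were parsed back (matched on paper, df, t, p comparator,
#' p and d at rendering precision); false alarms are parsed records that
#' match no rendered record.
#'
#' @param parsed Records returned by [extract_records()].
#' @param rendered The records given to [render_corpus()].
#' @return A list with `recovery` (fraction in \code{[0, 1]}), `n_rendered`,
#'   `n_parsed`, `n_matched` and `false_alarms` (count).
#' @export
validate_extraction <- function(parsed, rendered) {
  key <- function(x) paste(x$paper_id, x$df, x$t, x$p_cmp, x$p, x$d,
                           sep = "|")
  kp <- table(key(parsed))
  kr <- table(key(rendered))
  shared <- intersect(names(kp), names(kr))
  n_match <- sum(pmin(kp[shared], kr[shared]))
  list(
    recovery = n_match / nrow(rendered),
    n_rendered = nrow(rendered),
    n_parsed = nrow(parsed),
    n_matched = as.integer(n_match),
    false_alarms = as.integer(nrow(parsed) - n_match)
  )
}
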