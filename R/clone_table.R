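#' Construct a clone abundance table
#'
#' A clone table holds one subject's TCR\eqn{\beta} repertoire as observed by
#' immunosequencing: opaque clone identifiers with positive integer template
#' counts. It is the raw input from which all repertoire metrics
#' (\code{\link{compute_metrics}}) are derived.
#'
#' @param clone_id Character vector of unique clone identifiers.
#' @param templates Positive integer template counts, one per clone.
#' @param subject_id Single string identifying the subject.
#'
#' @return A tibble of class `tcr_clone_table` with columns `clone_id` and
#'   `templates` and a `subject_id` attribute.
#' @export
#' @examples
#' ct <- clone_table(c("c1", "c2", "c3"), c(5L, 3L, 2L), subject_id = "s1")
#' compute_metrics(ct, k = 2)
clone_table <- function(clone_id, templates, subject_id = "subject") {
  tbl <- tibble::tibble(
    clone_id = as.character(clone_id),
    templates = templates
  )
  validate_clone_table(tbl, subject_id = subject_id)
}

#' Validate a clone table
#'
#' Checks the structural invariants of a repertoire table: counts are positive
#' integers, clone identifiers are unique and non-missing, and the table is
#' non-empty. Fractional template counts are rejected rather than rounded,
#' because repertoire size is a count of sequenced T cells.
#'
#' @param tbl A data frame with columns `clone_id` and `templates`.
#' @param subject_id Subject identifier to attach.
#' @return The validated table, classed `tcr_clone_table`.
#' @export
validate_clone_table <- function(tbl, subject_id = "subject") {
  if (!all(c("clone_id", "templates") %in% names(tbl))) {
    stop("clone table must have columns 'clone_id' and 'templates'",
         call. = FALSE)
  }
  if (nrow(tbl) == 0L) {
    stop("empty clone table: a repertoire must contain at least one clone",
         call. = FALSE)
  }
  tmpl <- tbl$templates
  if (!is.numeric(tmpl) || anyNA(tmpl)) {
    stop("template counts must be numeric and non-missing", call. = FALSE)
  }
  if (any(tmpl != floor(tmpl))) {
    bad <- which(tmpl != floor(tmpl))[1L]
    stop(sprintf("fractional template count (%s) in row %d: counts are numbers of sequenced cells",
                 format(tmpl[bad]), bad), call. = FALSE)
  }
  if (any(tmpl < 1)) {
    bad <- which(tmpl < 1)[1L]
    stop(sprintf("non-positive template count (%s) in row %d (clone '%s')",
                 format(tmpl[bad]), bad, tbl$clone_id[bad]), call. = FALSE)
  }
  if (anyNA(tbl$clone_id) || anyDuplicated(tbl$clone_id)) {
    dup <- tbl$clone_id[duplicated(tbl$clone_id)][1L]
    stop(sprintf("clone identifiers must be unique and non-missing (duplicate: '%s')",
                 if (is.na(dup)) "NA" else dup), call. = FALSE)
  }
  out <- tibble::as_tibble(tbl[, c("clone_id", "templates")])
  out$templates <- as.numeric(tmpl)
  attr(out, "subject_id") <- as.character(subject_id)
  class(out) <- c("tcr_clone_table", class(out))
  out
}

#' Subject identifier of a clone table
#' @param x A `tcr_clone_table`.
#' @return The subject id string.
#' @export
subject_id <- function(x) attr(x, "subject_id") %||% "subject"

#' Read a clone abundance table from disk
#'
#' Supports two dialects: `"simple"`, a two-column TSV with header
#' `clone_id`/`templates`, and `"airr"`, an AIRR Rearrangement-style TSV from
#' which a clone identity column and a template/duplicate count column are
#' extracted (column names configurable, defaulting to the AIRR fields
#' `clone_id` and `duplicate_count`). Rows with zero or negative counts are
#' rejected, not dropped.
#'
#' @param path Path to a TSV file.
#' @param dialect `"simple"` or `"airr"`.
#' @param clone_col,count_col Column names used by the `"airr"` dialect.
#' @param subject_id Subject id to attach; defaults to the file name without
#'   extension.
#' @return A validated [clone_table()].
#' @export
read_clone_table <- function(path,
                             dialect = c("simple", "airr"),
                             clone_col = "clone_id",
                             count_col = "duplicate_count",
                             subject_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop(sprintf("clone table file not found: '%s'", path), call. = FALSE)
  }
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0L) {
    stop(sprintf("empty clone table file: '%s'", path), call. = FALSE)
  }
  if (dialect == "simple") {
    need <- c("clone_id", "templates")
  } else {
    need <- c(clone_col, count_col)
  }
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L) {
    stop(sprintf("'%s': missing required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  tbl <- tibble::tibble(
    clone_id = as.character(raw[[need[1L]]]),
    templates = raw[[need[2L]]]
  )
  validate_clone_table(tbl, subject_id = subject_id)
}

#' Write a clone table in the simple two-column TSV dialect
#' @param x A `tcr_clone_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clone_table <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x)[, c("clone_id", "templates")], path,
                   progress = FALSE)
  invisible(path)
}

#' Repertoire summary metrics: S, D, S_k and P_k
#'
#' Computes the repertoire size \eqn{S} (total templates sequenced), the
#' TCR\eqn{\beta} diversity \eqn{D} (richness: number of unique clonotypes),
#' the top-k clone mass \eqn{S_k} (total templates of the \eqn{k} most
#' abundant clones; \eqn{S_k = S} when \eqn{k \ge D}) and its percentage
#' \eqn{P_k = 100 \cdot S_k / S}, together with base-10 logs of \eqn{S} and
#' \eqn{D}. All logarithms in this package are base 10 ("dex" scale).
#'
#' The result is independent of clone ordering: ties at the rank-k boundary
#' carry equal counts, so any tie-break yields the same \eqn{S_k}.
#'
#' @param x A [clone_table()], or a bare numeric vector of template counts
#'   (the fast path used by large-scale simulation checks).
#' @param k Integer vector of top-k cutoffs (default `c(10, 100, 1000)`,
#'   the headline cutoff being 1000).
#' @return A one-row tibble with columns `subject_id`, `S`, `D`, one
#'   `S_<k>` and `P_<k>` column per requested `k`, `log10_S`, `log10_D`.
#' @export
#' @examples
#' compute_metrics(clone_table(c("a", "b", "c"), c(5, 3, 2)), k = 2)
compute_metrics <- function(x, k = c(10L, 100L, 1000L)) {
  if (inherits(x, "tcr_clone_table")) {
    counts <- x$templates
    sid <- subject_id(x)
  } else if (is.numeric(x)) {
    counts <- x
    sid <- "subject"
    if (length(counts) == 0L) {
      stop("empty count vector", call. = FALSE)
    }
    if (any(counts < 1 | counts != floor(counts))) {
      stop("template counts must be positive integers", call. = FALSE)
    }
  } else {
    stop("x must be a clone table or a numeric count vector", call. = FALSE)
  }
  k <- as.integer(k)
  if (length(k) == 0L || any(is.na(k)) || any(k < 1L)) {
    stop("k must be a non-empty vector of positive integers", call. = FALSE)
  }
  S <- sum(counts)
  D <- length(counts)
  csum <- cumsum(sort(counts, decreasing = TRUE))
  S_k <- ifelse(k >= D, S, csum[pmin(k, D)])
  cols <- list(subject_id = sid, S = S, D = D)
  for (i in seq_along(k)) {
    cols[[paste0("S_", k[i])]] <- S_k[i]
    cols[[paste0("P_", k[i])]] <- 100 * S_k[i] / S
  }
  cols$log10_S <- log10(S)
  cols$log10_D <- log10(D)
  tibble::new_tibble(cols, nrow = 1L)
}
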