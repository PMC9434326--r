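#' Parse the sampling design from wide-matrix column names
#'
#' Wide expression tables have one feature-id column followed by sample
#' columns named `"<timepoint>.<replicate>"` (hours, 1-based replicate),
#' e.g. `"0.1", "0.2", "0.3", "2.1", ...` for a 2-h-resolution design with
#' 3 replicates.
#'
#' @param x A wide expression tibble/data frame, or a character vector of its
#'   sample column names.
#' @return A tibble with columns `column`, `time` (h), `replicate`.
#' @examples
#' parse_design(c("0.1", "0.2", "2.1", "2.2"))
#' @export
parse_design <- function(x) {
  nms <- if (is.character(x)) x else sample_cols(x)
  m <- regmatches(nms, regexec("^(.+)\\.([0-9]+)$", nms))
  bad <- vapply(m, length, 0L) != 3
  times <- suppressWarnings(vapply(m, function(g) as.numeric(g[2]), 0))
  reps <- suppressWarnings(vapply(m, function(g) as.integer(g[3]), 0L))
  bad <- bad | !is.finite(times) | is.na(reps)
  if (any(bad)) {
    abort(paste0("malformed sample column name(s): ",
                 paste(nms[bad], collapse = ", "),
                 " (expected \"<timepoint>.<replicate>\")"),
          class = "circatrend_parse_error")
  }
  out <- tibble::tibble(column = nms, time = times, replicate = reps)
  tps <- sort(unique(out$time))
  if (any(diff(tps) <= 0)) {
    abort("timepoints must be strictly increasing",
          class = "circatrend_parse_error")
  }
  out
}

sample_cols <- function(df) setdiff(names(df), "feature_id")

check_matrix <- function(df, complete = FALSE) {
  if (!is.data.frame(df) || names(df)[1] != "feature_id") {
    abort("expected a wide expression table with a `feature_id` first column",
          class = "circatrend_parse_error")
  }
  if (anyDuplicated(df$feature_id)) {
    abort("duplicate feature ids", class = "circatrend_parse_error")
  }
  if (complete && anyNA(df[sample_cols(df)])) {
    abort("matrix contains missing values; run impute_missing() first",
          class = "circatrend_incomplete_matrix")
  }
  invisible(df)
}

values_matrix <- function(df) {
  m <- as.matrix(df[sample_cols(df)])
  storage.mode(m) <- "double"
  rownames(m) <- df$feature_id
  m
}

#' Read a wide expression matrix
#'
#' Reads a CSV (or TSV) with a feature-id column followed by
#' `"<timepoint>.<replicate>"` sample columns. Empty cells and `"NA"` are
#' treated as missing. Duplicate feature ids and malformed headers are
#' rejected; non-numeric body cells raise a parse error naming the offending
#' row and column.
#'
#' @param path File path.
#' @param delim Field delimiter; `","` by default, use `"\t"` for TSV.
#' @return A tibble whose first column is `feature_id`, remaining columns
#'   numeric samples; attribute-free, design recoverable via [parse_design()].
#' @export
read_wide_matrix <- function(path, delim = ",") {
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), na = c("", "NA"), comment = "#",
    progress = FALSE, show_col_types = FALSE)
  if (ncol(raw) < 2) {
    abort("expected a feature-id column plus at least one sample column",
          class = "circatrend_parse_error")
  }
  names(raw)[1] <- "feature_id"
  parse_design(sample_cols(raw))
  out <- raw
  for (cn in sample_cols(raw)) {
    v <- suppressWarnings(as.numeric(raw[[cn]]))
    bad <- which(is.na(v) & !is.na(raw[[cn]]))
    if (length(bad)) {
      abort(sprintf("non-numeric value \"%s\" at row %d, column \"%s\"",
                    raw[[cn]][bad[1]], bad[1], cn),
            class = "circatrend_parse_error")
    }
    out[[cn]] <- v
  }
  check_matrix(out)
  out
}

#' Write a wide expression matrix
#'
#' Inverse of [read_wide_matrix()]: finite values round-trip exactly,
#' missing values round-trip to missing.
#'
#' @param df Wide expression tibble.
#' @param path Output file path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_wide_matrix <- function(df, path, delim = ",") {
  check_matrix(df)
  readr::write_delim(df, path, delim = delim, na = "NA", progress = FALSE)
  invisible(path)
}

#' Write a results table
#'
#' Writes a fit-results tibble as TSV, preceded by a `#`-prefixed provenance
#' header line recording the package version and any parameters supplied.
#'
#' @param results A results tibble (e.g. from [tidy()] on a fit object).
#' @param path Output file path.
#' @param params Optional named list of run parameters recorded in the
#'   header comment.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, params = list()) {
  ver <- as.character(utils::packageVersion("circatrend"))
  extra <- if (length(params)) {
    paste0(" ", paste(names(params), unlist(params), sep = "=",
                      collapse = " "))
  } else ""
  header <- paste0("# circatrend ", ver, extra)
  writeLines(header, path)
  readr::write_tsv(results, path, na = "NA", append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_results <- function(path) {
  readr::read_tsv(path, comment = "#", na = "NA", progress = FALSE,
                  show_col_types = FALSE)
}

#' Convert hours post synchronization to circadian time
#'
#' Circadian time (CT) anchors the clock to a reference marker's peak (here
#' conventionally the peak/trough of a reference clock gene such as *Per2*):
#' \eqn{CT = (HPS - \mathrm{offset}) \bmod 24}.
#'
#' @param hours Hours post synchronization (HPS), finite numeric.
#' @param ct_offset Offset (h) between HPS 0 and CT 0.
#' @return CT values in `[0, 24)`.
#' @examples
#' hps_to_ct(26, 0) # 2
#' hps_to_ct(5, 8)  # 21
#' @export
hps_to_ct <- function(hours, ct_offset = 0) {
  if (!is.numeric(hours) || any(!is.finite(hours)) ||
      !is.numeric(ct_offset) || any(!is.finite(ct_offset))) {
    abort("inputs must be finite", class = "circatrend_invalid_parameter")
  }
  (hours - ct_offset) %% 24
}
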