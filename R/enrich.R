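#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact test by probability ordering: the p-value sums the
#' hypergeometric probabilities of all tables (with the observed margins)
#' whose probability does not exceed the observed table's. The reported
#' primary odds ratio is the sample OR \eqn{ad/bc}, with a Haldane
#' correction (+0.5 per cell) when any cell is zero; the conditional
#' maximum-likelihood OR (the convention of `fisher.test()`) is reported
#' alongside, since published ORs may follow either convention.
#'
#' @param table A 2x2 matrix of non-negative integer counts, rows = group
#'   membership, columns = category membership (or four counts `a, b, c, d`
#'   given via `...`).
#' @param ... When `table` is a single number, the remaining three cell
#'   counts `b`, `c`, `d` (row-wise).
#' @return A one-row tibble with `odds_ratio` (sample, Haldane-corrected on
#'   zero cells), `odds_ratio_cmle`, and `p_value`.
#' @examples
#' fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))
#' fisher_exact_2x2(10, 10, 10, 10)
#' @export
fisher_exact_2x2 <- function(table, ...) {
  if (is.matrix(table)) {
    m <- table
  } else {
    cells <- c(table, ...)
    if (length(cells) != 4) {
      abort("supply a 2x2 matrix or four cell counts",
            class = "circatrend_invalid_input")
    }
    m <- matrix(cells, 2, 2, byrow = TRUE)
  }
  if (!all(dim(m) == c(2, 2)) || any(m < 0) || any(m != round(m)) ||
      anyNA(m)) {
    abort("cells must be non-negative integers",
          class = "circatrend_invalid_input")
  }
  if (sum(m) == 0) {
    abort("Fisher's exact test undefined for an all-zero table",
          class = "circatrend_undefined_test")
  }
  ft <- fisher.test(m)
  a <- m[1, 1]; b <- m[1, 2]; c0 <- m[2, 1]; d <- m[2, 2]
  if (any(m == 0)) {
    a <- a + 0.5; b <- b + 0.5; c0 <- c0 + 0.5; d <- d + 0.5
  }
  tibble::tibble(odds_ratio = (a * d) / (b * c0),
                 odds_ratio_cmle = unname(ft$estimate),
                 p_value = ft$p.value)
}

#' Build a 2x2 membership table from labeled features
#'
#' Cross-tabulates features by membership in a focal group and a focal
#' category: `a` counts features in both, `b` focal group only, `c` focal
#' category only, `d` neither. Rows with a missing group or category label
#' are excluded, with the excluded count reported as an attribute and a
#' message.
#'
#' @param assignments Tibble with one row per feature.
#' @param group,category Column names (strings) holding the group and
#'   category labels.
#' @param focal_group,focal_category The focal levels.
#' @return A 2x2 integer matrix with an `n_excluded` attribute.
#' @examples
#' x <- tibble::tibble(biotype = c("lnc", "lnc", "m", "m"),
#'                     ac = c("damped", "forced", "damped", "forced"))
#' build_category_table(x, "biotype", "ac", "lnc", "damped")
#' @export
build_category_table <- function(assignments, group, category, focal_group,
                                 focal_category) {
  g <- assignments[[group]]
  k <- assignments[[category]]
  if (is.null(g) || is.null(k)) {
    abort("`group`/`category` columns not found",
          class = "circatrend_invalid_input")
  }
  keep <- !is.na(g) & !is.na(k)
  n_excluded <- sum(!keep)
  if (n_excluded > 0) {
    message(n_excluded, " unlabeled feature(s) excluded")
  }
  g <- g[keep]; k <- k[keep]
  m <- matrix(c(sum(g == focal_group & k == focal_category),
                sum(g == focal_group & k != focal_category),
                sum(g != focal_group & k == focal_category),
                sum(g != focal_group & k != focal_category)),
              2, 2, byrow = TRUE,
              dimnames = list(c(focal_group, paste0("not_", focal_group)),
                              c(focal_category,
                                paste0("not_", focal_category))))
  attr(m, "n_excluded") <- n_excluded
  m
}

#' Enrichment of each category level in a focal group
#'
#' For every level of `category`, tests whether membership in `focal_group`
#' is associated with that level by Fisher's exact test, BH-adjusting
#' across the family of tests. This covers the common questions "is each AC
#' category enriched for a biotype?" and "is each biotype enriched for
#' circadian features?" — pass the appropriate columns.
#'
#' @inheritParams build_category_table
#' @return A tibble with one row per category level: the 2x2 cell counts,
#'   `odds_ratio`, `odds_ratio_cmle`, `p_value`, `bh_q`.
#' @export
enrich_categories <- function(assignments, group, category, focal_group) {
  lvls <- sort(unique(stats::na.omit(assignments[[category]])))
  out <- purrr::map_dfr(lvls, function(lv) {
    m <- suppressMessages(
      build_category_table(assignments, group, category, focal_group, lv))
    res <- fisher_exact_2x2(m)
    tibble::tibble(group = focal_group, category = lv,
                   a = m[1, 1], b = m[1, 2], c = m[2, 1], d = m[2, 2]) |>
      dplyr::bind_cols(res)
  })
  if (nrow(out)) out$bh_q <- bh_adjust(out$p_value)
  out
}

#' Overlap between a hit list and an annotation set
#'
#' Counts hits that carry an annotation (e.g. oscillating lncRNAs present
#' in a disease database). `n_overlap` counts matching entries of
#' `hit_ids` including duplicates (e.g. transcript isoforms of one
#' annotated gene); `n_overlap_unique` collapses duplicates. The
#' "only" counts are over unique ids.
#'
#' @param hit_ids Character vector of hit identifiers (duplicates allowed).
#' @param annotation_ids Character vector of annotated identifiers.
#' @return A one-row tibble with `n_overlap`, `n_overlap_unique`,
#'   `n_hits_only`, `n_annotation_only`.
#' @examples
#' annotation_overlap(c("a", "b"), c("b", "c"))
#' @export
annotation_overlap <- function(hit_ids, annotation_ids) {
  ann <- unique(annotation_ids)
  hits_u <- unique(hit_ids)
  tibble::tibble(
    n_overlap = sum(hit_ids %in% ann),
    n_overlap_unique = sum(hits_u %in% ann),
    n_hits_only = sum(!hits_u %in% ann),
    n_annotation_only = sum(!ann %in% hits_u))
}
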