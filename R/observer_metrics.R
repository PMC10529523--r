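# Inter-observer comparison statistics: variance percentage with its NA
# convention, composition-category match percentages, and the chi-squared
# test on observer x category counts.

#' Variance percentage between two observers
#'
#' `(obs1 - obs2) / obs1 * 100`, the per-nodule disagreement statistic for
#' cystic-percentage estimates. Conventions: when `obs1 = 0` and
#' `obs2 > 0` the deviation is undefined and `NA` is returned; when both
#' are 0 there is no deviation and 0 is returned.
#'
#' @param obs1 Reference observer's cystic percentage in \[0, 100\]
#'   (vectorised).
#' @param obs2 Comparison observer's cystic percentage in \[0, 100\].
#' @return Numeric vector (possibly `NA`).
#' @export
#' @examples
#' variance_percentage(10, 8)   # 20
#' variance_percentage(5, 14)   # -180
#' variance_percentage(0, 22)   # NA
variance_percentage <- function(obs1, obs2) {
  if (any(!is.finite(obs1)) || any(!is.finite(obs2)) ||
      any(obs1 < 0 | obs1 > 100) || any(obs2 < 0 | obs2 > 100)) {
    stop("observer percentages must lie in [0, 100]", call. = FALSE)
  }
  out <- ifelse(obs1 > 0, (obs1 - obs2) / obs1 * 100,
                ifelse(obs2 > 0, NA_real_, 0))
  as.numeric(out)
}

#' Truncate toward zero at a fixed number of decimals
#'
#' The printed-table rendering convention: 97.77 -> 97.7 (one decimal),
#' 68.571 -> 68.57 (two decimals).
#'
#' @param x Numeric vector.
#' @param digits Number of decimals kept (default 1).
#' @return Numeric vector truncated toward zero.
#' @export
truncate_decimals <- function(x, digits = 1L) {
  trunc(x * 10^digits) / 10^digits
}

#' Observer table constructor
#'
#' @param df Data frame with a `nodule_id` column and one numeric column
#'   per observer, entries in \[0, 100\].
#' @return The validated data.frame with class `observer_table`.
#' @export
observer_table <- function(df) {
  stopifnot(is.data.frame(df), "nodule_id" %in% names(df))
  obs_cols <- setdiff(names(df), "nodule_id")
  if (length(obs_cols) < 2) stop("need at least two observers", call. = FALSE)
  for (cl in obs_cols) {
    v <- df[[cl]]
    if (any(!is.finite(v)) || any(v < 0 | v > 100)) {
      stop(sprintf("column `%s` has entries outside [0, 100]", cl), call. = FALSE)
    }
  }
  class(df) <- c("observer_table", class(df))
  df
}

observer_columns <- function(table) setdiff(names(table), "nodule_id")

#' Variance-percentage table against a reference observer
#'
#' Computes [variance_percentage()] of every non-reference observer column
#' against the reference column, row by row.
#'
#' @param table An [observer_table()].
#' @param reference_column Name of the reference observer (the constant
#'   Observer 2, e.g. `"DSS"`).
#' @param render Optional decimal truncation of the output: `NULL` (raw)
#'   or number of decimals for [truncate_decimals()].
#' @return Data frame (`variance_table`) with `nodule_id` and one column
#'   per non-reference observer; `NA` where the convention dictates.
#' @export
variance_table <- function(table, reference_column = "DSS", render = NULL) {
  stopifnot(inherits(table, "observer_table"))
  if (!reference_column %in% names(table)) {
    stop(sprintf("reference column `%s` not found", reference_column), call. = FALSE)
  }
  ref <- table[[reference_column]]
  out <- data.frame(nodule_id = table$nodule_id)
  for (cl in setdiff(observer_columns(table), reference_column)) {
    vp <- variance_percentage(table[[cl]], ref)
    if (!is.null(render)) vp <- truncate_decimals(vp, render)
    out[[cl]] <- vp
  }
  class(out) <- c("variance_table", class(out))
  out
}

#' Nodule composition categorisation scheme
#'
#' Ordered breakpoints on \[0, 100\] cystic percent defining composition
#' categories. The default uses the standard ultrasound composition
#' vocabulary with breaks at 10/50/90: solid, predominantly solid,
#' predominantly cystic, cystic.
#'
#' @param breakpoints Strictly increasing breakpoints inside (0, 100).
#' @param category_names One more name than breakpoints.
#' @return A list of class `composition_scheme`.
#' @export
composition_scheme <- function(breakpoints = c(10, 50, 90),
                               category_names = c("solid",
                                                  "predominantly solid",
                                                  "predominantly cystic",
                                                  "cystic")) {
  if (any(diff(breakpoints) <= 0) || any(breakpoints <= 0) ||
      any(breakpoints >= 100)) {
    stop("breakpoints must be strictly increasing inside (0, 100)", call. = FALSE)
  }
  if (length(category_names) != length(breakpoints) + 1L) {
    stop("need one more category name than breakpoints", call. = FALSE)
  }
  structure(list(breakpoints = breakpoints, category_names = category_names),
            class = "composition_scheme")
}

#' Composition category of a cystic percentage
#'
#' Boundary values belong to the upper interval: with the default scheme
#' the bins are \[0,10), \[10,50), \[50,90), \[90,100\].
#'
#' @param cystic_percent Numeric vector in \[0, 100\].
#' @param scheme A [composition_scheme()].
#' @return Factor of category names.
#' @export
composition_category <- function(cystic_percent, scheme = composition_scheme()) {
  stopifnot(inherits(scheme, "composition_scheme"))
  if (any(!is.finite(cystic_percent)) ||
      any(cystic_percent < 0 | cystic_percent > 100)) {
    stop("cystic percentages must lie in [0, 100]", call. = FALSE)
  }
  idx <- findInterval(cystic_percent, scheme$breakpoints) + 1L
  factor(scheme$category_names[idx], levels = scheme$category_names)
}

#' Classification match percentage between one observer and a reference
#'
#' Percentage of nodules assigned the same composition category by the
#' observer and the reference.
#'
#' @param table An [observer_table()].
#' @param observer,reference Column names.
#' @param scheme A [composition_scheme()].
#' @return Percentage in \[0, 100\].
#' @export
classification_match_percentage <- function(table, observer, reference = "DSS",
                                            scheme = composition_scheme()) {
  stopifnot(inherits(table, "observer_table"),
            observer %in% names(table), reference %in% names(table))
  a <- composition_category(table[[observer]], scheme)
  b <- composition_category(table[[reference]], scheme)
  100 * mean(a == b)
}

#' Overall match percentage of several observers against a reference
#'
#' Two readings of the all-observer agreement are computed and both
#' returned: `all_agree_pct`, the percentage of nodules on which every
#' listed observer and the reference share one category (the primary
#' reading), and `mean_pairwise_pct`, the mean of the per-observer match
#' percentages against the reference.
#'
#' @param table An [observer_table()].
#' @param observers Observer column names (>= 2).
#' @param reference Reference column name.
#' @param scheme A [composition_scheme()].
#' @return List with `all_agree_pct` and `mean_pairwise_pct`.
#' @export
all_observer_match_percentage <- function(table, observers, reference = "DSS",
                                          scheme = composition_scheme()) {
  stopifnot(length(observers) >= 2)
  cats <- lapply(c(observers, reference), function(cl) {
    composition_category(table[[cl]], scheme)
  })
  agree <- Reduce(`&`, lapply(cats[-1], function(x) x == cats[[1]]))
  pairwise <- vapply(observers, classification_match_percentage, numeric(1),
                     table = table, reference = reference, scheme = scheme)
  list(all_agree_pct = 100 * mean(agree),
       mean_pairwise_pct = mean(pairwise))
}

#' Chi-squared test of observer composition distributions
#'
#' Pearson chi-squared (uncorrected) on the observers x categories
#' contingency table of category counts, testing whether the observers
#' (including the reference column) distribute nodules over the
#' composition categories differently.
#'
#' @param table An [observer_table()].
#' @param scheme A [composition_scheme()].
#' @param observers Columns to include (default: all observer columns).
#' @return List with `statistic`, `df`, `p_value` and the `counts` table.
#'   A degenerate table (a single realised category) returns statistic 0,
#'   p-value 1 with a warning.
#' @export
chi_squared_variance_test <- function(table, scheme = composition_scheme(),
                                      observers = observer_columns(table)) {
  stopifnot(inherits(table, "observer_table"), length(observers) >= 2)
  counts <- t(vapply(observers, function(cl) {
    as.integer(base::table(composition_category(table[[cl]], scheme)))
  }, integer(length(scheme$category_names))))
  colnames(counts) <- scheme$category_names
  rownames(counts) <- observers
  realized <- counts[, colSums(counts) > 0, drop = FALSE]
  if (ncol(realized) < 2) {
    warning("only one composition category realised; test degenerate")
    return(list(statistic = 0, df = 0L, p_value = 1, counts = counts))
  }
  ct <- suppressWarnings(stats::chisq.test(realized, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), counts = counts)
}
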