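#' Bilateral asymmetry index
#'
#' Percent imbalance between left-origin and right-origin synaptic budgets:
#' `AI = (LL - RR) / (RR + LL) * 100` for ipsilateral connectivity, and the
#' same formula on (LR, RL) for contralateral connectivity. Positive values
#' mean a left bias; the index is antisymmetric under swapping its
#' arguments and bounded in \[-100, 100\]. When both counts are zero the
#' index is undefined and returned as `NA` (never coerced to zero).
#'
#' @param left,right Non-negative counts (LL and RR, or LR and RL).
#'   Vectorized.
#' @return Asymmetry index in percent, `NA` where `left + right == 0`.
#' @export
asymmetry_index <- function(left, right) {
  if (any(left < 0 | right < 0, na.rm = TRUE))
    abort_validation("counts must be non-negative")
  tot <- left + right
  out <- ifelse(tot == 0, NA_real_, (left - right) / tot * 100)
  if (any(tot == 0, na.rm = TRUE))
    message(sprintf("asymmetry index undefined for %d zero-total pair(s)",
                    sum(tot == 0, na.rm = TRUE)))
  out
}

#' Spearman rank correlation with a large-sample p value
#'
#' Rho is the Pearson correlation of mid-ranks (ties averaged); the p value
#' comes from the standard t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' Pairs with a missing value in either sequence are dropped first.
#'
#' @param x,y Equal-length numeric vectors; at least 3 complete pairs.
#' @return List with `rho`, `p_value`, `n` (complete pairs used) and
#'   `n_excluded`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y))
    abort_validation("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  n_excluded <- sum(!ok)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3)
    abort_insufficient(sprintf(
      "need at least 3 complete pairs for a rank correlation, have %d", n))
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0) {
    message("rank correlation undefined for a constant sequence")
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                n_excluded = n_excluded))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (is.na(rho)) {
    p <- NA_real_
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n, n_excluded = n_excluded)
}

#' Cluster-level bilateral symmetry report
#'
#' Builds one asymmetry record per (cluster, direction) from hemisphere
#' budgets and tests the correspondence of ipsi- and contralateral
#' connectivity across clusters with Spearman's rank correlation, per
#' direction. By default the correlation is computed on left-share
#' percentages (`100 * LL / (LL + RR)` vs `100 * LR / (LR + RL)`);
#' `measure = "count"` correlates the raw ipsi- and contralateral totals
#' instead. Undefined indices are excluded pairwise and the exclusion count
#' reported.
#'
#' @param budgets `data.frame` with columns `cluster`, `direction`, `LL`,
#'   `RR`, `LR`, `RL` (one row per cluster and direction); the list output
#'   of [hemisphere_budgets] rows can be bound into this form.
#' @param measure `"percent"` (default) or `"count"`.
#' @return List with `records` (the budgets plus `AI_ipsi`, `AI_contra`)
#'   and `correlation`, a per-direction list of [spearman_rho] results or
#'   an `insufficient_data` marker when fewer than 3 clusters have defined
#'   values.
#' @export
symmetry_report <- function(budgets, measure = c("percent", "count")) {
  measure <- match.arg(measure)
  need <- c("cluster", "direction", "LL", "RR", "LR", "RL")
  miss <- setdiff(need, names(budgets))
  if (length(miss))
    abort_validation(paste0("budget table missing column(s): ",
                            paste(miss, collapse = ", ")))
  if (!nrow(budgets))
    abort_insufficient("no clusters with defined budgets")
  rec <- budgets
  rec$AI_ipsi <- suppressMessages(asymmetry_index(rec$LL, rec$RR))
  rec$AI_contra <- suppressMessages(asymmetry_index(rec$LR, rec$RL))
  correlation <- lapply(split(rec, rec$direction), function(d) {
    if (measure == "percent") {
      xi <- ifelse(d$LL + d$RR == 0, NA_real_, 100 * d$LL / (d$LL + d$RR))
      yc <- ifelse(d$LR + d$RL == 0, NA_real_, 100 * d$LR / (d$LR + d$RL))
    } else {
      xi <- d$LL + d$RR
      yc <- d$LR + d$RL
    }
    tryCatch(spearman_rho(xi, yc),
             vagusnet_insufficient_data_error = function(e)
               list(insufficient_data = TRUE, message = conditionMessage(e)))
  })
  list(records = rec, correlation = correlation, measure = measure)
}

#' Write a symmetry report to CSV + JSON
#'
#' @param report Output of [symmetry_report].
#' @param csv_path,json_path Output paths.
#' @export
write_symmetry_report <- function(report, csv_path, json_path) {
  utils::write.csv(report$records, csv_path, row.names = FALSE)
  jsonlite::write_json(report$correlation, json_path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(csv_path)
}
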