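#' Measure specifications for the correlation matrix
#'
#' The eight adherence/attendance measures (plus derived coverage thresholds)
#' in their reporting order, each tagged continuous or binary. Pairs of
#' continuous measures are correlated with Pearson's r; pairs with at least
#' one binary member use Kendall's tau-b.
#'
#' @return Tibble with `name`, `label`, `kind`.
#' @export
measure_specs <- function() {
  tibble::tribble(
    ~name, ~label, ~kind,
    "pct_days_covered", "% of days covered", "continuous",
    "coverage_gt80", "Coverage >80%", "binary",
    "coverage_gt95", "Coverage >95%", "binary",
    "gap_gt30", "Coverage gap >30 days", "binary",
    "avg_selfreport", "Average self-report adherence", "continuous",
    "any_imperfect_selfreport", "Any self-report adherence less than perfect", "binary",
    "pct_visits_on_or_before", "% of visits on or before scheduled day", "continuous",
    "pct_visits_within_3d", "% of visits within 3 days of scheduled day", "continuous",
    "pct_visits_before_exhaustion", "% of visits before last dispensing finished", "continuous"
  )
}

# adds the derived threshold columns the matrix needs
measure_columns <- function(snapshots) {
  dplyr::mutate(
    snapshots,
    coverage_gt80 = .data$pct_days_covered > 80,
    coverage_gt95 = .data$pct_days_covered > 95
  )
}

#' Pearson product-moment correlation cell
#'
#' @param x,y Numeric vectors; incomplete pairs are dropped.
#' @return One-row tibble: `method`, `estimate`, `p_value`, `n`, `note`
#'   (the estimate is absent, with a reason, when either vector has zero
#'   variance or fewer than 3 complete pairs remain).
#' @export
pearson_r <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  cell <- function(est, p, note = NA_character_) {
    tibble::tibble(method = "pearson", estimate = est, p_value = p,
                   n = n, note = note)
  }
  if (n < 3L) return(cell(NA_real_, NA_real_, "fewer than 3 complete pairs"))
  if (sd(x) == 0 || sd(y) == 0) return(cell(NA_real_, NA_real_, "zero variance"))
  ct <- cor.test(x, y, method = "pearson")
  cell(unname(ct$estimate), ct$p.value)
}

#' Kendall tau-b correlation cell
#'
#' Tie-corrected Kendall rank correlation; equals exhaustive
#' concordant/discordant pair counting with tie correction. The p-value uses
#' the two-sided normal approximation with tie-corrected variance; with
#' `exact = TRUE` and at most 7 observations, a full-enumeration permutation
#' p-value is computed instead.
#'
#' @param x,y Vectors (numeric or logical); incomplete pairs are dropped.
#' @param exact Use the exact permutation p-value (n <= 7 only).
#' @return One-row tibble as in [pearson_r()], with `method = "kendall"`.
#' @export
kendall_tau <- function(x, y, exact = FALSE) {
  ok <- complete.cases(x, y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  cell <- function(est, p, note = NA_character_) {
    tibble::tibble(method = "kendall", estimate = est, p_value = p,
                   n = n, note = note)
  }
  if (n < 3L) return(cell(NA_real_, NA_real_, "fewer than 3 complete pairs"))
  if (sd(x) == 0 || sd(y) == 0) {
    return(cell(NA_real_, NA_real_, "all observations tied"))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "kendall", exact = FALSE))
  est <- unname(ct$estimate)
  if (exact) {
    if (n > 7L) abort("exact permutation p-value is only enumerable for n <= 7")
    perms <- permutations_of(n)
    tau0 <- abs(est)
    taus <- apply(perms, 1L, function(pp) {
      suppressWarnings(stats::cor(x, y[pp], method = "kendall"))
    })
    p <- mean(abs(taus) >= tau0 - 1e-12)
    return(cell(est, p))
  }
  cell(est, ct$p.value)
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Correlation matrix among adherence measures
#'
#' Pairwise correlations among the measures of [measure_specs()], computed on
#' snapshots taken at the index visit. The coefficient is Pearson's r iff
#' both measures are continuous, Kendall's tau-b otherwise; each cell uses
#' pairwise-complete observations, so n varies by pair (self-report pairs
#' drop 2-level-scale patients; timeliness pairs drop patients with no
#' recorded scheduled dates).
#'
#' @param snapshots Tibble from [cohort_snapshots()] (`at = "index"`).
#' @param specs Measure specification tibble (default [measure_specs()]).
#' @return A `correlation_matrix`: tibble of cells (`measure1`, `measure2`,
#'   `method`, `estimate`, `p_value`, `n`, `note`) for every unordered pair.
#' @export
correlation_matrix <- function(snapshots, specs = measure_specs()) {
  dat <- measure_columns(snapshots)
  miss <- setdiff(specs$name, names(dat))
  if (length(miss)) {
    abort(paste("snapshots lack measure column(s):", paste(miss, collapse = ", ")))
  }
  pairs <- utils::combn(seq_len(nrow(specs)), 2L)
  cells <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    x <- dat[[specs$name[i1]]]
    y <- dat[[specs$name[i2]]]
    cell <- if (specs$kind[i1] == "continuous" && specs$kind[i2] == "continuous") {
      pearson_r(x, y)
    } else {
      kendall_tau(x, y)
    }
    dplyr::mutate(cell, measure1 = specs$name[i1], measure2 = specs$name[i2],
                  .before = 1L)
  })
  structure(dplyr::bind_rows(cells), class = c("correlation_matrix",
                                               class(tibble::tibble())))
}

#' @method autoplot correlation_matrix
#' @export
autoplot.correlation_matrix <- function(object, ...) {
  lv <- unique(c(object$measure1, object$measure2))
  df <- dplyr::mutate(object,
                      measure1 = factor(.data$measure1, levels = lv),
                      measure2 = factor(.data$measure2, levels = rev(lv)))
  ggplot2::ggplot(df, ggplot2::aes(.data$measure1, .data$measure2,
                                   fill = .data$estimate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$estimate), "", sprintf("%.2f", .data$estimate))
    ), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "r / tau-b") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 40, hjust = 1))
}
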