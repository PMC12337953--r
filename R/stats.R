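#' @include AllClasses.R
NULL

.checkGroups <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  small <- names(groups)[vapply(groups, length, integer(1)) < 2L]
  if (length(small))
    stop("every group needs >= 2 observations; offending: ",
         paste(small, collapse = ", "))
  groups
}

.stackGroups <- function(groups) {
  data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)),
                   levels = names(groups))
  )
}

#' One-way ANOVA across proteome groups
#'
#' Classical fixed-effects one-way ANOVA of per-protein scalars (ADS, PPDR,
#' PS scores) pooled by proteome.
#'
#' @param groups named list of numeric vectors, one per group (>= 2 groups,
#'   each with >= 2 observations).
#' @return list with \code{f_stat}, \code{df_between}, \code{df_within},
#'   \code{p_value}.
#' @examples
#' oneWayAnova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))
#' @export
oneWayAnova <- function(groups) {
  groups <- .checkGroups(groups)
  d <- .stackGroups(groups)
  if (stats::var(d$value) == 0)
    stop("degenerate data: zero variance within and between groups")
  fit <- stats::oneway.test(value ~ group, data = d, var.equal = TRUE)
  list(f_stat = unname(fit$statistic),
       df_between = as.integer(fit$parameter[["num df"]]),
       df_within = as.integer(fit$parameter[["denom df"]]),
       p_value = unname(fit$p.value))
}

#' Tukey HSD pairwise comparisons
#'
#' All pairwise mean differences with studentized-range family-wise adjusted
#' p-values, as used for comparing mean scores between proteomes.
#'
#' @inheritParams oneWayAnova
#' @return \code{data.frame} with columns group_a, group_b, diff, lwr, upr,
#'   p_adj; exactly \eqn{k(k-1)/2} rows for k groups.
#' @export
tukeyHsd <- function(groups) {
  groups <- .checkGroups(groups)
  d <- .stackGroups(groups)
  tk <- stats::TukeyHSD(stats::aov(value ~ group, data = d))$group
  pair <- strsplit(rownames(tk), "-", fixed = TRUE)
  data.frame(
    group_a = vapply(pair, `[`, character(1), 1L),
    group_b = vapply(pair, `[`, character(1), 2L),
    diff = unname(tk[, "diff"]), lwr = unname(tk[, "lwr"]),
    upr = unname(tk[, "upr"]), p_adj = unname(tk[, "p adj"]),
    row.names = NULL
  )
}

#' Pairwise t-tests between groups
#'
#' Welch (unequal-variance) two-sample t-tests for every pair of groups,
#' with optional multiplicity correction (none by default; Tukey HSD is
#' reported separately).
#'
#' @inheritParams oneWayAnova
#' @param correction a \code{p.adjust} method (default \code{"none"}).
#' @param pooled use the pooled-variance (Student) t instead of Welch.
#' @return \code{data.frame} with columns group_a, group_b, diff, statistic,
#'   p_value, p_adj.
#' @export
pairwiseT <- function(groups, correction = "none", pooled = FALSE) {
  groups <- .checkGroups(groups)
  nm <- names(groups)
  pairs <- utils::combn(nm, 2L)
  rows <- apply(pairs, 2L, function(ab) {
    x <- groups[[ab[1]]]; y <- groups[[ab[2]]]
    if (stats::var(x) == 0 && stats::var(y) == 0)
      stop("degenerate variance: both '", ab[1], "' and '", ab[2],
           "' are constant")
    tt <- stats::t.test(x, y, var.equal = pooled)
    data.frame(group_a = ab[1], group_b = ab[2],
               diff = mean(x) - mean(y),
               statistic = unname(tt$statistic),
               p_value = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_value, method = correction)
  out
}

#' Pearson chi-squared test on a contingency table
#'
#' Plain Pearson statistic (no continuity correction) on an r x c table of
#' counts, e.g. the proteome-by-quadrant table from
#' [quadrantContingency()]. Expected counts are \eqn{E_{ij} = row_i \times
#' col_j / N} and \eqn{dof = (r-1)(c-1)}.
#'
#' @param table numeric matrix of non-negative counts with positive row and
#'   column sums.
#' @return list with \code{chi2}, \code{dof}, \code{p_value},
#'   \code{expected} (matrix with the observed margins).
#' @export
chiSquaredTest <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(!is.finite(table)))
    stop("counts must be finite and non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("every row and column must have a positive sum")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(chi2 = unname(ct$statistic),
       dof = as.integer(ct$parameter),
       p_value = unname(ct$p.value),
       expected = ct$expected)
}
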