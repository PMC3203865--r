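#' Per-condition response counts
#'
#' @param n_g,n_l,n_n Non-negative integer counts of global, local and
#'   non-responsive cells.
#' @return An object of class `response_counts` with fields `n_g`, `n_l`,
#'   `n_n`, `N`.
#' @export
response_counts <- function(n_g, n_l, n_n) {
  v <- c(n_g, n_l, n_n)
  if (any(v < 0) || any(v != round(v)))
    stop_param("counts must be non-negative integers")
  N <- sum(v)
  if (N < 1) stop_param("total count N must be >= 1")
  structure(list(n_g = as.integer(n_g), n_l = as.integer(n_l),
                 n_n = as.integer(n_n), N = as.integer(N)),
            class = "response_counts")
}

#' Multinomial proportion estimates with standard deviations
#'
#' The three response probabilities are estimated as count fractions,
#' `p_k = n_k / N`, with the standard deviation of each estimate given by
#' the marginal binomial form `sqrt(p_k * (1 - p_k) / N)` — the standard
#' estimator for one component of a multinomial.
#'
#' @param counts A [response_counts()].
#' @return An object of class `proportion_estimate` with numeric vectors
#'   `p` and `sd` (named `global`, `local`, `none`) and the total `N`.
#' @examples
#' estimate_proportions(response_counts(8, 2, 0))
#' @export
estimate_proportions <- function(counts) {
  stopifnot(inherits(counts, "response_counts"))
  n <- c(global = counts$n_g, local = counts$n_l, none = counts$n_n)
  p <- n / counts$N
  structure(list(p = p, sd = sqrt(p * (1 - p) / counts$N), N = counts$N),
            class = "proportion_estimate")
}

#' @export
print.proportion_estimate <- function(x, ...) {
  cat(sprintf("proportions (N = %d):\n", x$N))
  for (k in names(x$p))
    cat(sprintf("  %-6s p = %.4f (sd %.4f)\n", k, x$p[k], x$sd[k]))
  invisible(x)
}

# All tables compatible with the given margins, enumerated recursively
# row by row (compositions of each row margin bounded by the remaining
# column margins). Returns a matrix with one table per row (cells in
# row-major order).
enumerate_margin_tables <- function(row_margins, col_margins) {
  nc <- length(col_margins)
  compositions <- function(total, caps) {
    if (length(caps) == 1L) {
      if (total <= caps) return(matrix(total, 1, 1))
      return(matrix(0, 0, 1))
    }
    out <- list()
    for (v in 0:min(total, caps[1])) {
      rest <- compositions(total - v, caps[-1])
      if (nrow(rest)) out[[length(out) + 1L]] <- cbind(v, rest)
    }
    if (!length(out)) return(matrix(0, 0, length(caps)))
    do.call(rbind, out)
  }
  recurse <- function(rows_left, cols_remaining) {
    if (length(rows_left) == 1L) {
      # last row is forced by the column margins
      return(matrix(cols_remaining, 1, nc))
    }
    first <- compositions(rows_left[1], cols_remaining)
    out <- list()
    for (i in seq_len(nrow(first))) {
      rest <- recurse(rows_left[-1], cols_remaining - first[i, ])
      out[[length(out) + 1L]] <-
        cbind(matrix(first[i, ], nrow(rest), nc, byrow = TRUE), rest)
    }
    do.call(rbind, out)
  }
  recurse(row_margins, col_margins)
}

# Log multivariate-hypergeometric probability of each table (rows of
# `tables`, cells row-major) under fixed margins.
log_table_prob <- function(tables, row_margins, col_margins) {
  const <- sum(lgamma(row_margins + 1)) + sum(lgamma(col_margins + 1)) -
    lgamma(sum(row_margins) + 1)
  const - rowSums(lgamma(tables + 1))
}

#' Exact (Freeman-Halton) test of independence for an r x c table
#'
#' Exact conditional test with both margins fixed: all tables with the
#' observed margins are enumerated, and the p-value is the total
#' multivariate-hypergeometric probability of tables whose probability does
#' not exceed that of the observed table (with a relative slack of 1e-12
#' on the comparison, so floating-point ties are counted). For a 2 x 2
#' table this is the classic two-sided Fisher exact test; for larger
#' tables it is the Freeman-Halton extension. Rows or columns whose margin
#' is zero are dropped with a warning; a table reduced to a single row or
#' column admits only one outcome and yields p = 1.
#'
#' @param table Non-negative integer matrix (conditions x classes).
#' @param detail If `TRUE`, also return the enumerated tables and their
#'   probabilities.
#' @return The p-value, or with `detail = TRUE` a list with `p.value`,
#'   `tables`, `probs` and `observed_prob`.
#' @examples
#' fisher_exact(matrix(c(3, 1, 1, 3), 2, 2))   # 0.4857...
#' @export
fisher_exact <- function(table, detail = FALSE) {
  m <- as.matrix(table)
  if (any(m < 0) || any(m != round(m)))
    stop_param("table cells must be non-negative integers")
  rs <- rowSums(m); cs <- colSums(m)
  if (any(rs == 0) || any(cs == 0)) {
    warning("dropping rows/columns with zero margin")
    m <- m[rs > 0, cs > 0, drop = FALSE]
    rs <- rowSums(m); cs <- colSums(m)
  }
  if (nrow(m) < 2L || ncol(m) < 2L) {
    if (length(m) == 0L) stop_param("empty table after margin reduction")
    p <- 1
    if (!detail) return(p)
    return(list(p.value = p, tables = matrix(as.vector(t(m)), 1),
                probs = 1, observed_prob = 1))
  }
  tables <- enumerate_margin_tables(rs, cs)
  lp <- log_table_prob(tables, rs, cs)
  lp_obs <- log_table_prob(matrix(as.vector(t(m)), 1), rs, cs)
  probs <- exp(lp)
  p <- sum(probs[lp <= lp_obs + log1p(1e-12)])
  p <- min(p, 1)
  if (!detail) return(p)
  list(p.value = p, tables = tables, probs = probs,
       observed_prob = exp(lp_obs))
}

#' Compare a treated condition against the control
#'
#' Builds the 2 x 3 contingency table of (global, local, none) counts for
#' the control and treated conditions, runs the exact test of independence
#' ([fisher_exact()]; class columns empty in both conditions are dropped),
#' and reports both proportion estimates. Significance is flagged at
#' p < 0.05.
#'
#' @param control,treated [response_counts()] for the two conditions.
#' @return A list with `p.value`, `significant`, `table`,
#'   `control_estimate`, `treated_estimate`.
#' @export
compare_conditions <- function(control, treated) {
  stopifnot(inherits(control, "response_counts"),
            inherits(treated, "response_counts"))
  tab <- rbind(control = c(global = control$n_g, local = control$n_l,
                           none = control$n_n),
               treated = c(treated$n_g, treated$n_l, treated$n_n))
  p <- fisher_exact(tab)  # empty class columns dropped there, with a warning
  list(p.value = p, significant = p < 0.05, table = tab,
       control_estimate = estimate_proportions(control),
       treated_estimate = estimate_proportions(treated))
}

#' Cohort-level report: proportions per condition and tests vs control
#'
#' Tallies the classified responses of each condition, estimates the
#' multinomial proportions with their standard deviations (the bar-graph /
#' error-bar content of a cohort figure), and tests every non-control
#' condition against the control with the exact contingency-table test.
#'
#' @param records Data frame with columns `condition` and `class` (values
#'   in `global`, `local`, `none`), one row per cell.
#' @param control Name of the control condition (default `"control"`).
#' @return An object of class `cohort_report`: `estimates` (data frame
#'   with counts, proportions and sds per condition) and `tests` (data
#'   frame of p-values vs control; empty when only the control is present).
#' @export
cohort_report <- function(records, control = "control") {
  if (!all(c("condition", "class") %in% names(records)))
    stop_param("'records' needs columns 'condition' and 'class'")
  bad <- setdiff(unique(records$class), c("global", "local", "none"))
  if (length(bad))
    stop_param("unknown class label(s): %s", paste(bad, collapse = ", "))
  conds <- unique(as.character(records$condition))
  if (!control %in% conds)
    stop_param("no '%s' condition in the records", control)
  counts <- lapply(setNames(conds, conds), function(cn) {
    cl <- records$class[records$condition == cn]
    response_counts(sum(cl == "global"), sum(cl == "local"),
                    sum(cl == "none"))
  })
  est <- do.call(rbind, lapply(conds, function(cn) {
    e <- estimate_proportions(counts[[cn]])
    data.frame(condition = cn, N = e$N,
               n_global = counts[[cn]]$n_g, n_local = counts[[cn]]$n_l,
               n_none = counts[[cn]]$n_n,
               p_global = e$p[["global"]], p_local = e$p[["local"]],
               p_none = e$p[["none"]],
               sd_global = e$sd[["global"]], sd_local = e$sd[["local"]],
               sd_none = e$sd[["none"]])
  }))
  others <- setdiff(conds, control)
  tests <- if (length(others)) {
    do.call(rbind, lapply(others, function(cn) {
      cmp <- suppressWarnings(compare_conditions(counts[[control]],
                                                 counts[[cn]]))
      data.frame(condition = cn, p_value = cmp$p.value,
                 significant = cmp$significant)
    }))
  } else data.frame(condition = character(0), p_value = numeric(0),
                    significant = logical(0))
  structure(list(estimates = est, tests = tests, control = control),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("cohort_report\n")
  print(x$estimates, row.names = FALSE)
  if (nrow(x$tests)) {
    cat(sprintf("exact tests vs '%s' (significant at p < 0.05):\n",
                x$control))
    print(x$tests, row.names = FALSE)
  }
  invisible(x)
}
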