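# Contingency tabulation, Pearson chi-square and logistic regression --
# the analysis layer that turns coded records (or the shipped count
# fixtures) into the published tables and test statistics.

#' Labelled contingency table
#'
#' Validates a count matrix (non-negative integers) and attaches margins.
#'
#' @param counts Integer matrix with row/column dimnames.
#' @param row_var,col_var Optional variable names for labelling.
#' @return A `contingency_table`: counts, row/col margins, `N`.
#' @export
contingency_table <- function(counts, row_var = NULL, col_var = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  structure(list(counts = counts,
                 row_margin = rowSums(counts),
                 col_margin = colSums(counts),
                 N = sum(counts),
                 row_var = row_var, col_var = col_var),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> %s x %s, N=%d\n",
              x$row_var %||% "rows", x$col_var %||% "cols", x$N))
  print(x$counts)
  invisible(x)
}

# Level order and display labels for a schema variable.
var_levels <- function(records, var) {
  sch <- coded_schema()
  if (var %in% names(sch$levels)) return(sch$levels[[var]])
  if (var %in% sch$symptoms ||
      var %in% c("witness", "sought_assistance", "delayed_assistance",
                 "immediate_treatment") ||
      var %in% c("any_traditional", "any_nontraditional",
                 "any_nontraditional_excl_msc")) {
    return(c("yes", "no"))
  }
  sort(unique(stats::na.omit(as.character(records[[var]]))))
}

var_values <- function(records, var) {
  x <- records[[var]]
  if (is.logical(x)) ifelse(is.na(x), NA_character_, ifelse(x, "yes", "no"))
  else as.character(x)
}

#' Cross-tabulate coded records
#'
#' Counts record pairs over two schema variables, using only records
#' where both are non-missing. Logical symptom variables are labelled
#' yes/no (yes first); categorical variables follow the schema's level
#' order. The derived group flags of [derive_flags()] are computed on
#' the fly when requested.
#'
#' @param records Coded records data frame.
#' @param row_var,col_var Variable names.
#' @param filter Optional logical vector or predicate function on
#'   `records` selecting the analysis subset.
#' @return A [contingency_table()]. Rows/columns whose margin is zero
#'   are dropped.
#' @export
crosstab <- function(records, row_var, col_var, filter = NULL) {
  records <- as_coded_df(records)
  derived <- c("any_traditional", "any_nontraditional",
               "any_nontraditional_excl_msc")
  if (any(c(row_var, col_var) %in% derived)) {
    records <- cbind(records, derive_flags(records))
  }
  for (v in c(row_var, col_var)) {
    if (!v %in% names(records)) stop("unknown variable: ", v, call. = FALSE)
  }
  keep <- rep(TRUE, nrow(records))
  if (!is.null(filter)) {
    keep <- if (is.function(filter)) filter(records) else filter
    keep[is.na(keep)] <- FALSE
  }
  sub <- records[keep, , drop = FALSE]
  rv <- var_values(sub, row_var)
  cv <- var_values(sub, col_var)
  ok <- !is.na(rv) & !is.na(cv)
  if (!any(ok)) {
    stop(sprintf("empty selection for %s x %s%s", row_var, col_var,
                 if (is.null(filter)) "" else " under the supplied filter"),
         call. = FALSE)
  }
  tab <- table(factor(rv[ok], levels = var_levels(records, row_var)),
               factor(cv[ok], levels = var_levels(records, col_var)))
  m <- matrix(as.integer(tab), nrow = nrow(tab), dimnames = dimnames(tab))
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  contingency_table(m, row_var, col_var)
}

#' Chi-square survival function
#'
#' Upper-tail probability of the chi-square distribution, the p-value
#' scale used by all tests in the package. For `df = 2` it equals
#' `exp(-x/2)` exactly.
#'
#' @param x Non-negative statistic.
#' @param df Degrees of freedom (>= 1).
#' @return `P(X >= x)`.
#' @export
chi2_sf <- function(x, df) {
  stopifnot(all(x >= 0), all(df >= 1))
  stats::pchisq(x, df, lower.tail = FALSE)
}

#' Pearson chi-square test of independence
#'
#' `X^2 = sum (O - E)^2 / E` with `E = row * col / N`,
#' `df = (r-1)(c-1)`, no continuity correction (required to reproduce
#' the published p-values from their printed counts). Expected counts
#' below 5 trigger a warning, not a switch to an exact test.
#'
#' @param tab A [contingency_table()] or count matrix. Every margin must
#'   be positive.
#' @return A `test_result`: `statistic`, `df`, `p`, and the printed
#'   renderings `p_printed_2dp`, `p_printed_3dp`.
#' @export
pearson_chi2 <- function(tab) {
  if (!inherits(tab, "contingency_table")) tab <- contingency_table(tab)
  if (any(tab$row_margin == 0) || any(tab$col_margin == 0)) {
    stop("zero margin in contingency table", call. = FALSE)
  }
  O <- tab$counts
  E <- outer(tab$row_margin, tab$col_margin) / tab$N
  if (any(E < 5)) {
    warning(sprintf("%d expected count(s) below 5 (min %.2f)",
                    sum(E < 5), min(E)), call. = FALSE)
  }
  statistic <- sum((O - E)^2 / E)
  df <- (nrow(O) - 1L) * (ncol(O) - 1L)
  p <- chi2_sf(statistic, df)
  fp <- format_p(p)
  structure(list(statistic = statistic, df = df, p = p,
                 p_printed_2dp = fp[["p_2dp"]], p_printed_3dp = fp[["p_3dp"]]),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("X-squared = %.4f, df = %d, p = %s (2dp %s)\n",
              x$statistic, x$df, x$p_printed_3dp, x$p_printed_2dp))
  invisible(x)
}

#' Render a p-value in publication style
#'
#' Both the 2- and 3-decimal renderings with the leading zero dropped
#' (".056", ".01"); values of 1 keep their integer part ("1.00").
#'
#' @param p Probability in [0, 1].
#' @return Named character vector with elements `p_2dp` and `p_3dp`.
#' @export
format_p <- function(p) {
  stopifnot(p >= 0, p <= 1)
  fmt <- function(d) sub("^0\\.", ".", sprintf(paste0("%.", d, "f"), p))
  c(p_2dp = fmt(2), p_3dp = fmt(3))
}

#' Logistic regression with Wald, likelihood-ratio and score tests
#'
#' Binomial maximum-likelihood fit (iteratively reweighted least squares
#' via `glm`, deviance tolerance 1e-10, at most 50 iterations). Reports
#' per-coefficient Wald tests and model-level likelihood-ratio and Rao
#' score tests against the intercept-only model. On a 2x2 problem the
#' score test is algebraically identical to the Pearson chi-square.
#' Complete separation is flagged (any |coefficient| > 15 marks the fit
#' non-converged) rather than silently returned.
#'
#' @param outcome Binary (0/1 or logical) response vector.
#' @param design Numeric design matrix, or a single predictor vector. An
#'   intercept column is prepended unless the first column is constant 1.
#' @return A `logistic_fit`: `coefficients`, `se`, `wald_z`, `wald_p`,
#'   `lrt_stat`/`lrt_p`, `score_stat`/`score_p`, `df`, `converged`,
#'   `iterations`.
#' @export
fit_logistic <- function(outcome, design) {
  y <- as.numeric(outcome)
  stopifnot(all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L) {
    stop("degenerate outcome: all responses identical", call. = FALSE)
  }
  X <- as.matrix(design)
  if (!all(X[, 1] == 1)) X <- cbind(`(Intercept)` = 1, X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)) - 1L)
  colnames(X)[colnames(X) == ""] <- paste0("x", which(colnames(X) == ""))
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient", call. = FALSE)
  fit <- stats::glm.fit(X, y, family = stats::binomial(),
                        control = stats::glm.control(epsilon = 1e-10, maxit = 50))
  beta <- fit$coefficients
  # Wald: inverse Fisher information at the MLE
  mu <- fit$fitted.values
  W <- mu * (1 - mu)
  info <- crossprod(X * sqrt(W))
  vcov <- solve(info)
  se <- sqrt(diag(vcov))
  wald_z <- beta / se
  wald_p <- 2 * stats::pnorm(-abs(wald_z))
  # LRT and Rao score: full model vs intercept-only
  df_test <- ncol(X) - 1L
  lrt_stat <- max(0, fit$null.deviance - fit$deviance)
  lrt_p <- if (df_test > 0) chi2_sf(lrt_stat, df_test) else NA_real_
  p0 <- mean(y)
  U <- crossprod(X, y - p0)
  V <- p0 * (1 - p0) * crossprod(X)
  score_stat <- max(0, drop(t(U) %*% solve(V, U)))
  score_p <- if (df_test > 0) chi2_sf(score_stat, df_test) else NA_real_
  converged <- fit$converged && all(abs(beta) <= 15)
  structure(list(coefficients = beta, se = se, vcov = vcov,
                 wald_z = wald_z, wald_p = wald_p,
                 lrt_stat = lrt_stat, lrt_p = lrt_p,
                 score_stat = score_stat, score_p = score_p,
                 df = df_test, converged = converged,
                 iterations = fit$iter,
                 deviance = fit$deviance,
                 null_deviance = fit$null.deviance),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic_fit>", if (!x$converged) "(NOT converged / separated)", "\n")
  print(data.frame(estimate = x$coefficients, se = x$se,
                   z = x$wald_z, wald_p = x$wald_p))
  cat(sprintf("LRT X2 = %.4f (p = %.4g); score X2 = %.4f (p = %.4g); df = %d\n",
              x$lrt_stat, x$lrt_p, x$score_stat, x$score_p, x$df))
  invisible(x)
}

#' Expand a printed contingency table into records
#'
#' Materialises individual records consistent with one printed count
#' table, so that record-level operations (crosstab, logistic fits) can
#' be exercised on published counts. Joint consistency across several
#' tables cannot be recovered from marginals and is not attempted.
#'
#' @param counts Matrix of counts; rows are levels of `row_var`, columns
#'   levels of `col_var` (use "yes"/"no" for symptom flags).
#' @param row_var,col_var Schema variable names.
#' @param fixed Named list of constant fields added to every record
#'   (e.g. `list(narrator = "first")`).
#' @return Data frame of records with columns `story_id`, `row_var`,
#'   `col_var` and the fixed fields.
#' @export
expand_table_records <- function(counts, row_var, col_var, fixed = list()) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry row and column labels (dimnames)", call. = FALSE)
  }
  decode <- function(var, lab) {
    sch <- coded_schema()
    if (var %in% sch$symptoms || !var %in% names(sch$levels)) {
      if (lab %in% c("yes", "no")) return(lab == "yes")
    }
    lab
  }
  rows <- list()
  k <- 0L
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      n <- counts[i, j]
      if (n == 0) next
      rec <- c(list(), fixed)
      rec[[row_var]] <- decode(row_var, rownames(counts)[i])
      rec[[col_var]] <- decode(col_var, colnames(counts)[j])
      rows <- c(rows, rep(list(rec), n))
      k <- k + n
    }
  }
  df <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  df <- cbind(story_id = sprintf("rec-%04d", seq_len(nrow(df))), df,
              stringsAsFactors = FALSE)
  df
}
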