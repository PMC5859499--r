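# Full-factorial fixed-effects variance decomposition.
#
# The crossover design is balanced by construction, so sums of squares for
# every main effect and interaction have the classical closed form via
# nested mean differencing (inclusion-exclusion over marginal means).  Mean
# squares are used descriptively - as the average contribution of each
# factor or interaction to the variability - not for F-tests.

#' Factorial ANOVA variance table
#'
#' Decomposes the total (centered) sum of squares of `response` over all
#' `2^k - 1` main effects and interactions of `k` factors, plus a residual.
#' Balanced complete designs use the exact closed-form decomposition;
#' unbalanced data fall back to sequential (Type-I) sums of squares via
#' [stats::aov()] in the factor order given, with a logged caveat.
#'
#' @param data data.frame with the factor columns and the response column.
#' @param factors character vector of factor column names (order matters
#'   only for the unbalanced fallback).
#' @param response response column name, typically `"cq"` or `"dcq"`.
#' @return a `variance_table`: data.frame with columns `term` (factor names
#'   joined by `:`), `df`, `ss`, `ms`, ordered by descending mean square
#'   with the residual row last.  Attributes: `response`, `method`,
#'   `total_ss`, `n`.
#' @export
factorial_anova <- function(data, factors, response = "cq") {
  stopifnot(is.data.frame(data), length(factors) >= 1L)
  missing_cols <- setdiff(c(factors, response), names(data))
  if (length(missing_cols) > 0L) {
    stop("column(s) not in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  y <- data[[response]]
  stopifnot(is.numeric(y), all(is.finite(y)))
  f <- lapply(data[factors], function(v) factor(as.character(v)))
  names(f) <- factors
  n <- length(y)
  total_ss <- sum((y - mean(y))^2)

  cell <- interaction(f, drop = FALSE)
  counts <- table(droplevels(cell))
  balanced <- length(counts) == prod(vapply(f, nlevels, integer(1))) &&
    length(unique(as.integer(counts))) == 1L

  if (balanced) {
    k <- length(factors)
    subsets <- lapply(seq_len(2^k - 1L), function(m) {
      which(bitwAnd(m, 2^(seq_len(k) - 1L)) > 0L)
    })
    # per-observation marginal mean for each subset of factors
    marg <- c(list(rep(mean(y), n)),
              lapply(subsets, function(s) {
                stats::ave(y, f[s], FUN = mean)
              }))
    rows <- lapply(subsets, function(s) {
      subs_of_s <- Filter(function(q) all(q %in% s), subsets)
      e <- (-1)^length(s) * marg[[1L]]
      for (q in subs_of_s) {
        idx <- match(sum(2^(q - 1L)),
                     vapply(subsets, function(z) sum(2^(z - 1L)), numeric(1)))
        e <- e + (-1)^(length(s) - length(q)) * marg[[idx + 1L]]
      }
      data.frame(
        term = paste(factors[s], collapse = ":"),
        df = prod(vapply(f[s], nlevels, integer(1)) - 1L),
        ss = sum(e^2), stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    resid_ss <- max(total_ss - sum(tab$ss), 0)
    resid_df <- n - prod(vapply(f, nlevels, integer(1)))
    method <- "balanced-closed-form"
  } else {
    message("design is unbalanced; using sequential (Type-I) sums of ",
            "squares in the order: ", paste(factors, collapse = ", "))
    df_aov <- data.frame(f, .y = y)
    form <- stats::as.formula(paste(".y ~", paste(factors, collapse = " * ")))
    sm <- summary(stats::aov(form, data = df_aov))[[1L]]
    term_names <- trimws(rownames(sm))
    is_resid <- term_names == "Residuals"
    tab <- data.frame(term = term_names[!is_resid],
                      df = sm$Df[!is_resid],
                      ss = sm$`Sum Sq`[!is_resid], stringsAsFactors = FALSE)
    resid_ss <- if (any(is_resid)) sm$`Sum Sq`[is_resid] else 0
    resid_df <- if (any(is_resid)) sm$Df[is_resid] else 0L
    method <- "sequential-type1"
  }

  tab$ms <- ifelse(tab$df > 0L, tab$ss / tab$df, NA_real_)
  tab <- tab[order(-tab$ms), , drop = FALSE]
  if (resid_df > 0L || resid_ss > 1e-12 * max(total_ss, 1)) {
    tab <- rbind(tab, data.frame(
      term = "residual", df = resid_df, ss = resid_ss,
      ms = if (resid_df > 0L) resid_ss / resid_df else NA_real_))
  }
  rownames(tab) <- NULL
  structure(tab, class = c("variance_table", "data.frame"),
            response = response, method = method, total_ss = total_ss,
            n = n)
}

#' Filter a variance table by mean square
#'
#' Keeps rows whose mean square is at least `ms_threshold` (default 1 Cq^2),
#' preserving the order - the convention used when reporting only the
#' factors that contribute visibly to variability.
#'
#' @param table a `variance_table` from [factorial_anova()].
#' @param ms_threshold minimum mean square retained.
#' @return filtered `variance_table` (attributes preserved).
#' @export
filter_report <- function(table, ms_threshold = 1) {
  stopifnot(inherits(table, "variance_table"))
  keep <- !is.na(table$ms) & table$ms >= ms_threshold
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("response", "method", "total_ss", "n")] <-
    attributes(table)[c("response", "method", "total_ss", "n")]
  class(out) <- class(table)
  out
}

#' @export
print.variance_table <- function(x, ...) {
  cat(sprintf("Variance decomposition of '%s' (%s), n = %d, total SS = %.4g\n",
              attr(x, "response"), attr(x, "method"), attr(x, "n"),
              attr(x, "total_ss")))
  print.data.frame(x, ...)
  invisible(x)
}
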