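# Grid search over mixture-fraction pairs.
#
# The goal of a reference-sample pair is a useful spread of designed-in
# abundance differences: every target analyte's predicted |dCq| within a
# usable band (default one cycle, i.e. two-fold up or down), differences in
# both directions represented, and analytes well separated in the
# Bland-Altman (mean Cq, dCq) plane so the pattern is diagnostic.

#' Enumerate candidate mixture-design pairs on a fraction grid
#'
#' Builds all distinct simplex points whose per-component weights are drawn
#' from `grid`, then all unordered pairs of distinct points.  A pair and its
#' label-swapped twin (Mix1 and Mix2 exchanged, which only flips the sign of
#' every dCq) count as one candidate.
#'
#' @param components character vector of component identifiers.
#' @param grid numeric vector of allowed per-component weights.
#' @param grid_type `"ratio"` (default): every weight combination is
#'   normalized to the simplex; `"fraction"`: only combinations already
#'   summing to 1 (within 1e-9) are kept, unnormalized.
#' @return list of pairs; each element is a list of two [mixture_design()]s
#'   named `"Mix1"` and `"Mix2"`.
#' @examples
#' length(enumerate_designs(c("A", "B", "C"), grid = c(1, 3)))
#' @export
enumerate_designs <- function(components, grid,
                              grid_type = c("ratio", "fraction")) {
  grid_type <- match.arg(grid_type)
  stopifnot(length(components) >= 2L, length(grid) >= 1L)
  tuples <- as.matrix(expand.grid(rep(list(grid), length(components)),
                                  KEEP.OUT.ATTRS = FALSE))
  sums <- rowSums(tuples)
  if (grid_type == "fraction") {
    tuples <- tuples[abs(sums - 1) <= 1e-9, , drop = FALSE]
  } else {
    tuples <- tuples[sums > 0, , drop = FALSE]
    tuples <- tuples / rowSums(tuples)
  }
  key <- apply(round(tuples, 12L), 1L, paste, collapse = ",")
  points <- tuples[!duplicated(key), , drop = FALSE]
  n <- nrow(points)
  pairs <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      pairs[[length(pairs) + 1L]] <- list(
        Mix1 = mixture_design("Mix1", components, fractions = points[i, ]),
        Mix2 = mixture_design("Mix2", components, fractions = points[j, ])
      )
    }
  }
  pairs
}

#' Score a candidate design pair against component profiles
#'
#' Predicts both mixtures from the collapsed pure-component profiles
#' (averaged over all measurement strata), forms per-analyte Bland-Altman
#' points, and evaluates feasibility and a separation score.
#'
#' Feasible means: every analyte's predicted |dCq| is at most
#' `max_abs_dcq`, and both signs of dCq occur (so the pair discriminates in
#' both directions).  The score is the minimum pairwise Euclidean distance
#' between analyte points in the (mean Cq / `scale[1]`, dCq / `scale[2]`)
#' plane: larger means the analytes are better separated.
#'
#' @param pair list of two [mixture_design()]s (as from
#'   [enumerate_designs()]).
#' @param profiles collapsed pure-cell-line Cq table.
#' @param max_abs_dcq feasibility bound on |dCq| (cycles, default 1).
#' @param min_separation minimum score required for feasibility (default 0).
#' @param scale per-axis scale constants (cycles) for the score metric.
#' @param exclude_analytes analytes ignored when scoring (e.g. a
#'   normalization control).
#' @return object of class `design_candidate`: list with `pair`, `points`
#'   (per-analyte Bland-Altman data.frame), `score`, `feasible`,
#'   `max_observed_dcq`.
#' @export
score_design_pair <- function(pair, profiles, max_abs_dcq = 1,
                              min_separation = 0, scale = c(1, 1),
                              exclude_analytes = character()) {
  prof <- profiles[!profiles$analyte %in% toupper(exclude_analytes), ,
                   drop = FALSE]
  pred <- predict_pair_profiles(prof, pair, incomplete = "error")
  m1 <- pred[pred$sample == toupper(pair[[1]]$name), ]
  m2 <- pred[pred$sample == toupper(pair[[2]]$name), ]
  avg1 <- tapply(m1$cq, m1$analyte, mean)
  avg2 <- tapply(m2$cq, m2$analyte, mean)
  points <- bland_altman(avg1, avg2)
  dcq <- points$delta_cq
  feasible <- all(abs(dcq) <= max_abs_dcq) && any(dcq > 0) && any(dcq < 0)
  score <- NA_real_
  if (feasible) {
    xy <- cbind(points$mean_cq / scale[1], points$delta_cq / scale[2])
    score <- if (nrow(xy) < 2L) Inf else min(stats::dist(xy))
    feasible <- score >= min_separation
    if (!feasible) score <- NA_real_
  }
  structure(list(pair = pair, points = points, score = score,
                 feasible = feasible, max_observed_dcq = max(abs(dcq))),
            class = "design_candidate")
}

#' @export
print.design_candidate <- function(x, ...) {
  cat(sprintf("<design_candidate> %s vs %s | feasible: %s | score: %s\n",
              paste(sprintf("%.3g", x$pair[[1]]$fractions), collapse = ":"),
              paste(sprintf("%.3g", x$pair[[2]]$fractions), collapse = ":"),
              x$feasible,
              ifelse(is.na(x$score), "-", sprintf("%.4f", x$score))))
  invisible(x)
}

#' Rank scored design candidates
#'
#' Feasible candidates sorted by descending score; ties broken by smaller
#' maximum |dCq|, then lexicographically on the concatenated fractions, so
#' the ordering is deterministic.
#'
#' @param candidates list of `design_candidate` objects.
#' @return list of feasible candidates in rank order (empty, with a warning,
#'   if none is feasible).
#' @export
rank_designs <- function(candidates) {
  stopifnot(all(vapply(candidates, inherits, logical(1), "design_candidate")))
  feas <- Filter(function(c) isTRUE(c$feasible), candidates)
  if (length(feas) == 0L) {
    warning("no feasible candidate", call. = FALSE)
    return(list())
  }
  score <- vapply(feas, `[[`, numeric(1), "score")
  maxd <- vapply(feas, `[[`, numeric(1), "max_observed_dcq")
  lex <- vapply(feas, function(c) {
    paste(sprintf("%.12f", c(c$pair[[1]]$fractions, c$pair[[2]]$fractions)),
          collapse = ",")
  }, character(1))
  feas[order(-score, maxd, lex)]
}
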