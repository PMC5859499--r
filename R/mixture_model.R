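# In-silico mixture Cq prediction under the additive linear-abundance model.
#
# On the linear scale a Cq value Y corresponds to an abundance proportional
# to 2^-Y.  A mixture combining components at fractions phi_c therefore has
# predicted Cq
#
#   M = -log2( sum_c 2^(-Y_c) * phi_c )
#
# evaluated here in a numerically stable log-sum-exp form.

#' Construct a mixture design
#'
#' A mixture design names the components (e.g. cell lines) and the fraction
#' of each on the unit simplex.  Fractions may be given directly or as
#' integer mixing ratios (e.g. `ratio = c(1, 3, 1)`), which are normalized.
#'
#' @param name design label, e.g. `"Mix1"`.
#' @param components character vector of component identifiers (ordered).
#' @param fractions numeric fractions summing to 1 (exclusive with `ratio`).
#' @param ratio non-negative mixing ratio, normalized to fractions.
#' @return object of class `mixture_design` with elements `name`,
#'   `components`, `fractions`.
#' @examples
#' mixture_design("Mix1", c("H226", "H358", "H460"), ratio = c(1, 3, 1))
#' @export
mixture_design <- function(name, components, fractions = NULL, ratio = NULL) {
  components <- toupper(as.character(components))
  if (is.null(fractions) == is.null(ratio)) {
    stop("supply exactly one of 'fractions' or 'ratio'", call. = FALSE)
  }
  if (!is.null(ratio)) {
    if (any(ratio < 0) || sum(ratio) <= 0) {
      stop("ratio must be non-negative with positive sum", call. = FALSE)
    }
    fractions <- ratio / sum(ratio)
  }
  fractions <- as.numeric(fractions)
  if (length(fractions) != length(components)) {
    stop("components and fractions must have equal length", call. = FALSE)
  }
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must be non-negative and sum to 1 (within 1e-9)",
         call. = FALSE)
  }
  structure(list(name = as.character(name), components = components,
                 fractions = fractions),
            class = "mixture_design")
}

#' @export
print.mixture_design <- function(x, ...) {
  cat(sprintf("<mixture_design> %s: %s\n", x$name,
              paste(sprintf("%s=%.4g", x$components, x$fractions),
                    collapse = ", ")))
  invisible(x)
}

#' Predict the Cq of a designed mixture from component Cq values
#'
#' Abundance is assumed additive and linear on the `2^-Cq` scale, so the
#' mixture Cq is `-log2(sum_c 2^(-Y_c) * phi_c)`.  The sum is evaluated
#' shifted by the smallest component Cq (log-sum-exp) so that weakly
#' expressed components near the detection ceiling cannot underflow.
#'
#' @param component_cqs named numeric vector of component Cq values; names
#'   are matched (case-insensitively) against `design$components`.  Components
#'   with zero fraction may be missing.
#' @param design a [mixture_design()].
#' @return predicted mixture Cq (cycles); always within the range of the
#'   component Cq values that have positive fraction.
#' @examples
#' d <- mixture_design("Mix1", c("A", "B", "C"), fractions = c(0.2, 0.6, 0.2))
#' predict_mixture_cq(c(A = 20, B = 25, C = 30), d)
#' @export
predict_mixture_cq <- function(component_cqs, design) {
  stopifnot(inherits(design, "mixture_design"))
  names(component_cqs) <- toupper(names(component_cqs))
  y <- component_cqs[design$components]
  phi <- design$fractions
  active <- phi > 0
  if (any(is.na(y[active]))) {
    stop("missing Cq for component(s): ",
         paste(design$components[active & is.na(y)], collapse = ", "),
         call. = FALSE)
  }
  y <- y[active]
  phi <- phi[active]
  y0 <- min(y)
  # -log2 sum phi * 2^-y  ==  y0 - log2 sum phi * 2^(y0 - y)
  unname(y0 - log2(sum(phi * 2^(y0 - y))))
}

#' Predict Mix1/Mix2 profiles for every measurement stratum
#'
#' Applies [predict_mixture_cq()] to collapsed pure-cell-line profiles,
#' stratified by (analyte, isolation_lab, isolation_rep, pcr_lab): each
#' stratum plays the role of one hypothetical mixture preparation measured
#' under one measurement process.
#'
#' @param profiles collapsed Cq table with `source == "PURE_CELL_LINE"`.
#' @param designs list of [mixture_design()] objects (typically the pair).
#' @param incomplete `"skip"` (default) to drop strata missing a component
#'   with a warning, or `"error"`.
#' @return Cq table of predictions with `source = "IN_SILICO_MIXTURE"`,
#'   `sample` the design name, and `plate` of the form `"insilico_<pcr>"`.
#' @export
predict_pair_profiles <- function(profiles, designs,
                                  incomplete = c("skip", "error")) {
  incomplete <- match.arg(incomplete)
  if (inherits(designs, "mixture_design")) designs <- list(designs)
  stopifnot(all(vapply(designs, inherits, logical(1), "mixture_design")))
  prof <- profiles[profiles$source == "PURE_CELL_LINE", , drop = FALSE]
  if (!all(prof$is_well_average)) {
    stop("profiles must be collapsed with collapse_wells() first",
         call. = FALSE)
  }
  strata <- unique(prof[c("analyte", "isolation_lab", "isolation_rep",
                          "pcr_lab")])
  rows <- list()
  n_skipped <- 0L
  for (k in seq_len(nrow(strata))) {
    st <- strata[k, ]
    sel <- prof$analyte == st$analyte &
      prof$isolation_lab == st$isolation_lab &
      prof$isolation_rep == st$isolation_rep &
      prof$pcr_lab == st$pcr_lab
    cqs <- stats::setNames(prof$cq[sel], prof$sample[sel])
    for (d in designs) {
      have <- d$components[d$fractions > 0] %in% names(cqs)
      if (!all(have)) {
        if (incomplete == "error") {
          stop("stratum ", paste(unlist(st), collapse = "/"),
               " is missing component(s): ",
               paste(d$components[d$fractions > 0][!have], collapse = ", "),
               call. = FALSE)
        }
        n_skipped <- n_skipped + 1L
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        analyte = st$analyte, source = "IN_SILICO_MIXTURE",
        sample = toupper(d$name), isolation_lab = st$isolation_lab,
        isolation_rep = st$isolation_rep, pcr_lab = st$pcr_lab,
        plate = paste0("insilico_", st$pcr_lab), well = NA_integer_,
        cq = predict_mixture_cq(cqs, d), is_well_average = TRUE,
        stringsAsFactors = FALSE
      )
    }
  }
  if (n_skipped > 0L) {
    warning(sprintf("skipped %d incomplete stratum/design combination(s)",
                    n_skipped), call. = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bland-Altman points for a pair of per-analyte profiles
#'
#' For each analyte shared by the two maps, computes the mean Cq
#' `(mix1 + mix2) / 2` and the difference `delta_cq = mix1 - mix2`.  A
#' negative delta means the analyte is more abundant in the first mixture
#' (lower Cq = more starting material).
#'
#' @param mix1,mix2 named numeric vectors, analyte -> Cq.
#' @return data.frame with columns `analyte`, `mean_cq`, `delta_cq`.
#' @export
bland_altman <- function(mix1, mix2) {
  names(mix1) <- toupper(names(mix1))
  names(mix2) <- toupper(names(mix2))
  shared <- intersect(names(mix1), names(mix2))
  only <- c(setdiff(names(mix1), shared), setdiff(names(mix2), shared))
  if (length(only) > 0L) {
    warning("analyte(s) present in only one profile excluded: ",
            paste(only, collapse = ", "), call. = FALSE)
  }
  if (length(shared) == 0L) stop("no shared analytes", call. = FALSE)
  data.frame(analyte = shared,
             mean_cq = (mix1[shared] + mix2[shared]) / 2,
             delta_cq = mix1[shared] - mix2[shared],
             row.names = NULL, stringsAsFactors = FALSE)
}
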