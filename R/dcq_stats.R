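# dCq and ddCq difference statistics between a mixture pair.
#
# dCq = Cq(Mix1) - Cq(Mix2) for the same analyte, paired within a
# measurement unit; negative dCq means the analyte is more abundant in Mix1.
# ddCq first normalizes each Cq to a control analyte measured on the same
# plate and sample, which cancels per-plate additive effects exactly.

.dcq_unit_keys <- c("analyte", "source", "isolation_lab", "isolation_rep",
                    "pcr_lab")

#' Per-replicate dCq between two mixtures
#'
#' @param x collapsed Cq table containing both mixtures.
#' @param mix1,mix2 sample labels of the pair (default `"MIX1"`, `"MIX2"`).
#' @param pairing `"plate"` (default): Mix1 and Mix2 are paired within the
#'   same plate (co-plated mixtures); `"isolation"`: Cq values are first
#'   averaged over plates within each (analyte, isolation replicate, PCR lab)
#'   unit and then differenced - for layouts where the pair is not co-plated.
#' @return data.frame with the pairing keys plus `dcq`; unpaired units are
#'   dropped with a warning.
#' @export
delta_cq <- function(x, mix1 = "MIX1", mix2 = "MIX2",
                     pairing = c("plate", "isolation")) {
  pairing <- match.arg(pairing)
  stopifnot(all(x$is_well_average))
  mix1 <- toupper(mix1); mix2 <- toupper(mix2)
  keys <- .dcq_unit_keys
  if (pairing == "plate") keys <- c(keys, "plate")
  a <- x[x$sample == mix1, , drop = FALSE]
  b <- x[x$sample == mix2, , drop = FALSE]
  if (pairing == "isolation") {
    a <- stats::aggregate(a["cq"], by = a[keys], FUN = mean)
    b <- stats::aggregate(b["cq"], by = b[keys], FUN = mean)
  }
  m <- merge(a[c(keys, "cq")], b[c(keys, "cq")], by = keys,
             suffixes = c("_mix1", "_mix2"))
  n_unpaired <- nrow(a) + nrow(b) - 2L * nrow(m)
  if (nrow(m) == 0L) {
    stop("no pairable ", mix1, "/", mix2, " units", call. = FALSE)
  }
  if (n_unpaired > 0L) {
    warning(sprintf("%d unpaired observation(s) dropped", n_unpaired),
            call. = FALSE)
  }
  m$dcq <- m$cq_mix1 - m$cq_mix2
  m <- m[do.call(order, m[keys]), c(keys, "dcq"), drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Per-replicate ddCq with a control analyte
#'
#' Each target Cq is first adjusted by subtracting the Cq of the control
#' analyte measured on the same sample and plate; the adjusted values of the
#' two mixtures are then differenced:
#' `ddCq = (Cq_t(Mix1) - Cq_ctl(Mix1)) - (Cq_t(Mix2) - Cq_ctl(Mix2))`.
#' Any additive constant shared within a plate x sample unit cancels
#' exactly.
#'
#' @inheritParams delta_cq
#' @param control control analyte label (e.g. `"miR-16"`).
#' @return data.frame as [delta_cq()], control analyte excluded, column
#'   named `dcq` (the ddCq values).
#' @export
delta_delta_cq <- function(x, control, mix1 = "MIX1", mix2 = "MIX2") {
  stopifnot(all(x$is_well_average))
  control <- toupper(control)
  if (!control %in% x$analyte) {
    stop("control analyte ", control, " not present", call. = FALSE)
  }
  unit <- c("source", "sample", "isolation_lab", "isolation_rep", "pcr_lab",
            "plate")
  ctl <- x[x$analyte == control, c(unit, "cq")]
  names(ctl)[names(ctl) == "cq"] <- "cq_ctl"
  tgt <- x[x$analyte != control, , drop = FALSE]
  m <- merge(tgt, ctl, by = unit)
  n_lost <- nrow(tgt) - nrow(m)
  if (nrow(m) == 0L) {
    stop("control analyte missing on every plate/sample unit", call. = FALSE)
  }
  if (n_lost > 0L) {
    warning(sprintf("%d observation(s) without a same-plate control dropped",
                    n_lost), call. = FALSE)
  }
  m$cq <- m$cq - m$cq_ctl
  m$cq_ctl <- NULL
  delta_cq(m, mix1 = mix1, mix2 = mix2, pairing = "plate")
}

#' Summarize dCq (or ddCq) values by group
#'
#' @param values output of [delta_cq()] or [delta_delta_cq()].
#' @param grouping `"by_isolation"` (one summary per isolation replicate,
#'   over plates), `"by_plate"` (one per plate, over isolations), or
#'   `"overall"`.  Groups are always additionally stratified by analyte,
#'   source, isolation lab and PCR lab.
#' @return data.frame with `analyte`, `source`, `isolation_lab`, `pcr_lab`,
#'   `grouping`, `group_id`, `mean_dcq`, `sd_dcq` (sample SD, `NA` when
#'   `n < 2`), `n`.
#' @export
summarize_dcq <- function(values,
                          grouping = c("by_isolation", "by_plate",
                                       "overall")) {
  grouping <- match.arg(grouping)
  stopifnot(nrow(values) > 0L, "dcq" %in% names(values))
  keys <- c("analyte", "source", "isolation_lab", "pcr_lab")
  gid <- switch(grouping,
    by_isolation = as.character(values$isolation_rep),
    by_plate = as.character(values$plate),
    overall = "all")
  by <- c(values[keys], list(group_id = gid))
  mean_df <- stats::aggregate(values["dcq"], by = by, FUN = mean)
  sd_df <- stats::aggregate(values["dcq"], by = by,
                            FUN = function(v) if (length(v) >= 2L)
                              stats::sd(v) else NA_real_)
  n_df <- stats::aggregate(values["dcq"], by = by, FUN = length)
  out <- mean_df
  names(out)[names(out) == "dcq"] <- "mean_dcq"
  out$sd_dcq <- sd_df$dcq
  out$n <- as.integer(n_df$dcq)
  out$grouping <- grouping
  cols <- c(keys, "grouping", "group_id", "mean_dcq", "sd_dcq", "n")
  out <- out[do.call(order, out[c(keys, "group_id")]), cols, drop = FALSE]
  rownames(out) <- NULL
  out
}
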