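# Domain model for quantification-cycle (Cq) observations.
#
# A Cq table is an ordinary data.frame with one row per well (or per
# within-plate well average) and the canonical columns below.  All label
# columns are matched case-insensitively and stored upper-case.

#' Canonical column names of a Cq table
#'
#' A Cq table is a data.frame with one row per well measurement (or per
#' within-plate well average) and these columns:
#' \describe{
#'   \item{analyte}{assay identifier, e.g. \code{"MIR-21"}}
#'   \item{source}{one of \code{"PURE_CELL_LINE"}, \code{"RNA_MIXTURE"},
#'     \code{"CELL_MIXTURE"}, \code{"IN_SILICO_MIXTURE"}}
#'   \item{sample}{component cell line (pure source) or mixture label}
#'   \item{isolation_lab, pcr_lab}{\code{"BDL"} or \code{"BRL"}}
#'   \item{isolation_rep}{positive integer extraction replicate}
#'   \item{plate}{plate identifier}
#'   \item{well}{well index within the plate (\code{NA} once collapsed)}
#'   \item{cq}{quantification cycle, in cycles}
#'   \item{is_well_average}{logical; \code{TRUE} after [collapse_wells()]}
#' }
#' @format Character vector of the ten canonical column names.
#' @export
cq_columns <- c("analyte", "source", "sample", "isolation_lab",
                "isolation_rep", "pcr_lab", "plate", "well", "cq",
                "is_well_average")

.cq_sources <- c("PURE_CELL_LINE", "RNA_MIXTURE", "CELL_MIXTURE",
                 "IN_SILICO_MIXTURE")
.cq_labs <- c("BDL", "BRL")

#' Assemble a validated Cq table
#'
#' Normalizes labels (upper-case), coerces types, and validates every row.
#' This is the single constructor through which all Cq data (read from file
#' or simulated) passes.
#'
#' @param df data.frame containing at least the canonical columns
#'   (`well` and `is_well_average` may be absent: `well` defaults to 1 and
#'   `is_well_average` to `FALSE`).
#' @param cq_range plausible Cq range; observations outside it are rejected
#'   (or dropped, see `na_policy`).
#' @param na_policy what to do with missing or out-of-range Cq values:
#'   `"drop"` (default; removes the rows with a warning reporting counts),
#'   `"ceiling"` (imputes the upper end of `cq_range`), or `"error"`.
#' @return data.frame with the canonical columns, label columns upper-case.
#' @export
as_cq_table <- function(df, cq_range = c(0, 40),
                        na_policy = c("drop", "ceiling", "error")) {
  na_policy <- match.arg(na_policy)
  stopifnot(is.data.frame(df))
  if (!"well" %in% names(df)) df$well <- 1L
  if (!"is_well_average" %in% names(df)) df$is_well_average <- FALSE
  missing_cols <- setdiff(cq_columns, names(df))
  if (length(missing_cols) > 0L) {
    stop("Cq table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- df[cq_columns]
  for (col in c("analyte", "source", "sample", "isolation_lab", "pcr_lab")) {
    out[[col]] <- toupper(trimws(as.character(out[[col]])))
  }
  out$plate <- trimws(as.character(out$plate))
  out$isolation_rep <- as.integer(out$isolation_rep)
  out$well <- suppressWarnings(as.integer(out$well))
  out$cq <- suppressWarnings(as.numeric(out$cq))
  out$is_well_average <- as.logical(out$is_well_average)

  bad_source <- !out$source %in% .cq_sources
  if (any(bad_source)) {
    stop("Unknown source value(s): ",
         paste(unique(out$source[bad_source]), collapse = ", "),
         " (rows ", paste(utils::head(which(bad_source), 5L), collapse = ", "),
         ")", call. = FALSE)
  }
  bad_lab <- !(out$isolation_lab %in% .cq_labs & out$pcr_lab %in% .cq_labs)
  if (any(bad_lab)) {
    stop("isolation_lab/pcr_lab must be one of ",
         paste(.cq_labs, collapse = ", "), "; offending rows: ",
         paste(utils::head(which(bad_lab), 5L), collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(out$isolation_rep)) || any(out$isolation_rep < 1L)) {
    stop("isolation_rep must be a positive integer", call. = FALSE)
  }

  bad_cq <- is.na(out$cq) | !is.finite(out$cq) |
    out$cq <= cq_range[1] | out$cq > cq_range[2]
  if (any(bad_cq)) {
    rows <- which(bad_cq)
    if (na_policy == "error") {
      stop("Missing or out-of-range Cq in rows: ",
           paste(utils::head(rows, 10L), collapse = ", "), call. = FALSE)
    } else if (na_policy == "ceiling") {
      out$cq[rows] <- cq_range[2]
      warning(sprintf("%d Cq value(s) missing/out-of-range imputed at ceiling %g",
                      length(rows), cq_range[2]), call. = FALSE)
    } else {
      out <- out[!bad_cq, , drop = FALSE]
      warning(sprintf("dropped %d row(s) with missing/out-of-range Cq (kept %d)",
                      length(rows), nrow(out)), call. = FALSE)
    }
  }

  key <- do.call(paste, c(out[c("analyte", "source", "sample", "isolation_lab",
                                "isolation_rep", "pcr_lab", "plate", "well")],
                          sep = "\r"))
  if (anyDuplicated(key)) {
    stop("Duplicate observation key(s) at rows: ",
         paste(utils::head(which(duplicated(key)), 10L), collapse = ", "),
         call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Read a Cq table from CSV
#'
#' Reads an RFC-4180 CSV with a header row, optionally remapping arbitrary
#' column headers onto the canonical schema, then validates via
#' [as_cq_table()].
#'
#' @param path CSV file path.
#' @param dialect optional named list/vector mapping canonical column names to
#'   the headers used in the file (e.g. `list(analyte = "miRNA")`), or a path
#'   to a YAML file of such `key: value` pairs.  Unmapped canonical names are
#'   looked up verbatim (case-insensitively).
#' @inheritParams as_cq_table
#' @return validated Cq table.
#' @export
read_cq_table <- function(path, dialect = NULL, cq_range = c(0, 40),
                          na_policy = "drop") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (is.character(dialect) && length(dialect) == 1L && file.exists(dialect)) {
    dialect <- yaml::read_yaml(dialect)
  }
  dialect <- as.list(dialect)
  lower <- tolower(names(raw))
  pick <- function(canon) {
    header <- if (!is.null(dialect[[canon]])) dialect[[canon]] else canon
    hit <- match(tolower(header), lower)
    if (is.na(hit) && canon %in% c("well", "is_well_average")) return(NULL)
    if (is.na(hit)) {
      stop(sprintf("column '%s' (for canonical '%s') not found in %s",
                   header, canon, path), call. = FALSE)
    }
    raw[[hit]]
  }
  cols <- lapply(cq_columns, pick)
  names(cols) <- cq_columns
  df <- as.data.frame(cols[!vapply(cols, is.null, logical(1))],
                      stringsAsFactors = FALSE)
  as_cq_table(df, cq_range = cq_range, na_policy = na_policy)
}

#' Write a Cq table to CSV in the canonical schema
#'
#' @param x validated Cq table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cq_table <- function(x, path) {
  stopifnot(all(cq_columns %in% names(x)))
  utils::write.csv(x[cq_columns], path, row.names = FALSE, quote = TRUE,
                   na = "")
  invisible(path)
}

#' Average replicate wells within a plate
#'
#' Collapses well-level Cq observations to one row per
#' (analyte, source, sample, isolation_lab, isolation_rep, pcr_lab, plate)
#' group, with `cq` the arithmetic mean of the member wells.  Downstream
#' analyses all operate on collapsed tables: a "Cq value" is the within-plate
#' average over replicate wells.
#'
#' @param x Cq table with `is_well_average = FALSE` throughout.
#' @return collapsed Cq table (`well = NA`, `is_well_average = TRUE`).
#' @export
collapse_wells <- function(x) {
  stopifnot(is.data.frame(x), all(cq_columns %in% names(x)))
  if (any(x$is_well_average)) {
    stop("input mixes well-level and already-averaged observations",
         call. = FALSE)
  }
  keys <- c("analyte", "source", "sample", "isolation_lab", "isolation_rep",
            "pcr_lab", "plate")
  agg <- stats::aggregate(x["cq"], by = x[keys], FUN = mean)
  agg$well <- NA_integer_
  agg$is_well_average <- TRUE
  agg <- agg[do.call(order, agg[keys]), cq_columns, drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Measurement-scenario lookup for the two-laboratory crossover
#'
#' The study comprises seven measurement scenarios: pathways 1-4 are the pure
#' cell-line crossover (each isolation lab x each PCR lab), pathways 5-6 the
#' RNA mixtures isolated at the reference lab and measured at each PCR lab,
#' and pathway 7 the cell mixtures processed entirely at the reference lab.
#' The numbering is configurable because the canonical table is supplementary
#' material; this default follows the workflow figures.
#'
#' @return data.frame with columns `scenario_id`, `source`, `isolation_lab`,
#'   `pcr_lab`.
#' @export
scenario_table <- function() {
  data.frame(
    scenario_id = 1:7,
    source = c(rep("PURE_CELL_LINE", 4), "RNA_MIXTURE", "RNA_MIXTURE",
               "CELL_MIXTURE"),
    isolation_lab = c("BDL", "BDL", "BRL", "BRL", "BRL", "BRL", "BRL"),
    pcr_lab = c("BDL", "BRL", "BDL", "BRL", "BDL", "BRL", "BRL"),
    stringsAsFactors = FALSE
  )
}

#' Assign scenario ids to a Cq table
#'
#' @param x Cq table.
#' @param table scenario lookup, by default [scenario_table()].  In-silico
#'   mixture predictions inherit the pure-cell-line pathway of the
#'   measurement process that produced the component profiles.
#' @return integer vector of scenario ids (`NA` where no pathway matches).
#' @export
scenario_id <- function(x, table = scenario_table()) {
  src <- ifelse(x$source == "IN_SILICO_MIXTURE", "PURE_CELL_LINE", x$source)
  key <- paste(src, x$isolation_lab, x$pcr_lab)
  tab_key <- paste(table$source, table$isolation_lab, table$pcr_lab)
  table$scenario_id[match(key, tab_key)]
}
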