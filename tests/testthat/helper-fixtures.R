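# Small in-code fixtures shared across test files.

# Well-level table: one analyte/plate with three wells.
tiny_well_df <- function(cq = c(24.9, 25.0, 25.1)) {
  data.frame(
    analyte = "miR-21", source = "pure_cell_line", sample = "H358",
    isolation_lab = "BDL", isolation_rep = 1L, pcr_lab = "BRL",
    plate = "p1", well = seq_along(cq), cq = cq,
    is_well_average = FALSE, stringsAsFactors = FALSE
  )
}

# Random well-level table with n_groups groups x wells_per wells each.
random_well_table <- function(n_groups = 40, wells_per = 3, seed = 1) {
  set.seed(seed)
  g <- expand.grid(
    analyte = paste0("MIR-", 1:5), sample = c("H226", "H358", "H460"),
    isolation_rep = 1:3, stringsAsFactors = FALSE
  )[seq_len(n_groups), ]
  rows <- g[rep(seq_len(n_groups), each = wells_per), ]
  rows$source <- "PURE_CELL_LINE"
  rows$isolation_lab <- "BDL"
  rows$pcr_lab <- "BRL"
  rows$plate <- "P1"
  rows$well <- rep(seq_len(wells_per), n_groups)
  rows$cq <- round(runif(nrow(rows), 20, 34), 3)
  rows$is_well_average <- FALSE
  as_cq_table(rows)
}

# Collapsed pure-cell-line profiles with explicit per-line means,
# replicated over strata (no noise unless sd > 0).
profile_table <- function(means, n_reps = 1, iso_labs = "BDL",
                          pcr_labs = "BDL", sd = 0, seed = 1) {
  set.seed(seed)
  stopifnot(is.matrix(means))
  g <- expand.grid(analyte = rownames(means), sample = colnames(means),
                   isolation_lab = iso_labs, isolation_rep = seq_len(n_reps),
                   pcr_lab = pcr_labs, stringsAsFactors = FALSE)
  g$source <- "PURE_CELL_LINE"
  g$plate <- paste0("P", g$isolation_rep)
  g$well <- NA_integer_
  g$cq <- means[cbind(g$analyte, g$sample)] + rnorm(nrow(g), 0, sd)
  g$is_well_average <- TRUE
  as_cq_table(g)
}

# Collapsed Mix1/Mix2 observations from explicit per-unit Cq values.
mixture_table <- function(mix1_cq, mix2_cq, analyte = "MIR-21",
                          source = "RNA_MIXTURE", n_reps = NULL,
                          plates = "P1", pcr_lab = "BRL") {
  if (is.null(n_reps)) n_reps <- length(mix1_cq) / length(plates)
  g <- expand.grid(plate = plates, isolation_rep = seq_len(n_reps),
                   stringsAsFactors = FALSE)
  build <- function(sample, cq) {
    data.frame(analyte = analyte, source = source, sample = sample,
               isolation_lab = "BRL", isolation_rep = g$isolation_rep,
               pcr_lab = pcr_lab, plate = g$plate, well = NA_integer_,
               cq = cq, is_well_average = TRUE, stringsAsFactors = FALSE)
  }
  as_cq_table(rbind(build("MIX1", mix1_cq), build("MIX2", mix2_cq)))
}

# Test-scale MCMC schedule.
test_mcmc <- list(n_chains = 2, n_iter = 1500, burn_in = 500, thin = 1)
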