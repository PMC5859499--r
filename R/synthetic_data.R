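# Synthetic Cq data with the structure of the two-laboratory crossover.
#
# The generator emulates the seven measurement scenarios: a profiling phase
# (three cell lines isolated at each lab on three occasions, each isolate
# measured by RT-qPCR at both labs; pathways 1-4), RNA mixtures (two
# designed mixtures prepared from four isolations at the reference lab,
# each pair measured on triplicate plates at both labs; pathways 5-6), and
# cell mixtures (mixed before isolation, processed entirely at the
# reference lab; pathway 7).
#
# Observation model, all terms in Cq cycles:
#   cq = true component (or mixture) Cq
#      + isolation-lab shift (per analyte, when isolated at BRL)
#      + PCR-lab shift (per analyte x cell line, when measured at BDL)
#      + N(0, sigma_iso)   shared within an isolation event
#      + N(0, sigma_plate) shared within a physical plate
#      + N(0, sigma_well)  per well
# Mixture-phase component profiles additionally receive a per-isolation
# batch perturbation N(0, batch_sd) per analyte x cell line, emulating
# expansion-batch drift between cell cultures.  True mixture Cq values are
# derived from (perturbed) component profiles with predict_mixture_cq(),
# never drawn directly, so the additive linear-abundance model holds
# exactly in the noise-free limit.

.default_cell_lines <- c("H226", "H358", "H460")
.default_analytes <- c("MIR-16", "MIR-21", "MIR-126", "MIR-210", "MIR-375",
                       "MIR-486")

.default_cell_means <- function() {
  m <- matrix(c(
    # H226, H358, H460
    19.8, 20.0, 20.1,   # MIR-16 control: abundant, near-identical
    24.5, 22.5, 24.5,   # MIR-21: highest in H358, most abundant target
    27.0, 28.6, 28.6,   # MIR-126: highest in H226
    27.5, 25.5, 27.0,   # MIR-210: highest in H358
    35.0, 31.0, 28.5,   # MIR-375: highest in H460, near ceiling in H226
    35.0, 31.5, 31.3    # MIR-486: H358 ~ H460, near ceiling in H226
  ), nrow = 6, byrow = TRUE,
  dimnames = list(.default_analytes, .default_cell_lines))
  m
}

.default_pcr_shift <- function() {
  m <- matrix(0, 6, 3,
              dimnames = list(.default_analytes, .default_cell_lines))
  # cell-line-specific PCR-lab sensitivity for MIR-126 and MIR-486
  m["MIR-126", ] <- c(0.0, 0.5, 0.3)
  m["MIR-486", ] <- c(0.0, 0.8, -0.2)
  m
}

#' Simulation configuration for the crossover study
#'
#' Defaults encode the qualitative structure of the study: six assays
#' (five targets plus the miR-16 control) across three lung-cancer cell
#' lines whose designed mixtures (1:3:1 vs 3:1:1 of H226:H358:H460) yield
#' per-analyte dCq values within one cycle in both directions; an
#' isolation-lab shift for miR-21 (more abundant when isolated at BRL); and
#' PCR-lab shifts for miR-126/miR-486 that vary across cell lines.
#'
#' @param cell_means analyte x cell-line matrix of true Cq means (cycles).
#' @param iso_lab_shift named per-analyte shift (cycles) added when
#'   `isolation_lab == "BRL"`.
#' @param pcr_lab_shift analyte x cell-line matrix (cycles) added when
#'   `pcr_lab == "BDL"`.
#' @param sigma_iso,sigma_plate,sigma_well random-effect SDs (cycles) for
#'   isolation events, plates, and wells.
#' @param batch_sd SD (cycles) of the per-isolation component perturbation
#'   in the mixture phases (expansion-batch drift).
#' @param n_iso_reps profiling isolation replicates per lab (default 3).
#' @param n_mix_isolations mixture-phase isolations (default 4).
#' @param n_mix_plates replicate plates per PCR lab in the mixture phases
#'   (default 3).
#' @param n_wells replicate wells per plate (default 3).
#' @param designs list of two [mixture_design()]s (default Mix1 = 1:3:1,
#'   Mix2 = 3:1:1 over H226, H358, H460).
#' @param detection_ceiling Cq at or above which an observation is flagged
#'   as single-molecule detection or noise (default 35); values are flagged,
#'   not altered.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(cell_means = .default_cell_means(),
                              iso_lab_shift = c("MIR-21" = -0.4),
                              pcr_lab_shift = .default_pcr_shift(),
                              sigma_iso = 0.15, sigma_plate = 0.10,
                              sigma_well = 0.15, batch_sd = 0.10,
                              n_iso_reps = 3, n_mix_isolations = 4,
                              n_mix_plates = 3, n_wells = 3,
                              designs = NULL, detection_ceiling = 35) {
  stopifnot(is.matrix(cell_means), !is.null(dimnames(cell_means)),
            all(cell_means > 0 & cell_means < 40),
            sigma_iso >= 0, sigma_plate >= 0, sigma_well >= 0,
            batch_sd >= 0, n_iso_reps >= 1, n_mix_isolations >= 1,
            n_mix_plates >= 1, n_wells >= 1)
  analytes <- toupper(rownames(cell_means))
  lines <- toupper(colnames(cell_means))
  rownames(cell_means) <- analytes
  colnames(cell_means) <- lines
  shift <- stats::setNames(numeric(length(analytes)), analytes)
  if (length(iso_lab_shift) > 0L) {
    shift[toupper(names(iso_lab_shift))] <- iso_lab_shift
  }
  if (is.null(pcr_lab_shift)) {
    pcr_lab_shift <- matrix(0, length(analytes), length(lines),
                            dimnames = list(analytes, lines))
  }
  dimnames(pcr_lab_shift) <- lapply(dimnames(pcr_lab_shift), toupper)
  stopifnot(identical(dim(pcr_lab_shift), dim(cell_means)))
  if (is.null(designs)) {
    designs <- list(mixture_design("Mix1", lines, ratio = c(1, 3, 1)),
                    mixture_design("Mix2", lines, ratio = c(3, 1, 1)))
  }
  stopifnot(length(designs) == 2L,
            all(vapply(designs, inherits, logical(1), "mixture_design")))
  structure(list(cell_means = cell_means, iso_lab_shift = shift,
                 pcr_lab_shift = pcr_lab_shift, sigma_iso = sigma_iso,
                 sigma_plate = sigma_plate, sigma_well = sigma_well,
                 batch_sd = batch_sd, n_iso_reps = n_iso_reps,
                 n_mix_isolations = n_mix_isolations,
                 n_mix_plates = n_mix_plates, n_wells = n_wells,
                 designs = designs, detection_ceiling = detection_ceiling),
            class = "simulation_config")
}

# True component Cq for one measurement process (no random terms).
.component_true_cq <- function(config, analyte, line, isolation_lab,
                               pcr_lab) {
  n <- max(length(analyte), length(line), length(isolation_lab),
           length(pcr_lab))
  analyte <- rep_len(analyte, n)
  line <- rep_len(line, n)
  unname(config$cell_means[cbind(analyte, line)] +
           (rep_len(isolation_lab, n) == "BRL") *
             config$iso_lab_shift[analyte] +
           (rep_len(pcr_lab, n) == "BDL") *
             config$pcr_lab_shift[cbind(analyte, line)])
}

#' Noise-free truth implied by a simulation configuration
#'
#' Evaluates, per analyte and measurement process, the true component Cq
#' values and the true mixture pair Cq (via [predict_mixture_cq()]) and dCq.
#' This is the ground truth that recovery tests and reports compare
#' against.
#'
#' @param config a [simulation_config()].
#' @return data.frame with columns `analyte`, `isolation_lab`, `pcr_lab`,
#'   `cq_mix1`, `cq_mix2`, `dcq`.
#' @export
simulation_truth <- function(config) {
  analytes <- rownames(config$cell_means)
  lines <- colnames(config$cell_means)
  grid <- expand.grid(analyte = analytes, isolation_lab = c("BDL", "BRL"),
                      pcr_lab = c("BDL", "BRL"), stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(k) {
    g <- grid[k, ]
    cqs <- stats::setNames(
      .component_true_cq(config, g$analyte, lines, g$isolation_lab,
                         g$pcr_lab), lines)
    m1 <- predict_mixture_cq(cqs, config$designs[[1L]])
    m2 <- predict_mixture_cq(cqs, config$designs[[2L]])
    data.frame(g, cq_mix1 = m1, cq_mix2 = m2, dcq = m1 - m2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Simulate the profiling phase (pure cell lines, pathways 1-4)
#'
#' Well-level Cq observations for every analyte x cell line x isolation lab
#' x isolation replicate x PCR lab x well.  One plate per (PCR lab,
#' isolation replicate) carries all analytes and samples, so plate effects
#' are shared the way a physical plate would share them.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed (deterministic output).
#' @return well-level Cq table with an `at_ceiling` flag column.
#' @export
simulate_profiling_phase <- function(config, seed = 1) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  analytes <- rownames(config$cell_means)
  lines <- colnames(config$cell_means)
  labs <- c("BDL", "BRL")
  reps <- seq_len(config$n_iso_reps)

  iso_eff <- array(stats::rnorm(length(lines) * 2 * length(reps), 0,
                                config$sigma_iso),
                   dim = c(length(lines), 2, length(reps)),
                   dimnames = list(lines, labs, reps))
  plate_eff <- matrix(stats::rnorm(2 * length(reps), 0, config$sigma_plate),
                      2, length(reps), dimnames = list(labs, reps))

  g <- expand.grid(well = seq_len(config$n_wells), analyte = analytes,
                   sample = lines, isolation_lab = labs,
                   isolation_rep = reps, pcr_lab = labs,
                   stringsAsFactors = FALSE)
  true_cq <- .component_true_cq(config, g$analyte, g$sample,
                                g$isolation_lab, g$pcr_lab)
  cq <- true_cq +
    iso_eff[cbind(g$sample, g$isolation_lab, g$isolation_rep)] +
    plate_eff[cbind(g$pcr_lab, g$isolation_rep)] +
    stats::rnorm(nrow(g), 0, config$sigma_well)
  out <- data.frame(
    analyte = g$analyte, source = "PURE_CELL_LINE", sample = g$sample,
    isolation_lab = g$isolation_lab, isolation_rep = g$isolation_rep,
    pcr_lab = g$pcr_lab,
    plate = paste0("P", g$pcr_lab, g$isolation_rep), well = g$well,
    cq = cq, is_well_average = FALSE, stringsAsFactors = FALSE)
  out <- as_cq_table(out)
  out$at_ceiling <- out$cq >= config$detection_ceiling
  out
}

#' Simulate a mixture phase (pathways 5-6 or 7)
#'
#' RNA mixtures (`"rna_mixture"`): components isolated at BRL, mixed, and
#' each pair measured on `n_mix_plates` plates at both PCR labs.  Cell
#' mixtures (`"cell_mixture"`): mixed before isolation and processed only
#' at BRL.  True mixture Cq values come from [predict_mixture_cq()] applied
#' to the per-isolation (batch-perturbed) component profiles.
#'
#' @param config a [simulation_config()].
#' @param phase `"rna_mixture"` or `"cell_mixture"`.
#' @param seed integer seed.
#' @return well-level Cq table with an `at_ceiling` flag column.
#' @export
simulate_mixture_phase <- function(config,
                                   phase = c("rna_mixture", "cell_mixture"),
                                   seed = 1) {
  stopifnot(inherits(config, "simulation_config"))
  phase <- match.arg(phase)
  set.seed((as.integer(seed) + ifelse(phase == "rna_mixture", 0L, 1L)) %%
             .Machine$integer.max)
  analytes <- rownames(config$cell_means)
  lines <- colnames(config$cell_means)
  pcr_labs <- if (phase == "rna_mixture") c("BDL", "BRL") else "BRL"
  reps <- seq_len(config$n_mix_isolations)
  plates <- seq_len(config$n_mix_plates)
  source_lab <- toupper(phase)

  batch <- array(stats::rnorm(length(analytes) * length(lines) *
                                length(reps), 0, config$batch_sd),
                 dim = c(length(analytes), length(lines), length(reps)),
                 dimnames = list(analytes, lines, reps))
  iso_eff <- matrix(stats::rnorm(length(lines) * length(reps), 0,
                                 config$sigma_iso),
                    length(lines), length(reps),
                    dimnames = list(lines, reps))
  plate_eff <- matrix(stats::rnorm(2 * length(plates), 0,
                                   config$sigma_plate),
                      2, length(plates),
                      dimnames = list(c("BDL", "BRL"), plates))

  # true mixture Cq per (analyte, rep, pcr lab, design)
  mix_names <- vapply(config$designs, function(d) toupper(d$name),
                      character(1))
  truth <- expand.grid(analyte = analytes, isolation_rep = reps,
                       pcr_lab = pcr_labs, sample = mix_names,
                       stringsAsFactors = FALSE)
  truth$cq_true <- vapply(seq_len(nrow(truth)), function(k) {
    tr <- truth[k, ]
    comp <- .component_true_cq(config, tr$analyte, lines, "BRL",
                               tr$pcr_lab) +
      batch[tr$analyte, , tr$isolation_rep] +
      iso_eff[, tr$isolation_rep]
    d <- config$designs[[match(tr$sample, mix_names)]]
    predict_mixture_cq(stats::setNames(comp, lines), d)
  }, numeric(1))

  g <- expand.grid(well = seq_len(config$n_wells), plate = plates,
                   analyte = analytes, isolation_rep = reps,
                   pcr_lab = pcr_labs, sample = mix_names,
                   stringsAsFactors = FALSE)
  key <- paste(g$analyte, g$isolation_rep, g$pcr_lab, g$sample)
  tkey <- paste(truth$analyte, truth$isolation_rep, truth$pcr_lab,
                truth$sample)
  cq <- truth$cq_true[match(key, tkey)] +
    plate_eff[cbind(g$pcr_lab, g$plate)] +
    stats::rnorm(nrow(g), 0, config$sigma_well)
  out <- data.frame(
    analyte = g$analyte, source = source_lab, sample = g$sample,
    isolation_lab = "BRL", isolation_rep = g$isolation_rep,
    pcr_lab = g$pcr_lab, plate = paste0("P", g$plate), well = g$well,
    cq = cq, is_well_average = FALSE, stringsAsFactors = FALSE)
  out <- as_cq_table(out)
  out$at_ceiling <- out$cq >= config$detection_ceiling
  out
}
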