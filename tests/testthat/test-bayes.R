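# One-cell dataset: n observations of a single fixed mean.
one_cell_table <- function(n, mean_cq, sd, seed) {
  set.seed(seed)
  as_cq_table(data.frame(
    analyte = "MIR-21", source = "RNA_MIXTURE", sample = "MIX1",
    isolation_lab = "BRL", isolation_rep = rep(1:2, length.out = n),
    pcr_lab = "BRL", plate = paste0("P", seq_len(n)), well = NA,
    cq = rnorm(n, mean_cq, sd), is_well_average = TRUE))
}

test_that("a single fixed mean is recovered and draws are reproducible", {
  tab <- one_cell_table(30, 24, 0.2, seed = 301)
  fit <- fit_mixed_model(tab, "MIR-21", seed = 5, include_plate = FALSE,
                         include_isolation = FALSE, n_chains = 2,
                         n_iter = 1500, burn_in = 500)
  mu <- fit$draws[, 1]
  expect_lt(abs(mean(mu) - 24), 3 * sd(mu))
  fit2 <- fit_mixed_model(tab, "MIR-21", seed = 5, include_plate = FALSE,
                          include_isolation = FALSE, n_chains = 2,
                          n_iter = 1500, burn_in = 500)
  expect_identical(fit$draws, fit2$draws)
  expect_true(all(fit$diagnostics$rhat < 1.05, na.rm = TRUE))
})

test_that("the plate-SD posterior is calibrated on synthetic data", {
  # 20 replicate simulations with sigma_plate = 0.3; the central 95%
  # interval should cover the truth in at least ~90% of them
  sigma_plate <- 0.3
  covered <- 0L
  for (r in 1:20) {
    set.seed(1000 + r)
    n_plates <- 12
    plate_eff <- rnorm(n_plates, 0, sigma_plate)
    d <- expand.grid(plate = seq_len(n_plates), sample = c("MIX1", "MIX2"),
                     isolation_rep = 1:2, stringsAsFactors = FALSE)
    d$cq <- 25 + ifelse(d$sample == "MIX2", 1, 0) + plate_eff[d$plate] +
      rnorm(nrow(d), 0, 0.15)
    tab <- as_cq_table(data.frame(
      analyte = "MIR-21", source = "RNA_MIXTURE", sample = d$sample,
      isolation_lab = "BRL", isolation_rep = d$isolation_rep,
      pcr_lab = "BRL", plate = paste0("P", d$plate), well = NA,
      cq = d$cq, is_well_average = TRUE))
    fit <- fit_mixed_model(tab, "MIR-21", seed = r, n_chains = 2,
                           n_iter = 1500, burn_in = 500,
                           include_isolation = FALSE)
    ci <- quantile(fit$draws[, "sd_plate"], c(0.025, 0.975))
    if (ci[1] <= sigma_plate && sigma_plate <= ci[2]) covered <- covered + 1L
  }
  expect_gte(covered, 17L)
})

test_that("curves are normalized, peak at the mode, and match the conjugate
           closed form when random effects are absent", {
  tab <- one_cell_table(40, 25, 0.3, seed = 302)
  sig <- 0.3
  fit <- fit_mixed_model(tab, "MIR-21", seed = 9, include_plate = FALSE,
                         include_isolation = FALSE, sigma_resid = sig,
                         n_chains = 4, n_iter = 6000, burn_in = 1000)
  w <- setNames(1, fit$cells$cell)
  cv <- marginal_likelihood_curve(fit, w, label = "mean Cq")
  expect_equal(max(cv$likelihood), 1)
  expect_true(!is.unsorted(cv$grid, strictly = TRUE))
  expect_equal(cv$likelihood[which.max(cv$likelihood)],
               cv$likelihood[match(cv$peak, cv$grid)])
  # conjugate oracle: with sigma known and an effectively flat prior the
  # profile likelihood of the mean is N(ybar, sigma^2/n), normalized
  ybar <- mean(tab$cq)
  n <- nrow(tab)
  oracle <- exp(-n * (cv$grid - ybar)^2 / (2 * sig^2))
  # the kernel-smoothed curve carries O(bw^2) bias; moments are exact
  expect_lt(max(abs(cv$likelihood - oracle / max(oracle))), 0.05)
  expect_equal(cv$post_mean, ybar, tolerance = 1e-3)
  expect_equal(cv$post_sd, sig / sqrt(n), tolerance = 0.05)
})

test_that("functional curves are invariant to a global Cq shift", {
  cfg <- simulation_config()
  rna <- collapse_wells(simulate_mixture_phase(cfg, "rna_mixture", 77))
  shifted <- rna
  shifted$cq <- shifted$cq + 3.7
  fit_a <- fit_mixed_model(rna, "MIR-21", seed = 4, n_chains = 2,
                           n_iter = 1500, burn_in = 500)
  fit_b <- fit_mixed_model(shifted, "MIR-21", seed = 4, n_chains = 2,
                           n_iter = 1500, burn_in = 500)
  w <- dcq_weights(fit_a, source = "RNA_MIXTURE", pcr_lab = "BRL")
  cv_a <- marginal_likelihood_curve(fit_a, w)
  cv_b <- marginal_likelihood_curve(fit_b, w)
  # same seed: fixed-mean draws shift by the constant, contrasts match
  expect_equal(cv_b$post_mean, cv_a$post_mean, tolerance = 1e-8)
  expect_equal(cv_b$peak, cv_a$peak, tolerance = 1e-8)
})

test_that("an unknown cell in a functional is rejected", {
  tab <- one_cell_table(10, 24, 0.2, seed = 303)
  fit <- fit_mixed_model(tab, "MIR-21", seed = 2, include_plate = FALSE,
                         include_isolation = FALSE, n_chains = 2,
                         n_iter = 600, burn_in = 100)
  expect_error(
    marginal_likelihood_curve(fit, c("NOT_A_CELL" = 1)), "absent")
  expect_error(dcq_weights(fit, source = "CELL_MIXTURE"), "no cells")
})

test_that("scenario comparison computes peaks, signs, and overlap", {
  mk_curve <- function(center, width = 0.2, label = "c") {
    grid <- seq(center - 1, center + 1, length.out = 401)
    lik <- exp(-(grid - center)^2 / (2 * width^2))
    structure(list(label = label, grid = grid, likelihood = lik / max(lik),
                   peak = center, post_mean = center, post_sd = width,
                   variant = 1), class = "likelihood_curve")
  }
  same <- compare_scenarios(list(a = mk_curve(-0.5), b = mk_curve(-0.5)))
  expect_equal(same$pairs$overlap, 1, tolerance = 1e-6)
  expect_true(same$all_same_sign)

  # disjoint triangular curves
  tri <- function(center, label) {
    grid <- seq(center - 0.1, center + 0.1, length.out = 101)
    lik <- 1 - abs(grid - center) / 0.1
    structure(list(label = label, grid = grid, likelihood = lik,
                   peak = center, post_mean = center, post_sd = 0.05,
                   variant = 1), class = "likelihood_curve")
  }
  far <- compare_scenarios(list(a = tri(-1, "a"), b = tri(1, "b")))
  expect_equal(far$pairs$overlap, 0, tolerance = 1e-8)
  expect_true(far$pairs$separated)
  expect_false(far$all_same_sign)

  # shifted Gaussians: overlap of unit-area equal-width normals is
  # 2 * pnorm(-delta / (2 * sigma))
  delta <- 0.3
  gg <- compare_scenarios(list(a = mk_curve(0.2), b = mk_curve(0.2 + delta)))
  expect_equal(gg$pairs$overlap, 2 * pnorm(-delta / (2 * 0.2)),
               tolerance = 0.01)
})

test_that("model variants agree on peak location for well-identified data", {
  cfg <- simulation_config(batch_sd = 0)
  rna <- collapse_wells(simulate_mixture_phase(cfg, "rna_mixture", 88))
  res <- run_variants(
    rna, "MIR-21",
    functionals = list(
      dcq_brl = function(fit) dcq_weights(fit, source = "RNA_MIXTURE",
                                          pcr_lab = "BRL")),
    seed = 10, n_chains = 2, n_iter = 2500, burn_in = 500)
  expect_equal(nrow(res$consistency), 1L)
  expect_lt(res$consistency$peak_spread, 0.05)
  # single variant behaves as fit + curve
  solo <- run_variants(
    rna, "MIR-21",
    functionals = list(
      dcq_brl = function(fit) dcq_weights(fit, source = "RNA_MIXTURE",
                                          pcr_lab = "BRL")),
    variants = 1, seed = 10, n_chains = 2, n_iter = 1500, burn_in = 500)
  expect_s3_class(solo$curves[["1"]]$dcq_brl, "likelihood_curve")
  solo2 <- run_variants(
    rna, "MIR-21",
    functionals = list(
      dcq_brl = function(fit) dcq_weights(fit, source = "RNA_MIXTURE",
                                          pcr_lab = "BRL")),
    variants = 1, seed = 10, n_chains = 2, n_iter = 1500, burn_in = 500)
  expect_identical(solo$consistency, solo2$consistency)
})
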