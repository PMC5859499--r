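# Bayesian mixed-effects assessment of average dCq values.
#
# For one target analyte at a time, observed Cq values are modeled as
#
#   y_j = mu_cell(j) + u_plate(j) + v_isolation(j) + e_j
#
# with a fixed mean mu for every (source, isolation lab, PCR lab, sample)
# combination and zero-mean normal random effects for plate and isolation.
# Fitting is by a Gibbs-within-Metropolis sampler: fixed means and random
# effects have conjugate normal full conditionals; the three standard
# deviations are updated by random-walk Metropolis on the log scale under
# half-normal (or half-Cauchy) priors.
#
# Quantities of interest are linear functionals of the fixed means (an
# average dCq is mu[Mix1 cell] - mu[Mix2 cell]; lab-bias contrasts are
# differences of such dCq values).  Uncertainty is reported as a marginal
# likelihood curve: the likelihood of the data as a function of the
# functional's value with every other parameter integrated out.  Under the
# (effectively flat on the relevant scale) priors used for the fixed means,
# this curve is proportional to the posterior density of the functional, so
# it is computed as a normalized kernel-density estimate of the functional's
# posterior draws.

.variant_prior <- function(variant) {
  switch(as.character(variant),
    "1" = list(family = "half-normal", scale = 5, include_isolation = TRUE),
    "2" = list(family = "half-cauchy", scale = 2.5, include_isolation = TRUE),
    "3" = list(family = "half-normal", scale = 5, include_isolation = FALSE),
    stop("variant must be 1, 2 or 3", call. = FALSE))
}

.log_prior_sd <- function(s, family, scale) {
  if (family == "half-normal") {
    stats::dnorm(s, 0, scale, log = TRUE)
  } else {
    stats::dcauchy(s, 0, scale, log = TRUE)
  }
}

#' Fit the Bayesian mixed-effects Cq model for one analyte
#'
#' @param x collapsed Cq table (any mix of sources); only rows for `analyte`
#'   are used.
#' @param analyte target analyte label.
#' @param variant model perturbation: 1 = half-normal(5) priors on all SDs
#'   (reference model); 2 = half-Cauchy(2.5) priors; 3 = half-normal priors
#'   with the isolation random effect removed.
#' @param seed integer seed; two runs with the same seed give identical
#'   draws.
#' @param n_chains,n_iter,burn_in,thin MCMC schedule (kept draws per chain
#'   are `(n_iter - burn_in) / thin`).
#' @param include_plate include the plate random effect (default `TRUE`).
#' @param include_isolation include the isolation random effect; `NULL`
#'   (default) defers to the variant.
#' @param sigma_resid if given, the residual SD is fixed at this value
#'   instead of sampled (used for conjugate closed-form checks).
#' @param prior_mean,prior_mean_sd normal prior on each fixed cell mean
#'   (default N(25, 100^2), effectively flat over the Cq range).
#' @param proposal_sd random-walk proposal SD on log(sigma).
#' @return object of class `posterior_samples`: list with `draws` (matrix,
#'   one column per parameter: `mu.<cell>` means, `sd_plate`, `sd_iso`,
#'   `sd_resid`), `chain` (chain index per row), `cells` (data.frame mapping
#'   cell labels to source/labs/sample), `diagnostics` (split R-hat and
#'   effective sample size per parameter), and the call metadata.
#' @export
fit_mixed_model <- function(x, analyte, variant = 1, seed = 1,
                            n_chains = 4, n_iter = 5000, burn_in = 1000,
                            thin = 1, include_plate = TRUE,
                            include_isolation = NULL, sigma_resid = NULL,
                            prior_mean = 25, prior_mean_sd = 100,
                            proposal_sd = 0.25) {
  vp <- .variant_prior(variant)
  if (is.null(include_isolation)) include_isolation <- vp$include_isolation
  analyte <- toupper(analyte)
  d <- x[x$analyte == analyte, , drop = FALSE]
  if (nrow(d) == 0L) stop("no observations for analyte ", analyte,
                          call. = FALSE)
  if (!all(d$is_well_average)) {
    stop("fit_mixed_model expects collapsed (well-averaged) data",
         call. = FALSE)
  }

  y <- d$cq
  n <- length(y)
  cell_lab <- paste(d$source, d$isolation_lab, d$pcr_lab, d$sample,
                    sep = "|")
  cell <- factor(cell_lab)
  # in-silico predictions are derived quantities, not physical plate
  # measurements: they carry no plate effect of their own
  has_plate <- d$source != "IN_SILICO_MIXTURE"
  plate <- factor(ifelse(has_plate,
                         paste(d$source, d$pcr_lab, d$plate, sep = "|"),
                         NA))
  # an isolation unit is one sample-preparation event: each cell line and
  # each mixture is isolated (or mixed) separately within a replicate
  iso <- factor(paste(d$source, d$isolation_lab, d$isolation_rep, d$sample,
                      sep = "|"))
  if (include_plate && nlevels(plate) < 2L) {
    warning("fewer than 2 plates; dropping plate random effect",
            call. = FALSE)
    include_plate <- FALSE
  }
  if (include_isolation && nlevels(iso) < 2L) {
    warning("fewer than 2 isolations; dropping isolation random effect",
            call. = FALSE)
    include_isolation <- FALSE
  }

  G <- nlevels(cell); K <- nlevels(plate); L <- nlevels(iso)
  ic <- as.integer(cell); ip <- as.integer(plate); il <- as.integer(iso)
  idx_p <- which(!is.na(ip)); ipp <- ip[idx_p]
  n_g <- tabulate(ic, G); n_k <- tabulate(ipp, K); n_l <- tabulate(il, L)
  ybar_g <- as.vector(rowsum(y, ic)) / n_g
  uvec_of <- function(u) {
    z <- numeric(n)
    if (length(idx_p) > 0L) z[idx_p] <- u[ipp]
    z
  }

  keep <- seq.int(burn_in + 1L, n_iter, by = thin)
  par_names <- c(paste0("mu.", levels(cell)), "sd_plate", "sd_iso",
                 "sd_resid")
  set.seed(as.integer(seed) %% .Machine$integer.max)

  run_chain <- function(chain_id) {
    mu <- ybar_g + stats::rnorm(G, 0, 0.5)
    u <- numeric(K); v <- numeric(L)
    sig_e <- if (is.null(sigma_resid)) {
      max(stats::sd(y - mu[ic]), 0.05) * exp(stats::rnorm(1, 0, 0.3))
    } else sigma_resid
    sig_p <- 0.2 * exp(stats::rnorm(1, 0, 0.3))
    sig_i <- 0.2 * exp(stats::rnorm(1, 0, 0.3))
    out <- matrix(NA_real_, length(keep), length(par_names))
    row <- 0L
    for (t in seq_len(n_iter)) {
      resid0 <- y - uvec_of(u) - v[il]
      prec <- n_g / sig_e^2 + 1 / prior_mean_sd^2
      mean_mu <- (as.vector(rowsum(resid0, ic)) / sig_e^2 +
                    prior_mean / prior_mean_sd^2) / prec
      mu <- stats::rnorm(G, mean_mu, 1 / sqrt(prec))

      if (include_plate) {
        r <- (y - mu[ic] - v[il])[idx_p]
        prec <- n_k / sig_e^2 + 1 / sig_p^2
        u <- stats::rnorm(K, (as.vector(rowsum(r, ipp)) / sig_e^2) / prec,
                          1 / sqrt(prec))
      }
      if (include_isolation) {
        r <- y - mu[ic] - uvec_of(u)
        prec <- n_l / sig_e^2 + 1 / sig_i^2
        v <- stats::rnorm(L, (as.vector(rowsum(r, il)) / sig_e^2) / prec,
                          1 / sqrt(prec))
      }

      resid <- y - mu[ic] - uvec_of(u) - v[il]
      if (is.null(sigma_resid)) {
        ls <- log(sig_e)
        ls_new <- ls + stats::rnorm(1, 0, proposal_sd)
        s_new <- exp(ls_new)
        log_acc <-
          sum(stats::dnorm(resid, 0, s_new, log = TRUE)) -
          sum(stats::dnorm(resid, 0, sig_e, log = TRUE)) +
          .log_prior_sd(s_new, vp$family, vp$scale) -
          .log_prior_sd(sig_e, vp$family, vp$scale) + ls_new - ls
        if (log(stats::runif(1)) < log_acc) sig_e <- s_new
      }
      if (include_plate) {
        ls <- log(sig_p)
        ls_new <- ls + stats::rnorm(1, 0, proposal_sd)
        s_new <- exp(ls_new)
        log_acc <-
          sum(stats::dnorm(u, 0, s_new, log = TRUE)) -
          sum(stats::dnorm(u, 0, sig_p, log = TRUE)) +
          .log_prior_sd(s_new, vp$family, vp$scale) -
          .log_prior_sd(sig_p, vp$family, vp$scale) + ls_new - ls
        if (log(stats::runif(1)) < log_acc) sig_p <- s_new
      }
      if (include_isolation) {
        ls <- log(sig_i)
        ls_new <- ls + stats::rnorm(1, 0, proposal_sd)
        s_new <- exp(ls_new)
        log_acc <-
          sum(stats::dnorm(v, 0, s_new, log = TRUE)) -
          sum(stats::dnorm(v, 0, sig_i, log = TRUE)) +
          .log_prior_sd(s_new, vp$family, vp$scale) -
          .log_prior_sd(sig_i, vp$family, vp$scale) + ls_new - ls
        if (log(stats::runif(1)) < log_acc) sig_i <- s_new
      }

      if (t %in% keep) {
        row <- row + 1L
        out[row, ] <- c(mu,
                        if (include_plate) sig_p else NA_real_,
                        if (include_isolation) sig_i else NA_real_,
                        sig_e)
      }
    }
    out
  }

  chains <- lapply(seq_len(n_chains), run_chain)
  draws <- do.call(rbind, chains)
  colnames(draws) <- par_names
  chain_idx <- rep(seq_len(n_chains), each = length(keep))

  cells <- unique(data.frame(cell = cell_lab, source = d$source,
                             isolation_lab = d$isolation_lab,
                             pcr_lab = d$pcr_lab, sample = d$sample,
                             stringsAsFactors = FALSE))
  cells <- cells[order(cells$cell), , drop = FALSE]
  rownames(cells) <- NULL

  diag <- .mcmc_diagnostics(draws, chain_idx)
  bad <- diag$rhat > 1.05 & !is.na(diag$rhat)
  if (any(bad)) {
    warning("split R-hat > 1.05 for: ",
            paste(diag$parameter[bad], collapse = ", "), call. = FALSE)
  }

  structure(list(draws = draws, chain = chain_idx, cells = cells,
                 analyte = analyte, variant = variant,
                 diagnostics = diag,
                 meta = list(seed = seed, n_chains = n_chains,
                             n_iter = n_iter, burn_in = burn_in,
                             thin = thin, include_plate = include_plate,
                             include_isolation = include_isolation,
                             prior = vp)),
            class = "posterior_samples")
}

# Split R-hat and a simple autocorrelation-based effective sample size.
.mcmc_diagnostics <- function(draws, chain_idx) {
  split_chains <- function(col) {
    lapply(split(col, chain_idx), function(ch) {
      h <- floor(length(ch) / 2L)
      list(ch[seq_len(h)], ch[seq.int(h + 1L, 2L * h)])
    }) |> unlist(recursive = FALSE)
  }
  rhat_ess <- function(col) {
    if (anyNA(col) || stats::var(col) < 1e-300) {
      return(c(NA_real_, NA_real_))
    }
    sc <- split_chains(col)
    m <- length(sc); nn <- length(sc[[1L]])
    means <- vapply(sc, mean, numeric(1))
    vars <- vapply(sc, stats::var, numeric(1))
    W <- mean(vars); B <- nn * stats::var(means)
    var_hat <- (nn - 1) / nn * W + B / nn
    rhat <- sqrt(var_hat / W)
    rho <- stats::acf(col, lag.max = min(100L, length(col) - 1L),
                      plot = FALSE)$acf[-1L]
    pos <- which(rho < 0.05)
    cut <- if (length(pos) > 0L) pos[1L] - 1L else length(rho)
    ess <- length(col) / (1 + 2 * sum(rho[seq_len(cut)]))
    c(rhat, ess)
  }
  res <- apply(draws, 2L, rhat_ess)
  data.frame(parameter = colnames(draws), rhat = res[1L, ],
             ess = res[2L, ], row.names = NULL)
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("<posterior_samples> analyte %s, variant %d: %d draws (%d chains), %d cell means\n",
              x$analyte, x$variant, nrow(x$draws), x$meta$n_chains,
              nrow(x$cells)))
  cat(sprintf("  max split R-hat: %.3f\n",
              max(x$diagnostics$rhat, na.rm = TRUE)))
  invisible(x)
}

#' Weights of an average-dCq functional
#'
#' Builds the weight vector (over fixed cell means) for the average dCq of
#' one measurement scenario: `mean over matching Mix1 cells - mean over
#' matching Mix2 cells`.
#'
#' @param samples a `posterior_samples` object.
#' @param source,isolation_lab,pcr_lab cell filters (`NULL` = any; when more
#'   than one cell matches a mixture, their means are averaged).
#' @param mix1,mix2 sample labels of the pair.
#' @return named numeric weight vector over the model's cells.
#' @export
dcq_weights <- function(samples, source = NULL, isolation_lab = NULL,
                        pcr_lab = NULL, mix1 = "MIX1", mix2 = "MIX2") {
  cells <- samples$cells
  sel <- rep(TRUE, nrow(cells))
  if (!is.null(source)) sel <- sel & cells$source %in% toupper(source)
  if (!is.null(isolation_lab)) {
    sel <- sel & cells$isolation_lab %in% toupper(isolation_lab)
  }
  if (!is.null(pcr_lab)) sel <- sel & cells$pcr_lab %in% toupper(pcr_lab)
  w <- stats::setNames(numeric(nrow(cells)), cells$cell)
  i1 <- sel & cells$sample == toupper(mix1)
  i2 <- sel & cells$sample == toupper(mix2)
  if (!any(i1) || !any(i2)) {
    stop("no cells match the requested mixture pair", call. = FALSE)
  }
  w[i1] <- 1 / sum(i1)
  w[i2] <- -1 / sum(i2)
  w
}

#' Marginal likelihood curve for a linear functional of the fixed means
#'
#' Evaluates the posterior draws of `weights %*% mu`, smooths them with a
#' Gaussian kernel (Silverman's rule bandwidth), and returns the density on
#' a grid normalized so that its maximum is one.  With the diffuse priors
#' used for the fixed means this normalized posterior density is the
#' normalized marginal likelihood of the functional.
#'
#' @param samples a `posterior_samples` object.
#' @param weights named weight vector over cells (see [dcq_weights()]), or
#'   any numeric vector matching the model's cells in order.
#' @param grid ordered numeric grid (cycles); default is the posterior mode
#'   +/- 4 posterior SDs at 201 points.
#' @param label curve label carried into reports.
#' @return object of class `likelihood_curve`: list with `label`, `grid`,
#'   `likelihood` (max 1), `peak` (grid value of the maximum), `post_mean`,
#'   `post_sd`, `variant`.
#' @export
marginal_likelihood_curve <- function(samples, weights, grid = NULL,
                                      label = "functional") {
  cells <- samples$cells$cell
  if (!is.null(names(weights))) {
    missing_cells <- setdiff(names(weights)[weights != 0], cells)
    if (length(missing_cells) > 0L) {
      stop("functional references cell(s) absent from the model: ",
           paste(missing_cells, collapse = ", "), call. = FALSE)
    }
    w <- stats::setNames(numeric(length(cells)), cells)
    w[names(weights)] <- weights
  } else {
    stopifnot(length(weights) == length(cells))
    w <- weights
  }
  mu_draws <- samples$draws[, paste0("mu.", cells), drop = FALSE]
  fdraw <- as.vector(mu_draws %*% w)
  m <- mean(fdraw); s <- stats::sd(fdraw)
  if (is.null(grid)) {
    dd <- stats::density(fdraw, bw = "nrd0")
    mode0 <- dd$x[which.max(dd$y)]
    grid <- seq(mode0 - 4 * s, mode0 + 4 * s, length.out = 201L)
  }
  stopifnot(!is.unsorted(grid, strictly = TRUE))
  dens <- stats::density(fdraw, bw = "nrd0", from = min(grid),
                         to = max(grid), n = length(grid))
  lik <- stats::approx(dens$x, dens$y, xout = grid, rule = 2)$y
  lik <- lik / max(lik)
  structure(list(label = label, grid = grid, likelihood = lik,
                 peak = grid[which.max(lik)], post_mean = m, post_sd = s,
                 variant = samples$variant),
            class = "likelihood_curve")
}

#' @export
print.likelihood_curve <- function(x, ...) {
  cat(sprintf("<likelihood_curve> %s (variant %s): peak %.3f, posterior %.3f +/- %.3f\n",
              x$label, x$variant, x$peak, x$post_mean, x$post_sd))
  invisible(x)
}

#' Compare marginal-likelihood curves across scenarios
#'
#' For every pair of curves, reports the peak locations, whether the peaks
#' agree in sign, and an overlap coefficient: the integral of the pointwise
#' minimum of the two curves after each is normalized to unit area.  1 means
#' identical curves, 0 disjoint support.
#'
#' @param curves list of `likelihood_curve` objects (named list names are
#'   used as labels).
#' @param overlap_threshold pairs with overlap below this are flagged as
#'   separated (default 0.25).
#' @return list with `pairs` (data.frame: labels, peaks, `sign_agreement`,
#'   `overlap`, `separated`), `all_same_sign`, `min_overlap`.
#' @export
compare_scenarios <- function(curves, overlap_threshold = 0.25) {
  stopifnot(length(curves) >= 2L,
            all(vapply(curves, inherits, logical(1), "likelihood_curve")))
  labels <- names(curves)
  if (is.null(labels)) {
    labels <- vapply(curves, `[[`, character(1), "label")
  }
  rng <- range(unlist(lapply(curves, `[[`, "grid")))
  common <- seq(rng[1], rng[2], length.out = 512L)
  unit_area <- function(cv) {
    y <- stats::approx(cv$grid, cv$likelihood, xout = common, yleft = 0,
                       yright = 0)$y
    y / .trapz(common, y)
  }
  dens <- lapply(curves, unit_area)
  combs <- utils::combn(length(curves), 2L)
  rows <- apply(combs, 2L, function(idx) {
    i <- idx[1L]; j <- idx[2L]
    ov <- .trapz(common, pmin(dens[[i]], dens[[j]]))
    data.frame(curve1 = labels[i], curve2 = labels[j],
               peak1 = curves[[i]]$peak, peak2 = curves[[j]]$peak,
               sign_agreement = sign(curves[[i]]$peak) ==
                 sign(curves[[j]]$peak),
               overlap = ov, separated = ov < overlap_threshold,
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  rownames(pairs) <- NULL
  peaks <- vapply(curves, `[[`, numeric(1), "peak")
  list(pairs = pairs,
       all_same_sign = all(peaks > 0) || all(peaks < 0),
       min_overlap = min(pairs$overlap))
}

.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1L) + y[-1L]) / 2)

#' Fit all model perturbations and report peak consistency
#'
#' Repeats the fit and curve construction under the three model variants
#' (see [fit_mixed_model()]) and summarizes how much the peak of each
#' functional moves across variants.
#'
#' @param x collapsed Cq table.
#' @param analyte target analyte.
#' @param functionals named list; each element is a function
#'   `(posterior_samples) -> weights` (typically a [dcq_weights()] wrapper).
#' @param variants variants to run (default `1:3`).
#' @param seed base seed; variant `v` uses `seed + v`.
#' @param ... passed to [fit_mixed_model()] (MCMC schedule etc.).
#' @return list with `curves` (nested: variant -> functional ->
#'   `likelihood_curve`) and `consistency` (data.frame of peak locations per
#'   functional and variant with their spread).
#' @export
run_variants <- function(x, analyte, functionals, variants = 1:3, seed = 1,
                         ...) {
  stopifnot(length(functionals) >= 1L, !is.null(names(functionals)))
  curves <- list()
  for (v in variants) {
    fit <- fit_mixed_model(x, analyte, variant = v, seed = seed + v, ...)
    curves[[as.character(v)]] <- lapply(
      stats::setNames(names(functionals), names(functionals)),
      function(fn) {
        marginal_likelihood_curve(fit, functionals[[fn]](fit), label = fn)
      })
  }
  rows <- lapply(names(functionals), function(fn) {
    peaks <- vapply(curves, function(cv) cv[[fn]]$peak, numeric(1))
    data.frame(functional = fn,
               t(stats::setNames(peaks, paste0("variant", names(curves)))),
               peak_spread = max(peaks) - min(peaks),
               stringsAsFactors = FALSE)
  })
  list(curves = curves, consistency = do.call(rbind, rows))
}
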