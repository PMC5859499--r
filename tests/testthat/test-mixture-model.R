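# Reference evaluation of the additive linear-abundance model, used as the
# independent oracle throughout: straight high-precision arithmetic on the
# linear scale, no log-sum-exp shift.
naive_mixture_cq <- function(y, phi) -log2(sum(phi * 2^(-y)))

test_that("mixture designs accept fractions or ratios and validate", {
  d <- mixture_design("Mix1", c("H226", "H358", "H460"), ratio = c(1, 3, 1))
  expect_identical(d$fractions, c(1, 3, 1) / 5)
  expect_error(mixture_design("m", c("a", "b"), fractions = c(0.5, 0.6)),
               "sum to 1")
  expect_error(mixture_design("m", c("a", "b"), fractions = c(0.5, 0.5),
                              ratio = c(1, 1)), "exactly one")
  expect_error(mixture_design("m", c("a", "b"), ratio = c(-1, 2)),
               "non-negative")
})

test_that("prediction honors boundary identities", {
  d_eq <- mixture_design("m", c("A", "B", "C"), fractions = c(0.2, 0.6, 0.2))
  expect_identical(predict_mixture_cq(c(A = 25, B = 25, C = 25), d_eq), 25)
  d_pure <- mixture_design("m", c("A", "B", "C"), fractions = c(1, 0, 0))
  expect_identical(predict_mixture_cq(c(A = 30, B = 12, C = 39), d_pure), 30)
  # zero-fraction components may be missing entirely
  expect_identical(predict_mixture_cq(c(A = 30), d_pure), 30)
  expect_error(predict_mixture_cq(c(B = 20, C = 21), d_eq), "A")
})

test_that("prediction matches direct evaluation on the worked example", {
  d <- mixture_design("m", c("A", "B", "C"), fractions = c(0.2, 0.6, 0.2))
  got <- predict_mixture_cq(c(A = 20, B = 25, C = 30), d)
  expect_equal(got, naive_mixture_cq(c(20, 25, 30), c(0.2, 0.6, 0.2)),
               tolerance = 1e-12)
  expect_equal(got, 22.19, tolerance = 1e-3)
})

test_that("prediction is permutation invariant, monotone, and bounded", {
  set.seed(401)
  for (rep in 1:50) {
    y <- runif(3, 18, 36)
    phi <- {
      w <- runif(3)
      w / sum(w)
    }
    comps <- c("A", "B", "C")
    d <- mixture_design("m", comps, fractions = phi)
    m <- predict_mixture_cq(setNames(y, comps), d)
    # permutation of components together with fractions
    p <- sample(3)
    dp <- mixture_design("m", comps[p], fractions = phi[p])
    expect_equal(predict_mixture_cq(setNames(y, comps), dp), m,
                 tolerance = 1e-12)
    # bounded by contributing component Cq values
    expect_gte(m, min(y) - 1e-12)
    expect_lte(m, max(y) + 1e-12)
    # more abundance (lower Cq) in any active component lowers the mixture Cq
    y2 <- y
    y2[1] <- y[1] - 0.5
    expect_lt(predict_mixture_cq(setNames(y2, comps), d), m)
    # linear-scale additivity
    expect_equal(2^(-m), sum(phi * 2^(-y)), tolerance = 1e-9)
  }
})

test_that("pair prediction covers every stratum and respects bounds", {
  means <- matrix(c(24, 22, 25,
                    28, 30, 29), nrow = 2, byrow = TRUE,
                  dimnames = list(c("MIR-21", "MIR-126"),
                                  c("H226", "H358", "H460")))
  prof <- profile_table(means, n_reps = 3, iso_labs = c("BDL", "BRL"),
                        pcr_labs = c("BDL", "BRL"), sd = 0.2, seed = 5)
  designs <- list(mixture_design("Mix1", colnames(means), ratio = c(1, 3, 1)),
                  mixture_design("Mix2", colnames(means), ratio = c(3, 1, 1)))
  pred <- predict_pair_profiles(prof, designs)
  # 2 analytes x 3 reps x 2 iso labs x 2 pcr labs x 2 designs
  expect_equal(nrow(pred), 2 * 3 * 2 * 2 * 2)
  expect_equal(unique(pred$source), "IN_SILICO_MIXTURE")
  for (k in seq_len(nrow(pred))) {
    sel <- prof$analyte == pred$analyte[k] &
      prof$isolation_lab == pred$isolation_lab[k] &
      prof$isolation_rep == pred$isolation_rep[k] &
      prof$pcr_lab == pred$pcr_lab[k]
    expect_gte(pred$cq[k], min(prof$cq[sel]))
    expect_lte(pred$cq[k], max(prof$cq[sel]))
  }
})

test_that("identical component profiles give identical mixtures", {
  means <- matrix(25, 1, 3,
                  dimnames = list("MIR-21", c("H226", "H358", "H460")))
  prof <- profile_table(means)
  designs <- list(mixture_design("Mix1", colnames(means), ratio = c(1, 3, 1)),
                  mixture_design("Mix2", colnames(means), ratio = c(3, 1, 1)))
  pred <- predict_pair_profiles(prof, designs)
  expect_equal(diff(pred$cq), 0)
})

test_that("incomplete strata are skipped with a warning or raise", {
  means <- matrix(c(24, 22, 25), 1, 3,
                  dimnames = list("MIR-21", c("H226", "H358", "H460")))
  prof <- profile_table(means)
  prof <- prof[prof$sample != "H460", ]
  d <- list(mixture_design("Mix1", c("H226", "H358", "H460"),
                           ratio = c(1, 3, 1)))
  expect_warning(out <- predict_pair_profiles(prof, d), "skipped")
  expect_null(out)
  expect_error(predict_pair_profiles(prof, d, incomplete = "error"), "H460")
})

test_that("bland_altman computes mean/difference per shared analyte", {
  expect_equal(bland_altman(c(A = 24), c(A = 24)),
               data.frame(analyte = "A", mean_cq = 24, delta_cq = 0))
  ba <- bland_altman(c(A = 23), c(A = 25))
  expect_equal(ba$mean_cq, 24)
  expect_equal(ba$delta_cq, -2)
  expect_warning(one <- bland_altman(c(A = 23, B = 30), c(A = 25)), "B")
  expect_equal(one$analyte, "A")

  set.seed(77)
  nm <- paste0("T", 1:50)
  m1 <- setNames(runif(50, 20, 35), nm)
  m2 <- setNames(runif(50, 20, 35), nm)
  ba <- bland_altman(m1, m2)
  expect_equal(ba$mean_cq, unname((m1 + m2) / 2)[match(ba$analyte, nm)])
  expect_equal(ba$delta_cq, unname(m1 - m2)[match(ba$analyte, nm)])
})
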