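test_that("fraction-grid enumeration matches stars-and-bars counting", {
  # brute force: all 3-tuples on a step-0.2 grid summing to 1
  grid <- seq(0, 1, by = 0.2)
  combos <- expand.grid(grid, grid, grid)
  oracle_points <- sum(abs(rowSums(combos) - 1) <= 1e-9)
  expect_equal(oracle_points, choose(5 + 2, 2))
  pairs <- enumerate_designs(c("A", "B", "C"), grid, grid_type = "fraction")
  expect_equal(length(pairs), choose(oracle_points, 2))
})

test_that("ratio grids include the reciprocal 1:3:1 / 3:1:1 pair once", {
  pairs <- enumerate_designs(c("H226", "H358", "H460"), c(1, 3))
  fr <- lapply(pairs, function(p) list(p$Mix1$fractions, p$Mix2$fractions))
  has_pair <- any(vapply(fr, function(f) {
    (isTRUE(all.equal(f[[1]], c(1, 3, 1) / 5)) &&
       isTRUE(all.equal(f[[2]], c(3, 1, 1) / 5))) ||
      (isTRUE(all.equal(f[[1]], c(3, 1, 1) / 5)) &&
         isTRUE(all.equal(f[[2]], c(1, 3, 1) / 5)))
  }, logical(1)))
  expect_true(has_pair)
  # 7 distinct simplex points from {1,3}^3 -> 21 unordered pairs
  expect_equal(length(pairs), choose(7, 2))
})

test_that("degenerate two-component {0,1} grid yields only pure pairs", {
  pairs <- enumerate_designs(c("A", "B"), c(0, 1), grid_type = "fraction")
  expect_equal(length(pairs), 1L)
  fr <- c(pairs[[1]]$Mix1$fractions, pairs[[1]]$Mix2$fractions)
  expect_true(all(fr %in% c(0, 1)))
})

test_that("scoring flags degenerate geometry and matches the distance oracle", {
  lines <- c("H226", "H358", "H460")
  pair <- list(Mix1 = mixture_design("Mix1", lines, ratio = c(1, 3, 1)),
               Mix2 = mixture_design("Mix2", lines, ratio = c(3, 1, 1)))

  # identical profiles across cell lines: every dCq is 0, no sign diversity
  flat <- profile_table(matrix(25, 3, 3, dimnames = list(
    paste0("T", 1:3), lines)))
  cand <- score_design_pair(pair, flat)
  expect_false(cand$feasible)
  expect_true(is.na(cand$score))

  # two analytes with identical rows map to coincident points: score 0
  m <- matrix(c(24, 22, 25,
                24, 22, 25,
                26, 27, 25), 3, 3, byrow = TRUE,
              dimnames = list(paste0("T", 1:3), lines))
  cand0 <- score_design_pair(pair, profile_table(m))
  expect_true(cand0$feasible)
  expect_equal(cand0$score, 0)

  # 5-analyte geometry vs brute-force min pairwise distance
  set.seed(19)
  m5 <- matrix(runif(15, 22, 30), 5, 3,
               dimnames = list(paste0("T", 1:5), lines))
  cand5 <- score_design_pair(pair, profile_table(m5), max_abs_dcq = Inf)
  pts <- cand5$points
  oracle <- Inf
  for (i in 1:4) for (j in (i + 1):5) {
    oracle <- min(oracle, sqrt((pts$mean_cq[i] - pts$mean_cq[j])^2 +
                                 (pts$delta_cq[i] - pts$delta_cq[j])^2))
  }
  if (cand5$feasible) expect_equal(cand5$score, oracle)
})

test_that("swapping mixture labels negates dCq but not feasibility/score", {
  lines <- c("H226", "H358", "H460")
  set.seed(23)
  m <- matrix(runif(12, 22, 30), 4, 3,
              dimnames = list(paste0("T", 1:4), lines))
  prof <- profile_table(m)
  pair <- list(Mix1 = mixture_design("Mix1", lines, ratio = c(1, 3, 1)),
               Mix2 = mixture_design("Mix2", lines, ratio = c(3, 1, 1)))
  swapped <- list(Mix1 = mixture_design("Mix1", lines, ratio = c(3, 1, 1)),
                  Mix2 = mixture_design("Mix2", lines, ratio = c(1, 3, 1)))
  a <- score_design_pair(pair, prof, max_abs_dcq = 2)
  b <- score_design_pair(swapped, prof, max_abs_dcq = 2)
  expect_equal(a$feasible, b$feasible)
  expect_equal(b$points$delta_cq[match(a$points$analyte, b$points$analyte)],
               -a$points$delta_cq)
  if (a$feasible) expect_equal(a$score, b$score)
})

test_that("ranking is deterministic and matches a sort oracle", {
  fake <- function(score, maxd, fr1) {
    structure(list(
      pair = list(mixture_design("Mix1", c("A", "B"), fractions = fr1),
                  mixture_design("Mix2", c("A", "B"),
                                 fractions = rev(fr1))),
      points = NULL, score = score, feasible = !is.na(score),
      max_observed_dcq = maxd), class = "design_candidate")
  }
  one <- rank_designs(list(fake(0.4, 1, c(0.5, 0.5))))
  expect_equal(one[[1]]$score, 0.4)
  two <- rank_designs(list(fake(0.3, 1, c(0.5, 0.5)),
                           fake(0.8, 1, c(0.2, 0.8))))
  expect_equal(vapply(two, `[[`, numeric(1), "score"), c(0.8, 0.3))

  set.seed(5)
  cands <- lapply(1:100, function(i) {
    fake(round(runif(1), 3), round(runif(1, 0.5, 1), 3),
         c(p <- round(runif(1), 3), 1 - p))
  })
  ranked <- rank_designs(cands)
  scores <- vapply(ranked, `[[`, numeric(1), "score")
  expect_equal(scores, sort(scores, decreasing = TRUE))
  expect_warning(empty <- rank_designs(list(fake(NA, 2, c(0.5, 0.5)))),
                 "no feasible")
  expect_length(empty, 0)
})
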