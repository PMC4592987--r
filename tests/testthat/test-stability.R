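test_that("expression filter applies a strict cutoff on the mean", {
  tcm <- toy_tcm(c(-3, -3, -3, -3,
                   0, 0, 0, 0,
                   -2, -2, -2, -2), times = c(0, 4, 8, 12))
  keep <- expression_filter(tcm, cutoff = -2)
  expect_equal(unname(keep), c(FALSE, TRUE, FALSE))
  rel <- toy_tcm(c(0, 1, 2, 3), times = c(0, 4, 8, 12),
                 scale = "relative_to_t0")
  expect_error(expression_filter(rel), "relative|t0")
})

test_that("time-effect ANOVA matches the by-definition decomposition", {
  # hand oracle on groups (1,2),(2,3),(3,4)
  x <- c(1, 2, 2, 3, 3, 4)
  time <- c(0, 0, 4, 4, 8, 8)
  grand <- mean(x)
  mg <- tapply(x, time, mean)
  ssb <- sum(2 * (mg - grand)^2)
  ssw <- sum((x - mg[as.character(time)])^2)
  f <- (ssb / 2) / (ssw / 3)
  p_oracle <- stats::pf(f, 2, 3, lower.tail = FALSE)
  expect_equal(anova_time(x, time), p_oracle, tolerance = 1e-12)

  # constant gene -> p = 1; extreme separation -> p ~ 0
  expect_equal(anova_time(rep(1, 6), time), 1)
  expect_lt(anova_time(c(0, 0.001, 0, -0.001, 10, 10.001),
                       c(0, 0, 4, 4, 8, 8)), 1e-6)
  expect_error(anova_time(1:3, c(0, 4, 8)), "replication")
})

test_that("ANOVA agrees with the sum-of-squares oracle on random toys", {
  set.seed(11)
  for (i in 1:100) {
    k <- sample(3:6, 1); reps <- sample(2:4, 1)
    time <- rep(seq_len(k) * 2, each = reps)
    x <- stats::rnorm(length(time))
    mg <- tapply(x, time, mean)
    grand <- mean(x)
    ssb <- sum(reps * (mg - grand)^2)
    ssw <- sum((x - mg[as.character(time)])^2)
    df1 <- k - 1; df2 <- length(x) - k
    p_oracle <- stats::pf((ssb / df1) / (ssw / df2), df1, df2,
                          lower.tail = FALSE)
    expect_lt(abs(anova_time(x, time) - p_oracle), 1e-10)
  }
})

test_that("regression prediction intervals match the closed form and lm", {
  t <- c(0, 2, 4, 6); y <- c(1.0, 1.1, 0.9, 1.0)
  fit <- fit_regression_pi(y, t, level = 0.95)
  # independent route: lm + predict(interval = "prediction")
  lmfit <- stats::lm(y ~ t)
  pred <- stats::predict(lmfit, newdata = data.frame(t = t),
                         interval = "prediction", level = 0.95)
  expect_equal(fit$bounds$lower, unname(pred[, "lwr"]), tolerance = 1e-10)
  expect_equal(fit$bounds$upper, unname(pred[, "upr"]), tolerance = 1e-10)
  expect_equal(fit$slope, unname(coef(lmfit)[2]))
  expect_equal(fit$sigma, summary(lmfit)$sigma)

  # zero-residual line degenerates to the fitted values
  fit0 <- fit_regression_pi(c(1, 2, 3, 4), c(0, 1, 2, 3))
  expect_equal(fit0$bounds$lower, fit0$bounds$fit, tolerance = 1e-8)

  # wider level gives strictly wider intervals
  fit50 <- fit_regression_pi(y, t, level = 0.5)
  expect_true(all(fit$bounds$upper > fit50$bounds$upper))
  expect_true(all(fit$bounds$lower < fit50$bounds$lower))
  expect_error(fit_regression_pi(c(1, 2), c(0, 1)), "3 points")
  expect_error(fit_regression_pi(c(1, 2, 3), c(1, 1, 1)), "distinct")
})

test_that("PIRS matches direct formula evaluation and its invariances", {
  t <- c(0, 2, 4, 6); y <- c(1.0, 1.1, 0.9, 1.0)
  fit <- fit_regression_pi(y, t)
  sc <- pirs_score(fit, y)
  # direct formula oracle from the closed-form OLS pieces
  n <- 4; tbar <- mean(t); stt <- sum((t - tbar)^2)
  b <- sum((t - tbar) * (y - mean(y))) / stt
  a <- mean(y) - b * tbar
  s <- sqrt(sum((y - a - b * t)^2) / (n - 2))
  half <- qt(0.975, 2) * s * sqrt(1 + 1 / n + (t - tbar)^2 / stt)
  m <- mean(y)
  pirs_oracle <- sum(abs(a + b * t + half - m) + abs(a + b * t - half - m))
  expect_equal(sc$pirs, pirs_oracle, tolerance = 1e-10)

  # flat noiseless gene scores exactly 0
  flat <- rep(2, 6)
  tf <- c(0, 0, 4, 4, 8, 8)
  expect_equal(pirs_score(fit_regression_pi(flat, tf), flat)$pirs, 0)

  # shift invariance: adding a constant moves bounds and mean together
  sc_shift <- pirs_score(fit_regression_pi(y + 5, t), y + 5)
  expect_equal(sc_shift$pirs, sc$pirs, tolerance = 1e-10)

  # doubling residual noise strictly increases PIRS
  resid <- y - (a + b * t)
  y2 <- (a + b * t) + 2 * resid
  expect_gt(pirs_score(fit_regression_pi(y2, t), y2)$pirs, sc$pirs)

  # width variant equals the sum of interval widths
  scw <- pirs_score(fit, y, formula = "width")
  expect_equal(scw$pirs, sum(2 * half), tolerance = 1e-10)
})

test_that("PIRS grows with noise scale on a fixed design", {
  set.seed(21)
  tf <- rep(seq(0, 44, 4), each = 2)
  base_noise <- stats::rnorm(length(tf))
  scales <- c(0.05, 0.1, 0.2, 0.4)
  pirs <- vapply(scales, function(sg) {
    y <- 2 + sg * base_noise
    pirs_score(fit_regression_pi(y, tf), y)$pirs
  }, numeric(1))
  expect_true(all(diff(pirs) > 0))
})

test_that("SD/RSD candidates use the 0.5 percent rule", {
  tcm <- toy_tcm(c(rep(2, 4),
                   2.009, 1.991, 2.009, 1.991,
                   2.02, 1.98, 2.02, 1.98), times = c(0, 4, 8, 12))
  tab <- sd_rsd(tcm)
  # sd of (2.009, 1.991, ...) is ~0.0104 > 0.01 -> not candidate
  expect_equal(tab$candidate, c(TRUE, FALSE, FALSE))
  tcm2 <- toy_tcm(c(rep(2, 4), 2.004, 1.996, 2.004, 1.996),
                  times = c(0, 4, 8, 12))
  tab2 <- sd_rsd(tcm2)
  expect_true(tab2$candidate[2])  # sd ~0.0046 <= 0.01
  expect_equal(tab2$rsd[2], tab2$sd[2] / 2)
  # zero mean -> rsd undefined, flagged with a reason
  tcm3 <- toy_tcm(c(-1, 1, -1, 1), times = c(0, 4, 8, 12))
  tab3 <- sd_rsd(tcm3)
  expect_false(tab3$candidate[1])
  expect_equal(tab3$reason[1], "zero mean")
})

test_that("cross-course candidates require averaged plus one individual", {
  mk <- function(sds) toy_tcm(unlist(lapply(sds, function(s)
    2 + s * c(-1, 1, -1, 1) / 2)), times = c(0, 4, 8, 12))
  # gene order g01..g03; candidate iff sd <= 0.01
  avg <- mk(c(0.005, 0.005, 0.5))     # g01, g02 candidates in averaged
  c1 <- mk(c(0.005, 0.5, 0.005))      # g01, g03
  c2 <- mk(c(0.5, 0.5, 0.005))        # g03 only
  expect_equal(cross_course_candidates(list(c1, c2), avg), "g01")
  expect_error(cross_course_candidates(list(), avg), "at least one")
})

test_that("jaccard similarity of top-k rankings", {
  expect_equal(jaccard_topk(c("a", "b", "c"), c("a", "b", "c"), 3), 1)
  expect_equal(jaccard_topk(c("a", "b"), c("c", "d"), 2), 0)
  expect_equal(jaccard_topk(c("x", "y", "z"), c("x", "y", "w"), 3), 0.5)
  expect_error(jaccard_topk(c("a"), c("b"), 0), "positive")
})

test_that("quintile report returns the lowest-PIRS genes per expression bin", {
  set.seed(31)
  n <- 100
  scores <- data.frame(gene_id = sprintf("g%03d", 1:n),
                       mean_expr = seq(0, 3, length.out = n),
                       pirs = stats::runif(n, 1, 2))
  # plant one near-zero-PIRS gene in each bin of 20
  planted <- c(5, 25, 45, 65, 85)
  scores$pirs[planted] <- 0.01
  rep10 <- quintile_report(scores, per_quintile = 2)
  expect_equal(nrow(rep10), 10)
  expect_equal(as.integer(table(rep10$quintile)), rep(2L, 5))
  expect_true(all(scores$gene_id[planted] %in% rep10$gene_id))

  rep5 <- quintile_report(scores[1:5, ], per_quintile = 1)
  expect_equal(nrow(rep5), 5)
  expect_error(quintile_report(scores[1:4, ]), "5 genes")
  expect_error(quintile_report(scores, scale = "relative_to_t0"),
               "relative")
})

test_that("stability report composes the ENCAS chain", {
  sim <- planted_sim(seed = 4, n_genes = 100)
  calls <- truth_rhythm_calls(sim$truth)
  rep1 <- stability_report(sim$courses[[1]], rhythm = calls)
  expect_equal(nrow(rep1), 100)
  expect_equal(rep1$is_encas,
               rep1$passes_expression & rep1$passes_rhythm & rep1$passes_anova)
  truth <- sim$truth
  # low-expressed genes fail the expression filter
  expect_true(all(!rep1$passes_expression[truth$class == "low_expressed"]))
  # cyclers are rejected by the imported rhythm calls
  expect_true(all(!rep1$passes_rhythm[truth$class == "cycler"]))
  # planted genes pass everything and rank first
  planted <- which(truth$class == "planted")
  expect_true(all(rep1$is_encas[planted]))
  expect_setequal(rep1$gene_id[which(rep1$pirs_rank <= 5)],
                  head(rep1$gene_id[order(rep1$pirs)], 5))
  # unreplicated course: ANOVA skipped, recorded
  sim1 <- simulate_expression(expression_sim_spec(
    n_genes = 20, time_points = seq(0, 8, 2), replicates = 1, courses = 1,
    seed = 6))
  rep_unrep <- stability_report(sim1$courses[[1]])
  expect_true(any(grepl("anova", attr(rep_unrep, "skipped"))))
  expect_true(all(rep_unrep$passes_anova))
})
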