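test_that("kendall S and tau match direct pair enumeration", {
  expect_equal(kendall_s(c(1, 2, 3), c(1, 2, 3)), list(S = 3L, tau = 1))
  expect_equal(kendall_s(c(3, 2, 1), c(1, 2, 3)), list(S = -3L, tau = -1))
  r <- kendall_s(c(1, 3, 2, 4), c(1, 2, 3, 4))
  expect_equal(r$S, 4L)
  expect_equal(r$tau, 4 / 6)
  # tied series: tau defined as 0
  expect_equal(kendall_s(c(1, 1, 1), c(1, 2, 3))$tau, 0)
  expect_error(kendall_s(1:3, 1:4), "length")
  # random cases against the brute-force oracle, with ties
  set.seed(42)
  for (i in 1:20) {
    x <- sample(1:4, 8, replace = TRUE)
    ref <- stats::rnorm(8)
    expect_equal(kendall_s(x, ref)$S, as.integer(brute_kendall_S(x, ref)))
  }
})

test_that("exact JTK p at n = 6 equals full permutation enumeration", {
  time <- seq(0, 20, by = 4)      # 6 samples, one per time point
  x <- c(0.2, 1.5, 0.3, -1.1, -0.2, 0.9)
  res <- jtk_test(x, time, periods = 22, exact_limit = 8)
  # oracle: enumerate all 6! permutations, max |S| across the same references
  refs <- refprimer:::.jtk_references(time, 22)
  perms <- refprimer:::.all_permutations(6)
  obs <- max(vapply(refs, function(r) abs(brute_kendall_S(x, r$wave)),
                    numeric(1)))
  tail_count <- 0
  for (b in seq_len(nrow(perms))) {
    xb <- x[perms[b, ]]
    mx <- max(vapply(refs, function(r) abs(brute_kendall_S(xb, r$wave)),
                     numeric(1)))
    if (mx >= obs) tail_count <- tail_count + 1
  }
  expect_equal(res$p_value, tail_count / nrow(perms))
})

test_that("constant series is never called rhythmic", {
  time <- rep(seq(0, 20, by = 4), each = 2)
  res <- jtk_test(rep(1.5, length(time)), time)
  expect_equal(res$p_value, 1)
})

test_that("a noiseless cycler attains the smallest achievable p", {
  time <- seq(0, 44, by = 2)
  x <- cos(2 * pi * time / 22)
  set.seed(7)
  res <- jtk_test(x, time, periods = 22, n_perm = 2000)
  # Monte-Carlo branch: smallest possible p is 1 / (B + 1)
  expect_equal(res$p_value, 1 / 2001)
  expect_equal(res$best_period, 22)
})

test_that("exact and Monte-Carlo branches agree on n = 8 toys", {
  time <- seq(0, 28, by = 4)      # 8 samples
  set.seed(5)
  for (i in 1:5) {
    x <- stats::rnorm(8)
    p_exact <- jtk_test(x, time, exact_limit = 8)$p_value
    p_mc <- jtk_test(x, time, exact_limit = 0, n_perm = 4000)$p_value
    expect_lt(abs(p_exact - p_mc), 3 * sqrt(p_exact * (1 - p_exact) / 4000) + 1e-3)
  }
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # q >= p elementwise; order-invariance up to the inverse permutation
  set.seed(3)
  p <- stats::runif(30)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  perm <- sample(30)
  expect_equal(bh_adjust(p[perm]), q[perm])
  # non-decreasing in sorted-p order
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("imported rhythm calls use a strict q < alpha", {
  path <- tempfile(fileext = ".tsv")
  write.table(data.frame(gene_id = c("geneA", "geneB"),
                         q_value = c(0.01, 0.05)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  calls <- read_rhythm_calls(path, alpha = 0.05)
  expect_equal(calls$is_rhythmic, c(TRUE, FALSE))
  # empty file with header -> zero rows
  write.table(data.frame(gene_id = character(0), q_value = numeric(0)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(nrow(read_rhythm_calls(path)), 0)
  # missing columns -> error
  write.table(data.frame(gene = "x", q = 0.1), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_rhythm_calls(path), "q_value")
})

test_that("screening shares the permutation null across tie patterns", {
  sim <- simulate_expression(expression_sim_spec(
    n_genes = 12, time_points = seq(0, 44, by = 4), seed = 9))
  set.seed(1)
  scr <- jtk_screen(sim$courses[[1]], n_perm = 2000)
  expect_equal(nrow(scr), 12)
  expect_true(all(scr$q_value >= scr$p_value - 1e-12))
  # per-gene results identical to standalone jtk_test under the same null
  set.seed(1)
  solo <- jtk_test(sim$courses[[1]]$values[1, ],
                   sim$courses[[1]]$samples$time, n_perm = 2000)
  expect_equal(scr$p_value[1], solo$p_value)
})
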