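test_that("size factors follow the median-of-ratios formula", {
  # all samples identical -> all factors 1
  m <- matrix(rep(c(5, 10, 20), 3), ncol = 3)
  rownames(m) <- paste0("f", 1:3)
  expect_equal(unname(size_factors(m)), c(1, 1, 1))
  # sample B = 2 x sample A -> factors (1/sqrt(2), sqrt(2))
  m2 <- cbind(a = c(10, 30, 5), b = c(20, 60, 10))
  rownames(m2) <- paste0("f", 1:3)
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)))
  # single feature (4, 16): geometric mean 8, factors (0.5, 2)
  m3 <- matrix(c(4, 16), nrow = 1, dimnames = list("f1", c("a", "b")))
  expect_equal(unname(size_factors(m3)), c(0.5, 2))
  # no all-nonzero feature -> informative error
  m4 <- matrix(c(0, 5, 5, 0), nrow = 2)
  rownames(m4) <- paste0("f", 1:2)
  expect_error(size_factors(m4), "pseudo-count")
})

test_that("size factors agree with the reference implementation", {
  skip_if_not_installed("DESeq2")
  sim <- simulate_counts(n_features = 300, dispersion = 0.2, seed = 8,
                         fold_changes = c(4, 4, 0.25))
  m <- circprofiler:::counts_matrix(sim$counts)
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-12)
})

test_that("dispersion estimation recovers truth and respects edge cases", {
  # constant counts across samples: raw dispersion 0
  m <- matrix(50, nrow = 3, ncol = 6,
              dimnames = list(paste0("f", 1:3), paste0("s", 1:6)))
  cond <- rep(c("a", "b"), each = 3)
  d <- estimate_dispersion(m, rep(1, 6), cond)
  expect_equal(d$dispersion_raw, rep(0, 3))
  # Poisson counts: median estimate near zero
  sim <- simulate_counts(n_features = 400, n_per_condition = 10,
                         dispersion = 0, seed = 3)
  d0 <- estimate_dispersion(sim$counts, size_factors(sim$counts),
                            sim$design$condition)
  expect_lte(median(d0$dispersion_raw), 0.05)
  # NB alpha = 0.5, mean 100, n = 50: recovered within +/- 0.2
  simr <- simulate_counts(n_features = 800, n_per_condition = 25,
                          dispersion = 0.5, mean_sdlog = 0, seed = 12)
  dr <- estimate_dispersion(simr$counts, size_factors(simr$counts),
                            simr$design$condition)
  expect_lt(abs(median(dr$dispersion_raw) - 0.5), 0.2)
})

test_that("the exact test is null-calibrated and matches the binomial limit", {
  # identical condition profiles: p = 1
  m <- matrix(rep(c(10, 25, 40), 6), ncol = 6,
              dimnames = list(paste0("f", 1:3), paste0("s", 1:6)))
  cond <- rep(c("normal", "tumor"), each = 3)
  res <- nb_test(m, rep(1, 6), rep(0.1, 3), cond)
  expect_true(all(res$p_value > 0.999))
  # dispersion -> 0 converges to the conditional binomial exact test
  binom_exact <- function(kA, kB) {
    kS <- kA + kB
    probs <- stats::dbinom(0:kS, kS, 0.5)
    sum(probs[probs <= probs[kA + 1] * (1 + 1e-7)])
  }
  set.seed(33)
  for (i in 1:25) {
    kA <- sample(0:25, 1); kB <- sample(0:25, 1)
    if (kA + kB == 0) next
    got <- circprofiler:::nb_exact_p(kA, kB, sA = 3, sB = 3, alpha = 0,
                                     nA = 3, nB = 3)
    expect_equal(got, binom_exact(kA, kB), tolerance = 1e-10)
  }
  # all-zero features are degenerate with p = 1
  mz <- matrix(0, nrow = 1, ncol = 6,
               dimnames = list("z", paste0("s", 1:6)))
  rz <- nb_test(mz, rep(1, 6), 0.1, cond)
  expect_true(rz$degenerate)
  expect_equal(rz$p_value, 1)
  expect_true(is.nan(rz$fold_change))
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  # brute force: adj_i = min over j with p_j >= p_i of n * p_j / rank_j
  brute_bh <- function(p) {
    n <- length(p)
    o <- order(p)
    r <- numeric(n)
    adj <- n / seq_len(n) * p[o]
    for (i in seq_len(n)) adj[i] <- min(adj[i:n], 1)
    r[o] <- adj
    r
  }
  set.seed(5)
  for (i in 1:30) {
    p <- stats::runif(sample(1:200, 1))
    expect_equal(bh_fdr(p), brute_bh(p), tolerance = 1e-12)
    expect_equal(bh_fdr(p), stats::p.adjust(p, "BH"), tolerance = 1e-12)
  }
})

test_that("status labels use strict fold-change and FDR thresholds", {
  res <- tibble::tibble(
    fold_change = c(2.5, 2.0, 0.4, 0.5, 3, Inf, 0, NaN),
    fdr = c(0.01, 0.01, 0.04, 0.04, 0.05, 0.01, 0.01, 0.01)
  )
  out <- filter_de(res)
  expect_equal(out$status,
               c("up", "unchanged", "down", "unchanged", "unchanged",
                 "up", "down", "unchanged"))
})

test_that("rescaling one sample moves its size factor and not fold changes", {
  sim <- simulate_counts(n_features = 300, dispersion = 0.1, seed = 21,
                         fold_changes = c(8, 0.125))
  de1 <- run_de(sim$counts, sim$design)
  scaled <- sim$counts
  scaled$normal_1 <- scaled$normal_1 * 4
  de2 <- run_de(scaled, sim$design)
  sf1 <- attr(de1, "size_factors"); sf2 <- attr(de2, "size_factors")
  # size factors are defined up to the geometric-mean reference, so the
  # invariant quantity is the ratio to another sample, which moves by the
  # scaling constant exactly
  expect_equal(unname((sf2["normal_1"] / sf2["tumor_1"]) /
                        (sf1["normal_1"] / sf1["tumor_1"])), 4,
               tolerance = 1e-9)
  # normalized means all rescale by a common constant: fold changes are
  # exactly invariant
  expect_equal(de1$fold_change, de2$fold_change, tolerance = 1e-9)
})

test_that("tidy, glance and autoplot work on a fitted DE object", {
  sim <- simulate_counts(n_features = 120, dispersion = 0.1, seed = 2,
                         fold_changes = c(8, 8))
  de <- run_de(sim$counts, sim$design)
  td <- tidy(de)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "circ_de"))
  gl <- glance(de)
  expect_equal(gl$n_features, 120)
  expect_equal(gl$n_up + gl$n_down + gl$n_unchanged, 120)
  p <- ggplot2::autoplot(de)
  expect_s3_class(p, "ggplot")
})
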