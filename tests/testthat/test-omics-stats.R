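two_group <- function(n = 3) {
  stats::setNames(rep(c("control", "treated"), each = n),
                  c(paste0("c", seq_len(n)), paste0("t", seq_len(n))))
}

test_that("preprocess imputes the per-feature minimum, then log-transforms", {
  v <- rbind(f1 = c(4, NA, 8, 6, 5, 9), f2 = c(1, 2, 3, 4, 5, 6))
  colnames(v) <- names(two_group())
  tab <- sample_table(v, two_group())
  out <- preprocess(tab, log_base = "e")
  expect_equal(out$values["f1", ], log(c(4, 4, 8, 6, 5, 9)),
               ignore_attr = TRUE)
  expect_equal(out$values["f2", ], log(1:6), ignore_attr = TRUE)
  expect_true(out$log_transformed)
  # no missing values: plain log, unchanged shape
  v2 <- rbind(f1 = c(4, 7, 8, 6, 5, 9), f2 = 1:6 + 0)
  colnames(v2) <- names(two_group())
  out2 <- preprocess(sample_table(v2, two_group()), "2")
  expect_equal(dim(out2$values), dim(v2))
  expect_equal(out2$values, log2(v2))
})

test_that("all-missing features are dropped with a warning, or error on demand", {
  v <- rbind(f1 = c(1, 2, 3, 4, 5, 6), f2 = rep(NA_real_, 6))
  colnames(v) <- names(two_group())
  tab <- sample_table(v, two_group())
  expect_warning(out <- preprocess(tab), "f2")
  expect_equal(rownames(out$values), "f1")
  expect_error(suppressWarnings(preprocess(tab, drop_all_missing = FALSE)),
               "f2")
})

test_that("Welch t-test matches the closed form on the worked example", {
  w <- welch_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(w$t, -1.224745, tolerance = 1e-6)
  expect_equal(w$df, 4, tolerance = 1e-9)
  expect_equal(w$p, 0.2878641, tolerance = 1e-5)
})

test_that("Welch t-test degenerate and error cases", {
  w <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w$t, 0)
  expect_equal(w$p, 1)
  expect_error(welch_test(c(1, 2), 5), "at least 2")
  expect_equal(welch_test(c(2, 2, 2), c(2, 2))$p, 1)
  expect_error(welch_test(c(2, 2, 2), c(3, 3)), "zero variance")
})

test_that("Welch t is antisymmetric in the groups and p symmetric", {
  set.seed(21)
  for (i in 1:25) {
    a <- stats::rnorm(sample(2:8, 1))
    b <- stats::rnorm(sample(2:8, 1), mean = stats::runif(1, -1, 1))
    ab <- welch_test(a, b)
    ba <- welch_test(b, a)
    expect_equal(ab$t, -ba$t)
    expect_equal(ab$p, ba$p)
  }
})

test_that("BH q-values match hand-worked examples and validate input", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.5), 0.5)
  expect_equal(bh_fdr(c(0.005, 0.5)), c(0.01, 0.5))
  expect_equal(bh_fdr(numeric()), numeric())
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.5, -0.1)), "\\[0, 1\\]")
})

test_that("BH q-values equal the literal step-up reference on random vectors", {
  set.seed(31)
  for (i in 1:150) {
    p <- stats::runif(sample(1:100, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p), bh_reference(p))
  }
})

test_that("BH q-values are monotone in p and bounded by 1", {
  set.seed(32)
  p <- stats::runif(50)
  q <- bh_fdr(p)
  expect_true(all(q <= 1), info = "capped at 1")
  expect_true(all(q >= p * 1 / length(p)))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("differential recovers an exact e-fold change and flags nothing else", {
  set.seed(41)
  n <- 4
  v <- matrix(exp(stats::rnorm(10 * 2 * n, 5, 0.3)), nrow = 10,
              dimnames = list(paste0("f", 1:10), names(two_group(n))))
  trt <- two_group(n) == "treated"
  v["f1", trt] <- v["f1", !trt] * exp(1)
  tab <- preprocess(sample_table(v, two_group(n)), "e")
  d <- differential(tab)
  expect_equal(d$log_fc[d$feature == "f1"], 1, tolerance = 1e-9)
  expect_true(all(d$q >= d$p - 1e-12))
})

test_that("differential of an empty table is empty", {
  v <- matrix(numeric(), 0, 6, dimnames = list(character(),
                                               names(two_group())))
  tab <- sample_table(v, two_group())
  tab$log_transformed <- TRUE
  tab$log_base <- "e"
  expect_equal(nrow(differential(tab)), 0)
})

test_that("under a null design the q < 0.1 flag rate respects FDR control", {
  set.seed(43)
  n_feat <- 40
  reps <- 60
  prop <- numeric(reps)
  for (r in seq_len(reps)) {
    v <- matrix(exp(stats::rnorm(n_feat * 8, 5, 0.4)), nrow = n_feat,
                dimnames = list(paste0("f", seq_len(n_feat)),
                                names(two_group(4))))
    d <- differential(preprocess(sample_table(v, two_group(4)), "e"))
    prop[r] <- mean(d$significant)
  }
  mcse <- stats::sd(prop) / sqrt(reps)
  expect_lte(mean(prop), 0.1 + 3 * mcse)
})

test_that("pairwise correlation handles modes, symmetry and edge cases", {
  a <- data.frame(feature = c("x", "y", "z"), log_fc = c(1, 2, 3),
                  q = c(0.01, 0.01, 0.5))
  b <- data.frame(feature = c("x", "y", "z"), log_fc = c(1, 2, 4),
                  q = c(0.01, 0.01, 0.01))
  r_all <- pairwise_correlation(a, b)
  expect_equal(r_all$r, 0.981981, tolerance = 1e-5)
  expect_equal(r_all$n_common, 3)
  # identical profiles correlate perfectly
  expect_equal(pairwise_correlation(a, a)$r, 1)
  # perfect anti-correlation
  b2 <- data.frame(feature = c("x", "y", "z"), log_fc = c(3, 2, 1), q = 0.01)
  expect_equal(pairwise_correlation(a, b2)$r, -1)
  # symmetric in its arguments
  expect_equal(pairwise_correlation(a, b)$r, pairwise_correlation(b, a)$r)
  # significant-only mode drops z (q = 0.5 in a) leaving 2 features -> error
  expect_error(pairwise_correlation(a, b, mode = "significant"),
               "fewer than 3 common features")
})

test_that("hierarchical clustering merges the most correlated conditions first", {
  set.seed(51)
  base <- stats::rnorm(60)
  profiles <- rbind(A = base + stats::rnorm(60, sd = 0.05),
                    B = base + stats::rnorm(60, sd = 0.05),
                    C = stats::rnorm(60))
  tree <- hier_cluster(profiles)
  expect_s3_class(tree, "hclust")
  expect_equal(nrow(tree$merge), 2)      # n - 1 merges
  first <- sort(tree$labels[-tree$merge[1, ]])
  expect_equal(first, c("A", "B"))
  expect_true(all(diff(tree$height) >= -1e-12))
  # two identical conditions: single merge at height 0
  t2 <- hier_cluster(rbind(A = base, B = base))
  expect_equal(nrow(t2$merge), 1)
  expect_equal(t2$height, 0, tolerance = 1e-12)
  expect_error(hier_cluster(rbind(A = base)), "at least 2")
})
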