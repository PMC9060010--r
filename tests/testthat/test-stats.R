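test_that("exact Mann-Whitney reproduces the documented small-n cases", {
  res <- mann_whitney_exact(c(1, 2, 3), c(4, 5, 6))
  expect_identical(res$U, 0)
  expect_equal(res$p, 0.1) # the n = 3 vs 3 floor: never below 0.1
  expect_identical(res$method, "exact")

  res4 <- mann_whitney_exact(1:4, 5:8)
  expect_identical(res4$U, 0)
  expect_equal(res4$p, 2 / 70)

  same <- mann_whitney_exact(c(2, 5, 9), c(2, 5, 9))
  expect_equal(same$U, 9 / 2) # n^2 / 2 under full ties
  expect_equal(same$p, 1)
  expect_error(mann_whitney_exact(numeric(0), 1:3), "non-empty")
})

test_that("exact p equals brute-force enumeration for 100 random datasets", {
  withr::local_seed(99)
  for (i in 1:100) {
    na <- sample(1:6, 1)
    nb <- sample(1:6, 1)
    # mix of continuous and heavily tied data
    if (i %% 2) {
      a <- rnorm(na); b <- rnorm(nb, 0.5)
    } else {
      a <- sample(1:4, na, TRUE); b <- sample(2:5, nb, TRUE)
    }
    alt <- sample(c("two.sided", "greater", "less"), 1)
    got <- mann_whitney_exact(a, b, alternative = alt)
    want <- mwu_brute(a, b, alternative = alt)
    expect_equal(got$U, want$U, label = sprintf("U (case %d)", i))
    expect_equal(got$p, want$p, tolerance = 1e-12,
                 label = sprintf("p (case %d)", i))
  }
})

test_that("U is invariant under monotone transforms and U_A + U_B = nA nB", {
  withr::local_seed(5)
  for (i in 1:20) {
    a <- rexp(sample(2:8, 1))
    b <- rexp(sample(2:8, 1))
    ua <- mann_whitney_exact(a, b)
    ub <- mann_whitney_exact(b, a)
    expect_equal(ua$U + ub$U, length(a) * length(b))
    tr <- mann_whitney_exact(log(a + 1), log(b + 1))
    expect_equal(tr$U, ua$U)
    expect_equal(tr$p, ua$p)
  }
})

test_that("large samples fall back to the tie-corrected normal approximation", {
  withr::local_seed(11)
  a <- rnorm(30)
  b <- rnorm(25, 0.8)
  got <- mann_whitney_exact(a, b)
  expect_identical(got$method, "normal")
  ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p, ref$p.value, tolerance = 1e-9)
})

test_that("Student's t matches the pooled-variance closed form", {
  res <- students_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$t, -sqrt(1.5), tolerance = 1e-12)
  expect_identical(res$df, 4L)
  ref <- t.test(c(1, 2, 3), c(2, 3, 4), var.equal = TRUE)
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  eq <- students_t(c(1, 2, 3), c(3, 1, 2))
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  expect_error(students_t(1, c(1, 2)), "at least 2")
  expect_error(students_t(c(2, 2), c(2, 2)), "zero pooled variance")
})

test_that("both percent conventions are reported, labelled", {
  expect_equal(percent_difference(10, 10),
               list(percent_ratio = 100, percent_change = 0))
  expect_equal(percent_difference(10, 16.5),
               list(percent_ratio = 165, percent_change = 65))
  expect_equal(percent_difference(10, 5.5),
               list(percent_ratio = 55, percent_change = -45))
  expect_error(percent_difference(0, 5), "non-zero")
})

test_that("compare_groups summarises, tests and stars per metric", {
  recs <- rbind(
    metrics_record("a1", "young", mean_length_um = 30, n_branches = 6),
    metrics_record("a2", "young", mean_length_um = 32, n_branches = 5),
    metrics_record("a3", "young", mean_length_um = 31, n_branches = 7),
    metrics_record("b1", "aged", mean_length_um = 40, n_branches = 3),
    metrics_record("b2", "aged", mean_length_um = 39, n_branches = 2),
    metrics_record("b3", "aged", mean_length_um = 42, n_branches = 4))
  cmp <- compare_groups(recs, metrics = c("mean_length_um", "n_branches"),
                        reference = "young")
  len <- cmp[cmp$metric == "mean_length_um", ]
  # complete separation at n = 3 vs 3: exact p bottoms out at 0.1, no star
  expect_identical(len$U, 0)
  expect_equal(len$p_mwu, 0.1)
  expect_identical(len$stars, "")
  expect_equal(len$percent_change,
               100 * (mean(c(40, 39, 42)) / mean(c(30, 32, 31)) - 1))
  # identical groups: p = 1 everywhere
  same <- rbind(recs[1:3, ], transform(recs[1:3, ], group = "aged"))
  cs <- compare_groups(same, metrics = "mean_length_um")
  expect_equal(cs$p_mwu, 1)
  expect_error(compare_groups(recs[1:3, ]), "two groups")
  expect_error(compare_groups(recs, metrics = "intensity_ratio"),
               "absent")
})
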