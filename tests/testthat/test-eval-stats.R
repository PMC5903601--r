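test_that("confusion metrics reproduce the published holdout arithmetic", {
  # 171 holdout subjects: 77 cases (35 detected), 94 controls (80 detected)
  truth <- rep(c("case", "control"), c(77, 94))
  pred <- c(rep(c("case", "control"), c(35, 42)),
            rep(c("control", "case"), c(80, 14)))
  rep_ <- evaluate_predictions(pred, truth, baseline_rate = 94 / 171)
  # published values are printed to 4 digits (specificity truncated)
  expect_lt(abs(rep_$sensitivity - 0.4545), 1e-4)
  expect_lt(abs(rep_$specificity - 0.8510), 1e-4)
  expect_lt(abs(rep_$jstat - 0.3055), 2e-4)
  expect_equal(round(rep_$accuracy, 4), 0.6725)
  # predict-all-control baseline accuracy
  allc <- evaluate_predictions(rep("control", 171), truth)
  expect_equal(round(allc$accuracy, 4), 0.5497)
})

test_that("perfect predictions give unit metrics", {
  truth <- rep(c("case", "control"), 10)
  r <- evaluate_predictions(truth, truth, baseline_rate = 0.5)
  expect_equal(r$accuracy, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_equal(r$jstat, 1)
  expect_equal(r$binomial_p, 0.5^20)
})

test_that("report internals stay consistent for random predictions", {
  set.seed(81)
  for (case in 1:20) {
    n <- sample(10:60, 1)
    truth <- sample(c("case", "control"), n, TRUE)
    if (length(unique(truth)) < 2) truth[1:2] <- c("case", "control")
    pred <- sample(c("case", "control"), n, TRUE)
    r <- evaluate_predictions(pred, truth)
    expect_equal(r$jstat, r$sensitivity + r$specificity - 1,
                 tolerance = 1e-12)
    expect_equal(r$TP + r$FP + r$TN + r$FN, n)
    expect_equal(r$accuracy, (r$TP + r$TN) / n, tolerance = 1e-12)
    expect_gte(r$binomial_p, 0); expect_lte(r$binomial_p, 1)
  }
})

test_that("exact binomial comparison matches direct tail summation", {
  r <- evaluate_predictions(rep("case", 8), rep(c("case", "control"), 4),
                            baseline_rate = 0.5)
  # 4 correct of 8 at rate 0.5: P(X >= 4)
  expect_equal(r$binomial_p, sum(dbinom(4:8, 8, 0.5)), tolerance = 1e-12)
})

test_that("the exact McNemar test handles degenerate and typical cases", {
  truth <- rep(c("case", "control"), 10)
  pred <- sample(truth)
  expect_equal(mcnemar_test(pred, pred, truth), 1)

  # b = c: symmetric discordance
  pa <- truth; pa[1:2] <- rev(truth[1:2])
  pb <- truth; pb[3:4] <- rev(truth[3:4])
  expect_equal(mcnemar_test(pa, pb, truth), 1)

  # b = 10, c = 2 against direct two-sided binomial enumeration
  truth2 <- rep("case", 30)
  pa2 <- rep("case", 30); pb2 <- rep("case", 30)
  pa2[1:2] <- "control"              # a wrong on 1:2
  pb2[3:12] <- "control"             # b wrong on 3:12 -> b = 10, c = 2
  got <- mcnemar_test(pa2, pb2, truth2)
  dens <- dbinom(0:12, 12, 0.5)
  want <- sum(dens[dens <= dbinom(10, 12, 0.5) + 1e-12])
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("permutation tests preserve class counts and calibrate", {
  set.seed(82)
  n <- 40
  X <- matrix(rnorm(n * 4), n, 4)
  y <- rep(c("case", "control"), n / 2)
  res <- permutation_test(X, y, iters = 200, seed = 5)
  expect_length(res$null_accuracies, 200L)
  expect_gt(res$p_value, 0); expect_lte(res$p_value, 1)
  # null features: mean null accuracy within 2 SE of the majority rate
  se <- sd(res$null_accuracies) / sqrt(200)
  expect_lt(abs(mean(res$null_accuracies) - 0.5), max(2 * se, 0.05))
})

test_that("a strong signal yields a small permutation p-value", {
  set.seed(83)
  n <- 40
  y <- rep(c("case", "control"), n / 2)
  X <- matrix(rnorm(n * 4), n, 4) + 3 * (y == "case")
  res <- permutation_test(X, y, iters = 99, seed = 6)
  expect_lte(res$p_value, 0.05)
  expect_equal(res$observed, 1)
})

test_that("site-balanced subsampling equalizes case:control per site", {
  cohort <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:12),
    label = c(rep("case", 3), "control",            # site A: 3:1
              rep(c("case", "control"), 2),         # site B: 2:2
              rep("case", 4)),                      # site C: 4:0
    site = rep(c("A", "B", "C"), each = 4),
    split = "train", structural_path = "", functional_path = "")
  bal <- site_balanced_subsets(cohort, seed = 3)
  tab <- table(bal$site, bal$label)
  expect_equal(unname(tab["A", "case"]), 1L)
  expect_equal(unname(tab["A", "control"]), 1L)
  expect_equal(unname(tab["B", "case"]), 2L)
  expect_equal(unname(tab["B", "control"]), 2L)
  expect_false("C" %in% bal$site)
})

test_that("the site-only model measures the planted confound ceiling", {
  # single site: majority-class rate
  one <- tibble::tibble(subject_id = sprintf("s%d", 1:10),
                        label = rep(c("case", "control"), c(7, 3)),
                        site = "X", split = "train",
                        structural_path = "", functional_path = "")
  r1 <- site_only_model(one)
  expect_equal(r1$accuracy, 0.7)

  # label a deterministic function of site -> accuracy 1
  set.seed(84)
  det <- tibble::tibble(subject_id = sprintf("s%02d", 1:40),
                        site = rep(c("A", "B"), each = 20),
                        split = "train", structural_path = "",
                        functional_path = "")
  det$label <- ifelse(det$site == "A", "case", "control")
  r2 <- site_only_model(det, seed = 2)
  expect_equal(r2$accuracy, 1)

  # planted association of known strength: accuracy ~ Bayes rate
  set.seed(85)
  n <- 400
  site <- rep(c("A", "B"), each = n / 2)
  p_case <- ifelse(site == "A", 0.8, 0.2)
  lab <- ifelse(runif(n) < p_case, "case", "control")
  pl <- tibble::tibble(subject_id = sprintf("s%03d", 1:n), label = lab,
                       site = site, split = "train",
                       structural_path = "", functional_path = "")
  r3 <- site_only_model(pl, seed = 3)
  expect_lt(abs(r3$accuracy - 0.8), 0.05)
})

test_that("component group comparison calibrates under the null and finds a planted shift", {
  set.seed(86)
  Tn <- 91; n <- 120
  labels <- rep(c("case", "control"), n / 2)
  null_tc <- lapply(1:n, function(i) matrix(rnorm(Tn * 2), Tn, 2))
  r0 <- component_group_comparison(null_tc, labels, component = 1)
  expect_lte(r0$n_significant, qbinom(0.95, Tn, 0.05) + 3)
  expect_gt(r0$n_reduced, qbinom(0.005, Tn, 0.5))
  expect_lt(r0$n_reduced, qbinom(0.995, Tn, 0.5))

  shift_t <- 1:30
  planted <- lapply(1:n, function(i) {
    A <- matrix(rnorm(Tn * 2), Tn, 2)
    if (labels[i] == "case") A[shift_t, 1] <- A[shift_t, 1] - 1
    A
  })
  r1 <- component_group_comparison(planted, labels, component = 1)
  expect_gte(r1$n_significant, 25)
  expect_gte(r1$n_reduced, 30)

  flat <- lapply(1:n, function(i) matrix(rep(c(1, 0), each = Tn), Tn, 2))
  expect_error(component_group_comparison(flat, labels, 1), "zero-variance")
})
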