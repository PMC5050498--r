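test_that("AUC equals exhaustive pair counting, including ties", {
  labs <- c(rep("PD", 4), rep("control", 4))
  # perfect separation
  expect_equal(roc_auc(c(5, 6, 7, 8, 1, 2, 3, 4), labs)$auc, 1)
  # all ties
  expect_equal(roc_auc(rep(1, 8), labs)$auc, 0.5)
  # random instances against the brute-force oracle
  withr::local_seed(19)
  for (i in 1:25) {
    n <- sample(6:50, 1)
    is_pos <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    s <- round(rnorm(n), sample(c(1, 2, 8), 1))  # coarse rounding forces ties
    r <- roc_auc(s, ifelse(is_pos, "PD", "control"))
    expect_equal(r$auc, oracle_auc(s, is_pos))
    expect_equal(r$n_pos, sum(is_pos))
  }
  expect_error(roc_auc(1:4, rep("PD", 4)), "both classes")
})

test_that("ROC curve is a valid monotone staircase from (0,0) to (1,1)", {
  withr::local_seed(23)
  s <- rnorm(30)
  r <- roc_auc(s, ifelse(runif(30) < 0.5, "PD", "control"))
  cv <- r$curve
  expect_equal(cv$fpr[1], 0)
  expect_equal(cv$tpr[1], 0)
  expect_equal(cv$fpr[nrow(cv)], 1)
  expect_equal(cv$tpr[nrow(cv)], 1)
  expect_false(is.unsorted(cv$fpr))
  expect_false(is.unsorted(cv$tpr))
  expect_true(r$ci95[1] <= r$auc && r$auc <= r$ci95[2])
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::local_seed(29)
  s <- rnorm(40)
  labs <- ifelse(runif(40) < 0.45, "PD", "control")
  a0 <- roc_auc(s, labs)$auc
  expect_equal(roc_auc(exp(s), labs)$auc, a0)
  expect_equal(roc_auc(3 * s - 7, labs)$auc, a0)
  expect_equal(roc_auc(atan(s), labs)$auc, a0)
})

test_that("DeLong self-test and antisymmetric case behave as expected", {
  withr::local_seed(31)
  labs <- ifelse(runif(30) < 0.5, "PD", "control")
  s <- rnorm(30)
  self <- delong_test(s, s, labs)
  expect_equal(self$z, 0)
  expect_equal(self$p, 1)
  # separable scores vs their negation: maximal |z|, p near 0
  sep <- ifelse(labs == "PD", 1, 0) + runif(30, 0, 0.1)
  anti <- delong_test(sep, -sep, labs)
  expect_equal(anti$auc_a, 1)
  expect_equal(anti$auc_b, 0)
  expect_lt(anti$p, 1e-6)
})

test_that("confusion statistics compute the three ratios with 2-dp rounding", {
  cs <- confusion_stats(30, 12, 36, 7)
  expect_equal(cs$sensitivity, 30 / 42)
  expect_equal(cs$specificity, 36 / 43)
  expect_equal(cs$accuracy, 66 / 85)
  expect_equal(c(cs$sensitivity_2dp, cs$specificity_2dp, cs$accuracy_2dp),
               c(0.71, 0.84, 0.78))
  perfect <- confusion_stats(10, 0, 10, 0)
  expect_equal(c(perfect$sensitivity, perfect$specificity, perfect$accuracy),
               c(1, 1, 1))
  expect_error(confusion_stats(0, 0, 5, 5), "zero subjects")
  # rounding is half-up (0.745 -> 0.75, not banker's 0.74)
  expect_equal(confusion_stats(149, 51, 1, 1)$sensitivity_2dp, 0.75)
})

test_that("generalized Youden cutoff maximizes the cost-weighted index", {
  # separable scores: sensitivity = specificity = 1 at any costs
  labs4 <- c("PD", "PD", "control", "control")
  cut <- youden_cutoff(c(0.2, 0.3, 0.0, 0.1), labs4)
  expect_equal(cut$sensitivity, 1)
  expect_equal(cut$specificity, 1)
  expect_gt(cut$threshold, 0.1)
  expect_lt(cut$threshold, 0.2)
  # confusion invariants hold on every result
  expect_equal(cut$sensitivity, cut$tp / (cut$tp + cut$fn))
  expect_equal(cut$specificity, cut$tn / (cut$tn + cut$fp))
  expect_equal(cut$accuracy, (cut$tp + cut$tn) / 4)

  withr::local_seed(41)
  for (i in 1:15) {
    n <- 40
    labs <- ifelse(runif(n) < 0.5, "PD", "control")
    if (length(unique(labs)) < 2) next
    s <- round(rnorm(n, mean = (labs == "PD") * 0.5), 2)
    is_pos <- labs == "PD"
    prev <- mean(is_pos)
    for (costs in list(c(1, 1), c(2, 1), c(1, 2))) {
      res <- youden_cutoff(s, labs, cost_fn = costs[1], cost_fp = costs[2])
      # exhaustive scan oracle over all thresholds
      m <- (costs[2] / costs[1]) * ((1 - prev) / prev)
      thr_all <- c(-Inf, sort(unique(s)), Inf)
      best <- max(sapply(thr_all, function(th) {
        se <- mean(s[is_pos] >= th)
        sp <- mean(s[!is_pos] < th)
        se - m * (1 - sp)
      }))
      got <- res$sensitivity - m * (1 - res$specificity)
      expect_equal(got, best, tolerance = 1e-12)
    }
    # higher FN cost never yields lower sensitivity than higher FP cost
    se_fn <- youden_cutoff(s, labs, cost_fn = 2, cost_fp = 1)$sensitivity
    se_fp <- youden_cutoff(s, labs, cost_fn = 1, cost_fp = 2)$sensitivity
    expect_gte(se_fn, se_fp)
  }
})

test_that("equal costs and balanced prevalence reduce to classical Youden J", {
  withr::local_seed(43)
  for (i in 1:10) {
    s <- rnorm(30, mean = rep(c(0.4, 0), each = 15))
    labs <- rep(c("PD", "control"), each = 15)
    res <- youden_cutoff(s, labs, cost_fn = 1, cost_fp = 1)
    is_pos <- labs == "PD"
    thr_all <- c(-Inf, sort(unique(s)), Inf)
    bestJ <- max(sapply(thr_all, function(th) {
      mean(s[is_pos] >= th) + mean(s[!is_pos] < th) - 1
    }))
    expect_equal(res$sensitivity + res$specificity - 1, bestJ,
                 tolerance = 1e-12)
  }
})

test_that("cross-dataset validation is symmetric and leak-free", {
  simA <- tiny_cohort(seed = 51)
  simB <- simulate_cohort(sim_config(n_pd = 4, n_control = 4, seed = 52),
                          id_prefix = "T")
  fa <- featurize(simA$events)
  fb <- featurize(simB$events)
  cfg <- nqi_config(n_models = 10, seed = 1)
  cv <- cross_dataset_validate(fa, simA$meta, fb, simB$meta, cfg)
  expect_equal(nrow(cv$scores), 16)
  # swapping datasets leaves the combined score multiset unchanged
  cv2 <- cross_dataset_validate(fb, simB$meta, fa, simA$meta, cfg)
  expect_equal(sort(cv2$scores$nqi), sort(cv$scores$nqi))
  expect_equal(cv2$roc_combined$auc, cv$roc_combined$auc)
  # overlapping subjects are rejected
  expect_error(cross_dataset_validate(fa, simA$meta, fa, simA$meta, cfg),
               "share subject")
})

test_that("window-level evaluation inherits subject labels", {
  simA <- tiny_cohort(seed = 53)
  simB <- simulate_cohort(sim_config(n_pd = 4, n_control = 4, seed = 54),
                          id_prefix = "T")
  fa <- featurize(simA$events)
  fb <- featurize(simB$events)
  cfg <- nqi_config(n_models = 10, seed = 1)
  pw <- per_window_auc(fa, simA$meta, fb, simB$meta, cfg)
  expect_equal(nrow(pw$window_scores), nrow(fa) + nrow(fb))
  lab <- dplyr::distinct(pw$window_scores, subject_id, group)
  meta <- dplyr::bind_rows(simA$meta, simB$meta)
  expect_equal(lab$group,
               meta$group[match(lab$subject_id, meta$subject_id)])
  # duplicating every window leaves the AUC unchanged
  pw_dup <- roc_auc(rep(pw$window_scores$window_nqi, 2),
                    rep(pw$window_scores$group, 2))
  expect_equal(pw_dup$auc, pw$roc$auc)
})

test_that("adjusted logistic flags separation and matches nested fits", {
  withr::local_seed(61)
  n <- 60
  dat <- tibble::tibble(
    group = rep(c("PD", "control"), each = n / 2),
    nqi = rnorm(n, mean = (rep(c(1, 0), each = n / 2)) * 0.3, sd = 0.3),
    age = rnorm(n, 60, 10),
    sex = sample(c("F", "M"), n, replace = TRUE),
    education_years = rnorm(n, 15, 4),
    typing_speed = runif(n, 60, 160)
  )
  fit <- adjusted_logistic(dat)
  expect_false(fit$separation)
  expect_true(all(c("nqi", "age", "education_years", "typing_speed") %in%
                    fit$coefficients$term))
  expect_true(is.finite(glance(fit)$score_p))
  # score identical to the label indicator -> separation flag, p withheld
  dat2 <- dplyr::mutate(dat, nqi = as.numeric(group == "PD"))
  fit2 <- adjusted_logistic(dat2)
  expect_true(fit2$separation)
  expect_true(is.na(glance(fit2)$score_p))
  # zeroed covariates reduce to the univariate fit
  dat3 <- dplyr::mutate(dat, age = 0, education_years = 0, typing_speed = 0)
  fit3 <- adjusted_logistic(dat3, covariates = character(0))
  uni <- stats::glm(I(group == "PD") ~ nqi, family = stats::binomial(),
                    data = dat3)
  expect_equal(fit3$coefficients$estimate[fit3$coefficients$term == "nqi"],
               unname(stats::coef(uni)["nqi"]), tolerance = 1e-8)
})

test_that("evaluation objects expose tidy/glance/autoplot views", {
  withr::local_seed(71)
  s <- rnorm(30, rep(c(0.5, 0), each = 15))
  labs <- rep(c("PD", "control"), each = 15)
  r <- roc_auc(s, labs)
  expect_named(glance(r), c("auc", "ci_low", "ci_high", "se", "n_pos",
                            "n_neg"))
  expect_s3_class(tidy(r), "tbl_df")
  expect_s3_class(ggplot2::autoplot(r), "ggplot")
})
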