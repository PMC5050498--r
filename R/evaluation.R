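# ROC/AUC with DeLong inference, cost-weighted cutoffs, confusion stats,
# cross-dataset validation and covariate-adjusted logistic significance.

as_binary_labels <- function(labels, positive = "PD") {
  if (is.logical(labels)) labels <- ifelse(labels, positive, "control")
  labels <- as.character(labels)
  pos <- labels == positive
  if (!any(pos) || all(pos)) {
    stop("both classes must be present (positive class '", positive, "')",
         call. = FALSE)
  }
  pos
}

roc_object <- function(scores, is_pos) {
  # direction is fixed: higher score -> positive class. Letting the curve
  # auto-orient would bias AUC upward on null data.
  pROC::roc(response = factor(is_pos, levels = c(FALSE, TRUE)),
            predictor = scores, levels = c(FALSE, TRUE), direction = "<",
            quiet = TRUE)
}

#' ROC curve and AUC with DeLong confidence interval
#'
#' The AUC equals the Mann-Whitney U statistic normalized by
#' `n_pos * n_neg`, with ties counted one half. The 95% CI uses the DeLong
#' structural-components variance; when the AUC exceeds 0.95 the interval is
#' computed on the logit scale to stay inside `[0, 1]`.
#'
#' @param scores Numeric per-subject (or per-window) scores; higher means
#'   more PD-like.
#' @param labels Class labels; the positive class is `positive`.
#' @param positive Label of the positive (diseased) class. Default `"PD"`.
#' @return An object of class `nqi_roc`: `auc`, `ci95`, `se`, `curve`
#'   (tibble of `fpr`, `tpr`, `threshold`), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, positive = "PD") {
  is_pos <- as_binary_labels(labels, positive)
  stopifnot(length(scores) == length(is_pos), all(is.finite(scores)))
  r <- roc_object(scores, is_pos)
  # AUC as the exact normalized Mann-Whitney U statistic (ties counted one
  # half); numerically this is the curve area, but the rank form is exact
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  rk <- rank(scores)
  auc <- (sum(rk[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # pROC warns that the DeLong variance of a degenerate (AUC = 1) curve is
  # zero; that is the intended value here, the CI collapses.
  v <- suppressWarnings(as.numeric(pROC::var(r, method = "delong")))
  se <- sqrt(v)
  z <- stats::qnorm(0.975)
  if (auc > 0.95 && se > 0 && auc < 1) {
    # logit-scale interval, delta method
    lg <- stats::qlogis(auc)
    se_lg <- se / (auc * (1 - auc))
    ci <- stats::plogis(c(lg - z * se_lg, lg + z * se_lg))
  } else {
    ci <- pmin(1, pmax(0, c(auc - z * se, auc + z * se)))
  }
  curve <- tibble::tibble(
    fpr = 1 - r$specificities,
    tpr = r$sensitivities,
    threshold = r$thresholds
  ) |>
    dplyr::arrange(.data$fpr, .data$tpr)
  structure(
    list(auc = auc, ci95 = ci, se = se, curve = curve,
         n_pos = sum(is_pos), n_neg = sum(!is_pos)),
    class = "nqi_roc"
  )
}

#' @export
print.nqi_roc <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), %d positive / %d negative\n",
              x$auc, x$ci95[1], x$ci95[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
tidy.nqi_roc <- function(x, ...) x$curve

#' @export
glance.nqi_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, ci_low = x$ci95[1], ci_high = x$ci95[2],
                 se = x$se, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' DeLong test for two correlated ROC curves
#'
#' Two-sided test of equal AUC for two score sets measured on the same
#' subjects, using the paired DeLong covariance of the structural
#' components. Identical score sets give `z = 0`, `p = 1`; a degenerate
#' (zero) variance with unequal AUCs is an error.
#'
#' @param scores_a,scores_b Paired score vectors on the same subjects.
#' @param labels Shared class labels.
#' @param positive Positive-class label.
#' @return List with `z`, `p`, `auc_a`, `auc_b`, and `var_diff` (the DeLong
#'   variance of the AUC difference).
#' @export
delong_test <- function(scores_a, scores_b, labels, positive = "PD") {
  is_pos <- as_binary_labels(labels, positive)
  stopifnot(length(scores_a) == length(is_pos),
            length(scores_b) == length(is_pos))
  ra <- roc_object(scores_a, is_pos)
  rb <- roc_object(scores_b, is_pos)
  auc_a <- as.numeric(pROC::auc(ra))
  auc_b <- as.numeric(pROC::auc(rb))
  tst <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  z <- as.numeric(tst$statistic)
  p <- as.numeric(tst$p.value)
  if (is.nan(z)) {
    if (isTRUE(all.equal(auc_a, auc_b))) {
      # identical AUCs with zero variance of the (zero) difference
      z <- 0
      p <- 1
    } else {
      stop("degenerate DeLong variance (",
           signif(auc_a, 4), " vs ", signif(auc_b, 4),
           "); scores may be constant", call. = FALSE)
    }
  } else if (is.infinite(z)) {
    # both curves degenerate (variance 0) but AUCs differ: the difference is
    # as certain as the data allow
    p <- 0
  }
  var_diff <- if (z != 0) ((auc_a - auc_b) / z)^2 else NA_real_
  list(z = z, p = p, auc_a = auc_a, auc_b = auc_b, var_diff = var_diff)
}

#' Sensitivity, specificity and accuracy from a confusion table
#'
#' Also reports two-decimal presentation values rounded half-up, the
#' convention used when tabulating cutoff performance.
#'
#' @param tp,fn,tn,fp Non-negative confusion counts; `tp + fn > 0` and
#'   `tn + fp > 0`.
#' @return Tibble with exact `sensitivity`, `specificity`, `accuracy` and
#'   their rounded counterparts.
#' @export
confusion_stats <- function(tp, fn, tn, fp) {
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  if (tp + fn == 0 || tn + fp == 0) {
    stop("undefined metric: a class has zero subjects", call. = FALSE)
  }
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  acc <- (tp + tn) / (tp + fn + tn + fp)
  tibble::tibble(
    sensitivity = sens, specificity = spec, accuracy = acc,
    sensitivity_2dp = round_half_up(sens, 2),
    specificity_2dp = round_half_up(spec, 2),
    accuracy_2dp = round_half_up(acc, 2)
  )
}

round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

#' Cost-weighted cutoff by the generalized Youden index
#'
#' Chooses the score threshold maximizing
#' `J = sensitivity - m * (1 - specificity)` with
#' `m = (cost_fp / cost_fn) * (1 - prevalence) / prevalence`, prevalence
#' estimated from the evaluated sample. With equal costs and balanced
#' prevalence this reduces to the classical Youden
#' `J = sensitivity + specificity - 1`. Candidate thresholds are midpoints
#' between adjacent sorted unique scores plus the two infinities; a score at
#' or above the threshold is classified positive. Ties break toward higher
#' specificity.
#'
#' @param scores Numeric scores, higher = more PD-like.
#' @param labels Class labels.
#' @param cost_fn,cost_fp Misclassification costs per false negative / false
#'   positive (only their ratio matters). Both `> 0`.
#' @param positive Positive-class label.
#' @return A one-row tibble of class `nqi_cutoff`: costs, threshold,
#'   sensitivity, specificity, accuracy and the confusion counts.
#' @export
youden_cutoff <- function(scores, labels, cost_fn = 1, cost_fp = 1,
                          positive = "PD") {
  is_pos <- as_binary_labels(labels, positive)
  stopifnot(cost_fn > 0, cost_fp > 0, all(is.finite(scores)))
  u <- sort(unique(scores))
  thresholds <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  prev <- mean(is_pos)
  m <- (cost_fp / cost_fn) * ((1 - prev) / prev)
  stats_at <- function(thr) {
    pred_pos <- scores >= thr
    tp <- sum(pred_pos & is_pos)
    fn <- sum(!pred_pos & is_pos)
    tn <- sum(!pred_pos & !is_pos)
    fp <- sum(pred_pos & !is_pos)
    se <- tp / (tp + fn)
    sp <- tn / (tn + fp)
    c(tp = tp, fn = fn, tn = tn, fp = fp, se = se, sp = sp,
      j = se - m * (1 - sp))
  }
  tab <- t(vapply(thresholds, stats_at, numeric(7)))
  best_j <- max(tab[, "j"])
  cand <- which(tab[, "j"] >= best_j - 1e-12)
  # tie-break toward higher specificity, then the higher threshold
  cand <- cand[order(-tab[cand, "sp"], -thresholds[cand])]
  k <- cand[1]
  row <- tab[k, ]
  out <- tibble::tibble(
    cost_fn = cost_fn, cost_fp = cost_fp, threshold = thresholds[k],
    sensitivity = row[["se"]], specificity = row[["sp"]],
    accuracy = (row[["tp"]] + row[["tn"]]) / length(scores),
    tp = as.integer(row[["tp"]]), fn = as.integer(row[["fn"]]),
    tn = as.integer(row[["tn"]]), fp = as.integer(row[["fp"]])
  )
  class(out) <- c("nqi_cutoff", class(out))
  out
}

#' Cutoff table under several misclassification-cost assumptions
#'
#' Convenience wrapper running [youden_cutoff()] for a set of
#' (cost per FN, cost per FP) pairs — by default equal costs, FN twice FP,
#' and FP twice FN.
#'
#' @inheritParams youden_cutoff
#' @param cost_pairs List of `c(cost_fn, cost_fp)` pairs.
#' @return Tibble with one row per cost assumption.
#' @export
cutoff_table <- function(scores, labels,
                         cost_pairs = list(c(1, 1), c(2, 1), c(1, 2)),
                         positive = "PD") {
  purrr::map_dfr(cost_pairs, function(cp) {
    youden_cutoff(scores, labels, cost_fn = cp[1], cost_fp = cp[2],
                  positive = positive)
  })
}

#' Two-cohort cross-dataset validation
#'
#' Trains the ensemble on cohort A and scores cohort B, then the reverse;
#' the combined score list is the union of the two held-out folds, evaluated
#' once without any further training. Subject sets must be disjoint.
#'
#' @param features_a,meta_a Features and metadata of cohort A.
#' @param features_b,meta_b Features and metadata of cohort B.
#' @param cfg An [nqi_config()].
#' @return List of class `nqi_crossval`: `scores` (tibble with
#'   `subject_id, dataset, n_windows, nqi, group`), and `roc_a`, `roc_b`,
#'   `roc_combined` ([roc_auc()] objects; the fold ROC is computed on the
#'   cohort being scored). Zero-variance fold scores yield AUC 0.5 and a
#'   `flat_fold` flag.
#' @export
cross_dataset_validate <- function(features_a, meta_a, features_b, meta_b,
                                   cfg = nqi_config()) {
  overlap <- intersect(meta_a$subject_id, meta_b$subject_id)
  if (length(overlap) > 0) {
    stop("datasets share subject(s): ", paste(overlap, collapse = ", "),
         call. = FALSE)
  }
  fit_a <- train_nqi(features_a, meta_a, cfg)
  fit_b <- train_nqi(features_b, meta_b, cfg)
  score_fold <- function(fit, features, meta, tag) {
    score_subjects(fit, features, meta) |>
      dplyr::inner_join(meta[, c("subject_id", "group")], by = "subject_id") |>
      dplyr::mutate(dataset = tag, .after = "subject_id")
  }
  scores_b <- score_fold(fit_a, features_b, meta_b, "B")
  scores_a <- score_fold(fit_b, features_a, meta_a, "A")
  combined <- dplyr::bind_rows(scores_a, scores_b)
  fold_roc <- function(sc) {
    r <- roc_auc(sc$nqi, sc$group)
    # constant scores: every pair is a tie, AUC 1/2; flagged
    if (stats::sd(sc$nqi) == 0) r$flat_fold <- TRUE
    r
  }
  structure(
    list(scores = combined,
         roc_a = fold_roc(scores_a),
         roc_b = fold_roc(scores_b),
         roc_combined = fold_roc(combined)),
    class = "nqi_crossval"
  )
}

#' @export
print.nqi_crossval <- function(x, ...) {
  cat(sprintf("cross-dataset validation\n  fold A  AUC %.3f\n  fold B  AUC %.3f\n  combined AUC %.3f (n = %d)\n",
              x$roc_a$auc, x$roc_b$auc, x$roc_combined$auc,
              nrow(x$scores)))
  invisible(x)
}

#' Window-level ROC across two cohorts
#'
#' Same cross-training scheme as [cross_dataset_validate()], but every
#' retained 90-second window is treated as an independent observation with
#' the diagnostic label inherited from its subject.
#'
#' @inheritParams cross_dataset_validate
#' @return List with `window_scores` (tibble
#'   `subject_id, dataset, window_index, window_nqi, group`) and `roc`
#'   (an [roc_auc()] object over windows).
#' @export
per_window_auc <- function(features_a, meta_a, features_b, meta_b,
                           cfg = nqi_config()) {
  overlap <- intersect(meta_a$subject_id, meta_b$subject_id)
  if (length(overlap) > 0) {
    stop("datasets share subject(s): ", paste(overlap, collapse = ", "),
         call. = FALSE)
  }
  fit_a <- train_nqi(features_a, meta_a, cfg)
  fit_b <- train_nqi(features_b, meta_b, cfg)
  win_fold <- function(fit, features, meta, tag) {
    predict(fit, features) |>
      dplyr::inner_join(meta[, c("subject_id", "group")], by = "subject_id") |>
      dplyr::transmute(.data$subject_id, dataset = tag, .data$window_index,
                       .data$window_nqi, .data$group)
  }
  win <- dplyr::bind_rows(win_fold(fit_a, features_b, meta_b, "B"),
                          win_fold(fit_b, features_a, meta_a, "A"))
  list(window_scores = win, roc = roc_auc(win$window_nqi, win$group))
}

#' Covariate-adjusted logistic significance of a score
#'
#' Maximum-likelihood logistic regression of the diagnostic label on the
#' score plus the standard covariates (age, sex, years of education, typing
#' speed), reporting the Wald z and p per term. Perfect or quasi-perfect
#' separation is flagged and the score-term p-value withheld, since Wald
#' inference is meaningless there.
#'
#' @param data Tibble with columns `group`, the score column named by
#'   `score`, and the covariates.
#' @param score Name of the score column. Default `"nqi"`.
#' @param covariates Covariate column names; must be present in `data` with
#'   no missing values.
#' @param positive Positive-class label.
#' @return List of class `nqi_logistic`: `coefficients` (tibble
#'   `term, estimate, std_error, z, p`), `separation` flag, the `fit`.
#' @export
adjusted_logistic <- function(data, score = "nqi",
                              covariates = c("age", "sex", "education_years",
                                             "typing_speed"),
                              positive = "PD") {
  needed <- c("group", score, covariates)
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0) {
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(data[, needed])) stop("missing values in model columns",
                                  call. = FALSE)
  y <- as_binary_labels(data$group, positive)
  df <- data.frame(.y = y, data[, c(score, covariates), drop = FALSE],
                   check.names = FALSE)
  form <- stats::reformulate(c(score, covariates), response = ".y")
  sep_warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        sep_warned <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  prob <- stats::fitted(fit)
  separation <- sep_warned || all(abs(prob - y) < 1e-6)
  cf <- summary(fit)$coefficients
  coef_tbl <- tibble::tibble(
    term = rownames(cf),
    estimate = unname(cf[, "Estimate"]),
    std_error = unname(cf[, "Std. Error"]),
    z = unname(cf[, "z value"]),
    p = unname(cf[, "Pr(>|z|)"])
  )
  if (separation) {
    coef_tbl$p[coef_tbl$term == score] <- NA_real_
  }
  structure(list(coefficients = coef_tbl, separation = separation,
                 fit = fit, score = score),
            class = "nqi_logistic")
}

#' @export
tidy.nqi_logistic <- function(x, ...) x$coefficients

#' @export
glance.nqi_logistic <- function(x, ...) {
  tibble::tibble(
    separation = x$separation,
    score_p = x$coefficients$p[x$coefficients$term == x$score],
    deviance = x$fit$deviance,
    null_deviance = x$fit$null.deviance,
    n = length(x$fit$y)
  )
}

#' @export
print.nqi_logistic <- function(x, ...) {
  if (x$separation) cat("[perfect separation flagged]\n")
  print(x$coefficients)
  invisible(x)
}
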