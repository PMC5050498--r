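test_that("UPDRS-III normalization uses the fixed 108-point scale", {
  expect_equal(normalize_updrs(0), 0)
  expect_equal(normalize_updrs(108), 1)
  expect_equal(normalize_updrs(20.6), 20.6 / 108)
  expect_error(normalize_updrs(109), "\\[0, 108\\]")
  expect_error(normalize_updrs(-1), "\\[0, 108\\]")
})

test_that("SVR fit matches a primal-objective oracle on toy problems", {
  toys <- list(
    list(x = matrix(c(0, 0.25, 0.5, 0.75, 1)), y = c(0.05, 0.2, 0.45, 0.6, 0.9)),
    list(x = matrix(c(-1, -0.4, 0.1, 0.6, 1.2)), y = c(1, 0.7, 0.5, 0.2, 0)),
    list(x = matrix(c(0.1, 0.3, 0.5, 0.7, 0.9)), y = c(0.15, 0.28, 0.5, 0.61, 0.84))
  )
  for (toy in toys) {
    for (C in c(0.5, 2)) {
      fit <- svr_fit(toy$x, toy$y, C = C, epsilon = 0.05)
      orc <- oracle_svr(toy$x, toy$y, C = C, eps = 0.05)
      expect_equal(fit$w, orc$w, tolerance = 1e-4)
      expect_equal(fit$b, orc$b, tolerance = 1e-4)
      # and the solver's objective is no worse than the oracle's
      expect_lte(svr_primal(fit$w, fit$b, toy$x, toy$y, C, 0.05),
                 orc$value + 1e-6)
    }
  }
})

test_that("flat targets give w = 0 exactly and b equal to the target", {
  withr::local_seed(2)
  x <- matrix(runif(14), 7, 2)
  fit <- svr_fit(x, rep(0.3, 7), C = 0.094, epsilon = 0.052)
  expect_identical(fit$w, c(0, 0))
  expect_equal(fit$b, 0.3)
})

test_that("duplicating points with C halved leaves the optimum unchanged", {
  x <- matrix(c(0, 0.25, 0.5, 0.75, 1))
  y <- c(0.05, 0.2, 0.45, 0.6, 0.9)
  f1 <- svr_fit(x, y, C = 1, epsilon = 0.05)
  f2 <- svr_fit(rbind(x, x), c(y, y), C = 0.5, epsilon = 0.05)
  # equal primal objectives (the duplicated problem is an exact reweighting)
  expect_equal(svr_primal(f2$w, f2$b, x, y, 1, 0.05),
               svr_primal(f1$w, f1$b, x, y, 1, 0.05), tolerance = 1e-6)
  expect_equal(f2$w, f1$w, tolerance = 1e-4)
  expect_equal(f2$b, f1$b, tolerance = 1e-4)
})

test_that("ensemble training is reproducible and the median contract holds", {
  sim <- tiny_cohort(seed = 31)
  f <- featurize(sim$events)
  cfg <- nqi_config(n_models = 20, seed = 123)
  m1 <- train_nqi(f, sim$meta, cfg)
  m2 <- train_nqi(f, sim$meta, cfg)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$b, m2$b)

  # median aggregation: even ensemble median = mean of central order stats
  probe <- f[1, ]
  outputs <- as.numeric(m1$W %*% t(as.matrix(probe[, c("v_out", "v_skew",
                                                       "h1", "h2", "h3",
                                                       "h4", "v_de")]))) + m1$b
  srt <- sort(outputs)
  expect_equal(predict(m1, probe)$window_nqi,
               (srt[10] + srt[11]) / 2)
})

test_that("single-model ensemble equals the base SVR and degenerate bagging collapses", {
  sim <- tiny_cohort(seed = 32, n_pd = 2, n_control = 2)
  f <- featurize(sim$events)
  # identical training vectors -> every bootstrap sample is identical
  f1 <- f[rep(1, 12), ]
  meta1 <- sim$meta[sim$meta$subject_id == f1$subject_id[1], ]
  m <- train_nqi(f1, meta1, nqi_config(n_models = 8, seed = 5))
  expect_equal(max(apply(m$W, 2, stats::sd)), 0)
  expect_equal(stats::sd(m$b), 0)
  # its prediction equals a direct SVR fit on the same (constant) sample
  x <- as.matrix(f1[, c("v_out", "v_skew", "h1", "h2", "h3", "h4", "v_de")])
  direct <- svr_fit(x, normalize_updrs(rep(meta1$updrs3, 12)), 0.094, 0.052)
  expect_equal(as.numeric(m$W[1, ]), direct$w, tolerance = 1e-10)
})

test_that("median prediction equals a sort-based oracle on random ensembles", {
  withr::local_seed(77)
  for (n_models in c(4, 5, 20)) {
    fake <- structure(
      list(W = matrix(rnorm(n_models * 7), n_models, 7),
           b = rnorm(n_models), cfg = nqi_config(n_models = n_models),
           scaling = NULL, fingerprint = list()),
      class = "nqi_model")
    x <- tibble::tibble(subject_id = "s", window_index = 0,
                        v_out = runif(1), v_skew = runif(1), h1 = runif(1),
                        h2 = runif(1), h3 = runif(1), h4 = runif(1),
                        v_de = runif(1), n_samples = 40L)
    outs <- as.numeric(fake$W %*% t(as.matrix(x[, 3:9]))) + fake$b
    srt <- sort(outs)
    med <- if (n_models %% 2 == 0) {
      (srt[n_models / 2] + srt[n_models / 2 + 1]) / 2
    } else {
      srt[(n_models + 1) / 2]
    }
    expect_equal(predict(fake, x)$window_nqi, med)
    # median of identical models is that model's output
    same <- fake
    same$W <- fake$W[rep(1, n_models), ]
    same$b <- rep(fake$b[1], n_models)
    expect_equal(predict(same, x)$window_nqi, outs[1], tolerance = 1e-12)
  }
})

test_that("subject scores are the mean of window scores, order-invariant", {
  sim <- tiny_cohort(seed = 33, n_pd = 2, n_control = 2)
  f <- featurize(sim$events)
  m <- train_nqi(f, sim$meta, nqi_config(n_models = 10, seed = 3))
  sc <- score_subjects(m, f)
  wsc <- predict(m, f)
  byhand <- tapply(wsc$window_nqi, wsc$subject_id, mean)
  expect_equal(sc$nqi, as.numeric(byhand[sc$subject_id]))
  # shuffled window order gives identical scores
  sc2 <- score_subjects(m, f[sample(nrow(f)), ])
  expect_equal(dplyr::arrange(sc2, subject_id), dplyr::arrange(sc, subject_id))
  # subject with no retained window is excluded and reported
  expect_warning(
    score_subjects(m, f[f$subject_id != sim$meta$subject_id[1], ], sim$meta),
    "no retained window")
})

test_that("adding a constant to all targets shifts predictions by that constant", {
  sim <- tiny_cohort(seed = 34, n_pd = 2, n_control = 2)
  f <- featurize(sim$events)
  meta <- sim$meta
  cfg <- nqi_config(n_models = 6, seed = 9)
  m0 <- train_nqi(f, meta, cfg)
  meta_shift <- dplyr::mutate(meta, updrs3 = updrs3 + 20)
  m1 <- train_nqi(f, meta_shift, cfg)
  p0 <- predict(m0, f)$window_nqi
  p1 <- predict(m1, f)$window_nqi
  expect_equal(p1, p0 + 20 / 108, tolerance = 1e-5)
})

test_that("model serialization round-trips to identical predictions", {
  sim <- tiny_cohort(seed = 35, n_pd = 2, n_control = 2)
  f <- featurize(sim$events)
  m <- train_nqi(f, sim$meta, nqi_config(n_models = 12, seed = 4))
  path <- withr::local_tempfile(fileext = ".json")
  write_nqi_model(m, path)
  m2 <- read_nqi_model(path)
  expect_equal(predict(m2, f)$window_nqi, predict(m, f)$window_nqi,
               tolerance = 1e-12)
  expect_equal(m2$cfg$C, m$cfg$C)
  expect_equal(m2$fingerprint$data_hash, m$fingerprint$data_hash)
})

test_that("tidy and glance summarize the ensemble", {
  sim <- tiny_cohort(seed = 36, n_pd = 2, n_control = 2)
  f <- featurize(sim$events)
  m <- train_nqi(f, sim$meta, nqi_config(n_models = 5, seed = 2))
  td <- tidy(m)
  expect_equal(nrow(td), 5)
  expect_named(td, c("model", "v_out", "v_skew", "h1", "h2", "h3", "h4",
                     "v_de", "bias"))
  gl <- glance(m)
  expect_equal(gl$n_models, 5)
  expect_equal(gl$C, 0.094)
  expect_equal(gl$epsilon, 0.052)
})

test_that("grid search returns the LOO-AUC argmax with deterministic tie-breaks", {
  sim <- tiny_cohort(seed = 37, n_pd = 3, n_control = 3)
  f <- featurize(sim$events)
  cfg <- nqi_config(n_models = 5, seed = 7)
  # size-1 grid returns that pair
  g1 <- grid_search_nqi(f, sim$meta, C_grid = 0.094, eps_grid = 0.052,
                        cfg = cfg)
  expect_equal(g1$C, 0.094)
  expect_equal(g1$epsilon, 0.052)
  # a huge epsilon swallows every target: the fit is flat, predictions are
  # constant within a fold, and constant scores give AUC 0.5
  m_flat <- train_nqi(f, sim$meta, nqi_config(n_models = 5, seed = 7,
                                              epsilon = 10))
  flat_scores <- score_subjects(m_flat, f)
  expect_equal(stats::sd(flat_scores$nqi), 0)
  expect_equal(roc_auc(flat_scores$nqi,
                       sim$meta$group[match(flat_scores$subject_id,
                                            sim$meta$subject_id)])$auc, 0.5)
  # and the degenerate pair is never selected over a separating pair
  g2 <- grid_search_nqi(f, sim$meta, C_grid = c(0.094),
                        eps_grid = c(0.052, 10), cfg = cfg)
  tab <- g2$auc_table
  if (tab$auc[tab$epsilon == 0.052] > max(0.5, tab$auc[tab$epsilon == 10])) {
    expect_equal(g2$epsilon, 0.052)
  }
})
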