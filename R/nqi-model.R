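# Bagged linear epsilon-SVR ensemble mapping window features to nQi scores.

#' Normalize a UPDRS-III motor score to the unit interval
#'
#' Divides by the fixed 108-point maximum of the UPDRS part-III scale, so
#' regression targets are comparable across cohorts (no per-cohort min-max).
#'
#' @param updrs3 Integer score(s) on the 0-108 scale.
#' @return `updrs3 / 108`.
#' @export
normalize_updrs <- function(updrs3) {
  if (any(is.na(updrs3)) || any(updrs3 < 0) || any(updrs3 > 108)) {
    stop("updrs3 must lie in [0, 108]", call. = FALSE)
  }
  updrs3 / 108
}

#' Fit one linear epsilon-SVR base model
#'
#' Minimizes the standard primal objective
#' `0.5 * ||w||^2 + C * sum(xi + xi*)` under the epsilon-insensitive
#' constraints, via the LibSVM solver. With all targets equal the flat
#' function inside the tube has zero loss and minimal norm, so `w = 0` and
#' `b` equals the common target.
#'
#' @param x Numeric feature matrix (rows = training vectors).
#' @param y Numeric targets (normalized UPDRS-III scores).
#' @param C Regularization constant, `> 0`.
#' @param epsilon Insensitive-tube half-width, `> 0`.
#' @param tolerance Solver termination tolerance.
#' @return A list of class `svr_model` with elements `w` (weight vector) and
#'   `b` (bias).
#' @export
svr_fit <- function(x, y, C, epsilon, tolerance = 1e-6) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), C > 0, epsilon > 0)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite values in SVR training data", call. = FALSE)
  }
  fit <- e1071::svm(x, y, type = "eps-regression", kernel = "linear",
                    cost = C, epsilon = epsilon, scale = FALSE,
                    tolerance = tolerance, fitted = FALSE)
  w <- if (fit$tot.nSV == 0) {
    rep(0, ncol(x))
  } else {
    as.numeric(t(fit$coefs) %*% fit$SV)
  }
  structure(list(w = w, b = -fit$rho), class = "svr_model")
}

#' @export
predict.svr_model <- function(object, newdata, ...) {
  as.numeric(as.matrix(newdata) %*% object$w + object$b)
}

#' Ensemble configuration
#'
#' Defaults are the operating constants of the scoring pipeline: an ensemble
#' of 200 linear epsilon-SVR models with `C = 0.094` and `epsilon = 0.052`
#' (selected upstream by leave-one-subject-out AUC grid search on an
#' independent tuning cohort), bagged by resampling window-level feature
#' vectors with replacement.
#'
#' @param n_models Number of base models in the ensemble.
#' @param C SVR regularization constant.
#' @param epsilon SVR insensitive-tube half-width.
#' @param seed Integer seed for the bootstrap resampling.
#' @param bootstrap_unit `"window"` (default) resamples individual window
#'   feature vectors; `"subject"` resamples whole subjects with their
#'   windows, to probe sensitivity to within-subject correlation.
#' @param scale_features If `TRUE`, z-score features using means/sds fit on
#'   the training set only. Off by default: the features are already bounded
#'   (fractions, histogram masses, small overlaps in seconds).
#' @param tolerance SVR solver tolerance.
#' @return A list of class `nqi_config`.
#' @export
nqi_config <- function(n_models = 200, C = 0.094, epsilon = 0.052,
                       seed = 20161005,
                       bootstrap_unit = c("window", "subject"),
                       scale_features = FALSE, tolerance = 1e-6) {
  stopifnot(n_models >= 1, C > 0, epsilon > 0)
  structure(
    list(n_models = as.integer(n_models), C = C, epsilon = epsilon,
         seed = as.integer(seed),
         bootstrap_unit = match.arg(bootstrap_unit),
         scale_features = isTRUE(scale_features), tolerance = tolerance),
    class = "nqi_config"
  )
}

feature_matrix <- function(features) {
  missing <- setdiff(FEATURE_COLUMNS, names(features))
  if (length(missing) > 0) {
    stop("feature table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  as.matrix(features[, FEATURE_COLUMNS])
}

#' Train the bagged nQi ensemble
#'
#' Joins per-window features with subject metadata, normalizes the UPDRS-III
#' targets to `[0, 1]`, and fits `n_models` linear epsilon-SVR base models,
#' each on a bootstrap sample (drawn with replacement, size equal to the
#' training set) of the window-level feature vectors. Reproducible given
#' `cfg$seed`.
#'
#' @param features Per-window feature tibble from [featurize()].
#' @param meta Subject metadata with `subject_id` and `updrs3`.
#' @param cfg An [nqi_config()].
#' @return An object of class `nqi_model`: weight matrix `W`
#'   (`n_models x 7`), bias vector `b`, the config, optional feature scaling
#'   constants, and a training fingerprint.
#' @export
train_nqi <- function(features, meta, cfg = nqi_config()) {
  stopifnot(inherits(cfg, "nqi_config"))
  train <- dplyr::inner_join(
    features, meta[, c("subject_id", "updrs3")], by = "subject_id"
  )
  if (nrow(train) == 0) stop("empty training set", call. = FALSE)
  x <- feature_matrix(train)
  y <- normalize_updrs(train$updrs3)
  scaling <- NULL
  if (cfg$scale_features) {
    mu <- colMeans(x)
    sd_ <- apply(x, 2, stats::sd)
    sd_[sd_ == 0] <- 1
    x <- sweep(sweep(x, 2, mu), 2, sd_, "/")
    scaling <- list(center = mu, scale = sd_)
  }
  n <- nrow(x)
  subj <- train$subject_id
  fits <- withr::with_seed(cfg$seed, {
    lapply(seq_len(cfg$n_models), function(m) {
      idx <- if (cfg$bootstrap_unit == "window") {
        sample.int(n, n, replace = TRUE)
      } else {
        ids <- unique(subj)
        picked <- sample(ids, length(ids), replace = TRUE)
        unlist(lapply(picked, function(s) which(subj == s)), use.names = FALSE)
      }
      svr_fit(x[idx, , drop = FALSE], y[idx], cfg$C, cfg$epsilon,
              cfg$tolerance)
    })
  })
  structure(
    list(
      W = do.call(rbind, lapply(fits, `[[`, "w")),
      b = vapply(fits, `[[`, numeric(1), "b"),
      cfg = cfg,
      scaling = scaling,
      fingerprint = list(
        n_train = n,
        n_subjects = length(unique(subj)),
        data_hash = rlang::hash(list(x, y)),
        target_normalizer = 108
      )
    ),
    class = "nqi_model"
  )
}

#' @export
print.nqi_model <- function(x, ...) {
  cat("nQi ensemble: ", nrow(x$W), " linear eps-SVR models (C = ",
      x$cfg$C, ", epsilon = ", x$cfg$epsilon, ")\n",
      "trained on ", x$fingerprint$n_train, " windows from ",
      x$fingerprint$n_subjects, " subjects\n", sep = "")
  invisible(x)
}

#' Per-window nQi predictions
#'
#' Applies every base model to each feature vector and takes the median of
#' the ensemble outputs (for an even ensemble, the mean of the two central
#' order statistics).
#'
#' @param object A trained [train_nqi()] model.
#' @param features Per-window feature tibble.
#' @param ... Unused.
#' @return The input tibble with a `window_nqi` column appended.
#' @export
predict.nqi_model <- function(object, features, ...) {
  x <- feature_matrix(features)
  if (!is.null(object$scaling)) {
    x <- sweep(sweep(x, 2, object$scaling$center), 2,
               object$scaling$scale, "/")
  }
  preds <- x %*% t(object$W) + matrix(object$b, nrow(x), length(object$b),
                                      byrow = TRUE)
  dplyr::mutate(features,
                window_nqi = apply(preds, 1, stats::median))
}

#' Subject-level nQi scores
#'
#' A subject's nQi is the arithmetic mean of their per-window scores over
#' the whole typing session. Subjects contributing zero retained windows are
#' absent from the output (reported via attribute `"excluded"` when `meta`
#' is supplied).
#'
#' @param model A trained [train_nqi()] model.
#' @param features Per-window feature tibble for the subjects to score.
#' @param meta Optional metadata; when given, subjects in `meta` with no
#'   retained window are recorded in the `"excluded"` attribute.
#' @return Tibble `subject_id, n_windows, nqi`.
#' @export
score_subjects <- function(model, features, meta = NULL) {
  if (nrow(features) == 0) stop("no retained windows to score", call. = FALSE)
  scores <- predict(model, features) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(n_windows = dplyr::n(),
                     nqi = mean(.data$window_nqi), .groups = "drop")
  if (!is.null(meta)) {
    excluded <- setdiff(meta$subject_id, scores$subject_id)
    if (length(excluded) > 0) {
      warning(length(excluded),
              " subject(s) had no retained window and were excluded: ",
              paste(excluded, collapse = ", "), call. = FALSE)
    }
    attr(scores, "excluded") <- excluded
  }
  scores
}

#' Hyperparameter grid search by leave-one-subject-out AUC
#'
#' For every `(C, epsilon)` pair, runs a leave-one-subject-out loop: the
#' ensemble is trained on the remaining subjects' windows and the held-out
#' subject scored; the AUC of the held-out scores against the diagnostic
#' labels is the pair's figure of merit. Ties break toward smaller `C`, then
#' smaller `epsilon`. Folds whose training set contains a single class are
#' skipped with a warning.
#'
#' @param features Per-window feature tibble.
#' @param meta Subject metadata with `subject_id`, `group`, `updrs3`.
#' @param C_grid,eps_grid Candidate values. Defaults: `C` log-spaced
#'   `2^-10 .. 2^4` (15 points); `epsilon` `0.01 .. 0.1` by 0.01.
#' @param cfg Base [nqi_config()]; its `C`/`epsilon` are overridden per grid
#'   point. Use a small `n_models` to keep the search tractable.
#' @return List with `C`, `epsilon` (the argmax pair) and `auc_table`, a
#'   tibble of the LOO AUC for every pair.
#' @export
grid_search_nqi <- function(features, meta,
                            C_grid = 2^seq(-10, 4, length.out = 15),
                            eps_grid = seq(0.01, 0.1, by = 0.01),
                            cfg = nqi_config(n_models = 25)) {
  stopifnot(length(C_grid) > 0, length(eps_grid) > 0)
  meta <- meta[meta$subject_id %in% features$subject_id, ]
  if (length(unique(meta$group)) < 2) {
    stop("grid search needs both classes present", call. = FALSE)
  }
  grid <- tidyr::expand_grid(C = sort(C_grid), epsilon = sort(eps_grid))
  auc_table <- purrr::pmap_dfr(grid, function(C, epsilon) {
    cfg_pt <- cfg
    cfg_pt$C <- C
    cfg_pt$epsilon <- epsilon
    held <- purrr::map_dfr(meta$subject_id, function(s) {
      train_meta <- meta[meta$subject_id != s, ]
      if (length(unique(train_meta$group)) < 2) {
        warning("fold for subject ", s,
                " has a single training class; skipped", call. = FALSE)
        return(NULL)
      }
      fit <- train_nqi(features[features$subject_id != s, ], train_meta,
                       cfg_pt)
      score_subjects(fit, features[features$subject_id == s, ])
    })
    held <- dplyr::inner_join(held, meta[, c("subject_id", "group")],
                              by = "subject_id")
    tibble::tibble(C = C, epsilon = epsilon,
                   auc = roc_auc(held$nqi, held$group)$auc)
  })
  best <- auc_table |>
    dplyr::arrange(dplyr::desc(.data$auc), .data$C, .data$epsilon) |>
    dplyr::slice(1)
  list(C = best$C, epsilon = best$epsilon, auc_table = auc_table)
}

MODEL_FORMAT_VERSION <- 1L

#' Serialize / restore an nQi model as structured text
#'
#' Versioned JSON holding the config (C, epsilon, ensemble size, seed), the
#' target-normalization convention, optional feature scaling constants and
#' all per-model `(w, b)` pairs at full precision, so a round trip restores
#' identical predictions.
#'
#' @param model A trained [train_nqi()] model.
#' @param path File path.
#' @return `path` (write) or the restored `nqi_model` (read).
#' @export
write_nqi_model <- function(model, path) {
  stopifnot(inherits(model, "nqi_model"))
  payload <- list(
    format = "nqi_model",
    version = MODEL_FORMAT_VERSION,
    cfg = unclass(model$cfg),
    scaling = model$scaling,
    fingerprint = model$fingerprint,
    W = model$W,
    b = model$b
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_nqi_model
#' @export
read_nqi_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "nqi_model")) {
    stop("not an nqi_model file: ", path, call. = FALSE)
  }
  if (payload$version > MODEL_FORMAT_VERSION) {
    stop("model file version ", payload$version, " is newer than supported",
         call. = FALSE)
  }
  cfg <- payload$cfg
  cfg$n_models <- as.integer(cfg$n_models)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "nqi_config"
  scaling <- payload$scaling
  if (!is.null(scaling)) {
    scaling <- list(center = as.numeric(scaling$center),
                    scale = as.numeric(scaling$scale))
  }
  W <- payload$W
  if (!is.matrix(W)) W <- do.call(rbind, lapply(W, as.numeric))
  storage.mode(W) <- "double"
  structure(
    list(W = W,
         b = as.numeric(payload$b),
         cfg = cfg,
         scaling = scaling,
         fingerprint = payload$fingerprint),
    class = "nqi_model"
  )
}

#' Tidy the base models of an nQi ensemble
#'
#' @param x A trained [train_nqi()] model.
#' @param ... Unused.
#' @return One row per base model: `model`, the 7 feature weights, `bias`.
#' @export
tidy.nqi_model <- function(x, ...) {
  W <- x$W
  colnames(W) <- FEATURE_COLUMNS
  dplyr::bind_cols(tibble::tibble(model = seq_len(nrow(W))),
                   tibble::as_tibble(W),
                   tibble::tibble(bias = x$b))
}

#' One-row summary of an nQi ensemble
#'
#' @param x A trained [train_nqi()] model.
#' @param ... Unused.
#' @return Tibble with ensemble size, hyperparameters, seed and training
#'   dimensions.
#' @export
glance.nqi_model <- function(x, ...) {
  tibble::tibble(
    n_models = nrow(x$W),
    C = x$cfg$C,
    epsilon = x$cfg$epsilon,
    seed = x$cfg$seed,
    bootstrap_unit = x$cfg$bootstrap_unit,
    n_train_windows = x$fingerprint$n_train,
    n_train_subjects = x$fingerprint$n_subjects
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
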