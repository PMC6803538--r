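#' Fuse nodal feature tables from two modalities
#'
#' Column-concatenates EEG and fNIRS feature tables for the same trials
#' (64 channels x 5 metrics = 320 EEG columns plus 48 x 5 = 240 fNIRS
#' columns = 560 fused columns for the full montages).  Normalization is
#' deliberately *not* applied here: per-column z-scoring parameters are fit
#' inside the training folds of [repeated_cv()].
#'
#' @param eeg A `feature_table` (or NULL/empty).
#' @param fnirs A `feature_table` (or NULL/empty).
#' @return A fused `feature_table` with column names prefixed by modality.
#' @export
fuse_features <- function(eeg, fnirs) {
  empty <- function(x) is.null(x) || ncol(x$features) == 0L
  if (empty(fnirs)) return(eeg)
  if (empty(eeg)) return(fnirs)
  if (nrow(eeg$features) != nrow(fnirs$features) ||
      !identical(as.character(eeg$labels), as.character(fnirs$labels)))
    stop("feature tables have mismatching trials or labels")
  f1 <- eeg$features; colnames(f1) <- paste0("eeg.", colnames(f1))
  f2 <- fnirs$features; colnames(f2) <- paste0("fnirs.", colnames(f2))
  structure(list(features = cbind(f1, f2), labels = eeg$labels,
                 modality = "fused", density = eeg$density,
                 window_s = eeg$window_s),
            class = "feature_table")
}

# stratified fold assignment: per class, shuffled indices dealt round-robin
.stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Grid-searched RBF support vector classifier
#'
#' Fits a C-support-vector classifier with an RBF kernel (libsvm via
#' e1071), choosing the penalty `C` and kernel width `gamma` that maximize
#' stratified inner cross-validation accuracy on the training data only.
#' Ties break toward the smallest `C`, then the smallest `gamma`.
#'
#' @param x Training instances x features matrix (already normalized).
#' @param y Training labels (>= 2 classes present).
#' @param C_grid,gamma_grid Candidate values (defaults: powers of two,
#'   `2^seq(-5, 15, 2)` and `2^seq(-15, 3, 2)`).
#' @param inner_folds Inner CV folds (default 5).
#' @return list: `model` (fitted on all of `x`), `C`, `gamma`,
#'   `inner_accuracy`.
#' @export
grid_search_train <- function(x, y, C_grid = 2^seq(-5, 15, 2),
                              gamma_grid = 2^seq(-15, 3, 2),
                              inner_folds = 5L) {
  y <- droplevels(factor(y))
  if (nlevels(y) < 2L) stop("training set contains a single class")
  C_grid <- sort(C_grid); gamma_grid <- sort(gamma_grid)
  best <- list(acc = -1, C = C_grid[1], gamma = gamma_grid[1])
  if (length(C_grid) > 1L || length(gamma_grid) > 1L) {
    nf <- min(inner_folds, min(table(y)))
    fold <- if (nf >= 2L) .stratified_folds(y, nf) else NULL
    for (C in C_grid) for (g in gamma_grid) {
      acc <- if (is.null(fold)) {
        fit <- e1071::svm(x, y, kernel = "radial", cost = C, gamma = g,
                          scale = FALSE)
        mean(stats::predict(fit, x) == y)
      } else {
        correct <- 0L
        for (f in seq_len(nf)) {
          tr <- fold != f
          if (nlevels(droplevels(y[tr])) < 2L) next
          fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "radial",
                            cost = C, gamma = g, scale = FALSE)
          correct <- correct +
            sum(stats::predict(fit, x[!tr, , drop = FALSE]) == y[!tr])
        }
        correct / length(y)
      }
      if (acc > best$acc + 1e-12) best <- list(acc = acc, C = C, gamma = g)
    }
  }
  model <- e1071::svm(x, y, kernel = "radial", cost = best$C,
                      gamma = best$gamma, scale = FALSE)
  list(model = model, C = best$C, gamma = best$gamma,
       inner_accuracy = max(best$acc, 0))
}

#' Repeated stratified cross-validated intention decoding
#'
#' `n_reps` repetitions of stratified `n_folds`-fold cross-validation over
#' trials.  All fitting happens strictly inside each training fold: feature
#' z-scoring parameters, Relief-F feature ranking (top `n_keep` features
#' kept), and the SVM grid search ([grid_search_train()], nested inner CV).
#' With the 84-trial paradigm and 10 folds, each fold trains on ~25 and
#' tests on ~3 trials per condition.
#'
#' @param ft A `feature_table` (or a bare instances x features matrix).
#' @param labels Required if `ft` is a bare matrix.
#' @param n_reps,n_folds Repetitions and folds (defaults 10, 10).
#' @param n_keep Features kept after Relief-F (default 60).
#' @param k_neighbors Relief-F neighbors (default 10).
#' @param C_grid,gamma_grid SVM grids (see [grid_search_train()]).
#' @param inner_folds Inner CV folds of the grid search (default 5).
#' @param tuning `"nested"` (default: grid search inside every training
#'   fold) or `"pooled"` (compatibility mode: one grid search on the full
#'   data before cross-validation; optimistically biased).
#' @param seed Integer seed driving fold assignment (repetition r uses
#'   `seed + r`).
#' @return A `cv_result` list: `accuracy` (overall mean), `fold_accuracy`
#'   (reps x folds), `confusion` (summed class x class counts, rows =
#'   truth), `selected_count` (how often each feature was selected),
#'   `params` (chosen C/gamma per fold), `n_keep`.
#' @export
repeated_cv <- function(ft, labels = NULL, n_reps = 10L, n_folds = 10L,
                        n_keep = 60L, k_neighbors = 10L,
                        C_grid = 2^seq(-5, 15, 2),
                        gamma_grid = 2^seq(-15, 3, 2),
                        inner_folds = 5L,
                        tuning = c("nested", "pooled"), seed = 1L) {
  tuning <- match.arg(tuning)
  if (inherits(ft, "feature_table")) {
    X <- ft$features; y <- factor(ft$labels)
  } else {
    X <- as.matrix(ft); y <- factor(labels)
  }
  stopifnot(nrow(X) == length(y))
  if (any(table(y) < n_folds))
    stop("labels cannot be stratified into ", n_folds, " folds")
  old <- .save_rng(); on.exit(.restore_rng(old))

  pooled_par <- NULL
  if (tuning == "pooled") {
    set.seed(seed)
    mu <- colMeans(X); sd0 <- apply(X, 2, stats::sd); sd0[sd0 == 0] <- 1
    Xz <- sweep(sweep(X, 2, mu), 2, sd0, "/")
    rl <- relieff_rank(Xz, y, k_neighbors = k_neighbors, n_keep = n_keep)
    gs <- grid_search_train(Xz[, rl$selected, drop = FALSE], y,
                            C_grid, gamma_grid, inner_folds)
    pooled_par <- list(C = gs$C, gamma = gs$gamma)
  }

  classes <- levels(y)
  conf <- matrix(0L, length(classes), length(classes),
                 dimnames = list(truth = classes, predicted = classes))
  fold_acc <- matrix(NA_real_, n_reps, n_folds)
  sel_count <- numeric(ncol(X))
  names(sel_count) <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  params <- list()
  for (r in seq_len(n_reps)) {
    set.seed(seed + r)
    fold <- .stratified_folds(y, n_folds)
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      # fit normalization on the training fold only
      mu <- colMeans(X[tr, , drop = FALSE])
      sd0 <- apply(X[tr, , drop = FALSE], 2, stats::sd); sd0[sd0 == 0] <- 1
      Ztr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sd0, "/")
      Zte <- sweep(sweep(X[!tr, , drop = FALSE], 2, mu), 2, sd0, "/")
      rl <- relieff_rank(Ztr, y[tr], k_neighbors = k_neighbors,
                         n_keep = n_keep)
      sel <- rl$selected
      sel_count[sel] <- sel_count[sel] + 1
      if (tuning == "pooled") {
        fit <- e1071::svm(Ztr[, sel, drop = FALSE], y[tr],
                          kernel = "radial", cost = pooled_par$C,
                          gamma = pooled_par$gamma, scale = FALSE)
        cg <- pooled_par
      } else {
        gs <- grid_search_train(Ztr[, sel, drop = FALSE], y[tr],
                                C_grid, gamma_grid, inner_folds)
        fit <- gs$model
        cg <- list(C = gs$C, gamma = gs$gamma)
      }
      pred <- stats::predict(fit, Zte[, sel, drop = FALSE])
      truth <- y[!tr]
      fold_acc[r, f] <- mean(pred == truth)
      conf <- conf + table(factor(truth, classes), factor(pred, classes))
      params[[length(params) + 1L]] <- c(rep = r, fold = f, C = cg$C,
                                         gamma = cg$gamma)
    }
  }
  structure(list(accuracy = sum(diag(conf)) / sum(conf),
                 fold_accuracy = fold_acc, confusion = conf,
                 selected_count = sel_count,
                 params = do.call(rbind, params), n_keep = n_keep),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> mean accuracy %.1f%% over %d x %d folds\n",
              100 * x$accuracy, nrow(x$fold_accuracy),
              ncol(x$fold_accuracy)))
  print(x$confusion)
  invisible(x)
}

#' Compare decoding accuracy across modalities
#'
#' One-way ANOVA of per-subject accuracies across modality columns, with
#' Bonferroni-corrected pairwise t-tests, the comparison used to contrast
#' EEG, fNIRS and fused decoders over a cohort.
#'
#' @param acc subjects x modalities numeric matrix (named columns).
#' @return list: `F`, `df`, `p`, `posthoc` (pairwise corrected p matrix),
#'   `means` (per-modality mean accuracy).
#' @export
modality_comparison <- function(acc) {
  acc <- as.matrix(acc)
  if (nrow(acc) < 2L) stop("need >= 2 subjects")
  if (is.null(colnames(acc)))
    colnames(acc) <- paste0("modality", seq_len(ncol(acc)))
  y <- as.vector(acc)
  g <- factor(rep(colnames(acc), each = nrow(acc)), levels = colnames(acc))
  if (max(tapply(y, g, stats::var)) < 1e-24)
    stop("degenerate accuracy table: zero variance in every modality")
  a <- stats::anova(stats::lm(y ~ g))
  ph <- stats::pairwise.t.test(y, g, p.adjust.method = "bonferroni",
                               pool.sd = TRUE)$p.value
  list(F = a$`F value`[1], df = c(a$Df[1], a$Df[2]), p = a$`Pr(>F)`[1],
       posthoc = ph, means = colMeans(acc))
}
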