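#' Kernel specification
#'
#' The three kernels supported, each with exactly the parameters it needs:
#' linear `(x . y)` with penalty `C`; RBF `exp(-||x - y||^2 / r^2)` with
#' `C` and width `r` (note the width parameterization: backends expressed
#' in `gamma` use `gamma = 1 / r^2`); polynomial `((x . y) + 1)^d` with `C`
#' and integer degree `d`.
#'
#' @param kind One of `"linear"`, `"rbf"`, `"polynomial"`.
#' @param C Soft-margin penalty, > 0.
#' @param r RBF width, > 0 (RBF only).
#' @param d Polynomial degree, integer >= 1 (polynomial only).
#' @return A `kernel_spec` list.
#' @export
#' @examples
#' kernel_spec("rbf", C = 10, r = 0.5)
kernel_spec <- function(kind = c("rbf", "linear", "polynomial"),
                        C = 1, r = NULL, d = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(C) || length(C) != 1L || !is.finite(C) || C <= 0) {
    stopf("C must be a positive number")
  }
  if (kind == "rbf") {
    if (is.null(r)) r <- 1
    if (!is.numeric(r) || r <= 0) stopf("r must be a positive width")
    d <- NULL
  } else if (kind == "polynomial") {
    if (is.null(d)) d <- 3L
    if (!is_count(d)) stopf("d must be an integer degree >= 1")
    r <- NULL
  } else {
    r <- NULL
    d <- NULL
  }
  structure(list(kind = kind, C = C, r = r, d = d), class = "kernel_spec")
}

# Translate a kernel_spec into e1071::svm arguments.
svm_args <- function(kernel) {
  switch(kernel$kind,
         linear = list(kernel = "linear", cost = kernel$C),
         rbf = list(kernel = "radial", cost = kernel$C,
                    gamma = 1 / kernel$r^2),
         polynomial = list(kernel = "polynomial", cost = kernel$C,
                           degree = kernel$d, gamma = 1, coef0 = 1))
}

#' Train a one-vs-one multiclass SVM
#'
#' Fits one soft-margin binary SVM per unordered class pair — `k(k-1)/2`
#' models for k classes — each restricted to the samples of its two
#' classes. Features are min-max scaled with parameters fitted on the
#' training data only; the scaler is stored in the model and reapplied at
#' prediction time.
#'
#' @param x Data frame or matrix of training features.
#' @param y Class labels (integers or factor), >= 2 classes, each with
#'   >= 2 samples.
#' @param kernel A [kernel_spec()].
#' @return An `ovo_model`.
#' @export
train_ovo <- function(x, y, kernel = kernel_spec("rbf")) {
  stopifnot(inherits(kernel, "kernel_spec"))
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2L) stopf("training error: need at least 2 classes")
  tab <- table(y)
  if (any(tab < 2L)) {
    stopf("training error: class(es) %s have fewer than 2 samples",
          paste(names(tab)[tab < 2L], collapse = ", "))
  }
  scaler <- fit_scaler(x)
  xs <- apply_scaler(scaler, x)
  pairs <- utils::combn(classes, 2L, simplify = FALSE)
  args0 <- svm_args(kernel)
  models <- lapply(pairs, function(p) {
    sel <- y %in% p
    ysub <- factor(y[sel], levels = p)
    do.call(e1071::svm, c(list(x = xs[sel, , drop = FALSE], y = ysub,
                               scale = FALSE, probability = FALSE), args0))
  })
  names(models) <- vapply(pairs, paste, "", collapse = "|")
  structure(list(classes = classes, pairs = pairs, models = models,
                 kernel = kernel, scaler = scaler,
                 feature_names = colnames(x)),
            class = "ovo_model")
}

#' Majority vote over pairwise decision values
#'
#' Given signed decision values for each unordered class pair (positive
#' means the first class of the pair wins), each pair casts one vote per
#' sample and the class with the most votes is returned. Ties are broken by
#' the largest sum of signed decision values in the tied classes' favour,
#' then by the lowest class id.
#'
#' @param decisions m x p matrix of signed decision values, one column per
#'   class pair.
#' @param pairs List of length-2 character vectors naming each column's
#'   class pair (first element wins on positive values).
#' @param classes Ordered character vector of all class ids.
#' @return Character vector of winning classes, with the vote matrix
#'   attached as attribute `votes`.
#' @export
ovo_vote <- function(decisions, pairs, classes) {
  decisions <- as.matrix(decisions)
  m <- nrow(decisions)
  k <- length(classes)
  votes <- matrix(0L, m, k, dimnames = list(NULL, classes))
  score <- matrix(0, m, k, dimnames = list(NULL, classes))
  for (p in seq_along(pairs)) {
    a <- pairs[[p]][1]
    b <- pairs[[p]][2]
    dv <- decisions[, p]
    win_a <- dv >= 0
    votes[, a] <- votes[, a] + win_a
    votes[, b] <- votes[, b] + !win_a
    score[, a] <- score[, a] + dv
    score[, b] <- score[, b] - dv
  }
  out <- character(m)
  for (i in seq_len(m)) {
    top <- which(votes[i, ] == max(votes[i, ]))
    if (length(top) > 1L) {
      top <- top[score[i, top] == max(score[i, top])]
    }
    out[i] <- classes[top[1L]]  # lowest class id among remaining ties
  }
  attr(out, "votes") <- votes
  out
}

#' Predict classes with a one-vs-one model
#'
#' Applies the stored scaler, collects each binary model's signed decision
#' value and resolves the vote with [ovo_vote()].
#'
#' @param object An [train_ovo()] model.
#' @param newdata Feature rows with the model's feature columns.
#' @param votes If `TRUE`, attach the per-class vote matrix as attribute
#'   `votes`.
#' @param ... Unused.
#' @return Predicted class labels (integer if the training labels were).
#' @export
predict.ovo_model <- function(object, newdata, votes = FALSE, ...) {
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata)) &&
      ncol(newdata) == length(object$feature_names)) {
    colnames(newdata) <- object$feature_names
  }
  if (!all(object$feature_names %in% colnames(newdata))) {
    stopf("feature mismatch: model expects columns %s",
          paste(object$feature_names, collapse = ", "))
  }
  xs <- apply_scaler(object$scaler, newdata)
  dec <- matrix(0, nrow(xs), length(object$pairs))
  for (p in seq_along(object$pairs)) {
    fit <- object$models[[p]]
    pr <- predict(fit, xs, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # e1071 names the column "a/b" with positive values favouring a;
    # orient so positive favours the pair's first class.
    first <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]][1L]
    dec[, p] <- if (identical(first, object$pairs[[p]][1L])) dv[, 1L] else -dv[, 1L]
  }
  out <- ovo_vote(dec, object$pairs, object$classes)
  v <- attr(out, "votes")
  if (!anyNA(suppressWarnings(as.integer(object$classes)))) {
    out <- as.integer(out)
  }
  if (votes) attr(out, "votes") <- v else attr(out, "votes") <- NULL
  out
}

#' Cross-validated error rate of a kernel/parameter candidate
#'
#' Stratified k-fold cross-validation on the training set; the fitness is
#' the mean error rate (1 - accuracy) over folds, the quantity minimized
#' during hyperparameter tuning. Folds whose training part loses all but
#' one class are skipped with a logged note.
#'
#' @param x,y Training features and labels.
#' @param kind Kernel kind (see [kernel_spec()]).
#' @param params Candidate position: `log10(C)` for linear;
#'   `c(log10(C), log10(r))` for RBF; `c(log10(C), d)` for polynomial.
#' @param folds Number of folds, >= 2.
#' @param seed Integer seed for the fold assignment.
#' @return Scalar loss in \[0, 1\].
#' @export
cv_fitness <- function(x, y, kind = "rbf", params, folds = 5L, seed = 1L) {
  if (!is_count(folds) || folds < 2) stopf("folds must be >= 2")
  x <- as.matrix(x)
  y <- as.character(y)
  kernel <- params_to_kernel(kind, params)
  fold_id <- with_seed(seed, {
    id <- integer(length(y))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      id[idx] <- rep_len(seq_len(folds), length(idx))
    }
    id
  })
  errs <- rep(NA_real_, folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (length(unique(y[tr])) < 2L) {
      wq_note("cv", "fold ", f, " skipped: training part has a single class")
      next
    }
    fit <- train_ovo(x[tr, , drop = FALSE], y[tr], kernel)
    pred <- predict(fit, x[!tr, , drop = FALSE])
    errs[f] <- mean(as.character(pred) != y[!tr])
  }
  if (all(is.na(errs))) stopf("cross-validation failed in every fold")
  mean(errs, na.rm = TRUE)
}

params_to_kernel <- function(kind, params) {
  switch(kind,
         linear = kernel_spec("linear", C = 10^params[1]),
         rbf = kernel_spec("rbf", C = 10^params[1], r = 10^params[2]),
         polynomial = kernel_spec("polynomial", C = 10^params[1],
                                  d = max(1L, as.integer(round(params[2])))),
         stopf("unknown kernel kind '%s'", kind))
}

#' Tune kernel hyperparameters with the particle swarm optimizer
#'
#' Runs [pso_optimize()] over the kernel's parameter box — positions are
#' `log10(C)` (and `log10(r)` for RBF, degree for polynomial) — with the
#' stratified cross-validated error rate ([cv_fitness()]) as the objective.
#'
#' @param x,y Training features and labels.
#' @param kind Kernel kind.
#' @param pso_cfg A [pso_config()]; its `bounds` are replaced by
#'   `search_bounds`.
#' @param search_bounds 2-row low/high matrix for the position. Defaults:
#'   `log10(C)` in \[-2, 3\]; `log10(r)` in \[-3, 1\]; degree in \[1, 5\].
#' @param folds,cv_seed Cross-validation control.
#' @return List with `kernel` (the tuned [kernel_spec()]), `loss` (CV error
#'   at the optimum), `history` (global-best loss per iteration) and
#'   `iterations`.
#' @export
pso_tune <- function(x, y, kind = "rbf", pso_cfg = NULL,
                     search_bounds = NULL, folds = 5L, cv_seed = 1L) {
  if (is.null(search_bounds)) {
    search_bounds <- switch(kind,
                            linear = cbind(c(-2, 3)),
                            rbf = cbind(c(-2, 3), c(-3, 1)),
                            polynomial = cbind(c(-2, 3), c(1, 5)))
  }
  if (is.null(pso_cfg)) {
    pso_cfg <- pso_config(search_bounds)
  } else {
    pso_cfg$bounds <- as.matrix(search_bounds)
    rownames(pso_cfg$bounds) <- c("low", "high")
  }
  objective <- function(pos) cv_fitness(x, y, kind, pos, folds, cv_seed)
  fit <- pso_optimize(objective, pso_cfg)
  list(kernel = params_to_kernel(kind, fit$par), loss = fit$value,
       history = fit$history, iterations = fit$iterations)
}
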