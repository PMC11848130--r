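#' Univariate ROC-AUC screening
#'
#' Ranks candidate features by their ability to separate fallers from
#' non-fallers on their own, using direction-agnostic discrimination
#' `max(AUC, 1 - AUC)` - a feature whose low values mark fallers is as
#' useful as one whose high values do. Returns the top `k` with their raw
#' AUCs; ties are broken by feature name. Constant features get AUC 0.5 and
#' rank last.
#'
#' @param x Data frame or matrix of feature columns.
#' @param y 0/1 outcome per row.
#' @param k How many features to retain (clipped to the number available).
#' @return Data frame `feature`, `auc`, `auc_directed`, ranked.
#' @export
univariate_screen <- function(x, y, k = 10L) {
  x <- as.data.frame(x)
  aucs <- vapply(names(x), function(nm) {
    v <- x[[nm]]
    keep <- !is.na(v) & !is.na(y)
    if (length(unique(v[keep])) < 2L) return(0.5)
    if (length(unique(y[keep])) < 2L) return(0.5)
    roc_auc(v[keep], y[keep])
  }, numeric(1))
  dir <- pmax(aucs, 1 - aucs)
  o <- order(-dir, names(x))
  out <- data.frame(feature = names(x)[o], auc = unname(aucs[o]),
                    auc_directed = unname(dir[o]))
  utils::head(out, min(k, nrow(out)))
}

# core NearMiss-1 selection on a numeric matrix; returns kept negative rows
.nearmiss_neg <- function(x, pos, neg, want, n_neighbors) {
  mu <- colMeans(x)
  sd <- sqrt(colSums(sweep(x, 2, mu)^2) / max(1L, nrow(x) - 1L))
  sd[sd == 0 | is.na(sd)] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sd, "/")
  nn <- min(n_neighbors, length(pos))
  d2 <- outer(rowSums(xs[neg, , drop = FALSE]^2),
              rowSums(xs[pos, , drop = FALSE]^2), "+") -
    2 * xs[neg, , drop = FALSE] %*% t(xs[pos, , drop = FALSE])
  d2[d2 < 0] <- 0
  D <- sqrt(d2)
  # mean of the nn smallest entries per row, without per-row sorts
  acc <- numeric(length(neg))
  for (j in seq_len(nn)) {
    cm <- max.col(-D, ties.method = "first")
    idx <- cbind(seq_along(neg), cm)
    acc <- acc + D[idx]
    D[idx] <- Inf
  }
  score <- acc / nn
  neg[order(score, neg)[seq_len(want)]]
}

#' NearMiss (version 1) undersampling of the majority class
#'
#' Retains the negatives closest to the positive class: each negative is
#' scored by its mean Euclidean distance (on standardized features) to its
#' `n_neighbors` nearest positives, and the `ratio_neg * n_pos` negatives
#' with the smallest scores are kept. Positives are always kept. Ties break
#' by row index, so the selection is deterministic.
#'
#' @param x Feature matrix/data frame.
#' @param y 0/1 labels.
#' @param ratio_neg Negatives retained per positive (the study ratio 1:4
#'   means `ratio_neg = 4`).
#' @param n_neighbors Positive neighbours averaged per negative (clipped to
#'   the number of positives).
#' @return Integer row indices of the retained rows, in original order.
#'   Attribute `"kept_negatives"` lists the selected negative rows.
#' @export
nearmiss_undersample <- function(x, y, ratio_neg = 4, n_neighbors = 3L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  pos <- which(y == 1L); neg <- which(y == 0L)
  if (!length(pos) || !length(neg)) stop("need both classes to undersample")
  want <- round(ratio_neg * length(pos))
  if (want >= length(neg)) {
    if (want > length(neg))
      warning("requested ", want, " negatives but only ", length(neg),
              " available; keeping all")
    return(structure(sort(c(pos, neg)), kept_negatives = neg))
  }
  kept <- .nearmiss_neg(x, pos, neg, want, n_neighbors)
  structure(sort(c(pos, kept)), kept_negatives = sort(kept))
}

#' Stratified group k-fold assignment
#'
#' Splits participants (groups) into k folds so that every group's rows land
#' in a single fold and positive groups are spread as evenly as achievable
#' (per-fold positive counts differ by at most one group). Deterministic
#' given `seed`.
#'
#' @param y 0/1 label per row (constant within a group).
#' @param groups Group identifier per row.
#' @param k Number of folds (`k <=` number of groups).
#' @param seed RNG seed for the shuffle.
#' @return Integer fold id (1..k) per row.
#' @export
stratified_group_kfold <- function(y, groups, k = 5L, seed = 0L) {
  groups <- as.character(groups)
  y <- as.integer(y)
  gtab <- tapply(y, groups, function(v) {
    if (length(unique(v)) != 1L)
      stop("group with inconsistent labels; the outcome is participant-level")
    v[1]
  })
  gsize <- table(groups)
  gnames <- names(gtab)
  if (length(gnames) < k) stop("fewer groups than folds")
  if (sum(gtab == 1L) < k)
    warning("fewer positive groups than folds; some folds will lack positives")
  ord <- with_seed(seed, sample(seq_along(gnames)))
  gnames <- gnames[ord]
  glab <- gtab[gnames]
  gsz <- as.integer(gsize[gnames])
  fold_of <- stats::setNames(integer(length(gnames)), gnames)
  fold_pos <- integer(k); fold_n <- integer(k)
  # positives first: to the fold with fewest positives (then fewest rows)
  for (i in order(-glab)) {
    f <- if (glab[i] == 1L) order(fold_pos, fold_n)[1] else order(fold_n, fold_pos)[1]
    fold_of[gnames[i]] <- f
    fold_pos[f] <- fold_pos[f] + glab[i]
    fold_n[f] <- fold_n[f] + gsz[i]
  }
  unname(fold_of[groups])
}

# IRLS for logistic regression; lambda = 0 is the plain ML fit, a small
# lambda (intercept unpenalized) is the separation fallback
.irls_logit <- function(X, y, lambda = 0, tol = 1e-8, max_iter = 100L) {
  p <- ncol(X)
  beta <- numeric(p)
  pen <- diag(rep(lambda, p)); pen[1, 1] <- 0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    Xw <- X * w
    new <- tryCatch(drop(solve(crossprod(Xw, X) + pen, crossprod(Xw, z))),
                    error = function(e) NULL)
    if (is.null(new)) return(list(coef = beta, converged = FALSE))
    done <- max(abs(new - beta)) < tol
    beta <- new
    if (done) {
      converged <- TRUE
      break
    }
  }
  list(coef = beta, converged = converged)
}

#' Fit a logistic fall-risk model
#'
#' Maximum-likelihood logistic regression on standardized features
#' (standardization constants are estimated from the training rows and
#' stored with the model). If the fit separates (non-convergence or runaway
#' coefficients), it is refit with a small quadratic penalty and flagged.
#'
#' @param x Feature matrix/data frame (training rows).
#' @param y 0/1 outcome.
#' @param lambda Ridge penalty used only on detected separation.
#' @return A `tristep_logistic` model: `features`, `coef` (intercept +
#'   standardized slopes), `center`, `scale`, `penalized`.
#' @export
fit_logistic <- function(x, y, lambda = 1e-4) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("single-class outcome; cannot fit")
  mu <- colMeans(x)
  sd <- sqrt(colSums(sweep(x, 2, mu)^2) / max(1L, nrow(x) - 1L))
  sd[sd == 0 | is.na(sd)] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sd, "/")
  X <- cbind(`(Intercept)` = 1, xs)
  fit <- .irls_logit(X, y)
  beta <- fit$coef
  penalized <- FALSE
  if (!fit$converged || anyNA(beta) || any(abs(beta) > 15)) {
    beta <- .irls_logit(X, y, lambda = lambda)$coef
    penalized <- TRUE
  }
  names(beta) <- c("(Intercept)", colnames(x))
  structure(list(features = colnames(x), coef = beta, center = mu,
                 scale = sd, penalized = penalized),
            class = "tristep_logistic")
}

#' @export
predict.tristep_logistic <- function(object, newdata, ...) {
  nd <- as.data.frame(newdata)
  x <- if (all(object$features %in% names(nd)))
    as.matrix(nd[, object$features, drop = FALSE])
  else if (ncol(nd) == length(object$features))
    as.matrix(nd)  # positional fallback for unnamed matrices
  else stop("newdata lacks the model features")
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  drop(stats::plogis(object$coef[1] + xs %*% object$coef[-1]))
}

#' @export
print.tristep_logistic <- function(x, ...) {
  cat("<tristep_logistic>", if (x$penalized) "(penalized fit)" else "", "\n")
  print(round(x$coef, 4))
  invisible(x)
}

#' One cross-validated run of a feature combination
#'
#' Splits rows by [stratified_group_kfold()], applies NearMiss undersampling
#' and standardization to the training part of each fold only, fits the
#' logistic model, and pools each row's held-out score. Per-fold training
#' artifacts (retained rows, standardization constants) are returned so
#' leakage can be audited.
#'
#' @param x Feature data frame.
#' @param y 0/1 outcome per row.
#' @param groups Participant id per row.
#' @param features Character vector of feature columns to use.
#' @param k Folds.
#' @param seed Fold-assignment seed.
#' @param ratio_neg NearMiss negatives per positive.
#' @param n_neighbors NearMiss neighbours.
#' @return List: `scores` (held-out score per row), `roc`, `pr`, `folds`,
#'   `artifacts` (per fold: `train_rows`, `kept_rows`, `center`, `scale`).
#' @export
cv_run <- function(x, y, groups, features, k = 5L, seed = 0L, ratio_neg = 4,
                   n_neighbors = 3L) {
  x <- as.data.frame(x)
  fold <- stratified_group_kfold(y, groups, k = k, seed = seed)
  scores <- rep(NA_real_, length(y))
  artifacts <- vector("list", k)
  for (f in seq_len(k)) {
    test <- which(fold == f)
    train <- which(fold != f)
    xm <- as.matrix(x[train, features, drop = FALSE])
    keep_local <- nearmiss_undersample(xm, y[train], ratio_neg = ratio_neg,
                                       n_neighbors = n_neighbors)
    kept <- train[keep_local]
    model <- fit_logistic(x[kept, features, drop = FALSE], y[kept])
    scores[test] <- predict(model, x[test, , drop = FALSE])
    artifacts[[f]] <- list(train_rows = train, kept_rows = kept,
                           center = model$center, scale = model$scale)
  }
  list(scores = scores, roc = roc_auc(scores, y), pr = pr_auc(scores, y),
       folds = fold, artifacts = artifacts)
}

.combo_label <- function(fs) paste(sort(fs), collapse = "+")

#' Exhaustive small-combination model search
#'
#' For every combination of the candidate features of the requested sizes,
#' runs one cross-validated evaluation per (fold count, seed) pair - by
#' default folds 3, 4 and 5 with two seeds each, six runs - with NearMiss
#' undersampling applied inside the training folds only, and scores the
#' combination by its mean pooled PR-AUC across runs. The winner is the
#' highest mean PR-AUC; ties prefer fewer features, then lexicographic
#' order. The final model is refit on the full NearMiss-resampled training
#' data.
#'
#' @param x Feature data frame (training cohort, one sex).
#' @param y 0/1 outcome per row.
#' @param groups Participant id per row.
#' @param candidates Candidate feature names (>= 3), e.g. from
#'   [univariate_screen()].
#' @param sizes Combination sizes (default 3:5).
#' @param folds Fold counts (default 3:5).
#' @param seeds Seeds per fold count (default c(0, 1)).
#' @param ratio_neg NearMiss ratio (default 4, i.e. 1:4).
#' @param n_neighbors NearMiss neighbours.
#' @return A `model_search_report`: `table` (one row per combination with
#'   mean/sd PR-AUC and ROC-AUC), `winner`, `final_model`, `config`.
#' @export
search_combinations <- function(x, y, groups, candidates, sizes = 3:5,
                                folds = 3:5, seeds = c(0L, 1L),
                                ratio_neg = 4, n_neighbors = 3L) {
  x <- as.data.frame(x)
  if (length(candidates) < 3L)
    stop("combination search needs at least 3 candidate features")
  if (length(unique(y)) < 2L) stop("single-class outcome")
  sizes <- sizes[sizes <= length(candidates)]
  combos <- unlist(lapply(sizes, function(s)
    utils::combn(sort(candidates), s, simplify = FALSE)), recursive = FALSE)
  runs <- expand.grid(k = folds, seed = seeds)
  # fold assignments depend only on labels/groups: compute once per run,
  # as do the per-fold train/test index sets
  n <- length(y)
  yv <- as.integer(y)
  splits <- list()
  for (i in seq_len(nrow(runs))) {
    fold <- stratified_group_kfold(yv, groups, k = runs$k[i], seed = runs$seed[i])
    for (f in seq_len(runs$k[i]))
      splits[[length(splits) + 1L]] <-
        list(run = i, test = which(fold == f), train = which(fold != f))
  }
  xmat <- as.matrix(x[, sort(unique(unlist(combos))), drop = FALSE])
  eval_combo <- function(fs) {
    scores <- matrix(NA_real_, n, nrow(runs))
    for (sp in splits) {
      train <- sp$train; test <- sp$test
      xm <- xmat[train, fs, drop = FALSE]
      yt <- yv[train]
      pos <- which(yt == 1L); neg <- which(yt == 0L)
      want <- round(ratio_neg * length(pos))
      keep_local <- if (want >= length(neg)) seq_along(train) else
        sort(c(pos, .nearmiss_neg(xm, pos, neg, want, n_neighbors)))
      kept <- train[keep_local]
      model <- fit_logistic(xmat[kept, fs, drop = FALSE], yv[kept])
      xs <- sweep(sweep(xmat[test, fs, drop = FALSE], 2, model$center),
                  2, model$scale, "/")
      scores[test, sp$run] <-
        stats::plogis(model$coef[1] + drop(xs %*% model$coef[-1]))
    }
    prs <- apply(scores, 2, pr_auc, labels = yv)
    rocs <- apply(scores, 2, roc_auc, labels = yv)
    c(mean_pr = mean(prs), sd_pr = stats::sd(prs),
      mean_roc = mean(rocs), sd_roc = stats::sd(rocs))
  }
  stats_m <- t(vapply(combos, eval_combo, numeric(4)))
  tab <- data.frame(combination = vapply(combos, .combo_label, character(1)),
                    size = lengths(combos), stats_m)
  o <- order(-tab$mean_pr, tab$size, tab$combination)
  tab <- tab[o, ]
  rownames(tab) <- NULL
  winner <- strsplit(tab$combination[1], "+", fixed = TRUE)[[1]]
  keep_local <- nearmiss_undersample(as.matrix(x[, winner, drop = FALSE]), y,
                                     ratio_neg = ratio_neg,
                                     n_neighbors = n_neighbors)
  final <- fit_logistic(x[keep_local, winner, drop = FALSE], y[keep_local])
  structure(list(table = tab, winner = winner, final_model = final,
                 config = list(sizes = sizes, folds = folds, seeds = seeds,
                               ratio_neg = ratio_neg,
                               n_neighbors = n_neighbors,
                               n_combinations = length(combos))),
            class = "model_search_report")
}

#' @export
print.model_search_report <- function(x, ...) {
  cat("<model_search_report>", x$config$n_combinations, "combinations\n")
  cat("winner:", paste(x$winner, collapse = " + "), "\n")
  print(utils::head(x$table, 5))
  invisible(x)
}

#' External validation of a fitted model
#'
#' Scores a held-out cohort and reports ROC-AUC (DeLong 95% CI) and PR-AUC
#' (stratified bootstrap percentile 95% CI) with their interpretation bands.
#'
#' @param model A `tristep_logistic` model.
#' @param x Validation feature data frame (must contain the model features).
#' @param y 0/1 outcome.
#' @param level Confidence level.
#' @param B Bootstrap resamples for the PR interval.
#' @param seed Bootstrap seed.
#' @return List: `scores`, `roc` and `pr` (each `estimate`, `lo`, `hi`,
#'   `band`), `n`, `prevalence`.
#' @export
evaluate_external <- function(model, x, y, level = 0.95, B = 2000L,
                              seed = 1L) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stop("validation set has a single class; cannot evaluate")
  scores <- predict(model, x)
  roc <- auc_ci(scores, y, "roc", level = level)
  pr <- auc_ci(scores, y, "pr", level = level, B = B, seed = seed)
  roc$band <- classify_band(roc$estimate)
  pr$band <- classify_band(pr$estimate)
  list(scores = scores, roc = roc, pr = pr, n = length(y),
       prevalence = mean(y))
}
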