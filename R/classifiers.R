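#' Configure a classifier for the evaluation zoo
#'
#' The ten-member zoo mirrors the common GUI-toolbox presets those names
#' denote: four SVMs (linear, quadratic, cubic, medium-Gaussian), three
#' k-nearest-neighbour variants (cosine metric k=10, coarse k=100,
#' distance-weighted k=10), and three ensembles (subspace kNN, boosted
#' trees, subspace discriminant). Hyperparameters are overridable through
#' `...`.
#'
#' @param name One of `"lsvm"`, `"qsvm"`, `"csvm"`, `"mgsvm"`,
#'   `"cosine_knn"`, `"coarse_knn"`, `"wknn"`, `"esknn"`, `"ebt"`, `"esd"`.
#' @param seed Seed for any stochastic component (subspace draws, boosting).
#' @param ... Family-specific overrides: `cost`, `degree`, `gamma` (SVMs);
#'   `k`, `metric`, `weighted` (kNN); `n_learners`, `subspace_dim`,
#'   `nrounds`, `max_depth` (ensembles).
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(name, seed = 1L, ...) {
  name <- match.arg(name, c("lsvm", "qsvm", "csvm", "mgsvm", "cosine_knn",
                            "coarse_knn", "wknn", "esknn", "ebt", "esd"))
  defaults <- switch(name,
    lsvm = list(cost = 1),
    qsvm = list(cost = 1, degree = 2L),
    csvm = list(cost = 1, degree = 3L),
    mgsvm = list(cost = 1),
    cosine_knn = list(k = 10L, metric = "cosine", weighted = FALSE),
    coarse_knn = list(k = 100L, metric = "euclidean", weighted = FALSE),
    wknn = list(k = 10L, metric = "euclidean", weighted = TRUE),
    esknn = list(n_learners = 30L, k = 1L),
    ebt = list(nrounds = 30L, max_depth = 3L, eta = 0.3),
    esd = list(n_learners = 30L))
  pars <- utils::modifyList(defaults, list(...))
  structure(list(name = name, seed = assert_count(seed, "seed", min = 0L),
                 pars = pars),
            class = "classifier_config")
}

#' The full ten-classifier zoo
#' @param seed Seed shared by all members.
#' @return List of [classifier_config()]s, one per zoo member.
#' @export
default_zoo <- function(seed = 1L) {
  lapply(c("lsvm", "qsvm", "csvm", "mgsvm", "cosine_knn", "coarse_knn",
           "wknn", "esknn", "ebt", "esd"),
         classifier_config, seed = seed)
}

# ---- internal fit/predict engines -----------------------------------------
# Each returns list(pred = factor over levels(ytr), scores = n x K matrix).

svm_fit_predict <- function(Xtr, ytr, Xte, cfg) {
  kernel <- switch(cfg$name, lsvm = "linear", mgsvm = "radial", "polynomial")
  args <- list(x = Xtr, y = ytr, kernel = kernel, cost = cfg$pars$cost,
               scale = FALSE)
  if (kernel == "polynomial") {
    args$degree <- cfg$pars$degree
    args$coef0 <- 1
  }
  if (kernel == "radial") {
    # "medium" Gaussian: kernel scale sqrt(d), i.e. gamma = 1/d
    args$gamma <- cfg$pars$gamma %||% (1 / ncol(Xtr))
  }
  fit <- do.call(e1071::svm, args)
  pr <- stats::predict(fit, Xte, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  lev <- levels(ytr)
  scores <- matrix(0, nrow(Xte), length(lev), dimnames = list(NULL, lev))
  # aggregate pairwise decision values into per-class margins
  for (cn in colnames(dv)) {
    pair <- strsplit(cn, "/", fixed = TRUE)[[1]]
    scores[, pair[1]] <- scores[, pair[1]] + dv[, cn]
    scores[, pair[2]] <- scores[, pair[2]] - dv[, cn]
  }
  list(pred = factor(as.character(pr), levels = lev), scores = scores)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Distance-vote kNN supporting euclidean/cosine metrics and inverse-distance
# weighting; scores are normalised class vote masses.
knn_fit_predict <- function(Xtr, ytr, Xte, k, metric = "euclidean",
                            weighted = FALSE) {
  k <- min(k, nrow(Xtr))
  lev <- levels(ytr)
  if (metric == "cosine") {
    nt <- sqrt(rowSums(Xtr^2)); nt[nt == 0] <- 1
    ne <- sqrt(rowSums(Xte^2)); ne[ne == 0] <- 1
    D <- 1 - (Xte %*% t(Xtr)) / outer(ne, nt)
  } else {
    D <- outer(rowSums(Xte^2), rep(1, nrow(Xtr))) +
      outer(rep(1, nrow(Xte)), rowSums(Xtr^2)) - 2 * Xte %*% t(Xtr)
    D[D < 0] <- 0
    D <- sqrt(D)
  }
  scores <- matrix(0, nrow(Xte), length(lev), dimnames = list(NULL, lev))
  for (i in seq_len(nrow(Xte))) {
    nn <- order(D[i, ])[seq_len(k)]
    w <- if (weighted) 1 / (D[i, nn] + 1e-12) else rep(1, k)
    for (j in seq_len(k)) {
      scores[i, as.character(ytr[nn[j]])] <-
        scores[i, as.character(ytr[nn[j]])] + w[j]
    }
  }
  scores <- scores / pmax(rowSums(scores), 1e-300)
  list(pred = factor(lev[max.col(scores, ties.method = "first")], levels = lev),
       scores = scores)
}

subspace_ensemble_fit_predict <- function(Xtr, ytr, Xte, cfg, learner) {
  lev <- levels(ytr)
  d <- ncol(Xtr)
  dim_sub <- cfg$pars$subspace_dim %||% max(1L, floor(d / 2))
  acc <- matrix(0, nrow(Xte), length(lev), dimnames = list(NULL, lev))
  n_ok <- 0L
  with_seed(cfg$seed, {
    for (b in seq_len(cfg$pars$n_learners)) {
      cols <- sort(sample.int(d, min(dim_sub, d)))
      sc <- tryCatch(learner(Xtr[, cols, drop = FALSE], ytr,
                             Xte[, cols, drop = FALSE]),
                     error = function(e) NULL)
      if (!is.null(sc)) {
        acc <- acc + sc
        n_ok <- n_ok + 1L
      }
    }
  })
  if (n_ok == 0L) stop("all subspace learners failed", call. = FALSE)
  scores <- acc / n_ok
  list(pred = factor(lev[max.col(scores, ties.method = "first")], levels = lev),
       scores = scores)
}

esknn_fit_predict <- function(Xtr, ytr, Xte, cfg) {
  subspace_ensemble_fit_predict(Xtr, ytr, Xte, cfg, function(xtr, y, xte) {
    knn_fit_predict(xtr, y, xte, k = cfg$pars$k)$scores
  })
}

esd_fit_predict <- function(Xtr, ytr, Xte, cfg) {
  subspace_ensemble_fit_predict(Xtr, ytr, Xte, cfg, function(xtr, y, xte) {
    # collinear subspaces are expected when d approaches n; lda still
    # returns a usable posterior, so its collinearity warning is noise here
    fit <- suppressWarnings(MASS::lda(xtr, grouping = y))
    post <- stats::predict(fit, xte)$posterior
    full <- matrix(0, nrow(xte), nlevels(y), dimnames = list(NULL, levels(y)))
    full[, colnames(post)] <- post
    full
  })
}

ebt_fit_predict <- function(Xtr, ytr, Xte, cfg) {
  lev <- levels(ytr)
  with_seed(cfg$seed, {
    dtr <- xgboost::xgb.DMatrix(Xtr, label = as.integer(ytr) - 1L)
    fit <- xgboost::xgb.train(
      params = list(objective = "multi:softprob", num_class = length(lev),
                    max_depth = cfg$pars$max_depth, eta = cfg$pars$eta,
                    nthread = 1L),
      data = dtr, nrounds = cfg$pars$nrounds, verbose = 0)
  })
  pr <- stats::predict(fit, xgboost::xgb.DMatrix(Xte))
  scores <- matrix(pr, nrow(Xte), length(lev), byrow = is.null(dim(pr)),
                   dimnames = list(NULL, lev))
  if (!is.null(dim(pr))) scores <- matrix(as.numeric(pr), nrow(Xte),
                                          length(lev),
                                          dimnames = list(NULL, lev))
  list(pred = factor(lev[max.col(scores, ties.method = "first")], levels = lev),
       scores = scores)
}

# Train on (Xtr, ytr), predict Xte. Single dispatch point for the zoo.
fit_predict <- function(cfg, Xtr, ytr, Xte) {
  stopifnot(inherits(cfg, "classifier_config"))
  ytr <- droplevels(as.factor(ytr))
  switch(cfg$name,
    lsvm = , qsvm = , csvm = , mgsvm = svm_fit_predict(Xtr, ytr, Xte, cfg),
    cosine_knn = , coarse_knn = , wknn =
      knn_fit_predict(Xtr, ytr, Xte, k = cfg$pars$k,
                      metric = cfg$pars$metric,
                      weighted = cfg$pars$weighted),
    esknn = esknn_fit_predict(Xtr, ytr, Xte, cfg),
    ebt = ebt_fit_predict(Xtr, ytr, Xte, cfg),
    esd = esd_fit_predict(Xtr, ytr, Xte, cfg))
}
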