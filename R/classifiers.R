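#' The classifier variant grid
#'
#' Four supervised families with the hyperparameter enumerations commonly
#' benchmarked for wearable fall detection — 4 SVM, 12 KNN, 2 naive Bayes
#' and 2 decision-tree variants:
#' \itemize{
#'   \item SVM (4): linear, quadratic, cubic and medium-Gaussian kernels.
#'     The medium-Gaussian preset uses kernel scale `sqrt(d)` (`d` =
#'     number of features), i.e. an RBF kernel with `gamma = 1/d`. Box
#'     constraint 1.
#'   \item KNN (12): Euclidean, Minkowski (exponent 3), Chebychev and
#'     cosine distances, each with K in 5, 10, 50; uniform neighbour
#'     weighting.
#'   \item Naive Bayes (2): Gaussian densities, or per-feature kernel
#'     density estimates with normal-reference bandwidths.
#'   \item Decision tree (2): Gini impurity, with the number of internal
#'     splits capped at 4 ("coarse") or 100 ("fine").
#' }
#'
#' @return List of `model_spec` objects in canonical order (SVM kernels,
#'   then KNN distance-major/K-minor, then NB, then DT). The order is part
#'   of the public contract: report tables and tie-breaks index into it.
#' @export
model_grid <- function() {
  grid <- list()
  for (kern in c("linear", "quadratic", "cubic", "medium_gaussian"))
    grid <- c(grid, list(model_spec("SVM", kernel = kern)))
  for (d in c("euclidean", "minkowski", "chebychev", "cosine"))
    for (k in c(5L, 10L, 50L))
      grid <- c(grid, list(model_spec("KNN", distance = d, k = k)))
  for (dens in c("gaussian", "kde"))
    grid <- c(grid, list(model_spec("NB", density = dens)))
  for (pol in c("coarse", "fine"))
    grid <- c(grid, list(model_spec("DT", depth_policy = pol)))
  grid
}

#' Construct a classifier specification
#'
#' @param family One of `"SVM"`, `"KNN"`, `"NB"`, `"DT"`.
#' @param ... Family-specific hyperparameters: `kernel` (SVM), `distance`
#'   and `k` (KNN), `density` (NB), `depth_policy` (DT).
#' @param seed Integer seed recorded with the spec and set before training.
#' @return A `model_spec`.
#' @export
model_spec <- function(family = c("SVM", "KNN", "NB", "DT"), ...,
                       seed = 1L) {
  family <- match.arg(family)
  hp <- list(...)
  id <- switch(family,
    SVM = { stopifnot(hp$kernel %in% c("linear", "quadratic", "cubic",
                                       "medium_gaussian"))
            sprintf("svm_%s", hp$kernel) },
    KNN = { stopifnot(hp$distance %in% c("euclidean", "minkowski",
                                         "chebychev", "cosine"),
                      hp$k >= 1)
            sprintf("knn_%s_k%d", hp$distance, hp$k) },
    NB  = { stopifnot(hp$density %in% c("gaussian", "kde"))
            sprintf("nb_%s", hp$density) },
    DT  = { stopifnot(hp$depth_policy %in% c("coarse", "fine"))
            sprintf("dt_%s", hp$depth_policy) })
  label <- switch(family,
    SVM = sprintf("SVM (%s kernel)", gsub("_", " ", hp$kernel)),
    KNN = sprintf("KNN (%s, %d neighbors)", hp$distance, hp$k),
    NB  = sprintf("Naive Bayes (%s)",
                  if (hp$density == "kde") "KDE" else "Gaussian"),
    DT  = sprintf("Decision Tree (%s)", hp$depth_policy))
  structure(list(family = family, hyperparameters = hp, id = id,
                 label = label, seed = as.integer(seed)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec %s: %s>\n", x$id, x$label))
  invisible(x)
}

CLASS_LEVELS <- c("ADL", "FALL")

as_binary_labels <- function(y) {
  y <- factor(as.character(y), levels = CLASS_LEVELS)
  if (anyNA(y)) stop("labels must be 'ADL' or 'FALL'")
  y
}

#' Train one classifier variant
#'
#' @param spec A `model_spec`.
#' @param x Numeric feature matrix (rows = trials), normally standardised.
#' @param y Labels coercible to the `ADL`/`FALL` factor; both classes must
#'   be present.
#' @return A `fds_model` usable with [predict.fds_model()].
#' @export
fds_train <- function(spec, x, y) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- as_binary_labels(y)
  if (nrow(x) != length(y)) stop("x and y length mismatch")
  missing <- CLASS_LEVELS[!(CLASS_LEVELS %in% y)]
  if (length(missing))
    stop(sprintf("training labels contain no '%s' examples", missing[1]))
  set.seed(spec$seed)
  hp <- spec$hyperparameters
  fit <- switch(spec$family,
    SVM = {
      kern <- switch(hp$kernel,
        linear = list(kernel = "linear"),
        quadratic = list(kernel = "polynomial", degree = 2, gamma = 1,
                         coef0 = 1),
        cubic = list(kernel = "polynomial", degree = 3, gamma = 1,
                     coef0 = 1),
        medium_gaussian = list(kernel = "radial", gamma = 1 / ncol(x)))
      do.call(e1071::svm,
              c(list(x = x, y = y, scale = FALSE, cost = 1), kern))
    },
    KNN = {
      k_eff <- hp$k
      if (k_eff > nrow(x) - 1) {
        k_eff <- nrow(x) - 1L
        warning(sprintf(
          "KNN: K=%d exceeds available neighbours; clamped to %d",
          hp$k, k_eff))
      }
      list(x = x, y = y, k = k_eff, distance = hp$distance)
    },
    NB = {
      if (hp$density == "gaussian") {
        e1071::naiveBayes(x = as.data.frame(x), y = y)
      } else {
        nb_kde_fit(x, y)
      }
    },
    DT = {
      cap <- if (hp$depth_policy == "coarse") 4L else 100L
      dt_fit_capped(x, y, cap)
    })
  structure(list(spec = spec, fit = fit, p = ncol(x),
                 feature_names = colnames(x), levels = CLASS_LEVELS),
            class = "fds_model")
}

# --- KNN ------------------------------------------------------------------

knn_distances <- function(test, train, distance) {
  switch(distance,
    euclidean = {
      cr <- tcrossprod(test, train)
      d2 <- outer(rowSums(test^2), rowSums(train^2), "+") - 2 * cr
      sqrt(pmax(d2, 0))
    },
    minkowski = {
      t(apply(test, 1, function(r)
        (colSums(abs(t(train) - r)^3))^(1 / 3)))
    },
    chebychev = {
      t(apply(test, 1, function(r) apply(abs(t(train) - r), 2, max)))
    },
    cosine = {
      nt <- sqrt(rowSums(test^2))
      nr <- sqrt(rowSums(train^2))
      nt[nt == 0] <- 1
      nr[nr == 0] <- 1
      1 - tcrossprod(test / nt, train / nr)
    })
}

knn_predict <- function(fit, newdata) {
  d <- knn_distances(newdata, fit$x, fit$distance)
  if (is.null(dim(d))) d <- matrix(d, nrow = nrow(newdata))
  apply(d, 1, function(row) {
    ord <- order(row)  # stable: ties by training index
    nb <- fit$y[ord[seq_len(fit$k)]]
    tab <- table(nb)
    if (length(tab) > 1 && tab[1] == tab[2])
      as.character(fit$y[ord[1]])  # tie: label of the single nearest
    else
      names(tab)[which.max(tab)]
  })
}

# --- Naive Bayes with per-feature KDE ------------------------------------

nb_kde_fit <- function(x, y) {
  classes <- levels(y)
  models <- lapply(classes, function(cl) {
    xc <- x[y == cl, , drop = FALSE]
    lapply(seq_len(ncol(x)), function(j) {
      v <- xc[, j]
      h <- stats::bw.nrd0(v)
      if (!is.finite(h) || h <= 0)
        h <- max(1e-3, 1e-3 * stats::sd(x[, j]))
      list(values = v, bw = h)
    })
  })
  names(models) <- classes
  priors <- table(y) / length(y)
  list(models = models, priors = priors, classes = classes)
}

nb_kde_predict <- function(fit, newdata) {
  ll <- sapply(fit$classes, function(cl) {
    m <- fit$models[[cl]]
    lp <- log(as.numeric(fit$priors[cl]))
    for (j in seq_len(ncol(newdata))) {
      dens <- vapply(newdata[, j], function(q)
        mean(stats::dnorm(q, m[[j]]$values, m[[j]]$bw)), 0)
      lp <- lp + log(dens + 1e-300)
    }
    lp
  })
  if (is.null(dim(ll))) ll <- matrix(ll, nrow = 1)
  fit$classes[max.col(ll, ties.method = "first")]
}

# --- Decision tree with a cap on the number of splits --------------------

n_splits <- function(fit) sum(fit$frame$var != "<leaf>")

dt_fit_capped <- function(x, y, cap) {
  df <- data.frame(.y = y, x)
  fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                      parms = list(split = "gini"),
                      control = rpart::rpart.control(
                        cp = 0, minsplit = 2, minbucket = 1, xval = 0))
  if (n_splits(fit) > cap) {
    for (cp in sort(unique(fit$cptable[, "CP"]))) {
      pruned <- rpart::prune(fit, cp = cp + 1e-12)
      if (n_splits(pruned) <= cap) { fit <- pruned; break }
    }
  }
  fit
}

#' Predict fall/ADL labels
#'
#' @param object A trained `fds_model`.
#' @param newdata Feature matrix with the training dimensionality.
#' @param ... Unused.
#' @return Factor of `ADL`/`FALL` labels, one per row; row order is
#'   preserved and each prediction depends only on its own row.
#' @export
predict.fds_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p)
    stop(sprintf("predict: model expects %d features, got %d", object$p,
                 ncol(newdata)))
  colnames(newdata) <- object$feature_names
  spec <- object$spec
  out <- switch(spec$family,
    SVM = as.character(predict(object$fit, newdata)),
    KNN = knn_predict(object$fit, newdata),
    NB = if (spec$hyperparameters$density == "gaussian")
           as.character(predict(object$fit, as.data.frame(newdata)))
         else nb_kde_predict(object$fit, newdata),
    DT = as.character(predict(object$fit, as.data.frame(newdata),
                              type = "class")))
  factor(out, levels = object$levels)
}
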