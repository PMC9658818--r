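# Five base classifiers behind one interface: train_classifier() returns a
# gait_model; score_classifier() returns rows on the probability simplex
# (one column per class seen in training); predict_classifier() takes the
# argmax with a lowest-class-id tie-break. Feature standardisation (z-score
# on training statistics) lives inside the model, so test data never leaks
# into fitting.

#' Specifications of the five candidate base classifiers
#'
#' 1 = BP network (one hidden layer, 10 units, sigmoidal activation,
#' softmax output, at most 500 epochs); 2 = nearest neighbour (k = 1);
#' 3/4/5 = SVM with linear / RBF / polynomial (degree 3) kernel, cost 1,
#' Platt-calibrated pairwise-coupled class probabilities.
#'
#' @return A list of 5 specs, each with `id`, `family`, `label` and
#'   `hyper` (a named list of hyperparameters).
#' @export
classifier_specs <- function() {
  list(
    list(id = 1L, family = "bp", label = "BP network",
         hyper = list(size = 10L, maxit = 500L)),
    list(id = 2L, family = "knn", label = "KNN (k = 1)",
         hyper = list(k = 1L)),
    list(id = 3L, family = "svm", label = "SVM (linear)",
         hyper = list(kernel = "linear", cost = 1)),
    list(id = 4L, family = "svm", label = "SVM (RBF)",
         hyper = list(kernel = "radial", cost = 1)),
    list(id = 5L, family = "svm", label = "SVM (polynomial)",
         hyper = list(kernel = "polynomial", cost = 1, degree = 3L))
  )
}

.get_spec <- function(spec) {
  if (is.numeric(spec)) {
    id <- as.integer(spec)
    if (length(id) != 1L || is.na(id) || id < 1L || id > 5L) {
      stop("classifier id must be in 1..5", call. = FALSE)
    }
    return(classifier_specs()[[id]])
  }
  stopifnot(is.list(spec), !is.null(spec$family))
  spec
}

#' Train one base classifier
#'
#' Features are standardised with training-set means and standard
#' deviations (constant columns get unit scale); the same transform is
#' applied at scoring time.
#'
#' @param spec A classifier id in 1..5 or a spec from
#'   [classifier_specs()].
#' @param X Numeric feature matrix/data.frame, rows = samples.
#' @param y Integer class labels (at least two distinct classes).
#' @param seed Integer seed for stochastic trainers (BP initial weights,
#'   SVM probability calibration folds).
#' @return A `gait_model` bound to its spec.
#' @export
train_classifier <- function(spec, X, y, seed = 1L) {
  spec <- .get_spec(spec)
  X <- as.matrix(X)
  y <- as.integer(y)
  if (nrow(X) != length(y)) stop("row/label mismatch", call. = FALSE)
  levels <- sort(unique(y))
  if (length(levels) < 2L) stop("training labels contain a single class",
                                call. = FALSE)
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  Xs <- scale(X, center = center, scale = scale)
  yf <- factor(y, levels = levels)
  fit <- with_seed(seed, switch(spec$family,
    bp = {
      nnet::nnet(Xs, nnet::class.ind(yf), size = spec$hyper$size,
                 softmax = TRUE, maxit = spec$hyper$maxit, trace = FALSE,
                 MaxNWts = 100000)
    },
    knn = list(train = Xs, y = y),
    svm = {
      gamma <- 1 / (ncol(Xs) * max(stats::var(as.vector(Xs)), 1e-12))
      args <- list(x = Xs, y = yf, kernel = spec$hyper$kernel,
                   cost = spec$hyper$cost, gamma = gamma,
                   probability = TRUE, scale = FALSE)
      if (!is.null(spec$hyper$degree)) args$degree <- spec$hyper$degree
      do.call(e1071::svm, args)
    },
    stop("unknown classifier family: ", spec$family, call. = FALSE)))
  structure(list(spec = spec, fit = fit, center = center, scale = scale,
                 levels = levels, seed = seed),
            class = "gait_model")
}

#' @export
print.gait_model <- function(x, ...) {
  cat(sprintf("gait_model: %s, %d classes, %d features\n", x$spec$label,
              length(x$levels), length(x$center)))
  invisible(x)
}

#' Per-class probability scores
#'
#' Every model family returns rows on the probability simplex over the
#' training classes: the BP network's softmax outputs, a one-hot row at
#' the nearest training neighbour for KNN (k = 1, distance ties broken
#' toward the earliest training sample), and Platt-calibrated
#' pairwise-coupled probabilities for the SVMs.
#'
#' @param model A `gait_model`.
#' @param X Matrix/data.frame of samples to score (or a single vector).
#' @return Numeric matrix, one row per sample, columns named by class id,
#'   each row summing to 1.
#' @export
score_classifier <- function(model, X) {
  stopifnot(inherits(model, "gait_model"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (ncol(X) != length(model$center)) {
    stop(sprintf("feature dimension mismatch: model expects %d, got %d",
                 length(model$center), ncol(X)), call. = FALSE)
  }
  Xs <- scale(X, center = model$center, scale = model$scale)
  m <- length(model$levels)
  Z <- switch(model$spec$family,
    bp = {
      p <- stats::predict(model$fit, Xs, type = "raw")
      matrix(p, ncol = m)
    },
    knn = {
      tr <- model$fit$train
      out <- matrix(0, nrow = nrow(Xs), ncol = m)
      for (i in seq_len(nrow(Xs))) {
        d2 <- colSums((t(tr) - Xs[i, ])^2)
        nn <- which.min(d2)   # ties -> earliest training sample
        out[i, match(model$fit$y[nn], model$levels)] <- 1
      }
      out
    },
    svm = {
      pr <- stats::predict(model$fit, Xs, probability = TRUE)
      p <- attr(pr, "probabilities")
      p[, match(as.character(model$levels), colnames(p)), drop = FALSE]
    })
  Z[Z < 0] <- 0
  Z <- Z / rowSums(Z)
  dimnames(Z) <- list(NULL, model$levels)
  Z
}

#' Crisp class prediction
#'
#' Argmax of [score_classifier()], ties broken toward the lowest class id.
#'
#' @inheritParams score_classifier
#' @return Integer vector of predicted class ids.
#' @export
predict_classifier <- function(model, X) {
  Z <- score_classifier(model, X)
  model$levels[max.col(Z, ties.method = "first")]
}
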