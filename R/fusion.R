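# Decision-level fusion of classifier outputs. A score matrix Z (rows =
# classifiers, columns = classes, each row on the probability simplex) is
# combined into one decision by one of eight rules: Dempster-Shafer
# evidence combination, majority voting, decision templates, and the five
# algebraic rules (sum, average, maximum, minimum, product). All argmax
# decisions break ties toward the lowest class id.

#' Canonical fusion-rule names
#'
#' In the fixed comparison order used by the stage-1 protocol.
#'
#' @return Character vector of the eight rule names.
#' @export
fusion_rules <- function() {
  c("vote", "max", "sum", "min", "average", "product", "dt", "ds")
}

.check_score_matrix <- function(Z) {
  Z <- as.matrix(Z)
  if (any(Z < -1e-9) || any(abs(rowSums(Z) - 1) > 1e-6)) {
    stop("score matrix rows must lie on the probability simplex",
         call. = FALSE)
  }
  Z
}

#' Construct a mass function over singletons and the full frame
#'
#' A basic probability assignment restricted to the focal sets this
#' pipeline needs: the m singleton classes plus the whole recognition
#' frame (Theta), which carries the source's undischarged uncertainty.
#'
#' @param singleton Numeric vector of singleton masses (one per class).
#' @param theta Mass assigned to the full frame.
#' @param class_ids Class ids naming the singletons; defaults to
#'   `seq_along(singleton)`.
#' @return A `mass_function`.
#' @export
mass_function <- function(singleton, theta = 0,
                          class_ids = seq_along(singleton)) {
  singleton <- as.numeric(singleton)
  if (any(singleton < -1e-12) || theta < -1e-12) {
    stop("masses must be non-negative", call. = FALSE)
  }
  tot <- sum(singleton) + theta
  if (abs(tot - 1) > 1e-9) {
    stop("masses must sum to 1 (got ", format(tot), ")", call. = FALSE)
  }
  structure(list(singleton = pmax(singleton, 0),
                 theta = max(theta, 0),
                 class_ids = as.integer(class_ids)),
            class = "mass_function")
}

#' @export
print.mass_function <- function(x, ...) {
  cat("mass_function over", length(x$singleton), "classes + Theta\n")
  print(round(stats::setNames(c(x$singleton, x$theta),
                              c(x$class_ids, "Theta")), 4))
  invisible(x)
}

#' Discount a classifier score row into a mass function
#'
#' Reliability discounting: singleton masses are `alpha` times the score
#' row and the remaining `1 - alpha` goes to the full frame. With
#' `alpha < 1` every source keeps some frame mass, so total conflict under
#' Dempster combination is impossible whenever any score is positive.
#'
#' @param row Score vector on the probability simplex.
#' @param alpha Source reliability in (0, 1].
#' @param class_ids Class ids naming the scores.
#' @return A `mass_function`.
#' @export
scores_to_mass <- function(row, alpha = 0.95, class_ids = seq_along(row)) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    stop("`alpha` must be in (0, 1]", call. = FALSE)
  }
  row <- as.numeric(row)
  if (any(row < -1e-9) || abs(sum(row) - 1) > 1e-6) {
    stop("`row` must lie on the probability simplex", call. = FALSE)
  }
  row <- pmax(row, 0) / sum(pmax(row, 0))
  mass_function(alpha * row, 1 - alpha, class_ids)
}

#' Dempster's rule of combination
#'
#' Conjunctive pooling of two mass functions over the focal sets
#' {singletons, Theta}: the unnormalised combined singleton mass is
#' `m1_j m2_j + m1_j m2_T + m1_T m2_j`, the combined frame mass is
#' `m1_T m2_T`, and everything is renormalised by `1 - K` where `K` (the
#' conflict) sums the products of incompatible singletons.
#'
#' @param m1,m2 `mass_function`s over the same frame.
#' @return The combined `mass_function`.
#' @section Total conflict: when `K = 1` (two certain, contradictory
#'   sources) the rule is undefined; a structured condition of class
#'   `gaitfuse_conflict` is raised so callers can fall back to another
#'   rule.
#' @export
ds_combine <- function(m1, m2) {
  stopifnot(inherits(m1, "mass_function"), inherits(m2, "mass_function"))
  if (!identical(m1$class_ids, m2$class_ids)) {
    stop("mass functions are over different frames", call. = FALSE)
  }
  s1 <- m1$singleton; s2 <- m2$singleton
  conflict <- sum(s1) * sum(s2) - sum(s1 * s2)   # sum_{j != l} s1_j s2_l
  denom <- 1 - conflict
  if (denom <= 1e-12) {
    stop(structure(class = c("gaitfuse_conflict", "error", "condition"),
                   list(message = "total conflict (K = 1) in Dempster's rule",
                        call = NULL)))
  }
  new_s <- (s1 * s2 + s1 * m2$theta + m1$theta * s2) / denom
  new_t <- (m1$theta * m2$theta) / denom
  mass_function(new_s, new_t, m1$class_ids)
}

#' Belief and plausibility of a singleton class
#'
#' For a singleton proposition A under a mass function restricted to
#' singletons plus the frame: `Bel(A) = m(A)` and
#' `Pl(A) = m(A) + m(Theta)`; the interval `[Bel, Pl]` brackets the
#' support for A.
#'
#' @param m A `mass_function`.
#' @param class_id One of `m$class_ids`.
#' @return Named numeric vector `c(bel = ..., pl = ...)`.
#' @export
bel_pl <- function(m, class_id) {
  stopifnot(inherits(m, "mass_function"))
  i <- match(as.integer(class_id), m$class_ids)
  if (is.na(i)) stop("unknown class id: ", class_id, call. = FALSE)
  c(bel = m$singleton[i], pl = m$singleton[i] + m$theta)
}

#' Dempster-Shafer fusion of a score matrix
#'
#' Each classifier's score row is discounted into a mass function
#' ([scores_to_mass()]) and the rows are folded together with
#' [ds_combine()]; the decision is the class with maximal combined
#' singleton mass (lowest id on ties). Dempster's rule is associative and
#' commutative, so the fold order does not affect the result.
#'
#' @param Z Score matrix (classifiers x classes), rows on the simplex.
#' @param alpha Reliability discount passed to [scores_to_mass()]; may be
#'   a single value or one per classifier.
#' @param class_ids Class ids naming the columns.
#' @param on_conflict What to do on total conflict (only reachable with
#'   `alpha = 1`): `"sum"` falls back to the sum rule, `"error"`
#'   re-raises the condition.
#' @return Integer class id, with the combined `mass_function` attached as
#'   attribute `"mass"` (`NULL` after a conflict fallback).
#' @export
ds_fuse <- function(Z, alpha = 0.95, class_ids = NULL,
                    on_conflict = c("sum", "error")) {
  on_conflict <- match.arg(on_conflict)
  Z <- .check_score_matrix(Z)
  if (nrow(Z) < 1L) stop("empty score matrix", call. = FALSE)
  if (is.null(class_ids)) class_ids <- seq_len(ncol(Z))
  if (length(alpha) == 1L) alpha <- rep(alpha, nrow(Z))
  res <- tryCatch({
    acc <- scores_to_mass(Z[1, ], alpha[1], class_ids)
    for (i in seq_len(nrow(Z))[-1]) {
      acc <- ds_combine(acc, scores_to_mass(Z[i, ], alpha[i], class_ids))
    }
    acc
  }, gaitfuse_conflict = function(e) {
    if (on_conflict == "error") stop(e)
    NULL
  })
  if (is.null(res)) {
    out <- algebraic_fuse(Z, "sum", class_ids)
    attr(out, "mass") <- NULL
    attr(out, "conflict_fallback") <- TRUE
    return(out)
  }
  out <- class_ids[which.max(res$singleton)]
  attr(out, "mass") <- res
  out
}

#' Majority vote over crisp labels
#'
#' Returns the class holding a strict majority (> n/2) of the votes; when
#' no class does, falls back to plurality, with ties broken toward the
#' lowest class id.
#'
#' @param labels Integer vector of member-classifier predictions.
#' @return Integer class id, with attribute `"majority"` saying whether a
#'   strict majority (rather than the plurality fallback) decided.
#' @export
majority_vote <- function(labels) {
  labels <- as.integer(labels)
  if (length(labels) == 0L) stop("no votes", call. = FALSE)
  counts <- table(labels)
  ids <- as.integer(names(counts))
  best <- which(counts == max(counts))
  winner <- min(ids[best])
  out <- winner
  attr(out, "majority") <- counts[[as.character(winner)]] > length(labels) / 2
  out
}

#' Fit decision templates
#'
#' The template of class c is the elementwise mean of the score matrices
#' of the training samples labelled c.
#'
#' @param score_matrices List of score matrices (one per training sample,
#'   all classifiers x classes with identical shape).
#' @param y Integer labels aligned with `score_matrices`.
#' @param class_ids The full set of class ids; every one must occur in
#'   `y`. Defaults to the score-matrix columns.
#' @return A `decision_templates` object: list of per-class template
#'   matrices plus `class_ids`.
#' @export
dt_fit <- function(score_matrices, y, class_ids = NULL) {
  stopifnot(length(score_matrices) == length(y), length(y) > 0L)
  y <- as.integer(y)
  if (is.null(class_ids)) class_ids <- seq_len(ncol(score_matrices[[1]]))
  missing <- setdiff(class_ids, y)
  if (length(missing) > 0L) {
    stop("no training samples for class(es): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  templates <- lapply(class_ids, function(c_id) {
    Reduce(`+`, score_matrices[y == c_id]) / sum(y == c_id)
  })
  structure(list(templates = templates, class_ids = as.integer(class_ids)),
            class = "decision_templates")
}

#' Predict with decision templates
#'
#' Similarity to class c is `1 - mean((Z - T_c)^2)` (squared-Euclidean
#' similarity); the decision is the most similar template, lowest class id
#' on ties.
#'
#' @param templates A `decision_templates` object from [dt_fit()].
#' @param Z Score matrix with the shape of the training matrices.
#' @return Integer class id, with the similarity vector attached as
#'   attribute `"similarity"`.
#' @export
dt_predict <- function(templates, Z) {
  stopifnot(inherits(templates, "decision_templates"))
  Z <- as.matrix(Z)
  if (!all(dim(Z) == dim(templates$templates[[1]]))) {
    stop("score matrix shape does not match the templates", call. = FALSE)
  }
  sim <- vapply(templates$templates,
                function(tpl) 1 - mean((Z - tpl)^2), numeric(1))
  out <- templates$class_ids[which.max(sim)]
  attr(out, "similarity") <- stats::setNames(sim, templates$class_ids)
  out
}

#' Algebraic fusion rules
#'
#' Per-class support `e_j` is the column sum, mean, maximum, minimum or
#' product of the score matrix; the decision is `argmax e_j` (lowest class
#' id on ties). Sum and average always agree. For the product rule every
#' score is floored at `1e-12` first, so a single one-hot member (KNN with
#' k = 1) cannot annihilate every class.
#'
#' @param Z Score matrix (classifiers x classes).
#' @param rule One of `"sum"`, `"average"`, `"max"`, `"min"`, `"product"`.
#' @param class_ids Class ids naming the columns.
#' @return Integer class id with the support vector as attribute
#'   `"support"`.
#' @export
algebraic_fuse <- function(Z, rule = c("sum", "average", "max", "min",
                                       "product"),
                           class_ids = NULL) {
  rule <- match.arg(rule)
  Z <- .check_score_matrix(Z)
  if (nrow(Z) < 1L) stop("empty score matrix", call. = FALSE)
  if (is.null(class_ids)) class_ids <- seq_len(ncol(Z))
  e <- switch(rule,
    sum = colSums(Z),
    average = colMeans(Z),
    max = apply(Z, 2, max),
    min = apply(Z, 2, min),
    product = apply(pmax(Z, 1e-12), 2, prod))
  out <- class_ids[which.max(e)]
  attr(out, "support") <- stats::setNames(e, class_ids)
  out
}

#' Fuse one score matrix by any of the eight rules
#'
#' Single dispatcher used by the evaluation protocol. `"vote"` votes over
#' the per-row argmax labels; `"dt"` requires fitted `templates`; `"ds"`
#' uses [ds_fuse()] with the given `alpha`; everything else is
#' [algebraic_fuse()].
#'
#' @param Z Score matrix (classifiers x classes).
#' @param rule One of [fusion_rules()].
#' @param class_ids Class ids naming the columns.
#' @param templates `decision_templates`, required for `rule = "dt"`.
#' @param alpha Reliability discount for `rule = "ds"`.
#' @return Integer class id (attributes stripped).
#' @export
fuse <- function(Z, rule, class_ids = NULL, templates = NULL, alpha = 0.95) {
  if (!rule %in% fusion_rules()) {
    stop("unknown fusion rule: '", rule, "' (expected one of ",
         paste(fusion_rules(), collapse = ", "), ")", call. = FALSE)
  }
  Z <- .check_score_matrix(Z)
  if (is.null(class_ids)) class_ids <- seq_len(ncol(Z))
  out <- switch(rule,
    vote = {
      labs <- class_ids[max.col(Z, ties.method = "first")]
      majority_vote(labs)
    },
    dt = {
      if (is.null(templates)) stop("rule 'dt' needs fitted templates",
                                   call. = FALSE)
      dt_predict(templates, Z)
    },
    ds = ds_fuse(Z, alpha = alpha, class_ids = class_ids),
    algebraic_fuse(Z, rule, class_ids))
  as.integer(out)
}
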