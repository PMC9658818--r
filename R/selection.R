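# Two-stage feature selection: MRMR (greedy mutual-information ranking,
# difference criterion) screens candidates, then BMSF (binary matrix
# shuffling filter, a wrapper around linear-SVM cross-validated accuracy)
# prunes them to a compact subset. BMSF here is a reconstruction from its
# one-line published description: random binary inclusion subsets are
# scored by SVM CV accuracy and a feature is kept when the subsets that
# include it are on average more accurate than those that exclude it, by
# a margin that is significant against the Welch standard error of the
# difference (otherwise a zero-effect feature would survive each round
# with probability one half and the filter would never thin pure noise).

# Equal-frequency discretisation into at most `bins` levels. When the
# number of distinct values is already <= bins the values themselves are
# the levels, so discrete features (e.g. a copy of the label) lose nothing.
discretize_ef <- function(f, bins) {
  ux <- unique(f)
  if (length(ux) <= bins) return(match(f, sort(ux)))
  qs <- stats::quantile(f, probs = seq(0, 1, length.out = bins + 1),
                        names = FALSE, type = 7)
  qs <- unique(qs)
  if (length(qs) < 2L) return(rep(1L, length(f)))
  findInterval(f, qs, rightmost.closed = TRUE, all.inside = TRUE)
}

.mi_from_codes <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

#' Plug-in mutual information between a feature and class labels
#'
#' The feature is discretised into equal-frequency bins (features with at
#' most `bins` distinct values are used as-is) and the plug-in estimate
#' `sum p(x,y) log(p(x,y) / (p(x) p(y)))` is computed in nats.
#'
#' @param f Numeric feature vector.
#' @param y Labels (any discrete vector of the same length).
#' @param bins Number of bins; defaults to `ceiling(sqrt(N))`.
#' @return Non-negative mutual information in nats. A constant feature has
#'   MI 0.
#' @export
mutual_information <- function(f, y, bins = ceiling(sqrt(length(f)))) {
  n <- length(f)
  if (n < 10L) stop("need at least 10 samples", call. = FALSE)
  if (length(y) != n) stop("`f` and `y` lengths differ", call. = FALSE)
  if (bins < 2L) stop("`bins` must be >= 2", call. = FALSE)
  max(0, .mi_from_codes(discretize_ef(as.numeric(f), bins), y))
}

#' MRMR feature ranking (difference criterion)
#'
#' Greedy forward selection: the first feature maximises relevance
#' `I(f; y)`; each later step maximises `I(f; y) - mean_{s in S} I(f; s)`
#' over features not yet selected (the difference form of the
#' max-relevance / min-redundancy criterion). All mutual informations use
#' the discretisation of [mutual_information()].
#'
#' @param X Numeric matrix or data.frame of features (rows = samples).
#' @param y Labels, one per row.
#' @param k Number of features to rank.
#' @param bins Discretisation bins, as in [mutual_information()].
#' @return Integer vector of `k` column indices in selection order.
#' @export
mrmr_rank <- function(X, y, k, bins = ceiling(sqrt(length(y)))) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (k > p) stop("`k` exceeds the number of features (", p, ")",
                  call. = FALSE)
  if (nrow(X) != length(y)) stop("row/label mismatch", call. = FALSE)
  codes <- apply(X, 2, discretize_ef, bins = bins)
  rel <- apply(codes, 2, function(cc) max(0, .mi_from_codes(cc, y)))
  selected <- integer(0)
  # redundancy[j] accumulates sum over selected s of I(f_j; f_s)
  red_sum <- numeric(p)
  remaining <- seq_len(p)
  for (step in seq_len(k)) {
    score <- if (length(selected) == 0L) rel[remaining] else
      rel[remaining] - red_sum[remaining] / length(selected)
    pick <- remaining[which.max(score)]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    if (length(remaining) > 0L && step < k) {
      red_sum[remaining] <- red_sum[remaining] +
        vapply(remaining, function(j)
          max(0, .mi_from_codes(codes[, j], codes[, pick])), numeric(1))
    }
  }
  selected
}

#' BMSF wrapper feature selection
#'
#' Binary-matrix shuffling filter over a candidate feature set: each row of
#' a random binary inclusion matrix defines a feature subset which is
#' scored by linear-SVM cross-validated accuracy; a feature is retained
#' when the mean accuracy of subsets including it exceeds that of subsets
#' excluding it by more than `z_keep` Welch standard errors of the
#' difference. The inclusion matrix is reshuffled over the surviving
#' candidates and the procedure iterates until the retained set is stable
#' or `max_iter` is reached; when every evaluated subset reaches identical
#' accuracy the remaining candidates are indistinguishable and the current
#' set is returned as stable. This is a reconstruction of the published
#' filter from its summary description; the update and stopping rules are
#' this package's own.
#'
#' @param X Numeric matrix/data.frame of candidate features (rows =
#'   samples, columns already screened, e.g. by [mrmr_rank()]).
#' @param y Labels, one per row.
#' @param n_rows Rows of the binary inclusion matrix per iteration. The
#'   standard error of an inclusion effect shrinks as `1 / sqrt(n_rows)`;
#'   the default resolves effects a few times smaller than the spread of
#'   subset accuracies.
#' @param max_iter Maximum shuffling iterations.
#' @param z_keep Retention threshold in Welch standard errors.
#' @param seed Integer seed making the whole search deterministic.
#' @param cv_folds Folds of the inner SVM cross-validation.
#' @param force_size Optional integer: truncate/grow the final subset to
#'   exactly this many features, ranked by each feature's mean inclusion
#'   accuracy. Default `NULL` lets the filter decide its own size.
#' @return A `selection_result`: list with `final_subset` (column indices
#'   into `X`), `objective_trace` (best subset accuracy per iteration),
#'   `converged`, `n_iter` and the configuration. With a non-`NULL`
#'   `force_size`, `final_subset` has exactly that length.
#' @export
bmsf_select <- function(X, y, n_rows = 128L, max_iter = 20L, seed = 1L,
                        cv_folds = 5L, z_keep = 1, force_size = NULL) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 2L) stop("need at least 2 candidate features", call. = FALSE)
  if (nrow(X) != length(y)) stop("row/label mismatch", call. = FALSE)
  yf <- factor(y)
  subset_acc <- function(cols) {
    # 5-fold CV accuracy of a linear SVM on the column subset
    m <- e1071::svm(X[, cols, drop = FALSE], yf, kernel = "linear",
                    cost = 1, scale = TRUE, cross = cv_folds)
    m$tot.accuracy / 100
  }
  with_seed(seed, {
    candidates <- seq_len(p)
    trace <- numeric(0)
    incl_acc <- stats::setNames(rep(NA_real_, p), colnames(X))
    converged <- FALSE
    iter <- 0L
    while (iter < max_iter) {
      iter <- iter + 1L
      q <- length(candidates)
      if (q <= 1L) break
      B <- matrix(stats::runif(n_rows * q) < 0.5, nrow = n_rows)
      # every row must propose a non-empty subset
      empty <- rowSums(B) == 0L
      if (any(empty)) B[cbind(which(empty),
                              sample.int(q, sum(empty), replace = TRUE))] <- TRUE
      acc <- vapply(seq_len(n_rows),
                    function(r) subset_acc(candidates[B[r, ]]), numeric(1))
      trace <- c(trace, max(acc))
      if (max(acc) - min(acc) < 1e-12) {
        # every subset performs identically: the remaining candidates
        # cannot be told apart, so the set is stable
        converged <- TRUE
        break
      }
      keep <- logical(q)
      for (j in seq_len(q)) {
        a_in <- acc[B[, j]]; a_out <- acc[!B[, j]]
        if (length(a_in) < 2L || length(a_out) < 2L) {
          keep[j] <- TRUE
          next
        }
        m_in <- mean(a_in); m_out <- mean(a_out)
        se <- sqrt(stats::var(a_in) / length(a_in) +
                   stats::var(a_out) / length(a_out))
        incl_acc[candidates[j]] <- m_in
        keep[j] <- (m_in - m_out) > z_keep * se
      }
      if (!any(keep)) {
        # degenerate draw: fall back to the best-scoring row's subset
        candidates <- candidates[B[which.max(acc), ]]
        next
      }
      new_candidates <- candidates[keep]
      if (identical(new_candidates, candidates)) {
        converged <- TRUE
        break
      }
      candidates <- new_candidates
    }
    final <- sort(candidates)
    if (!is.null(force_size)) {
      force_size <- as.integer(force_size)
      ranked <- order(incl_acc, decreasing = TRUE, na.last = TRUE)
      if (length(final) > force_size) {
        final <- sort(final[order(match(final, ranked))][seq_len(force_size)])
      } else if (length(final) < force_size) {
        extra <- setdiff(ranked, final)
        final <- sort(c(final, extra[seq_len(force_size - length(final))]))
      }
    }
    if (!converged && iter >= max_iter) {
      warning("BMSF did not stabilise within max_iter; returning best-so-far",
              call. = FALSE)
    }
    structure(list(
      final_subset = final,
      objective_trace = trace,
      converged = converged,
      n_iter = iter,
      inclusion_accuracy = incl_acc,
      config = list(n_rows = n_rows, max_iter = max_iter, seed = seed,
                    cv_folds = cv_folds, z_keep = z_keep,
                    force_size = force_size)
    ), class = "selection_result")
  })
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("BMSF selection: %d features retained after %d iteration(s)%s\n",
              length(x$final_subset), x$n_iter,
              if (x$converged) " (stable)" else ""))
  cat("  indices:", paste(x$final_subset, collapse = ", "), "\n")
  invisible(x)
}

#' Two-stage MRMR-BMSF selection
#'
#' Convenience driver: MRMR screens `k_mrmr` candidates from the full
#' feature matrix, BMSF prunes them, and the result is reported in
#' original-column indices.
#'
#' @inheritParams bmsf_select
#' @param k_mrmr Candidates to screen in the MRMR stage (default 100).
#' @param ... Passed to [bmsf_select()].
#' @return A `selection_result` whose `final_subset` and added
#'   `mrmr_ranking` index the columns of `X`.
#' @export
select_features <- function(X, y, k_mrmr = 100L, ...) {
  ranking <- mrmr_rank(X, y, k = min(k_mrmr, ncol(as.matrix(X))))
  res <- bmsf_select(as.matrix(X)[, ranking, drop = FALSE], y, ...)
  res$mrmr_ranking <- ranking
  res$final_subset <- sort(ranking[res$final_subset])
  names(res$inclusion_accuracy) <- NULL
  res
}

#' Group selected features by kinematic channel
#'
#' Features derived from the same kinematic parameter form one group — the
#' unit removed in the missing-sensor robustness analysis.
#'
#' @param names Character vector of composed feature names (as produced by
#'   [feature_names()]).
#' @return Named list: one integer vector of positions in `names` per
#'   distinct channel abbreviation, in order of first appearance. The
#'   groups partition `seq_along(names)`.
#' @export
group_features_by_channel <- function(names) {
  if (length(names) == 0L) stop("`names` must be non-empty", call. = FALSE)
  ch <- parse_feature_name(names)$channel_abbr
  split(seq_along(names), factor(ch, levels = unique(ch)))
}

#' Serialize a selection result to JSON
#'
#' @param x A `selection_result`.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_selection <- function(x, path) {
  stopifnot(inherits(x, "selection_result"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
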