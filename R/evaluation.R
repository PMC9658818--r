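# Two-stage evaluation protocol. Stage 1: repeated stratified ten-fold CV
# of every (ensemble, fusion rule) pair, counting how often fusion matches
# or beats the best single member, to pick the fusion rule. Stage 2:
# missing-feature-group ablation under the chosen rule, summarised by the
# mean and population SD of the five scenario accuracies, to pick the
# ensemble.

#' Stratified k-fold partition
#'
#' Shuffles each class separately and deals its members round-robin into
#' the folds, so per-class counts across folds differ by at most one.
#'
#' @param y Integer labels.
#' @param k Number of folds.
#' @param seed Integer seed; identical seeds give identical folds.
#' @return List of `k` integer index vectors partitioning `seq_along(y)`.
#' @export
stratified_kfold <- function(y, k = 10L, seed = 1L) {
  y <- as.integer(y)
  counts <- table(y)
  if (any(counts < k)) {
    small <- names(counts)[counts < k]
    stop("class(es) ", paste(small, collapse = ", "),
         " have fewer than k = ", k, " members", call. = FALSE)
  }
  with_seed(seed, {
    folds <- vector("list", k)
    offset <- 0L
    for (cls in as.integer(names(counts))) {
      idx <- sample(which(y == cls))
      # rotate the starting fold per class so remainders spread evenly
      assign_to <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      for (f in seq_len(k)) {
        folds[[f]] <- c(folds[[f]], idx[assign_to == f])
      }
      offset <- (offset + length(idx)) %% k
    }
    lapply(folds, sort)
  })
}

.check_ensemble <- function(ids, min_size = 1L) {
  ids <- sort(unique(as.integer(ids)))
  if (length(ids) < min_size || any(is.na(ids)) || any(ids < 1L | ids > 5L)) {
    stop("ensemble must be a set of classifier ids in 1..5", call. = FALSE)
  }
  ids
}

ensemble_name <- function(ids) paste(ids, collapse = ",")

# Core engine: one pass of `repeats` repeated stratified k-fold CVs,
# training each needed classifier once per fold and reusing its scores
# across every ensemble and rule. Returns percentage accuracies.
cv_engine <- function(X, y, ensembles, rules, k = 10L, repeats = 10L,
                      seed = 1L, alpha = 0.95) {
  X <- as.matrix(X)
  y <- as.integer(y)
  ensembles <- lapply(ensembles, .check_ensemble)
  stopifnot(all(rules %in% fusion_rules()))
  ids_all <- sort(unique(unlist(ensembles)))
  n_ens <- length(ensembles)
  rep_seeds <- with_seed(seed, sample.int(2147483646L, repeats))
  correct <- matrix(0, n_ens, length(rules),
                    dimnames = list(vapply(ensembles, ensemble_name, ""),
                                    rules))
  member_correct <- stats::setNames(numeric(5), 1:5)
  n_pred <- 0L
  need_dt <- "dt" %in% rules
  for (r in seq_len(repeats)) {
    folds <- stratified_kfold(y, k, rep_seeds[r])
    for (f in seq_len(k)) {
      te <- folds[[f]]
      tr <- setdiff(seq_along(y), te)
      models <- lapply(ids_all, function(id) {
        train_classifier(id, X[tr, , drop = FALSE], y[tr],
                         seed = (rep_seeds[r] + 131L * f + id) %% 2147483647L)
      })
      names(models) <- ids_all
      levels <- models[[1]]$levels
      Zte <- lapply(models, function(m)
        score_classifier(m, X[te, , drop = FALSE]))
      Ztr <- if (need_dt)
        lapply(models, function(m)
          score_classifier(m, X[tr, , drop = FALSE])) else NULL
      for (id in ids_all) {
        pred <- levels[max.col(Zte[[as.character(id)]], ties.method = "first")]
        member_correct[id] <- member_correct[id] + sum(pred == y[te])
      }
      for (e in seq_len(n_ens)) {
        ids_e <- as.character(ensembles[[e]])
        templates <- if (need_dt) {
          tpl <- lapply(levels, function(cls) {
            do.call(rbind, lapply(ids_e, function(id)
              colMeans(Ztr[[id]][y[tr] == cls, , drop = FALSE])))
          })
          structure(list(templates = tpl, class_ids = as.integer(levels)),
                    class = "decision_templates")
        } else NULL
        for (i in seq_along(te)) {
          Z <- do.call(rbind, lapply(ids_e, function(id) Zte[[id]][i, ]))
          for (ru in seq_along(rules)) {
            p <- fuse(Z, rules[ru], class_ids = levels,
                      templates = templates, alpha = alpha)
            if (p == y[te[i]]) correct[e, ru] <- correct[e, ru] + 1
          }
        }
      }
      n_pred <- n_pred + length(te)
    }
  }
  member_acc <- 100 * member_correct / n_pred
  member_acc[setdiff(1:5, ids_all)] <- NA_real_
  list(
    rule_acc = 100 * correct / n_pred,
    member_acc = member_acc,
    single_max = vapply(ensembles, function(ids) max(member_acc[ids]),
                        numeric(1)),
    n_predictions = n_pred
  )
}

#' Repeated stratified cross-validation of one fused ensemble
#'
#' For each repeat the data is re-folded, every member classifier is
#' trained per fold, test samples are fused under `rule`, and accuracy is
#' accumulated; the best member's single-classifier accuracy is computed
#' on identical folds.
#'
#' @param X Feature matrix/data.frame (rows = samples).
#' @param y Integer labels.
#' @param ensemble Classifier ids (subset of 1..5); a single id degrades
#'   every rule to that classifier's own prediction.
#' @param rule One of [fusion_rules()].
#' @param k Folds per repeat.
#' @param repeats Number of repeated CVs.
#' @param seed Master seed; all fold and training seeds derive from it.
#' @param alpha Reliability discount for the Dempster-Shafer rule.
#' @return A `scenario_result`: list with `ensemble`, `rule`,
#'   `accuracy` (fused accuracy, %), `single_max` (%), `member_accuracy`
#'   (named, %) and the run parameters.
#' @export
run_cv <- function(X, y, ensemble, rule = "ds", k = 10L, repeats = 10L,
                   seed = 1L, alpha = 0.95) {
  ensemble <- .check_ensemble(ensemble)
  res <- cv_engine(X, y, list(ensemble), rule, k = k, repeats = repeats,
                   seed = seed, alpha = alpha)
  structure(list(
    ensemble = ensemble, rule = rule,
    accuracy = unname(res$rule_acc[1, 1]),
    single_max = unname(res$single_max[1]),
    member_accuracy = res$member_acc[ensemble],
    k = k, repeats = repeats, seed = seed, alpha = alpha
  ), class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Ensemble {%s}, rule '%s': fused %.2f%% vs single max %.2f%%\n",
              ensemble_name(x$ensemble), x$rule, x$accuracy, x$single_max))
  invisible(x)
}

#' Stage 1: compare fusion rules across candidate ensembles
#'
#' Runs repeated stratified CV for every ensemble under all `rules`
#' (training each classifier once per fold and reusing its scores), then
#' for each rule counts (a) the ensembles whose fused accuracy is at least
#' the best single member's and (b) the ensembles for which the rule
#' attains the row maximum. The selected rule maximises (a), with ties
#' broken by (b) and then by the fixed order of [fusion_rules()].
#'
#' @inheritParams run_cv
#' @param ensembles List of classifier-id vectors (each of size >= 2).
#' @param rules Fusion rules to compare.
#' @return A `stage1_result`: list with `table` (data.frame: ensemble,
#'   single_max, one column per rule, in %), `counts` (data.frame: rule,
#'   `n_ge_single`, `n_row_max`), and `best_rule`.
#' @export
stage1_compare <- function(X, y, ensembles, rules = fusion_rules(),
                           k = 10L, repeats = 10L, seed = 1L, alpha = 0.95) {
  if (length(ensembles) < 1L) stop("need at least one ensemble",
                                   call. = FALSE)
  ensembles <- lapply(ensembles, .check_ensemble, min_size = 2L)
  res <- cv_engine(X, y, ensembles, rules, k = k, repeats = repeats,
                   seed = seed, alpha = alpha)
  tab <- data.frame(ensemble = rownames(res$rule_acc),
                    single_max = res$single_max,
                    res$rule_acc, check.names = FALSE,
                    row.names = NULL, stringsAsFactors = FALSE)
  counts <- stage1_counts(tab, rules)
  structure(list(table = tab, counts = counts,
                 best_rule = counts$rule[1],
                 member_accuracy = res$member_acc),
            class = "stage1_result")
}

# Counting and rule selection on a stage-1 shaped table; exposed
# separately so it can also run on published tables.
stage1_counts <- function(tab, rules = fusion_rules()) {
  rules <- rules[rules %in% names(tab)]
  acc <- as.matrix(tab[, rules, drop = FALSE])
  eps <- 1e-9
  n_ge <- colSums(acc >= tab$single_max - eps)
  row_max <- apply(acc, 1, max)
  n_max <- colSums(acc >= row_max - eps)
  ord <- order(-n_ge, -n_max, match(rules, fusion_rules()))
  data.frame(rule = rules[ord], n_ge_single = unname(n_ge[ord]),
             n_row_max = unname(n_max[ord]), stringsAsFactors = FALSE)
}

#' @export
print.stage1_result <- function(x, ...) {
  cat("Stage-1 comparison (accuracies in %):\n")
  print(cbind(x$table[1:2],
              round(x$table[-(1:2)], 2)), row.names = FALSE)
  cat("\nSelected rule:", x$best_rule, "\n")
  invisible(x)
}

#' Remove one feature group from a feature matrix
#'
#' Drops all columns of the group `g` (a channel abbreviation or an index
#' into `groups`), emulating the failure of one kinematic sensor.
#'
#' @param X Feature matrix/data.frame with named columns.
#' @param groups Named list of column-index groups, as produced by
#'   [group_features_by_channel()].
#' @param g Group name or index.
#' @return `X` without the group's columns (names preserved).
#' @export
ablate_group <- function(X, groups, g) {
  if (is.character(g)) {
    if (!g %in% names(groups)) stop("unknown feature group: ", g,
                                    call. = FALSE)
    drop_idx <- groups[[g]]
  } else {
    g <- as.integer(g)
    if (is.na(g) || g < 1L || g > length(groups)) {
      stop("unknown feature group index: ", g, call. = FALSE)
    }
    drop_idx <- groups[[g]]
  }
  X[, -drop_idx, drop = FALSE]
}

#' Mean and population SD of scenario accuracies
#'
#' Summarises the five missing-feature-scenario accuracies of one
#' ensemble: the arithmetic mean (reported in %) and the population
#' standard deviation (divisor N) of the accuracies expressed as
#' fractions.
#'
#' @param acc Numeric vector of exactly 5 accuracies in percent.
#' @return A `robustness_summary`: list with `per_scenario` (%), `mean`
#'   (%) and `sd` (fraction).
#' @export
robustness_summary <- function(acc) {
  acc <- as.numeric(acc)
  if (length(acc) != 5L || anyNA(acc)) {
    stop("expected exactly 5 scenario accuracies", call. = FALSE)
  }
  frac <- acc / 100
  structure(list(per_scenario = acc,
                 mean = mean(acc),
                 sd = sqrt(mean((frac - mean(frac))^2))),
            class = "robustness_summary")
}

#' @export
print.robustness_summary <- function(x, ...) {
  cat(sprintf("Robustness: mean %.2f%%, population SD %.4f\n",
              x$mean, x$sd))
  invisible(x)
}

#' Stage 2: pick the ensemble from robustness summaries
#'
#' Returns the entry with the highest mean scenario accuracy; ties are
#' broken by the smaller standard deviation, then by the smaller ensemble.
#'
#' @param summaries Named list of [robustness_summary()] objects; names
#'   are ensemble id strings such as `"3,4,5"`.
#' @return The winning ensemble's name.
#' @export
stage2_select <- function(summaries) {
  if (length(summaries) == 0L) stop("no summaries given", call. = FALSE)
  stopifnot(!is.null(names(summaries)))
  means <- vapply(summaries, function(s) s$mean, numeric(1))
  sds <- vapply(summaries, function(s) s$sd, numeric(1))
  sizes <- lengths(strsplit(names(summaries), ","))
  names(summaries)[order(-means, sds, sizes)][1]
}

#' Stage 2: missing-feature robustness of candidate ensembles
#'
#' For every feature group of `X` (one per kinematic channel among the
#' columns), removes the group, reruns repeated stratified CV for each
#' ensemble under `rule`, and summarises each ensemble's five scenario
#' accuracies with [robustness_summary()]; the final ensemble is chosen by
#' [stage2_select()]. Classifiers are retrained on the reduced feature set
#' in each scenario.
#'
#' @inheritParams stage1_compare
#' @param rule The single fusion rule selected in stage 1.
#' @return A `stage2_result`: list with `scenario_accuracy` (ensembles x
#'   scenarios, %), `single_max` (same shape), `summaries` (named list of
#'   `robustness_summary`), and `selected` (ensemble name).
#' @export
run_robustness <- function(X, y, ensembles, rule = "ds", k = 10L,
                           repeats = 10L, seed = 1L, alpha = 0.95) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("X must have composed feature names",
                                 call. = FALSE)
  ensembles <- lapply(ensembles, .check_ensemble, min_size = 2L)
  groups <- group_features_by_channel(colnames(X))
  n_scen <- length(groups)
  ens_names <- vapply(ensembles, ensemble_name, "")
  acc <- matrix(NA_real_, length(ensembles), n_scen,
                dimnames = list(ens_names, paste0("no_", gsub(" ", "_",
                                                  names(groups)))))
  smax <- acc
  for (s in seq_len(n_scen)) {
    Xs <- ablate_group(X, groups, s)
    res <- cv_engine(Xs, y, ensembles, rule, k = k, repeats = repeats,
                     seed = seed + s, alpha = alpha)
    acc[, s] <- res$rule_acc[, 1]
    smax[, s] <- res$single_max
  }
  if (n_scen == 5L) {
    summaries <- stats::setNames(
      lapply(seq_along(ensembles), function(e) robustness_summary(acc[e, ])),
      ens_names)
    selected <- stage2_select(summaries)
  } else {
    # the 5-scenario summary convention only applies to 5 channel groups
    summaries <- NULL
    selected <- ens_names[which.max(rowMeans(acc))]
  }
  structure(list(scenario_accuracy = acc, single_max = smax,
                 summaries = summaries, selected = selected,
                 rule = rule),
            class = "stage2_result")
}

#' @export
print.stage2_result <- function(x, ...) {
  cat(sprintf("Stage-2 robustness under rule '%s' (accuracies in %%):\n",
              x$rule))
  print(round(x$scenario_accuracy, 2))
  cat("\nSelected ensemble: {", x$selected, "}\n", sep = "")
  invisible(x)
}
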