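# Plain-text I/O. Trial datasets travel as long-format CSV
# (trial_id, label, channel_abbr, t_index, value) with a JSON sidecar for
# the generating configuration; feature matrices as wide CSV with composed
# feature names and a final label column. Everything round-trips within
# float printing precision.

#' Write a trial dataset to CSV
#'
#' Long format, one row per (trial, channel, sample):
#' `trial_id, label, channel_abbr, t_index, value`. A JSON sidecar at
#' `<path>.json` records the sample rate and, when present, the full
#' synthetic configuration, so [read_trials()] reconstructs the dataset
#' losslessly.
#'
#' @param dataset A `gait_dataset` or plain list of `trial_recording`s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(dataset, path) {
  trials <- if (inherits(dataset, "gait_dataset")) dataset$trials else dataset
  labels <- if (inherits(dataset, "gait_dataset")) dataset$labels
            else vapply(trials, function(tr) as.integer(tr$label), 1L)
  rows <- lapply(seq_along(trials), function(i) {
    ch <- trials[[i]]$channels
    data.frame(trial_id = i, label = labels[i],
               channel_abbr = rep(rownames(ch), each = ncol(ch)),
               t_index = rep(seq_len(ncol(ch)), times = nrow(ch)),
               value = as.vector(t(ch)), stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  meta <- list(sample_rate = trials[[1]]$sample_rate,
               n_trials = length(trials))
  if (inherits(dataset, "gait_dataset")) {
    meta$config <- unclass(dataset$config)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a trial dataset from CSV
#'
#' Inverse of [write_trials()]. Fails loudly: an empty file, missing
#' columns, or a trial missing one of the 22 channels is an error naming
#' the offending trial/channel, never a silently truncated dataset.
#'
#' @param path CSV path written by [write_trials()].
#' @return A `gait_dataset` (its `config` is restored from the sidecar
#'   when available, otherwise `NULL`).
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   stop("cannot parse ", path, ": ", conditionMessage(e),
                        call. = FALSE))
  needed <- c("trial_id", "label", "channel_abbr", "t_index", "value")
  if (nrow(df) == 0L) stop("empty trial file: ", path, call. = FALSE)
  if (!all(needed %in% names(df))) {
    stop("trial CSV must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  known <- kinematic_channels()$abbr
  bad <- setdiff(unique(df$channel_abbr), known)
  if (length(bad) > 0L) {
    stop("unknown channel abbreviation(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else NULL
  fs <- if (!is.null(meta$sample_rate)) as.numeric(meta$sample_rate) else 100
  ids <- sort(unique(df$trial_id))
  trials <- vector("list", length(ids))
  labels <- integer(length(ids))
  for (i in seq_along(ids)) {
    sub <- df[df$trial_id == ids[i], ]
    have <- unique(sub$channel_abbr)
    miss <- setdiff(known, have)
    if (length(miss) > 0L) {
      stop("trial ", ids[i], " is missing channel(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    len <- max(sub$t_index)
    m <- matrix(NA_real_, length(known), len, dimnames = list(known, NULL))
    m[cbind(match(sub$channel_abbr, known), sub$t_index)] <- sub$value
    if (anyNA(m)) {
      stop("trial ", ids[i], " has missing samples", call. = FALSE)
    }
    labels[i] <- as.integer(sub$label[1])
    trials[[i]] <- structure(list(channels = m, sample_rate = fs,
                                  label = labels[i]),
                             class = "trial_recording")
  }
  cfg <- if (!is.null(meta$config)) {
    c0 <- meta$config
    synth_config(n_per_class = unlist(c0$n_per_class),
                 duration_s = c0$duration_s, sample_rate = c0$sample_rate,
                 noise_sd = c0$noise_sd,
                 class_separation = c0$class_separation, seed = c0$seed)
  } else NULL
  structure(list(trials = trials, labels = labels, config = cfg),
            class = "gait_dataset")
}

#' Write / read a feature matrix CSV
#'
#' Wide format: one row per trial, 462 (or fewer, after selection) named
#' feature columns and a final integer `label` column.
#'
#' @param df Data.frame as produced by [feature_matrix()].
#' @param path CSV path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_feature_matrix <- function(df, path) {
  stopifnot("label" %in% names(df))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L || !"label" %in% names(df)) {
    stop("feature CSV must be non-empty with a `label` column",
         call. = FALSE)
  }
  df
}

# Known run-config keys with defaults; unknown keys are rejected on load.
.default_run_config <- function() {
  list(
    seed = 1L,
    output_dir = "gaitfuse-run",
    synth = list(n_per_class = unname(reference_class_counts()),
                 duration_s = 2, sample_rate = 100, noise_sd = 0.15,
                 class_separation = 1),
    selection = list(k_mrmr = 100L, n_rows = 128L, max_iter = 20L,
                     cv_folds = 5L, z_keep = 1, force_size = NULL),
    cv = list(k = 10L, repeats = 10L, alpha = 0.95),
    ensembles = list(c(1, 2), c(1, 4), c(2, 4), c(3, 4), c(3, 5),
                     c(1, 2, 4), c(1, 3, 5), c(3, 4, 5), c(1, 3, 4, 5)),
    rules = fusion_rules()
  )
}

#' Load a YAML run configuration
#'
#' Missing keys take their documented defaults; unknown keys are an
#' error naming the key.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A validated run-config list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- .default_run_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_known <- function(base, new, prefix = "") {
    for (key in names(new)) {
      full <- paste0(prefix, key)
      if (!key %in% names(base)) {
        stop("unknown config key: ", full, call. = FALSE)
      }
      if (is.list(base[[key]]) && !is.null(names(base[[key]])) &&
          is.list(new[[key]])) {
        base[[key]] <- merge_known(base[[key]], new[[key]],
                                   paste0(full, "."))
      } else {
        base[[key]] <- new[[key]]
      }
    }
    base
  }
  cfg <- merge_known(cfg, user)
  if (!all(unlist(cfg$rules) %in% fusion_rules())) {
    stop("unknown fusion rule in config: ",
         paste(setdiff(unlist(cfg$rules), fusion_rules()), collapse = ", "),
         call. = FALSE)
  }
  cfg
}
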