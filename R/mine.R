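# Interpretable rule mining: shallow tree ensembles over glycan features,
# rule deduplication with estimator support, precision/recall validity
# filters, and iterative refinement over rule-satisfying subsets.

#' Rule-mining configuration
#'
#' Defaults: ensembles of 50 depth-one trees (depth two as fallback),
#' trained on a stratified 80% split; a rule is valid when its held-out
#' precision is at least 0.3, its recall at least 0.1, and at least 15% of
#' the estimators propose it; mining iterates for up to five levels and
#' stops early at precision 1.0.
#'
#' @param n_estimators Number of trees per ensemble.
#' @param max_depth_first Tree depth for the first pass.
#' @param max_depth_fallback Depth used when the first pass yields no valid
#'   rule.
#' @param train_fraction Fraction of glycans used for fitting.
#' @param min_precision,min_recall,min_estimator_support Validity floors
#'   (inclusive).
#' @param max_levels Maximum number of rule levels.
#' @param stop_precision Precision at which mining stops.
#' @param seed Integer seed driving the split and the bootstraps.
#' @return A `mining_config` list.
#' @export
mining_config <- function(n_estimators = 50L, max_depth_first = 1L,
                          max_depth_fallback = 2L, train_fraction = 0.8,
                          min_precision = 0.3, min_recall = 0.1,
                          min_estimator_support = 0.15, max_levels = 5L,
                          stop_precision = 1.0, seed = 1L) {
  cfg <- list(
    n_estimators = as.integer(n_estimators),
    max_depth_first = as.integer(max_depth_first),
    max_depth_fallback = as.integer(max_depth_fallback),
    train_fraction = train_fraction,
    min_precision = min_precision,
    min_recall = min_recall,
    min_estimator_support = min_estimator_support,
    max_levels = as.integer(max_levels),
    stop_precision = stop_precision,
    seed = as.integer(seed)
  )
  stopifnot(cfg$n_estimators >= 1L, cfg$max_depth_first >= 1L,
            cfg$max_depth_fallback >= cfg$max_depth_first,
            cfg$train_fraction > 0, cfg$train_fraction <= 1,
            cfg$min_precision > 0, cfg$min_precision <= 1,
            cfg$min_recall > 0, cfg$min_recall <= 1,
            cfg$max_levels >= 1L)
  structure(cfg, class = "mining_config")
}

# ---- decision trees --------------------------------------------------------

# Best Gini split of y over feature column x. Thresholds sit half a unit
# above each observed value (count features are integers, so cuts read as
# "feature >= 0.5"); midpoints are used if a value+0.5 would overshoot.
best_split_feature <- function(x, y) {
  u <- sort(unique(x))
  if (length(u) < 2L) return(NULL)
  cuts <- u[-length(u)] + 0.5
  hi <- u[-1L]
  bad <- cuts >= hi
  cuts[bad] <- (u[-length(u)][bad] + hi[bad]) / 2
  n <- length(y)
  pos <- sum(y)
  best <- NULL
  for (t in cuts) {
    left <- x < t
    n1 <- sum(left)
    p1 <- sum(y[left])
    n2 <- n - n1
    p2 <- pos - p1
    g1 <- 1 - (p1 / n1)^2 - ((n1 - p1) / n1)^2
    g2 <- 1 - (p2 / n2)^2 - ((n2 - p2) / n2)^2
    imp <- (n1 * g1 + n2 * g2) / n
    if (is.null(best) || imp < best$impurity - 1e-12) {
      best <- list(threshold = t, impurity = imp)
    }
  }
  best
}

best_split <- function(X, y) {
  parent_gini <- {
    p <- mean(y)
    1 - p^2 - (1 - p)^2
  }
  best <- NULL
  for (j in seq_len(ncol(X))) {
    s <- best_split_feature(X[, j], y)
    if (is.null(s)) next
    if (s$impurity >= parent_gini - 1e-12) next
    if (is.null(best) || s$impurity < best$impurity - 1e-12) {
      best <- c(s, list(feature = colnames(X)[j]))
    }
  }
  best
}

# Fit a depth-limited tree and return every root-to-leaf path whose leaf
# predicts "bound" (> 50% bound in the training rows reaching it), as a
# list of condition tibbles (feature, op in {">=", "<"}, threshold).
fit_tree_paths <- function(X, y, depth) {
  grow <- function(rows, conds, d) {
    yy <- y[rows]
    if (d == 0L || length(unique(yy)) == 1L) {
      if (mean(yy) > 0.5 && length(conds) > 0L) return(list(conds))
      return(list())
    }
    s <- best_split(X[rows, , drop = FALSE], yy)
    if (is.null(s)) {
      if (mean(yy) > 0.5 && length(conds) > 0L) return(list(conds))
      return(list())
    }
    left <- rows[X[rows, s$feature] < s$threshold]
    right <- setdiff(rows, left)
    c(
      grow(left, c(conds, list(list(feature = s$feature, op = "<",
                                    threshold = s$threshold))), d - 1L),
      grow(right, c(conds, list(list(feature = s$feature, op = ">=",
                                     threshold = s$threshold))), d - 1L)
    )
  }
  grow(seq_along(y), list(), depth)
}

conds_to_tibble <- function(conds) {
  tibble::tibble(
    feature = vapply(conds, `[[`, character(1), "feature"),
    op = vapply(conds, `[[`, character(1), "op"),
    threshold = vapply(conds, `[[`, numeric(1), "threshold")
  )
}

rule_key <- function(conds_tbl) {
  paste(sort(paste0(conds_tbl$feature, " ", conds_tbl$op, " ",
                    format(conds_tbl$threshold, trim = TRUE))),
        collapse = " & ")
}

#' Does each glycan satisfy a rule?
#'
#' @param features Feature tibble (from [build_feature_matrix()]) or
#'   numeric matrix.
#' @param conditions Tibble with columns `feature`, `op`, `threshold`.
#' @return Logical vector, one element per glycan.
#' @export
rule_satisfied <- function(features, conditions) {
  X <- if (is.matrix(features)) features else feature_matrix_parts(features)
  ok <- rep(TRUE, nrow(X))
  for (i in seq_len(nrow(conditions))) {
    f <- conditions$feature[i]
    if (!f %in% colnames(X)) {
      stop("rule refers to unknown feature '", f, "'", call. = FALSE)
    }
    v <- X[, f]
    ok <- ok & if (conditions$op[i] == ">=") v >= conditions$threshold[i]
               else v < conditions$threshold[i]
  }
  ok
}

# ---- candidate proposal ----------------------------------------------------

# Stratified train/test split; returns logical train mask.
stratified_split <- function(labels, train_fraction, seed) {
  n <- length(labels)
  train <- rep(FALSE, n)
  withr::with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      k <- max(1L, round(train_fraction * length(idx)))
      k <- min(k, length(idx) - 1L)  # keep at least one per class in test
      if (length(idx) == 1L) k <- 1L
      train[sample(idx, k)] <- TRUE
    }
  })
  train
}

#' Propose candidate rules from a tree ensemble
#'
#' Fits `n_estimators` depth-limited trees on bootstrap resamples of the
#' training split; every root-to-leaf path predicting "bound" becomes a
#' candidate conjunction. Duplicate conjunctions (canonical form) are
#' merged, with `estimator_support` the fraction of trees containing the
#' conjunction.
#'
#' @param features Feature tibble or matrix.
#' @param labels 0/1 binder labels, one per glycan.
#' @param config A [mining_config()].
#' @param depth Tree depth (defaults to `config$max_depth_first`).
#' @param train Optional logical train mask; if missing, a seeded
#'   stratified split is made.
#' @return Tibble: `rule_id`, `conditions` (list column),
#'   `estimator_support`.
#' @export
propose_rules <- function(features, labels, config = mining_config(),
                          depth = config$max_depth_first, train = NULL) {
  X <- if (is.matrix(features)) features else feature_matrix_parts(features)
  labels <- as.integer(labels)
  if (sum(labels == 1L) < 5L || sum(labels == 0L) < 5L) {
    stop("insufficient class balance: need >= 5 bound and >= 5 unbound ",
         "glycans (have ", sum(labels == 1L), " / ", sum(labels == 0L), ")",
         call. = FALSE)
  }
  if (is.null(train)) {
    train <- stratified_split(labels, config$train_fraction, config$seed)
  }
  Xt <- X[train, , drop = FALSE]
  yt <- labels[train]

  paths_by_tree <- withr::with_seed(config$seed + 1L, {
    lapply(seq_len(config$n_estimators), function(b) {
      rows <- sample.int(nrow(Xt), replace = TRUE)
      fit_tree_paths(Xt[rows, , drop = FALSE], yt[rows], depth)
    })
  })

  seen <- new.env(parent = emptyenv())
  for (tree in paths_by_tree) {
    keys_this_tree <- character()
    for (p in tree) {
      tb <- conds_to_tibble(p)
      key <- rule_key(tb)
      if (key %in% keys_this_tree) next  # count each tree once per rule
      keys_this_tree <- c(keys_this_tree, key)
      if (is.null(seen[[key]])) {
        seen[[key]] <- list(conditions = tb, count = 1L)
      } else {
        seen[[key]]$count <- seen[[key]]$count + 1L
      }
    }
  }
  keys <- sort(names(seen), method = "radix")
  tibble::tibble(
    rule_id = keys,
    conditions = lapply(keys, function(k) seen[[k]]$conditions),
    estimator_support = vapply(keys, function(k) seen[[k]]$count,
                               integer(1)) / config$n_estimators
  )
}

#' Precision and recall of a rule
#'
#' Precision is the fraction of rule-satisfying glycans that bind; recall
#' is the fraction of all binders that satisfy the rule.
#'
#' @param conditions Condition tibble (`feature`, `op`, `threshold`).
#' @param features Feature tibble or matrix.
#' @param labels 0/1 binder labels.
#' @return Named numeric vector `c(precision =, recall =)`; precision is
#'   `NA` when no glycan satisfies the rule.
#' @export
evaluate_rule <- function(conditions, features, labels) {
  sat <- rule_satisfied(features, conditions)
  labels <- as.integer(labels)
  tp <- sum(sat & labels == 1L)
  c(precision = if (sum(sat) == 0L) NA_real_ else tp / sum(sat),
    recall = if (sum(labels) == 0L) NA_real_ else tp / sum(labels))
}

#' Filter candidate rules by the validity thresholds
#'
#' Keeps rules with precision >= `min_precision`, recall >= `min_recall`
#' and estimator support >= `min_estimator_support` (all inclusive). Rules
#' with undefined precision (no satisfying glycan in the evaluation set)
#' are dropped.
#'
#' @param candidates Tibble from [propose_rules()] with `precision` and
#'   `recall` columns added.
#' @param config A [mining_config()].
#' @return The filtered tibble.
#' @export
filter_valid <- function(candidates, config = mining_config()) {
  candidates |>
    dplyr::filter(
      !is.na(.data$precision),
      .data$precision >= config$min_precision,
      .data$recall >= config$min_recall,
      .data$estimator_support >= config$min_estimator_support
    )
}

# ---- iterative mining ------------------------------------------------------

#' Mine a multi-level rule set for one lectin
#'
#' Level 1 is the best valid rule over all glycans, mined at depth one and
#' falling back to depth two when no depth-one rule passes the validity
#' filters. Each subsequent level restricts to the glycans satisfying the
#' previous level's rule and must strictly improve precision. When several
#' rules pass the filters at one level, they are recorded as alternatives
#' (`1a`, `1b`, ...); the highest-ranked one defines the subset for the
#' next level. Mining stops when no valid rule is found, when precision
#' reaches `stop_precision`, or after `max_levels` levels.
#'
#' Rules are ranked by precision, then recall, then estimator support, then
#' canonical rule id. Precision/recall are computed on a held-out 20%
#' split; below 25 glycans the full subset is used instead (recorded in the
#' level's `evaluation` field).
#'
#' @param features Feature tibble (from [build_feature_matrix()]) or
#'   matrix.
#' @param labels 0/1 binder labels for one lectin, one per glycan row.
#' @param config A [mining_config()].
#' @param lectin_id Optional identifier carried into the result.
#' @return A `lectin_ruleset`: tibble of levels (`level`, `alternative`,
#'   `rule_id`, `conditions`, `precision`, `recall`, `estimator_support`,
#'   `depth`, `evaluation`), a `stop_reason`, and the config. Use
#'   [tidy()] / [glance()].
#' @export
mine_ruleset <- function(features, labels, config = mining_config(),
                         lectin_id = NA_character_) {
  X <- if (is.matrix(features)) features else feature_matrix_parts(features)
  labels <- as.integer(labels)
  stopifnot(nrow(X) == length(labels))

  rows <- rep(TRUE, nrow(X))
  levels_out <- list()
  prev_precision <- -Inf
  stop_reason <- NULL

  for (lev in seq_len(config$max_levels)) {
    Xs <- X[rows, , drop = FALSE]
    ys <- labels[rows]
    lev_cfg <- config
    lev_cfg$seed <- config$seed + 1000L * lev

    found <- tryCatch(
      mine_one_level(Xs, ys, lev_cfg),
      error = function(e) structure(list(msg = conditionMessage(e)),
                                    class = "mine_stop")
    )
    if (inherits(found, "mine_stop")) {
      stop_reason <- found$msg
      break
    }
    if (is.null(found)) {
      stop_reason <- "no valid rule"
      break
    }
    best <- found$rules[1L, ]
    if (best$precision <= prev_precision) {
      stop_reason <- "no rule improved precision"
      break
    }
    n_alt <- nrow(found$rules)
    alt_tags <- if (n_alt > 1L) letters[seq_len(n_alt)] else NA_character_
    for (a in seq_len(n_alt)) {
      r <- found$rules[a, ]
      levels_out[[length(levels_out) + 1L]] <- tibble::tibble(
        level = lev,
        alternative = alt_tags[a],
        rule_id = r$rule_id,
        conditions = r$conditions,
        precision = unname(r$precision),
        recall = unname(r$recall),
        estimator_support = unname(r$estimator_support),
        depth = found$depth,
        evaluation = found$evaluation
      )
    }
    prev_precision <- best$precision
    rows <- rows & rule_satisfied(X, best$conditions[[1L]])
    if (best$precision >= config$stop_precision) {
      stop_reason <- sprintf("precision %.1f reached", config$stop_precision)
      break
    }
  }
  if (is.null(stop_reason)) stop_reason <- "maximum levels reached"

  structure(
    list(
      lectin_id = lectin_id,
      levels = if (length(levels_out)) dplyr::bind_rows(levels_out) else
        tibble::tibble(level = integer(), alternative = character(),
                       rule_id = character(), conditions = list(),
                       precision = numeric(), recall = numeric(),
                       estimator_support = numeric(), depth = integer(),
                       evaluation = character()),
      stop_reason = stop_reason,
      config = config
    ),
    class = "lectin_ruleset"
  )
}

# One level: propose at first depth, fall back to the deeper depth; rank
# valid rules. Returns NULL when nothing passes.
mine_one_level <- function(X, y, config) {
  small <- nrow(X) < 25L
  train <- if (small) rep(TRUE, nrow(X)) else
    stratified_split(y, config$train_fraction, config$seed)
  evaluation <- if (small) "full set (subset < 25 glycans)" else
    "held-out 20%"
  eval_rows <- if (small) rep(TRUE, nrow(X)) else !train

  for (depth in unique(c(config$max_depth_first, config$max_depth_fallback))) {
    cands <- propose_rules(X, y, config, depth = depth, train = train)
    if (nrow(cands) == 0L) next
    pr <- t(vapply(cands$conditions, evaluate_rule,
                   numeric(2), features = X[eval_rows, , drop = FALSE],
                   labels = y[eval_rows]))
    cands$precision <- unname(pr[, "precision"])
    cands$recall <- unname(pr[, "recall"])
    valid <- filter_valid(cands, config)
    if (nrow(valid) > 0L) {
      valid <- valid[order(-valid$precision, -valid$recall,
                           -valid$estimator_support, valid$rule_id,
                           method = "radix"), ]
      return(list(rules = valid, depth = depth, evaluation = evaluation))
    }
  }
  NULL
}

#' @export
print.lectin_ruleset <- function(x, ...) {
  cat("<lectin_ruleset>",
      if (!is.na(x$lectin_id)) paste0(" ", x$lectin_id), ": ",
      length(unique(x$levels$level)), " level(s); stop: ", x$stop_reason,
      "\n", sep = "")
  if (nrow(x$levels)) {
    lab <- paste0(x$levels$level,
                  ifelse(is.na(x$levels$alternative), "",
                         x$levels$alternative))
    for (i in seq_len(nrow(x$levels))) {
      cat(sprintf("  rule %-3s %s  (precision %.2f, recall %.2f, support %.2f)\n",
                  lab[i], x$levels$rule_id[i], x$levels$precision[i],
                  x$levels$recall[i], x$levels$estimator_support[i]))
    }
  }
  invisible(x)
}

#' Tidy a mined rule set
#' @param x A `lectin_ruleset`.
#' @param ... Unused.
#' @return Tibble of rule levels with precision, recall and support.
#' @export
tidy.lectin_ruleset <- function(x, ...) {
  out <- x$levels
  out$lectin_id <- x$lectin_id
  dplyr::relocate(out, "lectin_id")
}

#' One-row summary of a mined rule set
#' @param x A `lectin_ruleset`.
#' @param ... Unused.
#' @return Tibble: lectin id, number of levels, terminal precision/recall,
#'   stop reason.
#' @export
glance.lectin_ruleset <- function(x, ...) {
  primary <- x$levels[is.na(x$levels$alternative) |
                        x$levels$alternative == "a", ]
  tibble::tibble(
    lectin_id = x$lectin_id,
    n_levels = length(unique(x$levels$level)),
    terminal_precision = if (nrow(primary)) primary$precision[nrow(primary)]
      else NA_real_,
    terminal_recall = if (nrow(primary)) primary$recall[nrow(primary)]
      else NA_real_,
    stop_reason = x$stop_reason
  )
}

#' Serialize rule sets to JSON
#'
#' @param rulesets A `lectin_ruleset` or a (possibly named) list of them.
#' @param path Optional output file; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
ruleset_to_json <- function(rulesets, path = NULL) {
  if (inherits(rulesets, "lectin_ruleset")) rulesets <- list(rulesets)
  payload <- lapply(rulesets, function(rs) {
    list(
      lectin_id = rs$lectin_id,
      stop_reason = rs$stop_reason,
      levels = lapply(seq_len(nrow(rs$levels)), function(i) {
        lv <- rs$levels[i, ]
        list(
          level = lv$level,
          alternative = lv$alternative,
          rule = lv$rule_id,
          conditions = lv$conditions[[1L]],
          precision = lv$precision,
          recall = lv$recall,
          estimator_support = lv$estimator_support,
          depth = lv$depth,
          evaluation = lv$evaluation
        )
      })
    )
  })
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
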