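# Per-lectin annotation: automated bound-vs-unbound feature contrasts
# within the rule-satisfying subset (enhancer / inhibitor candidates),
# binders not covered by any rule (additional motifs), and report assembly
# in the Prefers / Tolerates / Inhibited-by layout.

primary_rule_conditions <- function(ruleset, level = 1L) {
  lv <- ruleset$levels[ruleset$levels$level == level &
                         (is.na(ruleset$levels$alternative) |
                            ruleset$levels$alternative == "a"), ]
  if (nrow(lv) == 0L) return(NULL)
  lv$conditions[[1L]]
}

#' Contrast features between bound and unbound rule-satisfying glycans
#'
#' Restricts to the glycans satisfying the predominant (level-1) rule,
#' then tests each feature's presence against binding in a 2x2 exact test
#' (two-sided Fisher), with Benjamini-Hochberg adjustment across features.
#' Positive direction means the feature is more prevalent among binders
#' (enhancer candidate); negative means more prevalent among non-binders
#' (inhibitor candidate). Features constant within the subset are skipped.
#' This automates the manual "look for features that account for the
#' difference" step and is labelled as such in rendered reports.
#'
#' @param ruleset A `lectin_ruleset` from [mine_ruleset()].
#' @param features Feature tibble or matrix.
#' @param labels 0/1 binder labels aligned with `features` rows.
#' @return Tibble: `feature`, `n_bound_present`, `n_bound`,
#'   `n_unbound_present`, `n_unbound`, `direction`, `p_value`, `q_value`,
#'   ordered by p-value. Empty (with a `note` attribute) when the
#'   rule-satisfying subset has a single class or there is no rule.
#' @export
contrast_features <- function(ruleset, features, labels) {
  X <- if (is.matrix(features)) features else feature_matrix_parts(features)
  labels <- as.integer(labels)
  empty <- tibble::tibble(
    feature = character(), n_bound_present = integer(), n_bound = integer(),
    n_unbound_present = integer(), n_unbound = integer(),
    direction = integer(), p_value = numeric(), q_value = numeric()
  )
  conds <- primary_rule_conditions(ruleset)
  if (is.null(conds)) {
    attr(empty, "note") <- "no rule mined; contrast skipped"
    return(empty)
  }
  sat <- rule_satisfied(X, conds)
  y <- labels[sat]
  Xs <- X[sat, , drop = FALSE]
  if (length(unique(y)) < 2L) {
    attr(empty, "note") <-
      "rule-satisfying subset contains a single class; contrast skipped"
    return(empty)
  }
  pres <- Xs > 0
  keep <- apply(pres, 2L, function(p) length(unique(p)) > 1L)
  if (!any(keep)) {
    attr(empty, "note") <- "no feature varies within the subset"
    return(empty)
  }
  pres <- pres[, keep, drop = FALSE]
  nb <- sum(y == 1L)
  nu <- sum(y == 0L)
  rows <- purrr::map_dfr(colnames(pres), function(f) {
    a <- sum(pres[, f] & y == 1L)   # bound, present
    b <- sum(pres[, f] & y == 0L)   # unbound, present
    p <- stats::fisher.test(
      matrix(c(a, nb - a, b, nu - b), nrow = 2L)
    )$p.value
    tibble::tibble(
      feature = f, n_bound_present = a, n_bound = nb,
      n_unbound_present = b, n_unbound = nu,
      direction = sign(a / nb - b / nu), p_value = p
    )
  })
  rows$q_value <- stats::p.adjust(rows$p_value, method = "BH")
  rows[order(rows$p_value, rows$feature, method = "radix"), ]
}

#' Binders not covered by any mined rule
#'
#' Bound glycans failing every recorded rule (all levels and alternatives)
#' are candidates for additional binding motifs; they are summarized by the
#' features shared by at least `min_share` of the group.
#'
#' @param ruleset A `lectin_ruleset`.
#' @param labels 0/1 binder labels.
#' @param features Feature tibble or matrix.
#' @param min_share Prevalence needed for a feature to count as shared
#'   (default 0.5).
#' @param feature_set Optional character vector restricting which features
#'   are summarized (defaults to the curated catalog names present in the
#'   matrix; falls back to all features).
#' @return List: `glycan_ids` (uncovered binders) and `shared_features`
#'   (tibble `feature`, `prevalence`).
#' @export
uncovered_binders <- function(ruleset, labels, features, min_share = 0.5,
                              feature_set = NULL) {
  X <- if (is.matrix(features)) features else feature_matrix_parts(features)
  labels <- as.integer(labels)
  # a glycan "follows the rules" when it satisfies a level-1 rule (primary
  # or alternative); deeper levels only refine within that subset
  covered <- rep(FALSE, nrow(X))
  lv1 <- ruleset$levels[ruleset$levels$level == 1L, ]
  if (nrow(lv1) > 0L) {
    for (i in seq_len(nrow(lv1))) {
      covered <- covered | rule_satisfied(X, lv1$conditions[[i]])
    }
  }
  unc <- which(labels == 1L & !covered)
  ids <- rownames(X)[unc]
  if (is.null(feature_set)) {
    feature_set <- intersect(default_motif_catalog()$name, colnames(X))
    if (length(feature_set) == 0L) feature_set <- colnames(X)
  }
  if (length(unc) == 0L) {
    return(list(glycan_ids = character(),
                shared_features = tibble::tibble(feature = character(),
                                                 prevalence = numeric())))
  }
  pres <- X[unc, feature_set, drop = FALSE] > 0
  prev <- colMeans(pres)
  shared <- tibble::tibble(feature = names(prev), prevalence = unname(prev)) |>
    dplyr::filter(.data$prevalence >= min_share) |>
    dplyr::arrange(dplyr::desc(.data$prevalence), .data$feature)
  list(glycan_ids = ids, shared_features = shared)
}

#' Assemble a per-lectin annotation report
#'
#' Combines the mined rule levels (the predominant specificity), the
#' feature contrast (enhancer candidates: significantly enriched in
#' binders; inhibitor candidates: significantly enriched in non-binders),
#' tolerated features (common among binders without significant
#' association), and the uncovered-binder summary.
#'
#' @param ruleset A `lectin_ruleset`.
#' @param features Feature tibble or matrix.
#' @param labels 0/1 binder labels.
#' @param q_cutoff BH-adjusted significance cutoff (default 0.05).
#' @param tolerate_prevalence Prevalence among binders above which a
#'   non-significant feature is listed as tolerated (default 0.2).
#' @return A `lectin_report` object.
#' @export
lectin_report <- function(ruleset, features, labels, q_cutoff = 0.05,
                          tolerate_prevalence = 0.2) {
  X <- if (is.matrix(features)) features else feature_matrix_parts(features)
  labels <- as.integer(labels)
  contrasts <- contrast_features(ruleset, X, labels)
  enh <- contrasts[contrasts$q_value < q_cutoff & contrasts$direction > 0, ]
  inh <- contrasts[contrasts$q_value < q_cutoff & contrasts$direction < 0, ]

  binders <- X[labels == 1L, , drop = FALSE]
  tolerated <- tibble::tibble(feature = character(), prevalence = numeric())
  if (nrow(binders) > 0L) {
    prev <- colMeans(binders > 0)
    sig <- contrasts$feature[contrasts$q_value < q_cutoff]
    cur <- intersect(default_motif_catalog()$name, colnames(X))
    if (length(cur) == 0L) cur <- colnames(X)
    tolerated <- tibble::tibble(feature = names(prev),
                                prevalence = unname(prev)) |>
      dplyr::filter(.data$feature %in% cur,
                    .data$prevalence >= tolerate_prevalence,
                    !.data$feature %in% sig) |>
      dplyr::arrange(dplyr::desc(.data$prevalence), .data$feature)
  }

  structure(
    list(
      lectin_id = ruleset$lectin_id,
      ruleset = ruleset,
      contrasts = contrasts,
      prefers = ruleset$levels$rule_id,
      enhancers = enh,
      inhibitors = inh,
      tolerated = tolerated,
      additional = uncovered_binders(ruleset, labels, X)
    ),
    class = "lectin_report"
  )
}

#' @export
print.lectin_report <- function(x, ...) {
  cat(render_report(x, format = "text"), sep = "\n")
  invisible(x)
}

#' Render an annotation report
#'
#' @param report A `lectin_report`.
#' @param format `"text"` (Prefers / Tolerates / Inhibited-by layout) or
#'   `"json"`.
#' @param path Optional output file.
#' @return Character vector of lines (text) or JSON string; invisibly when
#'   written to `path`.
#' @export
render_report <- function(report, format = c("text", "json"), path = NULL) {
  format <- match.arg(format)
  out <- if (format == "json") render_report_json(report) else
    render_report_text(report)
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

render_report_text <- function(x) {
  rs <- x$ruleset
  lines <- c(
    paste0("Lectin: ", if (is.na(x$lectin_id)) "(unnamed)" else x$lectin_id),
    "Predominant binding rules (machine-mined):"
  )
  if (nrow(rs$levels) == 0L) {
    lines <- c(lines, "  no rule found")
  } else {
    lab <- paste0(rs$levels$level,
                  ifelse(is.na(rs$levels$alternative), "",
                         rs$levels$alternative))
    lines <- c(lines, sprintf(
      "  rule %-3s %s  (precision %.2f, recall %.2f, support %.2f)",
      lab, rs$levels$rule_id, rs$levels$precision, rs$levels$recall,
      rs$levels$estimator_support))
  }
  lines <- c(lines, paste0("Stop reason: ", rs$stop_reason), "")
  fmt_feats <- function(tb, col = "feature") {
    if (nrow(tb) == 0L) "  (none)" else paste0("  ", tb[[col]])
  }
  lines <- c(
    lines,
    "Prefers (rule features and enriched-in-binder candidates):",
    fmt_feats(x$enhancers),
    "Tolerates (common among binders, no significant association):",
    fmt_feats(x$tolerated),
    "Inhibited by (enriched among rule-satisfying non-binders):",
    fmt_feats(x$inhibitors),
    "Additional binders not covered by the rules:"
  )
  if (length(x$additional$glycan_ids) == 0L) {
    lines <- c(lines, "  (none)")
  } else {
    lines <- c(
      lines,
      paste0("  ", length(x$additional$glycan_ids), " glycan(s): ",
             paste(x$additional$glycan_ids, collapse = ", ")),
      "  shared features:",
      if (nrow(x$additional$shared_features) == 0L) "    (none)" else
        sprintf("    %s (%.0f%%)", x$additional$shared_features$feature,
                100 * x$additional$shared_features$prevalence)
    )
  }
  c(lines,
    "",
    paste0("Note: enhancer/inhibitor candidates come from an automated ",
           "two-sided exact feature contrast (BH-adjusted), not expert ",
           "curation."))
}

render_report_json <- function(x) {
  rs <- x$ruleset
  payload <- list(
    schema_version = "1.0",
    lectin_id = x$lectin_id,
    rules = lapply(seq_len(nrow(rs$levels)), function(i) {
      lv <- rs$levels[i, ]
      list(level = lv$level, alternative = lv$alternative,
           rule = lv$rule_id, conditions = lv$conditions[[1L]],
           precision = lv$precision, recall = lv$recall,
           estimator_support = lv$estimator_support)
    }),
    stop_reason = rs$stop_reason,
    prefers = x$enhancers,
    tolerates = x$tolerated,
    inhibited_by = x$inhibitors,
    additional_binders = list(
      glycan_ids = x$additional$glycan_ids,
      shared_features = x$additional$shared_features
    ),
    method_note = paste0("enhancer/inhibitor candidates from automated ",
                         "two-sided exact feature contrast, BH-adjusted")
  )
  as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE, na = "null"))
}
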