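# A tiny deterministic setting: rule "A >= 0.5" mined beforehand; within
# the A-satisfying subset, binding is blocked exactly by feature I.
toy_ruleset <- function(features, labels, seed = 1) {
  mine_ruleset(features, labels, mining_config(seed = seed))
}

toy_contrast_data <- function(n = 60, seed = 2) {
  withr::with_seed(seed, {
    A <- rbinom(n, 1, 0.6)
    I <- rbinom(n, 1, 0.4)
    noise <- matrix(rpois(n * 4, 1), n, 4,
                    dimnames = list(NULL, paste0("x", 1:4)))
    X <- cbind(A = A, I = I, noise)
    rownames(X) <- paste0("g", 1:n)
    labels <- as.integer(A == 1 & I == 0)
    list(X = X, labels = labels)
  })
}

test_that("contrast counts are re-derivable and the inhibitor ranks first", {
  d <- toy_contrast_data()
  rs <- toy_ruleset(d$X, d$labels)
  expect_equal(rs$levels$rule_id[1], "A >= 0.5")
  ct <- contrast_features(rs, d$X, d$labels)
  expect_equal(ct$feature[1], "I")
  expect_equal(ct$direction[1], -1)
  expect_lt(ct$q_value[1], 0.05)
  # brute-force recount of the top row
  sat <- d$X[, "A"] >= 0.5
  y <- d$labels[sat]
  pres <- d$X[sat, "I"] > 0
  expect_equal(ct$n_bound_present[1], sum(pres & y == 1))
  expect_equal(ct$n_unbound_present[1], sum(pres & y == 0))
  expect_equal(ct$n_bound[1], sum(y))
  expect_equal(ct$n_unbound[1], sum(y == 0))
  # q-values are monotone in p-values
  expect_true(all(diff(ct$q_value[order(ct$p_value)]) >= -1e-12))
  # the rule feature itself is constant within the subset -> not tested
  expect_false("A" %in% ct$feature)
})

test_that("contrast on permuted labels finds nothing significant", {
  d <- toy_contrast_data(n = 120, seed = 5)
  rs <- toy_ruleset(d$X, d$labels)
  clean <- 0L
  withr::with_seed(11, {
    for (i in 1:10) {
      perm <- sample(d$labels)
      ct <- tryCatch(contrast_features(rs, d$X, perm),
                     error = function(e) NULL)
      n_sig <- if (is.null(ct) || nrow(ct) == 0L) 0L else
        sum(ct$q_value < 0.05)
      if (n_sig == 0L) clean <- clean + 1L
    }
  })
  expect_gte(clean, 9L)
})

test_that("single-class subsets give an empty, annotated contrast", {
  d <- toy_contrast_data()
  rs <- toy_ruleset(d$X, d$labels)
  all_bound <- rep(1L, length(d$labels))
  all_bound[d$X[, "A"] < 0.5] <- 0L  # within subset: single class
  ct <- contrast_features(rs, d$X, all_bound)
  expect_equal(nrow(ct), 0L)
  expect_match(attr(ct, "note"), "single class")
})

# hand-built single-rule ruleset, so coverage semantics are tested in
# isolation from the miner's alternative-rule bookkeeping
manual_ruleset <- function(feature = "A") {
  structure(list(
    lectin_id = "TOY",
    levels = tibble::tibble(
      level = 1L, alternative = NA_character_,
      rule_id = paste(feature, ">= 0.5"),
      conditions = list(tibble::tibble(feature = feature, op = ">=",
                                       threshold = 0.5)),
      precision = 1, recall = 1, estimator_support = 1, depth = 1L,
      evaluation = "full set"),
    stop_reason = "precision 1.0 reached",
    config = mining_config()
  ), class = "lectin_ruleset")
}

test_that("uncovered binders are grouped by their shared features", {
  d <- toy_contrast_data()
  rs <- manual_ruleset("A")
  # all binders satisfy the rule -> empty list
  unc <- uncovered_binders(rs, d$labels, d$X, feature_set = colnames(d$X))
  expect_length(unc$glycan_ids, 0L)

  # plant a secondary motif: 10 extra binders, all carrying feature S
  X2 <- cbind(d$X, S = 0)
  extra <- which(d$X[, "A"] == 0)[1:10]
  X2[extra, "S"] <- 1
  labels2 <- d$labels
  labels2[extra] <- 1L
  unc2 <- uncovered_binders(rs, labels2, X2, feature_set = colnames(X2))
  expect_setequal(unc2$glycan_ids, rownames(X2)[extra])
  expect_true("S" %in% unc2$shared_features$feature)
  expect_equal(
    unc2$shared_features$prevalence[unc2$shared_features$feature == "S"], 1)

  # a single uncovered binder lists its full feature set
  labels3 <- d$labels
  lone <- which(d$X[, "A"] == 0)[1]
  labels3[lone] <- 1L
  unc3 <- uncovered_binders(rs, labels3, d$X, feature_set = colnames(d$X))
  expect_equal(unc3$glycan_ids, rownames(d$X)[lone])
  expect_setequal(unc3$shared_features$feature,
                  colnames(d$X)[d$X[lone, ] > 0])
})

test_that("reports render deterministically in both formats", {
  d <- toy_contrast_data()
  rs <- toy_ruleset(d$X, d$labels)
  rep1 <- lectin_report(rs, d$X, d$labels)
  rep2 <- lectin_report(rs, d$X, d$labels)
  expect_identical(render_report(rep1, "text"), render_report(rep2, "text"))
  expect_identical(render_report(rep1, "json"), render_report(rep2, "json"))
  txt <- render_report(rep1, "text")
  expect_true(any(grepl(rs$stop_reason, txt, fixed = TRUE)))
  expect_true(any(grepl("Inhibited by", txt)))
  parsed <- jsonlite::fromJSON(render_report(rep1, "json"))
  expect_equal(parsed$schema_version, "1.0")
  expect_equal(parsed$inhibited_by$feature[1], "I")

  # lectin with no rule: explicit stanza
  flat <- matrix(rbinom(200, 1, 0.5), 20, 10,
                 dimnames = list(paste0("g", 1:20), paste0("f", 1:10)))
  rs0 <- structure(list(lectin_id = "EMPTY",
                        levels = rs$levels[0, ],
                        stop_reason = "no valid rule",
                        config = mining_config()),
                   class = "lectin_ruleset")
  rep0 <- lectin_report(rs0, flat, rbinom(20, 1, 0.5))
  expect_true(any(grepl("no rule found", render_report(rep0, "text"))))
})
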