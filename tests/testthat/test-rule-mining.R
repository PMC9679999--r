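make_features <- function(X) {
  tibble::tibble(glycan_id = paste0("g", seq_len(nrow(X)))) |>
    dplyr::bind_cols(tibble::as_tibble(X))
}

test_that("rule precision and recall count as defined", {
  # 10 satisfy, 8 of them bind, 40 bound in total
  n <- 100
  X <- matrix(0, n, 2, dimnames = list(NULL, c("A", "B")))
  X[1:10, "A"] <- 1
  labels <- integer(n)
  labels[1:8] <- 1L
  labels[11:42] <- 1L      # 8 + 32 = 40 bound
  conds <- tibble::tibble(feature = "A", op = ">=", threshold = 0.5)
  pr <- evaluate_rule(conds, make_features(X), labels)
  expect_equal(unname(pr["precision"]), 0.8)
  expect_equal(unname(pr["recall"]), 0.2)

  # rule that is always TRUE: precision = base rate, recall = 1
  always <- tibble::tibble(feature = "A", op = ">=", threshold = -1)
  pr2 <- evaluate_rule(always, make_features(X), labels)
  expect_equal(unname(pr2["precision"]), 0.4)
  expect_equal(unname(pr2["recall"]), 1)

  # perfect rule
  X2 <- X
  labels2 <- as.integer(X2[, "A"] >= 0.5)
  pr3 <- evaluate_rule(conds, make_features(X2), labels2)
  expect_equal(unname(pr3), c(1, 1))

  # unsatisfiable rule -> undefined precision
  none <- tibble::tibble(feature = "A", op = ">=", threshold = 99)
  expect_true(is.na(evaluate_rule(none, make_features(X), labels)["precision"]))
})

test_that("evaluate_rule matches brute-force counting on random fixtures", {
  withr::with_seed(42, {
    for (i in 1:30) {
      n <- sample(10:50, 1)
      p <- sample(3:8, 1)
      X <- matrix(rpois(n * p, 1), n, p,
                  dimnames = list(paste0("g", 1:n), paste0("f", 1:p)))
      labels <- rbinom(n, 1, 0.4)
      k <- sample(1:2, 1)
      conds <- tibble::tibble(
        feature = sample(colnames(X), k),
        op = sample(c(">=", "<"), k, replace = TRUE),
        threshold = sample(c(0.5, 1.5, 2.5), k, replace = TRUE)
      )
      expect_identical(evaluate_rule(conds, X, labels),
                       bf_evaluate_rule(conds, X, labels))
    }
  })
})

test_that("validity filtering is inclusive at every boundary", {
  cand <- tibble::tibble(
    rule_id = c("at", "p_low", "s_low", "r_low"),
    conditions = replicate(4, tibble::tibble(), simplify = FALSE),
    estimator_support = c(0.15, 0.5, 0.14, 0.5),
    precision = c(0.30, 0.29, 0.9, 0.9),
    recall = c(0.10, 0.5, 0.5, 0.09)
  )
  kept <- filter_valid(cand, mining_config())
  expect_equal(kept$rule_id, "at")
})

test_that("a perfectly predictive feature is proposed with high support", {
  withr::with_seed(7, {
    n <- 200
    X <- matrix(rpois(n * 10, 1), n, 10,
                dimnames = list(paste0("g", 1:n), paste0("f", 1:10)))
    X[, "f3"] <- rbinom(n, 1, 0.4)
    labels <- X[, "f3"]
    X[, "f9"] <- 5  # constant column: can never split
    hits <- 0L
    for (s in 1:10) {
      cands <- propose_rules(X, labels, mining_config(seed = s))
      top <- cands[grepl("^f3 >= ", cands$rule_id), ]
      if (nrow(top) == 1L && top$estimator_support >= 0.9) hits <- hits + 1L
      expect_false(any(grepl("f9", cands$rule_id)))
    }
    expect_gte(hits, 9L)
  })
})

test_that("permuted labels yield no valid rule in most seeds", {
  withr::with_seed(13, {
    n <- 200
    X <- matrix(rpois(n * 10, 1), n, 10,
                dimnames = list(paste0("g", 1:n), paste0("f", 1:10)))
    labels <- rbinom(n, 1, 0.1)
    clean <- 0L
    for (s in 1:10) {
      perm <- sample(labels)
      rs <- mine_ruleset(X, perm, mining_config(seed = s))
      if (nrow(rs$levels) == 0L) clean <- clean + 1L
    }
    expect_gte(clean, 9L)
  })
})

test_that("mining errors on degenerate label sets", {
  X <- matrix(rpois(200, 1), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("f", 1:10)))
  expect_error(propose_rules(X, rep(1L, 20), mining_config()),
               "class balance")
  expect_error(propose_rules(X, c(rep(1L, 16), rep(0L, 4)), mining_config()),
               "class balance")
})

test_that("mining is deterministic under a fixed seed", {
  lec <- lacnac_sia_inhibited_lectin()
  exp1 <- make_panel_experiment(21, c(list(lec), decoy_lectins()), cv = 0.1)
  zs <- process_scans(exp1$scans)
  feats <- aligned_features(zs, exp1$graphs)
  y <- zs$labels[, lec$name]
  rs1 <- mine_ruleset(feats, y, mining_config(seed = 5), lectin_id = "L")
  rs2 <- mine_ruleset(feats, y, mining_config(seed = 5), lectin_id = "L")
  expect_identical(tidy(rs1), tidy(rs2))
  expect_identical(rs1$stop_reason, rs2$stop_reason)
})

test_that("accepted level precisions increase strictly", {
  lec <- lacnac_sia_inhibited_lectin()
  for (s in c(31, 32)) {
    ex <- make_panel_experiment(s, c(list(lec), decoy_lectins()), cv = 0.1)
    zs <- process_scans(ex$scans)
    feats <- aligned_features(zs, ex$graphs)
    rs <- mine_ruleset(feats, zs$labels[, lec$name],
                       mining_config(seed = s))
    primary <- rs$levels[is.na(rs$levels$alternative) |
                           rs$levels$alternative == "a", ]
    if (nrow(primary) > 1L) {
      expect_true(all(diff(primary$precision) > 0))
    }
    expect_gte(nrow(primary), 1L)
  }
})

test_that("thresholds on count features sit between observed values", {
  withr::with_seed(3, {
    n <- 120
    X <- matrix(rpois(n * 5, 2), n, 5,
                dimnames = list(paste0("g", 1:n), paste0("f", 1:5)))
    labels <- as.integer(X[, "f1"] >= 2)
    cands <- propose_rules(X, labels, mining_config(seed = 1))
    thr <- unlist(lapply(cands$conditions, function(cd) cd$threshold))
    expect_true(all(thr %% 1 == 0.5))
  })
})
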