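test_that("trimmed spot average drops exactly one high and one low value", {
  expect_equal(robust_spot_average(c(100, 200, 300, 400, 500, 600)), 350)
  expect_equal(robust_spot_average(c(5, 5, 5, 5, 5, 5)), 5)
  expect_equal(robust_spot_average(c(0, 0, 0, 0, 0, 10000)), 0)
  expect_equal(robust_spot_average(c(1, 2, 3, 4)), 2.5)
  expect_error(robust_spot_average(c(1, 2, 3)), "4")
  expect_error(robust_spot_average(c(1, 2, 3, NA, 5, 6)))
})

test_that("per-array Z-scores use the sample SD and demand spread", {
  z <- zscore_array(c(0, 0, 0, 0, 10))
  expect_equal(unname(z[5]), (10 - 2) / sd(c(0, 0, 0, 0, 10)))
  expect_equal(unname(z[5]), 1.7889, tolerance = 1e-4)
  expect_equal(sum(z), 0, tolerance = 1e-12)
  expect_error(zscore_array(rep(7, 10)), "spread|degenerate")
  expect_error(zscore_array(c(1, 2)), "3")
})

test_that("low-signal arrays and inactive lectins are excluded as specified", {
  mk <- function(lectin, conc, peak) {
    tibble::tibble(glycan_id = paste0("g", 1:5), lectin_id = lectin,
                   concentration = conc, rfu = c(10, 20, 30, 40, peak))
  }
  averaged <- dplyr::bind_rows(
    mk("weak", 1, 3999), mk("weak", 10, 3999),
    mk("good", 1, 5000), mk("good", 10, 2000), mk("good", 0.1, 999),
    mk("single", 1, 4500)
  )
  ex <- exclude_low_signal(averaged)
  # best glycan below 4000 at every concentration -> lectin excluded
  expect_true("weak" %in% ex$excluded_lectins$lectin_id)
  # sub-1000 array dropped, lectin kept with two surviving arrays
  expect_true(any(ex$dropped_arrays$lectin_id == "good" &
                    ex$dropped_arrays$concentration == 0.1))
  expect_false("good" %in% ex$excluded_lectins$lectin_id)
  expect_setequal(unique(ex$kept$concentration[ex$kept$lectin_id == "good"]),
                  c(1, 10))
  # only one surviving array -> excluded even though it reaches 4000
  expect_true("single" %in% ex$excluded_lectins$lectin_id)
})

test_that("Stouffer combination matches the scalar oracle and its identities", {
  expect_equal(unname(stouffer_combine(list(c(g = 2.5)))), 2.5)
  z4 <- replicate(4, c(a = 3, b = -1), simplify = FALSE)
  expect_equal(stouffer_combine(z4), c(a = 6, b = -2))
  expect_equal(unname(stouffer_combine(list(c(g = 2), c(g = -2)))["g"]), 0)
  expect_error(stouffer_combine(list(c(a = 1), c(b = 1))), "differ")

  withr::with_seed(99, {
    for (i in 1:25) {
      k <- sample(2:6, 1)
      ids <- paste0("g", 1:20)
      zl <- lapply(seq_len(k), function(j)
        stats::setNames(rnorm(20), ids)[sample(ids)])
      expect_lt(max(abs(stouffer_combine(zl)[ids] - bf_stouffer(zl)[ids])),
                1e-12)
    }
  })
})

test_that("nonvarying glycans are averaged and weak ones flagged nonspecific", {
  ids <- paste0("g", 1:6)
  # g1: above threshold, signal flat across concentrations and weak at the
  #     top concentration -> nonspecific
  # g2: above threshold, flat but strong signal -> nonvarying only
  # g3: above threshold with a saturating (varying) signal -> untouched
  z_list <- list(
    stats::setNames(c(3.0, 3.0, 1.0, 0, -1, -2), ids),
    stats::setNames(c(3.0, 3.0, 3.0, 0, -1, -2), ids),
    stats::setNames(c(3.0, 3.0, 5.0, 0, -1, -2), ids),
    stats::setNames(c(3.0, 3.0, 7.0, 0, -1, -2), ids)
  )
  rfu_list <- list(
    stats::setNames(c(500, 9000, 800, 210, 190, 200), ids),
    stats::setNames(c(500, 9000, 3000, 200, 200, 200), ids),
    stats::setNames(c(500, 9000, 7000, 190, 210, 200), ids),
    stats::setNames(c(500, 9000, 9500, 200, 200, 200), ids)
  )
  zs <- stouffer_combine(z_list)
  fl <- flag_nonvarying(zs, z_list, rfu_list)
  expect_true(fl$flags$nonvarying[1])
  expect_true(fl$flags$nonspecific[1])   # 500 < 10% of 9500
  expect_true(fl$flags$nonvarying[2])
  expect_false(fl$flags$nonspecific[2])  # flat but strong
  expect_false(fl$flags$nonvarying[3])   # saturating curve
  # below-threshold glycans are never flagged however flat they are
  expect_false(any(fl$flags$nonvarying[4:6]))
  # flagged rows are replaced by the plain across-concentration mean Z
  expect_equal(unname(fl$zs["g1"]), 3)
  expect_equal(unname(fl$zs["g2"]), 3)
  expect_equal(unname(fl$zs["g3"]), unname(zs["g3"]))
})

test_that("variance exactly at the fraction cut is not flagged (strict <)", {
  ids <- c("hi", "ref", "low")
  # RFU variance of "hi" is 1 and of "ref" is 4 (the maximum); with a
  # fraction of 0.25 the cutoff is exactly 1.0 in floating point, so the
  # strict inequality must leave "hi" unflagged
  z_list <- list(
    stats::setNames(c(4, 2, 0), ids),
    stats::setNames(c(5, 2, 0), ids),
    stats::setNames(c(6, 2, 0), ids)
  )
  rfu_list <- list(
    stats::setNames(c(4, -1, 0), ids),
    stats::setNames(c(5, 1, 0), ids),
    stats::setNames(c(6, 3, 0), ids)
  )
  expect_equal(var(c(4, 5, 6)), 1)
  expect_equal(var(c(-1, 1, 3)), 4)
  zs <- stouffer_combine(z_list)
  fl <- flag_nonvarying(zs, z_list, rfu_list, var_frac = 0.25)
  expect_false(fl$flags$nonvarying[match("hi", fl$flags$glycan_id)])
  # just above the cut it is flagged
  fl2 <- flag_nonvarying(zs, z_list, rfu_list, var_frac = 0.26)
  expect_true(fl2$flags$nonvarying[match("hi", fl2$flags$glycan_id)])
})

test_that("background subtraction centers every glycan across lectins", {
  m <- rbind(c(4, 0, 0, 0), c(2, 2, 2, 2), c(1, 3, -1, 1))
  rownames(m) <- paste0("g", 1:3)
  colnames(m) <- paste0("l", 1:4)
  p <- subtract_background(m)
  expect_equal(unname(p[1, ]), c(3, -1, -1, -1))
  expect_equal(unname(p[2, ]), rep(0, 4))
  expect_equal(max(abs(rowSums(p))), 0, tolerance = 1e-12)
  expect_error(subtract_background(m[, 1, drop = FALSE]), "2 lectins")
})

test_that("binder calls are inclusive at the threshold and respect flags", {
  m <- matrix(c(1.645, 1.644, 3.0, 0), 2, 2,
              dimnames = list(c("a", "b"), c("x", "y")))
  ns <- matrix(c(FALSE, FALSE, TRUE, FALSE), 2, 2)
  lab <- call_binders(m, ns)
  expect_equal(lab["a", "x"], 1L)
  expect_equal(lab["b", "x"], 0L)
  expect_equal(lab["a", "y"], 0L)  # nonspecific wins over a 3.0 score
  expect_equal(drop_never_bound_glycans(lab), "a")
})

test_that("glycan row order never changes any score", {
  lec <- lacnac_lectin()
  exp1 <- make_panel_experiment(3, c(list(lec), decoy_lectins()), cv = 0.1)
  zs1 <- process_scans(exp1$scans)
  shuffled <- withr::with_seed(1, exp1$scans[sample(nrow(exp1$scans)), ])
  zs2 <- process_scans(shuffled)
  expect_identical(zs1$zs, zs2$zs)
  expect_identical(zs1$labels, zs2$labels)
})
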