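# From raw replicate spot fluorescence to combined, background-corrected
# Z-scores and binder labels.
#
# Stage order is fixed: trimmed spot average -> per-array Z-score ->
# array/lectin exclusion -> Stouffer combination -> nonvarying/nonspecific
# flags -> background subtraction -> binder call -> drop never-bound glycans.

#' One-tailed binding threshold on the Z scale
#'
#' The combined Z-score above which a glycan is called bound: the standard
#' normal quantile at one-tailed `p`. At the default `p = 0.05` this is
#' 1.645, i.e. a 95% one-sided confidence bound under the assumption that
#' most glycans on the array are unbound.
#'
#' @param p One-tailed tail probability (default 0.05).
#' @return The Z threshold.
#' @export
#' @examples
#' binding_threshold() # 1.645
binding_threshold <- function(p = 0.05) {
  stopifnot(is.numeric(p), p > 0, p < 1)
  stats::qnorm(1 - p)
}

#' Trimmed spot average
#'
#' The robust per-glycan fluorescence: the mean of the replicate spots
#' after removing exactly one maximal and one minimal value (the standard
#' 6-spot array readout reduces to an average of 4).
#'
#' @param spots Numeric vector of at least 4 finite RFU values.
#' @return The trimmed mean.
#' @export
#' @examples
#' robust_spot_average(c(100, 200, 300, 400, 500, 600)) # 350
robust_spot_average <- function(spots) {
  spots <- as.numeric(spots)
  if (length(spots) < 4L || anyNA(spots) || any(!is.finite(spots))) {
    stop("need at least 4 finite spot values", call. = FALSE)
  }
  drop_hi <- which.max(spots)
  spots <- spots[-drop_hi]
  drop_lo <- which.min(spots)
  mean(spots[-drop_lo])
}

#' Average replicate spots across a long-format scan table
#'
#' @param scans Tibble with columns `glycan_id`, `lectin_id`,
#'   `concentration`, and spot columns `spot1`, `spot2`, ... (>= 4).
#' @return Tibble with columns `glycan_id`, `lectin_id`, `concentration`,
#'   `rfu`.
#' @export
average_spots <- function(scans) {
  spot_cols <- grep("^spot[0-9]+$", names(scans), value = TRUE)
  if (length(spot_cols) < 4L) {
    stop("scan table needs at least 4 spot columns (spot1...)", call. = FALSE)
  }
  need <- c("glycan_id", "lectin_id", "concentration")
  if (!all(need %in% names(scans))) {
    stop("scan table missing columns: ",
         paste(setdiff(need, names(scans)), collapse = ", "), call. = FALSE)
  }
  sp <- as.matrix(scans[, spot_cols])
  rfu <- apply(sp, 1L, robust_spot_average)
  dplyr::tibble(
    glycan_id = scans$glycan_id,
    lectin_id = scans$lectin_id,
    concentration = scans$concentration,
    rfu = rfu
  )
}

#' Z-score one array
#'
#' Standardizes the averaged fluorescence of one array (one lectin at one
#' concentration) across glycans: `Z = (RFU - mean) / sd`, with the sample
#' (n-1) standard deviation. Valid under the assumption that most glycans
#' are unbound, so the array mean reflects no true binding.
#'
#' @param rfu Named numeric vector of per-glycan averaged RFUs (>= 3).
#' @return Named numeric vector of Z-scores.
#' @export
zscore_array <- function(rfu) {
  vals <- as.numeric(rfu)
  if (length(vals) < 3L) stop("need >= 3 glycans to Z-score", call. = FALSE)
  s <- stats::sd(vals)
  if (!is.finite(s) || s == 0) {
    stop("degenerate array: zero spread across glycans", call. = FALSE)
  }
  (vals - mean(vals)) / s
}

#' Exclude low-signal arrays and lectins
#'
#' Applies the screening filters: individual arrays whose highest averaged
#' signal is below `min_array_rfu` (default 1000 RFU) are dropped; lectins
#' that never reach `min_max_rfu` (default 4000 RFU) for any glycan at any
#' concentration, or are left with fewer than two surviving arrays, are
#' excluded entirely.
#'
#' @param averaged Tibble from [average_spots()].
#' @param min_array_rfu Per-array maximum-signal floor (default 1000).
#' @param min_max_rfu Per-lectin activity floor (default 4000).
#' @return A list with `kept` (filtered tibble), `dropped_arrays`,
#'   `excluded_lectins` (tibbles with a `reason` column).
#' @export
exclude_low_signal <- function(averaged, min_array_rfu = 1000,
                               min_max_rfu = 4000) {
  arr <- averaged |>
    dplyr::group_by(.data$lectin_id, .data$concentration) |>
    dplyr::summarise(max_rfu = max(.data$rfu), .groups = "drop")
  dropped_arrays <- arr |>
    dplyr::filter(.data$max_rfu < min_array_rfu) |>
    dplyr::mutate(reason = paste0("array max RFU < ", min_array_rfu))

  lect <- averaged |>
    dplyr::group_by(.data$lectin_id) |>
    dplyr::summarise(peak_rfu = max(.data$rfu), .groups = "drop")
  surviving <- arr |>
    dplyr::filter(.data$max_rfu >= min_array_rfu) |>
    dplyr::count(.data$lectin_id, name = "n_arrays")

  low_activity <- lect$lectin_id[lect$peak_rfu < min_max_rfu]
  few_arrays <- setdiff(
    unique(averaged$lectin_id),
    surviving$lectin_id[surviving$n_arrays >= 2L]
  )
  excluded_lectins <- dplyr::bind_rows(
    tibble::tibble(lectin_id = low_activity,
                   reason = paste0("no glycan >= ", min_max_rfu, " RFU")),
    tibble::tibble(lectin_id = setdiff(few_arrays, low_activity),
                   reason = paste0("<= 1 array with max RFU >= ",
                                   min_array_rfu))
  )

  kept <- averaged |>
    dplyr::anti_join(dropped_arrays[, c("lectin_id", "concentration")],
                     by = c("lectin_id", "concentration")) |>
    dplyr::filter(!.data$lectin_id %in% excluded_lectins$lectin_id)
  list(kept = kept, dropped_arrays = dropped_arrays,
       excluded_lectins = excluded_lectins)
}

#' Stouffer combination of per-concentration Z-scores
#'
#' The combined score for one lectin: per-glycan Z-scores across the
#' concentration series are summed and divided by the square root of the
#' number of concentrations.
#'
#' @param z_by_concentration List of named numeric vectors (one per
#'   concentration; identical glycan sets).
#' @return Named numeric vector of combined Z-scores.
#' @export
#' @examples
#' stouffer_combine(list(c(g1 = 3), c(g1 = 3), c(g1 = 3), c(g1 = 3))) # 6
stouffer_combine <- function(z_by_concentration) {
  stopifnot(length(z_by_concentration) >= 1L)
  ref <- names(z_by_concentration[[1L]])
  if (is.null(ref)) stop("Z vectors must be named by glycan id", call. = FALSE)
  for (z in z_by_concentration) {
    if (!identical(sort(names(z)), sort(ref))) {
      stop("glycan sets differ across concentrations", call. = FALSE)
    }
  }
  mat <- vapply(z_by_concentration, function(z) z[ref],
                numeric(length(ref)))
  mat <- matrix(mat, nrow = length(ref),
                dimnames = list(ref, NULL))
  rowSums(mat) / sqrt(length(z_by_concentration))
}

#' Flag nonvarying and nonspecific binders for one lectin
#'
#' A glycan that meets the combined-Z threshold but whose fluorescence
#' barely changes across the concentration series is suspect: a genuine
#' binder follows a saturation curve, while nonspecific sticking gives the
#' same signal at every probe concentration. Glycans whose
#' across-concentration RFU variance is below `var_frac` of the largest
#' such variance for that lectin have their combined score replaced by the
#' plain across-concentration average Z and are flagged `nonvarying`. If
#' such a glycan additionally sits below `signal_frac` of the maximum
#' signal on the top-concentration array it is flagged `nonspecific` and
#' will never be called a binder.
#'
#' @param zs Named combined Z vector for one lectin.
#' @param z_by_concentration List of per-concentration Z vectors (the input
#'   to [stouffer_combine()]).
#' @param rfu_by_concentration List of per-concentration averaged RFU
#'   vectors, same order and glycan sets; the last element is the highest
#'   concentration.
#' @param threshold Combined-Z binding threshold.
#' @param var_frac Variance fraction cutoff (strict `<`, default 0.10).
#' @param signal_frac Top-signal fraction cutoff (strict `<`, default 0.10).
#' @return List with `zs` (adjusted vector) and `flags` (tibble
#'   `glycan_id`, `nonvarying`, `nonspecific`).
#' @export
flag_nonvarying <- function(zs, z_by_concentration, rfu_by_concentration,
                            threshold = binding_threshold(),
                            var_frac = 0.10, signal_frac = 0.10) {
  ids <- names(zs)
  zmat <- vapply(z_by_concentration, function(z) z[ids], numeric(length(ids)))
  zmat <- matrix(zmat, nrow = length(ids), dimnames = list(ids, NULL))
  rmat <- vapply(rfu_by_concentration, function(r) r[ids],
                 numeric(length(ids)))
  rmat <- matrix(rmat, nrow = length(ids), dimnames = list(ids, NULL))
  if (ncol(zmat) < 2L) {
    return(list(zs = zs, flags = tibble::tibble(
      glycan_id = ids, nonvarying = FALSE, nonspecific = FALSE)))
  }
  v <- apply(rmat, 1L, stats::var)
  max_var <- max(v)
  top_rfu <- rmat[, ncol(rmat)]
  nonvarying <- zs >= threshold & v < var_frac * max_var
  nonspecific <- nonvarying &
    (top_rfu < signal_frac * max(top_rfu, na.rm = TRUE))
  zs[nonvarying] <- rowMeans(zmat)[nonvarying]
  list(
    zs = zs,
    flags = tibble::tibble(glycan_id = ids,
                           nonvarying = unname(nonvarying),
                           nonspecific = unname(nonspecific))
  )
}

#' Background-correct a combined Z matrix
#'
#' For each glycan, subtracts its average combined Z across all lectins, so
#' promiscuous background binding cancels; each corrected row sums to zero.
#'
#' @param zs Glycans-by-lectins numeric matrix of combined Z-scores.
#' @return Corrected matrix of the same shape.
#' @export
subtract_background <- function(zs) {
  stopifnot(is.matrix(zs))
  if (ncol(zs) < 2L) {
    stop("background subtraction needs >= 2 lectins", call. = FALSE)
  }
  sweep(zs, 1L, rowMeans(zs))
}

#' Call binders from a processed Z matrix
#'
#' Label 1 where the background-corrected combined Z meets the threshold
#' (inclusive) and the cell is not flagged nonspecific.
#'
#' @param processed Glycans-by-lectins corrected Z matrix.
#' @param nonspecific Logical matrix of the same shape (optional).
#' @param threshold Binding threshold (default [binding_threshold()]).
#' @return Integer 0/1 matrix.
#' @export
call_binders <- function(processed, nonspecific = NULL,
                         threshold = binding_threshold()) {
  lab <- (processed >= threshold) * 1L
  if (!is.null(nonspecific)) {
    stopifnot(identical(dim(nonspecific), dim(processed)))
    lab[nonspecific] <- 0L
  }
  storage.mode(lab) <- "integer"
  lab
}

#' Drop glycans never called bound
#'
#' @param labels Glycans-by-lectins 0/1 matrix.
#' @return Character vector of glycan ids with at least one binder call.
#' @export
drop_never_bound_glycans <- function(labels) {
  rownames(labels)[rowSums(labels) > 0L]
}

# ---- end-to-end processing -------------------------------------------------

#' Process raw array scans into combined Z-scores and binder labels
#'
#' Runs the full scoring pipeline on a long-format scan table: trimmed spot
#' averages, per-array Z-scores, low-signal array and lectin exclusion,
#' Stouffer combination across concentrations, nonvarying/nonspecific
#' flagging, background subtraction across lectins, binder calling, and
#' removal of glycans never bound by any lectin.
#'
#' @param scans Long tibble: `glycan_id`, `lectin_id`, `concentration`,
#'   `spot1...spotN` (N >= 4).
#' @param threshold Combined-Z binding threshold (default 1.645, one-tailed
#'   p = 0.05).
#' @param min_array_rfu,min_max_rfu Exclusion floors; see
#'   [exclude_low_signal()].
#' @param var_frac,signal_frac Nonvarying/nonspecific fractions; see
#'   [flag_nonvarying()].
#' @return A `zs_result` object: matrices `zs`, `processed`, `labels`
#'   (glycans kept after the never-bound drop), logical matrices
#'   `nonvarying`, `nonspecific`, and a `qc` list describing every
#'   exclusion. Use [tidy()] / [glance()] to get tibbles.
#' @export
process_scans <- function(scans, threshold = binding_threshold(),
                          min_array_rfu = 1000, min_max_rfu = 4000,
                          var_frac = 0.10, signal_frac = 0.10) {
  averaged <- average_spots(scans)
  excl <- exclude_low_signal(averaged, min_array_rfu = min_array_rfu,
                             min_max_rfu = min_max_rfu)
  kept <- excl$kept
  if (nrow(kept) == 0L) {
    stop("no arrays survive the exclusion filters", call. = FALSE)
  }
  glycans <- sort(unique(kept$glycan_id), method = "radix")
  lectins <- sort(unique(kept$lectin_id), method = "radix")

  zs <- matrix(NA_real_, length(glycans), length(lectins),
               dimnames = list(glycans, lectins))
  nonvarying <- nonspecific <- matrix(FALSE, length(glycans), length(lectins),
                                      dimnames = list(glycans, lectins))
  for (l in lectins) {
    sub <- kept[kept$lectin_id == l, ]
    concs <- sort(unique(sub$concentration))
    z_list <- lapply(concs, function(cc) {
      a <- sub[sub$concentration == cc, ]
      if (!setequal(a$glycan_id, glycans) || anyDuplicated(a$glycan_id)) {
        stop("lectin ", l, " at concentration ", cc,
             ": glycan set differs from the rest of the experiment",
             call. = FALSE)
      }
      z <- stats::setNames(zscore_array(a$rfu), a$glycan_id)
      z[glycans]
    })
    zs_l <- stouffer_combine(z_list)
    rfu_list <- lapply(concs, function(cc) {
      a <- sub[sub$concentration == cc, ]
      r <- stats::setNames(a$rfu, a$glycan_id)
      r[glycans]
    })
    fl <- flag_nonvarying(zs_l, z_list, rfu_list, threshold = threshold,
                          var_frac = var_frac, signal_frac = signal_frac)
    zs[, l] <- fl$zs[glycans]
    nonvarying[, l] <- fl$flags$nonvarying[match(glycans, fl$flags$glycan_id)]
    nonspecific[, l] <- fl$flags$nonspecific[match(glycans, fl$flags$glycan_id)]
  }

  processed <- subtract_background(zs)
  labels <- call_binders(processed, nonspecific, threshold = threshold)
  keep_glycans <- drop_never_bound_glycans(labels)
  dropped_glycans <- setdiff(glycans, keep_glycans)

  structure(
    list(
      zs = zs[keep_glycans, , drop = FALSE],
      processed = processed[keep_glycans, , drop = FALSE],
      labels = labels[keep_glycans, , drop = FALSE],
      nonvarying = nonvarying[keep_glycans, , drop = FALSE],
      nonspecific = nonspecific[keep_glycans, , drop = FALSE],
      threshold = threshold,
      qc = list(
        dropped_arrays = excl$dropped_arrays,
        excluded_lectins = excl$excluded_lectins,
        dropped_glycans = dropped_glycans,
        params = list(threshold = threshold, min_array_rfu = min_array_rfu,
                      min_max_rfu = min_max_rfu, var_frac = var_frac,
                      signal_frac = signal_frac)
      )
    ),
    class = "zs_result"
  )
}

#' @export
print.zs_result <- function(x, ...) {
  cat("<zs_result> ", nrow(x$zs), " glycans x ", ncol(x$zs), " lectins; ",
      sum(x$labels), " binder calls (threshold ",
      format(x$threshold, digits = 4), ")\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a processed array result
#'
#' @param x A `zs_result`.
#' @param ... Unused.
#' @return Long tibble: `glycan_id`, `lectin_id`, `zs`, `processed`,
#'   `label`, `nonvarying`, `nonspecific`.
#' @export
tidy.zs_result <- function(x, ...) {
  long <- function(m, col) {
    tibble::tibble(
      glycan_id = rep(rownames(m), times = ncol(m)),
      lectin_id = rep(colnames(m), each = nrow(m)),
      !!col := as.vector(m)
    )
  }
  long(x$zs, "zs") |>
    dplyr::left_join(long(x$processed, "processed"),
                     by = c("glycan_id", "lectin_id")) |>
    dplyr::left_join(long(x$labels, "label"),
                     by = c("glycan_id", "lectin_id")) |>
    dplyr::left_join(long(x$nonvarying, "nonvarying"),
                     by = c("glycan_id", "lectin_id")) |>
    dplyr::left_join(long(x$nonspecific, "nonspecific"),
                     by = c("glycan_id", "lectin_id"))
}

#' One-row summary of a processed array result
#' @param x A `zs_result`.
#' @param ... Unused.
#' @return Tibble with glycan/lectin/binder counts and exclusion totals.
#' @export
glance.zs_result <- function(x, ...) {
  tibble::tibble(
    n_glycans = nrow(x$zs),
    n_lectins = ncol(x$zs),
    n_binder_calls = sum(x$labels),
    n_dropped_arrays = nrow(x$qc$dropped_arrays),
    n_excluded_lectins = nrow(x$qc$excluded_lectins),
    n_dropped_glycans = length(x$qc$dropped_glycans),
    threshold = x$threshold
  )
}
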