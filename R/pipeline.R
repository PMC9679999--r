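# End-to-end orchestration: metadata-level exclusions, scoring, featurizing,
# rule mining, clustering, and report assembly, with a QC log and a
# provenance manifest.

#' Pipeline configuration
#'
#' Collects every stage's tunables in one place; the serialized config is
#' embedded in pipeline output for provenance. Defaults: binding threshold
#' 1.645 (one-tailed p = 0.05), 4000-RFU lectin activity floor, 1000-RFU
#' per-array floor, 10% variance and 10% top-signal fractions for the
#' nonvarying/nonspecific flags, and the standard [mining_config()].
#'
#' @param threshold Combined-Z binding threshold.
#' @param min_max_rfu,min_array_rfu Exclusion floors.
#' @param var_frac,signal_frac Flagging fractions.
#' @param mining A [mining_config()].
#' @param catalog Curated motif catalog tibble.
#' @param seed Integer seed (propagated to mining).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(threshold = binding_threshold(),
                            min_max_rfu = 4000, min_array_rfu = 1000,
                            var_frac = 0.10, signal_frac = 0.10,
                            mining = mining_config(),
                            catalog = default_motif_catalog(),
                            seed = 1L) {
  mining$seed <- as.integer(seed)
  structure(
    list(threshold = threshold, min_max_rfu = min_max_rfu,
         min_array_rfu = min_array_rfu, var_frac = var_frac,
         signal_frac = signal_frac, mining = mining, catalog = catalog,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Account for metadata-level lectin exclusions
#'
#' A lectin-preparation metadata table marks duplicate preparations
#' (`duplicate_of` set) and preparations excluded for cause
#' (`exclude_reason` non-empty, e.g. low binding activity or binding
#' incongruent with the literature). The unique annotatable lectins are the
#' preparations that are neither duplicates nor excluded.
#'
#' @param metadata Tibble with columns `lectin_id` and optionally
#'   `duplicate_of`, `exclude_reason`.
#' @return List: `n_preparations`, `n_duplicates`, per-reason exclusion
#'   counts, `n_unique_lectins`, and `unique_lectins` (ids).
#' @export
lectin_accounting <- function(metadata) {
  stopifnot("lectin_id" %in% names(metadata))
  dup <- if ("duplicate_of" %in% names(metadata)) {
    !is.na(metadata$duplicate_of) & nzchar(metadata$duplicate_of)
  } else rep(FALSE, nrow(metadata))
  reason <- if ("exclude_reason" %in% names(metadata)) {
    r <- metadata$exclude_reason
    r[is.na(r)] <- ""
    r
  } else rep("", nrow(metadata))
  excluded <- !dup & nzchar(reason)
  keep <- !dup & !nzchar(reason)
  by_reason <- table(reason[excluded])
  list(
    n_preparations = nrow(metadata),
    n_duplicates = sum(dup),
    n_excluded_by_reason = stats::setNames(as.integer(by_reason),
                                           names(by_reason)),
    n_unique_lectins = sum(keep),
    unique_lectins = metadata$lectin_id[keep]
  )
}

#' Synthetic lectin-preparation metadata fixture
#'
#' A metadata table emulating a large commercial-lectin screening campaign:
#' 116 preparations of which 42 are duplicate preparations of a lectin from
#' another vendor, 15 are excluded for low binding activity and 2 for
#' binding incongruent with the literature, leaving 57 unique annotatable
#' lectins. Entirely synthetic identifiers.
#'
#' @return Metadata tibble (`lectin_id`, `vendor`, `duplicate_of`,
#'   `exclude_reason`).
#' @export
example_lectin_metadata <- function() {
  n_unique <- 74L   # 57 annotated + 15 low-activity + 2 incongruent
  n_dup <- 42L
  base_ids <- sprintf("LEC%03d", seq_len(n_unique))
  vendors <- rep(c("VendorA", "VendorB", "VendorC"), length.out = n_unique)
  base <- tibble::tibble(
    lectin_id = paste0(base_ids, "_", vendors),
    vendor = vendors,
    duplicate_of = "",
    exclude_reason = ""
  )
  base$exclude_reason[1:15] <- "low binding activity"
  base$exclude_reason[16:17] <- "binding incongruent with literature"
  dup_src <- rep(seq_len(n_unique), length.out = n_dup)
  dups <- tibble::tibble(
    lectin_id = paste0(base_ids[dup_src], "_VendorD_", seq_len(n_dup)),
    vendor = "VendorD",
    duplicate_of = base$lectin_id[dup_src],
    exclude_reason = ""
  )
  dplyr::bind_rows(base, dups)
}

#' Run the full annotation pipeline
#'
#' Fixed stage order: metadata exclusions, trimmed spot averaging,
#' per-array Z-scores, low-signal exclusion, Stouffer combination,
#' nonvarying/nonspecific flagging, background subtraction, binder calls,
#' never-bound glycan removal; then featurization, per-lectin rule mining,
#' per-lectin annotation reports, and average-linkage profile clustering.
#'
#' @param scans Long scan tibble (`glycan_id`, `lectin_id`,
#'   `concentration`, `spot1...spotN`) or a path to such a CSV.
#' @param library Tibble mapping `glycan_id` to `structure` (condensed
#'   strings), or a path to such a CSV.
#' @param metadata Optional lectin metadata tibble/CSV path (see
#'   [lectin_accounting()]); duplicate and excluded-for-cause preparations
#'   are removed from the scans before scoring.
#' @param config A [pipeline_config()].
#' @return A `lectin_pipeline` list: `zs` (a `zs_result`), `features`,
#'   `rulesets`, `reports`, `clustering`, `qc`, `config`, `manifest`.
#' @export
run_pipeline <- function(scans, library, metadata = NULL,
                         config = pipeline_config()) {
  if (is.character(scans)) scans <- tibble::as_tibble(
    utils::read.csv(scans, stringsAsFactors = FALSE))
  if (is.character(library)) library <- tibble::as_tibble(
    utils::read.csv(library, stringsAsFactors = FALSE))
  if (is.character(metadata) && length(metadata) == 1L) {
    metadata <- tibble::as_tibble(
      utils::read.csv(metadata, stringsAsFactors = FALSE))
  }
  if (!all(c("glycan_id", "structure") %in% names(library))) {
    stop("library needs columns glycan_id, structure", call. = FALSE)
  }

  qc <- list(config = unclass_config(config))
  if (!is.null(metadata)) {
    acc <- lectin_accounting(metadata)
    qc$lectin_accounting <- acc
    scans <- scans[scans$lectin_id %in% c(acc$unique_lectins,
                                          setdiff(unique(scans$lectin_id),
                                                  metadata$lectin_id)), ]
  }
  if (nrow(scans) == 0L) stop("no scans left after metadata exclusions",
                              call. = FALSE)

  zs <- process_scans(scans, threshold = config$threshold,
                      min_array_rfu = config$min_array_rfu,
                      min_max_rfu = config$min_max_rfu,
                      var_frac = config$var_frac,
                      signal_frac = config$signal_frac)
  qc$scoring <- zs$qc

  kept_ids <- rownames(zs$labels)
  lib_kept <- library[match(kept_ids, library$glycan_id), ]
  if (anyNA(lib_kept$structure)) {
    stop("library is missing structures for glycans: ",
         paste(utils::head(kept_ids[is.na(lib_kept$structure)]),
               collapse = ", "), call. = FALSE)
  }
  graphs <- parse_library(lib_kept)
  features <- build_feature_matrix(graphs, catalog = config$catalog)

  rulesets <- list()
  reports <- list()
  for (l in colnames(zs$labels)) {
    y <- zs$labels[kept_ids, l]
    rs <- tryCatch(
      mine_ruleset(features, y, config = config$mining, lectin_id = l),
      error = function(e) {
        qc$mining_skipped[[l]] <<- conditionMessage(e)
        NULL
      }
    )
    if (is.null(rs)) next
    rulesets[[l]] <- rs
    reports[[l]] <- lectin_report(rs, features, y)
  }

  clustering <- if (ncol(zs$processed) >= 3L) {
    cluster_profiles(zs$processed)
  } else NULL

  manifest <- tibble::tibble(
    component = c("zs", "processed", "labels", "features", "rulesets"),
    hash = c(rlang::hash(zs$zs), rlang::hash(zs$processed),
             rlang::hash(zs$labels), rlang::hash(features),
             rlang::hash(lapply(rulesets, function(r)
               list(r$levels$rule_id, r$stop_reason))))
  )

  structure(
    list(zs = zs, features = features, rulesets = rulesets,
         reports = reports, clustering = clustering, qc = qc,
         config = config, manifest = manifest),
    class = "lectin_pipeline"
  )
}

unclass_config <- function(config) {
  out <- unclass(config)
  out$mining <- unclass(out$mining)
  out$catalog <- NULL  # bulky; catalog names suffice for provenance
  out$catalog_features <- config$catalog$name
  out
}

#' @export
print.lectin_pipeline <- function(x, ...) {
  cat("<lectin_pipeline> ", nrow(x$zs$zs), " glycans x ", ncol(x$zs$zs),
      " lectins; ", length(x$rulesets), " rule set(s)\n", sep = "")
  invisible(x)
}

#' Write the pipeline QC log as JSON
#'
#' Lists every exclusion with its triggering rule, the metadata accounting
#' (when provided), and the serialized configuration.
#'
#' @param pipeline A `lectin_pipeline` (or a bare QC list).
#' @param path Optional output file.
#' @return JSON string (invisibly when written).
#' @export
qc_log_json <- function(pipeline, path = NULL) {
  qc <- if (inherits(pipeline, "lectin_pipeline")) pipeline$qc else pipeline
  json <- jsonlite::toJSON(qc, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           na = "null", force = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
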