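# Featurization of a glycan library: curated motif presence (binary),
# systematic mono/disaccharide counts, and linker one-hot columns.

#' Systematically enumerated motif features of a library
#'
#' The union of all mono- and disaccharide motifs (including linkage) that
#' occur at least once in at least one glycan of the library, sorted
#' canonically. These are the "observed" systematic features that complement
#' the curated catalog.
#'
#' @param library A list of `glycan_graph` objects (typically named by
#'   glycan id).
#' @return Character vector of motif tokens.
#' @export
systematic_motifs <- function(library) {
  if (length(library) == 0L) {
    stop("glycan library is empty", call. = FALSE)
  }
  toks <- unlist(lapply(library, function(g) {
    c(names(enumerate_kmers(g, 1L)), names(enumerate_kmers(g, 2L)))
  }))
  sort(unique(toks), method = "radix")
}

#' Build the glycan feature matrix
#'
#' One row per glycan; columns are (in order) the curated catalog features
#' (presence/absence 0/1), the systematic mono- and disaccharide motif
#' counts, and one-hot linker indicator columns (`linker_Sp8`, ...;
#' `linker_none` when a glycan has no linker tag). The result is
#' deterministic for a fixed library, catalog and registry.
#'
#' @param library Named list of `glycan_graph` objects; names are glycan
#'   ids. An unnamed list gets ids `g1, g2, ...`.
#' @param catalog Curated catalog tibble (see [default_motif_catalog()]);
#'   may have zero rows.
#' @param registry Sugar registry.
#' @return A tibble with a `glycan_id` column followed by one numeric
#'   column per feature.
#' @export
#' @examples
#' lib <- list(chitobiose = parse_condensed("GlcNAcb1-4GlcNAc"))
#' build_feature_matrix(lib, catalog = default_motif_catalog()[0, ])
build_feature_matrix <- function(library, catalog = default_motif_catalog(),
                                 registry = default_sugar_registry()) {
  stopifnot(length(library) >= 1L)
  if (is.null(names(library))) {
    names(library) <- paste0("g", seq_along(library))
  }
  sys_feats <- systematic_motifs(library)
  cur_feats <- catalog$name
  linkers <- vapply(library, function(g) {
    if (is.na(g$linker)) "none" else g$linker
  }, character(1))
  link_feats <- paste0("linker_", sort(unique(linkers), method = "radix"))
  all_feats <- c(cur_feats, sys_feats, link_feats)
  if (anyDuplicated(all_feats)) {
    stop("duplicate feature names: ",
         paste(unique(all_feats[duplicated(all_feats)]), collapse = ", "),
         call. = FALSE)
  }

  # precompute each glycan's flat index once; every pattern reuses it
  library <- lapply(library, function(g) {
    attr(g, "index") <- graph_index(g)
    g
  })
  patterns <- compile_catalog(catalog, registry)
  cur_block <- matrix(0L, nrow = length(library), ncol = length(cur_feats),
                      dimnames = list(NULL, cur_feats))
  for (j in seq_along(patterns)) {
    cur_block[, j] <- vapply(library, function(g) {
      as.integer(match_motif(g, patterns[[j]]) > 0L)
    }, integer(1))
  }

  sys_block <- matrix(0L, nrow = length(library), ncol = length(sys_feats),
                      dimnames = list(NULL, sys_feats))
  for (i in seq_along(library)) {
    counts <- c(enumerate_kmers(library[[i]], 1L),
                enumerate_kmers(library[[i]], 2L))
    sys_block[i, names(counts)] <- as.integer(counts)
  }

  link_block <- matrix(0L, nrow = length(library), ncol = length(link_feats),
                       dimnames = list(NULL, link_feats))
  link_block[cbind(seq_along(library),
                   match(paste0("linker_", linkers), link_feats))] <- 1L

  out <- tibble::as_tibble(cbind(cur_block, sys_block, link_block))
  dplyr::bind_cols(tibble::tibble(glycan_id = names(library)), out)
}

#' Write a feature matrix to CSV
#' @param features Feature tibble from [build_feature_matrix()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

# Internal: split a feature tibble into id vector + numeric matrix.
feature_matrix_parts <- function(features) {
  stopifnot("glycan_id" %in% names(features))
  ids <- features$glycan_id
  mat <- as.matrix(features[, setdiff(names(features), "glycan_id"),
                            drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  mat
}
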