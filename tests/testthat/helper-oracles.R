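# Independent brute-force oracles and shared fixtures, written against the
# exported data structures only.

MAN9 <- paste0("Mana1-2Mana1-6(Mana1-2Mana1-3)Mana1-6",
               "(Mana1-2Mana1-2Mana1-3)Manb1-4GlcNAcb1-4GlcNAc")
BIANTENNARY <- paste0("Galb1-4GlcNAcb1-2Mana1-3",
                      "(Galb1-4GlcNAcb1-2Mana1-6)Manb1-4GlcNAcb1-4GlcNAc")
BIANTENNARY_COREFUC <- paste0("Galb1-4GlcNAcb1-2Mana1-3",
                              "(Galb1-4GlcNAcb1-2Mana1-6)",
                              "Manb1-4GlcNAcb1-4(Fuca1-6)GlcNAc")
BIANTENNARY_BISECT <- paste0("Galb1-4GlcNAcb1-2Mana1-3",
                             "(Galb1-4GlcNAcb1-2Mana1-6)(GlcNAcb1-4)",
                             "Manb1-4GlcNAcb1-4GlcNAc")

# All injective node maps, checked exhaustively: the independent oracle for
# match_motif. Counts distinct image sets admitting at least one valid map.
bf_match_motif <- function(g, m) {
  tpl <- m$template
  if (!is.na(m$linker) &&
      (is.na(g$linker) || !grepl(m$linker, g$linker))) {
    return(0L)
  }
  tids <- tpl$nodes$node_id
  gids <- g$nodes$node_id
  k <- length(tids)
  if (k > length(gids)) return(0L)

  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    unlist(lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }), recursive = FALSE)
  }
  carbon_ok <- function(t, gc) t == "?" || t == gc
  gleaves <- terminal_nodes(g)
  tleaves <- setdiff(tpl$nodes$node_id, tpl$edges$parent)

  valid_map <- function(mp) {
    for (i in seq_len(k)) {
      ti <- match(tids[i], tpl$nodes$node_id)
      vi <- match(mp[i], g$nodes$node_id)
      if (tpl$nodes$sugar[ti] != "Any" &&
          tpl$nodes$sugar[ti] != g$nodes$sugar[vi]) return(FALSE)
      need <- strsplit(tpl$nodes$substituents[ti], ";")[[1]]
      have <- strsplit(g$nodes$substituents[vi], ";")[[1]]
      if (!all(need %in% have)) return(FALSE)
    }
    for (e in seq_len(nrow(tpl$edges))) {
      te <- tpl$edges[e, ]
      mc <- mp[match(te$child, tids)]
      mpv <- mp[match(te$parent, tids)]
      ge <- g$edges[g$edges$child == mc & g$edges$parent == mpv, ]
      if (nrow(ge) != 1L) return(FALSE)
      if (!(te$anomer == "?" || te$anomer == ge$anomer)) return(FALSE)
      if (!carbon_ok(te$child_carbon, ge$child_carbon)) return(FALSE)
      if (!carbon_ok(te$parent_carbon, ge$parent_carbon)) return(FALSE)
    }
    imgs <- mp[match(tleaves, tids)]
    if (m$anchor == "terminal" && !all(imgs %in% gleaves)) return(FALSE)
    if (m$anchor == "internal" && any(imgs %in% gleaves)) return(FALSE)
    if (m$anchor == "root" && mp[match(tpl$root, tids)] != g$root) {
      return(FALSE)
    }
    if (nrow(m$forbidden) > 0L) {
      for (i in seq_len(nrow(m$forbidden))) {
        v <- mp[match(m$forbidden$node[i], tids)]
        if (m$forbidden$kind[i] == "extension") {
          kids <- g$edges[g$edges$parent == v, ]
          hit <- if (m$forbidden$position[i] == "?") nrow(kids) > 0L else
            any(kids$parent_carbon == m$forbidden$position[i])
          if (hit) return(FALSE)
        } else {
          vi <- match(v, g$nodes$node_id)
          subs <- strsplit(g$nodes$substituents[vi], ";")[[1]]
          if (any(startsWith(subs, m$forbidden$position[i]))) return(FALSE)
        }
      }
    }
    TRUE
  }

  images <- character()
  sets <- utils::combn(gids, k, simplify = FALSE)
  for (set in sets) {
    for (p in perms(set)) {
      if (valid_map(p)) {
        images <- c(images, paste(sort(set), collapse = ","))
        break  # one valid map per image set is enough
      }
    }
  }
  length(unique(images))
}

# Scalar per-glycan Stouffer oracle.
bf_stouffer <- function(z_by_concentration) {
  ids <- names(z_by_concentration[[1L]])
  out <- numeric(length(ids))
  names(out) <- ids
  for (gid in ids) {
    s <- 0
    for (z in z_by_concentration) s <- s + z[[gid]]
    out[gid] <- s / sqrt(length(z_by_concentration))
  }
  out
}

# Brute-force precision/recall by explicit counting.
bf_evaluate_rule <- function(conditions, X, labels) {
  sat <- rep(TRUE, nrow(X))
  for (i in seq_len(nrow(conditions))) {
    v <- X[, conditions$feature[i]]
    sat <- sat & if (conditions$op[i] == ">=") v >= conditions$threshold[i]
                 else v < conditions$threshold[i]
  }
  tp <- 0L
  n_sat <- 0L
  n_pos <- 0L
  for (i in seq_len(nrow(X))) {
    if (sat[i]) n_sat <- n_sat + 1L
    if (labels[i] == 1L) n_pos <- n_pos + 1L
    if (sat[i] && labels[i] == 1L) tp <- tp + 1L
  }
  c(precision = if (n_sat == 0L) NA_real_ else tp / n_sat,
    recall = if (n_pos == 0L) NA_real_ else tp / n_pos)
}

# Shared small simulated experiment (cached per test run).
make_panel_experiment <- function(seed, lectins, cv = 0.15,
                                  concentrations = c(0.1, 1, 10, 100)) {
  panel <- two_stage_panel(seed = seed)
  graphs <- parse_library(panel)
  cfg <- simulation_config(n_glycans = nrow(panel),
                           concentrations = concentrations,
                           spot_noise_cv = cv, seed = seed)
  scans <- simulate_experiment(lectins, graphs, cfg)
  list(panel = panel, graphs = graphs, cfg = cfg, scans = scans)
}

lacnac_lectin <- function(label_noise = 0) {
  synthetic_lectin(
    "LACNAC", motif_pattern("Galb1-4GlcNAc", "Galb1-4GlcNAc"),
    label_noise = label_noise
  )
}

lacnac_sia_inhibited_lectin <- function() {
  synthetic_lectin(
    "LACNAC_SIA_INH", motif_pattern("Galb1-4GlcNAc", "Galb1-4GlcNAc"),
    inhibitors = list(list(
      pattern = motif_pattern("Neu5Aca2-3Gal", "Neu5Aca2-3Gal"), fold = 0))
  )
}

decoy_lectins <- function() {
  list(
    synthetic_lectin("MAN_DECOY",
                     motif_pattern("Mana1-2Man", "Mana1-2Man",
                                   anchor = "terminal")),
    synthetic_lectin("CHI_DECOY",
                     motif_pattern("GlcNAcb1-4GlcNAcb1-4GlcNAc",
                                   "GlcNAcb1-4GlcNAcb1-4GlcNAc")),
    synthetic_lectin("T1_DECOY",
                     motif_pattern("Galb1-3GlcNAc", "Galb1-3GlcNAc",
                                   anchor = "terminal")),
    synthetic_lectin("SIA6_DECOY",
                     motif_pattern("Neu5Aca2-6Gal", "Neu5Aca2-6Gal")),
    synthetic_lectin("SIA3_DECOY",
                     motif_pattern("Neu5Aca2-3Gal", "Neu5Aca2-3Gal"))
  )
}

# Features + labels for one lectin out of a processed experiment, rows
# aligned to the kept glycans.
aligned_features <- function(zs, graphs, catalog = default_motif_catalog()) {
  kept <- rownames(zs$labels)
  feats <- build_feature_matrix(graphs[kept], catalog = catalog)
  feats[match(kept, feats$glycan_id), ]
}
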