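# Synthetic glycan arrays with planted ground truth. The generator emulates
# the composition of a large mammalian glycan array: branched N-glycans
# (with optional bisecting GlcNAc, core fucose, sialylation, polyLacNAc),
# high-mannose structures, O-glycan cores 1-4, and terminal-epitope probes
# (Lewis, blood groups, LacdiNAc, chitin oligomers, alpha-Gal, sulfated
# galactosides). Lectins are generative models: a predominant motif plus
# enhancer/inhibitor motifs, saturating concentration response, and
# multiplicative spot noise.

#' Define a synthetic lectin
#'
#' Binding is motif-driven: affinity is 1 when the predominant motif is
#' present (0 otherwise), multiplied by the fold factor of every matching
#' enhancer (> 1) and inhibitor (< 1; 0 is a hard knockout). The mean
#' fluorescence at concentration `c` follows a saturating response
#' `baseline + max_rfu * affinity * c / (c + kd_scale)`. `label_noise`
#' flips the underlying bound/unbound state of a random fraction of
#' glycans.
#'
#' @param name Lectin identifier.
#' @param predominant A [motif_pattern()].
#' @param enhancers,inhibitors Lists of `list(pattern = motif_pattern,
#'   fold = numeric)`.
#' @param kd_scale Half-saturation concentration (same units as the
#'   concentration series, default 5).
#' @param kd_sdlog Lognormal spread of per-glycan half-saturation around
#'   `kd_scale` (default 0.3): real glycans bind one lectin with a range
#'   of affinities, which is what makes signals vary across the
#'   concentration series.
#' @param max_rfu Saturated signal above baseline (default 30000).
#' @param label_noise Probability of flipping a glycan's true state
#'   (default 0).
#' @return A `synthetic_lectin` object.
#' @export
synthetic_lectin <- function(name, predominant, enhancers = list(),
                             inhibitors = list(), kd_scale = 5,
                             kd_sdlog = 0.3, max_rfu = 30000,
                             label_noise = 0) {
  stopifnot(inherits(predominant, "motif_pattern"),
            label_noise >= 0, label_noise < 0.5, kd_scale > 0,
            kd_sdlog >= 0, max_rfu > 0)
  for (e in c(enhancers, inhibitors)) {
    stopifnot(inherits(e$pattern, "motif_pattern"), is.numeric(e$fold),
              e$fold >= 0)
  }
  structure(
    list(name = name, predominant = predominant, enhancers = enhancers,
         inhibitors = inhibitors, kd_scale = kd_scale, kd_sdlog = kd_sdlog,
         max_rfu = max_rfu, label_noise = label_noise),
    class = "synthetic_lectin"
  )
}

#' Simulation configuration
#'
#' Defaults mirror typical array practice: a 4-point concentration series
#' from 0.1 to 100 ug/mL, six replicate spots per glycan, 15% multiplicative
#' spot noise, a 100-RFU baseline, and a library that is roughly 22% N-linked
#' and 19% O-linked glycans with the remainder terminal-epitope probes.
#'
#' @param n_glycans Library size (>= 20).
#' @param concentrations Concentration series (ug/mL, >= 2 points).
#' @param spots_per_glycan Replicate spots (>= 4, default 6).
#' @param spot_noise_cv Coefficient of variation of the multiplicative
#'   lognormal spot noise (default 0.15).
#' @param baseline_rfu Additive background signal (default 100).
#' @param class_fractions Named fractions for `n_glycan`, `o_glycan`,
#'   `epitope` (must sum to 1).
#' @param seed Integer seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_glycans = 200L,
                              concentrations = c(0.1, 1, 10, 100),
                              spots_per_glycan = 6L, spot_noise_cv = 0.15,
                              baseline_rfu = 100,
                              class_fractions = c(n_glycan = 0.223,
                                                  o_glycan = 0.185,
                                                  epitope = 0.592),
                              seed = 1L) {
  stopifnot(n_glycans >= 20L, length(concentrations) >= 2L,
            spots_per_glycan >= 4L, spot_noise_cv >= 0,
            abs(sum(class_fractions) - 1) < 1e-8,
            all(c("n_glycan", "o_glycan", "epitope") %in%
                  names(class_fractions)))
  structure(
    list(n_glycans = as.integer(n_glycans),
         concentrations = sort(concentrations),
         spots_per_glycan = as.integer(spots_per_glycan),
         spot_noise_cv = spot_noise_cv, baseline_rfu = baseline_rfu,
         class_fractions = class_fractions, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# Largest-remainder allocation: deterministic integer class counts.
allocate_counts <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0L) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  stats::setNames(as.integer(base), names(fractions))
}

# ---- structure templates ---------------------------------------------------

sample_n_glycan <- function() {
  if (stats::runif(1) < 0.25) {  # high-mannose
    n_man <- sample(3:9, 1L)
    return(high_mannose_string(n_man))
  }
  n_ant <- sample(2:4, 1L, prob = c(0.6, 0.25, 0.15))
  antenna <- function() {
    ext <- sample(c("none", "gal4", "gal3", "sia3", "sia6", "lex",
                    "polylacnac"),
                  1L, prob = c(0.15, 0.25, 0.1, 0.18, 0.18, 0.08, 0.06))
    switch(ext,
      none = "GlcNAcb1-2",
      gal4 = "Galb1-4GlcNAcb1-2",
      gal3 = "Galb1-3GlcNAcb1-2",
      sia3 = "Neu5Aca2-3Galb1-4GlcNAcb1-2",
      sia6 = "Neu5Aca2-6Galb1-4GlcNAcb1-2",
      lex  = "Galb1-4(Fuca1-3)GlcNAcb1-2",
      polylacnac = "Galb1-4GlcNAcb1-3Galb1-4GlcNAcb1-2"
    )
  }
  extra4 <- "Galb1-4GlcNAcb1-4"  # third antenna on the 3-arm
  extra6 <- "Galb1-4GlcNAcb1-6"  # fourth antenna on the 6-arm
  arm3 <- paste0(antenna(), if (n_ant >= 3L) paste0("(", extra4, ")"), "Mana1-3")
  arm6 <- paste0(antenna(), if (n_ant >= 4L) paste0("(", extra6, ")"), "Mana1-6")
  bisect <- if (stats::runif(1) < 0.2) "(GlcNAcb1-4)" else ""
  corefuc <- if (stats::runif(1) < 0.35) "(Fuca1-6)" else ""
  paste0(arm3, "(", arm6, ")", bisect, "Manb1-4GlcNAcb1-4", corefuc,
         "GlcNAc")
}

high_mannose_string <- function(n_man) {
  core <- "Manb1-4GlcNAcb1-4GlcNAc"
  arms <- switch(as.character(n_man),
    "3" = "Mana1-3(Mana1-6)",
    "4" = "Mana1-2Mana1-3(Mana1-6)",
    "5" = "Mana1-3(Mana1-3(Mana1-6)Mana1-6)",
    "6" = "Mana1-2Mana1-3(Mana1-3(Mana1-6)Mana1-6)",
    "7" = "Mana1-2Mana1-2Mana1-3(Mana1-3(Mana1-6)Mana1-6)",
    "8" = "Mana1-2Mana1-2Mana1-3(Mana1-2Mana1-3(Mana1-6)Mana1-6)",
    "9" = "Mana1-2Mana1-2Mana1-3(Mana1-2Mana1-3(Mana1-2Mana1-6)Mana1-6)"
  )
  paste0(arms, core)
}

sample_o_glycan <- function() {
  core <- sample(1:4, 1L, prob = c(0.4, 0.3, 0.15, 0.15))
  gal_ext <- function() {
    sample(c("", "Neu5Aca2-3", "Fuca1-2", "(3S)"), 1L,
           prob = c(0.5, 0.25, 0.15, 0.1))
  }
  arm6 <- function() {
    sample(c("", "Galb1-4", "Neu5Aca2-6Galb1-4",
             "Galb1-4GlcNAcb1-3Galb1-4"), 1L,
           prob = c(0.4, 0.3, 0.2, 0.1))
  }
  body <- switch(core,
    paste0(gal_ext(), "Galb1-3",
           sample(c("", "(Neu5Aca2-6)"), 1L, prob = c(0.7, 0.3)),
           "GalNAc"),
    paste0(gal_ext(), "Galb1-3(", arm6(), "GlcNAcb1-6)GalNAc"),
    paste0(sample(c("", "Galb1-4", "Galb1-3"), 1L), "GlcNAcb1-3GalNAc"),
    paste0(sample(c("", "Galb1-4"), 1L), "GlcNAcb1-3(",
           sample(c("", "Galb1-4"), 1L), "GlcNAcb1-6)GalNAc")
  )
  if (core == 1L && stats::runif(1) < 0.15) body <- "Neu5Aca2-6GalNAc"
  if (core == 1L && stats::runif(1) < 0.10) body <- "GalNAc"  # Tn
  body
}

sample_epitope <- function() {
  choice <- sample(c(
    "lewis_a", "lewis_x", "lewis_b", "lewis_y", "bgA", "bgB", "bgH",
    "lacdinac", "chitin", "alpha_gal", "lacnac", "sulfo", "sialyl",
    "forssman", "mannobiose"
  ), 1L)
  scaffold <- sample(c("Galb1-4Glc", "Galb1-4GlcNAcb1-3Galb1-4Glc"), 1L)
  switch(choice,
    lewis_a  = "Galb1-3(Fuca1-4)GlcNAcb1-3Galb1-4Glc",
    lewis_x  = "Galb1-4(Fuca1-3)GlcNAcb1-3Galb1-4Glc",
    lewis_b  = "Fuca1-2Galb1-3(Fuca1-4)GlcNAcb1-3Galb1-4Glc",
    lewis_y  = "Fuca1-2Galb1-4(Fuca1-3)GlcNAcb1-3Galb1-4Glc",
    bgA      = "GalNAca1-3(Fuca1-2)Galb1-4GlcNAc",
    bgB      = "Gala1-3(Fuca1-2)Galb1-4GlcNAc",
    bgH      = paste0("Fuca1-2", scaffold),
    lacdinac = "GalNAcb1-4GlcNAcb1-3Galb1-4Glc",
    chitin   = paste(rep("GlcNAcb1-4", sample(1:4, 1L)), collapse = "") |>
      paste0("GlcNAc"),
    alpha_gal = "Gala1-3Galb1-4GlcNAc",
    lacnac   = scaffold,
    sulfo    = sample(c("(3S)Galb1-4GlcNAc", "(6S)Galb1-4GlcNAc",
                        "Galb1-4(6S)GlcNAc"), 1L),
    sialyl   = paste0(sample(c("Neu5Aca2-3", "Neu5Aca2-6", "Neu5Gca2-3"),
                             1L, prob = c(0.45, 0.45, 0.1)), scaffold),
    forssman = "GalNAca1-3GalNAcb1-3Galb1-4Glc",
    mannobiose = sample(c("Mana1-2Man", "Mana1-3Man", "Mana1-6Man"), 1L)
  )
}

#' Generate a synthetic glycan library
#'
#' Draws unique structures from parametric templates with a deterministic
#' class allocation (largest-remainder rounding of the configured
#' N-glycan / O-glycan / epitope fractions). All structures parse and
#' round-trip under the condensed-dialect parser; duplicates (by canonical
#' form) are removed. N-glycan and epitope probes carry spacer linkers
#' (Sp codes); O-glycans carry Ser/Thr linkers.
#'
#' @param config A [simulation_config()].
#' @return Tibble with `glycan_id`, `structure` (canonical string), and
#'   `class`.
#' @export
generate_library <- function(config = simulation_config()) {
  counts <- allocate_counts(config$n_glycans, config$class_fractions)
  sp_codes <- c("Sp0", "Sp8", "Sp12", "Sp14", "Sp21", "Sp25")
  canon_cache <- new.env(parent = emptyenv())
  canonize <- function(s) {
    hit <- canon_cache[[s]]
    if (is.null(hit)) {
      hit <- to_canonical(parse_condensed(s))
      canon_cache[[s]] <- hit
    }
    hit
  }
  out <- withr::with_seed(config$seed, {
    rows <- list()
    for (cls in names(counts)) {
      seen <- new.env(parent = emptyenv())
      order_seen <- character()
      stale <- 0L
      while (length(order_seen) < counts[[cls]]) {
        if (stale > 2000L) {
          stop("template space exhausted for class '", cls, "': requested ",
               counts[[cls]], ", found ", length(order_seen),
               " unique structures", call. = FALSE)
        }
        s <- switch(cls,
                    n_glycan = sample_n_glycan(),
                    o_glycan = sample_o_glycan(),
                    epitope = sample_epitope())
        linker <- if (cls == "o_glycan") sample(c("Ser", "Thr"), 1L) else
          sample(sp_codes, 1L)
        s <- paste0(s, "-", linker)
        canon <- canonize(s)
        if (!is.null(seen[[canon]])) {
          stale <- stale + 1L
        } else {
          seen[[canon]] <- TRUE
          order_seen <- c(order_seen, canon)
          stale <- 0L
        }
      }
      rows[[cls]] <- tibble::tibble(structure = order_seen, class = cls)
    }
    dplyr::bind_rows(rows)
  })
  out$glycan_id <- sprintf("G%03d", seq_len(nrow(out)))
  dplyr::relocate(out, "glycan_id")
}

#' Parse a generated library into glycan graphs
#'
#' @param library Tibble from [generate_library()] (columns `glycan_id`,
#'   `structure`).
#' @param registry Sugar registry.
#' @return Named list of `glycan_graph` objects.
#' @export
parse_library <- function(library, registry = default_sugar_registry()) {
  graphs <- lapply(library$structure, parse_condensed, registry = registry)
  names(graphs) <- library$glycan_id
  graphs
}

# Noise-free affinity of one lectin for each glycan in a parsed library.
lectin_affinity <- function(lectin, graphs) {
  base <- vapply(graphs, function(g) {
    as.numeric(match_motif(g, lectin$predominant) > 0L)
  }, numeric(1))
  for (e in lectin$enhancers) {
    hit <- vapply(graphs, function(g) match_motif(g, e$pattern) > 0L,
                  logical(1))
    base[hit] <- base[hit] * e$fold
  }
  for (i in lectin$inhibitors) {
    hit <- vapply(graphs, function(g) match_motif(g, i$pattern) > 0L,
                  logical(1))
    base[hit] <- base[hit] * i$fold
  }
  base
}

#' Simulate multi-concentration array scans for one lectin
#'
#' Mean signal follows `baseline + max_rfu * affinity * c / (c + kd)`;
#' replicate spots are drawn i.i.d. with multiplicative lognormal noise of
#' the configured coefficient of variation (unit mean). With
#' `label_noise > 0` a seeded random fraction of glycans has its underlying
#' bound/unbound state flipped before signal generation.
#'
#' @param lectin A [synthetic_lectin()].
#' @param graphs Named list of parsed glycans (see [parse_library()]).
#' @param config A [simulation_config()].
#' @param seed_offset Integer added to the config seed (used to
#'   decorrelate lectins within one experiment).
#' @return Long tibble: `glycan_id`, `lectin_id`, `concentration`,
#'   `spot1` ... `spotN`.
#' @export
simulate_scans <- function(lectin, graphs, config = simulation_config(),
                           seed_offset = 0L) {
  aff <- lectin_affinity(lectin, graphs)
  n <- length(graphs)
  cv <- config$spot_noise_cv
  sdlog <- sqrt(log(1 + cv^2))
  withr::with_seed(config$seed + seed_offset, {
    if (lectin$label_noise > 0) {
      flip <- stats::runif(n) < lectin$label_noise
      aff[flip] <- ifelse(aff[flip] > 0, 0, 1)
    }
    # per-glycan affinity: each glycan has its own half-saturation point
    kd <- lectin$kd_scale * stats::rlnorm(n, sdlog = lectin$kd_sdlog)
    rows <- lapply(config$concentrations, function(cc) {
      mean_rfu <- config$baseline_rfu +
        lectin$max_rfu * aff * cc / (cc + kd)
      noise <- if (cv > 0) {
        stats::rlnorm(n * config$spots_per_glycan,
                      meanlog = -sdlog^2 / 2, sdlog = sdlog)
      } else {
        rep(1, n * config$spots_per_glycan)
      }
      spots <- matrix(mean_rfu * noise, nrow = n)
      colnames(spots) <- paste0("spot", seq_len(config$spots_per_glycan))
      dplyr::bind_cols(
        tibble::tibble(glycan_id = names(graphs), lectin_id = lectin$name,
                       concentration = cc),
        tibble::as_tibble(spots)
      )
    })
    dplyr::bind_rows(rows)
  })
}

#' Simulate a multi-lectin experiment
#'
#' @param lectins List of [synthetic_lectin()] objects.
#' @param graphs Named list of parsed glycans.
#' @param config A [simulation_config()].
#' @return Long scan tibble over all lectins (each lectin uses a distinct
#'   seed offset).
#' @export
simulate_experiment <- function(lectins, graphs,
                                config = simulation_config()) {
  dplyr::bind_rows(lapply(seq_along(lectins), function(i) {
    simulate_scans(lectins[[i]], graphs, config, seed_offset = 7919L * i)
  }))
}

#' Ground-truth labels and expected rule features for a synthetic lectin
#'
#' The deterministic bound/unbound state per glycan, ignoring all noise:
#' bound when the predominant motif is present and the product of matching
#' inhibitor folds stays at or above 0.5. Enhancers change magnitude, never
#' the truth. Also reports the feature names a correct rule miner should
#' recover.
#'
#' @param lectin A [synthetic_lectin()].
#' @param graphs Named list of parsed glycans.
#' @return List: `labels` (tibble `glycan_id`, `bound`),
#'   `expected_features` (character: predominant then inhibitor motif
#'   names).
#' @export
ground_truth <- function(lectin, graphs) {
  noiseless <- lectin
  noiseless$label_noise <- 0
  noiseless$enhancers <- list()
  aff <- lectin_affinity(noiseless, graphs)
  list(
    labels = tibble::tibble(glycan_id = names(graphs),
                            bound = as.integer(aff >= 0.5)),
    expected_features = c(
      lectin$predominant$name,
      vapply(lectin$inhibitors, function(i) i$pattern$name, character(1))
    )
  )
}

# ---- benchmark panel -------------------------------------------------------

#' Factorial LacNAc/sialylation benchmark panel
#'
#' A controlled glycan panel for ground-truth recovery studies of a
#' galactose-binding lectin inhibited by alpha2-3 sialylation. Three
#' groups: type-2 LacNAc carriers without any a2-3 sialyl cap
#' (`lacnac_open`), LacNAc carriers capped a2-3 (`lacnac_capped`), and
#' glycans without LacNAc (`no_lacnac`; chitin oligomers, high-mannose,
#' type-1 chains with or without caps). Decorations (core fucose, a2-6
#' sialylation, spacer linkers, chain length) are spread across groups so
#' that no single feature coincides with the conjunction "LacNAc present
#' and a2-3 cap absent"; recovering that truth requires a two-condition
#' rule.
#'
#' Group sizes default to 36/18/146 (a 200-glycan panel): every probe class
#' stays a clear minority of the array, as the Z-score model assumes, and
#' background subtraction across lectins keeps its margin.
#'
#' @param n_open,n_capped,n_other Group sizes.
#' @param seed Integer seed.
#' @return Tibble `glycan_id`, `structure`, `class` (the group).
#' @export
two_stage_panel <- function(n_open = 36L, n_capped = 18L, n_other = 146L,
                            seed = 1L) {
  sp <- c("Sp0", "Sp8", "Sp12", "Sp14", "Sp21", "Sp25")
  lacnac_chain <- function(cap, k, base) {
    paste0(cap, paste(rep("Galb1-4GlcNAcb1-3", k - 1), collapse = ""),
           "Galb1-4GlcNAc", if (base) "b1-3Galb1-4Glc" else "b1-2Man")
  }
  n_glycan <- function(cap3, cap6, fuc) {
    paste0(cap3, "Galb1-4GlcNAcb1-2Mana1-3(", cap6,
           "Galb1-4GlcNAcb1-2Mana1-6)Manb1-4GlcNAcb1-4",
           if (fuc) "(Fuca1-6)", "GlcNAc")
  }
  type1_chain <- function(cap, k) {
    paste0(cap, paste(rep("Galb1-3GlcNAcb1-3", k - 1), collapse = ""),
           "Galb1-3GlcNAc")
  }
  open_templates <- c(
    unlist(lapply(1:4, function(k) c(lacnac_chain("", k, TRUE),
                                     lacnac_chain("Neu5Aca2-6", k, FALSE),
                                     lacnac_chain("Neu5Aca2-6", k, TRUE)))),
    n_glycan("", "", FALSE), n_glycan("", "", TRUE),
    n_glycan("Neu5Aca2-6", "Neu5Aca2-6", FALSE),
    n_glycan("Neu5Aca2-6", "Neu5Aca2-6", TRUE)
  )
  capped_templates <- c(
    unlist(lapply(1:4, function(k) c(lacnac_chain("Neu5Aca2-3", k, TRUE),
                                     lacnac_chain("Neu5Aca2-3", k, FALSE)))),
    n_glycan("Neu5Aca2-3", "Neu5Aca2-3", FALSE),
    n_glycan("Neu5Aca2-3", "Neu5Aca2-3", TRUE),
    n_glycan("Neu5Aca2-3", "Neu5Aca2-6", FALSE)
  )
  other_templates <- c(
    vapply(2:8, function(k) paste(c(rep("GlcNAcb1-4", k - 1), "GlcNAc"),
                                  collapse = ""), character(1)),
    vapply(3:9, high_mannose_string, character(1)),
    unlist(lapply(1:3, function(k) c(type1_chain("", k),
                                     type1_chain("Neu5Aca2-6", k),
                                     type1_chain("Neu5Aca2-3", k),
                                     type1_chain("Fuca1-2", k))))
  )
  draw <- function(templates, n, cls) {
    pool <- as.vector(outer(templates, sp, function(a, b)
      paste0(a, "-", b)))
    if (n > length(pool)) {
      stop("template space exhausted for panel group '", cls, "'",
           call. = FALSE)
    }
    tibble::tibble(structure = sample(pool, n), class = cls)
  }
  out <- withr::with_seed(seed, dplyr::bind_rows(
    draw(open_templates, n_open, "lacnac_open"),
    draw(capped_templates, n_capped, "lacnac_capped"),
    draw(other_templates, n_other, "no_lacnac")
  ))
  out$structure <- vapply(out$structure, function(s)
    to_canonical(parse_condensed(s)), character(1))
  out$glycan_id <- sprintf("P%03d", seq_len(nrow(out)))
  dplyr::relocate(out, "glycan_id")
}
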