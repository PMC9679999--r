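# Subtree motif matching: the featurization primitive. A motif is a small
# rooted tree template; a match is an injective embedding of the template
# into a glycan that preserves parent/child relations and linkage labels.

#' Define a glycan motif pattern
#'
#' A motif pattern is a glycan fragment written in the condensed dialect,
#' with wildcards allowed: the pseudo-sugar `Any` matches any residue and
#' `?` in a linkage matches any anomer/carbon. The anchor restricts where in
#' a glycan the template may sit:
#' \describe{
#'   \item{`terminal`}{every leaf of the template must map onto a leaf
#'     (non-reducing terminus) of the glycan — e.g. terminal alpha-mannose;}
#'   \item{`root`}{the template root must map onto the reducing-end residue
#'     — e.g. core fucose, O-glycan cores;}
#'   \item{`internal`}{every leaf of the template must be further extended
#'     in the glycan;}
#'   \item{`anywhere`}{no positional restriction.}
#' }
#' `forbidden` lists context that must be absent on matched residues, as
#' `"node:kind:position"` entries joined by `|`, where `node` is the residue
#' index in left-to-right order of the pattern string, `kind` is
#' `extension` (no child linkage at that parent carbon; position `?` means
#' no children at all) or `substituent` (no decoration at that position).
#' `linker` is an optional regular expression the glycan's linker tag must
#' match (e.g. `"Ser|Thr"` for O-glycan cores).
#'
#' @param name Feature name.
#' @param pattern Condensed fragment string.
#' @param anchor One of `"anywhere"`, `"terminal"`, `"root"`, `"internal"`.
#' @param forbidden Forbidden-context string (see above), or `""`.
#' @param linker Optional linker regex or `NA`.
#' @param registry Sugar registry.
#' @return A `motif_pattern` object.
#' @export
#' @examples
#' m <- motif_pattern("terminal_man_a2", "Mana1-2Man", anchor = "terminal")
#' match_motif(parse_condensed("Mana1-2Mana1-3Man"), m)
motif_pattern <- function(name, pattern,
                          anchor = c("anywhere", "terminal", "root", "internal"),
                          forbidden = "", linker = NA_character_,
                          registry = default_sugar_registry()) {
  anchor <- match.arg(anchor)
  template <- parse_condensed(pattern, registry = registry)
  fb <- parse_forbidden(forbidden, template)
  fb$node_pos <- match(fb$node, template$nodes$node_id)
  structure(
    list(name = name, pattern = pattern, template = template,
         anchor = anchor, forbidden = fb, linker = linker,
         template_index = graph_index(template)),
    class = "motif_pattern"
  )
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("<motif_pattern> ", x$name, ": ", x$pattern, " [", x$anchor, "]\n",
      sep = "")
  invisible(x)
}

parse_forbidden <- function(forbidden, template) {
  if (is.null(forbidden) || is.na(forbidden) || !nzchar(forbidden)) {
    return(tibble::tibble(node = integer(), kind = character(),
                          position = character()))
  }
  parts <- strsplit(forbidden, "|", fixed = TRUE)[[1]]
  out <- purrr::map_dfr(parts, function(p) {
    f <- strsplit(p, ":", fixed = TRUE)[[1]]
    if (length(f) != 3L || !f[2] %in% c("extension", "substituent")) {
      stop("malformed forbidden-context entry '", p, "'", call. = FALSE)
    }
    tibble::tibble(node = as.integer(f[1]), kind = f[2], position = f[3])
  })
  if (!all(out$node %in% template$nodes$node_id)) {
    stop("forbidden-context refers to a residue not in the pattern",
         call. = FALSE)
  }
  out
}

#' Count embeddings of a motif pattern in a glycan
#'
#' Counts the distinct injective embeddings of the pattern's template into
#' the glycan that honour the anchor, the forbidden context, and any linker
#' requirement. Embeddings that use the same set of glycan residues (images
#' under an automorphism of the template) are counted once.
#'
#' @param g A `glycan_graph`.
#' @param m A [motif_pattern()].
#' @return Integer count (0 when the motif is absent).
#' @export
match_motif <- function(g, m) {
  stopifnot(inherits(g, "glycan_graph"), inherits(m, "motif_pattern"))
  if (!is.na(m$linker)) {
    if (is.na(g$linker) || !grepl(m$linker, g$linker)) return(0L)
  }
  gi <- attr(g, "index") %||% graph_index(g)
  ti <- m$template_index %||% graph_index(m$template)
  candidates <- if (m$anchor == "root") gi$root_pos else seq_len(gi$n)
  maps <- list()
  for (v in candidates) {
    maps <- c(maps, embed_node(ti, ti$root_pos, gi, v))
  }
  if (length(maps) == 0L) return(0L)
  keep <- vapply(maps, function(mp) {
    anchor_ok(ti, gi, mp, m$anchor) && forbidden_ok(ti, gi, mp, m$forbidden)
  }, logical(1))
  maps <- maps[keep]
  if (length(maps) == 0L) return(0L)
  images <- vapply(maps, function(mp) paste(sort(mp), collapse = ","),
                   character(1))
  length(unique(images))
}

# Flat positional index of a glycan graph for fast matching: everything is
# a plain vector addressed by node position (1..n) or edge position.
graph_index <- function(g) {
  ids <- g$nodes$node_id
  n <- length(ids)
  e_child <- match(g$edges$child, ids)
  e_parent <- match(g$edges$parent, ids)
  kids <- vector("list", n)
  if (length(e_parent)) {
    for (e in seq_along(e_parent)) {
      kids[[e_parent[e]]] <- c(kids[[e_parent[e]]], e)
    }
  }
  is_leaf <- !(seq_len(n) %in% e_parent)
  list(
    n = n, ids = ids, sugar = g$nodes$sugar, subst = g$nodes$substituents,
    e_child = e_child, e_parent = e_parent,
    anomer = g$edges$anomer, cc = g$edges$child_carbon,
    pc = g$edges$parent_carbon,
    kids = kids, is_leaf = is_leaf,
    root_pos = match(g$root, ids)
  )
}

# All embeddings mapping template position `t` to glycan position `v`;
# each map is an integer vector over template positions.
embed_node <- function(ti, t, gi, v) {
  if (!residue_compatible(ti, t, gi, v)) return(list())
  tkid_edges <- ti$kids[[t]]
  base <- integer(ti$n)
  base[t] <- v
  if (length(tkid_edges) == 0L) return(list(base))
  gkid_edges <- gi$kids[[v]]
  if (length(gkid_edges) < length(tkid_edges)) return(list())
  assign_children(ti, tkid_edges, gi, gkid_edges, logical(length(gkid_edges)),
                  base)
}

assign_children <- function(ti, tkid_edges, gi, gkid_edges, used, acc) {
  if (length(tkid_edges) == 0L) return(list(acc))
  te <- tkid_edges[1L]
  rest <- tkid_edges[-1L]
  out <- list()
  for (j in seq_along(gkid_edges)) {
    if (used[j]) next
    ge <- gkid_edges[j]
    if (!edge_compatible(ti, te, gi, ge)) next
    for (sub in embed_node(ti, ti$e_child[te], gi, gi$e_child[ge])) {
      merged <- pmax(acc, sub)
      used2 <- used
      used2[j] <- TRUE
      out <- c(out, assign_children(ti, rest, gi, gkid_edges, used2, merged))
    }
  }
  out
}

residue_compatible <- function(ti, t, gi, v) {
  sug <- ti$sugar[t]
  if (sug != "Any" && sug != gi$sugar[v]) return(FALSE)
  tsub <- ti$subst[t]
  if (nzchar(tsub)) {
    need <- strsplit(tsub, ";", fixed = TRUE)[[1]]
    have <- strsplit(gi$subst[v], ";", fixed = TRUE)[[1]]
    if (!all(need %in% have)) return(FALSE)
  }
  TRUE
}

# Unknown carbons in the glycan ("?") only match a wildcard in the
# template, never a specified carbon.
edge_compatible <- function(ti, te, gi, ge) {
  (ti$anomer[te] == "?" || ti$anomer[te] == gi$anomer[ge]) &&
    (ti$cc[te] == "?" || ti$cc[te] == gi$cc[ge]) &&
    (ti$pc[te] == "?" || ti$pc[te] == gi$pc[ge])
}

anchor_ok <- function(ti, gi, mp, anchor) {
  if (anchor %in% c("anywhere", "root")) return(TRUE)
  imgs <- mp[ti$is_leaf]
  if (anchor == "terminal") return(all(gi$is_leaf[imgs]))
  all(!gi$is_leaf[imgs])  # internal: every template leaf extended
}

forbidden_ok <- function(ti, gi, mp, fb) {
  if (nrow(fb) == 0L) return(TRUE)
  for (i in seq_len(nrow(fb))) {
    v <- mp[fb$node_pos[i]]
    if (fb$kind[i] == "extension") {
      kid_edges <- gi$kids[[v]]
      hit <- if (fb$position[i] == "?") length(kid_edges) > 0L else
        any(gi$pc[kid_edges] == fb$position[i])
      if (hit) return(FALSE)
    } else {
      subs <- strsplit(gi$subst[v], ";", fixed = TRUE)[[1]]
      if (any(startsWith(subs, fb$position[i]))) return(FALSE)
    }
  }
  TRUE
}

# ---- curated catalog -------------------------------------------------------

#' Default curated motif catalog
#'
#' The named glycan epitopes a specificity annotation works with: Lewis and
#' blood-group antigens, LacNAc types and polyLacNAc runs, LacdiNAc,
#' O-glycan cores 1-4 and the Tn/T/sialyl-Tn antigens, high-mannose
#' frameworks, terminal-residue features, sialylation and sulfation, core
#' and antenna fucosylation, bisecting GlcNAc, chitin oligomers, Forssman
#' and alpha-Gal. Curated features are scored as presence/absence. The
#' catalog is plain data (name, pattern, anchor, forbidden, linker) so it
#' can be replaced or extended via [read_motif_catalog()].
#'
#' @return A tibble with columns `name`, `pattern`, `anchor`, `forbidden`,
#'   `linker`.
#' @export
default_motif_catalog <- function() {
  tibble::tribble(
    ~name,               ~pattern,                                   ~anchor,    ~forbidden,                        ~linker,
    "lewis_a",           "Galb1-3(Fuca1-4)GlcNAc",                   "terminal", "",                                NA,
    "lewis_x",           "Galb1-4(Fuca1-3)GlcNAc",                   "terminal", "",                                NA,
    "lewis_b",           "Fuca1-2Galb1-3(Fuca1-4)GlcNAc",            "terminal", "",                                NA,
    "lewis_y",           "Fuca1-2Galb1-4(Fuca1-3)GlcNAc",            "terminal", "",                                NA,
    "blood_group_H",     "Fuca1-2Gal",                               "terminal", "",                                NA,
    "bgH_type1",         "Fuca1-2Galb1-3GlcNAc",                     "terminal", "",                                NA,
    "bgH_type2",         "Fuca1-2Galb1-4GlcNAc",                     "terminal", "",                                NA,
    "bgH_type3",         "Fuca1-2Galb1-3GalNAc",                     "terminal", "",                                NA,
    "blood_group_A",     "GalNAca1-3(Fuca1-2)Gal",                   "terminal", "",                                NA,
    "blood_group_B",     "Gala1-3(Fuca1-2)Gal",                      "terminal", "",                                NA,
    "alpha_gal",         "Gala1-3Gal",                               "terminal", "2:extension:2",                   NA,
    "forssman",          "GalNAca1-3GalNAc",                         "terminal", "",                                NA,
    "lacnac_type1",      "Galb1-3GlcNAc",                            "anywhere", "",                                NA,
    "lacnac_type2",      "Galb1-4GlcNAc",                            "anywhere", "",                                NA,
    "lacdinac",          "GalNAcb1-4GlcNAc",                         "terminal", "",                                NA,
    "polylacnac_2",      "Galb1-4GlcNAcb1-3Galb1-4GlcNAc",           "anywhere", "",                                NA,
    "polylacnac_3",      "Galb1-4GlcNAcb1-3Galb1-4GlcNAcb1-3Galb1-4GlcNAc", "anywhere", "",                        NA,
    "bisecting_glcnac",  "GlcNAcb1-4Manb1-4GlcNAc",                  "terminal", "",                                NA,
    "core_fucose",       "Fuca1-6GlcNAc",                            "root",     "",                                NA,
    "antenna_fucose",    "Fuca1-3GlcNAc",                            "anywhere", "",                                NA,
    "chitobiose",        "GlcNAcb1-4GlcNAc",                         "anywhere", "",                                NA,
    "chitin_4",          "GlcNAcb1-4GlcNAcb1-4GlcNAcb1-4GlcNAc",     "anywhere", "",                                NA,
    "n_core_man3",       "Mana1-6(Mana1-3)Manb1-4GlcNAcb1-4GlcNAc",  "anywhere", "",                                NA,
    "high_man5",         "Mana1-6(Mana1-3)Mana1-6(Mana1-3)Manb1-4GlcNAcb1-4GlcNAc", "anywhere", "",                NA,
    "high_man9",         "Mana1-2Mana1-6(Mana1-2Mana1-3)Mana1-6(Mana1-2Mana1-2Mana1-3)Manb1-4GlcNAcb1-4GlcNAc", "anywhere", "", NA,
    "terminal_man_a2",   "Mana1-2Man",                               "terminal", "",                                NA,
    "terminal_man_a3",   "Mana1-3Man",                               "terminal", "",                                NA,
    "terminal_man_a6",   "Mana1-6Man",                               "terminal", "",                                NA,
    "terminal_glcnac_b", "GlcNAcb1-?Any",                            "terminal", "",                                NA,
    "terminal_glcnac_a", "GlcNAca1-?Any",                            "terminal", "",                                NA,
    "terminal_galnac_a", "GalNAca1-?Any",                            "terminal", "",                                NA,
    "terminal_galnac_b", "GalNAcb1-?Any",                            "terminal", "",                                NA,
    "terminal_gal_b",    "Galb1-?Any",                               "terminal", "",                                NA,
    "terminal_gal_a",    "Gala1-?Any",                               "terminal", "",                                NA,
    "sialyl_a23",        "Neu5Aca2-3Any",                            "anywhere", "",                                NA,
    "sialyl_a26",        "Neu5Aca2-6Any",                            "anywhere", "",                                NA,
    "sialyl_a28",        "Neu5Aca2-8Neu5Ac",                         "anywhere", "",                                NA,
    "neu5gc",            "Neu5Gc",                                   "anywhere", "",                                NA,
    "kdn",               "KDN",                                      "anywhere", "",                                NA,
    "sulfo_3",           "(3S)Any",                                  "anywhere", "",                                NA,
    "sulfo_3_gal",       "(3S)Gal",                                  "anywhere", "",                                NA,
    "sulfo_6",           "(6S)Any",                                  "anywhere", "",                                NA,
    "tn_antigen",        "GalNAc",                                   "root",     "1:extension:3|1:extension:6",     "Ser|Thr",
    "core1_T",           "Galb1-3GalNAc",                            "root",     "",                                "Ser|Thr",
    "core2",             "Galb1-3(GlcNAcb1-6)GalNAc",                "root",     "",                                "Ser|Thr",
    "core3",             "GlcNAcb1-3GalNAc",                         "root",     "",                                "Ser|Thr",
    "core4",             "GlcNAcb1-3(GlcNAcb1-6)GalNAc",             "root",     "",                                "Ser|Thr",
    "sialyl_tn",         "Neu5Aca2-6GalNAc",                         "root",     "",                                "Ser|Thr"
  )
}

#' Read a motif catalog from a CSV config file
#'
#' Columns `name`, `pattern`, `anchor`, and optionally `forbidden` and
#' `linker` (see [motif_pattern()] for their syntax).
#'
#' @param path CSV file path.
#' @return A catalog tibble.
#' @export
read_motif_catalog <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("name", "pattern", "anchor")
  if (!all(req %in% names(df))) {
    stop("motif catalog must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(df$forbidden)) df$forbidden <- ""
  if (is.null(df$linker)) df$linker <- NA_character_
  df$forbidden[is.na(df$forbidden)] <- ""
  if (anyDuplicated(df$name)) {
    stop("duplicate feature names in motif catalog", call. = FALSE)
  }
  tibble::as_tibble(df[, c("name", "pattern", "anchor", "forbidden", "linker")])
}

# Compile catalog rows into motif_pattern objects once per featurization.
compile_catalog <- function(catalog, registry = default_sugar_registry()) {
  purrr::pmap(catalog, function(name, pattern, anchor, forbidden, linker, ...) {
    motif_pattern(name, pattern, anchor = anchor, forbidden = forbidden,
                  linker = linker, registry = registry)
  })
}
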