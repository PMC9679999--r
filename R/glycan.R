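#' @importFrom rlang %||%
NULL

# ---- glycan_graph class ----------------------------------------------------

#' Construct a glycan graph
#'
#' A `glycan_graph` is a rooted labelled tree: one node per monosaccharide,
#' one edge per glycosidic linkage, rooted at the reducing end. Nodes carry
#' optional substituents (sulfate `S`, acetyl `Ac`, phosphate `P` at a ring
#' position); edges carry the anomeric configuration and the child/parent
#' carbons of the linkage. An optional linker tag records the spacer through
#' which the glycan is printed on the array.
#'
#' Most users obtain graphs from [parse_condensed()] rather than calling
#' this constructor directly.
#'
#' @param nodes Tibble with columns `node_id` (integer), `sugar` (character),
#'   `substituents` (character; `""` or `;`-separated `"<pos><group>"` codes,
#'   e.g. `"3S"` or `"6S;9Ac"`).
#' @param edges Tibble with columns `child`, `parent` (node ids), `anomer`
#'   (`"a"`, `"b"` or `"?"`), `child_carbon`, `parent_carbon` (character,
#'   digit or `"?"`).
#' @param root Integer node id of the reducing-end residue.
#' @param linker Optional linker tag (e.g. `"Sp8"`) or `NA`.
#' @return A `glycan_graph` object.
#' @export
glycan_graph <- function(nodes, edges, root, linker = NA_character_) {
  g <- structure(
    list(
      nodes = tibble::as_tibble(nodes),
      edges = tibble::as_tibble(edges),
      root = as.integer(root),
      linker = as.character(linker)
    ),
    class = "glycan_graph"
  )
  validate_glycan_graph(g)
  g
}

validate_glycan_graph <- function(g) {
  n <- nrow(g$nodes)
  stopifnot(n >= 1L)
  if (anyDuplicated(g$nodes$node_id)) {
    stop("duplicate node ids in glycan graph", call. = FALSE)
  }
  if (!g$root %in% g$nodes$node_id) {
    stop("root id not among nodes", call. = FALSE)
  }
  if (nrow(g$edges) != n - 1L) {
    stop("glycan graph is not a tree: ", nrow(g$edges), " edges for ", n,
         " nodes", call. = FALSE)
  }
  if (n > 1L) {
    non_root <- setdiff(g$nodes$node_id, g$root)
    if (!setequal(g$edges$child, non_root) || anyDuplicated(g$edges$child)) {
      stop("every non-root node must be exactly one edge's child",
           call. = FALSE)
    }
  }
  invisible(g)
}

#' @export
print.glycan_graph <- function(x, ...) {
  cat("<glycan_graph> ", nrow(x$nodes), " residues",
      if (!is.na(x$linker)) paste0(", linker ", x$linker), "\n", sep = "")
  cat("  ", to_canonical(x), "\n", sep = "")
  invisible(x)
}

#' Number of residues in a glycan graph
#' @param g A `glycan_graph`.
#' @return Integer residue count.
#' @export
n_residues <- function(g) nrow(g$nodes)

# ---- dialect normalization -------------------------------------------------

# The array exports mix two spellings of the condensed dialect:
# "Galb1-4GlcNAc" and "Galβ1,4GlcNAc". Normalize greek anomers to ASCII,
# en/em dashes to hyphens, comma-separated linkage carbons to hyphenated
# ones, and strip whitespace. The comma rewrite only fires after an anomer
# letter so sugar symbols like "Neu5,9Ac2" are untouched.
normalize_condensed <- function(text) {
  s <- gsub("α", "a", text)
  s <- gsub("β", "b", s)
  s <- gsub("[‐‒–—−]", "-", s)
  s <- gsub("[[:space:]]", "", s)
  s <- gsub("([ab?])([0-9?]),([0-9?])", "\\1\\2-\\3", s)
  s
}

# ---- parser ----------------------------------------------------------------

#' Parse a condensed glycan structure string
#'
#' Parses the CFG/IUPAC-condensed dialect used on glycan arrays, e.g.
#' `"Galb1-4GlcNAcb1-2Mana1-3(Galb1-4GlcNAcb1-2Mana1-6)Manb1-4GlcNAcb1-4GlcNAc-Sp12"`.
#' Both ASCII (`b1-4`) and greek (`β1,4`) spellings are accepted and
#' normalized. Branches are parenthesized; substituents appear as prefixes
#' such as `(3S)Gal` (or the `3OSO3` spelling); an optional trailing
#' `-SpN` (or amino-acid) linker tag is stored on the graph but is not a
#' residue. Unknown anomers or carbons may be written `?`.
#'
#' @param text A non-empty condensed structure string.
#' @param registry Sugar registry tibble; see [default_sugar_registry()].
#' @return A [glycan_graph()].
#' @export
#' @examples
#' parse_condensed("GlcNAcb1-4GlcNAc")
#' parse_condensed("Mana1-6(Mana1-3)Man")
#' parse_condensed("Galb1-4(Fuca1-3)GlcNAc-Sp8")
parse_condensed <- function(text, registry = default_sugar_registry()) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text))) {
    stop("glycan string must be a single non-empty character value",
         call. = FALSE)
  }
  s <- normalize_condensed(text)

  # split off linker suffix
  linker <- NA_character_
  lk <- regmatches(s, regexpr("-(Sp[0-9]+|Ser|Thr|Asn|Gly)$", s))
  if (length(lk) == 1L && nzchar(lk)) {
    linker <- sub("^-", "", lk)
    s <- substr(s, 1L, nchar(s) - nchar(lk))
  }
  if (!nzchar(s)) {
    stop("glycan string '", text, "' has no residues", call. = FALSE)
  }

  depth <- cumsum((strsplit(s, "")[[1]] == "(") - (strsplit(s, "")[[1]] == ")"))
  if (any(depth < 0) || utils::tail(depth, 1) != 0) {
    stop("unbalanced parentheses in glycan string '", text, "'",
         call. = FALSE)
  }

  env <- new.env(parent = emptyenv())
  env$next_id <- 1L
  env$n_sugar <- character()
  env$n_subst <- character()
  env$e_child <- integer()
  env$e_parent <- integer()
  env$e_anomer <- character()
  env$e_cc <- character()
  env$e_pc <- character()
  aliases <- registry_aliases(registry)

  res <- parse_chain(s, 1L, env, aliases, registry, allow_dangling = FALSE)

  nodes <- tibble::new_tibble(
    list(node_id = seq_along(env$n_sugar), sugar = env$n_sugar,
         substituents = env$n_subst),
    nrow = length(env$n_sugar))
  edges <- tibble::new_tibble(
    list(child = env$e_child, parent = env$e_parent, anomer = env$e_anomer,
         child_carbon = env$e_cc, parent_carbon = env$e_pc),
    nrow = length(env$e_child))
  glycan_graph(nodes, edges, root = res$root, linker = linker)
}

# Recursive-descent parse of one chain. `offset` is the position of `s`
# within the full input, used in error messages. Residues attach as the
# parent of everything read before them at the same nesting level; a chain
# that ends in a linkage token (inside a branch) returns it as `dangling`.
parse_chain <- function(s, offset, env, aliases, registry, allow_dangling) {
  pos <- 1L
  n <- nchar(s)
  pending <- list()   # children awaiting the next residue
  substs <- character() # substituent prefixes for the next residue
  last_node <- NA_integer_

  while (pos <= n) {
    ch <- substr(s, pos, pos)
    if (ch == "(") {
      close <- matching_paren(s, pos)
      inner <- substr(s, pos + 1L, close - 1L)
      if (grepl("^[1-9?](S|P|Ac|OSO3)$", inner)) {
        substs <- c(substs, sub("OSO3$", "S", inner))
      } else {
        sub_res <- parse_chain(inner, offset + pos, env, aliases, registry,
                               allow_dangling = TRUE)
        if (is.null(sub_res$dangling)) {
          stop("branch '(", inner, ")' at offset ", offset + pos - 1L,
               " lacks a linkage to its parent", call. = FALSE)
        }
        pending <- c(pending, list(c(list(child = sub_res$root),
                                     sub_res$dangling)))
      }
      pos <- close + 1L
    } else {
      # residue token: longest registry alias at this position
      tok <- match_sugar(s, pos, aliases)
      if (is.na(tok)) {
        stop("unknown sugar symbol at offset ", offset + pos - 1L, " in '",
             s, "' (registry error)", call. = FALSE)
      }
      node_id <- env$next_id
      env$next_id <- env$next_id + 1L
      sub_str <- if (length(substs)) {
        p <- as.integer(substr(substs, 1L, 1L))
        if (anyDuplicated(p)) {
          stop("duplicate substituent position on residue at offset ",
               offset + pos - 1L, call. = FALSE)
        }
        paste(substs[order(p)], collapse = ";")
      } else ""
      env$n_sugar[node_id] <- registry_canonical(registry, tok)
      env$n_subst[node_id] <- sub_str
      for (p in pending) {
        k <- length(env$e_child) + 1L
        env$e_child[k] <- p$child
        env$e_parent[k] <- node_id
        env$e_anomer[k] <- p$anomer
        env$e_cc[k] <- p$child_carbon
        env$e_pc[k] <- p$parent_carbon
      }
      pending <- list()
      substs <- character()
      last_node <- node_id
      pos <- pos + nchar(tok)

      if (pos > n) break
      lk <- regmatches(substr(s, pos, n),
                       regexpr("^([ab?])([0-9?])-([0-9?])", substr(s, pos, n)))
      if (length(lk) == 0L || !nzchar(lk)) {
        stop("malformed or truncated linkage token at offset ",
             offset + pos - 1L, " in '", s, "'", call. = FALSE)
      }
      link <- list(anomer = substr(lk, 1L, 1L),
                   child_carbon = substr(lk, 2L, 2L),
                   parent_carbon = substr(lk, 4L, 4L))
      pos <- pos + nchar(lk)
      if (pos > n) {
        # dangling linkage: legal only inside a branch
        if (!allow_dangling) {
          stop("truncated linkage at end of '", s, "' (offset ",
               offset + pos - 2L, ")", call. = FALSE)
        }
        return(list(root = last_node, dangling = link))
      }
      pending <- c(pending, list(c(list(child = last_node), link)))
    }
  }
  if (length(pending) || length(substs)) {
    stop("glycan string '", s, "' ends before its root residue", call. = FALSE)
  }
  list(root = last_node, dangling = NULL)
}

matching_paren <- function(s, open_pos) {
  depth <- 0L
  for (i in open_pos:nchar(s)) {
    ch <- substr(s, i, i)
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth == 0L) return(i)
    }
  }
  stop("unbalanced parentheses", call. = FALSE)
}

match_sugar <- function(s, pos, aliases) {
  rest <- substr(s, pos, nchar(s))
  for (a in aliases) {
    if (startsWith(rest, a)) return(a)
  }
  NA_character_
}

# ---- canonical serialization ----------------------------------------------

node_token <- function(g, id) {
  i <- match(id, g$nodes$node_id)
  subs <- g$nodes$substituents[i]
  pre <- if (nzchar(subs)) {
    paste0("(", strsplit(subs, ";")[[1]], ")", collapse = "")
  } else ""
  paste0(pre, g$nodes$sugar[i])
}

children_of <- function(g, id) g$edges[g$edges$parent == id, , drop = FALSE]

#' Canonical condensed serialization of a glycan graph
#'
#' Produces a deterministic string: sibling branches are ordered by parent
#' carbon (ascending, unknown last) and then by the lexicographic order of
#' the serialized subtree, so the output is a pure function of structure —
#' two parses of the same glycan with permuted branches serialize
#' identically. The first sibling is written in line; the rest are
#' parenthesized. Round-trips through [parse_condensed()].
#'
#' @param g A `glycan_graph`.
#' @return A condensed structure string (with `-SpN` suffix if the graph
#'   has a linker).
#' @export
#' @examples
#' g <- parse_condensed("Mana1-6(Mana1-3)Man")
#' to_canonical(g)
to_canonical <- function(g) {
  s <- serialize_node(g, g$root)
  if (!is.na(g$linker)) s <- paste0(s, "-", g$linker)
  s
}

serialize_node <- function(g, id) {
  kids <- children_of(g, id)
  if (nrow(kids) == 0L) return(node_token(g, id))
  parts <- character(nrow(kids))
  for (i in seq_len(nrow(kids))) {
    parts[i] <- paste0(serialize_node(g, kids$child[i]), kids$anomer[i],
                       kids$child_carbon[i], "-", kids$parent_carbon[i])
  }
  pc_key <- ifelse(kids$parent_carbon == "?", 99L,
                   suppressWarnings(as.integer(kids$parent_carbon)))
  ord <- order(pc_key, parts, method = "radix")
  parts <- parts[ord]
  inline <- parts[1L]
  branches <- if (length(parts) > 1L) {
    paste0("(", parts[-1L], ")", collapse = "")
  } else ""
  paste0(inline, branches, node_token(g, id))
}

# ---- traversal -------------------------------------------------------------

#' Terminal (non-reducing end) residues of a glycan
#'
#' Returns the leaf nodes of the tree: residues with no further extension,
#' i.e. the non-reducing termini where terminal motifs such as terminal
#' alpha-mannose or blood-group antigens live. For a single-residue glycan
#' the root itself is terminal.
#'
#' @param g A `glycan_graph`.
#' @return Integer vector of node ids.
#' @export
terminal_nodes <- function(g) {
  leaves <- setdiff(g$nodes$node_id, unique(g$edges$parent))
  sort(leaves)
}

#' Enumerate mono- and disaccharide motifs of a glycan
#'
#' Systematic featurization: `k = 1` yields one token per residue (the sugar
#' symbol with its substituent prefixes, e.g. `"(3S)Gal"`), `k = 2` one
#' token per linkage in the form `"<child><anomer><c>-<c><parent>"`, e.g.
#' `"Galb1-4GlcNAc"`. The linker tag is never part of a motif token.
#'
#' @param g A `glycan_graph`.
#' @param k Motif size, 1 or 2.
#' @return A named integer vector of motif counts.
#' @export
#' @examples
#' enumerate_kmers(parse_condensed("Mana1-6(Mana1-3)Man"), k = 2)
enumerate_kmers <- function(g, k) {
  stopifnot(k %in% c(1L, 2L))
  toks <- if (k == 1L) {
    vapply(g$nodes$node_id, function(id) node_token(g, id), character(1))
  } else {
    if (nrow(g$edges) == 0L) return(stats::setNames(integer(), character()))
    vapply(seq_len(nrow(g$edges)), function(i) {
      e <- g$edges[i, ]
      paste0(node_token(g, e$child), e$anomer, e$child_carbon, "-",
             e$parent_carbon, node_token(g, e$parent))
    }, character(1))
  }
  tab <- table(toks)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

# Structural isomorphism via canonical strings (ignores node ids).
#' Test whether two glycan graphs are structurally identical
#' @param g1,g2 `glycan_graph` objects.
#' @return Logical.
#' @export
glycan_isomorphic <- function(g1, g2) {
  identical(to_canonical(g1), to_canonical(g2))
}
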