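#' Monosaccharide symbol registry
#'
#' The parser recognises sugar symbols through an extensible registry. The
#' default registry covers the monosaccharides that occur on mammalian-type
#' glycan arrays (SNFG vocabulary), plus common aliases (`NeuAc` for
#' `Neu5Ac`, greek-free spellings). A registry is a tibble with columns
#' `symbol` (canonical) and `alias` (what may appear in input; equal to
#' `symbol` for the canonical spelling).
#'
#' @return A tibble with columns `symbol` and `alias`.
#' @export
#' @examples
#' default_sugar_registry()
default_sugar_registry <- function() {
  symbols <- c(
    "Glc", "Gal", "Man", "GlcNAc", "GalNAc", "ManNAc", "Fuc",
    "Neu5Ac", "Neu5Gc", "Neu5,9Ac2", "KDN", "MurNAc", "GlcA", "IdoA",
    "GalA", "Xyl", "Rha", "Ara", "GlcN", "GalN", "Rib", "Kdo", "Any"
  )
  aliases <- tibble::tribble(
    ~symbol,   ~alias,
    "Neu5Ac",  "NeuAc",
    "Neu5Gc",  "NeuGc",
    "KDN",     "Kdn"
  )
  dplyr::bind_rows(
    tibble::tibble(symbol = symbols, alias = symbols),
    aliases
  )
}

#' Load a sugar registry from a plain-text file
#'
#' One sugar per line: the canonical symbol, optionally followed by a tab or
#' comma-separated list of aliases. Lines starting with `#` are ignored.
#'
#' @param path Path to the registry file.
#' @return A registry tibble (columns `symbol`, `alias`).
#' @export
read_sugar_registry <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    stop("registry file '", path, "' contains no sugar symbols", call. = FALSE)
  }
  rows <- purrr::map_dfr(lines, function(ln) {
    parts <- strsplit(ln, "[\t,]")[[1]]
    parts <- trimws(parts)
    parts <- parts[nzchar(parts)]
    tibble::tibble(symbol = parts[[1]], alias = parts)
  })
  dplyr::distinct(rows)
}

# Aliases sorted longest-first so greedy tokenization prefers the longest
# symbol (GlcNAc before Glc, Neu5,9Ac2 before Neu5Ac).
registry_aliases <- function(registry) {
  al <- registry$alias
  al[order(-nchar(al), al)]
}

registry_canonical <- function(registry, alias) {
  registry$symbol[match(alias, registry$alias)]
}

# Spacer/linker codes accepted as a trailing "-<tag>" suffix. Sp0..Sp25 plus
# amino-acid attachment tags seen on array structure exports.
linker_tags <- function() {
  c(paste0("Sp", 0:25), "Ser", "Thr", "Asn", "Gly")
}
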