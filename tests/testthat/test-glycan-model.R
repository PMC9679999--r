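test_that("condensed strings parse into the expected trees", {
  g <- parse_condensed("GlcNAcb1-4GlcNAc")
  expect_equal(n_residues(g), 2L)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$anomer, "b")
  expect_equal(g$edges$child_carbon, "1")
  expect_equal(g$edges$parent_carbon, "4")
  expect_true(is.na(g$linker))

  tri <- parse_condensed("Mana1-6(Mana1-3)Man")
  expect_equal(n_residues(tri), 3L)
  expect_setequal(tri$edges$parent_carbon, c("6", "3"))
  expect_true(all(tri$edges$parent == tri$root))
  expect_true(all(tri$nodes$sugar == "Man"))

  fuc <- parse_condensed("Galb1-4(Fuca1-3)GlcNAc")
  root_sugar <- fuc$nodes$sugar[match(fuc$root, fuc$nodes$node_id)]
  expect_equal(root_sugar, "GlcNAc")
  kids <- fuc$edges[fuc$edges$parent == fuc$root, ]
  expect_setequal(paste0(kids$anomer, kids$child_carbon, "-",
                         kids$parent_carbon), c("b1-4", "a1-3"))

  withlink <- parse_condensed(paste0(BIANTENNARY, "-Sp12"))
  expect_equal(withlink$linker, "Sp12")
  expect_equal(n_residues(withlink), 9L)
})

test_that("both dialect spellings normalize to the same structure", {
  ascii <- parse_condensed("Galb1-4(Fuca1-3)GlcNAc")
  greek <- parse_condensed("Galβ1,4(Fuc α1,3) GlcNAc")
  expect_true(glycan_isomorphic(ascii, greek))
})

test_that("sulfate decorations become substituents in either spelling", {
  a <- parse_condensed("(3S)Galb1-4GlcNAc")
  b <- parse_condensed("(3OSO3)Galb1-4GlcNAc")
  gal <- a$nodes[a$nodes$sugar == "Gal", ]
  expect_equal(gal$substituents, "3S")
  expect_true(glycan_isomorphic(a, b))
  expect_equal(names(enumerate_kmers(a, 2)), "(3S)Galb1-4GlcNAc")
})

test_that("canonical serialization is branch-order invariant and round-trips", {
  a <- parse_condensed("Mana1-3(Mana1-6)Man")
  b <- parse_condensed("Mana1-6(Mana1-3)Man")
  expect_identical(to_canonical(a), to_canonical(b))
  expect_identical(to_canonical(parse_condensed("Gal")), "Gal")
  expect_identical(to_canonical(parse_condensed("GlcNAcb1-4GlcNAc")),
                   "GlcNAcb1-4GlcNAc")

  fixtures <- c(MAN9, BIANTENNARY, BIANTENNARY_COREFUC, BIANTENNARY_BISECT,
                "Galb1-3(Fuca1-4)GlcNAcb1-3Galb1-4Glc-Sp8",
                "Neu5Aca2-6Galb1-4GlcNAc-Sp0",
                "(6S)(3S)Galb1-4GlcNAc")
  for (s in fixtures) {
    g1 <- parse_condensed(s)
    g2 <- parse_condensed(to_canonical(g1))
    expect_true(glycan_isomorphic(g1, g2), info = s)
  }
})

test_that("sibling permutations of a multi-branch residue canonicalize identically", {
  perms <- c(
    "Galb1-4GlcNAcb1-2Mana1-3(Galb1-4GlcNAcb1-2Mana1-6)(GlcNAcb1-4)Manb1-4GlcNAc",
    "Galb1-4GlcNAcb1-2Mana1-6(GlcNAcb1-4)(Galb1-4GlcNAcb1-2Mana1-3)Manb1-4GlcNAc",
    "GlcNAcb1-4(Galb1-4GlcNAcb1-2Mana1-3)(Galb1-4GlcNAcb1-2Mana1-6)Manb1-4GlcNAc"
  )
  canon <- vapply(perms, function(s) to_canonical(parse_condensed(s)),
                  character(1))
  expect_length(unique(canon), 1L)
})

test_that("parser rejects malformed input with informative errors", {
  expect_error(parse_condensed("Mana1-6(Mana1-3Man"), "parenthes")
  expect_error(parse_condensed("Galb1-4GlcNAcb1-"), "offset")
  expect_error(parse_condensed("Galb1-4Hex"), "registry")
  expect_error(parse_condensed("Galb1-"), "truncated|offset")
  expect_error(parse_condensed(""), "non-empty")
  expect_error(parse_condensed("Mana1-6"), "truncated|offset|root")
})

test_that("terminal residues are the non-reducing leaves", {
  chito <- parse_condensed("GlcNAcb1-4GlcNAc")
  leaves <- terminal_nodes(chito)
  expect_length(leaves, 1L)
  expect_false(chito$root %in% leaves)
  expect_length(terminal_nodes(parse_condensed("Mana1-6(Mana1-3)Man")), 2L)
  single <- parse_condensed("Gal")
  expect_identical(terminal_nodes(single), single$root)
})

test_that("k-mer enumeration counts nodes and edges exactly", {
  tri <- parse_condensed("Mana1-6(Mana1-3)Man")
  expect_equal(enumerate_kmers(tri, 2),
               c("Mana1-3Man" = 1L, "Mana1-6Man" = 1L))
  expect_equal(enumerate_kmers(parse_condensed("GlcNAcb1-4GlcNAc"), 1),
               c(GlcNAc = 2L))
  lex <- parse_condensed("Galb1-4(Fuca1-3)GlcNAc")
  expect_equal(enumerate_kmers(lex, 2),
               c("Fuca1-3GlcNAc" = 1L, "Galb1-4GlcNAc" = 1L))

  lib <- generate_library(simulation_config(n_glycans = 40, seed = 11))
  for (g in parse_library(lib)) {
    expect_equal(sum(enumerate_kmers(g, 2)), nrow(g$edges))
    expect_equal(sum(enumerate_kmers(g, 1)), n_residues(g))
  }
})

test_that("linker is stored but never enters motif tokens", {
  g <- parse_condensed("Galb1-4GlcNAc-Sp8")
  expect_equal(g$linker, "Sp8")
  expect_false(any(grepl("Sp", names(enumerate_kmers(g, 1)))))
  expect_false(any(grepl("Sp", names(enumerate_kmers(g, 2)))))
})

test_that("a registry file extends the sugar vocabulary", {
  path <- withr::local_tempfile(lines = c(
    "# custom registry", "Glc", "Gal", "Man", "GlcNAc", "Fuc",
    "Xyz\tXYZ,Xz"
  ), fileext = ".txt")
  reg <- read_sugar_registry(path)
  g <- parse_condensed("Xyzb1-4Glc", registry = reg)
  expect_equal(sort(g$nodes$sugar), c("Glc", "Xyz"))
  g2 <- parse_condensed("XYZb1-4Glc", registry = reg)
  expect_true(glycan_isomorphic(g, g2))
  expect_error(parse_condensed("Galb1-4Glc-Foo", registry = reg))
})
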