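test_that("motif embedding counts match curated expectations", {
  man9 <- parse_condensed(MAN9)
  tman2 <- motif_pattern("terminal_man_a2", "Mana1-2Man", anchor = "terminal")
  expect_equal(match_motif(man9, tman2), 3L)

  bisect <- motif_pattern("bisecting_glcnac", "GlcNAcb1-4Manb1-4GlcNAc",
                          anchor = "terminal")
  expect_equal(match_motif(parse_condensed(BIANTENNARY), bisect), 0L)
  expect_equal(match_motif(parse_condensed(BIANTENNARY_BISECT), bisect), 1L)

  corefuc <- motif_pattern("core_fucose", "Fuca1-6GlcNAc", anchor = "root")
  expect_equal(match_motif(parse_condensed(BIANTENNARY_COREFUC), corefuc), 1L)
  expect_equal(match_motif(parse_condensed(BIANTENNARY), corefuc), 0L)

  # anywhere-anchored LacNAc counts one embedding per antenna
  lacnac <- motif_pattern("lacnac_type2", "Galb1-4GlcNAc")
  expect_equal(match_motif(parse_condensed(BIANTENNARY), lacnac), 2L)
})

test_that("wildcard linkages in the glycan never match specified carbons", {
  g <- parse_condensed("Neu5Aca2-?Galb1-4GlcNAc")
  expect_equal(match_motif(g, motif_pattern("s3", "Neu5Aca2-3Gal")), 0L)
  expect_equal(match_motif(g, motif_pattern("s", "Neu5Aca2-?Gal")), 1L)
})

test_that("embedding counter agrees with the exhaustive oracle", {
  glycans <- lapply(c(
    MAN9, BIANTENNARY, BIANTENNARY_COREFUC, BIANTENNARY_BISECT,
    "Galb1-4(Fuca1-3)GlcNAcb1-3Galb1-4Glc-Sp8",
    "Fuca1-2Galb1-3(Fuca1-4)GlcNAcb1-3Galb1-4Glc",
    "Gala1-3Galb1-4GlcNAc", "Gala1-3(Fuca1-2)Galb1-4GlcNAc",
    "GlcNAcb1-4GlcNAcb1-4GlcNAcb1-4GlcNAc",
    "Neu5Aca2-6Galb1-3GalNAc-Thr", "(3S)Galb1-4(Fuca1-3)GlcNAc-Sp0"
  ), parse_condensed)
  patterns <- list(
    motif_pattern("tm2", "Mana1-2Man", anchor = "terminal"),
    motif_pattern("lacnac2", "Galb1-4GlcNAc"),
    motif_pattern("lex", "Galb1-4(Fuca1-3)GlcNAc", anchor = "terminal"),
    motif_pattern("chito", "GlcNAcb1-4GlcNAc"),
    motif_pattern("agal", "Gala1-3Gal", anchor = "terminal",
                  forbidden = "2:extension:2"),
    motif_pattern("cf", "Fuca1-6GlcNAc", anchor = "root"),
    motif_pattern("tgalb", "Galb1-?Any", anchor = "terminal"),
    motif_pattern("s3gal", "(3S)Gal"),
    motif_pattern("t_ag", "Galb1-3GalNAc", anchor = "root",
                  linker = "Ser|Thr"),
    motif_pattern("internal_gal", "Galb1-4GlcNAc", anchor = "internal")
  )
  for (g in glycans) {
    for (m in patterns) {
      expect_equal(match_motif(g, m), bf_match_motif(g, m),
                   info = paste(to_canonical(g), m$name))
    }
  }
})

test_that("relaxing forbidden context never decreases the count", {
  strict <- motif_pattern("agal", "Gala1-3Gal", anchor = "terminal",
                          forbidden = "2:extension:2")
  loose <- motif_pattern("agal", "Gala1-3Gal", anchor = "terminal")
  for (s in c("Gala1-3Galb1-4GlcNAc", "Gala1-3(Fuca1-2)Galb1-4GlcNAc",
              "Gala1-3Gal")) {
    g <- parse_condensed(s)
    expect_gte(match_motif(g, loose), match_motif(g, strict))
  }
  # blood-group B carries the fucose, so the strict alpha-Gal pattern
  # must reject it while the loose one matches
  bgb <- parse_condensed("Gala1-3(Fuca1-2)Galb1-4GlcNAc")
  expect_equal(match_motif(bgb, strict), 0L)
  expect_equal(match_motif(bgb, loose), 1L)
})

test_that("systematic motifs are the observed k-mer union", {
  chito <- parse_condensed("GlcNAcb1-4GlcNAc")
  tri <- parse_condensed("Mana1-6(Mana1-3)Man")
  expect_equal(systematic_motifs(list(chito)),
               c("GlcNAc", "GlcNAcb1-4GlcNAc"))
  expect_setequal(systematic_motifs(list(chito, tri)),
                  c("GlcNAc", "Man", "GlcNAcb1-4GlcNAc", "Mana1-3Man",
                    "Mana1-6Man"))
  expect_setequal(
    union(systematic_motifs(list(chito)), systematic_motifs(list(tri))),
    systematic_motifs(list(chito, tri))
  )
  expect_error(systematic_motifs(list()), "empty")
})

test_that("feature matrix layout and values are as specified", {
  lib <- list(chitobiose = parse_condensed("GlcNAcb1-4GlcNAc-Sp0"),
              lex = parse_condensed("Galb1-4(Fuca1-3)GlcNAc-Sp8"))
  fm <- build_feature_matrix(lib, catalog = default_motif_catalog())
  expect_s3_class(fm, "tbl_df")
  expect_equal(fm$glycan_id, c("chitobiose", "lex"))
  expect_equal(fm[["GlcNAcb1-4GlcNAc"]], c(1L, 0L))
  expect_equal(fm[["lewis_x"]], c(0L, 1L))
  expect_equal(fm[["linker_Sp0"]], c(1L, 0L))
  expect_equal(fm[["linker_Sp8"]], c(0L, 1L))
  # curated block binary, systematic block counts
  chit4 <- list(g = parse_condensed("GlcNAcb1-4GlcNAcb1-4GlcNAcb1-4GlcNAc"))
  fm4 <- build_feature_matrix(chit4, catalog = default_motif_catalog())
  expect_equal(fm4[["GlcNAcb1-4GlcNAc"]], 3L)  # count, not presence
  expect_equal(fm4[["chitobiose"]], 1L)        # curated stays binary
})

test_that("feature matrix is reproducible and rejects name collisions", {
  lib <- parse_library(generate_library(simulation_config(n_glycans = 30,
                                                          seed = 5)))
  f1 <- build_feature_matrix(lib)
  f2 <- build_feature_matrix(lib)
  expect_identical(f1, f2)

  clash <- default_motif_catalog()[1:2, ]
  clash$name <- c("dup", "dup")
  expect_error(build_feature_matrix(lib, catalog = clash), "duplicate")
})

test_that("a catalog round-trips through its CSV config format", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(default_motif_catalog(), path, row.names = FALSE,
                   na = "")
  back <- read_motif_catalog(path)
  expect_equal(back$name, default_motif_catalog()$name)
  expect_equal(back$pattern, default_motif_catalog()$pattern)
  # compiled patterns parse
  expect_silent(invisible(
    lapply(seq_len(nrow(back)), function(i)
      motif_pattern(back$name[i], back$pattern[i], anchor = back$anchor[i],
                    forbidden = back$forbidden[i], linker = back$linker[i]))
  ))
})
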