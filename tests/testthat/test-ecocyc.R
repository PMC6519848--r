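# Miniature flat-file fixtures are written inline; the dialect is the
# attribute-value form with UNIQUE-ID openers, "//" terminators,
# "/" continuation lines and "^" annotation lines.

write_fixture <- function(dir, ...) {
  files <- list(...)
  for (fn in names(files)) writeLines(files[[fn]], file.path(dir, fn))
  dir
}

test_that("attribute-value parsing: counts, comments, continuations, annotations", {
  dir <- withr::local_tempdir()
  write_fixture(dir,
    "reactions.dat" = c(
      "# header comment",
      "UNIQUE-ID - RXN-1", "LEFT - CPD-A", "^COEFFICIENT - 2", "RIGHT - CPD-B", "//",
      "UNIQUE-ID - RXN-2", "LEFT - CPD-B", "RIGHT - CPD-C", "//",
      "UNIQUE-ID - RXN-3", "LEFT - CPD-C", "RIGHT - CPD-A", "//"),
    "compounds.dat" = c("# only comments in here", "# nothing else"),
    "regulation.dat" = c(
      "UNIQUE-ID - REG-1",
      "COMMON-NAME - a regulation event whose description",
      "/continues on a second line",
      "REGULATOR - PROT-1", "REGULATED-ENTITY - G-1", "MODE - +", "//"))
  raw <- parse_flat_files(dir)
  expect_length(raw$files[["reactions.dat"]], 3)
  expect_length(raw$files[["compounds.dat"]], 0)
  # continuation concatenates with a single space (hand-parsed expectation)
  r <- raw$files[["regulation.dat"]][["REG-1"]]
  expect_equal(regmetnet:::record_values(r, "COMMON-NAME"),
               "a regulation event whose description continues on a second line")
  # annotation attaches to the preceding attribute
  rx <- raw$files[["reactions.dat"]][["RXN-1"]]
  left <- regmetnet:::record_entries(rx, "LEFT")
  expect_equal(left[[1]]$annotations$COEFFICIENT, "2")

  # idempotence: parsing twice yields the identical record set
  expect_identical(raw, parse_flat_files(dir))
})

test_that("malformed records error under strict parsing and are logged otherwise", {
  dir <- withr::local_tempdir()
  # strict mode demands all eight files
  expect_error(parse_flat_files(dir, strict = TRUE), "missing flat file")
  for (fn in setdiff(regmetnet:::.FLAT_FILES, "genes.dat"))
    writeLines("# empty", file.path(dir, fn))
  write_fixture(dir, "genes.dat" = c("PRODUCT - P-1", "UNIQUE-ID - G-1", "//"))
  expect_error(parse_flat_files(dir, strict = TRUE),
               "genes.dat:1.*no accession")
  raw <- parse_flat_files(dir, strict = FALSE)
  expect_match(raw$log, "genes.dat:1", all = FALSE)
  expect_length(raw$files[["genes.dat"]], 1)
})

test_that("vertex candidates: protein classification, class substitution, aliases", {
  dir <- withr::local_tempdir()
  write_fixture(dir,
    "compounds.dat" = c(
      "UNIQUE-ID - CAMP", "//",
      "UNIQUE-ID - ALA-DIPEP", "//",
      "UNIQUE-ID - GLY-DIPEP", "//",
      "UNIQUE-ID - CPD-15709", "ALIAS-OF - FRUCTOSE-6P", "//",
      "UNIQUE-ID - FRUCTOSE-6P", "//"),
    "classes.dat" = c(
      "UNIQUE-ID - DIPEPTIDES", "MEMBERS - ALA-DIPEP", "MEMBERS - GLY-DIPEP", "//"),
    "genes.dat" = c("UNIQUE-ID - G-CRP", "PRODUCT - CRP", "//"),
    "rnas.dat" = c("UNIQUE-ID - RNA-1", "GENE - G-CRP", "//"),
    "proteins.dat" = c(
      "UNIQUE-ID - CRP", "GENE - G-CRP", "//",
      "UNIQUE-ID - CRP-CAMP", "COMPONENTS - CRP", "COMPONENTS - CAMP", "//",
      "UNIQUE-ID - DIMER", "COMPONENTS - CRP", "^COEFFICIENT - 2", "//",
      "UNIQUE-ID - RNP", "COMPONENTS - CRP", "COMPONENTS - RNA-1", "//",
      "UNIQUE-ID - BROKEN", "COMPONENTS - NOSUCH", "//"))
  cand <- build_candidate_vertices(parse_flat_files(dir))
  vt <- setNames(cand$vertices$vtype, cand$vertices$id)
  expect_equal(unname(vt["CRP"]), "protein-monomer")
  expect_equal(unname(vt["CRP-CAMP"]), "protein-compound-complex")
  expect_equal(unname(vt["DIMER"]), "protein-protein-complex")
  expect_equal(unname(vt["RNP"]), "protein-RNA-complex")
  # class term absent, both members present as compounds
  expect_false("DIPEPTIDES" %in% names(vt))
  expect_true(all(c("ALA-DIPEP", "GLY-DIPEP") %in% names(vt)))
  # alias decoded to one canonical vertex, logged
  expect_false("CPD-15709" %in% names(vt))
  expect_true("FRUCTOSE-6P" %in% names(vt))
  expect_equal(cand$report$aliases$alias, "CPD-15709")
  # unclassifiable candidate excluded and reported
  expect_false("BROKEN" %in% names(vt))
  expect_match(cand$report$dropped$reason, "unidentified component", all = FALSE)
})

test_that("reversible reactions split into direction twins with swapped edges", {
  dir <- withr::local_tempdir()
  write_fixture(dir,
    "compounds.dat" = c("UNIQUE-ID - A", "//", "UNIQUE-ID - B", "//"),
    "reactions.dat" = c(
      "UNIQUE-ID - RXN-R", "LEFT - A", "RIGHT - B",
      "REACTION-DIRECTION - REVERSIBLE", "//"))
  net <- reconstruct_network(dir)
  rxn <- net$full$vertices$id[net$full$vertices$vtype == "reaction"]
  expect_setequal(rxn, c("RXN-R", "RXN-R_REV"))
  ep <- net$full$edges[net$full$edges$etype %in% c("educt", "product"), ]
  expect_equal(nrow(ep), 4)
  # the twin runs backwards: B is its educt, A its product
  expect_true(any(ep$source == "B" & ep$target == "RXN-R_REV" & ep$etype == "educt"))
  expect_true(any(ep$source == "RXN-R_REV" & ep$target == "A" & ep$etype == "product"))
})

test_that("regulation multiplies per transcription-unit gene; RNA regulators become genes", {
  dir <- withr::local_tempdir()
  write_fixture(dir,
    "genes.dat" = c("UNIQUE-ID - G1", "//", "UNIQUE-ID - G2", "//",
                    "UNIQUE-ID - G3", "//", "UNIQUE-ID - GS", "//"),
    "rnas.dat" = c("UNIQUE-ID - SRNA-1", "GENE - GS", "//"),
    "regulation.dat" = c(
      "UNIQUE-ID - REG-TU", "REGULATOR - SRNA-1",
      "REGULATED-ENTITY - G1", "REGULATED-ENTITY - G2", "REGULATED-ENTITY - G3",
      "MODE - -", "//",
      "UNIQUE-ID - REG-EMPTY", "REGULATOR - SRNA-1", "//"))
  raw <- parse_flat_files(dir)
  cand <- build_candidate_vertices(raw)
  ed <- build_edges(raw, cand)
  reg <- ed$edges[ed$edges$etype == "regulation", ]
  expect_equal(nrow(reg), 3)
  expect_true(all(reg$source == "GS"))       # RNA translated into encoding gene
  expect_setequal(reg$target, c("G1", "G2", "G3"))
  expect_true(all(reg$regulation_mode == -1L))
  # zero-gene transcription unit is dropped and logged
  expect_match(ed$dropped_processes$reason, "zero genes", all = FALSE)
})

test_that("processes citing unidentified participants are dropped entirely", {
  dir <- withr::local_tempdir()
  write_fixture(dir,
    "compounds.dat" = c("UNIQUE-ID - A", "//"),
    "reactions.dat" = c(
      "UNIQUE-ID - RXN-OK", "LEFT - A", "RIGHT - A", "//",
      "UNIQUE-ID - RXN-BAD", "LEFT - A", "RIGHT - GHOST", "//"))
  raw <- parse_flat_files(dir)
  cand <- build_candidate_vertices(raw)
  ed <- build_edges(raw, cand)
  expect_false("GHOST" %in% c(ed$edges$source, ed$edges$target))
  expect_equal(sum(ed$edges$target == "RXN-BAD" | ed$edges$source == "RXN-BAD"), 0)
  expect_match(ed$dropped_processes$process, "reaction:RXN-BAD", all = FALSE)
  expect_match(ed$dropped_processes$reason, "GHOST", all = FALSE)
})

test_that("reactions outside periplasm/inner membrane/cytosol are dropped", {
  dir <- withr::local_tempdir()
  write_fixture(dir,
    "compounds.dat" = c("UNIQUE-ID - A", "COMPARTMENT - e", "//"),
    "reactions.dat" = c(
      "UNIQUE-ID - RXN-EXT", "LEFT - A", "RIGHT - A",
      "RXN-LOCATIONS - CCO-EXTRACELLULAR", "//",
      "UNIQUE-ID - RXN-PERI", "LEFT - A", "RIGHT - A",
      "RXN-LOCATIONS - CCO-PERI-BAC", "//"))
  cand <- build_candidate_vertices(parse_flat_files(dir))
  expect_false("RXN-EXT" %in% cand$vertices$id)
  expect_true("RXN-PERI" %in% cand$vertices$id)
  expect_match(cand$report$dropped$reason, "outside periplasm", all = FALSE)
})

test_that("assembly extracts the largest weak component and rejects dangling edges", {
  dir <- withr::local_tempdir()
  # seven-vertex connected block + two-vertex satellite
  write_fixture(dir,
    "compounds.dat" = c("UNIQUE-ID - A", "//", "UNIQUE-ID - B", "//",
                        "UNIQUE-ID - C", "//", "UNIQUE-ID - X", "//",
                        "UNIQUE-ID - Y", "//"),
    "genes.dat" = c("UNIQUE-ID - G1", "PRODUCT - P1", "//"),
    "proteins.dat" = c("UNIQUE-ID - P1", "GENE - G1", "//"),
    "reactions.dat" = c(
      "UNIQUE-ID - R1", "LEFT - A", "RIGHT - B", "ENZYMES - P1", "//",
      "UNIQUE-ID - R2", "LEFT - B", "RIGHT - C", "//",
      "UNIQUE-ID - RX", "LEFT - X", "RIGHT - Y", "//"))
  net <- reconstruct_network(dir)
  expect_equal(n_vertices(net$full), 10)
  expect_equal(n_vertices(net$wcc), 7)
  expect_setequal(net$wcc$vertices$id, c("A", "B", "C", "G1", "P1", "R1", "R2"))

  expect_error(assemble_network(net$wcc$vertices,
                                data.frame(source = "A", target = "GHOST",
                                           etype = "product", logic = "disjunct")),
               "unknown vertices")

  # empty inputs give the empty graph
  empty <- reconstruct_network(withr::local_tempdir())
  expect_equal(n_vertices(empty$full), 0)
})

test_that("TOY-8 round-trips through flat files to an isomorphic graph", {
  dir <- withr::local_tempdir()
  emit_flat_files(toy8_graph(), dir)
  rec <- reconstruct_network(dir)
  expect_graph_identical(rec$full, toy8_graph())
  expect_graph_identical(rec$wcc, toy8_graph())
})
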