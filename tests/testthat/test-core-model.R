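test_that("reference map TSV parsing: shapes, pathway splitting, errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("edge_id\tsubstrate\tproduct\tec\tpathways",
               "e1\tC1\tC2\t1.1.1.1\t",
               "e2\tC2\tC3\t2.2.2.2\tmap00010;map00020"), f)
  mp <- load_reference_map(f)
  expect_equal(length(mp$compounds), 3L)
  expect_equal(nrow(mp$edges), 2L)
  expect_equal(mp$adjacency, list(2L, 1L))  # share C2
  expect_equal(mp$edges$pathways[[1L]], character(0))
  expect_setequal(mp$edges$pathways[[2L]], c("map00010", "map00020"))
  expect_identical(mp$label_index[["1.1.1.1"]], "e1")

  writeLines(c("edge_id\tsubstrate\tproduct\tec\tpathways",
               "e1\tC1\tC2\t1.1.1.1\t",
               "e1\tC2\tC3\t2.2.2.2\t"), f)
  expect_error(load_reference_map(f), "e1")

  writeLines(c("edge_id\tsubstrate\tproduct\tec\tpathways",
               "e1\tC1\tC2\t\t"), f)
  expect_error(load_reference_map(f), "EC")

  writeLines(c("edge_id\tsubstrate\tproduct\tec\tpathways",
               "e1\tC1\tC2\t1.1.1.1\tmapX",
               "e2\tC2\tC3"), f)
  expect_error(load_reference_map(f), "line 3")
})

test_that("profile TSV parsing: defaults, ordering, errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("organism\tec\tcopy_number",
               "o1\tA\t2", "o2\tA\t1", "o2\tB\t1"), f)
  pr <- load_profiles(f)
  expect_identical(pr$organisms, c("o1", "o2"))
  expect_equal(unname(pr$presence[, "A"]), c(TRUE, TRUE))
  expect_equal(unname(pr$presence[, "B"]), c(FALSE, TRUE))
  expect_equal(unname(pr$copy_number[, "A"]), c(2L, 1L))

  # copy_number column absent -> copy 1 for listed pairs
  writeLines(c("organism\tec", "o1\tA", "o2\tB"), f)
  pr2 <- load_profiles(f)
  expect_equal(unname(pr2$copy_number[, "A"]), c(1L, 0L))

  writeLines(c("organism\tec\tcopy_number", "o1\tA\t-1"), f)
  expect_error(load_profiles(f), "negative")

  writeLines("organism\tec\tcopy_number", f)
  expect_error(load_profiles(f), "empty")

  # explicit organism order is respected and validated
  writeLines(c("organism\tec\tcopy_number", "o2\tA\t1"), f)
  pr3 <- load_profiles(f, organisms_order = c("o9", "o2"))
  expect_identical(pr3$organisms, c("o9", "o2"))
  expect_error(load_profiles(f, organisms_order = "o9"), "not covered")
})

test_that("TSV writers round-trip the in-memory objects exactly", {
  ds <- make_systematic_validation_dataset(
    synthetic_spec(n_edges = 40L, n_pathways = 2L, pathway_size = 3L,
                   n_pos = 6L, n_neg = 6L, n_compounds = 10L, n_labels = 8L,
                   rng_seed = 3L))
  dir <- withr::local_tempdir()
  fmap <- file.path(dir, "refmap.tsv")
  fpro <- file.path(dir, "profiles.tsv")
  fphe <- file.path(dir, "phenotype.tsv")
  write_reference_map(ds$map, fmap)
  write_profiles(ds$profiles, fpro)
  write_phenotype(ds$phenotype, fphe)
  mp2 <- load_reference_map(fmap)
  expect_equal(mp2$edges, ds$map$edges)
  expect_identical(mp2$compounds, ds$map$compounds)
  ph2 <- load_phenotype(fphe)
  expect_identical(ph2$labels, ds$phenotype$labels)
  pr2 <- load_profiles(fpro, organisms_order = ph2$organisms)
  # writer drops all-absent labels; the loaded matrix must agree where defined
  common <- intersect(colnames(pr2$presence), colnames(ds$profiles$presence))
  expect_identical(pr2$presence[, common], ds$profiles$presence[, common])
  expect_true(all(ds$profiles$presence[, setdiff(colnames(ds$profiles$presence),
                                                 common)] == FALSE))
})

test_that("subsystem presence is a conjunction over distinct labels", {
  mp <- path_map(); pr <- path_profiles()
  expect_equal(unname(subsystem_presence(mp, pr, c("e1", "e2"))),
               c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  # empty set: vacuous conjunction
  expect_true(all(subsystem_presence(mp, pr, character(0))))
  # duplicate-label rule: a second edge with the same label adds no constraint
  mp2 <- reference_map(data.frame(
    edge_id = c("a", "b"), substrate = c("C1", "C2"), product = c("C2", "C3"),
    ec = c("1.1.1.1", "1.1.1.1"), pathways = ""))
  expect_equal(subsystem_presence(mp2, pr, c("a", "b")),
               subsystem_presence(mp2, pr, "a"))
  # label absent from the profiles -> all-zero vector
  mp3 <- reference_map(data.frame(
    edge_id = "z", substrate = "C1", product = "C2", ec = "9.9.9.9",
    pathways = ""))
  expect_false(any(subsystem_presence(mp3, pr, "z")))
  expect_error(subsystem_presence(mp, pr, "nope"), "unknown edge")
})

test_that("support counts and connectivity behave per definition", {
  phen <- phenotype_profile(stats::setNames(c(TRUE, TRUE, FALSE, FALSE),
                                            sprintf("o%d", 1:4)))
  expect_equal(support_counts(c(TRUE, TRUE, FALSE, TRUE), phen),
               c(k = 3L, k_p = 2L))
  expect_equal(support_counts(rep(FALSE, 4), phen), c(k = 0L, k_p = 0L))
  expect_equal(support_counts(unname(phen$labels), phen), c(k = 2L, k_p = 2L))
  expect_error(support_counts(c(TRUE, TRUE), phen), "length")

  mp <- path_map()
  expect_true(is_connected_subsystem(mp, c("e1", "e2")))
  expect_false(is_connected_subsystem(mp, c("e1", "e4")))
  expect_true(is_connected_subsystem(mp, character(0)))
  expect_true(is_connected_subsystem(mp, "e4"))
  expect_error(is_connected_subsystem(mp, "zz"), "unknown edge")
})

test_that("presence is anti-monotone in the edge set", {
  for (seed in 1:10) {
    b <- random_instance(seed)
    ids <- b$map$edges$edge_id
    phen <- b$phenotype
    set.seed(seed)
    for (r in 1:5) {
      sz <- sample.int(length(ids) - 1L, 1L)
      A <- sample(ids, sz)
      B <- unique(c(A, sample(ids, 2L)))
      pA <- subsystem_presence(b$map, b$profiles, A)
      pB <- subsystem_presence(b$map, b$profiles, B)
      expect_true(all(pB <= pA))
      sA <- support_counts(pA, phen); sB <- support_counts(pB, phen)
      expect_lte(sB[["k"]], sA[["k"]])
      expect_lte(sB[["k_p"]], sA[["k_p"]])
      # order-independence
      expect_identical(subsystem_presence(b$map, b$profiles, rev(B)), pB)
    }
  }
})

test_that("constructors enforce the type invariants", {
  expect_error(phenotype_profile(stats::setNames(c(TRUE, TRUE), c("a", "b"))),
               "non-empty")
  P <- matrix(TRUE, 2, 1, dimnames = list(c("a", "b"), "L"))
  cn <- matrix(c(1L, 0L), 2, 1)
  expect_error(profile_matrix(P, cn), "presence bit")
  expect_error(profile_matrix(P, matrix(-1L, 2, 1)), "non-negative")
  df <- data.frame(edge_id = "e", substrate = "A", product = "B", ec = "x",
                   pathways = "")
  expect_s3_class(reference_map(df), "reference_map")
})
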