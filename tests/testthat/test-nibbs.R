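test_that("seed generation follows the greedy least-alpha schedule", {
  # eB (alpha 1/20) founds first; eA (alpha 3/15) cannot lower it, so each
  # edge founds its own seed
  mp <- reference_map(data.frame(
    edge_id = c("eA", "eB"), substrate = c("C1", "C2"),
    product = c("C2", "C3"), ec = c("A", "B"), pathways = ""))
  orgs <- sprintf("o%d", 1:6)
  P <- matrix(FALSE, 6, 2, dimnames = list(orgs, c("A", "B")))
  P[, "A"] <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  P[, "B"] <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  pr <- profile_matrix(P)
  ph <- phenotype_profile(stats::setNames(seq_len(6) <= 3, orgs))
  seeds <- generate_seed_sets(mp, pr, ph)
  expect_equal(lapply(seeds, `[[`, "edge_ids"), list("eB", "eA"))
  expect_equal(vapply(seeds, `[[`, 0, "alpha"), c(0.05, 0.2),
               tolerance = 1e-12)
  expect_equal(vapply(seeds, `[[`, "", "born_from"), c("eB", "eA"))

  # when a neighbour lowers alpha, the seed absorbs (and marks) it: eA and eB
  # tie at alpha 3/15, eA founds by id, and the pair reaches 1/20
  P2 <- P
  P2[, "A"] <- c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE)
  P2[, "B"] <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  pr2 <- profile_matrix(P2)
  seeds2 <- generate_seed_sets(mp, pr2, ph)
  expect_length(seeds2, 1L)
  expect_equal(seeds2[[1L]]$edge_ids, c("eA", "eB"))
  expect_equal(seeds2[[1L]]$alpha, 0.05, tolerance = 1e-12)
})

test_that("every edge has alpha 1 -> all seeds are singletons; k_max=1 forces singletons", {
  mp <- path_map()
  P <- matrix(TRUE, 6, 4,
              dimnames = list(sprintf("o%d", 1:6),
                              c("1.1.1.1", "2.2.2.2", "3.3.3.3", "4.4.4.4")))
  pr <- profile_matrix(P)
  ph <- path_phen()
  seeds <- generate_seed_sets(mp, pr, ph)
  expect_true(all(lengths(lapply(seeds, `[[`, "edge_ids")) == 1L))

  b <- random_instance(2)
  seeds1 <- generate_seed_sets(b$map, b$profiles, b$phenotype,
                               nibbs_params(k_max = 1L))
  expect_true(all(lengths(lapply(seeds1, `[[`, "edge_ids")) == 1L))
})

test_that("seed-set coverage and strict alpha descent along growth", {
  for (seed in c(3, 8, 21)) {
    b <- random_instance(seed, m = 10L)
    seeds <- generate_seed_sets(b$map, b$profiles, b$phenotype)
    expect_setequal(unlist(lapply(seeds, `[[`, "edge_ids")),
                    b$map$edges$edge_id)
    for (s in seeds) {
      along <- vapply(seq_along(s$edge_ids), function(i)
        subsystem_alpha(b$map, b$profiles, b$phenotype, s$edge_ids[seq_len(i)]),
        0)
      expect_true(all(diff(along) < 0) || length(along) == 1L)
      expect_equal(s$alpha, along[length(along)], tolerance = 1e-12)
    }
  }
})

test_that("seed candidates respect adjacency, marking and the path-checked rule", {
  mp <- path_map(); pr <- path_profiles(); ph <- path_phen()
  # connected method: e3 is adjacent to e2, e4 is not
  cand <- generate_seed_candidates(mp, pr, ph, "e2", method = "connected")
  expect_true(all(cand$edge_id %in% c("e1", "e3")))
  # marked edges are excluded even if they would decrease alpha
  cand2 <- generate_seed_candidates(mp, pr, ph, "e1", marked = "e2",
                                    method = "connected")
  expect_false("e2" %in% cand2$edge_id)
  # candidates must strictly decrease alpha: e3 (ubiquitous) never qualifies
  expect_false("e3" %in%
    generate_seed_candidates(mp, pr, ph, "e1", method = "connected")$edge_id)

  # path-checked: eD is joined to eA by a path (eB, eC) whose labels are
  # present in every positive instance the augmented seed is present in
  mp4 <- reference_map(data.frame(
    edge_id = c("eA", "eB", "eC", "eD"),
    substrate = c("C1", "C2", "C3", "C4"), product = c("C2", "C3", "C4", "C5"),
    ec = c("A", "B", "C", "D"), pathways = ""))
  orgs <- sprintf("o%d", 1:6)
  P <- matrix(FALSE, 6, 4, dimnames = list(orgs, c("A", "B", "C", "D")))
  P[, "A"] <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  P[, "B"] <- P[, "C"] <- c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE)
  P[, "D"] <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  pr4 <- profile_matrix(P)
  ph4 <- phenotype_profile(stats::setNames(seq_len(6) <= 3, orgs))
  got <- generate_seed_candidates(mp4, pr4, ph4, "eA", method = "path_checked")
  expect_true("eD" %in% got$edge_id)
  # connected method excludes the same non-adjacent edge
  got2 <- generate_seed_candidates(mp4, pr4, ph4, "eA", method = "connected")
  expect_false("eD" %in% got2$edge_id)
  # severing the path (eC absent from a supporting positive) excludes eD
  P[3, "C"] <- FALSE
  got3 <- generate_seed_candidates(mp4, profile_matrix(P), ph4, "eA",
                                   method = "path_checked")
  expect_false("eD" %in% got3$edge_id)
})

test_that("expansion preserves support floors and absorbs neutral neighbours", {
  # seed {eA,eB} in 3 positives only; adjacent eC present everywhere:
  # delta=1 keeps the positive count at 3 and alpha stays 0.05
  mp <- reference_map(data.frame(
    edge_id = c("eA", "eB", "eC"),
    substrate = c("C1", "C2", "C3"), product = c("C2", "C3", "C4"),
    ec = c("A", "B", "C"), pathways = ""))
  orgs <- sprintf("o%d", 1:6)
  P <- matrix(FALSE, 6, 3, dimnames = list(orgs, c("A", "B", "C")))
  P[1:3, c("A", "B")] <- TRUE
  P[, "C"] <- TRUE
  pr <- profile_matrix(P)
  ph <- phenotype_profile(stats::setNames(seq_len(6) <= 3, orgs))
  sub <- expand_seed_set(mp, pr, ph, list(edge_ids = c("eA", "eB")),
                         nibbs_params(rng_seed = 1L))
  expect_setequal(sub$edge_ids, c("eA", "eB", "eC"))
  expect_equal(sub$alpha, 0.05, tolerance = 1e-12)
  expect_equal(sub$k_p, 3L)

  # no adjacent edges -> output equals the seed
  sub4 <- expand_seed_set(path_map(), path_profiles(), path_phen(),
                          list(edge_ids = "e4"), nibbs_params(rng_seed = 1L))
  expect_equal(sub4$edge_ids, "e4")

  # delta = 1 with every neighbour absent from one supporting positive
  P2 <- P
  P2[3, "C"] <- FALSE
  sub2 <- expand_seed_set(mp, profile_matrix(P2), ph,
                          list(edge_ids = c("eA", "eB")),
                          nibbs_params(rng_seed = 1L))
  expect_setequal(sub2$edge_ids, c("eA", "eB"))
  # ... but delta = 2/3 lets it in
  sub3 <- expand_seed_set(mp, profile_matrix(P2), ph,
                          list(edge_ids = c("eA", "eB")),
                          nibbs_params(delta = 2 / 3, rng_seed = 1L))
  expect_setequal(sub3$edge_ids, c("eA", "eB", "eC"))
})

test_that("nibbs_search output contract: filtering, dedup, order, determinism", {
  b <- random_instance(13)
  params <- nibbs_params(rng_seed = 7L)
  out1 <- nibbs_search(b$map, b$profiles, b$phenotype, params)
  out2 <- nibbs_search(b$map, b$profiles, b$phenotype, params)
  expect_identical(as.data.frame(out1), as.data.frame(out2))
  alphas <- vapply(out1, `[[`, 0, "alpha")
  expect_true(all(diff(alphas) >= 0))
  keys <- vapply(out1, function(s) set_key(s$edge_ids), "")
  expect_false(any(duplicated(keys)))
  for (s in out1) {
    expect_true(is_connected_subsystem(b$map, s$edge_ids))
    expect_true(all(s$seed_edge_ids %in% s$edge_ids))
    expect_lt(subsystem_alpha(b$map, b$profiles, b$phenotype, s$seed_edge_ids),
              params$alpha_s)
    # delta = 1: the expanded set keeps every seed-supporting positive
    seed_kp <- support_counts(
      subsystem_presence(b$map, b$profiles, s$seed_edge_ids), b$phenotype)
    expect_equal(s$k_p, seed_kp[["k_p"]])
  }
  # alpha_s = 0 admits no seeds
  expect_length(nibbs_search(b$map, b$profiles, b$phenotype,
                             nibbs_params(alpha_s = 0, rng_seed = 1L)), 0L)
})

test_that("nibbs recovers the planted core on a validation fixture", {
  ds <- make_systematic_validation_dataset(
    synthetic_spec(n_edges = 60L, n_pathways = 2L, pathway_size = 4L,
                   n_pos = 10L, n_neg = 10L, n_compounds = 15L,
                   n_labels = 12L, noise = 0, rng_seed = 5L))
  out <- nibbs_search(ds$map, ds$profiles, ds$phenotype,
                      nibbs_params(rng_seed = 5L))
  recovered <- unique(unlist(lapply(out, `[[`, "edge_ids")))
  expect_true(all(unlist(ds$truth$edge_ids) %in% recovered))
})

test_that("subsystem JSON round-trips the output contract", {
  b <- random_instance(4)
  out <- nibbs_search(b$map, b$profiles, b$phenotype, nibbs_params(rng_seed = 2L))
  f <- withr::local_tempfile(fileext = ".json")
  write_subsystems(out, f)
  back <- read_subsystems(f)
  expect_length(back, length(out))
  for (i in seq_along(out)) {
    expect_identical(back[[i]]$edge_ids, out[[i]]$edge_ids)
    expect_identical(back[[i]]$ec_labels, out[[i]]$ec_labels)
    expect_equal(back[[i]]$alpha, out[[i]]$alpha, tolerance = 1e-12)
  }
})
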