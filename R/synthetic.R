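# Synthetic data with planted phenotype-biased pathways.
#
# The systematic-validation construction plants a group of specialized
# pathways as an artificial phenotype: every organism receives background
# enzymes at a fixed presence rate, the planted pathway enzymes are then
# removed from every phenotype-non-expressing (N-group) organism, and kept
# in the expressing (P-group) organisms up to independent noise flips.  A
# search method that truly finds phenotype-related subsystems must recover
# the planted pathways as significant.

#' Specification for the synthetic generators
#'
#' Defaults mirror the validation construction at desk scale: 13 planted
#' pathways of 6 edges each, 130 organisms split 65/65 into P and N groups,
#' background enzymes present in any organism with probability 0.5, and a 5%
#' chance that a planted enzyme is flipped absent in a P-group organism.
#' Planted enzymes are never reused by background edges, so the artificial
#' bias is fully attributable.
#'
#' @param n_compounds background compound count.
#' @param n_edges total edge count (planted + background).
#' @param n_labels size of the background EC-label pool (labels are reused
#'   across background edges).
#' @param n_pathways number of planted pathways.
#' @param pathway_size edges per planted pathway.
#' @param n_pos,n_neg organism counts in the P and N groups.
#' @param background_presence probability a background label is present in
#'   any given organism.
#' @param noise probability a planted label is flipped absent in a P-group
#'   organism.
#' @param rng_seed integer seed; all generators are pure functions of
#'   (spec, seed).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_compounds = 60L, n_edges = 300L, n_labels = 40L,
                           n_pathways = 13L, pathway_size = 6L,
                           n_pos = 65L, n_neg = 65L,
                           background_presence = 0.5, noise = 0.05,
                           rng_seed = 1L) {
  spec <- list(
    n_compounds = assert_count(n_compounds, "n_compounds", 2L),
    n_edges = assert_count(n_edges, "n_edges", 1L),
    n_labels = assert_count(n_labels, "n_labels", 1L),
    n_pathways = assert_count(n_pathways, "n_pathways", 0L),
    pathway_size = assert_count(pathway_size, "pathway_size", 1L),
    n_pos = assert_count(n_pos, "n_pos", 1L),
    n_neg = assert_count(n_neg, "n_neg", 1L),
    background_presence = background_presence,
    noise = noise,
    rng_seed = assert_count(rng_seed, "rng_seed", 0L))
  for (pr in c("background_presence", "noise"))
    if (!is.numeric(spec[[pr]]) || spec[[pr]] < 0 || spec[[pr]] > 1)
      stop_input("`", pr, "` must be a probability in [0, 1]")
  if (spec$n_pathways * spec$pathway_size > spec$n_edges)
    stop_input("n_edges too small for the planted pathways (need >= ",
               spec$n_pathways * spec$pathway_size, ")")
  class(spec) <- "synthetic_spec"
  spec
}

#' Generate a reference map with planted pathways
#'
#' Builds a random connected background graph and plants `n_pathways`
#' edge-disjoint connected chains of `pathway_size` edges, each tagged with
#' its pathway id (`p01`, `p02`, ...) and anchored to a random background
#' compound.  Planted edges carry unique labels; background edges reuse
#' labels from the background pool and are grouped into background pathways
#' (`bg01`, ...).  Each planted pathway additionally receives up to
#' `2 * pathway_size` pendant "periphery" edges hanging off its compounds,
#' labeled from the background pool and tagged with the pathway id: they
#' emulate the reactions a reference pathway map carries beyond the biased
#' subsystem itself, so a pathway's population is larger than any
#' organism-specific restriction of it.
#'
#' The planted structure is attached as `attr(map, "planted")`: a list with
#' `pathway_ids`, per-pathway `edge_ids`, and `labels`.
#'
#' @param spec a [synthetic_spec()].
#' @param rng_seed seed, defaulting to `spec$rng_seed`.
#' @return A [reference_map()].
#' @export
generate_reference_map <- function(spec, rng_seed = spec$rng_seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(rng_seed, {
    n_planted <- spec$n_pathways * spec$pathway_size
    n_avail <- spec$n_edges - n_planted
    periphery_per <- if (spec$n_pathways > 0L)
      min(2L * spec$pathway_size, n_avail %/% (spec$n_pathways + 1L)) else 0L
    n_bg <- n_avail - periphery_per * spec$n_pathways
    bg <- NULL
    bg_comp <- character(0)
    if (n_bg > 0L) {
      n_c <- min(spec$n_compounds, n_bg + 1L)
      bg_comp <- sprintf("c%03d", seq_len(n_c))
      sub <- prod <- character(n_bg)
      for (i in seq_len(min(n_c - 1L, n_bg))) {   # random spanning tree
        sub[i] <- bg_comp[sample.int(i, 1L)]
        prod[i] <- bg_comp[i + 1L]
      }
      extra <- which(!nzchar(sub))
      for (i in extra) {
        pair <- sample.int(n_c, 2L)
        sub[i] <- bg_comp[pair[1L]]; prod[i] <- bg_comp[pair[2L]]
      }
      lab_idx <- sample.int(spec$n_labels, n_bg, replace = TRUE)
      bg <- data.frame(
        edge_id = sprintf("be%03d", seq_len(n_bg)),
        substrate = sub, product = prod,
        ec = sprintf("1.1.%d.1", lab_idx),
        pathways = sprintf("bg%02d", (seq_len(n_bg) - 1L) %/%
                             spec$pathway_size + 1L))
    }
    planted <- list()
    prows <- list()
    for (j in seq_len(spec$n_pathways)) {
      anchor <- if (length(bg_comp)) sample(bg_comp, 1L) else
        sprintf("pc%02d_0", j)
      comp <- c(anchor, sprintf("pc%02d_%d", j, seq_len(spec$pathway_size)))
      ids <- sprintf("pe%02d_%d", j, seq_len(spec$pathway_size))
      labs <- sprintf("9.%d.%d.1", j, seq_len(spec$pathway_size))
      rows <- data.frame(
        edge_id = ids,
        substrate = comp[-length(comp)], product = comp[-1L],
        ec = labs, pathways = sprintf("p%02d", j))
      if (periphery_per > 0L) {
        at <- sample(comp[-1L], periphery_per, replace = TRUE)
        rows <- rbind(rows, data.frame(
          edge_id = sprintf("xe%02d_%d", j, seq_len(periphery_per)),
          substrate = at,
          product = sprintf("xc%02d_%d", j, seq_len(periphery_per)),
          ec = sprintf("1.1.%d.1", sample.int(spec$n_labels, periphery_per,
                                              replace = TRUE)),
          pathways = sprintf("p%02d", j)))
      }
      prows[[j]] <- rows
      planted[[j]] <- list(pathway_id = sprintf("p%02d", j),
                           edge_ids = ids, labels = labs)
    }
    edges <- rbind(do.call(rbind, prows), bg)
    if (is.null(edges)) stop_input("spec generates no edges")
    map <- reference_map(edges)
    attr(map, "planted") <- list(
      pathway_ids = vapply(planted, `[[`, "", "pathway_id"),
      edge_ids = lapply(planted, `[[`, "edge_ids"),
      labels = lapply(planted, `[[`, "labels"))
    map
  })
}

#' Build the systematic-validation dataset
#'
#' Generates the planted-pathway reference map, then organism profiles: all
#' organisms receive background labels independently at
#' `background_presence`; all planted labels are given to every organism and
#' then *removed from every N-group organism*, creating the artificial bias;
#' each P-group organism additionally loses each planted label independently
#' with probability `noise`.  Copy numbers are 1 wherever present.
#'
#' @param spec a [synthetic_spec()].
#' @param rng_seed seed, defaulting to `spec$rng_seed`.
#' @return List with `map`, `profiles`, `phenotype` and `truth` (a list with
#'   `pathway_ids`, per-pathway `edge_ids`, and `planted_labels`, the planted
#'   enzyme complement defining the artificial phenotype).
#' @export
make_systematic_validation_dataset <- function(spec, rng_seed = spec$rng_seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  map <- generate_reference_map(spec, rng_seed = derive_seed(rng_seed, 1L))
  planted <- attr(map, "planted")
  planted_labels <- unlist(planted$labels)
  bg_labels <- sort(setdiff(unique(map$edges$ec), planted_labels))
  n_org <- spec$n_pos + spec$n_neg
  orgs <- sprintf("org%03d", seq_len(n_org))
  pos <- seq_len(spec$n_pos)
  pres <- with_seed(derive_seed(rng_seed, 2L), {
    P <- matrix(FALSE, n_org, length(bg_labels) + length(planted_labels),
                dimnames = list(orgs, c(bg_labels, planted_labels)))
    P[, bg_labels] <- stats::runif(n_org * length(bg_labels)) <
      spec$background_presence
    keep <- matrix(stats::runif(spec$n_pos * length(planted_labels)) >=
                     spec$noise, spec$n_pos, length(planted_labels))
    P[pos, planted_labels] <- keep
    P
  })
  profiles <- profile_matrix(pres)
  phen <- phenotype_profile(stats::setNames(seq_len(n_org) %in% pos, orgs))
  list(map = map, profiles = profiles, phenotype = phen,
       truth = list(pathway_ids = planted$pathway_ids,
                    edge_ids = planted$edge_ids,
                    planted_labels = planted_labels))
}

#' Generate a battery of random small instances
#'
#' Drives oracle-equivalence and approximation experiments: each instance is
#' a small random connected map with a planted biased core (a random
#' connected edge subset whose labels are present in every
#' phenotype-expressing organism and rarely in the others) plus unbiased
#' labels present at a moderate background rate.  Deterministic per seed.
#'
#' Organism counts are drawn from 9..10 (with 6 organisms split 3/3 the best
#' achievable alpha is exactly 0.05, which the strict `alpha < alpha_s` seed
#' filter would always exclude, leaving nothing to measure) and the maps are
#' kept dense -- compounds about half the edge count -- so the space of
#' connected subgraphs, i.e. the permutation null, is rich even at a dozen
#' edges.
#'
#' @param n_instances number of instances.
#' @param size_bounds integer vector `c(min, max)` for the edge count.
#' @param rng_seed integer seed.
#' @param core_negative_rate probability a core label leaks into a
#'   non-expressing organism.
#' @param background_rate presence probability of non-core labels.
#' @return List of instances, each a list with `map`, `profiles`,
#'   `phenotype`, `core_edge_ids`.
#' @export
generate_instance_battery <- function(n_instances, size_bounds = c(10L, 12L),
                                      rng_seed = 1L,
                                      core_negative_rate = 0.15,
                                      background_rate = 0.6) {
  n_instances <- assert_count(n_instances, "n_instances", 1L)
  stopifnot(length(size_bounds) == 2L, size_bounds[1L] >= 1L,
            size_bounds[1L] <= size_bounds[2L])
  lapply(seq_len(n_instances), function(inst) {
    with_seed(derive_seed(rng_seed, inst), {
      m <- if (size_bounds[1L] == size_bounds[2L]) size_bounds[1L] else
        sample(size_bounds[1L]:size_bounds[2L], 1L)
      n_c <- max(2L, ceiling(m / 2) + 1L)
      comp <- sprintf("x%02d", seq_len(n_c))
      sub <- prod <- character(m)
      for (i in seq_len(min(n_c - 1L, m))) {
        sub[i] <- comp[sample.int(i, 1L)]; prod[i] <- comp[i + 1L]
      }
      for (i in seq_len(m)[-seq_len(min(n_c - 1L, m))]) {
        pair <- sample.int(n_c, 2L)
        sub[i] <- comp[pair[1L]]; prod[i] <- comp[pair[2L]]
      }
      lab <- character(m)
      n_lab <- 0L
      for (i in seq_len(m)) {
        if (n_lab > 0L && stats::runif(1) < 0.1) {
          lab[i] <- sprintf("2.7.%d.1", sample.int(n_lab, 1L))
        } else {
          n_lab <- n_lab + 1L
          lab[i] <- sprintf("2.7.%d.1", n_lab)
        }
      }
      map <- reference_map(data.frame(
        edge_id = sprintf("e%02d", seq_len(m)),
        substrate = sub, product = prod, ec = lab, pathways = ""))
      # planted biased core: random connected edge subset
      k_core <- min(m, sample(3:4, 1L))
      core <- sample.int(m, 1L)
      while (length(core) < k_core) {
        fr <- setdiff(unique(unlist(map$adjacency[core])), core)
        if (!length(fr)) break
        core <- c(core, sample_one(fr))
      }
      core_labs <- unique(lab[core])
      n_org <- sample(9:10, 1L)
      p <- n_org %/% 2L
      orgs <- sprintf("o%02d", seq_len(n_org))
      labs_all <- sort(unique(lab))
      P <- matrix(stats::runif(n_org * length(labs_all)) < background_rate,
                  n_org, length(labs_all), dimnames = list(orgs, labs_all))
      P[seq_len(p), core_labs] <- TRUE
      P[(p + 1L):n_org, core_labs] <-
        stats::runif((n_org - p) * length(core_labs)) < core_negative_rate
      list(map = map,
           profiles = profile_matrix(P),
           phenotype = phenotype_profile(
             stats::setNames(seq_len(n_org) <= p, orgs)),
           core_edge_ids = sort(map$edges$edge_id[core]))
    })
  })
}
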