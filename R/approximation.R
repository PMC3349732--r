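# Jaccard-based approximation score between the NIBBS output and the exact
# maximally-biased subgraph set, with empirical p-values from random
# connected-subgraph null sets.

#' Jaccard index of two edge sets
#'
#' `|a intersect b| / |a union b|`; two empty sets score 1 by convention
#' (identical sets).
#'
#' @param a,b character vectors (edge-id sets; duplicates ignored).
#' @return Score in [0, 1].
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

#' Approximation score of a subgraph set against the exact MBS set
#'
#' For each maximally-biased subgraph `m_i` in `M`, `J_i` is the best Jaccard
#' index against any subgraph in `G`.  The score is the normalized Euclidean
#' (root-mean-square) distance between the vector `J` and the all-ones
#' optimum: `S = sqrt(sum((1 - J_i)^2) / |M|)`.  `S = 0` iff every `m_i` is
#' matched exactly; `S = 1` when nothing overlaps.  An empty `G` scores every
#' `J_i = 0`, hence `S = 1`.
#'
#' @param M non-empty list of edge-id sets (the exact MBS collection).
#' @param G list of edge-id sets (e.g. [nibbs_search()] output), possibly
#'   empty.
#' @return List with `J` (per-MBS best Jaccard scores) and `S`.
#' @export
approximation_score <- function(M, G) {
  M <- edge_id_sets(M)
  G <- edge_id_sets(G)
  if (!length(M)) stop_input("`M` must be non-empty")
  J <- vapply(M, function(m) {
    if (!length(G)) return(0)
    max(vapply(G, jaccard_index, 0, a = m))
  }, 0)
  list(J = J, S = sqrt(mean((1 - J)^2)))
}

#' Sample a random connected subgraph of a given size
#'
#' Uniformly chooses a start edge, then repeatedly adds a uniformly chosen
#' frontier edge (an edge sharing a compound with the current set) until the
#' requested size is reached.  This frontier sampler is fast but *not*
#' uniform over all connected subgraphs of that size, matching its use as a
#' permutation-null generator.  If growth gets stuck (start edge in a
#' too-small component) it retries with a fresh start, and errors after
#' `max_tries` failures.
#'
#' @param map a [reference_map()].
#' @param size number of edges, `>= 1`.
#' @param rng_seed optional integer seed (otherwise the caller's RNG stream
#'   is used).
#' @param max_tries bounded number of restarts.
#' @return Character vector of `size` edge ids forming a connected subsystem.
#' @export
sample_random_connected_subgraph <- function(map, size, rng_seed = NULL,
                                             max_tries = 100L) {
  stopifnot(inherits(map, "reference_map"))
  size <- assert_count(size, "size", 1L)
  m <- nrow(map$edges)
  if (size > m) stop_input("`size` exceeds the number of edges (", m, ")")
  adj <- map$adjacency
  draw <- function() {
    for (try in seq_len(max_tries)) {
      cur <- sample.int(m, 1L)
      frontier <- adj[[cur]]
      while (length(cur) < size) {
        frontier <- setdiff(frontier, cur)
        if (!length(frontier)) break
        nxt <- sample_one(frontier)
        cur <- c(cur, nxt)
        frontier <- union(frontier, adj[[nxt]])
      }
      if (length(cur) == size) return(sort(map$edges$edge_id[cur]))
    }
    stop_input("could not grow a connected subgraph of size ", size,
               " in ", max_tries, " attempts")
  }
  with_seed(rng_seed, draw())
}

# Internal index-based sampler reusing precomputed adjacency (hot loop of
# empirical_pvalues); consumes the current RNG stream.
sample_connected_idx <- function(adj, m, size, max_tries = 100L) {
  for (try in seq_len(max_tries)) {
    cur <- sample.int(m, 1L)
    frontier <- adj[[cur]]
    while (length(cur) < size) {
      frontier <- setdiff(frontier, cur)
      if (!length(frontier)) break
      nxt <- sample_one(frontier)
      cur <- c(cur, nxt)
      frontier <- union(frontier, adj[[nxt]])
    }
    if (length(cur) == size) return(cur)
  }
  stop_input("could not grow a connected subgraph of size ", size)
}

#' Empirical p-values for an approximation score
#'
#' Builds `n_random_sets` null replicates, each containing `|G|` random
#' connected subgraphs of the map, and compares their approximation scores
#' against `S(G)`.  Two null variants are computed in one pass:
#' `p1` draws each random subgraph's size uniformly from the multiset of
#' sizes in `G`; `p2` size-matches exactly (the j-th random subgraph has the
#' size of G's j-th subgraph).  Both use the add-one estimator
#' `p = (1 + #\{S(R) <= S(G)\}) / (n_random_sets + 1)`, so p is never zero.
#' With an empty `G` every replicate ties `S = 1` and both p-values are 1.
#'
#' @param M non-empty list of edge-id sets (exact MBS collection).
#' @param G list of edge-id sets (heuristic output).
#' @param map the [reference_map()] the subgraphs live in.
#' @param n_random_sets number of null replicates (>= 1), default 1000.
#' @param rng_seed optional integer seed.
#' @return An object of class `approx_report`: list with `J`, `S`, `p1`,
#'   `p2`, `n_random_sets`.
#' @export
empirical_pvalues <- function(M, G, map, n_random_sets = 1000L,
                              rng_seed = NULL) {
  stopifnot(inherits(map, "reference_map"))
  n_random_sets <- assert_count(n_random_sets, "n_random_sets", 1L)
  M <- edge_id_sets(M); G <- edge_id_sets(G)
  obs <- approximation_score(M, G)
  adj <- map$adjacency
  m <- nrow(map$edges)
  ids <- map$edges$edge_id
  M_idx <- lapply(M, function(s) match(unique(s), ids))
  sizes <- vapply(G, function(g) length(unique(g)), 0L)
  score_of <- function(R_idx) {
    J <- vapply(M_idx, function(mi) {
      if (!length(R_idx)) return(0)
      max(vapply(R_idx, function(ri)
        length(intersect(mi, ri)) / length(union(mi, ri)), 0))
    }, 0)
    sqrt(mean((1 - J)^2))
  }
  run <- function() {
    hit1 <- 0L; hit2 <- 0L
    for (r in seq_len(n_random_sets)) {
      if (length(sizes)) {
        sz1 <- sizes[sample.int(length(sizes), length(sizes), replace = TRUE)]
        R1 <- lapply(sz1, function(s) sample_connected_idx(adj, m, s))
        R2 <- lapply(sizes, function(s) sample_connected_idx(adj, m, s))
      } else {
        R1 <- list(); R2 <- list()
      }
      if (score_of(R1) <= obs$S) hit1 <- hit1 + 1L
      if (score_of(R2) <= obs$S) hit2 <- hit2 + 1L
    }
    c(hit1, hit2)
  }
  hits <- with_seed(rng_seed, run())
  out <- list(J = obs$J, S = obs$S,
              p1 = (1 + hits[1L]) / (n_random_sets + 1),
              p2 = (1 + hits[2L]) / (n_random_sets + 1),
              n_random_sets = n_random_sets)
  class(out) <- "approx_report"
  out
}

#' @export
print.approx_report <- function(x, ...) {
  cat(sprintf("approx_report: S=%.4f, p1=%.4g, p2=%.4g (%d random sets)\n",
              x$S, x$p1, x$p2, x$n_random_sets))
  invisible(x)
}
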