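# Exact enumeration of maximally-biased subgraphs.
#
# A maximally-biased subgraph (MBS) is a connected edge set g with
#   (1) no connected subgraph of g with alpha strictly below alpha(g), and
#   (2) no connected supergraph of g (within the map) with alpha <= alpha(g).
# "Subgraph"/"supergraph" are read as *connected* edge sets throughout,
# consistent with the network model in which only connected subgraphs are
# candidate metabolic systems.

#' Enumerate maximal frequent connected subgraphs
#'
#' A connected edge set is frequent when its positive support (the number of
#' phenotype-expressing organism networks it exists in) is at least
#' `threshold`; it is maximal when it is not a proper subset of another
#' connected frequent set.  Enumeration is a depth-first walk over connected
#' edge sets (each visited exactly once) with anti-monotone support pruning:
#' adding edges can only shrink the presence vector, so infrequent branches
#' are cut immediately.  Maximality needs only a one-edge check: any larger
#' connected frequent superset can be reached by adding one adjacent edge at
#' a time, and every intermediate set is frequent by anti-monotonicity.
#'
#' @param map a [reference_map()].
#' @param profiles a [profile_matrix()].
#' @param phen a [phenotype_profile()]; support counts positive organisms
#'   only.  Pass `NULL` to count support over all organisms.
#' @param threshold integer support threshold, `1 <= threshold <= |G+|`.
#' @return List of character edge-id sets (each sorted).
#' @export
enumerate_maximal_frequent_subgraphs <- function(map, profiles, phen, threshold) {
  ctx <- network_context(map, profiles, phen)
  pos <- if (is.null(phen)) seq_len(ctx$n_org) else ctx$pos
  threshold <- assert_count(threshold, "threshold", 1L)
  if (threshold > length(pos))
    stop_input("`threshold` must be between 1 and the positive instance count (",
               length(pos), ")")
  hits <- enum_max_frequent_idx(ctx, pos, threshold)
  lapply(hits, function(idx) sort(ctx$edge_ids[idx]))
}

# Core enumerator on integer edge indices.  Returns list of index vectors.
enum_max_frequent_idx <- function(ctx, pos, threshold) {
  m <- length(ctx$lab_col)
  Ppos <- ctx$P[pos, , drop = FALSE]
  edge_pres <- lapply(seq_len(m), function(i) Ppos[, ctx$lab_col[i]])
  adj <- ctx$adj
  results <- list()
  maximal <- function(sub, pres) {
    nb <- setdiff(sort(unique(unlist(adj[sub]))), sub)
    for (a in nb) if (sum(pres & edge_pres[[a]]) >= threshold) return(FALSE)
    TRUE
  }
  extend <- function(sub, pres, ext, root, excluded) {
    if (maximal(sub, pres)) results[[length(results) + 1L]] <<- sub
    while (length(ext)) {
      w <- ext[1L]; ext <- ext[-1L]
      new_pres <- pres & edge_pres[[w]]
      if (sum(new_pres) < threshold) next
      # new extension candidates: neighbours of w beyond the root, not
      # already in/adjacent-to the current set (ESU exclusive neighbourhood)
      cand <- adj[[w]]
      cand <- cand[cand > root & !excluded[cand]]
      excl2 <- excluded
      excl2[cand] <- TRUE
      excl2[w] <- TRUE
      extend(c(sub, w), new_pres, c(ext, cand), root, excl2)
    }
  }
  for (v in seq_len(m)) {
    pres <- edge_pres[[v]]
    if (sum(pres) < threshold) next
    ext <- adj[[v]][adj[[v]] > v]
    excluded <- rep(FALSE, m)
    excluded[v] <- TRUE
    excluded[ext] <- TRUE
    extend(v, pres, ext, v, excluded)
  }
  # cross-set subsumption safety net (should already hold by construction)
  if (length(results) > 1L) {
    keys <- lapply(results, sort)
    keep <- vapply(seq_along(keys), function(i) {
      !any(vapply(seq_along(keys), function(j)
        i != j && length(keys[[i]]) < length(keys[[j]]) &&
          all(keys[[i]] %in% keys[[j]]), NA))
    }, NA)
    results <- results[keep]
  }
  results
}

#' Exact enumeration of maximally-biased subgraphs (MBS-Enum)
#'
#' First enumerates all maximal frequent connected subgraphs of the positive
#' networks for every support threshold `1..|G+|` (plus the whole connected
#' components, which cover the degenerate zero-positive-support case), then
#' filters the deduplicated union down to the sets satisfying both MBS
#' criteria.  Criterion 1 is checked by exhaustive enumeration of the
#' candidate's connected subsets; criterion 2 by depth-first enumeration of
#' its connected supersets with an anti-monotone bound: once a superset's
#' positive support `k_p` is so low that even an all-positive-support
#' extension (`alpha(k_p, k_p)`, the smallest alpha any further superset can
#' reach) exceeds the candidate's alpha, the branch is cut.
#'
#' Exhaustive checking is intentional -- exactness is the contract -- so the
#' map size is guarded.
#'
#' @param map a [reference_map()].
#' @param profiles a [profile_matrix()].
#' @param phen a [phenotype_profile()].
#' @param max_edges_guard refuse maps with more edges than this unless
#'   `override_guard = TRUE`.
#' @param override_guard set `TRUE` to run anyway (may be very slow).
#' @return An object of class `mbs_result`: list with `subgraphs` (list of
#'   sorted edge-id sets), `alphas` (parallel numeric) and `thresholds_used`.
#' @export
mbs_enum <- function(map, profiles, phen, max_edges_guard = 25L,
                     override_guard = FALSE) {
  ctx <- network_context(map, profiles, phen)
  m <- length(ctx$edge_ids)
  if (m > max_edges_guard && !override_guard)
    stop_input("map has ", m, " edges, above the exhaustive-search guard (",
               max_edges_guard, "); pass override_guard = TRUE to force")
  p <- phen$p
  seen <- new.env(parent = emptyenv())
  cands <- list()
  push <- function(idx) {
    key <- canonical_key(idx)
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      cands[[length(cands) + 1L]] <<- sort(idx)
    }
  }
  for (t in seq_len(p))
    for (idx in enum_max_frequent_idx(ctx, ctx$pos, t)) push(idx)
  for (idx in connected_components_idx(ctx$adj)) push(idx)
  keep <- vapply(cands, function(idx) is_mbs_exact(ctx, idx), NA)
  sets <- cands[keep]
  alphas <- vapply(sets, function(idx) alpha_of(ctx, presence_of(ctx, idx)), 0)
  ord <- order(alphas, vapply(sets, canonical_key, ""))
  out <- list(subgraphs = lapply(sets[ord], function(i) sort(ctx$edge_ids[i])),
              alphas = alphas[ord],
              thresholds_used = seq_len(p))
  class(out) <- "mbs_result"
  out
}

#' @export
print.mbs_result <- function(x, ...) {
  cat(sprintf("mbs_result: %d maximally-biased subgraph(s); alpha range [%g, %g]\n",
              length(x$subgraphs),
              if (length(x$alphas)) min(x$alphas) else NA,
              if (length(x$alphas)) max(x$alphas) else NA))
  invisible(x)
}

# Edge sets of the connected components of the edge-adjacency structure.
connected_components_idx <- function(adj) {
  m <- length(adj)
  comp <- integer(m)
  cur <- 0L
  for (v in seq_len(m)) {
    if (comp[v]) next
    cur <- cur + 1L
    queue <- v
    comp[v] <- cur
    while (length(queue)) {
      x <- queue[1L]; queue <- queue[-1L]
      for (nb in adj[[x]]) if (!comp[nb]) { comp[nb] <- cur; queue <- c(queue, nb) }
    }
  }
  split(seq_len(m), comp)
}

# Both MBS criteria, checked exactly for one candidate index set.
is_mbs_exact <- function(ctx, idx) {
  alpha_g <- alpha_of(ctx, presence_of(ctx, idx))
  # criterion 1: no connected proper subset with strictly smaller alpha
  for (sub in connected_subsets_idx(ctx$adj, idx)) {
    if (length(sub) == length(idx)) next
    if (alpha_of(ctx, presence_of(ctx, sub)) < alpha_g) return(FALSE)
  }
  # criterion 2: no connected proper superset with alpha <= alpha_g
  !has_beating_superset(ctx, idx, alpha_g)
}

# All connected subsets of `idx` (including idx itself), via the same
# exclusive-neighbourhood walk restricted to the candidate's edges.
connected_subsets_idx <- function(adj, idx) {
  pos_in <- rep(FALSE, length(adj))
  pos_in[idx] <- TRUE
  results <- list()
  extend <- function(sub, ext, root, excluded) {
    results[[length(results) + 1L]] <<- sub
    while (length(ext)) {
      w <- ext[1L]; ext <- ext[-1L]
      cand <- adj[[w]]
      cand <- cand[cand > root & pos_in[cand] & !excluded[cand]]
      excl2 <- excluded
      excl2[cand] <- TRUE
      extend(c(sub, w), c(ext, cand), root, excl2)
    }
  }
  for (v in idx) {
    ext <- adj[[v]][adj[[v]] > v & pos_in[adj[[v]]]]
    excluded <- rep(FALSE, length(adj))
    excluded[v] <- TRUE
    excluded[ext] <- TRUE
    extend(v, ext, v, excluded)
  }
  results
}

# Depth-first search over connected proper supersets of `idx` within its
# connected component; TRUE as soon as one has alpha <= alpha_g.
has_beating_superset <- function(ctx, idx, alpha_g) {
  n <- ctx$phen$n; p <- ctx$phen$p
  visited <- new.env(parent = emptyenv())
  grow <- function(cur, pres) {
    frontier <- setdiff(sort(unique(unlist(ctx$adj[cur]))), cur)
    for (a in frontier) {
      nxt <- sort(c(cur, a))
      key <- canonical_key(nxt)
      if (!is.null(visited[[key]])) next
      visited[[key]] <- TRUE
      new_pres <- pres & ctx$P[, ctx$lab_col[a]]
      k_p <- sum(new_pres[ctx$pos])
      if (alpha_of(ctx, new_pres) <= alpha_g) return(TRUE)
      # best alpha any further superset can reach: all-positive support at
      # the current k_p (k_p only shrinks as edges are added)
      if (k_p >= 1 && hypergeom_tail_fast(n, p, k_p, k_p) > alpha_g) next
      if (k_p == 0 && 1 > alpha_g) next
      if (grow(nxt, new_pres)) return(TRUE)
    }
    FALSE
  }
  grow(sort(idx), presence_of(ctx, idx))
}

#' Brute-force maximally-biased subgraph oracle
#'
#' Independent reference implementation of the MBS definition: enumerates
#' *every* edge subset up to `max_size` (via [utils::combn()]), keeps the
#' connected ones (checked by a plain compound-reachability walk), computes
#' alpha for each, and applies the two MBS criteria literally by pairwise
#' subset comparison over that universe.  Exact whenever `max_size` covers
#' the whole map (the default); with a smaller `max_size` supersets beyond it
#' are not examined.
#'
#' @inheritParams mbs_enum
#' @param max_size largest edge-set size enumerated (default: all edges).
#' @param max_sets refuse inputs whose subset count exceeds this guard.
#' @return An `mbs_result` (with `thresholds_used = integer(0)`).
#' @export
brute_force_mbs <- function(map, profiles, phen, max_size = NULL,
                            max_sets = 2^20) {
  ctx <- network_context(map, profiles, phen)
  m <- length(ctx$edge_ids)
  if (is.null(max_size)) max_size <- m
  max_size <- min(assert_count(max_size, "max_size", 1L), m)
  if (m > 30L)
    stop_input("brute_force_mbs uses 32-bit edge-set masks; maps must have <= 30 edges")
  n_subsets <- sum(choose(m, seq_len(max_size)))
  if (n_subsets > max_sets)
    stop_input("would enumerate ", n_subsets, " subsets, above the guard (",
               max_sets, ")")
  ends <- map$edges[, c("substrate", "product")]
  conn <- function(idx) {
    if (length(idx) == 1L) return(TRUE)
    reached <- idx[1L]
    comp <- c(ends$substrate[idx[1L]], ends$product[idx[1L]])
    rest <- idx[-1L]
    repeat {
      hit <- rest[ends$substrate[rest] %in% comp | ends$product[rest] %in% comp]
      if (!length(hit)) return(FALSE)
      comp <- unique(c(comp, ends$substrate[hit], ends$product[hit]))
      reached <- c(reached, hit)
      rest <- setdiff(rest, hit)
      if (!length(rest)) return(TRUE)
    }
  }
  sets <- list(); masks <- numeric(0); alphas <- numeric(0)
  pow2 <- 2^(seq_len(m) - 1L)
  for (size in seq_len(max_size)) {
    cmb <- utils::combn(m, size, simplify = FALSE)
    for (idx in cmb) {
      if (!conn(idx)) next
      sets[[length(sets) + 1L]] <- idx
      masks[length(masks) + 1L] <- sum(pow2[idx])
      alphas[length(alphas) + 1L] <- alpha_of(ctx, presence_of(ctx, idx))
    }
  }
  keep <- vapply(seq_along(sets), function(i) {
    g <- masks[i]
    is_sub <- bitwAnd(masks, g) == masks  # h subset of g
    is_sup <- bitwAnd(masks, g) == g      # h superset of g
    proper <- masks != g
    if (any(is_sub & proper & alphas < alphas[i])) return(FALSE)
    if (any(is_sup & proper & alphas <= alphas[i])) return(FALSE)
    TRUE
  }, NA)
  sets <- sets[keep]; alphas <- alphas[keep]
  ord <- order(alphas, vapply(sets, canonical_key, ""))
  out <- list(subgraphs = lapply(sets[ord], function(i) sort(ctx$edge_ids[i])),
              alphas = alphas[ord],
              thresholds_used = integer(0))
  class(out) <- "mbs_result"
  out
}
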