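# NIBBS-Search: greedy seed-set generation followed by delta-controlled
# seed expansion.  The heuristic approximates the exact set of
# maximally-biased subgraphs that mbs_enum() computes.

#' NIBBS-Search parameters
#'
#' @param k_max maximum seed-set size (>= 1).  With `k_max = 1` every
#'   founding edge becomes its own singleton seed set.
#' @param alpha_s maximum seed alpha: only seed sets with `alpha < alpha_s`
#'   are expanded into subsystems.
#' @param delta fraction in (0, 1] of the seed-supporting positive instances
#'   that the expanded set must retain; the retention floor is
#'   `ceiling(delta * s0)` where `s0` is the seed's positive support.
#'   `delta = 1` demands presence in every positive instance the seed was
#'   present in and is the default (strongest-signal setting).
#' @param seed_method `"connected"` (seed candidates must share a compound
#'   with a seed edge, so seeds are connected subgraphs) or `"path_checked"`
#'   (any edge joined to the seed by a path whose edges are present in every
#'   positive instance the augmented seed would be present in).
#' @param rng_seed integer seed; the only randomness is the final tie-break
#'   during expansion, drawn from a per-seed-set substream so runs are fully
#'   reproducible.
#' @param restarts number of expansion attempts per seed set; the lowest-alpha
#'   result is kept.  Default 1 (no restarts).
#' @return An object of class `nibbs_params`.
#' @export
nibbs_params <- function(k_max = 5L, alpha_s = 0.05, delta = 1.0,
                         seed_method = c("connected", "path_checked"),
                         rng_seed = 1L, restarts = 1L) {
  k_max <- assert_count(k_max, "k_max", 1L)
  restarts <- assert_count(restarts, "restarts", 1L)
  if (!is.numeric(alpha_s) || length(alpha_s) != 1L || alpha_s < 0 || alpha_s > 1)
    stop_input("`alpha_s` must be in [0, 1]")
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0 || delta > 1)
    stop_input("`delta` must be in (0, 1]")
  seed_method <- match.arg(seed_method)
  obj <- list(k_max = k_max, alpha_s = alpha_s, delta = delta,
              seed_method = seed_method,
              rng_seed = assert_count(rng_seed, "rng_seed", 0L),
              restarts = restarts)
  class(obj) <- "nibbs_params"
  obj
}

#' Generate seed sets
#'
#' Edges are sorted ascending by their single-edge alpha (ties broken by edge
#' id).  Repeatedly, the unmarked edge with the least alpha founds a new seed
#' set and is marked; the seed grows greedily by the candidate edge giving
#' the greatest alpha decrease (which is also marked), until no candidate
#' strictly decreases alpha or the seed reaches `k_max` edges.  Generation
#' continues until every edge is marked, so every edge of the map belongs to
#' at least one seed set; filtering by `alpha_s` happens later, at expansion.
#'
#' @param map a [reference_map()].
#' @param profiles a [profile_matrix()].
#' @param phen a [phenotype_profile()].
#' @param params a [nibbs_params()].
#' @return List of seed sets, each a list with `edge_ids`, `alpha`,
#'   `presence`, `born_from` (the founding edge id).
#' @export
generate_seed_sets <- function(map, profiles, phen, params = nibbs_params()) {
  ctx <- network_context(map, profiles, phen)
  generate_seed_sets_ctx(ctx, params)
}

generate_seed_sets_ctx <- function(ctx, params) {
  m <- length(ctx$edge_ids)
  alpha1 <- single_edge_alphas(ctx)
  ord <- order(alpha1, ctx$edge_ids)
  marked <- rep(FALSE, m)
  seeds <- list()
  for (founder in ord) {
    if (marked[founder]) next
    marked[founder] <- TRUE
    sel <- founder
    pres <- presence_of(ctx, sel)
    alpha <- alpha1[founder]
    while (length(sel) < params$k_max) {
      cand <- seed_candidates_ctx(ctx, sel, pres, alpha, marked,
                                  params$seed_method)
      if (!nrow(cand)) break
      best <- cand[order(cand$alpha, ctx$edge_ids[cand$idx])[1L], ]
      sel <- c(sel, best$idx)
      marked[best$idx] <- TRUE
      pres <- pres & ctx$P[, ctx$lab_col[best$idx]]
      alpha <- best$alpha
    }
    seeds[[length(seeds) + 1L]] <- list(
      edge_ids = ctx$edge_ids[sel],
      alpha = alpha,
      presence = stats::setNames(pres, rownames(ctx$P)),
      born_from = ctx$edge_ids[founder],
      idx = sel, founder = founder)
  }
  seeds
}

single_edge_alphas <- function(ctx) {
  ucol <- unique(ctx$lab_col)
  a <- vapply(ucol, function(col) alpha_of(ctx, ctx$P[, col]), 0)
  a[match(ctx$lab_col, ucol)]
}

#' Seed-growth candidate edges
#'
#' Unmarked edges whose addition to the seed set strictly decreases its
#' alpha.  Under `method = "connected"` a candidate must share a compound
#' with a seed edge.  Under `method = "path_checked"` any unmarked edge
#' qualifies topologically if some path joins it to a seed edge through
#' edges whose labels are present in every positive instance that the
#' *augmented* seed set would be present in (so the connecting path can be
#' absorbed during expansion).
#'
#' @inheritParams generate_seed_sets
#' @param seed_edge_ids character vector: the current seed set.
#' @param marked character vector of edge ids excluded from candidacy.
#' @param method `"connected"` or `"path_checked"`.
#' @return data.frame with columns `edge_id` and `alpha` (the alpha of the
#'   augmented seed set), sorted ascending by alpha.
#' @export
generate_seed_candidates <- function(map, profiles, phen, seed_edge_ids,
                                     marked = character(0),
                                     method = c("connected", "path_checked")) {
  method <- match.arg(method)
  ctx <- network_context(map, profiles, phen)
  if (!length(seed_edge_ids)) stop_input("seed set must be non-empty")
  sel <- edge_indices(ctx, seed_edge_ids)
  mk <- rep(FALSE, length(ctx$edge_ids))
  mk[edge_indices(ctx, marked)] <- TRUE
  pres <- presence_of(ctx, sel)
  cand <- seed_candidates_ctx(ctx, sel, pres, alpha_of(ctx, pres), mk, method)
  out <- data.frame(edge_id = ctx$edge_ids[cand$idx], alpha = cand$alpha)
  out[order(out$alpha, out$edge_id), , drop = FALSE]
}

seed_candidates_ctx <- function(ctx, sel, pres, alpha, marked, method) {
  pool <- if (method == "connected") {
    setdiff(sort(unique(unlist(ctx$adj[sel]))), sel)
  } else {
    setdiff(seq_along(ctx$edge_ids), sel)
  }
  pool <- pool[!marked[pool]]
  if (!length(pool)) return(data.frame(idx = integer(0), alpha = numeric(0)))
  keep <- logical(length(pool)); alphas <- numeric(length(pool))
  for (j in seq_along(pool)) {
    e <- pool[j]
    aug <- pres & ctx$P[, ctx$lab_col[e]]
    a <- alpha_of(ctx, aug)
    if (a >= alpha) next
    if (method == "path_checked" && !path_links_seed(ctx, sel, e, aug)) next
    keep[j] <- TRUE
    alphas[j] <- a
  }
  data.frame(idx = pool[keep], alpha = alphas[keep])
}

# Does a path of edges, all present in every positive instance that the
# augmented seed set would be present in, join edge e to some seed edge?
path_links_seed <- function(ctx, sel, e, aug_pres) {
  inst <- ctx$pos[aug_pres[ctx$pos]]
  allowed_lab <- if (length(inst))
    colSums(ctx$P[inst, , drop = FALSE]) == length(inst)
  else rep(TRUE, ncol(ctx$P))
  allowed <- allowed_lab[ctx$lab_col]
  allowed[c(sel, e)] <- TRUE  # endpoints qualify by construction
  target <- rep(FALSE, length(allowed)); target[sel] <- TRUE
  queue <- e
  seen <- rep(FALSE, length(allowed)); seen[e] <- TRUE
  while (length(queue)) {
    x <- queue[1L]; queue <- queue[-1L]
    for (nb in ctx$adj[[x]]) {
      if (target[nb]) return(TRUE)
      if (!seen[nb] && allowed[nb]) { seen[nb] <- TRUE; queue <- c(queue, nb) }
    }
  }
  FALSE
}

#' Expand a seed set into a subsystem
#'
#' Maintains an edge set `E` (initially the seed) and the seed's positive
#' support `s0`.  Candidate edges are those adjacent to `E` whose addition
#' keeps the set present in at least `ceiling(delta * s0)` of the positive
#' instances the seed was present in.  Among candidates the cascade is:
#' (1) maximize the positive-instance count of the resulting set, (2)
#' greatest alpha decrease, (3) uniform random choice.  The loop stops when
#' no candidate remains.  Expansion is support-driven, not alpha-driven, so
#' the final alpha may sit above the seed's; the returned subsystem carries
#' both support counts so users can filter.
#'
#' @inheritParams generate_seed_sets
#' @param seed a seed set from [generate_seed_sets()] (or any list with an
#'   `edge_ids` field).
#' @param rng_seed seed for the random tie-break; defaults to
#'   `params$rng_seed`.
#' @return An object of class `subsystem`: list with `edge_ids`, `ec_labels`,
#'   `presence`, `k`, `k_p`, `alpha`, `seed_edge_ids`.
#' @export
expand_seed_set <- function(map, profiles, phen, seed,
                            params = nibbs_params(), rng_seed = NULL) {
  ctx <- network_context(map, profiles, phen)
  sel <- edge_indices(ctx, seed$edge_ids)
  with_seed(rng_seed %||% params$rng_seed,
            expand_seed_set_ctx(ctx, sel, params))
}

expand_seed_set_ctx <- function(ctx, sel, params) {
  pres <- presence_of(ctx, sel)
  s0 <- sum(pres[ctx$pos])
  floor_n <- ceiling(params$delta * s0)
  cur <- sel
  repeat {
    frontier <- setdiff(sort(unique(unlist(ctx$adj[cur]))), cur)
    if (!length(frontier)) break
    cnt <- integer(length(frontier)); ok <- logical(length(frontier))
    for (j in seq_along(frontier)) {
      aug <- pres & ctx$P[, ctx$lab_col[frontier[j]]]
      cnt[j] <- sum(aug[ctx$pos])
      ok[j] <- cnt[j] >= floor_n
    }
    if (!any(ok)) break
    frontier <- frontier[ok]; cnt <- cnt[ok]
    top <- frontier[cnt == max(cnt)]
    if (length(top) > 1L) {
      a <- vapply(top, function(e)
        alpha_of(ctx, pres & ctx$P[, ctx$lab_col[e]]), 0)
      top <- top[a == min(a)]
    }
    pick <- sample_one(top)
    cur <- c(cur, pick)
    pres <- pres & ctx$P[, ctx$lab_col[pick]]
  }
  new_subsystem(ctx, cur, seed_idx = sel)
}

new_subsystem <- function(ctx, idx, seed_idx = integer(0)) {
  idx <- sort(unique(idx))
  pres <- presence_of(ctx, idx)
  k <- sum(pres); k_p <- sum(pres[ctx$pos])
  obj <- list(edge_ids = ctx$edge_ids[idx],
              ec_labels = sort(unique(colnames(ctx$P)[ctx$lab_col[idx]])),
              presence = stats::setNames(pres, rownames(ctx$P)),
              k = k, k_p = k_p,
              alpha = hypergeom_tail_fast(ctx$phen$n, ctx$phen$p, k, k_p),
              seed_edge_ids = ctx$edge_ids[sort(seed_idx)])
  class(obj) <- "subsystem"
  obj
}

#' @export
print.subsystem <- function(x, ...) {
  cat(sprintf("subsystem: %d edge(s), %d EC label(s), k=%d, k_p=%d, alpha=%.4g\n",
              length(x$edge_ids), length(x$ec_labels), x$k, x$k_p, x$alpha))
  invisible(x)
}

#' Run NIBBS-Search
#'
#' Generates seed sets covering every edge, keeps those with
#' `alpha < alpha_s`, expands each under the `delta` retention rule,
#' deduplicates identical edge sets and returns the subsystems sorted by
#' ascending alpha.  Fully deterministic given `params$rng_seed`: each seed
#' set's expansion draws its tie-breaks from a substream derived from the
#' founding edge, so changing `alpha_s` only adds or removes subsystems.
#'
#' @inheritParams generate_seed_sets
#' @return List of [expand_seed_set()] subsystems (class `subsystem_list`),
#'   with the seed sets attached as attribute `"seed_sets"`.
#' @export
nibbs_search <- function(map, profiles, phen, params = nibbs_params()) {
  ctx <- network_context(map, profiles, phen)
  seeds <- generate_seed_sets_ctx(ctx, params)
  kept <- Filter(function(s) s$alpha < params$alpha_s, seeds)
  subs <- lapply(kept, function(s) {
    best <- NULL
    for (r in seq_len(params$restarts)) {
      sub <- with_seed(derive_seed(params$rng_seed, s$founder * 31L + r),
                       expand_seed_set_ctx(ctx, s$idx, params))
      if (is.null(best) || sub$alpha < best$alpha) best <- sub
    }
    best
  })
  keys <- vapply(subs, function(s) paste(s$edge_ids, collapse = ","), "")
  subs <- subs[!duplicated(keys)]
  ord <- order(vapply(subs, `[[`, 0, "alpha"),
               vapply(subs, function(s) s$edge_ids[1L], ""))
  out <- subs[ord]
  class(out) <- "subsystem_list"
  attr(out, "seed_sets") <- lapply(seeds, function(s)
    s[c("edge_ids", "alpha", "presence", "born_from")])
  attr(out, "params") <- params
  out
}

#' @export
print.subsystem_list <- function(x, ...) {
  cat(sprintf("subsystem_list: %d subsystem(s)\n", length(x)))
  for (s in x[seq_len(min(5L, length(x)))])
    cat(sprintf("  alpha=%.4g k=%d k_p=%d edges={%s}\n", s$alpha, s$k, s$k_p,
                paste(s$edge_ids, collapse = ",")))
  if (length(x) > 5L) cat("  ...\n")
  invisible(x)
}

#' Summarize subsystems as a data.frame
#'
#' @param x a `subsystem_list` from [nibbs_search()].
#' @param ... unused.
#' @return data.frame with one row per subsystem: `id`, `alpha`, `k`, `k_p`,
#'   `n_edges`, `edge_ids` (comma-joined).
#' @export
as.data.frame.subsystem_list <- function(x, ...) {
  data.frame(
    id = sprintf("s%d", seq_along(x)),
    alpha = vapply(x, `[[`, 0, "alpha"),
    k = vapply(x, `[[`, 0L, "k"),
    k_p = vapply(x, `[[`, 0L, "k_p"),
    n_edges = vapply(x, function(s) length(s$edge_ids), 0L),
    edge_ids = vapply(x, function(s) paste(s$edge_ids, collapse = ","), "")
  )
}

#' Write subsystems to JSON
#'
#' Serializes a list of subsystems as
#' `[{id, alpha, k, k_p, edge_ids, ec_labels, seed_edge_ids}, ...]`, the
#' output contract shared by [nibbs_search()] and [mbs_enum()].
#'
#' @param subsystems a `subsystem_list`, `mbs_result`, or list of subsystems.
#' @param path output file path.
#' @export
write_subsystems <- function(subsystems, path) {
  if (inherits(subsystems, "mbs_result")) {
    recs <- lapply(seq_along(subsystems$subgraphs), function(i)
      list(id = sprintf("m%d", i), alpha = subsystems$alphas[i],
           k = NA, k_p = NA, edge_ids = as.list(subsystems$subgraphs[[i]]),
           ec_labels = list(), seed_edge_ids = list()))
  } else {
    recs <- lapply(seq_along(subsystems), function(i) {
      s <- subsystems[[i]]
      list(id = sprintf("s%d", i), alpha = s$alpha, k = s$k, k_p = s$k_p,
           edge_ids = as.list(s$edge_ids), ec_labels = as.list(s$ec_labels),
           seed_edge_ids = as.list(s$seed_edge_ids))
    })
  }
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read subsystems from JSON
#'
#' @param path a file written by [write_subsystems()].
#' @return List of subsystem-shaped lists (fields `id`, `alpha`, `k`, `k_p`,
#'   `edge_ids`, `ec_labels`, `seed_edge_ids`).
#' @export
read_subsystems <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(recs, function(r) {
    r$edge_ids <- as.character(unlist(r$edge_ids))
    r$ec_labels <- as.character(unlist(r$ec_labels))
    r$seed_edge_ids <- as.character(unlist(r$seed_edge_ids))
    r
  })
}
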