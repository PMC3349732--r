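#' Phenotype-bias metric: upper-tail cumulative hypergeometric
#'
#' Given `n` organism-specific networks of which `p` are phenotype-expressing
#' (positive), a system present in `k` networks of which `k_p` are positive
#' has bias
#' \deqn{\alpha = \sum_{i=k_p}^{\min(k,p)} \frac{{p \choose i}{n-p \choose k-i}}{{n \choose k}},}
#' the probability of observing at least `k_p` positives among `k` draws
#' without replacement.  Smaller alpha means more phenotype-biased.  The sum
#' is evaluated in log-space (`lchoose`) for numerical stability.
#'
#' The metric has two monotonicity properties that the maximal-frequent
#' reduction of [mbs_enum()] relies on: with `k_p` fixed, decreasing `k`
#' (fewer negatives) never increases alpha; with `k - k_p` fixed, increasing
#' `k_p` never increases alpha.
#'
#' @param n total network count (positive integer).
#' @param p positive network count, `0 < p < n`.
#' @param k networks containing the system, `0 <= k <= n`.
#' @param k_p positive networks containing the system,
#'   `max(0, k - (n - p)) <= k_p <= min(k, p)`.
#' @return alpha, a probability in (0, 1].
#' @export
hypergeom_tail <- function(n, p, k, k_p) {
  n   <- assert_count(n, "n", 2L)
  p   <- assert_count(p, "p", 1L)
  k   <- assert_count(k, "k", 0L)
  k_p <- assert_count(k_p, "k_p", 0L)
  if (p >= n) stop_input("need 0 < p < n")
  if (k > n) stop_input("need k <= n")
  if (k_p > min(k, p)) stop_input("need k_p <= min(k, p)")
  if (k - k_p > n - p) stop_input("need k - k_p <= n - p")
  if (k_p <= max(0L, k - (n - p))) return(1)  # tail from the floor is exact
  i <- k_p:min(k, p)
  alpha <- sum(exp(lchoose(p, i) + lchoose(n - p, k - i) - lchoose(n, k)))
  min(alpha, 1)
}

#' Phenotype bias of a subsystem
#'
#' Composes [subsystem_presence()], [support_counts()] and
#' [hypergeom_tail()].  A subsystem absent from every organism (`k = 0`) has
#' alpha 1 (the tail from 0 covers all outcomes).
#'
#' @inheritParams subsystem_presence
#' @param phen a [phenotype_profile()].
#' @return alpha in (0, 1].
#' @export
subsystem_alpha <- function(map, profiles, phen, edge_ids) {
  pres <- subsystem_presence(map, profiles, edge_ids)
  sc <- support_counts(pres, phen)
  hypergeom_tail(phen$n, phen$p, sc[["k"]], sc[["k_p"]])
}

# Fast internal variant on a prebuilt context and integer indices.
alpha_of <- function(ctx, pres) {
  k <- sum(pres)
  hypergeom_tail_fast(ctx$phen$n, ctx$phen$p, k, sum(pres[ctx$pos]))
}

# No validation; callers guarantee the invariants.
hypergeom_tail_fast <- function(n, p, k, k_p) {
  if (k_p <= max(0L, k - (n - p))) return(1)
  i <- k_p:min(k, p)
  min(sum(exp(lchoose(p, i) + lchoose(n - p, k - i) - lchoose(n, k))), 1)
}

#' Hypergeometric pathway enrichment of a subsystem collection
#'
#' The edges of all subsystems are pooled into one deduplicated list `L`.
#' For each pathway `w` of the reference map, the pathway's edges form the
#' population; population successes are the pathway edges whose EC label
#' belongs to the target organism's enzyme set; the sample is `L` restricted
#' to the pathway's edges, and sample successes are the sample edges with an
#' organism-present label.  The p-value is the upper-tail hypergeometric
#' probability of at least the observed sample successes.  Pathways with an
#' empty population are omitted; an empty sample gives p = 1.  Output is
#' sorted by ascending p-value.
#'
#' No multiple-testing correction is applied by default; set
#' `p_adjust = TRUE` to add a Benjamini-Hochberg column.
#'
#' @param subsystems list of subsystems: objects with an `edge_ids` field, or
#'   bare character vectors of edge ids.
#' @param map a [reference_map()].
#' @param organism_labels character vector: the target organism's EC labels.
#' @param p_adjust add a `p_adj` (Benjamini-Hochberg) column?  Default off.
#' @return data.frame with columns `pathway_id`, `population`,
#'   `pop_successes`, `sample`, `sample_successes`, `p_value` (and optionally
#'   `p_adj`).
#' @export
pathway_enrichment <- function(subsystems, map, organism_labels,
                               p_adjust = FALSE) {
  stopifnot(inherits(map, "reference_map"))
  sets <- edge_id_sets(subsystems)
  L <- unique(unlist(sets, use.names = FALSE))
  if (length(L)) edge_indices(network_context_lite(map), L)
  pw_of_edge <- map$edges$pathways
  all_pw <- sort(unique(unlist(pw_of_edge, use.names = FALSE)))
  in_org <- map$edges$ec %in% organism_labels
  in_L <- map$edges$edge_id %in% L
  rows <- lapply(all_pw, function(w) {
    pop <- vapply(pw_of_edge, function(ps) w %in% ps, NA)
    N <- sum(pop)
    if (N == 0L) return(NULL)
    K <- sum(pop & in_org)
    samp <- pop & in_L
    n_s <- sum(samp)
    s <- sum(samp & in_org)
    pval <- if (n_s == 0L) 1 else
      hypergeom_tail_fast2(N, K, n_s, s)
    data.frame(pathway_id = w, population = N, pop_successes = K,
               sample = n_s, sample_successes = s, p_value = pval)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(pathway_id = character(0), population = integer(0),
                      pop_successes = integer(0), sample = integer(0),
                      sample_successes = integer(0), p_value = numeric(0))
  out <- out[order(out$p_value, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  if (p_adjust) out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out
}

# Upper tail P(X >= s) for a population of size N with K successes and n_s
# draws, tolerating K = 0 or K = N (which hypergeom_tail's phenotype
# invariants reject).
hypergeom_tail_fast2 <- function(N, K, n_s, s) {
  if (s <= max(0L, n_s - (N - K))) return(1)
  if (s > min(n_s, K)) return(0)
  i <- s:min(n_s, K)
  min(sum(exp(lchoose(K, i) + lchoose(N - K, n_s - i) - lchoose(N, n_s))), 1)
}

#' Write a pathway-enrichment table to TSV
#'
#' Columns: `pathway_id  population  pop_successes  sample
#' sample_successes  p_value`.
#'
#' @param enrichment data.frame from [pathway_enrichment()].
#' @param path output file path.
#' @export
write_enrichment <- function(enrichment, path) {
  utils::write.table(enrichment, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Coerce mixed subsystem representations to a list of edge-id character sets.
edge_id_sets <- function(subsystems) {
  if (inherits(subsystems, "subsystem")) subsystems <- list(subsystems)
  if (inherits(subsystems, "mbs_result")) return(subsystems$subgraphs)
  lapply(subsystems, function(s) {
    if (is.list(s) && !is.null(s$edge_ids)) as.character(s$edge_ids)
    else as.character(s)
  })
}
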