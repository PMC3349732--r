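#' Parameter sweep over the NIBBS grid
#'
#' Runs [nibbs_search()] at every point of a grid over `delta`, `k_max` and
#' `alpha_s` (components omitted from `grid` stay at their values in
#' `params`) and tabulates the subsystem count and the size and alpha
#' distributions.  The same `rng_seed` (and hence the same per-seed-set
#' expansion substreams) is used at every grid point, so rows differ only
#' through the parameters.
#'
#' Two qualitative trends are expected on planted-bias data: smaller `delta`
#' admits more expansion edges, giving fewer but larger subsystems; and the
#' subsystem count is non-decreasing in `alpha_s`, since raising the maximum
#' bias only lets more seed sets through the filter.
#'
#' @inheritParams generate_seed_sets
#' @param grid list with any of `delta`, `k_max`, `alpha_s` (numeric
#'   vectors).  Must produce at least one grid point.
#' @return data.frame with columns `delta`, `k_max`, `alpha_s`,
#'   `n_subsystems`, `median_size`, `mean_size`, `median_alpha`.
#' @export
run_parameter_sweep <- function(map, profiles, phen, grid,
                                params = nibbs_params()) {
  if (!is.list(grid)) stop_input("`grid` must be a list")
  unknown <- setdiff(names(grid), c("delta", "k_max", "alpha_s"))
  if (length(unknown))
    stop_input("unknown grid component(s): ", paste(unknown, collapse = ", "))
  g <- expand.grid(delta = grid$delta %||% params$delta,
                   k_max = grid$k_max %||% params$k_max,
                   alpha_s = grid$alpha_s %||% params$alpha_s)
  if (nrow(g) == 0L) stop_input("empty parameter grid")
  rows <- lapply(seq_len(nrow(g)), function(i) {
    pi <- nibbs_params(k_max = g$k_max[i], alpha_s = g$alpha_s[i],
                       delta = g$delta[i], seed_method = params$seed_method,
                       rng_seed = params$rng_seed, restarts = params$restarts)
    subs <- nibbs_search(map, profiles, phen, pi)
    sizes <- vapply(subs, function(s) length(s$edge_ids), 0L)
    alphas <- vapply(subs, `[[`, 0, "alpha")
    data.frame(delta = g$delta[i], k_max = g$k_max[i], alpha_s = g$alpha_s[i],
               n_subsystems = length(subs),
               median_size = if (length(sizes)) stats::median(sizes) else NA_real_,
               mean_size = if (length(sizes)) mean(sizes) else NA_real_,
               median_alpha = if (length(alphas)) stats::median(alphas) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Write a sweep table to TSV
#'
#' @param sweep data.frame from [run_parameter_sweep()].
#' @param path output file path.
#' @export
write_sweep <- function(sweep, path) {
  utils::write.table(sweep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
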