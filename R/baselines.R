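# Per-enzyme baseline methods for phenotype association: a Welch two-sample
# t-test on enzyme copy numbers and mutual information with a
# permutation-max threshold.  Both score enzymes one at a time, so unlike
# the subgraph search they cannot credit an enzyme for the company it keeps.

#' Per-enzyme Welch t-test on copy numbers
#'
#' For every EC label, compares copy numbers (absent = 0) between
#' phenotype-expressing and non-expressing organisms with a two-sided Welch
#' t-test.  A label is flagged when its p-value is at most `alpha_level` and
#' the positive-group mean is larger.  Labels that are absent everywhere, or
#' constant with equal means in both groups, cannot be informative: the
#' former are skipped with a warning, the latter get `t = 0, p = 1`.
#' Constant but unequal groups (zero variance, different means) are flagged
#' with `p = 0`.
#'
#' @param profiles a [profile_matrix()] (copy numbers are used).
#' @param phen a [phenotype_profile()]; both classes must have >= 2 organisms.
#' @param alpha_level significance level for flagging (default 0.05).
#' @return An object of class `baseline_result`: list with `method`,
#'   `score` (named t statistics), `p_value`, `threshold` (= `alpha_level`),
#'   `flagged` (character vector of EC labels), `skipped`.
#' @export
ttest_per_enzyme <- function(profiles, phen, alpha_level = 0.05) {
  stopifnot(inherits(profiles, "profile_matrix"),
            inherits(phen, "phenotype_profile"))
  if (!identical(phen$organisms, rownames(profiles$presence)))
    stop_input("phenotype and profile organism orders differ")
  if (phen$p < 2L || phen$n - phen$p < 2L)
    stop_input("both phenotype groups need >= 2 organisms")
  pos <- unname(phen$labels)
  copies <- profiles$copy_number
  labs <- colnames(copies)
  tstat <- pval <- stats::setNames(rep(NA_real_, length(labs)), labs)
  skipped <- character(0)
  for (lab in labs) {
    x <- copies[pos, lab]; y <- copies[!pos, lab]
    if (all(x == 0) && all(y == 0)) { skipped <- c(skipped, lab); next }
    vx <- stats::var(x); vy <- stats::var(y)
    if (vx == 0 && vy == 0) {
      if (mean(x) == mean(y)) { tstat[lab] <- 0; pval[lab] <- 1 }
      else { tstat[lab] <- sign(mean(x) - mean(y)) * Inf; pval[lab] <- 0 }
      next
    }
    tt <- stats::t.test(x, y, var.equal = FALSE)
    tstat[lab] <- unname(tt$statistic)
    pval[lab] <- tt$p.value
  }
  if (length(skipped))
    warning("skipped label(s) absent from every organism: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  means_pos <- colMeans(copies[pos, , drop = FALSE])
  means_neg <- colMeans(copies[!pos, , drop = FALSE])
  flagged <- labs[!is.na(pval) & pval <= alpha_level & means_pos > means_neg]
  out <- list(method = "ttest", score = tstat, p_value = pval,
              threshold = alpha_level, flagged = flagged, skipped = skipped)
  class(out) <- "baseline_result"
  out
}

#' Per-enzyme mutual information with a permutation-max threshold
#'
#' Computes, for every EC label, the mutual information (bits) between its
#' presence profile and the phenotype profile from the 2x2 contingency
#' table (zero-count cells contribute 0).  The significance threshold is the
#' maximum MI observed over `n_shuffles` independent permutations of *each*
#' label's presence vector against the fixed phenotype -- a single global
#' running max by default, or one per label with
#' `per_label_threshold = TRUE`.  Flagged labels have observed MI strictly
#' above the threshold.
#'
#' @param profiles a [profile_matrix()] (binary presence is used).
#' @param phen a [phenotype_profile()].
#' @param n_shuffles permutations per label (>= 1), default 100.
#' @param rng_seed optional integer seed for the permutations.
#' @param per_label_threshold compare each label against its own permutation
#'   max instead of the global one.
#' @return A `baseline_result` with `score` (named MI, bits), `threshold`
#'   (global numeric, or named vector when per-label) and `flagged`.
#' @export
mi_per_enzyme <- function(profiles, phen, n_shuffles = 100L, rng_seed = NULL,
                          per_label_threshold = FALSE) {
  stopifnot(inherits(profiles, "profile_matrix"),
            inherits(phen, "phenotype_profile"))
  if (!identical(phen$organisms, rownames(profiles$presence)))
    stop_input("phenotype and profile organism orders differ")
  n_shuffles <- assert_count(n_shuffles, "n_shuffles", 1L)
  pos <- unname(phen$labels)
  P <- profiles$presence
  labs <- colnames(P)
  mi <- stats::setNames(vapply(labs, function(l) mi_bits(P[, l], pos), 0), labs)
  # per-label permutation substreams: the shuffle set for a smaller n_shuffles
  # is a prefix of that for a larger one, so the running-max threshold (and
  # hence the flagged set) is exactly monotone in n_shuffles at a fixed seed
  null_max <- vapply(seq_along(labs), function(li) {
    v <- P[, labs[li]]
    with_seed(if (is.null(rng_seed)) NULL else derive_seed(rng_seed, li),
              max(vapply(seq_len(n_shuffles), function(i)
                mi_bits(v[sample.int(length(v))], pos), 0)))
  }, 0)
  names(null_max) <- labs
  threshold <- if (per_label_threshold) null_max else max(null_max)
  flagged <- if (per_label_threshold) labs[mi > null_max] else labs[mi > threshold]
  out <- list(method = "mi", score = mi, p_value = NULL,
              threshold = threshold, flagged = flagged, skipped = character(0))
  class(out) <- "baseline_result"
  out
}

# Mutual information (bits) of two logical vectors from their 2x2 table.
mi_bits <- function(x, y) {
  n <- length(x)
  mi <- 0
  for (a in c(TRUE, FALSE)) for (b in c(TRUE, FALSE)) {
    nab <- sum(x == a & y == b)
    if (nab == 0L) next
    pxy <- nab / n
    mi <- mi + pxy * log2(pxy / ((sum(x == a) / n) * (sum(y == b) / n)))
  }
  max(mi, 0)  # clip the -0 of exact independence
}

#' @export
print.baseline_result <- function(x, ...) {
  cat(sprintf("baseline_result (%s): %d label(s) scored, %d flagged\n",
              x$method, length(x$score), length(x$flagged)))
  invisible(x)
}

#' Write a baseline result to TSV
#'
#' Columns: `ec  score  flagged`.
#'
#' @param result a `baseline_result`.
#' @param path output file path.
#' @export
write_baseline <- function(result, path) {
  df <- data.frame(ec = names(result$score),
                   score = unname(result$score),
                   flagged = as.integer(names(result$score) %in% result$flagged))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
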