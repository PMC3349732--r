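# Small in-code fixtures shared across the suite.

# A 3-edge path C1-C2-C3-C4 plus a detached edge C5-C6.
path_map <- function() {
  reference_map(data.frame(
    edge_id   = c("e1", "e2", "e3", "e4"),
    substrate = c("C1", "C2", "C3", "C5"),
    product   = c("C2", "C3", "C4", "C6"),
    ec        = c("1.1.1.1", "2.2.2.2", "3.3.3.3", "4.4.4.4"),
    pathways  = c("map1", "map1", "map1;map2", "")))
}

# Profiles over 6 organisms (first 3 phenotype-positive) for path_map().
path_profiles <- function() {
  orgs <- sprintf("o%d", 1:6)
  labs <- c("1.1.1.1", "2.2.2.2", "3.3.3.3", "4.4.4.4")
  P <- matrix(FALSE, 6, 4, dimnames = list(orgs, labs))
  P[, "1.1.1.1"] <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)  # 3 pos + 1 neg
  P[, "2.2.2.2"] <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE) # 3 pos only
  P[, "3.3.3.3"] <- TRUE                                     # everywhere
  P[, "4.4.4.4"] <- c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE)
  profile_matrix(P)
}

path_phen <- function() {
  phenotype_profile(stats::setNames(c(rep(TRUE, 3), rep(FALSE, 3)),
                                    sprintf("o%d", 1:6)))
}

# Arbitrary map/profiles/phenotype triple for property-style loops.
random_instance <- function(seed, m = 8L, n_org = 8L) {
  generate_instance_battery(1L, size_bounds = c(m, m), rng_seed = seed)[[1L]]
}

# Independent brute-force hypergeometric tail: direct sum of choose() terms.
tail_by_sum <- function(n, p, k, k_p) {
  i <- k_p:min(k, p)
  sum(choose(p, i) * choose(n - p, k - i)) / choose(n, k)
}

set_key <- function(s) paste(sort(s), collapse = ",")
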