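#' Construct a reference metabolic map
#'
#' A reference map is the non-organism-specific universe of metabolic
#' reactions: vertices are chemical compounds and each edge is a reaction
#' converting a substrate compound to a product compound, labeled with the
#' Enzyme Commission (EC) number of its catalyzing enzyme class.  Edges are
#' stored directed (substrate to product, as reaction databases record them)
#' but adjacency and connectivity are undirected: two edges are adjacent iff
#' they share at least one compound endpoint, because a metabolic system is a
#' chain of reactions in which products of one reaction feed the next.
#'
#' @param edges data.frame with character columns `edge_id`, `substrate`,
#'   `product`, `ec` and either a character column `pathways`
#'   (semicolon-separated pathway ids, possibly empty) or a list column of
#'   character vectors.
#' @return An object of class `reference_map`: a list with `edges` (the
#'   validated edge table, `pathways` as a list column), `compounds`,
#'   `label_index` (EC label -> edge ids) and `adjacency` (per edge, the
#'   integer indices of edges sharing a compound).
#' @seealso [load_reference_map()], [is_connected_subsystem()]
#' @export
reference_map <- function(edges) {
  req <- c("edge_id", "substrate", "product", "ec")
  if (!is.data.frame(edges) || !all(req %in% names(edges)))
    stop_input("`edges` must be a data.frame with columns ",
               paste(req, collapse = ", "))
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  for (col in req) edges[[col]] <- as.character(edges[[col]])
  dup <- edges$edge_id[duplicated(edges$edge_id)]
  if (length(dup))
    stop_input("duplicate edge_id: ", paste(unique(dup), collapse = ", "))
  if (any(!nzchar(edges$ec) | is.na(edges$ec)))
    stop_input("every edge must carry a non-empty EC label; offending edge_id: ",
               paste(edges$edge_id[!nzchar(edges$ec) | is.na(edges$ec)],
                     collapse = ", "))
  if (is.null(edges$pathways)) edges$pathways <- rep("", nrow(edges))
  if (!is.list(edges$pathways)) {
    pw <- as.character(edges$pathways)
    pw[is.na(pw)] <- ""
    edges$pathways <- lapply(strsplit(pw, ";", fixed = TRUE),
                             function(x) x[nzchar(x)])
  } else {
    edges$pathways <- lapply(edges$pathways, function(x) {
      x <- as.character(x); x[nzchar(x) & !is.na(x)]
    })
  }
  rownames(edges) <- NULL
  compounds <- sort(unique(c(edges$substrate, edges$product)))
  obj <- list(
    edges       = edges,
    compounds   = compounds,
    label_index = split(edges$edge_id, edges$ec),
    adjacency   = edge_adjacency(edges)
  )
  class(obj) <- "reference_map"
  obj
}

# Per-edge integer adjacency: edges sharing >= 1 compound endpoint.
edge_adjacency <- function(edges) {
  m <- nrow(edges)
  touch <- split(rep(seq_len(m), 2L), c(edges$substrate, edges$product))
  adj <- vector("list", m)
  for (grp in touch) {
    grp <- unique(grp)
    if (length(grp) > 1L)
      for (i in grp) adj[[i]] <- c(adj[[i]], grp)
  }
  lapply(seq_len(m), function(i) {
    a <- adj[[i]]
    if (is.null(a)) integer(0) else sort(unique(a[a != i]))
  })
}

#' @export
print.reference_map <- function(x, ...) {
  cat(sprintf("reference_map: %d compounds, %d edges, %d EC labels, %d pathways\n",
              length(x$compounds), nrow(x$edges), length(x$label_index),
              length(unique(unlist(x$edges$pathways)))))
  invisible(x)
}

#' Read a reference map from TSV
#'
#' Expects a tab-separated file with header
#' `edge_id substrate product ec pathways`; `pathways` holds
#' semicolon-separated pathway ids and may be empty.  Row order is preserved
#' as edge order.  Duplicate edge ids, missing EC labels and rows with the
#' wrong field count are rejected (the latter with the offending line number).
#'
#' @param path path to the TSV file.
#' @return A [reference_map()].
#' @export
load_reference_map <- function(path) {
  check_tsv_shape(path, n_fields = 5L,
                  header = c("edge_id", "substrate", "product", "ec", "pathways"))
  df <- utils::read.delim(path, sep = "\t", quote = "", colClasses = "character",
                          na.strings = NULL, fill = FALSE)
  reference_map(df)
}

#' Write a reference map to TSV
#'
#' Inverse of [load_reference_map()]; round-trips exactly.
#'
#' @param map a [reference_map()].
#' @param path output file path.
#' @export
write_reference_map <- function(map, path) {
  stopifnot(inherits(map, "reference_map"))
  df <- map$edges
  df$pathways <- vapply(df$pathways, paste, "", collapse = ";")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Validate header and per-line field counts of a strict TSV dialect.
check_tsv_shape <- function(path, n_fields, header) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(lines)), 0L))]
  if (length(lines) < 2L)
    stop_input(path, ": empty file (need a header and at least one row)")
  got <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(got[seq_along(header)], header) &&
      !identical(got, header[seq_along(got)]))
    stop_input(path, ": expected header ", paste(header, collapse = "\\t"))
  # count tabs, not strsplit() pieces: a trailing empty field must still count
  nf <- vapply(lines, function(l) {
    hits <- gregexpr("\t", l, fixed = TRUE)[[1L]]
    sum(hits > 0L) + 1L
  }, 1L, USE.NAMES = FALSE)
  bad <- which(!(nf %in% n_fields))
  if (length(bad))
    stop_input(sprintf("%s: malformed row at line %d (%d fields, expected %s)",
                       path, bad[1L], nf[bad[1L]],
                       paste(n_fields, collapse = " or ")))
  invisible(TRUE)
}

#' Construct an organism-by-enzyme profile matrix
#'
#' Presence/absence (and copy number) of each EC label across a fixed,
#' ordered set of organisms.  An organism "has" a reference-map edge iff it
#' has the edge's EC label, so these profiles fully determine which
#' subsystems exist in which organism-specific networks -- no subgraph
#' isomorphism is ever solved.
#'
#' @param presence logical matrix, organisms x EC labels, with dimnames.
#' @param copy_number optional non-negative integer matrix of the same shape;
#'   defaults to `1` wherever present.  The presence bit must be set iff the
#'   copy number is positive.
#' @return An object of class `profile_matrix` with fields `organisms`,
#'   `presence`, `copy_number`.
#' @export
profile_matrix <- function(presence, copy_number = NULL) {
  if (!is.matrix(presence) || is.null(rownames(presence)) ||
      is.null(colnames(presence)))
    stop_input("`presence` must be a logical matrix with organism rownames and EC colnames")
  mode(presence) <- "logical"
  if (is.null(copy_number)) {
    copy_number <- matrix(0L, nrow(presence), ncol(presence),
                          dimnames = dimnames(presence))
    copy_number[presence] <- 1L
  } else {
    if (!identical(dim(copy_number), dim(presence)))
      stop_input("`copy_number` must match the shape of `presence`")
    if (any(copy_number < 0)) stop_input("copy numbers must be non-negative")
    dimnames(copy_number) <- dimnames(presence)
    if (!identical(unname(copy_number > 0), unname(presence)))
      stop_input("presence bit must be set exactly where copy_number > 0")
    mode(copy_number) <- "integer"
  }
  obj <- list(organisms = rownames(presence), presence = presence,
              copy_number = copy_number)
  class(obj) <- "profile_matrix"
  obj
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("profile_matrix: %d organisms x %d EC labels (%.1f%% present)\n",
              nrow(x$presence), ncol(x$presence), 100 * mean(x$presence)))
  invisible(x)
}

#' Read organism enzyme profiles from TSV
#'
#' Expects a tab-separated file `organism  ec  copy_number`; the third column
#' is optional and defaults to 1 for every listed (organism, EC) pair.
#' Absent pairs have copy number 0.  Organisms are ordered lexicographically
#' unless an explicit order is supplied; all downstream bit-vectors share
#' that order.
#'
#' @param path path to the TSV file.
#' @param organisms_order optional character vector fixing the organism order
#'   (and universe: it must cover every organism in the file).
#' @return A [profile_matrix()].
#' @export
load_profiles <- function(path, organisms_order = NULL) {
  check_tsv_shape(path, n_fields = c(2L, 3L),
                  header = c("organism", "ec", "copy_number"))
  df <- utils::read.delim(path, sep = "\t", quote = "", colClasses = "character",
                          na.strings = NULL, fill = FALSE)
  if (nrow(df) == 0L) stop_input(path, ": no profile rows")
  copies <- if ("copy_number" %in% names(df)) {
    cn <- suppressWarnings(as.numeric(df$copy_number))
    if (any(is.na(cn)))
      stop_input(path, ": non-numeric copy_number at data row ",
                 which(is.na(cn))[1L])
    if (any(cn < 0))
      stop_input(path, ": negative copy_number at data row ", which(cn < 0)[1L])
    as.integer(cn)
  } else rep(1L, nrow(df))
  orgs <- if (is.null(organisms_order)) sort(unique(df$organism)) else {
    missing <- setdiff(df$organism, organisms_order)
    if (length(missing))
      stop_input("organisms not covered by `organisms_order`: ",
                 paste(missing, collapse = ", "))
    as.character(organisms_order)
  }
  labs <- sort(unique(df$ec))
  copy <- matrix(0L, length(orgs), length(labs), dimnames = list(orgs, labs))
  copy[cbind(match(df$organism, orgs), match(df$ec, labs))] <- copies
  profile_matrix(copy > 0L, copy)
}

#' Write organism enzyme profiles to TSV
#'
#' Writes the present (copy number > 0) pairs of a [profile_matrix()] as
#' `organism  ec  copy_number` rows; inverse of [load_profiles()] given the
#' same organism order.
#'
#' @param profiles a [profile_matrix()].
#' @param path output file path.
#' @export
write_profiles <- function(profiles, path) {
  stopifnot(inherits(profiles, "profile_matrix"))
  idx <- which(profiles$copy_number > 0L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  df <- data.frame(organism = rownames(profiles$presence)[idx[, 1L]],
                   ec = colnames(profiles$presence)[idx[, 2L]],
                   copy_number = profiles$copy_number[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a phenotype profile
#'
#' Binary labeling of the organisms: 1 for phenotype-expressing (the positive
#' set G+), 0 otherwise (G-).  Both classes must be non-empty.  The organism
#' order must be the one shared with the [profile_matrix()].
#'
#' @param labels named logical (or 0/1) vector over organisms.
#' @return An object of class `phenotype_profile` with fields `organisms`,
#'   `labels` (logical), `n` (organism count) and `p` (positive count).
#' @export
phenotype_profile <- function(labels) {
  if (is.null(names(labels)) || !all(nzchar(names(labels))))
    stop_input("`labels` must be named by organism id")
  lab <- as.logical(labels)
  if (any(is.na(lab))) stop_input("labels must be 0/1")
  n <- length(lab); p <- sum(lab)
  if (p == 0L || p == n)
    stop_input("both phenotype classes must be non-empty (got ", p,
               " positives of ", n, ")")
  obj <- list(organisms = names(labels), labels = stats::setNames(lab, names(labels)),
              n = n, p = p)
  class(obj) <- "phenotype_profile"
  obj
}

#' @export
print.phenotype_profile <- function(x, ...) {
  cat(sprintf("phenotype_profile: %d organisms (%d positive, %d negative)\n",
              x$n, x$p, x$n - x$p))
  invisible(x)
}

#' Read a phenotype profile from TSV
#'
#' Expects `organism  label` with label in {0,1}.  Organisms are ordered
#' lexicographically unless `organisms_order` is given.
#'
#' @param path path to the TSV file.
#' @param organisms_order optional explicit organism order.
#' @return A [phenotype_profile()].
#' @export
load_phenotype <- function(path, organisms_order = NULL) {
  check_tsv_shape(path, n_fields = 2L, header = c("organism", "label"))
  df <- utils::read.delim(path, sep = "\t", quote = "", colClasses = "character",
                          na.strings = NULL, fill = FALSE)
  if (!all(df$label %in% c("0", "1")))
    stop_input(path, ": labels must be 0 or 1")
  ord <- organisms_order %||% sort(unique(df$organism))
  lab <- stats::setNames(rep(NA, length(ord)), ord)
  lab[df$organism] <- df$label == "1"
  if (any(is.na(lab)))
    stop_input("no phenotype label for organism(s): ",
               paste(ord[is.na(lab)], collapse = ", "))
  phenotype_profile(lab)
}

#' Write a phenotype profile to TSV
#'
#' @param phen a [phenotype_profile()].
#' @param path output file path.
#' @export
write_phenotype <- function(phen, path) {
  stopifnot(inherits(phen, "phenotype_profile"))
  df <- data.frame(organism = phen$organisms, label = as.integer(phen$labels))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- presence / support machinery ------------------------------------------

# Internal evaluation context binding a map to profiles (and optionally a
# phenotype).  P is the presence matrix augmented with all-FALSE columns for
# map labels absent from every organism; lab_col maps edge index -> column.
network_context <- function(map, profiles, phen = NULL) {
  stopifnot(inherits(map, "reference_map"), inherits(profiles, "profile_matrix"))
  P <- profiles$presence
  extra <- setdiff(unique(map$edges$ec), colnames(P))
  if (length(extra))
    P <- cbind(P, matrix(FALSE, nrow(P), length(extra),
                         dimnames = list(rownames(P), extra)))
  if (!is.null(phen)) {
    stopifnot(inherits(phen, "phenotype_profile"))
    if (!identical(phen$organisms, rownames(P)))
      stop_input("phenotype and profile organism orders differ")
  }
  list(P = P,
       lab_col  = match(map$edges$ec, colnames(P)),
       edge_ids = map$edges$edge_id,
       adj      = map$adjacency,
       n_org    = nrow(P),
       phen     = phen,
       pos      = if (is.null(phen)) integer(0) else which(unname(phen$labels)))
}

# Presence bit-vector of an edge-index set: AND over its distinct labels.
# Empty set -> all-ones (vacuous conjunction).
presence_of <- function(ctx, idx) {
  cols <- unique(ctx$lab_col[idx])
  if (!length(cols)) return(rep(TRUE, ctx$n_org))
  if (length(cols) == 1L) return(ctx$P[, cols])
  rowSums(ctx$P[, cols, drop = FALSE]) == length(cols)
}

edge_indices <- function(ctx, edge_ids) {
  idx <- match(edge_ids, ctx$edge_ids)
  if (anyNA(idx))
    stop_input("unknown edge id(s): ",
               paste(edge_ids[is.na(idx)], collapse = ", "))
  idx
}

#' Presence of a subsystem across organism-specific networks
#'
#' A subsystem (edge set of the reference map) exists in an organism iff the
#' organism has every *distinct* EC label of the edge set; two edges sharing
#' a label cost a single constraint.  Labels absent from the profile matrix
#' contribute an all-zero vector.  The empty edge set returns all-ones (a
#' vacuous conjunction, documented; empty sets never reach the bias metric in
#' the pipelines).
#'
#' @param map a [reference_map()].
#' @param profiles a [profile_matrix()].
#' @param edge_ids character vector of edge ids (a set; duplicates ignored).
#' @return Named logical vector over organisms.
#' @export
subsystem_presence <- function(map, profiles, edge_ids) {
  ctx <- network_context(map, profiles)
  pres <- presence_of(ctx, edge_indices(ctx, unique(edge_ids)))
  stats::setNames(as.logical(pres), rownames(ctx$P))
}

#' Support counts of a presence vector
#'
#' `k` is the number of organism-specific networks a system exists in and
#' `k_p` the number of those that are phenotype-expressing.
#'
#' @param presence logical vector over organisms.
#' @param phen a [phenotype_profile()] over the same organisms.
#' @return Named integer vector `c(k=, k_p=)`.
#' @export
support_counts <- function(presence, phen) {
  stopifnot(inherits(phen, "phenotype_profile"))
  if (length(presence) != phen$n)
    stop_input("presence vector length (", length(presence),
               ") does not match organism count (", phen$n, ")")
  pres <- as.logical(presence)
  c(k = sum(pres), k_p = sum(pres & unname(phen$labels)))
}

#' Is an edge set a connected subsystem?
#'
#' Connectivity is judged on the edge-induced undirected graph: edges are
#' adjacent iff they share a compound.  A singleton edge is connected; the
#' empty set is connected by convention.
#'
#' @param map a [reference_map()].
#' @param edge_ids character vector of edge ids.
#' @return `TRUE` or `FALSE`.
#' @export
is_connected_subsystem <- function(map, edge_ids) {
  stopifnot(inherits(map, "reference_map"))
  edge_ids <- unique(edge_ids)
  if (length(edge_ids) <= 1L) {
    edge_indices(network_context_lite(map), edge_ids)
    return(TRUE)
  }
  idx <- match(edge_ids, map$edges$edge_id)
  if (anyNA(idx))
    stop_input("unknown edge id(s): ", paste(edge_ids[is.na(idx)], collapse = ", "))
  sub <- map$edges[idx, c("substrate", "product")]
  g <- igraph::graph_from_data_frame(sub, directed = FALSE)
  igraph::is_connected(g)
}

# Minimal context when no profiles are involved (id validation only).
network_context_lite <- function(map) {
  list(edge_ids = map$edges$edge_id, n_org = 0L,
       lab_col = rep(NA_integer_, nrow(map$edges)),
       P = matrix(FALSE, 0, 0))
}
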