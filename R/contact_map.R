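#' Contact map over protein sites
#'
#' A `contact_map` stores a symmetric binary adjacency over `L` sites: entry
#' (i, k) is `TRUE` when sites i and k are in structural contact. The diagonal
#' is always zero (a site does not boost its own substitution rate).
#'
#' @param x a square 0/1 (or logical) matrix, or a two-column matrix or
#'   data frame of contact pairs (1-based site indices).
#' @param L number of sites; required when `x` is an edge list.
#' @return an object of class `contact_map`.
#' @seealso [contact_map_from_coordinates()], [synthetic_contact_map()],
#'   [submap()]
#' @export
contact_map <- function(x, L = NULL) {
  if (is.matrix(x) && ncol(x) == nrow(x) && (is.null(L) || L == nrow(x))) {
    adj <- x
    if (is.numeric(adj)) {
      if (!all(adj %in% c(0, 1))) stop("adjacency entries must be 0/1")
      adj <- adj > 0
    }
    if (!is.logical(adj)) stop("adjacency must be logical or 0/1 numeric")
    if (!isTRUE(all.equal(adj, t(adj)))) stop("contact map must be symmetric")
    diag(adj) <- FALSE
    dimnames(adj) <- NULL
  } else {
    edges <- as.matrix(x)
    if (is.null(L)) stop("L is required when constructing from an edge list")
    if (length(edges) && (ncol(edges) != 2))
      stop("edge list must have two columns")
    adj <- matrix(FALSE, L, L)
    if (length(edges)) {
      if (any(edges < 1 | edges > L)) stop("edge indices out of range [1, L]")
      if (any(edges[, 1] == edges[, 2])) stop("self-contacts are not allowed")
      adj[edges] <- TRUE
      adj[edges[, 2:1, drop = FALSE]] <- TRUE
    }
  }
  structure(list(L = nrow(adj), adj = adj), class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map: %d sites, %d contacts (mean degree %.2f)\n",
              x$L, sum(x$adj) / 2, sum(x$adj) / x$L))
  invisible(x)
}

#' @export
as.matrix.contact_map <- function(x, ...) x$adj * 1L

#' Number of contacts of each site
#' @param map a [contact_map()].
#' @return integer vector of per-site degrees.
#' @export
contact_degree <- function(map) {
  stopifnot(inherits(map, "contact_map"))
  as.integer(rowSums(map$adj))
}

# neighbor index lists (1-based), the form consumed by the C++ stepper
neighbor_list <- function(map) {
  lapply(seq_len(map$L), function(i) which(map$adj[i, ]))
}

#' Build a contact map from C-alpha coordinates
#'
#' Two sites are in contact when the Euclidean distance between their
#' coordinates is strictly smaller than `threshold` (default 10 Angstrom, the
#' convention used for simulation maps; avalanche analyses conventionally use
#' 8.5 Angstrom).
#'
#' @param coords numeric matrix with one row per site and 3 columns (Angstrom).
#' @param threshold contact distance cutoff in Angstrom; strict "<".
#' @return a [contact_map()].
#' @examples
#' xyz <- cbind(seq(0, 30, by = 6), 0, 0)
#' contact_map_from_coordinates(xyz, threshold = 10)
#' @export
contact_map_from_coordinates <- function(coords, threshold = 10) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 0) stop("coordinate list is empty")
  if (ncol(coords) != 3) stop("coords must have 3 columns")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0)
    stop("threshold must be a positive number")
  d <- as.matrix(stats::dist(coords))
  adj <- d < threshold
  diag(adj) <- FALSE
  dimnames(adj) <- NULL
  structure(list(L = nrow(adj), adj = adj), class = "contact_map")
}

#' Per-site structural class labels
#'
#' Two categories are distinguished: `"S"` (structured, e.g. secondary
#' structure assigned by STRIDE) and `"U"` (unstructured). Labels are consumed
#' by the two-class model; they are inputs, never computed by this package.
#'
#' @param labels character vector of `"S"`/`"U"` codes, one per site.
#' @return object of class `site_classes` (a validated character vector).
#' @export
site_classes <- function(labels) {
  labels <- as.character(labels)
  if (!all(labels %in% c("S", "U")))
    stop("labels must be 'S' (structured) or 'U' (unstructured)")
  structure(labels, class = "site_classes")
}

#' Generate a synthetic contact map with protein-like features
#'
#' Stand-in for contact maps computed from curated PDB structures. The map
#' always contains the backbone band (all pairs with `|i - k| <=
#' backbone_width`); inside each helix span it additionally contains the pairs
#' at along-chain offsets 3 and 4 (alpha-helix periodicity, the origin of the
#' observed conditional-probability peaks at distances 3-4); sparse long-range
#' contacts are added as a Poisson-distributed number of uniformly random
#' pairs with along-chain separation greater than `max(backbone_width, 4)`.
#' Residues inside helix spans are labeled structured (`"S"`), all others
#' unstructured (`"U"`).
#'
#' @param L number of sites (>= 10).
#' @param helix_spans list of inclusive 1-based index ranges `c(start, end)`;
#'   must not overlap.
#' @param long_range_per_site expected number of long-range contacts per site
#'   (mean long-range degree). The default 1.0 gives maps with mean total
#'   degree around 8-10 when combined with band and helix contacts, a
#'   realistic value for 10 Angstrom C-alpha maps.
#' @param backbone_width all pairs closer than or equal to this along-chain
#'   separation are in contact.
#' @param seed optional integer seed (the generator is deterministic given it).
#' @return list with elements `map` ([contact_map()]) and `classes`
#'   ([site_classes()]).
#' @export
synthetic_contact_map <- function(L, helix_spans = NULL, long_range_per_site = 1,
                                  backbone_width = 2, seed = NULL) {
  if (L < 10) stop("L must be at least 10")
  if (!is.null(seed)) set.seed(seed)
  adj <- matrix(FALSE, L, L)
  for (w in seq_len(backbone_width)) {
    idx <- seq_len(L - w)
    adj[cbind(idx, idx + w)] <- TRUE
  }
  covered <- rep(FALSE, L)
  for (span in helix_spans) {
    span <- as.integer(span)
    if (length(span) != 2 || span[1] > span[2] || span[1] < 1 || span[2] > L)
      stop("helix spans must be c(start, end) with 1 <= start <= end <= L")
    if (any(covered[span[1]:span[2]])) stop("helix spans must not overlap")
    covered[span[1]:span[2]] <- TRUE
    for (w in c(3L, 4L)) {
      i <- span[1]:(span[2] - w)
      i <- i[i >= span[1] & i + w <= span[2]]
      if (length(i)) adj[cbind(i, i + w)] <- TRUE
    }
  }
  min_sep <- max(backbone_width, 4L)
  n_pairs <- stats::rpois(1, L * long_range_per_site / 2)
  got <- 0L
  while (got < n_pairs) {
    need <- n_pairs - got
    i <- sample.int(L, 2L * need, replace = TRUE)
    k <- sample.int(L, 2L * need, replace = TRUE)
    keep <- abs(i - k) > min_sep
    i <- i[keep]; k <- k[keep]
    if (!length(i)) next
    take <- seq_len(min(need, length(i)))
    adj[cbind(i[take], k[take])] <- TRUE
    adj[cbind(k[take], i[take])] <- TRUE
    got <- got + length(take)
  }
  adj <- adj | t(adj)
  diag(adj) <- FALSE
  map <- structure(list(L = L, adj = adj), class = "contact_map")
  classes <- site_classes(ifelse(covered, "S", "U"))
  list(map = map, classes = classes)
}

#' Induced contact map on a window of sites
#'
#' Used to measure identity on a portion of a protein while the whole map is
#' evolved.
#'
#' @param map a [contact_map()].
#' @param start 1-based first site of the window.
#' @param length window length.
#' @return list with `map` (the induced [contact_map()]) and `parent_index`
#'   (integer vector mapping window sites to sites of `map`).
#' @export
submap <- function(map, start, length) {
  stopifnot(inherits(map, "contact_map"))
  if (start < 1 || length < 1 || start + length - 1 > map$L)
    stop("window [start, start + length) out of range")
  idx <- start:(start + length - 1)
  adj <- map$adj[idx, idx, drop = FALSE]
  list(map = structure(list(L = length, adj = adj), class = "contact_map"),
       parent_index = idx)
}
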