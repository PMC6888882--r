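#' Position-wise consensus of equal-length sequences
#'
#' Returns the string with, at each position, the most common character; ties
#' are broken lexicographically (documented convention).
#'
#' @param sequences character vector of equal-length residue strings.
#' @export
consensus_sequence <- function(sequences) {
  if (!length(sequences)) stop("no sequences given")
  chars <- strsplit(sequences, "")
  n <- lengths(chars)
  if (length(unique(n)) != 1) stop("sequences must have equal length")
  m <- do.call(rbind, chars)
  paste(apply(m, 2, function(col) names(which.max(table(col)))),
        collapse = "")
}

#' Mutation matrix from a time series of sequences
#'
#' Entry `m[i, t] = 1` when the sequence at time point t + 1 differs from the
#' one at time point t at site i (a substitution got fixed during that
#' interval); 0 is a match. For T time points the matrix has T - 1 columns.
#'
#' @param series time-ordered character vector of equal-length sequences
#'   (e.g. yearly consensus sequences).
#' @return integer matrix (sites x transitions) of class `mutation_matrix`.
#' @export
mutation_matrix_from_series <- function(series) {
  if (length(series) < 2) stop("need at least 2 time points")
  chars <- strsplit(series, "")
  if (length(unique(lengths(chars))) != 1)
    stop("sequences must have equal length")
  s <- do.call(cbind, chars)        # sites x times
  m <- (s[, -1, drop = FALSE] != s[, -ncol(s), drop = FALSE]) * 1L
  dimnames(m) <- NULL
  class(m) <- c("mutation_matrix", class(m))
  m
}

#' Mutation matrix from simulated substitution events
#'
#' Discretizes event times into `n_bins` equal-width bins spanning (0, t_max],
#' mirroring the yearly binning of real sequence series (33 bins matches the
#' 1981-2015 influenza record the analysis was designed around).
#'
#' @param events data frame with columns `site` and `time` (e.g. the `events`
#'   element of a [simulate_divergence()] result, optionally filtered to one
#'   branch).
#' @param L number of sites.
#' @param n_bins number of time bins.
#' @param t_max end of the binned interval; defaults to the latest event time.
#' @export
events_to_mutation_matrix <- function(events, L, n_bins = 33, t_max = NULL) {
  if (!all(c("site", "time") %in% names(events)))
    stop("events must have columns site and time")
  if (is.null(t_max)) t_max <- max(events$time)
  bin <- pmin(pmax(ceiling(events$time / t_max * n_bins), 1L), n_bins)
  m <- matrix(0L, L, n_bins)
  m[cbind(events$site, bin)] <- 1L
  class(m) <- c("mutation_matrix", class(m))
  m
}

#' Detect spatio-temporal substitution avalanches
#'
#' Builds the undirected graph whose nodes are the substitution events
#' (site i, time bin t) with `m[i, t] = 1` and whose links connect events
#' whose sites are in structural contact (or identical, when `self_links`)
#' and whose times differ by no more than `time_window` units. An avalanche
#' is a connected component of this graph; components of size <= 2 are
#' classified `"minor"` (isolated or paired substitutions), larger ones
#' `"avalanche"`.
#'
#' Contact maps for this analysis are conventionally built with an 8.5
#' Angstrom C-alpha cutoff (unlike the 10 Angstrom simulation default).
#'
#' @param m a [mutation_matrix_from_series()] result (or any 0/1 sites x
#'   times matrix).
#' @param map a [contact_map()] whose length matches `nrow(m)`.
#' @param time_window maximum time separation of linked events (inclusive).
#' @param self_links link repeated substitutions at the same site within the
#'   window (the convention for same-site repeats is not settled; exposed as
#'   a flag, default `TRUE`).
#' @return object of class `avalanche_partition`: data frame with columns
#'   `site`, `time`, `component`, `size`, `size_class`; attribute
#'   `n_components`.
#' @export
detect_avalanches <- function(m, map, time_window = 2, self_links = TRUE) {
  stopifnot(inherits(map, "contact_map"))
  if (nrow(m) != map$L)
    stop("mutation matrix site dimension must equal map length")
  if (!all(m %in% c(0, 1))) stop("mutation matrix entries must be 0/1")
  ev <- which(m == 1, arr.ind = TRUE)
  ev <- ev[order(ev[, 2], ev[, 1]), , drop = FALSE]
  n <- nrow(ev)
  if (n == 0) {
    out <- data.frame(site = integer(0), time = integer(0),
                      component = integer(0), size = integer(0),
                      size_class = character(0))
    attr(out, "n_components") <- 0L
    class(out) <- c("avalanche_partition", "data.frame")
    return(out)
  }
  from <- integer(0); to <- integer(0)
  for (a in seq_len(n)) {
    b <- a + seq_len(n - a)
    b <- b[ev[b, 2] - ev[a, 2] <= time_window]
    if (!length(b)) next
    linked <- map$adj[cbind(ev[a, 1], ev[b, 1])]
    if (self_links) linked <- linked | (ev[b, 1] == ev[a, 1])
    b <- b[linked]
    from <- c(from, rep(a, length(b))); to <- c(to, b)
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(from)) g <- igraph::add_edges(g, rbind(from, to))
  comp <- igraph::components(g)
  size <- comp$csize[comp$membership]
  out <- data.frame(site = unname(ev[, 1]), time = unname(ev[, 2]),
                    component = comp$membership, size = size,
                    size_class = ifelse(size <= 2, "minor", "avalanche"))
  attr(out, "n_components") <- comp$no
  class(out) <- c("avalanche_partition", "data.frame")
  out
}

#' Connect unmapped sites to their along-chain neighbors
#'
#' Sites of an alignment that could not be mapped to the reference structure
#' have no structural contacts; to keep the avalanche graph connected along
#' the chain, each such site is additionally put in contact with sites i - 1
#' and i + 1 (within bounds).
#'
#' @param map a [contact_map()].
#' @param unmapped integer vector of unmapped site indices.
#' @return a [contact_map()] with the extra contacts.
#' @export
pad_unmapped_sites <- function(map, unmapped) {
  stopifnot(inherits(map, "contact_map"))
  unmapped <- as.integer(unmapped)
  if (any(unmapped < 1 | unmapped > map$L)) stop("unmapped sites out of range")
  adj <- map$adj
  for (i in unmapped) {
    for (j in c(i - 1L, i + 1L)) {
      if (j >= 1 && j <= map$L) { adj[i, j] <- TRUE; adj[j, i] <- TRUE }
    }
  }
  structure(list(L = map$L, adj = adj), class = "contact_map")
}
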