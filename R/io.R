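#' Read C-alpha coordinates from a PDB-format file
#'
#' Minimal fixed-column reader: ATOM records with atom name CA, first model
#' only (reading stops at the first ENDMDL), first alternate location (altLoc
#' blank or "A"), one chain (the first chain encountered unless `chain` is
#' given). Insertion codes and multi-chain complexes beyond this selection are
#' not handled.
#'
#' @param path PDB file.
#' @param chain optional single-character chain identifier.
#' @return numeric matrix (residues x 3) of coordinates in Angstrom.
#' @export
read_pdb_ca <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  lines <- readLines(path, warn = FALSE)
  endmdl <- which(substr(lines, 1, 6) == "ENDMDL")
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1] - 1)]
  atom <- lines[substr(lines, 1, 6) == "ATOM  "]
  name <- trimws(substr(atom, 13, 16))
  altloc <- substr(atom, 17, 17)
  atom <- atom[name == "CA" & altloc %in% c(" ", "A")]
  if (!length(atom)) stop("no C-alpha atoms found in ", path)
  chains <- substr(atom, 22, 22)
  if (is.null(chain)) chain <- chains[1]
  atom <- atom[chains == chain]
  if (!length(atom)) stop("no C-alpha atoms for chain ", chain)
  xyz <- cbind(as.numeric(substr(atom, 31, 38)),
               as.numeric(substr(atom, 39, 46)),
               as.numeric(substr(atom, 47, 54)))
  if (any(!is.finite(xyz))) stop("malformed coordinates in ", path)
  xyz
}

#' Read and write contact maps as edge lists
#'
#' Plain-text format: a header line with the number of sites L, then one
#' whitespace-separated pair "i k" (1-based, i < k) per contact.
#'
#' @param map a [contact_map()].
#' @param path file path.
#' @export
write_contact_map <- function(map, path) {
  stopifnot(inherits(map, "contact_map"))
  e <- which(map$adj & upper.tri(map$adj), arr.ind = TRUE)
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  con <- file(path, "w"); on.exit(close(con))
  writeLines(as.character(map$L), con)
  if (nrow(e)) writeLines(paste(e[, 1], e[, 2]), con)
  invisible(path)
}

#' @rdname write_contact_map
#' @export
read_contact_map <- function(path) {
  if (!file.exists(path)) stop("cannot read contact map: ", path)
  lines <- readLines(path, warn = FALSE)
  L <- as.integer(lines[1])
  if (is.na(L) || L < 1) stop("bad contact map header in ", path)
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body)) {
    parts <- do.call(rbind, strsplit(trimws(body), "[[:space:]]+"))
    edges <- cbind(as.integer(parts[, 1]), as.integer(parts[, 2]))
  } else edges <- matrix(integer(0), 0, 2)
  contact_map(edges, L = L)
}

#' Read and write per-site structural class labels
#'
#' One-column text file of S/U codes, one per site.
#' @param classes a [site_classes()].
#' @param path file path.
#' @export
write_site_classes <- function(classes, path) {
  writeLines(unclass(site_classes(classes)), path)
  invisible(path)
}

#' @rdname write_site_classes
#' @export
read_site_classes <- function(path) {
  if (!file.exists(path)) stop("cannot read site classes: ", path)
  site_classes(trimws(readLines(path, warn = FALSE)))
}

#' Read and write binary alignments in a FASTA-like container
#'
#' Each record is a header line `>tag identity=<s> [key=value ...]` followed
#' by one line of 0/1 symbols.
#'
#' @param alignments list of [binary_alignment()] objects.
#' @param path file path.
#' @export
write_binary_alignments <- function(alignments, path) {
  if (inherits(alignments, "binary_alignment")) alignments <- list(alignments)
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(alignments)) {
    a <- alignments[[i]]
    tag <- if (is.na(a$source)) sprintf("aln%d", i) else a$source
    writeLines(sprintf(">%s identity=%.6f", tag, a$identity), con)
    writeLines(paste(a$symbols, collapse = ""), con)
  }
  invisible(path)
}

#' @rdname write_binary_alignments
#' @export
read_binary_alignments <- function(path) {
  if (!file.exists(path)) stop("cannot read alignments: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no records in ", path)
  lapply(hdr, function(h) {
    tag <- sub("^>", "", strsplit(lines[h], "[[:space:]]+")[[1]][1])
    symbols <- as.integer(strsplit(lines[h + 1], "")[[1]])
    id <- regmatches(lines[h], regexec("identity=([0-9.eE+-]+)", lines[h]))[[1]]
    binary_alignment(symbols,
                     identity = if (length(id) == 2) as.numeric(id[2]) else NULL,
                     source = tag)
  })
}

#' Write and read a conditional profile as TSV (columns d, N1, N0, P)
#' @param profile a `conditional_profile`.
#' @param path file path.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  if (!file.exists(path)) stop("cannot read profile: ", path)
  out <- utils::read.table(path, header = TRUE, sep = "\t")
  class(out) <- c("conditional_profile", "data.frame")
  out
}

#' Write an avalanche partition as TSV
#' @param partition an `avalanche_partition`.
#' @param path file path.
#' @export
write_partition_tsv <- function(partition, path) {
  utils::write.table(as.data.frame(partition), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition_tsv
#' @export
read_partition_tsv <- function(path) {
  if (!file.exists(path)) stop("cannot read partition: ", path)
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  attr(out, "n_components") <- length(unique(out$component))
  class(out) <- c("avalanche_partition", "data.frame")
  out
}

#' Read a time-tagged multi-FASTA sequence series
#'
#' Record headers must carry a `time=<number>` tag; records are returned in
#' ascending time order.
#'
#' @param path FASTA file.
#' @return character vector of sequences, names = times.
#' @export
read_sequence_series <- function(path) {
  if (!file.exists(path)) stop("cannot read series: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no records in ", path)
  ends <- c(hdr[-1] - 1, length(lines))
  seqs <- vapply(seq_along(hdr), function(i)
    paste(lines[(hdr[i] + 1):ends[i]], collapse = ""), character(1))
  tm <- vapply(lines[hdr], function(h) {
    m <- regmatches(h, regexec("time=([0-9.eE+-]+)", h))[[1]]
    if (length(m) != 2) stop("record header lacks a time= tag: ", h)
    as.numeric(m[2])
  }, numeric(1), USE.NAMES = FALSE)
  o <- order(tm)
  stats::setNames(seqs[o], tm[o])
}

#' Read and write flat key=value configuration files
#'
#' One `key = value` pair per line; blank lines and lines starting with `#`
#' are ignored. Values are returned as strings.
#'
#' @param path file path.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("cannot read config file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([^=[:space:]]+)[[:space:]]*=[[:space:]]*(.*)$", lines))
  bad <- lengths(kv) != 3
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  stats::setNames(lapply(kv, `[`, 3), vapply(kv, `[`, character(1), 2))
}

#' @rdname read_config
#' @param config named list or vector of values.
#' @export
write_config <- function(config, path) {
  writeLines(paste(names(config), unlist(config), sep = " = "), path)
  invisible(path)
}
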