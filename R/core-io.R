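# Reading/writing the standard formats the pipeline touches (FASTA, newick,
# TSV metadata, RAxML-style partition files) and supermatrix assembly.

#' Coerce to an aligned character matrix
#'
#' Alignments are represented throughout the package as upper-case character
#' matrices with one row per terminal (rownames are terminal ids) and one
#' column per aligned site. Allowed symbols are A/C/G/T, IUPAC ambiguity
#' codes, the alignment gap \code{-} and the missing-data symbols \code{?}
#' and \code{N}.
#'
#' @param x a named character vector of equal-length sequence strings, or a
#'   character matrix with rownames.
#' @return an upper-case character matrix with unique rownames.
#' @export
as_alignment <- function(x) {
  if (is.matrix(x)) {
    m <- toupper(x)
  } else if (is.character(x)) {
    if (is.null(names(x))) stop("sequences must be named")
    lens <- nchar(x)
    if (any(lens == 0L)) stop("empty sequence for id ", names(x)[lens == 0L][1L])
    if (length(unique(lens)) > 1L) {
      bad <- names(x)[lens != lens[1L]][1L]
      stop("ragged alignment: sequence '", bad, "' has length ",
           nchar(x[[bad]]), ", expected ", lens[1L])
    }
    m <- do.call(rbind, strsplit(toupper(x), "", fixed = TRUE))
    rownames(m) <- names(x)
  } else {
    stop("cannot coerce object of class ", class(x)[1L], " to an alignment")
  }
  if (is.null(rownames(m))) stop("alignment must have row names (terminal ids)")
  if (anyDuplicated(rownames(m)))
    stop("duplicate terminal id: ",
         rownames(m)[duplicated(rownames(m))][1L])
  if (ncol(m) == 0L) stop("alignment has zero columns")
  m
}

#' Read an aligned FASTA file
#'
#' Record order is preserved and sequences are upper-cased. Ragged records
#' and duplicate ids are rejected.
#'
#' @param path path to a FASTA file.
#' @return alignment matrix (see [as_alignment()]).
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- ape::read.dna(path, format = "fasta", as.character = TRUE,
                        as.matrix = FALSE)
  if (is.matrix(seqs)) {
    ids <- rownames(seqs)
    strs <- apply(seqs, 1L, paste, collapse = "")
  } else {
    ids <- names(seqs)
    strs <- vapply(seqs, paste, "", collapse = "")
  }
  names(strs) <- ids
  as_alignment(strs)
}

#' Write an alignment to FASTA
#'
#' @param aln alignment matrix.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_alignment <- function(aln, path) {
  aln <- as_alignment(aln)
  lines <- character(2L * nrow(aln))
  lines[c(TRUE, FALSE)] <- paste0(">", rownames(aln))
  lines[c(FALSE, TRUE)] <- apply(aln, 1L, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a voucher metadata table
#'
#' Tab-separated, with header columns \code{terminal_id}, \code{subtribe},
#' \code{subregion}, \code{region}, \code{landmass} and \code{fragments}
#' (comma-separated subset of the fragment names, possibly empty).
#'
#' @param path path to the TSV file.
#' @param regions optional declared region vocabulary; labels outside it are
#'   an error.
#' @param landmasses optional declared landmass vocabulary.
#' @param alignment_ids optional terminal ids present in the alignment;
#'   metadata rows for other terminals trigger a warning but are retained.
#' @return a data.frame, one row per voucher.
#' @export
read_metadata <- function(path, regions = NULL, landmasses = NULL,
                          alignment_ids = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  md <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("terminal_id", "subtribe", "subregion", "region",
                "landmass", "fragments")
  missing_cols <- setdiff(required, names(md))
  if (length(missing_cols))
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  validate_metadata(md, regions = regions, landmasses = landmasses,
                    alignment_ids = alignment_ids)
}

#' @rdname read_metadata
#' @param md a metadata data.frame.
#' @export
validate_metadata <- function(md, regions = NULL, landmasses = NULL,
                              alignment_ids = NULL) {
  if (anyDuplicated(md$terminal_id))
    stop("duplicate terminal_id in metadata: ",
         md$terminal_id[duplicated(md$terminal_id)][1L])
  if (!is.null(regions)) {
    bad <- setdiff(unique(md$region), regions)
    if (length(bad))
      stop("region label(s) not in declared list: ",
           paste(bad, collapse = ", "))
  }
  if (!is.null(landmasses)) {
    bad <- setdiff(unique(md$landmass), landmasses)
    if (length(bad))
      stop("landmass label(s) not in declared list: ",
           paste(bad, collapse = ", "))
  }
  if (!is.null(alignment_ids)) {
    orphan <- setdiff(md$terminal_id, alignment_ids)
    if (length(orphan))
      warning(length(orphan),
              " metadata terminal(s) absent from the alignment (retained)")
  }
  md
}

#' Which terminals carry a given fragment
#'
#' @param md metadata data.frame (see [read_metadata()]).
#' @param fragment fragment name, e.g. \code{"cox1"}.
#' @return logical vector along the rows of `md`.
#' @export
has_fragment <- function(md, fragment) {
  vapply(strsplit(md$fragments, ",", fixed = TRUE),
         function(f) fragment %in% trimws(f), NA)
}

#' Barrier classification between landmasses
#'
#' A barrier map classifies every unordered landmass pair as
#' \code{deep_sea} (sea deeper than 200 m), \code{shelf} (inundated shelf,
#' sea shallower than 100 m) or \code{contiguous}. It is data, not
#' hard-coded geography.
#'
#' @param df data.frame with columns \code{landmass_a}, \code{landmass_b},
#'   \code{barrier}.
#' @return a validated barrier-map data.frame.
#' @export
as_barrier_map <- function(df) {
  required <- c("landmass_a", "landmass_b", "barrier")
  if (!all(required %in% names(df)))
    stop("barrier map needs columns: ", paste(required, collapse = ", "))
  classes <- c("deep_sea", "shelf", "contiguous")
  bad <- setdiff(unique(df$barrier), classes)
  if (length(bad))
    stop("unknown barrier class(es): ", paste(bad, collapse = ", "))
  key <- barrier_key(df$landmass_a, df$landmass_b)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    conflict <- vapply(dup, function(k) {
      length(unique(df$barrier[key == k])) > 1L
    }, NA)
    if (any(conflict))
      stop("conflicting barrier class for pair ", dup[conflict][1L])
    df <- df[!duplicated(key), , drop = FALSE]
  }
  df
}

#' @rdname as_barrier_map
#' @param path TSV file with the three columns above.
#' @export
read_barrier_map <- function(path) {
  as_barrier_map(utils::read.delim(path, stringsAsFactors = FALSE))
}

barrier_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Look up the barrier class of a landmass pair
#'
#' @param bm barrier map (see [as_barrier_map()]).
#' @param a,b landmass labels (vectorised).
#' @return character vector of barrier classes.
#' @export
barrier_class <- function(bm, a, b) {
  key <- barrier_key(bm$landmass_a, bm$landmass_b)
  out <- bm$barrier[match(barrier_key(a, b), key)]
  if (anyNA(out))
    stop("landmass pair not classified in barrier map: ",
         paste(a[is.na(out)][1L], b[is.na(out)][1L], sep = " / "))
  out
}

#' Concatenate fragment alignments into a supermatrix
#'
#' Every taxon in the union (or in `taxa`, when given) receives a row; a
#' taxon absent from a fragment is filled with \code{?} across that
#' fragment's columns. \code{?} is deliberately distinct from the alignment
#' gap \code{-}; both are treated as missing downstream.
#'
#' @param fragments named list of alignment matrices.
#' @param taxa optional ordered taxon union; defaults to order of first
#'   appearance across fragments.
#' @return list with elements \code{alignment} and \code{scheme}, the latter
#'   a data.frame of 1-based inclusive column ranges per fragment.
#' @export
concatenate_fragments <- function(fragments, taxa = NULL) {
  if (!length(fragments)) stop("no fragments supplied")
  if (is.null(names(fragments)) || any(names(fragments) == ""))
    stop("fragments must be a named list")
  fragments <- lapply(fragments, as_alignment)
  if (is.null(taxa))
    taxa <- unique(unlist(lapply(fragments, rownames), use.names = FALSE))
  lens <- vapply(fragments, ncol, 0L)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  out <- matrix("?", nrow = length(taxa), ncol = sum(lens),
                dimnames = list(taxa, NULL))
  for (i in seq_along(fragments)) {
    frag <- fragments[[i]]
    present <- intersect(taxa, rownames(frag))
    out[present, starts[i]:ends[i]] <- frag[present, , drop = FALSE]
  }
  scheme <- data.frame(fragment = names(fragments), start = starts,
                       end = ends, row.names = NULL,
                       stringsAsFactors = FALSE)
  list(alignment = out, scheme = scheme)
}

#' Extract one fragment from a supermatrix
#'
#' @param aln concatenated alignment.
#' @param scheme partition scheme (see [concatenate_fragments()]).
#' @param fragment fragment name.
#' @param drop_empty drop rows with no resolved site in the fragment.
#' @return alignment matrix restricted to the fragment's columns.
#' @export
extract_partition <- function(aln, scheme, fragment, drop_empty = FALSE) {
  i <- match(fragment, scheme$fragment)
  if (is.na(i)) stop("no such fragment in scheme: ", fragment)
  sub <- aln[, scheme$start[i]:scheme$end[i], drop = FALSE]
  if (drop_empty) {
    resolved <- rowSums(matrix(sub %in% DNA_STATES, nrow = nrow(sub))) > 0L
    sub <- sub[resolved, , drop = FALSE]
  }
  sub
}

#' Write / read a RAxML-style partition file
#'
#' Lines have the form \code{DNA, cox1 = 1-1100}; coordinates are 1-based
#' inclusive.
#'
#' @param scheme partition-scheme data.frame.
#' @param path file path.
#' @return `read_partition_scheme` returns the scheme data.frame.
#' @export
write_partition_scheme <- function(scheme, path) {
  writeLines(sprintf("DNA, %s = %d-%d", scheme$fragment,
                     scheme$start, scheme$end), path)
  invisible(path)
}

#' @rdname write_partition_scheme
#' @export
read_partition_scheme <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  m <- regmatches(lines,
                  regexec("^\\s*\\w+\\s*,\\s*(\\S+)\\s*=\\s*(\\d+)\\s*-\\s*(\\d+)\\s*$",
                          lines))
  if (any(lengths(m) != 4L))
    stop("malformed partition line: ", lines[lengths(m) != 4L][1L])
  scheme <- data.frame(
    fragment = vapply(m, `[`, "", 2L),
    start = as.integer(vapply(m, `[`, "", 3L)),
    end = as.integer(vapply(m, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
  validate_scheme(scheme)
}

validate_scheme <- function(scheme, total_length = NULL) {
  o <- order(scheme$start)
  s <- scheme[o, , drop = FALSE]
  if (s$start[1L] != 1L) stop("partition scheme must start at column 1")
  if (any(s$end < s$start)) stop("partition with end before start")
  if (nrow(s) > 1L && any(s$start[-1L] != s$end[-nrow(s)] + 1L))
    stop("partition scheme has gaps or overlaps")
  if (!is.null(total_length) && s$end[nrow(s)] != total_length)
    stop("partition scheme does not cover the alignment")
  scheme
}

#' Read and write newick trees
#'
#' Thin wrappers over \pkg{ape} that give position-bearing parse errors and
#' keep multifurcations.
#'
#' @param path newick file path.
#' @return `read_tree` returns a `phylo` (or `multiPhylo` for several trees).
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close)
    stop("unbalanced parentheses in newick (", n_open, " '(' vs ",
         n_close, " ')') in ", path)
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse newick in ", path)
  tr
}

#' @rdname read_tree
#' @param tree a `phylo` or `multiPhylo`.
#' @param digits branch-length precision written to file.
#' @export
write_tree <- function(tree, path, digits = 10) {
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}
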