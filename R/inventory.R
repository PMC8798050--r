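# Diversity accounting: per-region described-vs-analyzed tables, endemism,
# and cross-landmass turnover classified by sea-barrier depth.

motu_members <- function(partition) {
  split(names(partition$assignment), partition$assignment)
}

# Per-mOTU set of values of a metadata column (e.g. region or landmass),
# restricted to terminals present in the metadata.
motu_occurrences <- function(partition, metadata, column) {
  idx <- match(names(partition$assignment), metadata$terminal_id)
  known <- !is.na(idx)
  vals <- metadata[[column]][idx[known]]
  cl <- partition$assignment[known]
  lapply(split(vals, cl), function(v) sort(unique(v)))
}

#' Ratio of analyzed to described species, rounded half-up
#'
#' @param analyzed mOTU count (numeric, vectorised).
#' @param described described-species count; zero yields `NA` ("not
#'   computable"), rendered as an em dash in reports.
#' @return numeric ratio rounded half-up to two decimals.
#' @export
described_ratio <- function(analyzed, described) {
  out <- ifelse(described > 0, round_half_up(analyzed / described, 2),
                NA_real_)
  unname(out)
}

#' Count mOTUs per geographic unit
#'
#' An mOTU contributes to every unit in which at least one member occurs
#' ("by occurrence"), so rows can share mOTUs; the unique total counts each
#' mOTU once.
#'
#' @param partition a `motu_partition`.
#' @param metadata metadata data.frame; terminals without a row are excluded
#'   with a warning count.
#' @param level metadata column to aggregate by (`"region"`, `"landmass"` or
#'   `"subregion"`).
#' @return list with `by_unit` (named integer vector) and `unique_total`.
#' @export
count_by_unit <- function(partition, metadata, level = "region") {
  idx <- match(names(partition$assignment), metadata$terminal_id)
  n_orphan <- sum(is.na(idx))
  if (n_orphan > 0L)
    warning(n_orphan, " terminal(s) without metadata excluded from counts")
  occ <- motu_occurrences(partition, metadata, level)
  units <- sort(unique(unlist(occ)))
  by_unit <- vapply(units, function(u)
    sum(vapply(occ, function(o) u %in% o, NA)), 0L)
  list(by_unit = by_unit, unique_total = length(occ))
}

#' Described-vs-analyzed diversity table
#'
#' Builds the headline inventory table: per geographic unit, the number of
#' described species, the mOTU count at each supplied threshold, and the
#' analyzed/described ratio (half-up, two decimals). A totals row is
#' appended: by-occurrence column sums plus the unique-mOTU totals, with the
#' total ratio computed from unique totals.
#'
#' @param partitions named list of `motu_partition`s, one per threshold
#'   (names label the count columns, e.g. `"2pct"`).
#' @param metadata metadata data.frame.
#' @param described data.frame with columns `unit` and `described`.
#' @param level metadata column defining the units.
#' @return data.frame (rows: units, totals) — see Details for columns.
#' @export
aggregate_regions <- function(partitions, metadata, described,
                              level = "region") {
  stopifnot(is.list(partitions), !is.null(names(partitions)))
  counts <- lapply(partitions, count_by_unit, metadata = metadata,
                   level = level)
  units <- sort(unique(c(described$unit,
                         unlist(lapply(counts, function(x)
                           names(x$by_unit))))))
  tab <- data.frame(unit = units, stringsAsFactors = FALSE)
  tab$described <- described$described[match(units, described$unit)]
  tab$described[is.na(tab$described)] <- 0L
  for (nm in names(counts)) {
    v <- counts[[nm]]$by_unit[units]
    v[is.na(v)] <- 0L
    tab[[paste0("motus_", nm)]] <- unname(v)
  }
  totals <- data.frame(unit = c("Total (by occurrence)",
                                "Total (unique mOTUs)"),
                       described = c(sum(tab$described), sum(tab$described)),
                       stringsAsFactors = FALSE)
  for (nm in names(counts)) {
    col <- paste0("motus_", nm)
    totals[[col]] <- c(sum(tab[[col]]), counts[[nm]]$unique_total)
  }
  out <- rbind(tab, totals)
  for (nm in names(counts)) {
    out[[paste0("ratio_", nm)]] <-
      described_ratio(out[[paste0("motus_", nm)]], out$described)
  }
  out
}

#' Totals and ratios from a plain count table
#'
#' Arithmetic companion to [aggregate_regions()] for count tables assembled
#' from published integers rather than from a partition: appends a totals
#' row (column sums) and recomputes every ratio column as
#' analyzed/described, half-up to two decimals.
#'
#' @param counts data.frame with column `unit`, column `described`, and one
#'   or more integer `motus_*` columns; rows must be disjoint units.
#' @return data.frame with a `Total` row and `ratio_*` columns.
#' @export
region_table <- function(counts) {
  stopifnot(all(c("unit", "described") %in% names(counts)))
  motu_cols <- grep("^motus_", names(counts), value = TRUE)
  total <- counts[1L, , drop = FALSE]
  total$unit <- "Total"
  total$described <- sum(counts$described)
  for (col in motu_cols) total[[col]] <- sum(counts[[col]])
  out <- rbind(counts, total)
  for (col in motu_cols) {
    out[[sub("^motus_", "ratio_", col)]] <-
      described_ratio(out[[col]], out$described)
  }
  out
}

#' Endemic mOTU counts and proportions
#'
#' An mOTU is endemic to a unit when all of its occurrences fall in that
#' single unit.
#'
#' @param partition a `motu_partition`.
#' @param metadata metadata data.frame.
#' @param level `"region"` or `"landmass"`.
#' @return list with `by_unit` (data.frame: unit, motus present, endemics,
#'   proportion endemic among present) and `global_proportion` (endemic
#'   mOTUs over all mOTUs with known occurrences).
#' @export
endemism_table <- function(partition, metadata,
                           level = c("region", "landmass")) {
  level <- match.arg(level)
  occ <- motu_occurrences(partition, metadata, level)
  occ <- occ[lengths(occ) > 0L]
  units <- sort(unique(unlist(occ)))
  endemic_unit <- vapply(occ, function(o)
    if (length(o) == 1L) o else NA_character_, "")
  by_unit <- data.frame(unit = units, stringsAsFactors = FALSE)
  by_unit$present <- vapply(units, function(u)
    sum(vapply(occ, function(o) u %in% o, NA)), 0L)
  by_unit$endemic <- vapply(units, function(u)
    sum(endemic_unit == u, na.rm = TRUE), 0L)
  by_unit$prop_endemic <- ifelse(by_unit$present > 0,
                                 by_unit$endemic / by_unit$present, NA_real_)
  list(by_unit = by_unit,
       global_proportion = mean(!is.na(endemic_unit)))
}

#' Cross-landmass turnover classified by barrier depth
#'
#' For every mOTU occurring on two or more landmasses, each spanned landmass
#' pair is classified by the barrier map; the table counts mOTUs with at
#' least one spanned pair in each barrier class (an mOTU is counted once per
#' class it spans). Single-landmass mOTUs are excluded.
#'
#' @param partition a `motu_partition`.
#' @param metadata metadata data.frame with a `landmass` column.
#' @param barriers barrier map (see [as_barrier_map()]).
#' @return list with `counts` (named integer vector over barrier classes),
#'   `n_multi_landmass`, and `per_motu` (data.frame: cluster, landmasses,
#'   classes spanned).
#' @export
turnover <- function(partition, metadata, barriers) {
  barriers <- as_barrier_map(barriers)
  occ <- motu_occurrences(partition, metadata, "landmass")
  multi <- occ[lengths(occ) >= 2L]
  classes <- c("deep_sea", "shelf", "contiguous")
  counts <- stats::setNames(integer(3L), classes)
  rows <- lapply(names(multi), function(cl) {
    lm <- multi[[cl]]
    prs <- utils::combn(lm, 2L)
    cls <- unique(barrier_class(barriers, prs[1L, ], prs[2L, ]))
    data.frame(cluster = cl, landmasses = paste(lm, collapse = ","),
               classes = paste(sort(cls), collapse = ","),
               stringsAsFactors = FALSE)
  })
  per_motu <- if (length(rows)) do.call(rbind, rows)
              else data.frame(cluster = character(0),
                              landmasses = character(0),
                              classes = character(0),
                              stringsAsFactors = FALSE)
  for (cl in classes) {
    counts[cl] <- sum(vapply(strsplit(per_motu$classes, ",", fixed = TRUE),
                             function(x) cl %in% x, NA))
  }
  list(counts = counts, n_multi_landmass = length(multi),
       per_motu = per_motu)
}

#' Write inventory tables to TSV with a human-readable summary
#'
#' Deterministic column order, totals rows intact, rounding applied exactly
#' once (upstream); a round-trip read reproduces integer columns exactly.
#'
#' @param tables named list of data.frames.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written; a `summary.txt` sketches each
#'   table.
#' @export
render_report <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  summaries <- character(0)
  for (nm in names(tables)) {
    path <- file.path(dir, paste0(nm, ".tsv"))
    df <- tables[[nm]]
    num <- vapply(df, is.double, NA)
    df[num] <- lapply(df[num], function(x) ifelse(is.na(x), "—",
                                                  format(x, trim = TRUE)))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, path)
    summaries <- c(summaries, sprintf("%s: %d row(s), %d column(s)", nm,
                                      nrow(tables[[nm]]),
                                      ncol(tables[[nm]])))
  }
  writeLines(summaries, file.path(dir, "summary.txt"))
  invisible(c(paths, file.path(dir, "summary.txt")))
}
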