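# Readers/writers for the on-disk formats the pipeline touches. All intervals
# are 0-based half-open (BED convention) everywhere inside the package;
# conversion to 1-based happens only when rendering reports.

REGION_CLASSES <- c("acetophenone_target", "internal_standard")

#' Read a target-region panel from a BED file
#'
#' Accepts 3-5 column BED: contig, start, end, then optionally a name column
#' (mapped to `gene_id`; also used as `region_id`) and a region class column
#' (`acetophenone_target` or `internal_standard`). Coordinates are 0-based
#' half-open. Rows with missing optional columns get defaults:
#' `region_id` = "contig:start-end", `gene_id` = `region_id`,
#' `region_class` = "acetophenone_target".
#'
#' @param path path to a tab-separated BED file (no header).
#' @return tibble with columns `region_id`, `contig`, `start`, `end`,
#'   `gene_id`, `region_class`, `length`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t0\t100\tgeneA", f)
#' read_bed(f)
read_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("BED file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort("BED file is empty")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  parse_row <- function(f, i) {
    if (length(f) < 3) {
      abort(sprintf("BED line %d: expected >= 3 tab-separated columns", i))
    }
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end)) {
      abort(sprintf("BED line %d: non-integer coordinates '%s', '%s'",
                    i, f[2], f[3]))
    }
    if (start < 0 || start >= end) {
      abort(sprintf("BED line %d: need 0 <= start < end, got [%d, %d)",
                    i, start, end))
    }
    name <- if (length(f) >= 4) f[4] else sprintf("%s:%d-%d", f[1], start, end)
    cls <- if (length(f) >= 5) f[5] else "acetophenone_target"
    if (!cls %in% REGION_CLASSES) {
      abort(sprintf("BED line %d: unknown region class '%s'", i, cls))
    }
    tibble(region_id = name, contig = f[1], start = start, end = end,
           gene_id = name, region_class = cls)
  }
  out <- bind_rows(purrr::imap(fields, parse_row))
  if (anyDuplicated(out$region_id)) {
    abort(sprintf("duplicated region_id in panel: %s",
                  paste(unique(out$region_id[duplicated(out$region_id)]),
                        collapse = ", ")))
  }
  mutate(out, length = .data$end - .data$start)
}

#' Write a target-region panel as 5-column BED
#'
#' Inverse of [read_bed()]: canonical 5-column files round-trip
#' byte-identically.
#'
#' @param regions tibble as returned by [read_bed()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  stopifnot_cols(regions, c("contig", "start", "end", "gene_id", "region_class"),
                 "regions")
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s", regions$contig,
                     as.integer(regions$start), as.integer(regions$end),
                     regions$gene_id, regions$region_class), path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' Sequences are uppercased; ids are the first whitespace-delimited token of
#' the header. Duplicate ids and empty records are errors.
#'
#' @param path path to an uncompressed FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate FASTA id(s): %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (any(Biostrings::width(set) == 0)) {
    abort(sprintf("empty FASTA record(s): %s",
                  paste(ids[Biostrings::width(set) == 0], collapse = ", ")))
  }
  setNames(toupper(as.character(set)), ids)
}

#' Write sequences to FASTA (60-column wrap)
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    abort("sequences must be named")
  }
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a per-base depth track from a bedGraph file
#'
#' Expects the 4-column bedGraph dialect contig/start/end/depth with 0-based
#' half-open intervals. Intervals must be non-overlapping within a contig
#' (adjacent equal-depth intervals are allowed and can be merged with
#' [merge_depth_track()]); bases absent from the track have depth 0.
#'
#' @param path path to a bedGraph file (no header).
#' @return tibble with columns `contig`, `start`, `end`, `depth`, sorted by
#'   contig then start.
#' @export
read_depth_track <- function(path) {
  if (!file.exists(path)) abort(sprintf("bedGraph file not found: %s", path))
  x <- readr::read_tsv(path, col_names = c("contig", "start", "end", "depth"),
                       col_types = readr::cols(
                         contig = readr::col_character(),
                         start = readr::col_integer(),
                         end = readr::col_integer(),
                         depth = readr::col_double()),
                       progress = FALSE)
  validate_depth_track(x)
}

#' @rdname read_depth_track
#' @param track depth-track tibble to validate.
#' @export
validate_depth_track <- function(track) {
  stopifnot_cols(track, c("contig", "start", "end", "depth"), "depth track")
  if (any(track$start < 0) || any(track$start >= track$end)) {
    abort("depth track: need 0 <= start < end for every interval")
  }
  if (any(track$depth < 0)) abort("depth track: negative depth")
  track <- arrange(track, .data$contig, .data$start)
  bad <- track |>
    group_by(.data$contig) |>
    summarise(overlap = any(.data$start < dplyr::lag(.data$end),
                            na.rm = TRUE), .groups = "drop") |>
    filter(.data$overlap)
  if (nrow(bad) > 0) {
    abort(sprintf("depth track: overlapping intervals on contig(s): %s",
                  paste(bad$contig, collapse = ", ")))
  }
  track
}

#' Merge adjacent equal-depth intervals of a depth track
#'
#' @param track tibble as returned by [read_depth_track()].
#' @return tibble in the same format with runs of touching equal-depth
#'   intervals collapsed.
#' @export
merge_depth_track <- function(track) {
  track <- validate_depth_track(track)
  track |>
    group_by(.data$contig) |>
    mutate(new_run = dplyr::row_number() == 1L |
             .data$start != dplyr::lag(.data$end) |
             .data$depth != dplyr::lag(.data$depth),
           run = cumsum(.data$new_run)) |>
    group_by(.data$contig, .data$run) |>
    summarise(start = min(.data$start), end = max(.data$end),
              depth = .data$depth[1], .groups = "drop") |>
    select("contig", "start", "end", "depth") |>
    arrange(.data$contig, .data$start)
}

#' Write a depth track as bedGraph
#'
#' @param track depth-track tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_depth_track <- function(track, path) {
  track <- validate_depth_track(track)
  writeLines(sprintf("%s\t%d\t%d\t%s", track$contig, as.integer(track$start),
                     as.integer(track$end), format(track$depth, trim = TRUE,
                                                   scientific = FALSE)),
             path)
  invisible(path)
}

#' Read a header-ed TSV with a required-column schema
#'
#' The only accepted table dialect is tab-separated with a header row;
#' comma-separated files are rejected. The literal string "NA" is the
#' missing-value marker and is propagated, never silently zeroed.
#'
#' @param path path to the TSV file.
#' @param required character vector of required column names.
#' @param col_types optional readr `cols()` specification.
#' @return tibble; extra columns beyond the schema are preserved.
#' @export
read_tsv_strict <- function(path, required = character(), col_types = NULL) {
  if (!file.exists(path)) abort(sprintf("table not found: %s", path))
  header <- readLines(path, n = 1)
  if (!grepl("\t", header) && grepl(",", header)) {
    abort(sprintf("%s: comma-separated tables are rejected; use TSV", path))
  }
  x <- readr::read_tsv(path, col_types = col_types, na = "NA",
                       progress = FALSE, show_col_types = FALSE)
  stopifnot_cols(x, required, sprintf("table '%s'", path))
  x
}

#' Write a tibble as TSV ("NA" missing-value marker)
#'
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_out <- function(x, path) {
  readr::write_tsv(x, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Requires columns `sample_id`, `species`, `provenance`; `sample_id` must be
#' unique and `provenance` non-empty (a provenance is the geographic origin
#' population of a sampled individual in a common-garden trial).
#'
#' @param path path to TSV.
#' @return tibble.
#' @export
read_sample_meta <- function(path) {
  x <- read_tsv_strict(path, required = c("sample_id", "species", "provenance"))
  if (anyDuplicated(x$sample_id)) abort("sample_id must be unique")
  if (any(is.na(x$provenance) | !nzchar(x$provenance))) {
    abort("provenance must be non-empty for every sample")
  }
  x
}
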