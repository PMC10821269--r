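# Tiled capture-bait design over padded target regions: pad, tile, predict
# melting temperature, filter on genome hits and Tm, and summarise the panel.

#' Pad target regions up- and downstream
#'
#' Extends every region by `pad_bp` in both directions, clamped to
#' `[0, contig_length)`. Region identity (ids, class) is preserved.
#'
#' @param regions panel tibble as from [read_bed()].
#' @param pad_bp non-negative integer padding (default 1000).
#' @param contig_lengths named numeric vector of contig lengths covering every
#'   contig referenced by `regions`.
#' @return tibble in the same format with updated `start`, `end`, `length`.
#' @export
pad_regions <- function(regions, pad_bp = 1000, contig_lengths) {
  stopifnot_cols(regions, c("region_id", "contig", "start", "end"), "regions")
  if (pad_bp < 0) abort("pad_bp must be >= 0")
  unknown <- setdiff(unique(regions$contig), names(contig_lengths))
  if (length(unknown) > 0) {
    abort(sprintf("contig_lengths missing contig(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  regions |>
    mutate(start = pmax(0L, as.integer(.data$start - pad_bp)),
           end = pmin(as.integer(contig_lengths[.data$contig]),
                      as.integer(.data$end + pad_bp)),
           length = .data$end - .data$start)
}

# Offsets of tiled baits over a region of length L. Regular offsets advance by
# `step`; when the last regular bait does not reach the 3' end, one extra bait
# is anchored at L - bait_len so every base is covered. Regions shorter than
# one bait get a single full-length bait.
tile_offsets <- function(L, bait_len, step) {
  if (L < 1) abort("region length must be >= 1")
  if (L <= bait_len) return(0L)
  regular <- seq.int(0L, L - bait_len, by = step)
  if ((L - bait_len) %% step != 0L) regular <- c(regular, L - bait_len)
  as.integer(regular)
}

# Closed-form bait count for a region of length L (matches tile_offsets()).
n_baits <- function(L, bait_len = 80, tiling_density = 2) {
  step <- max(1L, as.integer(round(bait_len / tiling_density)))
  ifelse(L <= bait_len, 1L,
         (L - bait_len) %/% step + 1L + as.integer((L - bait_len) %% step != 0L))
}

#' Tile capture baits across region sequences
#'
#' Produces `bait_len`-nt baits whose start offsets advance by
#' `round(bait_len / tiling_density)` (40 nt for the 80-nt / 2X default, i.e.
#' each target base is covered by ~2 baits). An end-anchored bait is added
#' whenever the regular tiling would leave the 3' end uncovered; regions
#' shorter than `bait_len` yield one bait spanning the whole region.
#'
#' @param region_seqs named character vector: region_id -> sequence (as from
#'   [read_fasta()] on the padded panel).
#' @param bait_len bait length in nt (default 80).
#' @param tiling_density mean number of baits covering each base (default 2).
#' @return tibble with columns `bait_id`, `region_id`, `offset` (0-based),
#'   `length`, `sequence`.
#' @export
tile_baits <- function(region_seqs, bait_len = 80, tiling_density = 2) {
  if (bait_len <= 0 || tiling_density <= 0) {
    abort("bait_len and tiling_density must be positive")
  }
  if (is.null(names(region_seqs)) || any(!nzchar(names(region_seqs)))) {
    abort("region_seqs must be a named character vector (region_id -> seq)")
  }
  if (any(!nzchar(region_seqs))) abort("empty region sequence")
  step <- max(1L, as.integer(round(bait_len / tiling_density)))
  purrr::imap(region_seqs, function(seq, rid) {
    L <- nchar(seq)
    off <- tile_offsets(L, bait_len, step)
    len <- pmin(bait_len, L)
    tibble(bait_id = sprintf("%s_b%04d", rid, seq_along(off)),
           region_id = rid, offset = off, length = as.integer(len),
           sequence = substr(rep(seq, length(off)), off + 1L, off + len))
  }) |>
    bind_rows()
}

#' Predicted hybrid melting temperature
#'
#' Two deterministic models:
#' \describe{
#'   \item{`gc_mismatch`}{GC/length formula with a linear mismatch penalty,
#'     `Tm = 81.5 + 16.6 log10(Na+/50mM) + 0.41 %GC - 675/N - %mismatch`.
#'     The salt term is written as an offset from the 50 mM reference so it is
#'     exactly zero at the default salt concentration.}
#'   \item{`wallace`}{`Tm = 2(A+T) + 4(G+C)`, the short-oligo rule.}
#' }
#'
#' @param seqs character vector of A/C/G/T sequences (ambiguity codes are
#'   rejected).
#' @param pct_mismatch percent mismatch between bait and hit (default 0).
#' @param method `"gc_mismatch"` (default) or `"wallace"`.
#' @param na_mM monovalent salt concentration in mM (default 50, the
#'   reference at which the salt term vanishes).
#' @return numeric vector of Tm in degrees Celsius.
#' @export
#' @examples
#' melting_temperature(strrep("AC", 40))  # 80-mer, 50% GC -> 93.5625
melting_temperature <- function(seqs, pct_mismatch = 0,
                                method = c("gc_mismatch", "wallace"),
                                na_mM = 50) {
  method <- match.arg(method)
  seqs <- toupper(seqs)
  if (any(!nzchar(seqs))) abort("empty sequence (N = 0)")
  if (any(grepl("[^ACGT]", seqs))) {
    abort("sequences must contain only A/C/G/T (ambiguity codes rejected)")
  }
  n <- nchar(seqs)
  gc <- (stringr::str_count(seqs, "G") + stringr::str_count(seqs, "C"))
  if (method == "wallace") {
    return(2 * (n - gc) + 4 * gc)
  }
  81.5 + 16.6 * log10(na_mM / 50) + 0.41 * (100 * gc / n) - 675 / n -
    pct_mismatch
}

#' Filter baits on genome hit count and melting temperature
#'
#' A bait is retained iff `hit_count <= max_hits` and
#' `tm_min_c <= tm_c <= tm_max_c`. All three thresholds are required: the
#' appropriate cutoffs depend on the reference genome and capture chemistry
#' and there is no universal default. Input order is preserved and the
#' filter is idempotent.
#'
#' @param baits tibble with populated `hit_count` and `tm_c` columns (join
#'   the output of [tile_baits()] with an alignment-hit table and
#'   [melting_temperature()] first).
#' @param max_hits maximum allowed genome hits per bait.
#' @param tm_min_c,tm_max_c Tm window in degrees Celsius.
#' @return the input tibble with a logical `retained` column; a one-row
#'   summary tibble (totals retained/dropped) is attached as attribute
#'   `"filter_summary"`.
#' @export
filter_baits <- function(baits, max_hits, tm_min_c, tm_max_c) {
  stopifnot_cols(baits, c("hit_count", "tm_c"), "baits")
  if (missing(max_hits) || missing(tm_min_c) || missing(tm_max_c)) {
    abort("max_hits, tm_min_c and tm_max_c are required (no defaults)")
  }
  if (tm_min_c > tm_max_c) abort("tm_min_c must be <= tm_max_c")
  if (nrow(baits) > 0 && (anyNA(baits$hit_count) || anyNA(baits$tm_c))) {
    abort("hit_count and tm_c must be populated on every bait")
  }
  out <- mutate(baits,
                retained = .data$hit_count <= max_hits &
                  .data$tm_c >= tm_min_c & .data$tm_c <= tm_max_c)
  attr(out, "filter_summary") <- tibble(
    n_total = nrow(out), n_retained = sum(out$retained),
    n_dropped = sum(!out$retained))
  out
}

#' Summarise a bait design against its panel
#'
#' @param panel panel tibble (as from [read_bed()] / [pad_regions()]).
#' @param baits bait tibble; every `region_id` must exist in the panel. A
#'   `retained` column, when present, is summarised too.
#' @return tibble with one row per region class plus a `total` row:
#'   `region_class`, `n_regions`, `target_bp`, `n_baits`, `n_retained`,
#'   `baits_per_kb`.
#' @export
design_report <- function(panel, baits) {
  stopifnot_cols(panel, c("region_id", "region_class", "length"), "panel")
  unknown <- setdiff(unique(baits$region_id), panel$region_id)
  if (length(unknown) > 0) {
    abort(sprintf("bait(s) reference unknown region(s): %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  if (!"retained" %in% names(baits)) baits$retained <- NA
  per_region <- baits |>
    group_by(.data$region_id) |>
    summarise(n_baits = n(), n_retained = sum(.data$retained),
              .groups = "drop")
  by_class <- panel |>
    left_join(per_region, by = "region_id") |>
    mutate(n_baits = dplyr::coalesce(.data$n_baits, 0L)) |>
    group_by(.data$region_class) |>
    summarise(n_regions = n(), target_bp = sum(.data$length),
              n_baits = sum(.data$n_baits),
              n_retained = sum(.data$n_retained), .groups = "drop")
  total <- summarise(by_class, region_class = "total",
                     n_regions = sum(.data$n_regions),
                     target_bp = sum(.data$target_bp),
                     n_baits = sum(.data$n_baits),
                     n_retained = sum(.data$n_retained))
  bind_rows(by_class, total) |>
    mutate(baits_per_kb = 1000 * .data$n_baits / .data$target_bp)
}
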