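#' Pipeline parameters
#'
#' Bundles every tunable threshold of the caller in one place. Defaults
#' follow the method's published settings where a value is stated
#' (`min_sv_size` 50 bp, `normalization_N` 900 bp, `edge_threshold_T` 0.7,
#' at most 20 signatures counted per evidence class) and conservative
#' heuristics elsewhere.
#'
#' @param min_mapq Minimum mapping quality for an alignment segment to be
#'   considered. Suppresses ambiguous placements in repeats, which otherwise
#'   generate spurious inter-alignment signatures.
#' @param min_sv_size Minimum size (bp) of a reported structural variant and
#'   of any signature other than a breakend.
#' @param gap_merge_tolerance Two same-type CIGAR gaps separated by at most
#'   this many aligned bases are merged into one intra-alignment signature;
#'   long-read indel errors commonly shatter one event into adjacent runs.
#' @param segment_gap_tolerance Maximum junction gap (bp) for two flanking
#'   segments to count as reference-adjacent (interspersed-duplication
#'   geometry) and for read-space contiguity tests.
#' @param min_distance Minimum reference distance (bp) for a segment to map
#'   "elsewhere": closer junctions are treated as alignment jitter rather
#'   than duplication transits or breakends.
#' @param max_segments Reads split into more than this many segments are
#'   skipped as likely mapping artifacts.
#' @param normalization_N Normalization constant N (bp) of the span-position
#'   distance; it sets the exchange rate between positional distance and
#'   span difference.
#' @param edge_threshold_T Signature pairs with span-position distance
#'   strictly below this threshold are connected in the clustering graph.
#' @param max_counted_per_class Cap on the number of signatures per evidence
#'   class (intra/inter) entering the count component of the cluster score.
#' @param match_distance Maximum distance (bp) between an insertion cluster
#'   and a breakend cluster for the two to be paired into an interspersed
#'   duplication call.
#' @param min_score Minimum cluster score for a call to be written to BED.
#'
#' @return A named list of class `sv_params`.
#' @export
sv_params <- function(min_mapq = 20L,
                      min_sv_size = 50L,
                      gap_merge_tolerance = 10L,
                      segment_gap_tolerance = 100L,
                      min_distance = 10000L,
                      max_segments = 10L,
                      normalization_N = 900,
                      edge_threshold_T = 0.7,
                      max_counted_per_class = 20L,
                      match_distance = 100L,
                      min_score = 0) {
  stopifnot(normalization_N > 0, edge_threshold_T > 0, min_sv_size > 0,
            max_counted_per_class > 0)
  structure(list(
    min_mapq = as.integer(min_mapq),
    min_sv_size = as.integer(min_sv_size),
    gap_merge_tolerance = as.integer(gap_merge_tolerance),
    segment_gap_tolerance = as.integer(segment_gap_tolerance),
    min_distance = as.integer(min_distance),
    max_segments = as.integer(max_segments),
    normalization_N = normalization_N,
    edge_threshold_T = edge_threshold_T,
    max_counted_per_class = as.integer(max_counted_per_class),
    match_distance = as.integer(match_distance),
    min_score = min_score
  ), class = "sv_params")
}
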