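#' @name signatures
#' @title SV signature tables
#' @description
#' A signature is evidence from a single read's alignment pointing to a
#' candidate structural variant. Signatures are kept in a flat `data.frame`
#' with one row per signature and columns:
#' \describe{
#'   \item{sig_type}{`DEL`, `INS`, `DUP`, `INV`, `TAN` or `BRK`.}
#'   \item{chrom, begin, end}{Affected reference interval, 0-based half-open.
#'     For `INS`, `end - begin` is the inserted length; for `BRK` the span is
#'     zero by definition.}
#'   \item{evidence_class}{`intra` (from a CIGAR gap inside one alignment) or
#'     `inter` (from split-alignment geometry). Only `DEL`/`INS` can be
#'     intra-alignment.}
#'   \item{read_name}{Provenance read.}
#'   \item{origin_chrom, origin_begin, origin_end}{Genomic origin of the
#'     inserted sequence; populated only for `DUP`.}
#'   \item{mate_chrom, mate_pos}{Partner locus of a breakend; only for `BRK`.}
#' }
NULL

empty_signature_df <- function() {
  data.frame(sig_type = character(), chrom = character(),
             begin = integer(), end = integer(),
             evidence_class = character(), read_name = character(),
             origin_chrom = character(), origin_begin = integer(),
             origin_end = integer(), mate_chrom = character(),
             mate_pos = integer(), stringsAsFactors = FALSE)
}

make_signature <- function(sig_type, chrom, begin, end, evidence_class,
                           read_name, origin_chrom = NA_character_,
                           origin_begin = NA_integer_,
                           origin_end = NA_integer_,
                           mate_chrom = NA_character_,
                           mate_pos = NA_integer_) {
  data.frame(sig_type = sig_type, chrom = chrom,
             begin = as.integer(begin), end = as.integer(end),
             evidence_class = evidence_class, read_name = read_name,
             origin_chrom = origin_chrom,
             origin_begin = as.integer(origin_begin),
             origin_end = as.integer(origin_end),
             mate_chrom = mate_chrom, mate_pos = as.integer(mate_pos),
             stringsAsFactors = FALSE)
}

bind_signatures <- function(lst) {
  lst <- Filter(function(x) !is.null(x) && nrow(x) > 0L, lst)
  if (length(lst) == 0L) return(empty_signature_df())
  do.call(rbind, lst)
}

#' Extract intra-alignment signatures from one alignment segment
#'
#' Scans the CIGAR of a single alignment record for large gaps: a deletion
#' run (`D`/`N`) of at least `min_sv_size` bp yields a `DEL` signature over
#' the deleted reference interval; an insertion run (`I`) of at least
#' `min_sv_size` bp yields an `INS` signature anchored at the insertion
#' point with `end = begin + inserted length`. Same-type gaps separated by
#' at most `gap_merge_tolerance` aligned bases are merged first, so events
#' shattered by indel sequencing errors are recovered whole.
#'
#' @param segment One-row segment `data.frame` (see [read_alignment_file()]).
#' @param min_sv_size Minimum event size in bp.
#' @param gap_merge_tolerance Maximum separation (aligned bases) for merging.
#' @return Signature `data.frame` (possibly empty).
#' @export
extract_intra_signatures <- function(segment, min_sv_size = 50L,
                                     gap_merge_tolerance = 10L) {
  stopifnot(nrow(segment) == 1L)
  ops <- GenomicAlignments::explodeCigarOps(segment$cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(segment$cigar)[[1]]
  ref_consumed <- lens * (ops %in% c("M", "D", "N", "=", "X"))
  ref_before <- segment$ref_start + cumsum(ref_consumed) - ref_consumed

  out <- list()
  for (gap in list(list(sel = ops %in% c("D", "N"), type = "DEL"),
                   list(sel = ops == "I", type = "INS"))) {
    idx <- which(gap$sel)
    if (length(idx) == 0L) next
    begin <- ref_before[idx]               # ref position of the gap
    glen <- lens[idx]
    ref_end_of <- begin + if (gap$type == "DEL") glen else 0L
    # merge runs separated by <= tolerance aligned bases
    grp <- cumsum(c(TRUE, begin[-1] - ref_end_of[-length(idx)] >
                      gap_merge_tolerance))
    for (g in unique(grp)) {
      sel <- grp == g
      total <- sum(glen[sel])
      if (total < min_sv_size) next
      if (gap$type == "DEL") {
        out[[length(out) + 1L]] <- make_signature(
          "DEL", segment$chrom, min(begin[sel]), max(ref_end_of[sel]),
          "intra", segment$read_name)
      } else {
        b <- min(begin[sel])
        out[[length(out) + 1L]] <- make_signature(
          "INS", segment$chrom, b, b + total, "intra", segment$read_name)
      }
    }
  }
  bind_signatures(out)
}

#' Extract inter-alignment signatures from a split read
#'
#' Examines adjacent pairs and consecutive triples of a read's alignment
#' segments (sorted by position on the read) for discordant placements and
#' orientations:
#' \itemize{
#'   \item reference gap exceeding the read gap: `DEL` over the gap;
#'   \item read gap exceeding the reference gap: `INS` at the junction;
#'   \item backward jump on the reference: `TAN` over the re-traversed
#'     interval (the hallmark of a tandem duplication);
#'   \item a triple with strand pattern `+,-,+` (or `-,+,-`) whose middle
#'     segment lies between the flanks: `INV` over the middle interval;
#'   \item a triple whose flanks are reference-adjacent while the middle
#'     segment maps elsewhere (other chromosome or beyond `min_distance`):
#'     `DUP` at the junction carrying the middle interval as genomic origin;
#'   \item any remaining pair joining distant loci: one `BRK` per junction
#'     side, each holding the other side as mate.
#' }
#'
#' @param segments Segment `data.frame` for one read, sorted by `read_start`.
#' @param params [sv_params()] list.
#' @return Signature `data.frame` with `evidence_class = "inter"`.
#' @export
extract_inter_signatures <- function(segments, params = sv_params()) {
  n <- nrow(segments)
  if (n < 2L) return(empty_signature_df())
  min_sv <- params$min_sv_size
  gap_tol <- params$segment_gap_tolerance
  min_dist <- params$min_distance
  read_name <- segments$read_name[1]
  out <- list()
  consumed_pair <- rep(FALSE, n - 1L)  # pairs absorbed by a triple rule

  # --- triples: inversion and interspersed-duplication geometry ---
  if (n >= 3L) {
    for (i in seq_len(n - 2L)) {
      # a window whose leading pair was absorbed by an earlier triple is an
      # overlap artifact (e.g. the normal gap between two nearby inversions
      # mimics an inverted middle segment)
      if (consumed_pair[i]) next
      s1 <- segments[i, ]; s2 <- segments[i + 1L, ]; s3 <- segments[i + 2L, ]
      flanks_match <- s1$chrom == s3$chrom && s1$strand == s3$strand
      if (!flanks_match) next
      read_contig <- (s2$read_start - s1$read_end) < gap_tol &&
        (s3$read_start - s2$read_end) < gap_tol
      inner_lo <- min(s1$ref_end, s3$ref_end)
      inner_hi <- max(s1$ref_start, s3$ref_start)

      # inversion: middle segment flipped, sitting between the flanks
      if (s2$chrom == s1$chrom && s2$strand != s1$strand && read_contig &&
          s2$ref_start >= inner_lo - gap_tol &&
          s2$ref_end <= inner_hi + gap_tol &&
          s2$ref_end - s2$ref_start >= min_sv) {
        out[[length(out) + 1L]] <- make_signature(
          "INV", s2$chrom, s2$ref_start, s2$ref_end, "inter", read_name)
        consumed_pair[c(i, i + 1L)] <- TRUE
        next
      }

      # interspersed duplication: flanks reference-adjacent, middle elsewhere
      junction_gap <- if (s1$strand == "+") s3$ref_start - s1$ref_end
                      else s1$ref_start - s3$ref_end
      junction <- if (s1$strand == "+") s1$ref_end else s3$ref_end
      middle_away <- s2$chrom != s1$chrom ||
        min(abs(s2$ref_start - junction), abs(s2$ref_end - junction)) >=
          min_dist
      span2 <- s2$ref_end - s2$ref_start
      if (abs(junction_gap) < gap_tol && read_contig && middle_away &&
          span2 >= min_sv) {
        out[[length(out) + 1L]] <- make_signature(
          "DUP", s1$chrom, junction, junction + span2, "inter", read_name,
          origin_chrom = s2$chrom, origin_begin = s2$ref_start,
          origin_end = s2$ref_end)
        consumed_pair[c(i, i + 1L)] <- TRUE
      }
    }
  }

  # --- pairs ---
  for (i in seq_len(n - 1L)) {
    if (consumed_pair[i]) next
    s1 <- segments[i, ]; s2 <- segments[i + 1L, ]
    read_gap <- s2$read_start - s1$read_end
    fired <- FALSE
    if (s1$chrom == s2$chrom && s1$strand == s2$strand) {
      fwd <- s1$strand == "+"
      ref_gap <- if (fwd) s2$ref_start - s1$ref_end
                 else s1$ref_start - s2$ref_end
      junction <- if (fwd) s1$ref_end else s2$ref_end
      # jumps beyond min_distance are breakend territory (rule f), not
      # deletion/insertion/tandem geometry
      if (ref_gap >= 0 && ref_gap <= min_dist &&
          ref_gap - max(0L, read_gap) >= min_sv) {
        out[[length(out) + 1L]] <- make_signature(
          "DEL", s1$chrom, junction, junction + (ref_gap - max(0L, read_gap)),
          "inter", read_name)
        fired <- TRUE
      } else if (ref_gap >= -gap_tol && read_gap - max(0L, ref_gap) >= min_sv) {
        len <- read_gap - max(0L, ref_gap)
        out[[length(out) + 1L]] <- make_signature(
          "INS", s1$chrom, junction, junction + len, "inter", read_name)
        fired <- TRUE
      } else if (ref_gap <= -min_sv && ref_gap >= -min_dist &&
                 abs(read_gap) < gap_tol) {
        # backward jump on the reference: tandem duplication
        tan <- if (fwd) c(s2$ref_start, s1$ref_end)
               else c(s1$ref_start, s2$ref_end)
        out[[length(out) + 1L]] <- make_signature(
          "TAN", s1$chrom, tan[1], tan[2], "inter", read_name)
        fired <- TRUE
      }
    }
    if (!fired) {
      side1 <- if (s1$strand == "+") s1$ref_end else s1$ref_start
      side2 <- if (s2$strand == "+") s2$ref_start else s2$ref_end
      distant <- s1$chrom != s2$chrom || abs(side2 - side1) >= min_dist
      if (distant) {
        out[[length(out) + 1L]] <- make_signature(
          "BRK", s1$chrom, side1, side1, "inter", read_name,
          mate_chrom = s2$chrom, mate_pos = side2)
        out[[length(out) + 1L]] <- make_signature(
          "BRK", s2$chrom, side2, side2, "inter", read_name,
          mate_chrom = s1$chrom, mate_pos = side1)
      }
    }
  }
  bind_signatures(out)
}

#' Collect all SV signatures from grouped alignments
#'
#' Runs intra-alignment extraction on every segment and inter-alignment
#' extraction on every multi-segment read, one read at a time. Reads split
#' into more than `params$max_segments` segments are skipped (and counted in
#' a warning) as likely mapping artifacts.
#'
#' @param grouped Named list of per-read segment tables from
#'   [group_segments_by_read()].
#' @param params [sv_params()] list.
#' @return Signature `data.frame` sorted by `chrom`, `begin`, `read_name`.
#' @export
collect_signatures <- function(grouped, params = sv_params()) {
  out <- vector("list", length(grouped))
  skipped <- 0L
  for (k in seq_along(grouped)) {
    segs <- grouped[[k]]
    if (nrow(segs) > params$max_segments) {
      skipped <- skipped + 1L
      next
    }
    intra <- lapply(seq_len(nrow(segs)), function(i) {
      extract_intra_signatures(segs[i, ], params$min_sv_size,
                               params$gap_merge_tolerance)
    })
    inter <- if (nrow(segs) >= 2L) extract_inter_signatures(segs, params)
    out[[k]] <- bind_signatures(c(intra, list(inter)))
  }
  if (skipped > 0L)
    warning(skipped, " read(s) with > ", params$max_segments,
            " segments skipped")
  sigs <- bind_signatures(out)
  sigs <- sigs[order(sigs$chrom, sigs$begin, sigs$read_name), , drop = FALSE]
  rownames(sigs) <- NULL
  sigs
}
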