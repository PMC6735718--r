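#' Reciprocal overlap of two genomic intervals
#'
#' Returns `min(ov / len(a), ov / len(b))` where `ov` is the shared length
#' under half-open semantics; 0 for intervals on different chromosomes.
#' Zero-length intervals (point events such as breakends) are treated as
#' length 1. Vectorized over all arguments.
#'
#' @param begin1,end1,begin2,end2 0-based half-open interval coordinates.
#' @param chrom1,chrom2 Optional chromosome names; if supplied, mismatching
#'   pairs score 0.
#' @return Numeric vector in `[0, 1]`.
#' @export
reciprocal_overlap <- function(begin1, end1, begin2, end2,
                               chrom1 = NULL, chrom2 = NULL) {
  len1 <- pmax(1, end1 - begin1)
  len2 <- pmax(1, end2 - begin2)
  ov <- pmax(0, pmin(begin1 + len1, begin2 + len2) - pmax(begin1, begin2))
  ro <- pmin(ov / len1, ov / len2)
  if (!is.null(chrom1) && !is.null(chrom2)) ro[chrom1 != chrom2] <- 0
  ro
}

# Collapse the five call/truth classes onto the four classes used for
# benchmarking: interspersed duplications and novel insertions are jointly
# evaluated as insertions, since both place inserted sequence at a point.
eval_class <- function(sv_class) {
  c(deletion = "DEL", inversion = "INV", tandem_duplication = "TAN",
    interspersed_duplication = "INS", novel_insertion = "INS")[sv_class]
}

#' Match SV calls to truth variants
#'
#' Greedy 1-to-1 matching by decreasing overlap quality. Interval classes
#' (deletions, inversions, tandem duplications) match when their reciprocal
#' overlap reaches `min_fraction`. Insertion-like classes place sequence at
#' a point, so pure interval overlap is uninformative; they match when the
#' insertion points lie within `ins_point_distance` bp and the inserted
#' lengths have a reciprocal ratio of at least `min_fraction`. With
#' `class_aware = TRUE`, classes must agree after merging interspersed
#' duplications and novel insertions into a joint insertion class.
#'
#' @param calls Call `data.frame` (columns `sv_class`, `chrom`, `begin`,
#'   `end`; insertion-like classes use `end = begin + inserted length`).
#' @param truth Truth `data.frame` in the same convention.
#' @param min_fraction Required reciprocal overlap (or length ratio), in
#'   `(0, 1]`.
#' @param class_aware Require matching (merged) classes.
#' @param ins_point_distance Maximum insertion-point distance in bp.
#' @return List with `tp` (a `data.frame` of `call_idx`, `truth_idx`,
#'   `overlap`), index vectors `fp_idx` and `fn_idx`, the counts `n_tp`,
#'   `n_fp`, `n_fn`, and `precision`/`recall`.
#' @export
match_calls_to_truth <- function(calls, truth, min_fraction = 0.5,
                                 class_aware = TRUE,
                                 ins_point_distance = 100L) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  nc <- nrow(calls); nt <- nrow(truth)
  cand <- NULL
  if (nc > 0L && nt > 0L) {
    cand <- expand.grid(call_idx = seq_len(nc), truth_idx = seq_len(nt))
    ci <- cand$call_idx; ti <- cand$truth_idx
    keep <- calls$chrom[ci] == truth$chrom[ti]
    if (class_aware)
      keep <- keep & eval_class(calls$sv_class[ci]) ==
        eval_class(truth$sv_class[ti])
    cand <- cand[keep, , drop = FALSE]
  }
  tp <- data.frame(call_idx = integer(), truth_idx = integer(),
                   overlap = numeric())
  if (!is.null(cand) && nrow(cand) > 0L) {
    ci <- cand$call_idx; ti <- cand$truth_idx
    is_ins <- eval_class(calls$sv_class[ci]) == "INS" &
      eval_class(truth$sv_class[ti]) == "INS"
    ro <- reciprocal_overlap(calls$begin[ci], calls$end[ci],
                             truth$begin[ti], truth$end[ti])
    len_c <- pmax(1, calls$end[ci] - calls$begin[ci])
    len_t <- pmax(1, truth$end[ti] - truth$begin[ti])
    ratio <- pmin(len_c, len_t) / pmax(len_c, len_t)
    point_ok <- abs(calls$begin[ci] - truth$begin[ti]) <= ins_point_distance
    cand$overlap <- ifelse(is_ins, ifelse(point_ok, ratio, 0), ro)
    cand <- cand[cand$overlap >= min_fraction, , drop = FALSE]
    cand <- cand[order(-cand$overlap, cand$call_idx, cand$truth_idx), ,
                 drop = FALSE]
    call_used <- rep(FALSE, nc)
    truth_used <- rep(FALSE, nt)
    for (k in seq_len(nrow(cand))) {
      i <- cand$call_idx[k]; j <- cand$truth_idx[k]
      if (call_used[i] || truth_used[j]) next
      call_used[i] <- TRUE
      truth_used[j] <- TRUE
      tp <- rbind(tp, cand[k, c("call_idx", "truth_idx", "overlap")])
    }
  }
  fp_idx <- setdiff(seq_len(nc), tp$call_idx)
  fn_idx <- setdiff(seq_len(nt), tp$truth_idx)
  list(tp = tp, fp_idx = fp_idx, fn_idx = fn_idx,
       n_tp = nrow(tp), n_fp = length(fp_idx), n_fn = length(fn_idx),
       precision = if (nc > 0L) nrow(tp) / nc else NA_real_,
       recall = if (nt > 0L) nrow(tp) / nt else NA_real_)
}

#' Precision-recall curve over score cutoffs
#'
#' Filters calls at each score cutoff and evaluates the surviving set
#' against the truth with [match_calls_to_truth()].
#'
#' @param calls Call `data.frame` with a `score` column.
#' @param truth Truth `data.frame`.
#' @param min_fraction Reciprocal-overlap requirement.
#' @param cutoffs Ascending numeric score thresholds.
#' @param class_aware Passed to [match_calls_to_truth()].
#' @return A `data.frame` with one row per cutoff: `cutoff`, `n_calls`,
#'   `tp`, `fp`, `fn`, `precision` (`NA` when no call survives), `recall`.
#' @export
precision_recall_curve <- function(calls, truth, min_fraction = 0.5,
                                   cutoffs = seq(0, 100, by = 10),
                                   class_aware = TRUE) {
  stopifnot(!is.unsorted(cutoffs))
  rows <- lapply(cutoffs, function(cut) {
    sub <- calls[calls$score >= cut, , drop = FALSE]
    m <- match_calls_to_truth(sub, truth, min_fraction, class_aware)
    data.frame(cutoff = cut, n_calls = nrow(sub), tp = m$n_tp, fp = m$n_fp,
               fn = m$n_fn, precision = m$precision,
               recall = if (nrow(truth) > 0L) m$n_tp / nrow(truth) else 0)
  })
  do.call(rbind, rows)
}
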