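#' @name calls
#' @title SV call tables
#' @description
#' A call table has one row per variant with columns `sv_class` (one of
#' `deletion`, `inversion`, `tandem_duplication`, `interspersed_duplication`,
#' `novel_insertion`), the destination locus `chrom`/`begin`/`end` (for the
#' two insertion-like classes `end = begin + inserted length`), the origin
#' locus `origin_chrom`/`origin_begin`/`origin_end` (interspersed
#' duplications only), the logical `cutpaste` flag, `score`, `support`
#' (number of member signatures) and a `read_names` list column.
NULL

empty_call_df <- function() {
  df <- data.frame(sv_class = character(), chrom = character(),
                   begin = integer(), end = integer(),
                   origin_chrom = character(), origin_begin = integer(),
                   origin_end = integer(), cutpaste = logical(),
                   score = numeric(), support = integer(),
                   stringsAsFactors = FALSE)
  df$read_names <- I(list())
  df
}

#' Pair insertion clusters with nearby breakend clusters
#'
#' An insertion whose junction coincides with a breakend pointing to a
#' distant locus is evidence for an interspersed duplication: the breakend's
#' mate identifies the genomic origin of the inserted sequence. Pairing is
#' greedy 1-to-1 by increasing distance between insertion point and breakend
#' (ties broken by lower insertion coordinate); a breakend cluster is used at
#' most once and only within `match_distance` bp on the same chromosome.
#'
#' @param ins_clusters,brk_clusters Cluster `data.frame`s (types INS / BRK).
#' @param match_distance Maximum pairing distance in bp.
#' @return List with `pairs` (a `data.frame` of `ins_idx`, `brk_idx`) and
#'   `unmatched_ins` (integer indices into `ins_clusters`).
#' @export
match_ins_to_brk <- function(ins_clusters, brk_clusters,
                             match_distance = 100L) {
  n_ins <- nrow(ins_clusters)
  pairs <- data.frame(ins_idx = integer(), brk_idx = integer())
  if (n_ins == 0L || nrow(brk_clusters) == 0L)
    return(list(pairs = pairs, unmatched_ins = seq_len(n_ins)))
  cand <- expand.grid(ins_idx = seq_len(n_ins),
                      brk_idx = seq_len(nrow(brk_clusters)))
  cand$dist <- abs(ins_clusters$begin[cand$ins_idx] -
                     brk_clusters$begin[cand$brk_idx])
  same_chrom <- ins_clusters$chrom[cand$ins_idx] ==
    brk_clusters$chrom[cand$brk_idx]
  cand <- cand[same_chrom & cand$dist <= match_distance, , drop = FALSE]
  cand <- cand[order(cand$dist, ins_clusters$begin[cand$ins_idx]), ,
               drop = FALSE]
  ins_used <- rep(FALSE, n_ins)
  brk_used <- rep(FALSE, nrow(brk_clusters))
  for (k in seq_len(nrow(cand))) {
    i <- cand$ins_idx[k]; j <- cand$brk_idx[k]
    if (ins_used[i] || brk_used[j]) next
    ins_used[i] <- TRUE
    brk_used[j] <- TRUE
    pairs <- rbind(pairs, data.frame(ins_idx = i, brk_idx = j))
  }
  list(pairs = pairs, unmatched_ins = which(!ins_used))
}

#' Annotate interspersed duplications as potential cut&paste insertions
#'
#' A duplication whose genomic origin overlaps a deletion call (by at least
#' one bp, half-open semantics) looks like sequence that was moved rather
#' than copied; such calls keep their class but are flagged
#' `cutpaste = TRUE`.
#'
#' @param dup_calls Call `data.frame` of class `interspersed_duplication`.
#' @param deletion_calls Call `data.frame` of class `deletion`.
#' @return `dup_calls` with the `cutpaste` column set.
#' @export
annotate_cutpaste <- function(dup_calls, deletion_calls) {
  if (nrow(dup_calls) == 0L) return(dup_calls)
  dup_calls$cutpaste <- vapply(seq_len(nrow(dup_calls)), function(i) {
    if (nrow(deletion_calls) == 0L) return(FALSE)
    any(deletion_calls$chrom == dup_calls$origin_chrom[i] &
          deletion_calls$begin < dup_calls$origin_end[i] &
          deletion_calls$end > dup_calls$origin_begin[i])
  }, logical(1))
  dup_calls
}

#' Combine signature clusters into classified SV calls
#'
#' Deletion, inversion and tandem-duplication clusters pass through
#' verbatim. Duplication clusters with a detected origin become interspersed
#' duplications. Insertion clusters are paired with nearby breakend clusters
#' ([match_ins_to_brk()]): a paired insertion becomes an interspersed
#' duplication whose origin is the breakend's mate locus; unpaired
#' insertions are called novel element insertions. Breakend clusters without
#' an insertion partner emit no call. Cut&paste annotation
#' ([annotate_cutpaste()]) is applied last.
#'
#' @param clusters Cluster `data.frame` from [cluster_signatures()].
#' @param params [sv_params()] list.
#' @return Call `data.frame` sorted by `chrom`, `begin`.
#' @export
combine_clusters <- function(clusters, params = sv_params()) {
  if (nrow(clusters) == 0L) return(empty_call_df())
  mk_call <- function(cl, sv_class, origin_chrom = NA_character_,
                      origin_begin = NA_integer_, origin_end = NA_integer_,
                      extra_reads = NULL) {
    df <- data.frame(sv_class = sv_class, chrom = cl$chrom,
                     begin = cl$begin, end = cl$end,
                     origin_chrom = origin_chrom,
                     origin_begin = as.integer(origin_begin),
                     origin_end = as.integer(origin_end),
                     cutpaste = FALSE, score = cl$score,
                     support = cl$n_members, stringsAsFactors = FALSE)
    df$read_names <- I(list(sort(unique(c(cl$read_names[[1]], extra_reads)))))
    df
  }
  calls <- list()
  direct <- c(DEL = "deletion", INV = "inversion", TAN = "tandem_duplication")
  for (i in which(clusters$sig_type %in% names(direct))) {
    cl <- clusters[i, ]
    calls[[length(calls) + 1L]] <- mk_call(cl, direct[[cl$sig_type]])
  }
  for (i in which(clusters$sig_type == "DUP")) {
    cl <- clusters[i, ]
    calls[[length(calls) + 1L]] <- mk_call(
      cl, "interspersed_duplication", cl$origin_chrom, cl$origin_begin,
      cl$origin_end)
  }
  ins <- clusters[clusters$sig_type == "INS", , drop = FALSE]
  brk <- clusters[clusters$sig_type == "BRK", , drop = FALSE]
  m <- match_ins_to_brk(ins, brk, params$match_distance)
  for (k in seq_len(nrow(m$pairs))) {
    cl <- ins[m$pairs$ins_idx[k], ]
    partner <- brk[m$pairs$brk_idx[k], ]
    ins_len <- cl$end - cl$begin
    calls[[length(calls) + 1L]] <- mk_call(
      cl, "interspersed_duplication", partner$mate_chrom, partner$mate_pos,
      partner$mate_pos + ins_len, extra_reads = partner$read_names[[1]])
  }
  for (i in m$unmatched_ins) {
    calls[[length(calls) + 1L]] <- mk_call(ins[i, ], "novel_insertion")
  }
  if (length(calls) == 0L) return(empty_call_df())
  calls <- do.call(rbind, calls)
  is_dup <- calls$sv_class == "interspersed_duplication"
  calls[is_dup, ] <- annotate_cutpaste(
    calls[is_dup, , drop = FALSE],
    calls[calls$sv_class == "deletion", , drop = FALSE])
  calls <- calls[order(calls$chrom, calls$begin), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}
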