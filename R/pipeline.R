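#' Run the full SV calling pipeline
#'
#' Executes collect, cluster, combine and write on an aligned read file:
#' reads alignment segments, extracts intra- and inter-alignment signatures,
#' clusters them with the span-position distance via maximal cliques,
#' combines clusters into the five SV classes and writes five BED files plus
#' a VCF into `out_dir`. Per-stage counts are logged via `message()`.
#'
#' @param alignments Path to a coordinate-sorted SAM or BAM file with
#'   supplementary alignments.
#' @param out_dir Output directory.
#' @param reference Optional reference FASTA; used for VCF REF bases.
#'   Contig names and lengths are always taken from the alignment header.
#' @param params [sv_params()] list of thresholds.
#' @return Invisibly, the call `data.frame`.
#' @export
run_pipeline <- function(alignments, out_dir, reference = NULL,
                         params = sv_params()) {
  bam <- as_bam(alignments)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (length(hdr) == 0L) stop("alignment file has no @SQ header lines")

  segments <- read_alignment_file(bam, min_mapq = params$min_mapq)
  message("segments: ", nrow(segments), " from ",
          length(unique(segments$read_name)), " reads")
  grouped <- group_segments_by_read(segments)
  signatures <- collect_signatures(grouped, params)
  message("signatures: ",
          paste(sprintf("%s=%d", names(table(signatures$sig_type)),
                        table(signatures$sig_type)), collapse = " "))
  clusters <- cluster_signatures(signatures, params)
  message("clusters: ", nrow(clusters))
  calls <- combine_clusters(clusters, params)
  message("calls: ",
          paste(sprintf("%s=%d", names(table(calls$sv_class)),
                        table(calls$sv_class)), collapse = " "))

  write_bed_files(calls, out_dir, min_score = params$min_score)
  write_vcf(calls, reference %||% hdr,
            file.path(out_dir, "variants.vcf"))
  invisible(calls)
}
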