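#' Write SV calls to five BED files
#'
#' One file per variant class: `deletions.bed`, `inversions.bed`,
#' `tandem_duplications.bed`, `interspersed_duplications.bed`,
#' `novel_insertions.bed`. Columns are chrom, 0-based start, exclusive end,
#' name, score (one decimal). The name field is the class name for simple
#' classes; interspersed duplications instead encode the origin locus and
#' the cut&paste annotation as `origin=<chrom>:<begin>-<end>;cutpaste=<bool>`.
#' Only calls with `score >= min_score` are written, sorted by chrom, start.
#'
#' @param calls Call `data.frame` from [combine_clusters()].
#' @param out_dir Output directory (created if absent).
#' @param min_score Minimum score for a call to be written.
#' @return Invisibly, the five file paths.
#' @export
write_bed_files <- function(calls, out_dir, min_score = 0) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  files <- c(deletion = "deletions.bed",
             inversion = "inversions.bed",
             tandem_duplication = "tandem_duplications.bed",
             interspersed_duplication = "interspersed_duplications.bed",
             novel_insertion = "novel_insertions.bed")
  paths <- file.path(out_dir, files)
  names(paths) <- names(files)
  calls <- calls[calls$score >= min_score, , drop = FALSE]
  for (cls in names(files)) {
    sub <- calls[calls$sv_class == cls, , drop = FALSE]
    sub <- sub[order(sub$chrom, sub$begin), , drop = FALSE]
    name <- if (cls == "interspersed_duplication" && nrow(sub) > 0L) {
      sprintf("origin=%s:%d-%d;cutpaste=%s", sub$origin_chrom,
              sub$origin_begin, sub$origin_end,
              ifelse(sub$cutpaste, "true", "false"))
    } else rep(cls, nrow(sub))
    out <- data.frame(sub$chrom, sub$begin, sub$end, name,
                      sprintf("%.1f", sub$score))
    write.table(out, paths[[cls]], sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(paths)
}

#' Write SV calls to a VCF file
#'
#' Produces a VCF 4.2 file with symbolic ALT alleles `<DEL>`, `<INV>`,
#' `<DUP:TANDEM>`, `<DUP:INT>` and `<INS>`. POS is 1-based; INFO carries
#' `SVTYPE`, `END`, `SVLEN` (negative for deletions) and `SUPPORT`;
#' interspersed duplications additionally carry the origin locus as
#' `CHR2`/`POS2`/`END2` and, where annotated, the `CUTPASTE` flag. QUAL is
#' the cluster score.
#'
#' @param calls Call `data.frame`.
#' @param reference Either a FASTA path (REF bases are looked up) or a named
#'   numeric vector of contig lengths (REF is reported as `N`).
#' @param out_path Output VCF path.
#' @return Invisibly, `out_path`.
#' @export
write_vcf <- function(calls, reference, out_path) {
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference)) {
    seqs <- Biostrings::readDNAStringSet(reference)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    contigs <- stats::setNames(Biostrings::width(seqs), names(seqs))
  } else {
    seqs <- NULL
    contigs <- reference
    if (is.null(names(contigs)) || !is.numeric(contigs))
      stop("reference must be a FASTA path or a named contig-length vector")
  }
  bad <- setdiff(unique(calls$chrom), names(contigs))
  if (length(bad) > 0L)
    stop("call(s) on contig(s) absent from the reference: ",
         paste(bad, collapse = ", "))

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=svclique",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs),
            as.integer(contigs)),
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=INV,Description=\"Inversion\">",
    "##ALT=<ID=DUP:TANDEM,Description=\"Tandem duplication\">",
    "##ALT=<ID=DUP:INT,Description=\"Interspersed duplication\">",
    "##ALT=<ID=INS,Description=\"Novel element insertion\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of the variant (negative for deletions)\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Number of supporting signatures\">",
    "##INFO=<ID=CHR2,Number=1,Type=String,Description=\"Chromosome of the duplication origin\">",
    "##INFO=<ID=POS2,Number=1,Type=Integer,Description=\"Start of the duplication origin (1-based)\">",
    "##INFO=<ID=END2,Number=1,Type=Integer,Description=\"End of the duplication origin\">",
    "##INFO=<ID=CUTPASTE,Number=0,Type=Flag,Description=\"Origin overlaps a deletion call (potential cut and paste insertion)\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")

  alt_of <- c(deletion = "<DEL>", inversion = "<INV>",
              tandem_duplication = "<DUP:TANDEM>",
              interspersed_duplication = "<DUP:INT>",
              novel_insertion = "<INS>")
  svtype_of <- c(deletion = "DEL", inversion = "INV",
                 tandem_duplication = "DUP",
                 interspersed_duplication = "DUP", novel_insertion = "INS")

  # sort records by contig order of the header, then position
  calls <- calls[order(match(calls$chrom, names(contigs)), calls$begin), ,
                 drop = FALSE]
  lines <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, ]
    pos <- cl$begin + 1L
    len <- cl$end - cl$begin
    svlen <- if (cl$sv_class == "deletion") -len else len
    end1 <- if (cl$sv_class %in% c("novel_insertion",
                                   "interspersed_duplication")) pos
            else cl$end
    info <- sprintf("SVTYPE=%s;END=%d;SVLEN=%d;SUPPORT=%d",
                    svtype_of[[cl$sv_class]], end1, svlen, cl$support)
    if (cl$sv_class == "interspersed_duplication") {
      info <- sprintf("%s;CHR2=%s;POS2=%d;END2=%d", info, cl$origin_chrom,
                      cl$origin_begin + 1L, cl$origin_end)
      if (isTRUE(cl$cutpaste)) info <- paste0(info, ";CUTPASTE")
    }
    refbase <- if (!is.null(seqs) && cl$chrom %in% names(seqs))
      as.character(Biostrings::subseq(seqs[[cl$chrom]], pos, pos)) else "N"
    lines[i] <- sprintf("%s\t%d\t%s\t%s\t%s\t%.1f\tPASS\t%s",
                        cl$chrom, pos, sprintf("svclique_%d", i), refbase,
                        alt_of[[cl$sv_class]], cl$score, info)
  }
  writeLines(c(header, lines), out_path)
  invisible(out_path)
}
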