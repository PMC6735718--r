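#' Read alignment segments from a SAM/BAM file
#'
#' Performs a sequential scan of a SAM or BAM file (no index required) and
#' returns one row per primary or supplementary alignment record passing the
#' mapping-quality filter. Secondary (flag 0x100) and unmapped (0x4) records
#' are skipped; supplementary records (0x800) are kept because they carry the
#' non-primary segments of split reads.
#'
#' Coordinates are 0-based half-open throughout the package. Read coordinates
#' (`read_start`, `read_end`) are expressed on the original, forward-oriented
#' read: for a reverse-strand record the roles of the leading and trailing
#' clips are swapped. Hard clips are treated exactly like soft clips so that
#' hard-clipped supplementary records preserve read-space geometry.
#'
#' @param path Path to a SAM or BAM file. SAM input is converted on the fly.
#' @param min_mapq Minimum mapping quality; records below it are dropped.
#' @return A `data.frame` of alignment segments with columns `read_name`,
#'   `chrom`, `ref_start`, `ref_end`, `read_start`, `read_end`, `strand`,
#'   `mapq`, `cigar`, `is_supplementary`.
#' @export
read_alignment_file <- function(path, min_mapq = 20L) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- as_bam(path)
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flags,
    what = c("qname", "flag", "rname", "pos", "mapq", "strand", "cigar"))
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(res$qname)
  if (n == 0L) return(empty_segments())

  no_cigar <- is.na(res$cigar) | res$cigar == "*"
  if (any(no_cigar))
    warning(sum(no_cigar), " mapped record(s) without a CIGAR were skipped")
  mapq <- res$mapq
  mapq[is.na(mapq)] <- 255L  # missing MAPQ means "unavailable", keep
  keep <- !no_cigar & mapq >= min_mapq
  if (!any(keep)) return(empty_segments())

  cigar <- res$cigar[keep]
  pos <- res$pos[keep]
  strand <- as.character(res$strand)[keep]
  flag <- res$flag[keep]

  ref_width <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
  coords <- read_space_coords(cigar, strand)

  data.frame(
    read_name = res$qname[keep],
    chrom = as.character(res$rname)[keep],
    ref_start = pos - 1L,
    ref_end = pos - 1L + ref_width,
    read_start = coords$read_start,
    read_end = coords$read_end,
    strand = strand,
    mapq = mapq[keep],
    cigar = cigar,
    is_supplementary = bitwAnd(flag, 0x800L) > 0L,
    stringsAsFactors = FALSE
  )
}

empty_segments <- function() {
  data.frame(read_name = character(), chrom = character(),
             ref_start = integer(), ref_end = integer(),
             read_start = integer(), read_end = integer(),
             strand = character(), mapq = integer(), cigar = character(),
             is_supplementary = logical(), stringsAsFactors = FALSE)
}

# Convert SAM input to a temporary BAM for scanning; pass BAM through.
as_bam <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "bam") return(path)
  dest <- tempfile(fileext = "")
  Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                   indexDestination = FALSE)
}

# Reconstruct the aligned interval on the original read from clip lengths.
# Leading clip = read_start on the forward strand; on the reverse strand the
# trailing clip of the record is the leading clip of the original read.
read_space_coords <- function(cigar, strand) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
  lead <- mapply(clip_length, ops, lens, MoreArgs = list(from_start = TRUE))
  trail <- mapply(clip_length, ops, lens, MoreArgs = list(from_start = FALSE))
  qwidth <- GenomicAlignments::cigarWidthAlongQuerySpace(
    cigar, after.soft.clipping = TRUE)
  start <- ifelse(strand == "-", trail, lead)
  list(read_start = as.integer(start),
       read_end = as.integer(start + qwidth))
}

clip_length <- function(ops, lens, from_start) {
  if (!from_start) {
    ops <- rev(ops)
    lens <- rev(lens)
  }
  total <- 0L
  for (i in seq_along(ops)) {
    if (ops[i] %in% c("S", "H")) total <- total + lens[i] else break
  }
  total
}

#' Group alignment segments by read
#'
#' Partitions the segment table into one group per read name, each sorted by
#' position on the original read (`read_start`, ties by `ref_start`, then
#' `chrom`). Downstream signature extraction walks each read's segments in
#' this order.
#'
#' @param segments Segment `data.frame` from [read_alignment_file()].
#' @return Named list of segment `data.frame`s, one per read.
#' @export
group_segments_by_read <- function(segments) {
  if (nrow(segments) == 0L) return(structure(list(), names = character()))
  groups <- split(segments, segments$read_name)
  lapply(groups, function(g) {
    g[order(g$read_start, g$ref_start, g$chrom), , drop = FALSE]
  })
}
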