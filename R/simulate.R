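#' Simulate a random reference genome
#'
#' Generates i.i.d. uniform A/C/G/T chromosomes, reproducibly per seed.
#' Stands in for a real reference so that the whole pipeline can be
#' exercised without downloads.
#'
#' @param n_chroms Number of chromosomes (`chr1`, `chr2`, ...).
#' @param length_bp Length of each chromosome in bp.
#' @param seed Optional integer seed; the caller's RNG state is untouched.
#' @return A [Biostrings::DNAStringSet] with named chromosomes.
#' @export
simulate_reference <- function(n_chroms = 1L, length_bp, seed = NULL) {
  stopifnot(n_chroms >= 1L)
  if (length_bp <= 0L) stop("chromosome length must be positive")
  with_seed(seed, {
    seqs <- vapply(seq_len(n_chroms), function(i) {
      paste(sample(c("A", "C", "G", "T"), length_bp, replace = TRUE),
            collapse = "")
    }, character(1))
    names(seqs) <- paste0("chr", seq_len(n_chroms))
    Biostrings::DNAStringSet(seqs)
  })
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Implant structural variants into a reference genome
#'
#' Places non-overlapping variants of the five classes on the reference and
#' realizes them in a donor genome: deletions remove sequence, inversions
#' reverse-complement it, tandem duplications double a segment in place,
#' interspersed duplications copy an origin segment to a distant
#' destination, and novel insertions add random sequence. Variant sizes are
#' drawn log-uniformly from `size_range`, mirroring the strong skew towards
#' small events in real SV size distributions.
#'
#' @param genome Reference [Biostrings::DNAStringSet].
#' @param counts Named integer vector over the classes `deletion`,
#'   `inversion`, `tandem_duplication`, `interspersed_duplication`,
#'   `novel_insertion` (absent names mean zero).
#' @param size_range Length-2 vector of minimum and maximum SV size in bp.
#' @param zygosity `"hom"` (all reads drawn from the donor) or `"het"`
#'   (variants on one haplotype; half the reads come from the reference).
#' @param seed Optional integer seed.
#' @param min_gap Minimum spacing in bp between implanted variants (and
#'   duplication origins), so neighbouring events stay separable.
#' @return List with `reference`, `donor` (both `DNAStringSet`), `truth`
#'   (a `data.frame` of implanted variants in reference coordinates; for the
#'   two insertion-like classes `end = begin + inserted length`) and the
#'   internal donor block map used by [synthesize_alignments()].
#' @export
implant_variants <- function(genome, counts, size_range = c(50L, 10000L),
                             zygosity = c("hom", "het"), seed = NULL,
                             min_gap = 2000L) {
  zygosity <- match.arg(zygosity)
  classes <- c("deletion", "inversion", "tandem_duplication",
               "interspersed_duplication", "novel_insertion")
  full <- stats::setNames(integer(5), classes)
  full[names(counts)] <- as.integer(counts)
  if (any(!names(counts) %in% classes)) stop("unknown SV class in counts")
  chrom_len <- stats::setNames(Biostrings::width(genome), names(genome))
  if (max(size_range) * 10 > max(chrom_len))
    warning("chromosomes are short relative to the maximum SV size")

  with_seed(seed, {
    occupied <- lapply(chrom_len, function(x) {
      data.frame(begin = integer(), end = integer())
    })
    draw_size <- function() {
      as.integer(round(exp(runif(1, log(size_range[1]),
                                 log(size_range[2])))))
    }
    place <- function(len, away_from = NULL) {
      # reserve [begin, begin+len) with a min_gap buffer on both sides
      for (try in seq_len(500L)) {
        chrom <- sample(names(chrom_len), 1L, prob = chrom_len)
        if (chrom_len[[chrom]] <= len + 2L * min_gap) next
        b <- sample.int(chrom_len[[chrom]] - len - min_gap, 1L) + min_gap
        occ <- occupied[[chrom]]
        if (any(occ$begin < b + len + min_gap & occ$end > b - min_gap)) next
        if (!is.null(away_from) && chrom == away_from$chrom &&
            min(abs(c(b, b + len) - away_from$pos)) < 15000L) next
        occupied[[chrom]] <<- rbind(occ, data.frame(begin = b, end = b + len))
        return(list(chrom = chrom, begin = b, end = b + len))
      }
      stop("infeasible packing: could not place all variants; ",
           "use a longer genome or fewer/smaller variants")
    }

    truth <- list()
    for (cls in classes) {
      for (k in seq_len(full[[cls]])) {
        len <- draw_size()
        if (cls %in% c("deletion", "inversion", "tandem_duplication")) {
          loc <- place(len)
          truth[[length(truth) + 1L]] <- data.frame(
            sv_class = cls, chrom = loc$chrom, begin = loc$begin,
            end = loc$end, origin_chrom = NA_character_,
            origin_begin = NA_integer_, origin_end = NA_integer_,
            length = len, zygosity = zygosity, stringsAsFactors = FALSE)
        } else if (cls == "novel_insertion") {
          loc <- place(1L)
          truth[[length(truth) + 1L]] <- data.frame(
            sv_class = cls, chrom = loc$chrom, begin = loc$begin,
            end = loc$begin + len, origin_chrom = NA_character_,
            origin_begin = NA_integer_, origin_end = NA_integer_,
            length = len, zygosity = zygosity, stringsAsFactors = FALSE)
        } else {
          dest <- place(1L)
          ori <- place(len, away_from = list(chrom = dest$chrom,
                                             pos = dest$begin))
          truth[[length(truth) + 1L]] <- data.frame(
            sv_class = cls, chrom = dest$chrom, begin = dest$begin,
            end = dest$begin + len, origin_chrom = ori$chrom,
            origin_begin = ori$begin, origin_end = ori$end,
            length = len, zygosity = zygosity, stringsAsFactors = FALSE)
        }
      }
    }
    truth <- do.call(rbind, truth)
    truth <- truth[order(truth$chrom, truth$begin), , drop = FALSE]
    rownames(truth) <- NULL

    blocks <- donor_blocks(truth, chrom_len)
    donor <- build_donor(genome, blocks)
    list(reference = genome, donor = donor$seqs, truth = truth,
         blocks = donor$blocks, zygosity = zygosity)
  })
}

# Translate the truth table into per-chromosome donor block maps. A block is
# a maximal donor stretch copied from one source interval on one strand (or
# novel sequence); columns: donor_start/donor_end (assigned later),
# src_chrom/src_start/src_end, strand, kind, novel_len.
donor_blocks <- function(truth, chrom_len) {
  out <- list()
  for (chrom in names(chrom_len)) {
    ev <- truth[truth$chrom == chrom, , drop = FALSE]
    ev <- ev[order(ev$begin), , drop = FALSE]
    cursor <- 0L
    blocks <- list()
    add <- function(src_start, src_end, strand = "+", kind = "ref",
                    src_chrom = chrom, novel_len = 0L) {
      if (kind != "novel" && src_end <= src_start) return()
      blocks[[length(blocks) + 1L]] <<- data.frame(
        src_chrom = if (kind == "novel") NA_character_ else src_chrom,
        src_start = src_start, src_end = src_end, strand = strand,
        kind = kind, novel_len = as.integer(novel_len),
        stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(ev))) {
      v <- ev[i, ]
      switch(v$sv_class,
        deletion = {
          add(cursor, v$begin)
          cursor <- v$end
        },
        inversion = {
          add(cursor, v$begin)
          add(v$begin, v$end, strand = "-", kind = "inv")
          cursor <- v$end
        },
        tandem_duplication = {
          add(cursor, v$end)
          add(v$begin, v$end, kind = "copy")
          cursor <- v$end
        },
        interspersed_duplication = {
          add(cursor, v$begin)
          add(v$origin_begin, v$origin_end, kind = "copy",
              src_chrom = v$origin_chrom)
          cursor <- v$begin
        },
        novel_insertion = {
          add(cursor, v$begin)
          add(0L, 0L, strand = "*", kind = "novel", novel_len = v$length)
          cursor <- v$begin
        })
    }
    add(cursor, chrom_len[[chrom]])
    b <- do.call(rbind, blocks)
    len <- ifelse(b$kind == "novel", b$novel_len, b$src_end - b$src_start)
    b$donor_end <- cumsum(len)
    b$donor_start <- b$donor_end - len
    out[[chrom]] <- b
  }
  out
}

build_donor <- function(genome, blocks) {
  seqs <- character(length(blocks))
  names(seqs) <- names(blocks)
  for (chrom in names(blocks)) {
    b <- blocks[[chrom]]
    parts <- character(nrow(b))
    for (i in seq_len(nrow(b))) {
      if (b$kind[i] == "novel") {
        parts[i] <- random_dna(b$novel_len[i])
      } else {
        s <- Biostrings::subseq(genome[[b$src_chrom[i]]],
                                b$src_start[i] + 1L, b$src_end[i])
        if (b$strand[i] == "-") s <- Biostrings::reverseComplement(s)
        parts[i] <- as.character(s)
      }
    }
    seqs[[chrom]] <- paste(parts, collapse = "")
  }
  list(seqs = Biostrings::DNAStringSet(seqs), blocks = blocks)
}

# Identity block map: used for reads drawn from the reference haplotype.
identity_blocks <- function(chrom_len) {
  lapply(stats::setNames(names(chrom_len), names(chrom_len)), function(ch) {
    data.frame(src_chrom = ch, src_start = 0L, src_end = chrom_len[[ch]],
               strand = "+", kind = "ref", novel_len = 0L,
               donor_start = 0L, donor_end = chrom_len[[ch]],
               stringsAsFactors = FALSE)
  })
}

#' Synthesize long-read split alignments from a simulated donor
#'
#' Tiles the donor genome with reads (log-normal lengths, median 8 kb,
#' truncated to 500 bp - 50 kb) and writes, for each read, the SAM records
#' an idealized aligner would produce: collinear stretches become one record
#' whose CIGAR carries `D`/`I` runs for small-to-medium deletions and
#' insertions (up to `max_inline` bp), while larger events, inversions and
#' duplication transits split the read into supplementary records with the
#' correct strands and clips. In `noisy` mode, indel-dominated sequencing
#' errors are injected into the alignments at `error_rate` before records
#' are written. Aligned stretches shorter than `min_piece` bp are treated as
#' unalignable, as a real aligner would.
#'
#' @param sim Result of [implant_variants()].
#' @param coverage Mean sequencing depth over the donor genome.
#' @param out_sam Output SAM path (coordinate-sorted, with header).
#' @param mode `"idealized"` (error-free alignments) or `"noisy"`.
#' @param error_rate Total per-base error rate in noisy mode.
#' @param error_profile Relative weights of insertion, deletion and
#'   substitution errors (substitutions leave the CIGAR unchanged).
#' @param read_length_median,read_length_sdlog,read_length_range Log-normal
#'   read-length model.
#' @param max_inline Largest event represented inside a single CIGAR.
#' @param min_piece Minimum aligned segment length in bp.
#' @param seed Optional integer seed.
#' @return Invisibly, a list with `path`, `n_reads`, `n_records` and
#'   `realized_coverage`.
#' @export
synthesize_alignments <- function(sim, coverage, out_sam,
                                  mode = c("idealized", "noisy"),
                                  error_rate = 0.1,
                                  error_profile = c(ins = 0.6, del = 0.3,
                                                    sub = 0.1),
                                  read_length_median = 8000,
                                  read_length_sdlog = 0.6,
                                  read_length_range = c(500L, 50000L),
                                  max_inline = 2000L, min_piece = 50L,
                                  seed = NULL) {
  mode <- match.arg(mode)
  if (coverage <= 0) stop("coverage must be positive")
  ref_len <- stats::setNames(Biostrings::width(sim$reference),
                             names(sim$reference))
  donor_len <- stats::setNames(Biostrings::width(sim$donor),
                               names(sim$donor))
  haplos <- list(donor = sim$blocks)
  if (identical(sim$zygosity, "het"))
    haplos$wildtype <- identity_blocks(ref_len)

  p_ins <- error_rate * error_profile[["ins"]] /
    sum(error_profile[c("ins", "del")], error_profile[["sub"]])
  p_del <- error_rate * error_profile[["del"]] /
    sum(error_profile[c("ins", "del")], error_profile[["sub"]])

  with_seed(seed, {
    target <- coverage * sum(donor_len)
    total <- 0
    n_reads <- 0L
    records <- list()
    while (total < target) {
      n_reads <- n_reads + 1L
      hap <- haplos[[sample.int(length(haplos), 1L)]]
      hap_len <- vapply(hap, function(b) max(b$donor_end), 0)
      len <- round(rlnorm(1, log(read_length_median), read_length_sdlog))
      len <- max(read_length_range[1], min(len, read_length_range[2]))
      chrom <- sample(names(hap_len), 1L, prob = hap_len)
      len <- min(len, hap_len[[chrom]])
      r0 <- sample.int(hap_len[[chrom]] - len + 1L, 1L) - 1L
      total <- total + len
      recs <- read_records(hap[[chrom]], r0, r0 + len,
                           sprintf("read_%06d", n_reads), mode,
                           p_ins, p_del, max_inline, min_piece)
      if (length(recs) > 0L) records[[length(records) + 1L]] <- recs
    }
    lines <- unlist(records, use.names = FALSE)
    write_sam(lines, ref_len, out_sam)
    invisible(list(path = out_sam, n_reads = n_reads,
                   n_records = length(lines),
                   realized_coverage = total / sum(donor_len)))
  })
}

# Build the SAM line(s) for one read spanning donor interval [r0, r1).
read_records <- function(blocks, r0, r1, qname, mode, p_ins, p_del,
                         max_inline, min_piece) {
  hit <- blocks[blocks$donor_end > r0 & blocks$donor_start < r1, ,
                drop = FALSE]
  if (nrow(hit) == 0L) return(character())
  pieces <- list()
  for (i in seq_len(nrow(hit))) {
    b <- hit[i, ]
    p0 <- max(r0, b$donor_start); p1 <- min(r1, b$donor_end)
    plen <- p1 - p0
    aligned <- b$kind != "novel" && plen >= min_piece
    src <- if (b$kind == "novel") c(NA_integer_, NA_integer_)
    else if (b$strand == "+")
      c(b$src_start + (p0 - b$donor_start), b$src_start + (p1 - b$donor_start))
    else
      c(b$src_start + (b$donor_end - p1), b$src_start + (b$donor_end - p0))
    pieces[[i]] <- list(q0 = p0 - r0, q1 = p1 - r0, len = plen,
                        chrom = b$src_chrom, src0 = src[1], src1 = src[2],
                        strand = b$strand, aligned = aligned)
  }

  # assemble alignment runs, merging collinear forward pieces across
  # small reference gaps (deletions) and small unaligned stretches
  # (insertions) into a single CIGAR
  items <- list()   # alternating "gap" (unaligned bp) and "run" items
  run <- NULL
  pending_gap <- 0L
  flush_run <- function() {
    if (!is.null(run)) items[[length(items) + 1L]] <<- run
    run <<- NULL
  }
  for (p in pieces) {
    if (!p$aligned) {
      pending_gap <- pending_gap + p$len
      next
    }
    merged <- FALSE
    if (!is.null(run) && run$strand == "+" && p$strand == "+" &&
        identical(run$chrom, p$chrom)) {
      g <- p$src0 - run$ref_end
      if (g >= 0L && g <= max_inline && pending_gap <= max_inline) {
        if (pending_gap > 0L) {
          run$ops <- c(run$ops, "I"); run$lens <- c(run$lens, pending_gap)
        }
        if (g > 0L) {
          run$ops <- c(run$ops, "D"); run$lens <- c(run$lens, g)
        }
        run$ops <- c(run$ops, "M"); run$lens <- c(run$lens, p$len)
        run$ref_end <- p$src1
        merged <- TRUE
      }
    }
    if (!merged) {
      flush_run()
      if (pending_gap > 0L)
        items[[length(items) + 1L]] <- list(gap = pending_gap)
      run <- list(chrom = p$chrom, ref_start = p$src0, ref_end = p$src1,
                  strand = p$strand, ops = "M", lens = p$len)
    }
    pending_gap <- 0L
  }
  flush_run()

  runs <- Filter(function(x) is.null(x$gap), items)
  if (length(runs) == 0L) return(character())

  if (mode == "noisy") {
    items <- lapply(items, function(it) {
      if (!is.null(it$gap)) return(it)
      noisy <- inject_noise(it$ops, it$lens, p_ins, p_del)
      it$ops <- noisy$ops; it$lens <- noisy$lens
      it
    })
  }

  # read offsets: walk items in read order
  q <- 0L
  for (k in seq_along(items)) {
    it <- items[[k]]
    if (!is.null(it$gap)) { q <- q + it$gap; next }
    items[[k]]$q_start <- q
    q <- q + sum(it$lens[it$ops %in% c("M", "I")])
  }
  read_len <- q
  runs <- Filter(function(x) is.null(x$gap), items)
  qlens <- vapply(runs, function(x) sum(x$lens[x$ops %in% c("M", "I")]), 0)
  primary <- which.max(qlens)

  vapply(seq_along(runs), function(k) {
    rn <- runs[[k]]
    qlen <- qlens[k]
    left <- rn$q_start; right <- read_len - rn$q_start - qlen
    if (rn$strand == "-") { tmp <- left; left <- right; right <- tmp }
    ops <- rn$ops; lens <- rn$lens
    if (rn$strand == "-") { ops <- rev(ops); lens <- rev(lens) }
    r <- rle(ops)  # coalesce adjacent same-op runs (e.g. M followed by M)
    if (any(r$lengths > 1L)) {
      grp <- rep(seq_along(r$lengths), r$lengths)
      lens <- as.integer(rowsum(lens, grp))
      ops <- r$values
    }
    if (right > 0L) { ops <- c(ops, "S"); lens <- c(lens, right) }
    if (left > 0L) { ops <- c("S", ops); lens <- c(left, lens) }
    cigar <- paste0(lens, ops, collapse = "")
    flag <- 0L
    if (rn$strand == "-") flag <- flag + 16L
    if (k != primary) flag <- flag + 2048L
    paste(qname, flag, rn$chrom, rn$ref_start + 1L, 60L, cigar,
          "*", 0L, 0L, "*", "*", sep = "\t")
  }, character(1))
}

# Inject per-base indel errors into the M stretches of an op list. A
# deletion error turns a template base into D (the read lacks it); an
# insertion error adds an extra read base (I) after a template base. The
# reference footprint of the run is preserved exactly.
inject_noise <- function(ops, lens, p_ins, p_del) {
  out_ops <- character(0)
  out_lens <- integer(0)
  for (i in seq_along(ops)) {
    if (ops[i] != "M") {
      out_ops <- c(out_ops, ops[i]); out_lens <- c(out_lens, lens[i])
      next
    }
    L <- lens[i]
    cat <- sample.int(3L, L, replace = TRUE,
                      prob = c(1 - p_ins - p_del, p_del, p_ins))
    n_ext <- sum(cat == 3L)
    if (n_ext == 0L && !any(cat == 2L)) {
      out_ops <- c(out_ops, "M"); out_lens <- c(out_lens, L)
      next
    }
    per <- ifelse(cat == 2L, "D", "M")
    cumins <- cumsum(cat == 3L)
    pos <- seq_len(L) + c(0L, cumins[-L])
    expanded <- character(L + n_ext)
    expanded[pos] <- per
    expanded[pos[cat == 3L] + 1L] <- "I"
    r <- rle(expanded)
    out_ops <- c(out_ops, r$values)
    out_lens <- c(out_lens, r$lengths)
  }
  r <- rle(out_ops)  # merge adjacent same-op runs across joins
  if (any(r$lengths > 1L)) {
    grp <- rep(seq_along(r$lengths), r$lengths)
    out_lens <- as.integer(rowsum(out_lens, grp))
    out_ops <- r$values
  }
  list(ops = out_ops, lens = out_lens)
}

write_sam <- function(lines, contig_len, path) {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(contig_len),
                      as.integer(contig_len)))
  if (length(lines) > 0L) {
    rname <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 3L)
    pos <- as.integer(vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "",
                             4L))
    lines <- lines[order(match(rname, names(contig_len)), pos)]
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Write a truth table to BED
#'
#' Columns: chrom, begin, end, class, origin (`<chrom>:<begin>-<end>` or
#' `.`). Coordinates are 0-based half-open reference coordinates; for the
#' insertion-like classes the interval encodes the inserted length.
#'
#' @param truth Truth `data.frame` from [implant_variants()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_truth_bed <- function(truth, path) {
  origin <- ifelse(is.na(truth$origin_chrom), ".",
                   sprintf("%s:%d-%d", truth$origin_chrom,
                           truth$origin_begin, truth$origin_end))
  out <- data.frame(truth$chrom, truth$begin, truth$end, truth$sv_class,
                    origin)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a truth BED written by [write_truth_bed()]
#'
#' @param path BED path.
#' @return Truth `data.frame`.
#' @export
read_truth_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "begin", "end", "sv_class",
                                        "origin"))
  ori <- regmatches(df$origin,
                    regexec("^(.+):([0-9]+)-([0-9]+)$", df$origin))
  df$origin_chrom <- vapply(ori, function(x)
    if (length(x)) x[2] else NA_character_, character(1))
  df$origin_begin <- vapply(ori, function(x)
    if (length(x)) as.integer(x[3]) else NA_integer_, integer(1))
  df$origin_end <- vapply(ori, function(x)
    if (length(x)) as.integer(x[4]) else NA_integer_, integer(1))
  df$origin <- NULL
  df
}

#' Simulate a complete truth-labelled dataset
#'
#' Convenience wrapper: simulates a reference, implants variants, writes
#' reference FASTA, truth BED and a SAM of synthesized read alignments into
#' `out_dir`. The defaults reproduce the package's standard benchmark
#' scenario: a 500 kb two-chromosome genome with 60 homozygous SVs
#' (20 deletions, 10 inversions, 10 tandem duplications, 15 interspersed
#' duplications, 5 novel insertions) of 50 bp - 10 kb at 6x coverage.
#'
#' @param out_dir Output directory.
#' @param n_chroms,chrom_length Genome shape.
#' @param counts Named variant counts per class.
#' @param size_range SV size range in bp.
#' @param coverage Sequencing depth.
#' @param mode `"idealized"` or `"noisy"` alignments.
#' @param error_rate Per-base error rate for noisy mode.
#' @param zygosity `"hom"` or `"het"`.
#' @param seed Integer seed governing every random choice.
#' @return List with the `implant_variants()` result (`sim`), the synthesis
#'   stats (`stats`) and file `paths`.
#' @export
simulate_dataset <- function(out_dir,
                             n_chroms = 2L, chrom_length = 250000L,
                             counts = c(deletion = 20L, inversion = 10L,
                                        tandem_duplication = 10L,
                                        interspersed_duplication = 15L,
                                        novel_insertion = 5L),
                             size_range = c(50L, 10000L),
                             coverage = 6, mode = "idealized",
                             error_rate = 0.1, zygosity = "hom",
                             seed = 1L) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- simulate_reference(n_chroms, chrom_length, seed = seed)
  sim <- implant_variants(genome, counts, size_range, zygosity,
                          seed = seed + 1L)
  paths <- list(reference = file.path(out_dir, "reference.fasta"),
                sam = file.path(out_dir, "reads.sam"),
                truth = file.path(out_dir, "truth.bed"))
  Biostrings::writeXStringSet(genome, paths$reference)
  stats <- synthesize_alignments(sim, coverage, paths$sam, mode = mode,
                                 error_rate = error_rate, seed = seed + 2L)
  write_truth_bed(sim$truth, paths$truth)
  list(sim = sim, stats = stats, paths = paths)
}
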