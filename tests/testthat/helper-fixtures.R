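# Builders for hand-constructed fixtures used across the suite.

make_segment <- function(chrom = "chr1", ref_start, ref_end, read_start,
                         read_end, strand = "+", read_name = "r1",
                         mapq = 60L, cigar = "*", is_supplementary = FALSE) {
  data.frame(read_name = read_name, chrom = chrom,
             ref_start = as.integer(ref_start),
             ref_end = as.integer(ref_end),
             read_start = as.integer(read_start),
             read_end = as.integer(read_end), strand = strand,
             mapq = as.integer(mapq), cigar = cigar,
             is_supplementary = is_supplementary, stringsAsFactors = FALSE)
}

make_sig <- function(sig_type = "DEL", chrom = "chr1", begin, end,
                     evidence_class = "intra", read_name = "r1", n = 1L,
                     ...) {
  rows <- lapply(seq_len(n), function(i) {
    svclique:::make_signature(sig_type, chrom, begin, end, evidence_class,
                              if (n == 1L) read_name
                              else paste0(read_name, "_", i), ...)
  })
  do.call(rbind, rows)
}

# Write a small SAM file from raw record fields.
write_test_sam <- function(records, path,
                           contigs = c(chr1 = 100000L, chr2 = 300000L,
                                       chr5 = 300000L)) {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), contigs))
  writeLines(c(header, records), path)
  path
}

sam_record <- function(qname = "r1", flag = 0L, rname = "chr1", pos,
                       mapq = 60L, cigar) {
  paste(qname, flag, rname, pos, mapq, cigar, "*", 0, 0, "*", "*",
        sep = "\t")
}

# Brute-force maximal-clique oracle: enumerate every vertex subset, keep
# cliques without a strict clique superset. Only usable for small graphs.
brute_force_cliques <- function(adj) {
  n <- nrow(adj)
  if (n == 0L) return(list())
  subsets <- lapply(seq_len(2^n - 1L), function(m) {
    which(bitwAnd(m, 2^(seq_len(n) - 1L)) > 0L)
  })
  is_clique <- vapply(subsets, function(s) {
    length(s) == 1L || all(adj[t(combn(s, 2))])
  }, logical(1))
  cliques <- subsets[is_clique]
  maximal <- vapply(seq_along(cliques), function(i) {
    !any(vapply(cliques, function(o) {
      length(o) > length(cliques[[i]]) && all(cliques[[i]] %in% o)
    }, logical(1)))
  }, logical(1))
  cliques[maximal]
}

# Canonical form for comparing clique sets regardless of order.
clique_key <- function(cliques) {
  sort(vapply(cliques, function(v) paste(sort(v), collapse = ","),
              character(1)))
}

random_adjacency <- function(n, p = 0.4) {
  adj <- matrix(FALSE, n, n)
  if (n >= 2L) {
    pairs <- t(combn(n, 2))
    on <- runif(nrow(pairs)) < p
    adj[pairs[on, , drop = FALSE]] <- TRUE
    adj[pairs[on, c(2, 1), drop = FALSE]] <- TRUE
  }
  adj
}
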