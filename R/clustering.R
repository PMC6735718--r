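#' Span-position distance between two SV signatures
#'
#' The span-position distance (SPD) combines a normalized span difference
#' (SD) with a positional difference (PD) scaled by a constant `N`:
#'
#' \deqn{SPD = SD + PD / N}
#'
#' where \eqn{SD = |span_1 - span_2| / \max(span_1, span_2) \in [0, 1)} and
#' \eqn{PD = \min(|B_1 - B_2|, |E_1 - E_2|, |mid_1 - mid_2|)}. `N` sets the
#' exchange rate between the two components: with `N = 900`, two equal-span
#' signatures 900 bp apart score the same SPD as two co-located signatures
#' of maximally different spans.
#'
#' Two zero-span signatures (breakends) have `SD = 0` by definition, so
#' breakend clustering degenerates to purely positional clustering.
#'
#' @param s1,s2 One-row signature `data.frame`s on the same chromosome and of
#'   the same type.
#' @param N Normalization constant in bp.
#' @return Non-negative numeric distance; 0 iff the intervals are identical.
#' @export
span_position_distance <- function(s1, s2, N = 900) {
  spd_components(s1$begin, s1$end, s2$begin, s2$end, N)$spd
}

# Vector-friendly SPD core used by both the scalar API and the graph builder.
spd_components <- function(b1, e1, b2, e2, N) {
  span1 <- e1 - b1
  span2 <- e2 - b2
  mx <- pmax(span1, span2)
  sd <- ifelse(mx == 0, 0, abs(span1 - span2) / mx)
  pd <- pmin(abs(b1 - b2), abs(e1 - e2), abs((b1 + e1) / 2 - (b2 + e2) / 2))
  list(sd = sd, pd = pd, spd = sd + pd / N)
}

#' Partition signatures into clustering buckets
#'
#' Splits a signature table by `(sig_type, chrom)`: signatures of different
#' types or chromosomes can never express the same variant, so no edge is
#' possible between them. Within a bucket, signatures are sorted by `begin`.
#' Pairs whose positional difference alone reaches `N * T` already have
#' `SPD >= PD/N >= T` and need no span comparison; the graph builder uses
#' this bound as a pruning step.
#'
#' @param signatures Signature `data.frame`.
#' @return Named list of bucket `data.frame`s, keyed `"<type>:<chrom>"`.
#' @export
partition_signatures <- function(signatures) {
  if (nrow(signatures) == 0L) return(structure(list(), names = character()))
  key <- paste(signatures$sig_type, signatures$chrom, sep = ":")
  buckets <- split(signatures, key)
  lapply(buckets, function(b) {
    b <- b[order(b$begin, b$end), , drop = FALSE]
    rownames(b) <- NULL
    b
  })
}

#' Build the signature graph for one bucket
#'
#' Vertices are signatures; an undirected edge connects two signatures iff
#' their span-position distance is strictly below `params$edge_threshold_T`.
#' For breakend buckets an edge additionally requires the two mate loci to
#' lie on the same chromosome within `N * T` bp, otherwise junctions to
#' unrelated partners would merge.
#'
#' @param bucket Homogeneous signature `data.frame` (one type, one chrom).
#' @param params [sv_params()] list.
#' @param prune If `TRUE` (default), span differences are only computed for
#'   pairs passing the positional bound `PD < N * T`; the resulting graph is
#'   provably identical to the unpruned one.
#' @return Logical adjacency matrix (no self-loops).
#' @export
build_graph <- function(bucket, params = sv_params(), prune = TRUE) {
  m <- nrow(bucket)
  adj <- matrix(FALSE, m, m)
  if (m < 2L) return(adj)
  N <- params$normalization_N
  Tt <- params$edge_threshold_T
  b <- bucket$begin; e <- bucket$end
  mid <- (b + e) / 2
  pd <- pmin(abs(outer(b, b, "-")), abs(outer(e, e, "-")),
             abs(outer(mid, mid, "-")))
  span <- e - b
  if (prune) {
    cand <- which(pd < N * Tt, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    if (nrow(cand) > 0L) {
      i <- cand[, 1]; j <- cand[, 2]
      mx <- pmax(span[i], span[j])
      sd <- ifelse(mx == 0, 0, abs(span[i] - span[j]) / mx)
      ok <- sd + pd[cand] / N < Tt
      adj[cand[ok, , drop = FALSE]] <- TRUE
      adj[cand[ok, c(2, 1), drop = FALSE]] <- TRUE
    }
  } else {
    mx <- outer(span, span, pmax)
    sd <- abs(outer(span, span, "-"))
    sd <- ifelse(mx == 0, 0, sd / mx)
    adj <- sd + pd / N < Tt
    diag(adj) <- FALSE
  }
  if (bucket$sig_type[1] == "BRK") {
    mate_ok <- outer(bucket$mate_chrom, bucket$mate_chrom, "==") &
      abs(outer(bucket$mate_pos, bucket$mate_pos, "-")) < N * Tt
    adj <- adj & mate_ok
  }
  adj
}

#' Enumerate all maximal cliques of an undirected graph
#'
#' Bron-Kerbosch enumeration with pivoting. Every maximal clique is returned
#' exactly once; isolated vertices appear as singleton cliques.
#'
#' @param adj Logical adjacency matrix (symmetric, empty diagonal).
#' @return List of sorted integer vertex vectors.
#' @export
enumerate_maximal_cliques <- function(adj) {
  n <- nrow(adj)
  if (n == 0L) return(list())
  nb <- lapply(seq_len(n), function(i) which(adj[i, ]))
  acc <- new.env(parent = emptyenv())
  acc$res <- vector("list", 64L)
  acc$k <- 0L
  rec <- function(R, P, X) {
    if (length(P) == 0L && length(X) == 0L) {
      acc$k <- acc$k + 1L
      if (acc$k > length(acc$res)) acc$res <- c(acc$res, vector("list", acc$k))
      acc$res[[acc$k]] <- R
      return()
    }
    # pivot: vertex of P union X with most neighbours in P
    pux <- c(P, X)
    deg <- vapply(pux, function(u) sum(P %in% nb[[u]]), 0L)
    u <- pux[which.max(deg)]
    for (v in setdiff(P, nb[[u]])) {
      rec(c(R, v), intersect(P, nb[[v]]), intersect(X, nb[[v]]))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
  }
  rec(integer(0), seq_len(n), integer(0))
  lapply(acc$res[seq_len(acc$k)], sort)
}

#' Resolve vertex sharing between maximal cliques
#'
#' Maximal cliques may overlap, but each signature should support exactly one
#' cluster. Cliques are ranked by decreasing size, then decreasing
#' preliminary score, then leftmost member position; walking down that order,
#' signatures already consumed by a higher-ranked clique are removed from
#' later ones and emptied cliques are dropped.
#'
#' @param cliques List of integer vertex vectors.
#' @param bucket Signature `data.frame` the vertices index into.
#' @param params [sv_params()] list.
#' @return List of pairwise-disjoint integer vertex vectors.
#' @export
resolve_overlapping_cliques <- function(cliques, bucket,
                                        params = sv_params()) {
  if (length(cliques) == 0L) return(list())
  cliques <- unique(lapply(cliques, sort))
  size <- lengths(cliques)
  prelim <- vapply(cliques, function(v) {
    score_cluster(bucket[v, , drop = FALSE], params)$total
  }, 0)
  leftmost <- vapply(cliques, function(v) min(bucket$begin[v]), 0)
  ord <- order(-size, -prelim, leftmost)
  used <- rep(FALSE, nrow(bucket))
  out <- list()
  for (i in ord) {
    v <- cliques[[i]][!used[cliques[[i]]]]
    if (length(v) == 0L) next
    used[v] <- TRUE
    out[[length(out) + 1L]] <- v
  }
  out
}

#' Score a signature cluster
#'
#' Computes the four score components of a cluster and their total
#' \eqn{S \in (0, 100]}:
#' \itemize{
#'   \item `n`: number of member signatures, counting at most 20 from each
#'     evidence class (intra/inter), so \eqn{n \in (0, 40]};
#'   \item `b`: bonus of 10 for the presence of any intra-alignment member
#'     plus 20 for any inter-alignment member, \eqn{b \in \{0, 10, 20, 30\}};
#'   \item `sp`: positional consistency
#'     \eqn{10 (1 - \min(1, s_{pos}/\bar{span}))} where \eqn{s_{pos}} is the
#'     population standard deviation of the member midpoints;
#'   \item `ss`: span consistency
#'     \eqn{20 (1 - \min(1, s_{span}/\bar{span}))} with \eqn{s_{span}} the
#'     population standard deviation of member spans.
#' }
#' For all-breakend clusters the mean span is 0; `sp`/`ss` then award the
#' full component when the corresponding deviation is 0 and nothing
#' otherwise. The total is clamped into `(0, 100]` (lower clamp 1).
#'
#' @param members Non-empty signature `data.frame`.
#' @param params [sv_params()] list.
#' @return List with `n`, `b`, `sp`, `ss`, `s_pos`, `s_span`, `mean_span`,
#'   `total`.
#' @export
score_cluster <- function(members, params = sv_params()) {
  stopifnot(nrow(members) > 0L)
  cap <- params$max_counted_per_class
  n_intra <- sum(members$evidence_class == "intra")
  n_inter <- sum(members$evidence_class == "inter")
  n <- min(cap, n_intra) + min(cap, n_inter)
  b <- 10 * (n_intra > 0) + 20 * (n_inter > 0)
  mid <- (members$begin + members$end) / 2
  span <- members$end - members$begin
  s_pos <- pop_sd(mid)
  s_span <- pop_sd(span)
  mean_span <- mean(span)
  if (mean_span > 0) {
    sp <- 10 * (1 - min(1, s_pos / mean_span))
    ss <- 20 * (1 - min(1, s_span / mean_span))
  } else {
    sp <- if (s_pos == 0) 10 else 0
    ss <- if (s_span == 0) 20 else 0
  }
  total <- min(100, max(1, n + b + sp + ss))
  list(n = n, b = b, sp = sp, ss = ss, s_pos = s_pos, s_span = s_span,
       mean_span = mean_span, total = total)
}

#' Cluster SV signatures
#'
#' Orchestrates the clustering stage: partition by type and chromosome,
#' build the span-position-distance graph per bucket, enumerate maximal
#' cliques, resolve vertex sharing, and score each resulting cluster. The
#' consensus interval of a cluster is the median of member begins and ends;
#' duplication clusters additionally carry the median origin interval and
#' breakend clusters the consensus mate locus.
#'
#' @param signatures Signature `data.frame` from [collect_signatures()].
#' @param params [sv_params()] list.
#' @return A `data.frame` with one row per cluster: `sig_type`, `chrom`,
#'   `begin`, `end`, member counts, the four score components, `score`,
#'   consensus origin/mate columns and a `read_names` list column; sorted by
#'   `chrom`, `begin`.
#' @export
cluster_signatures <- function(signatures, params = sv_params()) {
  buckets <- partition_signatures(signatures)
  rows <- list()
  for (bucket in buckets) {
    adj <- build_graph(bucket, params)
    cliques <- enumerate_maximal_cliques(adj)
    cliques <- resolve_overlapping_cliques(cliques, bucket, params)
    for (v in cliques) {
      mem <- bucket[v, , drop = FALSE]
      sc <- score_cluster(mem, params)
      row <- data.frame(
        sig_type = mem$sig_type[1], chrom = mem$chrom[1],
        begin = as.integer(round(median(mem$begin))),
        end = as.integer(round(median(mem$end))),
        n_members = nrow(mem),
        n_intra = sum(mem$evidence_class == "intra"),
        n_inter = sum(mem$evidence_class == "inter"),
        score_n = sc$n, score_b = sc$b, score_sp = sc$sp, score_ss = sc$ss,
        s_pos = sc$s_pos, s_span = sc$s_span, mean_span = sc$mean_span,
        score = sc$total,
        origin_chrom = NA_character_, origin_begin = NA_integer_,
        origin_end = NA_integer_,
        mate_chrom = NA_character_, mate_pos = NA_integer_,
        stringsAsFactors = FALSE)
      if (mem$sig_type[1] == "DUP") {
        row$origin_chrom <- modal_value(mem$origin_chrom)
        ori <- mem[mem$origin_chrom == row$origin_chrom, , drop = FALSE]
        row$origin_begin <- as.integer(round(median(ori$origin_begin)))
        row$origin_end <- as.integer(round(median(ori$origin_end)))
      }
      if (mem$sig_type[1] == "BRK") {
        row$mate_chrom <- modal_value(mem$mate_chrom)
        mm <- mem[mem$mate_chrom == row$mate_chrom, , drop = FALSE]
        row$mate_pos <- as.integer(round(median(mm$mate_pos)))
      }
      row$read_names <- I(list(sort(unique(mem$read_name))))
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(rows) == 0L) return(empty_cluster_df())
  clusters <- do.call(rbind, rows)
  clusters <- clusters[order(clusters$chrom, clusters$begin), , drop = FALSE]
  rownames(clusters) <- NULL
  clusters
}

empty_cluster_df <- function() {
  df <- data.frame(sig_type = character(), chrom = character(),
                   begin = integer(), end = integer(), n_members = integer(),
                   n_intra = integer(), n_inter = integer(),
                   score_n = numeric(), score_b = numeric(),
                   score_sp = numeric(), score_ss = numeric(),
                   s_pos = numeric(), s_span = numeric(),
                   mean_span = numeric(), score = numeric(),
                   origin_chrom = character(), origin_begin = integer(),
                   origin_end = integer(), mate_chrom = character(),
                   mate_pos = integer(), stringsAsFactors = FALSE)
  df$read_names <- I(list())
  df
}
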