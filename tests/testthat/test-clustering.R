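test_that("span-position distance reproduces its defining trade-off", {
  N <- 900
  # same span, 900 bp apart
  apart <- span_position_distance(make_sig(begin = 1000, end = 1500),
                                  make_sig(begin = 1900, end = 2400), N)
  expect_equal(apart, 1.0)
  # co-located, maximally different spans approaches 1 from below
  colocated <- span_position_distance(make_sig(begin = 1000, end = 1100),
                                      make_sig(begin = 550, end = 1550), N)
  expect_equal(colocated, 0.9)  # SD = 900/1000, PD = 0 (midpoints agree)
  # identity
  expect_equal(span_position_distance(make_sig(begin = 5, end = 55),
                                      make_sig(begin = 5, end = 55), N), 0)
})

test_that("SPD is a symmetric non-negative form with SD in [0,1)", {
  set.seed(42)
  n <- 10000
  b1 <- sample.int(1e6, n, replace = TRUE)
  e1 <- b1 + sample.int(5000, n, replace = TRUE)
  b2 <- sample.int(1e6, n, replace = TRUE)
  e2 <- b2 + sample.int(5000, n, replace = TRUE)
  f <- svclique:::spd_components
  d12 <- f(b1, e1, b2, e2, 900)
  d21 <- f(b2, e2, b1, e1, 900)
  expect_equal(d12$spd, d21$spd)
  expect_true(all(d12$sd >= 0 & d12$sd < 1))
  expect_true(all(d12$pd >= 0))
  expect_true(all(d12$spd >= 0))
  expect_true(all(f(b1, e1, b1, e1, 900)$spd == 0))
})

test_that("partitioning separates types and chromosomes and sorts buckets", {
  sigs <- rbind(make_sig(begin = 100, end = 200),
                make_sig(begin = 50, end = 120),
                make_sig(sig_type = "INS", begin = 100, end = 200),
                make_sig(chrom = "chr2", begin = 100, end = 200))
  buckets <- partition_signatures(sigs)
  expect_setequal(names(buckets), c("DEL:chr1", "DEL:chr2", "INS:chr1"))
  expect_equal(buckets$`DEL:chr1`$begin, c(50L, 100L))
  expect_equal(length(partition_signatures(sigs[0, ])), 0L)
})

test_that("graph edges follow the strict SPD threshold", {
  p <- sv_params()
  # identical signatures connect
  expect_true(build_graph(rbind(make_sig(begin = 1, end = 100),
                                make_sig(begin = 1, end = 100)), p)[1, 2])
  # SPD = 1.0 pair stays apart at T = 0.7
  far <- rbind(make_sig(begin = 1000, end = 1500),
               make_sig(begin = 1900, end = 2400))
  expect_false(build_graph(far, p)[1, 2])
  # threshold boundary: SPD = 0.9 connects only when T exceeds it
  pair <- rbind(make_sig(begin = 1000, end = 1100),
                make_sig(begin = 550, end = 1550))
  expect_false(build_graph(pair, p)[1, 2])
  expect_true(build_graph(pair, sv_params(edge_threshold_T = 0.95))[1, 2])
})

test_that("positional pruning never changes the graph", {
  p <- sv_params()
  set.seed(7)
  for (rep in 1:20) {
    m <- sample(2:40, 1)
    b <- sample.int(20000, m, replace = TRUE)
    bucket <- do.call(rbind, lapply(seq_len(m), function(i) {
      make_sig(begin = b[i], end = b[i] + sample.int(2000, 1),
               read_name = paste0("r", i))
    }))
    bucket <- bucket[order(bucket$begin), ]
    expect_identical(build_graph(bucket, p, prune = TRUE),
                     build_graph(bucket, p, prune = FALSE))
  }
})

test_that("breakend edges additionally require compatible mates", {
  p <- sv_params()
  b <- rbind(
    make_sig(sig_type = "BRK", begin = 5000, end = 5000,
             evidence_class = "inter", mate_chrom = "chr5", mate_pos = 100L),
    make_sig(sig_type = "BRK", begin = 5003, end = 5003,
             evidence_class = "inter", mate_chrom = "chr5", mate_pos = 110L),
    make_sig(sig_type = "BRK", begin = 5001, end = 5001,
             evidence_class = "inter", mate_chrom = "chr9", mate_pos = 100L))
  adj <- build_graph(b, p)
  expect_true(adj[1, 2])   # same mate chromosome, mates 10 bp apart
  expect_false(adj[1, 3])  # mate on a different chromosome
})

test_that("maximal cliques match brute-force enumeration", {
  # fixed shapes first
  tri <- matrix(FALSE, 3, 3); tri[cbind(c(1,2,1,3,2,3), c(2,1,3,1,3,2))] <- TRUE
  expect_equal(clique_key(enumerate_maximal_cliques(tri)), "1,2,3")
  path <- matrix(FALSE, 3, 3); path[cbind(c(1,2,2,3), c(2,1,3,2))] <- TRUE
  expect_equal(clique_key(enumerate_maximal_cliques(path)), c("1,2", "2,3"))
  # isolated vertices come back as singletons
  expect_equal(clique_key(enumerate_maximal_cliques(matrix(FALSE, 2, 2))),
               c("1", "2"))
  # randomized graphs against the subset-enumeration oracle
  set.seed(99)
  for (rep in 1:30) {
    adj <- random_adjacency(sample(1:12, 1), p = runif(1, 0.2, 0.8))
    expect_equal(clique_key(enumerate_maximal_cliques(adj)),
                 clique_key(brute_force_cliques(adj)))
  }
})

test_that("maximal cliques agree with an independent implementation", {
  skip_if_not_installed("igraph")
  set.seed(123)
  for (rep in 1:10) {
    adj <- random_adjacency(sample(5:25, 1), p = 0.5)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    ref <- lapply(igraph::max_cliques(g), as.integer)
    expect_equal(clique_key(enumerate_maximal_cliques(adj)), clique_key(ref))
  }
})

test_that("overlapping cliques resolve greedily into disjoint clusters", {
  p <- sv_params()
  bucket <- do.call(rbind, lapply(1:4, function(i) {
    make_sig(begin = 100 + i, end = 200 + i, read_name = paste0("r", i))
  }))
  # {1,2,3} beats {3,4}; the leftover singleton {4} survives
  out <- resolve_overlapping_cliques(list(c(1L, 2L, 3L), c(3L, 4L)), bucket, p)
  expect_equal(clique_key(out), c("1,2,3", "4"))
  # duplicates collapse
  out2 <- resolve_overlapping_cliques(list(c(1L, 2L), c(1L, 2L)), bucket, p)
  expect_equal(clique_key(out2), "1,2")
  # disjoint cliques pass through
  out3 <- resolve_overlapping_cliques(list(c(1L, 2L), c(3L, 4L)), bucket, p)
  expect_equal(clique_key(out3), c("1,2", "3,4"))
  expect_true(all(table(unlist(out)) == 1L))
})

test_that("cluster score components follow the published formulas", {
  p <- sv_params()
  # saturated perfect cluster: 20 intra + 20 inter at identical coordinates
  sat <- rbind(make_sig(begin = 1000, end = 1200, n = 25L),
               make_sig(begin = 1000, end = 1200, evidence_class = "inter",
                        read_name = "s", n = 25L))
  sc <- score_cluster(sat, p)
  expect_equal(sc$n, 40)
  expect_equal(sc$b, 30)
  expect_equal(sc$sp, 10)
  expect_equal(sc$ss, 20)
  expect_equal(sc$total, 100)

  # class cap and intra-only bonus
  sc35 <- score_cluster(make_sig(begin = 1, end = 100, n = 35L), p)
  expect_equal(sc35$n, 20)
  expect_equal(sc35$b, 10)

  # 3 identical intra + 1 identical inter
  sc4 <- score_cluster(rbind(
    make_sig(begin = 500, end = 700, n = 3L),
    make_sig(begin = 500, end = 700, evidence_class = "inter",
             read_name = "x")), p)
  expect_equal(sc4$n, 4)
  expect_equal(sc4$b, 30)
  expect_equal(sc4$total, 64)

  # dispersion discounts sp/ss through the normalized standard deviations
  spread <- rbind(make_sig(begin = 1000, end = 1100),
                  make_sig(begin = 1040, end = 1140, read_name = "r2"))
  scs <- score_cluster(spread, p)
  expect_equal(scs$s_pos, 20)   # midpoints 1050/1090, population sd
  expect_equal(scs$sp, 10 * (1 - 20 / 100))
  expect_equal(scs$ss, 20)      # identical spans

  # all-breakend cluster: zero mean span falls back to consistency flags
  brk <- rbind(make_sig(sig_type = "BRK", begin = 7, end = 7,
                        evidence_class = "inter",
                        mate_chrom = "chr2", mate_pos = 1L, n = 2L))
  scb <- score_cluster(brk, p)
  expect_equal(c(scb$sp, scb$ss), c(10, 20))
})

test_that("score grows monotonically with identical support", {
  p <- sv_params()
  comp <- function(k) score_cluster(make_sig(begin = 10, end = 510, n = k), p)
  for (k in c(1L, 5L, 19L)) {
    a <- comp(k); b <- comp(k + 1L)
    expect_true(b$n >= a$n)
    expect_true(b$total >= a$total)
    expect_true(a$total > 0 && a$total <= 100)
  }
})

test_that("clustering merges jittered mates and separates distant events", {
  p <- sv_params()
  set.seed(5)
  jitter <- do.call(rbind, lapply(1:6, function(i) {
    make_sig(begin = 10000 + sample(-5:5, 1), end = 10800 + sample(-5:5, 1),
             read_name = paste0("r", i))
  }))
  cl <- cluster_signatures(jitter, p)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_members, 6L)
  expect_true(abs(cl$begin - 10000) <= 5 && abs(cl$end - 10800) <= 5)

  two <- rbind(jitter,
               do.call(rbind, lapply(1:6, function(i) {
                 make_sig(begin = 60000, end = 60800,
                          read_name = paste0("s", i))
               })))
  cl2 <- cluster_signatures(two, p)
  expect_equal(nrow(cl2), 2L)
  expect_equal(cluster_signatures(jitter[0, ], p),
               svclique:::empty_cluster_df())
})
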