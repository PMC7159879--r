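params_default <- scoring_params()

test_that("align_pair recovers the hand-summed self-alignment score", {
  al <- align_pair("ACDEFGHK", "ACDEFGHK", params_default)
  # BLOSUM62 diagonal: A4 C9 D6 E5 F6 G6 H8 K5
  expect_equal(al$raw_score, 49)
  expect_equal(al$aligned_columns, 8L)
  expect_equal(al$coverage_a, 1.0)
  expect_equal(al$coverage_b, 1.0)
})

test_that("align_pair is symmetric and rejects bad residues", {
  a <- "MKVLAWQH"; b <- "MKVAWQHH"
  expect_equal(align_pair(a, b, params_default)$raw_score,
               align_pair(b, a, params_default)$raw_score)
  expect_error(align_pair("MKB1", "MKVA", params_default), "alphabet")
})

test_that("compositionally disjoint pairs never form an edge", {
  al <- align_pair("AAAA", "WWWW", params_default)
  oracle <- sw_oracle("AAAA", "WWWW")
  expect_lte(al$raw_score, 0)
  expect_lte(oracle$raw_score, 0)
  edges <- build_edges(c(a = "AAAA", b = "WWWW"), params_default,
                       prefilter = FALSE)
  expect_equal(nrow(edges), 0L)
})

test_that("bit_score matches the Karlin-Altschul closed form and is monotone", {
  expect_equal(bit_score(49, params_default),
               (0.267 * 49 - log(0.041)) / log(2), tolerance = 1e-12)
  expect_equal(bit_score(49, params_default), 23.48, tolerance = 1e-2)
  expect_equal(bit_score(0, params_default), -log(0.041) / log(2),
               tolerance = 1e-12)
  expect_equal(bit_score(0, params_default), 4.61, tolerance = 1e-2)
  raws <- seq(-10, 120, by = 7)
  expect_true(all(diff(bit_score(raws, params_default)) > 0))
})

test_that("edge criteria: identical pairs pass at L=0.9/S=1.89, unsatisfiable L blocks", {
  seqs <- c(p1 = "ACDEFGHK", p2 = "ACDEFGHK")
  edges <- build_edges(seqs, params_default)
  expect_equal(nrow(edges), 1L)
  expect_equal(edges$density, 23.48 / 8, tolerance = 1e-2)
  expect_gte(edges$density, 1.89)
  none <- build_edges(seqs, scoring_params(L = 1.01))
  expect_equal(nrow(none), 0L)
})

test_that("a shared half-length block fails two-sided coverage at L=0.9", {
  block <- "MKVLAWQHDE"
  s1 <- paste0(block, "PPPPPPPPPP")
  s2 <- paste0(block, "GGSSGGSSGG")
  al <- align_pair(s1, s2, params_default)
  oracle <- sw_oracle(s1, s2)
  expect_equal(al$raw_score, oracle$raw_score)
  expect_lt(oracle$coverage_a, 0.9)
  edges <- build_edges(c(a = s1, b = s2), params_default,
                       prefilter = FALSE)
  expect_equal(nrow(edges), 0L)
})

test_that("single linkage forms components, singletons, and deterministic representatives", {
  cs <- single_linkage(c("a", "b", "c"),
                       data.frame(protein_a = "a", protein_b = "b"))
  expect_equal(cs$clusters, list(c("a", "b"), "c"))
  cs0 <- single_linkage(c("x", "y"), data.frame(protein_a = character(0),
                                                protein_b = character(0)))
  expect_equal(lengths(cs0$clusters), c(1L, 1L))
  # longest member wins, ties lexicographic
  cs1 <- single_linkage(c("b", "a"), data.frame(protein_a = "a",
                                                protein_b = "b"),
                        lengths = c(b = 5, a = 9))
  expect_equal(cs1$representatives, "a")
  cs2 <- single_linkage(c("b", "a"), data.frame(protein_a = "a",
                                                protein_b = "b"),
                        lengths = c(b = 7, a = 7))
  expect_equal(cs2$representatives, "a")
})

test_that("clustering is invariant to permutations and transitively closed", {
  set.seed(42)
  ids <- paste0("p", 1:9)
  edges <- data.frame(protein_a = c("p1", "p2", "p5", "p7"),
                      protein_b = c("p2", "p3", "p6", "p8"))
  ref <- single_linkage(ids, edges)
  for (i in 1:5) {
    perm_ids <- sample(ids)
    perm_edges <- edges[sample(nrow(edges)), ]
    flip <- sample(c(TRUE, FALSE), nrow(perm_edges), replace = TRUE)
    tmp <- perm_edges$protein_a[flip]
    perm_edges$protein_a[flip] <- perm_edges$protein_b[flip]
    perm_edges$protein_b[flip] <- tmp
    got <- single_linkage(perm_ids, perm_edges)
    expect_equal(got$clusters, ref$clusters)
  }
  # transitivity: p1-p2, p2-p3 edges place p1 and p3 together
  m <- ref$membership
  expect_equal(m[["p1"]], m[["p3"]])
  # partition property
  expect_setequal(unlist(ref$clusters), ids)
  expect_equal(anyDuplicated(unlist(ref$clusters)), 0L)
})

test_that("build_edges agrees with the exhaustive DP oracle on short sequences", {
  set.seed(7)
  base <- random_aa(2, 12, seed = 7)
  mut <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    pos <- sample(seq_along(ch), k)
    for (p in pos) ch[p] <- sample(setdiff(c("A","C","D","E","F","G","H",
                                             "I","K","L","M","N","P","Q",
                                             "R","S","T","V","W","Y"),
                                           ch[p]), 1)
    paste(ch, collapse = "")
  }
  seqs <- c(f1a = base[1], f1b = mut(base[1], 1), f1c = mut(base[1], 2),
            f2a = base[2], f2b = mut(base[2], 1),
            r1 = random_aa(1, 10, seed = 101),
            r2 = random_aa(1, 12, seed = 102),
            r3 = random_aa(1, 11, seed = 103))
  got <- build_edges(seqs, params_default, prefilter = FALSE)
  got_pairs <- sort(paste(got$protein_a, got$protein_b))
  exp_pairs <- character(0)
  nm <- names(seqs)
  for (i in seq_along(seqs)) for (j in seq_along(seqs)) {
    if (i >= j) next
    o <- sw_oracle(seqs[[i]], seqs[[j]])
    if (o$raw_score <= 0) next
    dens <- bit_score(o$raw_score, params_default) / o$aligned_columns
    if (o$coverage_a >= 0.9 && o$coverage_b >= 0.9 && dens >= 1.89)
      exp_pairs <- c(exp_pairs, paste(nm[i], nm[j]))
  }
  expect_equal(got_pairs, sort(exp_pairs))
  # raw scores agree with the DP oracle for every aligned pair
  for (r in seq_len(nrow(got))) {
    o <- sw_oracle(seqs[[got$protein_a[r]]], seqs[[got$protein_b[r]]])
    expect_equal(got$raw_score[r], o$raw_score)
  }
})

test_that("identity mode thresholds on percent identity", {
  # internal substitution so the local alignment cannot trim it away
  seqs <- c(a = "MKVLAWQHDE", b = "MKVLAWQHDE", c = "MKVLTWQHDE")
  cs <- cluster_proteins(seqs, scoring_params(identity_mode = TRUE,
                                              S = 95))
  expect_equal(cs$membership[["a"]], cs$membership[["b"]])
  # 90% identity pair fails a 95% identity threshold
  expect_false(cs$membership[["a"]] == cs$membership[["c"]])
})
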