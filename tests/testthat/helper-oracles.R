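# Independent oracles used to validate the package implementations on
# small instances. These are deliberately naive (full DP with traceback,
# exhaustive enumeration) and share no code with the package.

blosum62_matrix <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Full Smith-Waterman affine-gap DP with traceback; returns the best raw
# score, alignment column count and per-sequence coverage. Gap of length
# L costs open + extend * L.
sw_oracle <- function(a, b, mat = blosum62_matrix, open = 11, extend = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)   # best ending in a match at (i, j)
  X <- matrix(NEG, n + 1, m + 1) # gap in b (A aligned to '-')
  Y <- matrix(NEG, n + 1, m + 1) # gap in a
  M[1, ] <- 0; M[, 1] <- 0
  ptr <- array("", dim = c(n + 1, m + 1, 3))
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- mat[A[i - 1], B[j - 1]]
    # "0" (fresh local start) wins ties so traceback terminates cleanly
    cand <- c(0, M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
    k <- which.max(cand)
    M[i, j] <- cand[k] + s
    ptr[i, j, 1] <- c("0", "M", "X", "Y")[k]
    cx <- c(M[i - 1, j] - open - extend, X[i - 1, j] - extend)
    kx <- which.max(cx)
    X[i, j] <- cx[kx]; ptr[i, j, 2] <- c("M", "X")[kx]
    cy <- c(M[i, j - 1] - open - extend, Y[i, j - 1] - extend)
    ky <- which.max(cy)
    Y[i, j] <- cy[ky]; ptr[i, j, 3] <- c("M", "Y")[ky]
  }
  best <- max(M)
  if (best <= 0)
    return(list(raw_score = 0, aligned_columns = 0,
                coverage_a = 0, coverage_b = 0))
  idx <- which(M == best, arr.ind = TRUE)[1, ]
  i <- idx[1]; j <- idx[2]; state <- "M"
  cols <- 0L; used_a <- 0L; used_b <- 0L
  while (i > 1 || j > 1) {
    if (state == "M") {
      prev <- ptr[i, j, 1]
      cols <- cols + 1L; used_a <- used_a + 1L; used_b <- used_b + 1L
      i <- i - 1; j <- j - 1
      if (prev == "0") break
      state <- prev
    } else if (state == "X") {
      prev <- ptr[i, j, 2]
      cols <- cols + 1L; used_a <- used_a + 1L
      i <- i - 1; state <- prev
    } else {
      prev <- ptr[i, j, 3]
      cols <- cols + 1L; used_b <- used_b + 1L
      j <- j - 1; state <- prev
    }
  }
  list(raw_score = as.numeric(best), aligned_columns = cols,
       coverage_a = used_a / n, coverage_b = used_b / m)
}

# Exhaustive-enumeration upper-tail hypergeometric probability: draw k
# organisms from m positives and n negatives, count draws with >= q
# positives, by direct combinatorial summation.
hyper_upper_oracle <- function(q, m, n, k) {
  total <- choose(m + n, k)
  hi <- min(m, k)
  if (q > hi) return(0)
  sum(vapply(q:hi, function(i) choose(m, i) * choose(n, k - i),
             numeric(1L))) / total
}

# Exact two-sided rank-sum p by enumeration of all assignments of the
# pooled ranks to group a (no ties assumed).
rank_sum_oracle <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  W_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combs <- utils::combn(length(pooled), na)
  Ws <- apply(combs, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  mu <- na * length(b) / 2
  mean(abs(Ws - mu) >= abs(W_obs - mu) - 1e-9)
}

# Exhaustive max-score non-overlapping hit selection (pairwise overlap
# <= tol), for validating resolve_hits on <= 5 hits.
resolve_oracle <- function(hits, tol = 10) {
  n <- nrow(hits)
  best_score <- -Inf; best <- integer(0)
  ov <- function(i, j)
    max(0L, min(hits$ali_end[i], hits$ali_end[j]) -
          max(hits$ali_start[i], hits$ali_start[j]) + 1L)
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    okpair <- TRUE
    if (length(sel) > 1)
      for (i in seq_along(sel)) for (j in seq_along(sel))
        if (i < j && ov(sel[i], sel[j]) > tol) okpair <- FALSE
    if (!okpair) next
    sc <- sum(hits$score[sel])
    if (sc > best_score + 1e-9) { best_score <- sc; best <- sel }
  }
  sort(hits$domain[best[order(hits$ali_start[best])]])
}

random_aa <- function(n, len, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N",
                   "P","Q","R","S","T","V","W","Y"),
                 len, replace = TRUE), collapse = ""), character(1L))
}

# small 3-phylum gene set with one planted VMAP-like run per genome,
# built directly (not via the generator) for unit tests
toy_templates <- function() read_templates()
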