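# Score-density single-linkage clustering of proteins, in the style of
# BLASTCLUST: an edge between two proteins requires (1) the local alignment
# to cover at least a fraction L of BOTH sequences and (2) the alignment's
# bit score per aligned column to reach the score-density threshold S.
# Connected components of the edge graph are the clusters.

.cs_env <- new.env(parent = emptyenv())

get_submat <- function(name) {
  key <- paste0("mat_", name)
  if (is.null(.cs_env[[key]])) {
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    .cs_env[[key]] <- get(name, envir = e)
  }
  .cs_env[[key]]
}

#' Scoring and clustering parameters
#'
#' Defaults follow gapped BLOSUM62 scoring with gap open 11 / extend 1, the
#' matching Karlin-Altschul parameters (lambda = 0.267, K = 0.041), and the
#' near-identity culling thresholds L = 0.9 (length coverage, both
#' sequences) and S = 1.89 (bits per aligned column). L and S are the knobs
#' practitioners adjust per use: high values cull near-identical sequences,
#' lower values group homologs for classification.
#'
#' @param matrix Substitution matrix name (a Biostrings data matrix).
#' @param gap_open,gap_extend Affine gap penalties (positive).
#' @param lambda,K Karlin-Altschul parameters for the raw-to-bit conversion.
#' @param L Coverage threshold fraction in (0, 1].
#' @param S Score-density threshold: bits per aligned column, or percent
#'   identity when `identity_mode` is TRUE.
#' @param identity_mode If TRUE, density is percent identity over aligned
#'   columns instead of bits per column.
#' @return Object of class `scoring_params`.
#' @export
scoring_params <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                           lambda = 0.267, K = 0.041,
                           L = 0.9, S = 1.89, identity_mode = FALSE) {
  # L > 1 is allowed as a deliberately unsatisfiable threshold
  stopifnot(L > 0, S > 0, gap_open > 0, gap_extend > 0, lambda > 0, K > 0)
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K,
                 L = L, S = S, identity_mode = isTRUE(identity_mode)),
            class = "scoring_params")
}

check_alphabet <- function(seq) {
  bad <- setdiff(strsplit(seq, "")[[1]], c(AA20, "X"))
  if (length(bad))
    stop("residue(s) outside the amino-acid alphabet: ",
         paste(unique(bad), collapse = ""))
  invisible(TRUE)
}

#' Best local alignment of two protein sequences
#'
#' Smith-Waterman local alignment under affine gap penalties (via
#' [Biostrings::pairwiseAlignment()]), returning the quantities the edge
#' criteria need: the raw score, the number of aligned columns (gap columns
#' included), and the coverage of each sequence (aligned residues divided
#' by sequence length).
#'
#' @param seq_a,seq_b Protein sequences (character scalars).
#' @param params A [scoring_params()] object.
#' @return List with `raw_score`, `aligned_columns`, `coverage_a`,
#'   `coverage_b`, `n_identical`.
#' @export
align_pair <- function(seq_a, seq_b, params = scoring_params()) {
  stopifnot(nchar(seq_a) >= 1, nchar(seq_b) >= 1)
  check_alphabet(seq_a); check_alphabet(seq_b)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "local", substitutionMatrix = get_submat(params$matrix),
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  pa <- as.character(Biostrings::pattern(aln))
  pb <- as.character(Biostrings::subject(aln))
  cols <- nchar(pa)
  # aligned residues of a sequence = alignment columns minus its gap columns
  cov_a <- (cols - lengths(regmatches(pa, gregexpr("-", pa)))) / nchar(seq_a)
  cov_b <- (cols - lengths(regmatches(pb, gregexpr("-", pb)))) / nchar(seq_b)
  nid <- sum(strsplit(pa, "")[[1]] == strsplit(pb, "")[[1]] &
               strsplit(pa, "")[[1]] != "-")
  list(raw_score = as.numeric(Biostrings::score(aln)),
       aligned_columns = cols,
       coverage_a = as.numeric(cov_a), coverage_b = as.numeric(cov_b),
       n_identical = nid)
}

#' Convert a raw alignment score to bits
#'
#' Standard Karlin-Altschul normalization: `(lambda * raw - ln K) / ln 2`.
#'
#' @param raw_score Raw score in substitution-matrix units.
#' @param params A [scoring_params()] object supplying lambda and K.
#' @return Bit score.
#' @export
bit_score <- function(raw_score, params = scoring_params()) {
  (params$lambda * raw_score - log(params$K)) / log(2)
}

#' Build similarity edges between proteins
#'
#' Emits an edge for an unordered pair iff both coverages reach `L` and the
#' score density reaches `S`. Pairs whose best local score is non-positive
#' never form an edge. A length-ratio prefilter (shorter/longer >= L) skips
#' pairs that could not plausibly satisfy two-sided coverage; it is a speed
#' heuristic and can be disabled.
#'
#' @param seqs Named character vector of protein sequences.
#' @param params A [scoring_params()] object.
#' @param prefilter Apply the length-ratio prefilter (default TRUE).
#' @return data.frame with one row per edge: `protein_a`, `protein_b`,
#'   `raw_score`, `bit_score`, `density`, `coverage_a`, `coverage_b`.
#' @export
build_edges <- function(seqs, params = scoring_params(), prefilter = TRUE) {
  stopifnot(length(seqs) >= 2, !is.null(names(seqs)))
  ids <- names(seqs)
  lens <- nchar(seqs)
  out <- list()
  n <- length(seqs)
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    if (prefilter) {
      ratio <- pmin(lens[i], lens[js]) / pmax(lens[i], lens[js])
      js <- js[ratio >= params$L]
    }
    if (!length(js)) next
    for (j in js) {
      al <- align_pair(seqs[[i]], seqs[[j]], params)
      if (al$raw_score <= 0) next
      if (al$coverage_a < params$L || al$coverage_b < params$L) next
      bits <- bit_score(al$raw_score, params)
      density <- if (params$identity_mode)
        100 * al$n_identical / al$aligned_columns
      else bits / al$aligned_columns
      if (density < params$S) next
      out[[length(out) + 1L]] <- data.frame(
        protein_a = ids[i], protein_b = ids[j],
        raw_score = al$raw_score, bit_score = bits, density = density,
        coverage_a = al$coverage_a, coverage_b = al$coverage_b,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(protein_a = character(0), protein_b = character(0),
                      raw_score = numeric(0), bit_score = numeric(0),
                      density = numeric(0), coverage_a = numeric(0),
                      coverage_b = numeric(0)))
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Single-linkage clustering from similarity edges
#'
#' Clusters are the connected components of the edge graph; ids without any
#' edge become singletons. The representative of a cluster is its longest
#' member (ties broken by lexicographically smallest id), or the
#' lexicographically smallest id when no lengths are supplied.
#'
#' @param ids Character vector of all member ids.
#' @param edges data.frame with columns `protein_a`, `protein_b` (extra
#'   columns ignored), endpoints all in `ids`.
#' @param lengths Optional named vector of sequence lengths for
#'   representative selection.
#' @return Object of class `cluster_set`: list with `clusters` (list of
#'   sorted member vectors), `representatives`, and `membership` (named
#'   integer vector id -> cluster index).
#' @export
single_linkage <- function(ids, edges, lengths = NULL) {
  ids <- sort(unique(as.character(ids)))
  if (nrow(edges)) {
    stray <- setdiff(c(edges$protein_a, edges$protein_b), ids)
    if (length(stray))
      stop("edge endpoints not in ids: ", paste(stray, collapse = ", "))
    g <- igraph::graph_from_data_frame(
      edges[, c("protein_a", "protein_b")], directed = FALSE,
      vertices = data.frame(name = ids))
    comp <- igraph::components(g)$membership[ids]
  } else {
    comp <- setNames(seq_along(ids), ids)
  }
  clusters <- lapply(split(ids, comp), sort)
  reps <- vapply(clusters, function(members) {
    if (!is.null(lengths)) {
      ln <- lengths[members]
      members <- members[ln == max(ln)]
    }
    sort(members)[1]
  }, character(1L))
  ord <- order(reps)
  clusters <- unname(clusters[ord])
  reps <- unname(reps[ord])
  membership <- setNames(rep(seq_along(clusters), lengths(clusters)),
                         unlist(clusters))
  structure(list(clusters = clusters, representatives = reps,
                 membership = membership[ids]),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("<cluster_set> ", length(x$clusters), " clusters over ",
      length(x$membership), " ids\n", sep = "")
  invisible(x)
}

#' Cluster proteins by coverage and score density
#'
#' Convenience wrapper: [build_edges()] followed by [single_linkage()].
#'
#' @inheritParams build_edges
#' @return A `cluster_set`.
#' @export
cluster_proteins <- function(seqs, params = scoring_params(),
                             prefilter = TRUE) {
  if (length(seqs) < 2)
    return(single_linkage(names(seqs),
                          data.frame(protein_a = character(0),
                                     protein_b = character(0)),
                          lengths = nchar(seqs)))
  edges <- build_edges(seqs, params, prefilter = prefilter)
  single_linkage(names(seqs), edges, lengths = nchar(seqs))
}

#' Write a cluster set as TSV
#' @param x A `cluster_set`.
#' @param path Output path.
#' @export
write_clusters <- function(x, path) {
  df <- data.frame(
    cluster_id = paste0("C", rep(seq_along(x$clusters),
                                 lengths(x$clusters))),
    representative = rep(x$representatives, lengths(x$clusters)),
    member = unlist(x$clusters), stringsAsFactors = FALSE)
  write_tsv(df, path)
}
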