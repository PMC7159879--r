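# Domain architectures: resolving overlapping domain hits into an ordered
# N->C architecture string per protein, the adjacency network over
# architectures, and the co-occurrence / paralog-distinctness / effector-
# associated-domain coupling statistics.

#' Resolve one protein's domain hits into an architecture
#'
#' Selects the subset of hits maximizing total bit score subject to every
#' kept pair overlapping by at most `overlap_tolerance` residues, then
#' orders the kept hits N to C by alignment start. Selection is exact
#' (exhaustive over subsets) up to 15 hits; beyond that a greedy
#' descending-score scan is used. Score ties are broken in favour of the
#' selection with more hits, then the earlier alignment starts.
#'
#' @param hits data.frame of hits for a single protein (columns `domain`,
#'   `ali_start`, `ali_end`, `score`).
#' @param overlap_tolerance Maximum pairwise overlap (residues, default 10).
#' @return Character vector of domain labels, N to C, with the kept hits as
#'   attribute `"hits"`.
#' @export
resolve_hits <- function(hits, overlap_tolerance = 10) {
  hits <- as.data.frame(hits)
  if (!nrow(hits)) return(character(0))
  if ("protein_id" %in% names(hits) &&
      length(unique(hits$protein_id)) > 1L)
    stop("resolve_hits expects hits for a single protein")
  n <- nrow(hits)
  ov <- function(i, j)
    max(0L, min(hits$ali_end[i], hits$ali_end[j]) -
          max(hits$ali_start[i], hits$ali_start[j]) + 1L)
  compat <- matrix(TRUE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    compat[i, j] <- ov(i, j) <= overlap_tolerance
  keep <- if (n <= 15L) {
    best <- NULL; best_key <- NULL
    for (mask in 0:(2^n - 1)) {
      sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
      if (length(sel) > 1L &&
          !all(compat[sel, sel][upper.tri(diag(length(sel)))])) next
      key <- c(sum(hits$score[sel]), length(sel))
      if (is.null(best) ||
          key[1] > best_key[1] + 1e-9 ||
          (abs(key[1] - best_key[1]) <= 1e-9 &&
             (key[2] > best_key[2] ||
                (key[2] == best_key[2] &&
                   earlier_starts(hits$ali_start[sel],
                                  hits$ali_start[best]))))) {
        best <- sel; best_key <- key
      }
    }
    best
  } else {
    ord <- order(-hits$score, hits$ali_start, hits$ali_end)
    sel <- integer(0)
    for (i in ord)
      if (all(compat[i, sel])) sel <- c(sel, i)
    sel
  }
  keep <- keep[order(hits$ali_start[keep], hits$ali_end[keep])]
  out <- as.character(hits$domain[keep])
  attr(out, "hits") <- hits[keep, , drop = FALSE]
  out
}

earlier_starts <- function(a, b) {
  a <- sort(a); b <- sort(b)
  k <- min(length(a), length(b))
  for (i in seq_len(k)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' Resolve architectures for all proteins
#'
#' @param hits data.frame of domain hits (from [read_domain_hits()]).
#' @param overlap_tolerance Passed to [resolve_hits()].
#' @return Named list: protein_id -> character vector of N-to-C domains.
#' @export
build_architectures <- function(hits, overlap_tolerance = 10) {
  if (!nrow(hits)) return(list())
  lapply(split(hits, hits$protein_id), resolve_hits,
         overlap_tolerance = overlap_tolerance)
}

#' Build the domain-adjacency network over architectures
#'
#' Nodes are domains with their occurrence counts (a domain repeated within
#' one protein counts once per repeat); a directed edge (d_i, d_j) counts
#' the proteins positions where d_j immediately follows d_i (N to C).
#' Edges are classed by two absolute thresholds (defaults 14 and 148,
#' calibrated on a ~1500-system dataset; scale for smaller data).
#'
#' @param architectures Named list of domain vectors (see
#'   [build_architectures()]).
#' @param thresholds Two increasing edge-count thresholds.
#' @return List with `nodes` (named counts), `edges` (data.frame `from`,
#'   `to`, `count`, `class`), and `thresholds`.
#' @export
build_network <- function(architectures, thresholds = c(14, 148)) {
  stopifnot(length(architectures) >= 1, length(thresholds) == 2,
            thresholds[1] <= thresholds[2])
  all_dom <- unlist(architectures, use.names = FALSE)
  nodes <- table(all_dom)
  nodes <- setNames(as.integer(nodes), names(nodes))
  pair_list <- lapply(architectures, function(a) {
    if (length(a) < 2L) return(NULL)
    data.frame(from = a[-length(a)], to = a[-1], stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, pair_list)
  if (is.null(pairs) || !nrow(pairs)) {
    edges <- data.frame(from = character(0), to = character(0),
                        count = integer(0), class = character(0))
  } else {
    tab <- stats::aggregate(list(count = rep(1L, nrow(pairs))),
                            by = pairs[c("from", "to")], FUN = sum)
    tab <- tab[order(tab$from, tab$to), , drop = FALSE]
    tab$class <- ifelse(tab$count > thresholds[2], "high",
                        ifelse(tab$count > thresholds[1], "mid", "low"))
    rownames(tab) <- NULL
    edges <- tab
  }
  list(nodes = nodes, edges = edges, thresholds = thresholds)
}

split_multi <- function(x, sep = ";") {
  if (is.list(x)) return(lapply(x, as.character))
  x <- as.character(x)
  if (!length(x)) return(list())
  lapply(strsplit(ifelse(is.na(x) | x == "", "", x), sep, fixed = TRUE),
         function(v) v[nzchar(v)])
}

#' Distribution of effector-domain counts per system instance
#'
#' @param instances data.frame of system instances (an `effectors` column,
#'   semicolon-joined or a list column).
#' @return List with `counts` (per instance), `histogram` (table),
#'   `mean`, `median` (both `NA` when there are no instances).
#' @export
effector_count_distribution <- function(instances) {
  eff <- split_multi(instances$effectors)
  counts <- lengths(eff)
  if (!length(counts))
    return(list(counts = integer(0), histogram = table(integer(0)),
                mean = NA_real_, median = NA_real_))
  list(counts = counts, histogram = table(counts),
       mean = mean(counts), median = median(counts))
}

#' Overlap and mutual-exclusivity statistics for two organism sets
#'
#' Reports the 2x2 presence table, the Jaccard overlap, and the two
#' hypergeometric tails on the co-occurrence count: the lower tail
#' (depletion; small when the sets are more mutually exclusive than
#' expected for their sizes) and the upper tail (enrichment).
#'
#' @param presence_a,presence_b Character vectors of organism ids.
#' @param universe Character vector containing both sets.
#' @return List with the contingency cells, `jaccard`, fractional overlaps,
#'   `p_depletion`, `p_enrichment`.
#' @export
overlap_and_exclusivity <- function(presence_a, presence_b, universe) {
  presence_a <- unique(presence_a); presence_b <- unique(presence_b)
  universe <- unique(universe)
  stopifnot(all(presence_a %in% universe), all(presence_b %in% universe))
  n_both <- length(intersect(presence_a, presence_b))
  n_a_only <- length(setdiff(presence_a, presence_b))
  n_b_only <- length(setdiff(presence_b, presence_a))
  n_neither <- length(universe) - n_both - n_a_only - n_b_only
  uni_size <- length(union(presence_a, presence_b))
  jac <- if (uni_size == 0) NA_real_ else n_both / uni_size
  mA <- length(presence_a)
  p_dep <- phyper(n_both, mA, length(universe) - mA, length(presence_b))
  p_enr <- phyper(n_both - 1, mA, length(universe) - mA, length(presence_b),
                  lower.tail = FALSE)
  list(n_both = n_both, n_a_only = n_a_only, n_b_only = n_b_only,
       n_neither = n_neither, jaccard = jac,
       frac_of_union = jac,
       frac_of_a = if (mA) n_both / mA else NA_real_,
       frac_of_b = if (length(presence_b)) n_both / length(presence_b)
                   else NA_real_,
       p_depletion = p_dep, p_enrichment = p_enr)
}

#' Paralogous-system distinctness per organism
#'
#' For one system type: the fraction of system-bearing organisms coding two
#' or more instances (the multi-system fraction), and among those, the
#' fraction in which every pair of instances carries a different effector
#' complement (distinctness).
#'
#' @param instances data.frame of system instances (`genome_id`,
#'   `system_type`, `effectors`).
#' @param system_type Restrict to one type (default: all rows).
#' @return List with `multi_system_fraction`, `distinct_fraction`,
#'   `per_organism` table.
#' @export
paralog_distinctness <- function(instances, system_type = NULL) {
  if (!is.null(system_type))
    instances <- instances[instances$system_type == system_type, ,
                           drop = FALSE]
  eff <- split_multi(instances$effectors)
  eff_key <- vapply(eff, function(v) paste(sort(v), collapse = "|"),
                    character(1L))
  by_org <- split(eff_key, instances$genome_id)
  n_org <- length(by_org)
  multi <- vapply(by_org, function(k) length(k) >= 2L, logical(1L))
  per_org <- data.frame(
    genome_id = names(by_org),
    n_instances = lengths(by_org),
    all_distinct = vapply(by_org, function(k)
      length(k) < 2L || !anyDuplicated(k), logical(1L)),
    stringsAsFactors = FALSE)
  rownames(per_org) <- NULL
  list(
    multi_system_fraction = if (n_org) mean(multi) else NA_real_,
    distinct_fraction = if (any(multi))
      mean(per_org$all_distinct[multi]) else NA_real_,
    per_organism = per_org)
}

#' Effector-associated domain (EAD) coupling
#'
#' EADs are small adaptor domains predicted to couple effectors to the core
#' machinery through homotypic pairing: one copy fused to a core component
#' of the system, another copy on a separate protein fused to an effector
#' or signaling domain. For each EAD family this reports, per genome with
#' systems, whether the EAD appears on a core-component protein, whether a
#' second non-core protein in the same genome carries the same EAD fused to
#' another domain, the coupling rate among genomes with a core-fused copy,
#' and an upper-tail hypergeometric p-value for the co-presence of the two
#' flags across genomes.
#'
#' @param architectures Named list protein_id -> domain vector.
#' @param instances data.frame of system instances with a `components`
#'   column (role=gene_id pairs, semicolon-joined) or a `component_proteins`
#'   column.
#' @param protein_genome Named character vector protein_id -> genome_id.
#' @param ead_labels Character vector of EAD family labels.
#' @return data.frame, one row per EAD family.
#' @export
ead_coupling <- function(architectures, instances, protein_genome,
                         ead_labels) {
  core_prot <- unique(unlist(lapply(
    split_multi(if ("component_proteins" %in% names(instances))
      instances$component_proteins else instances$components),
    function(v) sub("^.*=", "", v))))
  genomes <- sort(unique(protein_genome[names(architectures)]))
  sys_genomes <- sort(unique(instances$genome_id))
  rows <- lapply(ead_labels, function(ead) {
    carrier <- names(architectures)[vapply(architectures, function(a)
      ead %in% a, logical(1L))]
    core_fused <- carrier[carrier %in% core_prot]
    noncore <- setdiff(carrier, core_prot)
    aux <- noncore[vapply(architectures[noncore], function(a)
      length(setdiff(unique(a), ead)) >= 1L, logical(1L))]
    g_core <- unique(protein_genome[core_fused])
    g_aux <- unique(protein_genome[aux])
    both <- intersect(g_core, g_aux)
    u <- length(sys_genomes)
    p <- if (length(g_core) && length(g_aux))
      phyper(length(intersect(both, sys_genomes)) - 1,
             length(intersect(g_core, sys_genomes)),
             u - length(intersect(g_core, sys_genomes)),
             length(intersect(g_aux, sys_genomes)),
             lower.tail = FALSE)
    else NA_real_
    data.frame(ead = ead,
               n_genomes_core_fused = length(g_core),
               n_genomes_aux_fused = length(g_aux),
               n_genomes_coupled = length(both),
               coupling_rate = if (length(g_core))
                 length(both) / length(g_core) else NA_real_,
               p_copresence = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
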