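# Gene-neighborhood extraction and template-based system classification.
#
# The detection procedure anchors on a gene whose protein carries the
# template's anchor domain, extracts its genomic neighborhood, and accepts
# a system when an ordered run of consecutive genes carries the template's
# required component domains in order (read 5'->3' on the coding strand),
# subject to three conservation filters: (1) consecutive intergenic gaps
# within the run at most max_gap nucleotides (default 70), (2) uniform
# gene directionality within the run, and (3) the run's cluster-level
# signature present in more than one phylum.

#' Intergenic gap between two genes on the same replicon
#'
#' The number of nucleotides strictly between the two gene spans
#' (`b$start - a$end - 1`), floored at 0 for adjacent or overlapping genes.
#'
#' @param gene_a,gene_b Gene rows (list or 1-row data.frame with
#'   `replicon_id`, `start`, `end`); `gene_a` must not start after
#'   `gene_b`.
#' @return Non-negative integer gap in nucleotides.
#' @export
intergenic_gap <- function(gene_a, gene_b) {
  if (gene_a$replicon_id != gene_b$replicon_id)
    stop("genes lie on different replicons")
  if (gene_a$start > gene_b$start)
    stop("gene_a must start at or before gene_b")
  max(0L, as.integer(gene_b$start) - as.integer(gene_a$end) - 1L)
}

#' Extract the gene neighborhood around an anchor gene
#'
#' Up to `window` genes on each side of the anchor, on the anchor's
#' replicon, in genomic order, truncated at replicon ends.
#'
#' @param genome A [genome_record()].
#' @param anchor_gene_id Gene id of the anchor.
#' @param window Genes per side (default 5).
#' @return Object of class `neighborhood`: list with `anchor` (row),
#'   `members` (data.frame), `gaps` (length `nrow(members) - 1`),
#'   `genome_id`, `replicon_id`, `phylum`.
#' @export
extract_neighborhood <- function(genome, anchor_gene_id, window = 5) {
  stopifnot(window >= 0)
  g <- genome$genes
  i <- which(g$gene_id == anchor_gene_id)
  if (!length(i)) stop("anchor gene not found: ", anchor_gene_id)
  i <- i[1]
  rep_id <- g$replicon_id[i]
  on_rep <- which(g$replicon_id == rep_id)
  pos <- match(i, on_rep)
  lo <- max(1L, pos - window); hi <- min(length(on_rep), pos + window)
  members <- g[on_rep[lo:hi], , drop = FALSE]
  rownames(members) <- NULL
  gaps <- if (nrow(members) > 1L)
    vapply(seq_len(nrow(members) - 1L), function(j)
      intergenic_gap(members[j, ], members[j + 1L, ]), integer(1L))
  else integer(0)
  structure(list(anchor = g[i, , drop = FALSE], members = members,
                 gaps = gaps, genome_id = genome$genome_id,
                 replicon_id = rep_id, phylum = genome$phylum),
            class = "neighborhood")
}

#' Read system templates from a JSON config
#'
#' Ships with eight built-in gene-order grammars covering the MoxR/vWA
#' ternary systems (VMAP, iSTAND, FtsH, beta-propeller fusion), the
#' GTPase-centric systems (GAP1-N1, GAP1-N2), and the peptidase-coupled
#' systems (NucA + trypsin, EACC1 + caspase partner). Users can point to
#' their own JSON to extend the grammar set without code changes.
#'
#' @param path JSON path; defaults to the shipped template file.
#' @return Named list of template lists (`name`, `required`, `optional`,
#'   `anchor`, `effector_host`, `core_domain`, `max_gap`, `same_strand`,
#'   `strict_order`).
#' @export
read_templates <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "templates.json",
                        package = "conflictscan")
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  tpls <- lapply(cfg$templates, function(t) {
    t$required <- as.character(t$required)
    t$optional <- as.character(t$optional %||% character(0))
    if (!length(t$required)) stop("template ", t$name, ": empty required set")
    if (is.null(t$max_gap)) t$max_gap <- 70
    if (t$max_gap < 0) stop("template ", t$name, ": negative max_gap")
    if (is.null(t$same_strand)) t$same_strand <- TRUE
    if (is.null(t$strict_order)) t$strict_order <- TRUE
    if (is.null(t$anchor)) t$anchor <- t$required[length(t$required)]
    if (is.null(t$effector_host)) t$effector_host <- t$anchor
    if (is.null(t$core_domain)) t$core_domain <- t$effector_host
    t
  })
  setNames(tpls, vapply(tpls, `[[`, "", "name"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# how many leading labels of `required` does this architecture carry, in
# N->C order (a fused protein covers several consecutive components)
consume_required <- function(arch, required) {
  k <- 0L
  pos <- 0L
  for (r in required) {
    hit <- which(arch == r)
    hit <- hit[hit > pos]
    if (!length(hit)) break
    pos <- hit[1]
    k <- k + 1L
  }
  k
}

#' Match a system template against a neighborhood
#'
#' Searches the neighborhood for an ordered run of consecutive genes
#' carrying the template's required component domains in template order,
#' read 5' to 3' on the coding strand (for a minus-strand run the genomic
#' order is reversed before matching). A single protein carrying several
#' consecutive required domains in N->C order satisfies all of those roles
#' (fused components). All consecutive gaps within the run must be at most
#' `max_gap`, and with `same_strand` all run members must share one
#' strand. Genes carrying optional component domains are absorbed into the
#' run greedily. Effectors are the domains C-terminal to the core domain
#' on the designated effector-host protein.
#'
#' @param nbhd A [extract_neighborhood()] result.
#' @param architectures Named list protein_id -> N-to-C domain vector.
#' @param template One template from [read_templates()].
#' @param max_gap,same_strand Overrides of the template settings (used to
#'   relax individual filters).
#' @param require_anchor Only accept runs whose anchor role maps to the
#'   neighborhood's own anchor gene (default TRUE); prevents a
#'   neighboring system elsewhere in the window from being reported for
#'   this anchor.
#' @return A system-instance list, or `NULL` when nothing matches.
#' @export
match_template <- function(nbhd, architectures, template,
                           max_gap = NULL, same_strand = NULL,
                           require_anchor = TRUE) {
  max_gap <- max_gap %||% template$max_gap
  same_strand <- same_strand %||% template$same_strand
  members <- nbhd$members
  n <- nrow(members)
  if (!n) return(NULL)
  anchor_strand <- nbhd$anchor$strand
  ord <- if (anchor_strand == "-") rev(seq_len(n)) else seq_len(n)
  # gap_after[k]: intergenic gap between coding-order member k and k+1
  arch_of <- function(pid) architectures[[pid]] %||% character(0)
  req <- template$required
  best <- NULL
  for (s in seq_len(n)) {
    r <- 1L
    optcount <- 0L
    run_idx <- integer(0)       # coding-order positions
    roles <- list()
    run_strand <- members$strand[ord[s]]
    for (k in s:n) {
      gi <- ord[k]
      if (length(run_idx)) {
        prev <- ord[k - 1L]
        lo <- min(prev, gi); hi <- max(prev, gi)
        gap <- intergenic_gap(members[lo, ], members[hi, ])
        if (gap > max_gap) break
      }
      if (same_strand && members$strand[gi] != run_strand) break
      a <- arch_of(members$protein_id[gi])
      took <- consume_required(a, req[r:length(req)])
      if (r <= length(req) && took > 0L) {
        for (t in seq_len(took))
          roles[[req[r + t - 1L]]] <- members$gene_id[gi]
        r <- r + took
        run_idx <- c(run_idx, k)
      } else if (length(intersect(a, template$optional))) {
        optcount <- optcount + 1L
        run_idx <- c(run_idx, k)
      } else if (r <= length(req)) {
        break
      } else {
        break
      }
      if (r > length(req)) {
        # required all matched; greedily absorb trailing optional genes
        kk <- k + 1L
        while (kk <= n) {
          gi2 <- ord[kk]; prev <- ord[kk - 1L]
          lo <- min(prev, gi2); hi <- max(prev, gi2)
          if (intergenic_gap(members[lo, ], members[hi, ]) > max_gap) break
          if (same_strand && members$strand[gi2] != run_strand) break
          a2 <- arch_of(members$protein_id[gi2])
          if (!length(intersect(a2, template$optional))) break
          optcount <- optcount + 1L
          run_idx <- c(run_idx, kk)
          kk <- kk + 1L
        }
        cand <- finalize_instance(nbhd, members, ord, run_idx, roles,
                                  optcount, template, architectures)
        if (!is.null(cand) && require_anchor &&
            cand$anchor_gene_id != nbhd$anchor$gene_id)
          cand <- NULL
        if (!is.null(cand) &&
            (is.null(best) || cand$n_optional > best$n_optional ||
               (cand$n_optional == best$n_optional &&
                  cand$run_start < best$run_start)))
          best <- cand
        break
      }
    }
  }
  best
}

finalize_instance <- function(nbhd, members, ord, run_idx, roles,
                              optcount, template, architectures) {
  gi <- ord[run_idx]
  run <- members[gi, , drop = FALSE]
  # keep the run in genomic order; orientation is re-derived from the
  # anchor strand wherever coding order matters (e.g. signatures)
  run <- run[order(run$start), , drop = FALSE]
  rownames(run) <- NULL
  anchor_gene <- roles[[template$anchor]]
  if (is.null(anchor_gene)) return(NULL)
  ag <- members[members$gene_id == anchor_gene, , drop = FALSE]
  host_gene <- roles[[template$effector_host]]
  hg <- members[members$gene_id == host_gene, , drop = FALSE]
  host_arch <- architectures[[hg$protein_id[1]]] %||% character(0)
  core_pos <- which(host_arch == template$core_domain)
  effectors <- if (length(core_pos) && core_pos[1] < length(host_arch))
    host_arch[(core_pos[1] + 1L):length(host_arch)]
  else character(0)
  anchor_stop <- if (ag$strand[1] == "+") ag$end[1] else ag$start[1]
  list(system_type = template$name,
       genome_id = nbhd$genome_id,
       replicon_id = nbhd$replicon_id,
       phylum = nbhd$phylum,
       component_genes = roles,
       run = run,
       n_optional = optcount,
       effectors = effectors,
       anchor_gene_id = ag$gene_id[1],
       anchor_protein_id = ag$protein_id[1],
       anchor_stop = as.integer(anchor_stop),
       strand = run$strand[1],
       run_start = min(run$start),
       run_end = max(run$end))
}

#' Signature of a candidate neighborhood
#'
#' The ordered tuple of member protein-cluster ids (in coding-strand
#' order) together with the members' strand pattern relative to the first
#' member. The anchor gene is excluded by default: conservation is judged
#' on the context genes around the (given) anchor, so that effector
#' variability on the anchor protein does not mask a conserved context.
#'
#' @param members data.frame of run members in genomic order (columns
#'   `protein_id`, `strand`, `gene_id`).
#' @param cluster_map Named vector protein_id -> cluster id.
#' @param anchor_protein Protein id to exclude (or `NULL` to keep all).
#' @return Signature string.
#' @export
neighborhood_signature <- function(members, cluster_map,
                                   anchor_protein = NULL) {
  ref_strand <- if (!is.null(anchor_protein) &&
                    anchor_protein %in% members$protein_id)
    members$strand[match(anchor_protein, members$protein_id)]
  else members$strand[1]
  ord <- seq_len(nrow(members))
  if (identical(ref_strand, "-")) ord <- rev(ord)
  m <- members[ord, , drop = FALSE]
  rel <- ifelse(m$strand == ref_strand, "s", "o")
  keep <- if (is.null(anchor_protein)) rep(TRUE, nrow(m))
  else m$protein_id != anchor_protein
  pid <- m$protein_id[keep]
  if (any(!pid %in% names(cluster_map)))
    stop("missing cluster assignment for protein(s): ",
         paste(setdiff(pid, names(cluster_map)), collapse = ", "))
  paste(paste(cluster_map[pid], collapse = ","),
        paste(rel[keep], collapse = ""), sep = "|")
}

#' Multi-phylum conservation filter
#'
#' Retains a candidate iff its signature occurs in genomes from at least
#' `min_phyla` distinct phyla. The decision is independent of candidate
#' input order.
#'
#' @param candidates List of candidates, each a list with `members`
#'   (data.frame with `protein_id`, `strand`) and `phylum`; optionally
#'   `anchor_protein`.
#' @param cluster_map Named vector protein_id -> cluster id.
#' @param min_phyla Minimum number of distinct phyla (default 2).
#' @return Logical vector of retention decisions.
#' @export
conserved_neighborhood_filter <- function(candidates, cluster_map,
                                          min_phyla = 2) {
  if (!length(candidates)) return(logical(0))
  sigs <- vapply(candidates, function(cand)
    neighborhood_signature(cand$members, cluster_map,
                           cand$anchor_protein %||% NULL),
    character(1L))
  phyla <- vapply(candidates, function(cand)
    as.character(cand$phylum %||% NA_character_), character(1L))
  n_phyla <- vapply(split(phyla, sigs), function(p)
    length(unique(p[!is.na(p)])), integer(1L))
  unname(n_phyla[sigs] >= min_phyla)
}

#' Scan genomes for conflict-system instances
#'
#' End-to-end detection: per template, anchor genes are located by their
#' protein's anchor domain, neighborhoods extracted, gene-order templates
#' matched, and the multi-phylum conservation filter applied to the
#' cluster-level signatures of the matched runs. Overlapping instances of
#' the same template in a genome are deduplicated (most matched optional
#' components wins; ties go to the leftmost genomic instance).
#'
#' @param genomes Named list of [genome_record()]s (phyla filled in).
#' @param hits Domain-hit data.frame.
#' @param templates Template list from [read_templates()].
#' @param proteins Named character vector of protein sequences (needed to
#'   compute `cluster_map` when not supplied).
#' @param cluster_map Optional precomputed named vector
#'   protein_id -> cluster id for run member proteins.
#' @param window Genes per side for neighborhood extraction.
#' @param max_gap,same_strand Filter overrides (NULL = template values).
#' @param min_phyla Phylum threshold for the conservation filter.
#' @param cluster_params [scoring_params()] used when clustering run
#'   proteins internally. The default is a classification setting
#'   (L = 0.6, S = 0.8 bits/column) rather than the near-identity
#'   culling setting (L = 0.9, S = 1.89): conserved neighbors from
#'   different phyla are homologous, not near-identical, and the
#'   culling thresholds sit at the margin of typical within-family
#'   score densities.
#' @return data.frame of system instances: one row per instance with
#'   semicolon-joined `components` (role=gene_id) and `effectors`, plus
#'   anchor position fields used by the positional statistics.
#' @export
scan_genomes <- function(genomes, hits, templates = read_templates(),
                         proteins = NULL, cluster_map = NULL,
                         window = 5, max_gap = NULL, same_strand = NULL,
                         min_phyla = 2,
                         cluster_params = scoring_params(L = 0.6,
                                                         S = 0.8)) {
  architectures <- build_architectures(hits)
  candidates <- list()
  for (tpl in templates) {
    anchor_dom <- tpl$anchor
    for (g in genomes) {
      if (!nrow(g$genes)) next
      has_anchor <- vapply(g$genes$protein_id, function(p)
        anchor_dom %in% (architectures[[p]] %||% character(0)),
        logical(1L))
      for (agid in g$genes$gene_id[has_anchor]) {
        nbhd <- extract_neighborhood(g, agid, window = window)
        inst <- match_template(nbhd, architectures, tpl,
                               max_gap = max_gap,
                               same_strand = same_strand)
        if (!is.null(inst)) {
          inst$replicon_length <-
            as.integer(g$replicons[[inst$replicon_id]])
          candidates[[length(candidates) + 1L]] <- inst
        }
      }
    }
  }
  if (!length(candidates)) return(empty_instances())
  # conservation filter on run signatures
  run_prot <- unique(unlist(lapply(candidates, function(x)
    x$run$protein_id)))
  if (is.null(cluster_map)) {
    if (is.null(proteins))
      stop("either proteins or cluster_map must be supplied")
    cs <- cluster_proteins(proteins[run_prot], cluster_params)
    cluster_map <- cs$membership
  }
  # conservation is judged on the required-component context genes:
  # optional accessory genes vary between instances and the anchor's own
  # protein varies by effector complement, so neither is part of the
  # signature
  keep <- conserved_neighborhood_filter(
    lapply(candidates, function(x) {
      comp <- unlist(x$component_genes)
      list(members = x$run[x$run$gene_id %in% comp, , drop = FALSE],
           phylum = x$phylum,
           anchor_protein = x$anchor_protein_id)
    }),
    cluster_map, min_phyla = min_phyla)
  candidates <- candidates[keep]
  if (!length(candidates)) return(empty_instances())
  candidates <- dedup_instances(candidates)
  rows <- lapply(candidates, function(x) data.frame(
    system_type = x$system_type, genome_id = x$genome_id,
    replicon_id = x$replicon_id, phylum = x$phylum,
    anchor_gene_id = x$anchor_gene_id,
    anchor_protein_id = x$anchor_protein_id,
    anchor_stop = x$anchor_stop,
    replicon_length = x$replicon_length,
    strand = x$strand, run_start = x$run_start, run_end = x$run_end,
    n_optional = x$n_optional,
    components = paste(names(x$component_genes), "=",
                       unlist(x$component_genes),
                       sep = "", collapse = ";"),
    component_proteins = paste(
      names(x$component_genes), "=",
      vapply(unlist(x$component_genes), function(gid)
        x$run$protein_id[match(gid, x$run$gene_id)], character(1L)),
      sep = "", collapse = ";"),
    effectors = paste(x$effectors, collapse = ";"),
    stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$system_type, out$genome_id, out$run_start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_instances <- function() {
  data.frame(system_type = character(0), genome_id = character(0),
             replicon_id = character(0), phylum = character(0),
             anchor_gene_id = character(0),
             anchor_protein_id = character(0),
             anchor_stop = integer(0), replicon_length = integer(0),
             strand = character(0), run_start = integer(0),
             run_end = integer(0), n_optional = integer(0),
             components = character(0),
             component_proteins = character(0),
             effectors = character(0))
}

dedup_instances <- function(candidates) {
  keep <- rep(TRUE, length(candidates))
  for (i in seq_along(candidates)) {
    if (!keep[i]) next
    for (j in seq_along(candidates)) {
      if (i == j || !keep[j] || !keep[i]) next
      a <- candidates[[i]]; b <- candidates[[j]]
      if (a$system_type != b$system_type ||
          a$genome_id != b$genome_id ||
          a$replicon_id != b$replicon_id) next
      if (a$run_start > b$run_end || b$run_start > a$run_end) next
      drop_j <- (a$n_optional > b$n_optional) ||
        (a$n_optional == b$n_optional && a$run_start <= b$run_start)
      if (drop_j) keep[j] <- FALSE else keep[i] <- FALSE
    }
  }
  candidates[keep]
}

#' Re-verify an instance against the three conservation filters
#'
#' Checks, from the instance row and the raw gene coordinates, that all
#' consecutive run gaps are within `max_gap` and the run members share one
#' strand. (The multi-phylum condition is a dataset-level property tested
#' by [conserved_neighborhood_filter()].)
#'
#' @param instance One row of a [scan_genomes()] result.
#' @param genome The matching [genome_record()].
#' @param max_gap Gap bound (default 70).
#' @return TRUE, or a character description of the violated filter.
#' @export
verify_instance <- function(instance, genome, max_gap = 70) {
  g <- genome$genes
  run <- g[g$replicon_id == instance$replicon_id &
             g$start >= instance$run_start & g$end <= instance$run_end, ,
           drop = FALSE]
  run <- run[order(run$start), , drop = FALSE]
  if (nrow(run) > 1L) {
    gaps <- vapply(seq_len(nrow(run) - 1L), function(j)
      intergenic_gap(run[j, ], run[j + 1L, ]), integer(1L))
    if (any(gaps > max_gap)) return("gap")
    if (length(unique(run$strand)) > 1L) return("strand")
  }
  TRUE
}
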