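# Seeded generator of synthetic prokaryotic datasets with planted
# conflict systems and full ground truth. The generator emulates the
# statistical structure every pipeline stage assumes: multi-replicon gene
# tables with operon-like strand runs and geometric intergenic gaps;
# ternary/binary system neighborhoods planted with template gene order,
# operonic spacing and uniform strand; protein families emitted from
# random consensi at controlled per-site divergence; multicellularity
# flags with controlled conditional planting probabilities; anchor
# positions drawn uniformly or from a symmetric bimodal mixture; and
# decoy neighborhoods that each violate exactly one detection filter.

# core-domain consensus lengths (aa) per component family
COMPONENT_LENGTHS <- c(
  VMAP = 300, MoxR = 320, vWA = 250, iSTAND = 350, FtsH = 330,
  BetaPropeller = 280, DO_GTPase = 300, DO_GTPase_paralog = 300,
  GAP1_N1 = 220, GAP1_N2 = 240, GASH = 200, FNIII = 100,
  NucA = 180, Trypsin = 230, EACC1 = 400, Caspase = 260,
  Trypco1 = 150, Trypco2 = 150, ABhydrolase = 270, EAD1 = 80)

EFFECTOR_POOL <- c(
  TIR = 8, cNMPcyclase = 8, GGDEF = 5, SLOG = 4, PNPase = 4,
  Nudix = 3, Macro = 3, PIN = 3, REase = 3, HTH = 2, KH = 2,
  S1OB = 2, TGS = 1, MPTase = 1, CSD = 1, RelA = 1)

DECOY_DOMAINS <- paste0("DUF", c(1001, 1002, 1003, 1004, 1005))

#' Configuration for the synthetic dataset generator
#'
#' Defaults describe the study conditions the pipeline is validated
#' under: 300 genomes over three phyla, ~27% of informative organisms
#' multicellular, system planting at probability 0.3 given multicellular
#' versus 0.02 otherwise, 200 genes per genome with geometric intergenic
#' gaps (background mean 30 nt; within-system mean 15 nt, truncated at
#' the 70 nt neighborhood bound so every planted instance is structurally
#' valid), 1-11 effector domains per system averaging three, and fast
#' versus slow family divergence (per-site substitution probabilities
#' 0.3 and 0.05) for the entropy contrast.
#'
#' @param seed Integer seed; a fixed seed makes the full output
#'   byte-identical across runs.
#' @param n_genomes Number of genomes.
#' @param phyla Named numeric vector of phylum proportions (sums to 1).
#' @param multicellular_fraction Fraction of informative organisms
#'   flagged multicellular.
#' @param na_fraction Fraction of organisms with an NA flag.
#' @param p_system_given_mc,p_system_given_non_mc Per-template planting
#'   probabilities conditional on the multicellularity flag.
#' @param plant_templates Template names to plant (see
#'   [read_templates()]).
#' @param genes_per_genome Genes on the chromosome.
#' @param gene_length_mean Mean background gene length (nt).
#' @param intergenic_gap_mean Mean background intergenic gap (nt,
#'   geometric).
#' @param system_gap_mean Mean within-system intergenic gap (nt,
#'   geometric truncated at the template's `max_gap`).
#' @param effector_pool Named weights for effector-domain sampling.
#' @param effector_count_size,effector_count_prob Effector count per
#'   system is `1 + Binomial(size, prob)` (defaults give mean 3,
#'   range 1-11).
#' @param theta_component Per-site divergence within planted component
#'   families (must be small enough for family members to co-cluster).
#' @param theta_fast,theta_slow Divergence of the fast (effector-region)
#'   and slow (housekeeping control) alignment families.
#' @param family_n_seqs,family_length Rows and columns of emitted family
#'   alignments.
#' @param position_mode `"uniform"` or `"bimodal"` anchor placement.
#' @param position_modes,position_sd Modes and s.d. of the symmetric
#'   bimodal placement (defaults 0.33/0.67, 0.05).
#' @param decoy_rate Overall decoy frequency; decoys split evenly among
#'   the gap / strand / single-phylum violation types.
#' @param multi_system_fraction Fraction of system-bearing organisms
#'   carrying two or more paralogous systems.
#' @param p_optional Probability that an instance carries one optional
#'   component gene (templates that define optional components).
#' @param ead_rate Fraction of system-bearing genomes where an
#'   effector-associated domain is planted both on a core component and
#'   on a second, effector-fused protein.
#' @param bg_hit_rate Fraction of background proteins receiving an
#'   irrelevant domain hit.
#' @param plasmid_prob Probability that a genome carries a second,
#'   system-free replicon.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genomes = 300L,
                       phyla = c(Actinobacteria = 0.4,
                                 Cyanobacteria = 0.3,
                                 Proteobacteria = 0.3),
                       multicellular_fraction = 0.27,
                       na_fraction = 0.05,
                       p_system_given_mc = 0.3,
                       p_system_given_non_mc = 0.02,
                       plant_templates = "VMAP",
                       genes_per_genome = 200L,
                       gene_length_mean = 900,
                       intergenic_gap_mean = 30,
                       system_gap_mean = 15,
                       effector_pool = EFFECTOR_POOL,
                       effector_count_size = 10L,
                       effector_count_prob = 0.2,
                       theta_component = 0.05,
                       theta_fast = 0.3,
                       theta_slow = 0.05,
                       family_n_seqs = 30L,
                       family_length = 120L,
                       position_mode = c("uniform", "bimodal"),
                       position_modes = c(0.33, 0.67),
                       position_sd = 0.05,
                       decoy_rate = 0.1,
                       multi_system_fraction = 0.36,
                       p_optional = 0.3,
                       ead_rate = 0.9,
                       bg_hit_rate = 0.05,
                       plasmid_prob = 0.2) {
  position_mode <- match.arg(position_mode)
  probs <- c(multicellular_fraction, na_fraction, p_system_given_mc,
             p_system_given_non_mc, decoy_rate, multi_system_fraction,
             p_optional, ead_rate, bg_hit_rate, plasmid_prob,
             effector_count_prob, theta_component, theta_fast,
             theta_slow)
  stopifnot(all(probs >= 0 & probs <= 1),
            abs(sum(phyla) - 1) < 1e-8,
            n_genomes >= 1, genes_per_genome >= 10,
            seed == as.integer(seed))
  structure(as.list(environment()), class = "sim_config")
}

stage_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2^20) * 1013 + k * 7919) %% 2147483399L + 1L
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(list = ".Random.seed",
                                   envir = globalenv())),
          add = TRUE)
  set.seed(seed)
  expr
}

random_protein <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

mutate_consensus <- function(consensus_chars, theta) {
  L <- length(consensus_chars)
  out <- consensus_chars
  hit <- which(runif(L) < theta)
  if (length(hit)) {
    idx <- match(out[hit], AA20)
    repl <- sample.int(19L, length(hit), replace = TRUE)
    out[hit] <- vapply(seq_along(hit), function(i)
      setdiff(AA20, AA20[idx[i]])[repl[i]], character(1L))
  }
  out
}

#' Emit a protein family from a consensus at controlled divergence
#'
#' Every sequence mutates each consensus site independently with
#' probability `theta` to a uniformly chosen different residue. Because
#' sequences stay equal-length and unindelled, stacking them yields the
#' family's (trivial) multiple alignment.
#'
#' @param consensus Consensus sequence (character scalar).
#' @param n_seqs Number of family members.
#' @param theta Per-site substitution probability in `[0, 1]`.
#' @param seed Optional local seed (global RNG state is restored).
#' @param id_prefix Prefix for member ids.
#' @return List with `sequences` (named character vector) and `msa`.
#' @export
emit_family <- function(consensus, n_seqs, theta, seed = NULL,
                        id_prefix = "fam") {
  stopifnot(theta >= 0, theta <= 1, n_seqs >= 1)
  cons <- strsplit(toupper(consensus), "")[[1]]
  with_seed(seed, {
    rows <- vapply(seq_len(n_seqs), function(i)
      paste(mutate_consensus(cons, theta), collapse = ""), character(1L))
    ids <- sprintf("%s_%03d", id_prefix, seq_len(n_seqs))
    list(sequences = setNames(rows, ids), msa = msa(ids, rows))
  })
}

#' Draw normalized anchor positions
#'
#' Either uniform on `[0, 1]` or a symmetric two-mode Gaussian mixture
#' (modes at `modes`, s.d. `sd`, reflected into `[0, 1]`), emulating a
#' two-arm chromosomal placement preference.
#'
#' @param n Number of positions.
#' @param mode `"uniform"` or `"bimodal"`.
#' @param modes,sd Mixture parameters.
#' @param seed Optional local seed.
#' @return Numeric vector in `[0, 1]`.
#' @export
draw_anchor_positions <- function(n, mode = c("uniform", "bimodal"),
                                  modes = c(0.33, 0.67), sd = 0.05,
                                  seed = NULL) {
  mode <- match.arg(mode)
  with_seed(seed, {
    if (mode == "uniform") return(runif(n))
    centre <- sample(modes, n, replace = TRUE)
    x <- rnorm(n, centre, sd)
    # reflect stray draws back into [0, 1]
    x <- abs(x); x <- ifelse(x > 1, 2 - x, x)
    pmin(pmax(x, 0), 1)
  })
}

rgeom_trunc <- function(n, mean, upper) {
  p <- 1 / (mean + 1)
  u <- runif(n) * stats::pgeom(upper, p)
  stats::qgeom(u, p)
}

#' Plant system presence and multicellularity flags
#'
#' The planting stage of the generator, exposed separately because the
#' enrichment calibration only needs flags and presence: assigns each
#' genome a phylum and a multicellularity flag, then plants instances of
#' each configured template with the configured conditional
#' probabilities (NA-flagged organisms plant at the non-multicellular
#' rate). Organisms drawn as multi-system receive two or more instances.
#'
#' @param config A [sim_config()].
#' @return List with `metadata` (data.frame `genome_id`, `phylum`,
#'   `multicellular`) and `presence` (data.frame `genome_id`,
#'   `system_type`, `instance` index).
#' @export
simulate_presence <- function(config) {
  md <- with_seed(stage_seed(config$seed, 1L), {
    ids <- sprintf("G%04d", seq_len(config$n_genomes))
    phylum <- sample(names(config$phyla), config$n_genomes,
                     replace = TRUE, prob = config$phyla)
    flag <- ifelse(runif(config$n_genomes) < config$na_fraction, NA,
                   runif(config$n_genomes) <
                     config$multicellular_fraction)
    data.frame(genome_id = ids, phylum = phylum, multicellular = flag,
               stringsAsFactors = FALSE)
  })
  presence <- with_seed(stage_seed(config$seed, 3L), {
    rows <- list()
    for (tpl in config$plant_templates) {
      p <- ifelse(!is.na(md$multicellular) & md$multicellular,
                  config$p_system_given_mc,
                  config$p_system_given_non_mc)
      has <- runif(config$n_genomes) < p
      n_inst <- ifelse(has,
                       1L + ifelse(runif(config$n_genomes) <
                                     config$multi_system_fraction,
                                   1L + rbinom(config$n_genomes, 2L, 0.2),
                                   0L),
                       0L)
      idx <- which(n_inst > 0L)
      if (length(idx))
        rows[[tpl]] <- data.frame(
          genome_id = rep(md$genome_id[idx], n_inst[idx]),
          system_type = tpl,
          instance = unlist(lapply(n_inst[idx], seq_len)),
          stringsAsFactors = FALSE)
    }
    if (length(rows)) do.call(rbind, rows)
    else data.frame(genome_id = character(0),
                    system_type = character(0), instance = integer(0))
  })
  rownames(presence) <- NULL
  list(metadata = md, presence = presence)
}

#' Generate a complete synthetic dataset with ground truth
#'
#' Produces genomes, proteins, domain hits, family alignments, organism
#' metadata and the planted ground truth, optionally writing everything
#' to `out_dir` in the package's exchange formats (gene table TSV,
#' FASTA, domain-hit TSV, aligned FASTA per family, metadata TSV,
#' ground-truth JSON). Decoy neighborhoods each violate exactly one of
#' the three detection filters (one oversized gap, one flipped strand,
#' or confinement to a single phylum), so each filter's rejection
#' behaviour is independently testable.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional output directory.
#' @param templates Template set (defaults to the shipped grammars).
#' @return List with `genomes` (named list of [genome_record()]),
#'   `proteins` (named character), `hits` (data.frame), `msas` (named
#'   list), `metadata` (data.frame), `ground_truth` (list with
#'   `instances`, `decoys`, `families`).
#' @export
generate_dataset <- function(config = sim_config(), out_dir = NULL,
                             templates = read_templates()) {
  for (tpl in config$plant_templates)
    if (!tpl %in% names(templates))
      stop("unknown template in plant_templates: ", tpl)
  pres <- simulate_presence(config)
  md <- pres$metadata

  # consensus sequences for every component family and effector domain
  families <- with_seed(stage_seed(config$seed, 2L), {
    fams <- lapply(COMPONENT_LENGTHS, random_protein)
    effs <- lapply(setNames(rep(100L, length(config$effector_pool)),
                            names(config$effector_pool)), random_protein)
    decoy_core <- lapply(COMPONENT_LENGTHS, random_protein)
    names(decoy_core) <- paste0(names(COMPONENT_LENGTHS), "_decoyfam")
    c(fams, effs, decoy_core)
  })

  # per-instance draws and decoy assignment
  plan <- with_seed(stage_seed(config$seed, 4L), {
    inst <- pres$presence
    n <- nrow(inst)
    inst$x <- draw_anchor_positions(n, config$position_mode,
                                    config$position_modes,
                                    config$position_sd)
    inst$strand <- sample(c("+", "-"), n, replace = TRUE)
    inst$n_eff <- 1L + rbinom(n, config$effector_count_size,
                              config$effector_count_prob)
    inst$effectors <- vapply(inst$n_eff, function(k)
      paste(sample(names(config$effector_pool), k, replace = TRUE,
                   prob = config$effector_pool), collapse = ";"),
      character(1L))
    inst$optional <- vapply(seq_len(n), function(i) {
      tpl <- templates[[inst$system_type[i]]]
      if (length(tpl$optional) && runif(1) < config$p_optional)
        sample(tpl$optional, 1L) else NA_character_
    }, character(1L))
    # decoys: equal numbers of the three violation types, spread over
    # phyla (strand/gap decoys) or confined to the first phylum
    n_decoy <- max(2L, round(config$decoy_rate * config$n_genomes / 3))
    tpl0 <- config$plant_templates[1]
    mk_decoy <- function(type, genome_ids)
      data.frame(genome_id = genome_ids, type = type,
                 system_type = tpl0,
                 strand = sample(c("+", "-"), length(genome_ids),
                                 replace = TRUE),
                 x = runif(length(genome_ids)),
                 stringsAsFactors = FALSE)
    by_phy <- split(md$genome_id, md$phylum)
    # round-robin over phyla so each decoy signature spans >= 2 phyla
    pool <- unlist(lapply(seq_len(max(lengths(by_phy))), function(i)
      vapply(by_phy, function(v)
        if (i <= length(v)) v[i] else NA_character_, character(1L))))
    pool <- pool[!is.na(pool)]
    k1 <- min(n_decoy, length(pool) %/% 2)
    decoys <- rbind(
      mk_decoy("gap", pool[seq_len(k1)]),
      mk_decoy("strand", pool[k1 + seq_len(k1)]),
      mk_decoy("phylum", by_phy[[1]][seq_len(min(n_decoy,
                                                 length(by_phy[[1]])))]))
    inst$ead <- rep(FALSE, n)
    sys_genomes <- unique(inst$genome_id)
    if (length(sys_genomes)) {
      ead_g <- sys_genomes[runif(length(sys_genomes)) < config$ead_rate]
      inst$ead[match(ead_g, inst$genome_id)] <- TRUE
    }
    list(instances = inst, decoys = decoys)
  })

  built <- with_seed(stage_seed(config$seed, 5L), {
    build_all_genomes(md, plan, config, templates, families)
  })

  msas <- with_seed(stage_seed(config$seed, 6L), {
    comp_fams <- unique(unlist(lapply(
      templates[config$plant_templates], `[[`, "required")))
    out <- lapply(setNames(comp_fams, comp_fams), function(f)
      emit_family(families[[f]], config$family_n_seqs,
                  config$theta_component, id_prefix = f)$msa)
    out$fast_effector_region <- emit_family(
      random_protein(config$family_length), config$family_n_seqs,
      config$theta_fast, id_prefix = "fast")$msa
    out$slow_control_polB <- emit_family(
      random_protein(config$family_length), config$family_n_seqs,
      config$theta_slow, id_prefix = "slow")$msa
    out
  })

  result <- list(genomes = built$genomes, proteins = built$proteins,
                 hits = built$hits, msas = msas, metadata = md,
                 ground_truth = list(instances = built$truth,
                                     decoys = built$decoy_truth,
                                     families = families))
  if (!is.null(out_dir)) write_dataset(result, out_dir)
  result
}

write_dataset <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_gene_table(result$genomes, file.path(out_dir, "gene_table.tsv"))
  write_fasta(result$proteins, file.path(out_dir, "proteins.fasta"))
  write_domain_hits(result$hits, file.path(out_dir, "hits.tsv"))
  write_metadata(result$metadata, file.path(out_dir, "metadata.tsv"))
  for (nm in names(result$msas))
    write_msa_fasta(result$msas[[nm]],
                    file.path(out_dir, paste0("msa_", nm, ".fasta")))
  jsonlite::write_json(
    list(instances = result$ground_truth$instances,
         decoys = result$ground_truth$decoys),
    file.path(out_dir, "ground_truth.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

# Assemble every genome: lay out background genes and planted blocks,
# compute coordinates, emit protein sequences and domain hits.
build_all_genomes <- function(md, plan, config, templates, families) {
  genomes <- list()
  prot_acc <- list()
  hit_acc <- list()
  truth_rows <- list()
  decoy_rows <- list()
  inst_by_g <- split(plan$instances,
                     factor(plan$instances$genome_id,
                            levels = md$genome_id))
  dec_by_g <- split(plan$decoys,
                    factor(plan$decoys$genome_id, levels = md$genome_id))
  for (gi in seq_len(nrow(md))) {
    gid <- md$genome_id[gi]
    blocks <- c(
      if (nrow(inst_by_g[[gid]]))
        lapply(seq_len(nrow(inst_by_g[[gid]])), function(i)
          system_block(inst_by_g[[gid]][i, ], config, templates,
                       decoy_type = NA_character_)),
      if (nrow(dec_by_g[[gid]]))
        lapply(seq_len(nrow(dec_by_g[[gid]])), function(i)
          system_block(dec_by_g[[gid]][i, ], config, templates,
                       decoy_type = dec_by_g[[gid]]$type[i])))
    g <- build_genome(gid, md$phylum[gi], md$multicellular[gi], blocks,
                      config, families)
    genomes[[gid]] <- g$record
    prot_acc[[gid]] <- g$proteins
    hit_acc[[gid]] <- g$hits
    if (nrow(g$truth)) truth_rows[[gid]] <- g$truth
    if (nrow(g$decoys)) decoy_rows[[gid]] <- g$decoys
  }
  hits <- do.call(rbind, unname(hit_acc))
  if (is.null(hits))
    hits <- data.frame(protein_id = character(0), domain = character(0),
                       ali_start = integer(0), ali_end = integer(0),
                       score = numeric(0), evalue = numeric(0))
  rownames(hits) <- NULL
  truth <- do.call(rbind, unname(truth_rows))
  if (is.null(truth)) truth <- empty_truth()
  rownames(truth) <- NULL
  decoys <- do.call(rbind, unname(decoy_rows))
  if (is.null(decoys))
    decoys <- data.frame(genome_id = character(0), type = character(0),
                         system_type = character(0),
                         anchor_gene_id = character(0))
  rownames(decoys) <- NULL
  list(genomes = genomes, proteins = unlist(unname(prot_acc)),
       hits = hits, truth = truth, decoy_truth = decoys)
}

empty_truth <- function() {
  data.frame(genome_id = character(0), system_type = character(0),
             anchor_gene_id = character(0), components = character(0),
             effectors = character(0), anchor_stop = integer(0),
             replicon_length = integer(0), strand = character(0),
             x_intended = numeric(0))
}

# Describe one planted block (system or decoy) as a list of gene specs
# in coding order; genomic order is reversed for '-' blocks.
system_block <- function(row, config, templates, decoy_type) {
  tpl <- templates[[row$system_type]]
  fam_suffix <- if (identical(decoy_type, "phylum")) "_decoyfam" else ""
  genes <- lapply(tpl$required, function(role)
    list(role = role, family = paste0(role, fam_suffix),
         domains = role, is_anchor = role == tpl$anchor))
  # effectors ride C-terminal on the effector-host protein
  eff <- if (!is.null(row$effectors) && !is.na(row$effectors) &&
             nzchar(row$effectors))
    strsplit(row$effectors, ";", fixed = TRUE)[[1]] else character(0)
  host_i <- match(tpl$effector_host, tpl$required)
  genes[[host_i]]$effectors <- eff
  if (!is.null(row$optional) && !is.na(row$optional))
    genes[[length(genes) + 1L]] <- list(role = "optional",
                                        family = row$optional,
                                        domains = row$optional,
                                        is_anchor = FALSE)
  if (isTRUE(row$ead)) genes[[host_i]]$ead <- TRUE
  strands <- rep(row$strand, length(genes))
  if (identical(decoy_type, "strand") && length(genes) >= 2L)
    strands[2L] <- setdiff(c("+", "-"), row$strand)
  gaps <- rgeom_trunc(length(genes) - 1L, config$system_gap_mean,
                      tpl$max_gap)
  if (identical(decoy_type, "gap"))
    gaps[1L] <- tpl$max_gap + 50L
  list(template = tpl$name, genes = genes, strands = strands,
       gaps = gaps, x = row$x, block_strand = row$strand,
       decoy_type = decoy_type,
       ead = isTRUE(row$ead))
}

build_genome <- function(gid, phylum, mc_flag, blocks, config,
                         families) {
  n_slots <- config$genes_per_genome
  # choose non-overlapping slot ranges for the blocks, near the target
  # normalized positions
  taken <- rep(FALSE, n_slots)
  placed <- list()
  for (b in blocks) {
    len <- length(b$genes)
    start <- min(max(1L, round(b$x * (n_slots - len - 1)) + 1L),
                 n_slots - len + 1L)
    tries <- 0L
    while (any(taken[start:(start + len - 1L)]) && tries < n_slots) {
      start <- start %% (n_slots - len + 1L) + 1L
      tries <- tries + 1L
    }
    if (any(taken[start:(start + len - 1L)])) next  # genome saturated
    taken[start:(start + len - 1L)] <- TRUE
    b$start_slot <- start
    placed[[length(placed) + 1L]] <- b
  }
  # slot plan: background genes everywhere except planted slots
  slot_block <- rep(NA_integer_, n_slots)
  slot_pos <- rep(NA_integer_, n_slots)  # coding-order index in block
  for (bi in seq_along(placed)) {
    b <- placed[[bi]]
    len <- length(b$genes)
    # genomic order: coding order on '+', reversed on '-'
    order_in_genome <- if (b$block_strand == "+") seq_len(len)
    else rev(seq_len(len))
    slot_block[b$start_slot + seq_len(len) - 1L] <- bi
    slot_pos[b$start_slot + seq_len(len) - 1L] <- order_in_genome
  }
  # background strand runs: Markov chain with flip probability 0.25
  strands <- character(n_slots)
  s <- sample(c("+", "-"), 1L)
  for (i in seq_len(n_slots)) {
    if (runif(1) < 0.25) s <- setdiff(c("+", "-"), s)
    strands[i] <- s
  }
  lengths_nt <- pmax(150L, round(rnorm(n_slots, config$gene_length_mean,
                                       200)))
  lengths_nt <- lengths_nt - lengths_nt %% 3L
  gaps_nt <- rgeom(n_slots, 1 / (config$intergenic_gap_mean + 1))
  ead_extra <- any(vapply(placed, function(b) isTRUE(b$ead),
                          logical(1L)))
  # per-slot protein composition
  prot_seq <- character(n_slots)
  prot_dom <- vector("list", n_slots)
  for (i in seq_len(n_slots)) {
    bi <- slot_block[i]
    if (is.na(bi)) {
      prot_seq[i] <- ""  # filled later (random background)
      next
    }
    b <- placed[[bi]]
    gspec <- b$genes[[slot_pos[i]]]
    segs <- gspec$family
    doms <- gspec$domains
    if (isTRUE(gspec$ead)) { segs <- c("EAD1", segs); doms <- c("EAD1", doms) }
    if (!is.null(gspec$effectors) && length(gspec$effectors)) {
      segs <- c(segs, gspec$effectors)
      doms <- c(doms, gspec$effectors)
    }
    seq_parts <- vapply(segs, function(f)
      paste(mutate_consensus(strsplit(families[[f]], "")[[1]],
                             config$theta_component), collapse = ""),
      character(1L))
    prot_seq[i] <- paste(seq_parts, collapse = "")
    seg_len <- nchar(seq_parts)
    ends <- cumsum(seg_len)
    starts <- ends - seg_len + 1L
    prot_dom[[i]] <- data.frame(domain = doms, ali_start = starts,
                                ali_end = ends,
                                stringsAsFactors = FALSE)
    strands[i] <- b$strands[slot_pos[i]]
    lengths_nt[i] <- nchar(prot_seq[i]) * 3L
  }
  # within-block intergenic gaps: gaps_nt[i] is the gap AFTER slot i;
  # block gaps are in coding order, so reverse them for '-' blocks
  for (b in placed) {
    len <- length(b$genes)
    if (len < 2L) next
    gg <- if (b$block_strand == "+") b$gaps else rev(b$gaps)
    gaps_nt[b$start_slot + seq_len(len - 1L) - 1L] <- gg
  }
  # background proteins
  bg <- which(!nzchar(prot_seq))
  if (length(bg)) {
    aa_len <- pmax(50L, lengths_nt[bg] %/% 3L)
    big <- sample(AA20, sum(aa_len), replace = TRUE)
    idx <- rep(seq_along(bg), aa_len)
    prot_seq[bg] <- vapply(split(big, idx), paste, character(1L),
                           collapse = "")
  }
  # optional EAD auxiliary protein: repurpose one background gene
  if (ead_extra && length(bg)) {
    i <- bg[1L]
    eff_lab <- names(config$effector_pool)[1L]
    seq_parts <- c(
      paste(mutate_consensus(strsplit(families[["EAD1"]], "")[[1]],
                             config$theta_component), collapse = ""),
      paste(mutate_consensus(strsplit(families[[eff_lab]], "")[[1]],
                             config$theta_component), collapse = ""))
    prot_seq[i] <- paste(seq_parts, collapse = "")
    seg_len <- nchar(seq_parts)
    ends <- cumsum(seg_len); starts <- ends - seg_len + 1L
    prot_dom[[i]] <- data.frame(domain = c("EAD1", eff_lab),
                                ali_start = starts, ali_end = ends,
                                stringsAsFactors = FALSE)
    lengths_nt[i] <- nchar(prot_seq[i]) * 3L
  }
  # background domain hits on a small fraction of background proteins
  for (i in setdiff(bg, if (ead_extra && length(bg)) bg[1L] else integer(0)))
    if (runif(1) < config$bg_hit_rate) {
      L <- nchar(prot_seq[i])
      a <- sample.int(max(1L, L - 60L), 1L)
      prot_dom[[i]] <- data.frame(domain = sample(DECOY_DOMAINS, 1L),
                                  ali_start = a,
                                  ali_end = min(L, a + 59L),
                                  stringsAsFactors = FALSE)
    }
  # coordinates: start_{i+1} = start_i + len_i + gap_i, so that the
  # nucleotides strictly between gene i and i+1 number exactly gap_i
  starts_nt <- 101L + cumsum(c(0L, (lengths_nt + gaps_nt)[-n_slots]))
  ends_nt <- starts_nt + lengths_nt - 1L
  chrom_len <- ends_nt[n_slots] + 200L
  gene_ids <- sprintf("%s_g%03d", gid, seq_len(n_slots))
  prot_ids <- sprintf("%s_p%03d", gid, seq_len(n_slots))
  genes <- data.frame(gene_id = gene_ids, protein_id = prot_ids,
                      replicon_id = "chr", start = starts_nt,
                      end = ends_nt, strand = strands,
                      stringsAsFactors = FALSE)
  replicons <- c(chr = chrom_len)
  # optional system-free plasmid
  if (runif(1) < config$plasmid_prob) {
    np <- max(5L, round(0.1 * n_slots))
    plen <- pmax(150L, round(rnorm(np, config$gene_length_mean, 200)))
    plen <- plen - plen %% 3L
    pgap <- rgeom(np, 1 / (config$intergenic_gap_mean + 1))
    pstart <- 101L + cumsum(c(0L, (plen + pgap)[-np]))
    pend <- pstart + plen - 1L
    paa <- pmax(50L, plen %/% 3L)
    big <- sample(AA20, sum(paa), replace = TRUE)
    pseq <- vapply(split(big, rep(seq_len(np), paa)), paste,
                   character(1L), collapse = "")
    pgid <- sprintf("%s_pl_g%03d", gid, seq_len(np))
    ppid <- sprintf("%s_pl_p%03d", gid, seq_len(np))
    genes <- rbind(genes, data.frame(
      gene_id = pgid, protein_id = ppid, replicon_id = "plasmid",
      start = pstart, end = pend,
      strand = sample(c("+", "-"), np, replace = TRUE),
      stringsAsFactors = FALSE))
    replicons <- c(replicons, plasmid = pend[np] + 200L)
    prot_seq <- c(prot_seq, pseq)
    prot_ids <- c(prot_ids, ppid)
  }
  record <- genome_record(gid, replicons, genes, phylum = phylum,
                          multicellular = mc_flag)
  # hits with +-3 aa jitter
  hit_rows <- list()
  for (i in which(!vapply(prot_dom, is.null, logical(1L)))) {
    d <- prot_dom[[i]]
    L <- nchar(prot_seq[i])
    jit_a <- sample(-3:3, nrow(d), replace = TRUE)
    jit_b <- sample(-3:3, nrow(d), replace = TRUE)
    a <- pmin(pmax(d$ali_start + jit_a, 1L), L)
    e <- pmin(pmax(d$ali_end + jit_b, 1L), L)
    swap <- a > e
    if (any(swap)) { tmp <- a[swap]; a[swap] <- e[swap]; e[swap] <- tmp }
    hit_rows[[length(hit_rows) + 1L]] <- data.frame(
      protein_id = prot_ids[i], domain = d$domain, ali_start = a,
      ali_end = e, score = round(runif(nrow(d), 80, 200), 1),
      evalue = signif(10^-runif(nrow(d), 10, 50), 3),
      stringsAsFactors = FALSE)
  }
  hits <- if (length(hit_rows)) do.call(rbind, hit_rows)
  else data.frame(protein_id = character(0), domain = character(0),
                  ali_start = integer(0), ali_end = integer(0),
                  score = numeric(0), evalue = numeric(0))
  # ground truth
  truths <- list(); decs <- list()
  for (bi in seq_along(placed)) {
    b <- placed[[bi]]
    in_block <- which(slot_block == bi)
    anchor_pos <- which(vapply(b$genes, function(g)
      isTRUE(g$is_anchor), logical(1L)))
    anchor_slot <- in_block[match(anchor_pos, slot_pos[in_block])]
    a_stop <- if (strands[anchor_slot] == "+") ends_nt[anchor_slot]
    else starts_nt[anchor_slot]
    if (is.na(b$decoy_type)) {
      comp <- vapply(seq_along(b$genes), function(k) {
        g <- b$genes[[k]]
        if (g$role == "optional") return(NA_character_)
        paste0(g$role, "=", gene_ids[in_block[match(k, slot_pos[in_block])]])
      }, character(1L))
      eff <- unlist(lapply(b$genes, function(g) g$effectors))
      truths[[length(truths) + 1L]] <- data.frame(
        genome_id = gid, system_type = b$template,
        anchor_gene_id = gene_ids[anchor_slot],
        components = paste(comp[!is.na(comp)], collapse = ";"),
        effectors = paste(eff, collapse = ";"),
        anchor_stop = a_stop, replicon_length = chrom_len,
        strand = b$block_strand, x_intended = b$x,
        stringsAsFactors = FALSE)
    } else {
      decs[[length(decs) + 1L]] <- data.frame(
        genome_id = gid, type = b$decoy_type, system_type = b$template,
        anchor_gene_id = gene_ids[anchor_slot],
        stringsAsFactors = FALSE)
    }
  }
  list(record = record,
       proteins = setNames(prot_seq, prot_ids),
       hits = hits,
       truth = if (length(truths)) do.call(rbind, truths)
       else empty_truth(),
       decoys = if (length(decs)) do.call(rbind, decs)
       else data.frame(genome_id = character(0), type = character(0),
                       system_type = character(0),
                       anchor_gene_id = character(0)))
}
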