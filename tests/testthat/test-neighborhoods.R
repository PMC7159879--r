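# A hand-built two-phylum mini-dataset with one VMAP-like run per genome.
# Gene/protein layout is fully explicit so each filter can be violated
# precisely.
mini_genome <- function(gid, phylum, starts, ends, strands,
                        doms_list) {
  n <- length(starts)
  genes <- data.frame(
    gene_id = sprintf("%s_g%d", gid, seq_len(n)),
    protein_id = sprintf("%s_p%d", gid, seq_len(n)),
    replicon_id = "chr", start = starts, end = ends, strand = strands,
    stringsAsFactors = FALSE)
  g <- genome_record(gid, c(chr = max(ends) + 500), genes,
                     phylum = phylum)
  hits <- do.call(rbind, lapply(seq_len(n), function(i) {
    if (!length(doms_list[[i]])) return(NULL)
    k <- length(doms_list[[i]])
    data.frame(protein_id = genes$protein_id[i],
               domain = doms_list[[i]],
               ali_start = seq(1, by = 150, length.out = k),
               ali_end = seq(120, by = 150, length.out = k),
               score = 100, evalue = 1e-30, stringsAsFactors = FALSE)
  }))
  list(genome = g, hits = hits)
}

vmap_run_genome <- function(gid, phylum, gaps = c(30, 10),
                            strands = c("+", "+", "+"),
                            effectors = c("TIR", "PIN")) {
  lens <- c(900, 960, 750)
  starts <- integer(3); ends <- integer(3)
  starts[1] <- 1000
  for (i in 1:3) {
    if (i > 1) starts[i] <- ends[i - 1] + gaps[i - 1] + 1
    ends[i] <- starts[i] + lens[i] - 1
  }
  mini_genome(gid, phylum, starts, ends, strands,
              list("VMAP", "MoxR", c("vWA", effectors)))
}

test_that("intergenic gap follows the strictly-between convention", {
  g <- function(s, e) list(replicon_id = "chr", start = s, end = e)
  expect_equal(intergenic_gap(g(100, 200), g(250, 400)), 49L)
  expect_equal(intergenic_gap(g(100, 200), g(201, 300)), 0L)
  expect_equal(intergenic_gap(g(100, 200), g(150, 300)), 0L)
  expect_error(intergenic_gap(list(replicon_id = "a", start = 1, end = 2),
                              list(replicon_id = "b", start = 5, end = 9)),
               "different replicons")
})

test_that("neighborhood extraction windows and truncates correctly", {
  starts <- seq(1000, by = 1000, length.out = 13)
  ends <- starts + 800
  mg <- mini_genome("G1", "Actinobacteria", starts, ends,
                    rep("+", 13), rep(list(character(0)), 13))
  nb <- extract_neighborhood(mg$genome, "G1_g7", window = 5)
  expect_equal(nrow(nb$members), 11L)
  nb1 <- extract_neighborhood(mg$genome, "G1_g1", window = 5)
  expect_lte(nrow(nb1$members), 6L)
  # stored gaps equal gaps recomputed from coordinates
  m <- nb$members
  recomputed <- vapply(seq_len(nrow(m) - 1), function(i)
    max(0L, m$start[i + 1] - m$end[i] - 1L), integer(1))
  expect_equal(nb$gaps, recomputed)
  expect_error(extract_neighborhood(mg$genome, "nope"), "not found")
})

test_that("template matching enforces order, gap, and strand filters", {
  tpl <- read_templates()[["VMAP"]]
  ok <- vmap_run_genome("G1", "Actinobacteria")
  archs <- build_architectures(ok$hits)
  nb <- extract_neighborhood(ok$genome, "G1_g3")
  inst <- match_template(nb, archs, tpl)
  expect_false(is.null(inst))
  expect_equal(unlist(inst$component_genes),
               c(VMAP = "G1_g1", MoxR = "G1_g2", vWA = "G1_g3"))
  expect_equal(inst$effectors, c("TIR", "PIN"))
  expect_equal(inst$anchor_stop, nb$anchor$end)

  big_gap <- vmap_run_genome("G2", "Actinobacteria", gaps = c(120, 10))
  archs2 <- build_architectures(big_gap$hits)
  expect_null(match_template(
    extract_neighborhood(big_gap$genome, "G2_g3"), archs2, tpl))
  # the same neighborhood matches when the gap filter is relaxed
  expect_false(is.null(match_template(
    extract_neighborhood(big_gap$genome, "G2_g3"), archs2, tpl,
    max_gap = 200)))

  flipped <- vmap_run_genome("G3", "Actinobacteria",
                             strands = c("+", "-", "+"))
  archs3 <- build_architectures(flipped$hits)
  expect_null(match_template(
    extract_neighborhood(flipped$genome, "G3_g3"), archs3, tpl))
  expect_false(is.null(match_template(
    extract_neighborhood(flipped$genome, "G3_g3"), archs3, tpl,
    same_strand = FALSE)))
})

test_that("minus-strand runs match after coding-order reversal", {
  tpl <- read_templates()[["VMAP"]]
  # genomic order vWA, MoxR, VMAP all on '-' = coding order VMAP->MoxR->vWA
  mg <- mini_genome("G4", "Cyanobacteria",
                    starts = c(1000, 2000, 3000),
                    ends = c(1970, 2970, 3900),
                    strands = c("-", "-", "-"),
                    list(c("vWA", "REase"), "MoxR", "VMAP"))
  archs <- build_architectures(mg$hits)
  inst <- match_template(extract_neighborhood(mg$genome, "G4_g1"),
                         archs, tpl)
  expect_false(is.null(inst))
  expect_equal(inst$component_genes$vWA, "G4_g1")
  expect_equal(inst$component_genes$VMAP, "G4_g3")
  # minus-strand anchor stop is its start coordinate
  expect_equal(inst$anchor_stop, 1000L)
})

test_that("fused components satisfy multiple consecutive roles", {
  tpl <- read_templates()[["BetaPropeller"]]
  # MoxR gene followed by one protein fused vWA+BetaPropeller
  mg <- mini_genome("G5", "Actinobacteria",
                    starts = c(1000, 2000), ends = c(1980, 3500),
                    strands = c("+", "+"),
                    list("MoxR", c("vWA", "BetaPropeller")))
  archs <- build_architectures(mg$hits)
  inst <- match_template(extract_neighborhood(mg$genome, "G5_g2"),
                         archs, tpl)
  expect_false(is.null(inst))
  expect_equal(inst$component_genes$vWA, "G5_g2")
  expect_equal(inst$component_genes$BetaPropeller, "G5_g2")
})

test_that("the multi-phylum filter keeps cross-phylum signatures only", {
  mk <- function(gid, phylum) {
    mg <- vmap_run_genome(gid, phylum)
    m <- mg$genome$genes[1:2, ]  # context genes (VMAP, MoxR)
    list(members = m, phylum = phylum)
  }
  cands <- list(mk("A1", "Actinobacteria"), mk("C1", "Cyanobacteria"),
                mk("A2", "Actinobacteria"))
  # map all context proteins of the same role to one cluster
  prot <- unlist(lapply(cands, function(x) x$members$protein_id))
  cluster_map <- setNames(rep(c(1L, 2L), length(cands)), prot)
  keep <- conserved_neighborhood_filter(cands, cluster_map)
  expect_true(all(keep))
  # single-phylum-only signatures are dropped regardless of count
  cands1 <- list(mk("A1", "Actinobacteria"), mk("A2", "Actinobacteria"),
                 mk("A3", "Actinobacteria"))
  prot1 <- unlist(lapply(cands1, function(x) x$members$protein_id))
  keep1 <- conserved_neighborhood_filter(
    cands1, setNames(rep(c(1L, 2L), 3), prot1))
  expect_false(any(keep1))
  # decision is invariant to candidate order
  perm <- c(3L, 1L, 2L)
  expect_equal(conserved_neighborhood_filter(cands[perm], cluster_map),
               keep[perm])
  expect_error(conserved_neighborhood_filter(
    cands, cluster_map[-1]), "missing cluster assignment")
})

test_that("scan recovers planted systems and rejects single-phylum plants", {
  cfg <- sim_config(seed = 5, n_genomes = 10, genes_per_genome = 30,
                    p_system_given_mc = 0.8, p_system_given_non_mc = 0.4,
                    decoy_rate = 0)
  d <- generate_dataset(cfg)
  inst <- scan_genomes(d$genomes, d$hits, proteins = d$proteins)
  tr <- d$ground_truth$instances
  expect_gte(mean(tr$anchor_gene_id %in% inst$anchor_gene_id), 0.95)
  expect_true(all(inst$anchor_gene_id %in% tr$anchor_gene_id))
  # every emitted instance re-verifies the gap and strand filters
  for (r in seq_len(nrow(inst)))
    expect_true(isTRUE(verify_instance(inst[r, ],
                                       d$genomes[[inst$genome_id[r]]])))
})

test_that("shuffled domain labels produce no instances", {
  cfg <- sim_config(seed = 6, n_genomes = 8, genes_per_genome = 30,
                    p_system_given_mc = 0.7, p_system_given_non_mc = 0.3,
                    decoy_rate = 0)
  d <- generate_dataset(cfg)
  hits <- d$hits
  set.seed(99)
  hits$domain <- sample(hits$domain)  # destroy gene-order grammar
  inst <- scan_genomes(d$genomes, hits, proteins = d$proteins)
  tr <- d$ground_truth$instances
  # no planted anchor survives label shuffling
  expect_equal(sum(inst$anchor_gene_id %in% tr$anchor_gene_id), 0L)
})

test_that("raising max_gap never decreases the instance count", {
  cfg <- sim_config(seed = 8, n_genomes = 8, genes_per_genome = 30,
                    p_system_given_mc = 0.8, p_system_given_non_mc = 0.4)
  d <- generate_dataset(cfg)
  n70 <- nrow(scan_genomes(d$genomes, d$hits, proteins = d$proteins))
  n200 <- nrow(scan_genomes(d$genomes, d$hits, proteins = d$proteins,
                            max_gap = 200))
  expect_gte(n200, n70)
})
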