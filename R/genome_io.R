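#' @importFrom stats median p.adjust pchisq phyper rbinom rgeom rnorm runif
#'   setNames wilcox.test
#' @importFrom utils read.delim write.table
NULL

GENE_TABLE_COLS <- c("genome_id", "replicon_id", "replicon_length",
                     "gene_id", "protein_id", "start", "end", "strand")

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct an annotated genome record
#'
#' A genome record bundles one organism's ordered gene complement across its
#' replicons with the organism-level metadata used by the downstream
#' statistics: the phylum (needed by the multi-phylum conservation filter)
#' and the curated multicellularity flag (TRUE/FALSE/NA; the trait tested by
#' the enrichment layer).
#'
#' @param genome_id Unique genome identifier.
#' @param replicons Named numeric vector of replicon lengths (nt).
#' @param genes data.frame with columns `gene_id`, `protein_id`,
#'   `replicon_id`, `start`, `end`, `strand`. Coordinates are 1-based
#'   inclusive; minus-strand genes keep `start < end` and carry orientation
#'   only in `strand`.
#' @param organism Organism name (free text).
#' @param phylum Phylum label, or `NA`.
#' @param multicellular Logical flag: `TRUE`, `FALSE` or `NA` (no
#'   information).
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(genome_id, replicons, genes,
                          organism = "", phylum = NA_character_,
                          multicellular = NA) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  if (is.null(names(replicons)) || anyDuplicated(names(replicons)))
    stop("replicons must be a uniquely named vector of lengths")
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  need <- c("gene_id", "protein_id", "replicon_id", "start", "end", "strand")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop("genes is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(genes)) {
    genes$start <- as.integer(genes$start)
    genes$end <- as.integer(genes$end)
    bad <- which(genes$start > genes$end)
    if (length(bad))
      stop("gene ", genes$gene_id[bad[1]], ": start > end")
    if (!all(genes$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'")
    if (anyDuplicated(genes$gene_id))
      stop("duplicate gene_id within genome ", genome_id)
    unknown <- setdiff(unique(genes$replicon_id), names(replicons))
    if (length(unknown))
      stop("genes reference unknown replicon(s): ",
           paste(unknown, collapse = ", "))
    over <- genes$end > replicons[genes$replicon_id]
    if (any(over))
      stop("gene ", genes$gene_id[which(over)[1]],
           " extends beyond its replicon")
    genes <- genes[order(genes$replicon_id, genes$start), , drop = FALSE]
    rownames(genes) <- NULL
  }
  structure(
    list(genome_id = genome_id, organism = organism, phylum = phylum,
         multicellular = multicellular,
         replicons = replicons, genes = genes),
    class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record> ", x$genome_id,
      " [", x$phylum, ", multicellular=", x$multicellular, "]\n",
      "  ", length(x$replicons), " replicon(s), ",
      nrow(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Read a gene feature table (TSV) into genome records
#'
#' The gene table is the simplified internal exchange format: one row per
#' gene with columns `genome_id`, `replicon_id`, `replicon_length`,
#' `gene_id`, `protein_id`, `start`, `end`, `strand`.
#'
#' @param path Path to the TSV file.
#' @param metadata Optional metadata data.frame (see [read_metadata()]);
#'   merged onto the records when given.
#' @return Named list of [genome_record()] objects, one per `genome_id`.
#' @export
read_gene_table <- function(path, metadata = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(GENE_TABLE_COLS, names(df))
  if (length(miss))
    stop("gene table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(df)) {
    key <- paste(df$genome_id, df$gene_id)
    if (anyDuplicated(key))
      stop("duplicate (genome_id, gene_id): ", key[duplicated(key)][1])
    badstrand <- which(!df$strand %in% c("+", "-"))
    if (length(badstrand))
      stop("row ", badstrand[1], ": strand '", df$strand[badstrand[1]],
           "' not in {+,-}")
    badcoord <- which(as.integer(df$start) > as.integer(df$end))
    if (length(badcoord))
      stop("row ", badcoord[1], ": start > end for gene ",
           df$gene_id[badcoord[1]])
  }
  out <- lapply(split(df, df$genome_id), function(g) {
    reps <- g[!duplicated(g$replicon_id), c("replicon_id", "replicon_length")]
    replicons <- setNames(as.numeric(reps$replicon_length), reps$replicon_id)
    genome_record(g$genome_id[1], replicons,
                  g[, c("gene_id", "protein_id", "replicon_id",
                        "start", "end", "strand")])
  })
  if (!is.null(metadata)) out <- merge_metadata(out, metadata)
  out[order(names(out))]
}

#' Write genome records to a gene feature table (TSV)
#'
#' @param genomes A `genome_record` or list of them.
#' @param path Output path.
#' @return Invisibly, the written data.frame.
#' @export
write_gene_table <- function(genomes, path) {
  if (inherits(genomes, "genome_record")) genomes <- list(genomes)
  rows <- lapply(genomes, function(g) {
    if (!nrow(g$genes)) return(NULL)
    data.frame(genome_id = g$genome_id,
               replicon_id = g$genes$replicon_id,
               replicon_length = as.integer(g$replicons[g$genes$replicon_id]),
               gene_id = g$genes$gene_id,
               protein_id = g$genes$protein_id,
               start = g$genes$start, end = g$genes$end,
               strand = g$genes$strand,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- as.data.frame(setNames(
    rep(list(character(0)), length(GENE_TABLE_COLS)), GENE_TABLE_COLS))
  write_tsv(df, path)
  invisible(df)
}

#' Read a GFF3 annotation plus genomic FASTA into a genome record
#'
#' CDS features carrying `ID` and `protein_id` attributes become genes;
#' features without a `protein_id` are skipped with a warning. Replicon
#' lengths are taken from the FASTA sequence widths.
#'
#' @param gff_path Path to a GFF3 file.
#' @param fasta_path Path to the matching genomic FASTA.
#' @param genome_id Genome identifier; defaults to the GFF3 file stem.
#' @inheritParams genome_record
#' @return A [genome_record()].
#' @export
read_gff3_with_fasta <- function(gff_path, fasta_path,
                                 genome_id = sub("\\.gff3?$", "", basename(gff_path)),
                                 organism = "", phylum = NA_character_,
                                 multicellular = NA) {
  dna <- Biostrings::readDNAStringSet(fasta_path)
  replicons <- setNames(as.numeric(Biostrings::width(dna)),
                        sub("\\s.*$", "", names(dna)))
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(gff_path, format = "gff3")
    gdf <- as.data.frame(gr)
    gdf <- gdf[gdf$type == "CDS", , drop = FALSE]
    df <- if (!nrow(gdf)) data.frame(
      replicon_id = character(0), start = integer(0), end = integer(0),
      strand = character(0), gene_id = character(0),
      protein_id = character(0), stringsAsFactors = FALSE)
    else data.frame(
      replicon_id = as.character(gdf$seqnames),
      start = gdf$start, end = gdf$end,
      strand = as.character(gdf$strand),
      gene_id = if ("ID" %in% names(gdf)) as.character(gdf$ID)
                else NA_character_,
      protein_id = if ("protein_id" %in% names(gdf))
        as.character(gdf$protein_id) else NA_character_,
      stringsAsFactors = FALSE)
  } else {
    df <- parse_gff3_cds(gff_path)
  }
  df$strand[!df$strand %in% c("+", "-")] <- "+"
  drop <- is.na(df$protein_id) | df$protein_id == ""
  if (any(drop)) {
    warning(sum(drop), " CDS feature(s) without protein_id skipped")
    df <- df[!drop, , drop = FALSE]
  }
  if (nrow(df) && any(is.na(df$gene_id)))
    df$gene_id[is.na(df$gene_id)] <- df$protein_id[is.na(df$gene_id)]
  unknown <- setdiff(unique(df$replicon_id), names(replicons))
  if (length(unknown))
    stop("GFF3 references replicon(s) absent from FASTA: ",
         paste(unknown, collapse = ", "))
  genome_record(genome_id, replicons, df, organism = organism,
                phylum = phylum, multicellular = multicellular)
}

# minimal CDS extractor used when rtracklayer is unavailable
parse_gff3_cds <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9L)
  if (length(bad))
    stop("GFF3 line ", bad[1], ": expected 9 tab-separated columns")
  m <- do.call(rbind, fields)
  keep <- m[, 3] == "CDS"
  m <- m[keep, , drop = FALSE]
  if (!nrow(m))
    return(data.frame(replicon_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      gene_id = character(0), protein_id = character(0)))
  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(start) || anyNA(end))
    stop("GFF3: non-integer coordinate at CDS line ",
         which(is.na(start) | is.na(end))[1])
  attr_get <- function(attrs, key) {
    vapply(strsplit(attrs, ";", fixed = TRUE), function(kv) {
      kv <- trimws(kv)
      hit <- kv[startsWith(kv, paste0(key, "="))]
      if (length(hit)) sub("^[^=]*=", "", hit[1]) else NA_character_
    }, character(1L))
  }
  attrs <- m[, 9]
  data.frame(replicon_id = m[, 1], start = start, end = end,
             strand = m[, 7],
             gene_id = attr_get(attrs, "ID"),
             protein_id = attr_get(attrs, "protein_id"),
             stringsAsFactors = FALSE)
}

#' Read per-protein domain hits
#'
#' Two dialects are supported: a simple TSV with header `protein_id`,
#' `domain`, `ali_start`, `ali_end`, `score`, `evalue`, and the HMMER3
#' per-domain table (`domtblout`), from which the alignment coordinates
#' (`ali from`/`ali to`), the per-domain bit score and the independent
#' E-value are taken.
#'
#' @param path Input path.
#' @param dialect `"tsv"` or `"domtblout"`.
#' @return data.frame with columns `protein_id`, `domain`, `ali_start`,
#'   `ali_end`, `score`, `evalue`.
#' @export
read_domain_hits <- function(path, dialect = c("tsv", "domtblout")) {
  dialect <- match.arg(dialect)
  empty <- data.frame(protein_id = character(0), domain = character(0),
                      ali_start = integer(0), ali_end = integer(0),
                      score = numeric(0), evalue = numeric(0))
  if (dialect == "tsv") {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- names(empty)
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("domain hit TSV missing columns: ", paste(miss, collapse = ", "))
    df <- df[, need]
  } else {
    lines <- readLines(path)
    keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
    idx <- which(keep)
    if (!length(idx)) return(empty)
    fields <- strsplit(trimws(lines[idx]), "[ \t]+")
    bad <- which(lengths(fields) < 22L)
    if (length(bad))
      stop("domtblout line ", idx[bad[1]], ": expected >= 22 columns, got ",
           lengths(fields)[bad[1]])
    m <- t(vapply(fields, function(f) f[1:22], character(22L)))
    df <- data.frame(protein_id = m[, 1], domain = m[, 4],
                     ali_start = as.integer(m[, 18]),
                     ali_end = as.integer(m[, 19]),
                     score = as.numeric(m[, 14]),
                     evalue = as.numeric(m[, 13]),
                     stringsAsFactors = FALSE)
  }
  if (nrow(df)) {
    if (anyNA(df$ali_start) || anyNA(df$ali_end) ||
        any(df$ali_start < 1L) || any(df$ali_start > df$ali_end))
      stop("invalid alignment coordinates in domain hits")
    if (any(!is.finite(df$score))) stop("non-finite domain hit score")
    if (any(df$evalue < 0)) stop("negative evalue in domain hits")
  }
  rownames(df) <- NULL
  df
}

#' Write domain hits as TSV
#' @param hits data.frame as returned by [read_domain_hits()].
#' @param path Output path.
#' @export
write_domain_hits <- function(hits, path) {
  write_tsv(hits[, c("protein_id", "domain", "ali_start", "ali_end",
                     "score", "evalue")], path)
}

#' Read an aligned FASTA file into an MSA object
#'
#' @param path Path to an aligned FASTA (equal-length rows, gap `-`).
#' @return Object of class `msa`: list with `ids` and `rows`.
#' @export
read_msa_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  rows <- as.character(aa)
  if (length(unique(nchar(rows))) > 1L)
    stop("ragged alignment: rows have unequal lengths")
  if (anyDuplicated(ids)) stop("duplicate sequence ids in alignment")
  msa(ids, unname(rows))
}

#' Construct an MSA object
#' @param ids Character vector of row labels.
#' @param rows Equal-length gapped sequences.
#' @return An object of class `msa`.
#' @export
msa <- function(ids, rows) {
  stopifnot(length(ids) == length(rows))
  if (length(rows) && length(unique(nchar(rows))) > 1L)
    stop("ragged alignment: rows have unequal lengths")
  if (anyDuplicated(ids)) stop("duplicate sequence ids in alignment")
  structure(list(ids = as.character(ids), rows = toupper(as.character(rows))),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("<msa> ", length(x$ids), " sequences x ",
      if (length(x$rows)) nchar(x$rows[1]) else 0L, " columns\n", sep = "")
  invisible(x)
}

#' Write an MSA object as aligned FASTA
#' @param x An `msa` object.
#' @param path Output path.
#' @export
write_msa_fasta <- function(x, path) {
  writeLines(as.vector(rbind(paste0(">", x$ids), x$rows)), path)
  invisible(path)
}

#' Write protein sequences as FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  invisible(path)
}

#' Read protein sequences from FASTA
#' @param path Input path.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
}

#' Read a newick tree
#'
#' Thin wrapper over [ape::read.tree()] that additionally rejects duplicate
#' leaf labels, which would make tree-congruence comparisons ambiguous.
#'
#' @param path Path to a newick file containing a single tree.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (inherits(tr, "multiPhylo")) stop("expected a single tree, found several")
  if (is.null(tr)) stop("could not parse newick file: ", path)
  if (anyDuplicated(tr$tip.label)) stop("duplicate leaf labels in tree")
  tr
}

#' Read the organism metadata table
#'
#' TSV with columns `genome_id`, `phylum`, `multicellular`; the flag is one
#' of `True`, `False`, `NA` (case-insensitive), mirroring a curated
#' per-organism annotation of multicellular/colonial/aggregative habit.
#'
#' @param path Input path.
#' @return data.frame with a logical `multicellular` column (NA allowed).
#' @export
read_metadata <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = list(multicellular = "character"))
  miss <- setdiff(c("genome_id", "phylum", "multicellular"), names(df))
  if (length(miss))
    stop("metadata missing columns: ", paste(miss, collapse = ", "))
  flag <- as.character(df$multicellular)
  flag[is.na(flag)] <- "NA"  # read.delim treats literal NA as missing
  flag <- toupper(trimws(flag))
  ok <- flag %in% c("TRUE", "FALSE", "NA", "")
  if (!all(ok))
    stop("metadata row ", which(!ok)[1], ": multicellular flag '",
         df$multicellular[which(!ok)[1]], "' not in {True,False,NA}")
  df$multicellular <- ifelse(flag == "TRUE", TRUE,
                             ifelse(flag == "FALSE", FALSE, NA))
  df
}

#' Write the organism metadata table
#' @param metadata data.frame with `genome_id`, `phylum`, `multicellular`.
#' @param path Output path.
#' @export
write_metadata <- function(metadata, path) {
  out <- metadata
  out$multicellular <- ifelse(is.na(out$multicellular), "NA",
                              ifelse(out$multicellular, "True", "False"))
  write_tsv(out[, c("genome_id", "phylum", "multicellular")], path)
}

#' Merge organism metadata onto genome records
#' @param genomes Named list of `genome_record`s.
#' @param metadata data.frame from [read_metadata()].
#' @return The list with `phylum` and `multicellular` fields filled;
#'   genomes absent from the metadata get `NA`.
#' @export
merge_metadata <- function(genomes, metadata) {
  idx <- match(vapply(genomes, `[[`, "", "genome_id"), metadata$genome_id)
  for (i in seq_along(genomes)) {
    if (!is.na(idx[i])) {
      genomes[[i]]$phylum <- metadata$phylum[idx[i]]
      genomes[[i]]$multicellular <- metadata$multicellular[idx[i]]
    }
  }
  genomes
}

#' Write a data.frame as a deterministic TSV
#'
#' Fixed column order (as given), no quoting, no row names; used by every
#' writer in the package so that identical inputs yield byte-identical
#' files.
#'
#' @param df data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}
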