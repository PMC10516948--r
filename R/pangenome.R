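#' Read per-genome gene calls from a TSV file
#'
#' The table must carry `gene_id`, `genome_id`, `start`, `end`, `strand`
#' and may carry `contig` and `aa_sequence`. Coordinates are 0-based,
#' half-open; `nt_length = end - start` is recomputed, never trusted.
#'
#' @param path path to a tab-separated gene-call table.
#' @return a `data.frame` of validated gene calls with an `nt_length` column.
#' @export
read_gene_calls <- function(path) {
  gc <- .read_tsv(path, "gene calls")
  validate_gene_calls(gc)
}

#' Validate a gene-call table
#'
#' @param gene_calls data.frame of gene calls.
#' @return the validated table (invisibly modified: `nt_length` recomputed).
#' @export
validate_gene_calls <- function(gene_calls) {
  .assert_cols(gene_calls, c("gene_id", "genome_id", "start", "end", "strand"),
               "gene calls")
  if (anyDuplicated(gene_calls$gene_id))
    stop("duplicate gene_id in gene calls: ",
         paste(unique(gene_calls$gene_id[duplicated(gene_calls$gene_id)]),
               collapse = ", "), call. = FALSE)
  bad <- gene_calls$end <= gene_calls$start
  if (any(bad))
    stop("gene calls with end <= start: ",
         paste(gene_calls$gene_id[bad], collapse = ", "), call. = FALSE)
  if (!all(gene_calls$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
  gene_calls$nt_length <- gene_calls$end - gene_calls$start
  gene_calls
}

#' Cluster amino-acid gene sequences into gene clusters
#'
#' Deterministic greedy centroid clustering on amino-acid k-mer Jaccard
#' similarity. Genes are processed in lexicographic `gene_id` order
#' (C collation); each gene joins the first existing cluster whose centroid
#' (the founding gene's k-mer set) has Jaccard similarity at or above
#' `similarity_threshold`, otherwise it founds a new cluster. For
#' externally computed pangenomes (e.g. blastp+MCL workflows) use
#' [import_clusters()] instead.
#'
#' @param gene_calls gene-call table with non-missing `aa_sequence`.
#' @param similarity_threshold Jaccard threshold in (0, 1]. Default 0.7.
#' @param kmer_size amino-acid k-mer size, 1-6. Default 4.
#' @return a membership `data.frame` with columns `gene_id`, `genome_id`,
#'   `cluster_id`, one row per gene.
#' @export
cluster_genes <- function(gene_calls, similarity_threshold = 0.7,
                          kmer_size = 4) {
  if (NROW(gene_calls) == 0L)
    stop("cluster_genes: no gene calls supplied", call. = FALSE)
  .assert_cols(gene_calls, c("gene_id", "genome_id", "aa_sequence"),
               "gene calls")
  if (!is.numeric(similarity_threshold) || length(similarity_threshold) != 1 ||
      similarity_threshold <= 0 || similarity_threshold > 1)
    stop("similarity_threshold must be in (0, 1]", call. = FALSE)
  aa <- gene_calls$aa_sequence
  if (any(is.na(aa) | aa == ""))
    stop("gene calls without amino-acid sequences: ",
         paste(gene_calls$gene_id[is.na(aa) | aa == ""], collapse = ", "),
         call. = FALSE)
  short <- nchar(aa) < kmer_size
  if (any(short))
    stop("amino-acid sequence shorter than kmer_size for gene(s): ",
         paste(gene_calls$gene_id[short], collapse = ", "), call. = FALSE)

  ord <- .radix_order(gene_calls$gene_id)
  codes <- aa_kmer_codes_cpp(aa[ord], as.integer(kmer_size))
  idx <- greedy_cluster_cpp(codes, similarity_threshold)
  membership <- data.frame(
    gene_id = gene_calls$gene_id[ord],
    genome_id = gene_calls$genome_id[ord],
    cluster_id = sprintf("GC_%06d", idx),
    stringsAsFactors = FALSE
  )
  membership
}

#' Jaccard similarity between the amino-acid k-mer sets of two sequences
#'
#' @param a,b amino-acid sequence strings.
#' @param kmer_size k-mer size, 1-6.
#' @return similarity in \[0, 1\].
#' @export
kmer_jaccard <- function(a, b, kmer_size = 4) {
  codes <- aa_kmer_codes_cpp(c(a, b), as.integer(kmer_size))
  kmer_jaccard_cpp(codes[[1]], codes[[2]])
}

#' Import externally computed gene-cluster membership
#'
#' Accepts a path or data.frame with columns `gene_id`, `genome_id`,
#' `cluster_id` (the three columns pangenome summary exports provide).
#'
#' @param x path to a TSV file, or a data.frame.
#' @param known_genomes optional character vector of valid genome ids;
#'   rows naming other genomes are an error.
#' @return a membership `data.frame` (`gene_id`, `genome_id`, `cluster_id`).
#' @export
import_clusters <- function(x, known_genomes = NULL) {
  tbl <- if (is.character(x)) .read_tsv(x, "cluster membership") else x
  .assert_cols(tbl, c("gene_id", "genome_id", "cluster_id"),
               "cluster membership")
  dup <- duplicated(tbl$gene_id)
  if (any(dup))
    stop("gene(s) assigned to more than one cluster: ",
         paste(unique(tbl$gene_id[dup]), collapse = ", "), call. = FALSE)
  if (!is.null(known_genomes)) {
    unk <- setdiff(unique(tbl$genome_id), known_genomes)
    if (length(unk))
      stop("unknown genome_id in cluster membership: ",
           paste(unk, collapse = ", "), call. = FALSE)
  }
  tbl[, c("gene_id", "genome_id", "cluster_id")]
}

#' Write cluster membership to a TSV file
#'
#' Round-trips with [import_clusters()].
#'
#' @param membership membership data.frame.
#' @param path output path.
#' @export
export_clusters <- function(membership, path) {
  .assert_cols(membership, c("gene_id", "genome_id", "cluster_id"),
               "cluster membership")
  .write_tsv(membership[.radix_order(membership$gene_id), ], path)
}

#' Assemble a pangenome object
#'
#' @param gene_calls validated gene-call table covering all genomes.
#' @param membership gene-to-cluster membership covering a subset (usually
#'   all) of the gene calls.
#' @return an object of class `pangenome` with fields `gene_calls`,
#'   `membership`, `genome_ids`, `cluster_ids`, and (after
#'   [classify_core_accessory()]) `core_ids` / `accessory_ids`.
#' @export
pangenome <- function(gene_calls, membership) {
  gene_calls <- validate_gene_calls(gene_calls)
  membership <- import_clusters(membership,
                                known_genomes = unique(gene_calls$genome_id))
  stray <- setdiff(membership$gene_id, gene_calls$gene_id)
  if (length(stray))
    stop("cluster membership names gene(s) absent from gene calls: ",
         paste(utils::head(stray, 5), collapse = ", "), call. = FALSE)
  structure(list(
    gene_calls = gene_calls,
    membership = membership,
    genome_ids = sort(unique(gene_calls$genome_id), method = "radix"),
    cluster_ids = sort(unique(membership$cluster_id), method = "radix"),
    core_ids = NULL,
    accessory_ids = NULL,
    core_fraction = NA_real_
  ), class = "pangenome")
}

#' @export
print.pangenome <- function(x, ...) {
  cat(sprintf("pangenome: %d genomes, %d gene calls, %d gene clusters\n",
              length(x$genome_ids), nrow(x$gene_calls), length(x$cluster_ids)))
  if (!is.null(x$core_ids))
    cat(sprintf("  core: %d clusters (core_fraction = %g), accessory: %d\n",
                length(x$core_ids), x$core_fraction, length(x$accessory_ids)))
  invisible(x)
}

#' Partition gene clusters into core and accessory bins
#'
#' A cluster is core when it occurs in at least
#' `ceiling(core_fraction * n_genomes)` distinct genomes. The default
#' `core_fraction = 1` is the strict rule: core clusters are those detected
#' in every genome of the pangenome.
#'
#' @param pg a `pangenome` object.
#' @param core_fraction fraction in (0, 1]. Default 1.
#' @return the pangenome with `core_ids` and `accessory_ids` filled.
#' @export
classify_core_accessory <- function(pg, core_fraction = 1.0) {
  stopifnot(inherits(pg, "pangenome"))
  if (!is.numeric(core_fraction) || length(core_fraction) != 1 ||
      is.na(core_fraction) || core_fraction <= 0 || core_fraction > 1)
    stop("core_fraction must be in (0, 1]", call. = FALSE)
  u <- unique(pg$membership[, c("cluster_id", "genome_id")])
  n_gen <- table(u$cluster_id)
  need <- ceiling(core_fraction * length(pg$genome_ids))
  core <- names(n_gen)[as.integer(n_gen) >= need]
  pg$core_ids <- sort(core, method = "radix")
  pg$accessory_ids <- sort(setdiff(pg$cluster_ids, core), method = "radix")
  pg$core_fraction <- core_fraction
  pg
}

#' Per-cluster genome occupancy
#'
#' @param membership membership data.frame.
#' @return named integer vector: number of distinct genomes per cluster.
#' @export
cluster_genome_counts <- function(membership) {
  u <- unique(membership[, c("cluster_id", "genome_id")])
  tab <- table(u$cluster_id)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[sort(names(out), method = "radix")]
}

#' Read a functional-annotation table
#'
#' Columns: `gene_id`, `source`, `accession`, `function`.
#'
#' @param path TSV path.
#' @return validated annotation data.frame.
#' @export
read_annotations <- function(path) {
  ann <- .read_tsv(path, "annotations")
  .assert_cols(ann, c("gene_id", "source", "accession"), "annotations")
  ann
}

#' Fraction of gene clusters carrying at least one annotation from a source
#'
#' A cluster counts once no matter how many of its member genes are
#' annotated.
#'
#' @param membership membership data.frame.
#' @param annotations annotation data.frame (`gene_id`, `source`,
#'   `accession`).
#' @param source one of `r paste(ANNOTATION_SOURCES, collapse = ", ")`.
#' @return fraction in \[0, 1\].
#' @export
annotation_coverage <- function(membership, annotations, source) {
  if (!source %in% ANNOTATION_SOURCES)
    stop("unknown annotation source: ", source, " (expected one of ",
         paste(ANNOTATION_SOURCES, collapse = ", "), ")", call. = FALSE)
  .assert_cols(annotations, c("gene_id", "source", "accession"), "annotations")
  ann <- annotations[annotations$source == source &
                       !is.na(annotations$accession) &
                       annotations$accession != "", , drop = FALSE]
  clusters <- unique(membership$cluster_id)
  if (!length(clusters)) return(NA_real_)
  hit <- unique(membership$cluster_id[membership$gene_id %in% ann$gene_id])
  length(hit) / length(clusters)
}

#' Read genome sequences from FASTA files
#'
#' @param paths named character vector of FASTA paths; names are genome ids
#'   (defaults to file base names without extension).
#' @return named list of named character vectors (contig sequences) per
#'   genome.
#' @export
read_genomes <- function(paths) {
  if (is.null(names(paths)) || any(names(paths) == ""))
    names(paths) <- tools::file_path_sans_ext(basename(paths))
  out <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("genome FASTA not found: ", p, call. = FALSE)
    s <- Biostrings::readDNAStringSet(p)
    stats::setNames(as.character(s), names(s))
  })
  out
}
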