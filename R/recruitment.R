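#' Read a metatranscriptomic read library (FASTA or FASTQ)
#'
#' @param path sequence file; format inferred from the extension
#'   (`.fastq`/`.fq` vs FASTA otherwise).
#' @param library_id identifier for the library (defaults to the file base
#'   name).
#' @param sample_id sample the library belongs to (defaults to
#'   `library_id`).
#' @return a list with `library_id`, `sample_id`, `reads` (named character
#'   vector of nucleotide sequences).
#' @export
read_library <- function(path, library_id = NULL, sample_id = NULL) {
  if (!file.exists(path)) stop("read library not found: ", path, call. = FALSE)
  fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE))
    "fastq" else "fasta"
  s <- Biostrings::readDNAStringSet(path, format = fmt)
  if (!length(s)) stop("read library is empty: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(s))
  if (anyDuplicated(ids))
    stop("duplicate read ids in library: ", path, call. = FALSE)
  library_id <- library_id %||% tools::file_path_sans_ext(basename(path))
  list(library_id = library_id,
       sample_id = sample_id %||% library_id,
       reads = stats::setNames(as.character(s), ids))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.genome_kmer_index <- function(genome, kmer_size) {
  contigs <- if (is.list(genome)) genome else as.list(genome)
  if (!length(genome) || !sum(nchar(unlist(genome))))
    stop("pseudo_map: empty genome", call. = FALSE)
  km <- list(); ct <- list(); ps <- list()
  for (nm in names(genome)) {
    seq <- toupper(genome[[nm]])
    n <- nchar(seq)
    if (n < kmer_size) next
    starts <- seq_len(n - kmer_size + 1L)
    km[[nm]] <- substring(seq, starts, starts + kmer_size - 1L)
    ct[[nm]] <- rep(nm, length(starts))
    ps[[nm]] <- starts - 1L  # 0-based, matching gene-call coordinates
  }
  kmer <- unlist(km, use.names = FALSE)
  keep <- !duplicated(kmer)  # first occurrence wins for position lookup
  list(kmer = kmer[keep],
       contig = unlist(ct, use.names = FALSE)[keep],
       pos = unlist(ps, use.names = FALSE)[keep])
}

#' Pseudo-map reads to a genome by exact k-mer matching
#'
#' A read is mapped when at least `min_kmer_hits` of its k-mers (either
#' strand) occur in the genome. Each mapped read is attributed to the gene
#' whose interval contains the plurality of matched k-mer start positions;
#' reads with a tied vote are counted as mapped but excluded from per-gene
#' counts. This is a desk-scale stand-in for a read aligner; summaries from
#' real alignments enter through [import_recruitment()].
#'
#' @param reads named character vector of read sequences (or the list
#'   returned by [read_library()]).
#' @param genome named character vector of contig sequences.
#' @param gene_calls optional gene-call table for this genome (used for
#'   per-gene counts; `contig` column must match contig names).
#' @param kmer_size nucleotide k-mer size. Default 21.
#' @param min_kmer_hits minimum matching k-mers for a read to map.
#'   Default 5.
#' @return list with `mapped_ids`, `n_mapped`, `n_total`, `gene_counts`
#'   (named integer vector over `gene_calls$gene_id`), `ambiguous`
#'   (number of mapped reads dropped from gene counts by vote ties).
#' @export
pseudo_map <- function(reads, genome, gene_calls = NULL, kmer_size = 21,
                       min_kmer_hits = 5) {
  if (is.list(reads) && !is.null(reads$reads)) reads <- reads$reads
  if (!length(reads)) stop("pseudo_map: no reads", call. = FALSE)
  idx <- .genome_kmer_index(genome, kmer_size)

  ids <- names(reads) %||% as.character(seq_along(reads))
  reads <- toupper(reads)
  lens <- nchar(reads)
  nk <- pmax(lens - kmer_size + 1L, 0L)
  usable <- nk > 0L

  # forward and reverse-complement k-mers for all reads in one pass
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(reads[usable])))
  fw_km <- rv_km <- vector("list", length(reads))
  ui <- which(usable)
  for (j in seq_along(ui)) {
    i <- ui[j]
    starts <- seq_len(nk[i])
    fw_km[[i]] <- substring(reads[i], starts, starts + kmer_size - 1L)
    rv_km[[i]] <- substring(rc[j], starts, starts + kmer_size - 1L)
  }
  all_km <- c(unlist(fw_km, use.names = FALSE), unlist(rv_km, use.names = FALSE))
  read_of <- c(rep(seq_along(reads), nk), rep(seq_along(reads), nk))
  m <- match(all_km, idx$kmer)

  hit <- !is.na(m)
  hits_per_read <- tabulate(read_of[hit], nbins = length(reads))
  mapped <- hits_per_read >= min_kmer_hits

  gene_counts <- NULL
  ambiguous <- 0L
  if (!is.null(gene_calls)) {
    gene_calls <- validate_gene_calls(gene_calls)
    gene_counts <- stats::setNames(integer(nrow(gene_calls)),
                                   gene_calls$gene_id)
    if (any(mapped) && any(hit)) {
      hctg <- idx$contig[m[hit]]
      hpos <- idx$pos[m[hit]]
      hread <- read_of[hit]
      gidx <- .locate_genes(hctg, hpos, gene_calls)
      keep <- mapped[hread] & !is.na(gidx)
      if (any(keep)) {
        votes <- table(read = hread[keep], gene = gidx[keep])
        for (r in rownames(votes)) {
          v <- votes[r, ]
          top <- which(v == max(v) & v > 0)
          if (length(top) == 1L) {
            g <- as.integer(colnames(votes)[top])
            gene_counts[g] <- gene_counts[g] + 1L
          } else ambiguous <- ambiguous + 1L
        }
      }
    }
  }
  list(mapped_ids = ids[mapped], n_mapped = sum(mapped),
       n_total = length(reads), gene_counts = gene_counts,
       ambiguous = ambiguous)
}

# map (contig, 0-based position) pairs to row indices of gene_calls;
# NA where the position falls in no annotated gene
.locate_genes <- function(contig, pos, gene_calls) {
  out <- rep(NA_integer_, length(pos))
  ctg <- if ("contig" %in% names(gene_calls)) gene_calls$contig
         else gene_calls$genome_id
  for (cg in unique(contig)) {
    rows <- which(ctg == cg)
    if (!length(rows)) next
    ord <- rows[order(gene_calls$start[rows])]
    sel <- which(contig == cg)
    k <- findInterval(pos[sel], gene_calls$start[ord])
    ok <- k > 0 & pos[sel] < gene_calls$end[ord][pmax(k, 1L)]
    out[sel[ok]] <- ord[k[ok]]
  }
  out
}

#' Competitively screen read libraries against candidate genomes
#'
#' Runs [pseudo_map()] for every library x genome pair and tabulates
#' mapped-read counts and mapping rates.
#'
#' @param libraries list of libraries ([read_library()] outputs or named
#'   character vectors of reads; list names are library ids).
#' @param genomes named list of genomes (named character vectors of
#'   contigs).
#' @param kmer_size,min_kmer_hits passed to [pseudo_map()].
#' @return a recruitment summary `data.frame` with columns `library_id`,
#'   `genome_id`, `mapped_reads`, `total_reads`, `mapping_rate`.
#' @export
recruit_libraries <- function(libraries, genomes, kmer_size = 21,
                              min_kmer_hits = 5) {
  if (is.null(names(libraries)))
    names(libraries) <- vapply(libraries, function(l)
      if (is.list(l)) l$library_id else stop("unnamed library"), "")
  rows <- list()
  for (lib in names(libraries)) {
    rd <- libraries[[lib]]
    if (is.list(rd)) rd <- rd$reads
    for (g in names(genomes)) {
      pm <- pseudo_map(rd, genomes[[g]], kmer_size = kmer_size,
                       min_kmer_hits = min_kmer_hits)
      rows[[length(rows) + 1L]] <- data.frame(
        library_id = lib, genome_id = g,
        mapped_reads = pm$n_mapped, total_reads = pm$n_total,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$mapping_rate <- out$mapped_reads / out$total_reads
  out
}

#' Import a recruitment summary table
#'
#' @param x TSV path or data.frame with columns `library_id`, `genome_id`,
#'   `mapped_reads`, `total_reads`. `mapping_rate` is recomputed, never
#'   trusted from input.
#' @return validated recruitment summary data.frame.
#' @export
import_recruitment <- function(x) {
  tbl <- if (is.character(x)) .read_tsv(x, "recruitment summary") else x
  .assert_cols(tbl, c("library_id", "genome_id", "mapped_reads",
                      "total_reads"), "recruitment summary")
  if (!.is_count(tbl$mapped_reads) || !.is_count(tbl$total_reads))
    stop("mapped_reads/total_reads must be non-negative integers",
         call. = FALSE)
  if (any(tbl$mapped_reads > tbl$total_reads))
    stop("mapped_reads exceeds total_reads for: ",
         paste(tbl$library_id[tbl$mapped_reads > tbl$total_reads],
               tbl$genome_id[tbl$mapped_reads > tbl$total_reads],
               sep = "/", collapse = ", "), call. = FALSE)
  tot <- tapply(tbl$total_reads, tbl$library_id, function(v) length(unique(v)))
  if (any(tot > 1))
    stop("total_reads differs across genomes within library: ",
         paste(names(tot)[tot > 1], collapse = ", "), call. = FALSE)
  tbl <- tbl[, c("library_id", "genome_id", "mapped_reads", "total_reads")]
  tbl$mapping_rate <- tbl$mapped_reads / tbl$total_reads
  tbl
}

#' Select the best reference genome from a recruitment summary
#'
#' The reference is the genome with the largest mean mapped-read count
#' across libraries; ties are broken by mean mapping rate, then by
#' lexicographic genome id.
#'
#' @param summary recruitment summary (see [import_recruitment()]).
#' @return list with `genome_id` (the selected reference) and `ranking`
#'   (data.frame of per-genome mean counts and rates, best first).
#' @export
select_reference <- function(summary) {
  summary <- import_recruitment(summary)
  if (!nrow(summary)) stop("empty recruitment summary", call. = FALSE)
  agg <- aggregate(cbind(mean_mapped = mapped_reads,
                         mean_rate = mapping_rate) ~ genome_id,
                   data = summary, FUN = mean)
  ord <- order(-agg$mean_mapped, -agg$mean_rate,
               agg$genome_id, method = "radix")
  ranking <- agg[ord, , drop = FALSE]
  rownames(ranking) <- NULL
  list(genome_id = ranking$genome_id[1], ranking = ranking)
}
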