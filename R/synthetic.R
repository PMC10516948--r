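#' Simulation configuration
#'
#' Defaults emulate the microcosm study design this package targets: five
#' treatments (BC, DISP, WAF, CEWAF, CEWAFN), triplicate libraries,
#' sampling days 0/7/17/28/42 with CEWAFN restricted to 0/7/42, and a
#' pangenome with a strict core shared by all genomes plus accessory
#' clusters carried by genome subsets.
#'
#' @param n_genomes number of genomes in the pangenome.
#' @param n_core_clusters clusters present in every genome.
#' @param n_accessory_clusters clusters present in genome subsets.
#' @param accessory_occurrence_prob per-genome carriage probability of an
#'   accessory cluster (at least one carrier enforced).
#' @param gene_length_range gene length range in bp (rounded to codons).
#' @param dna_substitution_rate per-base substitution rate applied to each
#'   cluster member relative to the cluster seed. Two members diverge at
#'   twice this rate, and every changed residue removes up to `k` shared
#'   amino-acid k-mers, so the default keeps within-cluster 4-mer Jaccard
#'   comfortably above the 0.7 clustering threshold even for the shortest
#'   genes.
#' @param treatments treatment labels; `BC` must be present.
#' @param replicates libraries per treatment x timepoint.
#' @param timepoints sampling days.
#' @param cewafn_timepoints sampling days for CEWAFN.
#' @param nb_dispersion NB dispersion alpha of simulated counts (0 =
#'   Poisson).
#' @param baseline_mean median per-gene baseline mean count.
#' @param baseline_sdlog log-normal spread of per-gene baselines.
#' @param n_genes number of genes for cluster-free count simulation
#'   (ignored when a pangenome truth is supplied).
#' @param n_de_genes number of DE genes to plant (one per chosen cluster
#'   when a pangenome truth is supplied).
#' @param de_log2fc planted absolute log2 fold change.
#' @param rho_core fraction of DE-containing clusters placed in the core.
#' @param read_length simulated read length (bp).
#' @param reads_per_library reads per simulated library.
#' @param error_rate per-base substitution error rate of simulated reads.
#' @param rng_seed master seed; every artifact derives its own stream from
#'   it.
#' @return validated `sim_config` list.
#' @export
sim_config <- function(n_genomes = 20,
                       n_core_clusters = 200,
                       n_accessory_clusters = 300,
                       accessory_occurrence_prob = 0.6,
                       gene_length_range = c(300, 1500),
                       dna_substitution_rate = 0.003,
                       treatments = TREATMENTS,
                       replicates = 3,
                       timepoints = c(0, 7, 17, 28, 42),
                       cewafn_timepoints = c(0, 7, 42),
                       nb_dispersion = 0.1,
                       baseline_mean = 50,
                       baseline_sdlog = 1,
                       n_genes = NULL,
                       n_de_genes = 250,
                       de_log2fc = 2,
                       rho_core = 0.4,
                       read_length = 100,
                       reads_per_library = 2000,
                       error_rate = 0.01,
                       rng_seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_genomes >= 1, n_core_clusters >= 0, n_accessory_clusters >= 0,
            n_core_clusters + n_accessory_clusters >= 1,
            accessory_occurrence_prob > 0, accessory_occurrence_prob < 1,
            length(gene_length_range) == 2, gene_length_range[1] >= 30,
            gene_length_range[2] >= gene_length_range[1],
            dna_substitution_rate >= 0, dna_substitution_rate < 1,
            "BC" %in% treatments, replicates >= 1,
            nb_dispersion >= 0, baseline_mean > 0, baseline_sdlog >= 0,
            n_de_genes >= 0, de_log2fc >= 0, rho_core >= 0, rho_core <= 1,
            read_length >= 21, reads_per_library >= 1,
            error_rate >= 0, error_rate < 1)
  cfg$rng_seed <- as.integer(rng_seed)
  class(cfg) <- "sim_config"
  cfg
}

.BASES <- c("A", "C", "G", "T")
.STOP <- c("TAA", "TAG", "TGA")

.random_cds <- function(len_codons) {
  codons <- apply(matrix(sample(.BASES, 3 * len_codons, replace = TRUE),
                         ncol = 3), 1, paste0, collapse = "")
  while (any(codons %in% .STOP))
    codons[codons %in% .STOP] <-
      apply(matrix(sample(.BASES, 3 * sum(codons %in% .STOP),
                          replace = TRUE), ncol = 3), 1, paste0,
            collapse = "")
  paste0("ATG", paste(codons, collapse = ""))
}

.mutate_dna <- function(seq, rate) {
  if (rate <= 0) return(seq)
  x <- strsplit(seq, "")[[1]]
  nm <- rbinom(1, length(x), rate)
  if (nm > 0) {
    pos <- sample.int(length(x), nm)
    x[pos] <- sample(.BASES, nm, replace = TRUE)
  }
  paste(x, collapse = "")
}

.translate_dna <- function(dna) {
  as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAStringSet(dna),
                          if.fuzzy.codon = "X")))
}

#' Simulate a pangenome with known cluster truth
#'
#' Core clusters occur in every genome; each accessory cluster occurs in a
#' Bernoulli subset (at least one genome enforced). Members of a cluster
#' are lightly mutated copies of a cluster seed coding sequence, so
#' [cluster_genes()] can recover the planted partition. About 30% of genes
#' are placed on the minus strand; about 70% of clusters receive a KOfam
#' annotation.
#'
#' @param config a [sim_config()].
#' @return list with `genomes` (named list of contig vectors),
#'   `gene_calls`, `annotations`, and `truth` (planted membership, core
#'   cluster ids, reference genome id, config echo).
#' @export
generate_pangenome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(.seed_offset(config$rng_seed, "pangenome"), {
    n_cl <- config$n_core_clusters + config$n_accessory_clusters
    cluster_ids <- sprintf("TC%04d", seq_len(n_cl))
    is_core <- seq_len(n_cl) <= config$n_core_clusters
    genome_ids <- sprintf("G%02d", seq_len(config$n_genomes))

    len_codons <- round(runif(n_cl, config$gene_length_range[1],
                              config$gene_length_range[2]) / 3)
    seeds <- vapply(len_codons, .random_cds, "")

    presence <- matrix(TRUE, n_cl, config$n_genomes,
                       dimnames = list(cluster_ids, genome_ids))
    for (i in which(!is_core)) {
      carry <- runif(config$n_genomes) < config$accessory_occurrence_prob
      if (!any(carry)) carry[sample.int(config$n_genomes, 1)] <- TRUE
      presence[i, ] <- carry
    }

    genomes <- list()
    gc_rows <- list()
    mem_rows <- list()
    for (j in seq_along(genome_ids)) {
      g <- genome_ids[j]
      cl_here <- which(presence[, j])
      parts <- character(0)
      pos <- 0L
      rows <- vector("list", length(cl_here))
      for (t in seq_along(cl_here)) {
        i <- cl_here[t]
        dna <- .mutate_dna(seeds[i], config$dna_substitution_rate)
        strand <- if (runif(1) < 0.3) "-" else "+"
        spacer <- paste(sample(.BASES, sample(50:200, 1), replace = TRUE),
                        collapse = "")
        genomic <- if (strand == "-")
          as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(dna))) else dna
        start <- pos + nchar(spacer)
        end <- start + nchar(dna)
        parts <- c(parts, spacer, genomic)
        pos <- end
        rows[[t]] <- data.frame(
          gene_id = sprintf("%s_g%04d", g, t), genome_id = g,
          contig = paste0(g, "_c1"), start = start, end = end,
          strand = strand, aa_sequence = NA_character_,
          cluster_id = cluster_ids[i], dna = dna,
          stringsAsFactors = FALSE)
      }
      gcj <- do.call(rbind, rows)
      gcj$aa_sequence <- .translate_dna(gcj$dna)
      genomes[[g]] <- stats::setNames(paste(parts, collapse = ""),
                                      paste0(g, "_c1"))
      gc_rows[[j]] <- gcj
    }
    gc_all <- do.call(rbind, gc_rows)
    membership <- gc_all[, c("gene_id", "genome_id", "cluster_id")]
    gene_calls <- validate_gene_calls(
      gc_all[, c("gene_id", "genome_id", "contig", "start", "end",
                 "strand", "aa_sequence")])

    annotated <- runif(n_cl) < 0.7
    ann <- gc_all[gc_all$cluster_id %in% cluster_ids[annotated], ,
                  drop = FALSE]
    ko <- sprintf("K%05d", match(ann$cluster_id, cluster_ids))
    annotations <- data.frame(
      gene_id = ann$gene_id, source = "KOfam", accession = ko,
      `function.` = paste("simulated function", ko),
      check.names = FALSE, stringsAsFactors = FALSE)
    names(annotations)[4] <- "function"

    list(genomes = genomes, gene_calls = gene_calls,
         annotations = annotations,
         truth = list(membership = membership,
                      core_ids = cluster_ids[is_core],
                      cluster_ids = cluster_ids,
                      reference_genome_id = genome_ids[1],
                      gene_dna = stats::setNames(gc_all$dna, gc_all$gene_id),
                      rng_seed = config$rng_seed,
                      config = unclass(config)))
  })
}

.design_samples <- function(config) {
  rows <- list()
  for (tr in config$treatments) {
    tps <- if (tr == "CEWAFN") config$cewafn_timepoints else config$timepoints
    for (tp in tps)
      for (r in seq_len(config$replicates))
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_t%02d_r%d", tr, tp, r),
          treatment = tr, time_days = tp, replicate = paste0("r", r),
          stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Simulate a treatment-structured count matrix with known DE truth
#'
#' Counts are NB(mean = baseline x 2^(lfc x treatment indicator) x library
#' size multiplier, dispersion alpha); library size multipliers are
#' log-uniform in \[0.5, 2\]. With a pangenome `truth`, genes are the
#' reference genome's gene calls and DE genes are planted one per chosen
#' cluster so that a fraction `rho_core` of DE-containing clusters are
#' core; planted effects apply (with a random common sign per gene) to all
#' non-control treatments. Without `truth`, `config$n_genes` cluster-free
#' genes are simulated.
#'
#' @param config a [sim_config()].
#' @param truth optional `truth` element of [generate_pangenome()] output.
#' @return list with `counts`, `gene_length`, `samples`, and `truth`
#'   (extended with the planted DE table and per-gene means).
#' @export
generate_counts <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(.seed_offset(config$rng_seed, "counts"), {
    if (!is.null(truth)) {
      ref <- truth$reference_genome_id
      mem <- truth$membership
      ref_mem <- mem[mem$genome_id == ref, , drop = FALSE]
      gene_ids <- sort(ref_mem$gene_id, method = "radix")
      gene_cluster <- ref_mem$cluster_id[match(gene_ids, ref_mem$gene_id)]
      gene_length <- stats::setNames(
        nchar(truth$gene_dna[gene_ids]), gene_ids)

      core_cl <- unique(gene_cluster[gene_cluster %in% truth$core_ids])
      acc_cl <- unique(setdiff(gene_cluster, truth$core_ids))
      n_core_de <- round(config$rho_core * config$n_de_genes)
      n_acc_de <- config$n_de_genes - n_core_de
      if (n_core_de > length(core_cl) || n_acc_de > length(acc_cl))
        stop(sprintf(paste("more DE genes requested than clusters available",
                           "(core: %d needed / %d available, accessory:",
                           "%d / %d)"),
                     n_core_de, length(core_cl), n_acc_de, length(acc_cl)),
             call. = FALSE)
      de_cl <- c(sample(core_cl, n_core_de), sample(acc_cl, n_acc_de))
      de_genes <- vapply(de_cl, function(cl)
        sample(gene_ids[gene_cluster == cl], 1), "")
    } else {
      if (is.null(config$n_genes))
        stop("generate_counts without pangenome truth needs config$n_genes",
             call. = FALSE)
      gene_ids <- sprintf("g%05d", seq_len(config$n_genes))
      gene_length <- stats::setNames(
        round(runif(config$n_genes, config$gene_length_range[1],
                    config$gene_length_range[2])), gene_ids)
      gene_cluster <- rep(NA_character_, length(gene_ids))
      if (config$n_de_genes > length(gene_ids))
        stop("more DE genes requested than genes available", call. = FALSE)
      de_genes <- sample(gene_ids, config$n_de_genes)
      de_cl <- rep(NA_character_, length(de_genes))
    }

    samples <- .design_samples(config)
    n_g <- length(gene_ids); n_s <- nrow(samples)
    baseline <- rlnorm(n_g, log(config$baseline_mean), config$baseline_sdlog)
    names(baseline) <- gene_ids
    size_mult <- exp(runif(n_s, log(0.5), log(2)))
    names(size_mult) <- samples$sample_id

    lfc <- stats::setNames(numeric(n_g), gene_ids)
    dir_sign <- sample(c(-1, 1), length(de_genes), replace = TRUE)
    lfc[de_genes] <- dir_sign * config$de_log2fc

    trt_ind <- as.numeric(samples$treatment != "BC")
    mu <- outer(baseline, size_mult) * 2^(lfc %o% trt_ind)
    counts <- if (config$nb_dispersion > 0)
      matrix(rnbinom(n_g * n_s, mu = as.vector(mu),
                     size = 1 / config$nb_dispersion), n_g, n_s)
    else matrix(rpois(n_g * n_s, as.vector(mu)), n_g, n_s)
    dimnames(counts) <- list(gene_ids, samples$sample_id)
    storage.mode(counts) <- "double"

    de_truth <- data.frame(
      gene_id = de_genes, cluster_id = de_cl,
      direction = if (length(de_genes)) ifelse(dir_sign > 0, "up", "down")
                  else character(),
      log2fc = dir_sign * config$de_log2fc,
      treatments = rep(paste(setdiff(config$treatments, "BC"),
                             collapse = ","), length(de_genes)),
      stringsAsFactors = FALSE, row.names = NULL)

    out_truth <- c(truth %||% list(),
                   list(de = de_truth, baseline = baseline,
                        size_multiplier = size_mult,
                        gene_cluster = stats::setNames(gene_cluster,
                                                       gene_ids),
                        rng_seed = config$rng_seed))
    list(counts = counts, gene_length = gene_length, samples = samples,
         truth = out_truth)
  })
}

#' Simulate read libraries from a genome's gene content
#'
#' Fixed-length reads are drawn from gene intervals with probability
#' proportional to per-gene expression weights, copied from the coding
#' sequence (strand-aware), and perturbed by substitution errors. Genes
#' shorter than the read length are skipped (with a recorded skip count).
#'
#' @param config a [sim_config()].
#' @param sim output of [generate_pangenome()].
#' @param genome_id genome to draw reads from (default: the truth
#'   reference genome).
#' @param n_libraries number of libraries to simulate.
#' @param expression optional named per-gene expression weights (default
#'   uniform over the genome's genes).
#' @return list of libraries, each with `library_id`, `reads` (named
#'   character), `truth_counts` (reads drawn per gene), `n_skipped`.
#' @export
generate_reads <- function(config, sim, genome_id = NULL, n_libraries = 1,
                           expression = NULL) {
  stopifnot(inherits(config, "sim_config"))
  genome_id <- genome_id %||% sim$truth$reference_genome_id
  gc <- sim$gene_calls[sim$gene_calls$genome_id == genome_id, , drop = FALSE]
  if (!nrow(gc)) stop("no gene calls for genome ", genome_id, call. = FALSE)
  dna <- sim$truth$gene_dna[gc$gene_id]
  ok <- nchar(dna) >= config$read_length
  n_skipped_genes <- sum(!ok)
  if (n_skipped_genes)
    warning(sprintf("%d gene(s) shorter than the read length were skipped",
                    n_skipped_genes))
  gc <- gc[ok, , drop = FALSE]; dna <- dna[ok]
  w <- if (is.null(expression)) rep(1, nrow(gc))
       else as.numeric(expression[gc$gene_id])
  w[is.na(w)] <- 0
  if (sum(w) <= 0) stop("no positive expression weights", call. = FALSE)

  libs <- list()
  for (l in seq_len(n_libraries)) {
    lib_id <- sprintf("%s_lib%02d", genome_id, l)
    libs[[lib_id]] <- withr::with_seed(
      .seed_offset(config$rng_seed, paste0("reads_", lib_id)), {
        gi <- sample.int(nrow(gc), config$reads_per_library, replace = TRUE,
                         prob = w)
        starts <- vapply(gi, function(i)
          sample.int(nchar(dna[i]) - config$read_length + 1L, 1L), 1L)
        reads <- substring(dna[gi], starts,
                           starts + config$read_length - 1L)
        if (config$error_rate > 0)
          reads <- vapply(reads, .mutate_dna, "",
                          rate = config$error_rate, USE.NAMES = FALSE)
        names(reads) <- sprintf("%s_read%05d", lib_id,
                                seq_len(config$reads_per_library))
        truth_counts <- stats::setNames(
          tabulate(gi, nbins = nrow(gc)), gc$gene_id)
        list(library_id = lib_id, reads = reads,
             truth_counts = truth_counts, n_skipped = n_skipped_genes)
      })
  }
  libs
}

#' Write simulated data in the formats the pipeline reads
#'
#' @param sim [generate_pangenome()] output.
#' @param dir output directory.
#' @param counts optional [generate_counts()] output.
#' @param reads optional [generate_reads()] output (written as FASTQ).
#' @return invisibly, the directory.
#' @export
write_simulation <- function(sim, dir, counts = NULL, reads = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in names(sim$genomes)) {
    ss <- Biostrings::DNAStringSet(sim$genomes[[g]])
    Biostrings::writeXStringSet(ss, file.path(dir, paste0(g, ".fasta")))
  }
  .write_tsv(sim$gene_calls, file.path(dir, "gene_calls.tsv"))
  .write_tsv(sim$annotations, file.path(dir, "annotations.tsv"))
  export_clusters(sim$truth$membership, file.path(dir, "true_clusters.tsv"))
  truth <- sim$truth
  truth$gene_dna <- NULL  # sequences already live in the FASTA files
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(counts)) {
    write_counts(counts$counts, counts$gene_length,
                 file.path(dir, "counts.tsv"))
    .write_tsv(counts$samples, file.path(dir, "samples.tsv"))
    .write_tsv(counts$truth$de, file.path(dir, "true_de.tsv"))
  }
  if (!is.null(reads)) {
    for (lib in names(reads)) {
      rd <- Biostrings::DNAStringSet(reads[[lib]]$reads)
      qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(rd)))
      Biostrings::writeXStringSet(
        rd, file.path(dir, paste0(lib, ".fastq")), format = "fastq",
        qualities = qual)
    }
  }
  invisible(dir)
}

#' Cross-check emitted truth against emitted data
#'
#' Verifies the invariants the generator promises: every gene in exactly
#' one cluster, core clusters present in all genomes, gene calls
#' consistent with genome sequences, and (when supplied) count-matrix
#' dimensions matching the sample table and DE truth genes existing.
#'
#' @param sim [generate_pangenome()] output.
#' @param counts optional [generate_counts()] output.
#' @return `TRUE` invisibly; errors on any inconsistency.
#' @export
validate_truth <- function(sim, counts = NULL) {
  mem <- sim$truth$membership
  if (anyDuplicated(mem$gene_id))
    stop("truth violated: gene in more than one cluster", call. = FALSE)
  if (!setequal(mem$gene_id, sim$gene_calls$gene_id))
    stop("truth violated: membership does not cover the gene calls",
         call. = FALSE)
  n_gen <- length(unique(sim$gene_calls$genome_id))
  occ <- cluster_genome_counts(mem)
  if (!all(occ[sim$truth$core_ids] == n_gen))
    stop("truth violated: a core cluster is missing from some genome",
         call. = FALSE)
  # spot-check coordinates: the genomic interval must encode the gene
  gc <- sim$gene_calls
  idx <- seq(1, nrow(gc), length.out = min(25, nrow(gc)))
  for (i in unique(round(idx))) {
    contig <- sim$genomes[[gc$genome_id[i]]][[gc$contig[i]]]
    sub <- substr(contig, gc$start[i] + 1, gc$end[i])
    dna <- sim$truth$gene_dna[[gc$gene_id[i]]]
    if (gc$strand[i] == "-")
      sub <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(sub)))
    if (!identical(sub, dna))
      stop("truth violated: gene call coordinates do not match sequence for ",
           gc$gene_id[i], call. = FALSE)
  }
  if (!is.null(counts)) {
    if (!identical(colnames(counts$counts), counts$samples$sample_id))
      stop("truth violated: count columns do not match the sample table",
           call. = FALSE)
    if (!all(counts$truth$de$gene_id %in% rownames(counts$counts)))
      stop("truth violated: DE truth gene absent from count matrix",
           call. = FALSE)
  }
  invisible(TRUE)
}
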