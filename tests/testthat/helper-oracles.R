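# Independent reference implementations used as oracles. These are written
# from the definitions alone and share no code with the package internals.

# k-mer set of an amino-acid string
oracle_kmers <- function(s, k) {
  s <- toupper(s)
  n <- nchar(s)
  if (n < k) return(character())
  unique(substring(s, 1:(n - k + 1), k:n))
}

oracle_jaccard <- function(a, b, k) {
  A <- oracle_kmers(a, k)
  B <- oracle_kmers(b, k)
  length(intersect(A, B)) / length(union(A, B))
}

# brute-force greedy centroid assignment: genes in lexicographic gene_id
# order; first centroid (founder sequence) at or above the threshold wins
oracle_cluster <- function(gene_calls, threshold = 0.7, k = 4) {
  gc <- gene_calls[order(gene_calls$gene_id, method = "radix"), ,
                   drop = FALSE]
  centroids <- character()
  assign <- integer(nrow(gc))
  for (i in seq_len(nrow(gc))) {
    hit <- 0L
    for (ci in seq_along(centroids)) {
      if (oracle_jaccard(gc$aa_sequence[i], centroids[ci], k) >= threshold) {
        hit <- ci
        break
      }
    }
    if (!hit) {
      centroids <- c(centroids, gc$aa_sequence[i])
      hit <- length(centroids)
    }
    assign[i] <- hit
  }
  stats::setNames(assign, gc$gene_id)
}

# brute-force scan of the DE table against the membership table
oracle_layers <- function(de, membership, reference_genome_id) {
  ref <- membership[membership$genome_id == reference_genome_id, ,
                    drop = FALSE]
  out <- list()
  for (tr in unique(de$contrast)) {
    for (dir_ in c("up", "down")) {
      genes <- de$gene_id[de$contrast == tr & de$status == dir_]
      for (cl in unique(ref$cluster_id)) {
        members <- ref$gene_id[ref$cluster_id == cl]
        if (any(members %in% genes))
          out[[length(out) + 1L]] <- data.frame(
            treatment = tr, direction = dir_, cluster_id = cl,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(treatment = character(), direction = character(),
                      cluster_id = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$treatment, res$direction, res$cluster_id,
            method = "radix"), , drop = FALSE]
}

# random amino-acid string
rand_aa <- function(n) paste(sample(setdiff(LETTERS, c("B", "J", "O",
                                                       "U", "X", "Z")),
                                    n, replace = TRUE), collapse = "")

# perturb a few residues of an amino-acid string
perturb_aa <- function(s, n_subs) {
  x <- strsplit(s, "")[[1]]
  pos <- sample.int(length(x), n_subs)
  x[pos] <- sample(LETTERS[1:20], n_subs, replace = TRUE)
  paste(x, collapse = "")
}

# three planted families of perturbed copies, for oracle-equivalence tests
make_family_fixture <- function(n_families = 3, copies = 4, len = 40,
                                n_subs = 1) {
  seeds <- replicate(n_families, rand_aa(len))
  rows <- list()
  for (f in seq_len(n_families))
    for (cp in seq_len(copies))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = sprintf("fam%d_g%d", f, cp),
        genome_id = sprintf("G%d", cp),
        aa_sequence = if (cp == 1) seeds[f] else perturb_aa(seeds[f], n_subs),
        family = f, stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

# membership table: n_core clusters in all genomes, n_acc in genome 1 only
make_membership_fixture <- function(n_core, n_acc, genomes = c("GA", "GB")) {
  core_idx <- rep(seq_len(n_core), each = length(genomes))
  core_gen <- rep(genomes, times = n_core)
  acc_idx <- n_core + seq_len(n_acc)
  idx <- c(core_idx, acc_idx)
  gen <- c(core_gen, rep(genomes[1], n_acc))
  data.frame(gene_id = sprintf("c%04d_%s", idx, gen),
             genome_id = gen,
             cluster_id = sprintf("CL%04d", idx),
             stringsAsFactors = FALSE)
}

# gene calls consistent with a membership fixture (dummy coordinates)
gene_calls_for <- function(membership) {
  data.frame(gene_id = membership$gene_id,
             genome_id = membership$genome_id,
             contig = paste0(membership$genome_id, "_c1"),
             start = (seq_len(nrow(membership)) - 1L) * 1000L,
             end = seq_len(nrow(membership)) * 1000L - 100L,
             strand = "+", stringsAsFactors = FALSE)
}
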