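#' Project DE calls onto gene clusters as per-treatment layers
#'
#' For every treatment contrast and direction (up / down), a cluster is
#' flagged when at least one of its member genes from the reference genome
#' has that DE status. Reference-genome DE genes that belong to no cluster
#' are reported as orphans (attribute `orphans`), never silently dropped.
#'
#' @param de DE result table ([wald_test()] / [wald_test_all()] output),
#'   possibly spanning several contrasts.
#' @param membership gene-to-cluster membership (see [import_clusters()]).
#' @param reference_genome_id genome the DE genes belong to.
#' @param gene_calls optional gene-call table; when supplied, every DE gene
#'   must appear among the reference genome's gene calls (error otherwise).
#' @return a `data.frame` of flagged (treatment, direction, cluster)
#'   triples with the number of supporting DE genes (`n_genes`), class
#'   `ca_layers`; attributes `orphans` (character) and `gene_counts`
#'   (per treatment x direction DE gene tallies).
#' @export
map_de_to_clusters <- function(de, membership, reference_genome_id,
                               gene_calls = NULL) {
  .assert_cols(de, c("gene_id", "contrast", "status"), "DE results")
  .assert_cols(membership, c("gene_id", "genome_id", "cluster_id"),
               "cluster membership")
  if (!is.null(gene_calls)) {
    ref_genes <- gene_calls$gene_id[gene_calls$genome_id ==
                                      reference_genome_id]
    unk <- setdiff(unique(de$gene_id), ref_genes)
    if (length(unk))
      stop("DE gene(s) not found among reference gene calls: ",
           paste(utils::head(unk, 5), collapse = ", "), call. = FALSE)
  }
  ref_mem <- membership[membership$genome_id == reference_genome_id, ,
                        drop = FALSE]
  hits <- de[de$status %in% c("up", "down"), , drop = FALSE]
  orphans <- sort(setdiff(unique(hits$gene_id), ref_mem$gene_id),
                  method = "radix")
  hits$cluster_id <- ref_mem$cluster_id[match(hits$gene_id, ref_mem$gene_id)]
  hits <- hits[!is.na(hits$cluster_id), , drop = FALSE]

  de_hits <- de[de$status %in% c("up", "down"), , drop = FALSE]
  gene_counts <- if (nrow(de_hits))
    aggregate(gene_id ~ contrast + status, data = de_hits, FUN = length)
  else data.frame(contrast = character(), status = character(),
                  gene_id = integer(), stringsAsFactors = FALSE)
  names(gene_counts) <- c("treatment", "direction", "n_genes")

  if (nrow(hits)) {
    layers <- aggregate(gene_id ~ contrast + status + cluster_id,
                        data = hits, FUN = length)
    names(layers) <- c("treatment", "direction", "cluster_id", "n_genes")
    layers <- layers[.radix_order(layers$treatment, layers$direction,
                                  layers$cluster_id), , drop = FALSE]
    rownames(layers) <- NULL
  } else {
    layers <- data.frame(treatment = character(), direction = character(),
                         cluster_id = character(), n_genes = integer(),
                         stringsAsFactors = FALSE)
  }
  structure(layers, class = c("ca_layers", "data.frame"),
            orphans = orphans, gene_counts = gene_counts,
            reference_genome_id = reference_genome_id)
}

#' Summarize a DE layer set over the core/accessory partition
#'
#' A cluster counts as DE when it is flagged in any treatment and any
#' direction; the headline statistic is
#' `core_pct = 100 * |DE clusters in core| / |DE clusters|`.
#'
#' @param layers `ca_layers` from [map_de_to_clusters()] (or any data.frame
#'   with `treatment`, `direction`, `cluster_id`).
#' @param pg a partitioned `pangenome` (after [classify_core_accessory()]).
#' @return object of class `ca_summary`: list with `overall`
#'   (`n_de_clusters_total`, `n_de_clusters_core`,
#'   `n_de_clusters_accessory`, `core_pct`, `accessory_pct`),
#'   `per_treatment` (same tallies per treatment), and `gene_counts`
#'   (per treatment x direction DE gene counts, when available).
#' @export
summarize_core_accessory <- function(layers, pg) {
  stopifnot(inherits(pg, "pangenome"))
  if (is.null(pg$core_ids))
    stop("pangenome is not partitioned; run classify_core_accessory() first",
         call. = FALSE)
  .assert_cols(layers, c("treatment", "direction", "cluster_id"), "layers")
  stray <- setdiff(unique(layers$cluster_id), pg$cluster_ids)
  if (length(stray))
    stop("layer cluster(s) absent from the pangenome: ",
         paste(utils::head(stray, 5), collapse = ", "), call. = FALSE)

  tally <- function(cl) {
    cl <- unique(cl)
    n <- length(cl)
    n_core <- length(intersect(cl, pg$core_ids))
    list(n_de_clusters_total = n,
         n_de_clusters_core = n_core,
         n_de_clusters_accessory = n - n_core,
         core_pct = if (n > 0) 100 * n_core / n else NA_real_,
         accessory_pct = if (n > 0) 100 * (n - n_core) / n else NA_real_)
  }
  overall <- tally(layers$cluster_id)
  per_treatment <- do.call(rbind, lapply(
    sort(unique(layers$treatment), method = "radix"), function(tr) {
      t <- tally(layers$cluster_id[layers$treatment == tr])
      data.frame(treatment = tr, t, stringsAsFactors = FALSE)
    }))
  structure(list(overall = overall, per_treatment = per_treatment,
                 gene_counts = attr(layers, "gene_counts")),
            class = "ca_summary")
}

#' Core/accessory percentages from printed DE-cluster counts
#'
#' Worked-example utility: given the number of DE clusters in the core
#' pangenome and the total number of DE clusters, return the summary
#' fractions without rerunning the pipeline.
#'
#' @param n_core DE clusters in the core pangenome.
#' @param n_total total DE clusters in the pangenome.
#' @return `ca_summary`-style overall list.
#' @export
ca_summary_from_counts <- function(n_core, n_total) {
  if (!.is_count(n_core) || !.is_count(n_total) || n_core > n_total)
    stop("need 0 <= n_core <= n_total, both integers", call. = FALSE)
  list(n_de_clusters_total = as.integer(n_total),
       n_de_clusters_core = as.integer(n_core),
       n_de_clusters_accessory = as.integer(n_total - n_core),
       core_pct = if (n_total > 0) 100 * n_core / n_total else NA_real_,
       accessory_pct = if (n_total > 0) 100 * (n_total - n_core) / n_total
                       else NA_real_)
}

#' @export
print.ca_summary <- function(x, ...) {
  o <- x$overall
  cat(sprintf("CA summary: %d DE clusters (%d core, %d accessory)\n",
              o$n_de_clusters_total, o$n_de_clusters_core,
              o$n_de_clusters_accessory))
  if (!is.na(o$core_pct))
    cat(sprintf("  core response: %.1f%%, accessory response: %.1f%%\n",
                o$core_pct, o$accessory_pct))
  invisible(x)
}

#' Mean per-cluster gene detection
#'
#' Averages per-gene covered fractions over the reference-genome member
#' genes of each cluster, per sample. Clusters without reference members
#' are absent from the result.
#'
#' @param coverage long data.frame with `sample_id`, `gene_id`, `fraction`
#'   (covered fraction of gene length, in \[0, 1\]).
#' @param membership cluster membership.
#' @param reference_genome_id reference genome id.
#' @return long data.frame `sample_id`, `cluster_id`, `detection`.
#' @export
detection_profile <- function(coverage, membership, reference_genome_id) {
  .assert_cols(coverage, c("sample_id", "gene_id", "fraction"), "coverage")
  if (any(is.na(coverage$fraction) | coverage$fraction < 0 |
            coverage$fraction > 1))
    stop("covered fractions must lie in [0, 1]", call. = FALSE)
  ref_mem <- membership[membership$genome_id == reference_genome_id, ,
                        drop = FALSE]
  cov <- coverage[coverage$gene_id %in% ref_mem$gene_id, , drop = FALSE]
  if (!nrow(cov))
    return(data.frame(sample_id = character(), cluster_id = character(),
                      detection = numeric(), stringsAsFactors = FALSE))
  cov$cluster_id <- ref_mem$cluster_id[match(cov$gene_id, ref_mem$gene_id)]
  out <- aggregate(fraction ~ sample_id + cluster_id, data = cov, FUN = mean)
  names(out)[names(out) == "fraction"] <- "detection"
  out[.radix_order(out$sample_id, out$cluster_id), , drop = FALSE]
}

#' Assemble a core-accessory metatranscriptome object
#'
#' @param pg partitioned `pangenome`.
#' @param layers `ca_layers` from [map_de_to_clusters()].
#' @param detection optional detection profile ([detection_profile()]).
#' @return object of class `ca_metatranscriptome` with fields `pangenome`,
#'   `layers`, `detection`, `summary`.
#' @export
ca_metatranscriptome <- function(pg, layers, detection = NULL) {
  summary <- summarize_core_accessory(layers, pg)
  structure(list(pangenome = pg, layers = layers, detection = detection,
                 summary = summary),
            class = "ca_metatranscriptome")
}

#' @export
print.ca_metatranscriptome <- function(x, ...) {
  print(x$pangenome)
  print(x$summary)
  invisible(x)
}

#' Export a core-accessory metatranscriptome bundle
#'
#' Writes `ca_clusters.tsv` (one row per cluster: genome presence/absence,
#' core flag, per treatment x direction DE flags) and `ca_summary.json`.
#' Round-trips with [import_ca()].
#'
#' @param ca `ca_metatranscriptome` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
export_ca <- function(ca, dir) {
  stopifnot(inherits(ca, "ca_metatranscriptome"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pg <- ca$pangenome
  clusters <- pg$cluster_ids
  u <- unique(pg$membership[, c("cluster_id", "genome_id")])
  tab <- data.frame(cluster_id = clusters, stringsAsFactors = FALSE)
  for (g in pg$genome_ids)
    tab[[paste0("p_", g)]] <-
      as.integer(clusters %in% u$cluster_id[u$genome_id == g])
  tab$n_genomes <- as.integer(rowSums(tab[, paste0("p_", pg$genome_ids),
                                          drop = FALSE]))
  tab$is_core <- as.integer(clusters %in% pg$core_ids)
  lay <- ca$layers
  keys <- if (nrow(lay))
    sort(unique(paste(lay$treatment, lay$direction, sep = "_")),
         method = "radix") else character()
  for (k in keys) {
    sel <- paste(lay$treatment, lay$direction, sep = "_") == k
    tab[[paste0("de_", k)]] <- as.integer(clusters %in% lay$cluster_id[sel])
  }
  p_tsv <- file.path(dir, "ca_clusters.tsv")
  .write_tsv(tab, p_tsv)
  p_json <- file.path(dir, "ca_summary.json")
  jsonlite::write_json(
    list(schema = "cameta-ca-summary/1",
         core_fraction = pg$core_fraction,
         overall = ca$summary$overall,
         per_treatment = ca$summary$per_treatment,
         gene_counts = ca$summary$gene_counts),
    p_json, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  if (!is.null(ca$detection))
    .write_tsv(ca$detection, file.path(dir, "ca_detection.tsv"))
  invisible(c(p_tsv, p_json))
}

#' Import a core-accessory metatranscriptome bundle
#'
#' Reads the files written by [export_ca()] back into their tabular form.
#'
#' @param dir bundle directory.
#' @return list with `clusters` (the wide cluster table), `layers` (long
#'   flagged triples reconstructed from the flag columns), `core_ids`, and
#'   `summary` (parsed JSON).
#' @export
import_ca <- function(dir) {
  tab <- .read_tsv(file.path(dir, "ca_clusters.tsv"), "CA cluster table")
  summ <- jsonlite::read_json(file.path(dir, "ca_summary.json"),
                              simplifyVector = TRUE)
  flag_cols <- grep("^de_", names(tab), value = TRUE)
  layers <- do.call(rbind, lapply(flag_cols, function(cl) {
    parts <- strsplit(sub("^de_", "", cl), "_")[[1]]
    dir_ <- parts[length(parts)]
    tr <- paste(parts[-length(parts)], collapse = "_")
    sel <- tab[[cl]] == 1
    if (!any(sel)) return(NULL)
    data.frame(treatment = tr, direction = dir_,
               cluster_id = tab$cluster_id[sel], stringsAsFactors = FALSE)
  }))
  if (is.null(layers))
    layers <- data.frame(treatment = character(), direction = character(),
                         cluster_id = character(), stringsAsFactors = FALSE)
  layers <- layers[.radix_order(layers$treatment, layers$direction,
                                layers$cluster_id), , drop = FALSE]
  rownames(layers) <- NULL
  list(clusters = tab, layers = layers,
       core_ids = tab$cluster_id[tab$is_core == 1], summary = summ)
}
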