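de_row <- function(gene, contrast, status) {
  data.frame(gene_id = gene, contrast = contrast, status = status,
             stringsAsFactors = FALSE)
}

test_that("clusters are flagged per treatment and direction independently", {
  mem <- make_membership_fixture(2, 2)  # CL0001-2 core, CL0003-4 GA-only
  de <- rbind(de_row("c0001_GA", "WAF", "up"),
              de_row("c0002_GA", "CEWAF", "up"),
              de_row("c0002_GB", "CEWAF", "down"),  # not a GA gene
              de_row("c0003_GA", "CEWAF", "down"),
              de_row("c0004_GA", "WAF", "ns"))
  lay <- map_de_to_clusters(de, mem, "GA")
  expect_s3_class(lay, "ca_layers")
  expect_equal(lay$cluster_id[lay$treatment == "WAF" & lay$direction == "up"],
               "CL0001")
  expect_equal(lay$cluster_id[lay$treatment == "CEWAF" &
                                lay$direction == "down"], "CL0003")
  # ns genes never flag; GB genes don't flag through GA's view
  expect_false("CL0004" %in% lay$cluster_id)

  # one cluster can be flagged in both directions of one treatment
  de2 <- rbind(de_row("c0001_GA", "CEWAF", "up"),
               de_row("c0001_GB", "CEWAF", "down"))
  lay2 <- map_de_to_clusters(de2, mem, "GB")
  expect_equal(nrow(lay2), 1L)  # only the GB gene maps through GB
  lay3 <- map_de_to_clusters(
    rbind(de_row("c0001_GA", "CEWAF", "up"),
          de_row("c0002_GA", "CEWAF", "down")), mem, "GA")
  expect_setequal(lay3$direction, c("up", "down"))
})

test_that("DE genes unknown to the reference error; orphans are reported", {
  mem <- make_membership_fixture(2, 1)
  gc <- gene_calls_for(mem)
  de <- de_row("nosuchgene", "WAF", "up")
  expect_error(map_de_to_clusters(de, mem, "GA", gene_calls = gc),
               "nosuchgene")
  # a reference gene outside any cluster becomes an orphan, not an error
  gc2 <- rbind(gc, data.frame(gene_id = "lonely", genome_id = "GA",
                              contig = "GA_c1", start = 90000L,
                              end = 90900L, strand = "+",
                              stringsAsFactors = FALSE))
  lay <- map_de_to_clusters(de_row("lonely", "WAF", "up"), mem, "GA",
                            gene_calls = gc2)
  expect_equal(attr(lay, "orphans"), "lonely")
  expect_equal(nrow(lay), 0L)
})

test_that("layer flags equal a brute-force join on a 30-cluster fixture", {
  withr::with_seed(61, {
    mem <- make_membership_fixture(15, 15, genomes = c("GA", "GB", "GC"))
    genes <- mem$gene_id
    de <- do.call(rbind, lapply(c("DISP", "WAF", "CEWAF"), function(tr) {
      pick <- sample(genes, 12)
      de_row(pick, tr, sample(c("up", "down", "ns"), 12, replace = TRUE))
    }))
    lay <- map_de_to_clusters(de, mem, "GA")
    oracle <- oracle_layers(de, mem, "GA")
    got <- as.data.frame(lay)[, c("treatment", "direction", "cluster_id")]
    expect_equal(`rownames<-`(got, NULL), `rownames<-`(oracle, NULL))
  })
})

test_that("core/accessory summary matches direct fraction arithmetic", {
  mem <- make_membership_fixture(4, 6)  # 4 core, 6 accessory
  pg <- classify_core_accessory(pangenome(gene_calls_for(mem), mem))
  lay <- data.frame(
    treatment = c("WAF", "WAF", "CEWAF"),
    direction = c("up", "down", "up"),
    cluster_id = c("CL0001", "CL0005", "CL0005"),
    stringsAsFactors = FALSE)
  s <- summarize_core_accessory(lay, pg)
  expect_equal(s$overall$n_de_clusters_total, 2L)
  expect_equal(s$overall$n_de_clusters_core, 1L)
  expect_equal(s$overall$core_pct, 50)
  expect_equal(s$overall$accessory_pct, 50)
  expect_equal(s$per_treatment$n_de_clusters_total,
               c(1L, 2L))  # CEWAF, WAF (sorted)

  # all-accessory case
  lay0 <- transform(lay, cluster_id = c("CL0005", "CL0006", "CL0007"))
  s0 <- summarize_core_accessory(lay0, pg)
  expect_equal(s0$overall$core_pct, 0)
  expect_equal(s0$overall$accessory_pct, 100)

  # no DE clusters: counts zero, percentages missing, no crash
  empty <- lay[0, ]
  se <- summarize_core_accessory(empty, pg)
  expect_equal(se$overall$n_de_clusters_total, 0L)
  expect_true(is.na(se$overall$core_pct))

  expect_error(summarize_core_accessory(
    transform(lay, cluster_id = "CL9999"), pg), "absent")
  expect_error(summarize_core_accessory(lay, pangenome(gene_calls_for(mem),
                                                       mem)),
               "not partitioned")
})

test_that("summary is invariant to layer order and duplicate flags, and conserves counts", {
  withr::with_seed(62, {
    mem <- make_membership_fixture(10, 20)
    pg <- classify_core_accessory(pangenome(gene_calls_for(mem), mem))
    cl <- sample(unique(mem$cluster_id), 12)
    lay <- data.frame(treatment = sample(c("WAF", "DISP"), 12, TRUE),
                      direction = sample(c("up", "down"), 12, TRUE),
                      cluster_id = cl, stringsAsFactors = FALSE)
    s1 <- summarize_core_accessory(lay, pg)
    s2 <- summarize_core_accessory(lay[sample(nrow(lay)), ], pg)
    s3 <- summarize_core_accessory(rbind(lay, lay), pg)
    expect_equal(s1$overall, s2$overall)
    expect_equal(s1$overall, s3$overall)
    o <- s1$overall
    expect_equal(o$n_de_clusters_core + o$n_de_clusters_accessory,
                 o$n_de_clusters_total)
    expect_equal(o$core_pct + o$accessory_pct, 100)
    # per-treatment totals can only exceed the overall union count
    expect_gte(sum(s1$per_treatment$n_de_clusters_total),
               o$n_de_clusters_total)
  })
})

test_that("worked-example fractions come straight from printed counts", {
  s <- ca_summary_from_counts(1, 4)
  expect_equal(s$core_pct, 25)
  expect_equal(s$accessory_pct, 75)
  expect_true(is.na(ca_summary_from_counts(0, 0)$core_pct))
  expect_error(ca_summary_from_counts(5, 4), "n_core <= n_total")
})

test_that("detection profile averages member genes and validates input", {
  mem <- make_membership_fixture(1, 1)  # CL0001 (GA+GB), CL0002 (GA)
  cov <- data.frame(sample_id = "s1",
                    gene_id = c("c0001_GA", "c0002_GA"),
                    fraction = c(0.2, 0.8), stringsAsFactors = FALSE)
  dp <- detection_profile(cov, mem, "GA")
  expect_equal(dp$detection, c(0.2, 0.8))

  # two genes of one cluster average
  mem2 <- rbind(mem, data.frame(gene_id = "c0001_GA2", genome_id = "GA",
                                cluster_id = "CL0001"))
  cov2 <- data.frame(sample_id = "s1",
                     gene_id = c("c0001_GA", "c0001_GA2"),
                     fraction = c(0.2, 0.8), stringsAsFactors = FALSE)
  dp2 <- detection_profile(cov2, mem2, "GA")
  expect_equal(dp2$detection, 0.5)

  expect_error(detection_profile(transform(cov, fraction = c(0.5, 1.2)),
                                 mem, "GA"), "\\[0, 1\\]")
})

test_that("a CA bundle survives an export/import round trip", {
  withr::with_seed(63, {
    mem <- make_membership_fixture(6, 10, genomes = c("GA", "GB", "GC"))
    pg <- classify_core_accessory(pangenome(gene_calls_for(mem), mem))
    cl <- sample(unique(mem$cluster_id), 8)
    de <- de_row(mem$gene_id[match(cl, mem$cluster_id)],
                 sample(c("WAF", "CEWAFN"), 8, TRUE),
                 sample(c("up", "down"), 8, TRUE))
    lay <- map_de_to_clusters(de, mem, "GA")
    ca <- ca_metatranscriptome(pg, lay)
    d <- withr::local_tempdir()
    export_ca(ca, d)
    back <- import_ca(d)
    expect_equal(nrow(back$clusters), length(pg$cluster_ids))
    expect_setequal(back$core_ids, pg$core_ids)
    expect_equal(back$layers,
                 `rownames<-`(as.data.frame(lay)[
                   order(lay$treatment, lay$direction, lay$cluster_id,
                         method = "radix"),
                   c("treatment", "direction", "cluster_id")], NULL))
    expect_equal(back$summary$overall$core_pct, ca$summary$overall$core_pct)

    # empty layer set still exports a valid bundle
    ca0 <- ca_metatranscriptome(pg, lay[0, ])
    d0 <- withr::local_tempdir()
    export_ca(ca0, d0)
    b0 <- import_ca(d0)
    expect_equal(nrow(b0$clusters), length(pg$cluster_ids))
    expect_equal(nrow(b0$layers), 0L)
  })
})
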