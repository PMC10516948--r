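mk_counts <- function(m, genes = sprintf("g%03d", seq_len(nrow(m))),
                      samples = sprintf("s%d", seq_len(ncol(m)))) {
  dimnames(m) <- list(genes, samples)
  storage.mode(m) <- "double"
  m
}

two_group_samples <- function(n_bc, n_trt, treatment = "WAF") {
  data.frame(
    sample_id = c(sprintf("bc%d", seq_len(n_bc)),
                  sprintf("tr%d", seq_len(n_trt))),
    treatment = c(rep("BC", n_bc), rep(treatment, n_trt)),
    time_days = 0, replicate = "r1", stringsAsFactors = FALSE)
}

test_that("tpm matches hand-computed values and sums to one million", {
  one <- mk_counts(matrix(7, 1, 1), "g1")
  expect_equal(tpm(one, c(g1 = 500))[1, 1], 1e6)

  eq <- mk_counts(matrix(c(10, 20, 5), 3, 1), c("a", "b", "c"))
  lens <- c(a = 1000, b = 2000, c = 500)  # equal per-base rates
  expect_equal(as.numeric(tpm(eq, lens)), rep(1e6 / 3, 3))

  two <- mk_counts(matrix(c(2, 4), 2, 1), c("a", "b"))
  got <- tpm(two, c(a = 100, b = 400))
  expect_equal(as.numeric(got), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)

  expect_error(tpm(two, c(a = 0, b = 400)), "length must be > 0")
})

test_that("tpm columns always sum to 1e6 and scale-invariance holds", {
  withr::with_seed(91, {
    for (i in 1:5) {
      m <- mk_counts(matrix(rpois(60, 20), 12, 5))
      lens <- stats::setNames(sample(200:2000, 12), rownames(m))
      tp <- tpm(m, lens)
      expect_equal(unname(colSums(tp)), rep(1e6, 5), tolerance = 1e-9)
      m2 <- m
      m2[, 3] <- m2[, 3] * 7  # per-sample scaling cancels
      expect_equal(tpm(m2, lens)[, 3], tp[, 3], tolerance = 1e-12)
    }
    z <- mk_counts(matrix(0, 4, 2))
    z[, 1] <- c(5, 0, 0, 0)
    tpz <- tpm(z, stats::setNames(rep(300, 4), rownames(z)))
    expect_equal(unname(tpz[, 2]), rep(0, 4))  # all-zero column stays zero
  })
})

test_that("size factors reproduce the median-of-ratios hand example", {
  a <- c(10, 40, 100, 7, 250)
  m <- mk_counts(cbind(a, 2 * a))
  sf <- size_factors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  expect_equal(prod(sf), 1, tolerance = 1e-12)  # geometric mean 1

  ident <- mk_counts(cbind(a, a))
  expect_equal(unname(size_factors(ident)), c(1, 1))

  perm <- m[sample(nrow(m)), , drop = FALSE]
  expect_equal(unname(size_factors(perm)), unname(sf))

  allzero <- mk_counts(matrix(c(0, 5, 3, 0), 2, 2))
  expect_error(size_factors(allzero), "pseudocount")
})

test_that("size factors agree with the DESeq2 implementation", {
  withr::with_seed(14, {
    m <- mk_counts(matrix(rnbinom(200 * 6, mu = 50, size = 5) + 1L, 200, 6))
    ours <- size_factors(m)
    ref <- DESeq2::estimateSizeFactorsForMatrix(m)
    expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
  })
})

test_that("dispersion estimates behave across Poisson, constant and NB data", {
  withr::with_seed(23, {
    cond <- rep(c("BC", "WAF"), each = 10)
    pois <- mk_counts(matrix(rpois(400 * 20, 100), 400, 20))
    d <- estimate_dispersion(pois, rep(1, 20), cond)
    expect_lt(mean(d$raw_alpha, na.rm = TRUE), 0.01)  # Poisson limit

    const <- mk_counts(matrix(42, 5, 20))
    dc <- estimate_dispersion(const, rep(1, 20), cond)
    expect_equal(dc$raw_alpha, rep(0, 5))

    nb <- mk_counts(matrix(rnbinom(500 * 20, mu = 80, size = 1 / 0.2),
                           500, 20))
    dn <- estimate_dispersion(nb, rep(1, 20), cond)
    expect_equal(mean(dn$raw_alpha, na.rm = TRUE), 0.2, tolerance = 0.05)
    expect_true(all(dn$shrunk_alpha >= 1e-8, na.rm = TRUE))
  })
})

test_that("bh_adjust reproduces the step-up procedure and passes NA through", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  got <- bh_adjust(c(0.01, NA, 0.04))
  expect_true(is.na(got[2]))
  expect_equal(got[-2], p.adjust(c(0.01, 0.04), "BH"))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  withr::with_seed(3, {
    p <- runif(100)
    expect_true(all(bh_adjust(p) >= p))
    expect_true(all(bh_adjust(p) <= 1))
  })
})

test_that("identical groups give zero fold change and ns status", {
  withr::with_seed(41, {
    base <- matrix(rpois(50 * 3, 60), 50, 3)
    st <- two_group_samples(3, 3)
    m <- mk_counts(cbind(base, base), samples = st$sample_id)
    de <- wald_test(m, st, "WAF")
    expect_equal(de$log2_fold_change, rep(0, 50))
    expect_true(all(de$status %in% c("ns", "low_count")))
    expect_true(all(de$padj >= de$p_value, na.rm = TRUE))
  })
})

test_that("swapping the group data negates every fold change", {
  withr::with_seed(42, {
    A <- matrix(rnbinom(40 * 3, mu = 50, size = 10), 40, 3)
    B <- matrix(rnbinom(40 * 3, mu = 90, size = 10), 40, 3)
    st <- two_group_samples(3, 3)
    de1 <- wald_test(mk_counts(cbind(A, B), samples = st$sample_id), st,
                     "WAF", cooks_cutoff = FALSE)
    de2 <- wald_test(mk_counts(cbind(B, A), samples = st$sample_id), st,
                     "WAF", cooks_cutoff = FALSE)
    expect_equal(de2$log2_fold_change, -de1$log2_fold_change,
                 tolerance = 1e-12)
    expect_equal(de2$p_value, de1$p_value, tolerance = 1e-12)
  })
})

test_that("wald_test enforces its design contract", {
  st <- two_group_samples(2, 2)
  m <- mk_counts(matrix(5, 10, 4), samples = st$sample_id)
  expect_error(wald_test(m, st, "CEWAF"), "absent")
  expect_error(wald_test(m, st, "BC"), "other than")
  st1 <- two_group_samples(3, 1)
  m1 <- mk_counts(matrix(5, 10, 4), samples = st1$sample_id)
  expect_error(wald_test(m1, st1, "WAF"), "WAF")
  stbad <- transform(st, treatment = c("BC", "BC", "OIL", "OIL"))
  expect_error(wald_test(m, stbad, "WAF"), "unknown treatment")
})

test_that("low counts are filtered and gross outliers flagged", {
  withr::with_seed(43, {
    st <- two_group_samples(4, 4)
    m <- mk_counts(matrix(rpois(30 * 8, 50), 30, 8),
                   samples = st$sample_id)
    m[1, ] <- c(0, 1, 0, 0, 0, 0, 1, 0)      # below min_base_mean
    m[2, 8] <- 5000                          # single wild replicate
    de <- wald_test(m, st, "WAF")
    expect_equal(de$status[1], "low_count")
    expect_true(is.na(de$padj[1]))
    expect_equal(de$status[2], "outlier")
    expect_true(is.na(de$p_value[2]))
    # outlier flagging can be disabled
    de2 <- wald_test(m, st, "WAF", cooks_cutoff = FALSE)
    expect_false("outlier" %in% de2$status)
  })
})

test_that("planted signal is detected with the right sign and direction", {
  withr::with_seed(44, {
    mu <- matrix(100, 60, 10)
    mu[1:5, 6:10] <- 400   # up in treatment
    mu[6:10, 6:10] <- 25   # down in treatment
    st <- two_group_samples(5, 5)
    m <- mk_counts(matrix(rnbinom(600, mu = mu, size = 10), 60, 10),
                   samples = st$sample_id)
    de <- wald_test(m, st, "WAF")
    expect_true(all(de$status[1:5] == "up"))
    expect_true(all(de$status[6:10] == "down"))
    expect_true(all(de$log2_fold_change[1:5] > 1))
    expect_true(all(de$log2_fold_change[6:10] < -1))
  })
})

test_that("count table IO round-trips", {
  withr::with_seed(45, {
    m <- mk_counts(matrix(rpois(40, 30), 8, 5))
    lens <- stats::setNames(sample(300:900, 8), rownames(m))
    f <- withr::local_tempfile(fileext = ".tsv")
    write_counts(m, lens, f)
    back <- read_counts(f)
    expect_equal(back$counts, m)
    expect_equal(back$gene_length, lens)
  })
})
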