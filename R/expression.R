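#' Read a gene count table
#'
#' Expected TSV layout: columns `gene_id`, `length`, then one column per
#' sample holding raw (integer) transcript counts.
#'
#' @param path TSV path.
#' @return list with `counts` (integer matrix, genes x samples, rownames =
#'   gene ids) and `gene_length` (named numeric, bp).
#' @export
read_counts <- function(path) {
  tbl <- .read_tsv(path, "count matrix")
  .assert_cols(tbl, c("gene_id", "length"), "count matrix")
  samples <- setdiff(names(tbl), c("gene_id", "length"))
  if (!length(samples)) stop("count matrix has no sample columns",
                             call. = FALSE)
  counts <- as.matrix(tbl[, samples, drop = FALSE])
  rownames(counts) <- tbl$gene_id
  storage.mode(counts) <- "double"
  .check_counts(counts)
  list(counts = counts,
       gene_length = stats::setNames(as.numeric(tbl$length), tbl$gene_id))
}

#' Write a gene count table (round-trips with [read_counts()])
#' @param counts genes x samples matrix with rownames.
#' @param gene_length named numeric vector of gene lengths (bp).
#' @param path output TSV path.
#' @export
write_counts <- function(counts, gene_length, path) {
  df <- data.frame(gene_id = rownames(counts),
                   length = as.numeric(gene_length[rownames(counts)]),
                   counts, check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

.check_counts <- function(counts) {
  if (!is.matrix(counts) || is.null(rownames(counts)) ||
      is.null(colnames(counts)))
    stop("counts must be a matrix with gene rownames and sample colnames",
         call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be non-negative integers", call. = FALSE)
  invisible(counts)
}

#' Read a sample metadata table
#'
#' Columns: `sample_id`, `treatment` (one of BC, DISP, WAF, CEWAF, CEWAFN),
#' `time_days`, `replicate`.
#'
#' @param path TSV path.
#' @return validated data.frame.
#' @export
read_samples <- function(path) {
  st <- .read_tsv(path, "sample table")
  validate_samples(st)
}

#' Validate a sample metadata table
#' @param samples data.frame with `sample_id`, `treatment`, `time_days`,
#'   `replicate`.
#' @return the validated data.frame.
#' @export
validate_samples <- function(samples) {
  .assert_cols(samples, c("sample_id", "treatment", "time_days", "replicate"),
               "sample table")
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in sample table", call. = FALSE)
  bad <- setdiff(unique(samples$treatment), TREATMENTS)
  if (length(bad))
    stop("unknown treatment(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(TREATMENTS, collapse = ", "), ")",
         call. = FALSE)
  samples
}

#' Transcripts-per-million normalization
#'
#' Per sample: `rate_g = count_g / length_kb_g`; `TPM_g = 1e6 * rate_g /
#' sum(rate)`. Every column of the result sums to one million, except
#' all-zero columns which stay all-zero.
#'
#' @param counts genes x samples count matrix.
#' @param gene_length named numeric gene lengths in bp (> 0).
#' @return numeric matrix of TPM values, same dimnames as `counts`.
#' @export
tpm <- function(counts, gene_length) {
  .check_counts(counts)
  len <- gene_length[rownames(counts)]
  if (any(is.na(len)))
    stop("gene_length missing for: ",
         paste(rownames(counts)[is.na(len)][1:5], collapse = ", "),
         call. = FALSE)
  if (any(len <= 0))
    stop("gene length must be > 0 (zero-length gene(s): ",
         paste(rownames(counts)[len <= 0], collapse = ", "), ")",
         call. = FALSE)
  rate <- counts / (len / 1000)
  denom <- colSums(rate)
  out <- sweep(rate, 2, ifelse(denom > 0, denom, 1), "/") * 1e6
  out[, denom == 0] <- 0
  out
}

#' Median-of-ratios size factors
#'
#' Per sample, the median ratio of its counts to the per-gene geometric
#' mean across samples, computed over reference genes (genes with no zero
#' count in any sample).
#'
#' @param counts genes x samples count matrix.
#' @return named numeric vector of positive size factors.
#' @export
size_factors <- function(counts) {
  .check_counts(counts)
  logc <- log(counts)
  lgm <- rowMeans(logc)
  use <- is.finite(lgm)
  if (!any(use))
    stop(paste("size_factors: every gene has a zero count in some sample;",
               "no reference genes for median-of-ratios. Consider adding a",
               "pseudocount or filtering samples."), call. = FALSE)
  apply(logc[use, , drop = FALSE], 2, function(lc) exp(median(lc - lgm[use])))
}

#' Per-gene negative-binomial dispersion estimates
#'
#' Gene-wise dispersions by method of moments on normalized counts within
#' condition groups, pooled by residual degrees of freedom, then shrunk
#' toward a fitted mean-dispersion trend `a0 + a1/mu`. The trend is fitted
#' to the untruncated gene-wise estimates (truncating first would bias it
#' upward); the reported `raw_alpha` is truncated at zero and the shrunk
#' value floored at 1e-8.
#'
#' @param counts genes x samples count matrix.
#' @param sf per-sample size factors (default [size_factors()]).
#' @param condition factor/character of per-sample condition labels.
#' @return data.frame: `gene_id`, `base_mean`, `raw_alpha`, `shrunk_alpha`,
#'   `trend_alpha` (`NA` for all-zero genes).
#' @export
estimate_dispersion <- function(counts, sf = size_factors(counts), condition) {
  .check_counts(counts)
  condition <- as.character(condition)
  if (length(condition) != ncol(counts))
    stop("condition length must match the number of samples", call. = FALSE)
  y <- sweep(counts, 2, sf, "/")
  mu <- rowMeans(y)

  num <- den <- numeric(nrow(counts))
  for (g in unique(condition)) {
    idx <- which(condition == g)
    n <- length(idx)
    if (n < 2) next
    sub <- y[, idx, drop = FALSE]
    m <- rowMeans(sub)
    v <- rowSums((sub - m)^2) / (n - 1)
    est <- ifelse(m > 0, (v - m) / m^2, NA_real_)
    w <- ifelse(is.na(est), 0, n - 1)
    est[is.na(est)] <- 0
    num <- num + w * est
    den <- den + w
  }
  if (all(den == 0))
    stop("estimate_dispersion: need at least 2 replicates in some condition",
         call. = FALSE)
  est_pooled <- ifelse(den > 0, num / den, NA_real_)

  ok <- !is.na(est_pooled) & mu > 0
  trend <- rep(1e-8, nrow(counts))
  if (sum(ok) >= 10) {
    fit <- lm(est_pooled[ok] ~ I(1 / mu[ok]))
    r <- resid(fit)
    keep <- abs(r) <= stats::quantile(abs(r), 0.99)  # guard the trend
    fit <- lm(est_pooled[ok][keep] ~ I(1 / mu[ok][keep]))
    a0 <- max(coef(fit)[1], 0)
    a1 <- max(coef(fit)[2], 0)
    trend <- pmax(a0 + a1 / pmax(mu, 1e-8), 1e-8)
  } else if (sum(ok) > 0) {
    trend <- rep(pmax(mean(est_pooled[ok]), 1e-8), nrow(counts))
  }

  df_resid <- sum(vapply(unique(condition), function(g)
    max(sum(condition == g) - 1L, 0L), 0L))
  w_trend <- 4 / (4 + df_resid)
  raw <- pmax(est_pooled, 0)
  shrunk <- pmax((1 - w_trend) * raw + w_trend * trend, 1e-8)
  raw[mu == 0] <- NA_real_
  shrunk[mu == 0] <- NA_real_
  trend[mu == 0] <- NA_real_
  data.frame(gene_id = rownames(counts), base_mean = mu,
             raw_alpha = raw, shrunk_alpha = shrunk, trend_alpha = trend,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg adjustment with missing-value passthrough
#'
#' @param p numeric vector of p-values in \[0, 1\]; `NA` entries are
#'   passed through and do not enter the adjustment.
#' @return adjusted p-values (same length, `NA` preserved).
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p-values must be numeric", call. = FALSE)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Negative-binomial Wald test of a treatment against the biotic control
#'
#' Fits per-gene NB group means with size-factor offsets and shrunk
#' dispersions, forms `log2_fold_change = log2((q_trt + c)/(q_BC + c))`
#' with a pseudo-fraction stabilizer `c = 0.5` normalized counts, and a
#' Wald statistic with a delta-method standard error from the NB variance
#' of the group-mean estimator. Genes whose maximum Cook's distance
#' exceeds the 0.99 quantile of F(2, n-2) are flagged `outlier` (p-value
#' dropped, not refit); genes with mean normalized count below
#' `min_base_mean` are flagged `low_count` and excluded from the BH
#' adjustment.
#'
#' @param counts genes x samples raw count matrix (inference always runs
#'   on raw counts with size factors; use [tpm()] for reporting).
#' @param samples sample table (see [validate_samples()]); `BC` is the
#'   baseline.
#' @param contrast treatment to compare against `BC`.
#' @param alpha_level adjusted-p significance threshold. Default 0.05.
#' @param time_days optional single timepoint; both groups are then
#'   restricted to that sampling day (per-timepoint mode). Default: pool
#'   all timepoints.
#' @param min_base_mean low-count filter on mean normalized count.
#'   Default 1.
#' @param cooks_cutoff set `FALSE` to disable outlier flagging.
#' @return data.frame with columns `gene_id`, `contrast`, `base_mean`,
#'   `log2_fold_change`, `se`, `wald_stat`, `p_value`, `padj`, `status`
#'   (`up`, `down`, `ns`, `outlier`, `low_count`).
#' @export
wald_test <- function(counts, samples, contrast, alpha_level = 0.05,
                      time_days = NULL, min_base_mean = 1,
                      cooks_cutoff = TRUE) {
  .check_counts(counts)
  samples <- validate_samples(samples)
  if (identical(contrast, "BC"))
    stop("contrast must be a treatment other than the biotic control (BC)",
         call. = FALSE)
  if (!contrast %in% samples$treatment)
    stop("contrast group absent from sample table: ", contrast, call. = FALSE)
  if (!"BC" %in% samples$treatment)
    stop("baseline group BC absent from sample table", call. = FALSE)
  sel <- samples[samples$treatment %in% c("BC", contrast), , drop = FALSE]
  if (!is.null(time_days))
    sel <- sel[sel$time_days == time_days, , drop = FALSE]
  miss <- setdiff(sel$sample_id, colnames(counts))
  if (length(miss))
    stop("samples absent from count matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (g in c("BC", contrast)) {
    n <- sum(sel$treatment == g)
    if (n < 2)
      stop(sprintf("group %s has %d sample(s); at least 2 replicates required",
                   g, n), call. = FALSE)
  }
  K <- counts[, sel$sample_id, drop = FALSE]
  grp <- sel$treatment
  sf <- size_factors(K)
  disp <- estimate_dispersion(K, sf, grp)
  alpha <- disp$shrunk_alpha
  alpha[is.na(alpha)] <- 1e-8

  i_bc <- grp == "BC"; i_tr <- grp == contrast
  S_bc <- sum(sf[i_bc]); S2_bc <- sum(sf[i_bc]^2)
  S_tr <- sum(sf[i_tr]); S2_tr <- sum(sf[i_tr]^2)
  q_bc <- rowSums(K[, i_bc, drop = FALSE]) / S_bc
  q_tr <- rowSums(K[, i_tr, drop = FALSE]) / S_tr

  c0 <- 0.5  # pseudo-fraction stabilizer, in normalized-count units
  lfc <- log2((q_tr + c0) / (q_bc + c0))
  vlog <- function(q, S, S2) (1 / ((q + c0) * S) + alpha * S2 / S^2) / log(2)^2
  se <- sqrt(vlog(q_bc, S_bc, S2_bc) + vlog(q_tr, S_tr, S2_tr))
  wald <- lfc / se
  p <- 2 * pnorm(-abs(wald))

  # Cook's distance from Pearson residuals under the two-group fit.
  # Residuals are scaled by the trend dispersion (the expected dispersion
  # at that expression level), not the gene-wise estimate: a single wild
  # replicate inflates its own gene-wise dispersion enough to mask itself.
  outlier <- rep(FALSE, nrow(K))
  if (isTRUE(cooks_cutoff) && ncol(K) > 2) {
    alpha_cook <- disp$trend_alpha
    alpha_cook[is.na(alpha_cook)] <- 1e-8
    mu_hat <- matrix(0, nrow(K), ncol(K))
    mu_hat[, i_bc] <- outer(q_bc, sf[i_bc])
    mu_hat[, i_tr] <- outer(q_tr, sf[i_tr])
    vmat <- mu_hat + alpha_cook * mu_hat^2
    r <- ifelse(vmat > 0, (K - mu_hat) / sqrt(vmat), 0)
    h <- numeric(ncol(K))
    h[i_bc] <- sf[i_bc] / S_bc
    h[i_tr] <- sf[i_tr] / S_tr
    D <- sweep(r^2 / 2, 2, h / (1 - h)^2, "*")
    thr <- qf(0.99, 2, ncol(K) - 2)
    outlier <- apply(D, 1, max) > thr
  }

  base_mean <- rowMeans(sweep(K, 2, sf, "/"))
  low <- base_mean < min_base_mean
  status <- rep("ns", nrow(K))
  p_out <- p
  p_out[outlier & !low] <- NA_real_
  status[outlier] <- "outlier"
  status[low] <- "low_count"
  testable <- !low & !outlier
  padj <- rep(NA_real_, nrow(K))
  padj[testable] <- bh_adjust(p_out[testable])
  sig <- testable & !is.na(padj) & padj < alpha_level
  status[sig & lfc > 0] <- "up"
  status[sig & lfc < 0] <- "down"
  p_out[low] <- NA_real_

  data.frame(gene_id = rownames(K), contrast = contrast,
             base_mean = base_mean, log2_fold_change = lfc, se = se,
             wald_stat = wald, p_value = p_out, padj = padj,
             status = status, stringsAsFactors = FALSE, row.names = NULL)
}

#' Run [wald_test()] for every non-control treatment present
#'
#' @inheritParams wald_test
#' @param treatments treatments to contrast against BC (default: all
#'   non-BC treatments in the sample table).
#' @return row-bound data.frame of per-contrast results.
#' @export
wald_test_all <- function(counts, samples, treatments = NULL,
                          alpha_level = 0.05, time_days = NULL,
                          min_base_mean = 1, cooks_cutoff = TRUE) {
  samples <- validate_samples(samples)
  if (is.null(treatments))
    treatments <- setdiff(intersect(TREATMENTS, unique(samples$treatment)),
                          "BC")
  do.call(rbind, lapply(treatments, function(tr)
    wald_test(counts, samples, tr, alpha_level = alpha_level,
              time_days = time_days, min_base_mean = min_base_mean,
              cooks_cutoff = cooks_cutoff)))
}

#' Shifted-log reporting transform of normalized counts
#'
#' `log2(count / size_factor + prior_count)`; a display/export transform
#' only, never used for inference.
#'
#' @param counts genes x samples count matrix.
#' @param sf size factors (default [size_factors()]).
#' @param prior_count pseudocount. Default 1.
#' @return numeric matrix.
#' @export
log_normalized <- function(counts, sf = size_factors(counts),
                           prior_count = 1) {
  .check_counts(counts)
  log2(sweep(counts, 2, sf, "/") + prior_count)
}
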