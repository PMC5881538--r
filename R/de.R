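# Negative-binomial differential expression in the classic (DESeq-1 style)
# form: median-of-ratios size factors, per-feature method-of-moments
# dispersion taken conservatively as the maximum of the per-feature estimate
# and a fitted mean-dispersion trend (a0 + a1/mu), and a two-sided exact
# test on condition-summed counts. The conservative maximum protects the
# type-I error at very small sample sizes (n = 3 per condition).

# counts tibbles carry feature_id (+ optional biotype) plus one numeric
# column per sample; this strips to a plain matrix
counts_matrix <- function(counts) {
  assert_tibble_cols(counts, "feature_id", "counts")
  num_cols <- setdiff(names(counts), c("feature_id", "biotype"))
  m <- as.matrix(counts[num_cols])
  rownames(m) <- counts$feature_id
  storage.mode(m) <- "double"
  if (any(m < 0)) abort("counts must be non-negative")
  m
}

#' Median-of-ratios size factors
#'
#' `factor_j = median_i count_ij / geometric_mean_i`, the median taken over
#' features with nonzero counts in every sample.
#'
#' @param counts Counts tibble (`feature_id`, optional `biotype`, one column
#'   per sample) or a numeric matrix.
#' @return Named numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  m <- if (is.matrix(counts)) counts else counts_matrix(counts)
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) {
    abort(paste0(
      "no feature has nonzero counts in all samples; size factors are ",
      "undefined (consider adding a pseudo-count)"
    ))
  }
  logg <- rowMeans(log(m[pos, , drop = FALSE]))
  apply(m[pos, , drop = FALSE], 2, function(col) {
    exp(median(log(col) - logg))
  })
}

#' Per-feature dispersion with a conservative trend maximum
#'
#' Method-of-moments on normalized counts pooled within conditions:
#' `alpha_raw = max(0, (s^2 - mu) / mu^2)` with the within-condition pooled
#' variance; then a mean-dispersion trend `alpha ~ a0 + a1/mu` is fitted by
#' least squares and the per-feature dispersion is the maximum of the raw
#' estimate and the fitted value.
#'
#' @param counts Counts tibble or matrix.
#' @param factors Size factors from [size_factors()].
#' @param condition Character/factor vector of sample conditions, one per
#'   sample column.
#' @return Tibble `feature_id`, `base_mean`, `dispersion_raw`,
#'   `dispersion_fit`, `dispersion`.
#' @export
estimate_dispersion <- function(counts, factors, condition) {
  m <- if (is.matrix(counts)) counts else counts_matrix(counts)
  stopifnot(length(factors) == ncol(m), length(condition) == ncol(m))
  if (max(table(condition)) < 2) {
    abort("need >= 2 samples in some condition to estimate dispersion")
  }
  norm <- sweep(m, 2, factors, "/")
  mu <- rowMeans(norm)
  conds <- unique(condition)
  ss <- matrix(0, nrow(m), length(conds))
  df <- 0L
  for (ci in seq_along(conds)) {
    idx <- which(condition == conds[ci])
    if (length(idx) < 2) next
    sub <- norm[, idx, drop = FALSE]
    ss[, ci] <- rowSums((sub - rowMeans(sub))^2)
    df <- df + length(idx) - 1L
  }
  s2 <- rowSums(ss) / max(df, 1L)
  raw <- pmax(0, (s2 - mu) / mu^2)
  raw[!is.finite(raw)] <- 0

  ok <- is.finite(mu) & mu > 0
  fit_vals <- rep(0, length(mu))
  if (sum(ok) >= 3) {
    fit <- lm(raw[ok] ~ I(1 / mu[ok]))
    a <- coef(fit)
    fit_vals[ok] <- pmax(0, a[1] + a[2] / mu[ok])
  }
  tibble(
    feature_id = rownames(m),
    base_mean = mu,
    dispersion_raw = raw,
    dispersion_fit = fit_vals,
    dispersion = pmax(raw, fit_vals)
  )
}

# two-sided NB exact test on condition-summed counts: under the null the
# feature has one common normalized mean q; the probability of a split
# (a, kS - a) of the total is the product of the two group-sum NB
# densities, and the p-value sums all splits as or less probable than the
# observed one. A group sum of n samples with per-sample dispersion alpha
# has dispersion alpha / n, i.e. NB size n / alpha. alpha -> 0 reduces to
# the (Poisson-conditional) binomial exact test.
nb_exact_p <- function(kA, kB, sA, sB, alpha, nA = 1L, nB = 1L) {
  kS <- kA + kB
  if (kS == 0) return(1)
  q <- (kA + kB) / (sA + sB)
  muA <- q * sA
  muB <- q * sB
  a <- 0:kS
  if (alpha <= 1e-12) {
    probs <- dpois(a, muA) * dpois(kS - a, muB)
  } else {
    probs <- dnbinom(a, mu = muA, size = nA / alpha) *
      dnbinom(kS - a, mu = muB, size = nB / alpha)
  }
  tot <- sum(probs)
  if (tot <= 0) return(1)
  p_obs <- probs[kA + 1]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]) / tot)
}

#' Negative-binomial exact test per feature
#'
#' @param counts Counts tibble or matrix.
#' @param factors Size factors.
#' @param dispersions Tibble from [estimate_dispersion()] (or a numeric
#'   vector of per-feature dispersions in row order).
#' @param condition Sample condition vector; `condition_order` names the
#'   (reference, treatment) pair — fold change is treatment over reference.
#' @param condition_order Length-2 character vector, default
#'   `c("normal", "tumor")`.
#' @param pseudocount Added to both normalized means for the fold change
#'   (default 0: a zero reference mean gives an infinite fold change,
#'   reported as `Inf`).
#' @return Tibble `feature_id`, `base_mean`, `fold_change`, `log2_fc`,
#'   `p_value`, `degenerate` (all-zero features: p = 1, fold change
#'   undefined).
#' @export
nb_test <- function(counts, factors, dispersions, condition,
                    condition_order = c("normal", "tumor"),
                    pseudocount = 0) {
  m <- if (is.matrix(counts)) counts else counts_matrix(counts)
  stopifnot(length(condition) == ncol(m))
  if (!all(condition_order %in% condition)) {
    abort("both conditions in condition_order must appear in `condition`")
  }
  alpha <- if (is.data.frame(dispersions)) {
    dispersions$dispersion[match(rownames(m), dispersions$feature_id)]
  } else dispersions
  stopifnot(length(alpha) == nrow(m))

  ref <- which(condition == condition_order[1])
  trt <- which(condition == condition_order[2])
  sA <- sum(factors[ref])
  sB <- sum(factors[trt])
  kA <- rowSums(m[, ref, drop = FALSE])
  kB <- rowSums(m[, trt, drop = FALSE])
  norm <- sweep(m, 2, factors, "/")
  mean_ref <- rowMeans(norm[, ref, drop = FALSE])
  mean_trt <- rowMeans(norm[, trt, drop = FALSE])

  p <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    p[i] <- nb_exact_p(kA[i], kB[i], sA, sB, alpha[i],
                       nA = length(ref), nB = length(trt))
  }
  degenerate <- kA + kB == 0
  fc <- (mean_trt + pseudocount) / (mean_ref + pseudocount)
  fc[degenerate] <- NaN
  p[degenerate] <- 1
  tibble(
    feature_id = rownames(m),
    base_mean = rowMeans(norm),
    fold_change = fc,
    log2_fc = log2(fc),
    p_value = p,
    degenerate = degenerate
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values (monotone, capped at 1).
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
  adj
}

#' Label features as up, down, or unchanged
#'
#' `up` iff fold change > `fc_up` and FDR < `max_fdr`; `down` iff fold
#' change < `fc_down` and FDR < `max_fdr` (all strict); otherwise
#' `unchanged`. Infinite fold changes (zero reference mean) satisfy the
#' up criterion; zero fold changes satisfy the down criterion.
#'
#' @param results Tibble with `fold_change` and `fdr` columns.
#' @param fc_up,fc_down Fold-change thresholds (defaults 2 and 0.5).
#' @param max_fdr FDR threshold (default 0.05).
#' @return `results` with a `status` column.
#' @export
filter_de <- function(results, fc_up = 2, fc_down = 0.5, max_fdr = 0.05) {
  assert_tibble_cols(results, c("fold_change", "fdr"), "results")
  fc <- results$fold_change
  sig <- results$fdr < max_fdr
  status <- rep("unchanged", nrow(results))
  status[!is.na(fc) & fc > fc_up & sig] <- "up"
  status[!is.na(fc) & fc < fc_down & sig] <- "down"
  results$status <- status
  results
}

#' Run the full differential-expression analysis
#'
#' Size factors, conservative dispersion, exact test, BH adjustment and
#' fold-change/FDR labelling in one call.
#'
#' @param counts Counts tibble (`feature_id`, optional `biotype`, one column
#'   per sample).
#' @param design Tibble `sample_id`, `condition` matching the sample
#'   columns.
#' @param condition_order Reference and treatment condition names.
#' @param fc_up,fc_down,max_fdr Thresholds for [filter_de()].
#' @return A `circ_de` object: the results tibble (`feature_id`,
#'   `base_mean`, `fold_change`, `log2_fc`, `p_value`, `fdr`, `status`, ...)
#'   with size factors and dispersions attached as attributes.
#' @export
run_de <- function(counts, design, condition_order = c("normal", "tumor"),
                   fc_up = 2, fc_down = 0.5, max_fdr = 0.05) {
  assert_tibble_cols(design, c("sample_id", "condition"), "design")
  m <- counts_matrix(counts)
  missing <- setdiff(design$sample_id, colnames(m))
  if (length(missing) > 0) {
    abort(sprintf("design samples absent from counts: %s",
                  paste(missing, collapse = ", ")))
  }
  m <- m[, design$sample_id, drop = FALSE]
  condition <- design$condition
  sf <- size_factors(m)
  disp <- estimate_dispersion(m, sf, condition)
  res <- nb_test(m, sf, disp, condition, condition_order)
  res$fdr <- bh_fdr(res$p_value)
  res <- filter_de(res, fc_up, fc_down, max_fdr)
  if ("biotype" %in% names(counts)) {
    res <- left_join(
      res, counts[, c("feature_id", "biotype")], by = "feature_id"
    )
  }
  structure(res,
            class = c("circ_de", class(res)),
            size_factors = sf,
            dispersions = disp,
            condition_order = condition_order,
            thresholds = c(fc_up = fc_up, fc_down = fc_down,
                           max_fdr = max_fdr))
}
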