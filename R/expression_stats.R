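## Relative-expression quantification (delta-delta-Ct), viability
## normalization, and the significance tests used on the tabular
## knockdown / proliferation / chemoresistance readouts.

#' Relative expression by the delta-delta-Ct method
#'
#' Per sample, replicate Ct values are averaged and
#' `dCt = Ct_target - Ct_reference` is formed; then
#' `ddCt = dCt - median(dCt of control samples)` and
#' `fold_change = E^(-ddCt)` with amplification efficiency `E` (default 2,
#' i.e. perfect doubling per cycle). Normalizing against the control
#' median makes the control group's own median fold change exactly 1 and
#' is robust to a single outlier control replicate.
#'
#' @param ct data.frame with columns `sample`, `condition` (`"treated"` /
#'   `"control"`), `gene`, `ct` (replicate rows allowed).
#' @param target_gene,reference_gene Gene identifiers; the reference
#'   (e.g. GAPDH) must differ from the target and be measured in every
#'   usable sample — samples missing it are excluded with a warning.
#' @param efficiency Amplification factor `E` (default 2).
#' @param control_summary `"median"` (default) or `"mean"` of the control
#'   dCt used as baseline.
#' @return data.frame (`sample`, `condition`, `dct`, `ddct`,
#'   `fold_change`).
#' @export
ddct_fold_change <- function(ct, target_gene, reference_gene,
                             efficiency = 2,
                             control_summary = c("median", "mean")) {
  control_summary <- match.arg(control_summary)
  stopifnot(target_gene != reference_gene, efficiency > 0)
  if (any(!is.finite(ct$ct))) stop("non-finite Ct value in table")
  mean_ct <- function(sample, gene) {
    v <- ct$ct[ct$sample == sample & ct$gene == gene]
    if (length(v)) mean(v) else NA_real_
  }
  samples <- unique(ct$sample)
  cond <- vapply(samples, function(s)
    ct$condition[ct$sample == s][1], "")
  tgt <- vapply(samples, mean_ct, numeric(1), gene = target_gene)
  ref <- vapply(samples, mean_ct, numeric(1), gene = reference_gene)
  usable <- !is.na(tgt) & !is.na(ref)
  if (any(!usable))
    warning(sprintf("%d sample(s) without %s or %s Ct excluded",
                    sum(!usable), target_gene, reference_gene))
  dct <- (tgt - ref)[usable]
  cond <- cond[usable]
  if (!any(cond == "control")) stop("no control samples in Ct table")
  base <- if (control_summary == "median") stats::median(dct[cond == "control"])
          else mean(dct[cond == "control"])
  ddct <- dct - base
  data.frame(sample = samples[usable], condition = cond,
             dct = dct, ddct = ddct,
             fold_change = efficiency^(-ddct),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Wilcoxon test with exact small-sample enumeration
#'
#' Signed-rank mode tests paired differences (or one sample against a
#' constant null value, e.g. control-normalized fold changes against 1);
#' rank-sum mode tests two independent groups. The two-sided p-value is
#' exact — full enumeration of the 2^n sign assignments (signed-rank) or
#' all group assignments (rank-sum) — whenever the effective sample size
#' is at most 12, and a normal approximation with tie correction and
#' continuity correction otherwise. Zero differences are dropped in
#' signed-rank mode and reported in `n_dropped`; when every difference is
#' zero the p-value is undefined and flagged rather than forced.
#'
#' @param a Numeric vector (first group, or paired measurements).
#' @param b Second group, paired vector, or a single null-hypothesis
#'   value in one-sample signed-rank mode.
#' @param mode `"signed_rank"` (default) or `"rank_sum"`.
#' @param exact_n_max Largest effective n for exact enumeration
#'   (default 12).
#' @return List with `statistic` (W: sum of positive-difference ranks, or
#'   rank sum of `a`), `p_value`, `n_effective`, `n_dropped`, `method`,
#'   `flagged`.
#' @export
wilcoxon_test <- function(a, b, mode = c("signed_rank", "rank_sum"),
                          exact_n_max = 12L) {
  mode <- match.arg(mode)
  if (mode == "signed_rank") {
    if (length(b) != 1L && length(a) != length(b))
      stop("paired vectors must have equal length")
    d <- a - b  # recycles a single null value across the sample
    n_dropped <- sum(d == 0)
    d <- d[d != 0]
    n <- length(d)
    if (n == 0L)
      return(list(statistic = NA_real_, p_value = NA_real_,
                  n_effective = 0L, n_dropped = n_dropped,
                  method = "undefined", flagged = TRUE))
    if (n < 3L)
      warning("fewer than 3 non-zero differences; test has no power")
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    mu <- sum(r) / 2
    if (n <= exact_n_max) {
      ## all 2^n sign assignments; the rank vector (ties included) is
      ## fixed, so W's null distribution is the set of subset sums
      signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
      Wdist <- as.vector(signs %*% r)
      p <- mean(abs(Wdist - mu) >= abs(W - mu) - 1e-9)
      method <- "exact_enumeration"
    } else {
      sigma <- sqrt(sum(r^2) / 4)
      z <- (abs(W - mu) - 0.5) / sigma
      p <- 2 * stats::pnorm(-max(z, 0))
      method <- "normal_approx"
    }
    return(list(statistic = W, p_value = min(p, 1), n_effective = n,
                n_dropped = n_dropped, method = method, flagged = FALSE))
  }
  ## rank-sum mode
  n1 <- length(a); n2 <- length(b)
  if (n1 < 3L || n2 < 3L)
    warning("fewer than 3 observations in a group; test has little power")
  r <- rank(c(a, b))
  W <- sum(r[seq_len(n1)])
  n <- n1 + n2
  if (n <= exact_n_max) {
    idx <- utils::combn(n, n1)
    Wdist <- colSums(matrix(r[idx], nrow = n1))
    mu <- n1 * (n + 1) / 2
    p <- mean(abs(Wdist - mu) >= abs(W - mu) - 1e-9)
    method <- "exact_enumeration"
  } else {
    mu <- n1 * (n + 1) / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) -
                                sum(ties^3 - ties) / (n * (n - 1)))
    z <- (abs(W - mu) - 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-max(z, 0))
    method <- "normal_approx"
  }
  list(statistic = W, p_value = min(p, 1), n_effective = n,
       n_dropped = 0L, method = method, flagged = FALSE)
}

#' Two-sided Student's t-test (pooled variance)
#'
#' Thin wrapper over [stats::t.test()] with `var.equal = TRUE`, adding
#' defined behaviour for degenerate inputs: zero pooled variance with
#' equal means gives `t = 0, p = 1`; zero pooled variance with unequal
#' means is flagged as degenerate (infinite separation at zero spread).
#'
#' @param a,b Numeric vectors, `n >= 2` each.
#' @return List with `statistic` (t), `p_value`, `df`, `flagged`.
#' @export
students_t_test <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(list(statistic = 0, p_value = 1,
                  df = length(a) + length(b) - 2L, flagged = FALSE))
    return(list(statistic = Inf * sign(mean(a) - mean(b)),
                p_value = 0, df = length(a) + length(b) - 2L,
                flagged = TRUE))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), flagged = FALSE)
}

#' Normalize viability measurements to the drug-free sample
#'
#' Each measurement is divided by the mean drug-free value of its own
#' (cell line, siRNA arm) group, so drug-free rows normalize to mean 1
#' and drug rows become fractions of untreated viability.
#'
#' @param v data.frame with columns `cell_line`, `arm` (`"targeting"` /
#'   `"scrambled"`), `concentration` (uM; 0 = drug-free), `value`.
#' @return Input data.frame with an added `normalized` column.
#' @export
normalize_viability <- function(v) {
  key <- paste(v$cell_line, v$arm, sep = "\r")
  out <- v
  out$normalized <- NA_real_
  for (k in unique(key)) {
    rows <- key == k
    base_rows <- rows & v$concentration == 0
    if (!any(base_rows)) {
      parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
      stop(sprintf("no drug-free row for cell line '%s', arm '%s'",
                   parts[1], parts[2]))
    }
    out$normalized[rows] <- v$value[rows] / mean(v$value[base_rows])
  }
  out
}
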