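## Spearman co-expression screen of a target transcript against an
## expression matrix, with ranked top-K export for downstream enrichment.

#' Co-expression screen configuration
#'
#' @param top_k Number of top-ranked genes to export (default 500, the
#'   size of the gene list handed to enrichment services; capped at the
#'   number of tested genes).
#' @param min_samples Minimum number of samples required (default 10).
#' @param p_method `"auto"` (default; t approximation for n >= 10, exact
#'   enumeration for n <= 8, seeded Monte-Carlo for n = 9),
#'   `"t_approx"`, or `"exact_permutation"`.
#' @param mc_permutations Monte-Carlo permutations when the exact
#'   enumeration is infeasible (default 10000).
#' @param mc_seed Seed for Monte-Carlo permutations (default 42).
#' @return A `coexpression_config` list.
#' @export
coexpression_config <- function(top_k = 500L, min_samples = 10L,
                                p_method = c("auto", "t_approx",
                                             "exact_permutation"),
                                mc_permutations = 10000L, mc_seed = 42L) {
  structure(list(top_k = as.integer(top_k),
                 min_samples = as.integer(min_samples),
                 p_method = match.arg(p_method),
                 mc_permutations = as.integer(mc_permutations),
                 mc_seed = as.integer(mc_seed)),
            class = "coexpression_config")
}

#' Spearman correlation with a small-sample-aware p-value
#'
#' rho is the Pearson correlation of average (tie-aware) ranks. The
#' two-sided p-value uses the t approximation with n - 2 degrees of
#' freedom for n >= 10; for smaller n it enumerates all n! rank
#' permutations exactly (n <= 8) or uses >= 10^4 seeded Monte-Carlo
#' permutations (n = 9), so small-panel screens are not at the mercy of
#' the asymptotic approximation.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`; ties permitted.
#' @param p_method See [coexpression_config()].
#' @param mc_permutations,mc_seed Monte-Carlo controls.
#' @return List with `rho`, `p_value`, `n`, `method`. Zero-variance input
#'   gives `rho = NA` and `flagged = TRUE` (a flagged skip, never a silent
#'   zero).
#' @examples
#' spearman_cor(1:3, c(2, 4, 6))$rho   # 1
#' @export
spearman_cor <- function(x, y, p_method = "auto",
                         mc_permutations = 10000L, mc_seed = 42L) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                method = "skipped", flagged = TRUE))
  rho <- stats::cor(x, y, method = "spearman")
  if (p_method == "auto")
    p_method <- if (n >= 10L) "t_approx" else "exact_permutation"
  if (p_method == "t_approx") {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t_approx"
  } else {
    rx <- rank(x); ry <- rank(y)
    eps <- 1e-12
    if (n <= 8L) {
      perms <- permutations_all(n)
      rperm <- apply(perms, 1L, function(pm) stats::cor(rx, ry[pm]))
      p <- mean(abs(rperm) >= abs(rho) - eps)
      method <- "exact_permutation"
    } else {
      rperm <- withr::with_seed(mc_seed, vapply(
        seq_len(mc_permutations),
        function(i) stats::cor(rx, sample(ry)), numeric(1)))
      ## add-one correction keeps Monte-Carlo p strictly positive
      p <- (sum(abs(rperm) >= abs(rho) - eps) + 1) / (mc_permutations + 1)
      method <- "mc_permutation"
    }
  }
  list(rho = rho, p_value = min(p, 1), n = n, method = method,
       flagged = FALSE)
}

## all n! permutations as an (n!, n) matrix; feasible for n <= 8
permutations_all <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_all(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub))
  }
  out
}

#' Screen an expression matrix for genes co-expressed with a target
#'
#' Computes Spearman rho and p for every non-target gene with non-zero
#' variance, and ranks by ascending p, ties broken by |rho| descending
#' then gene identifier — the ordering used to take the "top K lowest
#' p-value" gene list.
#'
#' @param mat Numeric matrix, genes in rows, samples in columns.
#' @param target_gene Row name of the target transcript.
#' @param config A [coexpression_config()].
#' @return data.frame (`gene`, `rho`, `p_value`, `rank`) sorted by rank;
#'   zero-variance genes are dropped and counted in
#'   `attr(, "n_skipped")`.
#' @export
coexpression_screen <- function(mat, target_gene,
                                config = coexpression_config()) {
  if (!(target_gene %in% rownames(mat)))
    stop("target gene not in matrix: ", target_gene)
  if (ncol(mat) < config$min_samples)
    stop(sprintf("need >= %d samples, got %d", config$min_samples,
                 ncol(mat)))
  target <- mat[target_gene, ]
  others <- setdiff(rownames(mat), target_gene)
  res <- lapply(others, function(g)
    spearman_cor(target, mat[g, ], p_method = config$p_method,
                 mc_permutations = config$mc_permutations,
                 mc_seed = config$mc_seed))
  flagged <- vapply(res, function(r) isTRUE(r$flagged), logical(1))
  df <- data.frame(gene = others[!flagged],
                   rho = vapply(res[!flagged], `[[`, numeric(1), "rho"),
                   p_value = vapply(res[!flagged], `[[`, numeric(1),
                                    "p_value"),
                   stringsAsFactors = FALSE)
  ord <- order(df$p_value, -abs(df$rho), df$gene)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  attr(df, "n_skipped") <- sum(flagged)
  df
}

#' Export the top-K ranked gene list as TSV
#'
#' Plain deterministic TSV (`gene`, `rho`, `p_value`, `rank`) suitable for
#' pasting into an external enrichment service.
#'
#' @param results Ranked data.frame from [coexpression_screen()].
#' @param top_k Number of genes to keep (capped at `nrow(results)`).
#' @param path Output path.
#' @return The exported data.frame, invisibly.
#' @export
export_gene_list <- function(results, top_k, path) {
  top_k <- min(top_k, nrow(results))
  out <- results[seq_len(top_k), c("gene", "rho", "p_value", "rank")]
  out$rho <- sprintf("%.6g", out$rho)
  out$p_value <- sprintf("%.6g", out$p_value)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(results[seq_len(top_k), ])
}
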