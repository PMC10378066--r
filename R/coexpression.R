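# Spearman co-expression screening within and across tissues.

.spearman_entry <- function(x, y, exact_max = 9L) {
  keep <- !is.na(x) & !is.na(y)
  n <- sum(keep)
  if (n < 4L) return(NULL)
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) return(NULL)
  has_ties <- any(duplicated(x)) || any(duplicated(y))
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman",
                    exact = (n <= exact_max && !has_ties))
  )
  c(rho = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Spearman co-expression matrix across tissue contexts
#'
#' Computes Spearman rank correlations for every gene pair in three
#' contexts: within tumour tissue (T-T), within adjacent tissue (TA-TA),
#' and between tissues (T-TA, ordered: tumour gene vs adjacent gene,
#' self-pairs included). Within-tissue contexts keep each unordered pair
#' once (gene_a < gene_b). Observations are used pairwise-complete;
#' entries with fewer than 4 complete pairs or a constant rank vector are
#' omitted with a warning. Two-sided p-values use the exact permutation
#' null for n <= 9 tie-free samples and the t-approximation otherwise.
#'
#' @param expression long data.frame: sample_id, gene, tissue (T/TA), value.
#' @param patients optional subset of sample ids.
#' @return data.frame: context, gene_a, gene_b, rho, p, n.
#' @export
spearman_matrix <- function(expression, patients = NULL) {
  if (!is.null(patients)) {
    expression <- expression[expression$sample_id %in% patients, ]
  }
  ids <- sort(unique(expression$sample_id))
  genes <- sort(unique(expression$gene))
  wide <- function(tissue) {
    sub <- expression[expression$tissue == tissue, ]
    m <- matrix(NA_real_, length(ids), length(genes),
                dimnames = list(ids, genes))
    m[cbind(match(sub$sample_id, ids), match(sub$gene, genes))] <- sub$value
    m
  }
  t_mat <- wide("T"); ta_mat <- wide("TA")
  out <- list(); dropped <- 0L
  add <- function(context, ga, gb, x, y) {
    e <- .spearman_entry(x, y)
    if (is.null(e)) { dropped <<- dropped + 1L; return(invisible()) }
    out[[length(out) + 1L]] <<- data.frame(
      context = context, gene_a = ga, gene_b = gb,
      rho = e[["rho"]], p = e[["p"]], n = as.integer(e[["n"]]),
      stringsAsFactors = FALSE)
  }
  for (i in seq_along(genes)) {
    for (j in seq_along(genes)) {
      if (j > i) {
        add("T-T", genes[i], genes[j], t_mat[, i], t_mat[, j])
        add("TA-TA", genes[i], genes[j], ta_mat[, i], ta_mat[, j])
      }
      add("T-TA", genes[i], genes[j], t_mat[, i], ta_mat[, j])
    }
  }
  if (dropped > 0L) {
    warning(dropped, " correlation entr", if (dropped == 1L) "y" else "ies",
            " omitted (fewer than 4 complete pairs or constant ranks)")
  }
  do.call(rbind, out)
}

#' Filter strong correlations
#'
#' Retains entries with correlation strictly above `r_min` (on the signed
#' coefficient by default, or on its absolute value) and p strictly below
#' `alpha`, sorted by descending correlation then ascending p.
#'
#' @param entries data.frame from [spearman_matrix()].
#' @param r_min correlation threshold (strict).
#' @param alpha significance threshold (strict).
#' @param sign_mode "positive" (default) keeps rho > r_min; "absolute"
#'   keeps |rho| > r_min.
#' @return Filtered, sorted data.frame.
#' @export
strong_correlations <- function(entries, r_min = 0.85, alpha = 0.05,
                                sign_mode = c("positive", "absolute")) {
  sign_mode <- match.arg(sign_mode)
  stat <- if (sign_mode == "positive") entries$rho else abs(entries$rho)
  keep <- stat > r_min & entries$p < alpha
  res <- entries[keep, , drop = FALSE]
  res <- res[order(-(if (sign_mode == "positive") res$rho else abs(res$rho)),
                   res$p), , drop = FALSE]
  rownames(res) <- NULL
  res
}
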