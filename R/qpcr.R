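# Efficiency-corrected qPCR relative quantification with reference-gene
# normalisation.

#' Amplification efficiency from a calibration-curve slope
#'
#' The per-cycle amplification factor E is derived from the slope of the
#' log-linear portion of the calibration curve (Cq vs log10 input):
#' E = 10^(-1/slope). A perfect doubling assay has slope -3.3219 and E = 2.
#'
#' @param slope calibration slope in Cq per log10(input); must be negative.
#' @return The efficiency E.
#' @export
efficiency_from_slope <- function(slope) {
  if (any(!is.finite(slope)) || any(slope >= 0)) {
    stop("calibration slope must be negative (non-amplifying curve)")
  }
  10^(-1 / slope)
}

#' Aggregate Cq replicates with a detection cutoff
#'
#' Replicates above the Cq cutoff (default 36 cycles) are treated as
#' non-detections and dropped; the aggregated Cq is the arithmetic mean of
#' the retained replicates. If every replicate exceeds the cutoff the
#' measurement is undetected (`NA`).
#'
#' @param cqs numeric vector of 1-3 replicate Cq values.
#' @param cutoff detection cutoff in cycles.
#' @return Mean Cq of detected replicates, or `NA_real_` if undetected.
#' @export
aggregate_replicates <- function(cqs, cutoff = 36) {
  cqs <- cqs[!is.na(cqs)]
  if (length(cqs) == 0L) stop("no replicates supplied")
  kept <- cqs[cqs <= cutoff]
  if (length(kept) == 0L) return(NA_real_)
  mean(kept)
}

#' Per-sample normalisation factor from reference genes
#'
#' The normalisation factor is the geometric mean of the (normalised)
#' quantities of the selected reference genes within one sample.
#'
#' @param ref_values numeric vector of per-reference-gene quantities (> 0),
#'   at least two genes.
#' @return The geometric mean.
#' @export
normalization_factor <- function(ref_values) {
  if (length(ref_values) < 2L) stop("at least two reference genes required")
  geometric_mean(ref_values)
}

#' Normalised expression from an aggregated Cq
#'
#' Relative quantity E^(-Cq) divided by the sample's normalisation factor.
#' An undetected Cq (`NA`) propagates to an undetected value.
#'
#' @param efficiency amplification efficiency E (> 1).
#' @param cq aggregated Cq, or `NA` if undetected.
#' @param nf normalisation factor (> 0).
#' @return Normalised quantity, or `NA_real_`.
#' @export
normalized_expression <- function(efficiency, cq, nf) {
  stopifnot(efficiency > 1, nf > 0)
  if (is.na(cq)) return(NA_real_)
  efficiency^(-cq) / nf
}

#' Rank candidate reference genes by expression stability
#'
#' geNorm-style stability measure: for each candidate gene j the statistic
#' M_j is the mean, over the other candidates k, of the standard deviation
#' across samples of log(x_j / x_k). Constant ratios give M = 0; the two
#' lowest-M genes are the recommended normalisation pair. Ties are broken
#' by label order.
#'
#' @param candidates numeric matrix, samples x candidate genes (positive
#'   values), with column names.
#' @return data.frame of gene and M, ordered by increasing M.
#' @export
rank_reference_stability <- function(candidates) {
  if (is.null(dim(candidates)) || ncol(candidates) < 2L) {
    stop("at least two candidate reference genes required")
  }
  if (nrow(candidates) < 2L) stop("at least two samples required")
  if (any(candidates <= 0)) stop("candidate expression must be positive")
  lx <- log(candidates)
  genes <- colnames(candidates)
  m <- vapply(seq_along(genes), function(j) {
    others <- setdiff(seq_along(genes), j)
    mean(vapply(others, function(k) stats::sd(lx[, j] - lx[, k]),
                numeric(1)))
  }, numeric(1))
  ord <- order(m, genes)
  data.frame(gene = genes[ord], M = m[ord], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Quantify a Cq triplicate table into normalised expression
#'
#' Full relative-quantification pipeline: per-well replicate aggregation
#' with the detection cutoff, efficiency correction E^(-Cq), and division
#' by the per-sample/per-tissue normalisation factor (geometric mean of the
#' reference genes). Reference genes default to the panel's validated pair
#' and are excluded from the output.
#'
#' @param cq_table long data.frame: sample_id, gene, tissue, cq_1..cq_3.
#' @param calibration data.frame with columns gene and slope (Cq per log10
#'   input); genes absent from it are assigned efficiency 2.
#' @param ref_genes reference genes used for the normalisation factor.
#' @param cutoff Cq detection cutoff.
#' @return Long data.frame: sample_id, gene, tissue, value (NA when the
#'   target or a reference was undetected).
#' @export
quantify_cq <- function(cq_table, calibration = NULL,
                        ref_genes = c("HPRT1", "POLR2A"), cutoff = 36) {
  stopifnot(all(c("sample_id", "gene", "tissue") %in% names(cq_table)))
  rep_cols <- grep("^cq_", names(cq_table), value = TRUE)
  if (!length(rep_cols)) stop("no cq_* replicate columns found")
  missing_refs <- setdiff(ref_genes, unique(cq_table$gene))
  if (length(missing_refs)) {
    stop("reference gene(s) absent from table: ",
         paste(missing_refs, collapse = ", "))
  }
  eff <- rep(2, nrow(cq_table))
  if (!is.null(calibration)) {
    e_by_gene <- stats::setNames(efficiency_from_slope(calibration$slope),
                                 calibration$gene)
    hit <- cq_table$gene %in% names(e_by_gene)
    eff[hit] <- e_by_gene[cq_table$gene[hit]]
  }
  agg <- apply(as.matrix(cq_table[, rep_cols, drop = FALSE]), 1L,
               aggregate_replicates, cutoff = cutoff)
  quantity <- ifelse(is.na(agg), NA_real_, eff^(-agg))
  df <- data.frame(cq_table[, c("sample_id", "gene", "tissue")],
                   quantity = quantity, stringsAsFactors = FALSE)
  is_ref <- df$gene %in% ref_genes
  key <- interaction(df$sample_id, df$tissue, drop = TRUE)
  nf_by_key <- tapply(seq_len(nrow(df)), key, function(idx) {
    refs <- df$quantity[idx][is_ref[idx]]
    if (length(refs) < 2L || any(is.na(refs))) return(NA_real_)
    normalization_factor(refs)
  })
  nf <- as.numeric(nf_by_key[as.character(key)])
  out <- df[!is_ref, , drop = FALSE]
  nf_out <- nf[!is_ref]
  out$value <- ifelse(is.na(out$quantity) | is.na(nf_out),
                      NA_real_, out$quantity / nf_out)
  out$quantity <- NULL
  rownames(out) <- NULL
  out
}
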