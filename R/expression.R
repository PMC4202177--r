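#' Read a gene expression matrix from tab-delimited text
#'
#' Expected layout: a header row of condition ids, first column gene ids,
#' numeric cells; empty cells or \code{NA} denote missing measurements.
#'
#' @param path file path.
#' @return an [ExpressionData-class]
#' @export
readExpressionMatrix <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    na.strings = c("NA", ""), stringsAsFactors = FALSE)
  gene_ids <- as.character(tab[[1L]])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- gene_ids
  ExpressionData(vals)
}

#' Filter genes by missing-value fraction
#'
#' Removes every gene whose fraction of missing conditions strictly exceeds
#' the threshold; a gene missing exactly the threshold fraction is kept.
#' The default of 0.2 drops genes with more than 20% missing values.
#'
#' @param x an [ExpressionData-class].
#' @param maxMissingFraction threshold in \[0, 1\].
#' @return the filtered [ExpressionData-class]; gene order is preserved.
#' @export
filterMissing <- function(x, maxMissingFraction = 0.2) {
  stopifnot(maxMissingFraction >= 0, maxMissingFraction <= 1)
  vals <- exprsValues(x)
  frac <- rowMeans(is.na(vals))
  keep <- frac <= maxMissingFraction
  if (!any(keep))
    stop("all genes exceed the missing-value threshold of ",
         maxMissingFraction)
  x[keep, ]
}

#' Impute missing expression values
#'
#' \code{row_mean} replaces each gap with the gene's observed mean.
#' \code{knn} replaces it with the average, at that condition, of the k
#' genes nearest in Euclidean distance computed over the conditions both
#' genes observe (distances are scaled to the number of shared conditions;
#' neighbours must observe the target condition). Observed values are never
#' changed.
#'
#' @param x an [ExpressionData-class]; every gene needs >= 1 observed value.
#' @param method \code{"row_mean"} (default) or \code{"knn"}.
#' @param k neighbour count for \code{knn}.
#' @return an [ExpressionData-class] with no missing values
#' @export
imputeExpression <- function(x, method = c("row_mean", "knn"), k = 10L) {
  method <- match.arg(method)
  vals <- exprsValues(x)
  n_obs <- rowSums(!is.na(vals))
  if (any(n_obs == 0L))
    stop("gene(s) with no observed values (filter first): ",
         paste(rownames(vals)[n_obs == 0L], collapse = ", "))
  if (!anyNA(vals)) return(x)
  if (method == "row_mean") {
    rm_ <- rowMeans(vals, na.rm = TRUE)
    idx <- which(is.na(vals), arr.ind = TRUE)
    vals[idx] <- rm_[idx[, 1L]]
  } else {
    filled <- vals
    for (i in which(rowSums(is.na(vals)) > 0L)) {
      gaps <- which(is.na(vals[i, ]))
      # mean squared difference over shared observed conditions
      d2 <- apply(vals, 1L, function(r) {
        sh <- !is.na(r) & !is.na(vals[i, ])
        if (!any(sh)) return(Inf)
        mean((r[sh] - vals[i, sh])^2)
      })
      d2[i] <- Inf
      for (j in gaps) {
        cand <- which(!is.na(vals[, j]) & is.finite(d2))
        if (!length(cand)) {
          filled[i, j] <- mean(vals[i, ], na.rm = TRUE)
          next
        }
        nn <- cand[order(d2[cand])][seq_len(min(k, length(cand)))]
        filled[i, j] <- mean(vals[nn, j])
      }
    }
    vals <- filled
  }
  out <- x
  SummarizedExperiment::assay(out, "exprs") <- vals
  out
}

#' Write cluster assignments to tab-delimited text
#'
#' @param model a [ClusterModel-class].
#' @param path output file (columns \code{gene_id}, \code{cluster}).
#' @export
writeClusterAssignments <- function(model, path) {
  write.table(data.frame(gene_id = names(model@assignments),
                         cluster = unname(model@assignments)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
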