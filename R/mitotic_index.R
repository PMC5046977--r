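#' The default nine-gene proliferation panel
#'
#' Intersection of a cell-proliferation expression cluster with an
#' independent proliferation signature: CDKN3, ILF2, KDELR2, RFC4,
#' TOP2A, MCM3, KPNA2, CKS2 and CDC2. CDC2 is the historical symbol of
#' CDK1; [computeMitoticIndex()] accepts either.
#'
#' @return character vector of nine gene symbols.
#' @export
mitoticPanel <- function() {
  c("CDKN3", "ILF2", "KDELR2", "RFC4", "TOP2A", "MCM3", "KPNA2", "CKS2",
    "CDC2")
}

#' Expression-based mitotic index
#'
#' The mitotic index of a sample is the average mRNA expression over the
#' proliferation gene panel (default: the nine-gene panel of
#' [mitoticPanel()]), on whatever scale the expression matrix supplies --
#' no internal transform is applied. Where the historical symbol CDC2 is
#' absent but its modern alias CDK1 is present, CDK1 is used (CDC2 is
#' preferred when both exist).
#'
#' @param expr genes-by-samples numeric expression matrix (e.g. from
#'   [readExpressionMatrix()]); missing values are allowed and dropped
#'   per sample.
#' @param panel character vector of panel genes.
#' @param allowPartial if FALSE (default), every panel gene must be
#'   present (an absent gene is an error listing the missing symbols);
#'   if TRUE, the mean is taken over the panel genes present.
#' @return data.frame with \code{sample_id}, \code{index} and
#'   \code{genes_used}.
#' @examples
#' m <- matrix(1:9, 9, 1, dimnames = list(mitoticPanel(), "s1"))
#' computeMitoticIndex(m)$index  # 5
#' @export
computeMitoticIndex <- function(expr, panel = mitoticPanel(),
                                allowPartial = FALSE) {
  expr <- as.matrix(expr)
  resolved <- panel
  aliasIdx <- which(panel == "CDC2" & !panel %in% rownames(expr))
  if (length(aliasIdx) > 0L && "CDK1" %in% rownames(expr))
    resolved[aliasIdx] <- "CDK1"
  present <- resolved[resolved %in% rownames(expr)]
  missing <- panel[!resolved %in% rownames(expr)]
  if (length(missing) > 0L && !allowPartial)
    .err("epitoc_input_error", "panel gene(s) absent from matrix: %s",
         paste(missing, collapse = ", "))
  if (length(present) == 0L)
    .err("epitoc_input_error", "no panel genes present in matrix")
  E <- expr[present, , drop = FALSE]
  data.frame(sample_id = colnames(E),
             index = colMeans(E, na.rm = TRUE),
             genes_used = colSums(!is.na(E)), row.names = NULL,
             stringsAsFactors = FALSE)
}
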