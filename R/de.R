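# Differential-expression table: load, filter by FDR and |logFC|,
# intersect with loss lists. The DE statistics themselves come from
# upstream tools (edgeR / DESeq2 style output); this module consumes their
# table.

#' Load a differential-expression table
#'
#' TSV with columns `gene_id`, `contrast` (time-point pair label), `logFC`
#' (binary-log fold change) and `FDR`. Malformed rows (unparseable logFC or
#' FDR, FDR outside \[0, 1\]) are dropped with a warning naming their line
#' numbers. Extra columns are carried through.
#'
#' @param path TSV file.
#' @return data.frame of DE records.
#' @export
load_de_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character")
  need <- c("gene_id", "contrast", "logFC", "FDR")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("DE table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  tab$logFC <- suppressWarnings(as.numeric(tab$logFC))
  tab$FDR <- suppressWarnings(as.numeric(tab$FDR))
  bad <- is.na(tab$logFC) | is.na(tab$FDR) | tab$FDR < 0 | tab$FDR > 1
  if (any(bad)) {
    warning("dropping malformed DE rows at line(s): ",
            paste(which(bad) + 1L, collapse = ", "), call. = FALSE)
    tab <- tab[!bad, , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab
}

#' Filter DE records to a significant gene set
#'
#' A gene qualifies when at least one of its records has `FDR < fdr_max`
#' (strict, matching the "FDR < 0.01" convention) and
#' `|logFC| >= theta_min` (the effect-size floor theta is a lower limit,
#' hence non-strict). Each gene is reported with its maximum-|logFC|
#' qualifying record.
#'
#' @param records data.frame from [load_de_table()].
#' @param fdr_max FDR threshold in (0, 1].
#' @param theta_min minimum absolute binary-log fold change (>= 0).
#' @return data.frame, one row per qualifying gene: `gene_id`, `contrast`,
#'   `logFC`, `FDR`, sorted by descending `logFC`.
#' @export
filter_de <- function(records, fdr_max = 0.01, theta_min = 0) {
  stopifnot(fdr_max > 0, fdr_max <= 1, theta_min >= 0)
  ok <- records$FDR < fdr_max & abs(records$logFC) >= theta_min
  rec <- records[ok, , drop = FALSE]
  if (!nrow(rec)) return(rec)
  rec <- rec[order(rec$gene_id, -abs(rec$logFC), rec$FDR), , drop = FALSE]
  rec <- rec[!duplicated(rec$gene_id), , drop = FALSE]
  rec <- rec[order(-rec$logFC, rec$gene_id), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Intersect a loss list with a DE gene list
#'
#' Genes common to both lists, ordered by descending logFC so a reader can
#' cut at any effect-size range. The result carries the loss list's
#' columns plus the DE fields; the counts of up- and down-regulated genes
#' are attached as attributes `n_up` / `n_down`.
#'
#' @param loss_list data.frame with a `gene_id` column (e.g. list-1).
#' @param de_genes data.frame from [filter_de()].
#' @return the intersection data.frame (list-3 layout).
#' @export
intersect_lists <- function(loss_list, de_genes) {
  common <- intersect(loss_list$gene_id, de_genes$gene_id)
  out <- loss_list[match(common, loss_list$gene_id), , drop = FALSE]
  de <- de_genes[match(common, de_genes$gene_id), , drop = FALSE]
  out$contrast <- de$contrast
  out$logFC <- de$logFC
  out$FDR <- de$FDR
  out <- out[order(-out$logFC, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_up") <- sum(out$logFC > 0)
  attr(out, "n_down") <- sum(out$logFC < 0)
  out
}
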