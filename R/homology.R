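# Gene-level homology weights: projection of the protein matrix to genes,
# top-u truncation per target species, ranks and back-ranks.

#' Homology weight of a gene pair
#'
#' `W(X, Y) = max w(x, y)` over all encoded protein pairs, optionally after
#' restricting the proteins considered; 0 when no matrix cell links the two
#' genes.
#'
#' @param gene_x,gene_y gene ids.
#' @param V a symmetrized `score_matrix`.
#' @param dataset the [ortho_dataset()] providing the protein-gene map.
#' @param protein_filter optional predicate `function(protein_id) logical`
#'   restricting which isoforms enter the maximum (e.g. a length or domain
#'   constraint); default keeps all.
#' @return numeric weight.
#' @export
gene_weight <- function(gene_x, gene_y, V, dataset, protein_filter = NULL) {
  pm <- dataset$protein_map
  px <- pm$protein_id[pm$gene_id == gene_x]
  py <- pm$protein_id[pm$gene_id == gene_y]
  if (!is.null(protein_filter)) {
    px <- px[vapply(px, protein_filter, logical(1))]
    py <- py[vapply(py, protein_filter, logical(1))]
  }
  if (!length(px) || !length(py)) return(0)
  cells <- as.data.table(V)[x %in% px & y %in% py]
  if (!nrow(cells)) 0 else max(cells$weight)
}

#' Build the table of homologs
#'
#' Projects the symmetrized protein matrix to gene pairs (maximum weight
#' over encoded-protein pairs; minimum E-value; maximum raw score), then for
#' every gene and every target species keeps at most `u` homologs with
#' weight > `weight_min` and E-value < `e_value_max`, sorted by descending
#' weight (ties: ascending E-value, then ascending target gene id). The
#' gene's own self-pair is excluded; within-species paralog entries are
#' kept. Ranks and back-ranks are annotated by [assign_ranks()].
#'
#' @param dataset an [ortho_dataset()].
#' @param V a symmetrized `score_matrix`.
#' @param params an [sl_params()] object (uses `u`, `weight_min`,
#'   `e_value_max`).
#' @param protein_filter optional isoform predicate, as in [gene_weight()].
#' @return a `homolog_table`: data.table with columns `query_gene`,
#'   `query_species`, `target_gene`, `target_species`, `weight`, `e_value`,
#'   `raw_score`, `rank`, `back_rank`.
#' @export
build_homolog_table <- function(dataset, V, params = sl_params(),
                                protein_filter = NULL) {
  if (!isTRUE(attr(V, "symmetrized")))
    stop("V must be symmetrized first (see symmetrize_matrix)",
         call. = FALSE)
  cells <- as.data.table(V)
  pm <- as.data.table(dataset$protein_map)
  if (!is.null(protein_filter)) {
    keep <- vapply(pm$protein_id, protein_filter, logical(1))
    pm <- pm[keep]
  }
  qx <- pm[, .(x = protein_id, query_gene = gene_id,
               query_species = species_id)]
  tx <- pm[, .(y = protein_id, target_gene = gene_id,
               target_species = species_id)]
  cells <- merge(cells, qx, by = "x", allow.cartesian = TRUE)
  cells <- merge(cells, tx, by = "y", allow.cartesian = TRUE)
  gpairs <- cells[, .(weight = max(weight), e_value = min(e_value),
                      raw_score = max(raw_score)),
                  by = .(query_gene, query_species, target_gene,
                         target_species)]
  gpairs <- gpairs[query_gene != target_gene]
  gpairs <- gpairs[weight > params$weight_min &
                     e_value < params$e_value_max]
  setorder(gpairs, query_gene, target_species, -weight, e_value,
           target_gene)
  gpairs <- gpairs[, head(.SD, params$u),
                   by = .(query_gene, target_species)]
  setcolorder(gpairs, c("query_gene", "query_species", "target_gene",
                        "target_species", "weight", "e_value", "raw_score"))
  assign_ranks(gpairs)
}

#' Annotate ranks and back-ranks
#'
#' Within each (query gene, target species) bucket, `rank` is the 1-based
#' position in descending-weight order. `back_rank` of an entry X -> Y is
#' the position of X in Y's reciprocal bucket over X's species, or `Inf`
#' when that bucket lacks X. An entry with rank 1 and back-rank 1 is a
#' bidirectional best hit.
#'
#' @param tab data.frame/data.table of homolog entries (sorted or not; the
#'   canonical order is imposed).
#' @return the table with `rank` and `back_rank` columns, keyed by
#'   (`query_gene`, `target_species`), class `homolog_table`.
#' @export
assign_ranks <- function(tab) {
  tab <- as.data.table(tab)
  setorder(tab, query_gene, target_species, -weight, e_value, target_gene)
  tab[, rank := seq_len(.N), by = .(query_gene, target_species)]
  rev_ranks <- tab[, .(query_gene = target_gene,
                       target_gene = query_gene,
                       back_rank = as.numeric(rank))]
  if ("back_rank" %in% names(tab)) tab[, back_rank := NULL]
  tab <- merge(tab, rev_ranks, by = c("query_gene", "target_gene"),
               all.x = TRUE, sort = FALSE)
  tab[is.na(back_rank), back_rank := Inf]
  setorder(tab, query_gene, target_species, -weight, e_value, target_gene)
  setkeyv(tab, c("query_gene", "target_species"))
  class(tab) <- unique(c("homolog_table", class(tab)))
  tab[]
}

#' Write / read the homolog-table interchange TSV
#'
#' Columns: query_gene, query_species, target_gene, target_species, weight,
#' e_value, raw_score, rank, back_rank (`Inf` serialized as `inf`).
#'
#' @param tab a `homolog_table`.
#' @param path TSV path.
#' @return `write_homolog_table` the path invisibly; `read_homolog_table`
#'   the table.
#' @export
write_homolog_table <- function(tab, path) {
  out <- as.data.frame(tab)
  out$back_rank <- ifelse(is.infinite(out$back_rank), "inf",
                          format(out$back_rank, trim = TRUE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_homolog_table
#' @export
read_homolog_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  tab$back_rank <- suppressWarnings(
    ifelse(tab$back_rank == "inf", Inf, as.numeric(tab$back_rank)))
  tab <- as.data.table(tab)
  setkeyv(tab, c("query_gene", "target_species"))
  class(tab) <- unique(c("homolog_table", class(tab)))
  tab[]
}
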