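# Three-species condition: exclude reference genes whose lower-species
# (fish/amphibian) orthologs themselves have orthologs in upper species.

#' Three-species condition flags
#'
#' For each gene X and each radius r_i: find every ortholog X* of X in each
#' lower species (the reference excluded) with the neighborhood radius set
#' to r_i; then ask whether X* has an ortholog X*' in any upper species,
#' again at radius r_i, with the lower species now playing the reference
#' role (same forward and backward checks). The flag for r_i is 0
#' ("broken") when such a chain X -> X* -> X*' exists, else 1. Middle
#' species are not consulted.
#'
#' @param ref_genes gene ids to test (typically the m = n = p = 0 list).
#' @param htab a `homolog_table` covering all species.
#' @param genes gene annotations for all species.
#' @param groups a [species_groups()] object.
#' @param params an [sl_params()]; its `radii` vector defines the flags.
#' @return data.frame: `gene` plus one 0/1 column `flag_<radius>` per
#'   radius.
#' @export
three_species_flags <- function(ref_genes, htab, genes, groups,
                                params = sl_params()) {
  lower_sp <- group_species(groups, "lower", drop_reference = TRUE)
  upper_sp <- group_species(groups, "upper")
  out <- data.frame(gene = ref_genes, stringsAsFactors = FALSE)
  for (r in params$radii) {
    pr <- params
    pr$radius <- r
    pr$radius_by_species <- NULL
    flag <- vapply(ref_genes, function(X) {
      for (f in sort(lower_sp)) {
        star <- call_presence(X, f, htab, genes, pr)
        if (star$status != "present") next
        for (a in sort(upper_sp)) {
          if (call_presence(star$ortholog, a, htab, genes,
                            pr)$status == "present")
            return(0L)  # chain found: condition broken at this radius
        }
      }
      1L
    }, integer(1))
    out[[sprintf("flag_%g", r)]] <- unname(flag)
  }
  out
}

#' Apply the final three-species filter
#'
#' Retains the genes whose three-species condition holds for at least one
#' radius (any flag equal to 1); genes with all-zero flags are excluded.
#'
#' @param gene_list data.frame with a `gene_id` column (a screened list).
#' @param flags data.frame from [three_species_flags()].
#' @return `gene_list` restricted to the retained genes, with the flag
#'   columns appended.
#' @export
apply_final_filter <- function(gene_list, flags) {
  m <- match(gene_list$gene_id, flags$gene)
  if (anyNA(m))
    stop("flags missing for: ",
         paste(head(gene_list$gene_id[is.na(m)], 3), collapse = ", "),
         call. = FALSE)
  fcols <- setdiff(names(flags), "gene")
  fmat <- as.matrix(flags[m, fcols, drop = FALSE])
  out <- cbind(gene_list, fmat)
  out[rowSums(fmat) > 0, , drop = FALSE]
}
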