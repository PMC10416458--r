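# Presence/absence calls: forward (local-synteny witness) check and
# backward (alternative-homolog) check per candidate ortholog.

#' Genes in the neighborhood of a gene
#'
#' All genes of the same species whose interval intersects
#' `[start - r, end + r]` (boundary touching counts) on the same
#' chromosome/scaffold, the focal gene excluded. Orientation is ignored.
#'
#' @param gene a gene id present in `genes`.
#' @param genes gene annotation data.frame (`gene_id`, `species_id`,
#'   `seq_id`, `start`, `end`).
#' @param r neighborhood radius in bp on either side of the gene.
#' @return character vector of gene ids.
#' @export
neighborhood_genes <- function(gene, genes, r) {
  g <- genes[genes$gene_id == gene, , drop = FALSE]
  if (nrow(g) != 1) stop("unknown gene: ", gene, call. = FALSE)
  hit <- genes$species_id == g$species_id &
    genes$seq_id == g$seq_id &
    genes$start <= g$end + r &
    genes$end >= g$start - r &
    genes$gene_id != gene
  genes$gene_id[hit]
}

# Witness pairs between two neighbor sets: homolog-table entries from a
# neighbor of X (in R) to a neighbor of X' (in A) that satisfy the beta
# condition. Greedy one-to-one matching in descending weight order so each
# gene serves at most one witness pair per side.
witness_pairs <- function(nb_ref, nb_tgt, tsp, htab, params) {
  if (!length(nb_ref) || !length(nb_tgt)) return(NULL)
  cand <- htab[.(nb_ref, tsp), nomatch = NULL]
  cand <- cand[target_gene %in% nb_tgt]
  if (params$beta == "bbh") cand <- cand[rank == 1 & back_rank == 1]
  else if (params$beta == "top1") cand <- cand[rank == 1]
  if (!nrow(cand)) return(NULL)
  setorder(cand, -weight, e_value, query_gene, target_gene)
  used_q <- character(0); used_t <- character(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!(cand$query_gene[i] %in% used_q) &&
        !(cand$target_gene[i] %in% used_t)) {
      keep[i] <- TRUE
      used_q <- c(used_q, cand$query_gene[i])
      used_t <- c(used_t, cand$target_gene[i])
    }
  }
  cand[keep]
}

#' Forward check of a candidate ortholog pair
#'
#' Confirms local synteny of an alpha-homolog pair (X, X'): at least
#' `witnesses_required` witness pairs (Y, Y') must exist with Y in X's
#' neighborhood, Y' in X''s neighborhood, Y != X, Y' != X', each witness
#' gene used at most once per side, and (Y, Y') satisfying the beta
#' condition (default: bidirectional best hit).
#'
#' @param X reference-species gene id.
#' @param Xp candidate gene id in the target species; must appear in X's
#'   homolog bucket for that species.
#' @param htab a `homolog_table`.
#' @param genes gene annotations for all species.
#' @param params an [sl_params()].
#' @return list with `ok` (logical) and `witnesses` (data.table of witness
#'   entries, possibly empty).
#' @export
forward_check <- function(X, Xp, htab, genes, params = sl_params()) {
  sp_x <- genes$species_id[match(X, genes$gene_id)]
  sp_xp <- genes$species_id[match(Xp, genes$gene_id)]
  bucket <- htab[.(X, sp_xp), nomatch = NULL]
  if (!Xp %in% bucket$target_gene)
    stop(Xp, " is not an alpha-homolog of ", X, " in the table",
         call. = FALSE)
  nb_ref <- neighborhood_genes(X, genes, species_radius(params, sp_x))
  nb_tgt <- neighborhood_genes(Xp, genes, species_radius(params, sp_xp))
  nb_ref <- setdiff(nb_ref, X)
  nb_tgt <- setdiff(nb_tgt, Xp)
  w <- witness_pairs(nb_ref, nb_tgt, sp_xp, htab, params)
  n_found <- if (is.null(w)) 0L else nrow(w)
  list(ok = n_found >= params$witnesses_required,
       witnesses = if (is.null(w)) data.table() else w)
}

#' Backward check of a candidate ortholog pair
#'
#' The candidate X' is rejected when the reference species holds an
#' alternative homolog U (U != X, U in X''s bucket over the reference
#' species) that itself passes the forward check against X' and is closer
#' to X' than X is: in the difference variant
#' `W(X', U) - W(X, X') > lambda` (strict, so exact ties never reject);
#' in the quotient variant `S(U, X') / S(X, X') > lambda1` on gene-level
#' raw scores.
#'
#' @inheritParams forward_check
#' @return list with `accepted` (logical), `rejecting_U` (gene id or NA)
#'   and `gap` (weight difference or score ratio for the rejecting U).
#' @export
backward_check <- function(X, Xp, htab, genes, params = sl_params()) {
  sp_x <- genes$species_id[match(X, genes$gene_id)]
  sp_xp <- genes$species_id[match(Xp, genes$gene_id)]
  cand_entry <- htab[.(X, sp_xp), nomatch = NULL][target_gene == Xp]
  if (!nrow(cand_entry))
    stop(Xp, " is not an alpha-homolog of ", X, call. = FALSE)
  w_x <- cand_entry$weight[1]
  s_x <- cand_entry$raw_score[1]
  alts <- htab[.(Xp, sp_x), nomatch = NULL]
  alts <- alts[target_gene != X]
  if (!nrow(alts)) return(list(accepted = TRUE, rejecting_U = NA_character_,
                               gap = NA_real_))
  for (i in seq_len(nrow(alts))) {
    U <- alts$target_gene[i]
    closer <- if (params$backward_variant == "difference")
      (alts$weight[i] - w_x) > params$lambda
    else
      (alts$raw_score[i] / s_x) > params$lambda1
    if (!closer) next
    # U must itself have local synteny with X' (forward check of (U, X'))
    if (forward_check(U, Xp, htab, genes, params)$ok) {
      gap <- if (params$backward_variant == "difference")
        alts$weight[i] - w_x else alts$raw_score[i] / s_x
      return(list(accepted = FALSE, rejecting_U = U, gap = gap))
    }
  }
  list(accepted = TRUE, rejecting_U = NA_character_, gap = NA_real_)
}

#' Call presence or absence of a gene in a target species
#'
#' Iterates X's alpha-candidates in species `species` in decreasing weight
#' order; the first candidate passing both the forward and the backward
#' check becomes the ortholog and the gene is called present. If every
#' candidate is rejected -- or the bucket is empty -- the gene is absent.
#'
#' @param X reference(-role) gene id.
#' @param species target species id.
#' @inheritParams forward_check
#' @return a `presence_call`: list with `ref_gene`, `species`, `status`
#'   (`"present"`/`"absent"`), `ortholog` (id or NA), `witnesses`
#'   (data.table for the accepted candidate) and `rejected` (data.frame
#'   trace: candidate, reason, rejecting U, gap).
#' @export
call_presence <- function(X, species, htab, genes, params = sl_params()) {
  bucket <- htab[.(X, species), nomatch = NULL]
  rejected <- list()
  if (nrow(bucket)) {
    for (i in seq_len(nrow(bucket))) {
      Xp <- bucket$target_gene[i]
      fwd <- forward_check(X, Xp, htab, genes, params)
      if (!fwd$ok) {
        rejected[[length(rejected) + 1L]] <- data.frame(
          candidate = Xp, reason = "forward", rejecting_U = NA_character_,
          gap = NA_real_)
        next
      }
      bwd <- backward_check(X, Xp, htab, genes, params)
      if (bwd$accepted) {
        return(structure(list(ref_gene = X, species = species,
                              status = "present", ortholog = Xp,
                              witnesses = fwd$witnesses,
                              rejected = do.call(rbind, rejected)),
                         class = "presence_call"))
      }
      rejected[[length(rejected) + 1L]] <- data.frame(
        candidate = Xp, reason = "backward", rejecting_U = bwd$rejecting_U,
        gap = bwd$gap)
    }
  }
  structure(list(ref_gene = X, species = species, status = "absent",
                 ortholog = NA_character_, witnesses = data.table(),
                 rejected = do.call(rbind, rejected)),
            class = "presence_call")
}

#' @export
print.presence_call <- function(x, ...) {
  cat(sprintf("%s in %s: %s%s\n", x$ref_gene, x$species, x$status,
              if (x$status == "present")
                sprintf(" (ortholog %s, %d witness pair(s))", x$ortholog,
                        nrow(x$witnesses)) else ""))
  invisible(x)
}

#' Presence calls for many genes and species
#'
#' @param ref_genes gene ids to screen (typically all genes of the
#'   reference species).
#' @param species character vector of target species.
#' @inheritParams forward_check
#' @return data.frame with one row per (gene, species): `ref_gene`,
#'   `species`, `status`, `ortholog`.
#' @export
call_presence_all <- function(ref_genes, species, htab, genes,
                              params = sl_params()) {
  grid <- expand.grid(ref_gene = ref_genes, species = species,
                      stringsAsFactors = FALSE)
  calls <- mapply(function(g, s) {
    pc <- call_presence(g, s, htab, genes, params)
    list(status = pc$status, ortholog = pc$ortholog)
  }, grid$ref_gene, grid$species, SIMPLIFY = FALSE)
  grid$status <- vapply(calls, `[[`, character(1), "status")
  grid$ortholog <- vapply(calls, `[[`, character(1), "ortholog")
  grid
}
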