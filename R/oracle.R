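# Brute-force presence/absence oracle: an independent implementation of
# the whole decision path by exhaustive enumeration -- full dense weight
# structure, fully sorted homolog lists, all witness pairs and all
# alternative homologs enumerated -- sharing nothing with the pipeline
# beyond the pairwise aligner and its surrogate E-value. Intended as the
# reference the fast path is tested against on small instances.

#' Brute-force oracle presence calls
#'
#' @param dataset an [ortho_dataset()]; refused beyond 300 genes per
#'   species or 8 species (guardrail -- the oracle is quadratic and meant
#'   for small instances).
#' @param params an [sl_params()].
#' @param ref_species species whose genes are screened.
#' @param target_species species to call against (default: all others).
#' @param e_value_cut hit threshold used when building cells.
#' @return data.frame `ref_gene`, `species`, `status`, `ortholog`.
#' @export
oracle_presence <- function(dataset, params = sl_params(),
                            ref_species, target_species = NULL,
                            e_value_cut = 0.1) {
  genes <- dataset$genes
  n_sp <- length(unique(genes$species_id))
  max_g <- max(table(genes$species_id))
  if (n_sp > 8 || max_g > 300)
    stop("oracle guardrail: dataset exceeds 300 genes x 8 species",
         call. = FALSE)
  if (is.null(target_species))
    target_species <- setdiff(unique(genes$species_id), ref_species)

  seqs <- dataset$sequences
  ids <- names(seqs)
  np <- length(ids)
  S <- sw_all_pairs(unname(seqs), blosum62(), aa_alphabet(), 11L, 1L)
  selfs <- diag(S)
  db <- sum(nchar(seqs))
  lens <- nchar(seqs)
  Efwd <- outer(lens, rep(1, np)) * db * 0.041 * exp(-0.267 * S)
  Emin <- pmin(Efwd, t(Efwd))
  kept <- Emin <= e_value_cut
  Wp <- 2 * S / outer(selfs, selfs, `+`)   # protein-level weights

  # gene-level projection by exhaustive max / min over kept protein pairs
  pm <- dataset$protein_map
  pidx <- split(match(pm$protein_id, ids), pm$gene_id)
  gid <- names(pidx)
  gsp <- genes$species_id[match(gid, genes$gene_id)]
  ng <- length(gid)
  gW <- matrix(0, ng, ng, dimnames = list(gid, gid))
  gE <- matrix(Inf, ng, ng, dimnames = list(gid, gid))
  gS <- matrix(0, ng, ng, dimnames = list(gid, gid))
  for (a in seq_len(ng)) for (b in seq_len(ng)) {
    pa <- pidx[[a]]; pb <- pidx[[b]]
    k <- kept[pa, pb, drop = FALSE]
    if (!any(k)) next
    wsub <- Wp[pa, pb, drop = FALSE]
    gW[a, b] <- max(wsub[k])
    gE[a, b] <- min(Emin[pa, pb, drop = FALSE][k])
    gS[a, b] <- max(S[pa, pb, drop = FALSE][k])
  }

  # fully sorted homolog list of gene a over species sp, thresholds and
  # top-u applied, ties broken by (desc weight, asc E, asc gene id);
  # precomputed once for every (gene, species)
  all_sp_ids <- unique(gsp)
  hl <- lapply(seq_len(ng), function(a) {
    lapply(setNames(all_sp_ids, all_sp_ids), function(sp) {
      cand <- which(gsp == sp & gid != gid[a] &
                      gW[a, ] > params$weight_min &
                      gE[a, ] < params$e_value_max)
      if (!length(cand)) return(integer(0))
      ord <- order(-gW[a, cand], gE[a, cand], gid[cand])
      cand[ord][seq_len(min(params$u, length(cand)))]
    })
  })
  hlist <- function(a, sp) hl[[a]][[sp]]
  neighborhood <- function(a, r) {
    g <- genes[match(gid[a], genes$gene_id), ]
    which(gsp == g$species_id &
            genes$seq_id[match(gid, genes$gene_id)] == g$seq_id &
            genes$start[match(gid, genes$gene_id)] <= g$end + r &
            genes$end[match(gid, genes$gene_id)] >= g$start - r &
            gid != gid[a])
  }
  beta_ok <- function(ya, yb) {
    la <- hlist(ya, gsp[yb]); lb <- hlist(yb, gsp[ya])
    switch(params$beta,
           bbh = length(la) > 0 && la[1] == yb &&
             length(lb) > 0 && lb[1] == ya,
           top1 = length(la) > 0 && la[1] == yb,
           topu = yb %in% la)
  }
  fwd_ok <- function(a, b) {
    ra <- species_radius(params, gsp[a]); rb <- species_radius(params, gsp[b])
    na_ <- neighborhood(a, ra); nb_ <- neighborhood(b, rb)
    if (!length(na_) || !length(nb_)) return(FALSE)
    pairs <- list()
    for (ya in na_) for (yb in nb_) {
      if (yb %in% hlist(ya, gsp[b]) && beta_ok(ya, yb))
        pairs[[length(pairs) + 1L]] <- c(ya, yb, gW[ya, yb], gE[ya, yb])
    }
    if (!length(pairs)) return(FALSE)
    p <- do.call(rbind, pairs)
    ord <- order(-p[, 3], p[, 4], gid[p[, 1]], gid[p[, 2]])
    p <- p[ord, , drop = FALSE]
    used_a <- used_b <- integer(0); cnt <- 0L
    for (i in seq_len(nrow(p))) {
      if (!(p[i, 1] %in% used_a) && !(p[i, 2] %in% used_b)) {
        cnt <- cnt + 1L
        used_a <- c(used_a, p[i, 1]); used_b <- c(used_b, p[i, 2])
      }
    }
    cnt >= params$witnesses_required
  }
  bwd_ok <- function(a, b) {   # TRUE when candidate b is accepted for a
    alts <- setdiff(hlist(b, gsp[a]), a)
    for (u in alts) {
      closer <- if (params$backward_variant == "difference")
        (gW[b, u] - gW[a, b]) > params$lambda
      else (gS[u, b] / gS[a, b]) > params$lambda1
      if (closer && fwd_ok(u, b)) return(FALSE)
    }
    TRUE
  }

  ref_idx <- which(gsp == ref_species)
  out <- list()
  for (a in ref_idx) for (sp in target_species) {
    status <- "absent"; ort <- NA_character_
    for (b in hlist(a, sp)) {
      if (fwd_ok(a, b) && bwd_ok(a, b)) {
        status <- "present"; ort <- gid[b]; break
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      ref_gene = gid[a], species = sp, status = status, ortholog = ort,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
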