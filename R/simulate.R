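# Synthetic multi-species genomes with planted orthology, paralogy, losses
# and synteny structure, plus a known-truth registry.

# Amino-acid background frequencies (Robinson & Robinson style, the
# composition underlying BLOSUM62), order matching aa_alphabet()[1:20].
aa_background <- function() {
  f <- c(A = 0.078, R = 0.051, N = 0.045, D = 0.054, C = 0.019, Q = 0.043,
         E = 0.063, G = 0.074, H = 0.022, I = 0.051, L = 0.091, K = 0.057,
         M = 0.022, F = 0.039, P = 0.052, S = 0.071, T = 0.058, W = 0.013,
         Y = 0.032, V = 0.064)
  f / sum(f)
}

#' Simulation configuration
#'
#' Defines the evolutionary scenario to emulate: species groups around a
#' reference, an ancestral gene complement laid out on chromosomes with
#' fixed spacing, per-species sequence divergence, planted gene losses,
#' paralog duplications, local synteny shuffling, and planted
#' "through-lower" chains (an ancestral duplication kept asymmetrically so
#' the reference gene is absent from uppers while its lower-species
#' ortholog still has an upper ortholog).
#'
#' @param groups,reference as in [species_groups()].
#' @param genes_per_genome ancestral protein-coding gene count.
#' @param n_chromosomes chromosomes the genes are spread over.
#' @param gene_length min/max peptide length (residues).
#' @param intergenic_spacing distance between successive gene starts, bp.
#'   The default 5e5 makes the standard 5 Mbp radius span about ten genes
#'   on either side.
#' @param divergence per-species substitution probability per residue.
#' @param duplication_rate per-gene, per-species probability of a random
#'   nearby paralog (a backward-check confounder).
#' @param paralog_divergence extra substitution probability applied to
#'   paralog copies.
#' @param synteny_shuffle_rate per-gene probability of swapping places with
#'   its right neighbor (local order shuffling).
#' @param isoform_rate per-gene, per-species probability of a second,
#'   truncated protein isoform.
#' @param loss_events list of planted losses: each element a list with
#'   `genes` (ancestral gene ids) and `species` and/or `groups` naming
#'   where the gene is deleted.
#' @param chain_genes ancestral gene ids planted as three-species chains:
#'   the reference keeps the gene and a diverged paralog, upper species
#'   keep only the paralog descendant, lower species keep only the
#'   original, middle species keep neither.
#' @param seed integer seed; a fixed seed makes the emitted dataset
#'   byte-identical across runs.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(groups, reference, genes_per_genome = 40L,
                       n_chromosomes = 2L, gene_length = c(60L, 90L),
                       intergenic_spacing = 5e5, divergence = 0.05,
                       duplication_rate = 0, paralog_divergence = 0.25,
                       synteny_shuffle_rate = 0, isoform_rate = 0,
                       loss_events = list(), chain_genes = character(),
                       seed = 1L) {
  sg <- species_groups(groups, reference)
  rates <- c(divergence, duplication_rate, paralog_divergence,
             synteny_shuffle_rate, isoform_rate)
  if (any(rates < 0 | rates > 1))
    stop("all rates must be in [0, 1]", call. = FALSE)
  gene_ids <- sprintf("g%03d", seq_len(genes_per_genome))
  loss_events <- lapply(loss_events, function(ev) {
    ev$genes <- as.character(unlist(ev$genes))
    if (!is.null(ev$groups)) ev$groups <- as.character(unlist(ev$groups))
    if (!is.null(ev$species)) ev$species <- as.character(unlist(ev$species))
    ev
  })
  for (ev in loss_events) {
    if (length(setdiff(ev$genes, gene_ids)))
      stop("loss event references unknown gene(s): ",
           paste(setdiff(ev$genes, gene_ids), collapse = ", "),
           call. = FALSE)
    bad <- setdiff(ev$groups, names(groups))
    if (length(bad))
      stop("loss event references unknown group(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    badsp <- setdiff(ev$species, group_species(sg))
    if (length(badsp))
      stop("loss event references unknown species: ",
           paste(badsp, collapse = ", "), call. = FALSE)
  }
  chain_genes <- as.character(unlist(chain_genes))
  if (length(setdiff(chain_genes, gene_ids)))
    stop("chain_genes references unknown gene(s)", call. = FALSE)
  structure(list(groups = sg, genes_per_genome = as.integer(genes_per_genome),
                 n_chromosomes = as.integer(n_chromosomes),
                 gene_length = gene_length,
                 intergenic_spacing = intergenic_spacing,
                 divergence = divergence,
                 duplication_rate = duplication_rate,
                 paralog_divergence = paralog_divergence,
                 synteny_shuffle_rate = synteny_shuffle_rate,
                 isoform_rate = isoform_rate,
                 loss_events = loss_events,
                 chain_genes = chain_genes, seed = as.integer(seed)),
            class = "sim_config")
}

random_peptide <- function(len) {
  aa <- strsplit(aa_alphabet(), "")[[1]][1:20]
  paste(sample(aa, len, replace = TRUE, prob = aa_background()),
        collapse = "")
}

# Substitute each residue with probability `rate`; replacements are drawn
# proportional to exp(BLOSUM62 score) over the 19 alternatives.
mutate_peptide <- function(seq, rate) {
  if (rate <= 0) return(seq)
  aa <- strsplit(aa_alphabet(), "")[[1]][1:20]
  B <- blosum62()[1:20, 1:20]
  res <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(res)) < rate)
  for (i in hit) {
    alt <- setdiff(aa, res[i])
    p <- exp(B[res[i], alt])
    res[i] <- sample(alt, 1, prob = p / sum(p))
  }
  paste(res, collapse = "")
}

resolve_event_species <- function(ev, groups) {
  sp <- ev$species
  if (!is.null(ev$groups))
    sp <- c(sp, unlist(lapply(ev$groups,
                              function(g) groups$groups[[g]]$species)))
  unique(sp)
}

#' Simulate a multi-species dataset with known truth
#'
#' Generates an ancestral genome of random peptides laid on chromosomes at
#' fixed spacing, then derives each species by applying planted losses and
#' chains, random paralog duplications, substitutions and local order
#' shuffles. Per-species gene ids are `<ancestral>_<species>`.
#'
#' @param config a [sim_config()].
#' @return list with `dataset` (an [ortho_dataset()]), `truth` (list:
#'   `ortholog_map` data.frame of expected per-species orthologs of each
#'   reference gene, `lost` planted-loss table, `paralogs` registry,
#'   `chain_genes`), and `config`.
#' @export
simulate_dataset <- function(config) {
  set.seed(config$seed)
  sg <- config$groups
  ref <- sg$reference
  all_sp <- group_species(sg)
  n <- config$genes_per_genome
  gene_ids <- sprintf("g%03d", seq_len(n))
  lens <- sample(seq(config$gene_length[1], config$gene_length[2]),
                 n, replace = TRUE)
  anc <- setNames(vapply(lens, random_peptide, character(1)), gene_ids)

  # chromosome layout: consecutive blocks, one slot per ancestral gene
  per_chr <- ceiling(n / config$n_chromosomes)
  chr <- sprintf("chr%d", ((seq_len(n) - 1) %/% per_chr) + 1)
  slot <- ((seq_len(n) - 1) %% per_chr) + 1
  start0 <- (slot - 1) * config$intergenic_spacing + 1

  # ancestral paralogs for planted chains
  chain <- config$chain_genes
  chain_par <- if (length(chain)) {
    setNames(vapply(chain, function(g)
      mutate_peptide(anc[[g]], config$paralog_divergence), character(1)),
      paste0(chain, "d"))
  } else character(0)

  lost_by_sp <- lapply(setNames(all_sp, all_sp), function(sp) character(0))
  for (ev in config$loss_events) {
    for (sp in resolve_event_species(ev, sg))
      lost_by_sp[[sp]] <- union(lost_by_sp[[sp]], ev$genes)
  }
  role_of <- function(sp) {
    for (g in sg$groups) if (sp %in% g$species) return(g$role)
  }

  seqs <- character(0)
  pm <- list(); gl <- list(); paralogs <- list()
  for (sp in all_sp) {
    role <- role_of(sp)
    keep_orig <- setdiff(gene_ids, lost_by_sp[[sp]])
    # chain semantics: original only in reference + lowers; paralog only in
    # reference + uppers; middles carry neither copy
    if (sp != ref) {
      if (role %in% c("upper", "middle"))
        keep_orig <- setdiff(keep_orig, chain)
    }
    carry_par <- if (sp == ref) names(chain_par)
    else if (role == "upper") names(chain_par) else character(0)

    rows <- list(); prows <- list()
    for (g in keep_orig) {
      i <- match(g, gene_ids)
      gid <- paste0(g, "_", sp)
      seq_sp <- mutate_peptide(anc[[g]], config$divergence)
      pid <- paste0(gid, ".p1")
      seqs[pid] <- seq_sp
      prows[[length(prows) + 1L]] <- data.frame(
        protein_id = pid, gene_id = gid, species_id = sp)
      if (config$isoform_rate > 0 &&
          stats::runif(1) < config$isoform_rate) {
        pid2 <- paste0(gid, ".p2")
        seqs[pid2] <- substr(seq_sp, 1, max(10, floor(nchar(seq_sp) * 0.75)))
        prows[[length(prows) + 1L]] <- data.frame(
          protein_id = pid2, gene_id = gid, species_id = sp)
      }
      glen <- nchar(seq_sp) * 3
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gid, species_id = sp, seq_id = chr[i],
        start = start0[i], end = start0[i] + glen - 1,
        strand = sample(c("+", "-"), 1), anc = g)
      # random paralog confounder adjacent to the gene
      if (config$duplication_rate > 0 &&
          stats::runif(1) < config$duplication_rate) {
        did <- paste0(g, "dup_", sp)
        dseq <- mutate_peptide(seq_sp, config$paralog_divergence)
        dpid <- paste0(did, ".p1")
        seqs[dpid] <- dseq
        prows[[length(prows) + 1L]] <- data.frame(
          protein_id = dpid, gene_id = did, species_id = sp)
        ds <- start0[i] + round(config$intergenic_spacing / 3)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = did, species_id = sp, seq_id = chr[i],
          start = ds, end = ds + nchar(dseq) * 3 - 1,
          strand = sample(c("+", "-"), 1), anc = NA_character_)
        paralogs[[length(paralogs) + 1L]] <- data.frame(
          gene_id = did, parent = paste0(g, "_", sp), species_id = sp)
      }
    }
    for (gp in carry_par) {
      g <- sub("d$", "", gp)
      i <- match(g, gene_ids)
      gid <- paste0(gp, "_", sp)
      seq_sp <- mutate_peptide(chain_par[[gp]], config$divergence)
      pid <- paste0(gid, ".p1")
      seqs[pid] <- seq_sp
      prows[[length(prows) + 1L]] <- data.frame(
        protein_id = pid, gene_id = gid, species_id = sp)
      ds <- start0[i] + round(config$intergenic_spacing / 2)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gid, species_id = sp, seq_id = chr[i],
        start = ds, end = ds + nchar(seq_sp) * 3 - 1,
        strand = sample(c("+", "-"), 1), anc = gp)
      paralogs[[length(paralogs) + 1L]] <- data.frame(
        gene_id = gid, parent = paste0(g, "_", sp), species_id = sp)
    }
    gsp <- do.call(rbind, rows)
    # local synteny shuffling: swap a gene with its right neighbor
    if (config$synteny_shuffle_rate > 0) {
      gsp <- gsp[order(gsp$seq_id, gsp$start), , drop = FALSE]
      for (i in seq_len(nrow(gsp) - 1)) {
        if (gsp$seq_id[i] == gsp$seq_id[i + 1] &&
            stats::runif(1) < config$synteny_shuffle_rate) {
          tmp <- gsp[i, c("start", "end")]
          gsp[i, c("start", "end")] <- gsp[i + 1, c("start", "end")]
          gsp[i + 1, c("start", "end")] <- tmp
        }
      }
    }
    gl[[sp]] <- gsp
    pm[[sp]] <- do.call(rbind, prows)
  }
  genes <- do.call(rbind, gl)
  anc_of <- setNames(genes$anc, genes$gene_id)
  genes$anc <- NULL
  rownames(genes) <- NULL
  protein_map <- do.call(rbind, pm)
  rownames(protein_map) <- NULL

  # expected ortholog of each reference gene in each other species: the
  # species' descendant of the same ancestral gene, if it survived
  ref_genes <- genes$gene_id[genes$species_id == ref]
  other <- setdiff(all_sp, ref)
  omap <- expand.grid(ref_gene = ref_genes, species = other,
                      stringsAsFactors = FALSE)
  omap$ortholog <- paste0(anc_of[omap$ref_gene], "_", omap$species)
  omap$ortholog[is.na(anc_of[omap$ref_gene])] <- NA
  omap$ortholog[!(omap$ortholog %in% genes$gene_id)] <- NA
  lost <- do.call(rbind, c(list(
    data.frame(gene = character(0), species = character(0))),
    lapply(names(lost_by_sp), function(sp)
      if (length(lost_by_sp[[sp]]))
        data.frame(gene = lost_by_sp[[sp]], species = sp))))
  list(dataset = ortho_dataset(seqs, protein_map, genes),
       truth = list(ortholog_map = omap, lost = lost,
                    paralogs = if (length(paralogs))
                      do.call(rbind, paralogs)
                    else data.frame(),
                    chain_genes = config$chain_genes),
       config = config)
}

#' Simulate a differential-expression table
#'
#' Emits an edgeR/DESeq2-style output table for the reference species'
#' genes: planted DE genes get FDR well under 0.01 and |logFC| >= 1.1 (the
#' smallest effect the screened data show at that threshold); the rest get
#' non-significant FDR and small fold changes.
#'
#' @param ref_genes reference-species gene ids.
#' @param de_genes subset of `ref_genes` planted as differentially
#'   expressed.
#' @param frac_down fraction of planted DE genes given a negative logFC.
#' @param seed integer seed.
#' @return data.frame with columns `gene_id`, `contrast`, `logFC`, `FDR`.
#' @export
simulate_de_table <- function(ref_genes, de_genes, frac_down = 0.4,
                              seed = 1L) {
  stopifnot(all(de_genes %in% ref_genes))
  set.seed(seed)
  n <- length(ref_genes)
  is_de <- ref_genes %in% de_genes
  lfc <- stats::runif(n, -0.8, 0.8)
  fdr <- stats::runif(n, 0.05, 1)
  ndown <- floor(sum(is_de) * frac_down)
  sgn <- sample(rep(c(-1, 1), c(ndown, sum(is_de) - ndown)))
  lfc[is_de] <- sgn * stats::runif(sum(is_de), 1.1, 6)
  fdr[is_de] <- stats::runif(sum(is_de), 1e-8, 1e-3)
  data.frame(gene_id = ref_genes, contrast = "0h_vs_24h",
             logFC = round(lfc, 3), FDR = signif(fdr, 3))
}
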