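# Gene-level projection, top-u truncation, ranks and back-ranks.

# hand-built symmetric gene-level weight scenario through the protein layer:
# self scores 100 everywhere so weight = raw/50... (w = 2s/(sxx+syy))
make_V <- function(cells) {
  prot <- unique(c(cells$x, cells$y))
  ss <- setNames(rep(1000, length(prot)), prot)
  fwd <- cells
  rev <- cells[cells$x != cells$y, c("y", "x", "raw_score", "e_value")]
  names(rev) <- c("x", "y", "raw_score", "e_value")
  all_cells <- rbind(fwd, rev,
                     data.frame(x = prot, y = prot, raw_score = 1000,
                                e_value = 1e-50))
  all_cells <- all_cells[!duplicated(all_cells[, c("x", "y")]), ]
  V <- synteloss:::score_matrix(data.table::as.data.table(all_cells), ss,
                                symmetrized = TRUE)
  synteloss:::recompute_weights(V)
}

toy_dataset <- function(gene_species, prot_of_gene = NULL) {
  genes <- data.frame(gene_id = names(gene_species),
                      species_id = unname(gene_species),
                      seq_id = "chr1",
                      start = seq_along(gene_species) * 1000,
                      end = seq_along(gene_species) * 1000 + 500,
                      strand = "+")
  if (is.null(prot_of_gene))
    prot_of_gene <- setNames(as.list(paste0(names(gene_species), ".p")),
                             names(gene_species))
  pm <- data.frame(
    protein_id = unlist(prot_of_gene),
    gene_id = rep(names(prot_of_gene), lengths(prot_of_gene)),
    species_id = gene_species[rep(names(prot_of_gene),
                                  lengths(prot_of_gene))])
  seqs <- setNames(rep("ACDEFGHIKLMNPQRSTVWY", nrow(pm)), pm$protein_id)
  ortho_dataset(seqs, pm, genes)
}

test_that("gene weight is the max over encoded protein pairs", {
  d <- toy_dataset(c(X = "R", Y = "A"),
                   list(X = c("x1", "x2"), Y = "y1"))
  V <- make_V(data.frame(x = c("x1", "x2"), y = c("y1", "y1"),
                         raw_score = c(400, 700), e_value = 1e-20))
  expect_equal(gene_weight("X", "Y", V, d), 0.7)
  # filter away the better isoform -> the weaker pair decides
  expect_equal(gene_weight("X", "Y", V, d,
                           protein_filter = function(p) p != "x2"), 0.4)
  # no cells between genes
  expect_equal(gene_weight("Y", "Y", V, d), 1)
})

test_that("top-u truncation keeps the u best homologs per species", {
  gs <- c(X = "R", A1 = "A", A2 = "A", A3 = "A", A4 = "A", A5 = "A")
  d <- toy_dataset(gs)
  V <- make_V(data.frame(
    x = "X.p", y = paste0("A", 1:5, ".p"),
    raw_score = c(900, 800, 500, 300, 100), e_value = 1e-20))
  ht <- build_homolog_table(d, V, sl_params(u = 3))
  bucket <- ht[ht$query_gene == "X" & ht$target_species == "A", ]
  expect_equal(bucket$target_gene, c("A1", "A2", "A3"))
  expect_equal(bucket$weight, c(0.9, 0.8, 0.5))
  expect_equal(bucket$rank, 1:3)
})

test_that("weight exactly at the threshold is excluded (strict >)", {
  d <- toy_dataset(c(X = "R", Y = "A", Z = "A"))
  # weight 0.07 exactly = 2*70/2000; weight 0.08 stays
  V <- make_V(data.frame(x = c("X.p", "X.p"), y = c("Y.p", "Z.p"),
                         raw_score = c(70, 80), e_value = 1e-20))
  ht <- build_homolog_table(d, V, sl_params())
  bucket <- ht[ht$query_gene == "X" & ht$target_species == "A", ]
  expect_equal(bucket$target_gene, "Z")
})

test_that("E-value threshold applies on top of the weight threshold", {
  d <- toy_dataset(c(X = "R", Y = "A", Z = "A"))
  V <- make_V(data.frame(x = c("X.p", "X.p"), y = c("Y.p", "Z.p"),
                         raw_score = c(500, 500), e_value = c(1e-20, 1e-3)))
  ht <- build_homolog_table(d, V, sl_params())
  bucket <- ht[ht$query_gene == "X" & ht$target_species == "A", ]
  expect_equal(bucket$target_gene, "Y")
})

test_that("mutual unique best hits get rank = back-rank = 1", {
  fx <- synteny_fixture()
  ht <- fx$htab
  xy <- ht[ht$query_gene == "X" & ht$target_gene == "Xp", ]
  expect_equal(xy$rank, 1)
  expect_equal(xy$back_rank, 1)
  yx <- ht[ht$query_gene == "Xp" & ht$target_gene == "X", ]
  expect_equal(yx$rank, 1)
  expect_equal(yx$back_rank, 1)
})

test_that("back-rank is infinite when the reciprocal list lacks the query", {
  e <- data.frame(query_gene = c("X", "Y"), query_species = "R",
                  target_gene = c("W", "W"), target_species = "A",
                  weight = c(0.9, 0.8), e_value = 1e-9, raw_score = 500)
  # W's own bucket lists only Y back
  e2 <- data.frame(query_gene = "W", query_species = "A",
                   target_gene = "Y", target_species = "R",
                   weight = 0.8, e_value = 1e-9, raw_score = 500)
  ht <- assign_ranks(rbind(e, e2))
  expect_equal(ht$back_rank[ht$query_gene == "X"], Inf)
  expect_equal(ht$back_rank[ht$query_gene == "Y" &
                              ht$target_gene == "W"], 1)
})

test_that("ranks match a from-scratch re-sort on a randomized toy table", {
  set.seed(42)
  sim <- quick_sim(seed = 5, genes = 12, divergence = 0.12,
                   duplication_rate = 0.2)
  V <- symmetrize_matrix(build_protein_matrix(sim$dataset))
  ht <- build_homolog_table(sim$dataset, V, sl_params())
  df <- as.data.frame(ht)
  # oracle: independent re-sort within each bucket
  for (key in sample(unique(paste(df$query_gene, df$target_species)), 20)) {
    parts <- strsplit(key, " ")[[1]]
    b <- df[df$query_gene == parts[1] & df$target_species == parts[2], ]
    o <- order(-b$weight, b$e_value, b$target_gene)
    expect_equal(b$rank[o], seq_len(nrow(b)))
  }
  # bucket cardinality never exceeds u
  counts <- table(paste(df$query_gene, df$target_species))
  expect_true(all(counts <= sl_params()$u))
})

test_that("raising the weight threshold never adds entries", {
  sim <- quick_sim(seed = 6, genes = 10, divergence = 0.15)
  V <- symmetrize_matrix(build_protein_matrix(sim$dataset))
  lo <- build_homolog_table(sim$dataset, V, sl_params(weight_min = 0.07))
  hi <- build_homolog_table(sim$dataset, V, sl_params(weight_min = 0.5))
  keys <- function(t) paste(t$query_gene, t$target_gene)
  expect_true(all(keys(hi) %in% keys(lo)))
  expect_lte(nrow(hi), nrow(lo))
})

test_that("homolog table round-trips through its TSV format", {
  fx <- synteny_fixture(with_U = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_homolog_table(fx$htab, path)
  back <- read_homolog_table(path)
  expect_equal(as.data.frame(back)[order(back$query_gene, back$target_gene),
                                   c("query_gene", "target_gene", "weight",
                                     "back_rank")],
               as.data.frame(fx$htab)[order(fx$htab$query_gene,
                                            fx$htab$target_gene),
                                      c("query_gene", "target_gene",
                                        "weight", "back_rank")],
               ignore_attr = TRUE)
})
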