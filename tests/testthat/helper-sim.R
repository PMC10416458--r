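# Shared simulation scaffolding: a standard vertebrate-like group layout
# (two lower groups with the reference among the amphibians, one middle,
# one upper) and hand-built homolog-table fixtures for the synteny checks.

std_groups <- function(n_fish = 2, n_middle = 1, n_upper = 2) {
  list(
    fish = list(species = paste0("fish", seq_len(n_fish)), role = "lower"),
    amph = list(species = "frog", role = "lower"),
    rept = list(species = if (n_middle > 0)
      paste0("liz", seq_len(n_middle)) else character(0), role = "middle"),
    mamm = list(species = paste0("mam", seq_len(n_upper)), role = "upper"))
}

quick_sim <- function(seed = 1, genes = 20, divergence = 0.05,
                      groups = std_groups(), ...) {
  simulate_dataset(sim_config(groups, reference = "frog",
                              genes_per_genome = genes,
                              divergence = divergence, seed = seed, ...))
}

# Hand-built two-species fixture for forward/backward checks.
# Reference species "R" carries X (and optionally U and witness Y);
# species "A" carries candidate Xp and witness Yp. Positions in bp.
synteny_fixture <- function(y_start = 5e4, yp_start = 6e4,
                            with_U = FALSE, u_weight = 0.9,
                            x_weight = 0.8, extra_entries = NULL) {
  genes <- data.frame(
    gene_id = c("X", "Y", "Xp", "Yp", if (with_U) "U"),
    species_id = c("R", "R", "A", "A", if (with_U) "R"),
    seq_id = c("chr1", "chr1", "chrA", "chrA", if (with_U) "chr1"),
    start = c(1e4, y_start, 1e4, yp_start, if (with_U) 2e4),
    end = c(1.2e4, y_start + 2e3, 1.2e4, yp_start + 2e3,
            if (with_U) 2.2e4),
    strand = "+")
  e <- function(q, qs, t, ts, w)
    data.frame(query_gene = q, query_species = qs, target_gene = t,
               target_species = ts, weight = w, e_value = 1e-20,
               raw_score = w * 1000)
  entries <- rbind(
    e("X", "R", "Xp", "A", x_weight), e("Xp", "A", "X", "R", x_weight),
    e("Y", "R", "Yp", "A", 0.95), e("Yp", "A", "Y", "R", 0.95),
    if (with_U) rbind(e("U", "R", "Xp", "A", u_weight),
                      e("Xp", "A", "U", "R", u_weight)),
    extra_entries)
  list(genes = genes, htab = assign_ranks(entries))
}
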