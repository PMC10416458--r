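# Neighborhoods, forward/backward checks, presence calls.

test_that("neighborhood membership is interval intersection with the
           padded window, same scaffold only", {
  genes <- data.frame(
    gene_id = c("X", "near", "boundary", "far", "other_scaf"),
    species_id = "R",
    seq_id = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    start = c(10e3, 4.9e6, 20e3 + 5e6, 6.2e6, 12e3),
    end = c(20e3, 4.92e6, 20e3 + 5e6 + 1e3, 6.21e6, 13e3),
    strand = "+")
  nb <- neighborhood_genes("X", genes, 5e6)
  expect_true("near" %in% nb)
  expect_true("boundary" %in% nb)   # starts exactly at X.end + r
  expect_false("far" %in% nb)
  expect_false("other_scaf" %in% nb)
  expect_false("X" %in% nb)
})

test_that("forward check passes with a BBH witness inside both radii", {
  fx <- synteny_fixture()
  res <- forward_check("X", "Xp", fx$htab, fx$genes, sl_params())
  expect_true(res$ok)
  expect_equal(res$witnesses$query_gene, "Y")
  expect_equal(res$witnesses$target_gene, "Yp")
})

test_that("forward check fails when the witness leaves the neighborhood", {
  fx <- synteny_fixture(y_start = 6e6)  # 6 Mbp from X, radius 5 Mbp
  res <- forward_check("X", "Xp", fx$htab, fx$genes, sl_params())
  expect_false(res$ok)
  # but a larger radius recovers it (monotonicity in r)
  res2 <- forward_check("X", "Xp", fx$htab, fx$genes, sl_params(radius = 7e6))
  expect_true(res2$ok)
})

test_that("a homologous witness that is not a BBH fails the default beta", {
  # second A-side gene outranks Yp in Y's bucket -> (Y, Yp) loses BBH
  extra <- data.frame(query_gene = c("Y", "Zp"), query_species = c("R", "A"),
                      target_gene = c("Zp", "Y"), target_species = c("A", "R"),
                      weight = 0.99, e_value = 1e-25, raw_score = 990)
  fx <- synteny_fixture(extra_entries = extra)
  # Zp sits far from Xp so it cannot serve as a witness itself
  fx$genes <- rbind(fx$genes, data.frame(
    gene_id = "Zp", species_id = "A", seq_id = "chrA2",
    start = 1e4, end = 1.2e4, strand = "+"))
  res <- forward_check("X", "Xp", fx$htab, fx$genes, sl_params())
  expect_false(res$ok)
  # relaxing beta to plain table membership accepts the pair again
  res2 <- forward_check("X", "Xp", fx$htab, fx$genes,
                        sl_params(beta = "topu"))
  expect_true(res2$ok)
})

test_that("forward check demands the configured number of witnesses", {
  fx <- synteny_fixture()
  res <- forward_check("X", "Xp", fx$htab, fx$genes,
                       sl_params(witnesses_required = 2))
  expect_false(res$ok)
})

test_that("forward check errors for a non-candidate pair", {
  fx <- synteny_fixture()
  expect_error(forward_check("Y", "Xp", fx$htab, fx$genes, sl_params()),
               "alpha-homolog")
})

test_that("backward check rejects through a closer alternative with
           synteny, and lambda relaxes it", {
  fx <- synteny_fixture(with_U = TRUE, u_weight = 0.9, x_weight = 0.8)
  # no alternative: accepted
  fx0 <- synteny_fixture()
  expect_true(backward_check("X", "Xp", fx0$htab, fx0$genes,
                             sl_params())$accepted)
  # gap 0.1 > lambda = 0: rejected by U
  res <- backward_check("X", "Xp", fx$htab, fx$genes, sl_params(lambda = 0))
  expect_false(res$accepted)
  expect_equal(res$rejecting_U, "U")
  expect_equal(res$gap, 0.1)
  # gap 0.1 is not > 0.15: accepted
  expect_true(backward_check("X", "Xp", fx$htab, fx$genes,
                             sl_params(lambda = 0.15))$accepted)
  # exact tie never rejects at lambda = 0 (strict inequality)
  fxt <- synteny_fixture(with_U = TRUE, u_weight = 0.8, x_weight = 0.8)
  expect_true(backward_check("X", "Xp", fxt$htab, fxt$genes,
                             sl_params(lambda = 0))$accepted)
})

test_that("quotient-variant backward check uses raw-score ratios", {
  fx <- synteny_fixture(with_U = TRUE, u_weight = 0.9, x_weight = 0.8)
  # S(U,Xp)/S(X,Xp) = 900/800 = 1.125
  p_rej <- sl_params(backward_variant = "quotient", lambda1 = 1.1)
  expect_false(backward_check("X", "Xp", fx$htab, fx$genes, p_rej)$accepted)
  p_acc <- sl_params(backward_variant = "quotient", lambda1 = 1.2)
  expect_true(backward_check("X", "Xp", fx$htab, fx$genes, p_acc)$accepted)
})

test_that("a rejecting alternative without local synteny does not reject", {
  fx <- synteny_fixture(with_U = TRUE)
  # strand U far away on its own scaffold: forward check for (U, Xp) fails
  fx$genes$seq_id[fx$genes$gene_id == "U"] <- "chr9"
  res <- backward_check("X", "Xp", fx$htab, fx$genes, sl_params())
  expect_true(res$accepted)
})

test_that("presence iterates candidates in decreasing weight order", {
  # candidate Bad outweighs Xp but has no witnesses (different scaffold);
  # Xp passes both checks -> present via the second candidate
  extra <- data.frame(query_gene = c("X", "Bad"), query_species = c("R", "A"),
                      target_gene = c("Bad", "X"), target_species = c("A", "R"),
                      weight = 0.97, e_value = 1e-22, raw_score = 970)
  fx <- synteny_fixture(extra_entries = extra)
  fx$genes <- rbind(fx$genes, data.frame(
    gene_id = "Bad", species_id = "A", seq_id = "chrA9",
    start = 1e4, end = 1.2e4, strand = "+"))
  pc <- call_presence("X", "A", fx$htab, fx$genes, sl_params())
  expect_equal(pc$status, "present")
  expect_equal(pc$ortholog, "Xp")
  expect_equal(pc$rejected$candidate, "Bad")
  expect_equal(pc$rejected$reason, "forward")
})

test_that("a gene with an empty bucket is absent", {
  fx <- synteny_fixture()
  pc <- call_presence("Y", "ZZZ_no_such_species", fx$htab, fx$genes,
                      sl_params())
  expect_equal(pc$status, "absent")
  expect_true(is.na(pc$ortholog))
})

test_that("per-species radius override drives the forward check", {
  fx <- synteny_fixture(y_start = 6e6, yp_start = 6e4)
  # witness is 6 Mbp away in R only; override R's radius
  p <- sl_params(radius = 5e6, radius_by_species = c(R = 7e6))
  expect_true(forward_check("X", "Xp", fx$htab, fx$genes, p)$ok)
  p2 <- sl_params(radius = 5e6, radius_by_species = c(A = 7e6))
  expect_false(forward_check("X", "Xp", fx$htab, fx$genes, p2)$ok)
})

test_that("per-call presence is monotone non-decreasing in lambda", {
  sim <- quick_sim(seed = 21, genes = 18, divergence = 0.1,
                   duplication_rate = 0.3)
  V <- symmetrize_matrix(build_protein_matrix(sim$dataset))
  ht <- build_homolog_table(sim$dataset, V)
  genes <- sim$dataset$genes
  refg <- genes$gene_id[genes$species_id == "frog"]
  targets <- setdiff(dataset_species(sim$dataset), "frog")
  set.seed(22)
  cases <- data.frame(g = sample(refg, 10, replace = TRUE),
                      s = sample(targets, 10, replace = TRUE))
  for (i in seq_len(nrow(cases))) {
    st <- vapply(seq(0, 0.6, by = 0.1), function(l) {
      call_presence(cases$g[i], cases$s[i], ht, genes,
                    sl_params(lambda = l))$status == "present"
    }, logical(1))
    expect_true(all(diff(st) >= 0))
  }
})

test_that("pipeline presence calls equal the brute-force oracle", {
  for (seed in c(31, 32)) {
    sim <- quick_sim(seed = seed, genes = 15, divergence = 0.1,
                     duplication_rate = 0.2, synteny_shuffle_rate = 0.1,
                     groups = std_groups(n_fish = 1, n_middle = 1,
                                         n_upper = 1))
    V <- symmetrize_matrix(build_protein_matrix(sim$dataset))
    ht <- build_homolog_table(sim$dataset, V)
    genes <- sim$dataset$genes
    refg <- genes$gene_id[genes$species_id == "frog"]
    pres <- call_presence_all(refg, setdiff(dataset_species(sim$dataset),
                                            "frog"), ht, genes)
    orc <- oracle_presence(sim$dataset, sl_params(), "frog")
    m <- merge(pres, orc, by = c("ref_gene", "species"))
    expect_equal(nrow(m), nrow(pres))
    expect_identical(m$status.x, m$status.y)
    expect_identical(m$ortholog.x, m$ortholog.y)
  }
})
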