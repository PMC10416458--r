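# Group counts, metaconditions, list building.

mock_calls <- function(present) {
  # present: named list gene -> character vector of species where present
  species <- c("fish1", "fish2", "liz1", "mam1", "mam2")
  do.call(rbind, lapply(names(present), function(g) {
    data.frame(ref_gene = g, species = species,
               status = ifelse(species %in% present[[g]], "present",
                               "absent"),
               ortholog = ifelse(species %in% present[[g]],
                                 paste0(g, "_", species), NA))
  }))
}

sg <- species_groups(std_groups(), "frog")

test_that("per-group presence counts tally the calls", {
  calls <- mock_calls(list(gA = c("fish1", "fish2"),
                           gB = c("fish1", "fish2", "liz1", "mam1", "mam2"),
                           gC = character(0)))
  cnt <- presence_counts(calls, sg)
  expect_equal(cnt$fish[cnt$gene == "gA"], 2)
  expect_equal(cnt$rept[cnt$gene == "gA"], 0)
  expect_equal(cnt$mamm[cnt$gene == "gA"], 0)
  expect_equal(cnt$fish[cnt$gene == "gB"], 2)
  expect_equal(cnt$mamm[cnt$gene == "gB"], 2)
  expect_equal(sum(cnt[cnt$gene == "gC", -1]), 0)
})

test_that("counts error when a configured species has no calls", {
  calls <- mock_calls(list(gA = "fish1"))
  calls <- calls[calls$species != "mam2", ]
  expect_error(presence_counts(calls, sg), "mam2")
})

test_that("metaconditions combine present_in atoms with and/or/not", {
  calls <- mock_calls(list(gA = c("fish1", "fish2"),
                           gB = c("fish1", "mam1"),
                           gC = "liz1"))
  cnt <- presence_counts(calls, sg)
  sel <- eval_metacondition(
    "present_in(fish, 1) and not present_in(mamm, 1)", cnt, sg)
  expect_equal(cnt$gene[sel], "gA")
  # anamniote-only selector: zero in every middle and upper group
  sel2 <- eval_metacondition(
    "not (present_in(rept, 1) or present_in(mamm, 1))", cnt, sg)
  expect_setequal(cnt$gene[sel2], c("gA"))
  # k = 0 atom is a tautology
  expect_true(all(eval_metacondition("present_in(fish, 0)", cnt, sg)))
  expect_error(eval_metacondition("present_in(plants, 1)", cnt, sg),
               "unknown group")
  expect_error(eval_metacondition("system('ls')", cnt, sg), "disallowed")
})

test_that("group-default k feeds bare present_in atoms", {
  grp <- std_groups()
  grp$fish$k <- 2
  sg2 <- species_groups(grp, "frog")
  calls <- mock_calls(list(gA = "fish1", gB = c("fish1", "fish2")))
  cnt <- presence_counts(calls, sg2)
  sel <- eval_metacondition("present_in(fish)", cnt, sg2)
  expect_equal(cnt$gene[sel], "gB")
})

test_that("raising k never adds genes (monotone screen)", {
  calls <- mock_calls(list(gA = "fish1", gB = c("fish1", "fish2"),
                           gC = character(0)))
  cnt <- presence_counts(calls, sg)
  for (k in 0:2) {
    lo <- eval_metacondition(sprintf("present_in(fish, %d)", k), cnt, sg)
    hi <- eval_metacondition(sprintf("present_in(fish, %d)", k + 1), cnt, sg)
    expect_true(all(cnt$gene[hi] %in% cnt$gene[lo]))
  }
})

test_that("gene lists carry coordinates, counts and ortholog ids,
           deterministically ordered", {
  sim <- quick_sim(seed = 9, genes = 10,
                   loss_events = list(list(genes = c("g002", "g008"),
                                           groups = c("rept", "mamm"))))
  V <- symmetrize_matrix(build_protein_matrix(sim$dataset))
  ht <- build_homolog_table(sim$dataset, V)
  genes <- sim$dataset$genes
  refg <- genes$gene_id[genes$species_id == "frog"]
  pres <- call_presence_all(refg, setdiff(dataset_species(sim$dataset),
                                          "frog"), ht, genes)
  l1 <- build_gene_list("present_in(fish) and not present_in(mamm, 1)",
                        pres, genes, sg)
  expect_setequal(l1$gene_id, c("g002_frog", "g008_frog"))
  expect_true(all(c("seq_id", "start", "fish", "mamm", "fish1", "mam1")
                  %in% names(l1)))
  expect_equal(l1$fish1, paste0(sub("_frog", "", l1$gene_id), "_fish1"))
  expect_equal(l1$mam1, c("", ""))
  # rerun is byte-identical
  l1b <- build_gene_list("present_in(fish) and not present_in(mamm, 1)",
                         pres, genes, sg)
  expect_identical(l1, l1b)
  # all-false condition gives a valid empty frame with the same columns
  l0 <- build_gene_list("present_in(fish, 99)", pres, genes, sg)
  expect_equal(nrow(l0), 0)
  expect_identical(names(l0), names(l1))
})

test_that("group validation rejects overlaps and a strayed reference", {
  bad <- std_groups()
  bad$rept$species <- c("liz1", "fish1")
  expect_error(species_groups(bad, "frog"), "disjoint")
  expect_error(species_groups(std_groups(), "nessie"), "reference")
})
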