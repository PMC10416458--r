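# End-to-end orchestration: scores -> homologs -> presence -> lists.

default_list1_expr <- function(groups) {
  g <- groups$groups
  roles <- vapply(g, `[[`, character(1), "role")
  ref_grp <- names(g)[vapply(g, function(x)
    groups$reference %in% x$species, logical(1))]
  lower <- setdiff(names(g)[roles == "lower"], character(0))
  upper <- names(g)[roles == "upper"]
  if (!length(lower) || !length(upper))
    stop("need at least one lower and one upper group for the default ",
         "screen condition", call. = FALSE)
  lower_use <- setdiff(lower, ref_grp)
  if (!length(lower_use)) lower_use <- lower
  lo <- paste(sprintf("present_in(%s)", lower_use), collapse = " or ")
  up <- paste(sprintf("present_in(%s, 1)", upper), collapse = " or ")
  sprintf("(%s) and not (%s)", lo, up)
}

default_list4_expr <- function(groups) {
  roles <- vapply(groups$groups, `[[`, character(1), "role")
  middle <- names(groups$groups)[roles == "middle"]
  if (!length(middle)) return(NULL)
  sprintf("not (%s)",
          paste(sprintf("present_in(%s, 1)", middle), collapse = " or "))
}

#' Run the full screen on in-memory inputs
#'
#' Executes the whole chain: score matrix, symmetrization, homolog table,
#' presence calls for every reference gene against every configured
#' species, per-group counts, the lost-gene list (list-1), DE filtering
#' (list-2), their intersection (list-3), the middle-zero subset (list-4)
#' and the three-species final filter.
#'
#' @param dataset an [ortho_dataset()].
#' @param de_records DE table (data.frame as from [load_de_table()]), or
#'   NULL to stop after list-1.
#' @param groups a [species_groups()] object.
#' @param params an [sl_params()].
#' @param fdr_max,theta_min DE thresholds (see [filter_de()]).
#' @param list1_expr metacondition for the lost-gene list; default:
#'   present in at least one non-reference lower group and in no upper
#'   group.
#' @param list4_expr metacondition applied on top of list-3; default:
#'   present in no middle group (`m = n = p = 0` bookkeeping); NULL when
#'   no middle groups are configured.
#' @param score_table optional precomputed protein score table.
#' @return list with elements `V`, `htab`, `presence`, `counts`, `list1`,
#'   `list2`, `list3`, `list4`, `flags`, `final`, and the conditions used.
#' @export
run_screen <- function(dataset, de_records, groups, params = sl_params(),
                       fdr_max = 0.01, theta_min = 0,
                       list1_expr = NULL, list4_expr = NULL,
                       score_table = NULL) {
  if (is.null(list1_expr)) list1_expr <- default_list1_expr(groups)
  if (is.null(list4_expr)) list4_expr <- default_list4_expr(groups)
  V <- symmetrize_matrix(build_protein_matrix(dataset,
                                              score_table = score_table))
  htab <- build_homolog_table(dataset, V, params)
  genes <- dataset$genes
  ref_genes <- genes$gene_id[genes$species_id == groups$reference]
  other_sp <- setdiff(group_species(groups), groups$reference)
  presence <- call_presence_all(ref_genes, other_sp, htab, genes, params)
  counts <- presence_counts(presence, groups)
  list1 <- build_gene_list(list1_expr, presence, genes, groups, counts)
  out <- list(V = V, htab = htab, presence = presence, counts = counts,
              list1 = list1, list1_expr = list1_expr,
              list4_expr = list4_expr)
  if (is.null(de_records)) return(out)
  list2 <- filter_de(de_records, fdr_max = fdr_max, theta_min = theta_min)
  list3 <- intersect_lists(list1, list2)
  list4 <- if (is.null(list4_expr)) list3 else {
    keep <- eval_metacondition(
      list4_expr, counts[match(list3$gene_id, counts$gene), , drop = FALSE],
      groups)
    list3[keep, , drop = FALSE]
  }
  flags <- three_species_flags(list4$gene_id, htab, genes, groups, params)
  final <- apply_final_filter(list4, flags)
  out$list2 <- list2; out$list3 <- list3; out$list4 <- list4
  out$flags <- flags; out$final <- final
  out$n_up <- sum(final$logFC > 0); out$n_down <- sum(final$logFC < 0)
  out
}

read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config
}

#' Run the pipeline from a config and write stage outputs
#'
#' The file-level entry point: reads proteomes and annotations (or a
#' [write_dataset()] directory), the DE table and optional precomputed
#' score table, runs [run_screen()], and writes every stage as TSV under
#' `output_dir` together with a JSON run manifest (config snapshot, input
#' checksums, package version) and a JSON evidence sidecar holding the
#' witness pairs and rejection traces for the final-list genes. Stage
#' outputs are pure functions of the inputs and configuration; a rerun
#' reproduces them byte-identically (the manifest's timestamp aside).
#'
#' @param config YAML path or equivalent list with fields `reference`,
#'   `groups` (name -> species/role/k), and either `dataset_dir` or
#'   `proteomes` + `annotations`; optional `de_table`, `score_table`,
#'   `params`, `fdr_max`, `theta_min`, `list1_condition`,
#'   `list4_condition`.
#' @param output_dir directory for stage outputs.
#' @return the [run_screen()] result, invisibly.
#' @export
run_pipeline <- function(config, output_dir) {
  cfg <- read_run_config(config)
  groups <- species_groups(cfg$groups, cfg$reference)
  params <- do.call(sl_params, if (is.null(cfg$params)) list()
                    else cfg$params)
  input_files <- character(0)
  if (!is.null(cfg$dataset_dir)) {
    dataset <- read_dataset(cfg$dataset_dir)
    input_files <- list.files(cfg$dataset_dir, full.names = TRUE)
  } else {
    prot <- read_proteome_fasta(cfg$proteomes)
    parts <- lapply(cfg$annotations, read_gene_annotations)
    genes <- do.call(rbind, lapply(parts, `[[`, "genes"))
    pmaps <- Filter(Negate(is.null), lapply(parts, `[[`, "protein_map"))
    pmap <- if (length(pmaps)) do.call(rbind, pmaps) else prot$protein_map
    dataset <- ortho_dataset(prot$sequences, pmap, genes)
    input_files <- c(cfg$proteomes, unlist(cfg$annotations))
  }
  de <- if (!is.null(cfg$de_table)) {
    input_files <- c(input_files, cfg$de_table)
    load_de_table(cfg$de_table)
  }
  st <- if (!is.null(cfg$score_table)) {
    input_files <- c(input_files, cfg$score_table)
    read_score_table(cfg$score_table)
  }
  res <- run_screen(dataset, de, groups, params,
                    fdr_max = if (is.null(cfg$fdr_max)) 0.01 else cfg$fdr_max,
                    theta_min = if (is.null(cfg$theta_min)) 0
                    else cfg$theta_min,
                    list1_expr = cfg$list1_condition,
                    list4_expr = cfg$list4_condition,
                    score_table = st)

  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(df, name) {
    write.table(as.data.frame(df), file.path(output_dir, name),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wtsv(as.data.table(res$V), "01_score_matrix.tsv")
  write_homolog_table(res$htab, file.path(output_dir,
                                          "02_homolog_table.tsv"))
  pres <- res$presence
  pres$ortholog[is.na(pres$ortholog)] <- ""
  wtsv(pres, "03_presence.tsv")
  wtsv(res$list1, "04_list1.tsv")
  stages <- c(list2 = "05_list2.tsv", list3 = "06_list3.tsv",
              list4 = "07_list4.tsv", flags = "08_three_species_flags.tsv",
              final = "09_final_list.tsv")
  for (nm in names(stages))
    if (!is.null(res[[nm]])) wtsv(res[[nm]], stages[[nm]])

  # evidence sidecar for the surviving genes: witnesses and rejections
  if (!is.null(res$final) && nrow(res$final)) {
    ev <- lapply(res$final$gene_id, function(g) {
      sp_calls <- lapply(setdiff(group_species(groups), groups$reference),
                         function(sp) {
        pc <- call_presence(g, sp, res$htab, dataset$genes, params)
        list(species = sp, status = pc$status,
             ortholog = if (is.na(pc$ortholog)) NULL else pc$ortholog,
             witnesses = if (nrow(pc$witnesses))
               pc$witnesses[, .(query_gene, target_gene, weight)]
             else NULL,
             rejected = pc$rejected)
      })
      list(gene = g, calls = sp_calls)
    })
    jsonlite::write_json(ev, file.path(output_dir, "evidence.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  manifest <- list(
    config = cfg,
    inputs = as.list(tools::md5sum(input_files[file.exists(input_files)])),
    package_version = as.character(utils::packageVersion("synteloss")),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}
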