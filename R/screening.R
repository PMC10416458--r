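# Species groups, per-group presence counts, metaconditions, gene lists.

#' Configure species groups
#'
#' Groups are disjoint named sets of species with a role relative to the
#' evolutionary stage under study: `lower` taxa emerged before it, `upper`
#' after, `middle` in between. Each group carries a minimum-presence
#' parameter `k` (default 1) used by `present_in(group, k)` atoms. The
#' reference species must belong to exactly one group. The machinery is
#' symmetric: choosing the reference from the upper group and swapping
#' roles turns the lost-gene screen into an emerged-gene screen.
#'
#' @param groups named list; each element a list with `species` (character
#'   vector), `role` (`"lower"`, `"middle"` or `"upper"`), and optional `k`.
#' @param reference reference species id.
#' @return an object of class `species_groups`.
#' @export
species_groups <- function(groups, reference) {
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be named", call. = FALSE)
  all_sp <- unlist(lapply(groups, `[[`, "species"))
  if (anyDuplicated(all_sp))
    stop("species groups must be disjoint", call. = FALSE)
  roles <- vapply(groups, `[[`, character(1), "role")
  if (!all(roles %in% c("lower", "middle", "upper")))
    stop("group role must be lower, middle or upper", call. = FALSE)
  if (sum(vapply(groups, function(g) reference %in% g$species,
                 logical(1))) != 1)
    stop("reference species must belong to exactly one group",
         call. = FALSE)
  groups <- lapply(groups, function(g) {
    g$species <- as.character(unlist(g$species))
    g$k <- if (is.null(g$k)) 1L else as.integer(g$k)
    if (g$k < 0) stop("k must be >= 0", call. = FALSE)
    g
  })
  structure(list(groups = groups, reference = reference),
            class = "species_groups")
}

group_species <- function(groups, roles = NULL, drop_reference = FALSE) {
  g <- groups$groups
  if (!is.null(roles))
    g <- g[vapply(g, `[[`, character(1), "role") %in% roles]
  sp <- unlist(lapply(g, `[[`, "species"), use.names = FALSE)
  if (drop_reference) sp <- setdiff(sp, groups$reference)
  sp
}

#' Per-group presence counts
#'
#' Counts, for each screened gene, the species of each group in which the
#' gene was called present (the classic m/n/p/q bookkeeping when the
#' groups are primitive mammals, birds, reptiles and fish).
#'
#' @param calls presence data.frame from [call_presence_all()]; must cover
#'   every species of every group.
#' @param groups a [species_groups()] object.
#' @return data.frame: `gene` plus one integer count column per group.
#' @export
presence_counts <- function(calls, groups) {
  genes <- unique(calls$ref_gene)
  out <- data.frame(gene = sort(genes), stringsAsFactors = FALSE)
  for (gname in names(groups$groups)) {
    sp <- setdiff(groups$groups[[gname]]$species, groups$reference)
    missing <- setdiff(sp, unique(calls$species))
    if (length(missing))
      stop("no presence calls for species: ",
           paste(missing, collapse = ", "), call. = FALSE)
    sub <- calls[calls$species %in% sp & calls$status == "present", ]
    cnt <- table(factor(sub$ref_gene, levels = out$gene))
    out[[gname]] <- as.integer(cnt)
  }
  out
}

#' Evaluate a metacondition over presence counts
#'
#' Metaconditions combine atoms `present_in(group, k)` -- true for a gene
#' when it is present in at least `k` species of `group` (omitting `k`
#' uses the group's configured `k`) -- with `and`, `or`, `not` and
#' parentheses. The grammar is a restricted R expression: only those
#' operators and atom calls are allowed.
#'
#' @param expr metacondition string, e.g.
#'   `"present_in(fish, 1) and not present_in(placentals, 1)"`.
#' @param counts data.frame from [presence_counts()].
#' @param groups a [species_groups()] object (validates group names).
#' @return logical vector over the rows of `counts`.
#' @export
eval_metacondition <- function(expr, counts, groups) {
  txt <- gsub("\\bAND\\b", "&", expr, ignore.case = TRUE)
  txt <- gsub("\\bOR\\b", "|", txt, ignore.case = TRUE)
  txt <- gsub("\\bNOT\\b", "!", txt, ignore.case = TRUE)
  parsed <- tryCatch(str2lang(txt),
                     error = function(e) stop("cannot parse metacondition: ",
                                              expr, call. = FALSE))
  check_ast <- function(e) {
    if (is.call(e)) {
      op <- as.character(e[[1]])
      if (op %in% c("&", "|", "!", "(")) {
        lapply(as.list(e)[-1], check_ast)
      } else if (op == "present_in") {
        gname <- as.character(e[[2]])
        if (!gname %in% names(groups$groups))
          stop("unknown group in metacondition: ", gname, call. = FALSE)
      } else stop("disallowed operator in metacondition: ", op,
                  call. = FALSE)
    } else if (!is.logical(e) && !is.numeric(e) && !is.name(e)) {
      stop("disallowed token in metacondition", call. = FALSE)
    }
    invisible(NULL)
  }
  check_ast(parsed)
  env <- new.env(parent = baseenv())
  env$present_in <- function(group, k = NULL) {
    group <- as.character(substitute(group))
    if (is.null(k)) k <- groups$groups[[group]]$k
    counts[[group]] >= k
  }
  res <- eval(parsed, env)
  rep_len(as.logical(res), nrow(counts))
}

#' Build a screened gene list
#'
#' Rows for the genes whose counts satisfy the metacondition, carrying
#' coordinates (and any pass-through annotation columns), per-group counts
#' and the called ortholog id in every non-reference species (empty string
#' when absent). Deterministically ordered by (seq_id, start, gene id).
#'
#' @param expr metacondition string, see [eval_metacondition()].
#' @param calls presence data.frame from [call_presence_all()].
#' @param genes gene annotations (provides coordinates for the screened
#'   genes).
#' @param groups a [species_groups()] object.
#' @param counts optional precomputed [presence_counts()].
#' @return data.frame gene list.
#' @export
build_gene_list <- function(expr, calls, genes, groups, counts = NULL) {
  if (is.null(counts)) counts <- presence_counts(calls, groups)
  sel <- counts$gene[eval_metacondition(expr, counts, groups)]
  gsub_ <- genes[match(sel, genes$gene_id), , drop = FALSE]
  base_cols <- intersect(
    c("gene_id", "seq_id", "start", "end", "strand", "symbol", "name"),
    names(gsub_))
  out <- gsub_[, base_cols, drop = FALSE]
  out <- cbind(out, counts[match(sel, counts$gene),
                           setdiff(names(counts), "gene"), drop = FALSE])
  for (sp in sort(unique(calls$species))) {
    sub <- calls[calls$species == sp, ]
    ort <- sub$ortholog[match(sel, sub$ref_gene)]
    out[[sp]] <- ifelse(is.na(ort), "", ort)
  }
  out <- out[order(out$seq_id, out$start, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
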