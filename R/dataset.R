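# Multi-species dataset container: protein sequences, protein-gene map,
# gene coordinates.

#' Assemble a multi-species dataset
#'
#' Bundles the three inputs every downstream step consumes: amino-acid
#' sequences, the protein-to-gene map, and gene coordinates. Protein ids
#' must be globally unique across species (as database accessions are);
#' gene coordinates are 1-based inclusive.
#'
#' @param sequences named character vector of amino-acid sequences; names are
#'   protein ids.
#' @param protein_map data.frame with columns `protein_id`, `gene_id`,
#'   `species_id`.
#' @param genes data.frame with columns `gene_id`, `species_id`, `seq_id`,
#'   `start`, `end`, `strand` (optional extra annotation columns such as
#'   `symbol`, `name` are carried through to outputs).
#' @return an object of class `ortho_dataset`.
#' @export
ortho_dataset <- function(sequences, protein_map, genes) {
  sequences <- unlist(as.list(sequences))
  if (is.null(names(sequences)) || anyNA(names(sequences)))
    stop("sequences must be named by protein id", call. = FALSE)
  if (anyDuplicated(names(sequences)))
    stop("protein ids must be globally unique", call. = FALSE)
  check_aa(sequences)
  protein_map <- as.data.frame(protein_map)
  need <- c("protein_id", "gene_id", "species_id")
  if (!all(need %in% names(protein_map)))
    stop("protein_map needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  genes <- as.data.frame(genes)
  needg <- c("gene_id", "species_id", "seq_id", "start", "end", "strand")
  if (!all(needg %in% names(genes)))
    stop("genes needs columns ", paste(needg, collapse = ", "),
         call. = FALSE)
  if (any(genes$start < 1) || any(genes$end < genes$start))
    stop("gene coordinates must satisfy 1 <= start <= end", call. = FALSE)
  if (anyDuplicated(genes$gene_id))
    stop("gene ids must be unique", call. = FALSE)
  missing <- setdiff(protein_map$protein_id, names(sequences))
  if (length(missing))
    stop("proteins in map without sequence: ",
         paste(head(missing, 3), collapse = ", "), call. = FALSE)
  orphan <- setdiff(protein_map$gene_id, genes$gene_id)
  if (length(orphan))
    stop("proteins mapped to unannotated genes: ",
         paste(head(orphan, 3), collapse = ", "), call. = FALSE)
  structure(list(sequences = sequences,
                 protein_map = protein_map,
                 genes = genes),
            class = "ortho_dataset")
}

#' @export
print.ortho_dataset <- function(x, ...) {
  cat(sprintf("ortho_dataset: %d proteins, %d genes, %d species\n",
              length(x$sequences), nrow(x$genes),
              length(unique(x$genes$species_id))))
  invisible(x)
}

#' Species ids present in a dataset
#' @param dataset an `ortho_dataset`.
#' @return character vector of species ids.
#' @export
dataset_species <- function(dataset) sort(unique(dataset$genes$species_id))

#' Read proteomes from FASTA
#'
#' Headers follow the convention `>protein_id gene=<gene_id>
#' species=<species_id>`; alternatively supply a sidecar mapping table and
#' plain-id headers.
#'
#' @param paths one or more FASTA files.
#' @param protein_map optional data.frame (`protein_id`, `gene_id`,
#'   `species_id`) used instead of header tags.
#' @return list with `sequences` (named character) and `protein_map`.
#' @export
read_proteome_fasta <- function(paths, protein_map = NULL) {
  aa <- do.call(c, lapply(paths, Biostrings::readAAStringSet))
  headers <- names(aa)
  seqs <- as.character(aa)
  ids <- sub("\\s.*$", "", headers)
  names(seqs) <- ids
  if (is.null(protein_map)) {
    gene <- sub(".*\\bgene=(\\S+).*", "\\1", headers)
    spec <- sub(".*\\bspecies=(\\S+).*", "\\1", headers)
    bad <- !grepl("\\bgene=", headers) | !grepl("\\bspecies=", headers)
    if (any(bad))
      stop("FASTA headers lack gene=/species= tags (and no sidecar map): ",
           paste(head(ids[bad], 3), collapse = ", "), call. = FALSE)
    protein_map <- data.frame(protein_id = ids, gene_id = gene,
                              species_id = spec)
  }
  list(sequences = seqs, protein_map = as.data.frame(protein_map))
}

#' Read gene annotations
#'
#' Flat TSV with columns `gene_id`, `species_id`, `seq_id`, `start`, `end`,
#' `strand` and optionally `protein_ids` (comma-separated), or GFF3 (`gene`
#' features carrying `ID`; `CDS` features carrying `protein_id` and a
#' `Parent` chain for the protein map). GFF3 carries no species field, so
#' `species_id` must be given for that format.
#'
#' @param path annotation file.
#' @param format `"tsv"` or `"gff3"`; `"auto"` decides from the extension.
#' @param species_id species of the annotated genome (GFF3 only).
#' @return list with `genes` data.frame and `protein_map` (NULL when the
#'   input has no protein column).
#' @export
read_gene_annotations <- function(path, format = c("auto", "tsv", "gff3"),
                                  species_id = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE))
      "gff3" else "tsv"
  }
  if (format == "tsv") {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "species_id", "seq_id", "start", "end", "strand")
    miss <- setdiff(need, names(tab))
    if (length(miss))
      stop("annotation TSV lacks columns: ", paste(miss, collapse = ", "),
           call. = FALSE)
    pm <- NULL
    if ("protein_ids" %in% names(tab)) {
      keep <- nzchar(tab$protein_ids) & !is.na(tab$protein_ids)
      pieces <- strsplit(tab$protein_ids[keep], ",", fixed = TRUE)
      pm <- data.frame(
        protein_id = trimws(unlist(pieces)),
        gene_id = rep(tab$gene_id[keep], lengths(pieces)),
        species_id = rep(tab$species_id[keep], lengths(pieces)))
      tab$protein_ids <- NULL
    }
    return(list(genes = tab, protein_map = pm))
  }
  parse_gff3(path, species_id)
}

# Minimal GFF3 reader: gene features define loci, CDS features map proteins.
parse_gff3 <- function(path, species_id) {
  if (is.null(species_id))
    stop("species_id is required when reading GFF3", call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(f) == 9L
  if (!all(ok)) stop("malformed GFF3 line(s): ",
                     paste(head(which(!ok), 3), collapse = ", "),
                     call. = FALSE)
  f <- do.call(rbind, f)
  attrs <- f[, 9]
  get_attr <- function(a, key) {
    pat <- sprintf(".*(^|;)%s=([^;]*).*", key)
    ifelse(grepl(sprintf("(^|;)%s=", key), a), sub(pat, "\\2", a),
           NA_character_)
  }
  is_gene <- f[, 3] == "gene"
  genes <- data.frame(
    gene_id = get_attr(attrs[is_gene], "ID"),
    species_id = species_id,
    seq_id = f[is_gene, 1],
    start = as.integer(f[is_gene, 4]),
    end = as.integer(f[is_gene, 5]),
    strand = f[is_gene, 7])
  sym <- get_attr(attrs[is_gene], "Name")
  if (any(!is.na(sym))) genes$symbol <- sym
  # resolve CDS -> mRNA -> gene through Parent links
  ids <- get_attr(attrs, "ID")
  parents <- get_attr(attrs, "Parent")
  parent_of <- setNames(parents, ids)
  is_cds <- f[, 3] == "CDS"
  pm <- NULL
  if (any(is_cds)) {
    prot <- get_attr(attrs[is_cds], "protein_id")
    par <- parents[is_cds]
    gene_of <- vapply(par, function(p) {
      while (!is.na(p) && !(p %in% genes$gene_id) && p %in% names(parent_of))
        p <- parent_of[[p]]
      if (is.na(p) || !(p %in% genes$gene_id)) NA_character_ else p
    }, character(1))
    keep <- !is.na(prot) & !is.na(gene_of)
    pm <- unique(data.frame(protein_id = prot[keep],
                            gene_id = unname(gene_of[keep]),
                            species_id = species_id))
  }
  list(genes = genes, protein_map = pm)
}

#' Write a dataset to FASTA + annotation TSV
#'
#' Emits one proteome FASTA (tagged headers) and one flat annotation TSV per
#' species under `dir`, in the formats [read_proteome_fasta()] and
#' [read_gene_annotations()] read back. Output bytes are a pure function of
#' the dataset.
#'
#' @param dataset an `ortho_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  pm <- dataset$protein_map
  for (sp in dataset_species(dataset)) {
    pms <- pm[pm$species_id == sp, , drop = FALSE]
    pms <- pms[order(pms$protein_id), , drop = FALSE]
    fa <- file.path(dir, paste0(sp, ".faa"))
    con <- file(fa, "w")
    for (i in seq_len(nrow(pms))) {
      cat(sprintf(">%s gene=%s species=%s\n%s\n", pms$protein_id[i],
                  pms$gene_id[i], sp, dataset$sequences[[pms$protein_id[i]]]),
          file = con)
    }
    close(con)
    g <- dataset$genes[dataset$genes$species_id == sp, , drop = FALSE]
    prot_by_gene <- split(pms$protein_id, pms$gene_id)
    g$protein_ids <- vapply(g$gene_id, function(id)
      paste(prot_by_gene[[id]], collapse = ","), character(1))
    g <- g[order(g$seq_id, g$start, g$gene_id), , drop = FALSE]
    ann <- file.path(dir, paste0(sp, ".genes.tsv"))
    write.table(g, ann, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, fa, ann)
  }
  invisible(paths)
}

#' Read back a dataset written by [write_dataset()]
#' @param dir directory holding `<species>.faa` / `<species>.genes.tsv` pairs.
#' @return an `ortho_dataset`.
#' @export
read_dataset <- function(dir) {
  fas <- list.files(dir, pattern = "\\.faa$", full.names = TRUE)
  if (!length(fas)) stop("no .faa files under ", dir, call. = FALSE)
  prot <- read_proteome_fasta(fas)
  anns <- list.files(dir, pattern = "\\.genes\\.tsv$", full.names = TRUE)
  parts <- lapply(anns, read_gene_annotations, format = "tsv")
  genes <- do.call(rbind, lapply(parts, `[[`, "genes"))
  ortho_dataset(prot$sequences, prot$protein_map, genes)
}
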