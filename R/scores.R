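# Sparse protein-pair score matrix: build, symmetrize, normalize.
#
# The matrix is held long-form as a data.table of cells (x, y, raw_score,
# e_value, weight); absent cells mean raw score 0 and infinite E-value.

score_matrix <- function(cells, self_scores, norm = "mean",
                         symmetrized = FALSE) {
  cells <- as.data.table(cells)
  setorder(cells, x, y)
  data.table::setattr(cells, "self_scores", self_scores)
  data.table::setattr(cells, "norm", norm)
  data.table::setattr(cells, "symmetrized", symmetrized)
  data.table::setattr(cells, "class",
                      unique(c("score_matrix", class(cells))))
  cells
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("score_matrix: %d cells over %d proteins (%s)\n",
              nrow(x), length(attr(x, "self_scores")),
              if (isTRUE(attr(x, "symmetrized"))) "symmetrized"
              else "directional"))
  NextMethod()
}

#' Read a precomputed raw-score table
#'
#' TSV with columns `query_protein`, `target_protein`, `raw_score`,
#' `e_value`, matching blastp `-outfmt "6 qseqid sseqid score evalue"` with
#' a header line.
#'
#' @param path TSV file.
#' @return data.frame of pairwise hits.
#' @export
read_score_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("query_protein", "target_protein", "raw_score", "e_value")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("score table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  tab
}

#' Build the sparse protein-pair score matrix
#'
#' All-vs-all cells over every protein of every species, including
#' within-species pairs. With the built-in aligner, identical sequences are
#' deduplicated before alignment and the cells re-expanded to every copy
#' afterwards; each directional cell gets a surrogate E-value and cells are
#' kept only when `e_value <= e_value_cut`. With a precomputed table, the
#' producer's scores and E-values are used verbatim (self cells missing from
#' the table are filled by the built-in aligner, since the normalization
#' denominator needs every self score).
#'
#' @param dataset an [ortho_dataset()].
#' @param e_value_cut hit threshold (default 0.1).
#' @param score_table optional precomputed table from [read_score_table()].
#' @param norm normalization denominator: `"mean"` (default), `"min"` or
#'   `"max"` of the two self-scores.
#' @param gap_open,gap_extend built-in aligner gap costs.
#' @return a `score_matrix` (directional; see [symmetrize_matrix()]).
#' @export
build_protein_matrix <- function(dataset, e_value_cut = 0.1,
                                 score_table = NULL,
                                 norm = c("mean", "min", "max"),
                                 gap_open = 11L, gap_extend = 1L) {
  norm <- match.arg(norm)
  if (length(unique(dataset$protein_map$species_id)) < 2)
    stop("need proteomes from at least two species", call. = FALSE)
  seqs <- dataset$sequences
  ids <- names(seqs)

  if (is.null(score_table)) {
    # deduplicate identical sequences, align representatives, re-expand
    grp <- match(seqs, unique(seqs))
    reps <- !duplicated(grp)
    rep_seqs <- seqs[reps]
    S <- sw_all_pairs(unname(rep_seqs), blosum62(), aa_alphabet(),
                      as.integer(gap_open), as.integer(gap_extend))
    self_rep <- diag(S)
    self_scores <- setNames(self_rep[grp], ids)
    db_res <- sum(nchar(seqs))
    lens <- nchar(rep_seqs)
    nrep <- length(rep_seqs)
    qi <- rep(seq_len(nrep), each = nrep)
    ti <- rep(seq_len(nrep), times = nrep)
    sc <- as.vector(t(S))          # row-major: query qi against target ti
    ev <- surrogate_evalue(sc, lens[qi], db_res)
    keep <- ev <= e_value_cut
    cells_rep <- data.table(qi = qi[keep], ti = ti[keep],
                            raw_score = as.numeric(sc[keep]),
                            e_value = ev[keep])
    # expand representative cells to all identical copies
    if (all(reps)) {
      cells <- data.table(x = ids[cells_rep$qi], y = ids[cells_rep$ti],
                          raw_score = cells_rep$raw_score,
                          e_value = cells_rep$e_value)
    } else {
      copies <- split(seq_along(ids), grp)
      nq <- lengths(copies)[cells_rep$qi]
      nt <- lengths(copies)[cells_rep$ti]
      idx <- rep(seq_len(nrow(cells_rep)), nq * nt)
      expand_pair <- function(q, t) {
        cq <- copies[[q]]; ct <- copies[[t]]
        list(x = rep(cq, each = length(ct)), y = rep(ct, length(cq)))
      }
      ex <- mapply(expand_pair, cells_rep$qi, cells_rep$ti, SIMPLIFY = FALSE)
      cells <- data.table(
        x = ids[unlist(lapply(ex, `[[`, "x"))],
        y = ids[unlist(lapply(ex, `[[`, "y"))],
        raw_score = cells_rep$raw_score[idx],
        e_value = cells_rep$e_value[idx])
    }
  } else {
    score_table <- as.data.table(score_table)
    unknown <- setdiff(unique(c(score_table$query_protein,
                                score_table$target_protein)), ids)
    if (length(unknown))
      stop("score table references unknown proteins: ",
           paste(head(unknown, 3), collapse = ", "), call. = FALSE)
    cells <- data.table(x = score_table$query_protein,
                        y = score_table$target_protein,
                        raw_score = as.numeric(score_table$raw_score),
                        e_value = as.numeric(score_table$e_value))
    cells <- cells[e_value <= e_value_cut]
    selfs <- cells[x == y]
    self_scores <- setNames(rep(NA_real_, length(ids)), ids)
    self_scores[selfs$x] <- selfs$raw_score
    todo <- is.na(self_scores)
    if (any(todo))
      self_scores[todo] <- as.numeric(align_raw_score(
        seqs[todo], seqs[todo], gap_open, gap_extend))
  }
  V <- score_matrix(cells, self_scores, norm = norm, symmetrized = FALSE)
  recompute_weights(V)
}

recompute_weights <- function(V) {
  ss <- attr(V, "self_scores")
  V[, weight := normalize_score(raw_score, ss[x], ss[y], attr(V, "norm"))]
  V
}

#' Symmetrize a score matrix
#'
#' For every unordered pair the larger raw score replaces the smaller and
#' the smaller E-value replaces the larger; a cell whose mirror is empty is
#' copied into it. Weights are then recomputed from the symmetrized raw
#' scores. Idempotent.
#'
#' @param V a `score_matrix` from [build_protein_matrix()].
#' @return the symmetrized `score_matrix`.
#' @export
symmetrize_matrix <- function(V) {
  cells <- as.data.table(V)[, .(x, y, raw_score, e_value)]
  cells[, `:=`(pair_lo = pmin(x, y), pair_hi = pmax(x, y))]
  merged <- cells[, .(raw_score = max(raw_score), e_value = min(e_value)),
                  by = .(pair_lo, pair_hi)]
  fwd <- merged[, .(x = pair_lo, y = pair_hi, raw_score, e_value)]
  rev <- merged[pair_lo != pair_hi,
                .(x = pair_hi, y = pair_lo, raw_score, e_value)]
  out <- score_matrix(rbindlist(list(fwd, rev)),
                      attr(V, "self_scores"), norm = attr(V, "norm"),
                      symmetrized = TRUE)
  recompute_weights(out)
}
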