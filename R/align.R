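# Pairwise local alignment and the normalized homology weight.

.sl <- new.env(parent = emptyenv())

# 20 standard amino acids plus X (unknown), the accepted residue alphabet.
aa_alphabet <- function() "ARNDCQEGHILKMFPSTWYVX"

# BLOSUM62 restricted to the accepted alphabet, cached per session.
blosum62 <- function() {
  if (is.null(.sl$blosum62)) {
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    aa <- strsplit(aa_alphabet(), "")[[1]]
    m <- env$BLOSUM62[aa, aa]
    storage.mode(m) <- "integer"
    .sl$blosum62 <- m
  }
  .sl$blosum62
}

check_aa <- function(seqs) {
  if (any(!nzchar(seqs))) stop("empty protein sequence", call. = FALSE)
  bad <- grepl(sprintf("[^%s]", aa_alphabet()), seqs)
  if (any(bad)) {
    stop("sequence contains residues outside the 20 amino acids + X: ",
         paste(head(names(seqs)[bad], 3), collapse = ", "), call. = FALSE)
  }
  invisible(seqs)
}

#' Raw local-alignment score of two peptides
#'
#' Optimal Smith--Waterman local alignment score under BLOSUM62 with affine
#' gap costs in the BLAST convention: a gap of length `k` costs
#' `gap_open + k * gap_extend` (defaults 11 and 1, the blastp defaults).
#' The score is symmetric in its arguments. Vectorized over pairs.
#'
#' @param x,y character vectors of amino-acid sequences (20 standard residues
#'   plus `X`); recycled to a common length.
#' @param gap_open,gap_extend affine gap parameters (non-negative integers).
#' @return integer vector of raw alignment scores (>= 0).
#' @examples
#' align_raw_score("A", "A")          # BLOSUM62 A/A diagonal entry
#' align_raw_score("HEAGAWGHEE", "PAWHEAE")
#' @export
align_raw_score <- function(x, y, gap_open = 11L, gap_extend = 1L) {
  n <- max(length(x), length(y))
  x <- rep_len(toupper(x), n); y <- rep_len(toupper(y), n)
  check_aa(x); check_aa(y)
  sw_pair_scores(x, y, blosum62(), aa_alphabet(),
                 as.integer(gap_open), as.integer(gap_extend))
}

#' Surrogate E-value for a raw alignment score
#'
#' Karlin--Altschul-style expect value `E = K * m * n * exp(-lambda * S)`
#' with the gapped BLOSUM62/11/1 constants (`lambda = 0.267`, `K = 0.041`).
#' It is a monotone surrogate used by the built-in aligner path: downstream
#' thresholds, ranks and bidirectional best hits depend only on the ordering
#' of scores, which this preserves. It is not numerically identical to the
#' E-value a full BLAST search would report. The precomputed score-table
#' input path carries the producer's E-values verbatim instead.
#'
#' @param score raw alignment score(s).
#' @param query_len query sequence length (residues).
#' @param db_residues total residues in the search space.
#' @param lambda,K Karlin--Altschul parameters.
#' @return numeric E-values.
#' @export
surrogate_evalue <- function(score, query_len, db_residues,
                             lambda = 0.267, K = 0.041) {
  K * as.numeric(query_len) * as.numeric(db_residues) *
    exp(-lambda * as.numeric(score))
}

#' Normalize a raw score to a homology weight
#'
#' `w(x, y) = 2 s(x, y) / (s(x, x) + s(y, y))` (method `"mean"`); the
#' denominator may instead be the smaller or larger self-score. The weight
#' is dimensionless, typically in `[0, 1]`, but is deliberately not clamped:
#' local alignment peculiarities can push it slightly above 1.
#'
#' @param s_xy raw score of the pair.
#' @param s_xx,s_yy self-alignment raw scores; must be positive.
#' @param method denominator choice: mean (default), min or max self-score.
#' @return numeric weight(s).
#' @examples
#' normalize_score(100, 100, 100)  # 1
#' normalize_score(60, 100, 140)   # 0.5
#' @export
normalize_score <- function(s_xy, s_xx, s_yy,
                            method = c("mean", "min", "max")) {
  method <- match.arg(method)
  if (any(s_xx <= 0) || any(s_yy <= 0))
    stop("self-alignment scores must be positive", call. = FALSE)
  switch(method,
    mean = 2 * s_xy / (s_xx + s_yy),
    min  = s_xy / pmin(s_xx, s_yy),
    max  = s_xy / pmax(s_xx, s_yy))
}
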