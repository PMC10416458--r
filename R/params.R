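# Algorithm parameters with the study's standard values as defaults.

#' Orthology-search parameters
#'
#' Collects every tunable of the presence/absence machinery. Defaults are
#' the standard parameter set: up to `u = 3` closest homologs per species at
#' weight > 0.07 and E-value < 1e-7; a 5 Mbp neighborhood on either side of
#' a gene; at least one witness pair under the bidirectional-best-hit (BBH)
#' condition; backward-check threshold `lambda = 0`; three-species radii
#' 1, 2 and 5 Mbp.
#'
#' @param u maximum homologs kept per (gene, target species); >= 1.
#' @param radius neighborhood half-width in bp, applied on either side of a
#'   gene's interval.
#' @param radius_by_species optional named numeric vector of per-species
#'   radius overrides.
#' @param witnesses_required minimum witness pairs for the forward check.
#' @param beta witness-pair homology condition: `"bbh"` (rank 1 and
#'   back-rank 1, default), `"top1"` (rank 1), or `"topu"` (any table
#'   entry).
#' @param lambda backward-check weight-gap threshold in `[0, 1]`
#'   (difference variant); `0` reproduces the plain backward check.
#' @param backward_variant `"difference"` (weight gap > lambda) or
#'   `"quotient"` (raw-score ratio > lambda1).
#' @param lambda1 raw-score ratio threshold (>= 1, quotient variant).
#' @param weight_min homolog-table weight threshold (strict >).
#' @param e_value_max homolog-table E-value threshold (strict <).
#' @param radii neighborhood radii for the three-species condition, bp.
#' @return an object of class `sl_params`.
#' @export
sl_params <- function(u = 3L, radius = 5e6, radius_by_species = NULL,
                      witnesses_required = 1L,
                      beta = c("bbh", "top1", "topu"),
                      lambda = 0,
                      backward_variant = c("difference", "quotient"),
                      lambda1 = 1,
                      weight_min = 0.07, e_value_max = 1e-7,
                      radii = c(1e6, 2e6, 5e6)) {
  beta <- match.arg(beta)
  backward_variant <- match.arg(backward_variant)
  if (u < 1) stop("u must be >= 1", call. = FALSE)
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  if (witnesses_required < 1)
    stop("witnesses_required must be >= 1", call. = FALSE)
  if (lambda < 0) stop("lambda must be non-negative", call. = FALSE)
  if (lambda1 < 1) stop("lambda1 must be >= 1", call. = FALSE)
  structure(list(u = as.integer(u), radius = radius,
                 radius_by_species = radius_by_species,
                 witnesses_required = as.integer(witnesses_required),
                 beta = beta, lambda = lambda,
                 backward_variant = backward_variant, lambda1 = lambda1,
                 weight_min = weight_min, e_value_max = e_value_max,
                 radii = radii),
            class = "sl_params")
}

species_radius <- function(params, species) {
  o <- params$radius_by_species
  if (!is.null(o) && species %in% names(o)) unname(o[[species]])
  else params$radius
}
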