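# Variant panels: per-variant metadata with ancestral allele frequencies.

#' Construct a variant panel
#'
#' A variant panel is a tibble with one row per variant and columns
#' `variant` (integer index), `chrom`, `pos_bp` (1-based physical position,
#' strictly increasing within chromosome), `p1` and `p0` (allele frequencies
#' in ancestral populations 1 and 0), and `feature_id` (`NA` for ordinary
#' variants, a label for variants belonging to a planted latent feature).
#' The ancestral frequency difference \eqn{\Delta_j = p_{j1} - p_{j0}}
#' determines how strongly a variant is differentiated between the two
#' ancestral populations.
#'
#' @param chrom Chromosome label per variant.
#' @param pos_bp 1-based physical position per variant.
#' @param p1,p0 Ancestral allele frequencies, in \[0, 1\].
#' @param feature_id Optional feature label per variant (default `NA`).
#' @return A tibble of class `variant_panel`.
#' @examples
#' variant_panel(chrom = c(1, 1, 2), pos_bp = c(100, 200, 100),
#'               p1 = c(.9, .5, .2), p0 = c(.1, .5, .25))
#' @export
variant_panel <- function(chrom, pos_bp, p1, p0, feature_id = NA_character_) {
  m <- length(pos_bp)
  if (length(chrom) == 1L) chrom <- rep(chrom, m)
  stopifnot(length(chrom) == m, length(p1) == m, length(p0) == m)
  check_prob(p1, "p1")
  check_prob(p0, "p0")
  panel <- tibble::tibble(
    variant = seq_len(m),
    chrom = as.character(chrom),
    pos_bp = as.numeric(pos_bp),
    p1 = as.numeric(p1),
    p0 = as.numeric(p0),
    feature_id = rep_len(as.character(feature_id), m)
  )
  bad <- panel |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(ok = all(diff(.data$pos_bp) > 0) || dplyr::n() == 1L) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad)) {
    abort(sprintf("positions must be strictly increasing within chromosome: %s",
                  paste(bad$chrom, collapse = ", ")))
  }
  class(panel) <- c("variant_panel", class(panel))
  panel
}

#' Ancestral frequency difference per variant
#'
#' @param panel A [variant_panel()].
#' @return Numeric vector \eqn{\Delta_j = p_{j1} - p_{j0}} in \[-1, 1\].
#' @export
panel_delta <- function(panel) {
  panel$p1 - panel$p0
}

#' Generate a synthetic variant panel under a Balding-Nichols model
#'
#' Draws ancestral allele frequencies for `n_chrom` synthetic chromosomes of
#' `variants_per_chrom` equally spaced variants. Each variant has an ancestral
#' frequency drawn uniformly on \[0.1, 0.9\], and population-specific
#' frequencies drawn from the Balding-Nichols Beta distribution with the
#' given fixation index, giving a realistic spread of frequency differences
#' between the two ancestral populations (the default `fst = 0.2` is typical
#' of the divergence between West African and European reference panels).
#' Frequencies are clipped to \[0.01, 0.99\] to keep every variant
#' polymorphic.
#'
#' @param n_chrom Number of chromosomes.
#' @param variants_per_chrom Variants per chromosome.
#' @param spacing_bp Distance between adjacent variants in base pairs.
#' @param fst Balding-Nichols fixation index in (0, 1).
#' @param seed Integer seed.
#' @return A [variant_panel()].
#' @examples
#' synthetic_panel(n_chrom = 2, variants_per_chrom = 10, seed = 1)
#' @export
synthetic_panel <- function(n_chrom = 6, variants_per_chrom = 1200,
                            spacing_bp = 1e4, fst = 0.2, seed = 1) {
  stopifnot(fst > 0, fst < 1)
  m <- n_chrom * variants_per_chrom
  with_seed(seed, {
    p_anc <- runif(m, 0.1, 0.9)
    shape <- (1 - fst) / fst
    p1 <- rbeta(m, p_anc * shape, (1 - p_anc) * shape)
    p0 <- rbeta(m, p_anc * shape, (1 - p_anc) * shape)
    variant_panel(
      chrom = rep(as.character(seq_len(n_chrom)), each = variants_per_chrom),
      pos_bp = rep(seq_len(variants_per_chrom) * spacing_bp, n_chrom),
      p1 = pmin(pmax(p1, 0.01), 0.99),
      p0 = pmin(pmax(p0, 0.01), 0.99)
    )
  })
}

#' Specify a multi-region latent feature
#'
#' A feature is a latent, per-individual binary indicator that shifts allele
#' frequencies inside one or more genomic regions simultaneously. It is the
#' minimal construction that makes a single principal component load on
#' variants in several regions across several chromosomes — the behaviour
#' observed for later PCs in admixed cohorts — without modelling the
#' underlying haplotype structure.
#'
#' @param regions A data frame (or tibble) with columns `chrom`, `start_bp`,
#'   `end_bp`; 1-based inclusive coordinates, may span several chromosomes.
#' @param carrier_freq Population frequency of the latent indicator, in
#'   \[0, 1\].
#' @param strength Allele-frequency shift applied inside the regions
#'   (+`strength` for carriers, -`strength` otherwise), in \[0, 0.5\].
#'   Shifted frequencies are clipped to \[0.01, 0.99\].
#' @param id Feature label.
#' @return An object of class `feature_spec`.
#' @examples
#' feature_spec(data.frame(chrom = c("2", "5"),
#'                         start_bp = c(1e6, 4e6), end_bp = c(1.2e6, 4.2e6)))
#' @export
feature_spec <- function(regions, carrier_freq = 0.5, strength = 0.45,
                         id = "feature1") {
  regions <- tibble::as_tibble(regions)
  stopifnot(all(c("chrom", "start_bp", "end_bp") %in% names(regions)))
  if (any(regions$end_bp < regions$start_bp)) {
    abort("feature regions must have start_bp <= end_bp.")
  }
  check_prob(carrier_freq, "carrier_freq")
  if (strength < 0 || strength > 0.5) {
    abort("`strength` must lie in [0, 0.5].")
  }
  regions$chrom <- as.character(regions$chrom)
  structure(list(regions = regions, carrier_freq = carrier_freq,
                 strength = strength, id = id),
            class = "feature_spec")
}

# Logical vector: which panel variants fall inside the feature's regions.
# Coordinates are 1-based inclusive on both sides.
feature_members <- function(panel, feature) {
  inside <- rep(FALSE, nrow(panel))
  for (r in seq_len(nrow(feature$regions))) {
    reg <- feature$regions[r, ]
    hit <- panel$chrom == reg$chrom &
      panel$pos_bp >= reg$start_bp & panel$pos_bp <= reg$end_bp
    if (!any(hit)) {
      warn(sprintf("feature '%s': region %s:%g-%g contains no panel variants; ignored.",
                   feature$id, reg$chrom, reg$start_bp, reg$end_bp))
    }
    inside <- inside | hit
  }
  inside
}
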