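#' Neighbor density of a plot
#'
#' Number of plants in the plot minus the focal, divided by plot area in
#' hectares.
#'
#' @param n_plants Plant count including the focal (>= 1).
#' @param plot_area Plot area in m^2 (> 0).
#' @return Density in plants per hectare.
#' @export
neighborDensity <- function(n_plants, plot_area) {
  if (any(plot_area <= 0)) stop("plot area must be positive", call. = FALSE)
  if (any(n_plants < 1)) stop("n_plants must be >= 1", call. = FALSE)
  (n_plants - 1) / (plot_area / 1e4)
}

#' Proportion of intraspecific neighbors
#'
#' @param abundances Named vector of neighbor counts by species (focal
#'   already removed).
#' @param focal_species Species of the focal plant.
#' @return Fraction of neighbors conspecific with the focal; `NA` when the
#'   neighborhood is empty.
#' @export
propIntraspecific <- function(abundances, focal_species) {
  total <- sum(abundances)
  if (total < 1) return(NA_real_)
  cons <- abundances[names(abundances) == focal_species]
  sum(cons) / total
}

#' Rarefied species richness
#'
#' Expected number of species in a random subsample of `n` individuals from
#' the neighborhood: `E[S_n] = sum_i (1 - C(N - N_i, n) / C(N, n))`,
#' evaluated with log-space binomial coefficients for numerical safety at
#' large N. The default subsample size n = 9 reflects a design with at
#' least 10 plants per plot, minus the focal.
#'
#' @param abundances Vector of species counts (focal removed).
#' @param n Subsample size; must satisfy `1 <= n <= sum(abundances)`.
#' @return Expected species count (<= observed richness, and equal to it
#'   when `n == sum(abundances)`).
#' @export
rarefiedRichness <- function(abundances, n = 9) {
  abundances <- abundances[abundances > 0]
  N <- sum(abundances)
  if (n < 1) stop("rarefaction subsample size must be >= 1", call. = FALSE)
  if (N < n)
    stop("under-occupied neighborhood: total abundance ", N, " < n = ", n,
         call. = FALSE)
  p_absent <- exp(lchoose(N - abundances, n) - lchoose(N, n))
  sum(1 - p_absent)
}

# deterministic Prim MST; ties broken by (distance, lower vertex index).
# returns edge matrix (i, j, d) with S-1 rows
primMST <- function(d) {
  S <- attr(d, "Size")
  dm <- as.matrix(d)
  in_tree <- c(1L, rep(0L, S - 1L))
  edges <- matrix(0, S - 1L, 3L)
  for (e in seq_len(S - 1L)) {
    ins <- which(in_tree == 1L); outs <- which(in_tree == 0L)
    sub <- dm[ins, outs, drop = FALSE]
    best <- which(sub == min(sub), arr.ind = TRUE)
    best <- best[order(ins[best[, 1]], outs[best[, 2]]), , drop = FALSE][1, ]
    i <- ins[best[1]]; j <- outs[best[2]]
    edges[e, ] <- c(min(i, j), max(i, j), dm[i, j])
    in_tree[j] <- 1L
  }
  edges
}

#' Functional evenness (FEve)
#'
#' Regularity of species spacing and abundance along the minimum spanning
#' tree of trait space. For each MST edge l joining species i and j,
#' `EW_l = d(i, j) / (w_i + w_j)` with w the relative abundances;
#' `PEW_l = EW_l / sum(EW)`; and
#' `FEve = (sum_l min(PEW_l, 1/(S-1)) - 1/(S-1)) / (1 - 1/(S-1))`.
#' Bounded in \[0, 1\]; 1 when species are perfectly evenly spread.
#' Invariant to uniform rescaling of abundances. Requires at least three
#' species; returns `NA` otherwise.
#'
#' @param traits Numeric matrix (species x traits), already standardized.
#' @param abundances Species abundances aligned with `traits` rows.
#' @return FEve in \[0, 1\], or `NA` for fewer than 3 species.
#' @export
functionalEvenness <- function(traits, abundances) {
  traits <- as.matrix(traits)
  S <- nrow(traits)
  if (S < 3) return(NA_real_)
  if (sum(abundances) <= 0) stop("zero total abundance", call. = FALSE)
  w <- abundances / sum(abundances)
  edges <- primMST(stats::dist(traits))
  ew <- edges[, 3] / (w[edges[, 1]] + w[edges[, 2]])
  if (sum(ew) == 0) return(NA_real_)   # all species coincident in trait space
  pew <- ew / sum(ew)
  thr <- 1 / (S - 1)
  (sum(pmin(pew, thr)) - thr) / (1 - thr)
}

#' Functional dispersion (FDis)
#'
#' Abundance-weighted mean distance of species to the abundance-weighted
#' centroid of trait space:
#' `FDis = sum_i a_i z_i / sum_i a_i`, with `z_i` the Euclidean distance of
#' species i to the centroid. Zero for a single species; invariant to
#' translation of trait space and to uniform abundance rescaling.
#'
#' @inheritParams functionalEvenness
#' @return FDis >= 0.
#' @export
functionalDispersion <- function(traits, abundances) {
  traits <- as.matrix(traits)
  if (sum(abundances) <= 0) stop("zero total abundance", call. = FALSE)
  w <- abundances / sum(abundances)
  centroid <- colSums(traits * w)
  z <- sqrt(rowSums(sweep(traits, 2, centroid)^2))
  sum(w * z)
}

#' Functional range
#'
#' Product of per-trait ranges on the standardized trait scale. Computed
#' for reporting only: it is highly redundant with species richness and is
#' never entered into the model ladder.
#'
#' @inheritParams functionalEvenness
#' @return Range product, or `NA` for fewer than 2 species.
#' @export
functionalRange <- function(traits) {
  traits <- as.matrix(traits)
  if (nrow(traits) < 2) return(NA_real_)
  prod(apply(traits, 2, function(x) diff(range(x))))
}

#' Standardize species traits over the full species pool
#'
#' Functional diversity indices use Euclidean distances on z-standardized
#' traits; the standardization is computed once over all species in the
#' dataset (not per plot) so trait space is common across neighborhoods.
#'
#' @param species Species table with sla, wood_density, max_height.
#' @return Matrix of standardized traits (rownames = species); rows with
#'   any missing trait are kept as NA and dropped per neighborhood.
#' @export
standardizeTraits <- function(species) {
  tr <- as.matrix(species[, c("sla", "wood_density", "max_height")])
  rownames(tr) <- species$species
  mu <- colMeans(tr, na.rm = TRUE)
  s <- apply(tr, 2, stats::sd, na.rm = TRUE)
  sweep(sweep(tr, 2, mu), 2, s, "/")
}

#' Per-focal neighborhood metrics
#'
#' Computes, for every focal plant, the attributes of its plot neighborhood
#' (all plants in the plot, any genus, minus the focal itself): neighbor
#' density (plants/ha), proportion of intraspecific neighbors, rarefied
#' richness at `n_rarefy` individuals, functional evenness, functional
#' dispersion and functional range. Species with any missing trait are
#' dropped from the trait-based indices (abundances renormalized) and
#' counted per plot in the `dropped_species` attribute. Neighborhoods with
#' fewer than `n_rarefy` neighbors get `NA` rarefied richness (the focal is
#' later excluded from models requiring it); FEve needs at least three
#' trait-complete species and FRange two.
#'
#' Metrics are cached per (plot, focal species): every focal of the same
#' species in the same plot sees the identical neighborhood.
#'
#' @param dataset A `revegDataset`.
#' @param focals Focal table from [filterFocals()].
#' @param n_rarefy Rarefaction subsample size (default 9).
#' @return data.frame with one row per focal: plant, plot, species, genus,
#'   density, prop_intra, richness, feve, fdis, frange.
#' @export
neighborhoodMetrics <- function(dataset, focals, n_rarefy = 9) {
  plots <- dataset$plots
  plants <- dataset$plants[!duplicated(dataset$plants$plant), ]  # one row/plant
  traits <- standardizeTraits(dataset$species)
  complete <- rownames(traits)[stats::complete.cases(traits)]

  plot_ab <- lapply(split(plants$species, plants$plot), table)
  area_of <- stats::setNames(plots$area, plots$plot)

  key <- paste(focals$plot, focals$species)
  ukey <- !duplicated(key)
  cache <- new.env(parent = emptyenv())
  dropped <- list()

  one <- function(plot_id, sp) {
    ab <- plot_ab[[plot_id]]
    n_tot <- sum(ab)
    ab[sp] <- ab[sp] - 1L                       # remove the focal individual
    ab <- ab[ab > 0]
    av <- as.numeric(ab); names(av) <- names(ab)
    keep <- names(av) %in% complete
    if (any(!keep))
      dropped[[length(dropped) + 1L]] <<-
        data.frame(plot = plot_id, species = names(av)[!keep])
    tv <- traits[names(av)[keep], , drop = FALSE]
    aw <- av[keep]
    c(density = neighborDensity(n_tot, area_of[[plot_id]]),
      prop_intra = propIntraspecific(av, sp),
      richness = if (sum(av) >= n_rarefy) rarefiedRichness(av, n_rarefy)
                 else NA_real_,
      feve = if (nrow(tv) >= 3) functionalEvenness(tv, aw) else NA_real_,
      fdis = if (nrow(tv) >= 1 && sum(aw) > 0) functionalDispersion(tv, aw)
             else NA_real_,
      frange = functionalRange(tv))
  }
  for (i in which(ukey))
    assign(key[i], one(focals$plot[i], focals$species[i]), envir = cache)

  vals <- t(vapply(key, function(k) get(k, envir = cache), numeric(6)))
  out <- data.frame(plant = focals$plant, plot = focals$plot,
                    species = focals$species, genus = focals$genus,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(vals))
  rownames(out) <- NULL
  attr(out, "dropped_species") <-
    if (length(dropped)) unique(do.call(rbind, dropped))
    else data.frame(plot = character(0), species = character(0))
  out
}
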