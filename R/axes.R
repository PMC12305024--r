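# Species-mean aggregation and construction of ecological axes (EC1 "light
# environment", EC2 "flight-related wing morphology") and the visual-trait
# principal component.

#' Species means of individual-level variables
#'
#' Arithmetic mean per species per variable, missing values excluded
#' pairwise. Any log transforms must be applied to the individual records
#' before calling this (aggregation happens after transform).
#'
#' @param records data.frame of individual records with a `species` column.
#' @param variables Character vector of numeric columns to aggregate.
#' @return data.frame: one row per species, mean columns plus `n_<var>`
#'   counts of non-missing records per cell.
#' @export
species_means <- function(records, variables) {
  stopifnot("species" %in% names(records))
  missing_vars <- setdiff(variables, names(records))
  if (length(missing_vars)) {
    stop("variables not in records: ", paste(missing_vars, collapse = ", "))
  }
  sp <- sort(unique(as.character(records$species)))
  out <- data.frame(species = sp, stringsAsFactors = FALSE)
  for (v in variables) {
    x <- records[[v]]
    m <- tapply(x, records$species, function(z) mean(z, na.rm = TRUE))[sp]
    n <- tapply(x, records$species, function(z) sum(!is.na(z)))[sp]
    m[n == 0] <- NA_real_
    out[[v]] <- as.numeric(m)
    out[[paste0("n_", v)]] <- as.integer(n)
  }
  out
}

#' Principal component analysis of a species-by-variable table
#'
#' Correlation-matrix PCA (variables z-scored): eigendecomposition of the
#' correlation matrix, components sorted by eigenvalue, retained components
#' those with eigenvalue >= `cutoff`. Component signs are flipped so that
#' each orientation rule holds (by default no rule; for the ecological axes
#' use `orientation = c(canopy_openness = 1, flight_height = 2)` to make
#' canopy openness load positively on component 1 and flight height on
#' component 2).
#'
#' @param table data.frame or matrix of numeric variables; a `species`
#'   column, if present, becomes row names.
#' @param cutoff Eigenvalue retention cutoff (default 1).
#' @param orientation Named integer vector: variable name -> component index
#'   whose loading for that variable must be >= 0.
#' @return Object of class `"eco_pca"`: `loadings` (variable x component),
#'   `scores` (observation x component), `eigenvalues`, `explained_pct`,
#'   `retained`, `dropped_rows`.
#' @export
pca_axes <- function(table, cutoff = 1, orientation = NULL) {
  tab <- as.data.frame(table)
  rn <- NULL
  if ("species" %in% names(tab)) {
    rn <- as.character(tab$species)
    tab <- tab[setdiff(names(tab), "species")]
  }
  tab <- tab[vapply(tab, is.numeric, logical(1))]
  if (ncol(tab) < 2L) stop("need >= 2 numeric variables")
  x <- as.matrix(tab)
  if (!is.null(rn)) rownames(x) <- rn
  complete <- stats::complete.cases(x)
  dropped <- rownames(x)[!complete]
  if (length(dropped)) {
    warning("dropping rows with missing cells: ", paste(dropped, collapse = ", "))
    x <- x[complete, , drop = FALSE]
  }
  if (nrow(x) < 3L) stop("need >= 3 complete rows")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant variable(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  }
  z <- scale(x)
  eg <- eigen(stats::cor(x), symmetric = TRUE)
  ev <- eg$values
  load <- eg$vectors
  dimnames(load) <- list(colnames(x), paste0("PC", seq_along(ev)))
  scores <- z %*% load
  if (!is.null(orientation)) {
    for (v in names(orientation)) {
      k <- orientation[[v]]
      if (!v %in% rownames(load)) stop("orientation variable not found: ", v)
      if (load[v, k] < 0) {
        load[, k] <- -load[, k]
        scores[, k] <- -scores[, k]
      }
    }
  }
  structure(list(loadings = load, scores = scores, eigenvalues = ev,
                 explained_pct = 100 * ev / sum(ev),
                 retained = which(ev >= cutoff),
                 dropped_rows = dropped),
            class = "eco_pca")
}

#' @export
print.eco_pca <- function(x, ...) {
  cat("<eco_pca> explained %:",
      paste(sprintf("%.2f", x$explained_pct), collapse = ", "), "\n")
  cat("retained components (eigenvalue >= cutoff):",
      paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}

#' Ecological-axes PCA
#'
#' The species-mean PCA behind the two ecological axes: spectral channel
#' catches, flight height, canopy openness and the three wing variables,
#' oriented so canopy openness loads positively on EC1 and flight height on
#' EC2.
#'
#' @param species_table Species-by-variable table (see [species_means()]).
#' @param variables Columns to include; defaults to the standard eight.
#' @param cutoff Eigenvalue cutoff.
#' @return `"eco_pca"` with components named EC1, EC2, ...
#' @export
ecological_axes <- function(species_table,
                            variables = c("q_uv", "q_b", "q_lw",
                                          "flight_height_m",
                                          "canopy_openness_pct",
                                          "wing_area_mm2", "aspect_ratio",
                                          "wing_loading_g_per_mm2"),
                            cutoff = 1) {
  tab <- species_table[c("species", intersect(variables, names(species_table)))]
  orientation <- c(canopy_openness_pct = 1, flight_height_m = 2)
  orientation <- orientation[names(orientation) %in% names(tab)]
  res <- pca_axes(tab, cutoff = cutoff, orientation = orientation)
  colnames(res$loadings) <- sub("^PC", "EC", colnames(res$loadings))
  colnames(res$scores) <- sub("^PC", "EC", colnames(res$scores))
  res
}

#' Visual-trait PCA
#'
#' Summarizes visual-pathway traits (red-facet proportion, eye surface area,
#' facet number and diameter, optic-lobe neuropil volumes, plus the
#' rest-of-central-brain allometric control) along principal components;
#' anatomical traits are expected log10-transformed upstream. Component 1 is
#' reported with per-trait loadings so the allometric-control loading can be
#' inspected.
#'
#' @param species_table Species-by-trait table.
#' @param traits Trait columns; default all numeric columns.
#' @param cutoff Eigenvalue cutoff.
#' @param orientation Optional orientation rule as in [pca_axes()].
#' @return `"eco_pca"`.
#' @export
visual_trait_pca <- function(species_table, traits = NULL, cutoff = 1,
                             orientation = NULL) {
  tab <- as.data.frame(species_table)
  if (is.null(traits)) {
    traits <- setdiff(names(tab)[vapply(tab, is.numeric, logical(1))],
                      "species")
  }
  pca_axes(tab[c(intersect("species", names(tab)), traits)],
           cutoff = cutoff, orientation = orientation)
}
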