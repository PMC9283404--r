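# Spatial autocorrelation QC: Mantel correlogram of daily detection
# profiles against between-camera distance.  The correlogram itself is
# computed by vegan::mantel.correlog; this module builds the community
# matrix and the distance matrices around it.

#' Mantel correlogram of per-site daily detection profiles
#'
#' Builds a sites x (species x day) count matrix from independence-filtered
#' detection records, computes an ecological dissimilarity between sites
#' (Bray-Curtis by default) and a great-circle geographic distance, and runs
#' a permutation Mantel correlogram (distance classes by Sturges' rule,
#' progressive Holm correction).
#'
#' @param records detection data.frame, already passed through
#'   [filter_independent()].
#' @param sites site table with coordinates.
#' @param n_perm permutations per distance class (default 10000).
#' @param n_classes optional number of distance classes (Sturges when
#'   `NULL`).
#' @param dissimilarity `"bray_curtis"` (default) or `"euclidean"`.
#' @param seed optional integer seed.
#' @param species optional subset of species to stack (default: all).
#' @return object of class `mantel_correlogram_result`: list with `classes`
#'   (data.frame `class_index, n_dist, mantel_r, p, p_corrected`), `n_perm`,
#'   `degenerate`, and the underlying vegan object as `vegan_fit`.
#' @export
mantel_correlogram <- function(records, sites, n_perm = 10000, n_classes = NULL,
                               dissimilarity = c("bray_curtis", "euclidean"),
                               seed = NULL, species = NULL) {
  dissimilarity <- match.arg(dissimilarity)
  usite <- unique(sites[, c("site_id", "latitude", "longitude")])
  if (anyNA(usite$latitude) || anyNA(usite$longitude))
    stopf("site coordinates are missing")
  if (nrow(usite) < 4) stopf("at least 4 sites are needed for a correlogram")
  species <- species %||% sort(unique(records$species))
  day <- as.Date(records$timestamp)
  col <- paste(records$species, day, sep = "|")
  comm <- table(factor(records$site_id, levels = usite$site_id),
                factor(col, levels = sort(unique(col))))
  comm <- matrix(as.numeric(comm), nrow = nrow(usite),
                 dimnames = dimnames(comm))
  if (sum(comm) == 0) stopf("degenerate: all-zero community matrix")
  d_eco <- if (dissimilarity == "bray_curtis")
    vegan::vegdist(comm, method = "bray") else stats::dist(comm)
  if (!all(is.finite(d_eco)) || stats::sd(d_eco) == 0) {
    return(structure(list(classes = NULL, n_perm = n_perm, degenerate = TRUE,
                          vegan_fit = NULL), class = "mantel_correlogram_result"))
  }
  d_geo <- stats::as.dist(geosphere::distm(
    cbind(usite$longitude, usite$latitude)) / 1000)
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::mantel.correlog(d_eco, D.geo = d_geo,
                                n.class = n_classes %||% 0,
                                nperm = n_perm, mult = "holm",
                                progressive = TRUE)
  m <- as.data.frame(fit$mantel.res)
  names(m) <- c("class_index", "n_dist", "mantel_r", "p", "p_corrected")
  structure(list(classes = m, n_perm = n_perm, degenerate = FALSE,
                 vegan_fit = fit), class = "mantel_correlogram_result")
}

#' @export
print.mantel_correlogram_result <- function(x, ...) {
  if (x$degenerate) {
    cat("Mantel correlogram: degenerate (zero ecological variance)\n")
  } else {
    cat(sprintf("Mantel correlogram (%d permutations per class):\n", x$n_perm))
    print(round(x$classes, 4))
  }
  invisible(x)
}
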