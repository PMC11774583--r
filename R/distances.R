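#' Great-circle distance between coordinate pairs (haversine)
#'
#' Vectorised great-circle distance on a spherical Earth, the standard choice
#' for distances between sampling sites. Uses the haversine formula with a
#' mean Earth radius of 6371 km by default; the radius only rescales all
#' distances by a common factor and therefore leaves Mantel correlations
#' unchanged.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees. Latitudes must
#'   lie in \[-90, 90\] and longitudes in \[-180, 180\].
#' @param radius_km Sphere radius in kilometres (default 6371.0).
#' @return Distance(s) in kilometres.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2, radius_km = 6371.0) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE)) {
    stop("latitude out of range [-90, 90]", call. = FALSE)
  }
  if (any(abs(c(lon1, lon2)) > 180, na.rm = TRUE)) {
    stop("longitude out of range [-180, 180]", call. = FALSE)
  }
  as.numeric(geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                                      r = radius_km))
}

#' Pairwise great-circle distances among sampling sites
#'
#' @param sites Data frame with columns \code{site_id}, \code{latitude},
#'   \code{longitude}; \code{site_id} must be unique.
#' @param radius_km Sphere radius in kilometres.
#' @return Labeled symmetric matrix of distances in km, with exact zeros on
#'   the diagonal.
#' @export
geo_site_distances <- function(sites, radius_km = 6371.0) {
  stopifnot(all(c("site_id", "latitude", "longitude") %in% names(sites)))
  if (anyDuplicated(sites$site_id)) {
    stop("duplicate site_id in site table", call. = FALSE)
  }
  n <- nrow(sites)
  m <- matrix(0, n, n, dimnames = list(sites$site_id, sites$site_id))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      j <- (i + 1):n
      d <- haversine_km(sites$latitude[i], sites$longitude[i],
                        sites$latitude[j], sites$longitude[j],
                        radius_km = radius_km)
      m[i, j] <- d
      m[j, i] <- d
    }
  }
  assert_distance_matrix(m, "geographic site matrix")
  m
}

#' Patristic distances among host taxa
#'
#' @param host_tree Host phylogeny (\code{phylo}) whose tips are host taxon
#'   identifiers.
#' @return Labeled symmetric matrix of host tip-to-tip distances.
#' @export
host_taxon_distances <- function(host_tree) {
  patristic_distances(host_tree)
}

#' Expand host-taxon and site distances to the bacterial-tip level
#'
#' Builds the two reference matrices every clade is tested against: for
#' bacterial tips i and j, the host-phylogenetic reference is the patristic
#' distance between their host taxa (exactly 0 for conspecific hosts) and the
#' geographic reference is the great-circle distance between their sampling
#' sites (exactly 0 for tips from the same site — sites are the unit of
#' geography).
#'
#' @param metadata Tip metadata (see [validate_dataset()]).
#' @param host_D Distance matrix over host taxa, e.g. from
#'   [host_taxon_distances()].
#' @param sites Site table with coordinates.
#' @param radius_km Sphere radius passed to [geo_site_distances()].
#' @return An object of class \code{reference_matrices}: a list with labeled
#'   matrices \code{host_phylo} and \code{geo} over \code{metadata$tip_id},
#'   sharing one label ordering.
#' @export
expand_to_tips <- function(metadata, host_D, sites, radius_km = 6371.0) {
  if (anyDuplicated(metadata$tip_id)) {
    stop("duplicate tip_id in metadata", call. = FALSE)
  }
  unknown_taxa <- setdiff(metadata$host_taxon_id, rownames(host_D))
  if (length(unknown_taxa)) {
    stop("host taxa missing from host distance matrix: ",
         paste(unknown_taxa, collapse = ", "), call. = FALSE)
  }
  unknown_sites <- setdiff(metadata$site_id, sites$site_id)
  if (length(unknown_sites)) {
    stop("sites missing from site table: ",
         paste(unknown_sites, collapse = ", "), call. = FALSE)
  }
  labs <- metadata$tip_id
  hidx <- match(metadata$host_taxon_id, rownames(host_D))
  host_phylo <- host_D[hidx, hidx, drop = FALSE]
  dimnames(host_phylo) <- list(labs, labs)

  site_D <- geo_site_distances(sites, radius_km = radius_km)
  sidx <- match(metadata$site_id, rownames(site_D))
  geo <- site_D[sidx, sidx, drop = FALSE]
  dimnames(geo) <- list(labs, labs)

  assert_distance_matrix(host_phylo, "host-phylogenetic reference")
  assert_distance_matrix(geo, "geographic reference")
  structure(list(host_phylo = host_phylo, geo = geo),
            class = "reference_matrices")
}

#' @export
print.reference_matrices <- function(x, ...) {
  cat("Reference matrices over", nrow(x$host_phylo), "bacterial tips\n")
  cat("  host_phylo: max", format(max(x$host_phylo), digits = 4), "\n")
  cat("  geo (km):   max", format(max(x$geo), digits = 6), "\n")
  invisible(x)
}
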