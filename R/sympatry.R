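#' Find scanned clades containing sympatric strains from both host genera
#'
#' Selects clades from a scan (optionally filtered by classification) that
#' contain at least one pair of tips sampled at the same site from hosts of
#' different genera — the configuration (e.g. \emph{Pan} and \emph{Gorilla}
#' at one field site) in which partner fidelity and geography make opposite
#' predictions.
#'
#' @param scan A \code{codiv_scan} object.
#' @param metadata Tip metadata (see [validate_dataset()]).
#' @param classification Optional character vector of classification labels
#'   (or the shorthands \code{"phylo"} / \code{"geo"}, meaning any clade
#'   significant for that reference); \code{NULL} keeps all tested clades.
#' @return Character vector of node_ids.
#' @export
find_heterogeneric_sympatric_clades <- function(scan, metadata,
                                                classification = NULL) {
  stopifnot(inherits(scan, "codiv_scan"))
  res <- scan$results
  keep <- rep(TRUE, nrow(res))
  if (!is.null(classification)) {
    if (identical(classification, "phylo")) {
      keep <- res$sig_phylo
    } else if (identical(classification, "geo")) {
      keep <- res$sig_geo
    } else {
      keep <- res$classification %in% classification
    }
  }
  meta_idx <- stats::setNames(seq_len(nrow(metadata)), metadata$tip_id)
  has_pair <- vapply(scan$clades, function(cl) {
    md <- metadata[meta_idx[cl$tips], ]
    any(vapply(split(md$host_genus, md$site_id),
               function(g) length(unique(g)) > 1, logical(1)))
  }, logical(1))
  res$node_id[keep & has_pair]
}

#' Host-fidelity test for a clade with sympatric heterogeneric strains
#'
#' For each strain (MAG) in the clade whose site hosts both genera, compares
#' its minimum patristic distance to a congeneric strain from a
#' \emph{different} site (allopatric conspecific-lineage comparator, A) with
#' its minimum distance to a heterogeneric strain from the \emph{same} site
#' (sympatric comparator, B). The strain is host-faithful when A < B; ties
#' count as not faithful and are flagged. The clade verdict is
#' \code{host_faithful} when every evaluated strain is faithful,
#' \code{geography_faithful} when none is, \code{mixed} otherwise, and
#' \code{not_applicable} when no strain has both comparator sets non-empty.
#'
#' @param clade_D Patristic distance matrix restricted to the clade's tips.
#' @param metadata Tip metadata covering those tips.
#' @param use_mean Use mean instead of minimum comparator distance.
#' @param majority Use majority rule instead of unanimity for the clade
#'   verdict (\code{host_faithful} when more than half the evaluated strains
#'   are faithful).
#' @return An object of class \code{sympatry_verdict}: list with
#'   \code{verdict}, \code{sympatric_sites}, \code{n_mags_evaluated},
#'   \code{per_mag} (data frame: tip_id, dist_allopatric_congeneric,
#'   dist_sympatric_heterogeneric, faithful, tie).
#' @export
sympatry_fidelity_test <- function(clade_D, metadata, use_mean = FALSE,
                                   majority = FALSE) {
  labs <- rownames(clade_D)
  md <- metadata[match(labs, metadata$tip_id), ]
  if (anyNA(md$tip_id)) {
    stop("metadata does not cover all clade tips", call. = FALSE)
  }
  by_site <- split(md$host_genus, md$site_id)
  symp_sites <- names(by_site)[vapply(by_site,
                                      function(g) length(unique(g)) > 1,
                                      logical(1))]
  agg <- if (use_mean) mean else min
  recs <- list()
  for (i in seq_along(labs)) {
    if (!md$site_id[i] %in% symp_sites) next
    allo_cong <- labs[md$host_genus == md$host_genus[i] &
                        md$site_id != md$site_id[i]]
    symp_het <- labs[md$host_genus != md$host_genus[i] &
                       md$site_id == md$site_id[i]]
    if (!length(allo_cong) || !length(symp_het)) next
    a <- agg(clade_D[labs[i], allo_cong])
    b <- agg(clade_D[labs[i], symp_het])
    recs[[length(recs) + 1L]] <- data.frame(
      tip_id = labs[i],
      dist_allopatric_congeneric = a,
      dist_sympatric_heterogeneric = b,
      faithful = a < b,
      tie = a == b,
      stringsAsFactors = FALSE
    )
  }
  per_mag <- if (length(recs)) {
    do.call(rbind, recs)
  } else {
    data.frame(tip_id = character(0),
               dist_allopatric_congeneric = numeric(0),
               dist_sympatric_heterogeneric = numeric(0),
               faithful = logical(0), tie = logical(0),
               stringsAsFactors = FALSE)
  }
  verdict <- if (nrow(per_mag) == 0) {
    "not_applicable"
  } else if (majority) {
    if (mean(per_mag$faithful) > 0.5) "host_faithful" else "geography_faithful"
  } else if (all(per_mag$faithful)) {
    "host_faithful"
  } else if (!any(per_mag$faithful)) {
    "geography_faithful"
  } else {
    "mixed"
  }
  structure(list(
    verdict = verdict,
    sympatric_sites = symp_sites,
    n_mags_evaluated = nrow(per_mag),
    per_mag = per_mag
  ), class = "sympatry_verdict")
}

#' @export
print.sympatry_verdict <- function(x, ...) {
  cat("Sympatry fidelity verdict:", x$verdict,
      "(", x$n_mags_evaluated, "strains evaluated at",
      length(x$sympatric_sites), "sympatric site(s) )\n")
  invisible(x)
}

#' Run the sympatry fidelity test across the clades of a scan
#'
#' @param scan A \code{codiv_scan} object.
#' @param tree The strain phylogeny the scan was run on.
#' @param metadata Tip metadata.
#' @param classification Passed to [find_heterogeneric_sympatric_clades()];
#'   default \code{"phylo"} (clades significantly associated with host
#'   phylogeny, the co-diversified set).
#' @param use_mean,majority Passed to [sympatry_fidelity_test()].
#' @return Data frame, one row per evaluated clade: node_id, verdict,
#'   n_mags_evaluated, n_faithful, n_sympatric_sites.
#' @export
sympatry_scan <- function(scan, tree, metadata, classification = "phylo",
                          use_mean = FALSE, majority = FALSE) {
  ids <- find_heterogeneric_sympatric_clades(scan, metadata, classification)
  D <- patristic_distances(tree)
  rows <- lapply(ids, function(id) {
    cl <- scan$clades[[match(id, vapply(scan$clades, `[[`, "", "node_id"))]]
    v <- sympatry_fidelity_test(D[cl$tips, cl$tips, drop = FALSE], metadata,
                                use_mean = use_mean, majority = majority)
    data.frame(node_id = id, verdict = v$verdict,
               n_mags_evaluated = v$n_mags_evaluated,
               n_faithful = sum(v$per_mag$faithful),
               n_sympatric_sites = length(v$sympatric_sites),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    node_id = character(0), verdict = character(0),
    n_mags_evaluated = integer(0), n_faithful = integer(0),
    n_sympatric_sites = integer(0), stringsAsFactors = FALSE)
  out
}
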