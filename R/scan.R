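#' Control parameters for the co-diversification scan
#'
#' @param max_diameter_fraction Clades qualify when their maximum within-clade
#'   tip-to-tip distance is at most this fraction of the tree-wide maximum
#'   tip-to-tip distance ("distal tenth"; inclusive comparison). Default 0.1.
#' @param n_permutations Permutations per Mantel test. Default 1000.
#' @param r_threshold Mantel r threshold for calling a clade significantly
#'   associated with a reference. Default 0.7.
#' @param delta_threshold Threshold on \code{r_phylo - r_geo} (delta) for the
#'   "independent of the other reference" calls. Default 0.5.
#' @param alpha Significance level applied to BH-corrected p-values.
#'   Default 0.05.
#' @param min_tips Minimum clade size tested; the default 6 guarantees at
#'   least 720 distinct permutations, keeping the permutation null
#'   non-degenerate at 1000 draws.
#' @param min_distinct_reference_values Minimum number of distinct host taxa
#'   (resp. sites) a clade must span for the corresponding test; clades below
#'   it are flagged untestable for that reference. Default 2.
#' @param include_stem Whether a clade's branch length includes the edge
#'   subtending its root node (part of the diversification history unique to
#'   the clade). Default \code{TRUE}.
#' @param seed Master RNG seed. Per-node permutation streams are derived from
#'   it by stable hashing of the node identifier, so results do not depend on
#'   node iteration order.
#' @return A list of class \code{scan_control}.
#' @export
scan_control <- function(max_diameter_fraction = 0.1,
                         n_permutations = 1000,
                         r_threshold = 0.7,
                         delta_threshold = 0.5,
                         alpha = 0.05,
                         min_tips = 6,
                         min_distinct_reference_values = 2,
                         include_stem = TRUE,
                         seed = 1L) {
  stopifnot(max_diameter_fraction > 0, max_diameter_fraction <= 1,
            n_permutations >= 1, min_tips >= 4,
            min_distinct_reference_values >= 2,
            alpha > 0, alpha < 1)
  structure(list(
    max_diameter_fraction = max_diameter_fraction,
    n_permutations = as.integer(n_permutations),
    r_threshold = r_threshold,
    delta_threshold = delta_threshold,
    alpha = alpha,
    min_tips = as.integer(min_tips),
    min_distinct_reference_values = as.integer(min_distinct_reference_values),
    include_stem = isTRUE(include_stem),
    seed = as.integer(seed)
  ), class = "scan_control")
}

#' Enumerate testable clades in the distal part of a phylogeny
#'
#' Returns every internal node whose clade diameter (maximum within-clade
#' tip-to-tip patristic distance) is at most
#' \code{max_diameter_fraction} times the tree-wide maximum tip-to-tip
#' distance and which contains at least \code{min_tips} tips. The comparison
#' is inclusive (a diameter of exactly the threshold qualifies) and nested
#' qualifying nodes are all returned.
#'
#' @param tree Strain phylogeny (\code{phylo} with branch lengths).
#' @param control A [scan_control()] list.
#' @return A list of clade specifications, each a list with \code{node} (ape
#'   node number), \code{node_id} (stable hash of the sorted tip set),
#'   \code{tips}, \code{n_tips}, \code{diameter} and
#'   \code{clade_branch_length}; the tree-wide diameter is attached as
#'   attribute \code{tree_diameter}.
#' @export
enumerate_testable_nodes <- function(tree, control = scan_control()) {
  info <- clade_table(tree)
  thresh <- control$max_diameter_fraction * info$tree_diameter
  internal <- (info$ntip + 1L):(info$ntip + tree$Nnode)
  keep <- internal[info$n_tips[internal] >= control$min_tips &
                     info$diameter[internal] <= thresh + 1e-12]
  out <- lapply(keep, function(v) {
    stem <- if (control$include_stem && !is.na(info$stem_length[v])) {
      info$stem_length[v]
    } else 0
    # tips sorted canonically so per-node permutation streams (and thus the
    # whole report) are invariant to input tip ordering
    list(
      node = v,
      node_id = clade_node_id(info$tipsets[[v]]),
      tips = sort(info$tipsets[[v]]),
      n_tips = info$n_tips[v],
      diameter = info$diameter[v],
      clade_branch_length = info$subtree_branch_length[v] + stem
    )
  })
  attr(out, "tree_diameter") <- info$tree_diameter
  out
}

#' Scan a strain phylogeny for clades diversifying with host phylogeny or
#' geography
#'
#' The central analysis: every internal node in the distal part of the strain
#' phylogeny (see [enumerate_testable_nodes()]) is tested, by Mantel
#' permutation test, for association between its within-clade patristic
#' distances and (a) host phylogenetic distances and (b) geographic
#' distances between sampling sites. Permutation p-values are
#' Benjamini-Hochberg corrected across all tested nodes, separately for the
#' host-phylogeny family and the geography family, and each clade is
#' classified from the two corrected tests and the statistic
#' \code{delta = r_phylo - r_geo} (see [classify_clades()]).
#'
#' Clades spanning fewer than \code{min_distinct_reference_values} distinct
#' host taxa (resp. sites), or whose reference distances are constant, are
#' flagged untestable for that reference; they are excluded from that BH
#' family but the other test still runs.
#'
#' @param tree Strain phylogeny (\code{phylo}).
#' @param metadata Tip metadata (see [validate_dataset()]).
#' @param sites Site table with coordinates.
#' @param host_tree Host phylogeny whose tips are host taxon identifiers.
#' @param control A [scan_control()] list.
#' @param refs Optionally, precomputed [expand_to_tips()] reference matrices.
#' @return An object of class \code{codiv_scan}: a list with \code{results}
#'   (one row per tested node), \code{clades} (the enumerated clade specs),
#'   \code{counts} (classification counts), \code{branch_fractions}
#'   (branch-length fraction of the tree covered by each significance class),
#'   \code{control}, and bookkeeping fields.
#' @export
codiv_scan <- function(tree, metadata, sites, host_tree,
                       control = scan_control(), refs = NULL) {
  val <- validate_dataset(tree, metadata, sites, host_tree)
  if (!val$valid) {
    stop("dataset failed validation; see validate_dataset()", call. = FALSE)
  }
  if (is.null(refs)) {
    refs <- expand_to_tips(metadata, host_taxon_distances(host_tree), sites)
  }
  stopifnot(inherits(refs, "reference_matrices"))
  if (!setequal(rownames(refs$host_phylo), tree$tip.label)) {
    stop("reference matrices do not cover the tree's tips", call. = FALSE)
  }

  clades <- enumerate_testable_nodes(tree, control)
  tree_diameter <- attr(clades, "tree_diameter")
  D <- patristic_distances(tree)
  meta_idx <- stats::setNames(seq_len(nrow(metadata)), metadata$tip_id)

  rows <- lapply(clades, function(cl) {
    tips <- cl$tips
    md <- metadata[meta_idx[tips], ]
    sub_D <- D[tips, tips, drop = FALSE]
    n_host <- length(unique(md$host_taxon_id))
    n_site <- length(unique(md$site_id))

    run_side <- function(ref, n_distinct, tag) {
      if (n_distinct < control$min_distinct_reference_values) {
        return(list(r = NA_real_, p = NA_real_, untestable = TRUE))
      }
      seed <- hash_fold(control$seed, cl$node_id, tag)
      mantel_permutation_test(sub_D, ref[tips, tips, drop = FALSE],
                              n_permutations = control$n_permutations,
                              seed = seed)
    }
    ph <- run_side(refs$host_phylo, n_host, "phylo")
    ge <- run_side(refs$geo, n_site, "geo")
    data.frame(
      node_id = cl$node_id,
      n_tips = cl$n_tips,
      n_host_taxa = n_host,
      n_sites = n_site,
      diameter = cl$diameter,
      clade_branch_length = cl$clade_branch_length,
      r_phylo = ph$r, p_phylo = ph$p,
      r_geo = ge$r, p_geo = ge$p,
      untestable_phylo = ph$untestable,
      untestable_geo = ge$untestable,
      stringsAsFactors = FALSE
    )
  })
  results <- do.call(rbind, rows)
  if (is.null(results)) {
    results <- data.frame(
      node_id = character(0), n_tips = integer(0), n_host_taxa = integer(0),
      n_sites = integer(0), diameter = numeric(0),
      clade_branch_length = numeric(0),
      r_phylo = numeric(0), p_phylo = numeric(0),
      r_geo = numeric(0), p_geo = numeric(0),
      untestable_phylo = logical(0), untestable_geo = logical(0),
      stringsAsFactors = FALSE
    )
  }
  # BH correction within each test family, across tested nodes only
  results$q_phylo <- NA_real_
  results$q_geo <- NA_real_
  ok_p <- !results$untestable_phylo
  ok_g <- !results$untestable_geo
  results$q_phylo[ok_p] <- adjust_bh(results$p_phylo[ok_p])
  results$q_geo[ok_g] <- adjust_bh(results$p_geo[ok_g])
  results$delta <- results$r_phylo - results$r_geo
  results <- classify_clades(results, control)
  # stable output order, independent of tree traversal order
  ord <- order(results$node_id)
  results <- results[ord, , drop = FALSE]
  rownames(results) <- NULL
  clades <- clades[ord]

  counts <- table(factor(results$classification, levels = classification_levels()))
  fractions <- vapply(
    list(phylo = results$sig_phylo,
         geo = results$sig_geo,
         phylo_independent_of_geo =
           results$classification == "phylo_independent_of_geo",
         geo_independent_of_phylo =
           results$classification == "geo_independent_of_phylo"),
    function(sel) {
      significant_branch_fraction(tree, clades[which(sel)],
                                  include_stem = control$include_stem)
    },
    numeric(1)
  )

  structure(list(
    results = results,
    clades = clades,
    counts = counts,
    branch_fractions = fractions,
    control = control,
    tree_diameter = tree_diameter,
    total_branch_length = total_branch_length(tree),
    n_tips = length(tree$tip.label)
  ), class = "codiv_scan")
}

classification_levels <- function() {
  c("phylo_independent_of_geo", "geo_independent_of_phylo", "both",
    "phylo_associated", "geo_associated", "none",
    "untestable_phylo", "untestable_geo")
}

#' Classify scanned clades from their two Mantel tests
#'
#' A clade is significantly associated with a reference when its Mantel r
#' exceeds \code{r_threshold} and its BH-corrected p-value is below
#' \code{alpha}. Clades significant for host phylogeny whose
#' \code{delta = r_phylo - r_geo} exceeds \code{delta_threshold} while the
#' geography test is non-significant are classified
#' \code{phylo_independent_of_geo}; the geography-independent class mirrors
#' this. Clades significant for both references with |delta| at or below the
#' threshold are \code{both}. A clade untestable on one side keeps the other
#' side's call; a clade untestable on a side and otherwise non-significant is
#' labeled by the untestable side.
#'
#' @param results Data frame with columns \code{r_phylo}, \code{q_phylo},
#'   \code{r_geo}, \code{q_geo}, \code{untestable_phylo},
#'   \code{untestable_geo} (as produced inside [codiv_scan()]).
#' @param control A [scan_control()] list.
#' @return \code{results} with logical columns \code{sig_phylo},
#'   \code{sig_geo} and a \code{classification} factor column added.
#' @export
classify_clades <- function(results, control = scan_control()) {
  rthr <- control$r_threshold
  dthr <- control$delta_threshold
  alpha <- control$alpha
  sigP <- !results$untestable_phylo &
    !is.na(results$r_phylo) & !is.na(results$q_phylo) &
    results$r_phylo > rthr & results$q_phylo < alpha
  sigG <- !results$untestable_geo &
    !is.na(results$r_geo) & !is.na(results$q_geo) &
    results$r_geo > rthr & results$q_geo < alpha
  delta <- results$r_phylo - results$r_geo
  cls <- rep("none", nrow(results))
  indP <- sigP & !is.na(delta) & delta > dthr &
    !results$untestable_geo & results$q_geo > alpha
  indG <- sigG & !is.na(delta) & delta < -dthr &
    !results$untestable_phylo & results$q_phylo > alpha
  cls[sigP] <- "phylo_associated"
  cls[sigG] <- "geo_associated"
  cls[sigP & sigG] <- "both"
  cls[indP] <- "phylo_independent_of_geo"
  cls[indG] <- "geo_independent_of_phylo"
  plain_none <- cls == "none"
  cls[plain_none & results$untestable_phylo] <- "untestable_phylo"
  cls[plain_none & !results$untestable_phylo & results$untestable_geo] <-
    "untestable_geo"
  results$sig_phylo <- sigP
  results$sig_geo <- sigG
  results$classification <- factor(cls, levels = classification_levels())
  results
}

#' Branch-length fraction covered by a set of clades
#'
#' Fraction of the tree's total branch length lying within any of the listed
#' clades, counting each edge once even when clades are nested or overlap.
#' By convention the edge subtending each clade's root node is part of the
#' clade (\code{include_stem = TRUE}); this can be switched off.
#'
#' @param tree Strain phylogeny (\code{phylo}).
#' @param clades List of clade specifications as returned by
#'   [enumerate_testable_nodes()] (elements need a \code{node} or \code{tips}
#'   entry), or a vector of internal node numbers.
#' @param include_stem Count the subtending edge of each clade root.
#' @return A fraction in \[0, 1\]; 0 for an empty clade list.
#' @export
significant_branch_fraction <- function(tree, clades, include_stem = TRUE) {
  if (length(clades) == 0) return(0)
  if (is.numeric(clades)) clades <- lapply(clades, function(v) list(node = v))
  ntip <- length(tree$tip.label)
  nodes <- vapply(clades, function(cl) {
    if (!is.null(cl$node)) {
      as.integer(cl$node)
    } else {
      as.integer(ape::getMRCA(tree, cl$tips))
    }
  }, integer(1))
  in_union <- logical(nrow(tree$edge))
  # mark all edges of each clade's subtree
  for (v in nodes) {
    stack <- v
    while (length(stack)) {
      cur <- stack[[1]]
      stack <- stack[-1]
      kids_idx <- which(tree$edge[, 1] == cur)
      in_union[kids_idx] <- TRUE
      stack <- c(stack, tree$edge[kids_idx, 2][tree$edge[kids_idx, 2] > ntip])
    }
    if (include_stem) {
      stem_idx <- which(tree$edge[, 2] == v)
      in_union[stem_idx] <- TRUE
    }
  }
  sum(tree$edge.length[in_union]) / sum(tree$edge.length)
}

#' @export
print.codiv_scan <- function(x, ...) {
  cat("Co-diversification scan\n")
  cat("  tips:", x$n_tips,
      " tested nodes:", nrow(x$results),
      " permutations:", x$control$n_permutations,
      " seed:", x$control$seed, "\n")
  cat("  tree max tip-to-tip distance:",
      format(x$tree_diameter, digits = 6), "\n")
  cat("  classification counts:\n")
  print(x$counts)
  cat("  branch-length fractions:\n")
  print(round(x$branch_fractions, 4))
  invisible(x)
}

#' @export
summary.codiv_scan <- function(object, ...) {
  res <- object$results
  out <- list(
    n_nodes = nrow(res),
    counts = object$counts,
    branch_fractions = object$branch_fractions,
    n_sig_phylo = sum(res$sig_phylo),
    n_sig_geo = sum(res$sig_geo),
    mean_delta = mean(res$delta, na.rm = TRUE),
    control = object$control
  )
  class(out) <- "summary.codiv_scan"
  out
}

#' @export
print.summary.codiv_scan <- function(x, ...) {
  cat("Co-diversification scan:", x$n_nodes, "tested nodes\n")
  cat("  significant vs host phylogeny (r >",
      x$control$r_threshold, ", q <", x$control$alpha, "):",
      x$n_sig_phylo, "\n")
  cat("  significant vs geography:", x$n_sig_geo, "\n")
  cat("  mean delta (r_phylo - r_geo):", format(x$mean_delta, digits = 4), "\n")
  print(x$counts)
  cat("  branch-length fractions:\n")
  print(round(x$branch_fractions, 4))
  invisible(x)
}
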