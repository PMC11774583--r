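#' Read a dataset directory written by [write_dataset()] or prepared by hand
#'
#' @param dir Directory containing \code{strains.nwk}, \code{tips.tsv},
#'   \code{sites.tsv}, \code{host.nwk}.
#' @return A \code{codiv_dataset}-like list (without truth unless
#'   \code{truth.tsv} is present).
#' @export
read_dataset <- function(dir) {
  need <- c("strains.nwk", "tips.tsv", "sites.tsv", "host.nwk")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    stop("dataset directory ", dir, " lacks: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- list(
    tree = read_newick(file.path(dir, "strains.nwk")),
    metadata = read_tsv(file.path(dir, "tips.tsv")),
    sites = read_tsv(file.path(dir, "sites.tsv")),
    host_tree = read_newick(file.path(dir, "host.nwk"))
  )
  truth_path <- file.path(dir, "truth.tsv")
  if (file.exists(truth_path)) out$truth <- read_tsv(truth_path)
  class(out) <- "codiv_dataset"
  out
}

scan_results_df <- function(scan) {
  res <- scan$results
  res$classification <- as.character(res$classification)
  res
}

scan_summary_df <- function(scan) {
  data.frame(
    classification = names(scan$counts),
    n_nodes = as.integer(scan$counts),
    stringsAsFactors = FALSE
  )
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — simulate (optional) -> scan -> sympatry ->
#' summarize — writing each stage's tables plus a run manifest into
#' \code{out_dir}. Either \code{config$simulate = TRUE} (a synthetic dataset
#' is generated from \code{config$synthetic}) or \code{config$dataset_dir}
#' must point to an existing dataset directory. All randomness derives from
#' \code{config$seed}.
#'
#' @param config A list with elements \code{seed} (integer, required),
#'   either \code{simulate = TRUE} (plus optional \code{synthetic}, a
#'   [synthetic_config()]) or \code{dataset_dir}; optional \code{control}
#'   (a [scan_control()]; its seed is overridden by \code{config$seed}),
#'   optional \code{traits} (data frame for [trait_anova()]).
#' @param out_dir Output directory (created; each stage writes only here).
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, a list with the scan object, sympatry table, taxon
#'   summaries and the manifest.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.null(config$seed)) stop("config$seed is required", call. = FALSE)
  if (!isTRUE(config$simulate) && is.null(config$dataset_dir)) {
    stop("config must set simulate = TRUE or dataset_dir", call. = FALSE)
  }
  if (!is.null(config$dataset_dir) && !dir.exists(config$dataset_dir)) {
    stop("dataset_dir does not exist: ", config$dataset_dir, call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[codivscan] ", ...)
  t0 <- Sys.time()
  stage_log <- list()
  tick <- function(stage, note) {
    stage_log[[stage]] <<- list(note = note,
                                elapsed_s = as.numeric(Sys.time() - t0,
                                                       units = "secs"))
    say(stage, ": ", note)
  }

  # --- simulate / load ---
  if (isTRUE(config$simulate)) {
    syn <- config$synthetic %||% synthetic_config(seed = config$seed)
    syn$seed <- as.integer(config$seed)
    dataset <- assemble_dataset(syn)
    write_dataset(dataset, file.path(out_dir, "dataset"))
    tick("simulate", paste0(nrow(dataset$metadata), " strains, ",
                            nrow(dataset$truth), " clades"))
  } else {
    dataset <- read_dataset(config$dataset_dir)
    tick("load", paste0(nrow(dataset$metadata), " strains"))
  }

  # --- scan ---
  control <- config$control %||% scan_control()
  control$seed <- as.integer(config$seed)
  scan <- codiv_scan(dataset$tree, dataset$metadata, dataset$sites,
                     dataset$host_tree, control = control)
  write_tsv(scan_results_df(scan), file.path(out_dir, "scan_results.tsv"))
  summary_df <- scan_summary_df(scan)
  frac_df <- data.frame(class = names(scan$branch_fractions),
                        branch_fraction = as.numeric(scan$branch_fractions),
                        stringsAsFactors = FALSE)
  write_tsv(summary_df, file.path(out_dir, "scan_summary.tsv"))
  write_tsv(frac_df, file.path(out_dir, "branch_fractions.tsv"))
  tick("scan", paste0(nrow(scan$results), " nodes tested"))

  # --- sympatry ---
  symp <- sympatry_scan(scan, dataset$tree, dataset$metadata,
                        classification = "phylo")
  write_tsv(symp, file.path(out_dir, "sympatry.tsv"))
  tick("sympatry", paste0(nrow(symp), " clades evaluated"))

  # --- summarize ---
  phy_sum <- taxon_summaries(scan, dataset$metadata, rank = "phylum")
  gen_sum <- taxon_summaries(scan, dataset$metadata, rank = "genus")
  write_tsv(phy_sum$summaries, file.path(out_dir, "taxon_summary_phylum.tsv"))
  write_tsv(gen_sum$summaries, file.path(out_dir, "taxon_summary_genus.tsv"))
  pw <- phylum_pairwise_tests(scan, dataset$tree, dataset$metadata)
  write_tsv(pw, file.path(out_dir, "phylum_pairwise.tsv"))
  anova_df <- NULL
  if (!is.null(config$traits)) {
    anova_df <- trait_anova(scan, dataset$tree, dataset$metadata,
                            config$traits, seed = config$seed)
    write_tsv(anova_df, file.path(out_dir, "trait_anova.tsv"))
  }
  tick("summarize", paste0(nrow(phy_sum$summaries), " phyla, ",
                           nrow(gen_sum$summaries), " genera"))

  manifest <- list(
    command = "run_pipeline",
    version = as.character(utils::packageVersion("codivscan")),
    seed = as.integer(config$seed),
    simulate = isTRUE(config$simulate),
    dataset_dir = config$dataset_dir %||% file.path(out_dir, "dataset"),
    control = unclass(control),
    input_digests = manifest_digests(config),
    stages = stage_log,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(out_dir, "manifest.json"))
  invisible(list(scan = scan, sympatry = symp,
                 phylum_summaries = phy_sum, genus_summaries = gen_sum,
                 pairwise = pw, trait_anova = anova_df, manifest = manifest))
}

manifest_digests <- function(config) {
  if (is.null(config$dataset_dir)) return(NULL)
  files <- list.files(config$dataset_dir, full.names = TRUE)
  if (!length(files)) return(NULL)
  as.list(tools::md5sum(files))
}
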