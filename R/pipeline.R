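#' Pipeline configuration
#'
#' Bundles the per-stage parameters of [run_pipeline()] with defaults at the
#' study's stated values: 500 semi-landmarks, 99.9% harmonic power, 10,000
#' null resamples for trait domains and 100,000 for outlines, 1000 bootstrap
#' replicates with 50% collapse, 2 outlines per NAC in the stratified tree
#' subsample. A configuration can also be read from YAML or JSON via
#' [read_pipeline_config()].
#'
#' @param generator a [generator_config()] used when no input files are
#'   given.
#' @param outdir output directory (default `"palaeotax-results"`).
#' @param seed top-level seed; stage seeds are derived from it.
#' @param semilandmarks semi-landmark count (default 500).
#' @param smooth_iterations outline smoothing passes (default 5).
#' @param harmonic_power cumulative power threshold (default 0.999).
#' @param resamples named vector of SES null draws per domain.
#' @param n_boot dendrogram bootstrap replicates (default 1000).
#' @param collapse_threshold bootstrap collapse threshold in percent.
#' @param per_nac outlines per NAC in the stratified subsample (default 2).
#' @param n_perm Mantel/disparity permutations (default 999).
#' @param cv_folds CART cross-validation folds (default 10).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            outdir = "palaeotax-results",
                            seed = 1L,
                            semilandmarks = 500L,
                            smooth_iterations = 5L,
                            harmonic_power = 0.999,
                            resamples = c(tools = 10000L,
                                          technology = 10000L,
                                          outlines = 100000L),
                            n_boot = 1000L,
                            collapse_threshold = 50,
                            per_nac = 2L,
                            n_perm = 999L,
                            cv_folds = 10L) {
  structure(list(generator = generator, outdir = outdir,
                 seed = as.integer(seed),
                 semilandmarks = as.integer(semilandmarks),
                 smooth_iterations = as.integer(smooth_iterations),
                 harmonic_power = harmonic_power, resamples = resamples,
                 n_boot = as.integer(n_boot),
                 collapse_threshold = collapse_threshold,
                 per_nac = as.integer(per_nac), n_perm = as.integer(n_perm),
                 cv_folds = as.integer(cv_folds)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a `generator`
#' block mirrors [generator_config()].
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  gen_args <- raw$generator %||% list()
  for (nm in c("trait_counts", "shape_dispersion_by_slice",
               "time_slice_weights")) {
    if (!is.null(gen_args[[nm]])) gen_args[[nm]] <- unlist(gen_args[[nm]])
  }
  gen <- do.call(generator_config, gen_args)
  args <- raw[setdiff(names(raw), "generator")]
  if (!is.null(args$resamples)) args$resamples <- unlist(args$resamples)
  do.call(pipeline_config, c(list(generator = gen), args))
}

#' Run the full coherence-analysis pipeline
#'
#' Orchestrates every stage on a dataset (simulated from
#' `config$generator` unless one is supplied): time-slice expansion of the
#' trait domains, outline preprocessing, harmonic calibration, PCA shape
#' space, all pairwise distances, the SES coherence table, bootstrapped Ward
#' consensus trees per domain, a Tools/Technology tanglegram comparison,
#' Mantel tests and correlograms against geography, the Spearman correlation
#' of cultural and chronological distance, disparity through time with
#' pairwise contrasts, and CART trait importance. All result files are
#' written to `config$outdir` along with a JSON manifest of parameters,
#' seeds and md5 hashes; rerunning with the same configuration reproduces
#' the hashes.
#'
#' @param config a [pipeline_config()].
#' @param dataset optional pre-built [simulate_dataset()] result (or
#'   compatible list) to analyse instead of simulating.
#' @return List of class `pipeline_result` with all stage outputs and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), dataset = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t_start <- Sys.time()
  stage_seed <- function(tag) .hash_seed(config$seed, tag)
  log_stage <- function(name, ...) {
    message(sprintf("[palaeotax] %-12s %s", name, sprintf(...)))
  }

  if (is.null(dataset)) {
    log_stage("simulate", "seed=%d n_nacs=%d", config$generator$seed,
              config$generator$n_nacs)
    dataset <- simulate_dataset(config$generator)
  }

  ## trait domains, expanded to one row per (NAC, time-slice)
  tools_x <- expand_timeslices(dataset$tools)
  tech_x <- expand_timeslices(dataset$technology)
  log_stage("expand", "tools %d->%d rows", nrow(dataset$tools$values),
            nrow(tools_x$values))

  ## outline preprocessing and shape space
  pre <- outline_set(lapply(dataset$outlines, preprocess_outline,
                            smooth_iterations = config$smooth_iterations,
                            k = config$semilandmarks))
  n_harm <- calibrate_harmonics(pre, config$harmonic_power)
  coeffs <- efa_coefficient_table(pre, n_harm)
  space <- pca_shapespace(coeffs)
  log_stage("efa", "%d outlines, %d harmonics, %d PCs", length(pre),
            n_harm, space$component_count)

  ## distances
  d_tools <- gower_distance(tools_x)
  d_tech <- gower_distance(tech_x)
  d_shape <- shape_distance(space)
  ometa <- outline_meta(dataset$outlines)
  d_geo_site <- geo_distance(
    data.frame(site_id = ometa$artefact_id, lat = ometa$lat,
               lon = ometa$lon), mode = "site")
  centroid_pts <- dataset$sites[c("lat", "lon")]
  d_geo_nac <- geo_distance(centroid_pts, mode = "regional_centroid",
                            nac_index = dataset$sites$nac_id)
  log_stage("distances", "gower x2, shape, geo x2")

  ## SES coherence table
  mem_tools <- stats::setNames(tools_x$meta$macro_unit,
                               rownames(tools_x$values))
  mem_tech <- stats::setNames(tech_x$meta$macro_unit,
                              rownames(tech_x$values))
  mem_out <- stats::setNames(unclass(dataset$map)[ometa$nac_id],
                             ometa$artefact_id)
  ses <- ses_table(
    domains = list(tools = d_tools, technology = d_tech,
                   outlines = d_shape),
    membership = list(tools = mem_tools, technology = mem_tech,
                      outlines = mem_out),
    resamples = config$resamples, seed = stage_seed("ses"))
  log_stage("ses", "%d (domain, unit) rows", nrow(ses))

  ## trees
  tree_tools <- bootstrap_consensus(tools_x, n_boot = config$n_boot,
                                    threshold = config$collapse_threshold,
                                    seed = stage_seed("boot:tools"))
  tree_tech <- bootstrap_consensus(tech_x, n_boot = config$n_boot,
                                   threshold = config$collapse_threshold,
                                   seed = stage_seed("boot:technology"))
  sub_idx <- stratified_subsample(ometa$nac_id, per_nac = config$per_nac,
                                  seed = stage_seed("subsample"))
  sub_space <- space$scores[sub_idx, , drop = FALSE]
  tree_out <- bootstrap_consensus(sub_space, n_boot = config$n_boot,
                                  threshold = config$collapse_threshold,
                                  seed = stage_seed("boot:outlines"))
  tangle <- tanglegram_compare(tree_tools, tree_tech)
  log_stage("trees", "%d shared Tools/Technology clades, entanglement %.3f",
            length(tangle$shared_clades), tangle$entanglement)

  ## space: Mantel tests + correlograms (NAC level for traits, site level
  ## for outlines)
  nac_ids_geo <- rownames(d_geo_nac)
  d_tools_nac <- gower_distance(dataset$tools)  # unexpanded, NAC rows
  d_tech_nac <- gower_distance(dataset$technology)
  common <- intersect(rownames(d_tools_nac), nac_ids_geo)
  mantel_res <- list(
    tools = mantel_test(dist_subset(d_tools_nac, common),
                        dist_subset(d_geo_nac, common),
                        n_perm = config$n_perm,
                        seed = stage_seed("mantel:tools")),
    technology = mantel_test(dist_subset(d_tech_nac, common),
                             dist_subset(d_geo_nac, common),
                             n_perm = config$n_perm,
                             seed = stage_seed("mantel:technology")),
    outlines = mantel_test(d_shape, d_geo_site, n_perm = config$n_perm,
                           seed = stage_seed("mantel:outlines")))
  correlograms <- list(
    tools = mantel_correlogram(dist_subset(d_tools_nac, common),
                               dist_subset(d_geo_nac, common),
                               n_perm = config$n_perm,
                               seed = stage_seed("corr:tools")),
    technology = mantel_correlogram(dist_subset(d_tech_nac, common),
                                    dist_subset(d_geo_nac, common),
                                    n_perm = config$n_perm,
                                    seed = stage_seed("corr:technology")),
    outlines = mantel_correlogram(d_shape, d_geo_site,
                                  n_perm = config$n_perm,
                                  seed = stage_seed("corr:outlines")))
  log_stage("mantel", "r(tools)=%.3f r(tech)=%.3f r(outl)=%.3f",
            mantel_res$tools$r, mantel_res$technology$r,
            mantel_res$outlines$r)

  ## time: single-slice subsets only
  single <- !grepl("|", dataset$nacs$time_slices, fixed = TRUE)
  single_ids <- dataset$nacs$nac_id[single]
  sl_nac <- stats::setNames(dataset$nacs$time_slices[single], single_ids)
  keep <- intersect(single_ids, rownames(d_tools_nac))
  d_time_nac <- timeslice_distance(sl_nac[keep])
  time_res <- list(
    tools = time_distance_correlation(dist_subset(d_tools_nac, keep),
                                      d_time_nac, n_perm = config$n_perm,
                                      seed = stage_seed("time:tools")),
    technology = time_distance_correlation(dist_subset(d_tech_nac, keep),
                                           d_time_nac,
                                           n_perm = config$n_perm,
                                           seed = stage_seed("time:technology")),
    outlines = time_distance_correlation(
      d_shape, timeslice_distance(
        stats::setNames(ometa$time_slice, ometa$artefact_id)),
      n_perm = config$n_perm, seed = stage_seed("time:outlines")))

  ## disparity through time
  disp <- disparity_by_timeslice(space, ometa$time_slice,
                                 n_boot = config$n_boot,
                                 seed = stage_seed("disparity"))
  slice_pairs <- utils::combn(
    disp$table$time_slice[disp$table$defined], 2, simplify = FALSE)
  contrasts <- do.call(rbind, lapply(slice_pairs, function(pr) {
    ct <- disparity_contrast(disp, pr[1], pr[2], n_perm = config$n_perm,
                             seed = stage_seed(paste0("contrast:",
                                                      pr[1], pr[2])))
    data.frame(slice_a = pr[1], slice_b = pr[2],
               diff = ct$observed_diff, p = ct$p)
  }))
  log_stage("disparity", "%s",
            paste(sprintf("%s=%.3f", disp$table$time_slice,
                          disp$table$disparity), collapse = " "))

  ## CART
  cart <- list(
    tools = fit_cart(dataset$tools, cv_folds = config$cv_folds,
                     seed = stage_seed("cart:tools")),
    technology = fit_cart(dataset$technology, cv_folds = config$cv_folds,
                          seed = stage_seed("cart:technology")))
  importance <- lapply(cart, variable_importance)
  log_stage("cart", "tools acc=%.2f tech acc=%.2f",
            cart$tools$training_accuracy,
            cart$technology$training_accuracy)

  ## write outputs + manifest
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)
  export_results(ses, out("ses_table.csv"), "csv")
  export_results(d_tools, out("dist_tools.csv"), "csv")
  export_results(d_tech, out("dist_technology.csv"), "csv")
  export_results(tree_tools, out("tree_tools.nwk"), "newick")
  export_results(tree_tech, out("tree_technology.nwk"), "newick")
  export_results(tree_out, out("tree_outlines.nwk"), "newick")
  for (d in names(correlograms)) {
    export_results(correlograms[[d]],
                   out(sprintf("correlogram_%s.csv", d)), "csv")
  }
  export_results(disp, out("disparity.csv"), "csv")
  utils::write.csv(contrasts, out("disparity_contrasts.csv"),
                   row.names = FALSE)
  for (d in names(importance)) {
    utils::write.csv(importance[[d]],
                     out(sprintf("cart_importance_%s.csv", d)),
                     row.names = FALSE)
  }
  shared_df <- data.frame(
    clade = vapply(tangle$shared_clades, paste, character(1),
                   collapse = "|"))
  utils::write.csv(shared_df, out("tanglegram_shared_clades.csv"),
                   row.names = FALSE)

  files <- list.files(config$outdir, full.names = TRUE)
  manifest <- list(
    seed = config$seed,
    parameters = unclass(config[setdiff(names(config),
                                        c("generator", "outdir"))]),
    generator = unclass(config$generator),
    n_harmonics = n_harm,
    pc_count = space$component_count,
    files = stats::setNames(as.list(unname(tools::md5sum(files))),
                            basename(files)),
    elapsed_sec = as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log_stage("done", "%.1f s, outputs in %s", manifest$elapsed_sec,
            config$outdir)

  structure(list(dataset = dataset, n_harmonics = n_harm, space = space,
                 distances = list(tools = d_tools, technology = d_tech,
                                  outlines = d_shape,
                                  geo_nac = d_geo_nac,
                                  geo_site = d_geo_site),
                 ses = ses, trees = list(tools = tree_tools,
                                         technology = tree_tech,
                                         outlines = tree_out),
                 tanglegram = tangle, mantel = mantel_res,
                 correlograms = correlograms, time = time_res,
                 disparity = disp, contrasts = contrasts, cart = cart,
                 importance = importance, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d SES rows, %d harmonics, %d PCs\n",
              nrow(x$ses), x$n_harmonics, x$space$component_count))
  invisible(x)
}
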