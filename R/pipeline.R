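## End-to-end pipeline: simulate (or read) -> rarefy -> diversity ->
## ordination and permutation tests -> time-decay -> per-group networks ->
## node roles -> robustness -> report. One master seed governs every
## stochastic stage through derived stream seeds, so identical
## configuration and seed reproduce every artifact byte for byte.

#' Pipeline configuration
#'
#' Either `simulation` (a [synthetic_config]; its seed is overridden by a
#' stream derived from `seed`) or all of `table_path`/`metadata_path`
#' (+ optional `env_path`) must be given.
#'
#' @param simulation optional [synthetic_config] to generate the inputs.
#' @param table_path,metadata_path,env_path optional input TSV paths.
#' @param rarefy_depth rarefaction depth; defaults to the simulation depth
#'   (or no rarefaction beyond validation when reading files and left
#'   NULL).
#' @param group_by metadata columns defining one network per group
#'   (default site and treatment).
#' @param prevalence_fraction prevalence rule for the per-group filter:
#'   an OTU must be present in more than this fraction of the group's
#'   samples (default 0.75; 27 samples give a cut of 21).
#' @param r_min,p_max fixed correlation/p thresholds (defaults 0.820 and
#'   0.001).
#' @param rmt_scan if TRUE, choose each group's r threshold by
#'   [rmt_threshold_scan], falling back to `r_min` when the scan selects
#'   nothing.
#' @param removal_fraction,removal_trials robustness settings (defaults
#'   0.5 and 100).
#' @param n_perm permutations for PERMANOVA/ANOSIM/Mantel (default 999).
#' @param tdr_scope pairing scope for [tdr_fit] (default "plot").
#' @param seed master seed.
#' @param outdir output directory for stage artifacts.
#' @return list of class `run_config`.
#' @export
run_config <- function(simulation = NULL, table_path = NULL,
                       metadata_path = NULL, env_path = NULL,
                       rarefy_depth = NULL,
                       group_by = c("site", "treatment"),
                       prevalence_fraction = 0.75,
                       r_min = 0.820, p_max = 0.001, rmt_scan = FALSE,
                       removal_fraction = 0.5, removal_trials = 100,
                       n_perm = 999, tdr_scope = "plot",
                       seed = 1L, outdir = tempfile("wetnet_run_")) {
  if (is.null(simulation) && (is.null(table_path) || is.null(metadata_path)))
    stop("provide either a simulation config or table_path + metadata_path",
         call. = FALSE)
  if (!is.null(simulation)) stopifnot(inherits(simulation, "synthetic_config"))
  stopifnot(prevalence_fraction > 0, prevalence_fraction < 1,
            removal_fraction > 0, removal_fraction <= 1,
            removal_trials >= 1, n_perm >= 1)
  structure(list(simulation = simulation, table_path = table_path,
                 metadata_path = metadata_path, env_path = env_path,
                 rarefy_depth = rarefy_depth, group_by = group_by,
                 prevalence_fraction = prevalence_fraction,
                 r_min = r_min, p_max = p_max, rmt_scan = rmt_scan,
                 removal_fraction = removal_fraction,
                 removal_trials = removal_trials, n_perm = n_perm,
                 tdr_scope = tdr_scope, seed = as.integer(seed),
                 outdir = outdir),
            class = "run_config")
}

config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$outdir <- NULL      # where results land is not part of the analysis
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(cfg), tmp)
  unname(tools::md5sum(tmp))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Build one co-occurrence network per sample group
#'
#' Splits the samples by the grouping columns (site and treatment by
#' default), applies the per-group prevalence filter (smallest integer
#' strictly greater than `prevalence_fraction * n_group`), computes the
#' Spearman matrix and builds the thresholded network.
#'
#' @param table an [otu_table].
#' @param metadata a [sample_metadata] covering the table.
#' @param group_by metadata columns defining the groups.
#' @param prevalence_fraction,r_min,p_max,rmt_scan see [run_config].
#' @return named list of `cooccur_network` objects; each carries the
#'   correlation pair in attribute `cor_pair` and any RMT scan in
#'   attribute `rmt`.
#' @export
make_group_networks <- function(table, metadata,
                                group_by = c("site", "treatment"),
                                prevalence_fraction = 0.75,
                                r_min = 0.820, p_max = 0.001,
                                rmt_scan = FALSE) {
  meta <- align_metadata(metadata, table)
  miss <- setdiff(group_by, names(meta))
  if (length(miss))
    stop("grouping column(s) absent from metadata: ",
         paste(miss, collapse = ", "), call. = FALSE)
  key <- do.call(paste, c(meta[group_by], sep = "."))
  out <- list()
  for (g in unique(key)) {
    ids <- meta$sample_id[key == g]
    if (length(ids) < 4)
      stop("group '", g, "' has ", length(ids),
           " samples; >= 4 required for correlation", call. = FALSE)
    if (length(ids) != 27)
      message("group '", g, "' has ", length(ids),
              " samples (27 in the emulated design)")
    sub <- subset_table(table, samples = ids)
    cut <- prevalence_cut(length(ids), prevalence_fraction)
    filtered <- prevalence_filter(sub, cut)
    cm <- spearman_matrix(filtered)
    scan <- NULL
    r_use <- r_min
    if (rmt_scan) {
      scan <- rmt_threshold_scan(cm)
      if (!is.na(scan$threshold)) r_use <- scan$threshold
    }
    net <- build_network(cm, r_min = r_use, p_max = p_max,
                         taxonomy = filtered$taxonomy)
    attr(net, "cor_pair") <- cm
    attr(net, "rmt") <- scan
    out[[g]] <- net
  }
  out
}

#' Run the full analysis pipeline
#'
#' Executes every stage under one master seed and writes all artifacts to
#' `config$outdir`: input tables (when simulated), the Bray-Curtis
#' distance matrix, PCoA coordinates, per-group networks (GraphML + edge
#' list + role table), and `report.json` / `report.txt`. Re-running with
#' the same configuration and seed reproduces the report byte for byte.
#'
#' @param config a [run_config].
#' @return list of class `run_report` (also serialised as JSON).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  streams <- split_seed(config$seed, 6)
  prov <- list(package = "wetnet",
               version = as.character(utils::packageVersion("wetnet")),
               seed = config$seed, config_hash = config_hash(config))
  hdr <- sprintf("# wetnet %s | seed %d | config %s", prov$version,
                 prov$seed, prov$config_hash)

  ## inputs
  if (!is.null(config$simulation)) {
    sim_cfg <- config$simulation
    sim_cfg$seed <- streams[1]
    ds <- run_stage("simulate", simulate_dataset(sim_cfg))
    run_stage("simulate", write_synthetic_dataset(ds, file.path(outdir,
                                                                "data")))
    table <- ds$table; metadata <- ds$metadata; env <- ds$env
    depth <- config$rarefy_depth %||% sim_cfg$depth
  } else {
    metadata <- run_stage("read", read_sample_metadata(config$metadata_path))
    table <- run_stage("read", read_otu_table(config$table_path, metadata))
    env <- if (!is.null(config$env_path))
      run_stage("read", read_env_table(config$env_path)) else NULL
    depth <- config$rarefy_depth
  }

  if (!is.null(depth))
    table <- run_stage("rarefy", rarefy_table(table, depth,
                                              seed = streams[2]))
  metadata <- align_metadata(metadata, table)

  ## diversity, ordination, permutation tests, time decay
  alpha <- run_stage("alpha", alpha_diversity(table))
  bray <- run_stage("beta", bray_curtis(table))
  utils::write.table(rbind(hdr), file.path(outdir, "bray_curtis.tsv"),
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  suppressWarnings(utils::write.table(
    data.frame(sample_id = rownames(bray), bray, check.names = FALSE),
    file.path(outdir, "bray_curtis.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, append = TRUE))
  ord <- run_stage("ordination", pcoa(bray, k = 2))
  coords <- data.frame(sample_id = rownames(ord$coordinates),
                       ord$coordinates, check.names = FALSE)
  utils::write.table(rbind(hdr), file.path(outdir, "pcoa_coordinates.tsv"),
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  suppressWarnings(utils::write.table(
    coords, file.path(outdir, "pcoa_coordinates.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE, append = TRUE))

  tests <- list(); tdr <- list()
  group_key <- do.call(paste, c(metadata[config$group_by], sep = "."))
  for (s in unique(metadata$site)) {
    in_site <- metadata$site == s
    ids <- metadata$sample_id[in_site]
    dsub <- bray[ids, ids]
    msub <- metadata[in_site, , drop = FALSE]
    tests[[s]] <- run_stage("tests", list(
      permanova_treatment = unclass(permanova(dsub, msub$treatment,
                                              n_perm = config$n_perm,
                                              seed = streams[3])),
      anosim_treatment = unclass(anosim(dsub, msub$treatment,
                                        n_perm = config$n_perm,
                                        seed = streams[3])),
      permanova_time = unclass(permanova(dsub, factor(msub$time_point),
                                         n_perm = config$n_perm,
                                         seed = streams[3]))
    ))
    if (!is.null(env)) {
      denv <- as.matrix(stats::dist(scale(env[ids, , drop = FALSE])))
      tests[[s]]$mantel_env <- unclass(
        run_stage("tests", mantel(dsub, denv, n_perm = config$n_perm,
                                  seed = streams[3])))
    }
  }
  for (g in unique(group_key)) {
    ids <- metadata$sample_id[group_key == g]
    tdr[[g]] <- run_stage("tdr", unclass(
      tdr_fit(bray[ids, ids], metadata, pairing_scope = config$tdr_scope)))
  }

  ## networks, roles, robustness
  nets <- run_stage("network", make_group_networks(
    table, metadata, group_by = config$group_by,
    prevalence_fraction = config$prevalence_fraction,
    r_min = config$r_min, p_max = config$p_max,
    rmt_scan = config$rmt_scan))
  networks <- list(); role_tables <- list()
  for (g in names(nets)) {
    net <- nets[[g]]
    mods <- run_stage("modules", detect_modules(net, seed = streams[4]))
    topo <- run_stage("topology", topology_metrics(net, mods))
    roles <- run_stage("roles",
                       classify_roles(zipi(net, mods$membership)))
    role_tables[[g]] <- roles
    safe <- gsub("[^A-Za-z0-9_.-]", "_", g)
    write_network(net, file.path(outdir, paste0("network_", safe,
                                                ".graphml")),
                  "graphml", membership = mods$membership, roles = roles)
    write_network(net, file.path(outdir, paste0("network_", safe,
                                                "_edges.csv")),
                  "edgelist")
    utils::write.table(rbind(hdr),
                       file.path(outdir, paste0("roles_", safe, ".tsv")),
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    suppressWarnings(utils::write.table(
      roles, file.path(outdir, paste0("roles_", safe, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE))
    rob_rand <- run_stage("robustness", simulate_removal(
      net, "random", fraction = config$removal_fraction,
      n_trials = config$removal_trials, seed = streams[5]))
    ks <- keystones(roles)
    rob_targ <- if (length(ks)) run_stage("robustness", simulate_removal(
      net, "targeted", fraction = config$removal_fraction, roles = roles,
      n_trials = config$removal_trials, seed = streams[5])) else NULL
    scan <- attr(net, "rmt")
    networks[[g]] <- list(
      topology = unclass(topo),
      r_threshold = igraph::graph_attr(net, "r_threshold"),
      rmt_threshold = if (!is.null(scan)) scan$threshold else NULL,
      n_keystones = length(ks),
      roles = as.list(table(roles$role)),
      robustness_random = rob_rand[c("mean", "sd", "trials")],
      robustness_targeted = if (!is.null(rob_targ))
        rob_targ[c("mean", "sd", "trials")] else NULL,
      robustness_comparison = if (!is.null(rob_targ))
        compare_robustness(rob_rand, rob_targ)["p"] else NULL
    )
  }

  ## keystone overlap between the two treatments of each site
  overlap <- list()
  if ("treatment" %in% config$group_by && "site" %in% config$group_by) {
    for (s in unique(metadata$site)) {
      gs <- names(role_tables)[startsWith(names(role_tables),
                                          paste0(s, "."))]
      if (length(gs) == 2)
        overlap[[s]] <- keystone_overlap(role_tables[[gs[1]]],
                                         role_tables[[gs[2]]])
    }
  }

  alpha_by_group <- lapply(split(alpha, group_key), function(a)
    list(n = nrow(a), mean_richness = mean(a$richness),
         mean_shannon = mean(a$shannon)))

  report <- structure(list(
    provenance = prov,
    alpha = alpha_by_group,
    ordination = list(
      proportion_explained = ord$proportion_explained,
      n_negative_eigenvalues = ord$n_negative),
    tests = tests,
    tdr = tdr,
    networks = networks,
    keystone_overlap = overlap
  ), class = "run_report")

  jsonlite::write_json(unclass_recursive(report),
                       file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  writeLines(utils::capture.output(print(report)),
             file.path(outdir, "report.txt"))
  invisible(report)
}

unclass_recursive <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_recursive) else unclass(x)
}

#' @export
print.run_report <- function(x, ...) {
  cat("wetnet run (seed ", x$provenance$seed, ", config ",
      x$provenance$config_hash, ")\n\n", sep = "")
  cat("Time-decay turnover rates (v, similarity/day):\n")
  for (g in names(x$tdr))
    cat(sprintf("  %-28s v = %-10s R2 = %-8s p = %s\n", g,
                fmt_num(x$tdr[[g]]$v), fmt_num(x$tdr[[g]]$r_squared),
                fmt_num(x$tdr[[g]]$p_value)))
  cat("\nNetworks:\n")
  for (g in names(x$networks)) {
    n <- x$networks[[g]]
    cat(sprintf(
      "  %-28s %d nodes, %d links, Q = %s, keystones = %d\n", g,
      n$topology$n_nodes, n$topology$n_links, fmt_num(n$topology$modularity),
      n$n_keystones))
    cat(sprintf("  %-28s robustness: random %s%s\n", "",
                fmt_num(n$robustness_random$mean),
                if (!is.null(n$robustness_targeted))
                  paste0(", targeted ", fmt_num(n$robustness_targeted$mean))
                else ""))
  }
  if (length(x$keystone_overlap)) {
    cat("\nKeystone overlap between treatments (%):\n")
    for (s in names(x$keystone_overlap))
      cat("  ", s, ": ", fmt_num(x$keystone_overlap[[s]]), "\n", sep = "")
  }
  invisible(x)
}
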