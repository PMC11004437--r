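## Synthetic OTU-table generator. Emulates a two-site, two-treatment,
## nine-season, three-plot sampling design (108 samples; 27 per
## site-by-treatment group): latent log-abundances carry a per-site shift,
## planted correlated OTU modules, treatment-specific AR(1) temporal drift
## and iid noise; counts are multinomial draws from the softmax composition
## at a fixed depth; environmental covariates are noisy linear images of
## the leading latent community axes.

# study sampling dates; extended two-monthly if more time points are asked
study_dates <- function(n) {
  base <- as.Date(c("2018-05-15", "2018-07-15", "2018-09-15", "2018-11-15",
                    "2019-04-15", "2019-07-15", "2019-09-15", "2019-11-15",
                    "2020-01-15"))
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, seq(base[length(base)], by = "2 months",
              length.out = n - length(base) + 1)[-1])
}

#' Configuration for the synthetic community generator
#'
#' Defaults reproduce the emulated study design: 2 sites x 2 treatments
#' (control/warming) x 9 seasonal time points x 3 plots = 108 samples, 27
#' per site-by-treatment group, 300 OTUs at 28,500 reads per sample, three
#' planted correlation modules of 15 OTUs at within-module Spearman 0.9,
#' and a warming drift rate 2.5 times the control rate (so warming
#' accelerates temporal turnover without shifting mean composition).
#'
#' @param n_sites,n_treatments,n_timepoints,n_plots design dimensions.
#' @param n_otus total OTUs (must cover the module sizes).
#' @param depth multinomial reads per sample.
#' @param module_spec list of `c(size, rho)` pairs: module size and target
#'   within-module Spearman correlation in \[0, 1).
#' @param drift_rate per-treatment AR(1) innovation scale on the latent
#'   log scale, per sqrt(day); recycled to `n_treatments`. Treatment 1 is
#'   "control".
#' @param ar_coef AR(1) coefficient between consecutive time points
#'   (default 1: pure accumulation, giving near-linear similarity decay).
#' @param site_effect_scale sd of the per-site log-abundance shift.
#' @param plot_effect_scale sd of the per-plot random effect (default 0).
#' @param noise_scale sd of the iid latent noise.
#' @param base_log_sd sd of baseline log-abundances of background OTUs.
#' @param env_vars number of environmental covariates.
#' @param env_community_correlation target Pearson correlation between
#'   each covariate and its latent community axis, in \[0, 1\].
#' @param seed master seed; expanded into per-stream seeds by
#'   [split_seed].
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_sites = 2, n_treatments = 2, n_timepoints = 9,
                             n_plots = 3, n_otus = 300, depth = 28500,
                             module_spec = list(c(15, 0.9), c(15, 0.9),
                                                c(15, 0.9)),
                             drift_rate = c(0.04, 0.10),
                             ar_coef = 1,
                             site_effect_scale = 1,
                             plot_effect_scale = 0,
                             noise_scale = 1,
                             base_log_sd = 1.5,
                             env_vars = 4,
                             env_community_correlation = 0.7,
                             seed = 1L) {
  cfg <- list(n_sites = as.integer(n_sites),
              n_treatments = as.integer(n_treatments),
              n_timepoints = as.integer(n_timepoints),
              n_plots = as.integer(n_plots),
              n_otus = as.integer(n_otus), depth = as.integer(depth),
              module_spec = lapply(module_spec, as.numeric),
              drift_rate = rep_len(as.numeric(drift_rate),
                                   as.integer(n_treatments)),
              ar_coef = as.numeric(ar_coef),
              site_effect_scale = as.numeric(site_effect_scale),
              plot_effect_scale = as.numeric(plot_effect_scale),
              noise_scale = as.numeric(noise_scale),
              base_log_sd = as.numeric(base_log_sd),
              env_vars = as.integer(env_vars),
              env_community_correlation = as.numeric(env_community_correlation),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_sites >= 1, n_treatments >= 1, n_timepoints >= 1,
              n_plots >= 1, n_otus >= 1, depth > 0, ar_coef >= 0,
              site_effect_scale >= 0, plot_effect_scale >= 0,
              noise_scale >= 0, base_log_sd >= 0, env_vars >= 0,
              env_community_correlation >= 0, env_community_correlation <= 1,
              all(drift_rate >= 0))
  })
  sizes <- vapply(cfg$module_spec, `[`, 0, 1)
  rhos <- vapply(cfg$module_spec, `[`, 0, 2)
  if (length(sizes) && (any(sizes < 2) || any(rhos < 0) || any(rhos >= 1)))
    stop("module sizes must be >= 2 and correlations in [0, 1)",
         call. = FALSE)
  if (sum(sizes) > cfg$n_otus)
    stop("module sizes (", sum(sizes), ") exceed n_otus (", cfg$n_otus, ")",
         call. = FALSE)
  # expected detected OTUs per sample under a uniform composition proxy
  if (cfg$n_otus * (1 - (1 - 1 / cfg$n_otus)^cfg$depth) < 2)
    stop("depth too small: fewer than 2 OTUs expected per sample",
         call. = FALSE)
  structure(cfg, class = "synthetic_config")
}

treatment_labels <- function(k) {
  if (k == 2) c("control", "warming")
  else if (k == 1) "control"
  else c("control", paste0("treatment", seq_len(k - 1)))
}

site_labels <- function(k) paste0("site", LETTERS[seq_len(k)])

#' Generate a synthetic community dataset
#'
#' See [synthetic_config] for the generating model. Fixed seed implies
#' bit-identical output.
#'
#' @param config a [synthetic_config].
#' @return object of class `synthetic_dataset`: `table` ([otu_table]),
#'   `metadata` ([sample_metadata]), `env` (samples x variables matrix),
#'   `truth` (planted module membership and drift rates), `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  streams <- split_seed(cfg$seed, 8)
  sites <- site_labels(cfg$n_sites)
  treatments <- treatment_labels(cfg$n_treatments)
  dates <- study_dates(cfg$n_timepoints)
  design <- expand.grid(plot = seq_len(cfg$n_plots),
                        time_idx = seq_len(cfg$n_timepoints),
                        treatment = treatments, site = sites,
                        stringsAsFactors = FALSE)
  design$time_point <- dates[design$time_idx]
  design$sample_id <- sprintf("%s_%s_t%02d_p%d", design$site,
                              design$treatment, design$time_idx, design$plot)
  ns <- nrow(design)
  otus <- sprintf("OTU%04d", seq_len(cfg$n_otus))
  sizes <- vapply(cfg$module_spec, `[`, 0, 1)
  rhos <- vapply(cfg$module_spec, `[`, 0, 2)
  module_of <- rep(NA_integer_, cfg$n_otus)
  if (length(sizes))
    module_of[seq_len(sum(sizes))] <- rep(seq_along(sizes), sizes)

  # baseline log-abundances; module OTUs are kept moderately abundant so
  # their planted correlation is observable through counting noise
  base <- with_seed(streams[1], {
    b <- stats::rnorm(cfg$n_otus, 0, cfg$base_log_sd)
    b[!is.na(module_of)] <- stats::rnorm(sum(!is.na(module_of)), 1, 0.5)
    b
  })
  site_eff <- with_seed(streams[2], matrix(
    stats::rnorm(cfg$n_sites * cfg$n_otus, 0, cfg$site_effect_scale),
    cfg$n_sites, cfg$n_otus, dimnames = list(sites, NULL)))

  x <- matrix(base, ns, cfg$n_otus, byrow = TRUE)
  x <- x + site_eff[design$site, , drop = FALSE]

  # shared module factors: a module OTU's stochastic part is
  # sqrt(rho_p) * f_module + sqrt(1 - rho_p) * e, both scaled by
  # noise_scale, so pairwise latent correlation is rho_p while the
  # marginal variance matches the background OTUs. The Pearson target
  # comes from the Gaussian-copula relation
  # rho_pearson = 2 sin(pi rho_spearman / 6).
  rho_p <- 2 * sin(pi * rhos / 6)
  if (length(sizes)) {
    fac <- with_seed(streams[3],
                     matrix(stats::rnorm(ns * length(sizes)), ns))
    for (j in which(!is.na(module_of))) {
      m <- module_of[j]
      x[, j] <- x[, j] + sqrt(rho_p[m]) * cfg$noise_scale * fac[, m]
    }
  }

  # AR(1) temporal drift per site-by-treatment group and OTU, shared by
  # the plots of the group; innovations scale with sqrt(days elapsed)
  gaps <- sqrt(c(0, diff(as.numeric(dates))))
  drift <- with_seed(streams[4], {
    out <- list()
    for (s in sites) for (w in seq_along(treatments)) {
      z <- matrix(0, cfg$n_timepoints, cfg$n_otus)
      for (t in seq_len(cfg$n_timepoints)[-1]) {
        z[t, ] <- cfg$ar_coef * z[t - 1, ] +
          cfg$drift_rate[w] * gaps[t] * stats::rnorm(cfg$n_otus)
      }
      out[[paste(s, treatments[w], sep = "\r")]] <- z
    }
    out
  })
  gkey <- paste(design$site, design$treatment, sep = "\r")
  for (g in unique(gkey)) {
    rows <- which(gkey == g)
    x[rows, ] <- x[rows, ] + drift[[g]][design$time_idx[rows], , drop = FALSE]
  }

  if (cfg$plot_effect_scale > 0) {
    pkey <- paste(design$site, design$treatment, design$plot, sep = "\r")
    upl <- unique(pkey)
    pe <- with_seed(streams[5], matrix(
      stats::rnorm(length(upl) * cfg$n_otus, 0, cfg$plot_effect_scale),
      length(upl), cfg$n_otus, dimnames = list(upl, NULL)))
    x <- x + pe[pkey, , drop = FALSE]
  }

  noise_sd <- rep(cfg$noise_scale, cfg$n_otus)
  if (length(sizes))
    noise_sd[!is.na(module_of)] <-
      cfg$noise_scale * sqrt(1 - rho_p[module_of[!is.na(module_of)]])
  x <- x + with_seed(streams[6],
                     matrix(stats::rnorm(ns * cfg$n_otus, 0, 1), ns) %*%
                       diag(noise_sd))

  # multinomial counts from the softmax composition
  comp <- exp(x - apply(x, 1, max))
  comp <- comp / rowSums(comp)
  counts <- with_seed(streams[7], {
    m <- matrix(0L, cfg$n_otus, ns)
    for (i in seq_len(ns))
      m[, i] <- stats::rmultinom(1, cfg$depth, comp[i, ])
    m
  })
  dimnames(counts) <- list(otus, design$sample_id)

  # environmental covariates: noisy images of the leading latent axes
  env <- NULL
  if (cfg$env_vars > 0) {
    n_axes <- min(cfg$env_vars, ns - 1, cfg$n_otus)
    scores <- stats::prcomp(x, center = TRUE, scale. = FALSE)$x
    env <- with_seed(streams[8], {
      rho <- cfg$env_community_correlation
      sapply(seq_len(cfg$env_vars), function(k) {
        axis <- scale(scores[, ((k - 1) %% n_axes) + 1])[, 1]
        rho * axis + sqrt(1 - rho^2) * stats::rnorm(ns)
      })
    })
    dimnames(env) <- list(design$sample_id,
                          paste0("env", seq_len(cfg$env_vars)))
  }

  metadata <- sample_metadata(data.frame(
    sample_id = design$sample_id, site = design$site,
    treatment = design$treatment, time_point = design$time_point,
    plot = paste0("p", design$plot), stringsAsFactors = FALSE))

  truth <- list(
    modules = stats::setNames(module_of[!is.na(module_of)],
                              otus[!is.na(module_of)]),
    drift_rate = stats::setNames(cfg$drift_rate, treatments)
  )
  structure(list(table = otu_table(counts), metadata = metadata, env = env,
                 truth = truth, config = cfg),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cfg <- x$config
  cat("Synthetic dataset:", cfg$n_sites, "sites x", cfg$n_treatments,
      "treatments x", cfg$n_timepoints, "times x", cfg$n_plots, "plots =",
      ncol(x$table$counts), "samples\n")
  cat("  ", cfg$n_otus, " OTUs at depth ", cfg$depth, "; ",
      length(unique(x$truth$modules)), " planted modules\n", sep = "")
  invisible(x)
}

#' Report what the generator planted
#'
#' Round-trips the ground truth: planted module membership per OTU (empty
#' mapping when no modules were configured, in `module_spec` order) and
#' the per-treatment drift rates.
#'
#' @param ds a `synthetic_dataset`.
#' @return list with `modules` (named integer vector) and `drift_rate`
#'   (named numeric vector).
#' @export
truth_report <- function(ds) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  ds$truth
}

#' Write a synthetic dataset to a directory
#'
#' Emits `otu_table.tsv`, `metadata.tsv`, `env.tsv` (when covariates were
#' generated) and `truth.json`. Fixed seed implies byte-identical files.
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_otu_table(ds$table, file.path(dir, "otu_table.tsv"))
  write_sample_metadata(ds$metadata, file.path(dir, "metadata.tsv"))
  if (!is.null(ds$env)) write_env_table(ds$env, file.path(dir, "env.tsv"))
  jsonlite::write_json(
    list(modules = as.list(ds$truth$modules),
         drift_rate = as.list(ds$truth$drift_rate)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a generator configuration from a YAML file
#'
#' Keys mirror the arguments of [synthetic_config]; `module_spec` is a
#' list of two-element `[size, rho]` entries.
#'
#' @param path YAML file.
#' @return a [synthetic_config].
#' @export
read_synthetic_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(synthetic_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(synthetic_config, vals)
}
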