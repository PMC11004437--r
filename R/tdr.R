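#' Time-decay relationship of community similarity
#'
#' Ordinary least-squares regression of community similarity
#' (1 - dissimilarity) on the time interval in days between paired
#' samples. The turnover rate v is the absolute slope (similarity per
#' day). Only pairs with a positive time interval enter the fit.
#'
#' @param d square symmetric dissimilarity matrix over samples.
#' @param metadata a [sample_metadata] covering the samples of `d`.
#' @param pairing_scope which sample pairs to regress: `"plot"` (default)
#'   pairs samples of the same site, treatment and plot across times;
#'   `"group"` pairs all samples of the same site and treatment across
#'   times, including cross-plot pairs.
#' @param log_log if TRUE, regress log10(similarity) on log10(days)
#'   (pairs with zero similarity are dropped); default FALSE, raw scales.
#' @return object of class `tdr_fit`: `slope`, `intercept`, `v = |slope|`,
#'   `r_squared`, `p_value` (two-sided, for the slope), `n_pairs`.
#' @export
tdr_fit <- function(d, metadata, pairing_scope = c("plot", "group"),
                    log_log = FALSE) {
  pairing_scope <- match.arg(pairing_scope)
  d <- check_distance_matrix(d)
  ids <- rownames(d)
  meta <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id))
    stop("samples absent from metadata: ",
         paste(ids[is.na(meta$sample_id)], collapse = ", "), call. = FALSE)
  key <- paste(meta$site, meta$treatment,
               if (pairing_scope == "plot") meta$plot else "", sep = "\r")
  same_scope <- outer(key, key, `==`)
  dt <- abs(outer(as.numeric(meta$time_point), as.numeric(meta$time_point),
                  `-`))
  sel <- upper.tri(d) & same_scope & dt > 0
  if (sum(sel) < 3)
    stop("fewer than 3 sample pairs with positive time interval in scope",
         call. = FALSE)
  days <- dt[sel]
  sim <- 1 - d[sel]
  if (length(unique(days)) < 2)
    stop("all time intervals equal; no regression possible", call. = FALSE)
  if (log_log) {
    ok <- sim > 0
    days <- log10(days[ok]); sim <- log10(sim[ok])
    if (length(sim) < 3) stop("too few positive similarities for log-log fit",
                              call. = FALSE)
  }
  if (stats::sd(sim) == 0) {
    # constant similarity: a flat line fits exactly, nothing decays
    return(structure(list(slope = 0, intercept = sim[1], v = 0,
                          r_squared = 0, p_value = NA_real_,
                          n_pairs = length(sim),
                          pairing_scope = pairing_scope, log_log = log_log),
                     class = "tdr_fit"))
  }
  fit <- stats::lm(sim ~ days)
  sm <- suppressWarnings(summary(fit))  # perfect fits are legitimate here
  coefs <- sm$coefficients
  slope <- coefs["days", "Estimate"]
  p_slope <- coefs["days", "Pr(>|t|)"]
  structure(list(
    slope = slope,
    intercept = coefs["(Intercept)", "Estimate"],
    v = abs(slope),
    r_squared = sm$r.squared,
    p_value = if (is.finite(p_slope)) p_slope else NA_real_,
    n_pairs = length(sim),
    pairing_scope = pairing_scope,
    log_log = log_log
  ), class = "tdr_fit")
}

#' @export
print.tdr_fit <- function(x, ...) {
  cat("Time-decay relationship (", x$pairing_scope, " pairs, n = ",
      x$n_pairs, ")\n", sep = "")
  cat("  v = ", fmt_num(x$v), " similarity/day  (slope ", fmt_num(x$slope),
      ")\n", sep = "")
  cat("  R2 = ", fmt_num(x$r_squared), ", p = ", fmt_num(x$p_value), "\n",
      sep = "")
  invisible(x)
}
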