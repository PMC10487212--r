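#' Origin-level chemistry defaults for the simulated sampling design
#'
#' Per-origin means and standard deviations of the four quality traits the
#' pipeline calibrates against: moisture content (MC, %), soluble solids
#' content (SSC, %), titratable acidity (TA, g/100 mL citric acid) and total
#' carotenoids content (CC, mg/100 g dry matter). The defaults describe six
#' pineapple origins with distinct maturity profiles (e.g. the heaviest,
#' wettest origin has the lowest soluble solids and carotenoids).
#'
#' @return A data.frame with one row per origin and columns
#'   `origin`, `<trait>_mean`, `<trait>_sd` for `mc`, `ssc`, `ta`, `cc`.
#' @export
origin_chemistry_defaults <- function() {
  data.frame(
    origin   = 1:6,
    mc_mean  = c(86.51, 86.70, 85.14, 88.54, 86.13, 86.35),
    mc_sd    = c(1.34, 2.24, 1.81, 1.28, 0.58, 1.10),
    ssc_mean = c(13.02, 12.42, 13.76, 10.52, 12.92, 13.18),
    ssc_sd   = c(1.19, 2.19, 1.17, 1.63, 0.53, 0.91),
    ta_mean  = c(0.96, 0.95, 0.92, 0.98, 0.61, 0.93),
    ta_sd    = c(0.07, 0.21, 0.15, 0.16, 0.14, 0.17),
    cc_mean  = c(0.34, 0.42, 0.35, 0.23, 0.35, 0.21),
    cc_sd    = c(0.12, 0.05, 0.12, 0.10, 0.09, 0.11)
  )
}

#' Default pooled inter-trait correlation targets
#'
#' Pooled (across-origin) Pearson correlations the generator reproduces.
#' The carotenoid row reflects the physiology of ripening flesh: carotenoids
#' rise as soluble solids rise and moisture falls, and are nearly unrelated
#' to acidity. The remaining pairs are weaker couplings chosen to keep the
#' joint correlation matrix positive definite.
#'
#' @return A symmetric 4x4 correlation matrix with dimnames
#'   `c("mc","ssc","ta","cc")`.
#' @export
chemistry_correlation_defaults <- function() {
  traits <- c("mc", "ssc", "ta", "cc")
  R <- diag(4)
  dimnames(R) <- list(traits, traits)
  R["cc", "mc"] <- R["mc", "cc"] <- -0.56
  R["cc", "ssc"] <- R["ssc", "cc"] <- 0.52
  R["cc", "ta"] <- R["ta", "cc"] <- -0.14
  R["mc", "ssc"] <- R["ssc", "mc"] <- -0.45
  R["mc", "ta"] <- R["ta", "mc"] <- 0.10
  R["ssc", "ta"] <- R["ta", "ssc"] <- -0.05
  R
}

# Pooled moments implied by a per-origin mean/SD table (equal origin weights).
pooled_moments <- function(params) {
  traits <- c("mc", "ssc", "ta", "cc")
  means <- as.matrix(params[paste0(traits, "_mean")])
  sds <- as.matrix(params[paste0(traits, "_sd")])
  colnames(means) <- colnames(sds) <- traits
  m <- colMeans(means)
  # population covariance of the origin means (between component)
  dev <- sweep(means, 2, m)
  B <- crossprod(dev) / nrow(means)
  W_var <- colMeans(sds^2)            # mean within-origin variance
  list(means = means, sds = sds, between = B, within_var = W_var,
       total_var = W_var + diag(B))
}

# Solve for the within-origin correlation matrix that makes the *pooled*
# correlations hit their targets, given that pooling adds the covariance of
# the origin means on top of the average within-origin covariance.
calibrate_within_correlation <- function(params, pooled_target) {
  pm <- pooled_moments(params)
  traits <- colnames(pooled_target)
  k <- length(traits)
  Rw <- diag(k)
  dimnames(Rw) <- dimnames(pooled_target)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      target_cov <- pooled_target[i, j] *
        sqrt(pm$total_var[i] * pm$total_var[j])
      mean_sd_prod <- mean(pm$sds[, i] * pm$sds[, j])
      r <- (target_cov - pm$between[i, j]) / mean_sd_prod
      Rw[i, j] <- Rw[j, i] <- r
    }
  }
  Rw
}

#' Generate a synthetic per-ROI reference chemistry table
#'
#' Simulates the wet-chemistry reference table of a multi-origin fruit
#' sampling design: `origins` geographic origins, `fruit_per_origin` fruit
#' each, and `regions_per_fruit` cylindrical regions of interest (ROIs) per
#' fruit slice. Traits are drawn through a Gaussian copula: a latent
#' multivariate normal carries the inter-trait correlation, split between a
#' per-fruit effect and a per-ROI effect, and is mapped to truncated-normal
#' marginals with the configured per-origin means and SDs (moisture bounded
#' in (0, 100) %, the other traits bounded below by 0).
#'
#' The `correlations` argument is the *pooled* correlation target (all rows,
#' all origins). Because pooling across origins adds the spread of the origin
#' means to the within-origin covariance, the generator calibrates the latent
#' within-origin correlation analytically so that the pooled sample
#' correlations converge to the configured values as n grows.
#'
#' @param design list with `origins`, `fruit_per_origin`, `regions_per_fruit`.
#' @param params per-origin mean/SD table, see [origin_chemistry_defaults()].
#' @param correlations pooled 4x4 correlation target, see
#'   [chemistry_correlation_defaults()].
#' @param fruit_var_share fraction of within-origin variance attributed to
#'   the between-fruit (rather than within-fruit, between-ROI) level.
#' @param seed integer seed; the same seed yields an identical table.
#' @return A data.frame with columns
#'   `origin, fruit, region, mc_pct, ssc_pct, ta_gpct, cc_mg100gdm`.
#' @export
generate_reference_table <- function(design = list(origins = 6L,
                                                   fruit_per_origin = 10L,
                                                   regions_per_fruit = 10L),
                                     params = origin_chemistry_defaults(),
                                     correlations = chemistry_correlation_defaults(),
                                     fruit_var_share = 0.5,
                                     seed = 1L) {
  stopifnot(design$origins >= 1, design$fruit_per_origin >= 1,
            design$regions_per_fruit >= 1,
            fruit_var_share >= 0, fruit_var_share <= 1)
  traits <- c("mc", "ssc", "ta", "cc")
  if (nrow(params) < design$origins) {
    stop("`params` must supply one row per origin (",
         design$origins, " needed, ", nrow(params), " given)")
  }
  params <- params[seq_len(design$origins), , drop = FALSE]
  sds <- as.matrix(params[paste0(traits, "_sd")])
  if (any(sds <= 0)) stop("all per-origin SDs must be > 0")
  if (any(sds < 1e-6)) {
    warning("near-zero SDs produce near-constant columns; ",
            "correlation targets are unreachable there")
  }

  Rw <- calibrate_within_correlation(params, correlations)
  degenerate_sds <- any(sds < 1e-6)
  if (any(abs(Rw[upper.tri(Rw)]) > 1)) {
    bad <- which(abs(Rw) > 1 & upper.tri(Rw), arr.ind = TRUE)
    pairs <- paste(apply(bad, 1, function(ij)
      paste(rownames(Rw)[ij[1]], colnames(Rw)[ij[2]], sep = "-")),
      collapse = ", ")
    if (degenerate_sds) {
      # near-constant columns cannot carry the requested correlation;
      # degrade gracefully so the marginal structure is still produced
      warning("correlation targets unreachable with near-constant ",
              "columns (pairs ", pairs, "); clamping")
      Rw[] <- pmin(pmax(Rw, -0.999), 0.999)
      diag(Rw) <- 1
    } else {
      stop("pooled correlation targets infeasible for these origin params: ",
           "implied within-origin |r| > 1 for pair(s) ", pairs)
    }
  }
  ed <- eigen(Rw, symmetric = TRUE)
  if (min(ed$values) < -1e-8) {
    if (degenerate_sds) {
      # nearest-PSD repair: clip eigenvalues and rescale to unit diagonal
      v <- pmax(ed$values, 1e-8)
      Rw <- ed$vectors %*% diag(v) %*% t(ed$vectors)
      d <- sqrt(diag(Rw))
      Rw <- Rw / tcrossprod(d)
    } else {
      stop("within-origin correlation matrix implied by the configuration ",
           "is not positive semi-definite (min eigenvalue ",
           signif(min(ed$values), 3), "); adjust `correlations` or `params`")
    }
  }
  # guard tiny negative eigenvalues from rounding
  L <- chol(Rw + diag(1e-10, length(traits)))

  n_f <- design$fruit_per_origin
  n_r <- design$regions_per_fruit
  rows_per_origin <- n_f * n_r

  with_seed(seed, {
    out <- vector("list", design$origins)
    for (o in seq_len(design$origins)) {
      z_fruit <- matrix(stats::rnorm(n_f * 4), n_f, 4) %*% L
      z_roi <- matrix(stats::rnorm(rows_per_origin * 4), rows_per_origin, 4) %*% L
      z <- sqrt(fruit_var_share) * z_fruit[rep(seq_len(n_f), each = n_r), ] +
        sqrt(1 - fruit_var_share) * z_roi
      u <- stats::pnorm(z)
      vals <- matrix(NA_real_, rows_per_origin, 4)
      lo <- c(0, 0, 0, 0)
      hi <- c(100, Inf, Inf, Inf)
      for (t in 1:4) {
        vals[, t] <- qtruncnorm(u[, t],
                                mean = params[[paste0(traits[t], "_mean")]][o],
                                sd = params[[paste0(traits[t], "_sd")]][o],
                                lo = lo[t], hi = hi[t])
      }
      out[[o]] <- data.frame(
        origin = o,
        fruit = rep(seq_len(n_f), each = n_r),
        region = rep(seq_len(n_r), times = n_f),
        mc_pct = vals[, 1], ssc_pct = vals[, 2],
        ta_gpct = vals[, 3], cc_mg100gdm = vals[, 4]
      )
    }
    ref <- do.call(rbind, out)
    rownames(ref) <- NULL
    class(ref) <- c("reference_table", "data.frame")
    ref
  })
}

#' Write / read a reference chemistry table as CSV
#'
#' Fixed header `origin,fruit,region,mc_pct,ssc_pct,ta_gpct,cc_mg100gdm`.
#'
#' @param ref a reference table data.frame.
#' @param path file path.
#' @return `read_reference_table` returns the table; `write_reference_table`
#'   returns `path` invisibly.
#' @export
write_reference_table <- function(ref, path) {
  cols <- c("origin", "fruit", "region",
            "mc_pct", "ssc_pct", "ta_gpct", "cc_mg100gdm")
  stopifnot(all(cols %in% names(ref)))
  utils::write.csv(as.data.frame(ref)[cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_reference_table
#' @export
read_reference_table <- function(path) {
  ref <- utils::read.csv(path)
  cols <- c("origin", "fruit", "region",
            "mc_pct", "ssc_pct", "ta_gpct", "cc_mg100gdm")
  missing <- setdiff(cols, names(ref))
  if (length(missing)) {
    stop("reference table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  class(ref) <- c("reference_table", "data.frame")
  ref
}

trait_columns <- function() {
  c(mc = "mc_pct", ssc = "ssc_pct", ta = "ta_gpct", cc = "cc_mg100gdm")
}
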