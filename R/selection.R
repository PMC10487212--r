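#' RReliefF feature weighting for a continuous target
#'
#' Regression Relief: for each instance, the `k_neighbors` nearest
#' instances (Manhattan distance on range-normalised features) contribute
#' rank-weighted estimates of the probabilities of a changed prediction
#' given a changed feature. Feature weights are
#' `W(f) = P(diff f | diff y) - P(diff f | same y)` in the standard
#' neighbour-counting form
#' `N_dYdF/N_dY - (N_dF - N_dYdF)/(m - N_dY)`. With
#' `n_iterations = nrow(X)` every instance is visited in order and the
#' result is deterministic (and invariant to sample order).
#'
#' @param X numeric matrix, candidate features (wavelengths) in columns.
#' @param y continuous target vector.
#' @param k_neighbors neighbours per instance (default 10).
#' @param n_iterations instances visited; default all (deterministic).
#' @param sigma rank-weighting scale of neighbour influence (default 20).
#' @param seed seed used only when `n_iterations < nrow(X)`.
#' @return data.frame `feature, weight` sorted by decreasing weight;
#'   attribute `weights` carries the unsorted named vector.
#' @export
rrelieff_rank <- function(X, y, k_neighbors = 10L, n_iterations = nrow(X),
                          sigma = 20, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (stats::sd(y) == 0) stop("constant target: RReliefF weights undefined")
  if (n < k_neighbors + 1) stop("need at least k_neighbors + 1 instances")
  rngs <- apply(X, 2, function(v) diff(range(v)))
  rngs[rngs == 0] <- 1                      # constant features: diffs are 0
  Xn <- sweep(sweep(X, 2, apply(X, 2, min)), 2, rngs, `/`)
  yr <- diff(range(y))
  yn <- (y - min(y)) / yr

  idx <- if (n_iterations >= n) seq_len(n) else
    with_seed(seed, sample.int(n, n_iterations))
  D <- as.matrix(stats::dist(Xn, method = "manhattan"))
  w_rank <- exp(-(seq_len(k_neighbors) / sigma)^2)
  w_rank <- w_rank / sum(w_rank)

  N_dY <- 0
  N_dF <- numeric(p)
  N_dYdF <- numeric(p)
  for (i in idx) {
    nb <- order(D[i, ])[2:(k_neighbors + 1)]
    dY <- abs(yn[nb] - yn[i])                       # k
    dF <- abs(Xn[nb, , drop = FALSE] -
                matrix(Xn[i, ], k_neighbors, p, byrow = TRUE))  # k x p
    N_dY <- N_dY + sum(w_rank * dY)
    N_dF <- N_dF + colSums(w_rank * dF)
    N_dYdF <- N_dYdF + colSums((w_rank * dY) * dF)
  }
  m <- length(idx)
  W <- N_dYdF / N_dY - (N_dF - N_dYdF) / (m - N_dY)
  names(W) <- colnames(X) %||% paste0("f", seq_len(p))
  out <- data.frame(feature = names(W), weight = W, row.names = NULL)
  out <- out[order(-out$weight), ]
  rownames(out) <- NULL
  attr(out, "weights") <- W
  out
}

#' Prune correlated wavelengths from a ranked list
#'
#' The ranking-and-uncorrelatedness second stage: take the `top_n`
#' best-ranked wavelengths, keep the rank-1 wavelength, drop every later
#' wavelength whose absolute Pearson correlation with it exceeds
#' `r_threshold`, advance to the next survivor and repeat, then truncate
#' the survivor list to `max_keep`.
#'
#' @param ranked character/numeric vector of wavelengths in rank order
#'   (best first), matching column names of `X`.
#' @param X spectra matrix with one column per wavelength.
#' @param y optional target used to report per-wavelength correlations.
#' @param top_n how many top-ranked wavelengths enter the loop.
#' @param r_threshold absolute-correlation removal threshold.
#' @param max_keep cap on survivors.
#' @return A `selection_result`: list with `method`, `wavelengths`,
#'   `per_wavelength_r`, `n_survivors_before_cap`.
#' @export
prune_correlated <- function(ranked, X, y = NULL, top_n = 20L,
                             r_threshold = 0.8, max_keep = 6L) {
  stopifnot(length(ranked) >= 1)
  ranked <- as.character(ranked)[seq_len(min(top_n, length(ranked)))]
  missing <- setdiff(ranked, colnames(X))
  if (length(missing)) {
    stop("ranked wavelengths absent from X: ", paste(missing, collapse = ", "))
  }
  survivors <- ranked
  i <- 1L
  while (i <= length(survivors)) {
    ref <- survivors[i]
    later <- survivors[-seq_len(i)]
    if (length(later)) {
      r <- vapply(later, function(w) {
        v <- safe_cor(X[, ref], X[, w])
        if (is.na(v)) 0 else v
      }, numeric(1))
      drop <- later[abs(r) > r_threshold]
      survivors <- setdiff(survivors, drop)
    }
    i <- i + 1L
  }
  n_before <- length(survivors)
  kept <- survivors[seq_len(min(max_keep, n_before))]
  r_y <- if (!is.null(y)) {
    vapply(kept, function(w) safe_cor(X[, w], y), numeric(1))
  } else {
    stats::setNames(rep(NA_real_, length(kept)), kept)
  }
  structure(list(method = "ranking_uncorrelatedness",
                 wavelengths = kept,
                 per_wavelength_r = r_y,
                 n_survivors_before_cap = n_before),
            class = "selection_result")
}

#' Correlation-based feature subset (CFS) merit
#'
#' `merit = k * rcf / sqrt(k + k (k - 1) * rff)` where `rcf` is the mean
#' absolute Pearson correlation between the subset's features and the
#' target and `rff` the mean absolute pairwise correlation between distinct
#' features: high individual relevance, low mutual redundancy.
#'
#' @param subset character vector of feature (wavelength) names.
#' @param X feature matrix with named columns.
#' @param y target vector.
#' @return The merit (scalar). Zero-variance features are excluded with a
#'   warning; an all-degenerate subset scores 0.
#' @export
cfs_merit <- function(subset, X, y) {
  stopifnot(length(subset) >= 1)
  sds <- apply(X[, subset, drop = FALSE], 2, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance feature(s) excluded from merit: ",
            paste(subset[sds == 0], collapse = ", "))
    subset <- subset[sds > 0]
    if (!length(subset)) return(0)
  }
  rcf <- abs(vapply(subset, function(f) stats::cor(X[, f], y), numeric(1)))
  k <- length(subset)
  rff_mean <- if (k > 1) {
    C <- abs(stats::cor(X[, subset, drop = FALSE]))
    mean(C[upper.tri(C)])
  } else 0
  k * mean(rcf) / sqrt(k + k * (k - 1) * rff_mean)
}

# merit from precomputed absolute correlation structures (fast path)
cfs_merit_cached <- function(sel, absCxy, absCxx) {
  k <- length(sel)
  if (k == 0) return(0)
  rcf <- mean(absCxy[sel])
  rff <- if (k > 1) {
    S <- absCxx[sel, sel, drop = FALSE]
    (sum(S) - k) / (k * (k - 1))
  } else 0
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

#' Best-first search over wavelength subsets by CFS merit
#'
#' Greedy hill-climbing with backtracking over the subset lattice: starting
#' from the empty set, the open list is a priority queue by merit; the best
#' unexpanded subset is expanded by single-feature additions and removals.
#' The search stops after `stale_limit` consecutive expansions that fail to
#' improve the best merit seen, and returns that best subset.
#'
#' @param candidates character vector of candidate feature names.
#' @param X feature matrix with named columns.
#' @param y target vector.
#' @param stale_limit non-improving expansions tolerated before stopping.
#' @return list with `subset` (character), `merit`, `n_expanded`.
#' @export
bestfirst_search <- function(candidates, X, y, stale_limit = 5L) {
  stopifnot(length(candidates) >= 1)
  candidates <- as.character(candidates)
  sds <- apply(X[, candidates, drop = FALSE], 2, stats::sd)
  candidates <- candidates[sds > 0]
  if (!length(candidates)) stop("no non-degenerate candidates")
  absCxy <- abs(vapply(candidates, function(f) stats::cor(X[, f], y),
                       numeric(1)))
  absCxx <- abs(stats::cor(X[, candidates, drop = FALSE]))
  p <- length(candidates)

  key_of <- function(sel) paste0("s:", paste(sort(sel), collapse = "|"))
  open_keys <- character(0); open_merit <- numeric(0)
  open_sets <- list()
  seen <- new.env(hash = TRUE, parent = emptyenv())
  push <- function(sel) {
    k <- key_of(sel)
    if (!is.null(seen[[k]])) return(invisible())
    seen[[k]] <- TRUE
    open_keys <<- c(open_keys, k)
    open_merit <<- c(open_merit, cfs_merit_cached(sel, absCxy, absCxx))
    open_sets[[length(open_sets) + 1]] <<- sel
    invisible()
  }
  push(character(0))
  best_sel <- character(0); best_merit <- 0
  stale <- 0L; expanded <- 0L
  eps <- 1e-10
  while (length(open_keys) && stale <= stale_limit) {
    i <- which.max(open_merit)
    sel <- open_sets[[i]]
    m <- open_merit[i]
    open_keys <- open_keys[-i]; open_merit <- open_merit[-i]
    open_sets[[i]] <- NULL
    expanded <- expanded + 1L
    if (m > best_merit + eps) {
      best_merit <- m; best_sel <- sel; stale <- 0L
    } else {
      stale <- stale + 1L
    }
    for (f in candidates) {
      child <- if (f %in% sel) setdiff(sel, f) else c(sel, f)
      if (length(child)) push(child)
    }
  }
  list(subset = sort(best_sel), merit = best_merit, n_expanded = expanded)
}

#' Reduce an oversize CFS subset to at most six wavelengths
#'
#' If the best-first subset has more than `max_size` members, every
#' `max_size`-member sub-subset is evaluated by CFS merit and the argmax is
#' returned (ties broken by the lexicographically smallest wavelength
#' list); otherwise the subset passes through unchanged.
#'
#' @param subset character vector from [bestfirst_search()].
#' @param X,y data used for merit evaluation.
#' @param max_size subset size cap (default 6).
#' @return A `selection_result` with `method = "subset_selection"`, the
#'   selected `wavelengths`, `per_wavelength_r` against `y`, `merit`, and
#'   `n_enumerated` sub-subsets.
#' @export
enumerate_six_member <- function(subset, X, y, max_size = 6L) {
  subset <- sort(as.character(subset))
  n_enum <- 0L
  if (length(subset) > max_size) {
    combos <- utils::combn(subset, max_size, simplify = FALSE)
    n_enum <- length(combos)
    merits <- vapply(combos, function(s) cfs_merit(s, X, y), numeric(1))
    best <- max(merits)
    tied <- which(merits >= best - 1e-12)
    if (length(tied) > 1) {
      ord <- order(vapply(combos[tied],
                          function(s) paste(sort(s), collapse = "|"),
                          character(1)))
      pick <- tied[ord[1]]
    } else pick <- tied[1]
    subset <- combos[[pick]]
    merit <- merits[pick]
  } else {
    merit <- cfs_merit(subset, X, y)
  }
  r_y <- vapply(subset, function(w) safe_cor(X[, w], y), numeric(1))
  structure(list(method = "subset_selection",
                 wavelengths = subset,
                 per_wavelength_r = r_y,
                 merit = merit,
                 n_enumerated = n_enum),
            class = "selection_result")
}

#' Select informative, commercially available wavelengths
#'
#' End-to-end wavelength selection for one trait: restrict the spectrum
#' grid to the availability-flagged candidates for the chosen modality,
#' then apply either the ranking-and-uncorrelatedness procedure (RReliefF
#' ranking, correlation pruning, at most six survivors) or the subset
#' procedure (CFS merit, best-first search, six-member enumeration).
#'
#' @param spectra fused spectra matrix (`r0420`-style column names).
#' @param y trait vector aligned with `spectra` rows.
#' @param availability an `availability_table`.
#' @param modality `"filter"` or `"light_source"`.
#' @param method `"rank"` or `"subset"`.
#' @param ... passed to [rrelieff_rank()] / [prune_correlated()] or
#'   [bestfirst_search()] / [enumerate_six_member()].
#' @return A `selection_result` with the chosen `wavelengths` (column
#'   names), numeric `wavelengths_nm`, per-wavelength correlations with the
#'   trait, and the method label.
#' @export
select_wavelengths <- function(spectra, y, availability,
                               modality = c("filter", "light_source"),
                               method = c("rank", "subset"), ...) {
  modality <- match.arg(modality)
  method <- match.arg(method)
  wl <- spectra_wavelengths(spectra)
  keep_wl <- filter_available(wl, availability, modality)
  keep <- wl %in% keep_wl
  Xc <- spectra[, keep, drop = FALSE]
  dots <- list(...)
  if (method == "rank") {
    rk_args <- dots[intersect(names(dots),
                              c("k_neighbors", "n_iterations", "sigma",
                                "seed"))]
    ranked <- do.call(rrelieff_rank, c(list(X = Xc, y = y), rk_args))
    pr_args <- dots[intersect(names(dots),
                              c("top_n", "r_threshold", "max_keep"))]
    res <- do.call(prune_correlated,
                   c(list(ranked = ranked$feature, X = Xc, y = y), pr_args))
  } else {
    bf_args <- dots[intersect(names(dots), "stale_limit")]
    bf <- do.call(bestfirst_search,
                  c(list(candidates = colnames(Xc), X = Xc, y = y), bf_args))
    en_args <- dots[intersect(names(dots), "max_size")]
    res <- do.call(enumerate_six_member,
                   c(list(subset = bf$subset, X = Xc, y = y), en_args))
  }
  res$modality <- modality
  res$wavelengths_nm <- as.numeric(sub("^r0*", "", res$wavelengths))
  res
}

#' @export
print.selection_result <- function(x, ...) {
  cat("selection_result [", x$method,
      if (!is.null(x$modality)) paste0(", ", x$modality), "]\n", sep = "")
  r <- x$per_wavelength_r
  wl <- x$wavelengths_nm %||% as.numeric(sub("^r0*", "", x$wavelengths))
  cat(paste(sprintf("%g nm (%s)", wl,
                    ifelse(is.na(r), "r n/a", sprintf("%.2f", r))),
            collapse = ", "), "\n")
  if (!is.null(x$merit)) cat("merit:", round(x$merit, 4), "\n")
  invisible(x)
}
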