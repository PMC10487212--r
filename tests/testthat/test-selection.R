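test_that("availability filtering keeps exactly the flagged wavelengths", {
  grid <- seq(420, 1600, by = 5)
  dense <- generate_availability_table("dense")
  expect_equal(filter_available(grid, dense, "filter"), grid)
  expect_equal(length(grid), 237)
  tab <- dense
  tab$available_filter[tab$wavelength == 495] <- FALSE
  expect_false(495 %in% filter_available(grid, tab, "filter"))
  expect_true(495 %in% filter_available(grid, tab, "light_source"))
  # light_source = LED union laser
  tab2 <- dense
  tab2$available_led[] <- tab2$wavelength < 1000
  tab2$available_laser[] <- tab2$wavelength %in% c(1065, 1550)
  got <- filter_available(grid, tab2, "light_source")
  expect_setequal(got, c(grid[grid < 1000], 1065, 1550))
  tab3 <- dense; tab3$available_laser[] <- FALSE; tab3$available_led[] <- FALSE
  expect_error(filter_available(grid, tab3, "light_source"), "no ")
})

test_that("availability tables round-trip and reject malformed rows", {
  tab <- generate_availability_table("sparse", seed = 3)
  expect_equal(tab$wavelength, seq(420, 1600, by = 5))
  f <- tempfile(fileext = ".csv")
  write_availability_table(tab, f)
  expect_identical(as.data.frame(read_availability_table(f)),
                   as.data.frame(tab))
  txt <- readLines(f)
  txt[5] <- sub("TRUE|FALSE", "maybe", txt[5])
  writeLines(txt, f)
  expect_error(read_availability_table(f), "line")
})

test_that("RReliefF agrees with a naive reimplementation", {
  set.seed(13)
  n <- 60
  X <- matrix(rnorm(n * 5), n, 5)
  colnames(X) <- paste0("f", 1:5)
  y <- X[, 2] + 0.3 * rnorm(n)
  got <- attr(rrelieff_rank(X, y), "weights")
  want <- naive_rrelieff(X, y)
  expect_equal(unname(got), unname(want), tolerance = 1e-12)
})

test_that("RReliefF ranks an exact copy of the target first", {
  set.seed(14)
  n <- 200
  y <- rnorm(n)
  X <- cbind(y, matrix(rnorm(n * 9), n, 9))
  colnames(X) <- c("copy", paste0("noise", 1:9))
  rk <- rrelieff_rank(X, y)
  expect_equal(rk$feature[1], "copy")
})

test_that("RReliefF degenerate inputs behave as specified", {
  set.seed(15)
  n <- 50
  X <- cbind(rnorm(n), rep(1, n)); colnames(X) <- c("a", "const")
  y <- X[, 1] + rnorm(n, 0, 0.1)
  w <- attr(rrelieff_rank(X, y), "weights")
  expect_lt(abs(w["const"]), 1e-12)
  expect_error(rrelieff_rank(X, rep(2, n)), "constant target")
  # all-instance iteration is invariant to sample order
  perm <- sample(n)
  w2 <- attr(rrelieff_rank(X[perm, ], y[perm]), "weights")
  expect_equal(w, w2, tolerance = 1e-12)
})

test_that("correlation pruning follows the survivor loop exactly", {
  set.seed(16)
  base <- rnorm(200)
  X <- cbind(A = base, B = 0.95 * base + rnorm(200, 0, 0.08),
             C = rnorm(200))
  stopifnot(abs(cor(X[, "A"], X[, "B"])) > 0.8,
            abs(cor(X[, "A"], X[, "C"])) < 0.8)
  res <- prune_correlated(c("A", "B", "C"), X)
  expect_equal(res$wavelengths, c("A", "C"))
  # all mutually uncorrelated: everything kept
  X2 <- matrix(rnorm(200 * 4), 200, 4); colnames(X2) <- letters[1:4]
  expect_equal(prune_correlated(letters[1:4], X2)$wavelengths, letters[1:4])
  # twenty identical columns collapse to the rank-1 wavelength
  X3 <- matrix(rep(base, 20), 200, 20)
  colnames(X3) <- paste0("w", 1:20)
  expect_equal(prune_correlated(colnames(X3), X3)$wavelengths, "w1")
  # survivors are capped at six
  X4 <- matrix(rnorm(200 * 10), 200, 10); colnames(X4) <- paste0("u", 1:10)
  res4 <- prune_correlated(colnames(X4), X4, max_keep = 6)
  expect_lte(length(res4$wavelengths), 6)
  expect_equal(res4$n_survivors_before_cap, 10)
})

test_that("pruning ignores candidates ranked below top_n", {
  set.seed(17)
  X <- matrix(rnorm(100 * 25), 100, 25); colnames(X) <- paste0("v", 1:25)
  r1 <- prune_correlated(paste0("v", 1:25), X, top_n = 20)
  r2 <- prune_correlated(paste0("v", 1:20), X, top_n = 20)
  expect_equal(r1$wavelengths, r2$wavelengths)
})

test_that("CFS merit matches its closed form", {
  set.seed(18)
  n <- 80
  x1 <- rnorm(n); y <- x1 + rnorm(n, 0, 0.5)
  X <- cbind(a = x1, b = x1, c = x1)
  # k = 1 reduces to |r_cf|
  expect_equal(cfs_merit("a", X, y), abs(cor(x1, y)))
  # k identical features with correlation r to y: merit stays r
  expect_equal(cfs_merit(c("a", "b", "c"), X, y), abs(cor(x1, y)),
               tolerance = 1e-12)
  # three-feature numeric case against direct evaluation
  X2 <- cbind(p = rnorm(n), q = rnorm(n), s = rnorm(n))
  y2 <- X2[, 1] - 0.5 * X2[, 2] + rnorm(n, 0, 0.3)
  rcf <- mean(abs(cor(X2, y2)))
  C <- abs(cor(X2)); rff <- mean(C[upper.tri(C)])
  want <- 3 * rcf / sqrt(3 + 3 * 2 * rff)
  expect_equal(cfs_merit(c("p", "q", "s"), X2, y2), want)
  Xz <- cbind(a = x1, z = rep(1, n))
  expect_warning(m <- cfs_merit(c("a", "z"), Xz, y), "zero-variance")
  expect_equal(m, abs(cor(x1, y)))
})

test_that("best-first search attains the exhaustive CFS maximum", {
  set.seed(19)
  for (rep in 1:5) {
    p <- sample(6:10, 1)
    n <- 50
    X <- matrix(rnorm(n * p), n, p)
    colnames(X) <- paste0("w", seq_len(p))
    beta <- rnorm(p) * rbinom(p, 1, 0.4)
    y <- X %*% beta + rnorm(n, 0, 0.8)
    bf <- bestfirst_search(colnames(X), X, y)
    subs <- unlist(lapply(seq_len(p), function(k) {
      utils::combn(colnames(X), k, simplify = FALSE)
    }), recursive = FALSE)
    best <- max(vapply(subs, function(s) cfs_merit(s, X, y), numeric(1)))
    expect_equal(bf$merit, best, tolerance = 1e-10)
  }
})

test_that("best-first isolates a single informative feature and resists
           duplicated redundancy", {
  set.seed(20)
  n <- 150
  info <- rnorm(n)
  X <- cbind(info = info, matrix(rnorm(n * 9, 0, 1), n, 9))
  colnames(X) <- c("info", paste0("noise", 1:9))
  y <- info + rnorm(n, 0, 0.2)
  bf <- bestfirst_search(colnames(X), X, y)
  expect_equal(bf$subset, "info")
  # adding an exact duplicate must not raise the achievable merit
  X2 <- cbind(X, info2 = info)
  bf2 <- bestfirst_search(colnames(X2), X2, y)
  expect_equal(bf2$merit, bf$merit, tolerance = 1e-10)
})

test_that("six-member enumeration reduces oversize subsets correctly", {
  set.seed(22)
  n <- 100
  X <- matrix(rnorm(n * 7), n, 7); colnames(X) <- paste0("w", 1:7)
  y <- rowSums(X[, 1:3]) + rnorm(n, 0, 0.5)
  r4 <- enumerate_six_member(paste0("w", 1:4), X, y)
  expect_equal(r4$wavelengths, paste0("w", 1:4))
  expect_equal(r4$n_enumerated, 0L)
  r7 <- enumerate_six_member(paste0("w", 1:7), X, y, max_size = 6)
  expect_equal(r7$n_enumerated, 7L)   # C(7, 6)
  expect_equal(length(r7$wavelengths), 6)
  combos <- utils::combn(paste0("w", 1:7), 6, simplify = FALSE)
  merits <- vapply(combos, function(s) cfs_merit(s, X, y), numeric(1))
  expect_gte(r7$merit + 1e-12, max(merits))
})

test_that("both procedures are deterministic given data and config", {
  ref <- generate_reference_table(seed = 6)
  sp <- make_roi_spectra(ref, controlled_optics(), seed = 2)
  avail <- generate_availability_table("dense")
  a <- select_wavelengths(sp, ref$mc_pct, avail, "filter", "rank")
  b <- select_wavelengths(sp, ref$mc_pct, avail, "filter", "rank")
  expect_identical(a$wavelengths, b$wavelengths)
  c1 <- select_wavelengths(sp, ref$cc_mg100gdm, avail, "filter", "subset")
  c2 <- select_wavelengths(sp, ref$cc_mg100gdm, avail, "filter", "subset")
  expect_identical(c1$wavelengths, c2$wavelengths)
  expect_equal(c1$merit, c2$merit)
})
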