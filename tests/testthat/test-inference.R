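# Group-level inference: F maps, ANCOVA, permutation FWE, effect sizes,
# and ERP summaries.

make_betas <- function(B, rg) {
  lapply(seq_len(nrow(B)), function(i)
    fake_beta_map(B[i, ], rg$grid, rg$mask))
}

test_that("one-sample F equals the squared t.test statistic", {
  set.seed(11)
  rg <- rect_grid_mask(4, 4, 5)
  n <- 12; nv <- 16 * 5
  B <- matrix(rnorm(n * nv, mean = 0.2), n, nv)
  map <- one_sample_F(make_betas(B, rg))
  expect_equal(map$df, c(1, n - 1))
  for (j in c(1, 17, 80)) {
    tt <- t.test(B[, j])
    expect_equal(map$stat[j], unname(tt$statistic)^2, tolerance = 1e-10)
  }
  # zero-variance voxel -> +Inf sentinel, recorded in provenance
  B2 <- B; B2[, 3] <- 1; B2[, 4] <- 0
  map2 <- one_sample_F(make_betas(B2, rg))
  expect_identical(map2$stat[3], Inf)
  expect_identical(map2$stat[4], 0)
  expect_equal(map2$provenance$n_infinite, 1)
  expect_error(one_sample_F(make_betas(B[1:2, , drop = FALSE], rg)), "3")
})

test_that("null one-sample F statistics follow F(1, n-1)", {
  set.seed(21)
  rg <- rect_grid_mask(8, 8, 30)
  n <- 23; nv <- 8 * 8 * 30
  B <- matrix(rnorm(n * nv), n, nv)
  map <- one_sample_F(make_betas(B, rg))
  ks <- suppressWarnings(
    ks.test(map$stat, function(q) pf(q, 1, n - 1)))
  expect_gt(ks$p.value, 0.01)
  # upper tail: fraction above the 0.001 quantile is near 0.001
  thr <- qf(0.999, 1, n - 1)
  expect_lt(abs(mean(map$stat > thr) - 0.001),
            3 * sqrt(0.001 * 0.999 / nv) + 1e-4)
})

test_that("group difference matches the pooled t.test oracle and is antisymmetric", {
  set.seed(31)
  rg <- rect_grid_mask(4, 4, 4)
  nv <- 64
  A <- matrix(rnorm(10 * nv, 0.5), 10, nv)
  B <- matrix(rnorm(14 * nv, 0.0), 14, nv)
  map <- group_difference(make_betas(A, rg), make_betas(B, rg))
  expect_equal(map$df, c(1, 22))
  for (j in c(2, 30, 64)) {
    tt <- t.test(A[, j], B[, j], var.equal = TRUE)
    expect_equal(map$t[j], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(map$stat[j], unname(tt$statistic)^2, tolerance = 1e-10)
  }
  rev_map <- group_difference(make_betas(B, rg), make_betas(A, rg))
  expect_equal(rev_map$t, -map$t, tolerance = 1e-12)
  expect_equal(rev_map$stat, map$stat, tolerance = 1e-12)
  expect_equal(map$provenance$test, "unpaired pooled-variance two-sample t")
  expect_error(group_difference(make_betas(A[1, , drop = FALSE], rg),
                                make_betas(B, rg)), "2 subjects")
})

test_that("ANCOVA slope, t and F match the per-voxel lm oracle", {
  set.seed(41)
  rg <- rect_grid_mask(4, 4, 4)
  n <- 25; nv <- 64
  des <- data.frame(sips = rnorm(n, 10, 3), age = rnorm(n, 22, 3))
  B <- matrix(rnorm(n * nv), n, nv) + outer(0.3 * des$sips, rep(1, nv))
  map <- ancova_map(make_betas(B, rg), des, "sips", nuisance = "age")
  expect_equal(map$df, c(1, n - 3))
  for (j in c(1, 33)) {
    sm <- summary(lm(B[, j] ~ des$age + des$sips))
    expect_equal(map$slope[j], unname(coef(sm)[3, 1]), tolerance = 1e-10)
    expect_equal(map$t[j], unname(coef(sm)[3, 3]), tolerance = 1e-10)
    expect_equal(map$stat[j], unname(coef(sm)[3, 3])^2, tolerance = 1e-10)
  }
  expect_error(ancova_map(make_betas(B, rg), transform(des, sips = 1), "sips"),
               "variance")
  desNA <- des; desNA$sips[2] <- NA
  expect_error(ancova_map(make_betas(B, rg), desNA, "sips"), "missing")
  expect_error(ancova_map(make_betas(B, rg), des, "height"), "height")
  expect_error(ancova_map(make_betas(B, rg), des[1:10, ], "sips"), "align")
})

test_that("identity permutations reproduce the observed statistics", {
  set.seed(51)
  rg <- rect_grid_mask(4, 4, 3)
  nv <- 48
  A <- matrix(rnorm(8 * nv), 8, nv)
  B <- matrix(rnorm(9 * nv), 9, nv)
  m1 <- one_sample_F(make_betas(A, rg))
  expect_equal(perm_stat(m1, rep(1, 8)), m1$stat, tolerance = 1e-10)
  m2 <- group_difference(make_betas(A, rg), make_betas(B, rg))
  expect_equal(perm_stat(m2, 1:17), m2$stat, tolerance = 1e-10)
  des <- data.frame(sips = rnorm(17, 10, 3))
  m3 <- ancova_map(make_betas(rbind(A, B), rg), des, "sips")
  expect_equal(perm_stat(m3, 1:17), m3$stat, tolerance = 1e-10)
})

test_that("cluster inference finds a planted cluster and is deterministic", {
  set.seed(61)
  rg <- rect_grid_mask(8, 8, 20)
  n <- 14
  dims <- c(8, 8, 20)
  arr <- array(0, dims)
  arr[3:5, 3:5, 6:12] <- 1.5            # planted block, 63 voxels
  signal <- as.numeric(arr)
  B <- matrix(rnorm(n * length(signal), sd = 1), n) +
    outer(rep(1, n), signal)
  map <- one_sample_F(make_betas(B, rg))
  cl <- cluster_inference(map, cdt_p = 0.001, n_perm = 300, seed = 5)
  expect_s3_class(cl, "cluster_result")
  expect_gt(nrow(cl), 0)
  top <- cl[1, ]
  expect_true(top$significant)
  expect_lt(top$p_cluster_fwe, 0.05)
  # the top cluster sits inside the planted block (grid coords are 10*index)
  expect_true(top$peak_x %in% (3:5 * 10))
  expect_true(top$peak_y %in% (3:5 * 10))
  expect_true(top$peak_ms >= 100 + 5 * 10 && top$peak_ms <= 100 + 11 * 10)
  expect_gte(top$extent, 40)
  cl2 <- cluster_inference(map, cdt_p = 0.001, n_perm = 300, seed = 5)
  expect_identical(cl, cl2)
  expect_warning(cluster_inference(map, n_perm = 50, seed = 1), "n_perm")
})

test_that("cluster inference under the null yields no significant clusters", {
  set.seed(71)
  rg <- rect_grid_mask(8, 8, 20)
  B <- matrix(rnorm(14 * 8 * 8 * 20), 14)
  map <- one_sample_F(make_betas(B, rg))
  cl <- cluster_inference(map, cdt_p = 0.01, n_perm = 300, seed = 9)
  if (nrow(cl) > 0) {
    expect_true(all(!cl$significant))
    expect_true(all(cl$p_cluster_fwe > 0.05))
  }
  # an all-zero map has no suprathreshold voxels at all
  map0 <- one_sample_F(make_betas(matrix(0, 5, 8 * 8 * 20), rg))
  cl0 <- cluster_inference(map0, n_perm = 100, seed = 1)
  expect_equal(nrow(cl0), 0)
})

test_that("connectivity changes cluster granularity as expected", {
  rg <- rect_grid_mask(6, 6, 6)
  n <- 10
  dims <- c(6, 6, 6)
  arr <- array(0, dims)
  arr[2, 2, 2] <- 3; arr[3, 3, 3] <- 3   # diagonal neighbours only
  # exact zeros off-signal: the zero-variance sentinel keeps them subthreshold
  B <- outer(rep(1, n), as.numeric(arr))
  sig <- which(as.numeric(arr) > 0)
  B[, sig] <- B[, sig] + matrix(rnorm(n * length(sig), sd = 0.01), n)
  map <- one_sample_F(make_betas(B, rg))
  cl6 <- cluster_inference(map, cdt_p = 0.001, n_perm = 100, seed = 3,
                           connectivity = 6)
  cl26 <- cluster_inference(map, cdt_p = 0.001, n_perm = 100, seed = 3,
                            connectivity = 26)
  expect_equal(nrow(cl6), 2)
  expect_equal(nrow(cl26), 1)
  expect_equal(cl26$extent[1], 2)
})

test_that("effect-size conversion is exact and monotone", {
  r <- cohen_f2(29, 1, 29)
  expect_equal(r$eta2_p, 0.5)
  expect_equal(r$f2, 1.0)
  expect_equal(cohen_f2(0, 1, 20)$f2, 0)
  f2s <- vapply(c(1, 5, 10, 50), function(F) cohen_f2(F, 1, 30)$f2, 0)
  expect_true(all(diff(f2s) > 0))
  # f2 = F * df1 / df2 algebraically
  expect_equal(cohen_f2(7, 2, 21)$f2, 7 * 2 / 21, tolerance = 1e-12)
  expect_error(cohen_f2(3, 1, 0), "df2")
  expect_error(cohen_f2(-1, 1, 10), "non-negative")
})

test_that("quantile split selects extreme trials and recovers planted effects", {
  ep <- make_epochs(1000)
  r <- seq_len(1000) / 100
  # amplitude at Fz proportional to the regressor
  fz <- which(ep$channels$name == "Fz")
  ep$data[, fz, ] <- r
  sp <- quantile_split_erp(ep, r, q = 0.15, electrodes = c("Fz", "Cz"))
  expect_equal(sp$n_side, 150)
  expect_identical(sp$low_trials, 1:150)
  expect_identical(sp$high_trials, 851:1000)
  expect_true(all(sp$high["Fz", ] > sp$low["Fz", ]))
  expect_true(all(sp$high["Cz", ] == 0))
  # q = 0.5 partitions the kept trials
  sp2 <- quantile_split_erp(ep, r, q = 0.5)
  expect_equal(sort(c(sp2$high_trials, sp2$low_trials)), 1:1000)
  # ties broken by trial order, deterministically
  sp3 <- quantile_split_erp(ep, rep(1, 1000), q = 0.1)
  expect_identical(sp3$low_trials, 1:100)
  expect_identical(sp3$high_trials, 901:1000)
  expect_error(quantile_split_erp(ep, r[1:10]), "align")
  expect_error(quantile_split_erp(ep, r, electrodes = "Oz9"), "electrode")
  # rejected trials are excluded from the split
  ep$kept[1:150] <- FALSE
  sp4 <- quantile_split_erp(ep, r, q = 0.15)
  expect_true(all(sp4$low_trials > 150))
})

test_that("classic MMN difference wave has the planted sign and magnitude", {
  tone <- rep(c(0, 0, 0, 0, 1), 40)
  ep <- make_epochs(200, tone = tone)
  fz <- which(ep$channels$name == "Fz")
  post <- ep$times >= 100 & ep$times <= 250
  # deviants more negative than standards at Fz: the mismatch negativity
  ep$data[tone == 1, fz, post] <- -2
  ep$data[tone == 0, fz, post] <- 1
  mm <- classic_mmn(ep)
  expect_equal(unname(mm$difference[fz, post]), rep(3, sum(post)))
  expect_true(all(mm$difference[fz, !post] == 0))
  expect_equal(dim(mm$difference), c(nrow(ep$channels), length(ep$times)))
  ep0 <- make_epochs(10, tone = rep(0, 10))
  expect_error(classic_mmn(ep0), "both")
})

test_that("maximum-intensity projection equals the brute-force maximum", {
  set.seed(91)
  arr <- array(rnorm(5 * 6 * 7), dim = c(5, 6, 7))
  mip <- max_intensity_projection(arr, axis = "x")
  expect_equal(dim(mip), c(6, 7))
  for (j in 1:6) for (k in 1:7)
    expect_equal(mip[j, k], max(arr[, j, k]))
  mipy <- max_intensity_projection(arr, axis = "y")
  expect_equal(mipy[2, 3], max(arr[2, , 3]))
  # stat_map input respects the scalp mask: out-of-mask lines are NA
  m <- montage_1020()
  g <- small_grid(m)
  pr <- build_projector(m, g)
  nv <- sum(pr$mask); nt <- length(g$ts)
  vals <- abs(rnorm(nv * nt))
  sm <- structure(list(stat = vals, df = c(1, 10), mask = pr$mask, grid = g,
                       n_voxels = nv, n_times = nt),
                  class = "stat_map")
  mp <- max_intensity_projection(sm)
  expect_equal(dim(mp), c(g$ny, nt))
  empty_rows <- which(colSums(pr$mask) == 0)
  if (length(empty_rows) > 0) expect_true(all(is.na(mp[empty_rows, ])))
  expect_true(all(mp[colSums(pr$mask) > 0, ] > 0))
})

test_that("cluster tables round-trip through TSV", {
  rg <- rect_grid_mask(6, 6, 6)
  n <- 8
  arr <- array(0, c(6, 6, 6)); arr[2:3, 2:3, 2:3] <- 2
  B <- matrix(rnorm(n * 216, sd = 0.5), n) + outer(rep(1, n), as.numeric(arr))
  map <- one_sample_F(make_betas(B, rg))
  cl <- cluster_inference(map, cdt_p = 0.01, n_perm = 100, seed = 2)
  f <- tempfile(fileext = ".tsv")
  write_cluster_table(cl, f)
  back <- read.delim(f)
  expect_equal(nrow(back), nrow(cl))
  expect_equal(back$extent, cl$extent)
  expect_equal(back$p_cluster_fwe, cl$p_cluster_fwe, tolerance = 1e-9)
})
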