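test_that("rasterized annulus matches per-pixel point-in-annulus oracle", {
  n <- 32; ctr <- c(15.5, 15.5)
  tc <- 2 * pi * (0:63) / 64
  endo <- cbind(ctr[1] + 5 * cos(tc), ctr[2] + 5 * sin(tc))
  epi <- cbind(ctr[1] + 10 * cos(tc), ctr[2] + 10 * sin(tc))
  mask <- rasterize_myocardium(endo, epi, c(n, n))
  # oracle: pixel-centre distance against the same polygons' radii; keep a
  # guard band around the radii where polygon-vs-circle flattening matters
  xg <- matrix(rep(0:(n - 1), each = n), n, n)
  yg <- matrix(rep(0:(n - 1), times = n), n, n)
  r <- sqrt((xg - ctr[1])^2 + (yg - ctr[2])^2)
  # polygon radius varies between r*cos(pi/64) and r; use exact bounds
  inner_lo <- 5 * cos(pi / 64); outer_lo <- 10 * cos(pi / 64)
  definite <- (r > 5 & r < outer_lo) # certainly inside for both shapes
  expect_true(all(mask[definite]))
  definite_out <- r < inner_lo | r > 10
  expect_true(!any(mask[definite_out]))
  # total count equals brute-force polygon containment
  expect_equal(sum(mask), sum(pracma::inpolygon(xg, yg, epi[, 1], epi[, 2]) &
                              !pracma::inpolygon(xg, yg, endo[, 1], endo[, 2])))
})

test_that("rasterization is translation-equivariant and rejects crossings", {
  tc <- 2 * pi * (0:31) / 32
  endo <- cbind(12 + 4 * cos(tc), 12 + 4 * sin(tc))
  epi <- cbind(12 + 8 * cos(tc), 12 + 8 * sin(tc))
  m1 <- rasterize_myocardium(endo, epi, c(32, 32))
  m2 <- rasterize_myocardium(endo + 3, epi + 3, c(32, 32))
  expect_identical(m2[4:32, 4:32], m1[1:29, 1:29])
  # crossing contours: endo sticking out of epi
  endo_bad <- cbind(12 + 10 * cos(tc), 12 + 4 * sin(tc))
  expect_error(rasterize_myocardium(endo_bad, epi, c(32, 32)), "cross")
})

test_that("a constant annulus unwraps to an exactly constant map", {
  sl <- make_annulus_slice(value_fun = function(r, th) 1100)
  u <- unwrap_slice(sl)
  expect_equal(dim(u), c(32, 192))
  expect_true(all(abs(u - 1100) < 1e-9))
})

test_that("angular ramp is recovered column by column", {
  # T1 = 1000 + clockwise angle (deg) from the landmark; landmark at pi/2
  sl <- make_annulus_slice(n = 96, r_endo = 14, r_epi = 24,
    value_fun = function(r, th) 1000 + (((th - pi / 2) %% (2 * pi)) * 180 / pi))
  u <- unwrap_slice(sl)
  col_means <- colMeans(u)
  expected <- 1000 + 360 * (seq_len(192) - 0.5) / 192
  # interior columns (away from the 0/360 wrap) track the analytic ramp
  interior <- 3:190
  expect_lt(max(abs(col_means[interior] - expected[interior])), 4)
  # each column is approximately constant
  expect_lt(max(apply(u[, interior], 2, sd)), 4)
})

test_that("unwrapped mean matches the mask mean within 1% on smooth phantoms", {
  sl <- make_annulus_slice(n = 96, r_endo = 14, r_epi = 24,
    value_fun = function(r, th) 1050 + 3 * r + 20 * sin(th))
  u <- unwrap_slice(sl)
  mask <- rasterize_myocardium(sl$endo, sl$epi, dim(sl$values))
  v <- sl$values[mask]
  expect_lt(abs(mean(u) - mean(v[v != 0])) / mean(v[v != 0]), 0.01)
})

test_that("landmark rotation circularly shifts the output columns", {
  vf <- function(r, th) 1000 + 100 * sin(th) + 4 * r
  sl <- make_annulus_slice(n = 96, r_endo = 14, r_epi = 24, value_fun = vf)
  u0 <- unwrap_slice(sl)
  k <- 24   # shift landmark by 24 angular steps (of 192), clockwise
  sl2 <- sl
  lm_th <- pi / 2 + 2 * pi * k / 192
  ctr <- c((96 - 1) / 2, (96 - 1) / 2)
  sl2$landmark <- c(x = ctr[1] + 24 * cos(lm_th), y = ctr[2] + 24 * sin(lm_th))
  u1 <- unwrap_slice(sl2)
  # column c of the shifted map equals column c + k of the original
  expect_equal(u1[, 1:(192 - k)], u0[, (k + 1):192], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(u1[, (192 - k + 1):192], u0[, 1:k], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("radially increasing T1 gives nondecreasing columns (endo at row 1)", {
  sl <- make_annulus_slice(n = 96, r_endo = 14, r_epi = 24,
    value_fun = function(r, th) 1000 + 10 * r)
  u <- unwrap_slice(sl)
  diffs <- apply(u, 2, diff)
  expect_true(all(diffs > -0.3))          # monotone up to interpolation jitter
  expect_true(mean(u[32, ]) > mean(u[1, ]))
})

test_that("R64 maps down-average to R32 maps on smooth phantoms", {
  sl <- make_annulus_slice(n = 96, r_endo = 14, r_epi = 24,
    value_fun = function(r, th) 1050 + 4 * r + 30 * sin(2 * th))
  u32 <- unwrap_slice(sl, unwrap_config(preset = "R32"))
  u64 <- unwrap_slice(sl, unwrap_config(preset = "R64"))
  down <- 0.25 * (u64[seq(1, 63, 2), seq(1, 383, 2)] +
                  u64[seq(2, 64, 2), seq(1, 383, 2)] +
                  u64[seq(1, 63, 2), seq(2, 384, 2)] +
                  u64[seq(2, 64, 2), seq(2, 384, 2)])
  expect_lt(mean(abs(down - unclass(u32))), 1)
})

test_that("stacking checks shapes and preserves values", {
  maps <- lapply(1:5, function(i)
    structure(matrix(i, 32, 192), class = c("rect_map", "matrix")))
  st <- stack_subject(maps)
  expect_equal(dim(st), c(160, 192))
  expect_true(all(st[1:32, ] == 1))
  expect_true(all(st[129:160, ] == 5))
  expect_error(stack_subject(maps[1:4]), "expected 5")
  maps[[3]] <- structure(matrix(0, 16, 96), class = c("rect_map", "matrix"))
  expect_error(stack_subject(maps), "mixed shapes")
  # R16 preset shape arithmetic
  s <- generate_subject("control", seed = 2)
  st16 <- unwrap_subject(s, unwrap_config(preset = "R16"))
  expect_equal(dim(st16), c(80, 96))
})

test_that("global and segmental T1 localize a single elevated sextant", {
  sl <- make_annulus_slice(value_fun = function(r, th) 1100)
  u_cols <- 192
  # elevate the first sextant clockwise from the landmark by +100 ms
  sl_el <- make_annulus_slice(value_fun = function(r, th) {
    ang <- (th - pi / 2) %% (2 * pi)
    1100 + 100 * (ang < pi / 3)
  })
  subj <- structure(list(subject_id = "x", cohort = "control", seed = 0,
                         slices = rep(list(sl), 5)), class = "t1_subject")
  gs <- global_segmental_t1(subj)
  expect_equal(gs$global, 1100)
  expect_equal(unname(gs$segmental), rep(1100, 30))
  subj$slices[[1]] <- sl_el
  gs2 <- global_segmental_t1(subj)
  seg1 <- gs2$segmental[1:6]
  expect_gt(seg1[1], 1195)              # elevated sextant
  expect_lt(max(seg1[3:5]), 1105)       # far segments unaffected
})
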