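test_that("spatial Gaussian kernel has the right support, mass and symmetry", {
  k <- make_spatial_gaussian(9, truncate = 3)
  expect_equal(dim(k), c(55, 55))
  expect_equal(sum(k), 1, tolerance = 1e-12)
  expect_equal(k, t(k))                         # k(x,y) = k(y,x)
  expect_equal(k, k[55:1, 55:1])                # k(x,y) = k(-x,-y)
  expect_error(make_spatial_gaussian(0), "rho_std")

  # sub-pixel std behaves like a discrete delta: filtering a static stack
  # (temporal box-2 is then the identity too) changes essentially nothing
  f <- st_filter(rho_std = 0.25, phi_size = 2, mode = "LL")
  stk <- make_integer_stack(7, H = 12L, W = 12L, T = 4L)
  static <- frame_stack(array(stk$frames[, , 1], dim = c(12, 12, 4)), 25)
  expect_equal(apply_separable(static, f)$frames, static$frames, tolerance = 2e-3)
})

test_that("temporal low-pass kernels are normalized and shaped as specified", {
  expect_equal(make_temporal_lowpass("box", 2), c(0.5, 0.5))
  expect_equal(make_temporal_lowpass("box", 8), rep(0.125, 8))
  g <- make_temporal_lowpass("gaussian", 8)
  expect_equal(sum(g), 1, tolerance = 1e-12)
  expect_equal(g, rev(g))                       # symmetric
  expect_true(all(diff(g[1:4]) > 0))            # unimodal rise to centre
  expect_error(make_temporal_lowpass("box", 1), "size")
})

test_that("psi is the zero-padded derivative of phi", {
  psi2 <- make_temporal_highpass(c(0.5, 0.5))
  expect_equal(psi2, c(0.25, -0.25))            # antisymmetric pair, c > 0
  for (size in c(2, 5, 8, 13)) {
    for (kind in c("box", "gaussian")) {
      psi <- make_temporal_highpass(make_temporal_lowpass(kind, size))
      expect_equal(sum(psi), 0, tolerance = 1e-12)
    }
  }
  # Gaussian phi: psi approximates the analytic derivative -t/s^2 g(t)
  size <- 11
  phi <- make_temporal_lowpass("gaussian", size)
  psi <- make_temporal_highpass(phi)
  xs <- seq_len(size) - (size + 1) / 2
  analytic <- -xs / (size / 4)^2 * phi
  expect_lt(max(abs(psi - analytic)[2:(size - 1)]), 0.08 * max(abs(analytic)))
})

test_that("biphasic kernel has zero mean and a single sign change after onset", {
  psi <- make_biphasic(n = 3, k = 1, support = 8)
  expect_length(psi, 17)
  expect_equal(sum(psi), 0, tolerance = 1e-12)
  # sign change of the continuous response at kt = sqrt((n+1)(n+2)) = sqrt(20)
  expect_gt(psi[4 + 1], 0)   # t = 4 < sqrt(20)
  expect_lt(psi[5 + 1], 0)   # t = 5 > sqrt(20)
  signs <- sign(psi[-1])     # t > 0
  expect_equal(sum(diff(signs[signs != 0]) != 0), 1)
  expect_error(make_biphasic(n = 0), "n must")
  expect_error(make_biphasic(n = 3, k = 1, support = 2), "support")
})

test_that("separable filtering preserves/kills DC and commutes", {
  const <- frame_stack(array(42, dim = c(10, 10, 8)), fps = 25)
  ll <- st_filter(rho_std = 1.5, phi_size = 4, mode = "LL")
  lh <- st_filter(rho_std = 1.5, phi_size = 4, mode = "LH")
  expect_equal(apply_separable(const, ll)$frames, const$frames, tolerance = 1e-9)
  expect_equal(max(abs(apply_separable(const, lh)$frames)), 0, tolerance = 1e-9)

  # spatial-then-temporal equals temporal-then-spatial
  stk <- make_integer_stack(11, H = 10L, W = 10L, T = 8L)
  a <- frozenframes:::conv_along(stk$frames, ll$rho_1d, 1L)
  a <- frozenframes:::conv_along(a, ll$rho_1d, 2L)
  a <- frozenframes:::conv_along(a, ll$phi, 3L)
  b <- frozenframes:::conv_along(stk$frames, ll$phi, 3L)
  b <- frozenframes:::conv_along(b, ll$rho_1d, 1L)
  b <- frozenframes:::conv_along(b, ll$rho_1d, 2L)
  expect_equal(a, b, tolerance = 1e-9)

  # linearity
  s1 <- make_integer_stack(12, H = 10L, W = 10L, T = 8L)
  s2 <- make_integer_stack(13, H = 10L, W = 10L, T = 8L)
  mix <- frame_stack(2 * s1$frames - 0.5 * s2$frames + 3, fps = 25)
  lin <- 2 * apply_separable(s1, ll)$frames -
    0.5 * apply_separable(s2, ll)$frames + 3
  expect_equal(apply_separable(mix, ll)$frames, lin, tolerance = 1e-9)

  expect_error(apply_separable(frame_stack(array(1, dim = c(4, 4, 2)), 25),
                               st_filter(1, phi_size = 4, mode = "LL")),
               "temporal filter size 4")
})

test_that("global luminance drift is invisible to the motion energy", {
  # f(x,y,t) = alpha * t: every frame is spatially constant, so the LH
  # response is too, and sigma_G vanishes identically
  tt <- 20
  frames <- array(rep(3.7 * seq_len(tt), each = 36), dim = c(6, 6, tt))
  stk <- frame_stack(frames, fps = 25)
  lh <- st_filter(rho_std = 1, phi_size = 4, mode = "LH")
  sigG <- spatial_std_signal(apply_separable(stk, lh), "sigma_G")
  expect_equal(max(sigG$values), 0, tolerance = 1e-9)
})
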