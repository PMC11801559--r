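test_that("local extrema match examples and a brute-force oracle", {
  p3 <- contrast_params(window = 3L)
  const <- matrix(0.4, 5, 5)
  ex <- compute_local_extrema(const, p3)
  expect_true(all(ex$local_max == 0.4) && all(ex$local_min == 0.4))

  spike <- matrix(0, 3, 3); spike[2, 2] <- 1
  ex <- compute_local_extrema(spike, p3)
  expect_true(all(ex$local_max == 1))
  expect_true(all(ex$local_min == 0))

  img <- matrix(runif(25), 5, 5)
  ex1 <- compute_local_extrema(img, contrast_params(window = 1L))
  expect_equal(ex1$local_max, img)
  expect_equal(ex1$local_min, img)

  set.seed(11)
  for (window in c(3L, 5L, 7L)) {
    x <- rand_norm_image(16, 16)
    got <- compute_local_extrema(x, contrast_params(window = window))
    want <- oracle_local_extrema(x, window)
    expect_equal(got$local_max, want$local_max)
    expect_equal(got$local_min, want$local_min)
    expect_true(all(got$local_min <= x & x <= got$local_max))
  }
})

test_that("removable factor follows beta = exp(-G var(T) / T) with eps guard", {
  params <- contrast_params(window = 3L)
  # constant image: var(T) = 0 so beta = 1 everywhere
  maps <- removable_factor(compute_local_extrema(matrix(0.4, 5, 5), params), params)
  expect_equal(maps$t_variance, 0)
  expect_true(all(maps$beta == 1))

  # hand-built extrema exercising the printed single-pixel value
  ex <- structure(list(local_max = matrix(1, 2, 2),
                       local_min = matrix(c(0.5, 0.3, 0.7, 0.5), 2, 2)),
                  class = "local_extrema")
  maps <- removable_factor(ex, params)
  expect_equal(maps$t_variance, var(c(0.5, 0.3, 0.7, 0.5)))  # n-1 denominator
  expect_equal(maps$beta[1, 1],
               exp(-1 * maps$t_variance / 0.5))
  # frozen spec example: G=1, var=0.04, T=0.5 -> exp(-0.08)
  ex2 <- structure(list(local_max = matrix(1, 2, 2),
                        local_min = matrix(0.5, 2, 2)), class = "local_extrema")
  m2 <- removable_factor(ex2, params)
  m2$t_variance <- 0.04
  beta <- exp(-ex2$local_max * 0.04 / pmax(ex2$local_min, params$eps))
  expect_equal(beta[1, 1], 0.923116, tolerance = 1e-6)

  # zero local minimum: eps guard keeps beta finite (underflows toward 0)
  ex0 <- structure(list(local_max = matrix(1, 2, 2),
                        local_min = matrix(c(0, 1, 0.5, 0.25), 2, 2)),
                   class = "local_extrema")
  m0 <- removable_factor(ex0, params)
  expect_true(all(is.finite(m0$beta)))
  expect_true(all(m0$beta > 0 | m0$beta == 0))  # no NaN/Inf
})

test_that("removable component and brightness exponent match direct evaluation", {
  params <- contrast_params(window = 3L)
  ex <- structure(list(local_max = matrix(0.8, 2, 2),
                       local_min = matrix(0.5, 2, 2)), class = "local_extrema")
  maps <- structure(list(beta = matrix(0.923116, 2, 2), t_variance = 0.04),
                    class = "attenuation_maps")
  maps <- removable_component(maps, ex)
  expect_equal(maps$removable, matrix(0.923116 * 0.5, 2, 2))
  expect_true(all(maps$removable <= ex$local_min))

  # psi example: G = 0.8, R = 0.2 -> ln(0.95)/ln(0.8)
  maps$removable <- matrix(0.2, 2, 2)
  maps <- brightness_exponent(maps, ex, params)
  expect_equal(maps$psi[1, 1], log(0.95) / log(0.8), tolerance = 1e-12)
  expect_equal(maps$psi[1, 1], 0.229867, tolerance = 1e-6)

  # R = 0 with G < 1 gives psi = 0; G = 1 gives psi = 1 by convention
  maps$removable <- matrix(0, 2, 2)
  expect_true(all(brightness_exponent(maps, ex, params)$psi == 0))
  ex1 <- structure(list(local_max = matrix(1, 2, 2),
                        local_min = matrix(0.5, 2, 2)), class = "local_extrema")
  maps$removable <- matrix(0.2, 2, 2)
  expect_true(all(brightness_exponent(maps, ex1, params)$psi == 1))
})

test_that("contrast stretch matches the worked example and stated clamps", {
  params <- contrast_params(window = 3L)
  ex <- structure(list(local_max = matrix(0.8, 2, 2),
                       local_min = matrix(0.5, 2, 2)), class = "local_extrema")
  maps <- structure(list(beta = matrix(1, 2, 2), t_variance = 0,
                         removable = matrix(0.2, 2, 2),
                         psi = matrix(log(0.95) / log(0.8), 2, 2)),
                    class = "attenuation_maps")
  e <- apply_contrast_enhancement(matrix(0.6, 2, 2), ex, maps, params)
  expect_equal(e[1, 1], 0.4 / 0.75, tolerance = 1e-9)  # 0.533333

  # identity limit: removable 0 and psi 0 reproduce the input
  img <- matrix(runif(16), 4, 4)
  maps0 <- structure(list(beta = matrix(0, 4, 4), t_variance = 0,
                          removable = matrix(0, 4, 4), psi = matrix(0, 4, 4)),
                     class = "attenuation_maps")
  ex0 <- structure(list(local_max = matrix(0.9, 4, 4),
                        local_min = matrix(0.1, 4, 4)), class = "local_extrema")
  expect_equal(apply_contrast_enhancement(img, ex0, maps0, params), img,
               tolerance = 1e-12)
})

test_that("contrast stage: range, identity limit, fixed/zero points, monotonicity", {
  set.seed(5)
  for (rep in 1:5) {
    img <- rand_norm_image(24, 24)
    res <- run_contrast_stage(img, contrast_params(window = 7L))
    expect_true(all(is.finite(res$enhanced)))
    expect_true(all(res$enhanced >= 0 & res$enhanced <= 1))

    # fixed point: where I = G the output equals G
    at_max <- which(img == res$extrema$local_max)
    expect_equal(res$enhanced[at_max], res$extrema$local_max[at_max],
                 tolerance = 1e-9)

    # zero point: where I = R (synthetically) the stretch yields 0
    maps <- res$maps; ex <- res$extrema
    probe <- maps$removable
    e0 <- apply_contrast_enhancement(probe, ex, maps, contrast_params(window = 7L))
    interior <- ex$local_max^maps$psi - maps$removable >= 1e-6
    expect_true(all(e0[interior] == 0))
  }

  # monotonicity in I for fixed G, R, psi on [R, G]
  params <- contrast_params(window = 3L)
  ex <- structure(list(local_max = matrix(0.9, 1, 50),
                       local_min = matrix(0.2, 1, 50)), class = "local_extrema")
  maps <- structure(list(beta = matrix(1, 1, 50), t_variance = 0.01,
                         removable = matrix(0.15, 1, 50),
                         psi = matrix(0.3, 1, 50)), class = "attenuation_maps")
  grid <- matrix(seq(0.15, 0.9, length.out = 50), 1, 50)
  e <- apply_contrast_enhancement(grid, ex, maps, params)
  expect_true(all(diff(as.vector(e)) > 0))

  # degenerate constant image passes through under the default policy
  const <- matrix(0.4, 8, 8)
  expect_equal(run_contrast_stage(const, contrast_params(window = 3L))$enhanced,
               const)
  # ...and zeroes under the zero policy
  pz <- contrast_params(window = 3L, degenerate_policy = "zero")
  expect_true(all(run_contrast_stage(const, pz)$enhanced == 0))

  # window 1: extrema equal the image, t_variance is the image variance
  img <- rand_norm_image(6, 6)
  r1 <- run_contrast_stage(img, contrast_params(window = 1L))
  expect_equal(r1$extrema$local_max, img)
  expect_equal(r1$maps$t_variance, var(as.vector(img)))
  expect_true(all(r1$enhanced >= 0 & r1$enhanced <= 1))
})
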