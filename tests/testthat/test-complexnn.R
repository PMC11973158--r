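test_that("impulse kernels act as complex scalars", {
  set.seed(1)
  x <- rand_cplx(6)
  w_id <- array(0i, c(3, 3, 1, 1)); w_id[2, 2, 1, 1] <- 1 + 0i
  expect_equal(complex_conv2d(x, w_id), x, tolerance = 1e-12)
  w_i <- array(0i, c(3, 3, 1, 1)); w_i[2, 2, 1, 1] <- 0 + 1i
  out <- complex_conv2d(x, w_i)
  expect_equal(Re(out), -Im(x), tolerance = 1e-12)
  expect_equal(Im(out), Re(x), tolerance = 1e-12)
})

test_that("complex convolution matches the direct multiply-accumulate oracle", {
  set.seed(2)
  for (trial in 1:3) {
    cin <- sample(1:3, 1); cout <- sample(1:3, 1)
    x <- array(complex(real = rnorm(4 * 4 * cin), imaginary = rnorm(4 * 4 * cin)),
               c(4, 4, cin))
    w <- array(complex(real = rnorm(9 * cin * cout), imaginary = rnorm(9 * cin * cout)),
               c(3, 3, cin, cout))
    b <- complex(real = rnorm(cout), imaginary = rnorm(cout))
    expect_equal(complex_conv2d(x, w, bias = b), oracle_complex_conv(x, w, b),
                 tolerance = 1e-6)
  }
})

test_that("component form and stacked matrix form agree", {
  set.seed(3)
  x <- array(complex(real = rnorm(8 * 8 * 2), imaginary = rnorm(8 * 8 * 2)), c(8, 8, 2))
  w <- array(complex(real = rnorm(9 * 2 * 3), imaginary = rnorm(9 * 2 * 3)), c(3, 3, 2, 3))
  b <- complex(real = rnorm(3), imaginary = rnorm(3))
  expect_equal(complex_conv2d(x, w, b, method = "component"),
               complex_conv2d(x, w, b, method = "matrix"), tolerance = 1e-7)
})

test_that("complex convolution is linear in input and kernel", {
  set.seed(4)
  x1 <- rand_cplx(5); x2 <- rand_cplx(5)
  w1 <- array(complex(real = rnorm(9), imaginary = rnorm(9)), c(3, 3, 1, 1))
  w2 <- array(complex(real = rnorm(9), imaginary = rnorm(9)), c(3, 3, 1, 1))
  a <- 0.7 - 1.2i
  expect_equal(complex_conv2d(x1 + a * x2, w1),
               complex_conv2d(x1, w1) + a * complex_conv2d(x2, w1),
               tolerance = 1e-10)
  expect_equal(complex_conv2d(x1, w1 + a * w2),
               complex_conv2d(x1, w1) + a * complex_conv2d(x1, w2),
               tolerance = 1e-10)
})

test_that("channel mismatches are rejected", {
  x <- array(0i, c(4, 4, 2))
  w <- array(0i, c(3, 3, 3, 1))
  expect_error(complex_conv2d(x, w), "channel mismatch")
})

test_that("split rectifier definition and idempotence", {
  expect_equal(complex_activation(-1 - 1i), 0 + 0i)
  expect_equal(complex_activation(2 + 3i), 2 + 3i)
  expect_equal(complex_activation(-1 + 2i), 0 + 2i)
  set.seed(5)
  x <- rand_cplx(6)
  expect_identical(complex_activation(complex_activation(x)), complex_activation(x))
  xp <- matrix(complex(real = abs(Re(x)), imaginary = abs(Im(x))), 6, 6)
  expect_identical(complex_activation(xp), xp)
})

test_that("complex L1 loss matches hand evaluations and its invariances", {
  expect_equal(complex_l1_loss(matrix(0 + 0i), matrix(1 + 1i)), 2.0)
  expect_equal(complex_l1_loss(matrix(c(0 + 0i, 0 + 0i), 1),
                               matrix(c(3 + 4i, -1 + 0i), 1)), 4.0)
  set.seed(6)
  y <- rand_cplx(5); y_hat <- rand_cplx(5)
  expect_equal(complex_l1_loss(y, y), 0)
  c0 <- 2.5 - 1.5i
  expect_equal(complex_l1_loss(y_hat + c0, y + c0), complex_l1_loss(y_hat, y),
               tolerance = 1e-12)
  expect_error(complex_l1_loss(rand_cplx(4), y), "shape")
  # batch list form averages over all voxels of all samples
  expect_equal(complex_l1_loss(list(matrix(0 + 0i), matrix(0 + 0i)),
                               list(matrix(3 + 4i), matrix(-1 + 0i))), 4.0)
})

test_that("convolution layer gradients match finite differences", {
  set.seed(7)
  x <- array(complex(real = rnorm(6 * 6 * 2), imaginary = rnorm(6 * 6 * 2)), c(6, 6, 2))
  w <- array(complex(real = rnorm(9 * 2 * 2), imaginary = rnorm(9 * 2 * 2)), c(3, 3, 2, 2))
  b <- complex(real = rnorm(2), imaginary = rnorm(2))
  # smooth scalar loss of the conv output
  loss_of <- function(out) sum(Re(out)^2 + Im(out)^2)
  fw <- fourierpd:::conv_fwd(x, w, b)
  gout <- 2 * fw$out
  gout <- array(complex(real = Re(gout), imaginary = Im(gout)), dim(fw$out))
  bw <- fourierpd:::conv_bwd(fw$cache, w, gout)
  eps <- 1e-6
  check <- function(getter, setter, ana) {
    idx <- sample(length(getter()), min(4, length(getter())))
    for (el in idx) for (comp in c(1, 1i)) {
      vp <- getter(); vp[el] <- vp[el] + eps * comp
      vm <- getter(); vm[el] <- vm[el] - eps * comp
      num <- (loss_of(setter(vp)) - loss_of(setter(vm))) / (2 * eps)
      a <- if (comp == 1) Re(ana[el]) else Im(ana[el])
      expect_equal(num, a, tolerance = 1e-4)
    }
  }
  check(function() w, function(v) fourierpd:::conv_fwd(x, v, b)$out, bw$gw)
  check(function() b, function(v) fourierpd:::conv_fwd(x, w, v)$out, bw$gb)
  check(function() x, function(v) fourierpd:::conv_fwd(v, w, b)$out, bw$gx)
})

test_that("kernel initialisation scale follows complex fan-in/fan-out", {
  set.seed(8)
  w <- init_complex_kernel(3, 3, 16, 16)
  target <- sqrt(1 / (9 * 16 + 9 * 16))
  expect_equal(stats::sd(Re(w)), target, tolerance = 0.05)
  expect_equal(stats::sd(Im(w)), target, tolerance = 0.05)
})
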