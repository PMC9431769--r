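## direct sliding-window oracle for the stride-2, kernel-5, "same"
## convolution (pad 1 before / 2 after in each spatial dimension)
naiveConv <- function(x, W, b, outC) {
  d <- dim(x)
  H <- d[1]; Wd <- d[2]; inC <- d[3]; N <- d[4]
  Ho <- H / 2; Wo <- Wd / 2
  xp <- array(0, c(H + 3, Wd + 3, inC, N))
  xp[2:(H + 1), 2:(Wd + 1), , ] <- x
  out <- array(0, c(Ho, Wo, outC, N))
  for (n in 1:N) for (oc in 1:outC) for (oi in 0:(Ho - 1))
    for (oj in 0:(Wo - 1)) {
      acc <- b[oc]
      for (dj in 0:4) for (di in 0:4) for (cc in 1:inC) {
        o <- dj * 5 + di + 1
        acc <- acc + xp[oi * 2 + di + 1, oj * 2 + dj + 1, cc, n] *
          W[(o - 1) * inC + cc, oc]
      }
      out[oi + 1, oj + 1, oc, n] <- acc
    }
  out
}

test_that("batched im2col convolution matches the direct oracle", {
  set.seed(1)
  l <- emgGAN:::newConv(8L, 8L, 3L, 4L)
  x <- array(rnorm(8 * 8 * 3 * 5), c(8, 8, 3, 5))
  got <- emgGAN:::layerForward(l, x, TRUE)$out
  expect_equal(got, naiveConv(x, l$W, l$b, 4L), tolerance = 1e-12)
})

test_that("transposed convolution is the exact adjoint of convolution", {
  set.seed(2)
  conv <- emgGAN:::newConv(8L, 8L, 2L, 3L)     # fine 8x8x2 -> coarse 4x4x3
  tconv <- emgGAN:::newTconv(4L, 4L, 3L, 2L)   # coarse 4x4x3 -> fine 8x8x2
  tconv$W <- conv$W                            # share kernel, zero biases
  conv$b <- numeric(3)
  tconv$b <- numeric(2)
  x <- array(rnorm(8 * 8 * 2 * 3), c(8, 8, 2, 3))   # fine
  y <- array(rnorm(4 * 4 * 3 * 3), c(4, 4, 3, 3))   # coarse
  lhs <- sum(emgGAN:::layerForward(conv, x, TRUE)$out * y)
  rhs <- sum(x * emgGAN:::layerForward(tconv, y, TRUE)$out)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("backpropagation matches finite differences in every layer", {
  set.seed(9)
  net <- emgGAN:::newNet(list(
    emgGAN:::newDense(6L, 32L),
    emgGAN:::newBnDense(32L),
    emgGAN:::newAct("tanh"),
    emgGAN:::newReshape(4L, 4L, 2L),
    emgGAN:::newTconv(4L, 4L, 2L, 3L),
    emgGAN:::newAct("lrelu"),
    emgGAN:::newBnConv(3L),
    emgGAN:::newConv(8L, 8L, 3L, 2L),
    emgGAN:::newFlatten(),
    emgGAN:::newDense(32L, 1L),
    emgGAN:::newAct("sigmoid")))
  N <- 4L
  x <- matrix(rnorm(6 * N), 6, N)
  w <- rnorm(N)
  lossOf <- function(nt) sum(w * as.vector(networkForward(nt, x, TRUE)$out))
  r <- networkForward(net, x, TRUE)
  bb <- emgGAN:::netBackward(emgGAN:::zeroGrads(r$net), matrix(w, 1, N))
  h <- 1e-6
  for (li in seq_along(net$layers)) {
    l <- net$layers[[li]]
    for (p in l$params) {
      g <- bb$net$layers[[li]][[paste0("g", p)]]
      for (i in sample(length(l[[p]]), min(3, length(l[[p]])))) {
        np <- net; np$layers[[li]][[p]][i] <- l[[p]][i] + h
        nm <- net; nm$layers[[li]][[p]][i] <- l[[p]][i] - h
        gn <- (lossOf(np) - lossOf(nm)) / (2 * h)
        expect_equal(g[i], gn, tolerance = 1e-4)
      }
    }
  }
  ## gradient with respect to the input
  for (i in sample(length(x), 5)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    fp <- sum(w * as.vector(networkForward(net, xp, TRUE)$out))
    fm <- sum(w * as.vector(networkForward(net, xm, TRUE)$out))
    expect_equal(bb$dx[i], (fp - fm) / (2 * h), tolerance = 1e-4)
  }
})

test_that("network builds are seed-deterministic", {
  cfg <- ganConfig(seed = 41L)
  g1 <- buildGenerator(cfg)
  g2 <- buildGenerator(cfg)
  expect_identical(emgGAN:::netParameters(g1), emgGAN:::netParameters(g2))
  d1 <- buildDiscriminator(cfg)
  d2 <- buildDiscriminator(cfg)
  expect_identical(emgGAN:::netParameters(d1), emgGAN:::netParameters(d2))
  g3 <- buildGenerator(ganConfig(seed = 42L))
  expect_false(identical(emgGAN:::netParameters(g1),
                         emgGAN:::netParameters(g3)))
})

test_that("generator and discriminator respect their output contracts", {
  cfg <- ganConfig(seed = 13L)
  G <- buildGenerator(cfg)
  D <- buildDiscriminator(cfg)
  z0 <- matrix(0, cfg@zDim, 2)
  out0 <- networkForward(G, z0)$out
  expect_equal(dim(out0), c(64, 64, 3, 2))
  expect_true(all(out0 >= -1 & out0 <= 1))
  set.seed(1)
  z <- matrix(rnorm(cfg@zDim * 32), cfg@zDim, 32)
  out <- networkForward(G, z, train = TRUE)$out
  expect_equal(dim(out), c(64, 64, 3, 32))
  expect_true(all(out >= -1 & out <= 1))
  p <- networkForward(D, out, train = TRUE)$out
  expect_true(all(p > 0 & p < 1))
  expect_equal(dim(p), c(1, 32))
})
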