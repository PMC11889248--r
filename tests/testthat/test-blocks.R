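test_that("conv_param_count reproduces the closed forms", {
  expect_equal(conv_param_count(3, 2, 4), 72)
  expect_equal(conv_param_count(3, 48, 48), 20736)
  expect_equal(conv_param_count(3, 48, 48, decomposed = TRUE), 2736)
  expect_equal(conv_param_count(1, 5, 7, decomposed = TRUE), 5 + 35)
  expect_equal(conv_param_count(3, 8, 8, groups = 8), 72)
  expect_equal(conv_param_count(3, 2, 4, bias = TRUE), 76)
})

test_that("decomposition savings over the three transformer-stage widths", {
  # local 3x3 C->C plus fusion 3x3 2C->C, standard minus decomposed
  saving <- function(C) {
    (conv_param_count(3, C, C) - conv_param_count(3, C, C, decomposed = TRUE)) +
      (conv_param_count(3, 2 * C, C) - conv_param_count(3, 2 * C, C, decomposed = TRUE))
  }
  expect_equal(saving(48), (8 * 48^2 - 9 * 48) + (16 * 48^2 - 18 * 48))
  expect_equal(sum(vapply(c(48, 64, 80), saving, 0)), 302016)
})

test_that("decomposed_conv equals the identity factorization and the naive oracle", {
  set.seed(31)
  C <- 4
  x <- rand_fmap(C, 6, 6)
  dw <- array(0, c(C, 3, 3)); dw[, 2, 2] <- 1   # identity depthwise kernels
  expect_equal(decomposed_conv(x, dw, diag(C)), x, tolerance = 1e-12)
  for (rep in 1:8) {
    Cin <- sample(2:4, 1); Cout <- sample(2:5, 1); stride <- sample(1:2, 1)
    x <- rand_fmap(Cin, 16, 16)
    dwk <- array(rnorm(Cin * 9), c(Cin, 3, 3))
    pwk <- matrix(rnorm(Cout * Cin), Cout, Cin)
    got <- decomposed_conv(x, dwk, pwk, stride = stride)
    mid <- oracle_depthwise(x, dwk, stride = stride, pad = 1)
    ref <- oracle_conv(mid, array(pwk, c(Cout, Cin, 1, 1)), stride = 1, pad = 0)
    expect_equal(got, ref, tolerance = 1e-5)
  }
  expect_error(decomposed_conv(rand_fmap(3, 4, 4), array(0, c(2, 3, 3)),
                               diag(2)), "does not match")
})

test_that("sedd composes a strided depthwise stage with SE reweighting", {
  set.seed(32)
  C <- 8
  x <- rand_fmap(C, 32, 32)
  w <- list(depthwise = array(rnorm(C * 9, sd = 0.3), c(C, 3, 3)),
            se = list(w1 = matrix(0, 2, C), w2 = matrix(0, C, 2)))
  # zeroed SE weights: plain depthwise halved
  expect_equal(sedd(x, w), 0.5 * oracle_depthwise(x, w$depthwise),
               tolerance = 1e-6)
  y2 <- sedd(x, w, stride = 2)
  expect_equal(dim(y2), c(C, 16, 16))
  # composition with live SE weights
  w$se <- se_params(C, 4)
  mid <- oracle_depthwise(x[, 1:8, 1:8, drop = FALSE], w$depthwise)
  expect_equal(sedd(x[, 1:8, 1:8, drop = FALSE], w),
               se_block(mid, w$se), tolerance = 1e-6)
})

test_that("mv2_dd_block honours stride, shortcut and attention contracts", {
  set.seed(33)
  x <- rand_fmap(8, 16, 16)
  b1 <- new_mv2_dd(8, 8, stride = 1, attention = "se")
  y1 <- mv2_dd_block(x, b1)
  expect_equal(dim(y1), dim(x))
  expect_true(all(is.finite(y1)))
  b2 <- new_mv2_dd(8, 12, stride = 2, attention = "nam")
  y2 <- mv2_dd_block(x, b2)
  expect_equal(dim(y2), c(12, 8, 8))
  expect_error(new_mv2_dd(8, 8, stride = 3), "stride")
  expect_error(new_mv2_dd(8, 8, expansion = 0), "expansion")
})

test_that("mv2 residual shortcut dominates when the branch is zeroed", {
  set.seed(34)
  x <- rand_fmap(6, 8, 8)
  b <- new_mv2_dd(6, 6, stride = 1, attention = "none")
  # zero the projection so the branch contributes nothing
  b$children$body$children$proj$par$w[] <- 0
  b$children$body$children$projbn$par$beta[] <- 0
  y <- mv2_dd_block(x, b)
  expect_equal(y, x, tolerance = 1e-12)
})

test_that("attention inside the block only rescales branch channels", {
  set.seed(35)
  x <- rand_fmap(6, 8, 8)
  b_none <- new_mv2_dd(6, 10, stride = 2, attention = "none")
  b_se <- new_mv2_dd(6, 10, stride = 2, attention = "se")
  # share every common weight so the two blocks differ only by SE
  for (nm in c("expand", "dw", "dwbn", "proj", "projbn")) {
    b_se$children$body$children[[nm]]$par <-
      b_none$children$body$children[[nm]]$par
  }
  pre_none <- x
  pre_se <- x
  ch_n <- b_none$children$body$children
  ch_s <- b_se$children$body$children
  for (nm in c("expand", "dw", "dwbn", "dwact")) {
    pre_none <- mnvit:::mod_fwd(ch_n[[nm]], if (nm == "expand") mnvit:::.batch1(pre_none) else pre_none, training = TRUE)
    pre_se <- mnvit:::mod_fwd(ch_s[[nm]], if (nm == "expand") mnvit:::.batch1(pre_se) else pre_se, training = TRUE)
  }
  att_out <- mnvit:::mod_fwd(ch_s$att, pre_se, training = TRUE)
  ratio <- att_out / pre_se
  # per-channel scaling factors strictly inside (0, 1)
  for (c in seq_len(dim(ratio)[1])) {
    rc <- ratio[c, , , ]
    expect_lt(max(abs(rc - rc[1])), 1e-8)
    expect_true(rc[1] > 0 && rc[1] < 1)
  }
})

test_that("mobilevit_block_dd preserves shape across configurations", {
  set.seed(36)
  x <- rand_fmap(8, 8, 8)
  for (att in c("none", "se", "nam")) for (dec in c(TRUE, FALSE)) {
    b <- new_mobilevit_dd(8, 12, depth = 1, heads = 2, decomposed = dec,
                          attention = att)
    y <- mobilevit_block_dd(x, b)
    expect_equal(dim(y), dim(x))
    expect_true(all(is.finite(y)))
  }
  b <- new_mobilevit_dd(8, 12, depth = 1, heads = 2)
  expect_error(mobilevit_block_dd(rand_fmap(8, 5, 6), b), "does not divide")
})

test_that("block structure follows the decomposition and attention flags", {
  std <- new_mobilevit_dd(8, 12, depth = 2, heads = 2, decomposed = FALSE,
                          attention = "none")
  # standard form: one 3x3 conv in local rep, one 3x3 conv in fusion
  expect_equal(dim(std$children$local$children$conv$par$w), c(8, 8, 3, 3))
  expect_equal(dim(std$children$fusion$children$conv$par$w), c(8, 16, 3, 3))
  expect_null(std$children$att)
  dd <- new_mobilevit_dd(8, 12, depth = 2, heads = 2, decomposed = TRUE,
                         attention = "nam")
  expect_equal(dim(dd$children$local$children$dw$par$w), c(8, 1, 3, 3))
  expect_equal(dim(dd$children$local$children$pw$par$w), c(8, 8, 1, 1))
  expect_equal(dd$children$att$kind, "nam")
  expect_length(std$children$transformer$children, 2L)
})

test_that("block parameter counts match the closed-form audit", {
  C <- 48L
  std <- new_mobilevit_dd(C, 64, depth = 2, decomposed = FALSE, attention = "none")
  dd <- new_mobilevit_dd(C, 64, depth = 2, decomposed = TRUE, attention = "none")
  expect_equal(count_parameters(std) - count_parameters(dd),
               (8 * C^2 - 9 * C) + (16 * C^2 - 18 * C))
  # depthwise + pointwise stage alone
  expect_equal(sum(lengths(dd$children$local$children$dw$par)) +
                 sum(lengths(dd$children$local$children$pw$par)),
               conv_param_count(3, C, C, decomposed = TRUE))
})

test_that("attention can sit before or after the local convolution", {
  set.seed(37)
  x <- rand_fmap(8, 8, 8)
  b_pre <- new_mobilevit_dd(8, 12, depth = 1, heads = 2, attention = "nam",
                            attention_first = TRUE)
  b_post <- new_mobilevit_dd(8, 12, depth = 1, heads = 2, attention = "nam",
                             attention_first = FALSE)
  # share all weights; only the placement differs
  mnvit:::assign_params(b_post, mnvit:::collect_params(b_pre, buffers = TRUE))
  y_pre <- mobilevit_block_dd(x, b_pre)
  y_post <- mobilevit_block_dd(x, b_post)
  expect_equal(dim(y_pre), dim(x))
  expect_equal(dim(y_post), dim(x))
  expect_false(isTRUE(all.equal(y_pre, y_post)))
})
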