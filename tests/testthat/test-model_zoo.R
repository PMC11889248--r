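test_that("forward pass yields finite logits of the declared shape", {
  set.seed(41)
  m <- build_model("MV2_SE_Mb_NAM", seed = 5, num_classes = 2, input_size = 64)
  x <- array(rnorm(3 * 64 * 64 * 2), c(3, 64, 64, 2))
  lg <- model_forward(m, x, training = TRUE)
  expect_equal(dim(lg), c(2L, 2L))
  expect_true(all(is.finite(lg)))
  lg2 <- model_forward(m, x, training = FALSE)
  expect_equal(dim(lg2), c(2L, 2L))
  expect_true(all(is.finite(lg2)))
})

test_that("attention placement follows the preset", {
  m <- build_model("MV2_SE_Mb_NAM", seed = 1, num_classes = 2, input_size = 64)
  kinds <- character(); paths <- character()
  mnvit:::walk_modules(m$net, function(mod, path) {
    if (mod$kind %in% c("se", "nam")) {
      kinds <<- c(kinds, mod$kind); paths <<- c(paths, path)
    }
  })
  se_paths <- paths[kinds == "se"]
  nam_paths <- paths[kinds == "nam"]
  # SE only inside MV2 blocks, NAM only inside MobileViT local representations
  expect_true(all(grepl("mv2_", se_paths)))
  expect_false(any(grepl("vit", se_paths)))
  expect_true(all(grepl("vit", nam_paths)))
  expect_length(se_paths, 7L)   # one per inverted-residual block
  expect_length(nam_paths, 3L)  # one per MobileViT stage
})

test_that("tr1/tr3 presets differ from their parent only in encoder depth", {
  p <- mn_presets(c("MV2_SE", "MV2_SE_Mb_tr1", "MV2_SE_Mb_tr3"))
  base <- p$MV2_SE; tr1 <- p$MV2_SE_Mb_tr1; tr3 <- p$MV2_SE_Mb_tr3
  for (f in setdiff(names(base), c("name", "transformer_depths"))) {
    expect_identical(tr1[[f]], base[[f]])
    expect_identical(tr3[[f]], base[[f]])
  }
  expect_equal(tr1$transformer_depths, c(1L, 1L, 1L))
  expect_equal(tr3$transformer_depths, c(3L, 3L, 3L))
  m1 <- build_model(tr1, seed = 1)
  m3 <- build_model(tr3, seed = 1)
  depth_of <- function(m, stage)
    length(m$net$children[[stage]]$children$vit$children$transformer$children)
  for (st in c("stage3", "stage4", "stage5")) {
    expect_equal(depth_of(m1, st), 1L)
    expect_equal(depth_of(m3, st), 3L)
  }
  expect_lt(count_parameters(m1), count_parameters(m3))
})

test_that("count_parameters equals a brute-force enumeration of all arrays", {
  for (nm in c("MobileViT", "Model_DSC", "MV2_NAM", "Mb_SE")) {
    m <- build_model(nm, seed = 1)
    brute <- 0L
    mnvit:::walk_modules(m$net, function(mod, path) {
      for (p in mod$par) brute <<- brute + length(p)
    })
    expect_identical(count_parameters(m), brute)
  }
})

test_that("parameter totals are invariant to input size", {
  a <- build_model("Model_DSC", seed = 1, input_size = 64)
  b <- build_model("Model_DSC", seed = 1, input_size = 256)
  expect_identical(count_parameters(a), count_parameters(b))
})

test_that("unknown preset names raise a configuration error", {
  expect_error(mn_presets("NoSuchModel"), "unknown preset")
  expect_error(build_model(42), "mn_variant_config")
})

test_that("count_macs matches hand-summed layer values on toy modules", {
  # 1x1 conv 4->8 on a 2x2 map: 1 * 4 * 8 * 4 = 128 MACs
  toy <- mnvit:::mod_conv2d(4, 8, 1)
  x <- array(rnorm(4 * 2 * 2), c(4, 2, 2, 1))
  aud <- mnvit:::.mn_audit
  aud$active <- TRUE; aud$macs <- 0
  mnvit:::mod_fwd(toy, x, training = FALSE)
  aud$active <- FALSE
  expect_equal(aud$macs, 128)
  # depthwise 3x3, 4 channels, stride 2 on 4x4 -> 2x2 output: 9 * 4 * 4 = 144
  dw <- mnvit:::mod_conv2d(4, 4, 3, stride = 2, groups = 4)
  aud$active <- TRUE; aud$macs <- 0
  mnvit:::mod_fwd(dw, array(rnorm(4 * 16), c(4, 4, 4, 1)), training = FALSE)
  aud$active <- FALSE
  expect_equal(aud$macs, 144)
  # two-layer toy model equals the sum of its per-layer values
  two <- mnvit:::mod_seq(list(a = mnvit:::mod_conv2d(2, 3, 3, pad = 1),
                              b = mnvit:::mod_conv2d(3, 5, 1)))
  aud$active <- TRUE; aud$macs <- 0
  mnvit:::mod_fwd(two, array(rnorm(2 * 36), c(2, 6, 6, 1)), training = FALSE)
  aud$active <- FALSE
  expect_equal(aud$macs, 9 * 2 * 3 * 36 + 1 * 3 * 5 * 36)
})

test_that("multiply-accumulates scale with spatial area", {
  m <- build_model("Model_DSC", seed = 1, num_classes = 2, input_size = 64)
  m64 <- count_macs(m, 64)
  m128 <- count_macs(m, 128)
  # the convolutional trunk scales with area (x4); attention score products
  # grow faster (sequence length quadruples), the constant head slower
  expect_gt(m128 / m64, 3.5)
  expect_lt(m128 / m64, 4.5)
})

test_that("the audit grid is consistent and decomposition always saves", {
  tab <- audit_variant_grid(c("MobileViT", "Model_DSC", "MV2_SE_Mb_tr1",
                              "MV2_SE_Mb_tr3"),
                            num_classes = 1000, input_size = 64,
                            file = file.path(tempdir(), "audit.csv"))
  expect_equal(nrow(tab), 4L)
  expect_equal(attr(tab, "baseline_dsc_diff"), 302016)
  expect_true(file.exists(file.path(tempdir(), "audit.csv")))
  expect_lt(tab$parameters[tab$preset == "MV2_SE_Mb_tr1"],
            tab$parameters[tab$preset == "MV2_SE_Mb_tr3"])
  # per-layer breakdown sums to the total
  m <- build_model("MV2_SE_Mb_NAM", seed = 1)
  s <- summary(m)
  expect_equal(sum(s$breakdown$parameters), count_parameters(m))
  # decomposition strictly reduces parameters whenever 8C^2 > 9C
  for (C in c(2L, 48L, 64L, 80L))
    expect_lt(conv_param_count(3, C, C, decomposed = TRUE),
              conv_param_count(3, C, C))
})
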