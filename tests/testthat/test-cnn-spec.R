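test_that("convolution output size follows the sliding-filter formula", {
  expect_equal(conv_output_size(5, 3, 1), 3)
  expect_equal(conv_output_size(5, 5, 1), 1)
  expect_equal(conv_output_size(7, 3, 2), 3)
  expect_error(conv_output_size(5, 6, 1), "exceeds")
  expect_error(conv_output_size(7, 3, 3), "divisible")
})

test_that("output size matches a brute-force sliding enumeration", {
  # oracle: count filter placements explicitly
  brute <- function(n, f, stride) {
    positions <- 0
    start <- 1
    while (start + f - 1 <= n) {
      positions <- positions + 1
      start <- start + stride
    }
    positions
  }
  for (n in 1:12) {
    for (f in 1:n) {
      for (s in 1:4) {
        if ((n - f) %% s == 0) {
          expect_equal(conv_output_size(n, f, s), brute(n, f, s),
                       info = sprintf("n=%d f=%d s=%d", n, f, s))
        } else {
          expect_error(conv_output_size(n, f, s))
        }
      }
    }
  }
})

test_that("parameter counting implements both conventions", {
  expect_equal(layer_param_count(3, 3, 8, mode = "paper"), 80)
  expect_equal(layer_param_count(3, 3, 8, input_depth = 2,
                                 mode = "standard"), 152)
  expect_equal(layer_param_count(1, 1, 1, input_depth = 1, "paper"), 2)
  expect_equal(layer_param_count(1, 1, 1, input_depth = 1, "standard"), 2)
})

test_that("shape propagation matches hand calculation for the default nets", {
  rep_full <- validate_spec(default_cnn_spec())
  # 36x100 -> conv 3x5 -> 34x96 -> conv 3x5 -> 32x92 -> pool -> 16x46
  expect_equal(rep_full$out_h[1:3], c(34, 32, 16))
  expect_equal(rep_full$out_w[1:3], c(96, 92, 46))
  expect_equal(rep_full$out_h[4], 16 * 46 * 32)
  expect_equal(rep_full$params_standard[1], 3 * 5 * 2 * 16 + 16)
  expect_equal(rep_full$params_standard[2], 3 * 5 * 16 * 32 + 32)
  expect_equal(attr(rep_full, "total_params"),
               sum(rep_full$params_standard))

  rep_red <- validate_spec(reduced_cnn_spec())
  expect_equal(rep_red$out_h[6], 3)
  expect_true(all(rep_red$out_h > 0 & rep_red$out_w > 0))
})

test_that("invalid geometry fails fast with the offending layer", {
  bad <- cnn_spec(c(6, 7, 2),
                  list(layer_conv(4, c(3, 3)), layer_conv(4, c(2, 2)),
                       layer_maxpool(c(2, 2)), layer_flatten(),
                       layer_dense(8), layer_output(3)), 3)
  # conv outputs 4x5, then 3x4; pool 2x2 cannot tile 3
  expect_error(validate_spec(bad), "layer 3")
  big_filter <- cnn_spec(c(6, 6, 1),
                         list(layer_conv(2, c(7, 3)), layer_conv(2, c(1, 1)),
                              layer_maxpool(c(1, 1)), layer_flatten(),
                              layer_dense(4), layer_output(2)), 2)
  expect_error(validate_spec(big_filter), "layer 1")
})

test_that("the topology contract is enforced", {
  expect_error(cnn_spec(c(4, 4, 1),
                        list(layer_conv(2), layer_maxpool(),
                             layer_flatten(), layer_dense(4),
                             layer_output(2)), 2),
               "topology")
  expect_error(cnn_spec(c(4, 4, 1),
                        list(layer_conv(2), layer_conv(2), layer_maxpool(),
                             layer_flatten(), layer_dense(4),
                             layer_output(3)), 2),
               "units")
})

test_that("specs round-trip through JSON", {
  spec <- reduced_cnn_spec()
  txt <- spec_to_json(spec)
  back <- spec_from_json(txt)
  expect_equal(validate_spec(back), validate_spec(spec))
  expect_equal(back$input_shape, spec$input_shape)
})
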