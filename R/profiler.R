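# Parameter and FLOP accounting. The FLOP model is
#   conv layer:            2*H*W*(Cin_g*Kh*Kw + 1)*Cout   (H, W: output dims)
#   fully connected layer: (2*I - 1)*O
# with normalization and activation layers costed at zero. Depthwise and
# grouped convolutions enter with their per-group input channel count.
# The per-layer breakdown is collected by replaying the model's own forward
# pass on a shape-only tensor, so the report measures exactly the executed
# graph and totals are the sums of the breakdown by construction.

#' FLOPs of a single convolution layer
#'
#' @param h,w output feature map height and width.
#' @param cin input channels seen by each filter (per-group count for
#'   grouped/depthwise convolutions).
#' @param k kernel width (square kernel), or length-2 `c(kh, kw)`.
#' @param cout output channels.
#' @return FLOP count.
#' @examples
#' flops_conv(10, 10, 3, 3, 8)  # 44800
#' @export
flops_conv <- function(h, w, cin, k, cout) {
  k <- if (length(k) == 1) c(k, k) else k
  2 * h * w * (cin * k[1] * k[2] + 1) * cout
}

#' FLOPs of a fully connected layer
#' @param i input dimension.
#' @param o output dimension.
#' @return FLOP count, `(2*i - 1)*o`.
#' @examples
#' flops_fc(10, 5)  # 95
#' @export
flops_fc <- function(i, o) (2 * i - 1) * o

#' Printed time-complexity bounds of SC, DSC and GSConv
#'
#' Evaluates the three complexity products for a convolution of the given
#' geometry, exactly as printed in the source formulas:
#' `T_SC = Wout*Hout*Kh*C1*C2`, `T_DSC = Wout*Hout*Kh*C1`,
#' `T_GSConv = Wout*Hout*Kw*Kh*C1`. The printed forms omit `Kw` from `T_SC`
#' and `C2` from `T_GSConv`; they are reproduced verbatim here, not
#' corrected (see the methods vignette).
#'
#' @param c1,c2 input/output channel counts.
#' @param kh,kw kernel height and width.
#' @param out_hw output `c(width, height)` (or height/width; symmetric use).
#' @return list with `T_SC`, `T_DSC`, `T_GSConv`.
#' @examples
#' complexity_bounds(4, 8, 3, 3, c(10, 10))  # 9600, 1200, 3600
#' @export
complexity_bounds <- function(c1, c2, kh, kw, out_hw) {
  stopifnot(all(out_hw > 0), c1 >= 1, c2 >= 1, kh >= 1, kw >= 1)
  a <- out_hw[1] * out_hw[2]
  list(T_SC = a * kh * c1 * c2,
       T_DSC = a * kh * c1,
       T_GSConv = a * kw * kh * c1)
}

#' Count trainable parameters of a model or module
#'
#' @param model any module built by this package.
#' @return exact integer count of trainable scalars (convolution weights and
#'   biases, batch-norm scale and shift).
#' @export
count_params <- function(model) n_params(model)

#' Profile a module's forward pass
#'
#' Replays `forward()` on a shape-only input and collects one record per
#' costed layer.
#'
#' @param model module to profile.
#' @param input_dims input dims `c(batch, channel, height, width)`; for a
#'   full detector use batch 1 and dims divisible by 32.
#' @return data frame with columns `name`, `type`, `params`, `flops`.
#' @export
profile_layers <- function(model, input_dims = c(1, 3, 640, 640)) {
  pr <- prof_start()
  on.exit(prof_stop())
  forward(model, tz_shape(input_dims))
  rec <- pr$records
  data.frame(
    name = vapply(rec, `[[`, character(1), "name"),
    type = vapply(rec, `[[`, character(1), "type"),
    params = vapply(rec, `[[`, numeric(1), "params"),
    flops = vapply(rec, `[[`, numeric(1), "flops")
  )
}

#' Total FLOPs of a model at a given input size
#'
#' @param model module to profile.
#' @param input_hw input `c(height, width)` in pixels (default 640x640).
#' @return total FLOP count for one forward pass (batch 1).
#' @export
count_flops <- function(model, input_hw = c(640, 640)) {
  sum(profile_layers(model, c(1, 3, input_hw))$flops)
}

#' Round to one decimal, half away from zero
#' @param x numeric.
#' @return rounded value (table-comparison convention).
#' @export
round1 <- function(x) floor(x * 10 + 0.5) / 10

#' Complexity report for a model variant
#'
#' Builds the variant, counts parameters and FLOPs, and returns totals with
#' a per-layer breakdown. Totals equal the sums of the breakdown exactly.
#'
#' @param variant a [model_variant()], or an already built model.
#' @param input_hw input size in pixels.
#' @param pins see [build_model()].
#' @return list with `variant`, `input_hw`, `total_params`, `params_m`
#'   (millions, 1 decimal), `total_flops`, `gflops` (1 decimal), `layers`.
#' @export
complexity_report <- function(variant, input_hw = c(640, 640),
                              pins = bgm_pins()) {
  model <- if (inherits(variant, "bgm_variant")) {
    build_model(variant, pins)
  } else variant
  layers <- profile_layers(model, c(1, 3, input_hw))
  total_params <- sum(layers$params)
  total_flops <- sum(layers$flops)
  structure(list(
    variant = model$hyper$variant,
    input_hw = as.integer(input_hw),
    total_params = total_params,
    params_m = round1(total_params / 1e6),
    total_flops = total_flops,
    gflops = round1(total_flops / 1e9),
    layers = layers
  ), class = "bgm_complexity_report")
}

#' @export
print.bgm_complexity_report <- function(x, ...) {
  v <- x$variant
  flags <- paste0(ifelse(c(v$use_mecs, v$use_bfm, v$use_gsc2f), "+", "-"),
                  c("MECS", "BFM", "GSC2F"), collapse = " ")
  cat(sprintf("detector complexity @ %dx%d [%s]\n",
              x$input_hw[1], x$input_hw[2], flags))
  cat(sprintf("  params: %s (%.1f M)\n",
              format(x$total_params, big.mark = ","), x$params_m))
  cat(sprintf("  flops:  %s (%.1f GFLOPs)\n",
              format(x$total_flops, big.mark = ",", scientific = FALSE),
              x$gflops))
  invisible(x)
}

#' Write a complexity report to JSON
#'
#' @param report a [complexity_report()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_complexity_json <- function(report, path) {
  v <- report$variant
  jsonlite::write_json(list(
    variant = list(use_mecs = v$use_mecs, use_bfm = v$use_bfm,
                   use_gsc2f = v$use_gsc2f, width_mult = v$width_mult,
                   depth_mult = v$depth_mult, num_classes = v$num_classes),
    input_hw = report$input_hw,
    total_params = report$total_params,
    gflops = report$gflops,
    layers = report$layers
  ), path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
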