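#' Vision-transformer architecture specification
#'
#' Hyperparameters of a ViT encoder, used purely for analytic accounting of
#' parameters, forward FLOPs and quantized storage; no weights are ever
#' instantiated. The `"vit_l16"` preset (224x224 input, patch 16, embed dim
#' 1024, depth 24, 16 heads, MLP ratio 4, class token, learned positional
#' embeddings) is the architecture of the frozen fundus-image encoder whose
#' 1024-dimensional outputs the simulated cohorts stand in for.
#'
#' @param image_size input side length in pixels.
#' @param patch_size patch side length in pixels; must divide `image_size`.
#' @param in_channels input channels.
#' @param embed_dim token embedding dimension; must be divisible by
#'   `num_heads`.
#' @param depth number of transformer blocks.
#' @param num_heads attention heads.
#' @param mlp_ratio hidden/embed width ratio of the block MLP.
#' @param has_cls_token whether a class token is prepended.
#' @param learned_pos_embed whether positional embeddings are learned
#'   parameters.
#' @return an object of class `vit_spec`.
#' @export
vit_spec <- function(image_size = 224, patch_size = 16, in_channels = 3,
                     embed_dim = 1024, depth = 24, num_heads = 16,
                     mlp_ratio = 4, has_cls_token = TRUE,
                     learned_pos_embed = TRUE) {
  check_scalar(image_size, "image_size", min = 1, integer = TRUE)
  check_scalar(patch_size, "patch_size", min = 1, integer = TRUE)
  check_scalar(in_channels, "in_channels", min = 1, integer = TRUE)
  check_scalar(embed_dim, "embed_dim", min = 1, integer = TRUE)
  check_scalar(depth, "depth", min = 0, integer = TRUE)
  check_scalar(num_heads, "num_heads", min = 1, integer = TRUE)
  check_scalar(mlp_ratio, "mlp_ratio", min = 0)
  if (image_size %% patch_size != 0) {
    stop_param("'image_size' (%d) not divisible by 'patch_size' (%d)",
               image_size, patch_size)
  }
  if (embed_dim %% num_heads != 0) {
    stop_param("'embed_dim' (%d) not divisible by 'num_heads' (%d)",
               embed_dim, num_heads)
  }
  structure(list(image_size = image_size, patch_size = patch_size,
                 in_channels = in_channels, embed_dim = embed_dim,
                 depth = depth, num_heads = num_heads,
                 mlp_ratio = mlp_ratio,
                 has_cls_token = isTRUE(has_cls_token),
                 learned_pos_embed = isTRUE(learned_pos_embed)),
            class = "vit_spec")
}

#' @rdname vit_spec
#' @param name preset name; only `"vit_l16"` is shipped.
#' @export
vit_preset <- function(name = "vit_l16") {
  name <- match.arg(name)
  vit_spec(224, 16, 3, 1024, 24, 16, 4, TRUE, TRUE)
}

#' FLOP counting convention
#'
#' Makes the implicit choices of FLOP-counting tools explicit so that
#' reported figures are auditable. The default convention counts each
#' multiply-accumulate of the patch-embedding convolution and of every
#' linear layer as 2 FLOPs and excludes bias additions, the attention
#' score/value matrix products, and normalizations/activations. With the
#' optional flags: bias adds contribute one FLOP per output element;
#' attention matmuls contribute `2 * tokens^2 * embed_dim` MACs per block
#' (QK^T plus attn*V); norms and activations are costed at 5 FLOPs per
#' LayerNorm element and 8 FLOPs per GELU element.
#'
#' @param flops_per_mac 1 or 2.
#' @param count_bias_adds,count_attention_matmuls,count_norms_activations
#'   logical flags enabling the corresponding terms.
#' @return an object of class `flop_convention`.
#' @export
flop_convention <- function(flops_per_mac = 2,
                            count_bias_adds = FALSE,
                            count_attention_matmuls = FALSE,
                            count_norms_activations = FALSE) {
  if (!flops_per_mac %in% c(1, 2)) {
    stop_param("'flops_per_mac' must be 1 or 2 (got %s)", flops_per_mac)
  }
  structure(list(flops_per_mac = flops_per_mac,
                 count_bias_adds = isTRUE(count_bias_adds),
                 count_attention_matmuls = isTRUE(count_attention_matmuls),
                 count_norms_activations = isTRUE(count_norms_activations)),
            class = "flop_convention")
}

# internal: token counts of a vit_spec
vit_tokens <- function(spec) {
  tp <- (spec$image_size / spec$patch_size)^2
  list(patch = tp, total = tp + as.integer(spec$has_cls_token))
}

#' Exact parameter count of a ViT encoder
#'
#' Closed-form sum over: patch-embedding convolution (weights + bias),
#' class token, learned positional embeddings, and per block two
#' LayerNorms, the fused QKV projection, the attention output projection
#' and the two-layer MLP (all with biases), plus the final LayerNorm.
#'
#' @param spec a [vit_spec()].
#' @return exact integer-valued count (as a double).
#' @examples
#' vit_param_count(vit_preset("vit_l16")) # 303301632
#' @export
vit_param_count <- function(spec) {
  stopifnot(inherits(spec, "vit_spec"))
  E <- spec$embed_dim
  r <- spec$mlp_ratio
  tk <- vit_tokens(spec)
  patch_embed <- spec$patch_size^2 * spec$in_channels * E + E
  cls <- if (spec$has_cls_token) E else 0
  pos <- if (spec$learned_pos_embed) tk$total * E else 0
  block <- 2 * (2 * E) +          # two layer-norms (scale + shift)
    (E * 3 * E + 3 * E) +         # QKV projection
    (E * E + E) +                 # attention output projection
    (E * r * E + r * E) +         # MLP expand
    (r * E * E + E)               # MLP contract
  patch_embed + cls + pos + spec$depth * block + 2 * E
}

#' Forward-pass FLOPs of a ViT encoder
#'
#' Under the default convention (see [flop_convention()]): MACs are the
#' patch-embedding convolution (`tokens_patch * patch^2 * channels * E`)
#' plus, per block and token, the QKV, output-projection and MLP matrix
#' products (`3E^2 + E^2 + 2rE^2`); the result is `flops_per_mac * MACs`.
#' Optional convention flags add the exactly specified bias, attention
#' matmul and norm/activation terms.
#'
#' @param spec a [vit_spec()].
#' @param conv a [flop_convention()].
#' @return FLOP count (double).
#' @examples
#' vit_forward_flops(vit_preset("vit_l16")) # 119292297216, i.e. 119.3 GFLOPs
#' @export
vit_forward_flops <- function(spec, conv = flop_convention()) {
  stopifnot(inherits(spec, "vit_spec"), inherits(conv, "flop_convention"))
  E <- spec$embed_dim
  r <- spec$mlp_ratio
  tk <- vit_tokens(spec)
  macs <- tk$patch * spec$patch_size^2 * spec$in_channels * E +
    spec$depth * tk$total * (3 * E^2 + E^2 + 2 * r * E^2)
  if (conv$count_attention_matmuls) {
    macs <- macs + spec$depth * 2 * tk$total^2 * E
  }
  flops <- conv$flops_per_mac * macs
  if (conv$count_bias_adds) {
    flops <- flops + tk$patch * E +
      spec$depth * tk$total * (3 * E + E + r * E + E)
  }
  if (conv$count_norms_activations) {
    ln_elems <- (2 * spec$depth + 1) * tk$total * E
    gelu_elems <- spec$depth * tk$total * r * E
    flops <- flops + 5 * ln_elems + 8 * gelu_elems
  }
  flops
}

#' Storage size of a quantized parameter set
#'
#' `ceil(param_count * bits / 8)` bytes. One MB is defined as 10^6 bytes,
#' the convention under which the 8-bit ViT-Large encoder (303,301,632
#' parameters) occupies 303.3 MB and its 32-bit version about 1.2 GB.
#'
#' @param param_count number of parameters.
#' @param bits 8, 16 or 32.
#' @return size in bytes.
#' @export
quantized_size_bytes <- function(param_count, bits) {
  check_scalar(param_count, "param_count", min = 0, integer = TRUE)
  if (!length(bits) == 1 || !bits %in% c(8, 16, 32)) {
    stop_param("'bits' must be one of 8, 16, 32 (got %s)",
               paste(bits, collapse = ","))
  }
  ceiling(param_count * bits / 8)
}

#' Affine quantize-dequantize emulation
#'
#' Per-vector affine post-training quantization: scale =
#' `(max - min) / (2^bits - 1)` (1 if the vector is constant), zero-point
#' `round(-min/scale)`, output `(round(v/scale + zp) - zp) * scale`. The
#' maximum reconstruction error is `scale / 2` and the map is idempotent at
#' fixed bit width. For a matrix, each row (one record's feature vector) is
#' quantized with its own scale and zero-point.
#'
#' @param v numeric vector, or matrix of row vectors.
#' @param bits integer in 2..16 (default 8).
#' @return object of the same shape as `v` on the quantization grid.
#' @export
quantize_dequantize <- function(v, bits = 8) {
  check_scalar(bits, "bits", min = 2, max = 16, integer = TRUE)
  if (length(v) == 0) stop_param("input vector is empty")
  if (!all(is.finite(v))) stop_param("input contains NaN or infinite values")
  levels <- 2^bits - 1
  if (is.matrix(v)) {
    lo <- apply(v, 1L, min)
    hi <- apply(v, 1L, max)
    scale <- (hi - lo) / levels
    const <- scale == 0 # constant rows are representable exactly
    scale[const] <- 1
    zp <- round(-lo / scale)
    # scale/zp recycle down columns: one quantizer per row
    out <- (round(v / scale + zp) - zp) * scale
    if (any(const)) out[const, ] <- v[const, ]
    out
  } else {
    lo <- min(v)
    hi <- max(v)
    if (hi == lo) {
      return(v) # a constant vector is representable exactly
    }
    scale <- (hi - lo) / levels
    zp <- round(-lo / scale)
    (round(v / scale + zp) - zp) * scale
  }
}
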