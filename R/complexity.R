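# Exact complexity accounting.
#
# Two kinds of figures are produced: symbolic per-layer operation counts
# (omega_* below, the standard window-attention complexity formulas), and
# exact whole-model audits (count_params, count_flops) computed from layer
# shapes alone. All arithmetic is kept below 2^53 so every integer is exact
# in double precision.

#' @noRd
check_query <- function(h, w, C, M = NULL) {
  v <- c(h = h, w = w, C = C)
  if (!is.null(M)) v <- c(v, M = M)
  if (any(v < 1) || any(v != floor(v))) {
    stop("complexity query fields must be positive integers", call. = FALSE)
  }
  invisible(NULL)
}

#' Operation count of global multi-head self-attention
#'
#' `4 h w C^2 + 2 (h w)^2 C`: the four channel projections plus the two
#' quadratic score/aggregation matrix products over all `h w` tokens.
#'
#' @param h,w Spatial extent in tokens.
#' @param C Channel count.
#' @return Exact integer count.
#' @export
omega_msa <- function(h, w, C) {
  check_query(h, w, C)
  check_exact_int(4 * h * w * C^2 + 2 * (h * w)^2 * C, "omega_msa")
}

#' Operation count of window multi-head self-attention
#'
#' `4 h w C^2 + 2 M^2 h w C`: restricting the score/aggregation products to
#' M x M windows makes the quadratic term linear in `h w`.
#'
#' @inheritParams omega_msa
#' @param M Window edge length in tokens.
#' @return Exact integer count.
#' @export
omega_wmsa <- function(h, w, C, M) {
  check_query(h, w, C, M)
  check_exact_int(4 * h * w * C^2 + 2 * M^2 * h * w * C, "omega_wmsa")
}

#' Operation count of Double Attention
#'
#' `5 h w C^2 + 3 M^2 h w C`: window attention plus one extra channel
#' projection (K2) and one extra windowed score product (Q K2^T).
#'
#' @inheritParams omega_wmsa
#' @return Exact integer count.
#' @export
omega_da <- function(h, w, C, M) {
  check_query(h, w, C, M)
  check_exact_int(5 * h * w * C^2 + 3 * M^2 * h * w * C, "omega_da")
}

#' Operation count of gated axial attention
#'
#' `4 h w C^2 + 2 (h^2 + w^2) C`.
#'
#' @inheritParams omega_msa
#' @return Exact integer count.
#' @export
omega_gaa <- function(h, w, C) {
  check_query(h, w, C)
  check_exact_int(4 * h * w * C^2 + 2 * (h^2 + w^2) * C, "omega_gaa")
}

# Per-stage (tokens h, w; channels C; heads n) shape walk shared by the param
# and MAC audits. Returns a list of stage descriptors.
#' @noRd
stage_shapes <- function(cfg, input_hw = cfg$input_hw) {
  h <- input_hw[1] %/% cfg$patch_size
  w <- input_hw[2] %/% cfg$patch_size
  ns <- length(cfg$depths)
  out <- vector("list", ns)
  for (s in seq_len(ns)) {
    out[[s]] <- list(h = h, w = w, C = cfg$embed_dim * 2^(s - 1),
                     depth = cfg$depths[s], heads = cfg$heads[s],
                     merge = s < ns)
    h <- h %/% 2L; w <- w %/% 2L
  }
  out
}

#' Exact learnable-parameter count from shapes
#'
#' Sums every learnable scalar of the configured model from layer shapes
#' alone, without instantiating weights; equals `n_params(build_model(cfg))`
#' exactly. Per block the count is `12 C^2 + 13 C + (2M-1)^2 heads` for
#' window attention (Q/K1/V/output projections with biases, two LayerNorms,
#' ratio-4 MLP, relative-position table) plus `C^2 + C` for the K2 projection
#' of the DA and DA_N variants.
#'
#' @param cfg A [model_config()].
#' @return Exact integer count.
#' @export
count_params <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  p <- cfg$patch_size
  C0 <- cfg$embed_dim
  total <- (p^2 * 3) * C0 + C0 + 2 * C0          # patch embed + its LayerNorm
  for (st in stage_shapes(cfg)) {
    C <- st$C
    hidden <- round(cfg$mlp_ratio * C)
    proj <- 4 * C^2 + (if (cfg$variant != "WMSA") C^2 else 0)
    bias <- if (cfg$use_bias) (if (cfg$variant != "WMSA") 5 * C else 4 * C) else 0
    rel <- if (cfg$use_relpos) (2 * cfg$window - 1)^2 * st$heads else 0
    mlp <- C * hidden + hidden + hidden * C + C
    block <- 2 * C + proj + bias + rel + 2 * C + mlp
    total <- total + st$depth * block
    if (st$merge) total <- total + 8 * C + (4 * C) * (2 * C)  # LN(4C) + 4C->2C
  }
  Cf <- cfg$embed_dim * 2^(length(cfg$depths) - 1)
  total <- total + 2 * Cf + Cf * cfg$num_classes + cfg$num_classes
  check_exact_int(total, "parameter count")
}

#' Exact multiply-accumulate count for one input
#'
#' Counts the MACs of every learned linear or convolutional projection (patch
#' embedding, Q/K1/K2/V, output projections, MLPs, patch mergings, head) for a
#' single forward pass. Two conventions are available:
#' \describe{
#'   \item{`"projections-only"`}{only the learned projections; the attention
#'     score (`Q K^T`) and aggregation (`A V`) matrix products are excluded.
#'     This is the convention under which the published table figures are
#'     reproduced (it matches what common FLOP counters report when attention
#'     matrix products are implemented as functional ops they do not trace).}
#'   \item{`"eq78"`}{adds the windowed matrix-product terms — `2 M^2 h w C`
#'     per window-attention block, `3 M^2 h w C` per DA/DA_N block — so the
#'     total matches the symbolic per-block formulas.}
#' }
#' Normalisations, activations, softmax and biases contribute zero MACs.
#'
#' @param cfg A [model_config()].
#' @param input_hw Input size in pixels (defaults to `cfg$input_hw`).
#' @param convention `"projections-only"` or `"eq78"`.
#' @return Exact integer MAC count.
#' @export
count_flops <- function(cfg, input_hw = cfg$input_hw,
                        convention = "projections-only") {
  stopifnot(inherits(cfg, "model_config"))
  if (!convention %in% c("projections-only", "eq78")) {
    stop(sprintf("unknown FLOP convention '%s'", convention), call. = FALSE)
  }
  if (any(input_hw %% cfg$patch_size != 0L)) {
    stop_dim("input %d x %d not divisible by patch size %d",
             input_hw[1], input_hw[2], cfg$patch_size)
  }
  p <- cfg$patch_size
  C0 <- cfg$embed_dim
  total <- (input_hw[1] %/% p) * (input_hw[2] %/% p) * (p^2 * 3) * C0
  for (st in stage_shapes(cfg, input_hw)) {
    hw <- st$h * st$w
    C <- st$C
    hidden <- round(cfg$mlp_ratio * C)
    nproj <- if (cfg$variant != "WMSA") 5 else 4
    block <- nproj * hw * C^2 + hw * (C * hidden + hidden * C)
    if (convention == "eq78") {
      nmat <- if (cfg$variant != "WMSA") 3 else 2
      block <- block + nmat * cfg$window^2 * hw * C
    }
    total <- total + st$depth * block
    if (st$merge) total <- total + (st$h %/% 2) * (st$w %/% 2) * (4 * C) * (2 * C)
  }
  Cf <- cfg$embed_dim * 2^(length(cfg$depths) - 1)
  total <- total + Cf * cfg$num_classes
  check_exact_int(total, "MAC count")
}

#' Complexity report for a configured model
#'
#' Bundles the symbolic per-layer operation counts at the stage-1 resolution
#' with the exact whole-model parameter and MAC audits, under both MAC
#' conventions.
#'
#' @param cfg A [model_config()].
#' @param input_hw Input size in pixels (defaults to `cfg$input_hw`).
#' @return List with `omega_msa`, `omega_wmsa`, `omega_da`, `omega_gaa`
#'   (stage-1 query), `params_total`, `flops_projections_only`, `flops_eq78`,
#'   and the one-decimal `params_M` / `flops_G` figures (projections-only).
#' @export
complexity_report <- function(cfg, input_hw = cfg$input_hw) {
  h <- input_hw[1] %/% cfg$patch_size
  w <- input_hw[2] %/% cfg$patch_size
  C <- cfg$embed_dim
  params <- count_params(cfg)
  fl_proj <- count_flops(cfg, input_hw, "projections-only")
  fl_eq <- count_flops(cfg, input_hw, "eq78")
  list(query = list(h = h, w = w, C = C, M = cfg$window),
       omega_msa = omega_msa(h, w, C),
       omega_wmsa = omega_wmsa(h, w, C, cfg$window),
       omega_da = omega_da(h, w, C, cfg$window),
       omega_gaa = omega_gaa(h, w, C),
       params_total = params,
       flops_projections_only = fl_proj,
       flops_eq78 = fl_eq,
       params_M = round_half_away(params / 1e6, 1L),
       flops_G = round_half_away(fl_proj / 1e9, 1L))
}

#' Method-comparison complexity table
#'
#' One row per attention variant with the columns of the published comparison
#' tables (`method`, `acc`, `flops_G`, `params_M`); the accuracy column is a
#' placeholder unless measured accuracies are supplied.
#'
#' @param cfg A [model_config()]; its `variant` field is overridden per row.
#' @param variants Character vector of variants to tabulate.
#' @param input_hw Input size in pixels.
#' @param convention MAC convention for the FLOPs column.
#' @param acc Optional named numeric vector of accuracies by variant.
#' @return `data.frame` with columns method, acc, flops_G, params_M.
#' @export
complexity_table <- function(cfg, variants = c("WMSA", "DA_N", "DA"),
                             input_hw = cfg$input_hw,
                             convention = "projections-only", acc = NULL) {
  rows <- lapply(variants, function(v) {
    vcfg <- cfg
    vcfg$variant <- v
    validate_model_config(vcfg)
    data.frame(
      method = c(WMSA = "W-MSA", DA_N = "DA-N", DA = "DA")[[v]],
      acc = if (!is.null(acc) && v %in% names(acc)) acc[[v]] else NA_real_,
      flops_G = round_half_away(count_flops(vcfg, input_hw, convention) / 1e9, 1L),
      params_M = round_half_away(count_params(vcfg) / 1e6, 1L)
    )
  })
  do.call(rbind, rows)
}
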