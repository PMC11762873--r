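# Shared fixture builders.

rand_fm <- function(h, w, C, seed = 1) {
  set.seed(seed)
  feature_map(array(rnorm(h * w * C), c(h, w, C)))
}

# Small attention setup on a 14 x 14 x 8 map (2 heads, M = 7): the largest
# geometry the scalar oracle is run on.
oracle_case <- function(variant = "DA", seed = 11, use_relpos = TRUE) {
  cfg <- attention_config(C = 8L, num_heads = 2L, M = 7L, variant = variant,
                          use_relpos = use_relpos)
  set.seed(seed)
  wts <- init_attention_weights(cfg)
  x <- rand_fm(14, 14, 8, seed = seed + 1)
  list(cfg = cfg, wts = wts, x = x)
}

# Mini backbone family used by the architecture/training tests.
mini_cfg <- function(variant = "DA", depths = c(1L, 1L), heads = c(2L, 4L),
                     embed_dim = 32L, input_hw = c(56L, 56L), window = 7L,
                     num_classes = 2L) {
  model_config(embed_dim = embed_dim, depths = depths, heads = heads,
               window = window, input_hw = input_hw, num_classes = num_classes,
               variant = variant)
}
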