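# Shared fixtures: everything is generated in code at test time.

tiny_codec <- function(sigma = 2) {
  codec_config(input_size = c(64, 64), heatmap_size = c(16, 16), sigma = sigma)
}

# In-memory synthetic dataset (64 px images).
make_wings <- function(n, domain = "target", seed = 1, render = TRUE,
                       image_size = 64) {
  generate_dataset(wing_template(),
                   generator_config(image_size = image_size, domain = domain,
                                    seed = seed),
                   n = n, render = render)
}

# Annotation-only index for split/protocol tests.
make_index <- function(n, seed = 1) make_wings(n, seed = seed,
                                               render = FALSE)$index

# A very small backbone for structural/gradient tests.
micro_config <- function(...) {
  backbone_config(base_width = 4, input_size = c(64, 64), in_channels = 1,
                  num_landmarks = 36, stage1_blocks = 1,
                  blocks_per_module = 1, num_modules = c(1, 1, 1),
                  stem_width = 4, ...)
}

param_values <- function(model) lapply(model$params, function(p) p$value)

# short constant-rate schedule for mechanics tests
quick_tc <- function(epochs, seed = 1) {
  train_config(base_lr = 1e-2, lr_drops = c(), max_epochs = epochs,
               batch_size = 8, seed = seed)
}
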