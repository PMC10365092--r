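# Shared fixtures, built once per test run.

# Small deterministic phantom: 20^3 grid, 2 tracts, modest noise.
tiny_spec <- function(...) {
  phantom_spec(grid_size = 20, n_tracts = 2, radius_vox = 1.8,
               n_directions = 30, n_b0 = 3, noise_sd = 1, ...)
}

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, fun) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- fun()
  .fixture_env[[name]]
}

tiny_subject <- function() {
  fixture("tiny_subject", function() make_phantom_subject(tiny_spec(), seed = 21))
}

tiny_prepared <- function() {
  fixture("tiny_prepared", function() {
    suppressMessages(prepare_subject(tiny_subject()))
  })
}

# A minimal model whose output is a known constant probability everywhere:
# all weights zero, output bias set to the logit.
constant_model <- function(p = 0.3, in_channels = 15, out_channels = 2,
                           depth = 1) {
  m <- build_model(unet_config(in_channels, out_channels, depth = depth,
                               base_filters = 2, dropout_rate = 0), seed = 1)
  m$params <- rapply(m$params, function(x) x * 0, how = "replace")
  m$params$out$b <- rep(log(p / (1 - p)), out_channels)
  m
}

# Probability stack wrapper around a bare (T, X, Y, Z, N) array.
as_stack <- function(probs, mode = "ttd", seed = 1) {
  structure(list(probs = probs, mode = mode,
                 transforms = vector("list", dim(probs)[1]), seed = seed),
            class = "probability_stack")
}
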