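# YAML (de)serialisation of model and run configurations.

config_to_list <- function(config) {
  mc <- config$model
  list(model = list(variant = mc$variant, input_side = mc$input_side,
                    input_channels = mc$input_channels,
                    encoder_filters = mc$encoder_filters,
                    decoder_filters = mc$decoder_filters,
                    width = mc$width, seed = mc$seed),
       batch_size = config$batch_size, epochs = config$epochs,
       optimizer = config$optimizer, learning_rate = config$learning_rate,
       augment = config$augment, threshold = config$threshold,
       seed = config$seed)
}

#' Write a run configuration to YAML
#' @param config a [run_config()].
#' @param path output path.
#' @export
write_run_config <- function(config, path) {
  writeLines(yaml::as.yaml(config_to_list(config)), path)
  invisible(path)
}

#' Read a run configuration from YAML
#' @param path YAML file with the keys written by [write_run_config()].
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  m <- y$model %||% list()
  mc <- model_config(
    input_side = m$input_side %||% 128L,
    input_channels = m$input_channels %||% 1L,
    variant = m$variant %||% "rdau",
    width = m$width %||% 1,
    seed = m$seed %||% 42L)
  run_config(model = mc,
             batch_size = y$batch_size,
             epochs = y$epochs %||% 300L,
             learning_rate = y$learning_rate %||% 1e-4,
             augment = y$augment %||% FALSE,
             threshold = y$threshold %||% 0.5,
             seed = y$seed %||% 1L)
}
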