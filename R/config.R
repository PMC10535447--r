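#' Build framework configuration from a named list
#'
#' Convenience constructor used by the YAML config loader and the CLI:
#' any subset of the hyperparameters may be given; the rest fall back to
#' the package defaults (lambda 0.03, gamma 0.8, T 10, I 10, E 50,
#' omega 0.006, ratio 2, batch size 32, initial lr 0.001, dropout 0.3).
#'
#' @param params named list; recognized names are `lambda`, `gamma`, `T`,
#'   `iterations`, `epochs`, `batch_size`, `initial_lr`, `dropout_rate`,
#'   `standardize`, `omega`, `ratio`, `seed`.
#' @return List with elements `cfg` ([assf_config()]) and `pspec`
#'   ([perturbation_spec()]).
#' @export
config_from_list <- function(params = list()) {
  g <- function(name, default) if (!is.null(params[[name]])) params[[name]] else default
  seed <- as.integer(g("seed", 1L))
  mcfg <- model_config(dropout_rate = g("dropout_rate", 0.3),
                       standardize = g("standardize", FALSE),
                       seed = seed)
  tcfg <- train_config(epochs = g("epochs", 50L),
                       batch_size = g("batch_size", 32L),
                       initial_lr = g("initial_lr", 0.001),
                       seed = seed)
  cfg <- assf_config(lambda = g("lambda", 0.03), gamma = g("gamma", 0.8),
                     T = g("T", 10L), iterations = g("iterations", 10L),
                     model = mcfg, train = tcfg, seed = seed)
  pspec <- perturbation_spec(omega = g("omega", 0.006),
                             ratio = g("ratio", 2L), seed = seed)
  list(cfg = cfg, pspec = pspec)
}

#' Read framework configuration from a YAML file
#'
#' @param path YAML file with any of the keys documented in
#'   [config_from_list()].
#' @return As [config_from_list()].
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read config files")
  }
  config_from_list(yaml::read_yaml(path))
}
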