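#' Default model configuration
#'
#' Every tunable parameter of the pipeline with its standard default:
#' time step `dt = 0.1`, length weight `v = 0.2`, regularization weight
#' `mu = 1.0`, VVF weight `lam_vvf = -0.1`, vesselness thresholds
#' `tau = eps_v = 0.05`, initialization height `rho = 2`, MRMSE window
#' radius `r = 12`; the kernel scale `sigma` defaults to the image-size
#' rule of [default_sigma()] (`NULL` here means "derive from the image"),
#' and `beta = NULL` selects the per-scale adaptive structuredness
#' sensitivity.
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    # evolution
    dt = 0.1, v = 0.2, mu = 1.0, lam_vvf = -0.1,
    lambda1 = 1, lambda2 = 1,
    band_width = 4, freeze_patience = 10,
    max_iters = 500, stop_frac = 1e-3, stop_patience = 20,
    energy_every = 1,
    # regularized step / kernel
    eps_h = 1, sigma = NULL,
    # vesselness / VVF
    scales = c(1, 1.5, 2, 3, 4, 5), alpha = 0.5, beta = NULL,
    tau = 0.05, eps_v = 0.05, invert = FALSE,
    # initialization
    rho = 2, init_threshold = 0.15, min_object_px = 20,
    # evaluation
    r = 12
  )
}

#' Validate a configuration list
#'
#' Rejects unknown keys (naming the offender) and fills missing keys with
#' defaults.
#'
#' @param config Named list of configuration values.
#' @return The completed configuration list.
#' @export
validate_config <- function(config) {
  def <- default_config()
  extra <- setdiff(names(config), names(def))
  if (length(extra))
    stop_validation("unknown configuration key(s): ",
                    paste(extra, collapse = ", "))
  utils::modifyList(def, config)
}

#' Read a configuration file
#'
#' Flat key-value YAML mirroring [default_config()]; unknown keys are
#' rejected, absent keys keep their defaults.
#'
#' @param path YAML file path.
#' @return Validated configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("cannot read config: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.null(cfg$scales)) cfg$scales <- as.numeric(cfg$scales)
  validate_config(cfg)
}

#' Write a configuration file
#'
#' @param config Configuration list.
#' @param path Output YAML path.
#' @return The path, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(validate_config(config), path)
  invisible(path)
}
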