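#' Default run configuration
#'
#' All tunable constants of the pipeline in one nested list: interface /
#' cross-edge / contact cutoffs (10, 10, 5 Angstrom), the network
#' architecture and the training schedule.  Round-trips through YAML;
#' unknown keys are rejected on read.
#'
#' @param seed master seed.
#' @return nested named list.
#' @export
runConfig <- function(seed = 1L) {
  list(seed = as.integer(seed),
       interfaceCutoff = 10.0,
       crossCutoff = 10.0,
       contactCutoff = 5.0,
       network = networkConfig(),
       training = trainingConfig(seed = seed))
}

#' Write / read a run configuration as YAML
#'
#' @param config a [runConfig()] list.
#' @param path YAML file.
#' @return `readRunConfig` returns the validated configuration list.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  def <- runConfig()
  .checkKeys(cfg, def, "config")
  # merge onto defaults so partial files are valid
  out <- utils::modifyList(def, cfg)
  out$network <- do.call(networkConfig, out$network[
    intersect(names(out$network),
              names(formals(networkConfig)))])
  out$training <- do.call(trainingConfig, out$training[
    intersect(names(out$training), names(formals(trainingConfig)))])
  out
}

.checkKeys <- function(cfg, def, where) {
  unknown <- setdiff(names(cfg), names(def))
  if (length(unknown) > 0)
    stop("unknown key(s) in ", where, ": ", paste(unknown, collapse = ", "))
  for (nm in names(cfg)) {
    if (is.list(def[[nm]]) && is.list(cfg[[nm]]))
      .checkKeys(cfg[[nm]], def[[nm]], paste0(where, "$", nm))
  }
  invisible(TRUE)
}
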