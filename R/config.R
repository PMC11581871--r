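#' Read a benchmark configuration from YAML
#'
#' The file holds three blocks — `genome`, `host_library`,
#' `parasite_library` — whose keys are the arguments of
#' [genome_pair_spec()] and [library_spec()], plus an optional `mapper`
#' block for [mapper_params()]. Missing keys fall back to the function
#' defaults, so a minimal file can set only what it needs.
#'
#' @param file Path to a YAML file.
#' @return list with elements `genome`, `host_library`,
#'   `parasite_library`, `mapper`.
#' @export
read_benchmark_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  build <- function(fun, block) do.call(fun, as.list(block))
  list(genome = build(genome_pair_spec, cfg$genome),
       host_library = build(library_spec, cfg$host_library),
       parasite_library = build(library_spec, cfg$parasite_library),
       mapper = build(mapper_params, cfg$mapper))
}

#' Write the resolved benchmark configuration to YAML
#'
#' Writes every resolved value (including defaults and seeds), so a run
#' can be reproduced from its logged configuration alone.
#'
#' @param genome,host_library,parasite_library,mapper Spec objects.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_benchmark_config <- function(genome, host_library, parasite_library,
                                   mapper, file) {
  yaml::write_yaml(list(genome = unclass(genome),
                        host_library = unclass(host_library),
                        parasite_library = unclass(parasite_library),
                        mapper = unclass(mapper)),
                   file)
  invisible(file)
}
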