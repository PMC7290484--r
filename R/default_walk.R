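#' The packaged default reward walk
#'
#' A 250-trial reward walk shipped with the package, pre-selected by
#' [select_reward_walk()] (20 candidates, 100 evaluation simulations per
#' candidate, seed 1) so that a purely model-based reference agent earns a
#' higher mean final score than a purely model-free one, as the task's
#' pre-simulation requires.
#'
#' @param config A [task_config()] used for validation on read.
#' @return A `twostep_walk`.
#' @export
default_reward_walk <- function(config = task_config()) {
  path <- system.file("extdata", "default_walk.csv", package = "twostepr",
                      mustWork = TRUE)
  read_reward_walk(path, config)
}
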