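#' Build the structure-based topology for a toy complex
#'
#' Applies [build_topology()] with the contact parameters the toy geometry
#' needs (stored in the structure's `meta$build_args`): a 6.5 nm contact
#' cutoff so the long-range contact network triangulates the filament and
#' anchors head/neck orientation, wells of width 1.2 nm and depth 3 energy
#' units (about 5 kT at 300 K).
#'
#' @param reference a toy [cg_structure()] from [make_toy_complex()].
#' @return a `topology`.
#' @export
toy_topology <- function(reference) {
  ba <- reference$meta$build_args
  if (is.null(ba)) stop("structure carries no toy build_args metadata")
  do.call(build_topology, c(list(reference = reference), ba))
}
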