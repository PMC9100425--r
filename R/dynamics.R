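#' Boltzmann constant in the package's reduced energy units (per K)
#' @export
k_boltzmann <- function() 0.0019872041

#' Run Langevin dynamics under the total fitting potential
#'
#' Underdamped Langevin dynamics (BAOAB splitting, uniform unit masses) of a
#' coarse-grained structure under
#' `V_protein + V_stage (+ V_restraint) (+ V_AFM)`. The random-force stream
#' is derived from `(config$seed, stream)` so replicas are independent and
#' each is bitwise reproducible.
#'
#' Records are taken every `config$record_interval` steps: step index,
#' cosine similarity (when the bias is on), the potential-energy components,
#' kinetic energy and the snapshot coordinates. A non-finite total energy
#' aborts the run with an error carrying the offending snapshot (condition
#' class `afmflex_dynamics_error`).
#'
#' @param initial a [cg_structure()] (>= 2 beads).
#' @param topology a [build_topology()] result for the same bead count.
#' @param config a [run_config()].
#' @param bias `NULL` for unbiased dynamics, or a list with `h_ref` (the
#'   leveled/cropped reference `afm_image`) and optional `mask`
#'   ([region_mask()] on `h_ref`; `NULL` = whole image). The bias strength
#'   and renderer widths come from `config`.
#' @param restraints optional [restraint_set()]; `restraint_stage` indexes
#'   its schedule.
#' @param restraint_stage 1-based schedule index (default: last stage).
#' @param stage a [stage_params()]; defaults to `config`'s stage settings.
#' @param stream integer replica stream index (default 0).
#' @return a `trajectory`: list with `records` (data.frame of step, cs,
#'   energy components, kinetic), `snapshots` (n x 3 x n_records array),
#'   `final` (structure), `n_beads`, and the effective settings.
#' @export
run_langevin <- function(initial, topology, config, bias = NULL,
                         restraints = NULL, restraint_stage = NULL,
                         stage = NULL, stream = 0L) {
  validate_run_config(config)
  if (n_beads(initial) != topology$n_beads)
    stop("structure and topology bead counts differ")
  if (is.null(stage))
    stage <- stage_params(config$stage_epsilon, config$stage_sigma)
  sigma_vec <- stage_sigma_vec(initial, stage)
  rc <- restraints_to_cpp(restraints, n_beads(initial))
  mult <- if (is.null(restraints)) 0 else {
    if (is.null(restraint_stage)) restraint_stage <- length(restraints$schedule)
    restraints$schedule[restraint_stage]
  }

  bias_on <- !is.null(bias) && config$k_bias > 0
  if (bias_on) {
    h_ref <- bias$h_ref
    m <- mask0(bias$mask, h_ref)
  } else {
    h_ref <- afm_image(matrix(0, 1, 1)) # placeholder, unused
    m <- c(0L, 0L, 0L, 0L)
  }

  out <- cpp_run_langevin(initial$coords, initial$radius,
                          topo_to_cpp(topology),
                          sigma_vec, stage$epsilon,
                          rc, mult,
                          bias_on, h_ref$heights,
                          h_ref$dx, h_ref$dy, h_ref$x0, h_ref$y0,
                          m[1], m[2], m[3], m[4],
                          config$k_bias, config$sigma_x, config$sigma_y,
                          config$gamma,
                          config$temperature, config$friction, config$dt,
                          config$n_steps, config$record_interval,
                          config$seed, as.integer(stream))

  if (out$aborted) {
    cond <- structure(class = c("afmflex_dynamics_error", "error", "condition"),
                      list(message = paste0("dynamics aborted: ",
                                            out$abort_message),
                           call = sys.call(),
                           snapshot = out$final_coords))
    stop(cond)
  }

  nr <- out$n_recorded
  records <- data.frame(step = out$steps[seq_len(nr)],
                        cs = out$cs[seq_len(nr)],
                        e_protein = out$e_protein[seq_len(nr)],
                        e_stage = out$e_stage[seq_len(nr)],
                        e_bias = out$e_bias[seq_len(nr)],
                        e_restraint = out$e_restraint[seq_len(nr)],
                        kinetic = out$kinetic[seq_len(nr)])
  final <- initial
  final$coords <- out$final_coords
  structure(list(records = records,
                 snapshots = out$snapshots,
                 final = final,
                 n_beads = n_beads(initial),
                 bias_on = bias_on,
                 stream = as.integer(stream),
                 config = config),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d beads, %d records%s\n", x$n_beads,
              nrow(x$records),
              if (x$bias_on)
                sprintf(", final c.s. %.4f", tail(x$records$cs, 1)) else ""))
  invisible(x)
}

#' Extract a recorded snapshot as a structure
#'
#' @param trajectory a [run_langevin()] result.
#' @param i record index.
#' @param template structure supplying radii/chains (default: the final
#'   structure of the trajectory).
#' @export
snapshot_structure <- function(trajectory, i, template = trajectory$final) {
  out <- template
  out$coords <- trajectory$snapshots[, , i]
  out
}

#' Kinetic-temperature estimate from a trajectory
#'
#' Equipartition estimate `T = 2 <KE> / (3 N k_B)` over the recorded
#' kinetic energies. Requires at least 100 records.
#'
#' @param trajectory a [run_langevin()] result.
#' @return temperature in K.
#' @export
temperature_estimate <- function(trajectory) {
  ke <- trajectory$records$kinetic
  if (length(ke) < 100L) stop("need >= 100 records for a temperature estimate")
  mean(2 * ke / (3 * trajectory$n_beads * k_boltzmann()))
}

#' Write trajectory records to CSV
#' @param trajectory a [run_langevin()] result.
#' @param path output path.
#' @export
write_trajectory_records <- function(trajectory, path) {
  utils::write.csv(trajectory$records, path, row.names = FALSE)
  invisible(path)
}
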