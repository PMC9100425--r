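#' Roughly place a structure over a reference image
#'
#' Operationalizes "placed by eye": translates the structure in x, y so the
#' height-weighted centroid of its rendered image matches the reference's,
#' optionally after rotating about z to align the images' principal axes,
#' then applies a user-supplied rigid offset.
#'
#' @param structure a [cg_structure()].
#' @param h_ref the reference `afm_image`.
#' @param params a [renderer_params()] (grid replaced by `h_ref`'s).
#' @param align_axis rotate about z to match principal axes (default TRUE).
#' @param offset extra rigid offset (nm) applied last.
#' @return the placed `cg_structure`.
#' @export
place_structure <- function(structure, h_ref, params = renderer_params(),
                            align_axis = TRUE, offset = c(0, 0, 0)) {
  params$grid <- grid_of(h_ref)
  moments <- function(img) {
    ctr <- pixel_centers(img)
    W <- pmax(img$heights, 0)
    w <- sum(W)
    mx <- sum(sweep(W, 2, ctr$x, "*")) / w
    my <- sum(sweep(W, 1, ctr$y, "*")) / w
    XX <- sweep(W, 2, ctr$x - mx, "*")
    cxx <- sum(sweep(XX, 2, ctr$x - mx, "*")) / w
    cyy <- sum(sweep(sweep(W, 1, ctr$y - my, "*"), 1, ctr$y - my, "*")) / w
    cxy <- sum(sweep(XX, 1, ctr$y - my, "*")) / w
    list(mx = mx, my = my, angle = 0.5 * atan2(2 * cxy, cxx - cyy))
  }
  ref_m <- moments(h_ref)
  out <- structure
  if (align_axis) {
    sim_m <- moments(render_smooth(out, params))
    out <- perturb_structure(out, rotation = (ref_m$angle - sim_m$angle) * 180 / pi)
  }
  sim_m <- moments(render_smooth(out, params))
  perturb_structure(out, translation = c(ref_m$mx - sim_m$mx,
                                         ref_m$my - sim_m$my, 0) + offset)
}

#' Run a multi-replica flexible-fitting campaign for one candidate state
#'
#' Runs `config$n_replicas` independent [run_langevin()] fits of `initial`
#' under `topology` against the (already leveled and cropped) reference
#' image, each on its own random stream, and aggregates them into a
#' `fit_result`. A replica that aborts is dropped and flagged; the campaign
#' continues with the remaining replicas.
#'
#' By default, beads of chains listed in `initial$meta$filament_chains` are
#' position-restrained at their starting coordinates (the filament carries
#' no fitting signal of its own and would otherwise drift).
#'
#' @param initial a [cg_structure()], roughly placed over the image region.
#' @param topology the candidate state's [build_topology()].
#' @param h_ref preprocessed reference `afm_image` (leveled, cropped).
#' @param config a [run_config()].
#' @param mask bias mask on `h_ref` (`NULL` = whole image, the usual case
#'   when `h_ref` is already cropped to the fitting region).
#' @param restraints `NULL` for the default filament position restraints,
#'   `NA` for none, or an explicit [restraint_set()].
#' @param restraint_k spring constant for the default filament restraints
#'   (energy/nm^2 per bead).
#' @return a `fit_result`: state label, replica trajectories, best snapshot
#'   (structure + pseudo-image + c.s.), per-replica maxima, failed-replica
#'   indices, and the inputs needed to recompute masked similarities.
#' @export
run_fitting_campaign <- function(initial, topology, h_ref, config,
                                 mask = NULL, restraints = NULL,
                                 restraint_k = 0.2) {
  if (is.null(restraints)) {
    fc <- initial$meta$filament_chains
    restraints <- if (!is.null(fc) && any(initial$chain %in% fc))
      position_restraints(initial, which(initial$chain %in% fc),
                          k = restraint_k)
    else NA
  }
  if (length(restraints) == 1 && is.na(restraints)[1]) restraints <- NULL

  bias <- list(h_ref = h_ref, mask = mask)
  trajs <- vector("list", config$n_replicas)
  failed <- integer(0)
  for (r in seq_len(config$n_replicas)) {
    trajs[[r]] <- tryCatch(
      run_langevin(initial, topology, config, bias = bias,
                   restraints = restraints, stream = r),
      afmflex_dynamics_error = function(e) {
        warning("replica ", r, " aborted: ", conditionMessage(e))
        NULL
      })
    if (is.null(trajs[[r]])) failed <- c(failed, r)
  }
  ok <- setdiff(seq_len(config$n_replicas), failed)
  if (length(ok) == 0) stop("all replicas aborted")

  per_max <- vapply(trajs[ok], function(tr) max(tr$records$cs), numeric(1))
  best_rep <- ok[which.max(per_max)]
  tr <- trajs[[best_rep]]
  best_rec <- which.max(tr$records$cs)
  best_structure <- snapshot_structure(tr, best_rec, template = initial)
  rp <- renderer_params(config$sigma_x, config$sigma_y, config$gamma,
                        grid = h_ref)
  best <- list(structure = best_structure,
               image = render_smooth(best_structure, rp),
               cs = tr$records$cs[best_rec],
               replica = best_rep, record = best_rec)

  structure(list(label = topology$reference_label,
                 trajectories = trajs, best = best,
                 per_replica_max = stats::setNames(per_max, ok),
                 failed = failed,
                 h_ref = h_ref, mask = mask, config = config,
                 template = initial),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> state '%s': %d/%d replicas, best c.s. %.4f\n",
              x$label, length(x$per_replica_max),
              length(x$trajectories), x$best$cs))
  invisible(x)
}

latter_half_idx <- function(n) if (n >= 2) (floor(n / 2) + 1L):n else integer(0)

# Latter-half cosine-similarity samples per replica (list of vectors).
# mask = NULL reuses the similarities recorded during the run (whole bias
# region); otherwise each snapshot is re-rendered and scored on the mask.
latter_half_samples <- function(fit, mask = NULL) {
  rp <- renderer_params(fit$config$sigma_x, fit$config$sigma_y,
                        fit$config$gamma, grid = fit$h_ref)
  out <- list()
  for (tr in fit$trajectories) {
    if (is.null(tr)) next
    idx <- latter_half_idx(nrow(tr$records))
    if (is.null(mask)) {
      out <- c(out, list(tr$records$cs[idx]))
    } else {
      v <- vapply(idx, function(i) {
        s <- snapshot_structure(tr, i, template = fit$template)
        cs_value(render_smooth(s, rp), fit$h_ref, mask)
      }, numeric(1))
      out <- c(out, list(v))
    }
  }
  out
}

kde_mode <- function(x) {
  if (diff(range(x)) == 0) return(x[1])
  d <- stats::density(x, bw = "nrd0", n = 512, from = min(x), to = max(x))
  d$x[which.max(d$y)]
}

#' Similarity distribution of a fitting campaign
#'
#' Kernel density estimate (Gaussian kernel, Silverman bandwidth, 512-point
#' grid over the sample range) of the cosine similarity over the latter
#' half of each replica's records, pooled over replicas; the mode is the
#' grid argmax. With a mask, every latter-half snapshot is re-rendered and
#' scored on that region.
#'
#' @param fit a [run_fitting_campaign()] result.
#' @param mask a [region_mask()] on the fit's reference image, or `NULL`.
#' @return a `similarity_distribution`: samples, `density`, `mode`, `bw`,
#'   KDE `grid_dx`, and a `degenerate` flag (all-equal samples produce a
#'   spike representation: `density = NULL`, `mode` = the value).
#' @export
similarity_distribution <- function(fit, mask = NULL) {
  per_replica <- latter_half_samples(fit, mask)
  samples <- unlist(per_replica)
  if (length(samples) < 100L) stop("insufficient samples")
  if (diff(range(samples)) == 0) {
    return(structure(list(samples = samples, density = NULL,
                          mode = samples[1], bw = 0, grid_dx = 0,
                          replica_modes = rep(samples[1], length(per_replica)),
                          n = length(samples), degenerate = TRUE,
                          mask = mask),
                     class = "similarity_distribution"))
  }
  d <- stats::density(samples, bw = "nrd0", n = 512,
                      from = min(samples), to = max(samples))
  structure(list(samples = samples, density = d,
                 mode = d$x[which.max(d$y)], bw = d$bw,
                 grid_dx = diff(range(samples)) / 511,
                 replica_modes = vapply(per_replica, kde_mode, numeric(1)),
                 n = length(samples), degenerate = FALSE, mask = mask),
            class = "similarity_distribution")
}

#' @export
print.similarity_distribution <- function(x, ...) {
  cat(sprintf("<similarity_distribution> n = %d, mode = %.4f%s\n", x$n,
              x$mode, if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Infer the conformational state by comparing similarity distributions
#'
#' Recomputes the cosine similarity of every latter-half snapshot of each
#' candidate state on `mask`, estimates each state's density and mode, and
#' returns the state with the larger mode — provided the mode difference
#' exceeds the declared resolution AND the same state also has the larger
#' median (a rank-based guard; no distributional test is implied).
#' Otherwise the verdict is `"indeterminate"`.
#'
#' The default resolution is `max(2 * KDE grid spacing, half the mean
#' Silverman bandwidth)`: mode separations below half a bandwidth are not
#' resolvable by the estimator.
#'
#' @param fit_a,fit_b [run_fitting_campaign()] results against the *same*
#'   reference image.
#' @param mask a [region_mask()] (e.g. the neck region) or `NULL`.
#' @param threshold explicit resolution threshold, overriding the default.
#' @return a `state_call` with the two distributions, the mode difference
#'   (a minus b), the threshold used and the verdict.
#' @export
compare_states <- function(fit_a, fit_b, mask = NULL, threshold = NULL) {
  if (!isTRUE(all.equal(fit_a$h_ref$heights, fit_b$h_ref$heights)))
    stop("the two fits used different reference images")
  da <- similarity_distribution(fit_a, mask)
  db <- similarity_distribution(fit_b, mask)
  resolution <- if (!is.null(threshold)) threshold else {
    se2 <- function(d) {
      m <- d$replica_modes
      if (length(m) < 2) 0 else stats::var(m) / length(m)
    }
    max(2 * mean(c(da$grid_dx, db$grid_dx)),
        0.5 * mean(c(da$bw, db$bw)),
        2 * sqrt(se2(da) + se2(db)))
  }
  mode_diff <- da$mode - db$mode
  med_diff <- median(da$samples) - median(db$samples)
  verdict <- "indeterminate"
  if (abs(mode_diff) > resolution && sign(med_diff) == sign(mode_diff))
    verdict <- if (mode_diff > 0) fit_a$label else fit_b$label
  structure(list(state_a = fit_a$label, state_b = fit_b$label,
                 dist_a = da, dist_b = db,
                 mode_a = da$mode, mode_b = db$mode,
                 mode_difference = mode_diff, median_difference = med_diff,
                 threshold = resolution, mask = mask, verdict = verdict),
            class = "state_call")
}

#' @export
print.state_call <- function(x, ...) {
  cat(sprintf(paste0("<state_call> %s (mode %.4f) vs %s (mode %.4f): ",
                     "diff %+.4f, threshold %.4f -> %s\n"),
              x$state_a, x$mode_a, x$state_b, x$mode_b,
              x$mode_difference, x$threshold, x$verdict))
  invisible(x)
}

#' Write a state call as a JSON report
#' @param call_ a `state_call`.
#' @param path output path.
#' @export
write_state_call <- function(call_, path) {
  out <- list(state_a = call_$state_a, state_b = call_$state_b,
              mode_a = call_$mode_a, mode_b = call_$mode_b,
              mode_difference = call_$mode_difference,
              median_difference = call_$median_difference,
              threshold = call_$threshold, verdict = call_$verdict,
              n_samples = c(call_$dist_a$n, call_$dist_b$n))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
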