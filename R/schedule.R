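#' Scan acquisition specification
#'
#' @param tr_seconds Repetition time in seconds.
#' @param n_volumes Number of volumes per run (may be `NA` until a schedule
#'   fixes it).
#' @param grid_shape Integer vector of length 3, the voxel grid dimensions.
#' @param voxel_size_mm Isotropic voxel size in millimetres (used to convert
#'   smoothing FWHM between mm and voxels).
#' @return A list of class `acquisition_spec`.
#' @export
acquisition_spec <- function(tr_seconds = 2, n_volumes = NA_integer_,
                             grid_shape = c(24L, 24L, 24L),
                             voxel_size_mm = 3) {
  stopifnot(tr_seconds > 0, length(grid_shape) == 3, all(grid_shape >= 1),
            voxel_size_mm > 0)
  structure(list(tr_seconds = tr_seconds,
                 n_volumes = as.integer(n_volumes),
                 grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm),
            class = "acquisition_spec")
}

#' Sound conditions used throughout the package
#' @export
sound_conditions <- function() c("forest", "crowd", "traffic")

#' Build a pseudo-randomised block stimulation schedule
#'
#' Draws a block order uniformly from all sequences in which no two
#' consecutive blocks share a condition (rejection sampling over random
#' permutations), then lays the blocks out as sound-block + inter-stimulus
#' interval pairs after a lead-in period. The volume count is
#' `lead_in + ceiling(span / TR) + lead_out` where span covers all blocks and
#' their trailing ISIs. The standard long design (12 s blocks, 12 s ISI,
#' 6 repetitions of 3 sounds, TR 2 s, lead-in 6 volumes) yields 222 volumes;
#' the short variant (6 s / 6 s, lead-in 9) yields 117.
#'
#' @param block_duration_s,isi_s Sound block and inter-stimulus durations (s).
#' @param reps_per_condition Repetitions of each condition per run.
#' @param acquisition An [acquisition_spec()]; its `n_volumes` is replaced by
#'   the computed count.
#' @param lead_in_volumes,lead_out_volumes Silent padding, in volumes.
#' @param conditions Character vector of condition names.
#' @param run_id Integer run identifier.
#' @param seed Integer seed for the order draw.
#' @return A list of class `stimulus_schedule` with elements `blocks`
#'   (data.frame: onset, duration, condition), `run_id`, `acquisition`.
#' @export
#' @examples
#' s <- build_schedule(seed = 1)
#' s$acquisition$n_volumes  # 222
build_schedule <- function(block_duration_s = 12, isi_s = 12,
                           reps_per_condition = 6,
                           acquisition = acquisition_spec(),
                           lead_in_volumes = 6, lead_out_volumes = 0,
                           conditions = sound_conditions(),
                           run_id = 1L, seed = 1L) {
  stopifnot(block_duration_s > 0, isi_s >= 0, reps_per_condition >= 0,
            lead_in_volumes >= 0, lead_out_volumes >= 0,
            inherits(acquisition, "acquisition_spec"))
  if (is.null(seed)) stop("a seed is required for the order draw")
  tr <- acquisition$tr_seconds
  n_cond <- length(conditions)
  n_blocks <- n_cond * reps_per_condition
  if (reps_per_condition >= 2 && n_cond < 2)
    stop("impossible ordering: cannot avoid consecutive repeats with ",
         n_cond, " condition(s) and ", reps_per_condition, " repetitions")

  order <- character(0)
  if (n_blocks > 0) {
    labels <- rep(conditions, each = reps_per_condition)
    order <- with_seed(seed, {
      ok <- FALSE
      for (attempt in seq_len(100000L)) {
        cand <- sample(labels)
        if (!any(cand[-1] == cand[-n_blocks])) { ok <- TRUE; break }
      }
      if (!ok) stop("impossible ordering constraint: no valid sequence found")
      cand
    })
  }

  onsets <- lead_in_volumes * tr + (seq_len(n_blocks) - 1) * (block_duration_s + isi_s)
  blocks <- data.frame(onset = as.numeric(onsets),
                       duration = rep(as.numeric(block_duration_s), n_blocks),
                       condition = order,
                       stringsAsFactors = FALSE)
  span <- n_blocks * (block_duration_s + isi_s)
  n_volumes <- lead_in_volumes + ceiling(span / tr) + lead_out_volumes
  acquisition$n_volumes <- as.integer(n_volumes)

  sched <- structure(list(blocks = blocks, run_id = as.integer(run_id),
                          acquisition = acquisition),
                     class = "stimulus_schedule")
  validate_schedule(sched)
  sched
}

validate_schedule <- function(sched) {
  b <- sched$blocks
  if (nrow(b) == 0) return(invisible(sched))
  if (is.unsorted(b$onset, strictly = TRUE))
    stop("schedule blocks must be sorted by onset")
  ends <- b$onset + b$duration
  if (any(b$onset[-1] < ends[-nrow(b)]))
    stop("schedule blocks overlap")
  if (any(b$condition[-1] == b$condition[-nrow(b)]))
    stop("two consecutive blocks share a condition")
  span_end <- max(ends)
  total_s <- sched$acquisition$n_volumes * sched$acquisition$tr_seconds
  if (total_s < span_end)
    stop("acquisition shorter than the stimulation span")
  invisible(sched)
}

#' @export
print.stimulus_schedule <- function(x, ...) {
  cat(sprintf("stimulus_schedule: run %d, %d blocks, %d volumes (TR %.3g s)\n",
              x$run_id, nrow(x$blocks), x$acquisition$n_volumes,
              x$acquisition$tr_seconds))
  if (nrow(x$blocks) > 0)
    cat("  order:", paste(x$blocks$condition, collapse = " "), "\n")
  invisible(x)
}

#' Schedules for a standard multi-run session
#'
#' @param n_runs Number of runs.
#' @param design `"long"` (12 s / 12 s, 222 volumes) or `"short"`
#'   (6 s / 6 s, 117 volumes).
#' @param acquisition Base [acquisition_spec()].
#' @param seed Integer; run `r` uses seed `seed + r`.
#' @return List of `stimulus_schedule`, one per run.
#' @export
session_schedules <- function(n_runs = 4, design = c("long", "short"),
                              acquisition = acquisition_spec(), seed = 1L) {
  design <- match.arg(design)
  stopifnot(n_runs >= 1)
  p <- if (design == "long") list(dur = 12, isi = 12, lead_in = 6)
       else list(dur = 6, isi = 6, lead_in = 9)
  lapply(seq_len(n_runs), function(r)
    build_schedule(p$dur, p$isi, reps_per_condition = 6,
                   acquisition = acquisition,
                   lead_in_volumes = p$lead_in, lead_out_volumes = 0,
                   run_id = r, seed = seed + r))
}
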