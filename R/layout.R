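#' Describe a block-design acquisition
#'
#' An acquisition layout records, for each (identical) run, the ordered block
#' sequence of rest and task conditions. Volumes are indexed 0-based within a
#' run, after the initial T1-equilibration volumes have been discarded; the
#' discard count is part of [rest_selection_config()], not of the layout.
#'
#' @param runs Number of runs (default 2).
#' @param blocks_per_run Tibble/data frame with columns `condition` and
#'   `duration_volumes` giving the full ordered per-run block sequence.
#'   Conditions named `"rest"` are inter-block baseline periods; a final
#'   `"end_rest"` block is the end-of-run baseline.
#' @param tr_s Repetition time in seconds (default 2).
#' @return An object of class `rfc_layout`.
#' @seealso [default_layout()] for the study design this package emulates.
#' @export
acquisition_layout <- function(runs = 2, blocks_per_run, tr_s = 2) {
  runs <- check_count(runs, "runs", lower = 1L)
  check_number(tr_s, "tr_s", lower = 1e-6)
  blocks <- tibble::as_tibble(blocks_per_run)
  if (!all(c("condition", "duration_volumes") %in% names(blocks))) {
    stop_restfc("`blocks_per_run` needs columns `condition` and `duration_volumes`.")
  }
  if (nrow(blocks) == 0L || any(blocks$duration_volumes < 1)) {
    stop_restfc("All block durations must be >= 1 volume.")
  }
  if (!any(blocks$condition %in% c("rest", "end_rest"))) {
    stop_restfc("Layout must contain at least one rest period per run.")
  }
  blocks$duration_volumes <- as.integer(blocks$duration_volumes)
  structure(
    list(runs = runs, blocks = blocks, tr_s = tr_s),
    class = "rfc_layout"
  )
}

#' The emulated study's acquisition layout
#'
#' Two runs; per run, five 20-s (10-volume) rest periods each followed by a
#' 60-s (30-volume) task block, one final 140-s (70-volume) task block, and a
#' 5-volume end-of-run rest. TR = 2 s. With the default
#' [rest_selection_config()] this yields 45 retained rest volumes per run and
#' 90 per participant.
#'
#' @param rest_duration_volumes Length of each inter-block rest period.
#' @param end_rest_volumes Length of the end-of-run rest.
#' @return An `rfc_layout`.
#' @export
default_layout <- function(rest_duration_volumes = 10, end_rest_volumes = 5) {
  rest_duration_volumes <- check_count(rest_duration_volumes, "rest_duration_volumes", 1L)
  end_rest_volumes <- check_count(end_rest_volumes, "end_rest_volumes", 0L)
  task <- c(reading = 30L, copying = 30L, silent_speech = 30L,
            brainstorming = 30L, correcting = 30L, creative_writing = 70L)
  blocks <- list()
  for (b in seq_along(task)[1:5]) {
    blocks[[length(blocks) + 1L]] <- tibble::tibble(
      condition = "rest", duration_volumes = rest_duration_volumes)
    blocks[[length(blocks) + 1L]] <- tibble::tibble(
      condition = names(task)[b], duration_volumes = task[[b]])
  }
  blocks[[length(blocks) + 1L]] <- tibble::tibble(
    condition = "creative_writing", duration_volumes = task[["creative_writing"]])
  if (end_rest_volumes > 0L) {
    blocks[[length(blocks) + 1L]] <- tibble::tibble(
      condition = "end_rest", duration_volumes = end_rest_volumes)
  }
  acquisition_layout(runs = 2, blocks_per_run = dplyr::bind_rows(blocks), tr_s = 2)
}

#' @export
print.rfc_layout <- function(x, ...) {
  cat(sprintf("<rfc_layout> %d run(s) x %d volumes (TR %gs)\n",
              x$runs, run_length(x), x$tr_s))
  cat(sprintf("  %d inter-block rest period(s), %d end-rest volume(s) per run\n",
              sum(x$blocks$condition == "rest"),
              sum(x$blocks$duration_volumes[x$blocks$condition == "end_rest"])))
  invisible(x)
}

run_length <- function(layout) sum(layout$blocks$duration_volumes)

# per-volume condition labels for one run (0-based volume i has label [i+1])
layout_conditions <- function(layout) {
  rep(layout$blocks$condition, layout$blocks$duration_volumes)
}

#' Configure rest-volume selection
#'
#' Controls how baseline volumes are retained from each rest period: the
#' first `drop_initial_per_rest` volumes of each inter-block rest are skipped
#' (to let task-evoked BOLD decay), the next `retained_per_rest` are kept,
#' and the last `end_rest_volumes` of each run are kept. The defaults retain
#' 8 of each 10-volume rest period plus 5 end-of-run volumes, reproducing the
#' emulated study's 90 retained volumes per participant; see the package
#' vignette for the ambiguity around dropping 2 vs 3 initial volumes.
#'
#' @param drop_initial_per_rest Volumes skipped at the start of each rest
#'   period (default 2).
#' @param retained_per_rest Volumes kept per rest period (default 8).
#' @param end_rest_volumes Volumes kept at the end of each run (default 5).
#' @param discard_run_initial_volumes T1-equilibration volumes dropped from
#'   the start of each raw run before any indexing (default 2).
#' @return An object of class `rfc_rest_config`.
#' @export
rest_selection_config <- function(drop_initial_per_rest = 2,
                                  retained_per_rest = 8,
                                  end_rest_volumes = 5,
                                  discard_run_initial_volumes = 2) {
  structure(
    list(
      drop_initial_per_rest = check_count(drop_initial_per_rest, "drop_initial_per_rest"),
      retained_per_rest = check_count(retained_per_rest, "retained_per_rest"),
      end_rest_volumes = check_count(end_rest_volumes, "end_rest_volumes"),
      discard_run_initial_volumes = check_count(discard_run_initial_volumes,
                                                "discard_run_initial_volumes")
    ),
    class = "rfc_rest_config"
  )
}

#' Select resting-state volumes from a block-design run
#'
#' For each inter-block rest period, skips `drop_initial_per_rest` volumes
#' and takes the next `retained_per_rest`; then takes the last
#' `end_rest_volumes` of the run. Indices are 0-based within a run (after
#' discarding initial equilibration volumes) and strictly increasing.
#'
#' @param layout An [acquisition_layout()].
#' @param cfg A [rest_selection_config()].
#' @return A list with `per_run` (list of integer index vectors, one per
#'   run), `n_per_run`, and `n_total` (across all runs).
#' @examples
#' sel <- select_rest_volumes(default_layout(), rest_selection_config())
#' sel$n_total  # 90
#' @export
select_rest_volumes <- function(layout, cfg = rest_selection_config()) {
  if (!inherits(layout, "rfc_layout")) stop_restfc("`layout` must be an rfc_layout.")
  if (!inherits(cfg, "rfc_rest_config")) stop_restfc("`cfg` must be a rest_selection_config.")

  blocks <- layout$blocks
  starts <- cumsum(c(0L, utils::head(blocks$duration_volumes, -1L)))
  idx <- integer(0)
  rest_no <- 0L
  for (b in seq_len(nrow(blocks))) {
    if (blocks$condition[b] == "rest") {
      rest_no <- rest_no + 1L
      need <- cfg$drop_initial_per_rest + cfg$retained_per_rest
      if (blocks$duration_volumes[b] < need) {
        stop_restfc(sprintf(
          "Rest period %d (%d volumes) is too short to drop %d and retain %d.",
          rest_no, blocks$duration_volumes[b],
          cfg$drop_initial_per_rest, cfg$retained_per_rest))
      }
      if (cfg$retained_per_rest > 0L) {
        first <- starts[b] + cfg$drop_initial_per_rest
        idx <- c(idx, seq.int(first, length.out = cfg$retained_per_rest))
      }
    }
  }
  if (cfg$end_rest_volumes > 0L) {
    end_blocks <- blocks$condition == "end_rest"
    n_end <- sum(blocks$duration_volumes[end_blocks])
    if (n_end < cfg$end_rest_volumes) {
      stop_restfc(sprintf(
        "End-of-run rest has %d volume(s); %d requested.",
        n_end, cfg$end_rest_volumes))
    }
    total <- run_length(layout)
    idx <- c(idx, seq.int(total - cfg$end_rest_volumes, total - 1L))
  }
  idx <- sort(unique(idx))

  # retained volumes must all be baseline, never task
  cond <- layout_conditions(layout)
  if (length(idx) && !all(cond[idx + 1L] %in% c("rest", "end_rest"))) {
    stop_restfc("Internal error: selected a non-rest volume.")
  }
  list(
    per_run = rep(list(idx), layout$runs),
    n_per_run = length(idx),
    n_total = length(idx) * layout$runs
  )
}
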